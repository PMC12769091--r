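#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Exact stochastic simulation of a linear templating CRN.
//
// Nodes are indexed 1..n_nodes with 0 the chemostatted null complex.
// Directed reactions come in reverse pairs (2i, 2i+1 in 0-based order).
// Reactions leaving the null complex fire at rate k * volume (zeroth
// order); all others at rate k * count(from). The per-event entropy term
// is log(propensity of the executed transition before the update /
// propensity of its reverse after the update), in k_B.
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List ssa_simulate_cpp(const IntegerVector& rfrom, const IntegerVector& rto,
                      const NumericVector& rate, int n_nodes, double volume,
                      double horizon, double max_events) {
  const int R = rfrom.size();
  std::vector<double> counts(n_nodes + 1, 0.0);
  std::vector<double> a(R);
  std::vector<double> times, ent;
  std::vector<int> reac;
  times.reserve(1 << 16); ent.reserve(1 << 16); reac.reserve(1 << 16);

  double t = 0.0;
  bool truncated = false;
  while (true) {
    double a0 = 0.0;
    for (int r = 0; r < R; ++r) {
      double c = (rfrom[r] == 0) ? volume : counts[rfrom[r]];
      a[r] = rate[r] * c;
      a0 += a[r];
    }
    if (a0 <= 0.0) break;  // absorbing; impossible with a null-outgoing edge
    t += R::exp_rand() / a0;
    if (t > horizon) break;
    double u = unif_rand() * a0;
    int r = 0;
    double acc = a[0];
    while (acc < u && r < R - 1) acc += a[++r];
    double afwd = a[r];
    if (rfrom[r] != 0) counts[rfrom[r]] -= 1.0;
    if (rto[r] != 0) counts[rto[r]] += 1.0;
    int rrev = (r % 2 == 0) ? r + 1 : r - 1;
    double crev = (rfrom[rrev] == 0) ? volume : counts[rfrom[rrev]];
    double arev = rate[rrev] * crev;  // > 0: the just-updated target holds >= 1
    times.push_back(t);
    reac.push_back(r + 1);
    ent.push_back(std::log(afwd / arev));
    if ((double)times.size() >= max_events) { truncated = true; break; }
  }

  return List::create(
    _["time"] = NumericVector(times.begin(), times.end()),
    _["reaction"] = IntegerVector(reac.begin(), reac.end()),
    _["entropy"] = NumericVector(ent.begin(), ent.end()),
    _["final_counts"] = NumericVector(counts.begin() + 1, counts.end()),
    _["t_end"] = std::min(t, horizon),
    _["truncated"] = truncated);
}

namespace {

struct Mol {
  std::vector<int> path;  // loop-erased node sequence
  int phase;              // 0 = production (since birth), 1 = degradation
  int prod;               // product that ended the production excursion
};

// Append node v to a loop-erased path: erase back to the first earlier
// occurrence of v if present, else push.
inline void append_loop_erased(std::vector<int>& path, int v) {
  for (size_t i = 0; i < path.size(); ++i) {
    if (path[i] == v) { path.resize(i + 1); return; }
  }
  path.push_back(v);
}

inline std::string key_of(const std::vector<int>& path, bool reversed) {
  std::string s;
  if (!reversed) {
    for (size_t i = 0; i < path.size(); ++i) {
      if (i) s += '>';
      s += std::to_string(path[i]);
    }
  } else {
    for (size_t i = path.size(); i-- > 0;) {
      if (i + 1 < path.size()) s += '>';
      s += std::to_string(path[i]);
    }
  }
  return s;
}

}  // namespace

// Replay an event log, tracking individual molecules, and classify
// completed excursions. A molecule is born when a reaction leaves the null
// complex; its node path is maintained under loop-erasure, so at any
// moment it is a self-avoiding walk of the network. First arrival at a
// product closes a production excursion assigned to that walk; the
// subsequent first return to the null complex closes a degradation
// excursion assigned to the loop-erased (reversed) walk from the product.
// When several molecules occupy the firing node, one is chosen uniformly
// at random (molecules are exchangeable, so per-molecule statistics are
// unaffected). Requires a log started from empty initial counts.
// [[Rcpp::export]]
List ssa_classify_cpp(const IntegerVector& ev_reac,
                      const NumericVector& ev_time,
                      const IntegerVector& rfrom, const IntegerVector& rto,
                      int n_nodes, const LogicalVector& is_product) {
  std::vector<Mol> pool;
  std::vector<int> freelist;
  std::vector<std::vector<int> > at(n_nodes + 1);

  std::vector<double> out_time;
  std::vector<int> out_type, out_prod;
  std::vector<std::string> out_key;

  const int n_ev = ev_reac.size();
  for (int i = 0; i < n_ev; ++i) {
    int r = ev_reac[i] - 1;
    int u = rfrom[r], v = rto[r];
    int m;
    if (u == 0) {
      if (!freelist.empty()) {
        m = freelist.back();
        freelist.pop_back();
      } else {
        pool.push_back(Mol());
        m = (int)pool.size() - 1;
      }
      pool[m].path.assign(1, 0);
      pool[m].phase = 0;
      pool[m].prod = -1;
    } else {
      std::vector<int>& vec = at[u];
      if (vec.empty()) stop("event log inconsistent: no molecule at firing node");
      int j = (int)(unif_rand() * vec.size());
      if (j >= (int)vec.size()) j = (int)vec.size() - 1;
      m = vec[j];
      vec[j] = vec.back();
      vec.pop_back();
    }
    Mol& mol = pool[m];
    if (v == 0) {
      if (mol.phase == 1) {
        append_loop_erased(mol.path, 0);
        // reversed loop-erased path is a SAW null -> ... -> product
        out_time.push_back(ev_time[i]);
        out_type.push_back(2);
        out_prod.push_back(mol.prod);
        out_key.push_back(key_of(mol.path, true));
      }
      freelist.push_back(m);
      continue;
    }
    append_loop_erased(mol.path, v);
    if (mol.phase == 0 && is_product[v]) {
      if (mol.path.size() < 2) stop("empty excursion after loop-erasure");
      out_time.push_back(ev_time[i]);
      out_type.push_back(1);
      out_prod.push_back(v);
      out_key.push_back(key_of(mol.path, false));
      mol.phase = 1;
      mol.prod = v;
      mol.path.assign(1, v);
    }
    at[v].push_back(m);
  }

  // Alive molecules: total, and per product those mid-degradation.
  std::vector<bool> alive(pool.size(), true);
  for (size_t k = 0; k < freelist.size(); ++k) alive[freelist[k]] = false;
  int n_alive = 0;
  IntegerVector degr_pending(n_nodes + 1, 0);
  for (size_t k = 0; k < pool.size(); ++k) {
    if (!alive[k]) continue;
    ++n_alive;
    if (pool[k].phase == 1) degr_pending[pool[k].prod] += 1;
  }

  return List::create(
    _["time"] = NumericVector(out_time.begin(), out_time.end()),
    _["type"] = IntegerVector(out_type.begin(), out_type.end()),
    _["product"] = IntegerVector(out_prod.begin(), out_prod.end()),
    _["pathway_key"] = CharacterVector(out_key.begin(), out_key.end()),
    _["n_alive"] = n_alive,
    _["degradation_pending"] = degr_pending);
}
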