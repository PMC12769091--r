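---
title: "Thermodynamic accuracy limits of templating networks: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic accuracy limits of templating networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(templimits)
```

## The model

`templimits` analyses template-directed assembly — transcription,
translation, tRNA charging, synthetic copying chemistries — at the level
of a chemostatted *linear* chemical reaction network (CRN). The tracked
species are intermediates (partial assemblies bound to catalysts) and M
possible products. Monomers, fuels, catalysts and templates are
chemostatted: held at fixed chemical potential by the environment, and
absorbed into effective rate constants. Each complex then holds at most
one tracked species or is empty, so the CRN is a graph: nodes are the
null complex Ø, intermediates and products; edges are reversible
reactions with mass-action rates.

Thermodynamic self-consistency enters through local detailed balance:
every edge has a k_BT-normalised free-energy change
δG̃ = −ln(k_fwd/k_rev), which decomposes (when the optional annotations
are supplied) as δG̃ = G̃_to − G̃_from + chemical work, the last term
collecting the chemical-potential change of chemostatted species turned
over by the reaction. Concentrations are dimensionless activities
relative to the standard concentration, with the null complex at unit
activity, so a single reversible step at equilibrium gives c = e^(−δG̃)
directly. These unit conventions (k_BT, nats, activities) are used
everywhere; `entropy_bound(units = "bits")` divides entropies by ln 2.

Two structural rules are enforced at construction: no reaction couples
two tracked species in the same complex (linearity; in particular no
product–product edges), and the graph must be connected from Ø. Product
symmetry — all products reachable from Ø by equivalent pathway sets — is
*verified*, never required: `check_product_symmetry()` reports per-pair
verdicts, and all bounds are computed per product so asymmetric networks
are analysed without modification. "Topologically equivalent" is
operationalised as isomorphism of the rooted subgraphs formed by each
product's self-avoiding walks (VF2 with the root and the focal product
coloured, parallel-edge multiplicities as edge colours) *plus* equality
of the pathway free-energy multisets within tolerance; this captures the
intended notion — same pathway structure, same overall free-energy
changes — while allowing intermediate energies and rates to differ.

## Pathways and the concentration bounds

A pathway is a self-avoiding walk (SAW) from Ø to a species, with
free-energy change δG̃_S equal to the signed sum of its edge free
energies (edges are reversible and may be traversed either way).
`enumerate_pathways()` performs an exhaustive depth-first search with an
explicit visited set. Exhaustiveness is non-negotiable — the bounds are
the *extremes* of δG̃_S — so the walk cap (default 10⁶ per species)
raises an error rather than truncating. SAWs cannot contain cycles by
definition: proofreading-style loops never enter a walk, they only add
alternative walks, and the test suite checks on loop-bearing fixtures
that adding a cycle leaves existing pathway sums untouched.

For every species, steady-state concentrations of linear chemostatted
CRNs obey e^(−δG̃_L) ≤ c ≤ e^(−δG̃_U) with δG̃_U/δG̃_L the min/max of
δG̃_S. `pathway_bounds()` reports these per product *and* per
intermediate (the theorem applies to any species, and the intermediate
bounds materially strengthen the property-based test suite). The
per-product spread ΔG̃ = δG̃_L − δG̃_U is reported per product, as a
single shared value when the products' extremes coincide, and in the
asymmetric pairwise form δG̃_L(Y) − δG̃_U(X) via `pair_delta_G()`.

## Steady states, fluxes and the Γ diagnostics

Because the CRN is linear, the steady state solves a linear system: the
node-balance equations with Ø as a constant unit-activity source
(`solve_steady_state()`, dense LU). A direct solve is exact and cheap at
desk scale; numerically we require a relative balance residual below
10⁻⁹ and warn above a condition estimate of 10¹². The ODE transient
integrator (`integrate_transient()`, deSolve/lsoda with rtol 10⁻¹⁰, atol
10⁻¹²) is retained as an *independent* oracle — the tests require
agreement to 10⁻⁶ relative on random 20-node networks — and for genuinely
transient questions, e.g. the short-time kinetic-specificity limit
p_X(t→0⁺) = k_X/(k_X+k_Y) of the two-product network, which the tests
verify to 10⁻⁴.

`edge_fluxes()` evaluates J⁺ = k_fwd·c_from, J⁻ = k_rev·c_to and the
entropy production rate σ = Σ (J⁺−J⁻) ln(J⁺/J⁻) ≥ 0 (k_B per unit time),
with the conventions that balanced edges contribute exactly zero and a
one-sided zero flux with nonzero net flux contributes Inf. Γ ratios are
computed from their steady-state definition Γ(δG̃) = e^(−δG̃)/c
(`gamma_ratio()`); the trajectory-count interpretation lives in the
stochastic module. `eq_identity_residual()` evaluates
ln(c_X/c_Y) − [ΔG̃ + ln(Γ_Y(δG̃_L)/Γ_X(δG̃_U))], an exact algebraic
identity at steady state given Γ's definition; it is exposed because it
is a sharp end-to-end consistency check across the pathway, bound and
solver code paths (the suite requires |residual| ≤ 10⁻⁹ on every product
pair of every fixture). Note the Γ's enter as a *ratio*: the favourable
production pathway's Γ_X ≥ 1 sits in the denominator, which is how a net
flux necessarily reduces the concentration ratio below its
pseudo-equilibrium value e^ΔG̃.

## Closed-form accuracy bounds

`specificity_bound()` implements p_max = (1+(M−1)e^(−ΔG̃))^(−1) and
p_low; `required_delta_G()` its inversion ln((M−1)(1−err)/err);
`entropy_bound()` minimises H(m) (see README) over integer m ∈ {1..M};
`overlap_threshold()` returns ln M + ln ln M, the leading-order spread
above which the entropy-minimising ensemble collapses to a single
product (higher-order corrections are not implemented). All of these are
evaluated in log space (`log1p`-style guards, log(M−1) computed as
log M + log1p(−1/M)) so they remain finite and monotone up to M = 2⁶³.

Numerical choices for the integer minimisation:

- exact vectorised scan for M ≤ 10⁷ (the default regime for every
  shipped analysis);
- integer ternary search above that, relying on the discrete
  unimodality of H(m); the tests verify the ternary path reproduces
  exhaustive scans exactly for a range of M up to 2¹⁴ across a 50-point
  spread grid;
- ties broken toward the smallest m (relevant only on measure-zero
  parameter sets; at ΔG̃ = 0 the profile is flat and m_min = 1 is
  returned by convention);
- a continuous-m relaxation (`continuous = TRUE`) is provided as a
  documented, slightly weaker alternative — never the default — and the
  tests confirm H_continuous ≤ H_min.

`sweep_bounds()` tabulates p_max, H_min/ln M, the max-specificity
ensemble's entropy/ln M, m_min/M and p_high over a ΔG̃/ln M grid; the
CSV is the artifact (plotting is out of scope).

## Stochastic simulation and trajectory classification

`simulate_ssa()` is an exact Gillespie simulation (Rcpp core, R's RNG,
seed mandatory) of the same network with the null complex chemostatted:
Ø-outgoing reactions fire at k_fwd·V, everything else at k·count, counts
being concentration × volume. No tau-leaping or hybrid acceleration is
provided — desk-scale exact SSA only. Each event records the entropy
exported to the environment, ln(a_fwd/a_rev), with the reverse
propensity evaluated just after the update; summed over a trajectory
this is the standard trajectory entropy production up to a bounded
start/end term.

The production/degradation trajectory ratio needs a rule for assigning
an excursion to a pathway, and the defining references leave that rule
open. `classify_trajectories()` uses **loop-erasure**: molecules are
tracked individually (when several occupy the firing node one is chosen
uniformly at random — molecules are exchangeable, so per-molecule
statistics are unaffected), each molecule's node history is loop-erased
on the fly, and thus is always a SAW of the network. Birth-to-first-
product-arrival closes a production excursion; first return to Ø
afterwards closes a degradation excursion on the reversed loop-erased
walk. Loop-erasure partitions *every* completed excursion uniquely onto
the same SAW set the bounds are built from, which is why we chose it.
One caveat is documented rather than hidden: loop-erasure commutes with
time reversal on chain-shaped pathway sets (where the identity
Γ̂ = e^(−δG̃_S)/c̄ is exact and the tests verify it within sampling
error), but on general graphs at a driven steady state the reversal
covariance of loop-erased walks is not guaranteed, so Γ̂ on such
networks should be read as the loop-erasure estimator of Γ.

Statistical conventions: default volume 1000 in the shipped analyses
(relative fluctuations ~3%), standard errors by batch means over ≥20
equal time batches (event streams are autocorrelated), and the
conservation identity production − degradation = molecules currently
mid-degradation is asserted per product. Empirical Γ̂ estimates from
finite windows started empty carry an O(1/T) transient bias (production
leads degradation by the standing population); the tests size volume and
horizon so this bias sits below the sampling error rather than
pretending it away.

## Fixture families and what they do (and do not) emulate

The generators define the study conditions for the test suite:

- `make_two_product_network()`: Ø⇌X, Ø⇌Y with equal δG̃ and arbitrary
  kinetics — zero spread, unbiased steady state, arbitrary transient
  bias.
- `make_symmetric_network()`: every product gets the same pathway
  lengths and δG̃_S multiset while intermediate energies and rates are
  randomised per product — the symmetric model, with kinetics
  unconstrained except by local detailed balance.
- `make_saturating_network()`: a *reconstruction* of a bound-saturating
  family (the primary sources only assert such a model exists): two
  2-edge pathways per product with sums g_U and g_L, the off-pathway
  slowed by ε on both rate constants of every edge — a purely kinetic
  move that preserves every δG̃. As ε→0 each product equilibrates with
  one pathway and the ensemble approaches the specificity bound in
  pseudo-equilibrium; at ε = 10⁻⁶ the solved p_max sits within 10⁻³ of
  the closed form, with σ smaller than the ε = 1 network's by more than
  three orders of magnitude.
- `make_random_consistent_network()`: random connected topologies with
  node energies uniform on [−5, 5] k_BT, edge chemical work uniform on
  [−3, 3] k_BT and forward rates log-uniform on [10⁻², 10²] (reverse
  rates fixed by local detailed balance). These ranges span strongly
  driven and near-equilibrium regimes while keeping the linear solves
  well-conditioned; they drive the central property test (100 networks
  of up to 30 nodes: every species inside its concentration bounds to
  10⁻⁷ relative, every product pair's identity residual below 10⁻⁹).

What passing these tests shows is internal: the bounds, solvers and
simulators agree with each other and with closed forms under the
symmetric, chemostatted, linear assumptions. Real copying machinery
violates several of those assumptions — catalyst sequestration
(non-linearity), product-specific pathway sets, finite monomer pools —
so the fixtures certify the mathematics, not any particular biological
parameterisation. A known omission: a counterexample network whose
accuracy cannot reach the bounds even with freely tunable rates is
described only in supplementary material we do not reproduce, so no such
fixture ships; nothing in this package asserts that every topology can
saturate the bounds.

## Degenerate inputs and tie-breaks, collected

- Missing or non-positive rate constants are construction errors (every
  reaction must be reversible); disconnected graphs and duplicate null
  complexes likewise.
- ΔG̃ = 0: specificity bound 1/M; entropy profile flat, m_min = 1 by
  tie-break.
- M < 2 is a domain error for the closed-form bounds (the single-product
  "bound" is trivially 1); M < 3 for the overlap threshold.
- Γ and the ratio identity are domain errors at zero concentration;
  σ-terms with one-sided zero flux report Inf.
- `entropy_per_event()` requires at least one completed production
  excursion.

## Problem sizes

The shipped analyses are deliberately desk-scale: exhaustive pathway
enumeration on ≤30-node networks, exact entropy-bound scans at M = 2²⁰,
ternary search cross-checked at M ≤ 2¹⁴ on 50-point grids, stochastic
runs at volume ~10²–10³ over horizons of tens of time units (10⁵–10⁶
events). These sizes were chosen to keep every quantity exactly
computable and every stochastic comparison inside 3 batch-means standard
errors; all scale parameters (caps, volumes, horizons, scan limits) are
user-configurable.
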