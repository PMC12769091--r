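# Node ordering used for the stochastic core: null complex first (index 0
# on the C++ side), then the remaining nodes in table order.
ssa_node_order <- function(network) {
  ids <- network$nodes$id
  null_id <- ids[network$nodes$kind == "null"]
  c(null_id, setdiff(ids, null_id))
}

# Directed reaction arrays (0-based node indices): reactions 2i-1 / 2i are
# the forward / reverse directions of edge i.
ssa_reactions <- function(network) {
  ord <- ssa_node_order(network)
  idx <- setNames(seq_along(ord) - 1L, ord)
  e <- network$edges
  n_e <- nrow(e)
  rfrom <- integer(2L * n_e)
  rto <- integer(2L * n_e)
  rate <- numeric(2L * n_e)
  rfrom[seq(1, 2 * n_e, by = 2)] <- idx[e$from]
  rto[seq(1, 2 * n_e, by = 2)] <- idx[e$to]
  rate[seq(1, 2 * n_e, by = 2)] <- e$k_fwd
  rfrom[seq(2, 2 * n_e, by = 2)] <- idx[e$to]
  rto[seq(2, 2 * n_e, by = 2)] <- idx[e$from]
  rate[seq(2, 2 * n_e, by = 2)] <- e$k_rev
  list(rfrom = rfrom, rto = rto, rate = rate, order = ord, index = idx)
}

#' Exact stochastic simulation of a templating network
#'
#' Runs the Gillespie algorithm on the linear network with the null complex
#' chemostatted: reactions leaving the null complex fire at rate
#' \code{k_fwd * volume} (zeroth order), all others at \code{k * count}.
#' Copy numbers correspond to \code{concentration * volume}. The
#' simulation starts from zero copies of every species. Each event record
#' carries the entropy exported to the environment by that transition,
#' \code{log(a_fwd / a_rev)} in k_B, with the reverse propensity evaluated
#' just after the update.
#'
#' @param network a [templating_network()].
#' @param volume system volume (copies per unit activity), > 0.
#' @param horizon simulated time span, > 0.
#' @param seed integer seed; required, no global RNG state is relied upon.
#' @param max_events hard cap on the number of recorded events.
#' @return Object of class \code{event_log}: list with vectors \code{time},
#'   \code{reaction} (directed reaction index), \code{edge},
#'   \code{direction} (+1 forward, -1 reverse), \code{entropy}, plus
#'   \code{final_counts} (named), \code{volume}, \code{horizon},
#'   \code{t_end}, \code{seed} and the node/reaction indexing needed to
#'   replay the log.
#' @export
simulate_ssa <- function(network, volume, horizon, seed, max_events = 2e7) {
  stopifnot(inherits(network, "templating_network"))
  if (volume <= 0 || horizon <= 0) {
    tnet_stop("volume and horizon must be positive", "tnet_domain_error")
  }
  if (missing(seed) || !is.finite(seed)) {
    tnet_stop("an integer seed is required", "tnet_domain_error")
  }
  rx <- ssa_reactions(network)
  set.seed(as.integer(seed))
  raw <- ssa_simulate_cpp(rx$rfrom, rx$rto, rx$rate,
                          n_nodes = length(rx$order) - 1L,
                          volume = volume, horizon = horizon,
                          max_events = max_events)
  if (isTRUE(raw$truncated)) {
    warning(sprintf("event budget (%g) exhausted at t = %g < horizon %g",
                    max_events, raw$t_end, horizon))
  }
  structure(
    list(time = raw$time,
         reaction = raw$reaction,
         edge = (raw$reaction + 1L) %/% 2L,
         direction = ifelse(raw$reaction %% 2L == 1L, 1L, -1L),
         entropy = raw$entropy,
         final_counts = setNames(raw$final_counts, rx$order[-1]),
         volume = volume, horizon = horizon, t_end = raw$t_end,
         seed = as.integer(seed), node_order = rx$order,
         rfrom = rx$rfrom, rto = rx$rto),
    class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Stochastic event log: %d events over t in [0, %g], volume %g, seed %d\n",
              length(x$time), x$t_end, x$volume, x$seed))
  invisible(x)
}

#' @export
as.data.frame.event_log <- function(x, ...) {
  lab <- paste0(x$node_order[x$rfrom + 1L], "->", x$node_order[x$rto + 1L])
  data.frame(time = x$time,
             edge_id = lab[x$reaction],
             direction = x$direction,
             stringsAsFactors = FALSE)
}

#' Time-averaged copy numbers from an event log
#'
#' @param log an [simulate_ssa()] event log.
#' @param burn_in fraction of the horizon discarded before averaging.
#' @return Named numeric vector of time-averaged counts per non-null node.
#' @export
time_average_counts <- function(log, burn_in = 0) {
  stopifnot(inherits(log, "event_log"))
  nodes <- log$node_order[-1]
  t0 <- burn_in * log$t_end
  # piecewise-constant counts: value after event i holds on [t_i, t_{i+1})
  tt <- c(0, log$time, log$t_end)
  out <- setNames(numeric(length(nodes)), nodes)
  from_n <- log$rfrom[log$reaction]
  to_n <- log$rto[log$reaction]
  for (j in seq_along(nodes)) {
    delta <- (to_n == j) - (from_n == j)
    n_traj <- c(0, cumsum(delta))
    dt <- pmax(pmin(tt[-1], log$t_end) - pmax(tt[-length(tt)], t0), 0)
    out[j] <- sum(n_traj * dt) / (log$t_end - t0)
  }
  out
}

#' Classify completed production and degradation excursions
#'
#' Replays an event log at the level of individual (exchangeable)
#' molecules. Each molecule's node history is loop-erased on the fly, so
#' it is always a self-avoiding walk of the network: the excursion from
#' the null complex to the first arrival at a product is a production
#' event assigned to that walk, and the subsequent first return to the
#' null complex is a degradation event assigned to the reversed
#' loop-erased walk. Empirical trajectory ratios
#' \code{Gamma_hat = production count / degradation count} are reported per
#' (product, pathway) against the exhaustively enumerated walk set, along
#' with entropy accounting and batch-means standard errors.
#'
#' @param log an [simulate_ssa()] event log (must start from empty initial
#'   counts, as [simulate_ssa()] logs do).
#' @param network the simulated network.
#' @param n_batches number of equal time batches for standard errors.
#' @param classify_seed seed for the (exchangeable) choice of molecule when
#'   several occupy the firing node; defaults to \code{log$seed + 1}.
#' @return Object of class \code{trajectory_stats}: list with
#'   \code{pathways} (data.frame: product, pathway_index, node_sequence,
#'   delta_g_S, n_production, n_degradation, gamma_hat),
#'   \code{excursions} (data.frame of the raw classified events),
#'   \code{entropy_total} (k_B), \code{n_production},
#'   \code{n_degradation}, \code{entropy_per_event},
#'   \code{entropy_per_event_se}, \code{mean_counts}, \code{n_alive},
#'   \code{degradation_pending} (named per product).
#' @export
classify_trajectories <- function(log, network, n_batches = 20,
                                  classify_seed = NULL) {
  stopifnot(inherits(log, "event_log"), inherits(network, "templating_network"))
  rx <- ssa_reactions(network)
  if (!identical(rx$order, log$node_order)) {
    tnet_stop("event log does not belong to this network", "tnet_lookup_error")
  }
  products <- network$nodes$id[network$nodes$kind == "product"]
  # enumerated walks, keyed by 0-based node-index sequences as used in C++
  path_df <- do.call(rbind, lapply(products, function(p) {
    paths <- enumerate_pathways(network, p)
    data.frame(
      product = p,
      pathway_index = seq_along(paths),
      node_sequence = vapply(paths, function(s) paste(s$nodes, collapse = "->"),
                             character(1)),
      key = vapply(paths, function(s) paste(rx$index[s$nodes], collapse = ">"),
                   character(1)),
      delta_g_S = vapply(paths, function(s) s$delta_g_S, numeric(1)),
      stringsAsFactors = FALSE)
  }))

  set.seed(as.integer(classify_seed %||% (log$seed + 1L)))
  cls <- ssa_classify_cpp(log$reaction, log$time, rx$rfrom, rx$rto,
                          n_nodes = length(rx$order) - 1L,
                          is_product = rx$order %in% products)
  exc <- data.frame(time = cls$time,
                    type = c("production", "degradation")[cls$type],
                    product = rx$order[cls$product + 1L],
                    key = cls$pathway_key,
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(exc$key), path_df$key)
  if (length(bad)) {
    stop("internal error: loop-erased excursion did not match an enumerated self-avoiding walk")
  }
  path_df$n_production <- vapply(path_df$key, function(k)
    sum(exc$key == k & exc$type == "production"), numeric(1))
  path_df$n_degradation <- vapply(path_df$key, function(k)
    sum(exc$key == k & exc$type == "degradation"), numeric(1))
  path_df$gamma_hat <- ifelse(path_df$n_degradation > 0,
                              path_df$n_production / path_df$n_degradation,
                              NA_real_)
  exc$pathway_index <- path_df$pathway_index[match(exc$key, path_df$key)]
  path_df$key <- NULL

  n_prod <- sum(exc$type == "production")
  n_degr <- sum(exc$type == "degradation")
  ent_total <- sum(log$entropy)

  # batch-means standard error of the entropy per production event
  ent_pe <- if (n_prod > 0) ent_total / n_prod else NA_real_
  ent_se <- NA_real_
  if (n_prod >= n_batches) {
    edges_t <- seq(0, log$t_end, length.out = n_batches + 1)
    b_ev <- findInterval(log$time, edges_t, rightmost.closed = TRUE)
    b_pr <- findInterval(exc$time[exc$type == "production"], edges_t,
                         rightmost.closed = TRUE)
    s_b <- vapply(seq_len(n_batches), function(b) sum(log$entropy[b_ev == b]),
                  numeric(1))
    p_b <- vapply(seq_len(n_batches), function(b) sum(b_pr == b), numeric(1))
    ok <- p_b > 0
    if (sum(ok) >= 2) {
      ratios <- s_b[ok] / p_b[ok]
      ent_se <- sd(ratios) / sqrt(sum(ok))
    }
  }

  pending <- setNames(cls$degradation_pending[rx$index[products] + 1L],
                      products)
  structure(
    list(pathways = path_df, excursions = exc,
         entropy_total = ent_total,
         n_production = n_prod, n_degradation = n_degr,
         entropy_per_event = ent_pe, entropy_per_event_se = ent_se,
         mean_counts = time_average_counts(log),
         n_alive = cls$n_alive, degradation_pending = pending,
         t_end = log$t_end, volume = log$volume),
    class = "trajectory_stats")
}

#' Entropy produced per completed production event
#'
#' Total trajectory entropy (k_B) divided by the number of completed
#' production excursions; tends to zero at pseudo-equilibrium and is
#' positive under a sustained cyclic flux.
#'
#' @param stats a [classify_trajectories()] result.
#' @return Numeric scalar, k_B per production event.
#' @export
entropy_per_event <- function(stats) {
  stopifnot(inherits(stats, "trajectory_stats"))
  if (stats$n_production == 0) {
    tnet_stop("no completed production events", "tnet_domain_error")
  }
  stats$entropy_total / stats$n_production
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat(sprintf("Trajectory statistics: %d production, %d degradation excursions over t = %g\n",
              x$n_production, x$n_degradation, x$t_end))
  cat(sprintf("  entropy per production event = %.4g +- %.2g k_B\n",
              x$entropy_per_event, x$entropy_per_event_se))
  print.data.frame(x$pathways, row.names = FALSE, digits = 5)
  invisible(x)
}
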