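# Fixtures built in code, and a naive independent path enumerator used as
# the oracle for the depth-first SAW implementation.

NULLC <- "Ø"

# A single chain null -> I1 -> ... -> Z with prescribed per-edge
# free-energy changes (unit forward rates).
chain_network <- function(dgs, product = "Z") {
  n <- length(dgs)
  inter <- if (n > 1) paste0("I", seq_len(n - 1)) else character(0)
  ids <- c(NULLC, inter, product)
  nodes <- data.frame(id = ids,
                      kind = c("null", rep("intermediate", n - 1), "product"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[-length(ids)], to = ids[-1],
                      k_fwd = 1, k_rev = exp(dgs), stringsAsFactors = FALSE)
  templating_network(nodes, edges)
}

# Two parallel two-edge pathways from null to one product Z, with pathway
# free-energy sums sum(a) and sum(b).
diamond_network <- function(a = c(-1, -1), b = c(0.5, 0.5),
                            k_a = c(1, 1), k_b = c(1, 1)) {
  nodes <- data.frame(id = c(NULLC, "IA", "IB", "Z"),
                      kind = c("null", "intermediate", "intermediate",
                               "product"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = c(NULLC, "IA", NULLC, "IB"),
                      to = c("IA", "Z", "IB", "Z"),
                      k_fwd = c(k_a, k_b),
                      k_rev = c(k_a, k_b) * exp(c(a, b)),
                      stringsAsFactors = FALSE)
  templating_network(nodes, edges)
}

# Independent brute-force enumerator of simple paths from the null complex
# to `target` over the reversible edge table; deliberately structured
# differently from the package implementation.
naive_paths <- function(net, target) {
  e <- net$edges
  null_id <- net$nodes$id[net$nodes$kind == "null"]
  found <- list()
  recurse <- function(path, dg) {
    u <- path[length(path)]
    if (u == target) {
      found[[length(found) + 1L]] <<- list(
        seq = paste(path, collapse = "->"), dg = dg)
      return(invisible(NULL))
    }
    for (i in seq_len(nrow(e))) {
      if (e$from[i] == u && !(e$to[i] %in% path)) {
        recurse(c(path, e$to[i]), dg + e$delta_g[i])
      }
      if (e$to[i] == u && !(e$from[i] %in% path)) {
        recurse(c(path, e$from[i]), dg - e$delta_g[i])
      }
    }
  }
  recurse(null_id, 0)
  data.frame(node_sequence = vapply(found, `[[`, character(1), "seq"),
             delta_g_S = vapply(found, `[[`, numeric(1), "dg"),
             stringsAsFactors = FALSE)
}

# Batch-means standard error of the time-averaged count of one node.
batch_count_se <- function(log, node, n_batches = 20, burn_in = 0.1) {
  t0 <- burn_in * log$t_end
  edges_t <- seq(t0, log$t_end, length.out = n_batches + 1)
  j <- match(node, log$node_order[-1])
  delta <- (log$rto[log$reaction] == j) - (log$rfrom[log$reaction] == j)
  tt <- c(0, log$time, log$t_end)
  n_traj <- c(0, cumsum(delta))
  avg <- vapply(seq_len(n_batches), function(b) {
    lo <- edges_t[b]; hi <- edges_t[b + 1]
    dt <- pmax(pmin(tt[-1], hi) - pmax(tt[-length(tt)], lo), 0)
    sum(n_traj * dt) / (hi - lo)
  }, numeric(1))
  list(mean = mean(avg), se = sd(avg) / sqrt(n_batches))
}
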