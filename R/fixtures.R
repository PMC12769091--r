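# Shared helper: build a chain pathway null -> I1 -> ... -> product of
# `length` edges whose per-edge free-energy changes are `dgs`, with random
# O(1) forward rates; reverse rates follow from local detailed balance.
# Node free energies `G` and per-edge chem_work are chosen consistently so
# validate_thermodynamics() passes by construction.
chain_edges <- function(null_id, inter_ids, product_id, dgs, k_fwd,
                        g_nodes, g_product) {
  ids <- c(null_id, inter_ids, product_id)
  g <- c(0, g_nodes, g_product)
  data.frame(
    from = ids[-length(ids)],
    to = ids[-1],
    k_fwd = k_fwd,
    k_rev = k_fwd * exp(dgs),
    chem_work = dgs - diff(g),
    stringsAsFactors = FALSE)
}

#' Minimal two-product network
#'
#' The simplest templating network: two products formed directly from the
#' null complex, with arbitrary forward kinetics but identical pathway
#' free-energy change \code{delta_g} on both edges (reverse rates chosen by
#' local detailed balance). Its free-energy spread is zero, so the steady
#' state is unbiased regardless of the kinetics; kinetic selectivity shows
#' up only transiently.
#'
#' @param k_X,k_Y forward rate constants for the two products.
#' @param delta_g shared pathway free-energy change, k_B T.
#' @return A [templating_network()] with products \code{"X"} and
#'   \code{"Y"}.
#' @export
make_two_product_network <- function(k_X = 1, k_Y = 1, delta_g = 0) {
  if (k_X <= 0 || k_Y <= 0) {
    tnet_stop("rates must be positive", "tnet_domain_error")
  }
  null_id <- null_complex_label()
  nodes <- data.frame(id = c(null_id, "X", "Y"),
                      kind = c("null", "product", "product"),
                      free_energy = c(0, delta_g, delta_g),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = null_id, to = c("X", "Y"),
                      k_fwd = c(k_X, k_Y),
                      k_rev = c(k_X, k_Y) * exp(delta_g),
                      chem_work = 0, stringsAsFactors = FALSE)
  templating_network(nodes, edges, meta = list(M = 2L, G0 = delta_g))
}

#' Symmetric multi-product network with prescribed pathway free energies
#'
#' Every product is connected to the null complex by the same set of chain
#' pathways (given lengths and total free-energy changes), realising the
#' symmetric model: topologically identical pathway sets with identical
#' free-energy multisets, while intermediate free energies and rate
#' constants are randomised per product (kinetics are unconstrained except
#' by local detailed balance).
#'
#' @param M number of products (>= 1).
#' @param pathway_specs list of pathway specifications, each a list with
#'   \code{length} (number of edges, >= 1) and \code{delta_g} (total
#'   pathway free-energy change, k_B T).
#' @param seed integer seed for the randomised energies and rates.
#' @return A [templating_network()] with products \code{"Z1"} ...
#'   \code{"ZM"}.
#' @export
make_symmetric_network <- function(M, pathway_specs, seed) {
  stopifnot(M >= 1, length(pathway_specs) >= 1)
  set.seed(as.integer(seed))
  null_id <- null_complex_label()
  g0 <- pathway_specs[[1]]$delta_g
  nodes <- data.frame(id = null_id, kind = "null", free_energy = 0,
                      stringsAsFactors = FALSE)
  edges <- NULL
  for (i in seq_len(M)) {
    pid <- paste0("Z", i)
    nodes <- rbind(nodes, data.frame(id = pid, kind = "product",
                                     free_energy = g0,
                                     stringsAsFactors = FALSE))
    for (p in seq_along(pathway_specs)) {
      spec <- pathway_specs[[p]]
      len <- spec$length
      stopifnot(len >= 1)
      inter <- if (len > 1) paste0("I", i, "_", p, "_", seq_len(len - 1)) else
        character(0)
      if (len > 1) {
        nodes <- rbind(nodes, data.frame(id = inter, kind = "intermediate",
                                         free_energy = runif(len - 1, -2, 2),
                                         stringsAsFactors = FALSE))
      }
      raw <- if (len > 1) runif(len - 1, -2, 2) else numeric(0)
      dgs <- c(raw, spec$delta_g - sum(raw))
      edges <- rbind(edges, chain_edges(
        null_id, inter, pid, dgs, k_fwd = 10^runif(len, -1, 1),
        g_nodes = nodes$free_energy[match(inter, nodes$id)],
        g_product = g0))
    }
  }
  templating_network(nodes, edges, meta = list(M = M, G0 = g0))
}

#' Bound-saturating network family
#'
#' A parameterised family that approaches the accuracy bounds as its
#' kinetics are tuned, using only moves the framework allows (rate
#' rescalings that preserve every edge free energy). Each product has
#' exactly two chain pathways of two edges with total free-energy changes
#' \code{g_U} and \code{g_L} (so the spread is \code{g_L - g_U}). For
#' product 1 the \code{g_L} pathway is slowed by the factor \code{epsilon}
#' (both rate constants of each edge, preserving local detailed balance);
#' for every other product the \code{g_U} pathway is slowed instead. As
#' \code{epsilon -> 0} each product couples to a single pathway and
#' equilibrates with it: \code{c_1 -> exp(-g_U)}, \code{c_i -> exp(-g_L)}
#' for i > 1, saturating the specificity bound in pseudo-equilibrium.
#'
#' @param M number of products (>= 2).
#' @param g_U,g_L pathway free-energy targets, k_B T, with
#'   \code{g_U <= g_L}.
#' @param epsilon slow-down factor in \code{(0, 1]}.
#' @param seed integer seed for the randomised rate prefactors and energy
#'   splits.
#' @return A [templating_network()].
#' @export
make_saturating_network <- function(M, g_U, g_L, epsilon, seed) {
  stopifnot(M >= 2, g_U <= g_L, epsilon > 0, epsilon <= 1)
  set.seed(as.integer(seed))
  null_id <- null_complex_label()
  nodes <- data.frame(id = null_id, kind = "null", free_energy = 0,
                      stringsAsFactors = FALSE)
  edges <- NULL
  targets <- c(U = g_U, L = g_L)
  for (i in seq_len(M)) {
    pid <- paste0("Z", i)
    nodes <- rbind(nodes, data.frame(id = pid, kind = "product",
                                     free_energy = g_U,
                                     stringsAsFactors = FALSE))
    for (lab in names(targets)) {
      g <- targets[[lab]]
      iid <- paste0("I", i, lab)
      d1 <- g / 2 + runif(1, -1, 1)
      dgs <- c(d1, g - d1)
      g_int <- runif(1, -1, 1)
      nodes <- rbind(nodes, data.frame(id = iid, kind = "intermediate",
                                       free_energy = g_int,
                                       stringsAsFactors = FALSE))
      k <- 10^runif(2, -0.5, 0.5)
      slow <- (i == 1 && lab == "L") || (i > 1 && lab == "U")
      if (slow) k <- k * epsilon
      edges <- rbind(edges, chain_edges(null_id, iid, pid, dgs, k_fwd = k,
                                        g_nodes = g_int, g_product = g_U))
    }
  }
  templating_network(nodes, edges,
                     meta = list(M = M, G0 = g_U))
}

#' Random thermodynamically consistent network
#'
#' Samples a connected, reversible linear network for property testing:
#' node free energies uniform in [-5, 5] k_B T, per-edge chemical work
#' uniform in [-3, 3] k_B T, forward rates log-uniform in [1e-2, 1e2], and
#' reverse rates fixed by local detailed balance, so
#' [validate_thermodynamics()] passes by construction. The topology is a
#' random spanning structure rooted at the null complex (products attach to
#' the null complex or intermediates only) plus \code{n_extra_edges}
#' additional random edges, which create alternative pathways and internal
#' cycles.
#'
#' @param n_intermediates,n_products node counts (>= 1 product).
#' @param n_extra_edges extra edges beyond the spanning structure.
#' @param seed integer seed.
#' @return A [templating_network()].
#' @export
make_random_consistent_network <- function(n_intermediates = 8,
                                           n_products = 3,
                                           n_extra_edges = 5, seed) {
  stopifnot(n_products >= 1, n_intermediates >= 0)
  set.seed(as.integer(seed))
  null_id <- null_complex_label()
  inter <- if (n_intermediates > 0) paste0("I", seq_len(n_intermediates)) else
    character(0)
  prods <- paste0("Z", seq_len(n_products))
  nodes <- data.frame(
    id = c(null_id, inter, prods),
    kind = c("null", rep("intermediate", n_intermediates),
             rep("product", n_products)),
    free_energy = c(0, runif(n_intermediates + n_products, -5, 5)),
    stringsAsFactors = FALSE)
  g <- setNames(nodes$free_energy, nodes$id)

  new_edge <- function(u, v) {
    cw <- runif(1, -3, 3)
    kf <- 10^runif(1, -2, 2)
    dg <- g[[v]] - g[[u]] + cw
    data.frame(from = u, to = v, k_fwd = kf, k_rev = kf * exp(dg),
               chem_work = cw, stringsAsFactors = FALSE)
  }

  edges <- NULL
  hubs <- null_id  # null + intermediates attached so far
  for (v in inter) {
    edges <- rbind(edges, new_edge(sample(hubs, 1), v))
    hubs <- c(hubs, v)
  }
  for (v in prods) {
    edges <- rbind(edges, new_edge(sample(hubs, 1), v))
  }
  all_ids <- nodes$id
  for (k in seq_len(n_extra_edges)) {
    repeat {
      u <- sample(hubs, 1)  # never a product, so no product-product edges
      v <- sample(setdiff(all_ids, u), 1)
      if (!any(edges$from == u & edges$to == v) &&
          !any(edges$from == v & edges$to == u)) break
    }
    edges <- rbind(edges, new_edge(u, v))
  }
  templating_network(nodes, edges, meta = list(M = n_products))
}

#' Add a reversible reaction to an existing network
#'
#' Convenience for building loop-bearing variants of fixtures (e.g.
#' proofreading-style cycles between intermediates). The extended network
#' is re-validated from scratch.
#'
#' @param network a [templating_network()].
#' @param from,to node ids.
#' @param k_fwd,k_rev positive rate constants.
#' @param chem_work optional chemical-work annotation, k_B T.
#' @return The extended [templating_network()].
#' @export
add_reaction <- function(network, from, to, k_fwd, k_rev, chem_work = NA) {
  stopifnot(inherits(network, "templating_network"))
  edges <- rbind(network$edges[, c("from", "to", "k_fwd", "k_rev", "chem_work")],
                 data.frame(from = from, to = to, k_fwd = k_fwd,
                            k_rev = k_rev, chem_work = chem_work,
                            stringsAsFactors = FALSE))
  templating_network(network$nodes, edges, network$meta)
}
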