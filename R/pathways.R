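# Adjacency list over node ids. Each entry is a list of steps
# (to, edge index, sign): sign +1 traverses the edge in its stored
# orientation (contributing +delta_g to a walk), -1 traverses it backwards.
build_adjacency <- function(network) {
  adj <- setNames(vector("list", nrow(network$nodes)), network$nodes$id)
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]],
                          list(list(to = e$to[i], edge = i, sign = 1)))
    adj[[e$to[i]]] <- c(adj[[e$to[i]]],
                        list(list(to = e$from[i], edge = i, sign = -1)))
  }
  adj
}

#' Enumerate self-avoiding walks from the null complex to a species
#'
#' Exhaustively enumerates the self-avoiding walks (SAWs) of the network
#' graph from the null complex to the target species by depth-first search
#' with an explicit visited set. Every edge is reversible, so edges may be
#' traversed in either direction; the free-energy change of a walk is the
#' signed sum of edge free energies, \code{delta_g_S = sum(sign * delta_g)}.
#' SAWs cannot contain cycles by definition, so internal loops (e.g.
#' proofreading cycles) never appear inside a walk; they can only add
#' further distinct walks.
#'
#' @param network a [templating_network()].
#' @param species id of a non-null node (product or intermediate).
#' @param cap maximum number of walks; exceeding it is an error, never a
#'   silent truncation, because the concentration bounds require the exact
#'   minimum and maximum of \code{delta_g_S}.
#' @return A list of class \code{pathway_set}; each element is a list with
#'   \code{product} (the target id), \code{nodes} (the visited node
#'   sequence), \code{edges} (edge row indices), \code{signs} (traversal
#'   directions) and \code{delta_g_S} (k_B T).
#' @export
enumerate_pathways <- function(network, species, cap = 1e6) {
  stopifnot(inherits(network, "templating_network"))
  if (!species %in% network$nodes$id) {
    tnet_stop(sprintf("unknown species '%s'", species), "tnet_lookup_error")
  }
  null_id <- network$nodes$id[network$nodes$kind == "null"]
  if (species == null_id) {
    tnet_stop("target species must not be the null complex", "tnet_lookup_error")
  }
  adj <- build_adjacency(network)
  dg <- network$edges$delta_g

  paths <- vector("list", 64L)
  n_found <- 0L
  node_seq <- character(nrow(network$nodes))
  edge_seq <- integer(nrow(network$nodes))
  sign_seq <- numeric(nrow(network$nodes))
  visited <- new.env(parent = emptyenv())

  record <- function(depth) {
    if (n_found >= cap) {
      tnet_stop(sprintf(
        "self-avoiding-walk cap exceeded for species '%s': more than %d walks (partial count)",
        species, cap), "tnet_enumeration_error")
    }
    n_found <<- n_found + 1L
    if (n_found > length(paths)) length(paths) <<- 2L * n_found
    idx <- seq_len(depth)
    paths[[n_found]] <<- list(
      product = species,
      nodes = c(null_id, node_seq[idx]),
      edges = edge_seq[idx],
      signs = sign_seq[idx],
      delta_g_S = sum(sign_seq[idx] * dg[edge_seq[idx]]))
  }

  walk <- function(u, depth) {
    for (step in adj[[u]]) {
      v <- step$to
      if (v == species) {
        node_seq[depth + 1L] <<- v
        edge_seq[depth + 1L] <<- step$edge
        sign_seq[depth + 1L] <<- step$sign
        record(depth + 1L)
      } else if (is.null(visited[[v]])) {
        visited[[v]] <- TRUE
        node_seq[depth + 1L] <<- v
        edge_seq[depth + 1L] <<- step$edge
        sign_seq[depth + 1L] <<- step$sign
        walk(v, depth + 1L)
        rm(list = v, envir = visited)
      }
    }
  }
  visited[[null_id]] <- TRUE
  walk(null_id, 0L)

  structure(paths[seq_len(n_found)], class = "pathway_set",
            species = species)
}

#' Tabulate the self-avoiding walks of a network
#'
#' @param network a [templating_network()].
#' @param species node ids to enumerate for; defaults to all products.
#' @param cap per-species walk cap, as in [enumerate_pathways()].
#' @return data.frame with columns \code{product}, \code{pathway_index},
#'   \code{node_sequence} (nodes joined by \code{"->"}) and
#'   \code{delta_g_S}.
#' @export
pathway_table <- function(network, species = NULL, cap = 1e6) {
  stopifnot(inherits(network, "templating_network"))
  if (is.null(species)) {
    species <- network$nodes$id[network$nodes$kind == "product"]
  }
  do.call(rbind, lapply(species, function(p) {
    paths <- enumerate_pathways(network, p, cap = cap)
    data.frame(
      product = p,
      pathway_index = seq_along(paths),
      node_sequence = vapply(paths, function(s)
        paste(s$nodes, collapse = "->"), character(1)),
      delta_g_S = vapply(paths, function(s) s$delta_g_S, numeric(1)),
      stringsAsFactors = FALSE)
  }))
}

#' Pathway free-energy extremes and concentration bounds
#'
#' For every species reachable from the null complex, the steady-state
#' concentration of a linear, connected, chemostatted network is bounded by
#' the extreme pathway free energies:
#' \code{exp(-delta_g_L) <= c <= exp(-delta_g_U)}, where
#' \code{delta_g_U = min_S delta_g_S} and \code{delta_g_L = max_S
#' delta_g_S} over the self-avoiding walks S from the null complex to the
#' species. The per-product accuracy scale is
#' \code{delta_G = delta_g_L - delta_g_U >= 0}; when all products share the
#' same extremes the single network-wide value is reported too.
#'
#' @param network a [templating_network()].
#' @param cap per-species walk cap, as in [enumerate_pathways()].
#' @param tol tolerance used to decide whether all products share the same
#'   extremes.
#' @return Object of class \code{pathway_bounds}: list with data.frames
#'   \code{products} and \code{intermediates} (columns \code{species},
#'   \code{n_pathways}, \code{delta_g_U}, \code{delta_g_L}, \code{c_U},
#'   \code{c_L}, \code{delta_G}), logical \code{shared} and scalar
#'   \code{network_delta_G} (NA unless shared).
#' @export
pathway_bounds <- function(network, cap = 1e6, tol = 1e-9) {
  stopifnot(inherits(network, "templating_network"))
  non_null <- network$nodes[network$nodes$kind != "null", , drop = FALSE]
  rows <- do.call(rbind, lapply(non_null$id, function(p) {
    paths <- enumerate_pathways(network, p, cap = cap)
    dgs <- vapply(paths, function(s) s$delta_g_S, numeric(1))
    data.frame(species = p,
               n_pathways = length(dgs),
               delta_g_U = min(dgs),
               delta_g_L = max(dgs),
               c_U = exp(-min(dgs)),
               c_L = exp(-max(dgs)),
               delta_G = max(dgs) - min(dgs),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  kind <- setNames(non_null$kind, non_null$id)
  prod_rows <- rows[kind[rows$species] == "product", , drop = FALSE]
  shared <- nrow(prod_rows) > 0 &&
    diff(range(prod_rows$delta_g_U)) <= tol &&
    diff(range(prod_rows$delta_g_L)) <= tol
  structure(
    list(products = prod_rows,
         intermediates = rows[kind[rows$species] == "intermediate", ,
                              drop = FALSE],
         shared = shared,
         network_delta_G = if (shared) prod_rows$delta_G[1] else NA_real_),
    class = "pathway_bounds")
}

#' Pairwise accuracy scale between two products
#'
#' For a (possibly asymmetric) network the free-energy scale entering the
#' steady-state concentration-ratio identity for products X and Y is
#' \code{delta_g_L(Y) - delta_g_U(X)}: the least favourable pathway of Y
#' against the most favourable pathway of X.
#'
#' @param bounds a [pathway_bounds()] result.
#' @param x,y product ids.
#' @return Numeric scalar, k_B T.
#' @export
pair_delta_G <- function(bounds, x, y) {
  stopifnot(inherits(bounds, "pathway_bounds"))
  p <- bounds$products
  if (!x %in% p$species || !y %in% p$species) {
    tnet_stop("unknown product id", "tnet_lookup_error")
  }
  p$delta_g_L[p$species == y] - p$delta_g_U[p$species == x]
}

#' @export
print.pathway_bounds <- function(x, ...) {
  cat("Pathway concentration bounds (k_BT / dimensionless activities)\n")
  print.data.frame(x$products, row.names = FALSE, digits = 6)
  if (x$shared) {
    cat(sprintf("Shared network delta_G = %.6g k_BT\n", x$network_delta_G))
  } else {
    cat("Products do not share pathway extremes; use per-product values.\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pathway_set <- function(x, ...) {
  data.frame(
    product = attr(x, "species"),
    pathway_index = seq_along(x),
    node_sequence = vapply(x, function(s) paste(s$nodes, collapse = "->"),
                           character(1)),
    delta_g_S = vapply(x, function(s) s$delta_g_S, numeric(1)),
    stringsAsFactors = FALSE)
}
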