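#' Construct a templating network
#'
#' Builds and validates a linear chemical reaction network for template-
#' directed assembly. Nodes are complexes: exactly one null complex (the
#' empty state from which assembly starts), any number of intermediates,
#' and at least one product. Edges are reversible mass-action reactions
#' whose rate constants have absorbed all chemostatted species (monomers,
#' fuels, catalysts, templates). The free-energy change of every edge is
#' fixed by local detailed balance, \code{delta_g = -log(k_fwd / k_rev)},
#' in units of k_B T.
#'
#' Node free energies and per-edge chemical work (the chemostat bookkeeping
#' term, the summed chemical-potential change of chemostatted species
#' turned over by the reaction) are optional annotations; when present they
#' are cross-checked against the rates by [validate_thermodynamics()].
#'
#' @param nodes data.frame with columns \code{id} (character, unique),
#'   \code{kind} (one of \code{"null"}, \code{"intermediate"},
#'   \code{"product"}) and optionally \code{free_energy} (numeric, k_B T;
#'   the null complex is the zero of energy).
#' @param edges data.frame with columns \code{from}, \code{to} (node ids),
#'   \code{k_fwd}, \code{k_rev} (positive rate constants) and optionally
#'   \code{chem_work} (numeric, k_B T).
#' @param meta optional list of annotations: \code{M} (product count),
#'   \code{L} (polymer length), \code{G0} (standard free energy of product
#'   formation, k_B T), \code{chemostats} (data.frame of species name and
#'   normalised chemical potential).
#' @return An object of class \code{templating_network}: a list with
#'   elements \code{nodes}, \code{edges} (with derived \code{delta_g}
#'   column), \code{meta} and \code{M}.
#' @seealso [load_network()], [write_network()], [validate_thermodynamics()]
#' @export
#' @examples
#' nodes <- data.frame(id = c("Ø", "Z"), kind = c("null", "product"))
#' edges <- data.frame(from = "Ø", to = "Z", k_fwd = 2, k_rev = 1)
#' net <- templating_network(nodes, edges)
#' net$edges$delta_g  # -log(2)
templating_network <- function(nodes, edges, meta = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)

  for (col in c("id", "kind")) {
    if (is.null(nodes[[col]])) {
      tnet_stop(sprintf("node table is missing required field '%s'", col),
                "tnet_parse_error")
    }
  }
  for (col in c("from", "to")) {
    if (is.null(edges[[col]])) {
      tnet_stop(sprintf("edge table is missing required field '%s'", col),
                "tnet_parse_error")
    }
  }
  for (col in c("k_fwd", "k_rev")) {
    if (is.null(edges[[col]]) || anyNA(edges[[col]])) {
      tnet_stop(sprintf(
        "edge table is missing rate constant '%s': every reaction must be reversible",
        col), "tnet_parse_error")
    }
  }

  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  if (is.null(nodes$free_energy)) nodes$free_energy <- NA_real_
  nodes$free_energy <- as.numeric(nodes$free_energy)
  nodes <- nodes[, c("id", "kind", "free_energy")]

  if (anyDuplicated(nodes$id)) {
    tnet_stop("node field 'id' contains duplicates", "tnet_validation_error")
  }
  bad_kind <- setdiff(unique(nodes$kind), c("null", "intermediate", "product"))
  if (length(bad_kind)) {
    tnet_stop(sprintf("node field 'kind' has invalid value(s): %s",
                      paste(bad_kind, collapse = ", ")),
              "tnet_validation_error")
  }
  if (sum(nodes$kind == "null") != 1L) {
    tnet_stop("network must contain exactly one node of kind 'null'",
              "tnet_validation_error")
  }
  if (!any(nodes$kind == "product")) {
    tnet_stop("network must contain at least one product node",
              "tnet_validation_error")
  }

  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$k_fwd <- as.numeric(edges$k_fwd)
  edges$k_rev <- as.numeric(edges$k_rev)
  if (is.null(edges$chem_work)) edges$chem_work <- NA_real_
  edges$chem_work <- as.numeric(edges$chem_work)
  edges <- edges[, c("from", "to", "k_fwd", "k_rev", "chem_work")]

  unknown <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(unknown)) {
    tnet_stop(sprintf("edge field 'from'/'to' references unknown node(s): %s",
                      paste(unknown, collapse = ", ")), "tnet_validation_error")
  }
  if (any(edges$from == edges$to)) {
    tnet_stop("edge connects a node to itself; self-loops are not reactions",
              "tnet_validation_error")
  }
  kind_of <- setNames(nodes$kind, nodes$id)
  if (any(kind_of[edges$from] == "product" & kind_of[edges$to] == "product")) {
    tnet_stop("edge connects two product nodes; products interconvert only via intermediates or the null complex",
              "tnet_validation_error")
  }
  if (any(!is.finite(edges$k_fwd)) || any(!is.finite(edges$k_rev)) ||
      any(edges$k_fwd <= 0) || any(edges$k_rev <= 0)) {
    tnet_stop("rate constants 'k_fwd'/'k_rev' must be positive and finite: every reaction must be reversible",
              "tnet_validation_error")
  }

  edges$delta_g <- edge_free_energy(edges$k_fwd, edges$k_rev)

  net <- structure(
    list(nodes = nodes, edges = edges, meta = meta,
         M = sum(nodes$kind == "product")),
    class = "templating_network")

  unreachable <- setdiff(nodes$id, reachable_nodes(net))
  if (length(unreachable)) {
    tnet_stop(sprintf("network graph is disconnected; unreachable from the null complex: %s",
                      paste(unreachable, collapse = ", ")),
              "tnet_connectivity_error")
  }
  if (!is.null(meta$M) && meta$M != net$M) {
    warning(sprintf("meta$M (%s) disagrees with the counted number of products (%d)",
                    meta$M, net$M))
  }
  net
}

# Node ids reachable from the null complex treating edges as undirected
# (every edge is reversible).
reachable_nodes <- function(network) {
  start <- network$nodes$id[network$nodes$kind == "null"]
  nbr <- split(c(network$edges$to, network$edges$from),
               c(network$edges$from, network$edges$to))
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(nbr[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Free-energy change of a reversible reaction from its rate constants
#'
#' Local detailed balance fixes the k_B T-normalised standard free-energy
#' change of a reversible reaction as \code{-log(k_fwd / k_rev)}. The
#' result is antisymmetric under swapping the two rates.
#'
#' @param k_fwd,k_rev positive rate constants (vectorised).
#' @return Numeric vector of free-energy changes in k_B T.
#' @export
#' @examples
#' edge_free_energy(2, 1)  # -log(2)
#' edge_free_energy(1, 2)  # +log(2)
edge_free_energy <- function(k_fwd, k_rev) {
  if (any(!is.finite(k_fwd)) || any(!is.finite(k_rev)) ||
      any(k_fwd <= 0) || any(k_rev <= 0)) {
    tnet_stop("rate constants must be positive and finite", "tnet_domain_error")
  }
  -log(k_fwd / k_rev)
}

#' Read a templating network from its JSON description
#'
#' Parses the network interchange format: a JSON object with keys
#' \code{"nodes"} (list of \code{{id, kind, free_energy?}}), \code{"edges"}
#' (list of \code{{from, to, k_fwd, k_rev, chem_work?}}) and optional
#' \code{"meta"} (\code{{M?, L?, G0?, chemostats?}}). A machine-readable
#' description of the format ships with the package
#' (\code{system.file("extdata", "network-schema.json", package = "templimits")}).
#'
#' @param document path to a JSON file, or a JSON string.
#' @return A validated [templating_network()].
#' @export
load_network <- function(document) {
  if (!is.character(document) || length(document) != 1L) {
    tnet_stop("document must be a file path or a JSON string",
              "tnet_parse_error")
  }
  txt <- if (grepl("^\\s*\\{", document)) document else {
    if (!file.exists(document)) {
      tnet_stop(sprintf("network file not found: %s", document),
                "tnet_parse_error")
    }
    paste(readLines(document, encoding = "UTF-8", warn = FALSE),
          collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyDataFrame = TRUE),
    error = function(e) tnet_stop(
      sprintf("invalid JSON in network document: %s", conditionMessage(e)),
      "tnet_parse_error"))
  for (key in c("nodes", "edges")) {
    if (is.null(doc[[key]])) {
      tnet_stop(sprintf("network document is missing top-level field '%s'", key),
                "tnet_parse_error")
    }
  }
  meta <- doc$meta %||% list()
  templating_network(doc$nodes, doc$edges, meta)
}

#' Write a templating network to a JSON file
#'
#' Serialises all node and edge fields at full double precision so that
#' \code{load_network(write_network(net, f))} reproduces the network
#' exactly.
#'
#' @param network a [templating_network()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "templating_network"))
  doc <- list(
    nodes = network$nodes,
    edges = network$edges[, c("from", "to", "k_fwd", "k_rev", "chem_work")],
    meta = if (length(network$meta)) network$meta else NULL)
  json <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                           digits = I(17), na = "null", pretty = TRUE,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Check the thermodynamic self-consistency of a network
#'
#' Produces a per-edge report of the checks a self-consistent network must
#' satisfy: reversibility (both rate constants positive), local detailed
#' balance (the stored \code{delta_g} equals \code{-log(k_fwd/k_rev)}),
#' and, when node free energies and chemical work are annotated, energy
#' consistency: \code{-log(k_fwd/k_rev)} must equal
#' \code{G_to - G_from + chem_work} (the null complex has zero free
#' energy). Connectivity from the null complex is re-verified.
#'
#' @param network a [templating_network()].
#' @param tol absolute tolerance (k_B T) on the residuals.
#' @return data.frame of class \code{tnet_validation} with columns
#'   \code{check}, \code{item}, \code{residual}, \code{pass}; attribute
#'   \code{"pass"} carries the overall verdict (checks that could not be
#'   evaluated for lack of annotations are skipped, not failed).
#' @export
validate_thermodynamics <- function(network, tol = 1e-8) {
  stopifnot(inherits(network, "templating_network"))
  e <- network$edges
  item <- paste0(e$from, "->", e$to)
  g <- setNames(network$nodes$free_energy, network$nodes$id)
  g[network$nodes$kind == "null"] <- 0

  rev_ok <- is.finite(e$k_fwd) & is.finite(e$k_rev) & e$k_fwd > 0 & e$k_rev > 0
  ldb_res <- e$delta_g + log(e$k_fwd / e$k_rev)
  en_res <- -log(e$k_fwd / e$k_rev) - (g[e$to] - g[e$from] + e$chem_work)

  rows <- rbind(
    data.frame(check = "reversibility", item = item, residual = NA_real_,
               pass = rev_ok, stringsAsFactors = FALSE),
    data.frame(check = "local_detailed_balance", item = item,
               residual = ldb_res, pass = abs(ldb_res) <= tol,
               stringsAsFactors = FALSE),
    data.frame(check = "energy_consistency", item = item, residual = en_res,
               pass = ifelse(is.na(en_res), NA, abs(en_res) <= tol),
               stringsAsFactors = FALSE),
    data.frame(check = "connectivity", item = "network", residual = NA_real_,
               pass = length(setdiff(network$nodes$id,
                                     reachable_nodes(network))) == 0L,
               stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  structure(rows, class = c("tnet_validation", "data.frame"),
            pass = all(rows$pass, na.rm = TRUE))
}

#' @export
print.tnet_validation <- function(x, ...) {
  cat("Thermodynamic validation report\n")
  overall <- attr(x, "pass")
  n_eval <- sum(!is.na(x$pass))
  n_fail <- sum(!x$pass, na.rm = TRUE)
  cat(sprintf("  %d checks evaluated, %d failed -> overall %s\n",
              n_eval, n_fail, if (overall) "PASS" else "FAIL"))
  if (n_fail > 0) {
    cat("Failed checks:\n")
    print.data.frame(x[!is.na(x$pass) & !x$pass, ], row.names = FALSE)
  }
  invisible(x)
}

#' Write a validation report as TSV
#'
#' @param report result of [validate_thermodynamics()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_validation_tsv <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Test pairwise topological equivalence of products
#'
#' The symmetric model assumes every product is connected to the null
#' complex by an equivalent set of reactions. This check operationalises
#' that notion per product pair: the subgraphs formed by the union of all
#' self-avoiding walks from the null complex to each product must be
#' isomorphic as rooted graphs (null complex and product distinguished,
#' parallel-edge multiplicities respected), and the multisets of pathway
#' free-energy changes \code{delta_g_S} must coincide within \code{tol}.
#' Symmetry is verified, not required: asymmetric networks remain valid and
#' all bounds are computed per product.
#'
#' @param network a [templating_network()].
#' @param tol absolute tolerance (k_B T) when comparing pathway free-energy
#'   multisets.
#' @param cap maximum number of self-avoiding walks per product.
#' @return data.frame with one row per unordered product pair and columns
#'   \code{product_a}, \code{product_b}, \code{isomorphic},
#'   \code{delta_g_match}, \code{equivalent}; attribute \code{"symmetric"}
#'   is \code{TRUE} when all pairs are equivalent (vacuously for M = 1).
#' @export
check_product_symmetry <- function(network, tol = 1e-6, cap = 1e6) {
  stopifnot(inherits(network, "templating_network"))
  products <- network$nodes$id[network$nodes$kind == "product"]
  empty <- data.frame(product_a = character(), product_b = character(),
                      isomorphic = logical(), delta_g_match = logical(),
                      equivalent = logical(), stringsAsFactors = FALSE)
  if (length(products) < 2L) {
    return(structure(empty, symmetric = TRUE))
  }
  info <- lapply(products, function(p) {
    paths <- enumerate_pathways(network, p, cap = cap)
    dgs <- sort(vapply(paths, function(s) s$delta_g_S, numeric(1)))
    eidx <- sort(unique(unlist(lapply(paths, function(s) s$edges))))
    list(dgs = dgs, graph = saw_subgraph(network, eidx, p))
  })
  names(info) <- products

  rows <- empty
  for (i in seq_len(length(products) - 1L)) {
    for (j in seq(i + 1L, length(products))) {
      a <- info[[products[i]]]; b <- info[[products[j]]]
      iso <- igraph::isomorphic(a$graph, b$graph, method = "vf2")
      dg_ok <- length(a$dgs) == length(b$dgs) &&
        (length(a$dgs) == 0L || max(abs(a$dgs - b$dgs)) <= tol)
      rows <- rbind(rows, data.frame(
        product_a = products[i], product_b = products[j],
        isomorphic = iso, delta_g_match = dg_ok,
        equivalent = iso && dg_ok, stringsAsFactors = FALSE))
    }
  }
  structure(rows, symmetric = all(rows$equivalent))
}

# Rooted, coloured igraph of the union of SAW edges leading to `product`:
# vertex colours distinguish the null complex (0), intermediates and
# foreign products (1) and the focal product (2); parallel edges are
# collapsed with their multiplicity as an (integer) edge colour so that
# VF2 isomorphism respects multigraph structure.
saw_subgraph <- function(network, edge_idx, product) {
  e <- network$edges[edge_idx, , drop = FALSE]
  verts <- unique(c(e$from, e$to, product))
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::E(g)$mult <- 1L
  g <- igraph::simplify(g, remove.loops = FALSE,
                        edge.attr.comb = list(mult = "sum"))
  kind <- setNames(network$nodes$kind, network$nodes$id)
  col <- ifelse(igraph::V(g)$name == product, 2L,
                ifelse(kind[igraph::V(g)$name] == "null", 0L, 1L))
  igraph::V(g)$color <- col
  igraph::E(g)$color <- igraph::E(g)$mult
  g
}

#' @export
print.templating_network <- function(x, ...) {
  cat(sprintf("Templating network: %d nodes (%d intermediates, %d products), %d reversible edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "intermediate"), x$M,
              nrow(x$edges)))
  if (!is.null(x$meta$G0)) cat(sprintf("  G0 = %g k_BT\n", x$meta$G0))
  if (!is.null(x$meta$L)) cat(sprintf("  L  = %g\n", x$meta$L))
  invisible(x)
}
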