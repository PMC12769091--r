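# Linear mass-action balance system for the non-null nodes, with the null
# complex chemostatted at activity 1: dc/dt = A c + b.
balance_system <- function(network) {
  ids <- network$nodes$id[network$nodes$kind != "null"]
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  b <- setNames(numeric(n), ids)
  e <- network$edges
  null_id <- network$nodes$id[network$nodes$kind == "null"]
  for (i in seq_len(nrow(e))) {
    u <- e$from[i]; v <- e$to[i]; kf <- e$k_fwd[i]; kr <- e$k_rev[i]
    if (u == null_id) {
      b[v] <- b[v] + kf
      A[v, v] <- A[v, v] - kr
    } else if (v == null_id) {
      b[u] <- b[u] + kr
      A[u, u] <- A[u, u] - kf
    } else {
      A[v, u] <- A[v, u] + kf
      A[u, u] <- A[u, u] - kf
      A[u, v] <- A[u, v] + kr
      A[v, v] <- A[v, v] - kr
    }
  }
  list(A = A, b = b, ids = ids)
}

new_concentration_profile <- function(network, conc, steady = TRUE,
                                      time = NA_real_) {
  nodes <- network$nodes[network$nodes$kind != "null", , drop = FALSE]
  df <- data.frame(node = nodes$id, kind = nodes$kind,
                   concentration = as.numeric(conc[nodes$id]),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("concentration_profile", "data.frame"),
            c_T = sum(df$concentration[df$kind == "product"]),
            steady_state = steady, time = time)
}

#' Solve the deterministic steady state of a templating network
#'
#' The network is linear (each complex carries at most one tracked
#' species), so with the null complex chemostatted at unit activity the
#' mass-action balance equations are linear in the concentrations and are
#' solved directly. Reactions leaving the null complex act as zeroth-order
#' sources at rate \code{k_fwd}.
#'
#' @param network a [templating_network()].
#' @param tol maximum permitted relative residual of the balance equations.
#' @param cond_warn condition-number threshold above which a warning is
#'   issued.
#' @return A \code{concentration_profile}: data.frame with columns
#'   \code{node}, \code{kind}, \code{concentration} (dimensionless
#'   activities) and attributes \code{c_T} (total product concentration),
#'   \code{steady_state = TRUE}.
#' @export
#' @examples
#' net <- make_two_product_network(2, 1, 0)
#' solve_steady_state(net)
solve_steady_state <- function(network, tol = 1e-9, cond_warn = 1e12) {
  stopifnot(inherits(network, "templating_network"))
  sys <- balance_system(network)
  cond <- kappa(sys$A, exact = FALSE)
  if (is.finite(cond) && cond > cond_warn) {
    warning(sprintf("balance system is ill-conditioned (condition estimate %.3g)",
                    cond))
  }
  conc <- tryCatch(
    solve(sys$A, -sys$b),
    error = function(err) tnet_stop(
      sprintf("singular balance system (condition estimate %.3g): %s",
              cond, conditionMessage(err)), "tnet_solver_error"))
  resid <- max(abs(sys$A %*% conc + sys$b)) / max(1, max(abs(sys$b)))
  if (resid > tol) {
    tnet_stop(sprintf(
      "steady-state residual %.3g exceeds tolerance %.3g (condition estimate %.3g)",
      resid, tol, cond), "tnet_solver_error")
  }
  new_concentration_profile(network, setNames(as.numeric(conc), sys$ids))
}

#' Integrate the mass-action transient of a templating network
#'
#' Solves the linear mass-action ODE system (null complex chemostatted at
#' unit activity) on a user-supplied time grid, starting from arbitrary
#' non-negative initial concentrations. The solution converges to
#' [solve_steady_state()] as t grows.
#'
#' @param network a [templating_network()].
#' @param times strictly increasing, non-negative time grid; if it does not
#'   start at 0, time 0 is prepended internally.
#' @param initial named numeric vector of initial concentrations over the
#'   non-null nodes (missing names default to 0), or a
#'   \code{concentration_profile}. Default: all zero.
#' @param rtol,atol integrator tolerances passed to [deSolve::ode()].
#' @return Object of class \code{transient_profiles}: list with
#'   \code{times} and \code{conc} (matrix, time by node).
#' @export
integrate_transient <- function(network, times, initial = NULL,
                                rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(network, "templating_network"))
  if (any(diff(times) <= 0) || any(times < 0)) {
    tnet_stop("time grid must be non-negative and strictly increasing",
              "tnet_domain_error")
  }
  sys <- balance_system(network)
  y0 <- setNames(numeric(length(sys$ids)), sys$ids)
  if (inherits(initial, "concentration_profile")) {
    y0[initial$node] <- initial$concentration
  } else if (!is.null(initial)) {
    if (is.null(names(initial))) {
      tnet_stop("initial concentrations must be a named vector",
                "tnet_domain_error")
    }
    y0[names(initial)] <- initial
  }
  if (any(y0 < 0)) {
    tnet_stop("initial concentrations must be non-negative",
              "tnet_domain_error")
  }
  grid <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::ode(
    y = y0, times = grid,
    func = function(t, y, parms) list(as.numeric(sys$A %*% y + sys$b)),
    rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    tnet_stop("stiff integration failed; see deSolve diagnostics",
              "tnet_solver_error")
  }
  conc <- sol[, sys$ids, drop = FALSE]
  keep <- match(times, grid)
  structure(list(times = times,
                 conc = conc[keep, , drop = FALSE],
                 kinds = setNames(network$nodes$kind, network$nodes$id)),
            class = "transient_profiles")
}

#' Extract one time point of a transient as a concentration profile
#'
#' @param transient a [integrate_transient()] result.
#' @param network the network the transient was integrated for.
#' @param i time index into \code{transient$times}.
#' @return A \code{concentration_profile} with \code{steady_state = FALSE}.
#' @export
profile_at <- function(transient, network, i) {
  stopifnot(inherits(transient, "transient_profiles"))
  conc <- setNames(as.numeric(transient$conc[i, ]),
                   colnames(transient$conc))
  new_concentration_profile(network, conc, steady = FALSE,
                            time = transient$times[i])
}

#' Per-edge fluxes and entropy production rate
#'
#' Evaluates, at the given concentrations, the forward flux
#' \code{J_fwd = k_fwd * c_from}, backward flux \code{J_rev = k_rev * c_to}
#' (the null complex has unit activity) and the net flux per edge, plus the
#' total entropy production rate
#' \code{sigma = sum((J_fwd - J_rev) * log(J_fwd / J_rev))} in k_B per unit
#' time. Edges with \code{J_fwd == J_rev} contribute zero; an edge with a
#' one-sided zero flux but nonzero net flux contributes \code{Inf}.
#'
#' @param network a [templating_network()].
#' @param profile a \code{concentration_profile}.
#' @return data.frame of class \code{flux_report} with per-edge columns
#'   \code{from}, \code{to}, \code{J_fwd}, \code{J_rev}, \code{J_net},
#'   \code{sigma_term}; attribute \code{"sigma"} holds the total.
#' @export
edge_fluxes <- function(network, profile) {
  stopifnot(inherits(network, "templating_network"),
            inherits(profile, "concentration_profile"))
  if (any(profile$concentration < 0)) {
    tnet_stop("concentrations must be non-negative", "tnet_domain_error")
  }
  conc <- setNames(profile$concentration, profile$node)
  null_id <- network$nodes$id[network$nodes$kind == "null"]
  conc[null_id] <- 1
  e <- network$edges
  jf <- e$k_fwd * as.numeric(conc[e$from])
  jr <- e$k_rev * as.numeric(conc[e$to])
  term <- ifelse(jf == jr, 0,
                 ifelse(jf <= 0 | jr <= 0, Inf, (jf - jr) * log(jf / jr)))
  out <- data.frame(from = e$from, to = e$to, J_fwd = jf, J_rev = jr,
                    J_net = jf - jr, sigma_term = term,
                    stringsAsFactors = FALSE)
  structure(out, class = c("flux_report", "data.frame"), sigma = sum(term))
}

#' @export
print.flux_report <- function(x, ...) {
  cat(sprintf("Edge flux report; entropy production rate sigma = %.6g k_B / time\n",
              attr(x, "sigma")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Production-to-degradation trajectory ratio of a pathway
#'
#' At steady state, thermodynamic self-consistency fixes the observed ratio
#' of production to degradation trajectories of a species along a pathway
#' with free-energy change \code{delta_g_S} as
#' \code{Gamma = exp(-delta_g_S) / c}. \code{Gamma = 1} on every pathway is
#' pseudo-equilibrium; deviations from unity imply a net flux.
#'
#' @param network a [templating_network()].
#' @param profile a steady-state \code{concentration_profile}.
#' @param species id of the species.
#' @param pathway either a pathway (an element of [enumerate_pathways()])
#'   or the numeric pathway free energy \code{delta_g_S} (k_B T).
#' @return Numeric scalar Gamma.
#' @export
gamma_ratio <- function(network, profile, species, pathway) {
  stopifnot(inherits(profile, "concentration_profile"))
  dg <- if (is.numeric(pathway)) pathway else pathway$delta_g_S
  conc <- profile$concentration[profile$node == species]
  if (length(conc) != 1L) {
    tnet_stop(sprintf("unknown species '%s'", species), "tnet_lookup_error")
  }
  if (conc <= 0) {
    tnet_stop("Gamma is undefined at zero concentration", "tnet_domain_error")
  }
  exp(-dg) / conc
}

#' Residual of the steady-state concentration-ratio identity
#'
#' For two products X and Y of a network at steady state,
#' \code{log(c_X / c_Y) = delta_G + log(Gamma_Y(delta_g_L) /
#' Gamma_X(delta_g_U))} holds exactly, with
#' \code{delta_G = delta_g_L(Y) - delta_g_U(X)},
#' \code{Gamma_X(delta_g_U)} the production/degradation trajectory ratio of
#' X on its most favourable pathway and \code{Gamma_Y(delta_g_L)} that of Y
#' on its least favourable pathway. This function returns the left side
#' minus the right side; it vanishes up to floating-point error and serves
#' as an internal-consistency diagnostic of solved steady states.
#'
#' @param network a [templating_network()].
#' @param profile a steady-state \code{concentration_profile}.
#' @param x,y product ids (the identity is stated for \code{c_X > c_Y}, but
#'   the residual is an identity for any ordering).
#' @param bounds optional precomputed [pathway_bounds()].
#' @return Numeric scalar residual (0 up to floating error).
#' @export
eq_identity_residual <- function(network, profile, x, y, bounds = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (is.null(bounds)) bounds <- pathway_bounds(network)
  p <- bounds$products
  if (!x %in% p$species || !y %in% p$species) {
    tnet_stop("unknown product id", "tnet_lookup_error")
  }
  cx <- profile$concentration[profile$node == x]
  cy <- profile$concentration[profile$node == y]
  if (cx <= 0 || cy <= 0) {
    tnet_stop("identity undefined at zero concentration", "tnet_domain_error")
  }
  dg_u_x <- p$delta_g_U[p$species == x]
  dg_l_y <- p$delta_g_L[p$species == y]
  delta_G <- dg_l_y - dg_u_x
  gamma_x <- exp(-dg_u_x) / cx
  gamma_y <- exp(-dg_l_y) / cy
  log(cx / cy) - (delta_G + log(gamma_y / gamma_x))
}

#' @export
print.concentration_profile <- function(x, ...) {
  state <- if (isTRUE(attr(x, "steady_state"))) "steady state" else
    sprintf("transient at t = %g", attr(x, "time"))
  cat(sprintf("Concentration profile (%s); c_T = %.6g\n", state,
              attr(x, "c_T")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
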