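# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  ifelse(x <= 18, log1p(exp(pmin(x, 18))),
         ifelse(x <= 33.3, x + exp(-x), x))
}

# log(M - 1) without losing precision for huge M.
log_m_minus_1 <- function(M) log(M) + log1p(-1 / M)

#' Product distribution, specificity and entropy of a concentration profile
#'
#' Normalises the product concentrations into the product ensemble
#' \code{p_i = c_i / c_T}, and evaluates the single-product specificity
#' \code{p_max = max_i p_i}, the Shannon entropy \code{H = -sum p_i log
#' p_i} (nats) and the transmitted information \code{log(M) - H}, the
#' channel capacity of the network viewed as a template-to-product
#' information channel.
#'
#' @param profile a \code{concentration_profile}.
#' @return Object of class \code{product_distribution}: list with \code{p}
#'   (named probabilities), \code{M}, \code{p_max}, \code{H} (nats),
#'   \code{info} (nats).
#' @export
product_distribution <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  conc <- profile$concentration[profile$kind == "product"]
  names(conc) <- profile$node[profile$kind == "product"]
  c_T <- sum(conc)
  if (c_T <= 0) {
    tnet_stop("all product concentrations are zero; distribution undefined",
              "tnet_domain_error")
  }
  p <- conc / c_T
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  structure(list(p = p, M = length(p), p_max = max(p), H = h,
                 info = log(length(p)) - h),
            class = "product_distribution")
}

#' @export
print.product_distribution <- function(x, ...) {
  cat(sprintf("Product ensemble over M = %d products\n", x$M))
  cat(sprintf("  p_max = %.6g, H = %.6g nats, info = %.6g nats\n",
              x$p_max, x$H, x$info))
  invisible(x)
}

#' Closed-form bound on single-product specificity
#'
#' The largest achievable steady-state probability of a single product,
#' given M possible products and a pathway free-energy spread
#' \code{delta_G} (k_B T), is
#' \code{p_max = 1 / (1 + (M - 1) exp(-delta_G))}, attained by one product
#' at the upper concentration bound and all others at the lower; the
#' remaining products then sit at \code{p_low = exp(-delta_G) * p_max}.
#' Computed in log space so it stays finite and monotone for M up to
#' 2^63.
#'
#' @param M number of possible products (>= 2).
#' @param delta_G free-energy spread, k_B T (>= 0); vectorised.
#' @return List with numeric vectors \code{p_max} and \code{p_low}.
#' @export
#' @examples
#' specificity_bound(16, 0)$p_max  # 1/16
specificity_bound <- function(M, delta_G) {
  if (length(M) != 1L || !is.finite(M) || M < 2) {
    tnet_stop("M must be a single count >= 2 (the single-product bound is trivially 1)",
              "tnet_domain_error")
  }
  if (any(!is.finite(delta_G)) || any(delta_G < 0)) {
    tnet_stop("delta_G must be finite and >= 0", "tnet_domain_error")
  }
  log_pmax <- -log1pexp(log_m_minus_1(M) - delta_G)
  list(p_max = exp(log_pmax), p_low = exp(log_pmax - delta_G))
}

#' Free-energy spread required for a target error rate
#'
#' Inverts the specificity bound: the smallest \code{delta_G} at which the
#' total error probability \code{1 - p_max} can reach \code{target_error}
#' is \code{log((M - 1) (1 - target_error) / target_error)}.
#'
#' @param M number of possible products (>= 2).
#' @param target_error desired total error probability, in
#'   \code{(0, (M - 1) / M]} (the upper endpoint is the uniform ensemble,
#'   which needs no drive).
#' @return Numeric, k_B T.
#' @export
#' @examples
#' required_delta_G(400, 1e-5)  # ~17.5 k_BT
required_delta_G <- function(M, target_error) {
  if (length(M) != 1L || !is.finite(M) || M < 2) {
    tnet_stop("M must be a single count >= 2", "tnet_domain_error")
  }
  if (any(target_error <= 0) || any(target_error > (M - 1) / M)) {
    tnet_stop("target_error must lie in (0, (M-1)/M]", "tnet_domain_error")
  }
  log_m_minus_1(M) + log1p(-target_error) - log(target_error)
}

#' Entropy along the two-level family of extremal ensembles
#'
#' Evaluates \code{H(m)}, the Shannon entropy (nats) of the ensemble with
#' \code{m} products at the upper concentration bound and \code{M - m} at
#' the lower bound:
#' \code{H(m) = (M - m) delta_G exp(-delta_G) / D + log(D)} with
#' \code{D = m + (M - m) exp(-delta_G)}.
#'
#' @param M number of possible products.
#' @param delta_G free-energy spread, k_B T (>= 0).
#' @param m number of high-concentration products, in \code{[1, M]};
#'   vectorised (need not be integer).
#' @return Numeric vector of entropies, nats.
#' @export
entropy_profile <- function(M, delta_G, m) {
  a <- exp(-delta_G)
  D <- m + (M - m) * a
  (M - m) * delta_G * a / D + log(D)
}

#' Lower bound on the entropy of the product ensemble
#'
#' Minimises [entropy_profile()] over the integer number \code{m} of
#' products held at the upper concentration bound, yielding the least
#' entropy any steady-state product ensemble can have at a given
#' free-energy spread. Reports the minimising \code{m_min} (smallest, on
#' ties), the bound \code{H_min}, and \code{p_high}, the total probability
#' carried by the \code{m_min} high-concentration products,
#' \code{p_high = m_min / (m_min + (M - m_min) exp(-delta_G))}.
#'
#' An exact vectorised scan over all m is used for \code{M <=
#' scan_limit}; beyond that the discrete unimodality of \code{H(m)} is
#' exploited by integer ternary search (verified against exhaustive scans
#' at small M in the test suite). Setting \code{continuous = TRUE}
#' additionally reports the relaxation in which m is treated as a
#' continuous variable (a slightly weaker bound, provided for reference and
#' never used as the default).
#'
#' @param M number of possible products (>= 2).
#' @param delta_G free-energy spread, k_B T (>= 0).
#' @param scan_limit largest M for which the exhaustive scan is used.
#' @param continuous also compute the continuous-m relaxation.
#' @param units \code{"nats"} (default) or \code{"bits"} for the reported
#'   entropies.
#' @return Object of class \code{entropy_bound}: list with \code{M},
#'   \code{delta_G}, \code{m_min}, \code{H_min}, \code{p_high},
#'   \code{method}, and (if requested) \code{m_continuous},
#'   \code{H_continuous}.
#' @export
entropy_bound <- function(M, delta_G, scan_limit = 1e7, continuous = FALSE,
                          units = c("nats", "bits")) {
  units <- match.arg(units)
  if (length(M) != 1L || !is.finite(M) || M < 2) {
    tnet_stop("M must be a single count >= 2", "tnet_domain_error")
  }
  if (length(delta_G) != 1L || !is.finite(delta_G) || delta_G < 0) {
    tnet_stop("delta_G must be a single finite value >= 0",
              "tnet_domain_error")
  }
  scale <- if (units == "bits") 1 / log(2) else 1

  if (delta_G == 0) {
    # H(m) = log(M) for every m; smallest minimiser by tie-break.
    m_min <- 1
    h_min <- log(M)
    method <- "degenerate"
  } else if (M <= scan_limit) {
    m <- seq_len(M)
    h <- entropy_profile(M, delta_G, m)
    m_min <- m[which.min(h)]
    h_min <- h[m_min]
    method <- "scan"
  } else {
    lo <- 1; hi <- M
    while (hi - lo > 4) {
      m1 <- floor(lo + (hi - lo) / 3)
      m2 <- ceiling(hi - (hi - lo) / 3)
      if (entropy_profile(M, delta_G, m1) <=
          entropy_profile(M, delta_G, m2)) hi <- m2 else lo <- m1
    }
    m <- seq(lo, hi)
    h <- entropy_profile(M, delta_G, m)
    m_min <- m[which.min(h)]
    h_min <- min(h)
    method <- "ternary"
  }
  out <- list(M = M, delta_G = delta_G, m_min = m_min,
              H_min = h_min * scale,
              p_high = m_min / (m_min + (M - m_min) * exp(-delta_G)),
              units = units, method = method)
  if (continuous) {
    if (delta_G == 0) {
      out$m_continuous <- 1
      out$H_continuous <- log(M) * scale
    } else {
      opt <- optimize(function(m) entropy_profile(M, delta_G, m),
                      interval = c(1, M))
      ends <- entropy_profile(M, delta_G, c(1, M))
      cand_m <- c(opt$minimum, 1, M)
      cand_h <- c(opt$objective, ends)
      k <- which.min(cand_h)
      out$m_continuous <- cand_m[k]
      out$H_continuous <- cand_h[k] * scale
    }
  }
  structure(out, class = "entropy_bound")
}

#' @export
print.entropy_bound <- function(x, ...) {
  cat(sprintf(
    "Entropy lower bound: M = %g, delta_G = %g k_BT -> H_min = %.6g %s (m_min = %g, p_high = %.6g)\n",
    x$M, x$delta_G, x$H_min, x$units, x$m_min, x$p_high))
  invisible(x)
}

#' Overlap threshold between the specificity and entropy bounds
#'
#' Leading-order free-energy spread above which the entropy-minimising
#' ensemble collapses onto the maximum-specificity ensemble (a single
#' product at the upper concentration bound): \code{log(M) + log(log(M))}.
#' Higher-order corrections of order \code{log(log M)/log M} are not
#' included.
#'
#' @param M number of possible products (>= 3, so the double log is
#'   defined).
#' @return Numeric, k_B T.
#' @export
overlap_threshold <- function(M) {
  if (any(!is.finite(M)) || any(M < 3)) {
    tnet_stop("M must be >= 3", "tnet_domain_error")
  }
  log(M) + log(log(M))
}

# Entropy (nats) of the maximum-specificity ensemble (one product at p_max,
# the rest at p_low); equals entropy_profile(M, delta_G, 1) exactly.
max_specificity_entropy <- function(M, delta_G) {
  log_pmax <- -log1pexp(log_m_minus_1(M) - delta_G)
  -log_pmax + (1 - exp(log_pmax)) * delta_G
}

#' Sweep the accuracy bounds over a grid of free-energy spreads
#'
#' Evaluates, for each M and each ratio \code{delta_G / log(M)}, the
#' specificity bound, the entropy lower bound (normalised by
#' \code{log(M)}), the entropy of the maximum-specificity ensemble
#' (normalised), the fraction of products at the upper concentration bound
#' in the entropy-minimising ensemble, and the total probability of those
#' high-concentration products.
#'
#' @param M_values vector of product counts (each >= 2).
#' @param ratio_grid non-negative grid of \code{delta_G / log(M)} values.
#' @param scan_limit passed to [entropy_bound()].
#' @return Long-format data.frame with columns \code{M}, \code{ratio},
#'   \code{p_max}, \code{Hmin_norm}, \code{Hspec_norm}, \code{m_frac},
#'   \code{p_high}.
#' @export
sweep_bounds <- function(M_values, ratio_grid = seq(0, 2, by = 0.05),
                         scan_limit = 1e7) {
  if (any(ratio_grid < 0)) {
    tnet_stop("ratio grid values must be >= 0", "tnet_domain_error")
  }
  rows <- lapply(M_values, function(M) {
    lnM <- log(M)
    do.call(rbind, lapply(ratio_grid, function(r) {
      dG <- r * lnM
      sp <- specificity_bound(M, dG)
      eb <- entropy_bound(M, dG, scan_limit = scan_limit)
      data.frame(M = M, ratio = r, p_max = sp$p_max,
                 Hmin_norm = eb$H_min / lnM,
                 Hspec_norm = max_specificity_entropy(M, dG) / lnM,
                 m_frac = eb$m_min / M, p_high = eb$p_high)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
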