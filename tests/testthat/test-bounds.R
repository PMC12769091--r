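# Networks of independent single-edge products give exact control over the
# steady-state concentrations feeding the distribution metrics.
conc_network <- function(conc) {
  ids <- paste0("Z", seq_along(conc))
  templating_network(
    data.frame(id = c(NULLC, ids),
               kind = c("null", rep("product", length(conc)))),
    data.frame(from = NULLC, to = ids, k_fwd = conc, k_rev = 1))
}

test_that("product distribution metrics", {
  d <- product_distribution(solve_steady_state(conc_network(rep(3, 4))))
  expect_equal(unname(d$p), rep(0.25, 4))
  expect_equal(d$H, log(4))
  expect_equal(d$info, 0)

  d <- product_distribution(solve_steady_state(conc_network(c(2, 1, 1))))
  expect_equal(unname(d$p), c(0.5, 0.25, 0.25))
  # direct summation: -sum p log p
  expect_equal(d$H, -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))))
  expect_equal(d$H, 1.0397208, tolerance = 1e-7)
  expect_equal(d$p_max, 0.5)
})

test_that("specificity bound: closed form, limits and inversion", {
  expect_equal(specificity_bound(16, 0)$p_max, 1 / 16)
  sp <- specificity_bound(400, 17.50)
  expect_equal(1 - sp$p_max, 1.0e-5, tolerance = 2e-2)
  expect_equal(sp$p_low, exp(-17.50) * sp$p_max)
  # exact half maximum at delta_G = log(M - 1)
  M <- 2^30
  expect_equal(specificity_bound(M, log(M - 1))$p_max, 0.5, tolerance = 1e-12)
  # monotone in delta_G, from 1/M toward 1 (strictly until it saturates in
  # double precision)
  g <- seq(0, 60, by = 0.5)
  p <- specificity_bound(400, g)$p_max
  expect_true(all(diff(p) >= 0))
  expect_true(all(diff(p[g <= 20]) > 0))
  expect_equal(p[1], 1 / 400)
  expect_gt(p[length(p)], 1 - 1e-10)
  expect_error(specificity_bound(1, 2), class = "tnet_domain_error")
  expect_error(specificity_bound(4, -0.1), class = "tnet_domain_error")

  expect_equal(required_delta_G(400, 1e-5),
               log((400 - 1) * (1 - 1e-5) / 1e-5))
  expect_equal(required_delta_G(400, 399 / 400), 0)
  # bisection oracle on the forward bound
  target <- 1e-3
  lo <- 0; hi <- 50
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (1 - specificity_bound(400, mid)$p_max > target) lo <- mid else hi <- mid
  }
  expect_equal(required_delta_G(400, target), (lo + hi) / 2, tolerance = 1e-10)
  expect_error(required_delta_G(400, 0), class = "tnet_domain_error")
})

# independent oracle: entropy of the two-level ensemble computed straight
# from its probabilities, minimised by exhaustive scan
oracle_entropy_min <- function(M, dG) {
  m <- seq_len(M)
  cl <- exp(-dG)
  tot <- m + (M - m) * cl
  p_hi <- 1 / tot
  p_lo <- cl / tot
  H <- -(m * p_hi * log(p_hi)) -
    ifelse(M - m > 0, (M - m) * p_lo * log(p_lo), 0)
  list(H_min = min(H), m_min = m[which.min(H)])
}

test_that("entropy bound matches the exhaustive distribution oracle", {
  for (M in c(2, 3, 7, 64, 1024)) {
    for (dG in c(0.1, 1, 0.5 * log(M), log(M), log(M) + 3)) {
      want <- oracle_entropy_min(M, dG)
      got <- entropy_bound(M, dG)
      expect_equal(got$H_min, want$H_min, tolerance = 1e-10)
      expect_equal(got$m_min, want$m_min)
    }
  }
  # degenerate drive: flat profile, smallest minimiser by tie-break
  eb <- entropy_bound(512, 0)
  expect_equal(eb$H_min, log(512))
  expect_equal(eb$m_min, 1)
  expect_equal(entropy_profile(512, 0, c(1, 17, 512)), rep(log(512), 3))
})

test_that("ternary search equals the exhaustive scan", {
  for (M in c(50, 63, 1000, 2^14)) {
    for (dG in seq(0.2, 1.6, by = 0.2) * log(M)) {
      scan <- entropy_bound(M, dG)
      tern <- entropy_bound(M, dG, scan_limit = 1)
      expect_equal(tern$method, "ternary")
      expect_equal(tern$m_min, scan$m_min)
      expect_equal(tern$H_min, scan$H_min, tolerance = 1e-12)
    }
  }
})

test_that("profile endpoints, p_high regime and the overlap threshold", {
  # H(M) = log M exactly; H(m) >= 0 everywhere
  for (M in c(4, 100, 4096)) {
    expect_equal(entropy_profile(M, 2.5, M), log(M))
    expect_true(all(entropy_profile(M, 2.5, seq_len(M)) >= 0))
  }
  # a small high-concentration set dominates well below delta_G = log M
  eb <- entropy_bound(2^20, 0.5 * log(2^20))
  expect_gt(eb$p_high, 0.5)
  expect_lt(eb$m_min / 2^20, 0.01)

  expect_equal(overlap_threshold(exp(exp(1))), exp(1) + 1)
  expect_error(overlap_threshold(2), class = "tnet_domain_error")
  # above the threshold (with margin) a single product minimises entropy;
  # at delta_G = log M it does not
  M <- 2^20
  expect_equal(entropy_bound(M, overlap_threshold(M) + 2)$m_min, 1)
  expect_gt(entropy_bound(M, log(M))$m_min, 1)
})

test_that("max-specificity entropy dominates H_min, collapsing at high drive", {
  for (M in c(2^6, 2^10, 2^14)) {
    for (r in seq(0.1, 2, by = 0.1)) {
      dG <- r * log(M)
      h_spec <- templimits:::max_specificity_entropy(M, dG)
      eb <- entropy_bound(M, dG)
      expect_gte(h_spec, eb$H_min - 1e-12)
      if (dG >= log(M) + 2 * log(log(M))) {
        expect_equal(h_spec, eb$H_min, tolerance = 1e-9)
      }
    }
  }
})

test_that("log-space evaluation stays finite and monotone at astronomical M", {
  M <- 2^63
  g <- seq(0, 2 * log(M), length.out = 41)
  p <- specificity_bound(M, g)$p_max
  expect_true(all(is.finite(p)))
  expect_true(all(diff(p) >= 0))
  eb_lo <- entropy_bound(M, 0.25 * log(M))
  eb_hi <- entropy_bound(M, 1.5 * log(M))
  expect_true(is.finite(eb_lo$H_min) && is.finite(eb_hi$H_min))
  expect_gt(eb_lo$H_min, eb_hi$H_min)
  expect_equal(eb_hi$m_min, 1)
})

test_that("continuous-m relaxation is a (slightly weaker) lower bound", {
  for (M in c(100, 2^12)) {
    for (dG in c(1, 0.5 * log(M), log(M))) {
      eb <- entropy_bound(M, dG, continuous = TRUE)
      expect_lte(eb$H_continuous, eb$H_min + 1e-12)
      expect_equal(eb$H_min, entropy_bound(M, dG)$H_min)
    }
  }
  # bits conversion
  eb <- entropy_bound(256, 0, units = "bits")
  expect_equal(eb$H_min, 8)
})

test_that("sweep table is pointwise-consistent and shows the transition", {
  tab <- sweep_bounds(c(2^4, 2^10, 2^20), ratio_grid = c(0, 0.5, 1, 1.5))
  expect_named(tab, c("M", "ratio", "p_max", "Hmin_norm", "Hspec_norm",
                      "m_frac", "p_high"))
  for (i in seq_len(nrow(tab))) {
    dG <- tab$ratio[i] * log(tab$M[i])
    expect_equal(tab$p_max[i], specificity_bound(tab$M[i], dG)$p_max)
    expect_equal(tab$p_high[i], entropy_bound(tab$M[i], dG)$p_high)
  }
  # at delta_G = log M the bound is M/(2M - 1): it tends to 1/2 from above
  # as M grows
  at1 <- tab[tab$ratio == 1, ]
  ordered <- at1$p_max[order(at1$M)]
  expect_true(all(diff(ordered) < 0))
  expect_true(all(ordered > 0.5))
  expect_equal(at1$p_max[at1$M == 2^20], 0.5, tolerance = 1e-5)
  expect_true(all(tab$p_max[tab$ratio == 0] == 1 / tab$M[tab$ratio == 0]))
  # entropy bound per unit length is non-increasing in the drive
  for (M in unique(tab$M)) {
    expect_true(all(diff(tab$Hmin_norm[tab$M == M]) <= 1e-12))
  }
})

test_that("steady-state ensembles respect both closed-form bounds", {
  for (seed in c(6, 21)) {
    net <- make_saturating_network(6, g_U = 0, g_L = 3, epsilon = 1e-4,
                                   seed = seed)
    d <- product_distribution(solve_steady_state(net))
    dG <- pathway_bounds(net)$network_delta_G
    expect_lte(d$p_max, specificity_bound(6, dG)$p_max + 1e-9)
    expect_gte(d$H, entropy_bound(6, dG)$H_min - 1e-9)
  }
})
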