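test_that("single-edge equilibrium and unbiased two-product steady state", {
  nodes <- data.frame(id = c(NULLC, "Z"), kind = c("null", "product"))
  edges <- data.frame(from = NULLC, to = "Z", k_fwd = 2, k_rev = 1)
  net <- templating_network(nodes, edges)
  prof <- solve_steady_state(net)
  expect_equal(prof$concentration, 2)
  expect_equal(prof$concentration, exp(-net$edges$delta_g))

  # equal pathway free energies, unequal kinetics: p_X = p_Y = 1/2
  two <- make_two_product_network(9, 1, delta_g = 0.7)
  prof <- solve_steady_state(two)
  p <- product_distribution(prof)
  expect_equal(as.numeric(p$p["X"]), 0.5, tolerance = 1e-12)
})

test_that("direct solve agrees with long-time ODE integration", {
  net <- make_random_consistent_network(14, 5, 8, seed = 31)
  expect_equal(nrow(net$nodes), 20)
  prof <- solve_steady_state(net)
  t_end <- 1e6 / min(c(net$edges$k_fwd, net$edges$k_rev))
  tr <- integrate_transient(net, times = c(t_end / 2, t_end))
  ode_prof <- profile_at(tr, net, 2)
  expect_equal(ode_prof$concentration, prof$concentration, tolerance = 1e-6)
})

test_that("transients respect the kinetic short-time limit and the fixed point", {
  two <- make_two_product_network(9, 1, delta_g = 0)
  t_small <- 1e-6 / max(two$edges$k_fwd, two$edges$k_rev)
  tr <- integrate_transient(two, times = c(t_small, 1e3))
  early <- profile_at(tr, two, 1)
  p_early <- product_distribution(early)
  expect_equal(as.numeric(p_early$p["X"]), 0.9, tolerance = 1e-4)
  late <- profile_at(tr, two, 2)
  expect_equal(as.numeric(product_distribution(late)$p["X"]), 0.5,
               tolerance = 1e-9)

  # a network initialised at its steady state stays there
  net <- make_random_consistent_network(4, 2, 3, seed = 8)
  ss <- solve_steady_state(net)
  tr <- integrate_transient(net, times = c(0.5, 1, 5), initial = ss)
  for (i in 1:3) {
    expect_equal(profile_at(tr, net, i)$concentration, ss$concentration,
                 tolerance = 1e-8)
  }
  expect_error(integrate_transient(net, times = c(2, 1)),
               class = "tnet_domain_error")
})

test_that("fluxes, entropy production and stationarity bookkeeping", {
  # a single chain at steady state is at detailed balance
  ch <- chain_network(c(-1, 0.5, 0.2))
  fl <- edge_fluxes(ch, solve_steady_state(ch))
  expect_equal(fl$J_net, rep(0, 3), tolerance = 1e-12)
  expect_equal(attr(fl, "sigma"), 0, tolerance = 1e-12)

  # unequal pathway free energies drive a sustained cycle flux
  dia <- diamond_network(a = c(-1, -1), b = c(0.5, 0.5))
  fl <- edge_fluxes(dia, solve_steady_state(dia))
  expect_gt(attr(fl, "sigma"), 0)
  expect_gt(max(abs(fl$J_net)), 1e-3)

  # stationarity: zero net flux into every node
  for (seed in c(1, 12)) {
    net <- make_random_consistent_network(7, 3, 6, seed = seed)
    fl <- edge_fluxes(net, solve_steady_state(net))
    for (nd in net$nodes$id[net$nodes$kind != "null"]) {
      influx <- sum(fl$J_net[fl$to == nd]) - sum(fl$J_net[fl$from == nd])
      expect_lt(abs(influx), 1e-9 * max(1, max(abs(fl$J_fwd))))
    }
  }
})

test_that("Gamma ratios diagnose pseudo-equilibrium vs driven operation", {
  ch <- chain_network(c(-1, 0.5))
  prof <- solve_steady_state(ch)
  path <- enumerate_pathways(ch, "Z")[[1]]
  expect_equal(gamma_ratio(ch, prof, "Z", path), 1, tolerance = 1e-12)

  dia <- diamond_network(a = c(-1, -1), b = c(0.5, 0.5))
  prof <- solve_steady_state(dia)
  paths <- enumerate_pathways(dia, "Z")
  dgs <- vapply(paths, `[[`, numeric(1), "delta_g_S")
  g_u <- gamma_ratio(dia, prof, "Z", paths[[which.min(dgs)]])
  g_l <- gamma_ratio(dia, prof, "Z", paths[[which.max(dgs)]])
  # most favourable production pathway: Gamma >= 1; least favourable <= 1
  expect_gte(g_u, 1)
  expect_lte(g_l, 1)
})

test_that("the concentration-ratio identity holds at every steady state", {
  for (seed in c(3, 17, 29)) {
    net <- make_random_consistent_network(8, 3, 6, seed = seed)
    prof <- solve_steady_state(net)
    b <- pathway_bounds(net)
    prods <- b$products$species
    for (x in prods) for (y in setdiff(prods, x)) {
      expect_lt(abs(eq_identity_residual(net, prof, x, y, bounds = b)), 1e-9)
    }
  }
})

test_that("rescaling one edge's rates moves the state, not the bounds", {
  net <- make_random_consistent_network(6, 2, 4, seed = 13)
  b0 <- pathway_bounds(net)
  scaled <- net
  scaled$edges$k_fwd[3] <- scaled$edges$k_fwd[3] * 50
  scaled$edges$k_rev[3] <- scaled$edges$k_rev[3] * 50
  scaled <- templating_network(scaled$nodes, scaled$edges, scaled$meta)
  b1 <- pathway_bounds(scaled)
  expect_equal(b1$products$delta_g_U, b0$products$delta_g_U, tolerance = 1e-12)
  expect_equal(b1$products$delta_g_L, b0$products$delta_g_L, tolerance = 1e-12)
  # the steady state may move but stays inside the (unchanged) interval
  prof <- solve_steady_state(scaled)
  cc <- setNames(prof$concentration, prof$node)
  rows <- rbind(b1$products, b1$intermediates)
  expect_true(all(cc[rows$species] >= rows$c_L * (1 - 1e-7) &
                    cc[rows$species] <= rows$c_U * (1 + 1e-7)))
})
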