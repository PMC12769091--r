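test_that("edge free energies follow local detailed balance", {
  expect_equal(edge_free_energy(1, 1), 0)
  expect_equal(edge_free_energy(exp(1), 1), -1)
  expect_equal(edge_free_energy(2, 1), -log(2))
  expect_equal(edge_free_energy(1, 2), log(2))
  # antisymmetry under argument swap, vectorised
  kf <- c(0.3, 2, 17); kr <- c(1.1, 5, 0.02)
  expect_equal(edge_free_energy(kf, kr), -edge_free_energy(kr, kf))
  expect_error(edge_free_energy(0, 1), class = "tnet_domain_error")
  expect_error(edge_free_energy(1, -2), class = "tnet_domain_error")
})

test_that("construction validates structure and derives delta_g", {
  nodes <- data.frame(id = c(NULLC, "Z"), kind = c("null", "product"))
  edges <- data.frame(from = NULLC, to = "Z", k_fwd = 2, k_rev = 1)
  net <- templating_network(nodes, edges)
  expect_equal(net$M, 1L)
  expect_equal(net$edges$delta_g, -log(2))

  # every reaction must be reversible
  expect_error(
    templating_network(nodes, data.frame(from = NULLC, to = "Z", k_fwd = 2)),
    class = "tnet_parse_error")
  expect_error(
    templating_network(nodes, data.frame(from = NULLC, to = "Z",
                                         k_fwd = 2, k_rev = 0)),
    class = "tnet_validation_error")
  # exactly one null complex
  expect_error(
    templating_network(
      data.frame(id = c("a", "b", "Z"), kind = c("null", "null", "product")),
      data.frame(from = c("a", "b"), to = "Z", k_fwd = 1, k_rev = 1)),
    class = "tnet_validation_error")
  # connectivity from the null complex
  expect_error(
    templating_network(
      data.frame(id = c(NULLC, "Z", "W"),
                 kind = c("null", "product", "product")),
      data.frame(from = NULLC, to = "Z", k_fwd = 1, k_rev = 1)),
    class = "tnet_connectivity_error")
  # no product-product reactions
  expect_error(
    templating_network(
      data.frame(id = c(NULLC, "Z", "W"),
                 kind = c("null", "product", "product")),
      data.frame(from = c(NULLC, "Z"), to = c("Z", "W"),
                 k_fwd = 1, k_rev = 1)),
    class = "tnet_validation_error")
})

test_that("JSON round trip preserves every field at full precision", {
  net <- make_saturating_network(4, g_U = -1.25, g_L = 3.7, epsilon = 0.37,
                                 seed = 11)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f)
  back <- load_network(f)
  expect_identical(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges, tolerance = 0)
  expect_equal(back$M, net$M)
  # and a second round trip is the identity on the file content
  f2 <- withr::local_tempfile(fileext = ".json")
  write_network(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("load_network rejects malformed documents naming the field", {
  expect_error(load_network('{"edges": []}'), "nodes",
               class = "tnet_parse_error")
  expect_error(load_network('{"nodes": []}'), "edges",
               class = "tnet_parse_error")
  doc <- paste0('{"nodes":[{"id":"n","kind":"null"},',
                '{"id":"Z","kind":"product"}],',
                '"edges":[{"from":"n","to":"Z","k_fwd":2}]}')
  expect_error(load_network(doc), "k_rev", class = "tnet_parse_error")
  expect_error(load_network("not json {"), class = "tnet_parse_error")
  net <- load_network(paste0(
    '{"nodes":[{"id":"n","kind":"null"},{"id":"Z","kind":"product"}],',
    '"edges":[{"from":"n","to":"Z","k_fwd":2,"k_rev":1}]}'))
  expect_equal(net$edges$delta_g, -log(2))
})

test_that("rate/energy invariants hold on generated networks", {
  for (seed in 1:5) {
    net <- make_random_consistent_network(6, 3, 5, seed = seed)
    # exp(-delta_g) * k_rev == k_fwd
    expect_equal(exp(-net$edges$delta_g) * net$edges$k_rev, net$edges$k_fwd,
                 tolerance = 1e-12)
    # swapping every edge direction negates every delta_g
    swapped <- templating_network(
      net$nodes,
      data.frame(from = net$edges$to, to = net$edges$from,
                 k_fwd = net$edges$k_rev, k_rev = net$edges$k_fwd,
                 chem_work = -net$edges$chem_work))
    expect_equal(swapped$edges$delta_g, -net$edges$delta_g)
    expect_true(attr(validate_thermodynamics(net), "pass"))
  }
})

test_that("validation flags a perturbed rate with the forced residual", {
  net <- make_two_product_network(2, 1, 0.5)
  expect_true(attr(validate_thermodynamics(net), "pass"))
  net$edges$k_fwd[1] <- 2 * net$edges$k_fwd[1]
  rep <- validate_thermodynamics(net)
  expect_false(attr(rep, "pass"))
  bad <- rep[!is.na(rep$pass) & !rep$pass, ]
  expect_true(all(abs(abs(bad$residual) - log(2)) < 1e-12))
})

test_that("product symmetry is detected and asymmetry flagged", {
  net <- make_symmetric_network(
    4, list(list(length = 2, delta_g = -2), list(length = 2, delta_g = 1)),
    seed = 5)
  rep <- check_product_symmetry(net)
  expect_true(attr(rep, "symmetric"))
  expect_equal(nrow(rep), choose(4, 2))

  # shift one pathway free energy of Z1 by +1 k_BT (rates and bookkeeping
  # updated together): all pairs involving Z1 become inequivalent
  shifted <- net
  i <- which(shifted$edges$to == "Z1")[1]
  shifted$edges$k_rev[i] <- shifted$edges$k_rev[i] * exp(1)
  shifted$edges$chem_work[i] <- shifted$edges$chem_work[i] + 1
  shifted <- templating_network(shifted$nodes, shifted$edges, shifted$meta)
  expect_true(attr(validate_thermodynamics(shifted), "pass"))
  rep2 <- check_product_symmetry(shifted)
  expect_false(attr(rep2, "symmetric"))
  bad <- rep2[!rep2$equivalent, ]
  expect_true(all(bad$product_a == "Z1" | bad$product_b == "Z1"))
  expect_true(all(rep2$equivalent[rep2$product_a != "Z1" &
                                    rep2$product_b != "Z1"]))

  # single product: vacuously symmetric, empty pair list
  single <- chain_network(c(-1, 0.5))
  rep3 <- check_product_symmetry(single)
  expect_true(attr(rep3, "symmetric"))
  expect_equal(nrow(rep3), 0L)
})
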