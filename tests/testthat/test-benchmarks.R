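test_that("closed-form moments satisfy their internal identities", {
  set.seed(21)
  for (i in 1:25) {
    g <- runif(1, -0.95, 0.95)
    # g2 must lie between g^2 and 1 for a valid angular distribution
    g2 <- runif(1, g^2, 1)
    mus <- runif(1, 0.2, 5)
    for (k in 1:4) {
      m <- infinite_moments(k, g, g2, mus)
      expect_equal(m[["d2"]], m[["z2"]] + m[["rho2"]])
      expect_equal(m[["rho2"]], m[["x2"]] + m[["y2"]])
      expect_equal(m[["x"]], 0)
      expect_equal(m[["y"]], 0)
      expect_gte(m[["x2"]], 0)
      # the general-order formulas must agree with the order-specific ones
      expect_equal(m[["z"]], mean_z_any_order(k, g, mus))
      expect_equal(m[["d2"]], mean_d2_any_order(k, g, mus), tolerance = 1e-12)
      expect_equal(m[["l"]], pathlength_moment(k, 1, mus))
      expect_equal(m[["l2"]], pathlength_moment(k, 2, mus))
    }
  }
})

test_that("anisotropic formulas reduce to the isotropic special case", {
  for (k in 1:4) {
    m <- infinite_moments(k, g = 0, g2 = 1 / 3, mus = 2)
    iso <- isotropic_second_moments(k, mus = 2)
    expect_equal(m[["x2"]], iso$x2, tolerance = 1e-12)
    expect_equal(m[["z2"]], iso$z2, tolerance = 1e-12)
    expect_equal(m[["rho2"]], iso$rho2, tolerance = 1e-12)
    expect_equal(m[["d2"]], iso$d2, tolerance = 1e-12)
  }
  # isotropic identities at any order: z2 - x2 = 2/mus^2, d2 = 2k/mus^2
  k <- 1:20
  iso <- isotropic_second_moments(k, mus = 1.5)
  expect_equal(iso$z2 - iso$x2, rep(2 / 1.5^2, 20))
  expect_equal(iso$rho2, 2 * iso$x2)
  expect_equal(iso$d2, 2 * k / 1.5^2)
  # d2 limit g -> 0 agrees with the isotropic value
  expect_equal(mean_d2_any_order(7, g = 0, mus = 1), 14)
  expect_equal(mean_d2_any_order(7, g = 1e-9, mus = 1), 14, tolerance = 1e-6)
})

test_that("mean z approaches the transport mean free path at high order", {
  expect_equal(mean_z_any_order(1e6, g = 0.9, mus = 1), 10, tolerance = 1e-9)
  expect_equal(mean_z_any_order(5, g = 0, mus = 1), 1)
  expect_equal(pathlength_moment(1, 3, mus = 2), 6 / 8)
})

test_that("invariant radiance and fluence scale with the squared index ratio", {
  expect_equal(invariant_radiance(1, 1), 1 / pi)
  expect_equal(invariant_radiance(2, 1), 4 / pi)
  expect_equal(invariant_radiance(1, 2), 1 / (4 * pi))
  expect_equal(invariant_fluence(1, 1), 4)
  expect_equal(invariant_fluence(2, 1), 16)
  expect_equal(invariant_fluence(1.4, 1.2) / invariant_radiance(1.4, 1.2),
               4 * pi)
  # slab specialization of the mean path length: 4 (n/ne)^2 V / Sigma
  expect_equal(invariant_layer_pathlength(1, 1, Vj = 0.05, Sigma = 1), 0.2)
  expect_equal(slab_layer_pathlength(0.1, 1, 1), 0.2)
  expect_equal(slab_layer_pathlength(0.1, 2, 1), 0.8)
  expect_equal(slab_layer_pathlength(10, 1.3, 1.3), 20)
})

test_that("theta_max matches an independent ray-tracing oracle", {
  # homogeneous high-index slab: arcsin(ne/n)
  sl <- layered_slab(s = 10, n = 1.5, mus = 0, ne = 1)
  expect_equal(theta_max(sl, 1), asin(1 / 1.5), tolerance = 1e-12)
  # any layer with nj <= ne keeps the full hemisphere
  sl2 <- layered_slab(s = c(1, 1), n = c(1.2, 1.4), mus = 0, ne = 2)
  expect_equal(theta_max(sl2), c(pi / 2, pi / 2))
  # random stacks against the Snell-invariant tracing oracle
  set.seed(22)
  for (i in 1:10) {
    M <- sample(2:6, 1)
    n <- runif(M, 1, 2)
    ne <- runif(1, 1, 2)
    sl3 <- layered_slab(s = rep(1, M), n = n, mus = 0, ne = ne)
    for (j in seq_len(M)) {
      # compare on the sine scale: asin amplifies grid error near pi/2
      expect_equal(sin(theta_max(sl3, j)), sin(theta_max_ray_oracle(n, ne, j)),
                   tolerance = 1e-3)
    }
  }
  expect_error(theta_max(sl, 2), "range")
})

test_that("trapped-regime solutions carry the (1 - cos theta_max) factor", {
  # index-matched: reduces to the scattering-case invariants exactly
  sl <- layered_slab(s = 10, n = 1, mus = 0, ne = 1)
  sol <- nonscattering_solutions(sl, 1)
  expect_equal(sol$theta_max, pi / 2)
  expect_equal(sol$fluence, invariant_fluence(1, 1))
  expect_equal(sol$pathlength, slab_layer_pathlength(10, 1, 1))
  # homogeneous n = 1.5 slab
  sl2 <- layered_slab(s = 10, n = 1.5, mus = 0, ne = 1)
  sol2 <- nonscattering_solutions(sl2, 1)
  expect_equal(sol2$pathlength, 2 * 10 * 1.5^2 * (1 - cos(asin(2 / 3))))
  expect_equal(sol2$fluence / (4 * pi * sol2$radiance_level),
               1 - sol2$cos_theta_max)
  # refuses scattering slabs
  sl3 <- layered_slab(s = 10, n = 1.5, mus = 1, ne = 1)
  expect_error(nonscattering_solutions(sl3, 1), "non-scattering")
})

test_that("benchmark_table assembles the per-order values in long form", {
  tb <- benchmark_table(hg_phase(0.9), mus = 1)
  expect_equal(nrow(tb), 40)
  expect_equal(tb$benchmark[tb$k == 3 & tb$quantity == "z"], 2.71)
  expect_equal(tb$benchmark[tb$k == 4 & tb$quantity == "l2"], 20)
})
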