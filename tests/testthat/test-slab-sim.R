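test_that("Fresnel reflectance reproduces its closed-form special cases", {
  expect_equal(fresnel_reflectance(1, 1.5, 1), ((1 - 1.5) / (1 + 1.5))^2)
  expect_equal(fresnel_reflectance(1.3, 1.3, c(0.2, 0.7, 1)), rep(0, 3))
  # total internal reflection beyond the critical angle
  expect_equal(fresnel_reflectance(1.5, 1, cos(60 * pi / 180)), 1)
  expect_error(fresnel_reflectance(1, 1.5, 0), "cos_i")
  # reciprocity: R(ni->nt, theta_i) = R(nt->ni, theta_t)
  set.seed(41)
  for (i in 1:20) {
    ni <- runif(1, 1, 2); nt <- runif(1, 1, 2)
    ci <- runif(1, 0.05, 1)
    st <- ni / nt * sqrt(1 - ci^2)
    if (st < 1) {
      expect_equal(fresnel_reflectance(ni, nt, ci),
                   fresnel_reflectance(nt, ni, sqrt(1 - st^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("refraction conserves the Snell invariant and is reversible", {
  expect_equal(refract(c(0, 0, 1), 1, 2), c(0, 0, 1))
  d <- c(sin(pi / 6), 0, cos(pi / 6))
  out <- refract(d, 1, 2)
  expect_equal(out[1], 0.25, tolerance = 1e-12)  # sin(theta_t) = 0.25
  set.seed(42)
  for (i in 1:20) {
    ni <- runif(1, 1, 2); nt <- runif(1, 1, 2)
    raw <- rnorm(3); raw[3] <- abs(raw[3]) + 0.7
    d0 <- raw / sqrt(sum(raw^2))
    si <- sqrt(1 - d0[3]^2)
    if (ni / nt * si < 1) {
      d1 <- refract(d0, ni, nt)
      expect_equal(nt * sqrt(1 - d1[3]^2), ni * si, tolerance = 1e-12)
      expect_equal(refract(d1, nt, ni), d0, tolerance = 1e-9)
    }
  }
  expect_error(refract(c(sin(1.2), 0, cos(1.2)), 1.8, 1), "internal")
})

test_that("every photon exits a non-absorbing slab and tallies are reproducible", {
  sl <- slab_profile("up4")
  t2 <- run_step2(sl, 2e4, seed = 43)
  expect_equal(t2$n_reflected + t2$n_transmitted, 2e4)
  expect_equal(t2$n_aborted, 0)
  expect_true(all(t2$rad_sum >= 0))
  t2b <- run_step2(sl, 2e4, seed = 43)
  expect_identical(t2$L_sum, t2b$L_sum)
  expect_identical(t2$rad_sum, t2b$rad_sum)
})

test_that("index-matched slabs give mean total path 2Z for any scattering", {
  # ballistic case: <L> = 2Z exactly in expectation (cosine-weighted 1/cos)
  sl0 <- layered_slab(s = 10, n = 1, mus = 0, ne = 1)
  pl0 <- estimate_pathlengths(run_step2(sl0, 2e5, seed = 44))
  expect_equal(pl0$mean[pl0$layer == "total"], 20, tolerance = 0.03)
  # scattering cases, one and several layers
  for (mus in c(0.5, 2)) {
    sl <- layered_slab(s = c(4, 6), n = 1, mus = mus, ne = 1)
    pl <- estimate_pathlengths(run_step2(sl, 1e5, seed = 45))
    tot <- pl[pl$layer == "total", ]
    expect_within_se(tot$mean, tot$se, 20)
  }
})

test_that("fluence and path-length invariants hold across scattering sweeps", {
  # the invariant depends only on (nj/ne); mus and phase must not matter
  bench <- invariant_fluence(slab_indices(slab_profile("up4")), 1)
  for (cfg in list(list(mus = 0.5, ph = hg_phase(0)),
                   list(mus = 2, ph = hg_phase(0.9)),
                   list(mus = 1, ph = rayleigh_phase()))) {
    sl <- slab_profile("up4", mus = cfg$mus, phase = cfg$ph)
    fl <- estimate_fluence(run_step2(sl, 2e5, seed = 46))
    expect_true(all(abs(fl$estimate - bench) < 4 * fl$se))
  }
})

test_that("a symmetric slab yields symmetric layer estimates", {
  sl <- layered_slab(s = rep(2, 4), n = c(1.3, 1.6, 1.6, 1.3), mus = 1,
                     ne = 1)
  pl <- estimate_pathlengths(run_step2(sl, 2e5, seed = 47))
  d <- abs(pl$mean[1] - pl$mean[4])
  expect_lt(d, 4 * sqrt(pl$se[1]^2 + pl$se[4]^2))
  d2 <- abs(pl$mean[2] - pl$mean[3])
  expect_lt(d2, 4 * sqrt(pl$se[2]^2 + pl$se[3]^2))
})

test_that("radiance integrates back to the fluence estimate exactly", {
  sl <- slab_profile("dw4")
  t2 <- run_step2(sl, 5e4, seed = 48, grid = angular_grid(90))
  rad <- estimate_radiance(t2)
  fl <- estimate_fluence(t2)
  for (j in 1:4) {
    sub <- rad[rad$layer == j, ]
    expect_equal(sum(sub$estimate * t2$grid$solid_angle), fl$estimate[j],
                 tolerance = 1e-9)
  }
  # angular grid covers the full sphere
  expect_equal(sum(angular_grid(37)$solid_angle), 4 * pi, tolerance = 1e-9)
})

test_that("trapped directions in a non-scattering high-index slab stay empty", {
  sl <- slab_profile("up4", mus = 0)
  t2 <- run_step2(sl, 1e5, seed = 49)
  rad <- estimate_radiance(t2)
  thm <- theta_max(sl)
  for (j in 1:4) {
    sub <- rad[rad$layer == j, ]
    # bins fully outside the populated support |cos theta| >= cos(theta_max)
    out <- sub$theta > thm[j] & sub$theta < pi - thm[j] &
      abs(sub$theta - thm[j]) > pi / 180 &
      abs(sub$theta - (pi - thm[j])) > pi / 180
    expect_true(all(sub$estimate[out] == 0))
    # and the populated plateau sits at the invariant level
    lev <- invariant_radiance(slab_indices(sl)[j], 1)
    inn <- sub$theta < thm[j] - pi / 90 & sub$se > 0
    expect_true(all(abs(sub$estimate[inn] - lev) < 5 * sub$se[inn]))
  }
})

test_that("the event cap aborts pathological photons and is reported", {
  sl <- slab_profile("up4")
  t2 <- run_step2(sl, 500, seed = 50, event_cap = 3)
  expect_gt(t2$n_aborted, 0)
})
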