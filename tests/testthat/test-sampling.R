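test_that("free-path sampler inverts the exponential law and matches its moments", {
  # closed-form spot checks
  expect_equal(sample_free_path(1, exp(-1)), 1.0)
  expect_equal(sample_free_path(2, exp(-1)), 0.5)
  # moments: <l^m> = m! / mus^m
  set.seed(11)
  for (mus in c(1, 2.5)) {
    l <- sample_free_path(mus, runif(2e5))
    m1 <- mc_mean_se(l)
    m2 <- mc_mean_se(l^2)
    expect_within_se(m1["mean"], m1["se"], 1 / mus)
    expect_within_se(m2["mean"], m2["se"], 2 / mus^2)
  }
  expect_error(sample_free_path(0, 0.5), "mus")
  expect_error(sample_free_path(1, 0), "inside")
  expect_error(sample_free_path(1, 1), "inside")
})

test_that("HG cosine sampler hits its endpoints and exact moments", {
  expect_equal(sample_hg_cosine(0, 0.5), 0)
  expect_equal(sample_hg_cosine(0.9, 0), -1)
  set.seed(12)
  for (g in c(0, 0.5, 0.9)) {
    ct <- sample_hg_cosine(g, runif(2e5))
    expect_true(all(abs(ct) <= 1))
    m1 <- mc_mean_se(ct)
    m2 <- mc_mean_se(ct^2)
    expect_within_se(m1["mean"], m1["se"], g)
    expect_within_se(m2["mean"], m2["se"], (1 + 2 * g^2) / 3)
  }
  expect_error(sample_hg_cosine(1, 0.5), "g")
})

test_that("Rayleigh cosine sampler matches its CDF and a rejection oracle", {
  expect_equal(sample_rayleigh_cosine(0.5), 0)
  expect_equal(sample_rayleigh_cosine(1), 1)
  expect_equal(sample_rayleigh_cosine(0), -1)
  set.seed(13)
  x <- sample_rayleigh_cosine(runif(1e5))
  m2 <- mc_mean_se(x^2)
  expect_within_se(m2["mean"], m2["se"], 0.4)
  # distributional agreement with an independent rejection sampler
  y <- rayleigh_rejection_oracle(1e5)
  ks <- suppressWarnings(stats::ks.test(x, y))
  expect_gt(ks$p.value, 0.01)
})

test_that("phase specs expose the exact (g, g2) pairs", {
  expect_equal(phase_moments(hg_phase(0)), c(g = 0, g2 = 1 / 3))
  expect_equal(phase_moments(hg_phase(0.9)), c(g = 0.9, g2 = 2.62 / 3))
  expect_equal(phase_moments(rayleigh_phase()), c(g = 0, g2 = 0.4))
  # HG(0) and Rayleigh share g = 0 but differ in g2
  expect_false(phase_moments(hg_phase(0))[["g2"]] ==
                 phase_moments(rayleigh_phase())[["g2"]])
  expect_error(hg_phase(1.2), "g")
})

test_that("direction rotation preserves the scattering cosine and unit norm", {
  expect_equal(as.numeric(scatter_direction(c(0, 0, 1), 1, 1.3)), c(0, 0, 1))
  expect_equal(as.numeric(scatter_direction(c(0, 0, 1), 0, 0)), c(1, 0, 0),
               tolerance = 1e-12)
  set.seed(14)
  n <- 2e4
  raw <- matrix(rnorm(3 * n), ncol = 3)
  dir <- raw / sqrt(rowSums(raw^2))
  ct <- runif(n, -1, 1)
  out <- scatter_direction(dir, ct, runif(n, 0, 2 * pi))
  expect_true(all(abs(rowSums(out^2) - 1) < 1e-9))
  expect_true(all(abs(rowSums(out * dir) - ct) < 1e-9))
  # azimuthal symmetry: transverse component relative to dir averages to zero
  trans <- out - ct * dir
  for (k in 1:3) {
    m <- mc_mean_se(trans[, k])
    expect_within_se(m["mean"], m["se"], 0)
  }
  # near-axial degenerate branch stays finite and exact
  nearz <- scatter_direction(c(0, 0, 1 - 1e-15), 0.3, 2.1)
  expect_true(all(is.finite(nearz)))
  expect_error(scatter_direction(c(0, 0, 2), 0.5, 0), "unit")
})

test_that("Lambertian launch directions are cosine-weighted about the normal", {
  set.seed(15)
  n <- 2e5
  d <- sample_lambertian_direction(runif(n), runif(n))
  expect_true(all(d[, 3] >= 0))
  m <- mc_mean_se(d[, 3])
  expect_within_se(m["mean"], m["se"], 2 / 3)
  # cos^2(theta) is uniform, so P(cos > 1/sqrt(2)) = 1/2
  frac <- mc_mean_se(as.numeric(d[, 3] > 1 / sqrt(2)))
  expect_within_se(frac["mean"], frac["se"], 0.5)
  # u1 = 1 gives normal incidence
  expect_equal(as.numeric(sample_lambertian_direction(1, 0.3)), c(0, 0, 1),
               tolerance = 1e-12)
  # works for a tilted normal too
  nrm <- c(1, 1, 1) / sqrt(3)
  d2 <- sample_lambertian_direction(runif(n), runif(n), inward_normal = nrm)
  m2 <- mc_mean_se(as.numeric(d2 %*% nrm))
  expect_within_se(m2["mean"], m2["se"], 2 / 3)
})
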