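#' Normalized deviation of a Monte Carlo estimate from its benchmark
#'
#' The one-sample t statistic \eqn{t = (\hat m - m_{RTE}) / SE(\hat m)}
#' comparing a Monte Carlo mean against the exact radiative-transfer value.
#' Quantities with zero variance (structurally exact tallies) have no t
#' statistic and must be compared by exact equality instead.
#'
#' @param estimate Monte Carlo estimate(s).
#' @param se Standard error(s) of the estimate, > 0.
#' @param benchmark Exact benchmark value(s).
#' @return Normalized deviation(s).
#' @export
normalized_deviation <- function(estimate, se, benchmark) {
  if (any(se <= 0)) {
    stop("se must be > 0; zero-variance quantities are compared for exact equality")
  }
  (estimate - benchmark) / se
}

#' One-sample t-test of an estimate against an exact benchmark
#'
#' Two-sided test of the null hypothesis that the Monte Carlo estimator is
#' unbiased for the benchmark.  For n > 1e4 the t distribution is
#' numerically indistinguishable from the standard normal, so the normal
#' tail is used; the rejection rule is the strict inequality p < alpha.
#'
#' @inheritParams normalized_deviation
#' @param n Sample size (number of photons), >= 2.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param label Optional label(s) for the tested quantity.
#' @return Data frame with columns `label`, `estimate`, `se`, `benchmark`,
#'   `n`, `t`, `p`, `reject`.
#' @export
one_sample_t <- function(estimate, se, benchmark, n, alpha = 0.05,
                         label = NA_character_) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1, all(n >= 2))
  t <- normalized_deviation(estimate, se, benchmark)
  n <- rep_len(n, length(t))
  p <- ifelse(n > 1e4, 2 * pnorm(-abs(t)), 2 * pt(-abs(t), df = n - 1))
  data.frame(label = rep_len(as.character(label), length(t)),
             estimate = estimate, se = se, benchmark = benchmark,
             n = n, t = t, p = p, reject = p < alpha)
}

#' Run the two-step verification
#'
#' Step 1 runs the infinite-medium simulator and tests every tallied moment
#' (orders 1..`k_max`) against the closed-form benchmarks; the transverse
#' first moments are tested against zero, and quantities that are
#' structurally exact at the first order (x, y and their squares, where the
#' pencil beam fixes the geometry, and the identity l1 = z1) are checked by
#' exact equality.  For orders above 4 the benchmarks cover the mean z, the
#' mean square distance, the path-length moments for every phase function,
#' and the full second-moment set for isotropic scattering.
#'
#' Step 2 runs the slab simulator and tests the per-layer fluence rate, the
#' per-layer and total mean path lengths and, optionally, the per-bin
#' radiance against the Lambertian-illumination invariants, switching to the
#' trapped-regime solutions when the slab is entirely non-scattering.  A run
#' with any aborted photon is marked failed.
#'
#' No multiple-testing correction is applied: with `m` tests at level
#' `alpha` about `alpha * m` false rejections are expected in a correct
#' code, and the report prints that expectation alongside the observed
#' count.
#'
#' @param step 1 or 2.
#' @param mus,phase,n_photons,k_max,seed Step-1 configuration (see
#'   [run_step1()]).
#' @param slab,grid Step-2 configuration (see [run_step2()]).
#' @param alpha Significance level for the individual t-tests.
#' @param radiance For step 2: also t-test each populated (layer, angle bin)
#'   radiance estimate (default FALSE; bins are many and slow to print).
#' @param radiance_layers Layers whose radiance is tested (default: all).
#' @param ... Passed to the simulator (e.g. the `.defect` fixtures).
#' @return Object of class `verification_report`: list with `step`,
#'   `records` (t-test rows), `exact` (exact-equality rows), `summary`, the
#'   configuration echo and the underlying tally object.
#' @export
run_verification <- function(step, mus = 1, phase = hg_phase(0),
                             n_photons = 1e6, k_max = 4, seed = 1,
                             slab = NULL, grid = angular_grid(180),
                             alpha = 0.05, radiance = FALSE,
                             radiance_layers = NULL, ...) {
  stopifnot(step %in% c(1, 2))
  if (step == 1) {
    tally <- run_step1(mus = mus, phase = phase, n_photons = n_photons,
                       k_max = k_max, seed = seed, ...)
    out <- verify_step1(tally, alpha)
  } else {
    if (is.null(slab)) stop("step 2 requires a slab description")
    tallies <- run_step2(slab = slab, n_photons = n_photons, grid = grid,
                         seed = seed, ...)
    out <- verify_step2(tallies, alpha, radiance = radiance,
                        radiance_layers = radiance_layers)
  }
  out
}

# step-1 benchmark for one (k, quantity); NA when no closed form is available
step1_benchmark <- function(k, quantity, g, g2, mus, isotropic) {
  if (quantity %in% c("x", "y")) return(0)
  if (quantity == "l") return(pathlength_moment(k, 1, mus))
  if (quantity == "l2") return(pathlength_moment(k, 2, mus))
  if (quantity == "d2") return(mean_d2_any_order(k, g, mus))
  if (quantity == "z") return(mean_z_any_order(k, g, mus))
  if (k <= 4) return(infinite_moments(k, g, g2, mus)[[quantity]])
  if (isotropic) {
    q <- if (quantity == "y2") "x2" else quantity
    return(isotropic_second_moments(k, mus)[[q]])
  }
  NA_real_
}

verify_step1 <- function(tally, alpha = 0.05) {
  cfg <- tally$config
  m <- phase_moments(cfg$phase)
  isotropic <- cfg$phase$kind == "hg" && cfg$phase$g == 0
  est <- moment_estimates(tally)
  est$benchmark <- mapply(step1_benchmark, est$k, est$quantity,
                          MoreArgs = list(g = m[["g"]], g2 = m[["g2"]],
                                          mus = cfg$mus,
                                          isotropic = isotropic))
  # structurally exact quantities: zero variance by construction
  exact_idx <- est$k == 1 & est$quantity %in% c("x", "y", "x2", "y2", "rho2")
  exact <- est[exact_idx, ]
  exact$pass <- exact$mean == exact$benchmark & exact$se == 0
  # per-photon identity l1 = z1 (pencil beam along z): sums must agree exactly
  exact <- rbind(exact, data.frame(
    k = 1, quantity = "l1==z1", mean = tally$sum["l", 1] / tally$n,
    se = 0, rel_se = NA_real_, n = tally$n,
    benchmark = tally$sum["z", 1] / tally$n,
    pass = tally$sum["l", 1] == tally$sum["z", 1] &&
      tally$sumsq["l", 1] == tally$sumsq["z", 1]
  ))
  testable <- est[!exact_idx & !is.na(est$benchmark), ]
  rec <- one_sample_t(testable$mean, testable$se, testable$benchmark,
                      n = testable$n, alpha = alpha,
                      label = paste0(testable$quantity, "[k=", testable$k, "]"))
  rec <- cbind(rec, k = testable$k, quantity = testable$quantity)
  new_verification_report(step = 1, records = rec, exact = exact,
                          alpha = alpha, config = cfg, tally = tally,
                          n_aborted = 0)
}

# exact populated fraction of an angular bin [lo, hi] for trapped-regime
# support theta <= th_max or theta >= pi - th_max (symmetric support)
bin_support_fraction <- function(lo, hi, th_max) {
  # solid angle ~ cos(lo) - cos(hi); overlap with [0, th_max]
  ov1 <- max(0, cos(min(lo, th_max)) - cos(min(hi, th_max)))
  # overlap with [pi - th_max, pi]
  lo2 <- max(lo, pi - th_max)
  ov2 <- max(0, cos(min(lo2, hi)) - cos(hi))
  (ov1 + ov2) / (cos(lo) - cos(hi))
}

verify_step2 <- function(tallies, alpha = 0.05, radiance = FALSE,
                         radiance_layers = NULL) {
  slab <- tallies$slab
  s <- slab_thicknesses(slab)
  nidx <- slab_indices(slab)
  M <- length(s)
  trapped <- all(slab_mus(slab) == 0)
  supp <- if (trapped) 1 - cos(theta_max(slab)) else rep(1, M)

  fl <- estimate_fluence(tallies)
  fl_bench <- invariant_fluence(nidx, slab$ne) * supp
  rec_fl <- one_sample_t(fl$estimate, fl$se, fl_bench, n = tallies$n,
                         alpha = alpha,
                         label = paste0("fluence[layer=", seq_len(M), "]"))

  pl <- estimate_pathlengths(tallies)
  pl_bench <- c(slab_layer_pathlength(s, nidx, slab$ne) * supp,
                sum(slab_layer_pathlength(s, nidx, slab$ne) * supp))
  rec_pl <- one_sample_t(pl$mean, pl$se, pl_bench, n = tallies$n,
                         alpha = alpha,
                         label = paste0("pathlength[layer=", pl$layer, "]"))

  exact <- NULL
  rec_rad <- NULL
  if (radiance) {
    if (is.null(radiance_layers)) radiance_layers <- seq_len(M)
    rad <- estimate_radiance(tallies, layers = radiance_layers)
    grid <- tallies$grid
    lev <- invariant_radiance(nidx, slab$ne)
    bins <- match(rad$theta, grid$centers)
    if (trapped) {
      thm <- theta_max(slab)
      frac <- mapply(function(j, b) {
        bin_support_fraction(grid$edges[b], grid$edges[b + 1], thm[j])
      }, rad$layer, bins)
    } else {
      frac <- rep(1, nrow(rad))
    }
    rad$benchmark <- lev[rad$layer] * frac
    # bins wholly outside the populated support must be exactly empty
    empty <- frac == 0
    exact <- if (any(empty)) {
      data.frame(label = paste0("radiance[layer=", rad$layer[empty],
                                ",theta=", round(rad$theta_deg[empty]),
                                "deg]"),
                 estimate = rad$estimate[empty],
                 benchmark = rep(0, sum(empty)),
                 pass = rad$estimate[empty] == 0)
    } else {
      NULL
    }
    tb <- rad[!empty & rad$se > 0, ]
    if (nrow(tb) > 0) {
      rec_rad <- one_sample_t(tb$estimate, tb$se, tb$benchmark, n = tallies$n,
                              alpha = alpha,
                              label = paste0("radiance[layer=", tb$layer,
                                             ",theta=", round(tb$theta_deg),
                                             "deg]"))
    }
  }
  rec <- rbind(rec_fl, rec_pl,
               if (!is.null(rec_rad)) rec_rad)
  new_verification_report(step = 2, records = rec, exact = exact,
                          alpha = alpha, config = tallies$config,
                          tally = tallies, n_aborted = tallies$n_aborted)
}

new_verification_report <- function(step, records, exact, alpha, config,
                                    tally, n_aborted) {
  tested <- nrow(records)
  rejected <- sum(records$reject)
  exact_fail <- if (!is.null(exact) && nrow(exact) > 0) sum(!exact$pass) else 0
  structure(list(
    step = step,
    records = records,
    exact = exact,
    alpha = alpha,
    summary = list(tested = tested, rejected = rejected,
                   expected_rejections = alpha * tested,
                   exact_checks = if (is.null(exact)) 0 else nrow(exact),
                   exact_failures = exact_fail,
                   n_aborted = n_aborted,
                   failed = n_aborted > 0 | exact_fail > 0),
    config = config,
    tally = tally
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Step-%d verification report (alpha = %g)\n", x$step, x$alpha))
  cat(sprintf("  t-tests: %d tested, %d rejected (expected ~%.1f false rejections)\n",
              s$tested, s$rejected, s$expected_rejections))
  if (s$exact_checks > 0) {
    cat(sprintf("  exact-equality checks: %d, failures: %d\n",
                s$exact_checks, s$exact_failures))
  }
  if (s$n_aborted > 0) {
    cat(sprintf("  WARNING: %g photon(s) aborted at the event cap -> run FAILED\n",
                s$n_aborted))
  }
  cat(sprintf("  max |t| = %.3f; share of |t| < 2: %.1f%%\n",
              max(abs(x$records$t)), 100 * mean(abs(x$records$t) < 2)))
  cat(if (s$failed) "  RESULT: FAILED\n" else "  RESULT: consistent with the benchmarks\n")
  invisible(x)
}

#' Write a verification report as JSON
#'
#' @param report A `verification_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "verification_report"))
  out <- list(step = report$step, alpha = report$alpha,
              summary = report$summary, records = report$records,
              exact = report$exact)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
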