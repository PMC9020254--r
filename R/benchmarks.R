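#' Exact moments of the scattering-event coordinates in an infinite medium
#'
#' Closed-form radiative-transfer values for the first and second moments of
#' the coordinates \eqn{(x_k, y_k, z_k)} of the k-th scattering event, for a
#' pencil beam injected along +z at the origin of an infinite non-absorbing
#' medium with scattering coefficient `mus` and a rotationally symmetric
#' phase function with cosine moments \eqn{g = \langle\cos\theta\rangle} and
#' \eqn{g_2 = \langle\cos^2\theta\rangle}.  Available for orders 1 to 4;
#' arbitrary-order formulas exist for \eqn{\langle z_k\rangle}
#' ([mean_z_any_order()]), \eqn{\langle d_k^2\rangle}
#' ([mean_d2_any_order()]), the path-length moments ([pathlength_moment()])
#' and, for isotropic scattering, all second moments
#' ([isotropic_second_moments()]).
#'
#' By symmetry \eqn{\langle x_k\rangle = \langle y_k\rangle = 0} at every
#' order, and the identities \eqn{\langle\rho_k^2\rangle =
#' \langle x_k^2\rangle + \langle y_k^2\rangle} and
#' \eqn{\langle d_k^2\rangle = \langle\rho_k^2\rangle + \langle z_k^2\rangle}
#' hold exactly.
#'
#' @param k Scattering order, 1 to 4.
#' @param g First moment of the scattering cosine (asymmetry factor).
#' @param g2 Second moment of the scattering cosine; defaults to the
#'   Henyey-Greenstein value \eqn{(1 + 2g^2)/3}.
#' @param mus Scattering coefficient, mm^-1.
#' @return Named numeric vector with elements `x`, `y`, `z` (mm), `x2`, `y2`,
#'   `z2`, `rho2`, `d2` (mm^2), `l` (mm), `l2` (mm^2).
#' @examples
#' infinite_moments(3, g = 0.9, g2 = 2.62 / 3)[["x2"]]  # 0.469933
#' @export
infinite_moments <- function(k, g = 0, g2 = (1 + 2 * g^2) / 3, mus = 1) {
  stopifnot(length(k) == 1L, k %in% 1:4, mus > 0, abs(g) < 1,
            g2 >= g^2, g2 <= 1)
  z <- switch(k,
    1 / mus,
    (1 + g) / mus,
    (1 + g + g^2) / mus,
    (1 + g + g^2 + g^3) / mus
  )
  x2 <- switch(k,
    0,
    (1 - g2) / mus^2,
    (3 / 2 + g - g * g2 - 3 / 2 * g2^2) / mus^2,
    (9 / 4 + 3 / 2 * g - 3 / 2 * g * g2^2 + g^2 - g^2 * g2 -
       3 / 4 * g2 + 3 / 4 * g2^2 - 9 / 4 * g2^3) / mus^2
  )
  z2 <- switch(k,
    2 / mus^2,
    2 * (1 + g + g2) / mus^2,
    (3 + 2 * g + 2 * g^2 + 2 * g * g2 + 3 * g2^2) / mus^2,
    (7 / 2 + 3 * g * (1 + g2^2) + 2 * g^2 * (1 + g2) + 2 * g^3 +
       3 / 2 * g2 - 3 / 2 * g2^2 + 9 / 2 * g2^3) / mus^2
  )
  rho2 <- 2 * x2
  c(x = 0, y = 0, z = z, x2 = x2, y2 = x2, z2 = z2,
    rho2 = rho2, d2 = rho2 + z2,
    l = pathlength_moment(k, 1, mus), l2 = pathlength_moment(k, 2, mus))
}

#' Mean z coordinate of the k-th scattering event, any order
#'
#' \eqn{\langle z_k\rangle = (1 - g^k) / (\mu_s (1 - g))}; for \eqn{g = 0}
#' this is \eqn{1/\mu_s} at every order, and the \eqn{k \to \infty} limit is
#' the transport mean free path \eqn{1 / (\mu_s (1 - g))}.
#'
#' @param k Scattering order(s), >= 1.
#' @inheritParams infinite_moments
#' @return Mean z in mm (vectorised over `k`).
#' @export
mean_z_any_order <- function(k, g = 0, mus = 1) {
  stopifnot(all(k >= 1), abs(g) < 1, mus > 0)
  if (g == 0) return(rep_len(1 / mus, length(k)))
  (1 - g^k) / (mus * (1 - g))
}

#' Mean square distance from the source at the k-th scattering event
#'
#' \eqn{\langle d_k^2\rangle = 2(k - (k+1)g + g^{k+1}) / (\mu_s^2 (1-g)^2)},
#' valid for any rotationally symmetric phase function and any order; for
#' \eqn{g = 0} it reduces to \eqn{2k/\mu_s^2}.
#'
#' @inheritParams mean_z_any_order
#' @return Mean square distance in mm^2 (vectorised over `k`).
#' @export
mean_d2_any_order <- function(k, g = 0, mus = 1) {
  stopifnot(all(k >= 1), abs(g) < 1, mus > 0)
  if (g == 0) return(2 * k / mus^2)
  2 * (k - (k + 1) * g + g^(k + 1)) / (mus^2 * (1 - g)^2)
}

#' Moments of the cumulative path length at the k-th scattering event
#'
#' The path to the k-th event is a sum of k exponential free paths, so its
#' m-th moment is the rising factorial
#' \eqn{\langle l_k^m\rangle = k(k+1)\cdots(k+m-1)/\mu_s^m}, independent of
#' the phase function.
#'
#' @param k Scattering order(s), >= 1.
#' @param m Moment order, >= 1.
#' @inheritParams infinite_moments
#' @return Moment in mm^m (vectorised over `k`).
#' @export
pathlength_moment <- function(k, m = 1, mus = 1) {
  stopifnot(all(k >= 1), length(m) == 1L, m >= 1, mus > 0)
  out <- rep_len(1, length(k))
  for (i in seq_len(m)) out <- out * (k + i - 1)
  out / mus^m
}

#' Second moments for isotropic scattering, any order
#'
#' For isotropic scattering the transverse and axial distributions coincide
#' after the first event, giving \eqn{\langle x_k^2\rangle =
#' \langle y_k^2\rangle = (2/3)(k-1)/\mu_s^2}, \eqn{\langle z_k^2\rangle =
#' (2/3)(k+2)/\mu_s^2} (so \eqn{\langle z_k^2\rangle - \langle x_k^2\rangle =
#' 2/\mu_s^2} exactly), \eqn{\langle\rho_k^2\rangle = (4/3)(k-1)/\mu_s^2}
#' and \eqn{\langle d_k^2\rangle = 2k/\mu_s^2}.
#'
#' @inheritParams mean_z_any_order
#' @return Named list with vectors `x2`, `z2`, `rho2`, `d2` (mm^2).
#' @export
isotropic_second_moments <- function(k, mus = 1) {
  stopifnot(all(k >= 1), mus > 0)
  list(x2 = 2 / 3 * (k - 1) / mus^2,
       z2 = 2 / 3 * (k + 2) / mus^2,
       rho2 = 4 / 3 * (k - 1) / mus^2,
       d2 = 2 * k / mus^2)
}

#' Benchmark table of infinite-medium moments for a phase function
#'
#' Convenience wrapper assembling [infinite_moments()] for orders 1..4 into
#' a long data frame, exportable as CSV/JSON.
#'
#' @param phase A [hg_phase()] or [rayleigh_phase()] object.
#' @param mus Scattering coefficient, mm^-1.
#' @param k Orders to tabulate (each must be in 1..4).
#' @return Data frame with columns `k`, `quantity`, `benchmark`.
#' @export
benchmark_table <- function(phase, mus = 1, k = 1:4) {
  m <- phase_moments(phase)
  rows <- lapply(k, function(kk) {
    v <- infinite_moments(kk, g = m[["g"]], g2 = m[["g2"]], mus = mus)
    data.frame(k = kk, quantity = names(v), benchmark = unname(v))
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Invariant solutions under Lambertian illumination
# ---------------------------------------------------------------------------

#' Invariant radiance, fluence rate and mean path lengths
#'
#' For a non-absorbing medium of external refractive index `ne` whose smooth
#' convex surface is illuminated by Lambertian radiation of radiance `I0`,
#' the internal radiance in a sub-volume of index `nj` is the constant
#' \eqn{(n_j/n_e)^2 I_0}, independent of position, direction and of all
#' scattering properties; the fluence rate is \eqn{4\pi} times that; and the
#' mean path length spent in a sub-volume \eqn{V_j} is
#' \eqn{4 (n_j/n_e)^2 V_j / \Sigma}, with \eqn{\Sigma} the external surface.
#' The only exception is a non-scattering slab (or sphere) with
#' \eqn{n_j > n_e}, where trapped directions are unreachable and the
#' solutions gain a \eqn{1 - \cos\theta_{jMax}} support factor: see
#' [nonscattering_solutions()].
#'
#' The default `I0 = 1/pi` corresponds to a unit incident flux, the
#' normalization used by the slab simulator.
#'
#' @param nj Refractive index of the sub-volume.
#' @param ne External refractive index.
#' @param I0 Source radiance, W m^-2 sr^-1.
#' @return `invariant_radiance()`: W m^-2 sr^-1; `invariant_fluence()`:
#'   W m^-2; `invariant_layer_pathlength()`: same units as `Vj / Sigma`.
#' @export
invariant_radiance <- function(nj, ne, I0 = 1 / pi) {
  stopifnot(all(nj > 0), ne > 0, I0 >= 0)
  (nj / ne)^2 * I0
}

#' @rdname invariant_radiance
#' @export
invariant_fluence <- function(nj, ne, I0 = 1 / pi) {
  4 * pi * invariant_radiance(nj, ne, I0)
}

#' @rdname invariant_radiance
#' @param Vj Sub-volume (e.g. mm^3).
#' @param Sigma External surface area (e.g. mm^2).  For a laterally infinite
#'   slab layer of thickness `sj` illuminated on both faces,
#'   `Vj / Sigma = sj / 2`, giving \eqn{\langle L_j\rangle = 2 s_j
#'   (n_j/n_e)^2}: use [slab_layer_pathlength()].
#' @export
invariant_layer_pathlength <- function(nj, ne, Vj, Sigma) {
  stopifnot(all(Vj > 0), Sigma > 0)
  4 * (nj / ne)^2 * Vj / Sigma
}

#' @rdname invariant_radiance
#' @param sj Slab layer thickness, mm.
#' @export
slab_layer_pathlength <- function(sj, nj, ne) {
  stopifnot(all(sj > 0))
  2 * sj * (nj / ne)^2
}

#' Maximum polar angle with radiation in a layer of a non-scattering slab
#'
#' In a non-scattering layered slab, radiation can only occupy directions
#' reachable by refraction from outside.  The Snell invariant
#' \eqn{n \sin\theta} is conserved across the plane-parallel interfaces and
#' total internal reflection blocks transmission whenever it would exceed the
#' next index, so the invariant of any ray reaching layer j is bounded by
#' the smallest index encountered on its entry path (including the external
#' medium).  Taking the less restrictive of the two faces,
#' \eqn{\sin\theta_{jMax} = \min(n_e, n_{between}) / n_j}, capped at 1
#' (\eqn{\theta_{jMax} = \pi/2}, full support, whenever \eqn{n_j} does not
#' exceed that minimum).
#'
#' @param slab A [layered_slab()].
#' @param j Layer index (1-based), or a vector of indices.
#' @return Maximum polar angle(s) in radians, in \eqn{(0, \pi/2]}.
#' @export
theta_max <- function(slab, j = seq_along(slab$layers)) {
  stopifnot(inherits(slab, "layered_slab"))
  n <- vapply(slab$layers, `[[`, numeric(1), "n")
  M <- length(n)
  if (any(j < 1 | j > M)) stop("layer index out of range")
  vapply(j, function(jj) {
    m_top <- min(slab$ne, n[seq_len(jj - 1)])
    m_bot <- min(slab$ne, n[seq_len(M - jj) + jj])
    s <- min(1, max(m_top, m_bot) / n[jj])
    asin(s)
  }, numeric(1))
}

#' Invariant solutions in a non-scattering layered slab (trapped regime)
#'
#' For a non-scattering slab layer with index above the external one, part of
#' the direction sphere is unreachable from outside; the radiance keeps the
#' level \eqn{(n_j/n_e)^2 I_0} on the populated support
#' \eqn{|\hat s \cdot \hat q| \ge \cos\theta_{jMax}} and vanishes elsewhere,
#' and the fluence rate and mean layer path length are scaled by
#' \eqn{1 - \cos\theta_{jMax}} relative to the scattering-case invariants.
#'
#' @param slab A [layered_slab()] with all layer scattering coefficients 0.
#' @param j Layer index (1-based).
#' @inheritParams invariant_radiance
#' @return List with `radiance_level` (W m^-2 sr^-1), `cos_theta_max`,
#'   `theta_max` (radians), `fluence` (W m^-2) and `pathlength` (mm).
#' @export
nonscattering_solutions <- function(slab, j, I0 = 1 / pi) {
  stopifnot(inherits(slab, "layered_slab"), length(j) == 1L)
  mus <- vapply(slab$layers, `[[`, numeric(1), "mus")
  if (any(mus > 0)) {
    stop("trapped-regime solutions require a non-scattering slab (all mus = 0)")
  }
  nj <- slab$layers[[j]]$n
  th <- theta_max(slab, j)
  lev <- invariant_radiance(nj, slab$ne, I0)
  fac <- 1 - cos(th)
  list(radiance_level = lev,
       cos_theta_max = cos(th),
       theta_max = th,
       fluence = 4 * pi * lev * fac,
       pathlength = slab_layer_pathlength(slab$layers[[j]]$s, nj, slab$ne) * fac)
}
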