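#' Sampling primitives for photon transport
#'
#' Low-level random-variate transforms used by the simulators, exposed so
#' that each can be checked in isolation against its target distribution.
#' All functions are vectorised over the uniform deviates `u`, which the
#' caller supplies (e.g. from [runif()]), keeping the transforms pure.
#'
#' `sample_free_path()` inverts the exponential free-path law: a medium with
#' scattering coefficient `mus` (mm^-1) has mean free path `1/mus`.
#'
#' @param mus Scattering coefficient, mm^-1, > 0.
#' @param u Uniform(0,1) deviates.
#' @return Path lengths in mm.
#' @export
sample_free_path <- function(mus, u) {
  stopifnot(is.numeric(mus), length(mus) == 1L, is.finite(mus))
  if (mus <= 0) stop("scattering coefficient mus must be > 0")
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  cpp_free_path(mus, as.numeric(u))
}

#' Henyey-Greenstein scattering cosine via the inverse CDF
#'
#' @param g Asymmetry factor, |g| < 1.
#' @inheritParams sample_free_path
#' @return Scattering cosines in \eqn{[-1, 1]}; the empirical moments
#'   converge to \eqn{\langle\cos\theta\rangle = g} and
#'   \eqn{\langle\cos^2\theta\rangle = (1 + 2g^2)/3}.
#' @export
sample_hg_cosine <- function(g, u) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g))
  if (abs(g) >= 1) stop("|g| must be < 1")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  cpp_hg_cosine(g, as.numeric(u))
}

#' Rayleigh scattering cosine via Cardano's closed-form CDF inversion
#'
#' The target density is \eqn{p(\mu) = (3/8)(1 + \mu^2)} on \eqn{[-1, 1]}
#' with CDF \eqn{F(\mu) = (3\mu + \mu^3 + 4)/8}; the cubic is inverted in
#' closed form (its discriminant is bounded away from zero, so no iterative
#' fallback is needed).
#'
#' @inheritParams sample_free_path
#' @return Scattering cosines; empirical mean converges to 0 and
#'   \eqn{\langle\cos^2\theta\rangle} to 0.4.
#' @export
sample_rayleigh_cosine <- function(u) {
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  cpp_rayleigh_cosine(as.numeric(u))
}

#' Rotate a direction by a sampled scattering angle
#'
#' Applies the standard local-frame rotation taking the current direction of
#' flight into the scattered direction with polar cosine `cos_theta` and
#' azimuth `phi` about the incident direction.  A degenerate branch handles
#' directions within 1e-12 of the z axis to avoid catastrophic cancellation.
#'
#' @param dir Numeric matrix (n x 3) or length-3 vector of unit direction
#'   cosines.
#' @param cos_theta Scattering cosines, |cos_theta| <= 1.
#' @param phi Azimuths in \eqn{[0, 2\pi)}.
#' @return Matrix (n x 3) of unit direction cosines whose dot product with
#'   the input equals `cos_theta` to within 1e-9.
#' @export
scatter_direction <- function(dir, cos_theta, phi) {
  if (is.null(dim(dir))) dir <- matrix(dir, ncol = 3)
  stopifnot(ncol(dir) == 3, all(abs(cos_theta) <= 1 + 1e-12))
  nrm <- sqrt(rowSums(dir^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("input directions must be unit vectors")
  n <- nrow(dir)
  cos_theta <- rep_len(pmin(1, pmax(-1, cos_theta)), n)
  phi <- rep_len(phi, n)
  cpp_scatter_direction(dir, cos_theta, phi)
}

#' Cosine-weighted (Lambertian) launch directions
#'
#' Samples directions with polar density \eqn{2\cos\theta\sin\theta} about
#' the inward surface normal (so \eqn{\cos\theta = \sqrt{u_1}}) and uniform
#' azimuth, the angular distribution of radiation crossing a surface under
#' direction-independent (Lambertian) radiance.
#'
#' @param u1,u2 Uniform(0,1) deviates.
#' @param inward_normal Length-3 unit vector pointing into the medium.
#' @return Matrix (n x 3) of unit directions on the inward hemisphere.
#' @export
sample_lambertian_direction <- function(u1, u2, inward_normal = c(0, 0, 1)) {
  stopifnot(length(inward_normal) == 3,
            abs(sum(inward_normal^2) - 1) < 1e-9,
            length(u1) == length(u2))
  ct <- sqrt(u1)
  n <- length(u1)
  base <- matrix(rep(inward_normal, each = n), ncol = 3)
  cpp_scatter_direction(base, ct, 2 * pi * u2)
}
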