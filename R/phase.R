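#' Phase-function specifications
#'
#' A phase function describes the probability density of the scattering
#' deflection angle.  Two analytic families are supported, chosen because
#' their cosine moments \eqn{g = \langle\cos\theta\rangle} and
#' \eqn{g_2 = \langle\cos^2\theta\rangle} are known exactly:
#' Henyey-Greenstein with asymmetry parameter \eqn{g} (isotropic scattering
#' is the \eqn{g = 0} special case) and Rayleigh,
#' \eqn{p(\mu) = (3/8)(1 + \mu^2)} on \eqn{[-1, 1]}.
#'
#' @param g Asymmetry factor, \eqn{-1 < g < 1} (Henyey-Greenstein only).
#' @return An object of class `phase_spec` with fields `kind` (`"hg"` or
#'   `"rayleigh"`) and, for HG, `g`.
#' @examples
#' phase_moments(hg_phase(0.9))   # (0.9, 2.62/3)
#' phase_moments(rayleigh_phase())  # (0, 0.4)
#' @export
hg_phase <- function(g = 0) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g))
  if (abs(g) >= 1) stop("Henyey-Greenstein asymmetry must satisfy |g| < 1")
  structure(list(kind = "hg", g = g), class = "phase_spec")
}

#' @rdname hg_phase
#' @export
rayleigh_phase <- function() {
  structure(list(kind = "rayleigh", g = 0), class = "phase_spec")
}

#' Exact cosine moments of a phase function
#'
#' @param spec A [hg_phase()] or [rayleigh_phase()] object.
#' @return Named numeric vector `c(g = ..., g2 = ...)` with the first and
#'   second moments of the scattering cosine: HG gives
#'   \eqn{(g, (1 + 2g^2)/3)}; Rayleigh gives \eqn{(0, 2/5)}.
#' @export
phase_moments <- function(spec) {
  stopifnot(inherits(spec, "phase_spec"))
  switch(spec$kind,
    hg = c(g = spec$g, g2 = (1 + 2 * spec$g^2) / 3),
    rayleigh = c(g = 0, g2 = 0.4),
    stop("unknown phase function kind: ", spec$kind)
  )
}

#' @export
print.phase_spec <- function(x, ...) {
  m <- phase_moments(x)
  if (x$kind == "hg") {
    cat(sprintf("Henyey-Greenstein phase function: g = %g (g2 = %.6g)\n",
                m[["g"]], m[["g2"]]))
  } else {
    cat("Rayleigh phase function (g = 0, g2 = 0.4)\n")
  }
  invisible(x)
}

# internal: integer code handed to the C++ simulators
phase_kind_code <- function(spec) {
  switch(spec$kind, hg = 0L, rayleigh = 1L)
}
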