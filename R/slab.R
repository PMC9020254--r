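#' Laterally infinite layered slab
#'
#' Describes a plane-parallel slab of ordered layers, each with a thickness
#' `s` (mm), refractive index `n`, scattering coefficient `mus` (mm^-1, 0 for
#' a non-scattering layer) and a phase function, embedded in an external
#' medium of refractive index `ne`.  Depth runs over \eqn{z \in [0, Z]} with
#' layer 1 at the illuminated `z = 0` face.
#'
#' @param s Layer thicknesses, mm (> 0).
#' @param n Layer refractive indices (> 0), recycled to `length(s)`.
#' @param mus Layer scattering coefficients, mm^-1 (>= 0), recycled.
#' @param phase A single [hg_phase()] / [rayleigh_phase()] or a list of one
#'   per layer.
#' @param ne External refractive index (> 0).
#' @return An object of class `layered_slab`: list with `layers` (each a list
#'   `s`, `n`, `mus`, `phase`) and `ne`.
#' @examples
#' layered_slab(s = rep(2.5, 4), n = c(1.2, 1.4, 1.6, 1.8), mus = 1, ne = 1)
#' @export
layered_slab <- function(s, n, mus = 1, phase = hg_phase(0), ne = 1) {
  stopifnot(all(s > 0), all(n > 0), all(mus >= 0), ne > 0)
  M <- length(s)
  n <- rep_len(n, M)
  mus <- rep_len(mus, M)
  if (inherits(phase, "phase_spec")) phase <- rep(list(phase), M)
  stopifnot(length(phase) == M,
            all(vapply(phase, inherits, logical(1), "phase_spec")))
  layers <- lapply(seq_len(M), function(j) {
    list(s = s[j], n = n[j], mus = mus[j], phase = phase[[j]])
  })
  structure(list(layers = layers, ne = ne), class = "layered_slab")
}

#' @export
print.layered_slab <- function(x, ...) {
  M <- length(x$layers)
  Z <- sum(vapply(x$layers, `[[`, numeric(1), "s"))
  cat(sprintf("Layered slab: %d layer(s), total thickness %g mm, ne = %g\n",
              M, Z, x$ne))
  show <- if (M > 8) c(1:4, M - 1, M) else seq_len(M)
  for (j in show) {
    ly <- x$layers[[j]]
    cat(sprintf("  layer %3d: s = %g mm, n = %g, mus = %g mm^-1, %s\n",
                j, ly$s, ly$n, ly$mus,
                if (ly$phase$kind == "hg") sprintf("HG g = %g", ly$phase$g)
                else "Rayleigh"))
    if (M > 8 && j == 4) cat("  ...\n")
  }
  invisible(x)
}

# internal accessors
slab_thicknesses <- function(slab) vapply(slab$layers, `[[`, numeric(1), "s")
slab_indices <- function(slab) vapply(slab$layers, `[[`, numeric(1), "n")
slab_mus <- function(slab) vapply(slab$layers, `[[`, numeric(1), "mus")

#' Angular grid for radiance tallies
#'
#' Uniform bins in the polar angle \eqn{\theta \in [0, \pi]} measured from
#' the +z slab normal.  Radiance estimates are normalized by the exact solid
#' angle of each bin, \eqn{\Delta\Omega_b = 2\pi(\cos\theta_b^- -
#' \cos\theta_b^+)}, which sums to \eqn{4\pi}.
#'
#' @param n_bins Number of bins (default 180, i.e. 1-degree bins).
#' @return Object of class `angular_grid` with fields `n_bins`, `edges`
#'   (radians, length `n_bins + 1`), `centers` and `solid_angle`.
#' @export
angular_grid <- function(n_bins = 180) {
  stopifnot(n_bins >= 1)
  edges <- seq(0, pi, length.out = n_bins + 1)
  structure(list(
    n_bins = as.integer(n_bins),
    edges = edges,
    centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    solid_angle = 2 * pi * (cos(edges[-(n_bins + 1)]) - cos(edges[-1]))
  ), class = "angular_grid")
}

#' Built-in refractive-index profile fixtures
#'
#' Synthetic layered-slab fixtures used throughout the verification suite:
#' a four-layer slab (2.5 mm layers) and a 100-layer slab (0.1 mm layers),
#' each 10 mm thick, with a monotonically increasing ("up", external index 1)
#' or decreasing ("dw", external index 2) refractive-index profile.  The
#' index values ramp linearly between 1.1 and 2.0; since the invariant
#' benchmarks hold for any profile, the exact ramp is a free choice and these
#' are synthetic stand-ins for published figure profiles.
#'
#' @param name One of `"up4"`, `"dw4"`, `"up100"`, `"dw100"`.
#' @param mus Scattering coefficient applied to every layer, mm^-1 (0 gives
#'   the non-scattering, trapped-photon regime for the "up" profiles).
#' @param phase Phase function for every layer.
#' @return A [layered_slab()].
#' @export
slab_profile <- function(name = c("up4", "dw4", "up100", "dw100"),
                         mus = 1, phase = hg_phase(0)) {
  name <- match.arg(name)
  M <- if (grepl("100", name)) 100L else 4L
  ramp <- seq(1.1, 2.0, length.out = M)
  if (startsWith(name, "up")) {
    layered_slab(s = rep(10 / M, M), n = ramp, mus = mus, phase = phase,
                 ne = 1)
  } else {
    layered_slab(s = rep(10 / M, M), n = rev(ramp), mus = mus, phase = phase,
                 ne = 2)
  }
}

#' Read / write a slab description as JSON
#'
#' The on-disk format is a JSON object
#' `{"ne": ..., "layers": [{"s": ..., "n": ..., "mus": ..., "phase": "hg",
#' "g": ...}, ...]}`; the round trip is lossless.
#'
#' @param path File path.
#' @return `read_slab_config()` returns a [layered_slab()];
#'   `write_slab_config()` returns `path` invisibly.
#' @export
read_slab_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(cfg$ne) || is.null(cfg$layers)) {
    stop("slab config must contain 'ne' and 'layers'")
  }
  ly <- cfg$layers
  phase <- lapply(seq_len(nrow(ly)), function(i) {
    if (identical(ly$phase[i], "rayleigh")) rayleigh_phase()
    else hg_phase(if (is.null(ly$g)) 0 else ly$g[i])
  })
  layered_slab(s = ly$s, n = ly$n, mus = ly$mus, phase = phase, ne = cfg$ne)
}

#' @rdname read_slab_config
#' @param slab A [layered_slab()].
#' @export
write_slab_config <- function(slab, path) {
  ly <- data.frame(
    s = slab_thicknesses(slab),
    n = slab_indices(slab),
    mus = slab_mus(slab),
    phase = vapply(slab$layers, function(l) l$phase$kind, character(1)),
    g = vapply(slab$layers, function(l) l$phase$g, numeric(1))
  )
  jsonlite::write_json(list(ne = slab$ne, layers = ly), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
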