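# Multilayer sample description.
#
# A sample is an ordered set of reflecting layers, each with an optical
# pathlength difference (total, round trip included), a reflectivity and
# its own dispersion coefficients — depth-varying dispersion across layers
# is the core feature being modelled. Speckle is realized by surrounding
# each layer with sub-resolution random scatterers.

#' Dispersion coefficients of one layer
#'
#' Quadratic (`a2`, group-velocity dispersion) and cubic (`a3`) spectral
#' phase. In `"pixel"` mode the phase added to a fringe of length P is
#' `a2 * u^2 + a3 * u^3` with `u = (j - j0) / (P/2)`, so a coefficient is
#' the phase in radians accrued at the edge of the detector; this makes
#' coefficient sweeps instrument-independent. In `"physical"` mode the
#' phase is `a2 * (k - k0)^2 + a3 * (k - k0)^3` with k in rad/um.
#' `a2 = a3 = 0` is transform-limited propagation.
#'
#' @param a2,a3 Finite numeric coefficients.
#' @param mode `"pixel"` (default) or `"physical"`.
#' @export
dispersion_spec <- function(a2 = 0, a3 = 0, mode = c("pixel", "physical")) {
  mode <- match.arg(mode)
  if (!is.finite(a2) || !is.finite(a3))
    stop_octadc("dispersion coefficients must be finite")
  structure(list(a2 = a2, a3 = a3, mode = mode), class = "oct_dispersion")
}

#' Multilayer reflecting sample
#'
#' @param delta_z_um Strictly increasing optical pathlength differences of
#'   the layers (um, total round-trip pathlength).
#' @param reflectivity Per-layer reflectivities in `[0, 1]`.
#' @param a2,a3 Per-layer dispersion coefficients (recycled if scalar).
#' @param dispersion_mode Coefficient convention, see [dispersion_spec()].
#' @param curvature_sag_um Depth sag of the parabolic lateral profile: layer
#'   depths at A-line x of A are offset by `sag * (2x/(A-1) - 1)^2`,
#'   emulating retinal curvature across the B-scan. 0 = flat layers.
#' @param speckle_density Expected number of sub-resolution scatterers per
#'   layer per A-line. 0 = pure specular layers.
#' @param speckle_jitter_um Half-width of the uniform depth jitter of
#'   speckle scatterers around their layer.
#' @return An `oct_sample`.
#' @export
layered_sample <- function(delta_z_um, reflectivity, a2 = 0, a3 = 0,
                           dispersion_mode = c("pixel", "physical"),
                           curvature_sag_um = 0,
                           speckle_density = 0,
                           speckle_jitter_um = 10) {
  dispersion_mode <- match.arg(dispersion_mode)
  n <- length(delta_z_um)
  if (n == 0) {
    layers <- data.frame(delta_z_um = numeric(0), reflectivity = numeric(0),
                         a2 = numeric(0), a3 = numeric(0))
  } else {
    if (any(diff(delta_z_um) <= 0))
      stop_octadc("delta_z_um must be strictly increasing")
    if (any(reflectivity < 0 | reflectivity > 1))
      stop_octadc("reflectivities must lie in [0, 1]")
    layers <- data.frame(delta_z_um = delta_z_um,
                         reflectivity = rep_len(reflectivity, n),
                         a2 = rep_len(a2, n), a3 = rep_len(a3, n))
  }
  structure(list(layers = layers,
                 dispersion_mode = dispersion_mode,
                 curvature_sag_um = curvature_sag_um,
                 speckle_density = speckle_density,
                 speckle_jitter_um = speckle_jitter_um),
            class = "oct_sample")
}

#' @export
print.oct_sample <- function(x, ...) {
  cat(sprintf("<oct_sample> %d layers, a2 in [%s], speckle %.0f/layer/A-line\n",
              nrow(x$layers),
              if (nrow(x$layers)) paste(signif(range(x$layers$a2), 3),
                                        collapse = ", ") else "",
              x$speckle_density))
  invisible(x)
}

#' Random retina-like sample matched to a coefficient ladder
#'
#' Draws a multilayer sample emulating the reflective banding of the retina:
#' one layer per depth band, where the depth axis `[0, z_max_um)` is split
#' into `length(c_values)` equal bands and the layer in band i carries
#' dispersion `c_values[i] + N(0, a2_jitter_sd)`. Reconstructing such a
#' sample with the coefficient ladder `c_values` therefore yields a stack in
#' which channel i is (near-)matched inside depth band i — the situation the
#' ground-truth stitching procedure is built for, and the synthetic stand-in
#' for tissue whose dispersion grows smoothly with depth.
#'
#' @param z_max_um Depth extent covered by the bands (um of pathlength).
#' @param c_values Ascending coefficient ladder (pixel mode).
#' @param a2_jitter_sd Gaussian jitter of each layer's a2 around its band
#'   coefficient.
#' @param reflectivity_range Uniform range of layer reflectivities.
#' @param margin Fraction of each band kept clear at both ends when placing
#'   the layer (keeps layers away from band boundaries).
#' @param seed Integer seed; the draw is deterministic given it.
#' @inheritParams layered_sample
#' @return An `oct_sample` with one layer per band.
#' @export
synth_retina_sample <- function(z_max_um,
                                c_values = c(-40, -20, 0, 20, 40),
                                a2_jitter_sd = 2,
                                reflectivity_range = c(0.3, 1),
                                margin = 0.2,
                                curvature_sag_um = 20,
                                speckle_density = 8,
                                speckle_jitter_um = 10,
                                seed = NULL) {
  n <- length(c_values)
  with_seed(seed, {
    edges <- seq(0, z_max_um, length.out = n + 1)
    lo <- edges[-(n + 1)] + margin * diff(edges)
    hi <- edges[-1] - margin * diff(edges)
    z <- sort(stats::runif(n, lo, hi))
    layered_sample(delta_z_um = z,
                   reflectivity = stats::runif(n, reflectivity_range[1],
                                               reflectivity_range[2]),
                   a2 = c_values + stats::rnorm(n, 0, a2_jitter_sd),
                   a3 = 0,
                   curvature_sag_um = curvature_sag_um,
                   speckle_density = speckle_density,
                   speckle_jitter_um = speckle_jitter_um)
  })
}

# Deterministic scatterer realization of a sample for A a-lines.
# Returns a data.frame (aline, z_um, refl, a2, a3): the specular layer line
# plus, if speckle_density > 0, Poisson-many sub-resolution scatterers per
# layer per a-line whose summed expected intensity matches the layer
# reflectivity. Geometry is drawn once per (sample, seed): repeated frames
# share it and differ only in detection noise.
scatterer_table <- function(sample, n_alines, seed = NULL) {
  layers <- sample$layers
  if (nrow(layers) == 0)
    return(data.frame(aline = integer(0), z_um = numeric(0),
                      refl = numeric(0), a2 = numeric(0), a3 = numeric(0)))
  sag <- if (n_alines > 1) {
    u <- 2 * (seq_len(n_alines) - 1) / (n_alines - 1) - 1
    sample$curvature_sag_um * u^2
  } else rep(0, n_alines)
  with_seed(seed, {
    out <- vector("list", nrow(layers))
    for (i in seq_len(nrow(layers))) {
      L <- layers[i, ]
      if (sample$speckle_density > 0) {
        counts <- pmax(1L, stats::rpois(n_alines, sample$speckle_density))
        total <- sum(counts)
        aline <- rep(seq_len(n_alines), counts)
        amp <- abs(stats::rnorm(total))
        # normalize per a-line so the expected intensity stays ~reflectivity
        denom <- sqrt(rep(counts, counts))
        refl <- L$reflectivity * (amp / denom)^2
        z <- L$delta_z_um + sag[aline] +
          stats::runif(total, -sample$speckle_jitter_um,
                       sample$speckle_jitter_um)
      } else {
        aline <- seq_len(n_alines)
        refl <- rep(L$reflectivity, n_alines)
        z <- L$delta_z_um + sag
      }
      out[[i]] <- data.frame(aline = aline, z_um = z, refl = refl,
                             a2 = L$a2, a3 = L$a3)
    }
    do.call(rbind, out)
  })
}
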