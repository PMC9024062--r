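# Interferogram synthesis.
#
# The detected spectral fringe from a multilayer sample is
#   S(k) = I_r(k) * (1 + sum_n r_n)
#        + sum_n 2 * sqrt(r_n) * I_r(k) * cos(k * dz_n + phi_n(k)) + noise,
# the real part of the sum of back-reflected fields beating against the
# reference, with the DC term (reference plus sample autocorrelation)
# approximated by the source envelope. phi_n is the layer's residual
# dispersion phase: a2 * u^2 + a3 * u^3 in pixel mode (u = centered,
# half-width-normalized pixel offset) or a2*(k-k0)^2 + a3*(k-k0)^3 in
# physical mode.

#' Detection noise description
#'
#' Additive white Gaussian noise on the fringe (sd in units of the
#' peak-normalized source envelope) plus optional shot noise whose standard
#' deviation scales with the square root of the local clean intensity.
#'
#' @param gaussian_sd Standard deviation of the additive Gaussian component.
#' @param shot_scale Scale of the signal-dependent component; 0 disables it.
#' @export
noise_model <- function(gaussian_sd = 0.05, shot_scale = 0) {
  structure(list(gaussian_sd = gaussian_sd, shot_scale = shot_scale),
            class = "oct_noise")
}

# Pixel-mode phase coordinate: u_j = (j - j0) / (P/2), j0 at grid center.
pixel_u <- function(P) {
  j <- seq_len(P)
  (j - (P + 1) / 2) / (P / 2)
}

# Dispersion phase (radians, length P) for coefficients on `grid`.
dispersion_phase <- function(grid, a2, a3 = 0,
                             mode = c("pixel", "physical")) {
  mode <- match.arg(mode)
  P <- length(grid$k_values)
  if (mode == "pixel") {
    u <- pixel_u(P)
  } else {
    u <- grid$k_values - grid$k0
  }
  a2 * u^2 + a3 * u^3
}

# Clean fringe matrix (P x A) for a scatterer table; no noise.
fringe_from_scatterers <- function(source, grid, scat, n_alines) {
  P <- length(grid$k_values)
  k <- grid$k_values
  envelope <- source_intensity_on_k(source, k)
  u <- pixel_u(P)
  uk <- k - grid$k0
  out <- matrix(0, P, n_alines)
  refl_tot <- numeric(n_alines)
  if (nrow(scat)) {
    pieces <- split(seq_len(nrow(scat)), scat$aline)
    for (nm in names(pieces)) {
      idx <- pieces[[nm]]
      a <- as.integer(nm)
      base <- if (scat$mode[idx[1]] == "pixel") u else uk
      phase <- outer(k, scat$z_um[idx]) +
        outer(base^2, scat$a2[idx]) + outer(base^3, scat$a3[idx])
      amp <- 2 * outer(envelope, sqrt(scat$refl[idx]))
      out[, a] <- rowSums(amp * cos(phase))
      refl_tot[a] <- sum(scat$refl[idx])
    }
  }
  out + outer(envelope, 1 + refl_tot)
}

add_detection_noise <- function(clean, noise, seed = NULL) {
  if (is.null(noise) ||
      (noise$gaussian_sd == 0 && noise$shot_scale == 0)) return(clean)
  with_seed(seed, {
    n <- clean + stats::rnorm(length(clean), 0, noise$gaussian_sd)
    if (noise$shot_scale > 0)
      n <- n + stats::rnorm(length(clean)) * noise$shot_scale *
        sqrt(pmax(clean, 0))
    n
  })
}

check_aliasing <- function(sample, grid) {
  if (nrow(sample$layers) &&
      any(sample$layers$delta_z_um > max_depth_um(grid)))
    warning(sprintf(
      "layer pathlength exceeds the unambiguous depth range (%.0f um); the peak will alias",
      max_depth_um(grid)), call. = FALSE)
}

#' Simulate one spectral interferogram (A-line)
#'
#' Synthesizes the detected fringe of `sample` on the uniform wavenumber
#' grid: DC background plus one cosine per scatterer, carrying each layer's
#' optical pathlength and residual dispersion phase, plus detection noise.
#' Deterministic given `rng_seed` (which seeds both the speckle realization
#' and the noise).
#'
#' @param source An `oct_source`.
#' @param grid The matching `oct_kgrid`.
#' @param sample An `oct_sample` (may be empty: returns the background).
#' @param a_line_index Which lateral position to synthesize.
#' @param noise `oct_noise` description or `NULL` for noise-free.
#' @param rng_seed Integer seed or `NULL`.
#' @param n_alines Lateral width used to evaluate the curvature profile
#'   (defaults to `a_line_index`).
#' @return Numeric fringe vector of length `P`.
#' @export
simulate_ascan_spectrum <- function(source, grid, sample,
                                    a_line_index = 1L,
                                    noise = NULL, rng_seed = NULL,
                                    n_alines = a_line_index) {
  stopifnot(inherits(source, "oct_source"), inherits(grid, "oct_kgrid"),
            inherits(sample, "oct_sample"))
  check_aliasing(sample, grid)
  scat <- scatterer_table(sample, n_alines,
                          seed = child_seed(rng_seed, 1L))
  scat$mode <- rep(sample$dispersion_mode, nrow(scat))
  scat <- scat[scat$aline == a_line_index, , drop = FALSE]
  scat$aline <- rep(1L, nrow(scat))
  clean <- fringe_from_scatterers(source, grid, scat, 1L)
  drop(add_detection_noise(clean, noise, child_seed(rng_seed, 2L)))
}

new_raw_frame <- function(fringes, source, grid, repeats = 1L,
                          frame_index = 1L, volume_index = 1L,
                          location_index = 1L, repeat_index = 1L) {
  structure(list(fringes = fringes, source = source, grid = grid,
                 repeats = as.integer(repeats),
                 frame_index = as.integer(frame_index),
                 volume_index = as.integer(volume_index),
                 location_index = as.integer(location_index),
                 repeat_index = as.integer(repeat_index)),
            class = "oct_raw_frame")
}

#' @export
print.oct_raw_frame <- function(x, ...) {
  cat(sprintf("<oct_raw_frame> %d px x %d A-lines (vol %d, loc %d, rep %d)\n",
              nrow(x$fringes), ncol(x$fringes), x$volume_index,
              x$location_index, x$repeat_index))
  invisible(x)
}

#' Simulate a volume of repeated B-scan interferograms
#'
#' Generates `n_bscans` lateral locations with `repeats` frames each.
#' Repeated frames at one location share the sample geometry (layers and
#' speckle realization) and differ only in the detection-noise draw,
#' mirroring a repeated-frame OCT acquisition protocol. Fully deterministic
#' given `rng_seed`.
#'
#' @param sample_sequence A single `oct_sample` used for every location, or
#'   a list of `n_bscans` samples.
#' @param n_bscans Number of lateral locations (>= 1).
#' @param a_lines_per_bscan A-lines per frame.
#' @param repeats Repeated frames per location (>= 1).
#' @param noise `oct_noise` or `NULL`.
#' @param rng_seed Integer seed.
#' @param source,grid Instrument description; defaults to the 840 nm / 50 nm
#'   source sampled on 512 pixels (desk-scale default).
#' @param volume_index Recorded in every frame's metadata.
#' @return An `oct_volume`: list of `oct_raw_frame`s (location-major order)
#'   plus instrument, scale metadata and the per-location ground-truth layer
#'   table (`truth`).
#' @export
simulate_volume <- function(sample_sequence, n_bscans, a_lines_per_bscan,
                            repeats = 1L, noise = noise_model(),
                            rng_seed = NULL,
                            source = make_source_spectrum(n_pixels = 512L),
                            grid = resample_to_k(source),
                            volume_index = 1L) {
  n_bscans <- as.integer(n_bscans)
  repeats <- as.integer(repeats)
  if (n_bscans < 1L) stop_octadc("n_bscans must be >= 1")
  if (repeats < 1L) stop_octadc("repeats must be >= 1")
  samples <- if (inherits(sample_sequence, "oct_sample"))
    rep(list(sample_sequence), n_bscans) else sample_sequence
  if (length(samples) != n_bscans)
    stop_octadc("sample_sequence must supply one sample per B-scan")
  frames <- vector("list", n_bscans * repeats)
  truth <- vector("list", n_bscans)
  fi <- 0L
  for (loc in seq_len(n_bscans)) {
    sample <- samples[[loc]]
    check_aliasing(sample, grid)
    scat <- scatterer_table(sample, a_lines_per_bscan,
                            seed = child_seed(rng_seed, 1L, loc))
    scat$mode <- rep(sample$dispersion_mode, nrow(scat))
    clean <- fringe_from_scatterers(source, grid, scat, a_lines_per_bscan)
    truth[[loc]] <- sample$layers
    for (rep_i in seq_len(repeats)) {
      fi <- fi + 1L
      fr <- add_detection_noise(clean, noise,
                                child_seed(rng_seed, 2L, loc, rep_i))
      frames[[fi]] <- new_raw_frame(fr, source, grid, repeats = repeats,
                                    frame_index = fi,
                                    volume_index = volume_index,
                                    location_index = loc,
                                    repeat_index = rep_i)
    }
  }
  structure(list(frames = frames, source = source, grid = grid,
                 n_bscans = n_bscans, repeats = repeats,
                 a_lines = as.integer(a_lines_per_bscan),
                 truth = truth, seed = rng_seed),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("<oct_volume> %d locations x %d repeats, %d x %d fringes\n",
              x$n_bscans, x$repeats, nrow(x$frames[[1]]$fringes), x$a_lines))
  invisible(x)
}

#' Simulate the synthetic retina benchmark
#'
#' Convenience wrapper producing a list of volumes of retina-like samples
#' whose per-band dispersion matches the coefficient ladder `c_values`
#' (see [synth_retina_sample()]): the standing-in for a repeated-frame
#' clinical acquisition used throughout the package's experiments.
#'
#' @param n_volumes Number of independent volumes.
#' @param locations B-scan locations per volume.
#' @param a_lines A-lines per B-scan.
#' @param repeats Repeated frames per location.
#' @param n_pixels Detector pixels.
#' @param c_values Coefficient ladder the samples are matched to.
#' @param noise Detection noise model.
#' @param seed Master seed; everything below derives from it.
#' @param ... Passed to [synth_retina_sample()].
#' @return List of `oct_volume`s.
#' @export
simulate_benchmark <- function(n_volumes = 2L, locations = 4L,
                               a_lines = 128L, repeats = 4L,
                               n_pixels = 512L,
                               c_values = c(-40, -20, 0, 20, 40),
                               noise = noise_model(), seed = 1L, ...) {
  source <- make_source_spectrum(n_pixels = n_pixels)
  grid <- resample_to_k(source)
  z_max <- max_depth_um(grid)
  lapply(seq_len(n_volumes), function(v) {
    samples <- lapply(seq_len(locations), function(loc)
      synth_retina_sample(z_max_um = z_max, c_values = c_values,
                          seed = child_seed(seed, 7L, v, loc), ...))
    simulate_volume(samples, n_bscans = locations,
                    a_lines_per_bscan = a_lines, repeats = repeats,
                    noise = noise, rng_seed = child_seed(seed, 8L, v),
                    source = source, grid = grid, volume_index = v)
  })
}
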