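# SD-OCT reconstruction with numeric dispersion compensation.
#
# Chain: background subtraction -> (k-space linearization, if the input is
# wavelength-sampled) -> analytic-signal construction -> spectral phase
# correction exp(i * phibar(k)) with phibar = -a2*(k-k0)^2 - a3*(k-k0)^3
# -> FFT -> magnitude of the positive-depth half. One second-order
# coefficient per reconstruction; a stack of reconstructions with a ladder
# of coefficients is the restoration network's input.

#' Remove the DC background of a raw frame
#'
#' Subtracts the per-detector-pixel mean across A-lines, the standard
#' background estimate for a frame of many laterally decorrelated A-lines.
#'
#' @param frame An `oct_raw_frame` with at least 2 A-lines.
#' @return The frame with zero-mean rows.
#' @export
subtract_background <- function(frame) {
  stopifnot(inherits(frame, "oct_raw_frame"))
  if (ncol(frame$fringes) < 2L)
    stop_octadc("background subtraction needs >= 2 A-lines; ",
                "the mean of a single A-line would annihilate the signal")
  frame$fringes <- frame$fringes - rowMeans(frame$fringes)
  frame$background_subtracted <- TRUE
  frame
}

#' Apply the dispersion-compensation phase correction
#'
#' Multiplies a complex spectrum elementwise by `exp(i * phibar)` with
#' `phibar = -(a2 * u^2 + a3 * u^3)`, `u` being the pixel-mode phase
#' coordinate (or `k - k0` in physical mode). A pure phase factor: the
#' magnitude spectrum is untouched, and correcting with the coefficients of
#' the residual sample dispersion cancels it exactly.
#'
#' @param complex_spectrum Complex vector or P x A matrix on `grid`.
#' @param grid The `oct_kgrid`.
#' @param a2,a3 Correction coefficients.
#' @param mode Coefficient convention, see [dispersion_spec()].
#' @return The corrected complex spectrum.
#' @export
apply_phase_correction <- function(complex_spectrum, grid, a2, a3 = 0,
                                   mode = c("pixel", "physical")) {
  P <- if (is.matrix(complex_spectrum)) nrow(complex_spectrum)
       else length(complex_spectrum)
  if (P != length(grid$k_values))
    stop_octadc("spectrum length does not match the wavenumber grid")
  phase <- -dispersion_phase(grid, a2, a3, mode = match.arg(mode))
  complex_spectrum * exp(1i * phase)
}

# Analytic (complex) fringe: zero the negative-depth half of the spectrum.
# Works columnwise on a matrix.
analytic_fringe <- function(fringes) {
  P <- nrow(fringes)
  F <- stats::mvfft(fringes)
  h <- numeric(P)
  h[1L] <- 1
  if (P %% 2 == 0) {
    h[2:(P / 2)] <- 2
    h[P / 2 + 1] <- 1
  } else {
    h[2:((P + 1) / 2)] <- 2
  }
  stats::mvfft(F * h, inverse = TRUE) / P
}

#' Reconstruct a depth profile from one fringe
#'
#' Analytic-signal construction, spectral phase correction, FFT, magnitude,
#' positive-depth half. Row 1 of the output is zero delay; depth increases
#' with row index at [depth_pitch_um()] per row.
#'
#' @param fringe Background-subtracted, k-uniform real fringe (length P) or
#'   P x A matrix.
#' @param grid The `oct_kgrid`.
#' @param a2,a3 Correction coefficients.
#' @param mode Coefficient convention.
#' @param pad_factor Integer >= 1; zero-pads the corrected spectrum to
#'   `pad_factor * P` before the FFT, sinc-interpolating the depth profile
#'   (used when sub-pixel peak widths must be measured). The output then has
#'   `pad_factor * P / 2` rows at `depth_pitch_um() / pad_factor` spacing.
#' @return Non-negative depth-intensity vector (length `P/2`) or matrix.
#' @export
reconstruct_ascan <- function(fringe, grid, a2 = 0, a3 = 0,
                              mode = c("pixel", "physical"),
                              pad_factor = 1L) {
  mode <- match.arg(mode)
  x <- if (is.matrix(fringe)) fringe else matrix(fringe, ncol = 1L)
  if (!all(is.finite(x))) stop_octadc("fringe contains non-finite values")
  P <- nrow(x)
  if (P != length(grid$k_values))
    stop_octadc("fringe length does not match the wavenumber grid")
  s <- analytic_fringe(x)
  s <- apply_phase_correction(s, grid, a2, a3, mode = mode)
  pad_factor <- as.integer(pad_factor)
  if (pad_factor > 1L) {
    s <- rbind(s, matrix(0 + 0i, P * (pad_factor - 1L), ncol(s)))
  }
  A <- stats::mvfft(s)
  half <- nrow(A) %/% 2L
  out <- Mod(A[seq_len(half), , drop = FALSE]) / P
  if (is.matrix(fringe)) out else drop(out)
}

new_bscan <- function(image, scale = "linear", depth_pitch_um = NA_real_,
                      provenance = list()) {
  structure(list(image = image, scale = scale,
                 depth_pitch_um = depth_pitch_um,
                 provenance = provenance),
            class = "oct_bscan")
}

#' @export
print.oct_bscan <- function(x, ...) {
  cat(sprintf("<oct_bscan> %d x %d (%s scale, a2 = %s)\n",
              nrow(x$image), ncol(x$image), x$scale,
              format(x$provenance$a2 %||% NA)))
  invisible(x)
}

#' Reconstruct a B-scan with one compensation coefficient
#'
#' Columnwise [reconstruct_ascan()] over a raw frame, after background
#' subtraction (applied here if the frame is still raw). The coefficient
#' used is recorded in the B-scan's provenance.
#'
#' @param frame An `oct_raw_frame`.
#' @param a2,a3 Correction coefficients.
#' @param mode Coefficient convention.
#' @return An `oct_bscan` with a `P/2 x A` linear-scale image.
#' @export
reconstruct_bscan <- function(frame, a2 = 0, a3 = 0,
                              mode = c("pixel", "physical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "oct_raw_frame"))
  if (!isTRUE(frame$background_subtracted))
    frame <- subtract_background(frame)
  img <- reconstruct_ascan(frame$fringes, frame$grid, a2, a3, mode = mode)
  new_bscan(img, scale = "linear",
            depth_pitch_um = depth_pitch_um(frame$grid),
            provenance = list(a2 = a2, a3 = a3, mode = mode,
                              frame_index = frame$frame_index,
                              volume_index = frame$volume_index,
                              location_index = frame$location_index,
                              repeat_index = frame$repeat_index))
}

#' Reconstruct a frame at a ladder of coefficients
#'
#' Builds the multichannel input of the restoration network: `n_channels`
#' B-scans of the same raw frame, compensated by coefficients equally
#' spaced from `c_min` to `c_max` inclusive (the single-channel case uses
#' the midpoint). All channels are co-registered by construction since they
#' come from the same fringes.
#'
#' @param frame An `oct_raw_frame`.
#' @param c_min,c_max Coefficient range.
#' @param n_channels One of 1, 3, 5, 7, 9.
#' @param mode Coefficient convention.
#' @return An `oct_stack`: list with `coefficients` (ascending) and
#'   `bscans` (one `oct_bscan` per coefficient).
#' @export
build_compensation_stack <- function(frame, c_min, c_max, n_channels = 5L,
                                     mode = c("pixel", "physical")) {
  mode <- match.arg(mode)
  n_channels <- as.integer(n_channels)
  if (!n_channels %in% c(1L, 3L, 5L, 7L, 9L))
    stop_octadc("n_channels must be one of 1, 3, 5, 7, 9")
  if (n_channels > 1L && !(c_min < c_max))
    stop_octadc("c_min must be < c_max for multichannel stacks")
  coeffs <- if (n_channels == 1L) (c_min + c_max) / 2
            else seq(c_min, c_max, length.out = n_channels)
  if (!isTRUE(frame$background_subtracted))
    frame <- subtract_background(frame)
  bscans <- lapply(coeffs, function(c2)
    reconstruct_bscan(frame, a2 = c2, mode = mode))
  structure(list(coefficients = coeffs, bscans = bscans,
                 frame_index = frame$frame_index,
                 volume_index = frame$volume_index,
                 location_index = frame$location_index,
                 repeat_index = frame$repeat_index),
            class = "oct_stack")
}

#' @export
print.oct_stack <- function(x, ...) {
  cat(sprintf("<oct_stack> %d channels, coefficients [%s]\n",
              length(x$coefficients),
              paste(signif(x$coefficients, 3), collapse = ", ")))
  invisible(x)
}

#' Logarithmic display scaling
#'
#' `20 * log10(I / max(I))`, clipped at `floor_db`, then min-max rescaled to
#' `[0, 1]` — the display convention for OCT B-scans, and the scale on which
#' training pairs and image-quality metrics operate by default.
#'
#' @param bscan A linear-scale `oct_bscan`.
#' @param floor_db Clipping floor in dB (negative), default -60.
#' @return An `oct_bscan` with `scale = "log"` and values in `[0, 1]`.
#' @export
log_display <- function(bscan, floor_db = -60) {
  stopifnot(inherits(bscan, "oct_bscan"))
  if (!identical(bscan$scale, "linear"))
    stop_octadc("log_display expects a linear-scale B-scan")
  m <- max(bscan$image)
  if (m <= 0) stop_octadc("cannot log-scale an all-zero image")
  db <- 20 * log10(pmax(bscan$image, 0) / m)
  db[!is.finite(db)] <- floor_db
  db <- pmax(db, floor_db)
  bscan$image <- (db - floor_db) / (-floor_db)
  bscan$scale <- "log"
  bscan$provenance$floor_db <- floor_db
  bscan
}
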