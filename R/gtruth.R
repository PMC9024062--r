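# Per-depth optimal coefficient discovery and ground-truth stitching.
#
# A single second-order coefficient compensates one depth band well; the
# all-depth ground truth is assembled by reconstructing the same raw frame
# with a ladder of coefficients and stitching, from each reconstruction,
# the depth band it optimizes (ascending coefficient index <-> increasing
# depth). Optimal coefficients are found automatically by maximizing a
# normalized sharpness score over a coefficient sweep.

#' Normalized sharpness of a depth band
#'
#' Intensity-squared concentration `sum(I^4) / sum(I^2)^2` over the band:
#' 1 for a single-pixel impulse, `1/M` for a uniform band of M pixels, and
#' invariant to global intensity scaling. Dispersion spreads peak energy
#' over more pixels, so a matched compensation maximizes this score.
#'
#' @param bscan An `oct_bscan` (linear scale recommended).
#' @param band Integer vector `c(first_row, last_row)` (1-based, inclusive)
#'   or `NULL` for the whole image.
#' @return Non-negative scalar; 0 for an all-zero band.
#' @export
sharpness_score <- function(bscan, band = NULL) {
  img <- if (inherits(bscan, "oct_bscan")) bscan$image else bscan
  if (!is.null(band)) {
    if (band[1] < 1 || band[2] > nrow(img) || band[1] > band[2])
      stop_octadc("band must lie within the image")
    img <- img[band[1]:band[2], , drop = FALSE]
  }
  e2 <- sum(img^2)
  if (e2 == 0) return(0)
  sum(img^4) / e2^2
}

#' Estimate the optimal compensation coefficient for a depth band
#'
#' Reconstructs `frame` at every coefficient of the sweep, scores the band's
#' sharpness, and refines the argmax by parabolic interpolation through the
#' top three scores. On a synthetic layer with dispersion a2 this recovers
#' the canceling correction coefficient (equal to the layer's a2, which the
#' Eq.-style phase correction subtracts).
#'
#' @param frame An `oct_raw_frame`.
#' @param band Row interval `c(first, last)` scored.
#' @param sweep `c(c_min, c_max, step)`; a single value means a one-point
#'   sweep.
#' @param mode Coefficient convention.
#' @return The estimated coefficient (scalar). A flat score landscape
#'   (max/min < 1 + 1e-6) triggers a warning and returns the sweep midpoint.
#' @export
estimate_optimal_coeff <- function(frame, band, sweep,
                                   mode = c("pixel", "physical")) {
  mode <- match.arg(mode)
  if (length(sweep) == 1L) return(sweep)
  cs <- if (length(sweep) == 3L) seq(sweep[1], sweep[2], by = sweep[3])
        else sweep
  if (length(cs) == 1L) return(cs)
  if (!isTRUE(frame$background_subtracted))
    frame <- subtract_background(frame)
  scores <- vapply(cs, function(c2)
    sharpness_score(reconstruct_bscan(frame, a2 = c2, mode = mode), band),
    numeric(1))
  if (max(scores) <= 0 || max(scores) / max(min(scores), .Machine$double.xmin) < 1 + 1e-6) {
    warning("degenerate sharpness landscape; returning the sweep midpoint",
            call. = FALSE)
    return((min(cs) + max(cs)) / 2)
  }
  i <- which.max(scores)
  if (i == 1L || i == length(cs)) return(cs[i])
  # parabola through the argmax and its neighbours
  y1 <- scores[i - 1L]; y2 <- scores[i]; y3 <- scores[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(cs[i])
  offset <- 0.5 * (y1 - y3) / denom
  cs[i] + offset * (cs[i + 1L] - cs[i])
}

#' Partition the depth axis into stitching bands
#'
#' @param n_bands Number of bands (equals the stack size when stitching).
#' @param z_rows Total number of depth rows.
#' @param boundaries `"auto"` for equal-height bands (remainder rows going
#'   to the last band), or an integer vector of `n_bands + 1` ascending row
#'   boundaries starting at 1 and ending at `z_rows + 1` (half-open bands).
#' @return An `oct_bands` object: list of `c(first, last)` row intervals
#'   (1-based, inclusive) that tile `[1, z_rows]` without gaps or overlaps.
#' @export
partition_depth_bands <- function(n_bands, z_rows, boundaries = "auto") {
  n_bands <- as.integer(n_bands); z_rows <- as.integer(z_rows)
  if (n_bands < 1L || n_bands > z_rows)
    stop_octadc("need 1 <= n_bands <= z_rows")
  if (identical(boundaries, "auto")) {
    h <- z_rows %/% n_bands
    starts <- 1L + h * (seq_len(n_bands) - 1L)
    ends <- c(starts[-1L] - 1L, z_rows)
  } else {
    b <- as.integer(boundaries)
    if (length(b) != n_bands + 1L || b[1] != 1L || b[n_bands + 1L] != z_rows + 1L ||
        any(diff(b) <= 0L))
      stop_octadc("explicit boundaries must be ", n_bands + 1L,
                  " ascending values from 1 to z_rows + 1")
    starts <- b[-(n_bands + 1L)]
    ends <- b[-1L] - 1L
  }
  structure(list(bands = Map(c, starts, ends), z_rows = z_rows),
            class = "oct_bands")
}

#' Stitch an all-depth-compensated ground truth
#'
#' Copies the rows of depth band i from B-scan i of the stack (channel 1,
#' lowest coefficient, feeds the shallowest band). With `feather = 0` the
#' stitch is hard; `feather = w` blends linearly across `w` rows at each
#' seam.
#'
#' @param stack An `oct_stack` whose size equals the number of bands.
#' @param bands An `oct_bands` partition of the stack's depth rows.
#' @param feather Seam blend width in rows (default 0).
#' @return An `oct_bscan` assembled from the per-band optimal channels.
#' @export
stitch_ground_truth <- function(stack, bands, feather = 0L) {
  stopifnot(inherits(stack, "oct_stack"), inherits(bands, "oct_bands"))
  n <- length(stack$bscans)
  if (length(bands$bands) != n)
    stop_octadc("number of bands (", length(bands$bands),
                ") must equal stack size (", n, ")")
  ref <- stack$bscans[[1L]]
  Z <- nrow(ref$image)
  if (bands$z_rows != Z)
    stop_octadc("bands cover ", bands$z_rows, " rows but the stack has ", Z)
  shapes <- vapply(stack$bscans, function(b) dim(b$image), integer(2))
  if (any(shapes != dim(ref$image)))
    stop_octadc("stack B-scans disagree in shape")
  out <- ref$image
  for (i in seq_len(n)) {
    rows <- bands$bands[[i]]
    out[rows[1]:rows[2], ] <- stack$bscans[[i]]$image[rows[1]:rows[2], ]
  }
  feather <- as.integer(feather)
  if (feather > 0L && n > 1L) {
    for (i in seq_len(n - 1L)) {
      seam <- bands$bands[[i]][2]
      lo <- max(1L, seam - feather + 1L)
      hi <- min(Z, seam + feather)
      w <- (seq(lo, hi) - lo + 0.5) / (hi - lo + 1)  # 0 -> channel i, 1 -> i+1
      blend <- (1 - w) * stack$bscans[[i]]$image[lo:hi, , drop = FALSE] +
        w * stack$bscans[[i + 1L]]$image[lo:hi, , drop = FALSE]
      out[lo:hi, ] <- blend
    }
  }
  new_bscan(out, scale = ref$scale, depth_pitch_um = ref$depth_pitch_um,
            provenance = list(stitched_from = stack$coefficients,
                              bands = bands$bands, feather = feather,
                              frame_index = stack$frame_index,
                              volume_index = stack$volume_index,
                              location_index = stack$location_index,
                              repeat_index = stack$repeat_index))
}
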