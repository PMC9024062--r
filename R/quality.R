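# Image-quality metrics and profile analysis.
#
# PSNR = 10*log10(s^2 / MSE) with s the maximum of the reconstructed image
# (auto mode) or a fixed dynamic range. SSIM combines luminance, contrast
# and structure terms with C1 = (K1*L)^2, C2 = (K2*L)^2, C3 = C2/2
# (K1 = 0.01, K2 = 0.03); local statistics use the conventional 11x11
# Gaussian window (sigma 1.5). MS-SSIM evaluates contrast/structure on a
# dyadic low-pass pyramid and luminance at the coarsest scale only.

#' Mean squared error
#' @param f,g Equal-shape numeric matrices (reference, reconstruction).
#' @export
mse <- function(f, g) {
  if (!identical(dim(f), dim(g))) stop_octadc("image shapes differ")
  mean((f - g)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' @param f Reference image (ground truth).
#' @param g Reconstructed image.
#' @param s `"auto"` (default) takes the peak from the reconstructed image
#'   `g`; a number fixes the dynamic range instead. Auto mode makes the
#'   metric asymmetric in its arguments — that is its definition, not a
#'   defect.
#' @return PSNR in dB; `+Inf` (with a warning) when the images are equal.
#' @export
psnr <- function(f, g, s = "auto") {
  e <- mse(f, g)
  if (e == 0) {
    warning("identical images: PSNR is infinite", call. = FALSE)
    return(Inf)
  }
  speak <- if (identical(s, "auto")) max(g) else s
  10 * log10(speak^2 / e)
}

#' SSIM parameters
#'
#' @param L Pixel dynamic range (1 for the package's normalized log images).
#' @param K1,K2 Stability constants (0.01, 0.03).
#' @param window,sigma Gaussian window size and width for local statistics.
#' @param scales Number of dyadic scales for [ms_ssim()].
#' @param weights Per-scale exponents, normalized to sum 1; the default is
#'   the canonical 5-scale set.
#' @export
ssim_params <- function(L = 1, K1 = 0.01, K2 = 0.03, window = 11L,
                        sigma = 1.5, scales = 5L,
                        weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  weights <- weights[seq_len(scales)]
  weights <- weights / sum(weights)
  structure(list(L = L, K1 = K1, K2 = K2, window = as.integer(window),
                 sigma = sigma, scales = as.integer(scales),
                 weights = weights,
                 C1 = (K1 * L)^2, C2 = (K2 * L)^2, C3 = (K2 * L)^2 / 2),
            class = "ssim_params")
}

gaussian_kernel1d <- function(window, sigma) {
  r <- (window - 1) / 2
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# Separable windowed correlation, 'valid' region only.
filter_valid <- function(x, w) {
  n <- length(w)
  H <- nrow(x); W <- ncol(x)
  # rows
  out <- matrix(0, H - n + 1L, W)
  for (t in seq_len(n))
    out <- out + w[t] * x[t:(H - n + t), , drop = FALSE]
  out2 <- matrix(0, nrow(out), W - n + 1L)
  for (t in seq_len(n))
    out2 <- out2 + w[t] * out[, t:(W - n + t), drop = FALSE]
  out2
}

ssim_components <- function(x, y, params) {
  w <- gaussian_kernel1d(params$window, params$sigma)
  mu_x <- filter_valid(x, w)
  mu_y <- filter_valid(y, w)
  sxx <- filter_valid(x * x, w) - mu_x^2
  syy <- filter_valid(y * y, w) - mu_y^2
  sxy <- filter_valid(x * y, w) - mu_x * mu_y
  sxx <- pmax(sxx, 0); syy <- pmax(syy, 0)
  C1 <- params$C1; C2 <- params$C2
  l <- (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1)
  cs <- (2 * sxy + C2) / (sxx + syy + C2)
  list(l = l, cs = cs)
}

#' Structural similarity index
#'
#' Mean of the local SSIM map: the product of the luminance term
#' `(2 mu_x mu_y + C1) / (mu_x^2 + mu_y^2 + C1)` and the combined
#' contrast-structure term `(2 sigma_xy + C2) / (sigma_x^2 + sigma_y^2 + C2)`
#' (unit exponents, where the structure constant C3 = C2/2 folds the
#' contrast and structure factors into one).
#'
#' @param x,y Equal-shape images.
#' @param params An [ssim_params()].
#' @return Scalar in `(-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(x, y, params = ssim_params()) {
  if (!identical(dim(x), dim(y))) stop_octadc("image shapes differ")
  if (min(dim(x)) < params$window)
    stop_octadc("image smaller than the SSIM window")
  comp <- ssim_components(x, y, params)
  mean(comp$l * comp$cs)
}

downsample2 <- function(x) {
  H <- 2L * (nrow(x) %/% 2L); W <- 2L * (ncol(x) %/% 2L)
  x <- x[seq_len(H), seq_len(W), drop = FALSE]
  0.25 * (x[seq(1L, H, 2L), seq(1L, W, 2L), drop = FALSE] +
          x[seq(2L, H, 2L), seq(1L, W, 2L), drop = FALSE] +
          x[seq(1L, H, 2L), seq(2L, W, 2L), drop = FALSE] +
          x[seq(2L, H, 2L), seq(2L, W, 2L), drop = FALSE])
}

#' Multi-scale structural similarity
#'
#' Iteratively low-passes (2x2 mean) and 2x-downsamples the pair,
#' evaluating the mean contrast-structure term at every scale and the
#' luminance term at the coarsest scale only, then combines them as an
#' exponent-weighted product. If the images are too small for the requested
#' number of scales it is reduced with a warning (the exponents are
#' renormalized); single-scale MS-SSIM with a unit weight equals [ssim()].
#'
#' @inheritParams ssim
#' @return Scalar; 1 iff the images are identical.
#' @export
ms_ssim <- function(x, y, params = ssim_params()) {
  if (!identical(dim(x), dim(y))) stop_octadc("image shapes differ")
  M <- params$scales
  max_M <- floor(log2(min(dim(x)) / params$window)) + 1L
  if (max_M < 1L)
    stop_octadc("image smaller than the SSIM window at every scale")
  if (M > max_M) {
    warning(sprintf("image supports only %d of %d scales; reducing",
                    max_M, M), call. = FALSE)
    M <- max_M
  }
  w <- params$weights[seq_len(M)]
  w <- w / sum(w)
  out <- 1
  for (j in seq_len(M)) {
    comp <- ssim_components(x, y, params)
    if (j < M) {
      out <- out * max(mean(comp$cs), 0)^w[j]
      x <- downsample2(x); y <- downsample2(y)
    } else {
      out <- out * max(mean(comp$l * comp$cs), 0)^w[j]
    }
  }
  out
}

#' Average groups of repeated B-scans
#'
#' Pixel mean of consecutive groups of `group_size` images (the repeated-
#' frame averaging applied before quantitative metrics).
#'
#' @param bscans List of `oct_bscan`s or matrices; length divisible by
#'   `group_size`.
#' @param group_size Frames per group.
#' @return List of `length(bscans) / group_size` averaged images, order
#'   preserved.
#' @export
average_repeats <- function(bscans, group_size) {
  n <- length(bscans)
  group_size <- as.integer(group_size)
  if (n %% group_size != 0L)
    stop_octadc(n, " images cannot be grouped by ", group_size)
  lapply(seq_len(n %/% group_size), function(gi) {
    grp <- bscans[(gi - 1L) * group_size + seq_len(group_size)]
    imgs <- lapply(grp, function(b)
      if (inherits(b, "oct_bscan")) b$image else b)
    out <- Reduce(`+`, imgs) / group_size
    if (inherits(grp[[1]], "oct_bscan")) {
      tmpl <- grp[[1]]; tmpl$image <- out
      tmpl$provenance$averaged <- group_size
      tmpl
    } else out
  })
}

#' Differential intensity image
#'
#' Absolute pixel-wise difference between the ground truth and a candidate
#' reconstruction, plus a rendering normalized to the pair's maximum
#' difference (displayed with a jet colormap by `plot()`).
#'
#' @param ground_truth,candidate Equal-shape images (or `oct_bscan`s).
#' @return An `oct_diff` with fields `difference` and `normalized`.
#' @export
difference_image <- function(ground_truth, candidate) {
  gt <- if (inherits(ground_truth, "oct_bscan")) ground_truth$image else ground_truth
  cd <- if (inherits(candidate, "oct_bscan")) candidate$image else candidate
  if (!identical(dim(gt), dim(cd))) stop_octadc("image shapes differ")
  d <- abs(gt - cd)
  m <- max(d)
  structure(list(difference = d,
                 normalized = if (m > 0) d / m else d),
            class = "oct_diff")
}

#' @export
plot.oct_diff <- function(x, ...) {
  jet <- grDevices::colorRampPalette(c("darkblue", "blue", "cyan", "yellow",
                                       "orange", "red"))(128)
  graphics::image(t(x$normalized)[, rev(seq_len(nrow(x$normalized)))],
                  col = jet, axes = FALSE, asp = nrow(x$normalized) /
                    ncol(x$normalized), ...)
  invisible(x)
}

#' Axial intensity profile with peak and FWHM analysis
#'
#' Averages `n_bscans_avg` neighbouring B-scans and `n_alines_avg` adjacent
#' A-lines around `column`, then reports the linear-scale depth profile,
#' its local maxima above a prominence threshold, and each peak's FWHM by
#' linear interpolation at half height — the reflective-band profile
#' analysis used to judge compensation quality at e.g. the outer retinal
#' bands.
#'
#' @param bscans List of linear-scale `oct_bscan`s (or matrices).
#' @param column Center A-line of the region of interest.
#' @param n_bscans_avg,n_alines_avg Averaging window sizes (must fit).
#' @param first_bscan Index of the first averaged B-scan.
#' @param min_prominence Peaks below `min_prominence * max(profile)` are
#'   ignored.
#' @return An `oct_profile`: `depth_rows`, `intensity`, and a `peaks`
#'   data.frame (`row`, `height`, `fwhm_rows`) sorted by depth.
#' @export
axial_profile <- function(bscans, column, n_bscans_avg = 6L,
                          n_alines_avg = 5L, first_bscan = 1L,
                          min_prominence = 0.1) {
  imgs <- lapply(bscans, function(b)
    if (inherits(b, "oct_bscan")) b$image else b)
  nb <- length(imgs)
  if (first_bscan + n_bscans_avg - 1L > nb)
    stop_octadc("B-scan averaging window exceeds the volume")
  half <- (n_alines_avg - 1L) %/% 2L
  cols <- (column - half):(column - half + n_alines_avg - 1L)
  if (min(cols) < 1L || max(cols) > ncol(imgs[[1]]))
    stop_octadc("A-line averaging window exceeds the image")
  avg <- Reduce(`+`, imgs[first_bscan + seq_len(n_bscans_avg) - 1L]) /
    n_bscans_avg
  profile <- rowMeans(avg[, cols, drop = FALSE])
  n <- length(profile)
  is_peak <- c(FALSE, profile[2:(n - 1)] > profile[1:(n - 2)] &
                 profile[2:(n - 1)] >= profile[3:n], FALSE)
  rows <- which(is_peak & profile >= min_prominence * max(profile))
  peaks <- data.frame(row = rows, height = profile[rows],
                      fwhm_rows = vapply(rows, function(r)
                        fwhm_interp(profile, r), numeric(1)))
  structure(list(depth_rows = seq_len(n), intensity = profile,
                 peaks = peaks[order(peaks$row), , drop = FALSE],
                 averaging = c(n_bscans = n_bscans_avg,
                               n_alines = n_alines_avg)),
            class = "oct_profile")
}

#' @export
print.oct_profile <- function(x, ...) {
  cat(sprintf("<oct_profile> %d rows, %d peaks (avg %dx%d)\n",
              length(x$intensity), nrow(x$peaks),
              x$averaging["n_bscans"], x$averaging["n_alines"]))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}
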