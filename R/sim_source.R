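# Broadband source model and wavenumber grid.
#
# The detector samples the interference spectrum uniformly in wavelength;
# reconstruction needs uniform wavenumber (k = 2*pi/lambda) samples, so the
# source carries both representations. Internally wavelengths are nm and
# wavenumbers rad/um, which puts optical pathlengths in um.

#' Gaussian broadband source sampled on a line detector
#'
#' Models the emission envelope of a superluminescent diode as a Gaussian in
#' wavelength, sampled linearly across `center +/- 2 * fwhm` on `n_pixels`
#' detector pixels and peak-normalized to 1. The defaults describe an
#' 840 nm near-infrared SLD on a 2048-pixel line camera, the instrument
#' class typically used for retinal SD-OCT.
#'
#' @param center_wavelength_nm Center wavelength in nm.
#' @param fwhm_bandwidth_nm Full width at half maximum of the intensity
#'   envelope in nm. Broader bandwidth means a narrower axial PSF.
#' @param n_pixels Number of detector pixels (>= 16).
#' @return An object of class `oct_source` with fields `wavelengths_nm`
#'   (strictly increasing), `intensity_au` (peak 1) and
#'   `center_wavelength_nm`.
#' @examples
#' src <- make_source_spectrum(840, 50, 512)
#' plot(src$wavelengths_nm, src$intensity_au, type = "l")
#' @export
make_source_spectrum <- function(center_wavelength_nm = 840,
                                 fwhm_bandwidth_nm = 50,
                                 n_pixels = 2048L) {
  if (!is.finite(center_wavelength_nm) || center_wavelength_nm <= 0)
    stop_octadc("center_wavelength_nm must be a positive number")
  if (!is.finite(fwhm_bandwidth_nm) || fwhm_bandwidth_nm <= 0)
    stop_octadc("fwhm_bandwidth_nm must be positive")
  n_pixels <- as.integer(n_pixels)
  if (is.na(n_pixels) || n_pixels < 16L)
    stop_octadc("n_pixels must be an integer >= 16")
  half_span <- 2 * fwhm_bandwidth_nm
  lambda <- seq(center_wavelength_nm - half_span,
                center_wavelength_nm + half_span,
                length.out = n_pixels)
  sigma <- fwhm_bandwidth_nm / (2 * sqrt(2 * log(2)))
  intensity <- exp(-((lambda - center_wavelength_nm)^2) / (2 * sigma^2))
  intensity <- intensity / max(intensity)   # peak exactly 1 on even grids
  structure(list(wavelengths_nm = lambda,
                 intensity_au = intensity,
                 center_wavelength_nm = center_wavelength_nm),
            class = "oct_source")
}

#' @export
print.oct_source <- function(x, ...) {
  cat(sprintf("<oct_source> %d px, %.0f nm center, span %.0f-%.0f nm\n",
              length(x$wavelengths_nm), x$center_wavelength_nm,
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Uniform wavenumber grid for a source spectrum
#'
#' Builds the uniform grid in k = 2*pi/lambda spanning the source's
#' wavelength range (k-space linearization target). `k0` is the
#' intensity-weighted centroid of k, the expansion point of the dispersion
#' phase polynomial.
#'
#' @param spectrum An `oct_source`.
#' @return An `oct_kgrid` with `k_values` (rad/um, uniformly spaced,
#'   increasing) and `k0`.
#' @export
resample_to_k <- function(spectrum) {
  stopifnot(inherits(spectrum, "oct_source"))
  lam_um <- spectrum$wavelengths_nm / 1000
  k_min <- 2 * pi / max(lam_um)
  k_max <- 2 * pi / min(lam_um)
  P <- length(lam_um)
  k <- seq(k_min, k_max, length.out = P)
  intens_k <- source_intensity_on_k(spectrum, k)
  k0 <- sum(k * intens_k) / sum(intens_k)
  structure(list(k_values = k, k0 = k0), class = "oct_kgrid")
}

# Source intensity envelope interpolated onto arbitrary k samples.
source_intensity_on_k <- function(spectrum, k) {
  lam_um <- spectrum$wavelengths_nm / 1000
  k_native <- 2 * pi / lam_um            # decreasing with pixel index
  stats::approx(rev(k_native), rev(spectrum$intensity_au),
                xout = k, rule = 2)$y
}

#' Resample a wavelength-uniform fringe onto the uniform k grid
#'
#' k-space linearization: detector data are sampled uniformly in wavelength;
#' this interpolates each A-line onto the uniform wavenumber grid required
#' before the FFT. Cubic spline interpolation by default; linear is the
#' cheaper fallback.
#'
#' @param fringes Numeric vector (one A-line) or P x A matrix sampled on the
#'   source's wavelength grid.
#' @param spectrum The `oct_source` describing the wavelength sampling.
#' @param grid Target `oct_kgrid` (same length).
#' @param method `"spline"` (default) or `"linear"`.
#' @return Fringe vector/matrix on the uniform k grid.
#' @export
linearize_fringe <- function(fringes, spectrum, grid,
                             method = c("spline", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(spectrum, "oct_source"), inherits(grid, "oct_kgrid"))
  lam_um <- spectrum$wavelengths_nm / 1000
  k_native <- rev(2 * pi / lam_um)
  one <- function(v) {
    v <- rev(v)                          # native k increases as lambda falls
    if (method == "spline")
      stats::spline(k_native, v, xout = grid$k_values, method = "natural")$y
    else
      stats::approx(k_native, v, xout = grid$k_values, rule = 2)$y
  }
  if (is.matrix(fringes)) apply(fringes, 2L, one) else one(fringes)
}

# Axial sampling pitch (um per depth row) of the FFT of a fringe on `grid`.
# Pathlengths here are total optical pathlength differences, so there is no
# extra factor of two.

#' @rdname resample_to_k
#' @export
depth_pitch_um <- function(grid) {
  stopifnot(inherits(grid, "oct_kgrid"))
  P <- length(grid$k_values)
  dk <- (max(grid$k_values) - min(grid$k_values)) / (P - 1)
  2 * pi / (P * dk)
}

# Maximum unambiguous pathlength difference before aliasing.
max_depth_um <- function(grid) {
  P <- length(grid$k_values)
  dk <- (max(grid$k_values) - min(grid$k_values)) / (P - 1)
  pi / dk
}
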