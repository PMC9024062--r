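# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_octadc <- function(..., class = "octadc_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Run an expression with a locally seeded RNG
#'
#' Seeds the generator for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded simulations never perturb the session
#' stream. `seed = NULL` leaves the current stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying inside
# the 32-bit signed range R requires of set.seed().
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1000003 + as.numeric(p)) %% 2147483629
  as.integer(h)
}

#' Interpolated full width at half maximum of a sampled peak
#'
#' Walks outward from `peak` to the half-maximum crossings and locates each
#' by linear interpolation between the bracketing samples. Returns width in
#' sample units, or `NA` if a crossing is not bracketed inside the vector.
#' @noRd
fwhm_interp <- function(y, peak = which.max(y)) {
  half <- y[peak] / 2
  n <- length(y)
  left <- NA_real_
  for (i in seq(peak, 2L)) {
    if (y[i - 1L] <= half) {
      left <- (i - 1L) + (half - y[i - 1L]) / (y[i] - y[i - 1L])
      break
    }
  }
  right <- NA_real_
  for (i in seq(peak, n - 1L)) {
    if (y[i + 1L] <= half) {
      right <- i + (y[i] - half) / (y[i] - y[i + 1L])
      break
    }
  }
  right - left
}

# Block-mean pooling of a matrix by integer factors (fr rows, fc cols).
# Trailing rows/cols that do not fill a block are dropped.
block_mean <- function(x, fr = 1L, fc = 1L) {
  fr <- as.integer(fr); fc <- as.integer(fc)
  if (fr == 1L && fc == 1L) return(x)
  nr <- nrow(x) %/% fr
  nc <- ncol(x) %/% fc
  x <- x[seq_len(nr * fr), seq_len(nc * fc), drop = FALSE]
  dim(x) <- c(fr, nr, fc, nc)
  out <- apply(x, c(2L, 4L), mean)
  out
}

assert_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_octadc(what, " must be a numeric matrix")
  if (!all(is.finite(x)))
    stop_octadc(what, " contains non-finite values")
  invisible(x)
}
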