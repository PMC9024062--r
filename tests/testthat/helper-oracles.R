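# Independent brute-force metric implementations: per-pixel loops over
# Gaussian-weighted patches, evaluating the luminance, contrast and
# structure terms separately (with C3 = C2/2, c * s folds into the
# combined contrast-structure term). Deliberately naive — these exist to
# pin the fast implementations, not to be fast.

naive_ssim_maps <- function(x, y, params) {
  w1 <- octadc:::gaussian_kernel1d(params$window, params$sigma)
  W <- outer(w1, w1)
  r <- (params$window - 1) / 2
  H <- nrow(x); Wd <- ncol(x)
  lmap <- csmap <- matrix(NA_real_, H - 2 * r, Wd - 2 * r)
  for (i in seq_len(H - 2 * r)) {
    for (j in seq_len(Wd - 2 * r)) {
      px <- x[i:(i + 2 * r), j:(j + 2 * r)]
      py <- y[i:(i + 2 * r), j:(j + 2 * r)]
      mx <- sum(W * px); my <- sum(W * py)
      vx <- sum(W * (px - mx)^2); vy <- sum(W * (py - my)^2)
      cxy <- sum(W * (px - mx) * (py - my))
      l <- (2 * mx * my + params$C1) / (mx^2 + my^2 + params$C1)
      cc <- (2 * sqrt(vx) * sqrt(vy) + params$C2) / (vx + vy + params$C2)
      ss <- (cxy + params$C3) / (sqrt(vx) * sqrt(vy) + params$C3)
      lmap[i, j] <- l
      csmap[i, j] <- cc * ss
    }
  }
  list(l = lmap, cs = csmap)
}

naive_ssim <- function(x, y, params) {
  m <- naive_ssim_maps(x, y, params)
  mean(m$l * m$cs)
}

naive_ms_ssim <- function(x, y, params) {
  M <- params$scales
  w <- params$weights[seq_len(M)]; w <- w / sum(w)
  out <- 1
  for (j in seq_len(M)) {
    m <- naive_ssim_maps(x, y, params)
    if (j < M) {
      out <- out * mean(m$cs)^w[j]
      x <- octadc:::downsample2(x); y <- octadc:::downsample2(y)
    } else out <- out * mean(m$l * m$cs)^w[j]
  }
  out
}
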