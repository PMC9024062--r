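# Training-pair manufacture: multichannel compensation stacks as inputs,
# stitched all-depth-compensated B-scans as targets.

# Shared normalization applied to every image fed to the network: optional
# axial/lateral block-mean pooling of the linear image, then log display
# compression to [0, 1] (per-image min-max by construction).
prep_image <- function(linear_img, norm) {
  pooled <- block_mean(linear_img, norm$pool_depth %||% 1L,
                       norm$pool_lateral %||% 1L)
  m <- max(pooled)
  if (m <= 0) stop_octadc("cannot normalize an all-zero image")
  db <- 20 * log10(pmax(pooled, 0) / m)
  db[!is.finite(db)] <- norm$floor_db
  db <- pmax(db, norm$floor_db)
  (db - norm$floor_db) / (-norm$floor_db)
}

normalize_stack <- function(stack, norm) {
  norm <- norm %||% list(floor_db = -60, pool_depth = 1L, pool_lateral = 1L)
  imgs <- lapply(stack$bscans, function(b) prep_image(b$image, norm))
  array(unlist(imgs, use.names = FALSE),
        c(nrow(imgs[[1]]), ncol(imgs[[1]]), length(imgs)))
}

#' Build training pairs from simulated volumes
#'
#' For every frame of every volume: reconstruct the `gt_channels`-coefficient
#' stack over `c_range`, stitch the all-depth ground truth from it (band i
#' from channel i), and pair it with an `n_channels` input stack over the
#' same range. The ground truth is always built from the full
#' `gt_channels = 5` stack regardless of the input channel count, and
#' splits are assigned volume-wise — no volume contributes to both splits.
#'
#' @param volumes List of `oct_volume`s (>= 2, so a split exists).
#' @param n_channels Input stack size (1, 3, 5, 7, 9).
#' @param c_range `c(c_min, c_max)` coefficient range (pixel mode).
#' @param bands Number of stitching bands (= `gt_channels`) or an
#'   `oct_bands` object on the full-resolution depth rows.
#' @param test_volumes Indices of the held-out volumes; default the last
#'   `max(1, round(2/9 * n))` volumes, mirroring a 7-train/2-test design.
#' @param gt_channels Stack size the ground truth is stitched from.
#' @param floor_db,pool_depth,pool_lateral Normalization: log-display floor
#'   and block-mean pooling factors applied to every image (pooling reduces
#'   e.g. 256-row B-scans to 128-row network inputs).
#' @param feather Seam blend width for the ground-truth stitch.
#' @return An `oct_dataset`: list of pairs (`input` H x W x C array,
#'   `target` H x W matrix in `[0, 1]`, `split`, provenance) plus the
#'   normalization record and the coefficient ladder.
#' @export
build_dataset <- function(volumes, n_channels = 5L, c_range = c(-40, 40),
                          bands = 5L, test_volumes = NULL,
                          gt_channels = 5L, floor_db = -60,
                          pool_depth = 2L, pool_lateral = 1L,
                          feather = 0L) {
  if (length(volumes) < 2L)
    stop_octadc("need >= 2 volumes for a train/test split")
  n_channels <- as.integer(n_channels)
  gt_channels <- as.integer(gt_channels)
  if (is.null(test_volumes))
    test_volumes <- length(volumes) - seq_len(max(1L, round(2 / 9 * length(volumes)))) + 1L
  if (length(test_volumes) >= length(volumes))
    stop_octadc("test_volumes would leave no training volumes")
  norm <- list(floor_db = floor_db, pool_depth = as.integer(pool_depth),
               pool_lateral = as.integer(pool_lateral))
  Z <- nrow(volumes[[1]]$frames[[1]]$fringes) %/% 2L
  if (!inherits(bands, "oct_bands"))
    bands <- partition_depth_bands(bands, Z)
  # input channel indices inside the gt stack when the ladders nest
  sub_idx <- if (n_channels == 1L) (gt_channels + 1L) / 2
             else seq(1L, gt_channels, length.out = n_channels)
  nested <- n_channels <= gt_channels && all(sub_idx == round(sub_idx))
  coeffs <- seq(c_range[1], c_range[2], length.out = gt_channels)
  pairs <- list()
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    split <- if (v %in% test_volumes) "test" else "train"
    for (fr in vol$frames) {
      stack_gt <- build_compensation_stack(fr, c_range[1], c_range[2],
                                           gt_channels)
      gt <- stitch_ground_truth(stack_gt, bands, feather = feather)
      if (nested) {
        in_stack <- stack_gt
        in_stack$bscans <- stack_gt$bscans[round(sub_idx)]
        in_stack$coefficients <- stack_gt$coefficients[round(sub_idx)]
      } else {
        in_stack <- build_compensation_stack(fr, c_range[1], c_range[2],
                                             n_channels)
      }
      pairs[[length(pairs) + 1L]] <- structure(list(
        input = normalize_stack(in_stack, norm),
        target = prep_image(gt$image, norm),
        split = split,
        volume = fr$volume_index, location = fr$location_index,
        repeat_index = fr$repeat_index,
        coefficients = in_stack$coefficients), class = "oct_pair")
    }
  }
  structure(list(pairs = pairs, n_channels = n_channels,
                 c_range = c_range, gt_coefficients = coeffs,
                 bands = bands, norm = norm,
                 test_volumes = test_volumes),
            class = "oct_dataset")
}

#' @export
print.oct_dataset <- function(x, ...) {
  tab <- table(vapply(x$pairs, `[[`, character(1), "split"))
  cat(sprintf("<oct_dataset> %d pairs (%s), %d channels, %dx%d\n",
              length(x$pairs),
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              x$n_channels, nrow(x$pairs[[1]]$target),
              ncol(x$pairs[[1]]$target)))
  invisible(x)
}

# The uncompensated reference of a pair: the mid channel of its (odd-sized)
# input stack, i.e. the reconstruction with the midpoint coefficient.
pair_uc_image <- function(pair) {
  C <- dim(pair$input)[3]
  pair$input[, , (C + 1L) %/% 2L]
}

#' Derive a lower-channel dataset from a nested one
#'
#' Subsets each pair's input stack to `n_channels` equally spaced channels
#' (sharing both endpoints; the 1-channel case keeps the midpoint), leaving
#' targets untouched. Only ladders that nest exactly are allowed, e.g.
#' 1/3/5 from a 5-channel dataset or 1/3/5/9 from a 9-channel one.
#' @param dataset An `oct_dataset`.
#' @param n_channels Target channel count.
#' @export
subset_channels <- function(dataset, n_channels) {
  stopifnot(inherits(dataset, "oct_dataset"))
  C <- dataset$n_channels
  n_channels <- as.integer(n_channels)
  if (n_channels == C) return(dataset)
  idx <- if (n_channels == 1L) (C + 1L) / 2
         else seq(1L, C, length.out = n_channels)
  if (any(idx != round(idx)))
    stop_octadc(n_channels, " channels do not nest inside ", C)
  idx <- as.integer(round(idx))
  dataset$pairs <- lapply(dataset$pairs, function(p) {
    p$input <- p$input[, , idx, drop = FALSE]
    p$coefficients <- p$coefficients[idx]
    p
  })
  dataset$n_channels <- n_channels
  dataset
}
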