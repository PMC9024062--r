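# The channel-count comparison: train one model per input-channel count
# (and per seed), evaluate PSNR / MS-SSIM of the predictions and of the
# uncompensated baseline against the stitched ground truth on the held-out
# split, after repeated-frame averaging.

# Group test pairs by (volume, location), average the images of each
# repeat group, and score candidate vs target.
score_split <- function(pairs, predict_fun, sp, group_repeats = TRUE) {
  keys <- vapply(pairs, function(p)
    sprintf("v%03d_l%03d", p$volume, p$location), character(1))
  groups <- split(seq_along(pairs), keys)
  rows <- lapply(groups, function(idx) {
    cand <- average_repeats(lapply(pairs[idx], predict_fun),
                            if (group_repeats) length(idx) else 1L)
    gt <- average_repeats(lapply(pairs[idx], `[[`, "target"),
                          if (group_repeats) length(idx) else 1L)
    data.frame(
      psnr_db = mapply(function(f, g) psnr(f, g), gt, cand),
      ms_ssim = mapply(function(f, g) ms_ssim(g, f, sp), gt, cand))
  })
  do.call(rbind, rows)
}

#' Channel-count comparison experiment
#'
#' Trains one restoration model per `channel_counts` entry per seed on the
#' dataset's training split, then evaluates PSNR and MS-SSIM of the
#' predictions — and of the uncompensated (mid-channel) baseline — against
#' the stitched ground truth on the held-out split. Repeated frames at a
#' location are averaged before metrics are computed. Channel ladders are
#' derived from the dataset by [subset_channels()], so every model sees the
#' same frames.
#'
#' @param dataset An `oct_dataset` whose channel ladder nests all requested
#'   counts (e.g. a 5-channel dataset for counts 1/3/5).
#' @param channel_counts Input channel counts to compare.
#' @param seeds One model is trained per (count, seed); metrics are
#'   averaged across seeds.
#' @param config Base [adcnet_config()]; its `n_channels` and `rng_seed`
#'   are overridden per run.
#' @param ssim_scales MS-SSIM scales used for scoring.
#' @param verbose Print one line per trained model.
#' @return An `oct_quality_report`: `summary` (per-variant mean/sd of both
#'   metrics, the `UC` row first), `per_image` rows, and the averaging
#'   protocol. `plot()` draws the mean +/- sd panels.
#' @export
run_channel_experiment <- function(dataset,
                                   channel_counts = c(1L, 3L, 5L),
                                   seeds = c(1L, 2L, 3L),
                                   config = adcnet_config(),
                                   ssim_scales = 3L,
                                   verbose = FALSE) {
  stopifnot(inherits(dataset, "oct_dataset"))
  sp <- ssim_params(scales = ssim_scales)
  test_pairs <- Filter(function(p) p$split == "test", dataset$pairs)
  if (length(test_pairs) == 0L) stop_octadc("dataset has no test split")
  per_image <- list()
  # model-independent uncompensated baseline
  uc <- score_split(test_pairs, pair_uc_image, sp)
  per_image[["UC"]] <- cbind(variant = "UC", seed = NA_integer_, uc)
  for (nc in channel_counts) {
    sub <- subset_channels(dataset, nc)
    for (sd_i in seeds) {
      cfg <- config
      cfg$n_channels <- as.integer(nc)
      cfg$rng_seed <- as.integer(sd_i)
      model <- adcnet_train(build_adcnet(cfg), sub)
      sc <- score_split(Filter(function(p) p$split == "test", sub$pairs),
                        function(p) adcnet_predict(model, p$input)$image, sp)
      if (verbose)
        message(sprintf("M%d seed %d: MS-SSIM %.4f, PSNR %.2f dB", nc, sd_i,
                        mean(sc$ms_ssim), mean(sc$psnr_db)))
      per_image[[sprintf("M%d_s%d", nc, sd_i)]] <-
        cbind(variant = sprintf("M%d", nc), seed = sd_i, sc)
    }
  }
  per_image <- do.call(rbind, per_image)
  rownames(per_image) <- NULL
  variants <- c("UC", sprintf("M%d", sort(channel_counts)))
  summary <- do.call(rbind, lapply(variants, function(v) {
    rows <- per_image[per_image$variant == v, ]
    data.frame(variant = v, n = nrow(rows),
               psnr_mean = mean(rows$psnr_db), psnr_sd = stats::sd(rows$psnr_db),
               ms_ssim_mean = mean(rows$ms_ssim),
               ms_ssim_sd = stats::sd(rows$ms_ssim))
  }))
  structure(list(summary = summary, per_image = per_image,
                 seeds = seeds, channel_counts = channel_counts,
                 averaging = "repeats averaged per location before metrics",
                 ssim_scales = ssim_scales),
            class = "oct_quality_report")
}

#' @export
print.oct_quality_report <- function(x, ...) {
  cat("<oct_quality_report>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.oct_quality_report <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  at <- seq_len(nrow(s))
  for (metric in c("ms_ssim", "psnr")) {
    m <- s[[paste0(metric, "_mean")]]
    sdv <- s[[paste0(metric, "_sd")]]
    sdv[is.na(sdv)] <- 0
    ylim <- range(c(m - sdv, m + sdv))
    graphics::plot(at, m, pch = 19, xaxt = "n", xlab = "", ylim = ylim,
         ylab = if (metric == "ms_ssim") "MS-SSIM" else "PSNR (dB)", ...)
    graphics::axis(1, at = at, labels = s$variant)
    graphics::arrows(at, m - sdv, at, m + sdv, angle = 90, code = 3,
                     length = 0.04)
    graphics::lines(at, m, lty = 2)
  }
  invisible(x)
}
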