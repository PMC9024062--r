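# Sharpness scoring, coefficient recovery, band partitioning, stitching.

test_that("sharpness score has its closed-form values and scale invariance", {
  impulse <- matrix(0, 10, 1); impulse[4] <- 5
  expect_equal(sharpness_score(impulse), 1)
  uniform <- matrix(1, 25, 1)
  expect_equal(sharpness_score(uniform), 1 / 25)
  set.seed(5)
  img <- matrix(runif(200), 20, 10)
  expect_equal(sharpness_score(img * 7.3), sharpness_score(img))
  expect_equal(sharpness_score(matrix(0, 5, 5)), 0)
  expect_error(sharpness_score(img, c(0, 10)), "within")
})

test_that("matched compensation scores sharper than mismatched in its band", {
  fr <- single_layer_fringe(200, 1, a2 = 18)
  row <- round(200 / depth_pitch_um(desk_grid))
  band <- c(row - 20, row + 20)
  score <- function(c2)
    sharpness_score(octadc:::new_bscan(
      matrix(reconstruct_ascan(fr, desk_grid, a2 = c2), ncol = 1)), band)
  expect_gt(score(18), score(-10))
  expect_gt(score(18), score(40))
})

test_that("optimal coefficient recovery cancels the injected dispersion", {
  # the background estimate is the mean over A-lines, so the layer needs
  # lateral structure (curvature + speckle) to survive subtraction
  samp <- layered_sample(250, 1, a2 = 30, curvature_sag_um = 30,
                         speckle_density = 4)
  v <- simulate_volume(samp, 1, 16, noise = NULL, rng_seed = 1)
  row <- round(250 / depth_pitch_um(desk_grid))
  band <- c(row - 30, row + 30)
  est <- estimate_optimal_coeff(v$frames[[1]], band, c(-40, 40, 5))
  expect_lt(abs(est - 30), 5)
  # dispersion-free layer recovers zero
  samp0 <- layered_sample(250, 1, curvature_sag_um = 30,
                          speckle_density = 4)
  v0 <- simulate_volume(samp0, 1, 16, noise = NULL, rng_seed = 1)
  expect_lt(abs(estimate_optimal_coeff(v0$frames[[1]], band,
                                       c(-40, 40, 5))), 5)
  expect_equal(estimate_optimal_coeff(v$frames[[1]], band, 12), 12)
})

test_that("flat sharpness landscapes fall back to the sweep midpoint", {
  # an empty frame scores zero everywhere: no coefficient can win
  fr <- octadc:::new_raw_frame(matrix(0, 256, 8),
                               make_source_spectrum(n_pixels = 256),
                               resample_to_k(make_source_spectrum(n_pixels = 256)))
  expect_warning(est <- estimate_optimal_coeff(fr, c(40, 100), c(-40, 40, 20)),
                 "degenerate|midpoint")
  expect_equal(est, 0)
})

test_that("depth bands tile the axis with the remainder in the last band", {
  b <- partition_depth_bands(5, 250)
  expect_equal(b$bands, list(c(1, 50), c(51, 100), c(101, 150),
                             c(151, 200), c(201, 250)))
  b2 <- partition_depth_bands(3, 10)
  expect_equal(b2$bands, list(c(1, 3), c(4, 6), c(7, 10)))
  expect_equal(partition_depth_bands(1, 64)$bands, list(c(1, 64)))
  expect_equal(partition_depth_bands(3, 9, c(1, 3, 6, 10))$bands,
               list(c(1, 2), c(3, 5), c(6, 9)))
  expect_error(partition_depth_bands(3, 9, c(1, 3, 3, 10)), "ascending")
  expect_error(partition_depth_bands(20, 10), "n_bands")
})

test_that("stitching copies bands bit-exactly and is idempotent", {
  fr <- frame_from_fringe(single_layer_fringe(200, 1))
  stack <- build_compensation_stack(fr, -40, 40, 5)
  Z <- nrow(stack$bscans[[1]]$image)
  # N identical B-scans stitch back to themselves for any bands
  same <- stack
  same$bscans <- rep(stack$bscans[3], 5)
  bands <- partition_depth_bands(5, Z)
  expect_identical(stitch_ground_truth(same, bands)$image,
                   stack$bscans[[3]]$image)
  # two-channel hard stitch is bit-exact per half
  two <- stack
  two$bscans <- stack$bscans[c(1, 5)]
  two$coefficients <- stack$coefficients[c(1, 5)]
  b2 <- partition_depth_bands(2, Z)
  st <- stitch_ground_truth(two, b2)
  expect_identical(st$image[1:(Z / 2), ], stack$bscans[[1]]$image[1:(Z / 2), ])
  expect_identical(st$image[(Z / 2 + 1):Z, ],
                   stack$bscans[[5]]$image[(Z / 2 + 1):Z, ])
  expect_error(stitch_ground_truth(two, bands), "must equal")
})

test_that("feathered stitching blends linearly across the seam", {
  img1 <- octadc:::new_bscan(matrix(0, 16, 4))
  img2 <- octadc:::new_bscan(matrix(1, 16, 4))
  stack <- structure(list(coefficients = c(-1, 1),
                          bscans = list(img1, img2)), class = "oct_stack")
  st <- stitch_ground_truth(stack, partition_depth_bands(2, 16), feather = 2)
  expect_equal(st$image[7:10, 1], c(0.125, 0.375, 0.625, 0.875))
  expect_equal(st$image[1:6, 1], rep(0, 6))
  expect_equal(st$image[11:16, 1], rep(1, 6))
})

test_that("stitched ground truth dominates every channel's band sharpness", {
  # one matched layer per band: channel i must win inside band i, and the
  # stitched image inherits the winner everywhere
  src <- make_source_spectrum(n_pixels = 512)
  grid <- resample_to_k(src)
  samp <- synth_retina_sample(octadc:::max_depth_um(grid),
                              a2_jitter_sd = 0, speckle_density = 0,
                              curvature_sag_um = 10, seed = 11)
  v <- simulate_volume(samp, 1, 32, noise = NULL, rng_seed = 2,
                       source = src, grid = grid)
  stack <- build_compensation_stack(v$frames[[1]], -40, 40, 5)
  bands <- partition_depth_bands(5, 256)
  gt <- stitch_ground_truth(stack, bands)
  for (i in 1:5) {
    band <- bands$bands[[i]]
    s_gt <- sharpness_score(gt, band)
    for (ch in 1:5)
      expect_gte(s_gt, sharpness_score(stack$bscans[[ch]], band) - 1e-12)
  }
})

test_that("datasets split by volume and share the 5-channel ground truth", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "oct_dataset")
  expect_length(ds$pairs, 8)          # 2 volumes x 2 locations x 2 repeats
  splits <- vapply(ds$pairs, `[[`, character(1), "split")
  vols <- vapply(ds$pairs, `[[`, integer(1), "volume")
  expect_true(all(tapply(splits, vols, function(s) length(unique(s))) == 1))
  expect_setequal(unique(splits), c("train", "test"))
  expect_equal(dim(ds$pairs[[1]]$input), c(32, 48, 5))
  expect_true(all(vapply(ds$pairs, function(p)
    max(p$target) <= 1 && min(p$target) >= 0, logical(1))))
  # 1-channel variant keeps the same target and the midpoint coefficient
  ds1 <- build_dataset(tiny_volumes(), n_channels = 1, pool_depth = 4)
  expect_equal(dim(ds1$pairs[[1]]$input)[3], 1)
  expect_equal(ds1$pairs[[1]]$coefficients, 0)
  expect_equal(ds1$pairs[[1]]$target, ds$pairs[[1]]$target)
  # deterministic rebuild
  ds_again <- build_dataset(tiny_volumes(), n_channels = 5, pool_depth = 4)
  expect_identical(ds$pairs[[1]]$input, ds_again$pairs[[1]]$input)
  expect_error(build_dataset(tiny_volumes()[1], n_channels = 5), ">= 2")
})

test_that("channel subsetting keeps endpoints and the midpoint", {
  ds <- tiny_dataset()
  d3 <- subset_channels(ds, 3)
  expect_equal(d3$pairs[[1]]$coefficients, c(-40, 0, 40))
  expect_identical(d3$pairs[[1]]$input[, , 2],
                   ds$pairs[[1]]$input[, , 3])
  d1 <- subset_channels(ds, 1)
  expect_equal(d1$pairs[[1]]$coefficients, 0)
  expect_identical(octadc:::pair_uc_image(ds$pairs[[1]]),
                   d1$pairs[[1]]$input[, , 1])
})
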