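# Restoration network: architecture contracts, loss, gradients, training.

tiny_cfg <- function(...) {
  defaults <- list(n_channels = 3, encoder_stages = 2, growth_per_block = 3,
                   base_filters = 4, rng_seed = 3)
  do.call(adcnet_config, utils::modifyList(defaults, list(...)))
}

test_that("the network preserves spatial shape and reports parameters", {
  m <- build_adcnet(tiny_cfg())
  x <- array(runif(16 * 24 * 2 * 3), c(16, 24, 2, 3))
  out <- nn_forward(m, x)$output
  expect_equal(dim(out), c(16, 24, 2, 1))
  expect_true(all(out >= 0 & out <= 1))   # sigmoid head
  expect_gt(m$n_params, 0)
})

test_that("channel count only changes the first convolution", {
  m1 <- build_adcnet(adcnet_config(n_channels = 1, encoder_stages = 2,
                                   growth_per_block = 3, base_filters = 4))
  m9 <- build_adcnet(adcnet_config(n_channels = 9, encoder_stages = 2,
                                   growth_per_block = 3, base_filters = 4))
  shapes <- function(m) Filter(Negate(is.null), lapply(m$nodes, function(n)
    if (n$op == "conv") c(n$cin, n$cout)))
  s1 <- shapes(m1); s9 <- shapes(m9)
  expect_equal(s1[[1]], c(1L, 4L))
  expect_equal(s9[[1]], c(9L, 4L))
  expect_identical(s1[-1], s9[-1])
})

test_that("indivisible inputs fail with the required padding named", {
  m <- build_adcnet(tiny_cfg())
  expect_error(adcnet_predict(m, array(0, c(15, 16, 3))), "pad to 16x16")
})

test_that("dice loss matches hand-evaluated overlap cases", {
  mask <- matrix(0, 8, 8); mask[3:6, 3:6] <- 1
  expect_equal(dice_loss(mask, mask), 0, tolerance = 1e-5)
  other <- matrix(0, 8, 8); other[1:2, 1:2] <- 1
  expect_equal(dice_loss(mask, other), 1, tolerance = 1e-4)
  expect_equal(dice_loss(0.5 * mask, mask), 1 / 3, tolerance = 1e-5)
  expect_true(dice_loss(matrix(runif(64), 8), matrix(runif(64), 8)) <= 1)
  expect_error(dice_loss(mask, matrix(0, 4, 4)), "shapes")
})

test_that("analytic gradients match finite differences through the graph", {
  m <- build_adcnet(tiny_cfg())
  set.seed(5)
  x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  loss_at <- function(model) {
    out <- nn_forward(model, x, training = TRUE)$output
    octadc:::loss_and_grad(out, y, "dice")$loss
  }
  fwd <- nn_forward(m, x, training = TRUE)
  lg <- octadc:::loss_and_grad(fwd$output, y, "dice")
  pg <- nn_backward(m, fwd, lg$grad)
  params <- octadc:::nn_get_params(m)
  set.seed(6)
  for (nm in sample(names(params), 8)) {
    id <- as.integer(sub("^n(\\d+)_.*", "\\1", nm))
    slot <- sub(".*_(W\\d+|b|gamma|beta)$", "\\1", nm)
    g <- pg[[id]]
    analytic <- if (startsWith(slot, "W"))
      g$W[[as.integer(sub("W", "", slot))]]
    else if (slot == "b") g$b
    else if (slot == "gamma") g$gamma else g$beta
    i <- sample(length(params[[nm]]), 1)
    eps <- 1e-5
    up <- params[[nm]]; up[i] <- up[i] + eps
    dn <- params[[nm]]; dn[i] <- dn[i] - eps
    fd <- (loss_at(octadc:::nn_set_param(m, nm, up)) -
             loss_at(octadc:::nn_set_param(m, nm, dn))) / (2 * eps)
    expect_equal(analytic[i], fd, tolerance = 1e-4)
  }
})

# Learnable toys. The mask toy (binary disk targets, noisy copies as input
# channels) suits the dice loss, whose optimum for continuous targets is a
# thresholded map rather than zero; the mean toy (target = channel-wise
# mean) is used where the loss kind is irrelevant.
mask_pairs <- function(n, hw = 16, channels = 3, seed = 21) {
  octadc:::with_seed(seed, lapply(seq_len(n), function(i) {
    cx <- runif(1, 5, hw - 4); cy <- runif(1, 5, hw - 4)
    r <- runif(1, 2.5, 4.5)
    d <- outer(seq_len(hw), seq_len(hw),
               function(a, b) sqrt((a - cx)^2 + (b - cy)^2))
    target <- (d <= r) * 1
    inp <- array(0, c(hw, hw, channels))
    for (ch in seq_len(channels))
      inp[, , ch] <- pmin(pmax(target + rnorm(hw * hw, 0, 0.3), 0), 1)
    list(input = inp, target = target, split = "train")
  }))
}

toy_pairs <- function(n, hw = 16, channels = 3, seed = 21) {
  octadc:::with_seed(seed, lapply(seq_len(n), function(i) {
    inp <- array(runif(hw * hw * channels), c(hw, hw, channels))
    list(input = inp, target = apply(inp, c(1, 2), mean), split = "train")
  }))
}

test_that("dice training descends on a learnable segmentation-style toy", {
  cfg <- tiny_cfg(epochs = 20, batch_size = 4, learning_rate = 5e-3,
                  val_fraction = 0)
  m <- adcnet_train(build_adcnet(cfg), mask_pairs(32))
  h <- m$history$log
  expect_equal(nrow(h), 20)
  expect_lt(h$train_loss[20], h$train_loss[1])
  expect_lt(h$train_loss[20], 0.5 * h$train_loss[1])
})

test_that("training is reproducible and frozen at zero learning rate", {
  cfg <- tiny_cfg(epochs = 3, batch_size = 8, learning_rate = 1e-3,
                  val_fraction = 0)
  pairs <- toy_pairs(12)
  h1 <- adcnet_train(build_adcnet(cfg), pairs)$history$log
  h2 <- adcnet_train(build_adcnet(cfg), pairs)$history$log
  expect_equal(h1$train_loss, h2$train_loss, tolerance = 1e-4)
  frozen <- adcnet_train(build_adcnet(cfg), pairs, learning_rate = 0)
  expect_lt(diff(range(frozen$history$log$train_loss)), 1e-8)
})

test_that("prediction is deterministic and validates channel counts", {
  m <- build_adcnet(tiny_cfg())
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p1 <- adcnet_predict(m, x)
  expect_s3_class(p1, "oct_bscan")
  expect_equal(dim(p1$image), c(16, 16))
  expect_true(all(p1$image >= 0 & p1$image <= 1))
  expect_identical(p1$image, adcnet_predict(m, x)$image)
  expect_error(adcnet_predict(m, array(0, c(16, 16, 5))),
               "5 channels.*expects 3")
  outs <- adcnet_predict_volume(m, list())
  expect_length(outs, 0)
})

test_that("a converged model memorizes better than the mid-channel input", {
  # 4 pairs where channels disagree; after convergence the prediction must
  # resemble the target more than the middle input channel does
  set.seed(30)
  pairs <- lapply(1:4, function(i) {
    target <- matrix(runif(16 * 16), 16)
    inp <- array(0, c(16, 16, 3))
    inp[, , 1] <- matrix(runif(256), 16)
    inp[, , 2] <- 0.3 * target + 0.7 * matrix(runif(256), 16)
    inp[, , 3] <- target
    list(input = inp, target = target, split = "train")
  })
  cfg <- tiny_cfg(epochs = 40, batch_size = 4, learning_rate = 5e-3,
                  val_fraction = 0)
  m <- adcnet_train(build_adcnet(cfg), pairs)
  p1 <- ssim_params(scales = 1)
  sc <- vapply(pairs, function(p) {
    pred <- adcnet_predict(m, p$input)$image
    ms_ssim(pred, p$target, p1) - ms_ssim(p$input[, , 2], p$target, p1)
  }, numeric(1))
  expect_gt(mean(sc), 0)
})

test_that("softmax and linear heads honour their contracts", {
  msm <- build_adcnet(tiny_cfg(final_activation = "softmax"))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  # single-channel softmax is degenerate: constant one
  expect_equal(max(abs(adcnet_predict(msm, x)$image - 1)), 0)
  mln <- build_adcnet(tiny_cfg(final_activation = "linear"))
  expect_false(all(adcnet_predict(mln, x)$image >= 0))
})

test_that("checkpoints round-trip and the encoder hook loads weights", {
  m <- build_adcnet(tiny_cfg())
  f <- withr::local_tempfile(fileext = ".rds")
  adcnet_save(m, f)
  m2 <- adcnet_load(f)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(adcnet_predict(m, x)$image, adcnet_predict(m2, x)$image)
  # encoder-only load: encoder weights equal, head untouched
  fresh <- build_adcnet(tiny_cfg(rng_seed = 99))
  hooked_cfg <- tiny_cfg(rng_seed = 99)
  hooked_cfg$pretrained_encoder_path <- f
  hooked <- build_adcnet(hooked_cfg)
  p_src <- octadc:::nn_get_params(m)
  p_hook <- octadc:::nn_get_params(hooked)
  p_fresh <- octadc:::nn_get_params(fresh)
  enc <- grep("_enc", names(p_src), value = TRUE)
  expect_equal(p_hook[enc], p_src[enc])
  head_nm <- grep("head", names(p_src), value = TRUE)
  expect_equal(p_hook[head_nm], p_fresh[head_nm])
})
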