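# The restoration network: a compact UNet-style encoder-decoder with dense
# blocks (concatenative convolution stages with intra-block skips), channel-
# halving transition blocks, max-pool downsampling, and a decoder that
# concatenates each upsampled map with the matching transition output.
# Batch norm + ReLU trail every convolution except the terminal one.

#' Configuration of the restoration network
#'
#' @param n_channels Input channels: 1, 3, 5, 7 or 9 partially compensated
#'   B-scans.
#' @param encoder_stages Number of dense-block/pool stages; input spatial
#'   dims must be divisible by `2^encoder_stages`.
#' @param growth_per_block Channels added by each convolution inside a dense
#'   block.
#' @param block_layers Convolutions per dense block.
#' @param base_filters Decoder convolution width (and bottleneck scale).
#' @param final_activation `"sigmoid"` (default), `"softmax"` or
#'   `"linear"`. Softmax over a single output channel is degenerate
#'   (constant 1) and is provided only for fidelity experiments; sigmoid
#'   preserves the `[0, 1]` image range while remaining trainable.
#' @param loss `"dice"` (default) or `"mae"`.
#' @param learning_rate Adam step size; default 1e-4.
#' @param epochs,batch_size Training schedule.
#' @param rng_seed Seed for initialization and batch shuffling; recorded in
#'   the model and every history artifact.
#' @param val_fraction Fraction of the training pairs held out for the
#'   per-epoch validation loss (best-checkpoint selection).
#' @param pretrained_encoder_path Optional RDS of named parameters written
#'   by [adcnet_save()]; matching encoder weights are loaded before
#'   training (transfer-learning hook).
#' @return An `adcnet_config` list.
#' @export
adcnet_config <- function(n_channels = 5L, encoder_stages = 4L,
                          growth_per_block = 16L, block_layers = 2L,
                          base_filters = 16L,
                          final_activation = c("sigmoid", "softmax", "linear"),
                          loss = c("dice", "mae"),
                          learning_rate = 1e-4, epochs = 20L,
                          batch_size = 4L, rng_seed = 1L,
                          val_fraction = 0.1,
                          pretrained_encoder_path = NULL) {
  n_channels <- as.integer(n_channels)
  if (!n_channels %in% c(1L, 3L, 5L, 7L, 9L))
    stop_octadc("n_channels must be one of 1, 3, 5, 7, 9")
  structure(list(n_channels = n_channels,
                 encoder_stages = as.integer(encoder_stages),
                 growth_per_block = as.integer(growth_per_block),
                 block_layers = as.integer(block_layers),
                 base_filters = as.integer(base_filters),
                 final_activation = match.arg(final_activation),
                 loss = match.arg(loss),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed),
                 val_fraction = val_fraction,
                 pretrained_encoder_path = pretrained_encoder_path),
            class = "adcnet_config")
}

#' Build the restoration network
#'
#' Assembles the encoder-decoder graph for `config` and initializes its
#' parameters (He-scaled, seeded by `config$rng_seed`). The encoder stacks
#' `encoder_stages` dense blocks, each a sequence of `block_layers`
#' convolutions whose outputs are concatenated onto the running feature map
#' (intra-block skip connections), followed by a 1x1 channel-halving
#' transition convolution and a 2x max-pool. The decoder mirrors the
#' encoder: 2x nearest-neighbour upsampling, concatenation with the
#' matching transition output, and a convolution stage. A terminal 1x1
#' convolution plus the configured activation produces the single-channel
#' compensated B-scan.
#'
#' @param config An [adcnet_config()].
#' @return An `oct_adcnet` model; `print()` reports the parameter count.
#' @export
build_adcnet <- function(config) {
  stopifnot(inherits(config, "adcnet_config"))
  g <- nn_builder(config$n_channels)
  cur <- g$input()
  # stem: lift the 1..9 input channels to a fixed width so the channel
  # count touches only the first convolution
  cur <- nn_cbr(g, cur, config$base_filters, name = "stem")
  trans <- integer(config$encoder_stages)
  for (s in seq_len(config$encoder_stages)) {
    for (l in seq_len(config$block_layers)) {
      r <- nn_cbr(g, cur, config$growth_per_block,
                  name = sprintf("enc%d_dense%d", s, l))
      cur <- g$concat(c(cur, r))
    }
    tw <- max(4L, g$channels[cur] %/% 2L)
    trans[s] <- nn_cbr(g, cur, tw, kernel = 1L,
                       name = sprintf("enc%d_trans", s))
    cur <- g$pool(trans[s])
  }
  cur <- nn_cbr(g, cur, 2L * config$base_filters, name = "bottleneck")
  for (s in rev(seq_len(config$encoder_stages))) {
    cur <- g$up(cur)
    cur <- g$concat(c(cur, trans[s]))
    cur <- nn_cbr(g, cur, config$base_filters, name = sprintf("dec%d", s))
  }
  out <- g$conv(cur, 1L, kernel = 1L, bias = TRUE, name = "head")
  out <- g$act(out, config$final_activation)
  nodes <- nn_init_params(g$nodes, config$rng_seed)
  model <- structure(list(nodes = nodes, config = config,
                          n_params = nn_param_count(nodes),
                          norm = NULL, seed = config$rng_seed),
                     class = "oct_adcnet")
  if (!is.null(config$pretrained_encoder_path))
    model <- adcnet_load_weights(model, config$pretrained_encoder_path,
                                 encoder_only = TRUE)
  model
}

#' @export
print.oct_adcnet <- function(x, ...) {
  cat(sprintf("<oct_adcnet> %d input channels, %d stages, %s parameters\n",
              x$config$n_channels, x$config$encoder_stages,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

check_divisible <- function(H, W, stages) {
  f <- 2L^stages
  if (H %% f != 0L || W %% f != 0L) {
    need_h <- ceiling(H / f) * f
    need_w <- ceiling(W / f) * f
    stop_octadc(sprintf(
      "input %dx%d is not divisible by 2^%d; pad to %dx%d",
      H, W, stages, need_h, need_w))
  }
}

#' Soft dice loss between two images in [0, 1]
#'
#' `1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)`, the continuous
#' relaxation of the dice overlap used to train the network: 0 for
#' identical images, 1 for disjoint support. For batched arrays the loss is
#' averaged per sample.
#'
#' @param pred,target Numeric arrays of identical shape with values in
#'   `[0, 1]`.
#' @param eps Stabilizer, default 1e-6.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred) %||% length(pred),
                 dim(target) %||% length(target)))
    stop_octadc("pred and target shapes differ")
  d <- dim(pred)
  if (!is.null(d) && length(d) == 4L && d[3] > 1L) {
    per <- vapply(seq_len(d[3]), function(n)
      dice_loss(pred[, , n, , drop = FALSE], target[, , n, , drop = FALSE],
                eps), numeric(1))
    return(mean(per))
  }
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

# Loss value and gradient wrt pred for batched (H, W, N, 1) arrays.
loss_and_grad <- function(pred, target, kind, eps = 1e-6) {
  d <- dim(pred)
  N <- d[3]
  grad <- array(0, d)
  total <- 0
  for (n in seq_len(N)) {
    p <- pred[, , n, , drop = FALSE]
    g <- target[, , n, , drop = FALSE]
    if (kind == "dice") {
      num <- 2 * sum(p * g) + eps
      den <- sum(p) + sum(g) + eps
      total <- total + (1 - num / den)
      grad[, , n, ] <- (num / den^2 - 2 * g / den) / N
    } else {                      # mae
      total <- total + mean(abs(p - g))
      grad[, , n, ] <- sign(p - g) / (length(p) * N)
    }
  }
  list(loss = total / N, grad = grad)
}

pairs_to_batch <- function(pairs, n_channels) {
  H <- nrow(pairs[[1]]$target); W <- ncol(pairs[[1]]$target)
  N <- length(pairs)
  x <- array(0, c(H, W, N, n_channels))
  y <- array(0, c(H, W, N, 1L))
  for (n in seq_len(N)) {
    x[, , n, ] <- pairs[[n]]$input
    y[, , n, 1L] <- pairs[[n]]$target
  }
  list(x = x, y = y)
}

#' Train the restoration network
#'
#' Seeded, shuffled mini-batch training with Adam on the dataset's training
#' split. A `val_fraction` of the training pairs is held out for the
#' per-epoch validation loss; the parameters with the best validation loss
#' are retained in the returned model. Deterministic given the seed.
#'
#' @param model An `oct_adcnet` from [build_adcnet()].
#' @param dataset An `oct_dataset` from [build_dataset()], or a plain list
#'   of training pairs.
#' @param epochs,batch_size,learning_rate Optional overrides of the model
#'   config.
#' @param verbose Print a one-line summary per epoch.
#' @return The trained model, with `model$history` (a data.frame of
#'   per-epoch train/validation loss, plus the seed and config) attached.
#' @export
adcnet_train <- function(model, dataset, epochs = NULL, batch_size = NULL,
                         learning_rate = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "oct_adcnet"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  pairs <- if (inherits(dataset, "oct_dataset"))
    Filter(function(p) p$split == "train", dataset$pairs) else dataset
  if (length(pairs) == 0L) stop_octadc("no training pairs supplied")
  if (inherits(dataset, "oct_dataset")) model$norm <- dataset$norm
  H <- nrow(pairs[[1]]$target); W <- ncol(pairs[[1]]$target)
  check_divisible(H, W, cfg$encoder_stages)
  n_val <- min(length(pairs) - 1L, max(0L, round(cfg$val_fraction * length(pairs))))
  with_seed(child_seed(cfg$rng_seed, 101L), {
    idx <- sample(length(pairs))
    val_idx <- head(idx, n_val)
    train_idx <- setdiff(idx, val_idx)
  })
  val_batch <- if (n_val > 0L)
    pairs_to_batch(pairs[val_idx], cfg$n_channels)
  state <- adam_init(model$nodes)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, nodes = model$nodes)
  t_adam <- 0L
  # one seeded permutation, reused every epoch: keeps runs (and the
  # frozen-optimizer degenerate case) exactly reproducible
  order_all <- with_seed(child_seed(cfg$rng_seed, 200L), sample(train_idx))
  for (epoch in seq_len(epochs)) {
    order_ep <- order_all
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, length(order_ep), by = batch_size)) {
      take <- order_ep[b0:min(b0 + batch_size - 1L, length(order_ep))]
      batch <- pairs_to_batch(pairs[take], cfg$n_channels)
      fwd <- nn_forward(model, batch$x, training = TRUE)
      model <- fwd$model
      lg <- loss_and_grad(fwd$output, batch$y, cfg$loss)
      if (!is.finite(lg$loss))
        stop_octadc("non-finite training loss at epoch ", epoch,
                    " (diverged); reduce the learning rate")
      ep_loss <- ep_loss + lg$loss; n_batches <- n_batches + 1L
      pgrads <- nn_backward(model, fwd, lg$grad)
      t_adam <- t_adam + 1L
      upd <- adam_step(model, state, pgrads, t_adam, lr)
      model <- upd$model; state <- upd$state
    }
    train_loss <- ep_loss / n_batches
    val_loss <- if (n_val > 0L) {
      out <- nn_forward(model, val_batch$x, training = FALSE)$output
      loss_and_grad(out, val_batch$y, cfg$loss)$loss
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    track <- if (is.na(val_loss)) train_loss else val_loss
    if (track < best$loss) best <- list(loss = track, nodes = model$nodes)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s", epoch, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
  }
  model$nodes <- best$nodes
  model$history <- structure(list(log = history, seed = cfg$rng_seed,
                                  loss = cfg$loss, learning_rate = lr,
                                  epochs = epochs, batch_size = batch_size),
                             class = "adcnet_history")
  model
}

#' @export
print.adcnet_history <- function(x, ...) {
  cat(sprintf("<adcnet_history> %d epochs (%s loss, lr %g, seed %d)\n",
              nrow(x$log), x$loss, x$learning_rate, x$seed))
  print(utils::tail(x$log, 3L), row.names = FALSE)
  invisible(x)
}

#' Predict a compensated B-scan from a compensation stack
#'
#' Inference is deterministic (batch-norm uses running statistics). The
#' stack is normalized exactly as the training pairs were (log display +
#' axial pooling recorded in `model$norm`) when an `oct_stack` is supplied;
#' a plain `H x W x C` array is assumed already normalized.
#'
#' @param model A trained `oct_adcnet`.
#' @param stack An `oct_stack` with `model$config$n_channels` channels, or
#'   a normalized input array.
#' @return An `oct_bscan` (log scale, values in `[0, 1]`).
#' @export
adcnet_predict <- function(model, stack) {
  stopifnot(inherits(model, "oct_adcnet"))
  nc <- model$config$n_channels
  if (inherits(stack, "oct_stack")) {
    if (length(stack$bscans) != nc)
      stop_octadc("stack has ", length(stack$bscans),
                  " channels but the model expects ", nc)
    arr <- normalize_stack(stack, model$norm)
    prov <- list(frame_index = stack$frame_index,
                 volume_index = stack$volume_index,
                 location_index = stack$location_index)
  } else {
    arr <- stack
    if (dim(arr)[3] != nc)
      stop_octadc("input has ", dim(arr)[3],
                  " channels but the model expects ", nc)
    prov <- list()
  }
  d <- dim(arr)
  check_divisible(d[1], d[2], model$config$encoder_stages)
  x <- array(arr, c(d[1], d[2], 1L, d[3]))
  out <- nn_forward(model, x, training = FALSE)$output
  img <- matrix(out[, , 1L, 1L], d[1], d[2])
  new_bscan(img, scale = "log",
            provenance = c(prov, list(model_channels = nc)))
}

#' @rdname adcnet_predict
#' @param stacks A list of `oct_stack`s (e.g. one per B-scan of a volume);
#'   processed sequentially, order preserved.
#' @export
adcnet_predict_volume <- function(model, stacks) {
  lapply(stacks, function(s) adcnet_predict(model, s))
}

#' Save / load model parameters
#'
#' Parameters (and batch-norm running statistics) are written as a named
#' list via RDS together with the config and seed. `adcnet_load_weights()`
#' copies every parameter whose name matches into `model`; with
#' `encoder_only = TRUE` only `enc*`-named weights are copied — the
#' transfer-learning hook for externally pretrained encoders.
#'
#' @param model An `oct_adcnet`.
#' @param path File path.
#' @export
adcnet_save <- function(model, path) {
  saveRDS(list(params = nn_get_params(model),
               bn_stats = lapply(model$nodes, function(n)
                 if (n$op == "bn") list(mean = n$running_mean,
                                        var = n$running_var)),
               config = model$config, norm = model$norm,
               history = model$history, seed = model$seed), path)
  invisible(path)
}

#' @rdname adcnet_save
#' @param encoder_only Copy only encoder weights.
#' @export
adcnet_load_weights <- function(model, path, encoder_only = FALSE) {
  chk <- readRDS(path)
  have <- nn_get_params(model)
  for (nm in names(chk$params)) {
    if (encoder_only && !grepl("_enc", nm)) next
    if (!nm %in% names(have)) next
    if (!identical(dim(have[[nm]]) %||% length(have[[nm]]),
                   dim(chk$params[[nm]]) %||% length(chk$params[[nm]]))) next
    model <- nn_set_param(model, nm, chk$params[[nm]])
  }
  if (!encoder_only && !is.null(chk$bn_stats)) {
    for (i in seq_along(model$nodes)) {
      if (model$nodes[[i]]$op == "bn" && !is.null(chk$bn_stats[[i]])) {
        model$nodes[[i]]$running_mean <- chk$bn_stats[[i]]$mean
        model$nodes[[i]]$running_var <- chk$bn_stats[[i]]$var
      }
    }
    model$norm <- chk$norm %||% model$norm
  }
  model
}

#' Restore a saved model
#'
#' Rebuilds the network from the stored config and loads all parameters.
#' @param path RDS written by [adcnet_save()].
#' @export
adcnet_load <- function(path) {
  chk <- readRDS(path)
  model <- build_adcnet(chk$config)
  model <- adcnet_load_weights(model, path)
  model$history <- chk$history
  model
}
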