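# Minimal computation-graph engine for the restoration network.
#
# Activations are dense arrays of dim c(H, W, N, C) (rows, cols, batch,
# channels; channels last so channel concatenation is contiguous). All
# convolutions are "same" 3x3 or 1x1, expressed as up-to-nine shifted
# matrix products against BLAS dgemm: for each kernel tap t with offset
# (dy, dx), Y += mat(shift(X, dy, dx)) %*% W[[t]], where mat() views the
# tensor as an (H*W*N) x C matrix. The adjoint of shift(dy, dx) is
# shift(-dy, -dx), which gives an exact, simple backward pass. Gradient
# correctness is pinned by a finite-difference test.

nn_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

nn_unmat <- function(m, H, W, N) {
  dim(m) <- c(H, W, N, ncol(m))
  m
}

# y[i, j, , ] = x[i + dy, j + dx, , ], zero outside.
nn_shift <- function(x, dy, dx) {
  if (dy == 0 && dx == 0) return(x)
  d <- dim(x)
  y <- array(0, d)
  di <- max(1L, 1L - dy):min(d[1], d[1] - dy)
  dj <- max(1L, 1L - dx):min(d[2], d[2] - dx)
  y[di, dj, , ] <- x[di + dy, dj + dx, , , drop = FALSE]
  y
}

conv_offsets <- expand.grid(dy = -1:1, dx = -1:1)

nn_conv_forward <- function(x, node) {
  d <- dim(x)
  if (node$kernel == 1L) {
    y <- nn_mat(x) %*% node$W[[1L]]
  } else {
    y <- nn_mat(nn_shift(x, -1L, -1L)) %*% node$W[[1L]]
    for (t in 2:9)
      y <- y + nn_mat(nn_shift(x, conv_offsets$dy[t], conv_offsets$dx[t])) %*%
        node$W[[t]]
  }
  if (!is.null(node$b)) y <- sweep(y, 2L, node$b, "+")
  nn_unmat(y, d[1], d[2], d[3])
}

nn_conv_backward <- function(x, node, dy_) {
  d <- dim(x)
  dym <- nn_mat(dy_)
  nt <- if (node$kernel == 1L) 1L else 9L
  dW <- vector("list", nt)
  dx <- NULL
  for (t in seq_len(nt)) {
    ody <- if (nt == 1L) 0L else conv_offsets$dy[t]
    odx <- if (nt == 1L) 0L else conv_offsets$dx[t]
    xs <- nn_shift(x, ody, odx)
    dW[[t]] <- crossprod(nn_mat(xs), dym)
    contrib <- nn_unmat(tcrossprod(dym, node$W[[t]]), d[1], d[2], d[3])
    dx <- if (is.null(dx)) nn_shift(contrib, -ody, -odx)
          else dx + nn_shift(contrib, -ody, -odx)
  }
  db <- if (!is.null(node$b)) colSums(dym) else NULL
  list(dx = dx, dW = dW, db = db)
}

nn_bn_forward <- function(x, node, training) {
  d <- dim(x)
  xm <- nn_mat(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
  } else {
    mu <- node$running_mean
    v <- node$running_var
    xc <- sweep(xm, 2L, mu)
  }
  invstd <- 1 / sqrt(v + node$eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, node$gamma, "*"), 2L, node$beta, "+")
  cache <- list(xhat = xhat, invstd = invstd, training = training)
  if (training) cache$batch_stats <- list(mu = mu, v = v)
  list(y = nn_unmat(y, d[1], d[2], d[3]), cache = cache)
}

nn_bn_backward <- function(node, cache, dy_) {
  d <- dim(dy_)
  dym <- nn_mat(dy_)
  xhat <- cache$xhat
  m <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, node$gamma, "*")
  if (cache$training) {
    t1 <- sweep(dxhat, 2L, colSums(dxhat) / m)
    t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / m, "*")
    dx <- sweep(t1 - t2, 2L, cache$invstd, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dx = nn_unmat(dx, d[1], d[2], d[3]), dgamma = dgamma, dbeta = dbeta)
}

nn_pool_forward <- function(x) {
  d <- dim(x)
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  v <- list(x[oi, oj, , , drop = FALSE], x[ei, oj, , , drop = FALSE],
            x[oi, ej, , , drop = FALSE], x[ei, ej, , , drop = FALSE])
  y <- pmax(v[[1]], v[[2]], v[[3]], v[[4]])
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4L)
  for (q in 1:4) {
    masks[[q]] <- (v[[q]] == y) & !taken
    taken <- taken | masks[[q]]
  }
  list(y = y, masks = masks)
}

nn_pool_backward <- function(dy_, masks, d_in) {
  dx <- array(0, d_in)
  oi <- seq(1L, d_in[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d_in[2], 2L); ej <- oj + 1L
  dx[oi, oj, , ] <- dy_ * masks[[1]]
  dx[ei, oj, , ] <- dy_ * masks[[2]]
  dx[oi, ej, , ] <- dy_ * masks[[3]]
  dx[ei, ej, , ] <- dy_ * masks[[4]]
  dx
}

nn_upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

nn_upsample_backward <- function(dy_) {
  d <- dim(dy_)
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  dy_[oi, oj, , , drop = FALSE] + dy_[ei, oj, , , drop = FALSE] +
    dy_[oi, ej, , , drop = FALSE] + dy_[ei, ej, , , drop = FALSE]
}

# ---- graph construction -------------------------------------------------

nn_builder <- function(n_channels) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$channels <- integer()
  add <- function(node, cout) {
    id <- length(env$nodes) + 1L
    node$id <- id
    env$nodes[[id]] <- node
    env$channels[id] <- cout
    id
  }
  env$input <- function() add(list(op = "input"), n_channels)
  env$conv <- function(from, cout, kernel = 3L, bias = FALSE, name = "") {
    add(list(op = "conv", inputs = from, kernel = as.integer(kernel),
             cin = env$channels[from], cout = as.integer(cout),
             bias = bias, name = name), cout)
  }
  env$bn <- function(from, name = "") {
    add(list(op = "bn", inputs = from, cout = env$channels[from],
             name = name), env$channels[from])
  }
  env$relu <- function(from) add(list(op = "relu", inputs = from),
                                 env$channels[from])
  env$pool <- function(from) add(list(op = "pool", inputs = from),
                                 env$channels[from])
  env$up <- function(from) add(list(op = "up", inputs = from),
                               env$channels[from])
  env$concat <- function(froms) add(list(op = "concat", inputs = froms),
                                    sum(env$channels[froms]))
  env$act <- function(from, kind) add(list(op = kind, inputs = from),
                                      env$channels[from])
  env
}

# Conv + batch-norm + ReLU unit (the trailing BN+ReLU follow every
# convolution in the architecture; the terminal conv is the exception).
nn_cbr <- function(g, from, cout, kernel = 3L, name = "") {
  c1 <- g$conv(from, cout, kernel = kernel, name = paste0(name, "_conv"))
  b1 <- g$bn(c1, name = paste0(name, "_bn"))
  g$relu(b1)
}

nn_init_params <- function(nodes, seed) {
  with_seed(seed, {
    for (i in seq_along(nodes)) {
      node <- nodes[[i]]
      if (node$op == "conv") {
        nt <- if (node$kernel == 1L) 1L else 9L
        fan_in <- node$cin * nt
        sdw <- sqrt(2 / fan_in)
        node$W <- lapply(seq_len(nt), function(t)
          matrix(stats::rnorm(node$cin * node$cout, 0, sdw),
                 node$cin, node$cout))
        node$b <- if (isTRUE(node$bias)) numeric(node$cout) else NULL
      } else if (node$op == "bn") {
        node$gamma <- rep(1, node$cout)
        node$beta <- numeric(node$cout)
        node$running_mean <- numeric(node$cout)
        node$running_var <- rep(1, node$cout)
        node$eps <- 1e-5
        node$momentum <- 0.1
      }
      nodes[[i]] <- node
    }
    nodes
  })
}

nn_param_count <- function(nodes) {
  sum(vapply(nodes, function(n) {
    if (n$op == "conv")
      length(n$W) * n$cin * n$cout + if (is.null(n$b)) 0L else n$cout
    else if (n$op == "bn") 2L * n$cout
    else 0L
  }, numeric(1)))
}

# ---- forward / backward -------------------------------------------------

nn_forward <- function(model, x, training = FALSE) {
  nodes <- model$nodes
  vals <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    node <- nodes[[i]]
    vals[[i]] <- switch(node$op,
      input = x,
      conv = nn_conv_forward(vals[[node$inputs]], node),
      bn = {
        r <- nn_bn_forward(vals[[node$inputs]], node, training)
        caches[[i]] <- r$cache
        if (training) {
          bs <- r$cache$batch_stats
          nodes[[i]]$running_mean <-
            (1 - node$momentum) * node$running_mean + node$momentum * bs$mu
          nodes[[i]]$running_var <-
            (1 - node$momentum) * node$running_var + node$momentum * bs$v
        }
        r$y
      },
      relu = pmax(vals[[node$inputs]], 0),
      pool = {
        r <- nn_pool_forward(vals[[node$inputs]])
        caches[[i]] <- r$masks
        r$y
      },
      up = nn_upsample_forward(vals[[node$inputs]]),
      concat = {
        parts <- vals[node$inputs]
        d <- dim(parts[[1]])
        array(unlist(parts, use.names = FALSE),
              c(d[1], d[2], d[3], sum(vapply(parts, function(p) dim(p)[4],
                                             numeric(1)))))
      },
      sigmoid = 1 / (1 + exp(-vals[[node$inputs]])),
      softmax = {
        v <- vals[[node$inputs]]
        e <- exp(sweep(nn_mat(v), 1L, apply(nn_mat(v), 1L, max)))
        nn_unmat(e / rowSums(e), dim(v)[1], dim(v)[2], dim(v)[3])
      },
      linear = vals[[node$inputs]],
      stop_octadc("unknown op ", node$op))
  }
  model$nodes <- nodes
  list(vals = vals, caches = caches, model = model,
       output = vals[[length(nodes)]])
}

nn_backward <- function(model, fwd, dout) {
  nodes <- model$nodes
  vals <- fwd$vals
  caches <- fwd$caches
  n <- length(nodes)
  dvals <- vector("list", n)
  pgrads <- vector("list", n)
  dvals[[n]] <- dout
  acc <- function(slot, g) {
    dvals[[slot]] <<- if (is.null(dvals[[slot]])) g else dvals[[slot]] + g
  }
  for (i in rev(seq_len(n))) {
    node <- nodes[[i]]
    g <- dvals[[i]]
    if (is.null(g) || node$op == "input") next
    switch(node$op,
      conv = {
        r <- nn_conv_backward(vals[[node$inputs]], node, g)
        pgrads[[i]] <- list(W = r$dW, b = r$db)
        acc(node$inputs, r$dx)
      },
      bn = {
        r <- nn_bn_backward(node, caches[[i]], g)
        pgrads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
        acc(node$inputs, r$dx)
      },
      relu = acc(node$inputs, g * (vals[[i]] > 0)),
      pool = acc(node$inputs,
                 nn_pool_backward(g, caches[[i]], dim(vals[[node$inputs]]))),
      up = acc(node$inputs, nn_upsample_backward(g)),
      concat = {
        at <- 0L
        for (src in node$inputs) {
          cs <- dim(vals[[src]])[4]
          acc(src, g[, , , at + seq_len(cs), drop = FALSE])
          at <- at + cs
        }
      },
      sigmoid = acc(node$inputs, g * vals[[i]] * (1 - vals[[i]])),
      softmax = {
        y <- vals[[i]]
        ym <- nn_mat(y); gm <- nn_mat(g)
        dx <- ym * sweep(gm, 1L, rowSums(gm * ym))
        acc(node$inputs, nn_unmat(dx, dim(y)[1], dim(y)[2], dim(y)[3]))
      },
      linear = acc(node$inputs, g))
    dvals[[i]] <- NULL   # free as we go
  }
  pgrads
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(nodes) {
  lapply(nodes, function(node) {
    if (node$op == "conv") {
      s <- list(mW = lapply(node$W, function(w) array(0, dim(w))),
                vW = lapply(node$W, function(w) array(0, dim(w))))
      if (!is.null(node$b)) {
        s$mb <- numeric(length(node$b)); s$vb <- numeric(length(node$b))
      }
      s
    } else if (node$op == "bn") {
      list(mg = numeric(node$cout), vg = numeric(node$cout),
           mb = numeric(node$cout), vb = numeric(node$cout))
    } else NULL
  })
}

adam_update <- function(m, v, g, t, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(m = m, v = v, step = lr * mhat / (sqrt(vhat) + eps))
}

adam_step <- function(model, state, pgrads, t, lr) {
  for (i in seq_along(model$nodes)) {
    g <- pgrads[[i]]
    if (is.null(g)) next
    node <- model$nodes[[i]]
    s <- state[[i]]
    if (node$op == "conv") {
      for (k in seq_along(node$W)) {
        u <- adam_update(s$mW[[k]], s$vW[[k]], g$W[[k]], t, lr)
        s$mW[[k]] <- u$m; s$vW[[k]] <- u$v
        node$W[[k]] <- node$W[[k]] - u$step
      }
      if (!is.null(node$b)) {
        u <- adam_update(s$mb, s$vb, g$b, t, lr)
        s$mb <- u$m; s$vb <- u$v
        node$b <- node$b - u$step
      }
    } else if (node$op == "bn") {
      u <- adam_update(s$mg, s$vg, g$gamma, t, lr)
      s$mg <- u$m; s$vg <- u$v
      node$gamma <- node$gamma - u$step
      u <- adam_update(s$mb, s$vb, g$beta, t, lr)
      s$mb <- u$m; s$vb <- u$v
      node$beta <- node$beta - u$step
    }
    model$nodes[[i]] <- node
    state[[i]] <- s
  }
  list(model = model, state = state)
}

# Flat named parameter access (used by the checkpoint hook and the
# finite-difference gradient test).
nn_get_params <- function(model) {
  out <- list()
  for (node in model$nodes) {
    if (node$op == "conv") {
      for (k in seq_along(node$W))
        out[[sprintf("n%03d_%s_W%d", node$id, node$name, k)]] <- node$W[[k]]
      if (!is.null(node$b))
        out[[sprintf("n%03d_%s_b", node$id, node$name)]] <- node$b
    } else if (node$op == "bn") {
      out[[sprintf("n%03d_%s_gamma", node$id, node$name)]] <- node$gamma
      out[[sprintf("n%03d_%s_beta", node$id, node$name)]] <- node$beta
    }
  }
  out
}

nn_set_param <- function(model, name, value) {
  m <- regmatches(name, regexec("^n(\\d+)_.*_(W\\d+|b|gamma|beta)$", name))[[1]]
  id <- as.integer(m[2])
  node <- model$nodes[[id]]
  slot <- m[3]
  if (startsWith(slot, "W")) node$W[[as.integer(sub("W", "", slot))]] <- value
  else if (slot == "b") node$b <- value
  else if (slot == "gamma") node$gamma <- value
  else node$beta <- value
  model$nodes[[id]] <- node
  model
}
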