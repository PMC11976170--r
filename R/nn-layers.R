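# Compact CNN engine used by the 1D and 2D classifiers and by Grad-CAM.
#
# Layers are environments holding parameters, Adam state and the caches needed
# for backpropagation. Tensors are base-R arrays in channels-last layout:
# (batch, length, channels) for 1D, (batch, height, width, channels) for 2D.
# Convolutions are evaluated as im2col matrix products so the heavy lifting is
# done by BLAS.

nn_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

nn_conv1d <- function(cin, cout, k, stride = 1L) {
  nn_layer("conv1d", cin = cin, cout = cout, k = as.integer(k),
           stride = as.integer(stride),
           W = he_init(k * cin, cout, k * cin), b = numeric(cout))
}

nn_conv2d <- function(cin, cout, k = 3L) {
  # 'same' zero padding, stride 1
  nn_layer("conv2d", cin = cin, cout = cout, k = as.integer(k),
           pad = (as.integer(k) - 1L) %/% 2L,
           W = he_init(k * k * cin, cout, k * k * cin), b = numeric(cout))
}

nn_relu <- function() nn_layer("relu")
nn_dropout <- function(p) nn_layer("dropout", p = p)
nn_batchnorm <- function(c) {
  nn_layer("bn", c = c, gamma = rep(1, c), beta = numeric(c),
           rmu = numeric(c), rvar = rep(1, c), mom = 0.9, eps = 1e-5)
}
nn_maxpool1d <- function(s) nn_layer("maxpool1d", s = as.integer(s))
nn_maxpool2d <- function() nn_layer("maxpool2d")
nn_globalmaxpool <- function() nn_layer("gmp")
nn_flatten <- function() nn_layer("flatten")
nn_dense <- function(din, dout) {
  nn_layer("dense", W = he_init(din, dout, din), b = numeric(dout))
}

# channel-last array -> (M, C) matrix view
flatten_channels <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

layer_forward <- function(l, x, training = FALSE, cache = training) {
  switch(l$type,
    conv1d = {
      d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
      Lout <- (L - l$k) %/% l$stride + 1L
      pos <- seq(1L, by = l$stride, length.out = Lout)
      cols <- matrix(0, N * Lout, l$k * C)
      for (j in seq_len(l$k)) {
        xs <- x[, pos + j - 1L, , drop = FALSE]
        dim(xs) <- c(N * Lout, C)
        cols[, ((j - 1L) * C + 1L):(j * C)] <- xs
      }
      y <- cols %*% l$W
      y <- y + rep(l$b, each = nrow(y))
      dim(y) <- c(N, Lout, l$cout)
      if (cache) { l$cols <- cols; l$in_dim <- d; l$pos <- pos }
      y
    },
    conv2d = {
      if (l$pad > 0L) {
        d0 <- dim(x)
        xp <- array(0, c(d0[1], d0[2] + 2L * l$pad, d0[3] + 2L * l$pad, d0[4]))
        xp[, l$pad + seq_len(d0[2]), l$pad + seq_len(d0[3]), ] <- x
        x <- xp
      }
      d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      Hout <- H - l$k + 1L; Wout <- W - l$k + 1L
      cols <- matrix(0, N * Hout * Wout, l$k * l$k * C)
      off <- 0L
      for (dj in seq_len(l$k)) {
        for (di in seq_len(l$k)) {
          xs <- x[, di:(di + Hout - 1L), dj:(dj + Wout - 1L), , drop = FALSE]
          dim(xs) <- c(N * Hout * Wout, C)
          cols[, off + seq_len(C)] <- xs
          off <- off + C
        }
      }
      y <- cols %*% l$W
      y <- y + rep(l$b, each = nrow(y))
      dim(y) <- c(N, Hout, Wout, l$cout)
      if (cache) { l$cols <- cols; l$in_dim <- d }
      y
    },
    relu = {
      m <- x > 0
      if (cache) l$mask <- m
      x * m
    },
    dropout = {
      if (training) {
        m <- array((runif(length(x)) >= l$p) / (1 - l$p), dim(x))
        l$mask <- m
        l$active <- TRUE
        x * m
      } else {
        l$active <- FALSE
        x
      }
    },
    bn = {
      d <- dim(x)
      xm <- flatten_channels(x)
      M <- nrow(xm)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        v[v < 0] <- 0
        l$rmu <- l$mom * l$rmu + (1 - l$mom) * mu
        l$rvar <- l$mom * l$rvar + (1 - l$mom) * v
      } else {
        mu <- l$rmu; v <- l$rvar
      }
      istd <- 1 / sqrt(v + l$eps)
      xhat <- (xm - rep(mu, each = M)) * rep(istd, each = M)
      y <- xhat * rep(l$gamma, each = M) + rep(l$beta, each = M)
      if (cache) { l$xhat <- xhat; l$istd <- istd; l$M <- M; l$trained_pass <- training }
      dim(y) <- d
      y
    },
    maxpool1d = {
      d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]; s <- l$s
      Lout <- L %/% s
      Lc <- Lout * s
      xc <- x[, seq_len(Lc), , drop = FALSE]
      dim(xc) <- c(N, s, Lout, C)
      y <- xc[, 1, , , drop = FALSE]
      dim(y) <- c(N, Lout, C)
      arg <- array(1L, c(N, Lout, C))
      for (j in 2:s) {
        xj <- xc[, j, , , drop = FALSE]
        dim(xj) <- c(N, Lout, C)
        upd <- xj > y
        y[upd] <- xj[upd]
        arg[upd] <- j
      }
      if (cache) { l$arg <- arg; l$in_dim <- d; l$Lc <- Lc }
      y
    },
    maxpool2d = {
      d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      H2 <- H %/% 2L; W2 <- W %/% 2L
      xc <- x[, seq_len(2L * H2), seq_len(2L * W2), , drop = FALSE]
      dim(xc) <- c(N, 2L, H2, 2L, W2, C)
      y <- NULL; arg <- NULL
      code <- 0L
      for (j2 in 1:2) {
        for (j1 in 1:2) {
          code <- code + 1L
          xj <- xc[, j1, , j2, , , drop = FALSE]
          dim(xj) <- c(N, H2, W2, C)
          if (is.null(y)) {
            y <- xj
            arg <- array(1L, c(N, H2, W2, C))
          } else {
            upd <- xj > y
            y[upd] <- xj[upd]
            arg[upd] <- code
          }
        }
      }
      if (cache) { l$arg <- arg; l$in_dim <- d }
      y
    },
    gmp = {
      d <- dim(x)
      sp <- prod(d[2:(length(d) - 1L)])
      C <- d[length(d)]
      xm <- x
      dim(xm) <- c(d[1], sp, C)
      y <- xm[, 1, , drop = FALSE]
      dim(y) <- c(d[1], C)
      arg <- matrix(1L, d[1], C)
      if (sp > 1) {
        for (j in 2:sp) {
          xj <- xm[, j, , drop = FALSE]
          dim(xj) <- c(d[1], C)
          upd <- xj > y
          y[upd] <- xj[upd]
          arg[upd] <- j
        }
      }
      if (cache) { l$arg <- arg; l$in_dim <- d; l$sp <- sp }
      y
    },
    flatten = {
      d <- dim(x)
      if (cache) l$in_dim <- d
      dim(x) <- c(d[1], prod(d[-1]))
      x
    },
    dense = {
      if (cache) l$x <- x
      y <- x %*% l$W
      y + rep(l$b, each = nrow(y))
    },
    stop("unknown layer type ", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv1d = {
      d <- l$in_dim; N <- d[1]; C <- d[3]
      Lout <- length(l$pos)
      dym <- dy
      dim(dym) <- c(N * Lout, l$cout)
      l$dW <- crossprod(l$cols, dym)
      l$db <- colSums(dym)
      dcol <- tcrossprod(dym, l$W)
      dx <- array(0, d)
      for (j in seq_len(l$k)) {
        blk <- dcol[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
        dim(blk) <- c(N, Lout, C)
        dx[, l$pos + j - 1L, ] <- dx[, l$pos + j - 1L, , drop = FALSE] + blk
      }
      dx
    },
    conv2d = {
      d <- l$in_dim; N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      Hout <- H - l$k + 1L; Wout <- W - l$k + 1L
      dym <- dy
      dim(dym) <- c(N * Hout * Wout, l$cout)
      l$dW <- crossprod(l$cols, dym)
      l$db <- colSums(dym)
      dcol <- tcrossprod(dym, l$W)
      dx <- array(0, d)
      off <- 0L
      for (dj in seq_len(l$k)) {
        for (di in seq_len(l$k)) {
          blk <- dcol[, off + seq_len(C), drop = FALSE]
          dim(blk) <- c(N, Hout, Wout, C)
          dx[, di:(di + Hout - 1L), dj:(dj + Wout - 1L), ] <-
            dx[, di:(di + Hout - 1L), dj:(dj + Wout - 1L), , drop = FALSE] + blk
          off <- off + C
        }
      }
      if (l$pad > 0L) {
        dx <- dx[, l$pad + seq_len(H - 2L * l$pad),
                 l$pad + seq_len(W - 2L * l$pad), , drop = FALSE]
      }
      dx
    },
    relu = dy * l$mask,
    dropout = if (isTRUE(l$active)) dy * l$mask else dy,
    bn = {
      d <- dim(dy)
      dym <- flatten_channels(dy)
      M <- l$M
      l$dgamma <- colSums(dym * l$xhat)
      l$dbeta <- colSums(dym)
      if (isTRUE(l$trained_pass)) {
        dxhat <- dym * rep(l$gamma, each = M)
        t1 <- colMeans(dxhat)
        t2 <- colMeans(dxhat * l$xhat)
        dx <- (dxhat - rep(t1, each = M) - l$xhat * rep(t2, each = M)) *
          rep(l$istd, each = M)
      } else {
        dx <- dym * rep(l$gamma * l$istd, each = M)
      }
      dim(dx) <- d
      dx
    },
    maxpool1d = {
      d <- l$in_dim; N <- d[1]; C <- d[3]; s <- l$s
      Lout <- l$Lc %/% s
      dxc <- array(0, c(N, s, Lout, C))
      for (j in seq_len(s)) {
        tmp <- array(0, c(N, Lout, C))
        sel <- l$arg == j
        tmp[sel] <- dy[sel]
        dxc[, j, , ] <- tmp
      }
      dim(dxc) <- c(N, l$Lc, C)
      if (l$Lc < d[2]) {
        dx <- array(0, d)
        dx[, seq_len(l$Lc), ] <- dxc
        dx
      } else dxc
    },
    maxpool2d = {
      d <- l$in_dim; N <- d[1]; C <- d[4]
      H2 <- dim(l$arg)[2]; W2 <- dim(l$arg)[3]
      dxc <- array(0, c(N, 2L, H2, 2L, W2, C))
      code <- 0L
      for (j2 in 1:2) {
        for (j1 in 1:2) {
          code <- code + 1L
          tmp <- array(0, c(N, H2, W2, C))
          sel <- l$arg == code
          tmp[sel] <- dy[sel]
          dxc[, j1, , j2, , ] <- tmp
        }
      }
      dim(dxc) <- c(N, 2L * H2, 2L * W2, C)
      if (2L * H2 < d[2] || 2L * W2 < d[3]) {
        dx <- array(0, d)
        dx[, seq_len(2L * H2), seq_len(2L * W2), ] <- dxc
        dx
      } else dxc
    },
    gmp = {
      d <- l$in_dim; N <- d[1]; C <- d[length(d)]
      dx <- array(0, c(N, l$sp, C))
      for (j in seq_len(l$sp)) {
        tmp <- matrix(0, N, C)
        sel <- l$arg == j
        tmp[sel] <- dy[sel]
        dx[, j, ] <- tmp
      }
      dim(dx) <- d
      dx
    },
    flatten = {
      dim(dy) <- l$in_dim
      dy
    },
    dense = {
      l$dW <- crossprod(l$x, dy)
      l$db <- colSums(dy)
      tcrossprod(dy, l$W)
    },
    stop("unknown layer type ", l$type))
}

nn_forward <- function(layers, x, training = FALSE, cache = training,
                       keep_output_of = 0L) {
  kept <- NULL
  for (i in seq_along(layers)) {
    x <- layer_forward(layers[[i]], x, training = training, cache = cache)
    if (i == keep_output_of) kept <- x
  }
  if (keep_output_of > 0L) list(out = x, kept = kept) else x
}

# Backpropagate dlogits down to (and excluding) layer `stop_after`; returns
# the gradient w.r.t. the output of layer `stop_after` (0 = input gradient).
nn_backward <- function(layers, dlogits, stop_after = 0L) {
  dy <- dlogits
  for (i in rev(seq_along(layers))) {
    if (i == stop_after) break
    dy <- layer_backward(layers[[i]], dy)
  }
  dy
}

nn_param_names <- function(l) {
  switch(l$type,
    conv1d = , conv2d = , dense = c("W", "b"),
    bn = c("gamma", "beta"),
    character(0))
}

nn_grad_name <- function(p) {
  c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")[[p]]
}

nn_adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    for (p in nn_param_names(l)) {
      g <- get(nn_grad_name(p), envir = l)
      mslot <- paste0("adam_m_", p)
      vslot <- paste0("adam_v_", p)
      m <- if (is.null(l[[mslot]])) g * 0 else l[[mslot]]
      v <- if (is.null(l[[vslot]])) g * 0 else l[[vslot]]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      assign(mslot, m, envir = l)
      assign(vslot, v, envir = l)
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      assign(p, get(p, envir = l) - lr * mhat / (sqrt(vhat) + eps), envir = l)
    }
  }
}

# Deep-copy all trainable parameters and normalisation statistics.
nn_snapshot <- function(layers) {
  lapply(layers, function(l) {
    out <- list()
    for (p in c(nn_param_names(l), if (l$type == "bn") c("rmu", "rvar"))) {
      out[[p]] <- get(p, envir = l)
    }
    out
  })
}

nn_restore <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (p in names(snap[[i]])) assign(p, snap[[i]][[p]], envir = layers[[i]])
  }
  invisible(layers)
}

# Drop caches after training so the model object stays small.
nn_clear_cache <- function(layers) {
  keep <- c("type", "cin", "cout", "k", "stride", "pad", "W", "b", "gamma",
            "beta", "rmu", "rvar", "mom", "eps", "c", "s", "p")
  for (l in layers) {
    rm(list = setdiff(ls(l), keep), envir = l)
  }
  invisible(layers)
}
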