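# Mini-batch Adam training with class-weighted cross-entropy and early
# stopping on a held-out (patient-disjoint) validation loss.

softmax_rows <- function(logits) {
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

# Class-weighted softmax cross-entropy; returns loss and d(loss)/d(logits).
nn_loss <- function(logits, yidx, class_weights) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  wi <- class_weights[yidx]
  sel <- cbind(seq_len(n), yidx)
  loss <- -sum(wi * log(pmax(p[sel], 1e-12))) / n
  g <- p
  g[sel] <- g[sel] - 1
  list(loss = loss, grad = g * (wi / n))
}

# x is an array whose first dimension indexes observations.
slice_obs <- function(x, idx) {
  d <- dim(x)
  if (length(d) == 2) x[idx, , drop = FALSE]
  else if (length(d) == 3) x[idx, , , drop = FALSE]
  else x[idx, , , , drop = FALSE]
}

nn_predict_logits <- function(layers, x, batch = 512L) {
  n <- dim(x)[1]
  out <- NULL
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    logits <- nn_forward(layers, slice_obs(x, idx), training = FALSE,
                         cache = FALSE)
    if (is.null(out)) out <- matrix(0, n, ncol(logits))
    out[idx, ] <- logits
  }
  out
}

# Core fitting routine shared by the 1D and 2D networks. X must carry the
# observation dimension first and include the trailing channel dimension.
nn_fit <- function(layers, X, yidx, class_weights, val_X, val_yidx,
                   epochs = 30L, batch = 64L, lr = 1e-3, patience = 5L,
                   verbose = FALSE) {
  n <- dim(X)[1]
  t_step <- 0L
  best_loss <- Inf
  best_snap <- NULL
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1, n, by = batch)) {
      idx <- perm[s:min(s + batch - 1L, n)]
      logits <- nn_forward(layers, slice_obs(X, idx), training = TRUE)
      lg <- nn_loss(logits, yidx[idx], class_weights)
      nn_backward(layers, lg$grad)
      t_step <- t_step + 1L
      nn_adam_step(layers, lr, t_step)
      ep_loss <- ep_loss + lg$loss
      nb <- nb + 1L
    }
    val_logits <- nn_predict_logits(layers, val_X)
    vl <- nn_loss(val_logits, val_yidx, class_weights)$loss
    vacc <- mean(max.col(val_logits, ties.method = "first") == val_yidx)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / nb,
                                val_loss = vl, val_acc = vacc))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f, val %.4f, val acc %.3f",
                      ep, ep_loss / nb, vl, vacc))
    }
    if (vl < best_loss - 1e-5) {
      best_loss <- vl
      best_snap <- nn_snapshot(layers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  if (!is.null(best_snap)) nn_restore(layers, best_snap)
  nn_clear_cache(layers)
  list(layers = layers, history = history)
}

# Architecture of the 1D network: two strided convolutions, max pooling,
# dropout, batch normalisation, flatten, dense, dropout, dense output.
build_cnn1d <- function(n_classes = 4L, input_len = 1600L,
                        widths = c(16L, 32L), kernel = 9L, dense = 64L,
                        dropout = 0.3) {
  l1 <- (input_len - kernel) %/% 4L + 1L
  l2 <- (l1 - kernel) %/% 2L + 1L
  lp <- l2 %/% 4L
  list(nn_conv1d(1L, widths[1], kernel, stride = 4L),
       nn_relu(),
       nn_conv1d(widths[1], widths[2], kernel, stride = 2L),
       nn_relu(),
       nn_maxpool1d(4L),
       nn_dropout(dropout),
       nn_batchnorm(widths[2]),
       nn_flatten(),
       nn_dense(lp * widths[2], dense),
       nn_relu(),
       nn_dropout(dropout),
       nn_dense(dense, n_classes))
}

# Architecture of the 2D network: four convolution + batch-norm blocks with
# max pooling after the second and third and global max pooling after the
# fourth, then a dense output layer. Input is the 8x8-pooled 28x28 scalogram.
build_cnn2d <- function(n_classes = 4L, widths = c(8L, 16L, 32L, 32L)) {
  list(nn_conv2d(1L, widths[1]), nn_batchnorm(widths[1]), nn_relu(),
       nn_conv2d(widths[1], widths[2]), nn_batchnorm(widths[2]), nn_relu(),
       nn_maxpool2d(),
       nn_conv2d(widths[2], widths[3]), nn_batchnorm(widths[3]), nn_relu(),
       nn_maxpool2d(),
       nn_conv2d(widths[3], widths[4]), nn_batchnorm(widths[4]), nn_relu(),
       nn_globalmaxpool(),
       nn_dense(widths[4], n_classes))
}

# Index (into the layer list) of the feature maps Grad-CAM should use: the
# activation directly following the last convolutional layer.
last_conv_output_index <- function(layers) {
  types <- vapply(layers, function(l) l$type, character(1))
  conv <- which(types %in% c("conv1d", "conv2d"))
  if (length(conv) == 0) return(0L)
  t <- max(conv)
  while (t < length(layers) && types[t + 1L] %in% c("bn", "relu")) t <- t + 1L
  t
}
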