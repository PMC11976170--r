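# Explainability layer: impurity-based feature importance, exact tree
# Shapley attributions, and gradient class-activation maps for the CNNs.

#' Impurity-based feature importance of a random forest
#'
#' Recomputes, per tree, the Gini impurity decrease contributed by every
#' split (weighted by the in-bag cover of the node) and aggregates the
#' per-tree normalised importances into a mean and SD per feature. The means
#' sum to 1.
#'
#' @param model A fitted `mep_rf`.
#' @return Data.frame with columns `feature`, `mean`, `sd`, ordered by
#'   decreasing mean importance.
#' @export
impurity_importance <- function(model) {
  if (!inherits(model, "mep_rf")) abort_param("model must be a fitted mep_rf")
  trees <- forest_structure(model)
  p <- length(model$feature_names)
  per_tree <- matrix(0, length(trees), p)
  for (t in seq_along(trees)) {
    tr <- trees[[t]]
    internal <- which(tr$childL >= 0L)
    if (length(internal) == 0) next
    gini <- function(nodes) {
      cnt <- tr$counts[nodes, , drop = FALSE]
      tot <- tr$cover[nodes]
      1 - rowSums((cnt / tot)^2)
    }
    wroot <- tr$cover[1]
    dec <- (tr$cover[internal] * gini(internal) -
            tr$cover[tr$childL[internal] + 1L] * gini(tr$childL[internal] + 1L) -
            tr$cover[tr$childR[internal] + 1L] * gini(tr$childR[internal] + 1L)) / wroot
    imp <- tapply(dec, tr$splitvar[internal], sum)
    per_tree[t, as.integer(names(imp)) + 1L] <- imp
    s <- sum(per_tree[t, ])
    if (s > 0) per_tree[t, ] <- per_tree[t, ] / s
  }
  out <- data.frame(feature = model$feature_names,
                    mean = colMeans(per_tree),
                    sd = apply(per_tree, 2, sd))
  out[order(-out$mean), ]
}

#' Shapley attributions of a random forest on a training subsample
#'
#' Exact path-dependent tree Shapley values for every explained observation,
#' feature and class, computed from the forest's own structure and in-bag
#' covers (no sampling approximation). Satisfies local accuracy: for each
#' observation and class, `base_value + sum(attributions)` equals the
#' forest's predicted probability.
#'
#' @param model A fitted `mep_rf`.
#' @param X Observations to explain; by default a random
#'   `sample_fraction` subsample of the training set (drawn with `seed`).
#' @param sample_fraction Fraction of training rows explained when `X` is
#'   `NULL` (default 0.2).
#' @param seed Seed of the explanation subsample.
#' @return List of class `attribution_report`: `shap` (n x feature x class
#'   array), `base_values` (per class), `X` (explained rows),
#'   `global_importance` (per-feature mean and SD of |attribution| pooled over
#'   classes), `sample_fraction`, `sample_index`.
#' @export
shap_attributions <- function(model, X = NULL, sample_fraction = 0.2,
                              seed = 1L) {
  if (!inherits(model, "mep_rf")) {
    abort_param("Shapley attributions require a tree model (mep_rf)")
  }
  sample_index <- NULL
  if (is.null(X)) {
    n <- nrow(model$X_train)
    sample_index <- with_seed(seed,
                              sort(sample.int(n, max(1L, round(sample_fraction * n)))))
    X <- model$X_train[sample_index, , drop = FALSE]
  }
  X <- as.matrix(X)
  trees <- forest_structure(model)
  p <- ncol(X)
  K <- length(MUSCLES)
  phi <- array(0, c(nrow(X), p, K),
               dimnames = list(NULL, model$feature_names, MUSCLES))
  base <- numeric(K)
  for (tr in trees) {
    res <- cpp_treeshap(tr$childL, tr$childR, tr$splitvar, tr$splitval,
                        tr$cover, tr$leafval, X)
    phi <- phi + res$phi
    base <- base + res$base
  }
  phi <- phi / length(trees)
  base <- base / length(trees)
  names(base) <- MUSCLES
  gi <- data.frame(feature = model$feature_names,
                   mean_abs = apply(abs(phi), 2, mean),
                   sd_abs = apply(abs(phi), 2, sd))
  gi <- gi[order(-gi$mean_abs), ]
  structure(list(shap = phi, base_values = base, X = X,
                 global_importance = gi,
                 sample_fraction = sample_fraction,
                 sample_index = sample_index, seed = as.integer(seed)),
            class = "attribution_report")
}

#' Signed directionality of Shapley attributions
#'
#' For each class and feature, the Pearson correlation between the feature
#' value and its attribution toward that class: a negative latency
#' correlation for a class means short latencies push predictions toward it.
#'
#' @param report An `attribution_report` from [shap_attributions].
#' @return Data.frame with columns `class`, `feature`, `correlation`,
#'   `direction` (`"positive"`/`"negative"`).
#' @export
shap_direction_summary <- function(report) {
  stopifnot(inherits(report, "attribution_report"))
  feats <- colnames(report$X)
  out <- expand.grid(class = MUSCLES, feature = feats,
                     stringsAsFactors = FALSE)
  out$correlation <- NA_real_
  for (i in seq_len(nrow(out))) {
    f <- out$feature[i]; k <- out$class[i]
    v <- report$X[, f]
    a <- report$shap[, f, k]
    if (sd(v) > 0 && sd(a) > 0) out$correlation[i] <- cor(v, a)
  }
  out$direction <- ifelse(out$correlation >= 0, "positive", "negative")
  out
}

#' Gradient class-activation map of a CNN
#'
#' Gradients of the class logit with respect to the last convolutional
#' feature maps are averaged per channel into weights; the weighted sum of
#' the maps is rectified and upsampled to the input resolution (length 1600
#' for the 1D network, 224 x 224 for the 2D network).
#'
#' @param model A fitted `mep_cnn`.
#' @param input One input in the model's representation: a 1600-sample trace,
#'   or a scalogram (224 x 224 or pooled 28 x 28).
#' @param class_index Target class: index 1-4 or muscle name.
#' @return List of class `attention_map` with `values` (non-negative vector
#'   of length 1600, or 224 x 224 matrix), `class`, `n_averaged = 1`.
#' @export
gradcam <- function(model, input, class_index) {
  if (!inherits(model, "mep_cnn")) {
    abort_param("Grad-CAM requires a model with convolutional layers")
  }
  if (is.character(class_index)) class_index <- match(class_index, MUSCLES)
  if (is.na(class_index) || class_index < 1 || class_index > 4) {
    abort_param("class_index must be 1-4 or a muscle name")
  }
  tgt <- last_conv_output_index(model$layers)
  if (tgt == 0L) abort_param("model has no convolutional layer")
  if (model$input == "time") {
    x <- as.numeric(input)
    if (length(x) != model$input_len) abort_format("expected a 1600-sample trace")
    arr <- array(x, c(1L, length(x), 1L))
  } else {
    arr <- pool_scalogram_stack(input)
    arr <- array(arr, c(dim(arr), 1L))
  }
  fw <- nn_forward(model$layers, arr, training = FALSE, cache = TRUE,
                   keep_output_of = tgt)
  K <- ncol(fw$out)
  dlogits <- matrix(0, 1, K)
  dlogits[1, class_index] <- 1
  dA <- nn_backward(model$layers, dlogits, stop_after = tgt)
  A <- fw$kept
  d <- dim(A)
  if (length(d) == 3) {           # (1, L, C)
    alpha <- colMeans(matrix(dA, d[2], d[3]))
    map <- as.vector(matrix(A, d[2], d[3]) %*% alpha)
    map <- pmax(map, 0)
    values <- upsample_linear(map, model$input_len)
  } else {                        # (1, H, W, C)
    Am <- matrix(A, d[2] * d[3], d[4])
    alpha <- colMeans(matrix(dA, d[2] * d[3], d[4]))
    map <- matrix(pmax(Am %*% alpha, 0), d[2], d[3])
    values <- upsample_bilinear(map, 224L, 224L)
  }
  structure(list(values = values, class = MUSCLES[class_index], n_averaged = 1L),
            class = "attention_map")
}

upsample_linear <- function(v, n_out) {
  n <- length(v)
  if (n == n_out) return(v)
  centers <- seq(1, n_out, length.out = n)
  approx(centers, v, xout = seq_len(n_out), rule = 2)$y
}

upsample_bilinear <- function(m, nr, nc) {
  r1 <- t(apply(m, 1, function(row) upsample_linear(row, nc)))
  apply(r1, 2, function(col) upsample_linear(col, nr))
}

#' Average attention maps by group
#'
#' Element-wise mean of Grad-CAM maps, overall or per muscle; shapes must
#' agree. `n_averaged` records the group size.
#'
#' @param maps List of `attention_map` objects.
#' @param by Optional grouping vector (e.g. muscle labels), one per map;
#'   `NULL` averages everything into one `"overall"` map.
#' @return A named list of `attention_map` objects (one per group).
#' @export
average_gradcams <- function(maps, by = NULL) {
  if (length(maps) == 0) abort_param("no maps to average")
  dims <- lapply(maps, function(m) dim(m$values) %||% length(m$values))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1) {
    abort_format("attention maps have mismatching shapes")
  }
  groups <- if (is.null(by)) rep("overall", length(maps)) else as.character(by)
  out <- list()
  for (g in unique(groups)) {
    sel <- which(groups == g)
    acc <- maps[[sel[1]]]$values
    if (length(sel) > 1) {
      for (i in sel[-1]) acc <- acc + maps[[i]]$values
    }
    out[[g]] <- structure(list(values = acc / length(sel), class = g,
                               n_averaged = length(sel)),
                          class = "attention_map")
  }
  out
}

#' Lower bound of the attention mass along the scale axis
#'
#' For a 2D attention map (rows = scales, ascending), the attention is
#' marginalised over time and the smallest scale at which the cumulative
#' attention mass (counted from the smallest scale upward) reaches `frac` of
#' the total is returned: the lower quartile (by default) of where the map's
#' attention lies in scale. A mass-based bound depends on how far down in
#' scale attention extends, not on where the profile happens to peak. Distal
#' muscles, carrying higher main frequencies, are expected to bound at
#' smaller scales than proximal muscles.
#'
#' @param map An `attention_map` with a 224 x 224 `values` matrix.
#' @param scale_axis Scale value per row (defaults to [cwt_scales]).
#' @param frac Cumulative mass fraction defining the bound.
#' @return The bounding scale (same units as `scale_axis`).
#' @export
attention_scale_bound <- function(map, scale_axis = cwt_scales(), frac = 0.25) {
  v <- if (inherits(map, "attention_map")) map$values else map
  if (!is.matrix(v)) abort_format("need a 2D attention map")
  marg <- rowSums(v)
  if (sum(marg) == 0) abort_degenerate("all-zero attention map")
  cum <- cumsum(marg) / sum(marg)
  scale_axis[which(cum >= frac)[1]]
}
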