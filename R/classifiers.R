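# Model training: patient-stratified splitting, class weighting, random
# forests on the time and feature representations, and the two CNNs.

#' Patient-stratified train/validation split
#'
#' Random patient-level partition targeting `fraction_train` of the
#' *recordings* in the training side; no patient contributes to both sides.
#' Deterministic for a given seed.
#'
#' @param meta Data.frame with a `patient_id` column (one row per recording).
#' @param fraction_train Target fraction of recordings in the training side.
#' @param seed Integer seed.
#' @return A list of class `split_plan` with `train_patient_ids`,
#'   `validation_patient_ids`, `fraction_train`, `seed`.
#' @export
patient_stratified_split <- function(meta, fraction_train = 0.7, seed = 1L) {
  pid <- as.character(meta$patient_id)
  patients <- unique(pid)
  if (length(patients) < 2) abort_param("need at least 2 patients to split")
  counts <- table(pid)[patients]
  with_seed(seed, {
    perm <- sample(patients)
  })
  cum <- cumsum(as.numeric(counts[perm]))
  target <- fraction_train * sum(counts)
  k <- which.min(abs(cum - target))
  k <- max(1L, min(k, length(patients) - 1L))
  structure(list(train_patient_ids = sort(perm[seq_len(k)]),
                 validation_patient_ids = sort(perm[-seq_len(k)]),
                 fraction_train = fraction_train, seed = as.integer(seed)),
            class = "split_plan")
}

#' Inverse-frequency class weights
#'
#' `weight_c = N / (4 * count_c)`, so that weighted class counts are equal;
#' errors when any of the four classes is absent.
#'
#' @param labels Factor or character vector of muscle labels.
#' @return Named numeric vector in the fixed class order EXT, APB, TA, AH.
#' @export
compute_class_weights <- function(labels) {
  labels <- factor(labels, levels = MUSCLES)
  counts <- table(labels)
  if (any(counts == 0)) {
    abort_param(paste("missing class(es):",
                      paste(names(counts)[counts == 0], collapse = ", ")))
  }
  w <- as.numeric(sum(counts) / (length(MUSCLES) * counts))
  names(w) <- MUSCLES
  w
}

default_rf_grid <- function(p) {
  if (p <= 10) {
    expand.grid(num_trees = c(100L, 200L), mtry = c(2L, 3L),
                min_node_size = c(5L, 25L))
  } else {
    # high-dimensional time representation: a lean grid keeps single-CPU
    # training tractable
    expand.grid(num_trees = 150L, mtry = as.integer(round(c(sqrt(p), p / 8))),
                min_node_size = 5L)
  }
}

fit_ranger <- function(X, y, weights, params, seed) {
  ranger::ranger(x = X, y = y, probability = TRUE,
                 num.trees = params$num_trees, mtry = params$mtry,
                 min.node.size = params$min_node_size,
                 class.weights = weights, keep.inbag = TRUE,
                 seed = seed, num.threads = 1L)
}

#' Train a random forest with an inner grid search
#'
#' Probability random forest on either the 1600-dimensional time
#' representation or the 5-dimensional feature representation. Hyperparameters
#' are selected from a documented default grid by accuracy on an inner
#' patient-stratified split of the training data, then the best configuration
#' is refit on the full training set with the supplied class weights.
#'
#' @param X Numeric matrix of predictors (rows = recordings).
#' @param y Muscle labels (factor or character, classes EXT/APB/TA/AH).
#' @param weights Class weights from [compute_class_weights]; computed from
#'   `y` when `NULL`.
#' @param grid Data.frame of candidate hyperparameters (`num_trees`, `mtry`,
#'   `min_node_size`); defaults depend on `ncol(X)`.
#' @param seed Integer seed controlling the inner split and all forest fits.
#' @param patient_ids Optional patient identifier per row; used for the inner
#'   patient-stratified selection split (falls back to a random row split).
#' @param inner_fraction Fraction of training recordings used to fit grid
#'   candidates.
#' @return An object of class `mep_rf` (also `mep_classifier`).
#' @export
train_random_forest <- function(X, y, weights = NULL, grid = NULL, seed = 1L,
                                patient_ids = NULL, inner_fraction = 0.75) {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = MUSCLES)
  if (anyNA(y)) abort_param("labels outside EXT/APB/TA/AH")
  if (is.null(weights)) weights <- compute_class_weights(y)
  if (is.null(grid)) grid <- default_rf_grid(ncol(X))
  if (nrow(grid) == 0) abort_param("empty hyperparameter grid")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  grid_results <- cbind(grid, inner_accuracy = NA_real_)
  if (nrow(grid) > 1) {
    if (!is.null(patient_ids)) {
      inner <- patient_stratified_split(data.frame(patient_id = patient_ids),
                                        inner_fraction, seed = seed + 1L)
      tr <- patient_ids %in% inner$train_patient_ids
    } else {
      tr <- rep(FALSE, nrow(X))
      tr[with_seed(seed + 1L,
                   sample.int(nrow(X), round(inner_fraction * nrow(X))))] <- TRUE
    }
    for (g in seq_len(nrow(grid))) {
      fit <- fit_ranger(X[tr, , drop = FALSE], y[tr], weights,
                        grid[g, ], seed = seed + 10L + g)
      pr <- predict(fit, X[!tr, , drop = FALSE], num.threads = 1L)$predictions
      pred <- MUSCLES[max.col(pr[, MUSCLES, drop = FALSE], ties.method = "first")]
      grid_results$inner_accuracy[g] <- mean(pred == as.character(y[!tr]))
    }
    best <- which.max(grid_results$inner_accuracy)
  } else {
    best <- 1L
  }
  fit <- fit_ranger(X, y, weights, grid[best, ], seed = seed)
  structure(list(family = if (ncol(X) <= 10) "rf_feature" else "rf_time",
                 fit = fit, classes = MUSCLES,
                 class_weights = weights,
                 grid_results = grid_results,
                 best_params = as.list(grid[best, , drop = FALSE]),
                 seed = as.integer(seed),
                 feature_names = colnames(X),
                 X_train = X, y_train = y,
                 cache = new.env(parent = emptyenv())),
            class = c("mep_rf", "mep_classifier"))
}

prepare_cnn_inner_split <- function(n, patient_ids, fraction, seed) {
  if (!is.null(patient_ids)) {
    inner <- patient_stratified_split(data.frame(patient_id = patient_ids),
                                      1 - fraction, seed = seed + 1L)
    which(patient_ids %in% inner$train_patient_ids)
  } else {
    with_seed(seed + 1L, sample.int(n, max(1L, round(fraction * n))))
  }
}

#' Train the 1D convolutional network on the time representation
#'
#' Two strided 1D convolutions, max pooling, dropout, batch normalisation,
#' a dense hidden layer and a 4-way softmax output, trained with Adam on the
#' class-weighted cross-entropy. A patient-disjoint slice of the training data
#' monitors early stopping.
#'
#' @param X Matrix of filtered, normalised traces (1600 columns), or an
#'   `mep_representation`.
#' @param y Muscle labels.
#' @param weights Class weights (computed from `y` when `NULL`).
#' @param seed Integer seed (weight initialisation, shuffling, dropout).
#' @param patient_ids Optional patient ids for the early-stopping split.
#' @param epochs,batch,lr,patience,monitor_fraction Training controls.
#' @param verbose Print per-epoch progress.
#' @return An object of class `mep_cnn` (also `mep_classifier`).
#' @export
train_cnn1d <- function(X, y, weights = NULL, seed = 1L, patient_ids = NULL,
                        epochs = 30L, batch = 64L, lr = 1e-3, patience = 5L,
                        monitor_fraction = 0.15, verbose = FALSE) {
  if (inherits(X, "mep_representation")) {
    patient_ids <- patient_ids %||% X$meta$patient_id
    X <- X$values
  }
  X <- as.matrix(X)
  if (ncol(X) != 1600L) abort_format("time representation must have 1600 columns")
  if (any(!is.finite(X))) abort_param("non-finite values in input")
  y <- factor(as.character(y), levels = MUSCLES)
  if (anyNA(y)) abort_param("labels outside EXT/APB/TA/AH")
  if (is.null(weights)) weights <- compute_class_weights(y)
  yidx <- as.integer(y)
  mon <- prepare_cnn_inner_split(nrow(X), patient_ids, monitor_fraction, seed)
  arr <- array(X, c(nrow(X), ncol(X), 1L))
  fit <- with_seed(seed, {
    layers <- build_cnn1d()
    nn_fit(layers, slice_obs(arr, setdiff(seq_len(nrow(X)), mon)),
           yidx[-mon], weights, slice_obs(arr, mon), yidx[mon],
           epochs = epochs, batch = batch, lr = lr, patience = patience,
           verbose = verbose)
  })
  structure(list(family = "cnn1d", layers = fit$layers, classes = MUSCLES,
                 class_weights = weights, history = fit$history,
                 input = "time", input_len = 1600L, seed = as.integer(seed)),
            class = c("mep_cnn", "mep_classifier"))
}

#' Train the 2D convolutional network on scalograms
#'
#' Four convolution/batch-norm blocks with max pooling after the second and
#' third and global max pooling after the fourth, closed by a dense softmax
#' output; fixed (non-tuned) hyperparameters. Scalograms are block-averaged
#' 8x8 to 28x28 before entering the network.
#'
#' @param X Scalogram stack: array `(n, 224, 224)` or pooled `(n, 28, 28)`
#'   from [scalogram_stack].
#' @inheritParams train_cnn1d
#' @return An object of class `mep_cnn` (also `mep_classifier`).
#' @export
train_cnn2d <- function(X, y, weights = NULL, seed = 1L, patient_ids = NULL,
                        epochs = 10L, batch = 64L, lr = 1e-3, patience = 4L,
                        monitor_fraction = 0.15, verbose = FALSE) {
  X <- pool_scalogram_stack(X)
  if (any(!is.finite(X))) abort_param("non-finite values in input")
  y <- factor(as.character(y), levels = MUSCLES)
  if (anyNA(y)) abort_param("labels outside EXT/APB/TA/AH")
  if (is.null(weights)) weights <- compute_class_weights(y)
  yidx <- as.integer(y)
  n <- dim(X)[1]
  mon <- prepare_cnn_inner_split(n, patient_ids, monitor_fraction, seed)
  arr <- array(X, c(dim(X), 1L))
  fit <- with_seed(seed, {
    layers <- build_cnn2d()
    nn_fit(layers, slice_obs(arr, setdiff(seq_len(n), mon)), yidx[-mon],
           weights, slice_obs(arr, mon), yidx[mon],
           epochs = epochs, batch = batch, lr = lr, patience = patience,
           verbose = verbose)
  })
  structure(list(family = "cnn2d", layers = fit$layers, classes = MUSCLES,
                 class_weights = weights, history = fit$history,
                 input = "scalogram", input_size = 28L, seed = as.integer(seed)),
            class = c("mep_cnn", "mep_classifier"))
}

# Accept full-resolution (n, 224, 224) or pre-pooled (n, 28, 28) stacks.
pool_scalogram_stack <- function(X) {
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  d <- dim(X)
  if (length(d) == 4 && d[4] == 1L) { dim(X) <- d[1:3]; d <- dim(X) }
  if (length(d) != 3) abort_format("scalogram stack must be a 3-d array")
  if (d[2] == 28L && d[3] == 28L) return(X)
  if (d[2] != 224L || d[3] != 224L) {
    abort_format("scalograms must be 224 x 224 (or pre-pooled 28 x 28)")
  }
  out <- array(0, c(d[1], 28L, 28L))
  grp <- rep(seq_len(28L), each = 8L)
  for (i in seq_len(d[1])) {
    a <- rowsum(X[i, , ], grp) / 8      # pool the scale axis: 28 x 224
    out[i, , ] <- t(rowsum(t(a), grp) / 8)  # pool the time axis: 28 x 28
  }
  out
}

#' Per-class probability predictions
#'
#' Common prediction contract for all model families: an `n x 4` matrix of
#' class probabilities in the fixed order EXT, APB, TA, AH, rows summing to 1.
#'
#' @param model A fitted `mep_classifier`.
#' @param X New data in the model's input representation (matrix of traces or
#'   features, or scalogram stack).
#' @return Probability matrix with one column per muscle.
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

#' @export
predict_proba.mep_rf <- function(model, X) {
  if (inherits(X, "mep_representation")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) != length(model$feature_names)) {
    abort_format("predictor count does not match the fitted model")
  }
  colnames(X) <- model$feature_names
  pr <- predict(model$fit, X, num.threads = 1L)$predictions
  pr <- pr[, MUSCLES, drop = FALSE]
  dimnames(pr) <- list(rownames(X), MUSCLES)
  pr
}

#' @export
predict_proba.mep_cnn <- function(model, X) {
  if (inherits(X, "mep_representation")) X <- X$values
  if (model$input == "time") {
    X <- as.matrix(X)
    if (ncol(X) != model$input_len) abort_format("expected 1600-sample traces")
    arr <- array(X, c(nrow(X), ncol(X), 1L))
  } else {
    X <- pool_scalogram_stack(X)
    arr <- array(X, c(dim(X), 1L))
  }
  logits <- nn_predict_logits(model$layers, arr)
  pr <- softmax_rows(logits)
  colnames(pr) <- MUSCLES
  pr
}

#' Threshold-gated classification
#'
#' Predicts the argmax class when its probability reaches the confidence
#' threshold and abstains otherwise. With four classes the maximum probability
#' is always >= 0.25, so the chance-level threshold never abstains. Argmax
#' ties resolve in the fixed class order.
#'
#' @param probabilities Probability vector (length 4) or matrix (n x 4).
#' @param threshold Decision threshold in `[0.25, 1)`.
#' @return Factor with levels `EXT`, `APB`, `TA`, `AH`, `abstain`.
#' @export
classify_with_threshold <- function(probabilities, threshold = 0.25) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0.25 || threshold >= 1) {
    abort_param("threshold must be in [0.25, 1)")
  }
  p <- if (is.matrix(probabilities)) probabilities else
    matrix(probabilities, nrow = 1)
  if (ncol(p) != 4) abort_format("need 4 class probabilities")
  pred <- MUSCLES[max.col(p, ties.method = "first")]
  pred[apply(p, 1, max) < threshold] <- "abstain"
  factor(pred, levels = c(MUSCLES, "abstain"))
}
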