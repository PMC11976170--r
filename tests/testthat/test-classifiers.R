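test_that("patient split is proportioned, disjoint and deterministic", {
  meta <- data.frame(patient_id = rep(sprintf("P%02d", 1:10), each = 5))
  sp <- patient_stratified_split(meta, 0.7, seed = 3)
  expect_length(sp$train_patient_ids, 7)
  expect_length(sp$validation_patient_ids, 3)
  expect_length(intersect(sp$train_patient_ids, sp$validation_patient_ids), 0)
  expect_identical(sp, patient_stratified_split(meta, 0.7, seed = 3))
  expect_false(identical(sp$train_patient_ids,
                         patient_stratified_split(meta, 0.7, seed = 4)$train_patient_ids))
  expect_error(patient_stratified_split(data.frame(patient_id = rep("P1", 5))),
               class = "mepmuscle_param_error")
})

test_that("class weights follow the inverse-frequency formula", {
  eq <- rep(c("EXT", "APB", "TA", "AH"), each = 10)
  expect_equal(unname(compute_class_weights(eq)), rep(1, 4))
  lab <- rep(c("EXT", "APB", "TA", "AH"), c(100, 300, 100, 100))
  w <- compute_class_weights(lab)
  expect_equal(unname(w), c(1.5, 0.5, 1.5, 1.5))
  # weighted class counts are balanced
  expect_equal(unname(w * table(factor(lab, c("EXT", "APB", "TA", "AH")))),
               rep(150, 4), ignore_attr = TRUE)
  # a strongly imbalanced clinical class mix gives weights ordered AH > TA > EXT > APB
  t1 <- rep(c("EXT", "APB", "TA", "AH"), c(11958, 15800, 5773, 3461))
  w1 <- compute_class_weights(t1)
  expect_true(all(diff(w1[c("APB", "EXT", "TA", "AH")]) > 0))
  expect_error(compute_class_weights(rep(c("EXT", "APB", "TA"), 5)),
               class = "mepmuscle_param_error")
})

test_that("threshold gating classifies, abstains, and validates", {
  expect_equal(as.character(classify_with_threshold(c(.7, .1, .1, .1), 0.5)),
               "EXT")
  expect_equal(as.character(classify_with_threshold(c(.26, .26, .24, .24), 0.3)),
               "abstain")
  expect_equal(as.character(classify_with_threshold(c(.3, .3, .2, .2), 0.3)),
               "EXT")  # tie broken by fixed class order
  set.seed(12)
  p <- matrix(rexp(400), 100, 4)
  p <- p / rowSums(p)
  expect_false(any(classify_with_threshold(p, 0.25) == "abstain"))
  expect_error(classify_with_threshold(c(.7, .1, .1, .1), 0.2),
               class = "mepmuscle_param_error")
})

separable_toy <- function(n = 200) {
  set.seed(30)
  centers <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), 4, 2, byrow = TRUE)
  y <- factor(rep(c("EXT", "APB", "TA", "AH"), length.out = n),
              levels = c("EXT", "APB", "TA", "AH"))
  X <- centers[as.integer(y), ] + matrix(rnorm(2 * n, 0, 0.3), n, 2)
  colnames(X) <- c("f1", "f2")
  list(X = X, y = y)
}

test_that("random forest separates a linearly separable toy problem", {
  toy <- separable_toy()
  rf <- train_random_forest(toy$X, toy$y,
                            grid = data.frame(num_trees = 50L, mtry = 2L,
                                              min_node_size = 1L), seed = 2)
  pr <- predict_proba(rf, toy$X)
  expect_equal(dim(pr), c(200, 4))
  expect_equal(unname(rowSums(pr)), rep(1, 200), tolerance = 1e-6)
  expect_equal(accuracy(classify_with_threshold(pr), toy$y), 1.0)
  expect_error(train_random_forest(toy$X, toy$y, grid = data.frame()),
               class = "mepmuscle_param_error")
})

test_that("a single fully grown tree is one-hot on well-separated clusters", {
  toy <- separable_toy()
  rf1 <- train_random_forest(toy$X, toy$y,
                             grid = data.frame(num_trees = 1L, mtry = 2L,
                                               min_node_size = 1L), seed = 4)
  pr <- predict_proba(rf1, toy$X)
  expect_true(all(pr %in% c(0, 1)))
  expect_equal(as.character(classify_with_threshold(pr)), as.character(toy$y))
})

test_that("random forest selection and fit are deterministic under a seed", {
  toy <- separable_toy()
  g <- expand.grid(num_trees = c(20L, 40L), mtry = 1:2, min_node_size = 5L)
  a <- train_random_forest(toy$X, toy$y, grid = g, seed = 6)
  b <- train_random_forest(toy$X, toy$y, grid = g, seed = 6)
  expect_identical(a$best_params, b$best_params)
  expect_identical(predict_proba(a, toy$X), predict_proba(b, toy$X))
})

num_grad_check <- function(layers, x, yidx, w, param_layers, eps = 1e-5) {
  logits <- mepmuscle:::nn_forward(layers, x, training = TRUE)
  lg <- mepmuscle:::nn_loss(logits, yidx, w)
  mepmuscle:::nn_backward(layers, lg$grad)
  worst <- 0
  for (li in param_layers) {
    l <- layers[[li]]
    for (p in mepmuscle:::nn_param_names(l)) {
      W <- get(p, envir = l)
      gW <- get(mepmuscle:::nn_grad_name(p), envir = l)
      for (idx in seq_len(min(4, length(W)))) {
        Wp <- W; Wp[idx] <- Wp[idx] + eps
        assign(p, Wp, envir = l)
        lp <- mepmuscle:::nn_loss(
          mepmuscle:::nn_forward(layers, x, training = TRUE), yidx, w)$loss
        Wm <- W; Wm[idx] <- Wm[idx] - eps
        assign(p, Wm, envir = l)
        lm <- mepmuscle:::nn_loss(
          mepmuscle:::nn_forward(layers, x, training = TRUE), yidx, w)$loss
        assign(p, W, envir = l)
        num <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(num - gW[idx]) / max(1e-6, abs(num), abs(gW[idx])))
      }
    }
  }
  worst
}

test_that("1D network backpropagation matches numeric gradients", {
  set.seed(40)
  layers <- list(mepmuscle:::nn_conv1d(1L, 3L, 5L, stride = 2L),
                 mepmuscle:::nn_relu(),
                 mepmuscle:::nn_maxpool1d(2L),
                 mepmuscle:::nn_batchnorm(3L),
                 mepmuscle:::nn_flatten(),
                 mepmuscle:::nn_dense(3L * 9L, 4L))
  x <- array(rnorm(2 * 40), c(2, 40, 1))
  # batch norm uses batch statistics, so gradients must be checked in
  # training mode with dropout disabled
  worst <- num_grad_check(layers, x, c(1L, 3L), rep(1, 4), c(1L, 4L, 6L))
  expect_lt(worst, 1e-4)
})

test_that("2D network backpropagation matches numeric gradients", {
  set.seed(41)
  layers <- list(mepmuscle:::nn_conv2d(1L, 2L),
                 mepmuscle:::nn_batchnorm(2L),
                 mepmuscle:::nn_relu(),
                 mepmuscle:::nn_maxpool2d(),
                 mepmuscle:::nn_conv2d(2L, 3L),
                 mepmuscle:::nn_relu(),
                 mepmuscle:::nn_globalmaxpool(),
                 mepmuscle:::nn_dense(3L, 4L))
  x <- array(rnorm(2 * 64), c(2, 8, 8, 1))
  worst <- num_grad_check(layers, x, c(2L, 4L), c(1, 2, 1, 1), c(1L, 2L, 5L, 8L))
  expect_lt(worst, 1e-4)
})

cnn_toy <- function(n = 160) {
  # four latency-coded trace classes
  set.seed(50)
  y <- factor(rep(c("EXT", "APB", "TA", "AH"), length.out = n),
              levels = c("EXT", "APB", "TA", "AH"))
  onset <- c(EXT = 22, APB = 32, TA = 45, AH = 60)[as.character(y)]
  X <- t(vapply(seq_len(n), function(i) {
    r <- generate_mep(waveform_params(onset[i], 300, n_phases = 4,
                                      noise_sd = 0.02))
    strip_artifact(r)
  }, numeric(1600)))
  list(X = X, y = y)
}

test_that("1D CNN learns a latency-coded toy task and predicts probabilities", {
  toy <- cnn_toy()
  m <- train_cnn1d(toy$X, toy$y, seed = 51, epochs = 6, batch = 32,
                   monitor_fraction = 0.2)
  pr <- predict_proba(m, toy$X)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
  expect_gt(accuracy(classify_with_threshold(pr), toy$y), 0.9)
  # frozen weights: repeated inference is identical
  expect_identical(pr, predict_proba(m, toy$X))
  expect_error(train_cnn1d(toy$X[, 1:100], toy$y),
               class = "mepmuscle_format_error")
})

test_that("2D CNN trains on pooled scalograms and predicts probabilities", {
  toy <- cnn_toy(120)
  sc <- scalogram_stack(toy$X, pool = 8L)
  m <- train_cnn2d(sc, toy$y, seed = 52, epochs = 4, batch = 32,
                   monitor_fraction = 0.2)
  pr <- predict_proba(m, sc)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
  expect_gt(accuracy(classify_with_threshold(pr), toy$y), 0.8)
  expect_error(train_cnn2d(array(0, c(4, 10, 10)), toy$y[1:4]),
               class = "mepmuscle_format_error")
})
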