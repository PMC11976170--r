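xai_toy <- function(n = 300, informative = 1) {
  set.seed(70)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  cuts <- stats::quantile(X[, informative], c(.25, .5, .75))
  y <- factor(c("EXT", "APB", "TA", "AH")[findInterval(X[, informative],
                                                       cuts) + 1L],
              levels = c("EXT", "APB", "TA", "AH"))
  list(X = X, y = y)
}

test_that("impurity importance finds the informative feature", {
  toy <- xai_toy()
  rf <- train_random_forest(toy$X, toy$y,
                            grid = data.frame(num_trees = 30L, mtry = 2L,
                                              min_node_size = 5L), seed = 71)
  imp <- impurity_importance(rf)
  expect_equal(sum(imp$mean), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "f1")
  expect_gt(imp$mean[1], 0.9)
  expect_error(impurity_importance(list()), class = "mepmuscle_param_error")
})

test_that("pure-noise features receive near-uniform importance", {
  set.seed(72)
  X <- matrix(rnorm(400 * 4), 400, 4)
  y <- factor(sample(c("EXT", "APB", "TA", "AH"), 400, replace = TRUE),
              levels = c("EXT", "APB", "TA", "AH"))
  rf <- train_random_forest(X, y,
                            grid = data.frame(num_trees = 50L, mtry = 2L,
                                              min_node_size = 5L), seed = 73)
  imp <- impurity_importance(rf)
  expect_true(all(abs(imp$mean - 0.25) < 0.1))
})

test_that("single-leaf trees yield zero attributions everywhere", {
  set.seed(74)
  X <- matrix(rnorm(200), 50, 4)
  y <- factor(rep(c("EXT", "APB", "TA", "AH"), length.out = 50),
              levels = c("EXT", "APB", "TA", "AH"))
  rf <- train_random_forest(X, y,
                            grid = data.frame(num_trees = 5L, mtry = 2L,
                                              min_node_size = 50L), seed = 75)
  rep_ <- shap_attributions(rf, X = X[1:5, ])
  expect_true(all(rep_$shap == 0))
})

test_that("tree Shapley values satisfy local accuracy on every observation", {
  toy <- xai_toy()
  rf <- train_random_forest(toy$X, toy$y,
                            grid = data.frame(num_trees = 25L, mtry = 2L,
                                              min_node_size = 5L), seed = 76)
  rep_ <- shap_attributions(rf, sample_fraction = 0.2, seed = 77)
  expect_equal(dim(rep_$shap)[1], 60)  # 20% of 300
  recon <- sweep(apply(rep_$shap, c(1, 3), sum), 2, rep_$base_values, "+")
  pr <- predict_proba(rf, rep_$X)
  expect_lt(max(abs(recon - pr)), 1e-6)
  expect_error(shap_attributions("not a model"),
               class = "mepmuscle_param_error")
})

test_that("tree Shapley values match brute-force Shapley enumeration", {
  set.seed(78)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(ifelse(X[, 1] > 0,
                     ifelse(X[, 2] > 0, "EXT", "APB"),
                     ifelse(X[, 3] > 0, "TA", "AH")),
              levels = c("EXT", "APB", "TA", "AH"))
  rf <- train_random_forest(X, y,
                            grid = data.frame(num_trees = 3L, mtry = 2L,
                                              min_node_size = 20L), seed = 79)
  trees <- mepmuscle:::forest_structure(rf)
  tr <- trees[[2]]
  res <- mepmuscle:::cpp_treeshap(tr$childL, tr$childR, tr$splitvar,
                                  tr$splitval, tr$cover, tr$leafval, X[1:6, ])
  for (i in 1:6) {
    for (k in 1:4) {
      expect_equal(unname(res$phi[i, , k]), oracle_shapley(tr, X[i, ], k),
                   tolerance = 1e-10)
    }
  }
})

test_that("duplicated identical features share attribution", {
  set.seed(80)
  base <- rnorm(400)
  X <- cbind(a = base, b = base, c = rnorm(400))
  y <- factor(c("EXT", "APB", "TA", "AH")[findInterval(base,
                                                       c(-0.7, 0, 0.7)) + 1L],
              levels = c("EXT", "APB", "TA", "AH"))
  rf <- train_random_forest(X, y,
                            grid = data.frame(num_trees = 60L, mtry = 2L,
                                              min_node_size = 10L), seed = 81)
  rep_ <- shap_attributions(rf, X = X, seed = 82)
  m <- apply(abs(rep_$shap), 2, mean)
  expect_lt(abs(m[["a"]] - m[["b"]]) / max(m[["a"]], m[["b"]]), 0.1)
})

test_that("Grad-CAM maps are rectified, shaped, and rf models are refused", {
  toy_tr <- t(vapply(1:24, function(i) {
    strip_artifact(generate_mep(waveform_params(25 + 5 * (i %% 4), 350,
                                                n_phases = 4,
                                                noise_sd = 0.02)))
  }, numeric(1600)))
  y <- factor(rep(c("EXT", "APB", "TA", "AH"), 6),
              levels = c("EXT", "APB", "TA", "AH"))
  m <- train_cnn1d(toy_tr, y, seed = 83, epochs = 2, batch = 8,
                   monitor_fraction = 0.25)
  am <- gradcam(m, toy_tr[1, ], "EXT")
  expect_s3_class(am, "attention_map")
  expect_length(am$values, 1600)
  expect_true(all(am$values >= 0))
  rf <- train_random_forest(matrix(rnorm(80), 20, 4),
                            factor(rep(c("EXT", "APB", "TA", "AH"), 5)),
                            grid = data.frame(num_trees = 5L, mtry = 2L,
                                              min_node_size = 5L), seed = 84)
  expect_error(gradcam(rf, toy_tr[1, ], 1), class = "mepmuscle_param_error")
  expect_error(gradcam(m, toy_tr[1, ], 9), class = "mepmuscle_param_error")
})

test_that("Grad-CAM averaging respects groups, identity and shapes", {
  mk <- function(v) structure(list(values = v, class = "EXT", n_averaged = 1L),
                              class = "attention_map")
  a <- mk(c(1, 2, 3)); b <- mk(c(3, 2, 1))
  avg <- average_gradcams(list(a, a))
  expect_equal(avg$overall$values, a$values)
  expect_equal(avg$overall$n_averaged, 2L)
  one <- average_gradcams(list(b))
  expect_equal(one$overall$values, b$values)
  grouped <- average_gradcams(list(a, b, a), by = c("EXT", "APB", "EXT"))
  expect_equal(grouped$EXT$values, c(1, 2, 3))
  expect_equal(grouped$APB$values, c(3, 2, 1))
  expect_error(average_gradcams(list(a, mk(c(1, 2)))),
               class = "mepmuscle_format_error")
})

test_that("attention scale bound tracks the lower quartile of attention mass", {
  v <- matrix(0, 224, 224)
  v[150:200, 100:120] <- 1  # uniform block over rows 150..200
  sc <- cwt_scales()
  expect_equal(attention_scale_bound(v), sc[150 + ceiling(0.25 * 51) - 1])
  expect_equal(attention_scale_bound(v, frac = 1e-9), sc[150])
  # shifting the block to smaller scales lowers the bound
  w <- matrix(0, 224, 224)
  w[50:100, 100:120] <- 1
  expect_lt(attention_scale_bound(w), attention_scale_bound(v))
})
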