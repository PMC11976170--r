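test_that("accuracy is the proportion correct", {
  expect_equal(accuracy(c("EXT", "APB"), c("EXT", "APB")), 1)
  expect_equal(accuracy(c("EXT", "APB", "TA", "TA"), c("EXT", "APB", "TA", "AH")),
               0.75)
  expect_error(accuracy(character(0), character(0)),
               class = "mepmuscle_param_error")
  set.seed(60)
  truths <- sample(c("EXT", "APB", "TA", "AH"), 10000, replace = TRUE)
  preds <- sample(c("EXT", "APB", "TA", "AH"), 10000, replace = TRUE)
  expect_lt(abs(accuracy(preds, truths) - 0.25), 0.02)
})

test_that("confusion matrix counts, normalises and conserves totals", {
  y <- rep(c("EXT", "APB", "TA", "AH"), each = 3)
  cm <- confusion_matrix(y, y)
  expect_equal(unname(diag(cm$counts)), rep(3L, 4))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0L)
  all_apb <- confusion_matrix(rep("APB", 12), y)
  expect_true(all(all_apb$counts[, c("EXT", "TA", "AH")] == 0))
  expect_equal(sum(all_apb$counts), 12L)
  expect_error(confusion_matrix(c("EXT", "??"), c("EXT", "APB")),
               class = "mepmuscle_param_error")
  # trace / total equals accuracy
  set.seed(61)
  p <- sample(c("EXT", "APB", "TA", "AH"), 200, replace = TRUE)
  t <- sample(c("EXT", "APB", "TA", "AH"), 200, replace = TRUE)
  cm2 <- confusion_matrix(p, t)
  expect_equal(sum(diag(cm2$counts)) / sum(cm2$counts), accuracy(p, t))
})

test_that("confidence curve: full retention at chance, monotone retention", {
  set.seed(62)
  p <- matrix(rexp(400), 100, 4)
  p <- p / rowSums(p)
  truths <- sample(c("EXT", "APB", "TA", "AH"), 100, replace = TRUE)
  cc <- confidence_curve(p, truths)
  expect_equal(cc$retained_fraction[cc$threshold == 0.25], 1)
  expect_true(all(diff(cc$retained_fraction) <= 1e-12))
  expect_equal(cc$accuracy_on_retained[cc$threshold == 0.25],
               accuracy(classify_with_threshold(p), truths))
  # perfect one-hot probabilities are always retained and always right
  onehot <- diag(4)[match(truths, c("EXT", "APB", "TA", "AH")), ]
  cc2 <- confidence_curve(onehot, truths)
  expect_true(all(cc2$accuracy_on_retained == 1))
  expect_true(all(cc2$retained_fraction == 1))
})

test_that("dispersion statistics follow the direct formulas", {
  expect_equal(unname(performance_dispersion(c(.8, .8, .8, .8))["sd"]), 0)
  a <- c(0.9, 0.8, 0.85, 0.7)
  d <- performance_dispersion(a)
  expect_equal(unname(d["sd"]), sd(100 * a))
  expect_equal(unname(d["cv"]), 100 * sd(100 * a) / mean(100 * a))
  # CV is invariant to rescaling all accuracies
  d2 <- performance_dispersion(100 * a * 0.5)
  expect_equal(unname(d2["cv"]), unname(d["cv"]))
})

test_that("bicentric t test: exact equality gives p = 1, offsets are detected", {
  v <- rep(c(1, 2, 3), 4)
  res <- compare_feature_across_centers(
    values = rep(v, 2),
    center = rep(c("T1", "T2"), each = length(v)),
    muscle = rep(rep(c("EXT", "APB", "TA", "AH"), each = 3), 2))
  expect_equal(res$p_value, rep(1, 4))
  expect_equal(res$t, rep(0, 4))
  # +3 ms latency offset is significant for every muscle at n = 200/group
  cfg <- cohort_config(seed = 63)
  set.seed(63)
  vals <- c(); cen <- c(); mus <- c()
  for (m in c("EXT", "APB", "TA", "AH")) {
    vals <- c(vals, sample_waveform_params(cfg, m, 200)$onset_latency,
              sample_waveform_params(cfg, m, 200, center = "T2")$onset_latency)
    cen <- c(cen, rep(c("T1", "T2"), each = 200))
    mus <- c(mus, rep(m, 400))
  }
  res2 <- compare_feature_across_centers(vals, cen, mus)
  expect_true(all(res2$significant))
  expect_true(all(res2$mean_T1 < res2$mean_T2))
  expect_equal(attr(res2, "n_tests"), 4L)
})
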