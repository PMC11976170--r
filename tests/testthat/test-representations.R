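test_that("band-pass filter: passband flat, stopband attenuated, zero-phase", {
  expect_true(all(bandpass_filter(numeric(1600)) == 0))
  h <- mepmuscle:::fir_taps()
  gain <- function(f) {
    Mod(sum(h * exp(-2i * pi * f * (seq_along(h) - 1) / 20000)))
  }
  expect_lt(abs(20 * log10(gain(500))), 1)
  expect_lt(20 * log10(gain(10)), -20)
  # time-domain: 500-Hz sinusoid keeps its amplitude over the central 80%
  s <- sin(2 * pi * 500 * (0:1599) / 20000)
  y <- bandpass_filter(s)
  central <- 161:1440
  ratio <- max(abs(y[central])) / max(abs(s[central]))
  expect_lt(abs(20 * log10(ratio)), 1)
  # zero-phase: the filtered peak is not delayed
  r <- make_clean_mep(onset = 40, freq = 400)
  x <- strip_artifact(r)
  expect_lt(abs(which.max(bandpass_filter(x)) - which.max(x)), 3)
  expect_error(bandpass_filter(numeric(100)), class = "mepmuscle_format_error")
})

test_that("filter is linear", {
  set.seed(4)
  x <- rnorm(1600); y <- rnorm(1600)
  a <- 2.3; b <- -0.7
  lhs <- bandpass_filter(a * x + b * y)
  rhs <- a * bandpass_filter(x) + b * bandpass_filter(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

test_that("per-patient normalisation scales each group to unit maximum", {
  x <- matrix(c(2, 1, -1, 0.5), 2, 2)  # patient max |.| = 2
  out <- normalize_per_patient(x, c("P1", "P1"))
  expect_equal(max(abs(out)), 1)
  expect_equal(out, x / 2)
  # two traces with maxima 1 and 4
  x2 <- rbind(c(1, 0), c(0, 4))
  out2 <- normalize_per_patient(x2, c("P1", "P1"))
  expect_equal(apply(abs(out2), 1, max), c(0.25, 1))
  # independent groups
  x3 <- rbind(c(2, 0), c(0, 8))
  out3 <- normalize_per_patient(x3, c("P1", "P2"))
  expect_equal(apply(abs(out3), 1, max), c(1, 1))
  # idempotence
  expect_equal(normalize_per_patient(out2, c("P1", "P1")), out2)
  expect_error(normalize_per_patient(rbind(c(0, 0)), "P1"),
               class = "mepmuscle_degenerate_error")
})

test_that("slope equals the mean first derivative per millisecond", {
  expect_equal(feature_slope(rep(2, 1600)), 0)
  expect_equal(feature_slope(0.01 * (0:1599)), 0.01 * 20)
  set.seed(6)
  x <- rnorm(1600)
  g <- numeric(1600)
  for (i in 2:1599) g[i] <- (x[i + 1] - x[i - 1]) / 2
  g[1] <- x[2] - x[1]; g[1600] <- x[1600] - x[1599]
  expect_equal(feature_slope(x), mean(g) * 20)
})

test_that("main frequency is the DFT magnitude argmax at 12.5-Hz bins", {
  s300 <- sin(2 * pi * 300 * (0:1599) / 20000)
  expect_lte(abs(feature_main_frequency(s300) - 300), 12.5)
  mix <- sin(2 * pi * 100 * (0:1599) / 20000) +
    2 * sin(2 * pi * 400 * (0:1599) / 20000)
  expect_lte(abs(feature_main_frequency(mix) - 400), 12.5)
  expect_error(feature_main_frequency(numeric(1600)),
               class = "mepmuscle_feature_error")
  set.seed(7)
  z <- bandpass_filter(rnorm(1600))
  expect_equal(feature_main_frequency(z), oracle_dft_argmax(z))
})

test_that("peak latency is the first prominent peak", {
  t <- (0:1599) / 20 + 20
  bump <- exp(-(t - 35)^2 / 2)
  expect_equal(feature_peak_latency(bump), 35, tolerance = 0.051)
  two <- exp(-(t - 30)^2 / 2) + exp(-(t - 40)^2 / 2)
  expect_equal(feature_peak_latency(two), 30, tolerance = 0.051)
  expect_error(feature_peak_latency(numeric(1600)),
               class = "mepmuscle_feature_error")
})

test_that("feature extraction assembles the five predictors", {
  r <- make_clean_mep(onset = 30, freq = 300, n_phases = 3)
  x <- bandpass_filter(strip_artifact(r))
  x <- x / max(abs(x))
  f <- extract_features(x)
  expect_named(f, c("peak_latency", "max_value", "n_peaks", "main_frequency",
                    "slope"))
  expect_equal(f$n_peaks, 3)
  expect_equal(f$max_value, 1)
  expect_lte(abs(f$main_frequency - 300), 12.5)
  expect_lt(abs(f$peak_latency - (30 + 250 / 300)), 2)
})

test_that("correlation screen reports exact and undefined correlations", {
  set.seed(10)
  x <- matrix(rnorm(30), 10, 3)
  dup <- cbind(x, x[, 1])
  expect_equal(correlation_screen(dup)[1, 4], 1)
  anti <- cbind(a = x[, 1], b = -x[, 1])
  expect_equal(correlation_screen(anti)[1, 2], -1)
  const <- cbind(x, k = rep(1, 10))
  expect_true(is.na(correlation_screen(const)[1, 4]))
  expect_error(correlation_screen(x[, 1, drop = FALSE]),
               class = "mepmuscle_param_error")
  big <- matrix(rnorm(20000), 10000, 2)
  expect_lt(abs(correlation_screen(big)[1, 2]), 0.05)
})

test_that("feature batch path matches the single-trace path", {
  cfg <- cohort_config(n_patients = 3L, recordings_per_patient_per_muscle = 2L,
                       seed = 15L)
  co <- generate_cohort(cfg)
  keep <- preselect(co)$is_mep & !is.na(co$meta$muscle)
  tr <- time_representation(co, keep)
  fr <- feature_representation(tr)
  i <- 3L
  single <- extract_features(tr$values[rownames(fr$values)[i] == rownames(tr$values), ])
  expect_equal(unname(fr$values[i, ]), unname(as.numeric(single[1, ])))
})
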