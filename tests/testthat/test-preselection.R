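test_that("artifact stripping keeps the last 1600 samples", {
  expect_length(strip_artifact(numeric(2000)), 1600)
  expect_error(strip_artifact(numeric(1999)), class = "mepmuscle_format_error")
  ramp <- 0:1999
  expect_equal(strip_artifact(ramp)[1], 400)
  expect_true(all(strip_artifact(numeric(2000)) == 0))
})

test_that("detection threshold: baseline mean and whole-trace SD", {
  expect_equal(unname(detection_threshold(numeric(1600))), c(0, 0))
  expect_equal(unname(detection_threshold(rep(3.7, 1600))), c(3.7, 0))
  # 400 Hz puts an integer cycle count into the 5-ms baseline window
  s <- sin(2 * pi * 400 * (0:1599) / 20000)
  th <- detection_threshold(s)
  expect_lt(abs(th[["mean_baseline"]]), 0.01)
  expect_equal(th[["sd_whole"]], sqrt(0.5), tolerance = 1e-2)
})

test_that("onset latency: no-crossing, programmed onset, and edge rule", {
  expect_true(is.na(onset_latency(numeric(1600))))
  r <- make_clean_mep(onset = 30, freq = 300, n_phases = 4)
  expect_true(onset_latency(strip_artifact(r)) >= 28 &&
              onset_latency(strip_artifact(r)) <= 31)
  edge <- c(5, numeric(1599))  # leaves the band at the first retained sample
  expect_equal(onset_latency(edge), 19)
})

test_that("end latency mirrors the onset rule from the end", {
  expect_true(is.na(end_latency(numeric(1600))))
  r <- generate_mep(waveform_params(30, 200, n_phases = 3))  # support 30-45 ms
  e <- end_latency(strip_artifact(r))
  expect_true(e >= 44 && e <= 47)
})

test_that("time reversal maps end latency onto onset latency", {
  set.seed(8)
  for (i in 1:10) {
    r <- make_clean_mep(onset = runif(1, 25, 55), freq = runif(1, 200, 500),
                        n_phases = sample(3:5, 1))
    x <- strip_artifact(r)
    expect_lt(abs(end_latency(x) - (120 - onset_latency(rev(x)))), 0.1)
  }
})

test_that("peak detection matches the brute-force prominence oracle", {
  expect_length(find_signal_peaks(seq_len(1600) / 100), 0)
  r <- make_clean_mep(onset = 35, freq = 300, n_phases = 3)
  x <- strip_artifact(r)
  pk <- find_signal_peaks(x)
  expect_length(pk, 3)
  expect_equal(diff(pk), rep(1000 / 300, 2), tolerance = 0.05)
  # single Gaussian bump peaks at its centre
  t <- (0:1599) / 20 + 20
  bump <- exp(-(t - 55)^2 / 4)
  expect_equal(find_signal_peaks(bump), 55, tolerance = 0.051)
  # random rough signals: exact agreement with the oracle
  set.seed(42)
  for (i in 1:25) {
    z <- rnorm(300)
    prom <- 2 * oracle_pop_sd(z)
    expect_identical(mepmuscle:::cpp_find_peaks(z, prom),
                     as.integer(oracle_find_peaks(z, prom)))
  }
})

test_that("preselection rule accepts bursts and rejects long signals", {
  ok <- contains_mep(make_clean_mep(onset = 30, freq = 300, n_phases = 3))
  expect_true(ok$is_mep)
  expect_equal(ok$duration, ok$end_latency - ok$onset_latency)
  expect_equal(ok$first_last_peak_interval,
               max(ok$peak_times) - min(ok$peak_times))
  # 45-ms-long burst fails the duration rule
  long <- generate_mep(waveform_params(30, 300, n_phases = 14,
                                       envelope_width = 45))
  expect_false(contains_mep(long)$is_mep)
})

test_that("preselection is scale invariant and deterministic", {
  r <- generate_mep(waveform_params(28, 350, n_phases = 4, noise_sd = 0.03))
  a <- contains_mep(r)
  r2 <- r
  r2$samples <- r$samples * 7.3
  b <- contains_mep(r2)
  expect_equal(a$onset_latency, b$onset_latency)
  expect_equal(a$end_latency, b$end_latency)
  expect_equal(length(a$peak_times), length(b$peak_times))
  expect_identical(a$is_mep, b$is_mep)
  expect_identical(contains_mep(r), a)
})

test_that("batch preselection agrees with the brute-force oracle", {
  cfg <- cohort_config(n_patients = 4L, recordings_per_patient_per_muscle = 3L,
                       seed = 9L)
  co <- generate_cohort(cfg)
  sel <- preselect(co)
  oracle <- vapply(seq_len(nrow(co$signals)),
                   function(i) oracle_preselect(co$signals[i, ]), logical(1))
  expect_identical(sel$is_mep, oracle)
  single <- contains_mep(co$signals[1, ])
  expect_identical(sel$is_mep[1], single$is_mep)
  expect_equal(sel$onset_latency[1], single$onset_latency)
})
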