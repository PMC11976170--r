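# The three classifier inputs: filtered/normalised time series, engineered
# feature vectors, and wavelet scalograms (see scalogram.R for the latter).

the <- new.env(parent = emptyenv())  # package-local cache (filter taps)

# Windowed-sinc (Hamming) linear-phase FIR band-pass taps, cached per design.
fir_taps <- function(low = 30, high = 1000, fs = SAMPLE_RATE, n_taps = 1601L) {
  key <- paste(low, high, fs, n_taps, sep = "_")
  if (is.null(the[[key]])) {
    the[[key]] <- signal::fir1(n_taps - 1L, c(low, high) / (fs / 2),
                               type = "pass")
  }
  the[[key]]
}

#' Band-pass filter a 1600-sample signal
#'
#' Linear-phase FIR band-pass (30-1000 Hz windowed-sinc design, 1601 taps,
#' Hamming window) applied by FFT convolution with group-delay compensation,
#' so the overall response is zero-phase and latency features are not shifted.
#' Output length equals input length.
#'
#' @param signal Numeric vector of length 1600, or a matrix with 1600 columns
#'   (one signal per row).
#' @param sample_rate Sampling rate in Hz (fixed at 20000).
#' @return Filtered signal(s), same shape as the input.
#' @export
bandpass_filter <- function(signal, sample_rate = SAMPLE_RATE) {
  if (sample_rate != SAMPLE_RATE) abort_param("sample_rate must be 20000 Hz")
  vec <- !is.matrix(signal)
  x <- if (vec) matrix(signal, nrow = 1) else signal
  if (ncol(x) != N_SAMPLES - ARTIFACT_SAMPLES) {
    abort_format("signals must have 1600 samples (artifact-stripped)")
  }
  h <- fir_taps(fs = sample_rate)
  n_taps <- length(h)
  delay <- (n_taps - 1L) / 2L
  nfft <- 4096L
  H <- fft(c(h, numeric(nfft - n_taps)))
  out <- matrix(0, nrow(x), ncol(x))
  chunk <- 1024L
  for (s in seq(1, nrow(x), by = chunk)) {
    rows <- s:min(s + chunk - 1L, nrow(x))
    X <- rbind(t(x[rows, , drop = FALSE]),
               matrix(0, nfft - ncol(x), length(rows)))
    Y <- stats::mvfft(stats::mvfft(X) * H, inverse = TRUE) / nfft
    out[rows, ] <- t(Re(Y[(delay + 1L):(delay + ncol(x)), , drop = FALSE]))
  }
  if (vec) out[1, ] else out
}

#' Normalise traces by the per-patient maximum
#'
#' Divides every trace of a patient by the maximum absolute value over that
#' patient's full set of traces, so each patient's largest excursion becomes
#' exactly 1. Groups are independent: amplitudes are not comparable across
#' patients afterwards.
#'
#' @param x Numeric matrix (one trace per row).
#' @param patient_id Vector of patient identifiers, one per row.
#' @return The normalised matrix.
#' @export
normalize_per_patient <- function(x, patient_id) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (length(patient_id) != nrow(x)) {
    abort_param("patient_id must have one entry per row")
  }
  for (pid in unique(patient_id)) {
    rows <- which(patient_id == pid)
    m <- max(abs(x[rows, , drop = FALSE]))
    if (m == 0) abort_degenerate(paste0("all-zero trace group for patient ", pid))
    x[rows, ] <- x[rows, , drop = FALSE] / m
  }
  x
}

#' Time representation of an accepted cohort
#'
#' Artifact stripping, band-pass filtering and per-patient normalisation of
#' the selected recordings; the input of the time-series random forest and
#' the 1D convolutional network.
#'
#' @param cohort An `mep_cohort`.
#' @param keep Logical vector or recording-id subset selecting the recordings
#'   (typically `preselect(cohort)$is_mep`); default keeps all.
#' @return A list of class `mep_representation` with `values` (matrix, 1600
#'   columns) and `meta` (matching metadata rows).
#' @export
time_representation <- function(cohort, keep = NULL) {
  stopifnot(inherits(cohort, "mep_cohort"))
  idx <- seq_len(nrow(cohort$signals))
  if (!is.null(keep)) {
    idx <- if (is.logical(keep)) which(keep) else
      match(keep, cohort$meta$recording_id)
  }
  meta <- cohort$meta[idx, , drop = FALSE]
  values <- bandpass_filter(strip_artifact(cohort$signals[idx, , drop = FALSE]))
  values <- normalize_per_patient(values, meta$patient_id)
  rownames(values) <- meta$recording_id
  structure(list(values = values, meta = meta, repr = "time"),
            class = "mep_representation")
}

#' Peak latency of a filtered trace
#'
#' Absolute time (ms) of the first local maximum whose prominence reaches
#' twice the population SD of the trace. Errors when no peak qualifies (such
#' traces are rejected by preselection upstream).
#'
#' @param filtered Numeric vector of length 1600 (filtered, normalised).
#' @return Peak latency in ms.
#' @export
feature_peak_latency <- function(filtered) {
  pk <- find_signal_peaks(filtered)
  if (length(pk) == 0) abort_feature("no prominent peak in trace")
  pk[1]
}

#' Main frequency of a filtered trace
#'
#' Frequency (Hz) at which the discrete Fourier magnitude of the trace is
#' maximal, over positive frequencies, at the raw bin resolution
#' `sample_rate / 1600 = 12.5 Hz` (no zero padding).
#'
#' @inheritParams feature_peak_latency
#' @param sample_rate Sampling rate in Hz.
#' @return Main frequency in Hz.
#' @export
feature_main_frequency <- function(filtered, sample_rate = SAMPLE_RATE) {
  if (all(filtered == 0)) abort_feature("all-zero trace has no main frequency")
  n <- length(filtered)
  mag <- Mod(fft(filtered))[2:(n %/% 2 + 1)]
  which.max(mag) * sample_rate / n
}

#' Mean slope of a filtered trace
#'
#' Mean of the central-difference first derivative (one-sided at the edges),
#' expressed in normalised units per millisecond.
#'
#' @inheritParams feature_peak_latency
#' @return Mean slope (units/ms).
#' @export
feature_slope <- function(filtered) {
  n <- length(filtered)
  g <- c(filtered[2] - filtered[1],
         (filtered[3:n] - filtered[1:(n - 2)]) / 2,
         filtered[n] - filtered[n - 1])
  mean(g) * (SAMPLE_RATE / 1000)
}

#' Extract the five engineered features of one trace
#'
#' Peak latency, maximum signal value, number of prominent peaks, main
#' frequency, and mean slope of a filtered, normalised trace.
#'
#' @inheritParams feature_peak_latency
#' @return A one-row data.frame with columns `peak_latency`, `max_value`,
#'   `n_peaks`, `main_frequency`, `slope`.
#' @export
extract_features <- function(filtered) {
  pk <- find_signal_peaks(filtered)
  if (length(pk) == 0) abort_feature("no prominent peak in trace")
  data.frame(peak_latency = pk[1],
             max_value = max(filtered),
             n_peaks = length(pk),
             main_frequency = feature_main_frequency(filtered),
             slope = feature_slope(filtered))
}

#' Feature representation of a time representation
#'
#' Applies [extract_features] to every trace; traces without a prominent peak
#' (never produced by preselected recordings) are dropped with a message.
#'
#' @param timerep An `mep_representation` from [time_representation].
#' @return A list of class `mep_representation` with `values` (matrix with the
#'   5 feature columns) and `meta`.
#' @export
feature_representation <- function(timerep) {
  stopifnot(inherits(timerep, "mep_representation"))
  x <- timerep$values
  n <- nrow(x)
  sdw <- sqrt(rowMeans(x^2) - rowMeans(x)^2)
  # spectra for all traces at once
  mag <- Mod(stats::mvfft(t(x)))[2:(ncol(x) %/% 2 + 1), , drop = FALSE]
  mainfreq <- max.col(t(mag), ties.method = "first") * SAMPLE_RATE / ncol(x)
  feats <- matrix(NA_real_, n, 5,
                  dimnames = list(rownames(x),
                                  c("peak_latency", "max_value", "n_peaks",
                                    "main_frequency", "slope")))
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    idx <- cpp_find_peaks(x[i, ], 2 * sdw[i])
    if (length(idx) == 0) { ok[i] <- FALSE; next }
    feats[i, ] <- c(stripped_time_ms(idx[1]), max(x[i, ]), length(idx),
                    mainfreq[i], feature_slope(x[i, ]))
  }
  if (any(!ok)) {
    message(sum(!ok), " trace(s) without a prominent peak dropped")
  }
  structure(list(values = feats[ok, , drop = FALSE],
                 meta = timerep$meta[ok, , drop = FALSE], repr = "feature"),
            class = "mep_representation")
}

#' Pearson correlation screen of candidate features
#'
#' Symmetric correlation matrix with unit diagonal used to audit feature
#' selection; pairs involving a constant column are reported as `NA`.
#'
#' @param x Numeric matrix (observations x features), at least 2 features and
#'   3 observations.
#' @return Correlation matrix.
#' @export
correlation_screen <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 3) {
    abort_param("need >= 2 features and >= 3 observations")
  }
  r <- suppressWarnings(cor(x))
  diag(r) <- 1
  r
}
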