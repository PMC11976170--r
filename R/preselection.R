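# Rule-based MEP preselection: decide whether a recording contains an MEP and
# expose the intermediate latency / duration / peak measurements.

# Absolute time (ms) of 1-based index i of the artifact-stripped signal.
stripped_time_ms <- function(i) (399 + i) / 20

as_samples <- function(recording) {
  if (inherits(recording, "mep_recording")) recording$samples else recording
}

#' Remove the stimulus-artifact window
#'
#' Drops the first 400 samples (20 ms) of a 2000-sample recording; all
#' preselection statistics are computed on the remaining 1600 samples. The
#' returned index `i` corresponds to absolute time `(399 + i) / 20` ms.
#'
#' @param recording An `mep_recording`, a numeric vector of length 2000, or a
#'   matrix with 2000 columns (one recording per row).
#' @return A vector of length 1600 (or a matrix with 1600 columns).
#' @export
strip_artifact <- function(recording) {
  x <- as_samples(recording)
  if (is.matrix(x)) {
    if (ncol(x) != N_SAMPLES) abort_format("recordings must have 2000 samples")
    return(x[, -seq_len(ARTIFACT_SAMPLES), drop = FALSE])
  }
  if (length(x) != N_SAMPLES) abort_format("recording must have 2000 samples")
  x[-seq_len(ARTIFACT_SAMPLES)]
}

#' Detection threshold for onset/end latency
#'
#' The signal is considered present wherever it leaves the band
#' `mean_baseline +/- sd_whole`, where `mean_baseline` is the mean of the last
#' 5 ms (100 samples) and `sd_whole` the population SD of the entire
#' artifact-stripped recording.
#'
#' @param signal Numeric vector of length 1600.
#' @return Named numeric vector `c(mean_baseline, sd_whole)`.
#' @export
detection_threshold <- function(signal) {
  n <- length(signal)
  c(mean_baseline = mean(signal[(n - 99):n]), sd_whole = pop_sd(signal))
}

#' Onset latency of an MEP
#'
#' Time, 1 ms before the first departure of the trace from the detection band
#' (see [detection_threshold]), in absolute ms from the stimulus. `NA` when
#' the trace never leaves the band (no MEP).
#'
#' @inheritParams detection_threshold
#' @return Onset latency in ms, or `NA_real_`.
#' @export
onset_latency <- function(signal) {
  th <- detection_threshold(signal)
  out <- abs(signal - th[["mean_baseline"]]) > th[["sd_whole"]]
  k <- which(out)
  if (length(k) == 0) return(NA_real_)
  stripped_time_ms(k[1]) - 1
}

#' End latency of an MEP
#'
#' Mirror of [onset_latency] scanning from the end of the recording: time,
#' 1 ms after the last departure from the detection band. The 1-ms empirical
#' shift is applied outward (later in time) so that `end - onset` brackets the
#' burst.
#'
#' @inheritParams detection_threshold
#' @return End latency in ms, or `NA_real_`.
#' @export
end_latency <- function(signal) {
  th <- detection_threshold(signal)
  out <- abs(signal - th[["mean_baseline"]]) > th[["sd_whole"]]
  k <- which(out)
  if (length(k) == 0) return(NA_real_)
  stripped_time_ms(k[length(k)]) + 1
}

#' Detect prominent peaks of a signal
#'
#' Local maxima whose topographic prominence is at least `prominence`
#' (default: twice the population SD of the signal, the same rule the feature
#' extractor uses). Returned as absolute times in ms, sorted ascending.
#'
#' @inheritParams detection_threshold
#' @param prominence Minimum peak prominence, in signal units.
#' @return Numeric vector of peak times (ms); empty when no peak qualifies.
#' @export
find_signal_peaks <- function(signal, prominence = 2 * pop_sd(signal)) {
  idx <- cpp_find_peaks(signal, prominence)
  stripped_time_ms(idx)
}

#' Apply the MEP preselection rule to one recording
#'
#' Composes [strip_artifact], [onset_latency], [end_latency] and
#' [find_signal_peaks]; a recording contains an MEP when at least one
#' prominent peak is detected, the duration (end minus onset latency) is less
#' than 40 ms, and the first-to-last peak interval is less than 35 ms.
#'
#' @param recording An `mep_recording` or numeric vector of length 2000.
#' @return A list of class `preselection_result` with `onset_latency`,
#'   `end_latency`, `duration`, `peak_times`, `first_last_peak_interval` and
#'   `is_mep`.
#' @export
contains_mep <- function(recording) {
  x <- strip_artifact(recording)
  on <- onset_latency(x)
  en <- end_latency(x)
  dur <- if (is.na(on) || is.na(en)) NA_real_ else en - on
  pk <- find_signal_peaks(x)
  span <- if (length(pk) >= 1) max(pk) - min(pk) else NA_real_
  is_mep <- length(pk) >= 1 && !is.na(dur) && dur < 40 && span < 35
  structure(list(onset_latency = on, end_latency = en, duration = dur,
                 peak_times = pk, first_last_peak_interval = span,
                 is_mep = is_mep),
            class = "preselection_result")
}

#' Preselect all recordings of a cohort
#'
#' Vectorised [contains_mep] over a cohort (or a bare signal matrix); returns
#' one row per recording with the intermediate measurements and the verdict.
#'
#' @param cohort An `mep_cohort` or a numeric matrix with 2000 columns.
#' @return A data.frame with columns `recording_id`, `onset_latency`,
#'   `end_latency`, `duration`, `n_peaks`, `first_last_peak_interval`,
#'   `is_mep`.
#' @export
preselect <- function(cohort) {
  signals <- if (inherits(cohort, "mep_cohort")) cohort$signals else cohort
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  x <- strip_artifact(signals)
  n <- nrow(x)
  m <- ncol(x)
  base_mean <- rowMeans(x[, (m - 99):m, drop = FALSE])
  mu <- rowMeans(x)
  sdw <- sqrt(rowMeans(x^2) - mu^2)
  sdw[sdw < 0] <- 0  # numerical guard

  onset <- end <- span <- rep(NA_real_, n)
  npk <- integer(n)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    out <- which(abs(xi - base_mean[i]) > sdw[i])
    if (length(out) > 0) {
      onset[i] <- stripped_time_ms(out[1]) - 1
      end[i] <- stripped_time_ms(out[length(out)]) + 1
    }
    idx <- cpp_find_peaks(xi, 2 * sdw[i])
    npk[i] <- length(idx)
    if (npk[i] >= 1) span[i] <- (max(idx) - min(idx)) / 20
  }
  dur <- end - onset
  ids <- if (inherits(cohort, "mep_cohort")) cohort$meta$recording_id else
    rownames(signals) %||% sprintf("R%06d", seq_len(n))
  data.frame(recording_id = ids, onset_latency = onset, end_latency = end,
             duration = dur, n_peaks = npk,
             first_last_peak_interval = span,
             is_mep = npk >= 1 & !is.na(dur) & dur < 40 &
               !is.na(span) & span < 35,
             stringsAsFactors = FALSE)
}
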