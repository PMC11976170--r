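#' Configuration for a synthetic MEP cohort
#'
#' Defines the statistical structure of a simulated cohort: per-muscle onset
#' latency and main-frequency distributions, the class mix, a center-level
#' latency shift, per-patient amplitude scaling, and the fraction of noise-only
#' traces. Defaults emulate the qualitative structure of routinely recorded
#' bicentric MEP data: upper-extremity latencies shorter than lower-extremity
#' ones, higher main frequency for distal (APB, AH) than proximal (EXT, TA)
#' muscles, a later-latency second center, and the class imbalance of a
#' supratentorial-surgery case mix (EXT 31.8%, APB 42.9%, TA 15.7%, AH 9.6%).
#'
#' @param n_patients Number of patients.
#' @param recordings_per_patient_per_muscle Average number of MEP recordings
#'   per patient and muscle; the per-muscle counts follow `class_proportions`.
#' @param class_proportions Named fractions over `EXT`, `APB`, `TA`, `AH`,
#'   summing to 1.
#' @param latency_mean,latency_sd Named per-muscle onset-latency mean/SD in ms.
#' @param frequency_mean,frequency_sd Named per-muscle main-frequency mean/SD
#'   in Hz.
#' @param center_latency_offset Latency shift in ms added to recordings from
#'   center `"T2"`.
#' @param noise_only_fraction Fraction of all recordings that contain no MEP.
#' @param patient_amplitude_spread Range of the per-patient multiplicative
#'   amplitude factor (drawn log-uniformly).
#' @param noise_sd Recording noise SD (amplitude units of an unscaled MEP).
#' @param artifact_amplitude Stimulus-artifact amplitude.
#' @param n_phases_range Integer range of carrier cycles per MEP.
#' @param center `"T1"` or `"T2"`; all patients of a cohort belong to one
#'   center, and `center_latency_offset` is applied when it is `"T2"`.
#' @param stimulation_probs Named probabilities for `TES`/`DCS` labels.
#' @param seed Integer seed; the full cohort is a deterministic function of
#'   the configuration including this seed.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200L,
                          recordings_per_patient_per_muscle = 13L,
                          class_proportions = c(EXT = 0.318, APB = 0.429,
                                                TA = 0.157, AH = 0.096),
                          latency_mean = c(EXT = 22, APB = 24, TA = 37, AH = 40),
                          latency_sd = c(EXT = 2, APB = 2, TA = 3, AH = 3),
                          frequency_mean = c(EXT = 300, APB = 450,
                                             TA = 300, AH = 450),
                          frequency_sd = c(EXT = 65, APB = 65, TA = 65, AH = 65),
                          center_latency_offset = 3,
                          noise_only_fraction = 0.08,
                          patient_amplitude_spread = c(0.5, 2),
                          noise_sd = 0.05,
                          artifact_amplitude = 3,
                          n_phases_range = c(3L, 5L),
                          center = "T1",
                          stimulation_probs = c(TES = 0.8, DCS = 0.2),
                          seed = 1L) {
  if (n_patients < 1) abort_param("n_patients must be >= 1")
  if (recordings_per_patient_per_muscle < 1) {
    abort_param("recordings_per_patient_per_muscle must be >= 1")
  }
  if (!all(MUSCLES %in% names(class_proportions))) {
    abort_param("class_proportions must be named with EXT, APB, TA, AH")
  }
  class_proportions <- class_proportions[MUSCLES]
  if (any(class_proportions < 0)) abort_param("class proportions must be >= 0")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort_param("class_proportions must sum to 1")
  }
  for (nm in c("latency_mean", "latency_sd", "frequency_mean", "frequency_sd")) {
    v <- get(nm)
    if (!all(MUSCLES %in% names(v))) {
      abort_param(paste(nm, "must be named with EXT, APB, TA, AH"))
    }
    assign(nm, v[MUSCLES])
  }
  if (noise_only_fraction < 0 || noise_only_fraction >= 1) {
    abort_param("noise_only_fraction must be in [0, 1)")
  }
  if (length(patient_amplitude_spread) != 2 ||
      any(patient_amplitude_spread <= 0) ||
      diff(patient_amplitude_spread) < 0) {
    abort_param("patient_amplitude_spread must be an increasing positive pair")
  }
  if (!center %in% c("T1", "T2")) abort_param("center must be 'T1' or 'T2'")
  structure(list(n_patients = as.integer(n_patients),
                 recordings_per_patient_per_muscle =
                   as.integer(recordings_per_patient_per_muscle),
                 class_proportions = class_proportions,
                 latency_mean = latency_mean, latency_sd = latency_sd,
                 frequency_mean = frequency_mean, frequency_sd = frequency_sd,
                 center_latency_offset = center_latency_offset,
                 noise_only_fraction = noise_only_fraction,
                 patient_amplitude_spread = patient_amplitude_spread,
                 noise_sd = noise_sd,
                 artifact_amplitude = artifact_amplitude,
                 n_phases_range = as.integer(n_phases_range),
                 center = center,
                 stimulation_probs = stimulation_probs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw ground-truth waveform parameters for a muscle
#'
#' Samples onset latencies (truncated so the burst respects the 20-95 ms
#' window), main frequencies, and cycle counts from the cohort distributions.
#' Latencies of center `"T2"` are shifted by `center_latency_offset`. Uses the
#' global RNG stream (seed externally).
#'
#' @param config A [cohort_config].
#' @param muscle One of `"EXT"`, `"APB"`, `"TA"`, `"AH"`.
#' @param n Number of draws.
#' @param center Overrides the config's center when given.
#' @return A data.frame with columns `onset_latency`, `main_frequency`,
#'   `n_phases`, `envelope_width`.
#' @export
sample_waveform_params <- function(config, muscle, n, center = config$center) {
  stopifnot(inherits(config, "cohort_config"))
  if (!muscle %in% MUSCLES) abort_param("unknown muscle")
  offset <- if (center == "T2") config$center_latency_offset else 0
  freq <- rtruncnorm(n, config$frequency_mean[[muscle]],
                     config$frequency_sd[[muscle]], lower = 100)
  n_phases <- sample(seq(config$n_phases_range[1], config$n_phases_range[2]),
                     n, replace = TRUE)
  width <- 1000 * n_phases / freq
  onset <- rtruncnorm(n, config$latency_mean[[muscle]] + offset,
                      config$latency_sd[[muscle]],
                      lower = 20.05, upper = 95 - width - 0.05)
  data.frame(onset_latency = onset, main_frequency = freq,
             n_phases = n_phases, envelope_width = width)
}

#' Generate a synthetic MEP cohort
#'
#' Produces the full set of recordings for `config$n_patients` patients:
#' per-muscle MEP counts apportioned by `class_proportions`, one log-uniform
#' amplitude factor per patient, muscle-specific latency and frequency draws
#' (with the center-T2 latency shift), additional noise-only traces, and the
#' stimulus artifact on every trace. Given an identical configuration
#' (including `seed`) the result is bit-identical.
#'
#' @param config A [cohort_config].
#' @return An object of class `mep_cohort`: a list with `signals` (numeric
#'   matrix, one row per recording, 2000 columns), `meta` (one row per
#'   recording: identifiers, labels and ground-truth columns), and
#'   `sample_rate`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    per_patient_mep <- apportion(4L * config$recordings_per_patient_per_muscle,
                                 config$class_proportions)
    names(per_patient_mep) <- MUSCLES
    n_mep_pp <- sum(per_patient_mep)
    f <- config$noise_only_fraction
    n_noise_pp <- as.integer(round(f * n_mep_pp / (1 - f)))
    n_pp <- n_mep_pp + n_noise_pp
    n_total <- config$n_patients * n_pp

    signals <- matrix(0, n_total, N_SAMPLES)
    muscle <- character(n_total)
    patient <- character(n_total)
    gt <- data.frame(gt_onset_latency = rep(NA_real_, n_total),
                     gt_main_frequency = NA_real_,
                     gt_n_phases = NA_integer_,
                     gt_envelope_width = NA_real_,
                     gt_amplitude = NA_real_)
    amp_scale <- numeric(n_total)

    spread <- log(config$patient_amplitude_spread)
    artifact <- artifact_transient(config$artifact_amplitude)
    t_ms <- recording_time_ms()

    row <- 0L
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", p)
      p_amp <- exp(runif(1, spread[1], spread[2]))
      for (m in MUSCLES) {
        k <- per_patient_mep[[m]]
        if (k == 0L) next
        par <- sample_waveform_params(config, m, k)
        amp <- p_amp * exp(rnorm(k, 0, 0.15))  # within-patient trial variability
        for (i in seq_len(k)) {
          row <- row + 1L
          burst <- par$envelope_width[i]
          idx <- which(t_ms >= par$onset_latency[i] &
                       t_ms <= par$onset_latency[i] + burst)
          tt <- t_ms[idx]
          env <- exp(-(tt - (par$onset_latency[i] + burst / 2))^2 /
                       (2 * (burst / 2)^2))
          wave <- numeric(N_SAMPLES)
          wave[idx] <- amp[i] * env *
            sin(2 * pi * par$main_frequency[i] * (tt - par$onset_latency[i]) / 1000)
          signals[row, ] <- wave + artifact +
            rnorm(N_SAMPLES, 0, config$noise_sd)
          muscle[row] <- m
          patient[row] <- pid
          amp_scale[row] <- p_amp
          gt$gt_onset_latency[row] <- par$onset_latency[i]
          gt$gt_main_frequency[row] <- par$main_frequency[i]
          gt$gt_n_phases[row] <- par$n_phases[i]
          gt$gt_envelope_width[row] <- burst
          gt$gt_amplitude[row] <- amp[i]
        }
      }
      if (n_noise_pp > 0L) {
        for (i in seq_len(n_noise_pp)) {
          row <- row + 1L
          signals[row, ] <- artifact + rnorm(N_SAMPLES, 0, config$noise_sd)
          muscle[row] <- NA_character_
          patient[row] <- pid
          amp_scale[row] <- p_amp
        }
      }
    }

    stim <- sample(names(config$stimulation_probs), n_total, replace = TRUE,
                   prob = config$stimulation_probs)
    meta <- data.frame(recording_id = sprintf("R%06d", seq_len(n_total)),
                       patient_id = patient,
                       muscle = factor(muscle, levels = MUSCLES),
                       center = config$center,
                       stimulation = stim,
                       amplitude_scale = amp_scale,
                       stringsAsFactors = FALSE)
    meta <- cbind(meta, gt)
    rownames(signals) <- meta$recording_id
    structure(list(signals = signals, meta = meta, sample_rate = SAMPLE_RATE),
              class = "mep_cohort")
  })
}

#' @export
print.mep_cohort <- function(x, ...) {
  tab <- table(x$meta$muscle, useNA = "ifany")
  cat(sprintf("<mep_cohort> %d recordings, %d patients, center %s\n",
              nrow(x$signals), length(unique(x$meta$patient_id)),
              paste(unique(x$meta$center), collapse = "/")))
  print(tab)
  invisible(x)
}

#' Write / read a cohort as a two-file CSV pair
#'
#' `write_cohort()` stores the dense signal matrix (one row per recording,
#' `recording_id` first column, 2000 sample columns) as `signals.csv` and the
#' metadata (including ground-truth columns when synthetic) as `metadata.csv`.
#' `read_cohort()` reconstructs the `mep_cohort` object.
#'
#' @param cohort An `mep_cohort`.
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   an `mep_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mep_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig <- data.table::as.data.table(cohort$signals)
  data.table::setnames(sig, paste0("s", seq_len(ncol(cohort$signals))))
  sig <- cbind(data.table::data.table(recording_id = cohort$meta$recording_id), sig)
  data.table::fwrite(sig, file.path(dir, "signals.csv"))
  data.table::fwrite(cohort$meta, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  sig <- data.table::fread(file.path(dir, "signals.csv"), data.table = FALSE)
  meta <- data.table::fread(file.path(dir, "metadata.csv"), data.table = FALSE,
                            na.strings = c("NA", ""))
  ids <- sig$recording_id
  signals <- as.matrix(sig[, -1, drop = FALSE])
  dimnames(signals) <- list(ids, NULL)
  meta$muscle <- factor(meta$muscle, levels = MUSCLES)
  structure(list(signals = signals, meta = meta, sample_rate = SAMPLE_RATE),
            class = "mep_cohort")
}
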