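#' Waveform parameters for one synthetic MEP
#'
#' Describes the deterministic part of a simulated motor-evoked potential:
#' a Gaussian-enveloped sinusoid riding on a 100-ms recording window, plus a
#' stimulus-artifact transient and additive white noise. The burst starts at
#' `onset_latency`, oscillates at `main_frequency` and is truncated after
#' `n_phases` full carrier cycles (the carrier ends on a zero crossing, so the
#' truncation is continuous); the Gaussian envelope spans the burst with
#' sigma = burst length / 2, flat enough that every carrier cycle contributes
#' a detectable positive peak.
#'
#' @param onset_latency Burst onset in ms after the stimulus. Must be >= 20 ms
#'   so the response starts after the excluded artifact window.
#' @param main_frequency Carrier frequency in Hz.
#' @param amplitude Peak amplitude in arbitrary units (>= 0; 0 gives a silent
#'   trace).
#' @param n_phases Number of full carrier cycles inside the envelope
#'   (integer >= 1); equals the number of positive peaks of the noiseless burst.
#' @param envelope_width Envelope width in ms. Defaults to the duration of
#'   `n_phases` carrier cycles; if smaller, the burst is truncated earlier.
#'   `onset_latency + envelope_width` must stay <= 95 ms so the burst ends
#'   before the 5-ms baseline window used by the detection threshold.
#' @param noise_sd Standard deviation of additive white Gaussian noise (>= 0).
#' @param artifact_amplitude Peak amplitude of the stimulus-artifact transient
#'   confined to the first 20 ms (>= 0).
#'
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(onset_latency, main_frequency, amplitude = 1,
                            n_phases = 4L,
                            envelope_width = 1000 * n_phases / main_frequency,
                            noise_sd = 0, artifact_amplitude = 0) {
  if (!is.numeric(onset_latency) || length(onset_latency) != 1 ||
      !is.finite(onset_latency)) {
    abort_param("onset_latency must be a finite number")
  }
  if (onset_latency < 20) {
    abort_param("onset_latency must be >= 20 ms (after the artifact window)")
  }
  if (!is.numeric(main_frequency) || main_frequency <= 0) {
    abort_param("main_frequency must be > 0 Hz")
  }
  if (!is.numeric(amplitude) || amplitude < 0) {
    abort_param("amplitude must be >= 0")
  }
  if (n_phases < 1 || n_phases != round(n_phases)) {
    abort_param("n_phases must be an integer >= 1")
  }
  if (!is.numeric(envelope_width) || envelope_width <= 0) {
    abort_param("envelope_width must be > 0 ms")
  }
  if (onset_latency + envelope_width > 95) {
    abort_param("onset_latency + envelope_width must be <= 95 ms")
  }
  if (noise_sd < 0) abort_param("noise_sd must be >= 0")
  if (artifact_amplitude < 0) abort_param("artifact_amplitude must be >= 0")
  structure(list(onset_latency = onset_latency,
                 main_frequency = main_frequency,
                 amplitude = amplitude,
                 n_phases = as.integer(n_phases),
                 envelope_width = envelope_width,
                 noise_sd = noise_sd,
                 artifact_amplitude = artifact_amplitude),
            class = "waveform_params")
}

# Time axis of the raw 2000-sample recording, in ms.
recording_time_ms <- function() (seq_len(N_SAMPLES) - 1) / (SAMPLE_RATE / 1000)

# Decaying oscillatory transient occupying samples 1..400 (0 to <20 ms) only.
artifact_transient <- function(amplitude) {
  out <- numeric(N_SAMPLES)
  if (amplitude > 0) {
    t <- (seq_len(ARTIFACT_SAMPLES) - 1) / 20  # ms
    out[seq_len(ARTIFACT_SAMPLES)] <- amplitude * exp(-t / 4) * cos(2 * pi * 0.6 * t)
  }
  out
}

# Noise-free MEP waveform for the given parameters (length 2000).
mep_waveform <- function(params) {
  p <- params
  t <- recording_time_ms()
  burst <- min(p$envelope_width, 1000 * p$n_phases / p$main_frequency)
  s <- numeric(N_SAMPLES)
  if (p$amplitude > 0) {
    idx <- which(t >= p$onset_latency & t <= p$onset_latency + burst)
    if (length(idx) > 0) {
      tt <- t[idx]
      env <- exp(-(tt - (p$onset_latency + burst / 2))^2 / (2 * (burst / 2)^2))
      s[idx] <- p$amplitude * env *
        sin(2 * pi * p$main_frequency * (tt - p$onset_latency) / 1000)
    }
  }
  s
}

new_mep_recording <- function(samples, muscle, patient_id, center, stimulation,
                              ground_truth = NULL) {
  structure(list(samples = samples,
                 sample_rate = SAMPLE_RATE,
                 muscle = muscle,
                 patient_id = patient_id,
                 center = center,
                 stimulation = stimulation,
                 ground_truth = ground_truth),
            class = "mep_recording")
}

#' Generate one synthetic MEP recording
#'
#' Builds a 2000-sample trace (100 ms at 20 kHz) as the sum of a stimulus
#' artifact transient (confined to the first 400 samples), a Gaussian-enveloped
#' sinusoid described by `params`, and white Gaussian noise. Randomness is
#' drawn from R's global RNG stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param params A [waveform_params] object.
#' @param muscle Muscle label, one of `"EXT"`, `"APB"`, `"TA"`, `"AH"`, or
#'   `NA` for unlabeled traces.
#' @param patient_id,center,stimulation Acquisition metadata.
#'
#' @return An object of class `mep_recording`; `ground_truth` stores `params`.
#' @export
generate_mep <- function(params, muscle = NA_character_, patient_id = "P001",
                         center = "T1", stimulation = "TES") {
  if (!inherits(params, "waveform_params")) {
    params <- do.call(waveform_params, as.list(params))
  }
  s <- mep_waveform(params) + artifact_transient(params$artifact_amplitude)
  if (params$noise_sd > 0) s <- s + rnorm(N_SAMPLES, 0, params$noise_sd)
  new_mep_recording(s, muscle, patient_id, center, stimulation, params)
}

#' Generate a noise-only recording (no MEP)
#'
#' Artifact transient plus white noise, with no enveloped oscillation; used to
#' exercise the negative branch of the preselection rule. The muscle label is
#' `NA`.
#'
#' @param noise_sd Noise standard deviation (>= 0).
#' @param artifact_amplitude Stimulus-artifact amplitude (>= 0).
#' @inheritParams generate_mep
#' @return An object of class `mep_recording`.
#' @export
generate_noise_only <- function(noise_sd, artifact_amplitude = 3,
                                patient_id = "P001", center = "T1",
                                stimulation = "TES") {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort_param("noise_sd must be >= 0")
  }
  if (artifact_amplitude < 0) abort_param("artifact_amplitude must be >= 0")
  s <- artifact_transient(artifact_amplitude)
  if (noise_sd > 0) s <- s + rnorm(N_SAMPLES, 0, noise_sd)
  new_mep_recording(s, NA_character_, patient_id, center, stimulation, NULL)
}

#' @export
print.mep_recording <- function(x, ...) {
  cat(sprintf("<mep_recording> %d samples @ %d Hz, muscle=%s, patient=%s, center=%s\n",
              length(x$samples), x$sample_rate,
              ifelse(is.na(x$muscle), "none", x$muscle), x$patient_id, x$center))
  invisible(x)
}
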