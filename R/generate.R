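# Synthetic session generator: ECG beat trains with stage-dependent HRV,
# SCL with tonic drift + phasic responses, and injectable artifacts.

# PQRST beat template: sum of 5 Gaussians (offset s, amplitude mV, width s).
BEAT_TEMPLATE <- data.frame(
  wave  = c("P", "Q", "R", "S", "T"),
  off_s = c(-0.200, -0.028, 0.000, 0.030, 0.250),
  amp   = c(0.120, -0.120, 1.000, -0.200, 0.280),
  sd_s  = c(0.022, 0.010, 0.011, 0.011, 0.055))

#' Generate a synthetic ECG record
#'
#' Places a sum-of-Gaussians PQRST template at cumulative RR times. The RR
#' sequence combines sinusoidal low-frequency (0.1 Hz) and high-frequency
#' (0.25 Hz) modulation with white jitter; the three components share the
#' requested total RR standard deviation (half the variance sinusoidal,
#' split by `lf_hf_mix`, half white). Optional transient spike artifacts
#' (>= 5x the R amplitude, < 0.5 s) emulate electrode pops.
#'
#' @param duration_s Record length in seconds (> 0).
#' @param rr_mean Mean RR interval in ms (200-2000).
#' @param rr_sd RR standard deviation in ms (>= 0).
#' @param lf_hf_mix Fraction of the sinusoidal RR variance assigned to the
#'   0.1 Hz component (rest to 0.25 Hz). Default 0.5.
#' @param fs Sampling rate in Hz (default 1024).
#' @param spike_rate Expected spike artifacts per minute (default 0).
#' @param seed RNG seed.
#' @param am_depth Amplitude-modulation depth of the R wave in `[0, 1)`;
#'   used by the cohort generator to plant an arousal-dependent pattern
#'   visible in scalograms. Default 0.
#' @param am_freq_hz Amplitude-modulation frequency in Hz (default 2).
#' @return A `signal_record` (channel `"ecg"`, mV) with attribute
#'   `"beat_times"` giving the true R-peak times in seconds.
#' @examples
#' ecg <- generate_ecg(10, rr_mean = 1000, rr_sd = 0, fs = 256, seed = 1)
#' length(attr(ecg, "beat_times"))
#' @export
generate_ecg <- function(duration_s, rr_mean, rr_sd = 0, lf_hf_mix = 0.5,
                         fs = 1024, spike_rate = 0, seed = 1L,
                         am_depth = 0, am_freq_hz = 2) {
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  if (!is.finite(rr_mean) || rr_mean < 200 || rr_mean > 2000) {
    stop("`rr_mean` must lie in [200, 2000] ms", call. = FALSE)
  }
  if (rr_sd < 0) stop("`rr_sd` must be >= 0", call. = FALSE)
  if (lf_hf_mix < 0 || lf_hf_mix > 1) {
    stop("`lf_hf_mix` must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n_beats <- ceiling(duration_s * 1000 / rr_mean) + 4L
    k <- seq_len(n_beats)
    t_prov <- (k - 1L) * rr_mean / 1000      # provisional times for phases
    a_sin <- sqrt(0.5) * rr_sd               # total sinusoidal SD
    a_lf <- sqrt(2 * a_sin^2 * lf_hf_mix)
    a_hf <- sqrt(2 * a_sin^2 * (1 - lf_hf_mix))
    ph_lf <- stats::runif(1, 0, 2 * pi)
    ph_hf <- stats::runif(1, 0, 2 * pi)
    rr <- rr_mean +
      a_lf * sin(2 * pi * 0.1 * t_prov + ph_lf) +
      a_hf * sin(2 * pi * 0.25 * t_prov + ph_hf) +
      stats::rnorm(n_beats, 0, sqrt(0.5) * rr_sd)
    rr <- pmax(rr, 250)                      # physiological floor
    beat_times <- rr_mean / 2000 + c(0, cumsum(rr[-n_beats])) / 1000
    beat_times <- beat_times[beat_times < duration_s - 0.05]

    n <- floor(duration_s * fs)
    values <- numeric(n)
    t_axis <- (seq_len(n) - 1L) / fs
    r_gain <- 1 + am_depth * sin(2 * pi * am_freq_hz * beat_times)
    for (b in seq_along(beat_times)) {
      tb <- beat_times[b]
      i0 <- max(1L, floor((tb - 0.45) * fs) + 1L)
      i1 <- min(n, ceiling((tb + 0.55) * fs))
      tt <- t_axis[i0:i1] - tb
      seg <- numeric(length(tt))
      for (w in seq_len(nrow(BEAT_TEMPLATE))) {
        amp <- BEAT_TEMPLATE$amp[w]
        if (BEAT_TEMPLATE$wave[w] == "R") amp <- amp * r_gain[b]
        seg <- seg + amp *
          exp(-((tt - BEAT_TEMPLATE$off_s[w])^2) /
                (2 * BEAT_TEMPLATE$sd_s[w]^2))
      }
      values[i0:i1] <- values[i0:i1] + seg
    }

    if (spike_rate > 0) {
      n_spikes <- stats::rpois(1, spike_rate * duration_s / 60)
      if (n_spikes > 0) {
        sp_t <- stats::runif(n_spikes, 0.3, duration_s - 0.3)
        sp_a <- stats::runif(n_spikes, 5, 9) *
          sample(c(-1, 1), n_spikes, replace = TRUE)
        sp_w <- stats::runif(n_spikes, 0.05, 0.2)
        for (s in seq_len(n_spikes)) {
          i0 <- max(1L, floor((sp_t[s] - sp_w[s]) * fs) + 1L)
          i1 <- min(n, ceiling((sp_t[s] + sp_w[s]) * fs))
          tt <- t_axis[i0:i1] - sp_t[s]
          values[i0:i1] <- values[i0:i1] +
            sp_a[s] * cos(pi * tt / (2 * sp_w[s]))^2
        }
      }
    }

    out <- signal_record(values, fs = fs, channel = "ecg", units = "mV")
    attr(out, "beat_times") <- beat_times
    out
  })
}

# Bi-exponential skin-conductance-response kernel, peak-normalized to 1.
scr_kernel <- function(t, tau_rise = 0.75, tau_decay = 2) {
  k <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  k / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
}

#' Generate a synthetic SCL record
#'
#' Tonic skin-conductance level (slow drift within the physiological
#' 2-20 microsiemens range) plus, at each trigger time, a phasic response
#' with a bi-exponential fast-rise/slow-decay kernel (tau_rise 0.75 s,
#' tau_decay 2 s) scaled by `scr_amplitude`. NaN runs (0.5-3 s) and
#' below-zero dips are injected at Poisson rates given per minute.
#'
#' @param protocol A [protocol_spec()]; sets the sampling rate and default
#'   duration.
#' @param trigger_times Stimulus onset times in seconds (within the session
#'   span).
#' @param scr_amplitude Phasic response amplitude in microsiemens.
#' @param artifact_rates Named list with `nan_gap_rate` and `negative_rate`
#'   in events/minute (missing entries default to 0).
#' @param seed RNG seed.
#' @param noise_sd Measurement noise SD in microsiemens (default 0.005).
#' @param duration_s Record length; defaults to [session_length()].
#' @return A `signal_record` (channel `"scl"`, microsiemens) with attribute
#'   `"trigger_times"`.
#' @export
generate_scl <- function(protocol, trigger_times, scr_amplitude = 0.5,
                         artifact_rates = list(), seed = 1L,
                         noise_sd = 0.005, duration_s = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"))
  duration_s <- duration_s %||% session_length(protocol)
  if (length(trigger_times) &&
      (min(trigger_times) < 0 || max(trigger_times) >= duration_s)) {
    stop("trigger times must lie within the session span", call. = FALSE)
  }
  rates <- list(nan_gap_rate = 0, negative_rate = 0)
  keep <- intersect(names(artifact_rates), names(rates))
  rates[keep] <- artifact_rates[keep]
  fs <- protocol$eda_fs
  with_seed(seed, {
    n <- floor(duration_s * fs)
    t_axis <- (seq_len(n) - 1L) / fs
    level <- stats::runif(1, 4, 16)
    drift <- 0.5 * sin(2 * pi * t_axis / stats::runif(1, 300, 600) +
                         stats::runif(1, 0, 2 * pi)) +
      0.3 * sin(2 * pi * t_axis / stats::runif(1, 120, 240) +
                  stats::runif(1, 0, 2 * pi)) +
      stats::runif(1, -0.2, 0.2) * t_axis / max(t_axis)
    values <- level + drift
    for (tr in trigger_times) {
      idx <- which(t_axis >= tr & t_axis <= tr + 20)
      values[idx] <- values[idx] +
        scr_amplitude * scr_kernel(t_axis[idx] - tr)
    }
    if (noise_sd > 0) values <- values + stats::rnorm(n, 0, noise_sd)

    if (rates$negative_rate > 0) {
      n_dip <- stats::rpois(1, rates$negative_rate * duration_s / 60)
      if (n_dip > 0) {
        dip_t <- stats::runif(n_dip, 1, duration_s - 1)
        for (d in seq_len(n_dip)) {
          idx <- which(t_axis >= dip_t[d] & t_axis <= dip_t[d] + 0.5)
          values[idx] <- -stats::runif(1, 0.05, 1)
        }
      }
    }
    if (rates$nan_gap_rate > 0) {
      n_gap <- stats::rpois(1, rates$nan_gap_rate * duration_s / 60)
      if (n_gap > 0) {
        gap_t <- stats::runif(n_gap, 1, duration_s - 4)
        gap_w <- stats::runif(n_gap, 0.5, 3)
        for (g in seq_len(n_gap)) {
          idx <- which(t_axis >= gap_t[g] & t_axis <= gap_t[g] + gap_w[g])
          idx <- idx[idx > 1L & idx < n]   # never blank the end points
          values[idx] <- NA_real_
        }
      }
    }

    out <- signal_record(values, fs = fs, channel = "scl", units = "uS")
    attr(out, "trigger_times") <- as.numeric(trigger_times)
    out
  })
}

#' Generate a cohort of synthetic sessions
#'
#' Each session follows the protocol timeline (baseline, then per category:
#' stimulus, rest, recall, rest). Emotion stages (stimulus and recall) have
#' heart rate elevated by `emotion_hr_shift` bpm and beat-to-beat
#' variability scaled by `emotion_rmssd_scale` relative to rest; a SAM
#' arousal label is drawn per emotion segment and controls the
#' amplitude-modulation depth planted in that segment's ECG.
#'
#' @param cohort A [cohort_config()].
#' @param protocol A [protocol_spec()].
#' @param signals Generate the ECG/SCL signals (default `TRUE`). With
#'   `FALSE` only annotations and ground truth are produced, which is much
#'   faster for dataset-bookkeeping work.
#' @return List of subject sessions; each has `subject`, `ecg`, `scl`,
#'   `annotations` (stage table with `sam` column) and `truth`
#'   (`trigger_times`, `stage_rr_mean` in ms).
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 1, seed = 1),
#'                        protocol_spec(ecg_fs = 256), signals = FALSE)
#' nrow(coh[[1]]$annotations)  # 29
#' @export
generate_cohort <- function(cohort, protocol = protocol_spec(),
                            signals = TRUE) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(protocol, "protocol_spec"))
  stages <- protocol_stages(protocol)
  n_stage <- nrow(stages)
  seeds <- derive_seeds(cohort$seed, cohort$n_subjects * (n_stage + 2L))
  sessions <- vector("list", cohort$n_subjects)
  for (s in seq_len(cohort$n_subjects)) {
    base_idx <- (s - 1L) * (n_stage + 2L)
    sess_seed <- seeds[base_idx + 1L]
    ann <- stages
    emo <- ann$stage %in% c("stimulus", "recall")
    subject_pars <- with_seed(sess_seed, {
      list(hr_base = stats::rnorm(1, 70, 5),
           rr_sd_base = stats::runif(1, 30, 50),
           sam = sample(1:9, sum(emo), replace = TRUE,
                        prob = cohort$sam_weights / sum(cohort$sam_weights)))
    })
    ann$sam <- NA_integer_
    ann$sam[emo] <- subject_pars$sam

    hr <- ifelse(emo, subject_pars$hr_base + cohort$emotion_hr_shift,
                 subject_pars$hr_base)
    rr_mean <- 60000 / hr
    rr_sd <- ifelse(emo, subject_pars$rr_sd_base * cohort$emotion_rmssd_scale,
                    subject_pars$rr_sd_base)
    depth <- numeric(n_stage)
    depth[emo] <- cohort$arousal_effect(ann$sam[emo])

    ecg <- NULL; scl <- NULL
    rr_realized <- rep(NA_real_, n_stage)
    if (signals) {
      pieces <- vector("list", n_stage)
      for (i in seq_len(n_stage)) {
        piece <- generate_ecg(
          duration_s = ann$end_s[i] - ann$start_s[i],
          rr_mean = rr_mean[i], rr_sd = rr_sd[i],
          fs = protocol$ecg_fs,
          spike_rate = cohort$artifact_rates$ecg_spike_rate,
          seed = seeds[base_idx + 1L + i],
          am_depth = depth[i])
        pieces[[i]] <- piece$values
        rr_realized[i] <- mean(diff(attr(piece, "beat_times"))) * 1000
      }
      ecg <- signal_record(unlist(pieces), fs = protocol$ecg_fs,
                           channel = "ecg", units = "mV")
      scl <- generate_scl(protocol, trigger_times = ann$start_s,
                          scr_amplitude = cohort$scr_amplitude,
                          artifact_rates = cohort$artifact_rates,
                          seed = seeds[base_idx + 2L])
    }
    sessions[[s]] <- list(
      subject = s,
      ecg = ecg, scl = scl,
      annotations = ann,
      truth = list(trigger_times = ann$start_s,
                   # realized mean (from the placed beats) when signals
                   # exist; the configured stage mean otherwise
                   stage_rr_mean = if (signals) rr_realized else rr_mean,
                   stage_rr_config = rr_mean,
                   sam = ann$sam))
  }
  sessions
}
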