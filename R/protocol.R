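# Experimental protocol description and cohort configuration.

EMOTION_CATEGORIES <- c("anger", "disgust", "fear", "happiness", "neutral",
                        "sadness", "surprise")

# 9-point SAM arousal distribution observed in the emotion-induction study
# the protocol mirrors; used as the default label prior for the generator.
DEFAULT_SAM_COUNTS <- c(24, 26, 34, 29, 51, 41, 31, 19, 11)

#' Session protocol specification
#'
#' The stimulus protocol: one baseline interval, then for each emotion
#' category an image stimulus, a rest period, an autobiographical recall and
#' a second rest period. A full session therefore contains
#' `1 + 4 * n_categories` intervals (29 for the default 7 categories).
#'
#' @param n_categories Number of emotion categories (default 7).
#' @param stimulus_s Image-stimulus duration in seconds (default 30).
#' @param rest_s Rest duration in seconds (default 60).
#' @param recall_s Autobiographical-recall duration in seconds (default 30).
#' @param baseline_s Baseline duration in seconds (default 30).
#' @param ecg_fs ECG sampling rate in Hz (default 1024).
#' @param eda_fs EDA/SCL sampling rate in Hz (default 32).
#' @return An object of class `protocol_spec`.
#' @examples
#' p <- protocol_spec()
#' nrow(protocol_stages(p))  # 29
#' @export
protocol_spec <- function(n_categories = 7L, stimulus_s = 30, rest_s = 60,
                          recall_s = 30, baseline_s = 30,
                          ecg_fs = 1024, eda_fs = 32) {
  durs <- c(stimulus_s, rest_s, recall_s, baseline_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all protocol durations must be positive", call. = FALSE)
  }
  if (n_categories < 1L) stop("need at least one category", call. = FALSE)
  if (ecg_fs <= 0 || eda_fs <= 0) stop("sampling rates must be positive",
                                       call. = FALSE)
  structure(list(n_categories = as.integer(n_categories),
                 stimulus_s = stimulus_s, rest_s = rest_s,
                 recall_s = recall_s, baseline_s = baseline_s,
                 ecg_fs = ecg_fs, eda_fs = eda_fs),
            class = "protocol_spec")
}

#' Stage timeline of a protocol
#'
#' Expands a [protocol_spec()] into its ordered stage table. Intervals are
#' half-open `[start_s, end_s)` and tile the session exactly.
#'
#' @param protocol A `protocol_spec`.
#' @return `data.frame` with columns `start_s`, `end_s`, `stage`
#'   (baseline/stimulus/rest/recall), `category`, `method`
#'   (image/recall/none).
#' @export
protocol_stages <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  cats <- if (protocol$n_categories <= length(EMOTION_CATEGORIES)) {
    EMOTION_CATEGORIES[seq_len(protocol$n_categories)]
  } else {
    c(EMOTION_CATEGORIES,
      paste0("category", seq_len(protocol$n_categories -
                                   length(EMOTION_CATEGORIES)) +
               length(EMOTION_CATEGORIES)))
  }
  stage <- c("baseline",
             unlist(lapply(cats, function(.) c("stimulus", "rest",
                                              "recall", "rest"))))
  category <- c("none", rep(cats, each = 4L))
  method <- c("none",
              rep(c("image", "image", "recall", "recall"),
                  times = protocol$n_categories))
  dur <- c(protocol$baseline_s,
           rep(c(protocol$stimulus_s, protocol$rest_s,
                 protocol$recall_s, protocol$rest_s),
               times = protocol$n_categories))
  end <- cumsum(dur)
  data.frame(start_s = c(0, end[-length(end)]), end_s = end,
             stage = stage, category = category, method = method,
             stringsAsFactors = FALSE)
}

#' Total session length in seconds
#' @param protocol A `protocol_spec`.
#' @return Session duration in seconds.
#' @export
session_length <- function(protocol) {
  protocol$baseline_s + protocol$n_categories *
    (protocol$stimulus_s + 2 * protocol$rest_s + protocol$recall_s)
}

#' Cohort simulation configuration
#'
#' Controls the physiological contrast between emotion and rest stages and
#' the artifact burden of a simulated cohort. Identical `(config, seed)`
#' pairs always produce identical cohorts.
#'
#' @param n_subjects Number of subjects (default 24, the study-scale cohort).
#' @param emotion_hr_shift Mean heart-rate elevation in emotion stages, bpm
#'   (default 10).
#' @param emotion_rmssd_scale Multiplicative change of beat-to-beat
#'   variability in emotion stages (default 0.7; sympathetic activation
#'   suppresses RMSSD).
#' @param scr_amplitude Phasic skin-conductance response amplitude in
#'   microsiemens (default 0.5).
#' @param artifact_rates Named list with events/minute entries
#'   `nan_gap_rate`, `negative_rate` (SCL) and `ecg_spike_rate` (ECG);
#'   all default 0.2.
#' @param arousal_effect Monotone function mapping SAM 1-9 to the
#'   amplitude-modulation depth planted in emotion-stage ECG (default
#'   linear from 0.05 to 0.35; beat-amplitude modulation beyond ~35%
#'   is not physiological and would defeat any R-peak detector).
#' @param sam_weights Length-9 non-negative weights for drawing SAM labels
#'   (default: the empirical 9-point distribution, see
#'   `emophysio:::DEFAULT_SAM_COUNTS`).
#' @param seed Master RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 24L,
                          emotion_hr_shift = 10,
                          emotion_rmssd_scale = 0.7,
                          scr_amplitude = 0.5,
                          artifact_rates = list(nan_gap_rate = 0.2,
                                                negative_rate = 0.2,
                                                ecg_spike_rate = 0.2),
                          arousal_effect = function(sam) 0.05 + 0.3 * (sam - 1) / 8,
                          sam_weights = DEFAULT_SAM_COUNTS,
                          seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  rates <- list(nan_gap_rate = 0, negative_rate = 0, ecg_spike_rate = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (any(unlist(rates) < 0)) stop("artifact rates must be >= 0",
                                   call. = FALSE)
  if (length(sam_weights) != 9L || any(sam_weights < 0) ||
      sum(sam_weights) <= 0) {
    stop("sam_weights must be 9 non-negative values with positive sum",
         call. = FALSE)
  }
  stopifnot(is.function(arousal_effect))
  structure(list(n_subjects = as.integer(n_subjects),
                 emotion_hr_shift = emotion_hr_shift,
                 emotion_rmssd_scale = emotion_rmssd_scale,
                 scr_amplitude = scr_amplitude,
                 artifact_rates = rates,
                 arousal_effect = arousal_effect,
                 sam_weights = as.numeric(sam_weights),
                 seed = as.integer(seed)),
            class = "cohort_config")
}
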