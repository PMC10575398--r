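# End-to-end orchestration: EDA branch -> ECG branch -> features /
# scalograms -> both classifiers -> cross-validated reports.

#' Extract the per-segment HRV dataset from a cohort
#'
#' Runs the full signal path for every session: SCL cleaning and trigger
#' detection, ECG down-sampling, segmentation, raw outlier removal,
#' R-peak detection and RR cleaning, then the 8 HRV features per
#' non-baseline segment. Sessions with more than `max_unusable_frac`
#' unusable segments are dropped (quality-control subject removal).
#'
#' @param cohort List of sessions (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param protocol The [protocol_spec()] the sessions follow.
#' @param target_fs ECG processing rate (default 256 Hz).
#' @param use_predicted_triggers Segment the ECG on trigger marks detected
#'   from the SCL (default `TRUE`); falls back to the stored annotations
#'   when the detected count does not match the protocol.
#' @param max_unusable_frac Drop a subject when more than this fraction of
#'   segments is unusable (default 0.2).
#' @return List with `features` (data.frame: subject, segment id, labels
#'   and the 8 features), `rr` (per-segment cleaned `rr_series`),
#'   `trigger_rmse` (pooled over sessions), `trigger_recall`,
#'   `dropped_subjects`, `n_subjects_in`, `log`.
#' @export
extract_cohort_features <- function(cohort, protocol = protocol_spec(),
                                    target_fs = 256,
                                    use_predicted_triggers = TRUE,
                                    max_unusable_frac = 0.2) {
  stages <- protocol_stages(protocol)
  n_stage <- nrow(stages)
  rows <- list(); rr_list <- list(); log <- character(0)
  sq_err <- numeric(0); n_truth <- 0L; n_matched <- 0L
  dropped <- integer(0)
  for (sess in cohort) {
    scl <- floor_negative(fill_gaps(sess$scl))
    trig <- detect_triggers(scl)
    if (!is.null(sess$truth$trigger_times)) {
      rmse_s <- tryCatch(trigger_rmse(trig, sess$truth$trigger_times,
                                      max_match_s = 7.5),
                         error = function(e) NULL)
      if (!is.null(rmse_s)) {
        m <- attr(rmse_s, "n_matched")
        sq_err <- c(sq_err, rep(rmse_s^2, m))   # pooled via per-pair MSE
        n_matched <- n_matched + m
        n_truth <- n_truth + length(sess$truth$trigger_times)
      }
    }
    ann <- if (use_predicted_triggers && nrow(trig) == n_stage) {
      a <- triggers_to_segments(trig, protocol)
      a$sam <- sess$annotations$sam
      a
    } else {
      if (use_predicted_triggers) {
        log <- c(log, sprintf(
          "subject %d: %d triggers detected (expected %d); using stored annotations",
          sess$subject, nrow(trig), n_stage))
      }
      sess$annotations
    }
    ecg <- if (sess$ecg$fs != target_fs) downsample(sess$ecg, target_fs)
    else sess$ecg
    snippets <- segment_session(ecg, ann)
    unusable <- 0L
    sess_rows <- list(); sess_rr <- list()
    for (i in seq_along(snippets)) {
      sn <- snippets[[i]]
      res <- tryCatch({
        cleaned <- remove_raw_outliers(sn$signal)
        rr <- clean_rr(detect_r_peaks(cleaned))
        list(rr = rr, feats = hrv_feature_vector(rr))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        unusable <- unusable + 1L
        log <- c(log, sprintf("subject %d segment %d unusable: %s",
                              sess$subject, i, conditionMessage(res)))
        next
      }
      a <- sn$annotation
      sess_rows[[length(sess_rows) + 1L]] <- data.frame(
        subject = sess$subject, segment = i, stage = a$stage,
        category = a$category, method = a$method,
        sam = if ("sam" %in% names(a)) a$sam else NA_integer_,
        state = if (a$stage %in% c("stimulus", "recall")) "emotion" else
          if (a$stage == "rest") "rest" else "baseline",
        t(res$feats), stringsAsFactors = FALSE)
      sess_rr[[length(sess_rr) + 1L]] <- res$rr
    }
    if (unusable / length(snippets) > max_unusable_frac) {
      dropped <- c(dropped, sess$subject)
      log <- c(log, sprintf("subject %d dropped (%d/%d segments unusable)",
                            sess$subject, unusable, length(snippets)))
      next
    }
    rows <- c(rows, sess_rows)
    rr_list <- c(rr_list, sess_rr)
  }
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  list(features = features, rr = rr_list,
       trigger_rmse = if (n_matched) sqrt(mean(sq_err)) else NA_real_,
       trigger_recall = if (n_truth) n_matched / n_truth else NA_real_,
       dropped_subjects = dropped,
       n_subjects_in = length(cohort),
       log = log)
}

#' Run the full two-branch pipeline on a cohort
#'
#' Executes the EDA branch, the ECG branch, HRV feature extraction, the
#' emotion/rest SVM with Monte Carlo cross-validation and (optionally)
#' the arousal-strength CNN on CWT scalogram images, and returns both
#' cross-validation reports plus a run manifest.
#'
#' @param cohort List of sessions, or a directory written by
#'   [write_cohort()].
#' @param protocol The [protocol_spec()].
#' @param svm_cfg [svm_config()] for the state model.
#' @param cnn_cfg [cnn_config()] for the arousal model.
#' @param k Monte Carlo CV folds (default 5).
#' @param val_frac Validation fraction per fold (default 0.2).
#' @param arousal Train the arousal model (default `TRUE`; the CNN
#'   dominates run time).
#' @param image_size Scalogram image side length (default 32 for CPU
#'   budgets; the rendering itself supports any size).
#' @param n_scales CWT scales for the arousal images (default 128 here;
#'   [cwt_scalogram()] defaults to the full 512).
#' @param seed Master seed for splits.
#' @param ... Passed to [extract_cohort_features()].
#' @return List with `state_report` and `arousal_report` ([cv_report()]
#'   objects; arousal `NULL` when skipped) and `manifest`.
#' @export
run_pipeline <- function(cohort, protocol = protocol_spec(),
                         svm_cfg = svm_config(), cnn_cfg = cnn_config(),
                         k = 5L, val_frac = 0.2, arousal = TRUE,
                         image_size = 32L, n_scales = 128L, seed = 1L,
                         ...) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  ext <- extract_cohort_features(cohort, protocol, ...)
  if (is.null(ext$features)) stop("no usable segments", call. = FALSE)
  feats <- ext$features
  feat_cols <- HRV_FEATURE_NAMES

  two <- feats[feats$state %in% c("emotion", "rest"), , drop = FALSE]
  x <- as.matrix(two[, feat_cols])
  y <- two$state
  splits <- monte_carlo_cv(y, k = k, val_frac = val_frac, seed = seed)
  state_report <- cv_report(
    y, splits,
    fit_fun = function(tr) {
      sc <- fit_feature_scaler(x[tr, , drop = FALSE])
      model <- train_emotion_detector(normalize_features(x[tr, , drop = FALSE], sc),
                                      y[tr], svm_cfg, seed = seed)
      list(model = model, scaler = sc)
    },
    predict_fun = function(m, idx) {
      predict_state(m$model,
                    normalize_features(x[idx, , drop = FALSE],
                                       m$scaler))$label
    },
    classes = c("emotion", "rest"))

  arousal_report <- NULL
  if (arousal) {
    emo <- feats[feats$state == "emotion" & !is.na(feats$sam), ,
                 drop = FALSE]
    if (nrow(emo) >= 6L) {
      images <- pipeline_arousal_images(cohort, protocol, emo,
                                        image_size, n_scales)
      lab <- arousal_to_class(emo$sam)
      if (length(unique(lab)) == 3L) {
        asplits <- monte_carlo_cv(lab, k = k, val_frac = val_frac,
                                  seed = seed + 1L)
        arousal_report <- cv_report(
          lab, asplits,
          fit_fun = function(tr) {
            train_arousal_classifier(images[tr], lab[tr], cnn_cfg)
          },
          predict_fun = function(m, idx) {
            vapply(idx, function(i) predict_arousal(m, images[[i]])$label,
                   character(1))
          },
          classes = c("low", "mid", "high"))
      } else {
        ext$log <- c(ext$log,
                     "arousal model skipped: not all 3 classes present")
      }
    }
  }

  manifest <- list(
    seed = seed,
    n_subjects_in = ext$n_subjects_in,
    dropped_subjects = ext$dropped_subjects,
    subject_reduction_pct = selection_reduction(
      ext$n_subjects_in, ext$n_subjects_in - length(ext$dropped_subjects)),
    segments_per_subject = nrow(protocol_stages(protocol)),
    n_feature_rows = nrow(feats),
    trigger_rmse_s = ext$trigger_rmse,
    trigger_recall = ext$trigger_recall,
    log = ext$log)
  list(state_report = state_report, arousal_report = arousal_report,
       manifest = manifest)
}

# Scalogram images for the emotion segments referenced by `emo`.
pipeline_arousal_images <- function(cohort, protocol, emo, image_size,
                                    n_scales) {
  target_fs <- 256
  by_subject <- split(seq_len(nrow(emo)), emo$subject)
  images <- vector("list", nrow(emo))
  for (subj in names(by_subject)) {
    sess <- Filter(function(s) s$subject == as.integer(subj), cohort)[[1L]]
    ecg <- if (sess$ecg$fs != target_fs) downsample(sess$ecg, target_fs)
    else sess$ecg
    snippets <- segment_session(ecg, sess$annotations)
    for (i in by_subject[[subj]]) {
      sn <- snippets[[emo$segment[i]]]$signal
      cleaned <- tryCatch(remove_raw_outliers(sn), error = function(e) sn)
      sc <- cwt_scalogram(cleaned, n_scales = n_scales,
                          fs_expected = target_fs)
      images[[i]] <- scalogram_to_image(sc, size = image_size)
    }
  }
  images
}
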