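# Dataset assembly (arousal conversion, splits, distribution tables) and
# classification metrics with 5-fold Monte Carlo cross-validation.

#' Convert a 9-point SAM arousal rating to the 3-class strength
#'
#' Ratings 1-3 map to `"low"`, 4-6 to `"mid"`, 7-9 to `"high"`.
#'
#' @param sam Integer vector of ratings in 1..9.
#' @return Character vector of `"low"`/`"mid"`/`"high"`.
#' @examples
#' arousal_to_class(c(1, 5, 9))
#' @export
arousal_to_class <- function(sam) {
  sam <- as.integer(sam)
  if (any(is.na(sam)) || any(sam < 1L) || any(sam > 9L)) {
    stop("SAM ratings must lie in 1..9", call. = FALSE)
  }
  c("low", "mid", "high")[(sam - 1L) %/% 3L + 1L]
}

#' Inverse-frequency class weights
#'
#' `w_i = N / m_i`, where `N` is the number of observations and `m_i` the
#' count of class `i`.
#'
#' @param labels Vector of class labels (factor or character). Use a
#'   factor to fix the class order; otherwise classes are sorted.
#' @return Named numeric vector of weights.
#' @examples
#' class_weights(rep(c("low", "mid", "high"), times = c(84, 121, 61)))
#' @export
class_weights <- function(labels) {
  f <- if (is.factor(labels)) labels else
    factor(labels, levels = sort(unique(as.character(labels))))
  m <- table(f)
  if (any(m == 0L)) stop("every class must be present", call. = FALSE)
  if (length(m) < 2L) stop("need at least two classes", call. = FALSE)
  w <- as.numeric(length(labels) / m)
  names(w) <- names(m)
  w
}

#' Build a confusion matrix
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class order; defaults to the sorted union.
#' @return K x K integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  classes <- classes %||% sort(unique(c(as.character(truth),
                                        as.character(predicted))))
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Per-class precision and recall from a confusion matrix
#'
#' One-vs-rest `TP / (TP + FP)` and `TP / (TP + FN)`. An empty predicted
#' class gives an undefined (`NA`) precision; recall of an empty true
#' class is `NA` as well (0/0).
#'
#' @param cm Confusion matrix (rows = truth, columns = predicted).
#' @param cls Class name or index.
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(cm, cls) {
  cm <- as.matrix(cm)
  if (is.character(cls)) cls <- match(cls, rownames(cm))
  tp <- cm[cls, cls]
  fp <- sum(cm[, cls]) - tp
  fn <- sum(cm[cls, ]) - tp
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`; `beta = 1` balances
#' precision and recall. Defined as 0 (with a warning) when both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta Weighting coefficient (default 1).
#' @return The score.
#' @export
f_beta <- function(precision, recall, beta = 1) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision == 0 && recall == 0) {
    warning("precision and recall both 0; F-beta defined as 0")
    return(0)
  }
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Monte Carlo cross-validation splits
#'
#' `k` independent random train/validation splits (repeated random
#' sub-sampling, not a partition). Class proportions are preserved within
#' one observation per split by stratified sampling.
#'
#' @param labels Label vector (defines stratification and dataset size).
#' @param k Number of splits (default 5).
#' @param val_frac Validation fraction in (0, 1) (default 0.2).
#' @param seed RNG seed.
#' @return List of `k` lists with integer index vectors `train` and
#'   `validation`.
#' @export
monte_carlo_cv <- function(labels, k = 5L, val_frac = 0.2, seed = 1L) {
  n <- length(labels)
  if (n < 2L) stop("dataset too small", call. = FALSE)
  if (val_frac <= 0 || val_frac >= 1) {
    stop("val_frac must lie in (0, 1)", call. = FALSE)
  }
  labels <- as.character(labels)
  seeds <- derive_seeds(seed, k)
  lapply(seq_len(k), function(i) {
    val <- with_seed(seeds[i], {
      unlist(lapply(split(seq_len(n), labels), function(idx) {
        n_val <- round(val_frac * length(idx))
        if (length(idx) == 1L) return(integer(0))
        sample(idx, n_val)
      }), use.names = FALSE)
    })
    list(train = setdiff(seq_len(n), val), validation = sort(val))
  })
}

#' Stratified train/test split over the 9-point SAM scale
#'
#' Roughly `train_frac` of the observations go to training; the test set
#' is constrained to contain at least one observation from every 9-point
#' SAM value present in the input.
#'
#' @param sam Integer vector of 9-point SAM ratings.
#' @param train_frac Training fraction (default 0.9).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(sam, train_frac = 0.9, seed = 1L) {
  n <- length(sam)
  n_test <- max(1L, floor((1 - train_frac) * n))
  present <- sort(unique(sam))
  scarce <- names(which(table(sam) < 2L))
  if (length(scarce)) {
    warning("SAM value(s) with < 2 observations: ",
            paste(scarce, collapse = ", "),
            "; test-set representation constraint relaxed there")
  }
  with_seed(seed, {
    test <- integer(0)
    for (v in present) {
      idx <- which(sam == v)
      if (length(idx) >= 2L || length(idx) == 1L) {
        test <- c(test, sample(idx, 1L))
      }
    }
    remaining <- setdiff(seq_len(n), test)
    extra <- n_test - length(test)
    if (extra > 0L) test <- c(test, sample(remaining, extra))
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Dataset distribution tables
#'
#' Bookkeeping tables for an annotated cohort: per-category emotion counts
#' by induction method, the 9-point and 3-class arousal distributions, and
#' the pooled emotion/rest totals (baseline segments are excluded from the
#' two-class set).
#'
#' @param cohort List of sessions from [generate_cohort()] (or any list
#'   whose elements carry an `annotations` data.frame with `stage`,
#'   `category`, `method` and `sam`).
#' @return List with `category_table` (category x method counts),
#'   `n_emotion`, `n_rest`, `sam_counts` (length 9) and `arousal_counts`
#'   (low/mid/high).
#' @export
dataset_summary <- function(cohort) {
  ann <- do.call(rbind, lapply(cohort, `[[`, "annotations"))
  if (is.null(ann) || !nrow(ann)) {
    return(list(category_table = table(character(0), character(0)),
                n_emotion = 0L, n_rest = 0L,
                sam_counts = stats::setNames(integer(9L),
                                             as.character(1:9)),
                arousal_counts = c(low = 0L, mid = 0L, high = 0L)))
  }
  emo <- ann[ann$stage %in% c("stimulus", "recall"), , drop = FALSE]
  rest <- ann[ann$stage == "rest", , drop = FALSE]
  cat_tab <- table(category = emo$category,
                   method = factor(emo$method, levels = c("image", "recall")))
  sam_tab <- table(factor(emo$sam, levels = 1:9))
  arous <- if (nrow(emo)) arousal_to_class(emo$sam[!is.na(emo$sam)]) else
    character(0)
  arous_tab <- table(factor(arous, levels = c("low", "mid", "high")))
  list(category_table = cat_tab,
       n_emotion = nrow(emo), n_rest = nrow(rest),
       sam_counts = stats::setNames(as.integer(sam_tab), names(sam_tab)),
       arousal_counts = stats::setNames(as.integer(arous_tab),
                                        names(arous_tab)))
}

#' Percent reduction from subject removal
#'
#' @param n_original,n_selected Subject (or observation) counts before and
#'   after the quality-control removal.
#' @return Reduction in percent, `100 * (1 - n_selected / n_original)`.
#' @examples
#' selection_reduction(24, 19)  # 20.83
#' @export
selection_reduction <- function(n_original, n_selected) {
  stopifnot(n_original > 0, n_selected >= 0, n_selected <= n_original)
  100 * (1 - n_selected / n_original)
}

#' Cross-validated classification report
#'
#' Evaluates a train/predict pair over Monte Carlo CV splits and
#' aggregates per-fold TP accuracy (diagonal sum over total), per-class
#' precision/recall/F1 and the summed confusion matrix. Undefined
#' precisions (empty predicted class) are excluded from macro means and
#' counted.
#'
#' @param labels Full label vector.
#' @param splits Splits from [monte_carlo_cv()].
#' @param fit_fun `function(train_idx)` returning a fitted model.
#' @param predict_fun `function(model, idx)` returning predicted labels
#'   for observations `idx`.
#' @param classes Class order for the confusion matrix.
#' @return An object of class `cv_report`: `per_fold` data.frame,
#'   `mean_accuracy`, `sd_accuracy`, `macro` (mean precision/recall/F1),
#'   `confusion` (summed), `n_undefined_precision`.
#' @export
cv_report <- function(labels, splits, fit_fun, predict_fun,
                      classes = sort(unique(as.character(labels)))) {
  labels <- as.character(labels)
  per_fold <- data.frame()
  cm_sum <- matrix(0L, length(classes), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  n_undef <- 0L
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    model <- fit_fun(sp$train)
    pred <- predict_fun(model, sp$validation)
    cm <- confusion_matrix(labels[sp$validation], pred, classes)
    cm_sum <- cm_sum + cm
    pr <- t(vapply(classes, function(cl) precision_recall(cm, cl),
                   numeric(2)))
    f1 <- mapply(f_beta, pr[, 1L], pr[, 2L])
    n_undef <- n_undef + sum(is.na(pr[, 1L]))
    per_fold <- rbind(per_fold, data.frame(
      fold = i, accuracy = sum(diag(cm)) / sum(cm),
      precision = mean(pr[, 1L], na.rm = TRUE),
      recall = mean(pr[, 2L], na.rm = TRUE),
      f1 = mean(f1, na.rm = TRUE)))
  }
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 sd_accuracy = stats::sd(per_fold$accuracy),
                 macro = colMeans(per_fold[, c("precision", "recall",
                                               "f1")]),
                 confusion = cm_sum,
                 n_undefined_precision = n_undef),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds, accuracy %.2f%% +- %.2f\n",
              nrow(x$per_fold), 100 * x$mean_accuracy,
              100 * (x$sd_accuracy %||% 0)))
  invisible(x)
}
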