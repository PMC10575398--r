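# Arousal conversion, metrics, splits and dataset bookkeeping.

test_that("arousal conversion follows the 3-class mapping", {
  expect_equal(arousal_to_class(c(1, 5, 9)), c("low", "mid", "high"))
  expect_equal(arousal_to_class(3), "low")
  expect_equal(arousal_to_class(4), "mid")
  expect_equal(arousal_to_class(6), "mid")
  expect_equal(arousal_to_class(7), "high")
  expect_error(arousal_to_class(0), "1..9")
  expect_error(arousal_to_class(10), "1..9")
})

test_that("class_weights implements w = N/m", {
  w <- class_weights(rep(c("low", "mid", "high"), times = c(84, 121, 61)))
  expect_equal(sort(unname(w)), sort(c(266 / 84, 266 / 121, 266 / 61)),
               tolerance = 1e-12)
  expect_equal(unname(class_weights(rep(c("a", "b", "c"), 5))),
               rep(3, 3))
  expect_error(class_weights(rep("a", 5)), "two classes")
  expect_error(class_weights(factor(rep("a", 5), levels = c("a", "b"))),
               "present")
})

test_that("precision/recall/F-beta match hand computations", {
  cm <- matrix(c(8, 3, 2, 7), 2, dimnames = list(truth = c("a", "b"),
                                                 predicted = c("a", "b")))
  pr <- precision_recall(cm, "a")
  expect_equal(unname(pr["precision"]), 8 / 11, tolerance = 1e-12)
  expect_equal(unname(pr["recall"]), 8 / 10, tolerance = 1e-12)

  perfect <- diag(c(5L, 9L))
  expect_equal(unname(precision_recall(perfect, 1)), c(1, 1))

  empty_pred <- matrix(c(0, 0, 5, 5), 2)   # nothing predicted as class 1
  pr2 <- precision_recall(empty_pred, 1)
  expect_true(is.na(pr2["precision"]))
  expect_equal(unname(pr2["recall"]), 0)

  expect_equal(f_beta(0.7, 0.7), 0.7)
  expect_equal(f_beta(0.5, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(f_beta(0.8, 0.4, beta = 1e-8), 0.8, tolerance = 1e-6)
  expect_warning(z <- f_beta(0, 0), "defined as 0")
  expect_equal(z, 0)
})

test_that("recall agrees with a per-observation tally oracle", {
  for (seed in 1:10) {
    n <- 60
    truth <- emophysio:::with_seed(seed, sample(c("x", "y", "z"), n, TRUE))
    pred <- emophysio:::with_seed(seed + 50,
                                  sample(c("x", "y", "z"), n, TRUE))
    cm <- confusion_matrix(truth, pred)
    expect_equal(sum(cm), n)
    for (cl in c("x", "y", "z")) {
      tally_tp <- sum(truth == cl & pred == cl)
      rec_oracle <- if (sum(truth == cl) == 0) NA_real_ else
        tally_tp / sum(truth == cl)
      prec_oracle <- if (sum(pred == cl) == 0) NA_real_ else
        tally_tp / sum(pred == cl)
      pr <- precision_recall(cm, cl)
      expect_equal(unname(pr["recall"]), rec_oracle)
      expect_equal(unname(pr["precision"]), prec_oracle)
    }
  }
})

test_that("Monte Carlo CV makes stratified, reproducible, distinct splits", {
  labs <- rep(c("a", "b"), each = 50)
  sp <- monte_carlo_cv(labs, k = 5, val_frac = 0.2, seed = 3)
  expect_length(sp, 5L)
  for (s in sp) {
    expect_length(s$validation, 20L)
    expect_length(intersect(s$train, s$validation), 0L)
    # class proportions preserved within one observation
    expect_lte(abs(sum(labs[s$validation] == "a") - 10), 1)
  }
  expect_identical(monte_carlo_cv(labs, k = 5, val_frac = 0.2, seed = 3),
                   sp)
  vals <- lapply(sp, `[[`, "validation")
  expect_gt(length(unique(vapply(vals, paste, character(1),
                                 collapse = ","))), 1L)
  expect_error(monte_carlo_cv(labs, val_frac = 1.2), "val_frac")
})

test_that("stratified split covers every SAM value in the test set", {
  sam <- emophysio:::with_seed(4, sample(1:9, 266, TRUE,
                                         prob = c(24, 26, 34, 29, 51, 41,
                                                  31, 19, 11)))
  sp <- stratified_split(sam, train_frac = 0.9, seed = 1)
  expect_length(sp$train, 240L)
  expect_length(sp$test, 26L)
  expect_setequal(unique(sam[sp$test]), sort(unique(sam)))
})

test_that("dataset summary reproduces the bookkeeping tables", {
  coh <- generate_cohort(cohort_config(n_subjects = 19, seed = 2),
                         protocol_spec(), signals = FALSE)
  s <- dataset_summary(coh)
  expect_true(all(s$category_table == 19L))
  expect_equal(dim(s$category_table), c(7L, 2L))
  expect_equal(s$n_emotion, 266L)
  expect_equal(sum(s$sam_counts), 266L)
  # 3-class counts are exact sums of their 9-point constituents
  expect_equal(unname(s$arousal_counts),
               unname(c(sum(s$sam_counts[1:3]), sum(s$sam_counts[4:6]),
                        sum(s$sam_counts[7:9]))))
  empty <- dataset_summary(list())
  expect_equal(empty$n_emotion, 0L)
  expect_equal(sum(empty$arousal_counts), 0L)
})

test_that("selection_reduction computes the removal percentage", {
  expect_equal(selection_reduction(24, 19), 100 * 5 / 24, tolerance = 1e-12)
  expect_equal(round(selection_reduction(24, 19), 2), 20.83)
  expect_equal(selection_reduction(10, 10), 0)
})

test_that("cv_report aggregates folds consistently", {
  labs <- rep(c("a", "b"), each = 30)
  splits <- monte_carlo_cv(labs, k = 4, val_frac = 0.25, seed = 9)
  # dummy majority-class model exercises the report plumbing
  rep_ <- cv_report(labs, splits,
                    fit_fun = function(tr) names(which.max(table(labs[tr]))),
                    predict_fun = function(m, idx) rep(m, length(idx)),
                    classes = c("a", "b"))
  expect_equal(sum(rep_$confusion),
               sum(vapply(splits, function(s) length(s$validation), 1L)))
  expect_equal(rep_$mean_accuracy, mean(rep_$per_fold$accuracy),
               tolerance = 1e-9)
  expect_gte(rep_$n_undefined_precision, 0L)
})
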