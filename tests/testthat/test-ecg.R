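# ECG decimation, segmentation, raw outlier removal, R peaks, RR cleaning.

test_that("downsample keeps length, amplitude and supports identity", {
  ecg <- generate_ecg(30, 800, 20, fs = 1024, seed = 1)
  ds <- downsample(ecg, 256)
  expect_equal(length(ds$values), 30 * 256)
  expect_equal(ds$fs, 256)

  t <- (0:(5 * 1024 - 1)) / 1024
  sine <- signal_record(sin(2 * pi * 5 * t), fs = 1024)
  ds_sine <- downsample(sine, 256)
  mid <- ds_sine$values[100:1180]       # away from filter edges
  expect_lt(abs(max(mid) - 1), 0.01)

  expect_identical(downsample(sine, 1024)$values, sine$values)
  expect_error(downsample(sine, 300), "integer factor")
})

test_that("segment_session cuts the protocol into 29 labeled snippets", {
  p <- protocol_spec(ecg_fs = 256)
  sess <- strong_cohort()[[1]]
  snips <- segment_session(sess$ecg, sess$annotations)
  expect_length(snips, 29L)
  stages <- vapply(snips, function(s) s$annotation$stage, character(1))
  expect_equal(sum(stages %in% c("stimulus", "recall")), 14L)
  expect_equal(sum(stages == "rest"), 14L)
  expect_equal(sum(stages == "baseline"), 1L)
  expect_equal(length(snips[[2]]$signal$values), 30 * 256)

  overlap <- data.frame(start_s = c(0, 20), end_s = c(30, 50))
  expect_error(segment_session(sess$ecg, overlap), "overlap")
  outside <- data.frame(start_s = 0, end_s = session_length(p) + 100)
  expect_error(segment_session(sess$ecg, outside), "span")
})

test_that("remove_raw_outliers executes the window-replacement rule", {
  fs <- 10
  base <- rep(c(-1, rep(0, 8), 1), 30)        # 30 windows of 1 s
  sig <- signal_record(base, fs = fs)
  clean <- remove_raw_outliers(sig)
  expect_identical(clean$values, sig$values)
  expect_length(attr(clean, "tagged_windows"), 0L)

  win <- function(w) ((w - 1) * fs + 1):(w * fs)
  spiky <- base
  spiky[win(5)[3]] <- 10                      # spike in interior window 5
  out <- remove_raw_outliers(signal_record(spiky, fs = fs))
  expect_equal(attr(out, "tagged_windows"), 5L)
  expect_identical(out$values[win(5)], base[win(4)])   # predecessor copy
  expect_identical(out$values[-win(5)], spiky[-win(5)])

  first <- base
  first[win(1)[3]] <- 10                      # spike in the first window
  out1 <- remove_raw_outliers(signal_record(first, fs = fs))
  expect_equal(attr(out1, "tagged_windows"), 1L)
  expect_identical(out1$values[win(1)], base[win(2)])  # successor rule

  runstart <- base
  runstart[win(1)[3]] <- 10
  runstart[win(2)[3]] <- -10                  # tagged run at the start
  out2 <- remove_raw_outliers(signal_record(runstart, fs = fs))
  expect_equal(attr(out2, "tagged_windows"), c(1L, 2L))
  expect_identical(out2$values[win(1)], base[win(3)])
  expect_identical(out2$values[win(2)], base[win(3)])
})

test_that("remove_raw_outliers preserves length and untagged windows", {
  for (seed in 1:5) {
    ecg <- generate_ecg(30, 800, 30, fs = 256, spike_rate = 6, seed = seed)
    out <- remove_raw_outliers(ecg)
    expect_length(out$values, length(ecg$values))
    tagged <- attr(out, "tagged_windows")
    keep <- setdiff(seq_len(30), tagged)
    idx <- unlist(lapply(keep, function(w) ((w - 1) * 256 + 1):(w * 256)))
    expect_identical(out$values[idx], ecg$values[idx])
  }
})

test_that("detect_r_peaks recovers generator truth", {
  ecg <- generate_ecg(60, 600, 0, fs = 256, seed = 3)
  rr <- detect_r_peaks(ecg)
  hr <- unname(hrv_rr_avg_and_hr(rr)["hr"])
  expect_lt(abs(hr - 100), 1)
  expect_true(all(diff(rr$peak_times) >= 0.2))   # refractory

  expect_error(detect_r_peaks(signal_record(rep(0, 2560), fs = 256)),
               "unusable")
})

test_that("GESD flags a planted outlier and matches a brute-force oracle", {
  iv <- emophysio:::with_seed(21, stats::rnorm(50, 800, 10))
  iv[20] <- 2000
  rr <- rr_series(cumsum(c(1, iv / 1000)))
  cleaned <- clean_rr(rr)
  expect_equal(attr(cleaned, "flagged"), 20L)
  expect_gt(cleaned$intervals[20], 700)
  expect_lt(cleaned$intervals[20], 900)
  expect_equal(cleaned$intervals[-20], iv[-20], tolerance = 1e-9)

  # independent oracle: critical values recomputed from the t quantile
  gesd_oracle <- function(x, alpha, max_out) {
    n <- length(x); vals <- x; idx <- seq_len(n); out <- integer(0)
    Rs <- c(); lams <- c()
    for (i in seq_len(max_out)) {
      dev <- abs(vals - mean(vals)); j <- which.max(dev)
      Rs <- c(Rs, dev[j] / stats::sd(vals))
      out <- c(out, idx[j]); vals <- vals[-j]; idx <- idx[-j]
      ni <- n - i + 1
      tq <- stats::qt(1 - alpha / (2 * ni), ni - 2)
      lams <- c(lams, (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni))
    }
    k <- which(Rs > lams)
    if (length(k)) out[seq_len(max(k))] else integer(0)
  }
  for (seed in 1:10) {
    x <- emophysio:::with_seed(seed, stats::rnorm(40, 0, 1))
    if (seed %% 2 == 0) x[seed] <- 6      # plant an outlier half the time
    expect_equal(sort(gesd_outliers(x, 0.05, 4)),
                 sort(gesd_oracle(x, 0.05, 4)))
  }
})

test_that("clean_rr is identity on clean data and a fixed point", {
  iv <- rep(800, 20)
  rr <- rr_series(cumsum(c(0.5, iv / 1000)))
  out <- clean_rr(rr)
  expect_length(attr(out, "flagged"), 0L)
  expect_equal(out$intervals, iv)

  noisy <- rr_series(cumsum(c(0.5, emophysio:::with_seed(
    3, stats::rnorm(60, 800, 25)) / 1000)))
  once <- clean_rr(noisy)
  twice <- clean_rr(once)
  expect_length(attr(twice, "flagged"), 0L)
  expect_equal(twice$intervals, once$intervals, tolerance = 1e-9)

  short <- rr_series(cumsum(c(0.5, 0.8, 0.8, 0.8)))
  expect_warning(same <- clean_rr(short), "fewer than 5")
  expect_equal(same$intervals, short$intervals)
})

test_that("modified Akima interpolation is exact on lines and local", {
  x <- 1:10
  expect_equal(makima_interp(x, 2 * x + 1, c(2.5, 7.25)),
               2 * c(2.5, 7.25) + 1, tolerance = 1e-12)
  # no overshoot on a step-like profile (the reason makima is used)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  yi <- makima_interp(seq_along(y), y, seq(1, 8, by = 0.1))
  expect_gte(min(yi), -1e-9)
  expect_lte(max(yi), 1 + 1e-9)
})
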