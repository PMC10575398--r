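# HRV features: time-domain formulas, Lomb-Scargle bands, normalization.

test_that("RMSSD and SDNN match hand evaluations and brute force", {
  expect_equal(hrv_rmssd(c(800, 800, 800)), 0)
  expect_equal(hrv_rmssd(c(800, 810)), 10)
  expect_equal(hrv_rmssd(c(700, 800, 600)), sqrt((100^2 + 200^2) / 2),
               tolerance = 1e-12)
  expect_equal(hrv_sdnn(c(800, 800, 800)), 0)
  expect_equal(hrv_sdnn(c(700, 800, 600)), sqrt((100^2 + 100^2) / 3),
               tolerance = 1e-12)

  rmssd_oracle <- function(iv) {
    acc <- 0
    for (i in seq_len(length(iv) - 1)) acc <- acc + (iv[i + 1] - iv[i])^2
    sqrt(acc / (length(iv) - 1))
  }
  sdnn_oracle <- function(iv) {
    mu <- sum(iv) / length(iv)
    acc <- 0
    for (v in iv) acc <- acc + (v - mu)^2
    sqrt(acc / length(iv))
  }
  for (seed in 1:100) {
    iv <- emophysio:::with_seed(seed, stats::runif(sample(2:50, 1), 400, 1500))
    expect_equal(hrv_rmssd(iv), rmssd_oracle(iv), tolerance = 1e-12)
    expect_equal(hrv_sdnn(iv), sdnn_oracle(iv), tolerance = 1e-12)
    # algebraic identity: sdnn^2 + mu^2 = mean(RR^2)
    expect_equal(hrv_sdnn(iv)^2 + mean(iv)^2, mean(iv^2),
                 tolerance = 1e-6)
  }
})

test_that("mean RR and HR follow the 60 s window identity", {
  expect_equal(unname(hrv_rr_avg_and_hr(rep(1000, 5))["hr"]), 60)
  expect_equal(unname(hrv_rr_avg_and_hr(rep(800, 5))["hr"]), 75)
  expect_equal(unname(hrv_rr_avg_and_hr(rep(600, 5))["hr"]), 100)
})

test_that("time-domain features are scale-equivariant", {
  iv <- emophysio:::with_seed(6, stats::runif(30, 600, 1000))
  c_ <- 1.7
  expect_equal(hrv_rmssd(c_ * iv), c_ * hrv_rmssd(iv))
  expect_equal(hrv_sdnn(c_ * iv), c_ * hrv_sdnn(iv))
  td <- hrv_rr_avg_and_hr(iv); tds <- hrv_rr_avg_and_hr(c_ * iv)
  expect_equal(unname(tds["rr_avg"]), c_ * unname(td["rr_avg"]))
  expect_equal(unname(tds["hr"]), unname(td["hr"]) / c_)
})

test_that("Lomb-Scargle localizes RR modulation and is deterministic", {
  t <- cumsum(rep(0.8, 200))
  iv <- 800 + 50 * sin(2 * pi * 0.1 * t)
  rr <- rr_series(c(0, cumsum(iv)) / 1000)
  p <- lomb_scargle(rr)
  f_hat <- p$frequency[which.max(p$power)]
  step <- max(diff(p$frequency[p$frequency < 0.12]))
  expect_lt(abs(f_hat - 0.1), 2 * step)
  expect_true(all(p$power >= 0))
  expect_true(all(diff(p$frequency) > 0))
  expect_identical(p, lomb_scargle(rr))

  const <- rr_series(cumsum(c(0, rep(0.8, 100))))
  p0 <- lomb_scargle(const)
  expect_lt(max(p0$power), 1e-8 * max(p$power))
  expect_error(lomb_scargle(rr_series(c(0, 0.8, 1.6, 2.4))), "at least 4")
})

test_that("band_power uses strict limits and sums interior points", {
  p <- data.frame(frequency = c(0.003, 0.01, 0.04, 0.1, 0.15, 0.2, 0.4),
                  power = c(1, 1, 1, 1, 1, 1, 1))
  # 0.04 and 0.15 sit on boundaries: in no band (strict inequalities)
  expect_equal(band_power(p, "LF"), 1)   # only 0.1
  expect_equal(band_power(p, "HF"), 1)   # only 0.2 (0.4 is the boundary)
  expect_equal(band_power(p, "VLF"), 1)  # only 0.01 (0.003 is the boundary)

  conc <- data.frame(frequency = c(0.003, 0.1, 0.399), power = c(0, 7, 0))
  expect_equal(band_power(conc, "LF"), 7)
  expect_equal(band_power(conc, "HF"), 0)

  # counting oracle on a uniform periodogram over the default grid
  grid <- exp(seq(log(0.003), log(0.4), length.out = 512))
  unif <- data.frame(frequency = grid, power = rep(2, 512))
  for (b in names(emophysio:::HRV_BANDS)) {
    lims <- emophysio:::HRV_BANDS[[b]]
    expect_equal(band_power(unif, b),
                 2 * sum(grid > lims[1] & grid < lims[2]))
  }
  narrow <- data.frame(frequency = c(0.2, 0.3), power = c(1, 1))
  expect_error(band_power(narrow, "LF"), "cover")
})

test_that("feature_vector composes the 8 features", {
  const <- rr_series(cumsum(c(0, rep(0.8, 40))))
  fv <- hrv_feature_vector(const)
  expect_length(fv, 8L)
  expect_named(fv, emophysio:::HRV_FEATURE_NAMES)
  expect_equal(unname(fv[c("rmssd", "sdnn")]), c(0, 0))
  expect_equal(unname(fv["rr_avg"]), 800)
  expect_equal(unname(fv["hr"]), 75)
  expect_true(is.na(fv["hf2lf"]) || fv["hf2lf"] >= 0)

  t <- cumsum(rep(0.5, 240))
  hf_mod <- 500 + 40 * sin(2 * pi * 0.25 * t)
  rr <- rr_series(c(0, cumsum(hf_mod)) / 1000)
  fv2 <- hrv_feature_vector(rr)
  expect_gt(fv2["hf"], fv2["lf"])
  expect_equal(unname(fv2["hf2lf"]), unname(fv2["hf"] / fv2["lf"]))
})

test_that("normalize_features scales to [0,1] with training ranges", {
  x <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  expect_warning(n <- normalize_features(x), "zero-range")
  expect_equal(unname(n[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(n[, "b"]), c(0, 0, 0))

  train <- cbind(a = c(0, 10), b = c(5, 15))
  sc <- fit_feature_scaler(train)
  test <- cbind(a = c(-5, 5, 20), b = c(10, 0, 30))
  nt <- normalize_features(test, sc)
  expect_equal(unname(nt[, "a"]), c(0, 0.5, 1))   # clipped outside range
  expect_equal(unname(nt[, "b"]), c(0.5, 0, 1))
  expect_error(normalize_features(cbind(c(1, Inf))), "infinite")
})
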