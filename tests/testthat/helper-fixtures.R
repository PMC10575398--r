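# Shared fixtures, built in code. Cohorts are cached so several test
# files can reuse one generation pass.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# ECG processed at 256 Hz directly: the decimation path is tested
# separately and generating at 1024 Hz would quadruple test time.
test_protocol <- function() protocol_spec(ecg_fs = 256)

clean_rates <- list(nan_gap_rate = 0, negative_rate = 0, ecg_spike_rate = 0)

strong_cohort <- function() cached("strong", {
  generate_cohort(cohort_config(n_subjects = 6, emotion_hr_shift = 15,
                                emotion_rmssd_scale = 0.5,
                                artifact_rates = clean_rates, seed = 101),
                  test_protocol())
})

strong_features <- function() cached("strong_feats", {
  extract_cohort_features(strong_cohort(), test_protocol())
})

null_cohort <- function() cached("null", {
  generate_cohort(cohort_config(n_subjects = 6, emotion_hr_shift = 0,
                                emotion_rmssd_scale = 1,
                                artifact_rates = clean_rates, seed = 102),
                  test_protocol())
})

# Planted-ridge scalogram-like images: class determined by which row band
# carries the bright ridge. Learnable by construction.
make_ridge_images <- function(n_per_class, size = 32L, seed = 7L,
                              noise_sd = 0.05) {
  emophysio:::with_seed(seed, {
    classes <- c("low", "mid", "high")
    third <- size %/% 3L
    bands <- lapply(0:2, function(k) (k * third + 1L):((k + 1L) * third))
    labels <- rep(classes, each = n_per_class)
    images <- lapply(rep(1:3, each = n_per_class), function(cls) {
      img <- matrix(abs(stats::rnorm(size * size, 0, noise_sd)), size, size)
      img[bands[[cls]], ] <- img[bands[[cls]], ] + 1
      array(img, c(size, size, 1L))
    })
    list(images = images, labels = labels)
  })
}

# Two well-separated Gaussian blobs in 8-D, pre-normalized to [0, 1].
make_toy_features <- function(n_per_class = 50L, sep = 0.6, seed = 5L) {
  emophysio:::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per_class * 8, 0.25, 0.05), ncol = 8),
               matrix(stats::rnorm(n_per_class * 8, 0.25 + sep, 0.05),
                      ncol = 8))
    colnames(x) <- emophysio:::HRV_FEATURE_NAMES
    list(x = pmin(pmax(x, 0), 1),
         y = rep(c("emotion", "rest"), each = n_per_class))
  })
}
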