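# Eight heart-rate-variability features: RMSSD, SDNN, mean RR, HR and
# Lomb-Scargle HF/LF/VLF band powers with the HF/LF ratio.

HRV_FEATURE_NAMES <- c("rmssd", "sdnn", "rr_avg", "hr",
                       "hf", "lf", "vlf", "hf2lf")

HRV_BANDS <- list(HF = c(0.15, 0.4), LF = c(0.04, 0.15),
                  VLF = c(0.003, 0.04))

get_intervals <- function(rr) {
  if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
}

#' Root mean square of successive RR differences (RMSSD)
#'
#' `sqrt(mean((RR[i+1] - RR[i])^2))` with the mean over the `N - 1`
#' successive differences.
#'
#' @param rr An [rr_series()] or numeric vector of RR intervals in ms.
#' @return RMSSD in ms.
#' @examples
#' hrv_rmssd(c(700, 800, 600))  # sqrt((100^2 + 200^2)/2)
#' @export
hrv_rmssd <- function(rr) {
  iv <- get_intervals(rr)
  if (length(iv) < 2L) stop("RMSSD needs at least 2 intervals", call. = FALSE)
  sqrt(sum(diff(iv)^2) / (length(iv) - 1L))
}

#' Standard deviation of RR intervals (SDNN)
#'
#' Population standard deviation (1/N normalization) of the RR intervals.
#'
#' @inheritParams hrv_rmssd
#' @return SDNN in ms.
#' @export
hrv_sdnn <- function(rr) {
  iv <- get_intervals(rr)
  if (length(iv) < 2L) stop("SDNN needs at least 2 intervals", call. = FALSE)
  sqrt(sum((iv - mean(iv))^2) / length(iv))
}

#' Mean RR interval and heart rate
#'
#' `rr_avg` is the mean RR interval in ms; `hr = 60000 / rr_avg` is the
#' equivalent number of beats in a 60 s window.
#'
#' @inheritParams hrv_rmssd
#' @return Named numeric vector `c(rr_avg = , hr = )`.
#' @export
hrv_rr_avg_and_hr <- function(rr) {
  iv <- get_intervals(rr)
  if (length(iv) < 1L) stop("need at least 1 interval", call. = FALSE)
  mu <- mean(iv)
  c(rr_avg = mu, hr = 60 * 1000 / mu)
}

#' Lomb-Scargle periodogram of an RR tachogram
#'
#' Classic Lomb-Scargle estimate for the inherently unevenly sampled
#' (peak time, interval) series, evaluated on a log-spaced grid covering
#' the VLF-HF range. The series is mean-centered; power is in native ms^2
#' units.
#'
#' @param rr An [rr_series()].
#' @param f_min,f_max Grid limits in Hz (defaults 0.003 and 0.4).
#' @param n_freq Number of grid points (default 512).
#' @return `data.frame` with columns `frequency` (Hz, strictly increasing)
#'   and `power` (>= 0).
#' @export
lomb_scargle <- function(rr, f_min = 0.003, f_max = 0.4, n_freq = 512L) {
  stopifnot(inherits(rr, "rr_series"))
  iv <- rr$intervals
  if (length(iv) < 4L) {
    stop("Lomb-Scargle needs at least 4 intervals", call. = FALSE)
  }
  t <- rr$peak_times[-1L]            # interval timestamped at its end beat
  y <- iv - mean(iv)
  freq <- exp(seq(log(f_min), log(f_max), length.out = n_freq))
  power <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    c_den <- sum(ct^2); s_den <- sum(st^2)
    pc <- if (c_den > 0) sum(y * ct)^2 / c_den else 0
    ps <- if (s_den > 0) sum(y * st)^2 / s_den else 0
    0.5 * (pc + ps)
  }, numeric(1))
  data.frame(frequency = freq, power = power)
}

#' Band power of a periodogram
#'
#' Sums the periodogram over grid points strictly inside the band
#' (`lower < f < upper`).
#'
#' @param p Periodogram `data.frame` (`frequency`, `power`).
#' @param band One of `"HF"` (0.15-0.4 Hz), `"LF"` (0.04-0.15 Hz),
#'   `"VLF"` (0.003-0.04 Hz).
#' @return Summed power.
#' @export
band_power <- function(p, band = c("HF", "LF", "VLF")) {
  band <- match.arg(band)
  lims <- HRV_BANDS[[band]]
  if (min(p$frequency) >= lims[2L] || max(p$frequency) <= lims[1L]) {
    stop("periodogram grid does not cover the requested band",
         call. = FALSE)
  }
  sum(p$power[p$frequency > lims[1L] & p$frequency < lims[2L]])
}

#' Assemble the 8-feature HRV vector for one segment
#'
#' @param rr A cleaned [rr_series()].
#' @return Named numeric vector with `rmssd`, `sdnn`, `rr_avg`, `hr`
#'   (time domain) and `hf`, `lf`, `vlf`, `hf2lf` (frequency domain).
#'   `hf2lf` is `NA` when LF power is zero; it is imputed at
#'   normalization time.
#' @export
hrv_feature_vector <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  td <- hrv_rr_avg_and_hr(rr)
  p <- lomb_scargle(rr)
  hf <- band_power(p, "HF"); lf <- band_power(p, "LF")
  vlf <- band_power(p, "VLF")
  c(rmssd = hrv_rmssd(rr), sdnn = hrv_sdnn(rr),
    rr_avg = unname(td["rr_avg"]), hr = unname(td["hr"]),
    hf = hf, lf = lf, vlf = vlf,
    hf2lf = if (lf > 0) hf / lf else NA_real_)
}

#' Fit a per-feature min-max scaler on training data
#'
#' Missing values (e.g. `hf2lf` with zero LF power) are imputed with the
#' training-column median before the ranges are computed.
#'
#' @param x Numeric training matrix (observations x features).
#' @return A `feature_scaler` object (per-column min, max, median).
#' @export
fit_feature_scaler <- function(x) {
  x <- as.matrix(x)
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  if (any(maxs - mins == 0)) {
    warning("zero-range feature column(s) mapped to 0: ",
            paste(colnames(x)[maxs - mins == 0], collapse = ", "))
  }
  structure(list(min = mins, max = maxs, median = med),
            class = "feature_scaler")
}

#' Min-max normalize a feature matrix to the unit interval
#'
#' Scaling parameters are fit on the training partition (pass the returned
#' scaler to normalize validation/test partitions with the training
#' ranges). Values outside the training range are clipped to `[0, 1]`;
#' zero-range columns map to 0.
#'
#' @param x Numeric matrix (observations x features), no infinities.
#' @param scaler Optional `feature_scaler` from [fit_feature_scaler()];
#'   fitted on `x` itself when omitted.
#' @return Matrix of the same shape with values in `[0, 1]` and the scaler
#'   attached as attribute `"scaler"`.
#' @export
normalize_features <- function(x, scaler = NULL) {
  x <- as.matrix(x)
  if (any(is.infinite(x))) stop("infinite feature values", call. = FALSE)
  if (is.null(scaler)) scaler <- fit_feature_scaler(x)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- scaler$median[j]
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2L, scaler$min, "-")
  out <- sweep(out, 2L, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out <- clamp01(out)
  attr(out, "scaler") <- scaler
  out
}
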