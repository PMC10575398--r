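# ECG down-sampling, segmentation, raw outlier removal, R-peak/RR
# extraction and RR-series cleaning.

#' Down-sample an ECG record by an integer factor
#'
#' Applies a zero-phase low-pass anti-alias FIR (windowed sinc, cutoff at
#' 80% of the new Nyquist frequency) and decimates. The default use is
#' 1024 -> 256 Hz (factor 4).
#'
#' @param ecg A `signal_record`.
#' @param target_fs Target rate in Hz; must divide `ecg$fs` exactly.
#' @return A `signal_record` at `target_fs` with
#'   `ceiling(n * target_fs / fs)` samples.
#' @export
downsample <- function(ecg, target_fs = 256) {
  stopifnot(inherits(ecg, "signal_record"))
  factor <- ecg$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop("`target_fs` must divide the sampling rate by an integer factor",
         call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(ecg)
  filtered <- fir_filter(ecg$values,
                         fir_lowpass_taps(65L, 0.8 * 0.5 / factor))
  out <- ecg
  out$values <- filtered[seq(1L, length(filtered), by = factor)]
  out$fs <- target_fs
  out
}

#' Cut a session signal into annotated snippets
#'
#' @param ecg A `signal_record` covering the whole session.
#' @param segments Annotation `data.frame` with `start_s`/`end_s` (and any
#'   label columns), non-overlapping and within the signal span.
#' @return List with one element per annotation row:
#'   `list(annotation = <row>, signal = <signal_record>)`. Sample index
#'   range is `[floor(start * fs), floor(end * fs))`.
#' @export
segment_session <- function(ecg, segments) {
  stopifnot(inherits(ecg, "signal_record"), is.data.frame(segments))
  seg <- segments[order(segments$start_s), , drop = FALSE]
  if (any(seg$end_s <= seg$start_s)) {
    stop("segments must have end_s > start_s", call. = FALSE)
  }
  if (nrow(seg) > 1L && any(seg$start_s[-1L] < seg$end_s[-nrow(seg)] - 1e-9)) {
    stop("segments overlap", call. = FALSE)
  }
  dur <- signal_duration(ecg)
  if (min(seg$start_s) < ecg$t0 - 1e-9 ||
      max(seg$end_s) > ecg$t0 + dur + 1e-9) {
    stop("segment outside the signal span", call. = FALSE)
  }
  lapply(seq_len(nrow(seg)), function(i) {
    i0 <- floor((seg$start_s[i] - ecg$t0) * ecg$fs) + 1L
    i1 <- floor((seg$end_s[i] - ecg$t0) * ecg$fs)
    i1 <- min(i1, length(ecg$values))
    list(annotation = seg[i, , drop = FALSE],
         signal = signal_record(ecg$values[i0:i1], fs = ecg$fs,
                                channel = ecg$channel,
                                t0 = seg$start_s[i], units = ecg$units))
  })
}

#' Sliding-window raw-signal outlier removal
#'
#' Splits a snippet into consecutive windows (default 1 s with a 1 s
#' stride, i.e. non-overlapping) and records each window's minimum and
#' maximum. A window is tagged when its minimum is more negative than
#' `k` times the mean window minimum, or its maximum exceeds `k` times the
#' mean window maximum. Each tagged window is replaced by its nearest
#' untagged predecessor window, or by its nearest untagged successor when
#' no untagged predecessor exists (first window, or a run of tagged
#' windows at the start). The output length is unchanged and untagged
#' windows are returned bit-identically.
#'
#' @param snippet A `signal_record`.
#' @param window_s Window length in seconds (default 1).
#' @param stride_s Window stride in seconds; must equal `window_s` (the
#'   replacement rule needs tiling windows).
#' @param k Threshold multiplier (default 2.5).
#' @return The cleaned `signal_record`, with attribute `"tagged_windows"`
#'   giving the 1-based indices of replaced windows.
#' @export
remove_raw_outliers <- function(snippet, window_s = 1, stride_s = window_s,
                                k = 2.5) {
  stopifnot(inherits(snippet, "signal_record"))
  if (abs(stride_s - window_s) > 1e-12) {
    stop("only stride_s == window_s (tiling windows) is supported",
         call. = FALSE)
  }
  wlen <- as.integer(round(window_s * snippet$fs))
  v <- snippet$values
  n_win <- length(v) %/% wlen
  if (n_win < 2L) stop("snippet shorter than two windows", call. = FALSE)
  idx <- function(w) ((w - 1L) * wlen + 1L):(w * wlen)
  mins <- vapply(seq_len(n_win), function(w) min(v[idx(w)]), numeric(1))
  maxs <- vapply(seq_len(n_win), function(w) max(v[idx(w)]), numeric(1))
  tagged <- which(mins < k * mean(mins) | maxs > k * mean(maxs))
  if (length(tagged) == n_win) {
    stop("all windows tagged as outliers; segment unusable", call. = FALSE)
  }
  out_v <- v
  untagged <- setdiff(seq_len(n_win), tagged)
  for (w in tagged) {
    pred <- untagged[untagged < w]
    src <- if (length(pred)) max(pred) else min(untagged[untagged > w])
    out_v[idx(w)] <- v[idx(src)]
  }
  out <- snippet
  out$values <- out_v
  attr(out, "tagged_windows") <- tagged
  out
}

#' Detect R peaks and extract the RR series
#'
#' Pan-Tompkins-style detector: 5-15 Hz band-pass, 5-point derivative,
#' squaring, 150 ms moving-window integration, then peak picking on the
#' integrated energy with an adaptive threshold and a 200 ms refractory
#' constraint. Each detection is refined to the local maximum of the
#' band-passed signal within +-100 ms, giving sample-accurate peak times.
#'
#' @param snippet A cleaned `signal_record` (nominally 256 Hz).
#' @return An [rr_series()] with peak times in seconds (relative to the
#'   session via the snippet's `t0`).
#' @export
detect_r_peaks <- function(snippet) {
  stopifnot(inherits(snippet, "signal_record"))
  v <- snippet$values
  fs <- snippet$fs
  if (anyNA(v)) stop("snippet contains missing values", call. = FALSE)
  bp <- fir_bandpass(v, 5, 15, fs)
  der <- c(0, 0, (2 * bp[5:length(bp)] + bp[4:(length(bp) - 1L)] -
                    bp[2:(length(bp) - 3L)] - 2 * bp[1:(length(bp) - 4L)]) / 8,
           0, 0)
  sq <- der^2
  integ <- moving_average(sq, round(0.15 * fs))
  thr <- 0.25 * mean(integ[integ >= stats::quantile(integ, 0.95)])
  cand <- find_peaks(integ, min_dist = round(0.2 * fs), height = thr)
  if (length(cand) < 2L) {
    stop("fewer than 2 R peaks found; segment unusable", call. = FALSE)
  }
  half <- round(0.1 * fs)
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(bp), i + half)
    as.integer(lo + which.max(bp[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory constraint after refinement
  keep <- c(TRUE, diff(peaks) >= round(0.2 * fs))
  peaks <- peaks[keep]
  if (length(peaks) < 2L) {
    stop("fewer than 2 R peaks found; segment unusable", call. = FALSE)
  }
  rr_series(snippet$t0 + (peaks - 1L) / fs)
}

#' Generalized extreme Studentized deviate (GESD) outlier test
#'
#' Two-sided GESD for up to `max_out` outliers in approximately normal
#' data: repeatedly remove the most extreme Studentized value and compare
#' each extreme statistic against its t-distribution critical value.
#'
#' @param x Numeric vector.
#' @param alpha Significance level (default 0.05).
#' @param max_out Maximum number of outliers tested.
#' @return Integer indices of the detected outliers in `x` (possibly
#'   empty).
#' @export
gesd_outliers <- function(x, alpha = 0.05, max_out) {
  n <- length(x)
  stopifnot(max_out >= 1L, n >= 3L)
  max_out <- min(max_out, n - 2L)
  pool <- seq_len(n)
  removed <- integer(0)
  R <- numeric(max_out)
  lam <- numeric(max_out)
  for (i in seq_len(max_out)) {
    xs <- x[pool]
    s <- stats::sd(xs)
    if (!is.finite(s) || s == 0) { R[i] <- 0 } else {
      dev <- abs(xs - mean(xs))
      j <- which.max(dev)
      R[i] <- dev[j] / s
      removed <- c(removed, pool[j])
      pool <- pool[-j]
    }
    ni <- n - i + 1L
    p <- 1 - alpha / (2 * ni)
    tq <- stats::qt(p, ni - 2L)
    lam[i] <- (ni - 1L) * tq / sqrt((ni - 2L + tq^2) * ni)
    if (R[i] == 0) break
  }
  n_out <- {
    hits <- which(R > lam)
    if (length(hits)) max(hits) else 0L
  }
  if (n_out == 0L) integer(0) else removed[seq_len(n_out)]
}

#' Clean an RR series with GESD and modified Akima interpolation
#'
#' Applies the generalized extreme Studentized deviate test to the RR
#' interval sequence (up to `ceiling(max_outlier_frac * N)` outliers at
#' level `alpha`); flagged intervals are replaced by modified-Akima
#' interpolation over the interval index. The series length is unchanged
#' and peak times are rebuilt from the first peak plus the cleaned
#' cumulative intervals.
#'
#' @param rr An [rr_series()].
#' @param alpha GESD significance level (default 0.05).
#' @param max_outlier_frac Maximum fraction of intervals that may be
#'   flagged (default 0.1).
#' @return A cleaned [rr_series()] with attribute `"flagged"` (indices of
#'   replaced intervals).
#' @export
clean_rr <- function(rr, alpha = 0.05, max_outlier_frac = 0.1) {
  stopifnot(inherits(rr, "rr_series"))
  iv <- rr$intervals
  n <- length(iv)
  if (n < 5L) {
    warning("fewer than 5 intervals; returned unchanged")
    attr(rr, "flagged") <- integer(0)
    return(rr)
  }
  flagged <- gesd_outliers(iv, alpha = alpha,
                           max_out = max(1L, ceiling(max_outlier_frac * n)))
  if (length(flagged)) {
    keep <- setdiff(seq_len(n), flagged)
    iv[flagged] <- makima_interp(keep, iv[keep], flagged)
  }
  out <- rr_series(rr$peak_times[1L] + c(0, cumsum(iv)) / 1000)
  attr(out, "flagged") <- sort(flagged)
  out
}
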