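#' Uniformly sampled physiological signal
#'
#' Container for a 1-D uniformly sampled signal (ECG in mV, SCL in
#' microsiemens). Missing samples are encoded as `NA` and must be removed by
#' the cleaning operations before feature extraction.
#'
#' @param values Numeric vector of samples (`NA` allowed before cleaning).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel Channel name, e.g. `"ecg"` or `"scl"`.
#' @param t0 Time of the first sample in seconds from session start.
#' @param units Physical units of `values`.
#' @return An object of class `signal_record`.
#' @examples
#' s <- signal_record(sin(seq(0, 2 * pi, length.out = 64)), fs = 32)
#' signal_duration(s)
#' @export
signal_record <- function(values, fs, channel = "signal", t0 = 0,
                          units = "") {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("a signal_record needs at least 2 samples", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         channel = as.character(channel), t0 = as.numeric(t0),
         units = as.character(units)),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record '%s'> %d samples @ %g Hz (%.1f s)%s\n",
              x$channel, length(x$values), x$fs, signal_duration(x),
              if (anyNA(x$values)) sprintf(", %d NA", sum(is.na(x$values)))
              else ""))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param x A `signal_record`.
#' @return Length of the record in seconds (`n / fs`).
#' @export
signal_duration <- function(x) length(x$values) / x$fs

#' Sample times of a signal
#' @param x A `signal_record`.
#' @return Numeric vector of sample times in seconds (t0 + k/fs).
#' @export
signal_times <- function(x) x$t0 + (seq_along(x$values) - 1L) / x$fs

#' R-peak time series with inter-beat intervals
#'
#' @param peak_times Strictly increasing R-peak times in seconds.
#' @param intervals Optional RR intervals in ms; recomputed from
#'   `peak_times` when omitted. Must equal `diff(peak_times) * 1000`.
#' @return An object of class `rr_series` with fields `peak_times`
#'   (seconds) and `intervals` (ms).
#' @export
rr_series <- function(peak_times, intervals = NULL) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 2L) {
    stop("an rr_series needs at least 2 peaks", call. = FALSE)
  }
  if (any(diff(peak_times) <= 0)) {
    stop("peak times must be strictly increasing", call. = FALSE)
  }
  expected <- diff(peak_times) * 1000
  if (is.null(intervals)) {
    intervals <- expected
  } else if (length(intervals) != length(peak_times) - 1L ||
             max(abs(intervals - expected)) > 1e-6) {
    stop("`intervals` inconsistent with `peak_times`", call. = FALSE)
  }
  structure(list(peak_times = peak_times, intervals = as.numeric(intervals)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, mean RR %.1f ms\n",
              length(x$peak_times), mean(x$intervals)))
  invisible(x)
}
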