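# Morlet continuous wavelet transform scalograms and their rendering to
# fixed-size images for the arousal classifier.

#' Morlet scale-to-frequency mapping
#'
#' Center frequency in Hz of an analytic Morlet wavelet (center angular
#' frequency `omega0`) at integer scale `a`: `f = omega0 * fs / (2 pi a)`.
#'
#' @param scale Scale (>= 1).
#' @param fs Sampling rate in Hz.
#' @param omega0 Morlet center frequency in rad/sample (default 6).
#' @return Frequency in Hz.
#' @export
scale_to_frequency <- function(scale, fs, omega0 = 6) {
  omega0 * fs / (2 * pi * scale)
}

#' Continuous wavelet transform scalogram of an ECG snippet
#'
#' Magnitude of the analytic Morlet CWT at integer scales (default 1-512),
#' computed in the frequency domain with zero padding. The configured
#' time-bandwidth value is carried in the metadata; the implemented
#' wavelet is the standard analytic Morlet with center frequency
#' `omega0 = 6` and unit-variance Gaussian envelope (see the methods
#' vignette for the parameter mapping).
#'
#' @param snippet A `signal_record` with finite values; `fs` must equal
#'   `fs_expected`.
#' @param n_scales Number of integer scales (default 512).
#' @param fs_expected Required sampling rate (default 256 Hz).
#' @param omega0 Morlet center frequency in rad/sample (default 6).
#' @param time_bandwidth Configured time-bandwidth value recorded in the
#'   metadata (default 0.234).
#' @return An object of class `scalogram`: list with `magnitude`
#'   (`n_scales` x `n_samples`, >= 0), `scales`, `fs`, `frequencies` (Hz
#'   per scale), `wavelet`, `time_bandwidth` and `coi` (cone-of-influence
#'   half-width per scale, in samples).
#' @export
cwt_scalogram <- function(snippet, n_scales = 512L, fs_expected = 256,
                          omega0 = 6, time_bandwidth = 0.234) {
  stopifnot(inherits(snippet, "signal_record"))
  if (abs(snippet$fs - fs_expected) > 1e-9) {
    stop(sprintf("snippet must be sampled at %g Hz", fs_expected),
         call. = FALSE)
  }
  v <- snippet$values
  if (any(!is.finite(v))) stop("snippet has non-finite values", call. = FALSE)
  n <- length(v)
  nfft <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(v, numeric(nfft - n)))
  omega <- 2 * pi * c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1L):1)) / nfft
  scales <- seq_len(n_scales)
  mag <- matrix(0, nrow = n_scales, ncol = n)
  pos <- omega > 0
  for (si in scales) {
    # analytic Morlet: psi_hat(s*w) = pi^(-1/4) sqrt(2) exp(-(s*w - w0)^2/2)
    psi_hat <- numeric(nfft)
    psi_hat[pos] <- pi^(-0.25) * sqrt(2 * pi * si / nfft) *
      exp(-0.5 * (si * omega[pos] - omega0)^2) * sqrt(nfft)
    w <- stats::fft(xf * psi_hat, inverse = TRUE) / nfft
    mag[si, ] <- Mod(w[seq_len(n)])
  }
  structure(list(magnitude = mag, scales = scales, fs = snippet$fs,
                 frequencies = scale_to_frequency(scales, snippet$fs,
                                                  omega0),
                 wavelet = "morlet", omega0 = omega0,
                 time_bandwidth = time_bandwidth,
                 coi = ceiling(sqrt(2) * scales)),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales x %d samples (Morlet, fs %g Hz)\n",
              nrow(x$magnitude), ncol(x$magnitude), x$fs))
  invisible(x)
}

#' Render a scalogram to a fixed-size image
#'
#' The magnitude is normalized by its maximum (making the rendering
#' invariant to input scaling), log-compressed, min-max scaled to
#' `[0, 1]`, resized by bilinear interpolation and replicated to three
#' channels.
#'
#' @param s A `scalogram`.
#' @param size Output side length in pixels (default 224).
#' @return Numeric array `size x size x 3` with values in `[0, 1]`.
#' @export
scalogram_to_image <- function(s, size = 224L) {
  stopifnot(inherits(s, "scalogram"), size >= 1L)
  m <- s$magnitude
  top <- max(m)
  if (top > 0) m <- m / top
  m <- log(m + 1e-6)
  rng <- range(m)
  m <- if (diff(rng) == 0) matrix(0, nrow(m), ncol(m)) else
    (m - rng[1L]) / diff(rng)
  img <- bilinear_resize(m, size, size)
  array(rep(clamp01(img), 3L), dim = c(size, size, 3L))
}
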