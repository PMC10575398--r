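# SCL pre-processing and emotional-stimulus trigger-mark detection.

#' Fill missing SCL samples by piecewise cubic spline interpolation
#'
#' Replaces every NaN/NA run with cubic-spline values fitted on the
#' non-missing samples; non-missing samples are returned unchanged. Runs
#' touching the first or last sample cannot be interpolated and are filled
#' by nearest-value extension (with a warning): spline extrapolation is
#' unstable there.
#'
#' @param scl A `signal_record` (typically the SCL channel).
#' @return A `signal_record` without missing values.
#' @export
fill_gaps <- function(scl) {
  stopifnot(inherits(scl, "signal_record"))
  v <- scl$values
  na <- is.na(v)
  if (!any(na)) return(scl)
  ok <- which(!na)
  if (!length(ok)) stop("signal is entirely missing", call. = FALSE)
  if (na[1L] || na[length(v)]) {
    warning("leading/trailing missing samples filled by nearest value")
    if (na[1L]) v[seq_len(ok[1L] - 1L)] <- v[ok[1L]]
    last <- ok[length(ok)]
    if (na[length(v)]) v[(last + 1L):length(v)] <- v[last]
    na <- is.na(v)
    ok <- which(!na)
  }
  if (any(na)) {
    v[na] <- stats::spline(x = ok, y = v[ok], xout = which(na),
                           method = "fmm")$y
  }
  out <- scl
  out$values <- v
  out
}

#' Floor non-physiological negative SCL values at zero
#'
#' Skin conductance is non-negative by physics; values below zero are
#' measurement faults and are clipped to zero.
#'
#' @param scl A `signal_record` without missing values (run [fill_gaps()]
#'   first).
#' @return A `signal_record` with `values = pmax(values, 0)`.
#' @export
floor_negative <- function(scl) {
  stopifnot(inherits(scl, "signal_record"))
  if (anyNA(scl$values)) {
    stop("floor_negative expects a gap-free signal; run fill_gaps() first",
         call. = FALSE)
  }
  out <- scl
  out$values <- pmax(scl$values, 0)
  out
}

#' Detect stimulus trigger marks from an SCL signal
#'
#' A phasic skin-conductance response starts with an abrupt slope increase,
#' so stimulus onsets appear as positive peaks of the second-order
#' derivative. The signal is moving-average smoothed, differentiated twice
#' (central finite differences), smoothed again, and peaks are picked
#' subject to a minimum separation and a relative prominence threshold.
#'
#' @param scl Cleaned `signal_record` (no missing values, non-negative).
#' @param smoothing_s Moving-average window in seconds (default 1).
#' @param min_separation_s Minimum distance between reported triggers in
#'   seconds (default 15, half the shortest protocol stage).
#' @param prominence_frac Peak height threshold as a fraction of the
#'   maximum second-derivative magnitude (default 0.1). Samples within
#'   2 s of a zero-valued run are excluded from both the reference and
#'   the peak candidates: skin conductance is strictly positive in vivo,
#'   so exact zeros only arise from floored negative artifacts, whose
#'   edges would otherwise dominate the derivative by orders of
#'   magnitude.
#' @return `data.frame` with columns `time_s` (strictly increasing) and
#'   `source = "predicted"`.
#' @export
detect_triggers <- function(scl, smoothing_s = 1, min_separation_s = 15,
                            prominence_frac = 0.1) {
  stopifnot(inherits(scl, "signal_record"))
  v <- scl$values
  if (anyNA(v) || any(v < 0)) {
    stop("detect_triggers expects a cleaned SCL signal", call. = FALSE)
  }
  w <- max(3L, round(smoothing_s * scl$fs))
  if (length(v) <= 2L * w) {
    stop("signal shorter than the smoothing window", call. = FALSE)
  }
  sm <- moving_average(v, w)
  n <- length(sm)
  d2 <- c(0, sm[3:n] - 2 * sm[2:(n - 1L)] + sm[1:(n - 2L)], 0)
  d2 <- moving_average(d2, w)
  if (any(v == 0)) {
    guard <- round(2 * scl$fs)
    bad <- which(v == 0)
    mask <- unique(pmax(1L, pmin(n, rep(bad, each = 2L * guard + 1L) +
                                   (-guard):guard)))
    d2[mask] <- 0
  }
  top <- max(abs(d2))
  if (top <= .Machine$double.eps) {
    return(data.frame(time_s = numeric(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- find_peaks(d2, min_dist = round(min_separation_s * scl$fs),
                    height = prominence_frac * top)
  data.frame(time_s = scl$t0 + (idx - 1L) / scl$fs,
             source = rep("predicted", length(idx)),
             stringsAsFactors = FALSE)
}

#' Convert trigger marks to protocol-labeled segments
#'
#' Consecutive trigger pairs define half-open intervals `[t_i, t_{i+1})`;
#' the final interval is closed at the session end. Intervals are labeled
#' by their position in the protocol sequence (baseline, then stimulus,
#' rest, recall, rest per category).
#'
#' @param triggers `data.frame` with a `time_s` column, sorted increasing.
#' @param protocol A [protocol_spec()]; supplies the stage sequence and the
#'   session end time.
#' @param session_end_s Session end in seconds (default
#'   [session_length()]).
#' @return Annotation `data.frame` (`start_s`, `end_s`, `stage`,
#'   `category`, `method`).
#' @export
triggers_to_segments <- function(triggers, protocol,
                                 session_end_s = session_length(protocol)) {
  stopifnot(inherits(protocol, "protocol_spec"))
  times <- sort(unique(as.numeric(triggers$time_s)))
  if (length(times) < 2L) {
    stop("need at least 2 triggers to form segments", call. = FALSE)
  }
  stages <- protocol_stages(protocol)
  n <- length(times)
  if (n != nrow(stages)) {
    warning(sprintf("expected %d triggers for the protocol, got %d",
                    nrow(stages), n))
  }
  out <- data.frame(start_s = times,
                    end_s = c(times[-1L], session_end_s),
                    stage = NA_character_, category = NA_character_,
                    method = NA_character_, stringsAsFactors = FALSE)
  m <- min(n, nrow(stages))
  out$stage[seq_len(m)] <- stages$stage[seq_len(m)]
  out$category[seq_len(m)] <- stages$category[seq_len(m)]
  out$method[seq_len(m)] <- stages$method[seq_len(m)]
  out
}

#' Root-mean-squared error between predicted and ground-truth triggers
#'
#' Predicted and truth marks are paired greedily by smallest absolute time
#' difference; the RMSE `sqrt(mean((x - xhat)^2))` is computed over matched
#' pairs. Unmatched marks are reported as misses / false alarms in
#' attributes.
#'
#' @param predicted,truth `data.frame`s with a `time_s` column (or numeric
#'   vectors of times).
#' @param max_match_s Pairs farther apart than this are left unmatched
#'   (default `Inf`).
#' @return RMSE in seconds, with attributes `n_matched`, `n_missed`
#'   (truth without a partner) and `n_false` (predictions without a
#'   partner).
#' @export
trigger_rmse <- function(predicted, truth, max_match_s = Inf) {
  p <- if (is.data.frame(predicted)) predicted$time_s else as.numeric(predicted)
  g <- if (is.data.frame(truth)) truth$time_s else as.numeric(truth)
  if (!length(p) || !length(g)) {
    stop("trigger_rmse needs non-empty predicted and truth marks",
         call. = FALSE)
  }
  d <- abs(outer(g, p, "-"))
  pairs <- matrix(numeric(0), ncol = 2L)
  while (nrow(d) && ncol(d) && min(d) <= max_match_s) {
    ij <- arrayInd(which.min(d), dim(d))
    pairs <- rbind(pairs, c(g[ij[1L]], p[ij[2L]]))
    g <- g[-ij[1L]]; p <- p[-ij[2L]]
    d <- d[-ij[1L], -ij[2L], drop = FALSE]
  }
  if (!nrow(pairs)) stop("no trigger pairs within max_match_s", call. = FALSE)
  out <- sqrt(mean((pairs[, 1L] - pairs[, 2L])^2))
  attr(out, "n_matched") <- nrow(pairs)
  attr(out, "n_missed") <- length(g)
  attr(out, "n_false") <- length(p)
  out
}
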