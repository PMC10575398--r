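# Internal numeric helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded generators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Centered moving average with edge replication; width forced odd.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < 2L) return(x)
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[
    (half + 1L):(half + length(x))]
}

# Local maxima above `height`, thinned so survivors are >= min_dist apart
# (greedy, tallest first). Returns integer indices in increasing order.
find_peaks <- function(x, min_dist = 1L, height = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  # allow boundary maxima (stimulus onsets can sit at the record edge)
  if (n >= 2L && x[1L] > x[2L]) cand <- c(1L, cand)
  if (n >= 2L && x[n] > x[n - 1L]) cand <- c(cand, n)
  cand <- cand[x[cand] > height]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

# Windowed-sinc (Hamming) low-pass FIR prototype; cutoff in cycles/sample.
fir_lowpass_taps <- function(n_taps, cutoff) {
  stopifnot(n_taps %% 2L == 1L, cutoff > 0, cutoff < 0.5)
  m <- n_taps - 1L
  k <- 0:m - m / 2
  h <- 2 * cutoff * sinc(2 * cutoff * k)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:m) / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Zero-phase FIR filtering with edge replication (symmetric taps only).
fir_filter <- function(x, taps) {
  half <- (length(taps) - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  y <- as.numeric(stats::filter(xp, taps, sides = 2L))
  y[(half + 1L):(half + length(x))]
}

# Band-pass by subtracting two low-pass responses.
fir_bandpass <- function(x, low_hz, high_hz, fs, n_taps = 65L) {
  lp_hi <- fir_lowpass_taps(n_taps, high_hz / fs)
  lp_lo <- fir_lowpass_taps(n_taps, low_hz / fs)
  fir_filter(x, lp_hi - lp_lo)
}

#' Modified Akima cubic Hermite interpolation
#'
#' Piecewise-cubic Hermite interpolant whose node slopes are the modified
#' Akima weights (secant-slope blend with |d1 + d2|/2 added to each weight),
#' the scheme commonly used to fill gaps in RR-interval series because it
#' avoids the overshoot of unconstrained cubic splines.
#'
#' @param x Strictly increasing abscissae of the known points.
#' @param y Ordinates of the known points.
#' @param xout Points at which to evaluate the interpolant.
#' @return Numeric vector of interpolated values at `xout`.
#' @export
makima_interp <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 2L, all(diff(x) > 0))
  n <- length(x)
  if (n == 2L) {
    # degenerate to linear
    return(y[1L] + (y[2L] - y[1L]) * (xout - x[1L]) / (x[2L] - x[1L]))
  }
  d <- diff(y) / diff(x)                      # secant slopes, length n-1
  # quadratic extrapolation of end slopes (two ghost secants each side)
  dd <- c(2 * d[1L] - d[2L], d, 2 * d[n - 1L] - d[n - 2L])
  dd <- c(2 * dd[1L] - dd[2L], dd, 2 * dd[length(dd)] - dd[length(dd) - 1L])
  # dd has length n+3; node i uses secants dd[i], dd[i+1], dd[i+2], dd[i+3]
  t_slope <- numeric(n)
  for (i in seq_len(n)) {
    d1 <- dd[i]; d2 <- dd[i + 1L]; d3 <- dd[i + 2L]; d4 <- dd[i + 3L]
    w1 <- abs(d4 - d3) + abs(d4 + d3) / 2
    w2 <- abs(d2 - d1) + abs(d2 + d1) / 2
    t_slope[i] <- if (w1 + w2 == 0) (d2 + d3) / 2 else (w1 * d2 + w2 * d3) / (w1 + w2)
  }
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n - 1L] <- n - 1L
  h <- x[idx + 1L] - x[idx]
  s <- (xout - x[idx]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[idx] + h10 * h * t_slope[idx] + h01 * y[idx + 1L] + h11 * h * t_slope[idx + 1L]
}

# Bilinear resize of a numeric matrix to out_rows x out_cols.
bilinear_resize <- function(mat, out_rows, out_cols) {
  nr <- nrow(mat); nc <- ncol(mat)
  stopifnot(nr >= 1L, nc >= 1L, out_rows >= 1L, out_cols >= 1L)
  ri <- if (out_rows == 1L) rep(1, 1L) else seq(1, nr, length.out = out_rows)
  ci <- if (out_cols == 1L) rep(1, 1L) else seq(1, nc, length.out = out_cols)
  r0 <- pmin(floor(ri), nr - 1L); r0[nr == 1L] <- 1L
  c0 <- pmin(floor(ci), nc - 1L); c0[nc == 1L] <- 1L
  if (nr == 1L) { r0 <- rep(1L, out_rows); fr <- rep(0, out_rows) } else fr <- ri - r0
  if (nc == 1L) { c0 <- rep(1L, out_cols); fc <- rep(0, out_cols) } else fc <- ci - c0
  r1 <- pmin(r0 + 1L, nr); c1 <- pmin(c0 + 1L, nc)
  top <- mat[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    mat[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  bot <- mat[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    mat[r1, c1, drop = FALSE] * outer(fr, fc)
  top + bot
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # argument order keeps dim()

`%||%` <- function(a, b) if (is.null(a)) b else a
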