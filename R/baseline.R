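#' Box-counting fractal dimension of a signal curve
#'
#' The curve `(t, x)` is normalised into the unit square, occupied boxes
#' are counted at dyadic box sizes `2^-2 .. 2^-7`, and the dimension is the
#' least-squares slope of `log(count)` versus `log(1/size)`. For each
#' column of boxes along `t` the count spans the min-max range of the
#' curve in that column, so a straight line yields a dimension near 1 and
#' rough noise approaches 2. A constant series returns 1 by convention.
#'
#' @param x numeric series, length at least 64.
#' @param sizes dyadic box sizes (fractions of the unit square).
#' @return Scalar dimension estimate, clamped to `[1, 2]`.
#' @export
boxcount_fd <- function(x, sizes = 2^-(2:7)) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 64)
  rng <- range(x)
  if (rng[1] == rng[2]) return(1.0)
  xs <- (x - rng[1]) / (rng[2] - rng[1])
  ts <- (seq_len(n) - 1) / (n - 1)
  counts <- vapply(sizes, function(eps) {
    col <- pmin(floor(ts / eps), 1 / eps - 1)  # box column per point
    sum(vapply(split(xs, col), function(seg) {
      floor(max(seg) / eps) - floor(min(seg) / eps) + 1
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(1 / sizes)), log(counts))
  min(2, max(1, unname(fit$coefficients[2])))
}

#' Mean sample entropy over fixed windows
#'
#' Splits the series into non-overlapping windows of `win_len` points,
#' computes sample entropy per window, and returns the mean over windows
#' with a defined value (the classical short-window entropy feature;
#' default window 512 points).
#'
#' @param x numeric series, length at least `win_len`.
#' @param m,r_frac sample entropy parameters (defaults 2 and 0.15).
#' @param win_len window length in points, default 512.
#' @return Scalar mean entropy, or `NA` if every window is undefined.
#' @export
windowed_sample_entropy <- function(x, m = 2, r_frac = 0.15, win_len = 512) {
  x <- as.numeric(x)
  stopifnot(length(x) >= win_len)
  nwin <- length(x) %/% win_len
  vals <- vapply(seq_len(nwin), function(k) {
    sample_entropy(x[((k - 1) * win_len + 1):(k * win_len)],
                   m = m, r_frac = r_frac)
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Orthonormal Daubechies-4 (8-tap) decomposition scaling filter.
db4_filter <- function() {
  c(0.23037781330885523, 0.71484657055254150, 0.63088076792959040,
    -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
    0.03288301166698295, -0.01059740178499728)
}

#' Periodised db4 discrete wavelet transform
#'
#' Orthogonal pyramid decomposition with the 8-tap Daubechies-4 filter and
#' periodic boundary handling, so coefficient energy equals signal energy
#' (Parseval). The input is truncated to a multiple of `2^levels` points.
#'
#' @param x numeric series.
#' @param levels decomposition depth.
#' @return List with `details` (list `d1..dL`, `d1` the finest / highest
#'   band), `approx` (level-`L` approximation), and `n_used`.
#' @export
dwt_db4 <- function(x, levels = 5) {
  h <- db4_filter()
  g <- rev(h) * c(1, -1)  # high-pass: g[n] = (-1)^n h[L-1-n], 0-based
  n_used <- (length(x) %/% 2^levels) * 2^levels
  stopifnot(n_used >= 2^levels, n_used >= length(h))
  a <- as.numeric(x[seq_len(n_used)])
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    n <- length(a)
    half <- n %/% 2L
    idx <- outer(2L * seq_len(half) - 2L, seq_along(h) - 1L, `+`) %% n + 1L
    seg <- matrix(a[idx], nrow = half)
    details[[lev]] <- as.numeric(seg %*% g)
    a <- as.numeric(seg %*% h)
  }
  names(details) <- paste0("d", seq_len(levels))
  list(details = details, approx = a, n_used = n_used)
}

#' Canonical EEG band definitions
#'
#' @return Data frame of the delta/theta/alpha/beta/gamma bands with the
#'   band edges (Hz) used by the classical feature set (beta 16-32,
#'   gamma 32-45).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 16, 32), hi = c(4, 8, 16, 32, 45),
             stringsAsFactors = FALSE)
}

#' db4 wavelet band energy
#'
#' Energy of the discrete-wavelet detail level(s) whose dyadic frequency
#' band best overlaps the requested band. The signal is first resampled to
#' `target_fs` (default 128 Hz) so the dyadic detail bands line up with
#' the canonical EEG bands (at 128 Hz: d1 = 32-64 Hz -> gamma,
#' d2 = 16-32 Hz -> beta, and so on); a level is selected when the overlap
#' covers at least half of the narrower of the two bands.
#'
#' @param x numeric series.
#' @param fs sampling rate of `x` (Hz), `fs >= 2 * hi`.
#' @param lo,hi band edges in Hz.
#' @param target_fs analysis rate the signal is resampled to (default
#'   128).
#' @param levels decomposition depth at `target_fs` (default 5).
#' @return Non-negative scalar energy (sum of squared detail
#'   coefficients).
#' @export
dwt_band_energy <- function(x, fs, lo, hi, target_fs = 128, levels = 5) {
  stopifnot(lo > 0, lo < hi)
  if (fs < 2 * hi) stop("band extends above Nyquist")
  if (fs != target_fs) {
    frac <- ratio_integers(target_fs / fs)
    x <- signal::resample(as.numeric(x), frac[1], frac[2])
  }
  dec <- dwt_db4(x, levels = levels)
  sel <- vapply(seq_len(levels), function(lev) {
    band_lo <- target_fs / 2^(lev + 1)
    band_hi <- target_fs / 2^lev
    ov <- max(0, min(hi, band_hi) - max(lo, band_lo))
    ov / min(band_hi - band_lo, hi - lo) >= 0.5
  }, logical(1))
  if (!any(sel)) stop("no dyadic detail level overlaps the requested band")
  sum(vapply(dec$details[sel], function(d) sum(d^2), numeric(1)))
}

# Small-integer ratio p/q approximating a rate factor.
ratio_integers <- function(f, max_den = 64) {
  for (q in seq_len(max_den)) {
    p <- f * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("resampling ratio is not a small rational; supply target_fs compatible with fs")
}
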