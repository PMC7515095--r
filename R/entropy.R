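#' Sample entropy
#'
#' Sample entropy of a series: `-log(A / B)` where `B` counts template
#' pairs of length `m` within tolerance `r` (Chebyshev distance, strict
#' `< r`, self-matches excluded) and `A` the corresponding count at length
#' `m + 1`, both over the same `N - m*tau` templates. The tolerance is
#' `r_frac` times the sample standard deviation of `x` unless
#' `relative = FALSE`, in which case `r_frac` is taken as an absolute
#' tolerance.
#'
#' When either count is zero the entropy is undefined; `NA` is returned
#' (a sentinel that propagates into feature matrices) rather than an error.
#'
#' @param x numeric series, length at least `m + 2`.
#' @param m embedding (template) length, default 2.
#' @param r_frac tolerance as a fraction of `sd(x)` (default 0.15), or an
#'   absolute tolerance when `relative = FALSE`.
#' @param tau embedding lag, default 1.
#' @param relative logical; interpret `r_frac` relative to `sd(x)`.
#' @return Non-negative scalar, or `NA` when undefined.
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.15, tau = 1, relative = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < m + 2) stop("series too short for sample entropy (need N >= m + 2)")
  if (r_frac <= 0) stop("tolerance must be positive")
  r <- if (relative) r_frac * sd(x) else r_frac
  if (!is.finite(r) || r == 0) return(0)  # constant series: all pairs match
  cnt <- sampen_counts(x, as.integer(m), r, as.integer(tau))
  if (anyNA(cnt) || cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[1] / cnt[2])
}

#' Fuzzy entropy
#'
#' Entropy of a fuzzy set of templates: templates of length `m` (lag
#' `tau`) are mean-removed, pair similarity is the fuzzy membership
#' `exp(-d^n / r)` with `d` the Chebyshev distance, and the entropy is
#' `log(phi_m) - log(phi_m1)` with `phi` the average pairwise similarity at
#' template lengths `m` and `m + 1`. Unlike sample entropy's hard
#' threshold, the exponential membership makes the estimate continuous
#' in `r`.
#'
#' @param x numeric series.
#' @param m template length, default 2.
#' @param r similarity tolerance (default 0.15). With `relative = TRUE`
#'   (default) the series is first standardised to unit SD, so `r` acts on
#'   normalised data and the estimate is scale-invariant; with
#'   `relative = FALSE` the series is used as given.
#' @param n fuzzy membership exponent, default 2.
#' @param tau embedding lag, default 1.
#' @param relative logical; standardise the series before comparison.
#' @return Non-negative scalar, or `NA` when undefined.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.15, n = 2, tau = 1,
                          relative = TRUE) {
  x <- as.numeric(x)
  if (length(x) - (m + 1) * tau < 1)
    stop("series too short for fuzzy entropy")
  if (r <= 0) stop("tolerance must be positive")
  if (relative) {
    sdx <- sd(x)
    if (!is.finite(sdx) || sdx == 0) return(0)  # constant series
    x <- x / sdx
  }
  phis <- fuzzen_phis(x, as.integer(m), r, n, as.integer(tau))
  if (anyNA(phis) || any(phis <= 0)) return(NA_real_)
  log(phis[1]) - log(phis[2])
}

#' Renyi entropy
#'
#' Order-`alpha` Renyi entropy `H_a = log(sum(p^a)) / (1 - a)` (natural
#' log). `renyi_entropy()` estimates the probabilities by evaluating a
#' Gaussian kernel density at each sample point and normalising to a
#' probability vector; `renyi_entropy_discrete()` applies the formula to a
#' supplied probability vector directly.
#'
#' @param x numeric series, length at least 2.
#' @param alpha Renyi order, `alpha >= 0`, `alpha != 1` (default 2).
#' @param bandwidth kernel width sigma, or `"auto"` for Silverman's rule
#'   `1.06 * sd(x) * n^(-1/5)`.
#' @return Scalar entropy (nats).
#' @export
renyi_entropy <- function(x, alpha = 2, bandwidth = "auto") {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  check_renyi_alpha(alpha)
  if (identical(bandwidth, "auto")) bandwidth <- 1.06 * sd(x) * n^(-1 / 5)
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive (or \"auto\")")
  # KDE evaluated at the sample points themselves
  dens <- vapply(x, function(xi)
    sum(stats::dnorm((xi - x) / bandwidth)) / (n * bandwidth), numeric(1))
  renyi_entropy_discrete(dens / sum(dens), alpha)
}

#' @rdname renyi_entropy
#' @param p probability vector (non-negative, normalised internally).
#' @export
renyi_entropy_discrete <- function(p, alpha = 2) {
  check_renyi_alpha(alpha)
  if (any(p < 0)) stop("probabilities must be non-negative")
  p <- p / sum(p)
  log(sum(p^alpha)) / (1 - alpha)
}

check_renyi_alpha <- function(alpha) {
  if (!is.numeric(alpha) || alpha < 0 || alpha == 1)
    stop("alpha must be >= 0 and != 1 (the alpha = 1 Shannon limit is out of scope)")
  invisible(alpha)
}

#' Fisher-Z confidence bounds for entropy values
#'
#' Entropy values are often bounded away from a normal sampling
#' distribution; this helper min-max maps them onto `[lo, hi]` (with
#' `hi < 1`), applies the Fisher Z-transform (`atanh`), forms a
#' normal-theory confidence interval for the mean on the Z scale, and maps
#' the centre and bounds back with `tanh`.
#'
#' @param values numeric vector, length at least 2.
#' @param lo,hi target range of the min-max map, default `[0, 0.99]`.
#' @param conf confidence level, default 0.95.
#' @return Named numeric vector `c(center, lower, upper)` on the mapped
#'   scale. Identical inputs give a zero-width interval.
#' @export
entropy_confidence_bounds <- function(values, lo = 0, hi = 0.99,
                                      conf = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  stopifnot(n >= 2, lo < hi, hi < 1)
  rng <- range(values)
  mapped <- if (rng[1] == rng[2]) rep((lo + hi) / 2, n)
            else lo + (values - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
  z <- atanh(mapped)
  zse <- sd(z) / sqrt(n)
  zcrit <- qnorm(1 - (1 - conf) / 2)
  zc <- mean(z)
  c(center = tanh(zc), lower = tanh(zc - zcrit * zse),
    upper = tanh(zc + zcrit * zse))
}

#' Per-channel entropy of a channel matrix
#'
#' Batch entry point: applies one of the scalar entropy estimators to every
#' row of a channels-by-samples matrix.
#'
#' @param mat numeric matrix, channels x N.
#' @param fun one of `"sample"`, `"fuzzy"`, `"renyi"`.
#' @param ... parameters forwarded to the estimator.
#' @return Named numeric vector, one value per channel (`NA` where
#'   undefined).
#' @export
channel_entropy <- function(mat, fun = c("sample", "fuzzy", "renyi"), ...) {
  fun <- match.arg(fun)
  f <- switch(fun, sample = sample_entropy, fuzzy = fuzzy_entropy,
              renyi = renyi_entropy)
  out <- apply(as.matrix(mat), 1, function(ch) f(ch, ...))
  names(out) <- rownames(mat)
  out
}
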