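#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) by envelope
#' sifting: cubic-spline upper/lower envelopes through the local
#' maxima/minima (with mirror extension of two extrema at each boundary),
#' subtraction of the mean envelope, and acceptance of a candidate IMF once
#' (a) its extrema and zero-crossing counts differ by at most one and (b)
#' the Cauchy-type criterion `sum((h_prev - h)^2) / sum(h_prev^2) < 0.2`
#' holds, with a cap of `max_sift` sifting passes per IMF; passes beyond
#' the cap (up to `5 * max_sift`) are spent only when condition (a) is
#' still violated, so accepted IMFs honour it. Extraction repeats on the
#' remainder until `max_imfs` IMFs are found or the remainder has fewer
#' than two maxima or minima (monotone residue).
#'
#' The decomposition is exact by construction: the elementwise sum of the
#' IMFs plus the residue reproduces the input.
#'
#' @param x finite numeric series, length at least 4.
#' @param max_imfs maximum number of IMFs to extract (default 11, the
#'   pipeline's decomposition depth for 20-s samples;
#'   [imf_count_formula()] gives the nominal data-length-based count).
#' @param sd_thresh sifting stop threshold (default 0.2).
#' @param max_sift sifting iteration cap per IMF (default 10).
#' @return An `imf_set`: list with `imfs` (list of series, highest
#'   frequency first), `residue`, `n`, and `meta` (method and parameters).
#' @export
emd <- function(x, max_imfs = 11, sd_thresh = 0.2, max_sift = 10) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 4, all(is.finite(x)))
  res <- emd_c(x, as.integer(max_imfs), sd_thresh, as.integer(max_sift))
  imfs <- if (ncol(res$imfs) > 0)
    lapply(seq_len(ncol(res$imfs)), function(j) res$imfs[, j]) else list()
  new_imf_set(imfs, res$residue, length(x),
              meta = list(method = "EMD", sd_thresh = sd_thresh,
                          max_sift = max_sift))
}

new_imf_set <- function(imfs, residue, n, meta) {
  structure(list(imfs = imfs, residue = as.numeric(residue), n = n,
                 meta = meta), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %s: %d IMFs + residue, N = %d\n",
              x$meta$method, length(x$imfs), x$n))
  invisible(x)
}

#' Ensemble empirical mode decomposition
#'
#' Adds independent Gaussian white noise (standard deviation
#' `noise_ratio * sd(x)`) to the input, decomposes each noisy copy with
#' [emd()], and averages the IMFs index-wise across the ensemble, which
#' suppresses mode mixing. With `noise_ratio = 0` and `ensembles = 1` the
#' result is identical to plain EMD. Fully deterministic given `seed`;
#' the caller's RNG state is left untouched. Ensemble members that produce
#' fewer IMFs than the deepest member are zero-padded before averaging
#' (a message reports the event).
#'
#' Note the averaged IMFs no longer sum exactly to the input: the
#' reconstruction error is the averaged residual noise, shrinking as
#' `1/sqrt(ensembles)`.
#'
#' @param x numeric series.
#' @param noise_ratio added-noise SD as a fraction of `sd(x)` (default
#'   0.1).
#' @param ensembles number of noise realisations (default 100).
#' @param max_imfs,sd_thresh,max_sift see [emd()].
#' @param seed integer master seed for the ensemble noise (default 1).
#' @return An `imf_set` with method tag `"EEMD"`.
#' @export
eemd <- function(x, noise_ratio = 0.1, ensembles = 100, max_imfs = 11,
                 seed = 1, sd_thresh = 0.2, max_sift = 10) {
  x <- as.numeric(x)
  stopifnot(noise_ratio >= 0, ensembles >= 1)
  n <- length(x)
  sdx <- sd(x)
  noise_sd <- noise_ratio * if (is.finite(sdx)) sdx else 0
  noise <- if (noise_sd > 0)
    with_local_seed(seed, matrix(rnorm(n * ensembles, sd = noise_sd),
                                 nrow = n))
  else matrix(0, n, ensembles)
  res <- eemd_c(x, noise, as.integer(max_imfs), sd_thresh,
                as.integer(max_sift))
  counts <- res$counts
  if (length(unique(counts)) > 1)
    message(sprintf("eemd: IMF counts differ across ensembles (%d-%d); shorter decompositions zero-padded",
                    min(counts), max(counts)))
  imfs <- if (ncol(res$imfs) > 0)
    lapply(seq_len(ncol(res$imfs)), function(j) res$imfs[, j]) else list()
  residue <- res$residue
  new_imf_set(imfs, residue, n,
              meta = list(method = "EEMD", noise_ratio = noise_ratio,
                          ensembles = ensembles, seed = seed,
                          sd_thresh = sd_thresh, max_sift = max_sift))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Nominal IMF count for a data length
#'
#' The dyadic rule `floor(log2(N)) - 1`: the number of IMFs a length-`N`
#' series nominally supports. Informational; the pipeline's default depth
#' is 11 for 20-s samples.
#'
#' @param n positive integer series length, `n >= 2`.
#' @return Integer IMF count.
#' @export
imf_count_formula <- function(n) {
  stopifnot(n >= 2)
  as.integer(floor(log2(n)) - 1)
}

#' Sum a contiguous range of IMFs
#'
#' `combine_imfs(set, 1, 2)` is the "IMF1-2" combination: the elementwise
#' sum of IMF1 and IMF2.
#'
#' @param set an `imf_set`.
#' @param i,j inclusive IMF index range, `1 <= i <= j <= length(set$imfs)`.
#' @return Numeric series.
#' @export
combine_imfs <- function(set, i, j = i) {
  stopifnot(inherits(set, "imf_set"))
  if (!(i >= 1 && i <= j && j <= length(set$imfs)))
    stop("IMF index range out of bounds")
  Reduce(`+`, set$imfs[i:j])
}

#' Signal energy
#'
#' Sum of squared samples, the per-IMF energy feature.
#'
#' @param x finite numeric series.
#' @return Non-negative scalar.
#' @export
imf_energy <- function(x) {
  stopifnot(all(is.finite(x)))
  sum(as.numeric(x)^2)
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram over 50%-overlapping segments.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param nseg segment length (default `min(256, length(x))`, rounded to
#'   even).
#' @return List with `freq` (Hz) and `power` (density, x^2/Hz).
#' @export
welch_psd <- function(x, fs, nseg = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(nseg)) nseg <- min(256L, n)
  nseg <- max(8L, (as.integer(nseg) %/% 2L) * 2L)
  step <- nseg %/% 2L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  starts <- seq(1L, n - nseg + 1L, by = step)
  u <- sum(win^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- abs(fft(seg))^2 / (u * fs)
    half <- p[seq_len(nf)]
    half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]  # one-sided
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1L) * fs / nseg, power = acc / length(starts))
}

#' Spectral description of an IMF
#'
#' Welch PSD of the series plus its `[5%, 95%]` spectral-mass band, the
#' convention used to report an IMF's frequency range.
#'
#' @param x numeric series, length at least 64.
#' @param fs sampling rate (Hz).
#' @param nseg Welch segment length, see [welch_psd()].
#' @return List with `freq`, `power`, `peak_freq`, and `band`
#'   (`c(lo, hi)` in Hz containing the central 90% of spectral mass).
#' @export
imf_psd <- function(x, fs, nseg = NULL) {
  stopifnot(length(x) >= 64)
  ps <- welch_psd(x, fs, nseg)
  cum <- cumsum(ps$power) / sum(ps$power)
  band <- c(ps$freq[which(cum >= 0.05)[1]], ps$freq[which(cum >= 0.95)[1]])
  list(freq = ps$freq, power = ps$power,
       peak_freq = ps$freq[which.max(ps$power)], band = band)
}

#' Write / read an IMF set as plain text
#'
#' The IMFs and residue are stored as one numeric matrix (columns IMF1..m,
#' residue last) with a JSON sidecar holding the method tag and
#' parameters.
#'
#' @param set an `imf_set`.
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @return `write_imf_set`: the base path, invisibly. `read_imf_set`: the
#'   restored `imf_set`.
#' @export
write_imf_set <- function(set, path) {
  stopifnot(inherits(set, "imf_set"))
  mat <- cbind(do.call(cbind, c(set$imfs, list(set$residue))))
  colnames(mat) <- c(sprintf("imf%d", seq_along(set$imfs)), "residue")
  utils::write.table(mat, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(set$meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_imf_set
#' @export
read_imf_set <- function(path) {
  mat <- as.matrix(utils::read.table(paste0(path, ".tsv"), header = TRUE,
                                     sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- ncol(mat) - 1L
  new_imf_set(lapply(seq_len(m), function(j) unname(mat[, j])),
              unname(mat[, m + 1L]), nrow(mat), meta)
}
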