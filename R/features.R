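#' Assemble the per-sample feature matrix
#'
#' Computes, per channel of every sample, either the multiscale
#' information-analysis (MIA) features -- MECI over `meci_scales`, energy
#' of the EEMD IMF `imf_index`, and fuzzy entropy of that IMF -- or the
#' classical comparison set: box-counting fractal dimension, windowed
#' sample entropy (512-point windows), and db4 wavelet beta (16-32 Hz) and
#' gamma (32-45 Hz) band energies. Column names encode
#' `feature__channel`.
#'
#' Preprocessing follows the analysis split of the pipeline: the
#' time-domain branch (MECI and all classical features) sees the notch +
#' 0.3-100 Hz band-passed signal, while the EEMD branch sees the
#' notch-only signal so the decomposition itself isolates low-frequency
#' artifact modes.
#'
#' Any channel-level estimator returning `NA` flags that cell; rows with
#' flagged cells are kept in the matrix and excluded later at training
#' time with a logged count.
#'
#' @param samples list of `eeg_sample` (shared channel count and rate).
#' @param feature_set `"mia"` or `"classical"`.
#' @param imf_index which EEMD IMF provides energy and fuzzy entropy
#'   (default 2, the high-frequency-oscillation mode).
#' @param meci_scales inclusive MSE scale range summed into MECI
#'   (default `c(1, 5)`).
#' @param m,r_frac sample-entropy parameters for the MSE curve.
#' @param fe_params list of fuzzy entropy parameters
#'   (`m`, `r`, `n`, `tau`).
#' @param eemd_params list of EEMD parameters (`noise_ratio`, `ensembles`,
#'   `max_imfs`, `seed`).
#' @param preprocess logical; apply the notch/band-pass stages (set
#'   `FALSE` if samples are already filtered -- EEMD then runs on the data
#'   as given).
#' @param verbose print progress every 20 samples.
#' @return A `feature_matrix`: list with `x` (samples x features), `y`
#'   (quadrant per row), `groups` (trial id per row), `subject_id`,
#'   `feature_set`.
#' @export
build_feature_matrix <- function(samples, feature_set = c("mia", "classical"),
                                 imf_index = 2, meci_scales = c(1, 5),
                                 m = 2, r_frac = 0.15,
                                 fe_params = list(m = 2, r = 0.15, n = 2,
                                                  tau = 1),
                                 eemd_params = list(noise_ratio = 0.1,
                                                    ensembles = 100,
                                                    max_imfs = 11, seed = 1),
                                 preprocess = TRUE, verbose = FALSE) {
  feature_set <- match.arg(feature_set)
  stopifnot(length(samples) > 0)
  fs <- samples[[1]]$fs
  nch <- nrow(samples[[1]]$data)
  chn <- rownames(samples[[1]]$data) %||% paste0("ch", seq_len(nch))
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stopifnot(nrow(s$data) == nch, s$fs == fs)
    time_mat <- s$data
    if (preprocess) {
      hi <- min(100, fs / 2 * 0.98)
      time_mat <- t(apply(s$data, 1, function(ch)
        bandpass_filter(notch_filter(ch, fs), fs, 0.3, hi)))
    }
    if (feature_set == "mia") {
      freq_mat <- if (preprocess)
        t(apply(s$data, 1, function(ch) notch_filter(ch, fs))) else s$data
      mec <- mse_batch(time_mat, s = meci_scales[2],
                       meci_scales = meci_scales, m = m,
                       r_frac = r_frac)$meci
      en <- numeric(nch); fe <- numeric(nch)
      for (ch in seq_len(nch)) {
        # IMF extraction is sequential, so truncating the decomposition at
        # imf_index leaves IMFs 1..imf_index bit-identical to a deeper run
        set <- eemd(freq_mat[ch, ],
                    noise_ratio = eemd_params$noise_ratio,
                    ensembles = eemd_params$ensembles,
                    max_imfs = min(eemd_params$max_imfs, imf_index),
                    seed = eemd_params$seed)
        if (length(set$imfs) < imf_index) {
          en[ch] <- NA_real_; fe[ch] <- NA_real_
        } else {
          imf <- set$imfs[[imf_index]]
          en[ch] <- imf_energy(imf)
          fe[ch] <- fuzzy_entropy(imf, m = fe_params$m, r = fe_params$r,
                                  n = fe_params$n, tau = fe_params$tau)
        }
      }
      row <- c(mec, en, fe)
      names(row) <- c(paste0("meci__", chn), paste0("energy__", chn),
                      paste0("fe__", chn))
    } else {
      fd <- apply(time_mat, 1, boxcount_fd)
      se <- apply(time_mat, 1, windowed_sample_entropy, m = m,
                  r_frac = r_frac, win_len = min(512, ncol(time_mat)))
      beta <- apply(time_mat, 1, dwt_band_energy, fs = fs, lo = 16, hi = 32)
      gam <- apply(time_mat, 1, dwt_band_energy, fs = fs, lo = 32, hi = 45)
      row <- c(fd, se, beta, gam)
      names(row) <- c(paste0("fd__", chn), paste0("se__", chn),
                      paste0("beta__", chn), paste0("gamma__", chn))
    }
    rows[[i]] <- row
    if (verbose && i %% 20 == 0)
      message(sprintf("features: %d / %d samples", i, length(samples)))
  }
  x <- do.call(rbind, rows)
  structure(list(
    x = x,
    y = vapply(samples, function(s) s$label, character(1)),
    groups = vapply(samples, function(s) s$trial_id, character(1)),
    subject_id = samples[[1]]$subject_id,
    feature_set = feature_set), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> subject %s (%s): %d samples x %d features, %d flagged cells\n",
              x$subject_id, x$feature_set, nrow(x$x), ncol(x$x),
              sum(is.na(x$x))))
  invisible(x)
}

#' Write a feature matrix as CSV
#'
#' Header row uses the `feature__channel` naming plus `label`, `trial_id`
#' and the feature-set tag.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_id, trial_id = fm$groups,
                   label = fm$y, feature_set = fm$feature_set,
                   fm$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta_cols <- c("subject_id", "trial_id", "label", "feature_set")
  structure(list(
    x = as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]),
    y = df$label, groups = df$trial_id, subject_id = df$subject_id[1],
    feature_set = df$feature_set[1]), class = "feature_matrix")
}
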