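#' Configuration for the synthetic EEG generator
#'
#' Describes a labelled synthetic study: recording geometry (channels,
#' rate, trial length), per-quadrant class structure of the high-frequency
#' (51-100 Hz) band, and artifact levels. The class effect mimics the
#' empirical pattern that emotion differences concentrate in the
#' high-frequency oscillations: arousal scales the band amplitude
#' (`class_gamma_gain`) and valence the band irregularity
#' (`class_complexity`, the noise fraction of a sinusoid/band-noise mix),
#' so HVHA trials carry the largest and most irregular high-band activity
#' and LVLA the smallest and most regular.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_subject trials per subject (balanced over the four
#'   quadrants).
#' @param trial_seconds trial duration (s).
#' @param fs sampling rate (Hz).
#' @param n_channels channel count; names are drawn evenly from the
#'   standard 32-channel montage.
#' @param class_gamma_gain named per-quadrant multiplier on the 51-100 Hz
#'   component amplitude.
#' @param class_complexity named per-quadrant noise fraction (0-1) of the
#'   high-band process; larger is more irregular.
#' @param gamma_base_amp high-band component SD (microvolts) at gain 1.
#' @param background_sd SD of the 1/f background (microvolts).
#' @param background_exponent exponent beta of the 1/f^beta background.
#' @param eog_rate EOG-like transients per minute.
#' @param line_noise_amp amplitude of the 50 Hz line component
#'   (microvolts).
#' @param seed master seed; the whole dataset is deterministic given the
#'   config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 1, n_trials_per_subject = 40,
                         trial_seconds = 60, fs = 512, n_channels = 32,
                         class_gamma_gain = c(HVHA = 2, LVHA = 2,
                                              HVLA = 1, LVLA = 1),
                         class_complexity = c(HVHA = 0.85, LVHA = 0.2,
                                              HVLA = 0.85, LVLA = 0.2),
                         gamma_base_amp = 6, background_sd = 8,
                         background_exponent = 1.5, eog_rate = 4,
                         line_noise_amp = 2, seed = 1) {
  stopifnot(all(sort(names(class_gamma_gain)) == sort(emotion_quadrants())),
            all(sort(names(class_complexity)) == sort(emotion_quadrants())),
            all(class_gamma_gain > 0), eog_rate >= 0, line_noise_amp >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# 1/f^beta Gaussian background, unit SD, via FFT spectral shaping.
powerlaw_noise <- function(n, exponent) {
  w <- rnorm(n)
  wf <- fft(w)
  f <- c(1, seq_len(n - 1))                     # avoid the DC singularity
  f <- pmin(f, n - f + 1)                       # symmetric frequency index
  shaped <- Re(fft(wf * f^(-exponent / 2), inverse = TRUE)) / n
  shaped / sd(shaped)
}

# Band-limited unit-SD Gaussian noise via FFT masking.
bandlimited_noise <- function(n, fs, lo, hi) {
  w <- rnorm(n)
  wf <- fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  wf[freq < lo | freq > hi] <- 0
  y <- Re(fft(wf, inverse = TRUE)) / n
  y / sd(y)
}

#' Add low-frequency EOG-like transient artifacts
#'
#' Superimposes randomly timed smooth raised-cosine bumps (0.3-0.6 s wide,
#' random sign, amplitude around `amplitude`) on the series. Their
#' spectral mass sits almost entirely below 10 Hz, emulating ocular
#' artifacts. Event count is Poisson with mean `rate` per minute.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param rate artifacts per minute, `>= 0`.
#' @param amplitude bump peak scale (microvolts), default 100.
#' @param seed optional seed making the call deterministic; `NULL` uses
#'   the current RNG stream.
#' @return Series with artifacts added.
#' @export
add_eog_artifacts <- function(x, fs, rate, amplitude = 100, seed = NULL) {
  stopifnot(rate >= 0)
  if (rate == 0) return(x)
  gen <- function() {
    n <- length(x)
    n_events <- stats::rpois(1, rate * n / fs / 60)
    y <- x
    for (k in seq_len(n_events)) {
      width <- runif(1, 0.3, 0.6)
      wpts <- max(3L, round(width * fs))
      start <- sample.int(max(1L, n - wpts), 1)
      bump <- 0.5 * (1 - cos(2 * pi * seq_len(wpts) / (wpts + 1)))
      amp <- sample(c(-1, 1), 1) * runif(1, 0.5, 1) * amplitude
      idx <- start:(start + wpts - 1L)
      y[idx] <- y[idx] + amp * bump
    }
    y
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Add a 50 Hz line-noise sinusoid
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param amp sinusoid amplitude, `>= 0`.
#' @param freq line frequency (Hz), default 50.
#' @return Series plus `amp * sin(2 pi freq t)`.
#' @export
add_line_noise <- function(x, fs, amp, freq = 50) {
  stopifnot(amp >= 0)
  if (amp == 0) return(x)
  t <- (seq_along(x) - 1) / fs
  x + amp * sin(2 * pi * freq * t)
}

#' Generate a labelled synthetic EEG study
#'
#' Produces one recording per trial (1/f background + class-dependent
#' 51-100 Hz component + 50 Hz line + EOG transients) and a ratings table
#' whose valence/arousal values land in each trial's intended quadrant.
#' Trials are balanced over the four quadrants. Fully deterministic per
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return List with `recordings` (list of `eeg_recording`) and `ratings`
#'   (data frame: subject_id, trial_id, valence, arousal, quadrant).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, {
    n <- round(cfg$trial_seconds * cfg$fs)
    chans <- deap_montage()[round(seq(1, 32, length.out = cfg$n_channels))]
    hi_band <- c(51, min(100, 0.45 * cfg$fs))
    if (diff(hi_band) < 3)
      stop("sampling rate too low for the 51-100 Hz class component")
    f0_range <- hi_band + c(0.15, -0.15) * diff(hi_band)
    recs <- list(); rat <- list()
    for (s in seq_len(cfg$n_subjects)) {
      sid <- sprintf("S%02d", s)
      quads <- rep(emotion_quadrants(),
                   length.out = cfg$n_trials_per_subject)
      for (tr in seq_len(cfg$n_trials_per_subject)) {
        q <- quads[tr]
        gain <- cfg$class_gamma_gain[[q]]
        w <- cfg$class_complexity[[q]]
        sig <- matrix(0, cfg$n_channels, n)
        for (ch in seq_len(cfg$n_channels)) {
          bg <- cfg$background_sd * powerlaw_noise(n, cfg$background_exponent)
          f0 <- runif(1, f0_range[1], f0_range[2])
          tone <- sqrt(2) * sin(2 * pi * f0 * (seq_len(n) - 1) / cfg$fs +
                                runif(1, 0, 2 * pi))
          bn <- bandlimited_noise(n, cfg$fs, hi_band[1], hi_band[2])
          comp <- (1 - w) * tone + w * bn
          comp <- comp / sd(comp) * cfg$gamma_base_amp * gain
          xch <- bg + comp
          xch <- add_line_noise(xch, cfg$fs, cfg$line_noise_amp)
          xch <- add_eog_artifacts(xch, cfg$fs, cfg$eog_rate)
          sig[ch, ] <- xch
        }
        tid <- sprintf("T%02d", tr)
        recs[[length(recs) + 1L]] <- recording(sig, cfg$fs, chans, sid, tid)
        hv <- q %in% c("HVHA", "HVLA"); ha <- q %in% c("HVHA", "LVHA")
        rat[[length(rat) + 1L]] <- data.frame(
          subject_id = sid, trial_id = tid,
          valence = if (hv) runif(1, 5.5, 8.5) else runif(1, 1.5, 4.5),
          arousal = if (ha) runif(1, 5.5, 8.5) else runif(1, 1.5, 4.5),
          stringsAsFactors = FALSE)
      }
    }
    ratings <- do.call(rbind, rat)
    ratings$quadrant <- assign_quadrant(ratings$valence, ratings$arousal)
    list(recordings = recs, ratings = ratings)
  })
}

#' Materialise a synthetic study directory
#'
#' Writes every trial in the plain-matrix format plus the ratings CSV, the
#' layout the reader side of the pipeline consumes.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @param format `"plain"` (TSV + JSON sidecar) or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(cfg, dir, format = c("plain", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(cfg)
  for (rec in ds$recordings) {
    base <- file.path(dir, paste0(rec$subject_id, "_", rec$trial_id))
    if (format == "plain") write_recording_plain(rec, base)
    else write_edf(rec, paste0(base, ".edf"))
  }
  write_ratings(ds$ratings, file.path(dir, "ratings.csv"))
  invisible(dir)
}
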