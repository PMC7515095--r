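#' Multichannel EEG recording
#'
#' A `Recording` bundles a channels-by-samples signal matrix (microvolts)
#' with its sampling rate and 10-20 montage channel names. It is the unit
#' of input for preprocessing and segmentation.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_names character vector of unique montage labels, one per
#'   channel row.
#' @param subject_id,trial_id opaque identifier strings.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(signal, fs, channel_names,
                      subject_id = "S01", trial_id = "T01") {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(signal), is.numeric(fs), length(fs) == 1L, fs > 0)
  if (length(channel_names) != nrow(signal))
    stop("channel_names length must equal the number of channels (rows)")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  rownames(signal) <- channel_names
  structure(
    list(signal = signal, fs = fs, channel_names = as.character(channel_names),
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s trial %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$trial_id, nrow(x$signal), ncol(x$signal),
              x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

#' Fixed-length labelled EEG segment
#'
#' A `Sample` is one non-overlapping window cut from a trial recording,
#' optionally carrying the trial's valence-arousal quadrant label.
#'
#' @param data numeric matrix, channels x N.
#' @param fs sampling rate (Hz).
#' @param subject_id,trial_id identifiers inherited from the recording.
#' @param segment_index 0-based index of the window within the trial.
#' @param label one of `"HVHA","LVHA","HVLA","LVLA"`, or `NA`.
#' @return An object of class `eeg_sample`.
#' @export
eeg_sample <- function(data, fs, subject_id, trial_id, segment_index,
                       label = NA_character_) {
  data <- as.matrix(data)
  if (!is.na(label)) label <- match.arg(label, emotion_quadrants())
  structure(
    list(data = data, fs = fs, n = ncol(data),
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         segment_index = as.integer(segment_index), label = label),
    class = "eeg_sample")
}

#' The four valence-arousal quadrant labels
#'
#' @return Character vector `c("HVHA","LVHA","HVLA","LVLA")` (High/Low
#'   Valence x High/Low Arousal).
#' @export
emotion_quadrants <- function() c("HVHA", "LVHA", "HVLA", "LVLA")

#' Map a valence/arousal self-assessment to its emotion quadrant
#'
#' Ratings are on the 1-9 self-assessment scale. A rating strictly above 5
#' counts as High; 5 or below counts as Low, so the plane is partitioned
#' exactly: valence > 5 and arousal > 5 is HVHA, valence <= 5 and
#' arousal > 5 is LVHA, valence > 5 and arousal <= 5 is HVLA, and both
#' <= 5 is LVLA.
#'
#' @param valence,arousal numeric ratings in `[1, 9]` (vectorised).
#' @return Character vector of quadrant labels.
#' @export
#' @examples
#' assign_quadrant(6, 7)  # "HVHA"
#' assign_quadrant(5, 5)  # "LVLA"
assign_quadrant <- function(valence, arousal) {
  if (any(!is.finite(valence)) || any(!is.finite(arousal)) ||
      any(valence < 1 | valence > 9) || any(arousal < 1 | arousal > 9))
    stop("valence and arousal ratings must lie in [1, 9]")
  hv <- valence > 5
  ha <- arousal > 5
  ifelse(ha, ifelse(hv, "HVHA", "LVHA"), ifelse(hv, "HVLA", "LVLA"))
}

#' Cut a recording into non-overlapping fixed-length samples
#'
#' The trial is divided into `floor(duration / window_seconds)` consecutive
#' windows of `round(fs * window_seconds)` points each; a trailing partial
#' window is discarded. Each segment inherits the trial's label.
#'
#' @param rec an `eeg_recording`.
#' @param window_seconds window length in seconds (default 20, the sample
#'   length used throughout the pipeline).
#' @param label optional quadrant label attached to every segment.
#' @return List of `eeg_sample` objects (empty, with a warning, if the
#'   recording is shorter than one window).
#' @export
segment_recording <- function(rec, window_seconds = 20, label = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"), window_seconds > 0)
  npts <- round(rec$fs * window_seconds)
  nseg <- floor(ncol(rec$signal) / npts)
  if (nseg < 1) {
    warning("recording shorter than one window; no segments produced")
    return(list())
  }
  lapply(seq_len(nseg) - 1L, function(k) {
    eeg_sample(rec$signal[, (k * npts + 1L):((k + 1L) * npts), drop = FALSE],
               fs = rec$fs, subject_id = rec$subject_id,
               trial_id = rec$trial_id, segment_index = k, label = label)
  })
}

#' Standard 32-channel montage and scalp regions
#'
#' `deap_montage()` returns the 32 active-electrode 10-20 labels in
#' recording order. `channel_regions()` maps montage labels onto the five
#' scalp regions used for the regional significance summary.
#'
#' @return `deap_montage()`: character vector of 32 labels.
#'   `channel_regions()`: named character vector, values in
#'   `frontal, central, temporal, parietal, occipital`.
#' @export
deap_montage <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4", "F8",
    "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' @rdname deap_montage
#' @export
channel_regions <- function() {
  reg <- c(
    Fp1 = "frontal", Fp2 = "frontal", AF3 = "frontal", AF4 = "frontal",
    F7 = "frontal", F3 = "frontal", Fz = "frontal", F4 = "frontal",
    F8 = "frontal",
    FC5 = "central", FC1 = "central", FC2 = "central", FC6 = "central",
    C3 = "central", Cz = "central", C4 = "central",
    T7 = "temporal", T8 = "temporal",
    CP5 = "parietal", CP1 = "parietal", CP2 = "parietal", CP6 = "parietal",
    P7 = "parietal", P3 = "parietal", Pz = "parietal", P4 = "parietal",
    P8 = "parietal",
    PO3 = "occipital", PO4 = "occipital", O1 = "occipital",
    Oz = "occipital", O2 = "occipital")
  reg
}
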