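#' Read a European Data Format (EDF) or BioSemi (BDF) recording
#'
#' Minimal reader for continuous EDF (16-bit) and BDF (24-bit) files:
#' parses the 256-byte header plus per-signal header fields, decodes the
#' data records, and applies the physical/digital calibration. Annotation
#' channels are not supported; all signals must share one sampling rate.
#'
#' @param path file path.
#' @param subject_id,trial_id identifiers attached to the returned
#'   recording (default: file name).
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, subject_id = NULL, trial_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1)
  is_bdf <- identical(as.integer(first), 255L)
  readChar(con, 7, useBytes = TRUE)           # rest of version field
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)  # patient/recording/date/time
  readChar(con, 8, useBytes = TRUE)           # header length
  readChar(con, 44, useBytes = TRUE)          # reserved
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  rd <- function(w) trimws(vapply(seq_len(ns), function(i)
    readChar(con, w, useBytes = TRUE), character(1)))
  labels <- rd(16)
  rd(80)                                      # transducer
  rd(8)                                       # physical dimension
  pmin <- as.numeric(rd(8)); pmax <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)                                      # prefilter
  spr <- as.integer(rd(8))                    # samples per data record
  rd(32)                                      # reserved
  if (length(unique(spr / dur)) != 1)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1] / dur
  bytes <- if (is_bdf) 3L else 2L
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (rec in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      if (is_bdf) {
        raw3 <- readBin(con, "raw", spr[ch] * 3L)
        m <- matrix(as.integer(raw3), nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        v <- readBin(con, "integer", spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      }
      gain <- (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
      sig[ch, ((rec - 1) * spr[ch] + 1):(rec * spr[ch])] <-
        (v - dmin[ch]) * gain + pmin[ch]
    }
  }
  base <- sub("\\.(edf|bdf)$", "", basename(path), ignore.case = TRUE)
  recording(sig, fs, make.unique(labels),
            subject_id = subject_id %||% base,
            trial_id = trial_id %||% base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixed_field <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as 16-bit EDF
#'
#' One data record per second; requires an integer sampling rate. Physical
#' calibration spans the per-channel data range over the full 16-bit
#' digital range.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_rec <- ncol(rec$signal) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  sig <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(sig)
  pmin <- apply(sig, 1, min); pmax <- apply(sig, 1, max)
  pmax <- ifelse(pmax == pmin, pmin + 1, pmax)
  # integer physical limits keep the 8-character header fields exact, so
  # reader and writer gains agree to quantisation level
  pmin <- floor(pmin); pmax <- ceiling(pmax)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(fixed_field(s, w), con, nchars = w,
                                  eos = NULL)
  put("0", 8)
  put(rec$subject_id, 80)
  put(rec$trial_id, 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(as.character(256 * (1 + ns)), 8)
  put("", 44)
  put(as.character(n_rec), 8)
  put("1", 8)
  put(as.character(ns), 4)
  for (l in rec$channel_names) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (v in pmin) put(as.character(v), 8)
  for (v in pmax) put(as.character(v), 8)
  for (i in seq_len(ns)) put(as.character(dmin), 8)
  for (i in seq_len(ns)) put(as.character(dmax), 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(as.character(fs), 8)
  for (i in seq_len(ns)) put("", 32)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (recix in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      v <- sig[ch, ((recix - 1) * fs + 1):(recix * fs)]
      dig <- as.integer(round((v - pmin[ch]) / gain[ch]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Plain-matrix recording fallback
#'
#' `write_recording_plain()` stores the signal as a TSV (channels in
#' columns) plus a JSON sidecar carrying the sampling rate, channel names
#' and identifiers; `read_recording_plain()` restores it. A portable
#' text-only alternative to EDF.
#'
#' @param rec an `eeg_recording`.
#' @param path base path; `<path>.tsv` and `<path>.json` are used.
#' @return The base path (write) or an `eeg_recording` (read).
#' @export
write_recording_plain <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  mat <- t(rec$signal)
  colnames(mat) <- rec$channel_names
  utils::write.table(mat, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_names = rec$channel_names,
         subject_id = rec$subject_id, trial_id = rec$trial_id),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording_plain
#' @export
read_recording_plain <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(paste0(path, ".tsv"), header = TRUE,
                                     sep = "\t", check.names = FALSE))
  recording(t(mat), meta$fs, meta$channel_names, meta$subject_id,
            meta$trial_id)
}

#' Read / write per-trial self-assessment ratings
#'
#' CSV with columns `subject_id, trial_id, valence, arousal`; reading
#' validates the 1-9 range and adds the `quadrant` column via
#' [assign_quadrant()].
#'
#' @param path CSV file path.
#' @return Data frame of ratings with quadrant labels.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_id", "valence", "arousal")
  if (!all(need %in% names(df)))
    stop("ratings file must have columns ", paste(need, collapse = ", "))
  df$quadrant <- assign_quadrant(df$valence, df$arousal)
  df
}

#' @rdname read_ratings
#' @param ratings data frame with the rating columns.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' Write segmented samples with a manifest
#'
#' Each sample's channel matrix goes to its own TSV under `dir`, and
#' `manifest.csv` lists subject, trial, segment index, label and file name
#' per sample.
#'
#' @param samples list of `eeg_sample`.
#' @param dir output directory (created if missing).
#' @return Path of the manifest, invisibly.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    fname <- sprintf("%s_%s_seg%02d.tsv", s$subject_id, s$trial_id,
                     s$segment_index)
    mat <- t(s$data)
    colnames(mat) <- rownames(s$data) %||% paste0("ch", seq_len(ncol(mat)))
    utils::write.table(mat, file.path(dir, fname), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    data.frame(subject_id = s$subject_id, trial_id = s$trial_id,
               segment_index = s$segment_index, label = s$label,
               file = fname, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
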