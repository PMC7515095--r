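test_that("quadrant mapping partitions the rating plane with inclusive-low boundary", {
  expect_equal(assign_quadrant(6, 7), "HVHA")
  expect_equal(assign_quadrant(5, 5), "LVLA")
  expect_equal(assign_quadrant(7, 3), "HVLA")
  expect_equal(assign_quadrant(3, 7), "LVHA")
  # every rating pair maps to exactly one of the four quadrants
  set.seed(42)
  v <- runif(500, 1, 9); a <- runif(500, 1, 9)
  q <- assign_quadrant(v, a)
  expect_true(all(q %in% emotion_quadrants()))
  expect_equal(unname(q[v > 5 & a > 5]),
               rep("HVHA", sum(v > 5 & a > 5)))
  expect_error(assign_quadrant(0.5, 5), "1, 9")
  expect_error(assign_quadrant(5, 9.5), "1, 9")
})

test_that("segmentation yields floor(duration/window) full windows and drops the tail", {
  rec <- recording(matrix(rnorm(2 * 512 * 60), 2), 512, c("Cz", "Pz"))
  segs <- segment_recording(rec, 20)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(s) s$n, numeric(1)) == 10240))
  expect_equal(vapply(segs, function(s) s$segment_index, integer(1)), 0:2)

  rec1 <- recording(matrix(rnorm(512 * 20), 1), 512, "Cz")
  expect_length(segment_recording(rec1, 20), 1)
  rec59 <- recording(matrix(rnorm(512 * 59), 1), 512, "Cz")
  expect_length(segment_recording(rec59, 20), 2)
  short <- recording(matrix(rnorm(512 * 5), 1), 512, "Cz")
  expect_warning(out <- segment_recording(short, 20), "shorter")
  expect_length(out, 0)

  # property: count = floor(duration / window) over random durations
  set.seed(7)
  for (k in 1:20) {
    dur <- runif(1, 20, 200); fs <- 64
    r <- recording(matrix(rnorm(round(fs * dur)), 1), fs, "Cz")
    expect_length(segment_recording(r, 20), floor(ncol(r$signal) / (fs * 20)))
  }
})

test_that("segments inherit identifiers and labels from the trial", {
  rec <- recording(matrix(rnorm(2 * 128 * 40), 2), 128, c("Fz", "Cz"),
                   subject_id = "S05", trial_id = "T17")
  segs <- segment_recording(rec, 20, label = "LVHA")
  expect_equal(segs[[2]]$subject_id, "S05")
  expect_equal(segs[[2]]$trial_id, "T17")
  expect_equal(segs[[1]]$label, "LVHA")
})

test_that("notch filter attenuates the mains tone and passes nearby frequencies", {
  fs <- 512
  mains <- tone(50, fs, 4)
  out <- notch_filter(mains, fs)
  expect_lt(rms(out), 0.1 * rms(mains))
  expect_equal(notch_filter(rep(0, 1024), fs), rep(0, 1024))
  low <- tone(10, fs, 4)
  expect_lt(abs(rms(notch_filter(low, fs)) / rms(low) - 1), 0.1)
  # passband gain within 1 dB at 5 Hz from the notch (central portion)
  near <- tone(45, fs, 4)
  mid <- 512:1536
  gain <- rms(notch_filter(near, fs)[mid]) / rms(near[mid])
  expect_lt(abs(20 * log10(gain)), 1)
  expect_error(notch_filter(rnorm(100), fs, freq = 300), "Nyquist|inside")
})

test_that("band-pass filter keeps in-band tones, rejects out-of-band, zero phase", {
  fs <- 512
  hi_tone <- tone(200, fs, 4)
  expect_lt(rms(bandpass_filter(hi_tone, fs)), 0.1 * rms(hi_tone))
  mid_tone <- tone(40, fs, 4)
  out <- bandpass_filter(mid_tone, fs)
  expect_lt(abs(rms(out) / rms(mid_tone) - 1), 0.1)
  expect_equal(bandpass_filter(rep(0, 512), fs), rep(0, 512))
  # zero phase: cross-correlation of a band-centre tone peaks at lag 0
  cc <- ccf(out, mid_tone, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass_filter(rnorm(100), fs, lo = 90, hi = 20), "band")
})

test_that("filters are linear", {
  fs <- 256
  set.seed(3)
  x <- rnorm(1024); y <- rnorm(1024)
  for (f in list(function(v) notch_filter(v, fs),
                 function(v) bandpass_filter(v, fs, 0.3, 100))) {
    lhs <- f(2.5 * x - 1.3 * y)
    rhs <- 2.5 * f(x) - 1.3 * f(y)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)
  }
})

test_that("EDF reader decodes a hand-built 16-bit file", {
  # build an EDF file byte-by-byte, independent of the package writer
  fs <- 32; n_rec <- 2; ns <- 2
  dig <- matrix(as.integer(round(seq(-30000, 30000,
                                     length.out = fs * n_rec * ns))),
                nrow = ns, byrow = TRUE)
  pmin <- c(-100, -50); pmax <- c(100, 50)
  path <- tempfile(fileext = ".edf")
  con <- file(path, "wb")
  put <- function(s, w) writeChar(formatC(s, width = w, flag = "-"), con,
                                  nchars = w, eos = NULL)
  put("0", 8); put("patient", 80); put("rec", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(as.character(256 * (1 + ns)), 8); put("", 44)
  put(as.character(n_rec), 8); put("1", 8); put(as.character(ns), 4)
  put("Cz", 16); put("Pz", 16)
  for (i in 1:ns) put("", 80)
  for (i in 1:ns) put("uV", 8)
  for (v in pmin) put(as.character(v), 8)
  for (v in pmax) put(as.character(v), 8)
  for (i in 1:ns) put("-32768", 8)
  for (i in 1:ns) put("32767", 8)
  for (i in 1:ns) put("", 80)
  for (i in 1:ns) put(as.character(fs), 8)
  for (i in 1:ns) put("", 32)
  for (r in 1:n_rec) for (ch in 1:ns)
    writeBin(dig[ch, ((r - 1) * fs + 1):(r * fs)], con, size = 2,
             endian = "little")
  close(con)

  rec <- read_edf(path)
  expect_equal(rec$fs, fs)
  expect_equal(rec$channel_names, c("Cz", "Pz"))
  expected <- (dig - (-32768)) * (pmax - pmin) / 65535 + pmin
  expect_equal(unname(rec$signal), expected, tolerance = 1e-10)
})

test_that("BDF 24-bit decoding handles negative values", {
  fs <- 16; vals <- as.integer(c(-(2^23), -1, 0, 1, 2^23 - 1,
                                 seq(-1e6, 1e6, length.out = 11)))
  path <- tempfile(fileext = ".bdf")
  con <- file(path, "wb")
  writeBin(as.raw(255), con)
  put <- function(s, w) writeChar(formatC(s, width = w, flag = "-"), con,
                                  nchars = w, eos = NULL)
  put("BIOSEMI", 7); put("p", 80); put("r", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(as.character(256 * 2), 8); put("", 44)
  put("1", 8); put("1", 8); put("1", 4)
  put("A1", 16); put("", 80); put("uV", 8)
  put(as.character(-(2^23)), 8); put(as.character(2^23 - 1), 8)
  put(as.character(-(2^23)), 8); put(as.character(2^23 - 1), 8)
  put("", 80); put(as.character(fs), 8); put("", 32)
  for (v in vals) {
    u <- if (v < 0) v + 2^24 else v
    writeBin(as.raw(c(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256)),
             con)
  }
  close(con)
  rec <- read_edf(path)
  # physical range equals digital range here, so values round-trip exactly
  expect_equal(unname(rec$signal[1, ]), as.numeric(vals), tolerance = 1e-7)
})

test_that("EDF writer round-trips through the reader", {
  set.seed(9)
  rec <- recording(matrix(rnorm(2 * 64 * 3, sd = 40), 2), 64, c("Fz", "Oz"),
                   "S01", "T03")
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path, subject_id = "S01", trial_id = "T03")
  expect_equal(back$fs, 64)
  expect_equal(back$channel_names, c("Fz", "Oz"))
  # 16-bit quantisation over the (integer-rounded) calibration range
  expect_lt(max(abs(back$signal - rec$signal)),
            1.05 * (diff(range(rec$signal)) + 2) / 65535)
})

test_that("plain-matrix recording and ratings round-trip", {
  rec <- recording(matrix(1:20 / 7, 2), 10, c("C3", "C4"), "S02", "T09")
  base <- tempfile()
  write_recording_plain(rec, base)
  back <- read_recording_plain(base)
  expect_equal(back$signal, rec$signal, tolerance = 1e-9)
  expect_equal(back$fs, 10)
  expect_equal(back$subject_id, "S02")

  rt <- data.frame(subject_id = "S02", trial_id = c("T01", "T02"),
                   valence = c(6.5, 2), arousal = c(8, 5))
  p <- tempfile(fileext = ".csv")
  write_ratings(rt, p)
  got <- read_ratings(p)
  expect_equal(got$quadrant, c("HVHA", "LVLA"))
})

test_that("sample writer produces per-sample files plus a manifest", {
  rec <- recording(matrix(rnorm(2 * 64 * 45), 2), 64, c("Fz", "Cz"),
                   "S01", "T02")
  segs <- segment_recording(rec, 20, label = "HVLA")
  dir <- tempfile()
  mpath <- write_samples(segs, dir)
  man <- read.csv(mpath)
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_equal(man$label, rep("HVLA", 2))
})
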