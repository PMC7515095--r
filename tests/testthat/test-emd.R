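test_that("EMD reconstruction is exact and a ramp yields no IMFs", {
  set.seed(131)
  for (k in 1:10) {
    x <- rnorm(512)
    d <- emd(x, max_imfs = 8)
    recon <- Reduce(`+`, d$imfs) + d$residue
    expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-8)
  }
  ramp <- seq(0, 1, length.out = 100)
  d <- emd(ramp, max_imfs = 5)
  expect_length(d$imfs, 0)
  expect_equal(d$residue, ramp)
})

test_that("the first IMF of a two-tone mixture carries the high tone", {
  set.seed(141)
  fs <- 512
  x <- tone(4, fs, 4) + tone(64, fs, 4) + rnorm(fs * 4, sd = 0.05)
  d <- emd(x, max_imfs = 6)
  peak <- imf_psd(d$imfs[[1]], fs)$peak_freq
  expect_gte(peak, 56)
  expect_lte(peak, 72)
})

test_that("accepted IMFs satisfy the extrema/zero-crossing condition", {
  set.seed(151)
  for (k in 1:10) {
    x <- rnorm(1024)
    d <- emd(x, max_imfs = 6)
    for (imf in d$imfs) {
      cnt <- eegmia:::extrema_zc_counts(imf)
      expect_lte(abs(cnt[1] - cnt[2]), 1)
    }
  }
})

test_that("IMF mean frequency decreases with index", {
  set.seed(161)
  fs <- 256
  x <- tone(8, fs, 8) + tone(40, fs, 8) + rnorm(fs * 8, sd = 0.3)
  d <- emd(x, max_imfs = 5)
  mean_freq <- vapply(d$imfs, function(imf) {
    ps <- welch_psd(imf, fs)
    sum(ps$freq * ps$power) / sum(ps$power)
  }, numeric(1))
  expect_true(all(diff(mean_freq) < 0))
})

test_that("EEMD with zero noise and one ensemble reduces to EMD", {
  set.seed(171)
  x <- rnorm(800)
  a <- eemd(x, noise_ratio = 0, ensembles = 1, max_imfs = 6, seed = 3)
  b <- emd(x, max_imfs = 6)
  expect_equal(a$imfs, b$imfs, tolerance = 0)
  expect_equal(a$residue, b$residue, tolerance = 0)
})

test_that("EEMD is deterministic given the seed and leaves the caller RNG alone", {
  set.seed(181)
  x <- rnorm(600)
  set.seed(999); before <- rnorm(1)
  set.seed(999)
  a <- eemd(x, 0.1, 10, max_imfs = 4, seed = 42)
  after <- rnorm(1)
  b <- eemd(x, 0.1, 10, max_imfs = 4, seed = 42)
  expect_identical(a$imfs, b$imfs)
  expect_identical(a$residue, b$residue)
  expect_identical(before, after)
})

test_that("EEMD reconstruction error shrinks with the ensemble average", {
  set.seed(191)
  fs <- 256
  x <- tone(64, fs, 4) + rnorm(fs * 4, sd = 0.2)
  E <- 50
  d <- eemd(x, noise_ratio = 0.1, ensembles = E, max_imfs = 8, seed = 7)
  err <- x - Reduce(`+`, d$imfs) - d$residue
  expect_lte(rms(err), 0.1 * sd(x) / sqrt(E) * 3)
})

test_that("the dyadic IMF-count rule matches its closed form", {
  expect_equal(imf_count_formula(10240), 12L)
  expect_equal(imf_count_formula(256), 7L)
  expect_equal(imf_count_formula(2), 0L)
})

test_that("IMF combination sums a contiguous index range", {
  set.seed(201)
  x <- rnorm(700)
  d <- emd(x, max_imfs = 5)
  expect_equal(combine_imfs(d, 2, 2), d$imfs[[2]])
  expect_equal(combine_imfs(d, 1, 2), d$imfs[[1]] + d$imfs[[2]])
  m <- length(d$imfs)
  expect_lt(max(abs(combine_imfs(d, 1, m) + d$residue - x)) / max(abs(x)),
            1e-8)
  expect_error(combine_imfs(d, 0, 2), "range")
  expect_error(combine_imfs(d, 1, m + 1), "range")
})

test_that("energy is the sum of squares", {
  expect_equal(imf_energy(rep(0, 10)), 0)
  expect_equal(imf_energy(c(1, 2, 3)), 14)
  expect_equal(imf_energy(c(3, 4)), 25)
})

test_that("EMD approximately conserves energy", {
  set.seed(211)
  x <- rnorm(1024)
  d <- emd(x, max_imfs = 8)
  tot <- sum(vapply(d$imfs, imf_energy, numeric(1))) + imf_energy(d$residue)
  expect_gte(tot, 0.9 * imf_energy(x))
})

test_that("Welch PSD localises a pure tone to one bin", {
  fs <- 512
  ps <- imf_psd(tone(64, fs, 2), fs)
  df <- ps$freq[2] - ps$freq[1]
  expect_lte(abs(ps$peak_freq - 64), df)
})

test_that("Welch PSD of white noise is flat on average", {
  set.seed(221)
  acc <- NULL
  for (k in 1:50) {
    ps <- welch_psd(rnorm(2048), fs = 256)
    acc <- if (is.null(acc)) ps$power else acc + ps$power
  }
  acc <- acc / 50
  keep <- ps$freq > 4 & ps$freq < 124  # away from DC/Nyquist window bins
  expect_lt(max(acc[keep]) / min(acc[keep]), 3)
})

test_that("spectral-mass band of band-limited noise stays near the band", {
  set.seed(231)
  x <- bandpass_filter(rnorm(4096), 256, 30, 60)
  band <- imf_psd(x, 256)$band
  expect_gte(band[1], 25)
  expect_lte(band[2], 70)
})

test_that("IMF sets serialise to text and back", {
  set.seed(241)
  x <- rnorm(300)
  d <- eemd(x, 0.1, 5, max_imfs = 3, seed = 2)
  base <- tempfile()
  write_imf_set(d, base)
  back <- read_imf_set(base)
  expect_equal(length(back$imfs), length(d$imfs))
  expect_equal(back$imfs[[2]], d$imfs[[2]], tolerance = 1e-6)
  expect_equal(back$meta$method, "EEMD")
  expect_equal(back$meta$ensembles, 5)
})
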