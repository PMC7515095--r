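# Independent brute-force oracles: direct double-loop evaluations of the
# entropy definitions, kept free of the package's C++ kernels.

se_oracle <- function(x, m = 2, r_frac = 0.15, relative = TRUE) {
  n <- length(x)
  r <- if (relative) r_frac * sd(x) else r_frac
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm < r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

fe_oracle <- function(x, m = 2, r = 0.15, nexp = 2, relative = TRUE) {
  if (relative) x <- x / sd(x)
  n <- length(x)
  rr <- r
  nt <- n - m
  sm <- 0; sm1 <- 0
  for (i in 1:(nt - 1)) {
    xi_m <- x[i:(i + m - 1)] - mean(x[i:(i + m - 1)])
    xi_m1 <- x[i:(i + m)] - mean(x[i:(i + m)])
    for (j in (i + 1):nt) {
      xj_m <- x[j:(j + m - 1)] - mean(x[j:(j + m - 1)])
      xj_m1 <- x[j:(j + m)] - mean(x[j:(j + m)])
      sm <- sm + exp(-max(abs(xi_m - xj_m))^nexp / rr)
      sm1 <- sm1 + exp(-max(abs(xi_m1 - xj_m1))^nexp / rr)
    }
  }
  np <- nt * (nt - 1) / 2
  log(sm / np) - log(sm1 / np)
}

renyi_oracle <- function(x, alpha = 2, bandwidth) {
  n <- length(x)
  p <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in 1:n) s <- s + dnorm((x[i] - x[j]) / bandwidth)
    p[i] <- s / (n * bandwidth)
  }
  p <- p / sum(p)
  log(sum(p^alpha)) / (1 - alpha)
}

# Pure tone helper.
tone <- function(freq, fs, seconds, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(fs * seconds) - 1)) / fs + phase)
}

rms <- function(x) sqrt(mean(x^2))

# Tiny labelled feature-matrix stub for classifier tests.
make_fm <- function(x, y, groups = NULL, subject = "S01",
                    feature_set = "mia") {
  structure(list(x = as.matrix(x), y = y,
                 groups = groups %||% as.character(seq_along(y)),
                 subject_id = subject, feature_set = feature_set),
            class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
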