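make_samples <- function(n, nch = 2, npts = 1280, fs = 128, labels = NULL,
                         seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    eeg_sample(matrix(rnorm(nch * npts), nch,
                      dimnames = list(paste0("ch", 1:nch), NULL)),
               fs = fs, subject_id = "S01",
               trial_id = sprintf("T%02d", i), segment_index = 0,
               label = if (is.null(labels)) NA_character_ else labels[i])
  })
}

test_that("feature matrix has 3 (MIA) or 4 (classical) features per channel", {
  samples <- make_samples(2, nch = 2)
  fm <- build_feature_matrix(samples,
                             eemd_params = list(noise_ratio = 0.1,
                                                ensembles = 2,
                                                max_imfs = 4, seed = 1))
  expect_equal(ncol(fm$x), 6)
  expect_true(all(grepl("^(meci|energy|fe)__ch[12]$", colnames(fm$x))))
  fmc <- build_feature_matrix(samples, feature_set = "classical")
  expect_equal(ncol(fmc$x), 8)
  expect_true(all(grepl("^(fd|se|beta|gamma)__", colnames(fmc$x))))
})

test_that("identical samples produce identical feature rows", {
  s <- make_samples(1, nch = 2)[[1]]
  twin <- eeg_sample(s$data, s$fs, s$subject_id, "T99", 0)
  fm <- build_feature_matrix(list(s, twin),
                             eemd_params = list(noise_ratio = 0.1,
                                                ensembles = 2,
                                                max_imfs = 4, seed = 1))
  expect_equal(unname(fm$x[1, ]), unname(fm$x[2, ]))
})

test_that("min-max scaling maps the training range to [-1, 1] without clipping", {
  train <- cbind(a = c(0, 10, 5), b = c(2, 2, 2))
  test <- cbind(a = c(20, -10), b = c(7, 0))
  sc <- scale_features(train, test)
  expect_equal(sc$train[, "a"], c(-1, 1, 0))
  expect_equal(sc$train[, "b"], c(0, 0, 0))  # constant column
  expect_equal(sc$test[, "a"], c(3, -3))     # linear extrapolation
  expect_equal(sc$test[, "b"], c(0, 0))
})

test_that("the scaling map is fitted on the training rows only", {
  set.seed(301)
  train <- matrix(rnorm(40), 10)
  test1 <- matrix(rnorm(20), 5)
  test2 <- test1 + 100
  a <- scale_features(train, test1)
  b <- scale_features(train, test2)
  expect_identical(a$lo, b$lo)
  expect_identical(a$hi, b$hi)
  expect_identical(a$train, b$train)
})

test_that("grouped folds keep all segments of a trial together", {
  set.seed(311)
  groups <- rep(sprintf("T%02d", 1:20), each = 3)
  y <- rep(rep(emotion_quadrants(), 5), each = 3)
  folds <- eegmia:::make_grouped_folds(groups, y, k = 5, seed = 2)
  split_check <- tapply(folds, groups, function(v) length(unique(v)))
  expect_true(all(split_check == 1))
  expect_setequal(unique(folds), 1:5)
})

test_that("well-separated classes are classified nearly perfectly and each sample is tested once", {
  set.seed(321)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2), n), matrix(rnorm(n * 2) + 6, n))
  colnames(x) <- c("f1", "f2")
  fm <- make_fm(x, rep(c("HVHA", "LVLA"), each = n))
  res <- crossval_svm(fm, k_folds = 10, seed = 1)
  expect_gte(res$metrics$accuracy, 0.95)
  expect_equal(sum(res$confusion), 2 * n)      # every sample tested once
  expect_false(anyNA(res$predicted))
  expect_equal(res$roc$mean_auc, 1, tolerance = 0.02)
})

test_that("permuted labels give chance-level accuracy on four balanced classes", {
  set.seed(331)
  n <- 120
  x <- matrix(rnorm(n * 4), n)
  colnames(x) <- paste0("f", 1:4)
  accs <- vapply(1:5, function(k) {
    y <- sample(rep(emotion_quadrants(), n / 4))
    crossval_svm(make_fm(x, y), k_folds = 10, seed = k,
                 grid = list(cost = c(1, 100), gamma = c(0.01, 1)))$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.15)
  expect_lte(mean(accs), 0.35)
})

test_that("rows with flagged cells are excluded with a message", {
  set.seed(341)
  x <- matrix(rnorm(80), 40)
  colnames(x) <- c("f1", "f2")
  x[3, 1] <- NA
  fm <- make_fm(x, rep(c("HVHA", "LVLA"), 20))
  expect_message(res <- crossval_svm(fm, k_folds = 5, seed = 1,
                                     grid = list(cost = 1, gamma = 0.5)),
                 "excluding 1")
  expect_equal(sum(res$confusion), 39)
})

test_that("confusion metrics reproduce hand computations", {
  cm <- diag(c(10, 10, 10, 10))
  dimnames(cm) <- list(emotion_quadrants(), emotion_quadrants())
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$precision, rep(1, 4))
  expect_equal(m$per_class$specificity, rep(1, 4))

  # degenerate predictor: always says class 1 on balanced truth
  always1 <- rbind(c(10, 10, 10, 10), matrix(0, 3, 4))
  dimnames(always1) <- list(emotion_quadrants(), emotion_quadrants())
  m1 <- confusion_metrics(always1)
  expect_equal(m1$accuracy, 0.25)
  expect_equal(m1$per_class$recall[1], 1)
  expect_equal(m1$per_class$recall[2:4], rep(0, 3))
  expect_true(all(is.na(m1$per_class$precision[2:4])))  # empty rows -> NA

  # 2-class: cm = [[8,2],[2,8]]
  cm2 <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  m2 <- confusion_metrics(cm2)
  expect_equal(m2$per_class$precision, c(0.8, 0.8))
  expect_equal(m2$per_class$recall, c(0.8, 0.8))
  expect_equal(m2$per_class$specificity, c(0.8, 0.8))
  expect_equal(m2$accuracy, 0.8)
})

test_that("confusion metrics are internally consistent on random matrices", {
  set.seed(351)
  for (k in 1:10) {
    cm <- matrix(rpois(16, 5), 4,
                 dimnames = list(emotion_quadrants(), emotion_quadrants()))
    m <- confusion_metrics(cm)
    expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
    expect_equal(m$per_class$precision, unname(diag(cm) / rowSums(cm)))
    expect_equal(m$per_class$recall, unname(diag(cm) / colSums(cm)))
  }
})

test_that("ROC construction is exact for perfect, reversed and random scores", {
  y <- rep(c("HVHA", "LVLA"), each = 10)
  perfect <- cbind(HVHA = c(10:1, -(1:10)), LVLA = c(-(10:1), 1:10))
  r <- averaged_roc(perfect, y)
  expect_equal(unname(r$auc), c(1, 1))
  reversed <- -perfect
  expect_equal(unname(averaged_roc(reversed, y)$auc), c(0, 0))

  set.seed(361)
  aucs <- replicate(20, {
    sc <- cbind(HVHA = rnorm(200), LVLA = rnorm(200))
    averaged_roc(sc, sample(rep(c("HVHA", "LVLA"), 100)))$mean_auc
  })
  expect_true(all(aucs > 0.4 & aucs < 0.6))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("a class without positives is excluded from the mean AUC", {
  y <- rep("HVHA", 10)
  sc <- cbind(HVHA = rnorm(10), LVLA = rnorm(10))
  expect_message(r <- averaged_roc(sc, y), "lacks positives")
  expect_true(is.na(r$auc[["HVHA"]]) && is.na(r$auc[["LVLA"]]))
})

test_that("significance routing calibrates under the null and detects strong effects", {
  set.seed(371)
  null_p <- replicate(100, {
    channel_significance(replicate(4, rnorm(20), simplify = FALSE))$p.value
  })
  rate <- mean(null_p < 0.05)
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)

  strong <- lapply(0:3, function(mu) rnorm(30, mean = mu, sd = 0.1))
  expect_lt(channel_significance(strong)$p.value, 1e-3)

  # heavy tails break the normality check and route to Kruskal-Wallis
  set.seed(381)
  heavy <- replicate(4, rcauchy(30), simplify = FALSE)
  expect_equal(channel_significance(heavy)$test, "kruskal")

  expect_error(channel_significance(list(rnorm(3))), "2")
  expect_error(channel_significance(list(rnorm(2), rnorm(2))), "at least 3")
})

test_that("region summary counts significant (feature, subject) pairs per channel", {
  chans <- names(channel_regions())
  all_null <- data.frame(channel = rep(chans, 3), p = 1)
  rs <- region_summary(all_null)
  expect_true(all(rs$per_channel$n == 0))

  all_sig <- data.frame(channel = rep(chans, 6), p = 0.01)  # 3 feat x 2 subj
  rs2 <- region_summary(all_sig)
  expect_true(all(rs2$per_channel$n == 6))
  expect_equal(sum(rs2$per_region$n), 6 * length(chans))

  # significance restricted to frontal channels dominates the region count
  frontal <- names(which(channel_regions() == "frontal"))
  mixed <- data.frame(channel = rep(chans, 4),
                      p = ifelse(rep(chans, 4) %in% frontal, 0.001, 0.5))
  rs3 <- region_summary(mixed)
  fr <- rs3$per_region$n[rs3$per_region$region == "frontal"]
  expect_true(all(fr > rs3$per_region$n[rs3$per_region$region != "frontal"]))

  # unmapped channels are dropped with a message
  expect_message(region_summary(data.frame(channel = "XX", p = 0.01)),
                 "unmapped")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(391)
  y <- sample(rep(c("A", "B"), 50))
  s <- rnorm(100) + (y == "A") * 0.8
  ours <- averaged_roc(cbind(A = s, B = -s), y)$auc[["A"]]
  ref <- as.numeric(pROC::auc(pROC::roc(response = y == "A", predictor = s,
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
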