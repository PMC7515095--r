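#' Min-max feature scaling to [-1, 1]
#'
#' Fits the per-column min-max map on the training rows only and applies
#' it to both sets (test values outside the training range extrapolate
#' linearly, no clipping). Columns constant in training map to 0
#' everywhere. Fitting on the training fold only avoids the information
#' leak of joint scaling; `joint = TRUE` reproduces the leaking variant
#' that scales the pooled rows.
#'
#' @param train numeric matrix of training rows.
#' @param test optional numeric matrix of test rows (same columns).
#' @param joint logical; fit the map on the pooled train + test rows.
#' @return List with `train`, `test` (scaled matrices; `test` `NULL` if
#'   not supplied) and the fitted `lo`, `hi` vectors.
#' @export
scale_features <- function(train, test = NULL, joint = FALSE) {
  train <- as.matrix(train)
  fit_on <- if (joint && !is.null(test)) rbind(train, test) else train
  lo <- apply(fit_on, 2, min, na.rm = TRUE)
  hi <- apply(fit_on, 2, max, na.rm = TRUE)
  span <- hi - lo
  map <- function(mm) {
    out <- sweep(sweep(mm, 2, lo), 2, ifelse(span == 0, 1, span), "/")
    out <- 2 * out - 1
    out[, span == 0] <- 0
    out
  }
  list(train = map(train),
       test = if (is.null(test)) NULL else map(as.matrix(test)),
       lo = lo, hi = hi)
}

# Grouped stratified fold assignment: every trial's segments stay in one
# fold; trials are dealt round-robin per class after a seeded shuffle.
make_grouped_folds <- function(groups, y, k, seed = 1) {
  trial_class <- tapply(y, groups, function(v) v[1])
  trials <- names(trial_class)
  fold_of <- integer(length(trials)); names(fold_of) <- trials
  with_local_seed(seed, {
    offset <- 0L
    for (cl in unique(trial_class)) {
      tr <- sample(trials[trial_class == cl])
      fold_of[tr] <- ((seq_along(tr) - 1L + offset) %% k) + 1L
      offset <- offset + length(tr)
    }
  })
  unname(fold_of[groups])
}

# Per-class scores from libsvm pairwise decision values: signed sums of
# the one-vs-one decision values involving each class.
pairwise_to_class_scores <- function(dv, classes) {
  scores <- matrix(0, nrow(dv), length(classes),
                   dimnames = list(NULL, classes))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, cn]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, cn]
  }
  scores
}

#' Per-subject cross-validated RBF-SVM classification
#'
#' Ten-fold (by default) cross-validation with folds grouped by trial --
#' all segments of one trial land in the same fold, preventing train/test
#' leakage -- and stratified by class. Within each training fold the RBF
#' cost and gamma are chosen by an inner grouped grid search, features are
#' min-max scaled to [-1, 1] with the map fitted on the training fold
#' (see [scale_features()]), and a one-versus-one multiclass SVM
#' (libsvm via \pkg{e1071}; `k(k-1)/2` pairwise machines with majority
#' vote) is trained. Test predictions are pooled into the confusion
#' matrix; overall accuracy is the mean of the per-fold accuracies.
#'
#' Rows containing flagged (missing) feature cells are excluded up front
#' with a message. Folds whose training part lacks a class are skipped
#' with a warning.
#'
#' @param fm a `feature_matrix`.
#' @param k_folds number of outer folds (default 10).
#' @param grid list with `cost` and `gamma` candidate vectors (default
#'   `2^seq(-5, 15, 4)` and `2^seq(-15, 3, 4)`).
#' @param seed seed for fold assignment.
#' @param inner_folds folds of the inner parameter search (default 5).
#' @param scaling `"train-only"` (default) or `"joint"`.
#' @return A `cv_result`: per-fold accuracy, pooled confusion matrix
#'   (rows predicted, columns actual), [confusion_metrics()] output,
#'   per-class decision scores, [averaged_roc()] output, chosen
#'   hyperparameters per fold, and fold assignments.
#' @export
crossval_svm <- function(fm, k_folds = 10,
                         grid = list(cost = 2^seq(-5, 15, by = 4),
                                     gamma = 2^seq(-15, 3, by = 4)),
                         seed = 1, inner_folds = 5,
                         scaling = c("train-only", "joint")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- stats::complete.cases(fm$x) & !is.na(fm$y)
  if (any(!keep))
    message(sprintf("crossval_svm: excluding %d row(s) with flagged cells or missing labels",
                    sum(!keep)))
  x <- fm$x[keep, , drop = FALSE]
  y <- fm$y[keep]; groups <- fm$groups[keep]
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (min(table(y)) < 1 || length(y) < k_folds)
    stop("too few samples for the requested folds")
  folds <- make_grouped_folds(groups, y, k_folds, seed)
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(predicted = classes, actual = classes))
  fold_acc <- rep(NA_real_, k_folds)
  chosen <- vector("list", k_folds)
  scores <- matrix(NA_real_, length(y), length(classes),
                   dimnames = list(NULL, classes))
  pred_all <- rep(NA_character_, length(y))
  for (f in seq_len(k_folds)) {
    te <- folds == f; tr <- !te
    if (!any(te)) next
    if (length(unique(y[tr])) < length(classes)) {
      warning(sprintf("fold %d: class missing from training part; fold skipped", f))
      next
    }
    sc <- scale_features(x[tr, , drop = FALSE], x[te, , drop = FALSE],
                         joint = scaling == "joint")
    par <- tune_rbf(sc$train, y[tr], groups[tr], grid, inner_folds,
                    seed + f)
    fit <- e1071::svm(x = sc$train, y = factor(y[tr], levels = classes),
                      kernel = "radial", cost = par$cost,
                      gamma = par$gamma, scale = FALSE)
    pr <- stats::predict(fit, sc$test, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    pred_all[te] <- as.character(pr)
    scores[te, ] <- pairwise_to_class_scores(dv, classes)
    fold_acc[f] <- mean(as.character(pr) == y[te])
    chosen[[f]] <- par
    for (i in which(te)) cm[pred_all[i], y[i]] <- cm[pred_all[i], y[i]] + 1L
  }
  structure(list(
    fold_accuracy = fold_acc,
    accuracy = mean(fold_acc, na.rm = TRUE),
    confusion = cm,
    metrics = confusion_metrics(cm),
    scores = scores, y = y, predicted = pred_all, folds = folds,
    roc = averaged_roc(scores[!is.na(pred_all), , drop = FALSE],
                       y[!is.na(pred_all)]),
    chosen_params = chosen,
    n_excluded = sum(!keep)), class = "cv_result")
}

# Inner grouped grid search maximising mean held-out accuracy.
tune_rbf <- function(x, y, groups, grid, inner_folds, seed) {
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma)
  if (nrow(combos) == 1L)
    return(list(cost = combos$cost[1], gamma = combos$gamma[1]))
  k <- min(inner_folds, length(unique(groups)))
  folds <- make_grouped_folds(groups, y, k, seed)
  classes <- sort(unique(y))
  acc <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    hits <- 0L; tot <- 0L
    for (f in seq_len(k)) {
      te <- folds == f; tr <- !te
      if (!any(te) || length(unique(y[tr])) < length(classes)) next
      fit <- e1071::svm(x = x[tr, , drop = FALSE],
                        y = factor(y[tr], levels = classes),
                        kernel = "radial", cost = combos$cost[ci],
                        gamma = combos$gamma[ci], scale = FALSE)
      pr <- stats::predict(fit, x[te, , drop = FALSE])
      hits <- hits + sum(as.character(pr) == y[te]); tot <- tot + sum(te)
    }
    acc[ci] <- if (tot > 0) hits / tot else 0
  }
  best <- which.max(acc)
  list(cost = combos$cost[best], gamma = combos$gamma[best])
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> accuracy %.2f%% over %d folds; mean AUC %.3f\n",
              100 * x$accuracy, sum(!is.na(x$fold_accuracy)),
              x$roc$mean_auc))
  print(x$confusion)
  invisible(x)
}

#' Confusion-matrix classification metrics
#'
#' For a square count matrix with predicted classes in rows and actual
#' classes in columns: per-class precision (`diag / row sum`), recall /
#' sensitivity (`diag / column sum`), specificity (`TN / (TN + FP)`),
#' unweighted macro averages, and overall accuracy (`trace / total`).
#' A class with an empty row or column reports `NA` for the affected
#' metric rather than 0.
#'
#' @param cm square non-negative integer matrix, predicted x actual.
#' @return List with `per_class` (data frame), `macro` (named vector) and
#'   `accuracy`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  classes <- colnames(cm) %||% as.character(seq_len(ncol(cm)))
  total <- sum(cm); dg <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  precision <- ifelse(rs > 0, dg / rs, NA_real_)
  recall <- ifelse(cs > 0, dg / cs, NA_real_)
  specificity <- vapply(seq_len(ncol(cm)), function(c) {
    tn <- total - rs[c] - cs[c] + dg[c]
    fp <- rs[c] - dg[c]
    if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  }, numeric(1))
  list(per_class = data.frame(class = classes, precision = precision,
                              recall = recall, sensitivity = recall,
                              specificity = specificity,
                              row.names = NULL),
       macro = c(precision = mean(precision, na.rm = TRUE),
                 recall = mean(recall, na.rm = TRUE),
                 specificity = mean(specificity, na.rm = TRUE)),
       accuracy = if (total > 0) sum(dg) / total else NA_real_)
}

#' One-versus-rest ROC curves and averaged AUC
#'
#' Builds a one-versus-rest ROC per class from the per-class decision
#' scores, computes the trapezoidal AUC (rank / Mann-Whitney form, ties
#' handled), and averages the per-class AUCs into the participant AUC.
#' Classes without both positives and negatives are excluded from the
#' mean with a message.
#'
#' @param scores numeric matrix, samples x classes, larger = more
#'   class-like.
#' @param y actual class per row.
#' @return List with `roc` (per-class data frames of `fpr`, `tpr`),
#'   `auc` (named vector) and `mean_auc`.
#' @export
averaged_roc <- function(scores, y) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(y))
  classes <- colnames(scores) %||% as.character(seq_len(ncol(scores)))
  colnames(scores) <- classes
  aucs <- stats::setNames(rep(NA_real_, length(classes)), classes)
  rocs <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    pos <- y == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      message(sprintf("averaged_roc: class %s lacks positives or negatives; excluded", cl))
      next
    }
    s <- scores[, cl]
    r <- rank(s)
    aucs[cl] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(s, decreasing = TRUE)
    tpr <- cumsum(pos[ord]) / n1
    fpr <- cumsum(!pos[ord]) / n0
    last <- !duplicated(s[ord], fromLast = TRUE)  # one point per threshold
    rocs[[cl]] <- data.frame(fpr = c(0, fpr[last]), tpr = c(0, tpr[last]))
  }
  list(roc = rocs, auc = aucs, mean_auc = mean(aucs, na.rm = TRUE))
}
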