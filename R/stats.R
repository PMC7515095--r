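#' Group-difference test with normality-based routing
#'
#' Tests whether a feature differs across groups (for example the four
#' emotion quadrants on one channel). If every group passes a Lilliefors
#' normality check and the groups pass Levene's homogeneity-of-variance
#' check (alpha = 0.05 each), a one-way ANOVA is used; otherwise the
#' Kruskal-Wallis rank test. Groups too small for the Lilliefors test
#' (n < 4) route to Kruskal-Wallis.
#'
#' @param groups list of numeric vectors, at least 2 groups of at least 3
#'   values each.
#' @param alpha significance level of the assumption checks (default
#'   0.05).
#' @return List with `p.value` and `test` (`"anova"` or `"kruskal"`);
#'   `p.value` is `NA` for degenerate input (a zero-variance group makes
#'   the checks undefined, in which case Kruskal-Wallis is still
#'   attempted).
#' @export
channel_significance <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("each group needs at least 3 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  degenerate <- vapply(groups, function(v) var(v) == 0, logical(1))
  parametric <- FALSE
  if (!any(degenerate)) {
    normal_ok <- all(vapply(groups, function(v) {
      if (length(v) < 4) return(FALSE)
      nortest::lillie.test(v)$p.value > alpha
    }, logical(1)))
    if (normal_ok) {
      lev <- car::leveneTest(values ~ g)
      parametric <- lev[["Pr(>F)"]][1] > alpha
    }
  }
  if (parametric) {
    p <- summary(aov(values ~ g))[[1]][["Pr(>F)"]][1]
    list(p.value = p, test = "anova")
  } else {
    p <- tryCatch(kruskal.test(values, g)$p.value,
                  error = function(e) NA_real_)
    list(p.value = p, test = "kruskal")
  }
}

#' Count significant channel effects and summarise by scalp region
#'
#' Given per-(feature, subject, channel) p-values, counts per channel the
#' number of (feature, subject) pairs with `p < alpha` and sums the
#' counts over the five scalp regions (frontal, central, temporal,
#' parietal, occipital). Channels absent from the region map are excluded
#' with a message.
#'
#' @param pvalues data frame with columns `channel` and `p` (one row per
#'   feature x subject x channel test).
#' @param alpha significance threshold, default 0.05.
#' @param regions named character vector channel -> region; default
#'   [channel_regions()].
#' @return List with `per_channel` and `per_region` data frames of counts
#'   `n`.
#' @export
region_summary <- function(pvalues, alpha = 0.05,
                           regions = channel_regions()) {
  stopifnot(all(c("channel", "p") %in% names(pvalues)))
  sig <- !is.na(pvalues$p) & pvalues$p < alpha
  per_channel <- stats::aggregate(
    list(n = sig), by = list(channel = pvalues$channel), FUN = sum)
  unmapped <- setdiff(per_channel$channel, names(regions))
  if (length(unmapped))
    message("region_summary: unmapped channel(s) excluded: ",
            paste(unmapped, collapse = ", "))
  mapped <- per_channel[per_channel$channel %in% names(regions), ]
  per_region <- if (nrow(mapped) == 0) {
    data.frame(region = character(0), n = integer(0))
  } else {
    mapped$region <- regions[mapped$channel]
    stats::aggregate(list(n = mapped$n),
                     by = list(region = mapped$region), FUN = sum)
  }
  list(per_channel = per_channel, per_region = per_region)
}
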