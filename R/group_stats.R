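#' Per-group descriptive summaries of the 14 variables
#'
#' Mean, sample SD, median and range per group and feature, in the layout of
#' a published three-group summary table.  A group with a single eye has an
#' undefined sample SD; it is reported as 0 with `degenerate = TRUE` so that
#' pipelines stay total.
#'
#' @param features data.frame with a `group` column and the 14 feature
#'   columns (extra id columns are ignored).
#' @param feature_cols which columns to summarize (default `feature_names`).
#' @return data.frame with columns `group`, `feature`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`, `degenerate`.
#' @export
summarize_features <- function(features, feature_cols = feature_names) {
  if (!"group" %in% names(features)) stop("features must have a 'group' column")
  feature_cols <- intersect(feature_cols, names(features))
  if (!length(feature_cols)) stop("no feature columns found")
  groups <- unique(as.character(features$group))
  rows <- list()
  for (g in groups) {
    sub <- features[features$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty group: ", g)
    for (f in feature_cols) {
      v <- sub[[f]]
      deg <- length(v) < 2L
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, feature = f, n = length(v),
        mean = mean(v), sd = if (deg) 0 else stats::sd(v),
        median = stats::median(v), min = min(v), max = max(v),
        degenerate = deg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the values against a normal distribution with
#' the sample mean and SD.  Because the parameters are estimated from the
#' same sample, the asymptotic KS p-value is conservative (the Lilliefors
#' caveat); it is reported as such and should be read as an upper bound.
#'
#' @param values numeric vector, n >= 5.
#' @return list with `statistic`, `p_value`, `n`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("need at least 5 values for the KS check")
  res <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = stats::sd(values)))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n = length(values))
}

#' Kruskal-Wallis omnibus test with pairwise post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across all groups (chi-square reference
#' with k-1 df), followed by pairwise Mann-Whitney tests.  Pairwise p-values
#' are unadjusted by default, matching the convention of reporting raw
#' pairwise p-values against 0.05; Holm adjustment is available.
#' When all values are identical the omnibus is degenerate: H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, same length, at least 2 groups with n >= 2.
#' @param adjust `"none"` or `"holm"` for the pairwise p-values.
#' @return list with `H`, `df`, `p_value` and a data.frame `pairwise`
#'   (columns `pair`, `statistic`, `p`, `significant` at 0.05).
#' @export
kruskal_wallis <- function(values, groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  if (length(unique(values)) == 1L) {
    omni <- list(H = 0, df = nlevels(groups) - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
    omni <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
  }
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(p) {
    a <- values[groups == p[1]]; b <- values[groups == p[2]]
    if (length(unique(c(a, b))) == 1L) {
      data.frame(pair = paste(p, collapse = " vs "), statistic = length(a) *
                   length(b) / 2, p = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = TRUE))
      data.frame(pair = paste(p, collapse = " vs "),
                 statistic = unname(wt$statistic), p = wt$p.value)
    }
  }))
  pw$p <- stats::p.adjust(pw$p, method = adjust)
  pw$significant <- pw$p < 0.05
  c(omni, list(pairwise = pw))
}

#' Run the hypothesis-testing layer over all features
#'
#' Applies [ks_normality()] per feature (pooled over groups) and
#' [kruskal_wallis()] per feature across the groups.
#'
#' @inheritParams summarize_features
#' @param adjust pairwise p-value adjustment, see [kruskal_wallis()].
#' @return data.frame with one row per feature and pairwise comparison.
#' @export
test_features <- function(features, feature_cols = feature_names,
                          adjust = "none") {
  feature_cols <- intersect(feature_cols, names(features))
  rows <- lapply(feature_cols, function(f) {
    ks <- ks_normality(features[[f]])
    kw <- kruskal_wallis(features[[f]], features$group, adjust = adjust)
    cbind(data.frame(feature = f, ks_stat = ks$statistic, ks_p = ks$p_value,
                     H = kw$H, H_df = kw$df, H_p = kw$p_value),
          kw$pairwise)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
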