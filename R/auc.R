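#' Empirical AUC by pair counting
#'
#' Mann-Whitney estimate of the area under the ROC curve: the fraction of
#' (diseased, healthy) pairs in which the diseased marker exceeds the
#' healthy one, counting ties as one half (computed via midranks, which is
#' algebraically identical to exhaustive pair counting).  The marker is
#' auto-oriented so that the reported AUC is >= 0.5, with the direction
#' recorded: `orientation = +1` when larger values indicate disease, `-1`
#' when smaller values do.
#'
#' @param scores numeric marker values.
#' @param labels disease indicator (logical, or coercible 0/1).
#' @return an `"auc_result"`: `auc`, `orientation`, `n_pos`, `n_neg`
#'   (`se`/`ci95` are `NA` until a variance method is applied, see
#'   [clustered_auc_ci()]).
#' @export
empirical_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute an AUC")
  a <- auc_raw(scores, labels)
  orientation <- if (a >= 0.5) 1L else -1L
  structure(list(auc = if (a >= 0.5) a else 1 - a,
                 se = NA_real_, ci95 = c(NA_real_, NA_real_),
                 ci95_untruncated = c(NA_real_, NA_real_),
                 orientation = orientation,
                 n_pos = n_pos, n_neg = n_neg, n_clusters = NA_integer_),
            class = "auc_result")
}

# Unoriented Mann-Whitney AUC: P(pos > neg) + 0.5 P(pos == neg).
auc_raw <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n_pos <- as.numeric(sum(labels)); n_neg <- as.numeric(sum(!labels))
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f", x$auc))
  if (is.finite(x$se))
    cat(sprintf(" (SE %.3f, 95%% CI %.3f-%.3f)", x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf(" [orientation %+d, %d pos / %d neg", x$orientation,
              x$n_pos, x$n_neg))
  if (is.finite(x$n_clusters)) cat(sprintf(", %d clusters", x$n_clusters))
  cat("]\n")
  invisible(x)
}

#' Cluster-adjusted AUC confidence interval
#'
#' AUC point estimate as in [empirical_auc()], with a standard error that
#' respects the pairing of eyes within patients: a leave-one-cluster-out
#' jackknife over patients.  The 95 percent CI is the Wald interval
#' `auc +/- 1.96 SE`; the truncated-to-`[0, 1]` form is returned as `ci95`
#' and the raw Wald interval (which can exceed 1, as Wald intervals for
#' AUCs near 1 do) as `ci95_untruncated`.  A leave-one-out replicate that
#' loses one class entirely is dropped from the jackknife.
#'
#' @inheritParams empirical_auc
#' @param cluster_ids patient identifier per observation; observations
#'   sharing an id are treated as correlated.
#' @return an `"auc_result"` with `se`, `ci95`, `ci95_untruncated` filled in.
#' @export
clustered_auc_ci <- function(scores, labels, cluster_ids) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels),
            length(cluster_ids) == length(labels))
  cluster_ids <- as.character(cluster_ids)
  clusters <- unique(cluster_ids)
  m <- length(clusters)
  if (m < 2L) stop("variance undefined with a single cluster")
  res <- empirical_auc(scores, labels)
  theta <- vapply(clusters, function(cl) {
    keep <- cluster_ids != cl
    if (sum(labels[keep]) == 0L || sum(!labels[keep]) == 0L) return(NA_real_)
    auc_raw(scores[keep], labels[keep])
  }, numeric(1))
  theta <- theta[is.finite(theta)]
  mj <- length(theta)
  if (mj < 2L) stop("too few informative clusters for a jackknife variance")
  se <- sqrt((mj - 1) / mj * sum((theta - mean(theta))^2))
  ci <- res$auc + c(-1, 1) * 1.96 * se
  res$se <- se
  res$ci95_untruncated <- ci
  res$ci95 <- pmin(pmax(ci, 0), 1)
  res$n_clusters <- m
  res
}

#' Analytic AUC of a binormal marker
#'
#' For a marker normally distributed in each class, the AUC equals
#' `Phi(|mu_pos - mu_neg| / sqrt(sd_pos^2 + sd_neg^2))`.  Used as an
#' analytic oracle for calibration and large-sample checks.
#'
#' @param mu_pos,sd_pos diseased-class mean and SD.
#' @param mu_neg,sd_neg healthy-class mean and SD.
#' @return AUC in `[0.5, 1]`.
#' @export
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  if (sd_pos <= 0 || sd_neg <= 0) stop("class SDs must be > 0")
  stats::pnorm(abs(mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' ROC curve points
#'
#' Empirical ROC curve (false positive rate, true positive rate) of an
#' oriented marker, one point per distinct threshold, for plotting and
#' export.
#'
#' @inheritParams empirical_auc
#' @param orientation `+1` if larger values indicate disease; `NULL` to
#'   auto-orient as in [empirical_auc()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, orientation = NULL) {
  labels <- as.logical(labels)
  if (is.null(orientation))
    orientation <- empirical_auc(scores, labels)$orientation
  s <- orientation * scores
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  data.frame(threshold = orientation * thr,
             fpr = vapply(thr, function(t) mean(s[!labels] >= t), numeric(1)),
             tpr = vapply(thr, function(t) mean(s[labels] >= t), numeric(1)))
}
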