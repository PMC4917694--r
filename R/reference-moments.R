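#' Published group moments of the 14 map variables
#'
#' Per-group summary statistics (mean, SD, median, range) of the 14
#' pachymetry/epithelial variables reported for the three study groups:
#' 104 normal eyes of healthy subjects, and the 22 keratoconic plus 22
#' topographically normal fellow eyes of 22 patients with asymmetric
#' keratoconus.  These moments are the calibration target of the map
#' generator and the parameter source of [feature_sample()].
#'
#' @param group optionally restrict to one of `"normal"`, `"keratoconic"`,
#'   `"fellow"`.
#' @return a `data.frame` with columns `group`, `feature`, `mean`, `sd`,
#'   `median`, `min`, `max`, `n`.
#' @export
reference_moments <- function(group = NULL) {
  f <- feature_names
  tab <- rbind(
    data.frame(group = "normal", feature = f, n = 104,
      mean   = c(17.39, 531.7, -20.50, 8.519, -155.9, -53.42, 537.6,
                 52.03, 53.38, 49.52, 56, -6.423, 1.549, 52.90),
      sd     = c(12.92, 30.17, 5.06, 12.70, 398.43, 11.81, 30.66,
                 3.27, 3.10, 3.73, 3.55, 3.04, 0.75, 3.09),
      median = c(17, 532, -20, 9, -141, -52, 538,
                 52, 53, 50, 56, -6, 1.40, 53),
      min    = c(-24, 454, -47, -40, -137, -97, 459,
                 37, 46, 33, 48, -25, 0.6, 42),
      max    = c(54, 592, -8, 48, 607, -26, 598,
                 60, 62, 57, 69, -2, 4.9, 61)),
    data.frame(group = "fellow", feature = f, n = 22,
      mean   = c(24.50, 503.2, -22.36, 15.950, -558.6, -57.50, 513.1,
                 53.27, 53.14, 49.09, 56.86, -7.818, 1.891, 52),
      sd     = c(20.05, 32.71, 9.42, 17.35, 591.70, 18.80, 31.90,
                 4.25, 4.50, 4.74, 4.52, 3.89, 0.99, 4.07),
      median = c(20, 499.5, -20.5, 15, -610, -52.5, 512.5,
                 52, 52.5, 49, 56.5, -6, 1.50, 53.23),
      min    = c(-1, 447, -48, -19, -1809, -103, 453,
                 48, 47, 37, 52, -20, 0.7, 49),
      max    = c(68, 597, -13, 48, 513, -37, 605,
                 67, 70, 64, 73, -3, 4.7, 68)),
    data.frame(group = "keratoconic", feature = f, n = 22,
      mean   = c(56.95, 458.0, -54.27, 44.770, -947.5, -114.60, 482.9,
                 55.55, 50.82, 41.18, 63.36, -22.090, 5.918, 48.59),
      sd     = c(28.49, 45.14, 23.72, 35.25, 549.53, 51.96, 30.62,
                 6.36, 5.86, 6.45, 8.45, 10.80, 3.19, 5.71),
      median = c(55, 451.5, -51, 41, -834, -99, 479,
                 55, 49.5, 42, 62, -20, 5.55, 47.5),
      min    = c(12, 380, -101, -38, -2369, -227, 416,
                 40, 41, 33, 47, -44, 1.7, 39),
      max    = c(114, 589, -14, 115, -206, -44, 536,
                 67, 64, 56, 80, -7, 13.8, 61)))
  rownames(tab) <- NULL
  if (!is.null(group)) {
    group <- match.arg(group, c("normal", "keratoconic", "fellow"))
    tab <- tab[tab$group == group, ]
  }
  tab[, c("group", "feature", "mean", "sd", "median", "min", "max", "n")]
}

#' Fast feature-level sampler from the published group moments
#'
#' Draws rows of the 14 variables directly from a multivariate normal with
#' the group's published means and SDs, bypassing map synthesis.  Useful for
#' statistical machinery tests and for large-sample ROC experiments where
#' only the marginal feature distributions matter.  Features are independent
#' unless a 14 x 14 correlation matrix is supplied.
#'
#' @param group `"normal"`, `"keratoconic"` or `"fellow"`.
#' @param n number of eyes to draw (0 gives an empty, correctly named table).
#' @param corr optional 14 x 14 positive semi-definite correlation matrix.
#' @return a `data.frame` of `n` rows with the 14 feature columns.
#' @export
feature_sample <- function(group, n, corr = NULL) {
  group <- match.arg(group, c("normal", "keratoconic", "fellow"))
  n <- as.integer(n)
  stopifnot(n >= 0)
  mom <- reference_moments(group)
  mom <- mom[match(feature_names, mom$feature), ]
  p <- length(feature_names)
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, p))
    names(out) <- feature_names
    return(out)
  }
  if (is.null(corr)) {
    draws <- matrix(stats::rnorm(n * p), n, p)
    draws <- sweep(sweep(draws, 2, mom$sd, "*"), 2, mom$mean, "+")
  } else {
    corr <- as.matrix(corr)
    if (!isTRUE(all.equal(dim(corr), c(p, p))))
      stop("corr must be ", p, " x ", p)
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("corr is not positive semi-definite")
    sigma <- diag(mom$sd) %*% corr %*% diag(mom$sd)
    draws <- MASS::mvrnorm(n, mu = mom$mean, Sigma = sigma)
    if (n == 1L) draws <- matrix(draws, 1)
  }
  out <- as.data.frame(draws)
  names(out) <- feature_names
  out
}
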