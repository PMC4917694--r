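#' Spline-based probability transform of a diagnostic marker
#'
#' Fits a penalized B-spline logistic regression (P-spline smooth with a
#' second-order difference penalty, estimated by penalized iteratively
#' reweighted least squares) of disease status on the marker, and returns
#' the fitted probability as a transformed marker.  For a marker whose
#' relationship with disease is not monotone, ranking eyes by this
#' estimated disease probability recovers the discrimination that the raw
#' marker hides.  The smoothing parameter is chosen by generalized
#' cross-validation unless `sp` (a fixed smoothing parameter) or `fixed_df`
#' (an unpenalized fit at that basis dimension) is given.  In the heavy
#' smoothing limit the second-order penalty shrinks the smooth to a linear
#' logistic fit.
#'
#' @param marker numeric marker values (n >= 20).
#' @param labels disease indicator.
#' @param k basis dimension of the P-spline (default 10).
#' @param sp optional fixed smoothing parameter (e.g. `1e6` for the
#'   near-linear limit).
#' @param fixed_df optional integer: fit an unpenalized spline with this
#'   basis dimension instead of GCV smoothing.
#' @return a `"marker_transform"`: the fitted mgcv model, a `transform`
#'   function mapping marker values to probabilities in `[0, 1]`, the basis
#'   spec and effective degrees of freedom.
#' @export
gam_transform <- function(marker, labels, k = 10, sp = NULL, fixed_df = NULL) {
  labels <- as.logical(labels)
  stopifnot(length(marker) == length(labels))
  if (length(marker) < 20L) stop("need n >= 20 to fit the probability transform")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  dat <- data.frame(x = marker, y = as.integer(labels))
  form <- if (!is.null(fixed_df))
    stats::as.formula(sprintf("y ~ s(x, bs = 'ps', k = %d, m = c(2, 2), fx = TRUE)",
                              as.integer(fixed_df)))
  else
    stats::as.formula(sprintf("y ~ s(x, bs = 'ps', k = %d, m = c(2, 2))",
                              as.integer(k)))
  fit <- tryCatch(
    mgcv::gam(form, family = stats::binomial(), data = dat,
              sp = sp, scale = -1, control = mgcv::gam.control(maxit = 100)),
    error = function(e) stop("probability-transform fit failed: ",
                             conditionMessage(e), call. = FALSE))
  if (!fit$converged)
    stop("penalized IRLS did not converge within 100 iterations (deviance ",
         signif(fit$deviance, 6), ")")
  # (quasi-)separation: fitted probabilities pinned to 0/1 -> refit with a
  # heavy roughness penalty, which acts as ridge stabilization on the smooth
  eps <- 1e-8
  if (is.null(sp) && all(fit$fitted.values < eps | fit$fitted.values > 1 - eps)) {
    warning("marker separates the classes; using a heavily penalized ",
            "(ridge-stabilized) fit")
    fit <- mgcv::gam(form, family = stats::binomial(), data = dat, sp = 1e4)
  }
  transform <- function(x) {
    as.numeric(stats::predict(fit, newdata = data.frame(x = x),
                              type = "response"))
  }
  structure(list(fit = fit, transform = transform, k = k,
                 sp = fit$sp, edf = sum(fit$edf),
                 coefficients = stats::coef(fit),
                 range = range(marker)),
            class = "marker_transform")
}

#' @export
print.marker_transform <- function(x, ...) {
  cat(sprintf("<marker_transform> P-spline logistic, k = %d, edf = %.2f\n",
              x$k, x$edf))
  invisible(x)
}

#' @export
predict.marker_transform <- function(object, newdata, ...) {
  object$transform(newdata)
}

#' Monotonicity check of a marker-disease relationship
#'
#' Decides whether the smooth estimated disease probability is monotone in
#' the marker over its observed range: the fitted transform
#' ([gam_transform()] at default smoothing) is evaluated on a fine grid and
#' declared monotone when all non-negligible slopes share one sign (slopes
#' below `tol` times the maximum absolute slope are treated as flat).
#' A constant marker carries no directional information and is returned as
#' monotone with `degenerate = TRUE`.
#'
#' @inheritParams gam_transform
#' @param tol relative slope tolerance band (default 0.05).
#' @return list with `monotone`, `degenerate`, `direction` (+1 increasing,
#'   -1 decreasing, 0 flat) and the fitted `transform`.
#' @export
monotonicity_check <- function(marker, labels, k = 10, tol = 0.05) {
  if (length(marker) < 20L) stop("need n >= 20 for the monotonicity check")
  if (stats::var(marker) == 0)
    return(list(monotone = TRUE, degenerate = TRUE, direction = 0L,
                transform = NULL))
  tr <- gam_transform(marker, labels, k = k)
  grid <- seq(min(marker), max(marker), length.out = 201)
  p <- tr$transform(grid)
  slopes <- diff(p)
  band <- tol * max(abs(slopes))
  signs <- unique(sign(slopes[abs(slopes) > band]))
  monotone <- length(signs) <= 1L
  list(monotone = monotone, degenerate = FALSE,
       direction = if (length(signs) == 1L) as.integer(signs) else 0L,
       transform = tr)
}

#' Logistic multi-marker combination
#'
#' Maximum-likelihood logistic regression (IRLS) of disease status on a set
#' of features; the fitted linear predictor is the combined marker.  The
#' in-sample AUC of the combination is computed with [empirical_auc()], or
#' with the cluster-adjusted CI of [clustered_auc_ci()] when patient ids
#' are supplied.  Complete separation is stabilized by a small ridge
#' penalty (with a warning); rank-deficient design matrices are rejected
#' with the collinear columns named.
#'
#' @param features data.frame of marker columns (no constant columns).
#' @param labels disease indicator.
#' @param cluster_ids optional patient ids for the cluster-adjusted CI.
#' @param ridge ridge penalty used only in the separation fallback.
#' @return a `"combined_model"`: coefficients, linear predictor, AUC result,
#'   convergence diagnostics and a `predict` closure.
#' @export
glm_combine <- function(features, labels, cluster_ids = NULL, ridge = 1e-3) {
  labels <- as.logical(labels)
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels))
  if (nrow(features) <= ncol(features) + 1L)
    stop("need more observations than features + 1")
  const <- vapply(features, function(v) stats::var(as.numeric(v)) == 0, logical(1))
  if (any(const)) stop("constant feature column(s): ",
                       paste(names(features)[const], collapse = ", "))
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  y <- as.integer(labels)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  separated <- sep_warn || !fit$converged
  if (separated) {
    warning("separation detected; refitting with a ridge-stabilized IRLS")
    fit <- ridge_logistic(X, y, lambda = ridge)
  }
  beta <- stats::coef(fit)
  eta <- as.numeric(X %*% beta)
  auc <- if (is.null(cluster_ids)) empirical_auc(eta, labels)
         else clustered_auc_ci(eta, labels, cluster_ids)
  structure(list(features = names(features), coefficients = beta,
                 linear_predictor = eta, auc = auc,
                 converged = fit$converged, separated = separated,
                 predict = function(newdata) {
                   Xn <- cbind(1, as.matrix(newdata[, names(features), drop = FALSE]))
                   stats::plogis(as.numeric(Xn %*% beta))
                 }),
            class = "combined_model")
}

# Minimal ridge-penalized logistic IRLS (intercept unpenalized); used only
# as the separation fallback of glm_combine.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100L, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- as.numeric(beta_new); names(beta) <- colnames(X)
      return(list(coefficients = beta, converged = TRUE, iterations = it))
    }
    beta <- as.numeric(beta_new)
  }
  names(beta) <- colnames(X)
  list(coefficients = beta, converged = FALSE, iterations = maxit)
}

#' @export
print.combined_model <- function(x, ...) {
  cat("<combined_model> logistic combination of:",
      paste(x$features, collapse = ", "), "\n")
  print(x$auc)
  invisible(x)
}

#' Single-variable diagnostic accuracy table
#'
#' For each feature, checks monotonicity of its relationship with disease,
#' applies the probability transform when it is non-monotone, and computes
#' the cluster-adjusted AUC.
#'
#' @param features data.frame with id columns and feature columns.
#' @param labels disease indicator per row.
#' @param cluster_ids patient ids per row.
#' @param feature_cols which features to evaluate.
#' @param transform_nonmonotone apply [gam_transform()] when the
#'   monotonicity check fails (default TRUE).
#' @return data.frame: feature, auc, se, ci_low, ci_high (truncated),
#'   ci_low_raw, ci_high_raw, orientation, transformed.
#' @export
auc_table <- function(features, labels, cluster_ids,
                      feature_cols = feature_names,
                      transform_nonmonotone = TRUE) {
  feature_cols <- intersect(feature_cols, names(features))
  rows <- lapply(feature_cols, function(f) {
    x <- features[[f]]
    transformed <- FALSE
    if (transform_nonmonotone && length(x) >= 20L && stats::var(x) > 0) {
      mc <- monotonicity_check(x, labels)
      if (!mc$monotone) {
        x <- mc$transform$transform(x)
        transformed <- TRUE
      }
    }
    a <- clustered_auc_ci(x, labels, cluster_ids)
    data.frame(feature = f, auc = a$auc, se = a$se,
               ci_low = a$ci95[1], ci_high = a$ci95[2],
               ci_low_raw = a$ci95_untruncated[1],
               ci_high_raw = a$ci95_untruncated[2],
               orientation = a$orientation, transformed = transformed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
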