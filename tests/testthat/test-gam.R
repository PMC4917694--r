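# Simulated designs with known truth for the probability transform.
monotone_design <- function(n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x))
  list(x = x, y = y)
}

ushaped_design <- function(n, seed) {
  # disease risk at both extremes of the marker
  set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(3 * (abs(x) - 0.8)))
  list(x = x, y = y)
}

test_that("transforming a monotone marker preserves its AUC", {
  d <- monotone_design(300, 1)
  tr <- gam_transform(d$x, d$y)
  expect_true(all(tr$transform(d$x) >= 0 & tr$transform(d$x) <= 1))
  a_raw <- empirical_auc(d$x, d$y)$auc
  a_tr <- empirical_auc(tr$transform(d$x), d$y)$auc
  expect_equal(a_tr, a_raw, tolerance = 1e-6)
})

test_that("the transform recovers discrimination hidden by a U-shape", {
  d <- ushaped_design(400, 2)
  a_raw <- empirical_auc(d$x, d$y)$auc
  tr <- gam_transform(d$x, d$y)
  a_tr <- empirical_auc(tr$transform(d$x), d$y)$auc
  expect_gte(a_tr, a_raw + 0.1)
})

test_that("heavy smoothing collapses to the plain logistic fit", {
  d <- monotone_design(250, 3)
  tr <- gam_transform(d$x, d$y, sp = 1e8)
  glm_fit <- glm(d$y ~ d$x, family = binomial())
  p_gam <- tr$transform(d$x)
  p_glm <- fitted(glm_fit)
  expect_lt(max(abs(p_gam - p_glm)), 0.01)
})

test_that("transform is reproducible from its stored fit", {
  d <- monotone_design(120, 4)
  tr <- gam_transform(d$x, d$y)
  grid <- seq(-2, 2, length.out = 11)
  expect_identical(tr$transform(grid), predict(tr, grid))
  expect_equal(tr$transform(grid), tr$transform(grid))
})

test_that("monotonicity check classifies known shapes", {
  d <- monotone_design(200, 5)
  expect_true(monotonicity_check(d$x, d$y)$monotone)
  u <- ushaped_design(200, 6)
  expect_false(monotonicity_check(u$x, u$y)$monotone)
  const <- monotonicity_check(rep(1, 50), rbinom(50, 1, 0.5))
  expect_true(const$degenerate)
  expect_error(monotonicity_check(rnorm(10), rbinom(10, 1, 0.5)), "n >= 20")
})

test_that("U-shapes are detected reliably across replicates", {
  hits <- vapply(1:50, function(i) {
    u <- ushaped_design(150, 100 + i)
    !monotonicity_check(u$x, u$y)$monotone
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("logistic combination of one feature preserves that feature's AUC", {
  set.seed(7)
  x <- rnorm(100); y <- rbinom(100, 1, plogis(x))
  if (!any(y)) y[1] <- 1
  cm <- glm_combine(data.frame(x = x), y)
  expect_equal(cm$auc$auc, empirical_auc(x, y)$auc, tolerance = 1e-12)
})

test_that("two informative independent features combine to a higher AUC", {
  set.seed(8)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  f1 <- rnorm(n, y * 1.0); f2 <- rnorm(n, y * 1.0)
  cm <- glm_combine(data.frame(f1 = f1, f2 = f2), y)
  singles <- c(empirical_auc(f1, y)$auc, empirical_auc(f2, y)$auc)
  expect_gte(cm$auc$auc, max(singles))
})

test_that("the published three-variable combination beats its components", {
  set.seed(9)
  kc <- feature_sample("keratoconic", 500)
  nl <- feature_sample("normal", 500)
  vars <- c("Min_Med", "S_I", "Min_ep")
  df <- rbind(kc[, vars], nl[, vars])
  y <- rep(c(1, 0), each = 500)
  cm <- glm_combine(df, y)
  singles <- vapply(vars, function(v) empirical_auc(df[[v]], y)$auc,
                    numeric(1))
  expect_gt(cm$auc$auc, max(singles))
})

test_that("degenerate designs are rejected with informative errors", {
  set.seed(10)
  x <- rnorm(50); y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  expect_error(glm_combine(data.frame(a = x, b = rep(2, 50)), y), "constant")
  expect_error(glm_combine(data.frame(a = x, b = 2 * x), y), "collinear.*b")
  expect_error(glm_combine(data.frame(a = x[1:2]), y[1:2]), "observations")
})

test_that("complete separation falls back to a ridge-stabilized fit", {
  x <- c(rnorm(30, -3), rnorm(30, 3))
  y <- rep(c(0, 1), each = 30)
  expect_warning(cm <- glm_combine(data.frame(x = x), y), "ridge")
  expect_true(cm$separated)
  expect_true(all(is.finite(cm$coefficients)))
  expect_equal(cm$auc$auc, 1)
  p <- cm$predict(data.frame(x = c(-5, 5)))
  expect_true(all(p > 0 & p < 1))
})

test_that("cluster ids propagate into the combined model's CI", {
  set.seed(11)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- rnorm(n, y)
  cm <- glm_combine(data.frame(x = x), y, cluster_ids = rep(1:(n / 2), 2))
  expect_true(is.finite(cm$auc$se))
  expect_equal(cm$auc$n_clusters, n / 2)
})
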