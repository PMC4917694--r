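test_that("AUC trivial cases: separation, pure ties, known pair count", {
  expect_equal(empirical_auc(c(1, 2, 3, 7, 8, 9), rep(c(FALSE, TRUE), each = 3))$auc, 1)
  expect_equal(empirical_auc(rep(5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  # pos {1,2,3}, neg {2,3,4}: 9 pairs enumerated by hand -> 2 wins + 2 ties
  r <- empirical_auc(c(1, 2, 3, 2, 3, 4), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 1 - (1 + 0.5 * 2) / 9)  # oriented above 0.5
  expect_equal(r$orientation, -1L)
  expect_error(empirical_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("rank formula equals exhaustive pair counting on random instances", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    scores <- sample(round(rnorm(n, 0, 2), 1))  # rounded -> ties occur
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    a <- kcmaps:::auc_raw(scores, labels)
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(12)
  scores <- rnorm(80); labels <- rbinom(80, 1, plogis(scores))
  if (!any(labels)) labels[1] <- 1
  a0 <- empirical_auc(scores, labels)$auc
  for (f in list(function(x) 3 * x - 7, exp, function(x) atan(x) + x^3 / 50))
    expect_equal(empirical_auc(f(scores), labels)$auc, a0, tolerance = 1e-12)
})

test_that("singleton clusters reduce to the ordinary delete-one jackknife", {
  set.seed(6)
  scores <- rnorm(30); labels <- rep(c(TRUE, FALSE), 15)
  res <- clustered_auc_ci(scores, labels, cluster_ids = seq_along(scores))
  theta <- vapply(seq_along(scores), function(i) {
    kcmaps:::auc_raw(scores[-i], labels[-i])
  }, numeric(1))
  m <- length(theta)
  expect_equal(res$se, sqrt((m - 1) / m * sum((theta - mean(theta))^2)),
               tolerance = 1e-12)
  expect_true(res$ci95[1] <= res$auc && res$auc <= res$ci95[2])
})

test_that("ignoring real clustering understates the AUC standard error", {
  # duplicated observations: once sharing a cluster, once split apart
  set.seed(30)
  base_s <- rnorm(20); base_l <- rep(c(TRUE, FALSE), 10)
  scores <- rep(base_s, each = 2); labels <- rep(base_l, each = 2)
  shared <- clustered_auc_ci(scores, labels, rep(1:20, each = 2))
  split <- clustered_auc_ci(scores, labels, 1:40)
  expect_gte(shared$se, split$se)
  expect_error(clustered_auc_ci(base_s, base_l, rep(1, 20)), "single cluster")
})

test_that("binormal AUC matches the closed form and the quadrature oracle", {
  expect_equal(binormal_auc(5, 2, 5, 3), 0.5)
  expect_equal(binormal_auc(1 + sqrt(8), 2, 1, 2), pnorm(1))
  # published Min moments, fellow (diseased) vs normal
  expect_equal(binormal_auc(503.2, 32.71, 531.7, 30.17),
               1 - oracle_binormal_quad(503.2, 32.71, 531.7, 30.17),
               tolerance = 1e-6)
  expect_error(binormal_auc(1, 0, 0, 1), "SDs")
})

test_that("binormal and empirical AUC agree on large samples", {
  set.seed(55)
  pos <- rnorm(1e5, 503.2, 32.71); neg <- rnorm(1e5, 531.7, 30.17)
  emp <- empirical_auc(c(pos, neg), rep(c(TRUE, FALSE), each = 1e5))$auc
  expect_equal(emp, binormal_auc(503.2, 32.71, 531.7, 30.17),
               tolerance = 0.005)
})

test_that("AUC agrees with an independent ROC implementation", {
  library(pROC)
  set.seed(20)
  scores <- rnorm(60); labels <- rbinom(60, 1, plogis(2 * scores))
  a <- empirical_auc(scores, labels)$auc
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("roc_points trace the empirical curve with trapezoid area = AUC", {
  set.seed(44)
  scores <- round(rnorm(40), 1); labels <- rbinom(40, 1, 0.4)
  labels[1:2] <- c(0, 1)
  pts <- roc_points(scores, labels)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  area <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(area, empirical_auc(scores, labels)$auc, tolerance = 1e-12)
})
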