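flat_profile <- function() {
  list(T0 = 540, k = 0, g = 0, h = 0, pnoise_amp = 0,
       E0 = 52, s = 0, ek = 0, enoise_amp = 0,
       K0 = 43, astig = 0, astig_axis = 0, steep_per_um = 0)
}

test_that("a degenerate cone with zero noise yields a uniform map", {
  eye <- generate_eye(flat_profile(), cone_params(depth = 0),
                      polar_grid(16, 32))
  expect_true(all(eye$pachymetry$values == 540))
  expect_equal(eye$pachymetry$center_value, 540)
  expect_true(all(eye$epithelium$values == 52))
})

test_that("cone parameter validation rejects impossible shapes", {
  expect_error(cone_params(depth = -1), "depth")
  expect_error(cone_params(width = 0), "width")
  expect_error(cone_params(epi_thinning = -2), "epi_thinning")
})

test_that("physically impossible calibrations are rejected with a clear error", {
  p <- flat_profile()
  cone <- cone_params(depth = 400, width = 1)  # drives pachymetry below 300 um
  expect_error(generate_eye(p, cone, polar_grid(16, 32)),
               "calibration rejected.*pachymetry.*depth")
})

test_that("cohort structure matches the study design", {
  spec <- cohort_spec(n_normal_subjects = 8, n_asym_kc_subjects = 5,
                      seed = 11, grid = polar_grid(16, 32))
  eyes <- generate_cohort(spec)
  expect_length(eyes, 2 * (8 + 5))
  groups <- vapply(eyes, `[[`, "", "group")
  pids <- vapply(eyes, `[[`, "", "patient_id")
  expect_equal(sum(groups == "normal"), 16)
  expect_equal(sum(groups == "keratoconic"), 5)
  expect_equal(sum(groups == "fellow"), 5)
  # every fellow eye's patient owns exactly one keratoconic eye,
  # and normal patients own none
  for (i in which(groups == "fellow"))
    expect_equal(sum(pids == pids[i] & groups == "keratoconic"), 1)
  for (i in which(groups == "normal"))
    expect_equal(sum(pids == pids[i] & groups == "keratoconic"), 0)
  # two eyes (one OD, one OS) per patient
  expect_true(all(table(pids) == 2))
})

test_that("cohorts are byte-identical under an identical spec", {
  spec <- cohort_spec(3, 2, seed = 99, grid = polar_grid(16, 32))
  f1 <- extract_features(generate_cohort(spec))
  f2 <- extract_features(generate_cohort(spec))
  expect_identical(f1, f2)
  f3 <- extract_features(generate_cohort(cohort_spec(3, 2, seed = 100,
                                                     grid = polar_grid(16, 32))))
  expect_false(identical(f1, f3))
})

test_that("intra-patient correlation of Min rises with rho", {
  # sample within-patient correlation vs a near-independent cohort
  corr_at <- function(rho, seed) {
    spec <- cohort_spec(n_normal_subjects = 200, n_asym_kc_subjects = 1,
                        seed = seed, rho = rho, grid = polar_grid(12, 24))
    ft <- extract_features(generate_cohort(spec))
    ft <- ft[ft$group == "normal", ]
    wide <- merge(ft[ft$side == "OD", c("patient_id", "Min")],
                  ft[ft$side == "OS", c("patient_id", "Min")],
                  by = "patient_id")
    cor(wide$Min.x, wide$Min.y)
  }
  expect_gt(corr_at(0.9, 21), corr_at(0.0, 21) + 0.15)
})

test_that("cohort spec validation fails before any simulation", {
  expect_error(cohort_spec(0, 22), "counts")
  expect_error(cohort_spec(52, 22, rho = 1.2), "rho")
  expect_error(cohort_spec(52, 22, calibration = list(normal = list())),
               "three groups")
})

test_that("feature_sample reproduces the published moments", {
  set.seed(123)
  fs <- feature_sample("normal", 1e5)
  expect_equal(mean(fs$Min), 531.7, tolerance = 0.005)
  expect_equal(sd(fs$Min), 30.17, tolerance = 0.02)
  expect_equal(mean(fs$SD), 1.549, tolerance = 0.02)
})

test_that("feature_sample handles empty and correlated draws", {
  empty <- feature_sample("fellow", 0)
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), feature_names)
  bad <- diag(14); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(feature_sample("normal", 10, corr = bad), "semi-definite")
  # identity correlation and independent draws agree in their moments
  set.seed(5); a <- feature_sample("keratoconic", 2e4)
  set.seed(5); b <- feature_sample("keratoconic", 2e4, corr = diag(14))
  expect_equal(colMeans(a), colMeans(b), tolerance = 0.02)
  expect_equal(vapply(a, sd, numeric(1)), vapply(b, sd, numeric(1)),
               tolerance = 0.03)
})
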