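test_that("constant maps give the degenerate feature values", {
  pach <- analytic_map(f = function(x, y) 540 + 0 * x)
  pf <- pachymetry_features(pach)
  expect_equal(pf[["SN_IT"]], 0)
  expect_equal(pf[["Min"]], 540)
  expect_equal(pf[["Min_Med"]], 0)
  expect_equal(pf[["S_I"]], 0)
  expect_equal(pf[["Min_Max"]], 0)
  expect_equal(pf[["CCT"]], 540)
  epi <- analytic_map(tag = "epithelium", f = function(x, y) 52 + 0 * x)
  ef <- epithelial_features(epi)
  expect_equal(unname(ef[c("Sup", "Inf_ep", "Min_ep", "Max", "CET")]),
               rep(52, 5))
  expect_equal(ef[["Min_Max_ep"]], 0)
  expect_equal(ef[["SD"]], 0)
})

test_that("extremes, median and SD match the exhaustive scan oracles", {
  for (seed in c(2, 9)) {
    m <- random_map(seed, 8, 8)
    pf <- pachymetry_features(m)
    ex <- oracle_extremes(m)
    pts <- kcmaps:::map_points(m, zone_geometry())
    expect_equal(pf[["Min"]], ex$min$v)
    expect_equal(pf[["Min_Max"]], ex$min$v - ex$max$v)
    expect_equal(pf[["Min_Med"]],
                 ex$min$v - oracle_weighted_median(pts$value, pts$weight))
    expect_equal(pf[["Y_location"]],
                 1000 * ex$min$r * sin(ex$min$a * pi / 180), tolerance = 1e-9)
    e <- random_map(seed + 50, 8, 8, tag = "epithelium")
    ef <- epithelial_features(e)
    pts_e <- kcmaps:::map_points(e, zone_geometry())
    expect_equal(ef[["SD"]], oracle_weighted_sd(pts_e$value, pts_e$weight))
  }
})

test_that("hand-placed minimum is located with the deterministic tie-break", {
  g <- polar_grid(8, 8)
  vals <- matrix(540, 8, 8)
  ai <- which(g$angles == 270)
  vals[5, ai] <- 500   # unique minimum, inferior meridian
  m <- thickness_map(vals, 540, g, "pachymetry")
  pf <- pachymetry_features(m)
  expect_equal(pf[["Min"]], 500)
  expect_equal(pf[["Y_location"]], -1000 * g$radii[5], tolerance = 1e-9)
  # tie: same value also placed further out -> inner point wins
  vals[7, ai] <- 500
  m2 <- thickness_map(vals, 540, g, "pachymetry")
  expect_equal(pachymetry_features(m2)[["Y_location"]], -1000 * g$radii[5],
               tolerance = 1e-9)
})

test_that("pure-cone arg-min sits at the grid point nearest the apex", {
  g <- polar_grid(64, 128)
  r <- matrix(g$radii, 64, 128)
  th <- matrix(g$angles, 64, 128, byrow = TRUE)
  x <- r * cospi(th / 180); y <- r * sinpi(th / 180)
  vals <- 540 - 80 * exp(-((x - 0)^2 + (y + 0.8)^2) / (2 * 1.2^2))
  m <- thickness_map(vals, 540 - 80 * exp(-0.64 / 2.88), g, "pachymetry")
  pf <- pachymetry_features(m)
  # exhaustive scan for the grid point nearest (0, -800 um)
  d2 <- x^2 + (y + 0.8)^2
  nearest <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  expect_equal(pf[["Y_location"]],
               1000 * y[nearest["row"], nearest["col"]], tolerance = 1e-9)
})

test_that("features are invariant to eye side for the same generated eye", {
  calib <- default_calibration()
  set.seed(31)
  pr <- draw_eye_profile(calib$keratoconic, z = 0.5)
  set.seed(77)
  od <- generate_eye(pr$profile, pr$cone, polar_grid(32, 64), "P1", "OD",
                     "keratoconic")
  set.seed(77)
  os <- generate_eye(pr$profile, pr$cone, polar_grid(32, 64), "P1", "OS",
                     "keratoconic")
  f_od <- extract_features(od)
  f_os <- extract_features(os)
  expect_equal(f_od[, feature_names], f_os[, feature_names], tolerance = 1e-10)
})

test_that("mirroring a map leaves all features except SN_IT unchanged", {
  m <- random_map(4)
  f1 <- pachymetry_features(m)
  f2 <- pachymetry_features(orient_map(m, "OS"))
  sym <- setdiff(names(f1), "SN_IT")
  expect_equal(f1[sym], f2[sym], tolerance = 1e-9)
})

test_that("grid refinement moves noise-free analytic features by < 1 um", {
  f <- function(x, y) 540 + 2 * x^2 + 3 * y - 60 * exp(-((x - 0.4)^2 +
                                                           (y + 0.9)^2) / 2)
  coarse <- analytic_map(64, 128, f = f)
  fine <- analytic_map(128, 256, f = f)
  pf1 <- pachymetry_features(coarse)
  pf2 <- pachymetry_features(fine)
  for (nm in setdiff(names(pf1), "Y_location"))
    expect_lt(abs(pf1[[nm]] - pf2[[nm]]), 1, label = nm)
  # thin-point localisation error stays below 50 um in the map plane
  expect_lt(abs(pf1[["Y_location"]] - pf2[["Y_location"]]), 50)
})

test_that("feature invariants hold on generated eyes", {
  ft <- cached_group_features("keratoconic")[1:100, ]
  expect_true(all(ft$Min_Med <= 0))
  expect_true(all(ft$Min_Max <= 0))
  expect_true(all(ft$Min_Max_ep <= 0))
  expect_true(all(ft$SD >= 0))
  expect_true(all(ft$Min_ep <= ft$CET & ft$CET <= ft$Max))
})
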