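# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# 500 map-level eyes per group at the default calibration (the calibration
# study condition); features extracted once.
cached_group_eyes <- function(group, n = 500L, seed = 7L) {
  key <- paste("eyes", group, n, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_group(group, n, seed = seed)
  .fixture_cache[[key]]
}

cached_group_features <- function(group, n = 500L, seed = 7L) {
  key <- paste("feat", group, n, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- extract_features(cached_group_eyes(group, n, seed))
  .fixture_cache[[key]]
}

# A small deterministic analytic test map (no randomness).
analytic_map <- function(n_radii = 16, n_angles = 32, tag = "pachymetry",
                         f = function(x, y) 540 + 2 * x - 3 * y + 4 * (x^2 + y^2)) {
  g <- polar_grid(n_radii, n_angles)
  r <- matrix(g$radii, n_radii, n_angles)
  th <- matrix(g$angles, n_radii, n_angles, byrow = TRUE)
  x <- r * cospi(th / 180); y <- r * sinpi(th / 180)
  thickness_map(f(x, y), f(0, 0), g, tag)
}

random_map <- function(seed, n_radii = 16, n_angles = 32, tag = "pachymetry") {
  set.seed(seed)
  g <- polar_grid(n_radii, n_angles)
  base <- if (tag == "epithelium") 52 else 540
  amp <- if (tag == "epithelium") 4 else 30
  vals <- base + matrix(runif(n_radii * n_angles, -amp, amp), n_radii, n_angles)
  thickness_map(vals, base + runif(1, -amp, amp), g, tag)
}
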