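#' Cone parameters of a synthetic keratoconic thinning pattern
#'
#' The disease signature imposed on a synthetic eye: a Gaussian stromal
#' depression at an (usually inferotemporal) apex, an epithelial depression
#' over the same apex, and an annulus of epithelial thickening around it.
#'
#' @param center_x,center_y apex offset from the vertex in um of map-plane
#'   displacement (temporal positive / superior positive, right-eye frame).
#' @param depth maximal stromal depression at the apex, um (>= 0).
#' @param width Gaussian radius of the depression, mm (> 0).
#' @param epi_thinning epithelial depression at the apex, um (>= 0).
#' @param epi_width Gaussian radius of the epithelial depression, mm;
#'   epithelial remodelling is more localized than the stromal depression
#'   (default 0.6 x `width`).
#' @param epi_annulus_amp amplitude of the annular epithelial thickening, um
#'   (>= 0).
#' @param epi_annulus_radius radius of the thickened annulus measured from
#'   the apex, mm.
#' @param epi_annulus_sigma radial Gaussian width of the annulus, mm.
#' @return an object of class `"cone_params"`.
#' @export
cone_params <- function(center_x = 0, center_y = 0, depth = 0, width = 1,
                        epi_thinning = 0, epi_width = 0.6 * width,
                        epi_annulus_amp = 0,
                        epi_annulus_radius = 1.8, epi_annulus_sigma = 0.6) {
  if (depth < 0) stop("cone depth must be >= 0")
  if (width <= 0) stop("cone width must be > 0")
  if (epi_thinning < 0) stop("epi_thinning must be >= 0")
  if (epi_width <= 0) stop("epi_width must be > 0")
  if (epi_annulus_amp < 0) stop("epi_annulus_amp must be >= 0")
  structure(list(center_x = center_x, center_y = center_y, depth = depth,
                 width = width, epi_thinning = epi_thinning,
                 epi_width = epi_width,
                 epi_annulus_amp = epi_annulus_amp,
                 epi_annulus_radius = epi_annulus_radius,
                 epi_annulus_sigma = epi_annulus_sigma),
            class = "cone_params")
}

# Smooth low-order random surface: a handful of broad Gaussian bumps with
# random centres inside the analysis area and N(0, amp) coefficients
# (winsorized at 2.5 SD).  Pointwise expectation is zero, so the surface
# perturbs extremes and dispersion without biasing zone means, and its
# smoothness keeps arg-min locations stable under grid refinement.
smooth_noise <- function(x, y, amp, n_bumps = 6L, bump_width = 0.9) {
  if (amp <= 0) return(list(field = 0 * x, center = 0))
  u <- stats::runif(n_bumps); th <- stats::runif(n_bumps, 0, 2 * pi)
  bx <- 2.5 * sqrt(u) * cos(th); by <- 2.5 * sqrt(u) * sin(th)
  cf <- pmin(pmax(stats::rnorm(n_bumps, 0, amp), -2.5 * amp), 2.5 * amp)
  field <- 0 * x; ctr <- 0
  for (m in seq_len(n_bumps)) {
    field <- field + cf[m] * exp(-((x - bx[m])^2 + (y - by[m])^2) / (2 * bump_width^2))
    ctr <- ctr + cf[m] * exp(-(bx[m]^2 + by[m]^2) / (2 * bump_width^2))
  }
  list(field = field, center = ctr)
}

#' Generate one synthetic eye
#'
#' Builds pachymetry, epithelial and axial-power maps from a surface profile
#' and a cone.  The pachymetry model is
#' `T0 + k r^p + g y + h x + noise - depth * G(cone)`, with `G` a Gaussian
#' in map-plane distance from the cone apex: base thickness, peripheral
#' thickening (radial exponent `p` = `rad_exp`, rescaled so `k` keeps its
#' per-mm^2 meaning at the 2.5 mm edge), vertical and nasal-temporal
#' gradients, a smooth random surface and the stromal depression.  The
#' epithelium is `E0 + s y + ek r^2 + noise - epi_thinning * G_e +
#' annulus ring` with `G_e` narrower than the stromal depression, and the
#' axial power map is `K0 + (astig/2) cos 2(theta - axis) + steepening`,
#' with steepening
#' proportional to the stromal depression but spatially broader than it
#' (curvature changes extend beyond the depression itself).
#'
#' Maps are generated in the oriented right-eye frame and mirrored when
#' `side = "OS"`, so that downstream orientation is exercised for left eyes.
#'
#' @param profile list of surface parameters: `T0`, `k`, `g`, `h`,
#'   `pnoise_amp` (pachymetry: base um, peripheral um mm^-2, vertical and
#'   nasal-temporal gradients um mm^-1, noise um; `h < 0` makes the nasal
#'   side thicker, the usual superonasal-over-inferotemporal asymmetry),
#'   `E0`, `s`, `ek`, `enoise_amp` (epithelium: base um, vertical gradient
#'   um mm^-1, radial curvature um mm^-2, noise um), `K0`, `astig`,
#'   `astig_axis`, `steep_per_um` (power map,
#'   diopters; steepening in D per um of apex depression).
#' @param cone a [cone_params()].
#' @param grid a [polar_grid()].
#' @param patient_id,side,group identifiers stored in the record.
#' @return an object of class `"eye_record"` with elements `patient_id`,
#'   `side`, `group`, `pachymetry`, `epithelium`, `power`, `slit_lamp_kc`.
#' @export
generate_eye <- function(profile, cone = cone_params(), grid = polar_grid(),
                         patient_id = "P000", side = "OD", group = "normal") {
  stopifnot(inherits(cone, "cone_params"))
  side <- match.arg(side, c("OD", "OS"))
  r <- matrix(grid$radii, grid$n_radii, grid$n_angles)
  th <- matrix(grid$angles, grid$n_radii, grid$n_angles, byrow = TRUE)
  x <- r * cospi(th / 180); y <- r * sinpi(th / 180)
  cx <- cone$center_x / 1000; cy <- cone$center_y / 1000
  d2 <- (x - cx)^2 + (y - cy)^2
  gcone <- exp(-d2 / (2 * cone$width^2))
  gcone0 <- exp(-(cx^2 + cy^2) / (2 * cone$width^2))

  np <- smooth_noise(x, y, profile$pnoise_amp)
  # radial profile k * r^p, rescaled so k keeps its meaning at the 2.5 mm
  # edge; p = 3 concentrates the peripheral thickening further out than a
  # paraboloid, lowering the area-weighted median relative to the extremes
  p_exp <- if (is.null(profile$rad_exp)) 2 else profile$rad_exp
  radial <- profile$k * r^p_exp / 2.5^(p_exp - 2)
  pach_v <- profile$T0 + radial + profile$g * y + profile$h * x +
    np$field - cone$depth * gcone
  pach_c <- profile$T0 + np$center - cone$depth * gcone0

  rho <- sqrt(d2)
  ring <- exp(-(rho - cone$epi_annulus_radius)^2 / (2 * cone$epi_annulus_sigma^2))
  ring0 <- exp(-(sqrt(cx^2 + cy^2) - cone$epi_annulus_radius)^2 /
                 (2 * cone$epi_annulus_sigma^2))
  gepi <- exp(-d2 / (2 * cone$epi_width^2))
  gepi0 <- exp(-(cx^2 + cy^2) / (2 * cone$epi_width^2))
  ne <- smooth_noise(x, y, profile$enoise_amp)
  epi_v <- profile$E0 + profile$s * y + profile$ek * r^2 + ne$field -
    cone$epi_thinning * gepi + cone$epi_annulus_amp * ring
  epi_c <- profile$E0 + ne$center - cone$epi_thinning * gepi0 +
    cone$epi_annulus_amp * ring0

  wp <- 1.6 * cone$width
  gpow <- exp(-d2 / (2 * wp^2))
  gpow0 <- exp(-(cx^2 + cy^2) / (2 * wp^2))
  steep <- profile$steep_per_um * cone$depth
  pow_v <- profile$K0 + (profile$astig / 2) * cospi((th - profile$astig_axis) / 90) +
    steep * gpow
  pow_c <- profile$K0 + steep * gpow0

  build <- function(vals, ctr, tag) {
    tryCatch(thickness_map(vals, ctr, grid, tag),
             error = function(e) stop("calibration rejected while building the ",
                                      tag, " map (T0=", signif(profile$T0, 4),
                                      ", E0=", signif(profile$E0, 4),
                                      ", depth=", signif(cone$depth, 4),
                                      "): ", conditionMessage(e), call. = FALSE))
  }
  rec <- list(patient_id = patient_id, side = side, group = group,
              pachymetry = build(pach_v, pach_c, "pachymetry"),
              epithelium = build(epi_v, epi_c, "epithelium"),
              power = thickness_map(pow_v, pow_c, grid, "power"),
              slit_lamp_kc = identical(group, "keratoconic"))
  if (side == "OS") {
    for (layer in c("pachymetry", "epithelium", "power"))
      rec[[layer]] <- orient_map(rec[[layer]], "OS")  # mirror into native OS frame
  }
  class(rec) <- "eye_record"
  rec
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("<eye_record> %s %s (%s)\n", x$patient_id, x$side, x$group))
  invisible(x)
}

# One winsorized-normal draw: mean + sev * z + sd * eps, eps ~ N(0,1)
# clipped at +/- 3 (keeps every generated map inside physical bounds).
wdraw <- function(mean, sd = 0, sev = 0, z = 0) {
  mean + sev * z + sd * pmin(pmax(stats::rnorm(1), -3), 3)
}

#' Draw per-eye surface and cone parameters for a group
#'
#' Samples one eye's generative parameters from the group's calibration
#' distributions, conditioned on the eye's latent severity `z` (a standard
#' normal, winsorized at +/- 3, shared structure across the two eyes of a
#' patient via [generate_cohort()]'s intra-patient correlation).  Severity
#' loads on base thickness (negatively), log cone depth, log epithelial
#' thinning and apex height (more severe = thinner, deeper, more inferior).
#'
#' @param gp one group's entry of [default_calibration()].
#' @param z latent severity.
#' @return list with `profile` and `cone` ready for [generate_eye()].
#' @export
draw_eye_profile <- function(gp, z = 0) {
  z <- pmin(pmax(z, -3), 3)
  depth <- exp(wdraw(gp$ldepth_mean, gp$ldepth_sd, gp$ldepth_sev, z))
  thin <- exp(wdraw(gp$lthin_mean, gp$lthin_sd, gp$lthin_sev, z))
  profile <- list(
    T0 = wdraw(gp$T0_mean, gp$T0_sd, gp$T0_sev, z),
    k = max(0, wdraw(gp$k_mean, gp$k_sd)),
    rad_exp = if (is.null(gp$rad_exp)) 2 else gp$rad_exp,
    g = wdraw(gp$g_mean, gp$g_sd),
    h = wdraw(gp$h_mean, gp$h_sd),
    pnoise_amp = gp$pnoise_amp,
    E0 = wdraw(gp$E0_mean, gp$E0_sd, gp$E0_sev, z),
    s = wdraw(gp$s_mean, gp$s_sd),
    ek = wdraw(gp$ek_mean, gp$ek_sd),
    enoise_amp = gp$enoise_amp,
    K0 = wdraw(gp$K0_mean, gp$K0_sd),
    astig = max(0.05, wdraw(gp$astig_mean, gp$astig_sd)),
    astig_axis = stats::runif(1, 0, 180),
    steep_per_um = gp$steep_per_um)
  cone <- cone_params(
    center_x = 1000 * wdraw(gp$cx_mean, gp$cx_sd),
    center_y = 1000 * wdraw(gp$cy_mean, gp$cy_sd, gp$cy_sev, z),
    depth = depth,
    width = max(0.5, wdraw(gp$width_mean, gp$width_sd)),
    epi_thinning = thin,
    epi_width = 0.6 * max(0.5, wdraw(gp$width_mean, gp$width_sd)),
    epi_annulus_amp = max(0, wdraw(gp$annamp_mean, gp$annamp_sd)),
    epi_annulus_radius = min(2.4, max(0.8, wdraw(gp$annrad_mean, gp$annrad_sd))),
    epi_annulus_sigma = gp$annsigma)
  list(profile = profile, cone = cone)
}

#' Default generator calibration
#'
#' Group-wise distributions of the generative parameters, fitted so that the
#' 14 variables extracted from generated maps reproduce the published group
#' means (see [reference_moments()]): thickness-valued features to within
#' 2 percent and difference/dispersion features to within 15 percent.
#' Each parameter is given as a mean plus optional across-eye SD (`_sd`)
#' and latent-severity loading (`_sev`); cone depth and epithelial thinning
#' are log-normal.
#'
#' @return named list with entries `normal`, `keratoconic`, `fellow`.
#' @export
default_calibration <- function() {
  base <- list(
    T0_sd = 20, T0_sev = -20,
    k_sd = 0.4, g_sd = 2.0, h_sd = 1.0,
    E0_sd = 2.6, E0_sev = -0.8, s_sd = 0.4, ek_sd = 0.15,
    ldepth_sd = 0.20, ldepth_sev = 0.20,
    lthin_sd = 0.20, lthin_sev = 0.20,
    width_sd = 0.08, cx_sd = 0.10,
    annamp_sd = 0.5, annrad_sd = 0.10, annsigma = 0.6,
    K0_mean = 42.5, K0_sd = 0.7,
    astig_mean = 0.9, astig_sd = 0.35,
    steep_per_um = 0.08)
  normal <- utils::modifyList(base, list(
    T0_mean = 546.091, k_mean = 3.29695, rad_exp = 3, g_mean = 4.74804,
    h_mean = -2.5685, pnoise_amp = 10.5323, width_mean = 1.1,
    E0_mean = 51.7736, s_mean = -0.637475, ek_mean = 0.108601,
    enoise_amp = 2.19383,
    ldepth_mean = 2.54145, cx_mean = 0.35, cy_mean = 0.6,
    cy_sd = 0.15, cy_sev = -0.05,
    lthin_mean = -0.201346, annamp_mean = 1.6319, annrad_mean = 1.0))
  fellow <- utils::modifyList(base, list(
    T0_mean = 524.346, k_mean = 2.69533, rad_exp = 3, g_mean = 5.85215,
    h_mean = -2.3387, pnoise_amp = 13.9235, width_mean = 1.1,
    E0_mean = 51.8085, s_mean = 0.27533, ek_mean = -0.24972,
    enoise_amp = 1.23694,
    ldepth_mean = 2.36674, ldepth_sd = 0.15, ldepth_sev = 0.15,
    cx_mean = 0.30, cy_mean = -0.185473, cy_sd = 0.12, cy_sev = -0.06,
    lthin_mean = 0.483007, annamp_mean = 4.55406, annrad_mean = 1.24065))
  keratoconic <- utils::modifyList(base, list(
    T0_mean = 515.119, k_mean = 4.40059, rad_exp = 2, g_mean = 11.4971,
    h_mean = -0.147233, pnoise_amp = 4.51613, width_mean = 1.0,
    E0_mean = 48.7273, s_mean = -0.117752, ek_mean = -1.07966,
    enoise_amp = 2.57476,
    ldepth_mean = 3.87613, ldepth_sd = 0.25, ldepth_sev = 0.30,
    cx_mean = 0.35, cy_mean = -0.873371, cy_sd = 0.18, cy_sev = -0.10,
    lthin_mean = 1.67788, lthin_sd = 0.25, lthin_sev = 0.25,
    annamp_mean = 15.5012, annrad_mean = 2.3))
  list(normal = normal, keratoconic = keratoconic, fellow = fellow)
}

# Draw an eye, rejecting (and redrawing) the rare severity-tail parameter
# combinations whose maps would leave the physical thickness bounds; the
# resulting mild truncation of the severity tail is part of the calibrated
# generative model (printed feature ranges are themselves bounded).
draw_valid_eye <- function(gp, z, grid, patient_id, side, group,
                           max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    pr <- draw_eye_profile(gp, z)
    eye <- tryCatch(generate_eye(pr$profile, pr$cone, grid, patient_id,
                                 side = side, group = group),
                    error = function(e) NULL)
    if (!is.null(eye)) return(eye)
    z <- z * 0.8  # pull a persistent offender towards typical severity
  }
  stop("calibration rejected: could not draw a physically valid ", group,
       " eye in ", max_tries, " attempts")
}

#' Cohort generator configuration
#'
#' @param n_normal_subjects number of healthy subjects (two normal eyes each).
#' @param n_asym_kc_subjects number of asymmetric-keratoconus patients (one
#'   keratoconic plus one topographically normal fellow eye each).
#' @param seed integer RNG seed; a cohort is a pure function of its spec.
#' @param rho intra-patient correlation of latent severity, in `[0, 1)`.
#' @param calibration group parameter set, defaults to [default_calibration()].
#' @param grid sampling grid, defaults to [polar_grid()].
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_normal_subjects = 52L, n_asym_kc_subjects = 22L,
                        seed = 1L, rho = 0.5,
                        calibration = default_calibration(),
                        grid = polar_grid()) {
  n_normal_subjects <- as.integer(n_normal_subjects)
  n_asym_kc_subjects <- as.integer(n_asym_kc_subjects)
  if (n_normal_subjects < 1L || n_asym_kc_subjects < 1L)
    stop("subject counts must be >= 1")
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("rho must be in [0, 1)")
  if (!all(c("normal", "keratoconic", "fellow") %in% names(calibration)))
    stop("calibration must name the three groups")
  structure(list(n_normal_subjects = n_normal_subjects,
                 n_asym_kc_subjects = n_asym_kc_subjects,
                 seed = as.integer(seed), rho = rho,
                 calibration = calibration, grid = grid),
            class = "cohort_spec")
}

#' Generate a synthetic two-eyes-per-patient cohort
#'
#' Healthy subjects contribute two normal eyes; asymmetric-keratoconus
#' patients contribute one keratoconic and one fellow eye (the affected side
#' chosen at random).  The two eyes of a patient share latent severities
#' drawn from a bivariate standard normal with correlation `rho`, which
#' propagates into within-patient correlation of the extracted features.
#'
#' @param spec a [cohort_spec()].
#' @return list of `2 * (n_normal_subjects + n_asym_kc_subjects)` eye records.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  a <- sqrt(spec$rho)
  draw_pair <- function() {
    shared <- stats::rnorm(1)
    a * shared + sqrt(1 - spec$rho) * stats::rnorm(2)
  }
  eyes <- list()
  for (i in seq_len(spec$n_normal_subjects)) {
    pid <- sprintf("N%03d", i)
    z <- draw_pair()
    for (j in 1:2) {
      eyes[[length(eyes) + 1L]] <-
        draw_valid_eye(spec$calibration$normal, z[j], spec$grid, pid,
                       side = c("OD", "OS")[j], group = "normal")
    }
  }
  for (i in seq_len(spec$n_asym_kc_subjects)) {
    pid <- sprintf("K%03d", i)
    z <- draw_pair()
    kc_side <- sample(c("OD", "OS"), 1)
    for (j in 1:2) {
      side <- c("OD", "OS")[j]
      grp <- if (side == kc_side) "keratoconic" else "fellow"
      eyes[[length(eyes) + 1L]] <-
        draw_valid_eye(spec$calibration[[grp]], z[j], spec$grid, pid,
                       side = side, group = grp)
    }
  }
  eyes
}

#' Generate eyes of a single group (calibration checks, accuracy experiments)
#'
#' Convenience sampler: `n` independent eyes of one group, latent severities
#' i.i.d. standard normal, alternating OD/OS sides, one patient per eye.
#'
#' @param group `"normal"`, `"keratoconic"` or `"fellow"`.
#' @param n number of eyes.
#' @param seed RNG seed.
#' @param calibration,grid as in [cohort_spec()].
#' @return list of `n` eye records.
#' @export
generate_group <- function(group, n, seed = 1L,
                           calibration = default_calibration(),
                           grid = polar_grid()) {
  group <- match.arg(group, c("normal", "keratoconic", "fellow"))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    draw_valid_eye(calibration[[group]], stats::rnorm(1), grid,
                   patient_id = sprintf("%s%04d", toupper(substr(group, 1, 1)), i),
                   side = c("OD", "OS")[1 + i %% 2], group = group)
  })
}
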