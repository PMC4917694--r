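#' Inferior-superior power asymmetry (I-S)
#'
#' Difference between the average axial surface power of 5 inferior and 5
#' superior points sampled 3 mm from the corneal centre at 30 degree
#' intervals (inferior at 210, 240, 270, 300, 330 degrees; superior at 30,
#' 60, 90, 120, 150; screen convention with 90 degrees superior).  Values of
#' 1.4 D or more are a keratoconus sign.
#'
#' @param power_map an oriented axial power [thickness_map()] (tag
#'   `"power"`) covering radius 3 mm.
#' @return I-S value in diopters.
#' @export
is_index <- function(power_map) {
  if (is.null(power_map)) stop("power map absent: I-S cannot be computed")
  stopifnot(inherits(power_map, "thickness_map"))
  g <- power_map$grid
  if (g$r_max < 3 - 1e-9) stop("power map must cover radius 3 mm")
  at <- function(angle) {
    ri <- which.min(abs(g$radii - 3))
    ai <- which.min(pmin(abs(g$angles - angle), 360 - abs(g$angles - angle)))
    power_map$values[ri, ai]
  }
  inf <- vapply(c(210, 240, 270, 300, 330), at, numeric(1))
  sup <- vapply(c(30, 60, 90, 120, 150), at, numeric(1))
  mean(inf) - mean(sup)
}

#' Central corneal power
#'
#' Area-weighted mean axial power over the central zone (default radius
#' 1.5 mm, i.e. the central 3 mm).  47.2 D or more is a keratoconus sign.
#'
#' @inheritParams is_index
#' @param radius averaging-zone radius in mm.
#' @return central power in diopters.
#' @export
central_power <- function(power_map, radius = 1.5) {
  stopifnot(inherits(power_map, "thickness_map"))
  g <- power_map$grid
  keep <- g$radii <= radius + 1e-12
  if (!any(keep)) stop("no grid rings inside the central-power zone")
  w <- matrix(g$radii[keep], sum(keep), g$n_angles)
  sum(power_map$values[keep, , drop = FALSE] * w) / sum(w)
}

#' Corneal astigmatism magnitude (AST)
#'
#' Steep-minus-flat central keratometry, estimated by least-squares fit of
#' `a + b cos 2t + c sin 2t` to the power values on the ring nearest
#' `radius`; AST is twice the fitted harmonic amplitude.
#'
#' @inheritParams is_index
#' @param radius keratometry ring radius in mm.
#' @return astigmatism magnitude in diopters (>= 0).
#' @export
astigmatism_index <- function(power_map, radius = 1.5) {
  stopifnot(inherits(power_map, "thickness_map"))
  g <- power_map$grid
  ri <- which.min(abs(g$radii - radius))
  v <- power_map$values[ri, ]
  t2 <- 2 * pi * g$angles / 180
  b <- 2 * mean(v * cos(t2)); cc <- 2 * mean(v * sin(t2))
  2 * sqrt(b^2 + cc^2)
}

#' Skewed radial axis index (SRAX)
#'
#' Angle between the steepest radial axis above the horizontal meridian and
#' the continuation of the steepest radial axis below it, in degrees
#' (0 for an untilted symmetric bow-tie).  Each semi-meridian's power is the
#' mean along its spoke.
#'
#' @inheritParams is_index
#' @return skew angle in degrees, in `[0, 90]`.
#' @export
srax_index <- function(power_map) {
  stopifnot(inherits(power_map, "thickness_map"))
  g <- power_map$grid
  spoke <- colMeans(power_map$values)
  sup <- g$angles > 0 & g$angles < 180
  inf <- g$angles > 180 & g$angles < 360
  th_s <- g$angles[sup][which.max(spoke[sup])]
  th_i <- g$angles[inf][which.max(spoke[inf])] - 180
  d <- abs(th_s - th_i)
  min(d, 180 - d)
}

#' KISA percent index
#'
#' Composite screening index `K * (I-S) * AST * SRAX / 300`, expressed in
#' percent; 100 percent or more is a keratoconus sign.  Each component can
#' be overridden (e.g. device-specific definitions) via the `components`
#' list; by default they are computed from the power map with
#' [central_power()], [is_index()], [astigmatism_index()] and
#' [srax_index()].  Negative I-S contributes no keratoconus evidence and is
#' floored at zero so that KISA stays non-negative.
#'
#' @inheritParams is_index
#' @param is_value optional precomputed I-S value.
#' @param components optional named list overriding `K`, `IS`, `AST`, `SRAX`.
#' @return KISA in percent (>= 0).
#' @export
kisa <- function(power_map = NULL, is_value = NULL, components = list()) {
  comp <- list(
    K = components$K %||% central_power(power_map),
    IS = components$IS %||% (is_value %||% is_index(power_map)),
    AST = components$AST %||% astigmatism_index(power_map),
    SRAX = components$SRAX %||% srax_index(power_map))
  bad <- names(comp)[!vapply(comp, function(v) is.numeric(v) && is.finite(v),
                             logical(1))]
  if (length(bad)) stop("KISA component not computable: ",
                        paste(bad, collapse = ", "))
  comp$IS <- max(0, comp$IS)
  100 * comp$K * comp$IS * comp$AST * comp$SRAX / 300
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Topographic keratoconus criteria for one eye
#'
#' Evaluates the four screening criteria on an oriented axial power map:
#' I-S >= 1.4 D, central power >= 47.2 D, KISA >= 100 percent, and
#' (optionally) a keratoconus predictability index KPI >= 0.23.  KPI is a
#' linear discriminant of quantitative topographic indices whose published
#' coefficients are device-specific; it is disabled unless a coefficient
#' function is supplied.
#'
#' @inheritParams is_index
#' @param thresholds named numeric vector of the four thresholds.
#' @param kpi_fun optional function(power_map) returning a KPI value.
#' @return object of class `"topo_criteria"`: values, thresholds and logical
#'   flags.
#' @export
topo_criteria <- function(power_map,
                          thresholds = c(IS = 1.4, K = 47.2, KISA = 100,
                                         KPI = 0.23),
                          kpi_fun = NULL) {
  isv <- is_index(power_map)
  kv <- central_power(power_map)
  kisav <- kisa(power_map, is_value = isv)
  kpiv <- if (is.null(kpi_fun)) NA_real_ else kpi_fun(power_map)
  flags <- c(IS = isv >= thresholds[["IS"]],
             K = kv >= thresholds[["K"]],
             KISA = kisav >= thresholds[["KISA"]],
             KPI = !is.na(kpiv) && kpiv >= thresholds[["KPI"]])
  structure(list(IS_value = isv, central_power = kv, KISA_percent = kisav,
                 KPI = kpiv, thresholds = thresholds, flags = flags),
            class = "topo_criteria")
}

#' @export
print.topo_criteria <- function(x, ...) {
  cat(sprintf("I-S %.2f D | K %.2f D | KISA %.1f%% | KPI %s | flags: %s\n",
              x$IS_value, x$central_power, x$KISA_percent,
              ifelse(is.na(x$KPI), "-", sprintf("%.2f", x$KPI)),
              paste(names(x$flags)[x$flags], collapse = ",")))
  invisible(x)
}

#' Assign a study group label to one eye
#'
#' Mirrors the study's group construction: an eye is `keratoconic` when it
#' shows slit-lamp keratoconus or exceeds any topographic criterion;
#' otherwise it is `fellow` when its patient's other eye is keratoconic, and
#' `normal` when not.
#'
#' @param criteria a [topo_criteria()].
#' @param slit_lamp_kc logical: slit-lamp findings compatible with
#'   keratoconus.
#' @param contralateral_kc logical: the patient's other eye is keratoconic.
#' @return `"keratoconic"`, `"fellow"` or `"normal"`.
#' @export
classify_eye <- function(criteria, slit_lamp_kc = FALSE,
                         contralateral_kc = FALSE) {
  stopifnot(inherits(criteria, "topo_criteria"))
  if (isTRUE(slit_lamp_kc) || any(criteria$flags)) return("keratoconic")
  if (isTRUE(contralateral_kc)) return("fellow")
  "normal"
}

#' Screen a cohort of eyes
#'
#' Orients each eye's power map, evaluates the topographic criteria and
#' assigns group labels, using each patient's slit-lamp flags to decide
#' contralateral status.
#'
#' @param eyes list of eye records.
#' @return data.frame with ids, criterion values, flags and assigned label.
#' @export
screen_cohort <- function(eyes) {
  if (inherits(eyes, "eye_record")) eyes <- list(eyes)
  slit <- vapply(eyes, function(e) isTRUE(e$slit_lamp_kc), logical(1))
  pid <- vapply(eyes, function(e) as.character(e$patient_id), character(1))
  rows <- lapply(seq_along(eyes), function(i) {
    e <- eyes[[i]]
    cr <- topo_criteria(orient_map(e$power, e$side))
    # contralateral keratoconus: any other eye of this patient is slit-lamp KC
    others <- setdiff(which(pid == pid[i]), i)
    contra <- any(slit[others])
    data.frame(patient_id = e$patient_id, side = e$side,
               group_true = e$group,
               IS_value = cr$IS_value, central_power = cr$central_power,
               KISA_percent = cr$KISA_percent,
               flag_IS = cr$flags[["IS"]], flag_K = cr$flags[["K"]],
               flag_KISA = cr$flags[["KISA"]],
               label = classify_eye(cr, slit[i], contra))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
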