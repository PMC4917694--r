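#' Polar measurement grid over the central cornea
#'
#' Thickness and power maps are sampled on a dense polar grid centred on the
#' corneal vertex: `n_radii` concentric rings (equally spaced, outermost ring
#' at `r_max` mm) times `n_angles` equally spaced spokes.  The vertex itself is
#' stored separately as `center_value` because it carries zero area.  After
#' orientation (see [orient_map()]) the angular convention is that of a right
#' eye: 0 deg = temporal, 90 deg = superior, 180 deg = nasal, 270 deg =
#' inferior, counterclockwise.
#'
#' @param n_radii number of radial rings (default 64).
#' @param n_angles number of angular spokes; must be even so that mirroring
#'   about the vertical axis maps grid angles onto grid angles (default 128).
#' @param r_max outermost ring radius in mm (default 3).
#' @return a list with `radii` (mm), `angles` (degrees in `[0, 360)`) and the
#'   grid dimensions, of class `"kc_grid"`.
#' @export
polar_grid <- function(n_radii = 64L, n_angles = 128L, r_max = 3.0) {
  n_radii <- as.integer(n_radii)
  n_angles <- as.integer(n_angles)
  if (n_radii < 2L || n_angles < 4L)
    stop("grid too coarse: need at least 2 radii and 4 angles")
  if (n_angles %% 2L != 0L)
    stop("n_angles must be even so that horizontal mirroring is grid-exact")
  structure(
    list(radii = seq(r_max / n_radii, r_max, length.out = n_radii),
         angles = seq(0, 360, length.out = n_angles + 1L)[seq_len(n_angles)],
         n_radii = n_radii, n_angles = n_angles, r_max = r_max),
    class = "kc_grid")
}

#' Thickness (or power) map on a polar grid
#'
#' @param values numeric matrix, `n_radii` rows (rings, innermost first) by
#'   `n_angles` columns (spokes in the order of `grid$angles`).
#' @param center_value scalar value at the vertex.
#' @param grid a [polar_grid()].
#' @param tag one of `"pachymetry"`, `"epithelium"`, `"power"`.  Pachymetry
#'   values must lie in \[300, 700\] um and epithelial values in \[20, 90\] um;
#'   values outside these physical bounds indicate a broken calibration and
#'   are rejected.
#' @return an object of class `"thickness_map"`.
#' @export
thickness_map <- function(values, center_value, grid, tag) {
  tag <- match.arg(tag, c("pachymetry", "epithelium", "power"))
  values <- unname(as.matrix(values))
  if (length(center_value) != 1L) stop("center_value must be a scalar")
  center_value <- as.numeric(center_value)
  if (nrow(values) != grid$n_radii || ncol(values) != grid$n_angles)
    stop("values must be n_radii x n_angles (", grid$n_radii, " x ",
         grid$n_angles, ")")
  all_v <- c(center_value, values)
  if (!all(is.finite(all_v)))
    stop("map contains non-finite values")
  bounds <- switch(tag,
                   pachymetry = c(300, 700),
                   epithelium = c(20, 90),
                   power = c(-Inf, Inf))
  if (tag != "power" && (min(all_v) < bounds[1] || max(all_v) > bounds[2]))
    stop(sprintf("%s map values outside physical bounds [%g, %g] um (range %g to %g)",
                 tag, bounds[1], bounds[2], min(all_v), max(all_v)))
  if (tag != "power" && min(all_v) <= 0)
    stop("thickness values must be strictly positive")
  structure(list(values = values, center_value = center_value,
                 grid = grid, tag = tag),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map '%s'> %d radii x %d angles, r <= %g mm\n",
              x$tag, x$grid$n_radii, x$grid$n_angles, x$grid$r_max))
  cat(sprintf("  center %.2f; range %.2f to %.2f\n",
              x$center_value, min(x$values), max(x$values)))
  invisible(x)
}

#' Orient a map into the right-eye (OD) frame
#'
#' Left-eye (OS) maps are mirrored about the vertical axis so that nasal and
#' temporal sectors coincide with those of a right eye; OD maps are returned
#' unchanged.  Mirroring sends the spoke at angle a to the spoke at
#' (180 - a) mod 360, which is grid-exact for an even number of spokes.
#'
#' @param map a [thickness_map()].
#' @param side `"OD"` or `"OS"`.
#' @return the oriented map.
#' @export
orient_map <- function(map, side) {
  stopifnot(inherits(map, "thickness_map"))
  if (!is.character(side) || length(side) != 1L || !side %in% c("OD", "OS"))
    stop("side must be \"OD\" or \"OS\"")
  if (side == "OD") return(map)
  ang <- map$grid$angles
  mirrored <- (180 - ang) %% 360
  idx <- match(round(mirrored, 9), round(ang, 9))
  if (anyNA(idx))
    stop("mirrored angles do not land on the grid; use an even n_angles")
  map$values <- map$values[, idx, drop = FALSE]
  map
}

#' Serialize eye records to the long CSV map format
#'
#' One row per grid point per layer: `patient_id, side, group, layer,
#' radius_mm, angle_deg, thickness_um` (power maps are included with the
#' value in diopters in the same column).  The vertex is written with
#' `radius_mm = 0`, `angle_deg = 0`.
#'
#' @param eyes a list of eye records from [generate_eye()] / [generate_cohort()].
#' @return a `data.frame` in the long format.
#' @export
maps_to_long <- function(eyes) {
  if (inherits(eyes, "eye_record")) eyes <- list(eyes)
  one_layer <- function(eye, layer, map) {
    g <- map$grid
    data.frame(patient_id = eye$patient_id, side = eye$side, group = eye$group,
               layer = layer,
               radius_mm = c(0, rep(g$radii, times = g$n_angles)),
               angle_deg = c(0, rep(g$angles, each = g$n_radii)),
               thickness_um = c(map$center_value, as.vector(map$values)))
  }
  out <- lapply(eyes, function(eye) {
    layers <- list(one_layer(eye, "pachymetry", eye$pachymetry),
                   one_layer(eye, "epithelium", eye$epithelium))
    if (!is.null(eye$power)) layers <- c(layers, list(one_layer(eye, "power", eye$power)))
    do.call(rbind, layers)
  })
  do.call(rbind, out)
}

#' Rebuild eye records from the long CSV map format
#'
#' Inverse of [maps_to_long()]; the grid is inferred from the unique radii
#' and angles present for each layer.
#'
#' @param df a data.frame in the long format written by [maps_to_long()].
#' @return a list of eye records.
#' @export
maps_from_long <- function(df) {
  need <- c("patient_id", "side", "group", "layer", "radius_mm", "angle_deg",
            "thickness_um")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  key <- interaction(df$patient_id, df$side, drop = TRUE)
  lapply(split(df, key), function(d) {
    layer_map <- function(ld, tag) {
      ctr <- ld$thickness_um[ld$radius_mm == 0]
      ld <- ld[ld$radius_mm > 0, ]
      radii <- sort(unique(ld$radius_mm))
      angles <- sort(unique(ld$angle_deg))
      g <- polar_grid(length(radii), length(angles), max(radii))
      vals <- matrix(NA_real_, length(radii), length(angles))
      vals[cbind(match(ld$radius_mm, radii), match(ld$angle_deg, angles))] <-
        ld$thickness_um
      thickness_map(vals, ctr[1], g, tag)
    }
    rec <- list(patient_id = d$patient_id[1], side = d$side[1], group = d$group[1],
                pachymetry = layer_map(d[d$layer == "pachymetry", ], "pachymetry"),
                epithelium = layer_map(d[d$layer == "epithelium", ], "epithelium"),
                power = if (any(d$layer == "power"))
                  layer_map(d[d$layer == "power", ], "power") else NULL)
    class(rec) <- "eye_record"
    rec
  })
}
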