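#' @rdname pachymetry_features
#' @format NULL
#' @export
feature_names <- c("SN_IT", "Min", "Min_Med", "S_I", "Y_location", "Min_Max",
                   "CCT", "Sup", "Inf_ep", "Min_ep", "Max", "Min_Max_ep",
                   "SD", "CET")

# Global extremes over the analysis area, including the vertex point.
# Tie-break for the arg-min/arg-max: vertex first, then smallest radius,
# then smallest angle (the construction order of `map_points`).
map_extremes <- function(map, geom) {
  pts <- map_points(map, geom)
  r <- c(0, pts$radius); a <- c(0, pts$angle); v <- c(map$center_value, pts$value)
  ord <- order(r, a)
  r <- r[ord]; a <- a[ord]; v <- v[ord]
  imin <- which.min(v); imax <- which.max(v)
  list(min = v[imin], max = v[imax],
       min_r = r[imin], min_angle = a[imin],
       max_r = r[imax], max_angle = a[imax])
}

weighted_median <- function(v, w) {
  ord <- order(v)
  v <- v[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  v[which(cw >= 0.5)[1]]
}

#' Pachymetry map variables
#'
#' Computes the seven pachymetry variables from an oriented total-thickness
#' map over the central 5 mm:
#' \describe{
#'   \item{SN_IT}{superonasal minus inferotemporal mean octant thickness
#'     (2-5 mm annulus), um.}
#'   \item{Min}{thickness of the thinnest point, um.}
#'   \item{Min_Med}{Min minus the area-weighted median of all analysed
#'     points, um (always <= 0).}
#'   \item{S_I}{superior minus inferior half-annulus mean, um.}
#'   \item{Y_location}{signed vertical offset of the thinnest point from the
#'     vertex, in um of map-plane displacement, positive superior.}
#'   \item{Min_Max}{Min minus the thickest point, um (always <= 0).}
#'   \item{CCT}{central (vertex) thickness, um.}
#' }
#' Medians are area-weighted over the polar grid; the vertex participates in
#' the extremes but carries zero area.  Arg-min ties are broken towards the
#' smallest radius, then the smallest angle.
#'
#' @param map an oriented pachymetry [thickness_map()].
#' @param geom a [zone_geometry()].
#' @return named numeric vector of the seven pachymetry variables.
#' @seealso [epithelial_features()], [extract_features()]
#' @export
pachymetry_features <- function(map, geom = zone_geometry()) {
  stopifnot(inherits(map, "thickness_map"))
  zm <- zone_means(map, geom)
  ex <- map_extremes(map, geom)
  pts <- map_points(map, geom)
  med <- weighted_median(pts$value, pts$weight)
  c(SN_IT = unname(zm["SN"] - zm["IT"]),
    Min = ex$min,
    Min_Med = ex$min - med,
    S_I = unname(zm["superior"] - zm["inferior"]),
    Y_location = 1000 * ex$min_r * sinpi(ex$min_angle / 180),
    Min_Max = ex$min - ex$max,
    CCT = map$center_value)
}

#' Epithelial map variables
#'
#' Computes the seven epithelial variables from an oriented epithelial
#' thickness map over the central 5 mm: `Sup` and `Inf_ep` (superior /
#' inferior half-annulus means), `Min_ep` and `Max` (global extremes),
#' `Min_Max_ep` (their difference, <= 0), `SD` (area-weighted population
#' standard deviation of all analysed points) and `CET` (vertex thickness).
#'
#' @inheritParams pachymetry_features
#' @return named numeric vector of the seven epithelial variables.
#' @export
epithelial_features <- function(map, geom = zone_geometry()) {
  stopifnot(inherits(map, "thickness_map"))
  zm <- zone_means(map, geom)
  ex <- map_extremes(map, geom)
  pts <- map_points(map, geom)
  m <- sum(pts$value * pts$weight) / sum(pts$weight)
  sdw <- sqrt(sum(pts$weight * (pts$value - m)^2) / sum(pts$weight))
  c(Sup = unname(zm["superior"]),
    Inf_ep = unname(zm["inferior"]),
    Min_ep = ex$min,
    Max = ex$max,
    Min_Max_ep = ex$min - ex$max,
    SD = sdw,
    CET = map$center_value)
}

#' Extract the 14 diagnostic variables for one eye or a cohort
#'
#' Orients each eye's maps into the right-eye frame and computes the seven
#' pachymetry plus seven epithelial variables.
#'
#' @param eyes an eye record or list of eye records ([generate_cohort()]).
#' @param geom a [zone_geometry()].
#' @return a `data.frame` with `patient_id`, `side`, `group` and the 14
#'   feature columns (`feature_names`).
#' @export
extract_features <- function(eyes, geom = zone_geometry()) {
  if (inherits(eyes, "eye_record")) eyes <- list(eyes)
  rows <- lapply(eyes, function(eye) {
    pach <- orient_map(eye$pachymetry, eye$side)
    epi <- orient_map(eye$epithelium, eye$side)
    feats <- c(pachymetry_features(pach, geom), epithelial_features(epi, geom))
    cbind(data.frame(patient_id = eye$patient_id, side = eye$side,
                     group = eye$group),
          as.data.frame(as.list(feats)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
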