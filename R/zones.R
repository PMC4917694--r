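#' Zone layout of the central 5 mm analysis area
#'
#' The analysed area is the central 5 mm of the cornea (radius 2.5 mm):
#' a central 2 mm disc (radius `central_radius`) plus a 2-5 mm annulus
#' (`central_radius` to `outer_radius`).  The annulus is split into superior
#' and inferior half-annuli (points strictly above / below the horizontal
#' meridian) and into eight 45 deg octants centred on the principal
#' semi-meridians of an oriented right eye: T (0), ST (45), S (90), SN (135),
#' N (180), IN (225), I (270), IT (315).  An annulus point belongs to octant X
#' when its angle lies within X's centre +/- 22.5 deg (half-open on the upper
#' side), so the octants partition the annulus exactly.
#'
#' @param central_radius radius of the central disc in mm (default 1.0).
#' @param outer_radius outer radius of the analysed area in mm (default 2.5).
#' @return an object of class `"zone_geometry"`.
#' @export
zone_geometry <- function(central_radius = 1.0, outer_radius = 2.5) {
  stopifnot(central_radius > 0, outer_radius > central_radius)
  structure(list(central_radius = central_radius, outer_radius = outer_radius,
                 octants = c("T", "ST", "S", "SN", "N", "IN", "I", "IT")),
            class = "zone_geometry")
}

# Long-form view of the grid points inside the analysis area, with the
# area weight of each polar cell (equal radial/angular spacing => area
# proportional to radius).
map_points <- function(map, geom) {
  g <- map$grid
  keep <- g$radii <= geom$outer_radius + 1e-12
  if (!any(keep)) stop("grid has no rings inside the analysis area")
  r <- rep(g$radii[keep], times = g$n_angles)
  a <- rep(g$angles, each = sum(keep))
  data.frame(radius = r, angle = a,
             value = as.vector(map$values[keep, , drop = FALSE]),
             weight = r)
}

octant_of <- function(angle_deg) {
  centers <- c("T", "ST", "S", "SN", "N", "IN", "I", "IT")
  centers[(floor((angle_deg + 22.5) / 45) %% 8) + 1]
}

#' Area-weighted zone means of a thickness map
#'
#' Returns the mean thickness of the central disc, the 2-5 mm annulus, its
#' superior and inferior half-annuli and its eight octants, each computed as
#' an area-weighted mean over the grid points inside the zone (polar cell
#' area is proportional to radius).  Points exactly on the horizontal
#' meridian belong to neither half-annulus.
#'
#' @param map an oriented [thickness_map()].
#' @param geom a [zone_geometry()].
#' @return named numeric vector with elements `central`, `annulus`,
#'   `superior`, `inferior` and the eight octant labels.
#' @export
zone_means <- function(map, geom = zone_geometry()) {
  stopifnot(inherits(map, "thickness_map"), inherits(geom, "zone_geometry"))
  pts <- map_points(map, geom)
  in_ann <- pts$radius > geom$central_radius
  wmean <- function(sel, zone) {
    if (!any(sel)) stop("zone '", zone, "' contains no grid points; grid too coarse")
    sum(pts$value[sel] * pts$weight[sel]) / sum(pts$weight[sel])
  }
  y <- pts$radius * sinpi(pts$angle / 180)
  out <- c(central = wmean(!in_ann, "central"),
           annulus = wmean(in_ann, "annulus"),
           superior = wmean(in_ann & y > 1e-12, "superior"),
           inferior = wmean(in_ann & y < -1e-12, "inferior"))
  oct <- octant_of(pts$angle)
  for (o in geom$octants) out[o] <- wmean(in_ann & oct == o, o)
  out
}
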