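#' Classify regional points as climatically suitable or unsuitable
#'
#' Intersects the global niche with the regional environmental space: each
#' regional point is mapped to its enclosing grid cell and labelled zone
#' `"A"` (suitable) when the cell belongs to the niche mask, `"B"`
#' otherwise. Points falling outside the grid ranges lie outside the global
#' environmental envelope and are therefore unsuitable by definition.
#'
#' @param niche a [delineate_niche()] result.
#' @param grid the [build_env_grid()] the niche was derived from.
#' @param regional_scores tibble with `pc1`, `pc2` (from [project_env()]).
#' @return the input tibble with a `zone` column (`"A"`/`"B"`).
#' @export
classify_points <- function(niche, grid, regional_scores) {
  stopifnot(inherits(niche, "niche_region"), inherits(grid, "env_grid"))
  if (nrow(regional_scores) == 0) abort("empty regional point set.")
  ix <- findInterval(regional_scores$pc1, grid$edges_x,
                     rightmost.closed = TRUE)
  iy <- findInterval(regional_scores$pc2, grid$edges_y,
                     rightmost.closed = TRUE)
  inside <- ix >= 1 & ix <= grid$R & iy >= 1 & iy <= grid$R
  zone <- rep("B", nrow(regional_scores))
  zone[inside] <- ifelse(niche$mask[cbind(ix[inside], iy[inside])], "A", "B")
  dplyr::mutate(regional_scores, zone = zone)
}

#' Attach elevations to classified regional points
#'
#' Synthetic regions carry elevations natively and bypass the DEM; points
#' from geographic coordinates are sampled from a gridded digital elevation
#' model by nearest-cell lookup (no interpolation, so results are
#' bit-stable).
#'
#' @param points tibble of classified points. If an `elevation` column is
#'   present it is used directly; otherwise `lon`/`lat` columns are looked
#'   up in `dem`.
#' @param dem optional DEM as a list with ascending coordinate vectors `x`,
#'   `y` and matrix `z` (`length(x)` x `length(y)`) of elevations.
#' @return a suitability table: tibble with `id`, `pc1`, `pc2`, `zone`,
#'   `elevation`.
#' @export
attach_elevation <- function(points, dem = NULL) {
  if (!"elevation" %in% names(points)) {
    if (is.null(dem)) abort("points carry no `elevation` and no DEM given.")
    stopifnot(all(c("x", "y", "z") %in% names(dem)))
    outside <- points$lon < min(dem$x) | points$lon > max(dem$x) |
      points$lat < min(dem$y) | points$lat > max(dem$y)
    if (any(outside))
      abort(paste0("points outside DEM extent: ",
                   paste(utils::head(points$id[outside], 10), collapse = ", ")))
    ix <- purrr::map_int(points$lon, ~ which.min(abs(dem$x - .x)))
    iy <- purrr::map_int(points$lat, ~ which.min(abs(dem$y - .x)))
    points$elevation <- dem$z[cbind(ix, iy)]
  }
  if (!"id" %in% names(points)) points$id <- seq_len(nrow(points))
  dplyr::select(points, "id", dplyr::any_of(c("pc1", "pc2")), "zone",
                "elevation")
}

#' Presence/absence series along elevation
#'
#' Turns a suitability table into the HOF input: one (elevation, indicator)
#' pair per regional point, suitable zone A coded 1 and unsuitable zone B
#' coded 0, sorted by elevation. Degenerate all-A or all-B series are
#' allowed but flagged (attribute `flag`), since response-curve fitting
#' cannot locate an upper limit without contrast.
#'
#' @param table a suitability table from [attach_elevation()] (any tibble
#'   with `zone` and `elevation` columns works).
#' @return tibble with `elevation` and `presence`, sorted by elevation.
#' @export
make_pa_series <- function(table) {
  if (nrow(table) == 0) abort("empty suitability table.")
  pa <- table |>
    dplyr::transmute(elevation = .data$elevation,
                     presence = as.integer(.data$zone == "A")) |>
    dplyr::arrange(.data$elevation)
  flag <- NULL
  if (all(pa$presence == 1)) {
    flag <- "no_upper_contrast"
    inform("all points suitable: series has no upper contrast")
  } else if (all(pa$presence == 0)) {
    flag <- "no_presences"
    inform("no suitable points: species has no regional presence signal")
  }
  attr(pa, "flag") <- flag
  pa
}
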