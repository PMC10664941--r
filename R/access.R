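#' Travel-speed table for the friction surface
#'
#' Per-landcover-class travel speeds (km/h), the on-road speed, a
#' per-degree slope penalty factor, and the walking floor speed applied to
#' barrier classes (water/protected) unless they are configured
#' impassable. Defaults describe a mixed motorised/walking scenario; a
#' walking-only analysis is a second table with all speeds near walking
#' pace.
#'
#' @param landcover_speeds named numeric, km/h per class of
#'   [landcover_classes] (barrier classes may be `NA`: floor applies).
#' @param road_speed km/h on road cells.
#' @param slope_penalty multiplicative speed factor per degree of slope,
#'   in (0, 1].
#' @param walking_floor km/h used for barrier classes (and as a global
#'   lower bound on effective speed).
#' @param barrier_impassable if `TRUE`, barrier cells get infinite
#'   friction instead of the walking floor.
#' @return object of class `speed_table`.
#' @export
speed_table <- function(landcover_speeds = c(builtup = 30, cropland = 10,
                                             trees = 8, grassland = 15,
                                             water_protected = NA),
                        road_speed = 60, slope_penalty = 0.97,
                        walking_floor = 1, barrier_impassable = FALSE) {
  if (slope_penalty <= 0 || slope_penalty > 1)
    stop("slope_penalty must lie in (0, 1]")
  if (walking_floor <= 0) stop("walking_floor must be positive")
  if (any(!is.na(landcover_speeds) & landcover_speeds <= 0))
    stop("all speeds must be positive")
  structure(list(landcover_speeds = landcover_speeds,
                 road_speed = road_speed, slope_penalty = slope_penalty,
                 walking_floor = walking_floor,
                 barrier_impassable = barrier_impassable),
            class = "speed_table")
}

#' Build the friction surface (minutes per metre)
#'
#' Cell speed is the road speed where a road is present, otherwise the
#' landcover-class speed, multiplied by `slope_penalty^(slope in degrees)`
#' and floored at the walking floor. Barrier classes (NA speed) get the
#' walking floor, or infinite friction if configured impassable. Friction
#' is `60 / (speed_kmh * 1000)` minutes per metre.
#'
#' @param landcover categorical landcover `grid_layer`.
#' @param roads 0/1 road `grid_layer`.
#' @param elevation elevation `grid_layer` (metres), used for slope.
#' @param speeds a [speed_table()].
#' @return friction `grid_layer` (min/m).
#' @export
build_friction_surface <- function(landcover, roads, elevation,
                                   speeds = speed_table()) {
  stopifnot_same_grid(landcover, roads, elevation)
  lc <- landcover$values
  codes <- sort(unique(as.vector(lc[!is.na(lc)])))
  known <- landcover_classes[names(speeds$landcover_speeds)]
  if (!all(codes %in% known))
    stop("unknown landcover class code(s): ",
         paste(setdiff(codes, known), collapse = ", "))
  sp_by_code <- stats::setNames(speeds$landcover_speeds, known)
  v <- matrix(sp_by_code[as.character(lc)], nrow(lc), ncol(lc))
  barrier <- is.na(v) & !is.na(lc)
  v[barrier] <- if (speeds$barrier_impassable) 0 else speeds$walking_floor
  road <- !is.na(roads$values) & roads$values > 0
  v[road] <- speeds$road_speed
  sl <- slope_degrees(elevation)$values
  v <- v * speeds$slope_penalty^sl
  impassable <- barrier & speeds$barrier_impassable
  v[!impassable] <- pmax(v[!impassable], speeds$walking_floor)
  fr <- 60 / (v * 1000)
  fr[impassable] <- Inf
  fr[is.na(lc)] <- NA_real_
  grid_layer(fr, landcover$cell_size, landcover$origin,
             name = "friction_min_per_m")
}

lattice_edges <- function(nr, nc) {
  idx <- matrix(seq_len(nr * nc), nr, nc)  # column-major cell ids
  e <- list(
    cbind(as.vector(idx[-nr, ]), as.vector(idx[-1, ]), 1),          # down
    cbind(as.vector(idx[, -nc]), as.vector(idx[, -1]), 1),          # right
    cbind(as.vector(idx[-nr, -nc]), as.vector(idx[-1, -1]), sqrt(2)),
    cbind(as.vector(idx[-1, -nc]), as.vector(idx[-nr, -1]), sqrt(2)))
  do.call(rbind, e)
}

#' Travel time to the nearest treating facility
#'
#' Exact multi-source Dijkstra over the 8-connected cell lattice. The
#' cost of an edge is the centre-to-centre distance (cell size, or cell
#' size x sqrt(2) diagonally) times the mean of the two cells' frictions.
#'
#' @param friction friction `grid_layer` (min/m), `Inf` = impassable.
#' @param facility_cells matrix/data.frame with columns `row`, `col` (or a
#'   facility data.frame from [generate_facilities()]).
#' @return travel-time `grid_layer` in minutes (0 at facility cells,
#'   `Inf` where unreachable).
#' @export
travel_time_surface <- function(friction, facility_cells) {
  f <- friction$values
  nr <- nrow(f); nc <- ncol(f)
  fc <- as.matrix(as.data.frame(facility_cells)[, c("row", "col")])
  if (nrow(fc) < 1L) stop("at least one facility is required")
  if (any(fc[, 1] < 1 | fc[, 1] > nr | fc[, 2] < 1 | fc[, 2] > nc))
    stop("facility outside the grid")
  ed <- lattice_edges(nr, nc)
  fa <- as.vector(f)[ed[, 1]]
  fb <- as.vector(f)[ed[, 2]]
  w <- ed[, 3] * friction$cell_size * (fa + fb) / 2
  keep <- is.finite(w)
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, t(ed[keep, 1:2]))
  igraph::E(g)$weight <- w[keep]
  src <- unique((fc[, 2] - 1L) * nr + fc[, 1])
  d <- igraph::distances(g, v = src, algorithm = "dijkstra")
  tt <- matrix(apply(d, 2L, min), nr, nc)
  tt[is.na(f)] <- NA_real_
  grid_layer(tt, friction$cell_size, friction$origin,
             name = "travel_time_min")
}

#' Per-EA travel time
#'
#' Population-weighted mean of cell travel times within each EA, or the
#' unweighted mean when no population raster is supplied (the default;
#' whether the source analysis weighted by population is unstated).
#'
#' @param surface travel-time `grid_layer`.
#' @param eas an `ea_set` or EA-id `grid_layer`.
#' @param population optional population `grid_layer` of cell weights.
#' @return data.frame: `ea_id`, `minutes`, `missing`.
#' @export
zonal_travel_time <- function(surface, eas, population = NULL) {
  ear <- resolve_ea_raster(eas)
  stopifnot_same_grid(surface, ear)
  ids <- if (inherits(eas, "ea_set")) eas$table$ea_id
         else sort(unique(as.vector(ear$values)))
  v <- as.vector(surface$values)
  z <- as.vector(ear$values)
  w <- if (is.null(population)) rep(1, length(v))
       else { stopifnot_same_grid(surface, population)
              as.vector(population$values) }
  ok <- !is.na(v) & !is.na(z) & !is.na(w) & is.finite(v)
  num <- tapply(v[ok] * w[ok], z[ok], sum)
  den <- tapply(w[ok], z[ok], sum)
  m <- rep(NA_real_, length(ids))
  idx <- match(names(num), as.character(ids))
  m[idx] <- as.numeric(num) / as.numeric(den)
  data.frame(ea_id = ids, minutes = m, missing = is.na(m))
}
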