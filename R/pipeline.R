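#' Run the full risk pipeline on a synthetic landscape
#'
#' simulate -> species richness -> travel time -> fragmentation ->
#' four risk indices -> the two cluster analyses -> registry statistics.
#'
#' @param config a [landscape_config()].
#' @param speeds a [speed_table()] for the friction surface.
#' @param n_c number of risk-profile clusters.
#' @return list: `sim` (generator bundle), `richness` (layer), `zonal`
#'   (per-EA richness), `travel_time` (layer + per-EA), `indices` (the
#'   four `risk_index` objects), `clusters` (list `risk`, `outcome`),
#'   `epi` (elevation fit + key tabulations).
#' @export
run_pipeline <- function(config = landscape_config(),
                         speeds = speed_table(), n_c = 4L) {
  sim <- simulate_landscape(config)

  thr <- species_thresholds(sim$species$occurrences)
  richness <- binarize_and_stack(sim$species$suitability, thr)
  zr <- zonal_mean(richness, sim$eas)

  friction <- build_friction_surface(sim$rasters$landcover,
                                     sim$rasters$roads,
                                     sim$rasters$elevation, speeds)
  tt <- travel_time_surface(friction, sim$facilities)
  ztt <- zonal_travel_time(tt, sim$eas)

  frag <- landscape_metrics(sim$rasters$landcover, sim$eas)
  counts <- attr(sim$cases, "ea_counts")
  indices <- build_all_indices(sim$eas$table, zr, counts, ztt, frag)

  clusters <- list(
    risk = run_analysis(indices, include_scarcity = FALSE, n_c = n_c),
    outcome = run_analysis(indices, include_scarcity = TRUE, n_c = n_c))

  person_years <- sim$eas$table$population * config$years
  fit <- poisson_elevation_fit(counts$cases, sim$truth$mean_elevation,
                               person_years)
  epi <- list(
    elevation_fit = fit,
    annual_average = annual_average(sim$cases, config$years),
    by_month = tabulate_cases(sim$cases, "month"),
    by_sex = tabulate_cases(sim$cases, "sex"),
    by_syndrome = tabulate_cases(sim$cases, "syndrome"))

  list(sim = sim, richness = richness, zonal = zr,
       travel_time = list(surface = tt, by_ea = ztt),
       friction = friction, indices = indices, clusters = clusters,
       epi = epi)
}

#' Export a simulated landscape to plain-text files
#'
#' Writes the EA table and case registry as CSV, rasters as ESRI ASCII
#' grids, EA polygons and facilities as GeoJSON, and the truth table as
#' CSV.
#'
#' @param sim output of [simulate_landscape()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_landscape <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(sim$eas$table, p("eas.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, p("truth.csv"), row.names = FALSE)
  utils::write.csv(sim$cases, p("cases.csv"), row.names = FALSE)
  utils::write.csv(sim$facilities, p("facilities.csv"), row.names = FALSE)
  write_grid_asc(sim$rasters$elevation, p("elevation.asc"))
  write_grid_asc(sim$rasters$landcover, p("landcover.asc"))
  write_grid_asc(sim$rasters$roads, p("roads.asc"))
  for (s in seq_along(sim$species$suitability))
    write_grid_asc(sim$species$suitability[[s]],
                   p(sprintf("suitability_sp%02d.asc", s)))
  utils::write.csv(sim$species$occurrences, p("occurrences.csv"),
                   row.names = FALSE)
  write_ea_geojson(sim$eas, p("eas.geojson"))
  write_facilities_geojson(sim$facilities, p("facilities.geojson"))
  invisible(dir)
}

#' Write EA block polygons as GeoJSON
#'
#' @param eas an `ea_set`.
#' @param path output file.
#' @param properties optional data.frame (keyed by `ea_id`) of extra
#'   per-feature properties, e.g. cluster labels for choropleth joins.
#' @return `path`, invisibly.
#' @export
write_ea_geojson <- function(eas, path, properties = NULL) {
  tab <- eas$table
  nr <- nrow(eas$raster$values)
  cs <- eas$raster$cell_size
  org <- eas$raster$origin
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    e <- tab[i, ]
    x0 <- org[1] + (e$col0 - 1) * cs; x1 <- org[1] + e$col1 * cs
    y1 <- org[2] + (nr - e$row0 + 1) * cs; y0 <- org[2] + (nr - e$row1) * cs
    props <- list(ea_id = e$ea_id, archetype = e$archetype,
                  population = e$population)
    if (!is.null(properties)) {
      j <- match(e$ea_id, properties$ea_id)
      for (nm in setdiff(names(properties), "ea_id"))
        props[[nm]] <- properties[[nm]][j]
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(list(
           c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_facilities_geojson <- function(facilities, path) {
  feats <- lapply(seq_len(nrow(facilities)), function(i) {
    f <- facilities[i, ]
    list(type = "Feature",
         properties = list(facility_id = f$facility_id, ea_id = f$ea_id,
                           treats_snakebite = f$treats_snakebite),
         geometry = list(type = "Point", coordinates = c(f$x, f$y)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
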