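#' Landcover class codes used by the synthetic landscape
#'
#' Integer codes of the categorical landcover raster: 1 built-up, 2 cropland,
#' 3 trees, 4 grassland, 5 water/protected (treated as a movement barrier
#' class by the healthcare-access module).
#' @export
landcover_classes <- c(builtup = 1, cropland = 2, trees = 3,
                       grassland = 4, water_protected = 5)

archetype_levels <- c("urban", "peri_urban", "commercial_protected",
                      "rural_poor")

## Archetype covariate profiles. The four planted archetypes realize the
## risk-profile semantics seen in EA-level snakebite risk mapping: urban EAs have
## very high exposure (building density, built-up cover) and very low
## susceptibility; peri-urban EAs low exposure and moderate-low
## susceptibility but frequent reported bites; commercial/agriculture and
## protected EAs moderate exposure (cropland/tree cover) with very low
## reported-case counts (tiny populations); rural-poor EAs very high
## susceptibility (poverty, firewood cooking, candle/paraffin lighting).
## Means are separated relative to the within-archetype sd so the planted
## structure is recoverable downstream.
archetype_profiles <- data.frame(
  archetype = archetype_levels,
  poverty            = c(0.10, 0.30, 0.45, 0.70),
  prop_firewood      = c(0.05, 0.30, 0.45, 0.85),
  prop_candles_paraffin = c(0.05, 0.25, 0.40, 0.70),
  prop_elderly       = c(0.03, 0.05, 0.06, 0.09),
  prop_children_youth = c(0.45, 0.55, 0.50, 0.62),
  building_density   = c(350, 60, 15, 35),    # buildings per km^2
  building_occupancy = c(5.5, 4.0, 3.5, 4.5), # persons per building
  poultry_prob       = c(0.30, 0.50, 0.40, 0.80),
  prop_builtup       = c(0.70, 0.15, 0.05, 0.05),
  prop_cropland      = c(0.05, 0.15, 0.55, 0.20),
  prop_trees         = c(0.05, 0.10, 0.35, 0.20),
  mean_population    = c(8000, 4000, 800, 2200),
  log_rate_effect    = c(-0.5, -0.1, -0.3, 0.3),
  stringsAsFactors = FALSE
)

prop_sd <- 0.04          # within-archetype sd of proportion covariates
bdens_sdlog <- 0.25      # lognormal sdlog of building density
pop_sdlog <- 0.30        # lognormal sdlog of EA population

#' Default categorical case-attribute distributions
#'
#' Probability tables driving the synthetic case registry: month of bite
#' (January peak, summer-heavy), hour of day (exactly 30% mass on the
#' 18:00-21:59 window), age band, sex, occupation, bite site, activity,
#' indoor/outdoor location, clinical syndrome (55% cytotoxic:
#' mild swelling, painful progressive swelling or venom ophthalmia),
#' first aid (66% any; 83% of those a tourniquet), antivenom receipt
#' (200/932), vials (truncated geometric on 1..25 with mean 5),
#' adrenaline pretreatment, adverse reaction, and outcome.
#'
#' @return named list of named probability vectors / scalars.
#' @export
default_attribute_tables <- function() {
  hour_window <- c(`18` = 0.085, `19` = 0.080, `20` = 0.070, `21` = 0.065)
  other_w <- c(`0` = .4, `1` = .3, `2` = .3, `3` = .3, `4` = .4, `5` = .6,
               `6` = .9, `7` = 1.1, `8` = 1.3, `9` = 1.3, `10` = 1.3,
               `11` = 1.3, `12` = 1.3, `13` = 1.3, `14` = 1.4, `15` = 1.6,
               `16` = 1.9, `17` = 2.4, `22` = 1.6, `23` = .8)
  other_w <- other_w / sum(other_w) * (1 - sum(hour_window))
  hour <- c(other_w, hour_window)
  hour <- hour[order(as.integer(names(hour)))]

  list(
    month = c(Jan = .155, Feb = .130, Mar = .110, Apr = .070, May = .050,
              Jun = .020, Jul = .015, Aug = .020, Sep = .050, Oct = .090,
              Nov = .140, Dec = .150),
    hour = hour,
    age_band = c(`0-9` = .125, `10-19` = .270, `20-29` = .187,
                 `30-39` = .145, `40-49` = .069, `50-59` = .048,
                 `60-69` = .025, `70-79` = .018, `80+` = .013,
                 `not recorded` = .100),
    sex = c(male = 511 / 932, female = 421 / 932),
    occupation = c(
      managers = 0, professionals = 7, technicians = 2, clerical = 1,
      services_sales = 11, skilled_agricultural = 20, craft_trades = 14,
      plant_machine_operators = 2, elementary = 65, armed_forces = 4,
      unemployed = 212, student = 327, self_employed = 13, retiree = 33,
      preschool_child = 53, unknown = 168) / 932,
    bite_site = c(foot_ankle_toe = .60, hand_finger_wrist = .14, leg = .08,
                  arm = .04, head_face = .02, trunk = .03,
                  `not recorded` = .09),
    activity = c(walking = .27, farming = .08, fetching_water = .06,
                 playing = .07, sleeping = .05, household_chores = .10,
                 other = .15, `not recorded` = .22),
    location = c(outdoors = .65, indoors = .13, `not recorded` = .22),
    syndrome = c(asymptomatic = .370, mild_swelling = .300,
                 painful_progressive_swelling = .245,
                 venom_ophthalmia = .005, progressive_weakness = .045,
                 bleeding = .002, `not recorded` = .033),
    first_aid_any = 0.66,
    first_aid_given_any = c(tourniquet = 0.83, incision = 0.10,
                            herbal = 0.12, bandage = 0.15),
    antivenom = 200 / 932,
    vials_mean = 5, vials_max = 25,
    adrenaline_given_antivenom = 0.84,
    reaction_given_antivenom = 0.35,
    outcome = c(recovered = .9302, died = .0107,
                long_term_impairment = .0086, unknown = .0505)
  )
}

#' Configuration of the synthetic mini-country
#'
#' Collects every tunable of the generator; defaults emulate a small
#' southern-African country: a 120 x 120 grid at 500 m, elevation spanning 71-1499 m,
#' 11 venomous species, ~400 enumeration areas over four archetypes
#' (urban, peri-urban, commercial/protected, rural-poor), 20 treating
#' health facilities, a 3.8% decrease in case rate per 100 m elevation
#' gain, and reported case-attribute distributions.
#'
#' @param rng_seed integer master seed; every generator stage derives its
#'   own child stream from it.
#' @param grid_rows,grid_cols grid dimensions (>= 20).
#' @param cell_size cell edge in metres.
#' @param n_species number of venomous species modelled.
#' @param n_eas number of enumeration areas (tiled blocks).
#' @param archetype_mix named proportions over the four archetypes, sum 1.
#' @param elevation_range metres, length 2 increasing.
#' @param elevation_noise relative amplitude of the smooth elevation noise
#'   field (0 gives a strictly monotone gradient).
#' @param elevation_rate_effect proportional decrease in case rate per
#'   100 m elevation gain, in [0, 1).
#' @param baseline_rate expected cases per 1,000 population per year at
#'   sea level for a zero-archetype-effect EA.
#' @param years registry observation period in years.
#' @param n_facilities number of treating health facilities.
#' @param n_urban_seeds number of urban cores on the landcover raster.
#' @param case_attribute_tables list as from [default_attribute_tables()].
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(rng_seed = 1L,
                             grid_rows = 120L, grid_cols = 120L,
                             cell_size = 500,
                             n_species = 11L,
                             n_eas = 400L,
                             archetype_mix = c(urban = 0.10,
                                               peri_urban = 0.20,
                                               commercial_protected = 0.15,
                                               rural_poor = 0.55),
                             elevation_range = c(71, 1499),
                             elevation_noise = 0.15,
                             elevation_rate_effect = 0.038,
                             baseline_rate = 0.5,
                             years = 2,
                             n_facilities = 20L,
                             n_urban_seeds = 3L,
                             case_attribute_tables = default_attribute_tables()) {
  if (grid_rows < 20L || grid_cols < 20L)
    stop("grid dimensions must be at least 20 x 20")
  if (n_species < 1L) stop("n_species must be >= 1")
  if (length(elevation_range) != 2L ||
      elevation_range[2] <= elevation_range[1])
    stop("elevation_range must be an increasing pair of metres")
  if (!all(names(archetype_mix) == archetype_levels))
    stop("archetype_mix must be named: ",
         paste(archetype_levels, collapse = ", "))
  if (abs(sum(archetype_mix) - 1) > 1e-9)
    stop("archetype_mix must sum to 1")
  if (any(archetype_mix < 0 | archetype_mix > 1))
    stop("archetype_mix proportions must lie in [0, 1]")
  if (elevation_rate_effect < 0 || elevation_rate_effect >= 1)
    stop("elevation_rate_effect must lie in [0, 1)")
  if (baseline_rate < 0) stop("baseline_rate must be non-negative")
  tbl <- case_attribute_tables
  for (nm in c("month", "hour", "age_band", "sex", "occupation", "bite_site",
               "activity", "location", "syndrome", "outcome"))
    if (abs(sum(tbl[[nm]]) - 1) > 1e-8)
      stop("case attribute table '", nm, "' must sum to 1")
  structure(
    list(rng_seed = as.integer(rng_seed), grid_rows = as.integer(grid_rows),
         grid_cols = as.integer(grid_cols), cell_size = cell_size,
         n_species = as.integer(n_species), n_eas = as.integer(n_eas),
         archetype_mix = archetype_mix, elevation_range = elevation_range,
         elevation_noise = elevation_noise,
         elevation_rate_effect = elevation_rate_effect,
         baseline_rate = baseline_rate, years = years,
         n_facilities = as.integer(n_facilities),
         n_urban_seeds = as.integer(n_urban_seeds),
         case_attribute_tables = tbl),
    class = "landscape_config")
}

## integer apportionment by largest remainder; preserves names
largest_remainder <- function(x) {
  n <- floor(x)
  rem <- round(sum(x)) - sum(n)
  if (rem > 0) {
    add <- order(x - n, decreasing = TRUE)[seq_len(rem)]
    n[add] <- n[add] + 1L
  }
  stats::setNames(as.integer(n), names(x))
}

## smooth random field as a sum of Gaussian bumps, standardized to sd 1
smooth_field <- function(nr, nc, k = 8L, sigma_range = c(8, 20)) {
  f <- matrix(0, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(k)) {
    cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
    s <- stats::runif(1, sigma_range[1], sigma_range[2])
    a <- stats::rnorm(1)
    f <- f + a * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * s^2))
  }
  if (stats::sd(f) > 0) f <- (f - mean(f)) / stats::sd(f)
  f
}

## integer line rasterization between two cells (Bresenham-style)
line_cells <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  cbind(row = round(seq(r0, r1, length.out = n)),
        col = round(seq(c0, c1, length.out = n)))
}

## per-archetype landcover painting parameters: class probabilities
## (matching the archetype landcover-proportion means) and a clumping
## weight: large -> few big patches, small -> speckled mosaic. Peri-urban
## blocks are painted as fine-grained mosaics (high fragmentation),
## commercial/protected as large homogeneous estates (low fragmentation).
paint_probs <- rbind(
  urban                = c(.70, .05, .05, .15, .05),
  peri_urban           = c(.15, .15, .10, .55, .05),
  commercial_protected = c(.05, .55, .35, .02, .03),
  rural_poor           = c(.05, .20, .20, .50, .05))
paint_clump <- c(urban = 3, peri_urban = 0.4,
                 commercial_protected = 3, rural_poor = 1.5)

#' Generate the synthetic raster stack
#'
#' Elevation is a west-high / east-low gradient plus a smooth seeded noise
#' field, rescaled to span `elevation_range` exactly. The grid is tiled
#' into EA blocks; each block receives a latent archetype (by
#' elevation-stratified allocation honouring `archetype_mix`, with urban
#' blocks nearest the urban cores), and its landcover cells are painted
#' consistently with that archetype: built-up cores in urban blocks, large
#' cropland/tree estates in commercial/protected blocks, fine mixed
#' mosaics in peri-urban blocks. Roads connect the urban cores. The
#' latent block map is carried as an attribute and consumed by
#' [generate_eas()], keeping EA covariates and the raster coherent.
#'
#' @param config a [landscape_config()].
#' @return list with `grid_layer`s `elevation`, `landcover`, `roads`
#'   (0/1), plus attributes `urban_seeds` and `ea_blocks` (block table +
#'   block-id raster).
#' @export
generate_rasters <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  n_eas <- config$n_eas
  with_seed(child_seed(config$rng_seed, 1L), {
    ## elevation: monotone decreasing west -> east plus smooth noise
    base <- matrix(rep((nc - seq_len(nc)) / (nc - 1), each = nr), nr, nc)
    noise <- if (config$elevation_noise > 0)
      config$elevation_noise * smooth_field(nr, nc) else 0
    raw <- base + noise
    er <- config$elevation_range
    elev <- er[1] + (raw - min(raw)) / (max(raw) - min(raw)) * (er[2] - er[1])

    ## EA block tiling
    td <- tile_dims(n_eas, nr, nc)
    rlen <- split_runs(nr, td[1]); clen <- split_runs(nc, td[2])
    r1 <- cumsum(rlen); r0 <- r1 - rlen + 1L
    c1 <- cumsum(clen); c0 <- c1 - clen + 1L
    bl <- expand.grid(bi = seq_len(td[1]), bj = seq_len(td[2]))
    bl <- bl[order(bl$bi, bl$bj), ]
    blocks <- data.frame(ea_id = seq_len(n_eas),
                         row0 = r0[bl$bi], row1 = r1[bl$bi],
                         col0 = c0[bl$bj], col1 = c1[bl$bj])
    block_m <- matrix(0L, nr, nc)
    for (e in blocks$ea_id)
      block_m[blocks$row0[e]:blocks$row1[e],
              blocks$col0[e]:blocks$col1[e]] <- e
    blocks$mean_elevation <- as.numeric(tapply(elev, block_m, mean))

    ## urban cores, kept away from the border
    seeds <- cbind(row = round(stats::runif(config$n_urban_seeds,
                                            0.15 * nr, 0.85 * nr)),
                   col = round(stats::runif(config$n_urban_seeds,
                                            0.15 * nc, 0.85 * nc)))
    cen_r <- (blocks$row0 + blocks$row1) / 2
    cen_c <- (blocks$col0 + blocks$col1) / 2
    d_urb <- Reduce(pmin, lapply(seq_len(nrow(seeds)), function(i)
      sqrt((cen_r - seeds[i, 1])^2 + (cen_c - seeds[i, 2])^2)))

    ## elevation-stratified archetype allocation: archetype counts match
    ## the mix inside each elevation stratum, so every archetype's
    ## elevation distribution tracks the landscape's and the planted
    ## elevation-rate effect is not confounded by archetype rate effects
    f_comm <- smooth_field(nr, nc)
    comm_score <- as.numeric(tapply(f_comm, block_m, mean))
    n_k <- largest_remainder(config$archetype_mix * n_eas)
    ord_elev <- order(blocks$mean_elevation)
    n_strata <- max(1L, min(10L, n_eas %/% 20L))
    stratum <- rep(seq_len(n_strata),
                   each = ceiling(n_eas / n_strata))[seq_len(n_eas)]
    archetype <- rep(NA_character_, n_eas)
    remaining <- n_k
    for (s in seq_len(n_strata)) {
      idx <- ord_elev[stratum == s]
      tgt <- pmin(largest_remainder(config$archetype_mix * length(idx)),
                  remaining)
      while (sum(tgt) < length(idx)) {
        j <- which.max(remaining - tgt)
        tgt[j] <- tgt[j] + 1L
      }
      remaining <- remaining - tgt
      by_urb <- idx[order(d_urb[idx])]
      urb <- by_urb[seq_len(tgt[["urban"]])]
      left <- setdiff(by_urb, urb)
      peri <- left[seq_len(tgt[["peri_urban"]])]
      left <- setdiff(left, peri)
      comm <- left[order(comm_score[left],
                         decreasing = TRUE)][seq_len(
                           tgt[["commercial_protected"]])]
      archetype[urb] <- "urban"
      archetype[peri] <- "peri_urban"
      archetype[comm] <- "commercial_protected"
      archetype[setdiff(left, comm)] <- "rural_poor"
    }
    blocks$archetype <- archetype

    ## paint landcover per block: class = argmax over classes of
    ## log(prob) + clump * spatial_field + Gumbel noise
    fields <- list(builtup = NULL, cropland = smooth_field(nr, nc),
                   trees = smooth_field(nr, nc), grassland = 0.3,
                   water_protected = smooth_field(nr, nc) - 1)
    lc <- matrix(0L, nr, nc)
    for (e in blocks$ea_id) {
      rs <- blocks$row0[e]:blocks$row1[e]
      cs_ <- blocks$col0[e]:blocks$col1[e]
      ncel <- length(rs) * length(cs_)
      a <- blocks$archetype[e]
      lam <- paint_clump[[a]]
      p <- paint_probs[a, ]
      ## built-up affinity: distance to block centre (compact core)
      ctr_r <- mean(rs); ctr_c <- mean(cs_)
      dctr <- sqrt(outer((rs - ctr_r)^2, (cs_ - ctr_c)^2, "+"))
      dctr <- 1 - dctr / (max(dctr) + 1e-9)
      sc <- matrix(NA_real_, ncel, 5L)
      for (k in 1:5) {
        f <- switch(k, dctr,
                    fields$cropland[rs, cs_], fields$trees[rs, cs_],
                    matrix(fields$grassland, length(rs), length(cs_)),
                    fields$water_protected[rs, cs_])
        sc[, k] <- log(p[k] + 1e-9) + lam * as.vector(f) -
          log(-log(stats::runif(ncel)))
      }
      lc[rs, cs_] <- matrix(max.col(sc, ties.method = "first"),
                            length(rs), length(cs_))
    }

    ## roads: chain the urban cores and tie them to the grid centre
    rd <- matrix(0, nr, nc)
    pts <- rbind(seeds, c(round(nr / 2), round(nc / 2)))
    for (i in seq_len(nrow(pts) - 1L)) {
      seg <- line_cells(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2])
      seg[, 1] <- pmin(pmax(seg[, 1], 1L), nr)
      seg[, 2] <- pmin(pmax(seg[, 2], 1L), nc)
      rd[seg] <- 1
    }

    out <- list(
      elevation = grid_layer(elev, config$cell_size, name = "elevation_m"),
      landcover = grid_layer(lc, config$cell_size, name = "landcover"),
      roads = grid_layer(rd, config$cell_size, name = "roads"))
    attr(out, "urban_seeds") <- seeds
    attr(out, "ea_blocks") <- list(
      table = blocks,
      raster = grid_layer(block_m, config$cell_size, name = "ea_id"))
    class(out) <- "landscape_rasters"
    out
  })
}

## nearly-equal integer partition of n into k runs; returns run lengths
split_runs <- function(n, k) {
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

## choose a tiling (a x b = n_eas) whose aspect matches the grid
tile_dims <- function(n_eas, nr, nc) {
  divs <- which(n_eas %% seq_len(n_eas) == 0)
  a <- divs[which.min(abs(log(divs^2 / n_eas) - log(nr / nc)))]
  c(a, n_eas %/% a)
}

#' Enumeration-area table with archetype-conditional covariates
#'
#' Consumes the latent EA block map created by [generate_rasters()] (which
#' fixes the tiling, the elevation-stratified archetype allocation, and an
#' archetype-consistent landcover raster) and draws the socio-economic
#' covariates from separated archetype means (see `archetype_profiles`):
#' the rural-poor archetype has the highest poverty/firewood means, the
#' urban archetype the highest building density. Landcover proportions
#' are computed zonally from the painted raster, so EA covariates and the
#' raster agree.
#'
#' @param config a [landscape_config()].
#' @param rasters output of [generate_rasters()].
#' @return list with `eas` (an `ea_set`: `$table` data.frame + `$raster`
#'   grid of EA ids) and `truth` (per-EA archetype, mean elevation and
#'   expected case rate per person-year).
#' @export
generate_eas <- function(config, rasters) {
  stopifnot(inherits(config, "landscape_config"))
  blocks_info <- attr(rasters, "ea_blocks")
  if (is.null(blocks_info))
    stop("`rasters` must come from generate_rasters() (ea_blocks missing)")
  n_eas <- config$n_eas
  stopifnot(nrow(blocks_info$table) == n_eas)
  with_seed(child_seed(config$rng_seed, 2L), {
    blocks <- blocks_info$table
    ea_raster <- blocks_info$raster
    ea_m <- ea_raster$values
    ea_id <- blocks$ea_id
    archetype <- blocks$archetype
    mean_elev <- blocks$mean_elevation

    lc <- rasters$landcover$values
    prop_class <- function(code)
      as.numeric(tapply(lc == code, ea_m, mean))

    prof <- archetype_profiles[match(archetype,
                                     archetype_profiles$archetype), ]
    draw_prop <- function(mu)
      pmin(pmax(stats::rnorm(n_eas, mu, prop_sd), 0.001), 0.999)
    tab <- data.frame(
      ea_id = ea_id, archetype = archetype,
      row0 = blocks$row0, row1 = blocks$row1,
      col0 = blocks$col0, col1 = blocks$col1,
      mean_elevation = mean_elev,
      population = pmax(50L, round(stats::rlnorm(
        n_eas, log(prof$mean_population), pop_sdlog))),
      poverty = draw_prop(prof$poverty),
      prop_firewood = draw_prop(prof$prop_firewood),
      prop_candles_paraffin = draw_prop(prof$prop_candles_paraffin),
      prop_elderly = draw_prop(prof$prop_elderly),
      prop_children_youth = draw_prop(prof$prop_children_youth),
      building_density = stats::rlnorm(n_eas, log(prof$building_density),
                                       bdens_sdlog),
      building_occupancy = pmax(1, stats::rnorm(n_eas,
                                                prof$building_occupancy, 0.4)),
      poultry = stats::rbinom(n_eas, 1, prof$poultry_prob),
      prop_builtup = prop_class(landcover_classes[["builtup"]]),
      prop_cropland = prop_class(landcover_classes[["cropland"]]),
      prop_trees = prop_class(landcover_classes[["trees"]]),
      stringsAsFactors = FALSE)

    rate <- config$baseline_rate / 1000 * exp(prof$log_rate_effect) *
      (1 - config$elevation_rate_effect)^(mean_elev / 100)
    truth <- data.frame(
      ea_id = ea_id, archetype = archetype, mean_elevation = mean_elev,
      expected_rate = rate,
      elevation_coef = log(1 - config$elevation_rate_effect),
      stringsAsFactors = FALSE)

    eas <- structure(list(table = tab, raster = ea_raster),
                     class = "ea_set")
    list(eas = eas, truth = truth)
  })
}

#' @export
print.ea_set <- function(x, ...) {
  cat(sprintf("<ea_set> %d enumeration areas on a %d x %d grid\n",
              nrow(x$table), nrow(x$raster$values), ncol(x$raster$values)))
  print(table(x$table$archetype))
  invisible(x)
}

#' Generate per-species suitability surfaces and occurrence points
#'
#' Each species' suitability is a logistic transform of a species-specific
#' linear combination of standardized elevation and landcover indicator
#' covariates (a stand-in for fitted niche-model output). Presence points
#' are sampled proportional to suitability; background points uniformly.
#'
#' @param config a [landscape_config()].
#' @param rasters output of [generate_rasters()].
#' @param weights optional `n_species x 7` matrix (intercept, elevation z,
#'   five landcover indicators); defaults to seeded Gaussian draws.
#' @param n_presence,n_background points sampled per species.
#' @return list with `suitability` (list of `grid_layer`s in `[0, 1]`),
#'   `occurrences` (data.frame: species, type, row, col, x, y, score) and
#'   the `weights` used.
#' @export
generate_species_layers <- function(config, rasters, weights = NULL,
                                    n_presence = 150L, n_background = 300L) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  ns <- config$n_species
  with_seed(child_seed(config$rng_seed, 3L), {
    elev <- rasters$elevation$values
    lc <- rasters$landcover$values
    X <- cbind(
      elev_z = as.vector((elev - mean(elev)) / stats::sd(elev)),
      vapply(landcover_classes, function(code) as.numeric(lc == code),
             numeric(nr * nc)))
    if (is.null(weights)) {
      weights <- cbind(stats::rnorm(ns, 0, 0.5),
                       matrix(stats::rnorm(ns * 6), ns, 6))
    }
    stopifnot(nrow(weights) == ns, ncol(weights) == 7L)
    colnames(weights) <- c("intercept", colnames(X))

    centers <- cell_centers(rasters$elevation)
    suit <- vector("list", ns)
    occ <- vector("list", ns)
    for (s in seq_len(ns)) {
      eta <- weights[s, 1] + X %*% weights[s, -1]
      p <- matrix(stats::plogis(eta), nr, nc)
      suit[[s]] <- grid_layer(p, config$cell_size,
                              name = sprintf("suitability_sp%02d", s))
      np <- min(n_presence, nr * nc)
      pres <- sample.int(nr * nc, np, prob = as.vector(p))
      bg <- sample.int(nr * nc, min(n_background, nr * nc))
      idx <- c(pres, bg)
      occ[[s]] <- data.frame(
        species = s,
        type = rep(c("presence", "background"), c(length(pres), length(bg))),
        row = centers$row[idx], col = centers$col[idx],
        x = centers$x[idx], y = centers$y[idx],
        score = as.vector(p)[idx])
    }
    list(suitability = suit, occurrences = do.call(rbind, occ),
         weights = weights)
  })
}

#' Place treating health facilities
#'
#' Facilities are placed in EAs sampled with archetype-dependent weights
#' concentrated on urban and peri-urban EAs, reflecting the observation
#' that treating facilities cluster in and near towns.
#'
#' @param config a [landscape_config()].
#' @param eas an `ea_set` from [generate_eas()].
#' @return data.frame: facility_id, ea_id, row, col, x, y, treats_snakebite.
#' @export
generate_facilities <- function(config, eas) {
  stopifnot(inherits(config, "landscape_config"), inherits(eas, "ea_set"))
  nf <- config$n_facilities
  if (nf < 1L) stop("at least one treating facility is required")
  with_seed(child_seed(config$rng_seed, 4L), {
    w_arch <- c(urban = 10, peri_urban = 5, commercial_protected = 1,
                rural_poor = 1)
    tab <- eas$table
    w <- w_arch[tab$archetype]
    pick <- sample.int(nrow(tab), nf, replace = TRUE, prob = w)
    row <- integer(nf); col <- integer(nf)
    for (i in seq_len(nf)) {
      e <- tab[pick[i], ]
      row[i] <- sample(e$row0:e$row1, 1L)
      col[i] <- sample(e$col0:e$col1, 1L)
    }
    nr <- nrow(eas$raster$values)
    cs <- eas$raster$cell_size
    data.frame(
      facility_id = seq_len(nf), ea_id = tab$ea_id[pick],
      row = row, col = col,
      x = eas$raster$origin[1] + (col - 0.5) * cs,
      y = eas$raster$origin[2] + (nr - row + 0.5) * cs,
      treats_snakebite = TRUE)
  })
}

## truncated geometric on 1..max_v tuned to a target mean
truncated_geometric_probs <- function(mean_v, max_v) {
  m_of_q <- function(q) {
    w <- q^(0:(max_v - 1))
    sum(seq_len(max_v) * w) / sum(w)
  }
  q <- stats::uniroot(function(q) m_of_q(q) - mean_v,
                      c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  w <- q^(0:(max_v - 1))
  w / sum(w)
}

sample_cat <- function(n, probs)
  sample(names(probs), n, replace = TRUE, prob = probs)

month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Generate the synthetic snakebite case registry
#'
#' Per-EA case counts are Poisson with
#' `log rate = log(baseline) + archetype effect +
#'  log(1 - elevation_rate_effect) * (EA mean elevation / 100 m)`,
#' scaled by EA population and the observation period. Case attributes are
#' drawn independently from the configured categorical tables.
#'
#' @param config a [landscape_config()].
#' @param eas an `ea_set` from [generate_eas()].
#' @param truth the matching truth table from [generate_eas()].
#' @param seed optional integer overriding the config-derived stream (used
#'   to draw replicate registries on one landscape).
#' @return data.frame of case records, one row per presentation.
#' @export
generate_cases <- function(config, eas, truth, seed = NULL) {
  stopifnot(inherits(config, "landscape_config"), inherits(eas, "ea_set"))
  if (config$baseline_rate < 0) stop("baseline_rate must be non-negative")
  if (is.null(seed)) seed <- child_seed(config$rng_seed, 5L)
  tbl <- config$case_attribute_tables
  with_seed(seed, {
    mu <- eas$table$population * truth$expected_rate * config$years
    counts <- stats::rpois(length(mu), mu)
    n <- sum(counts)
    ea_id <- rep(eas$table$ea_id, counts)
    if (n == 0L) {
      out <- empty_registry()
      attr(out, "ea_counts") <- data.frame(ea_id = eas$table$ea_id,
                                           cases = counts)
      return(out)
    }
    month_name <- sample_cat(n, tbl$month)
    month_num <- match(month_name, names(tbl$month))
    day <- vapply(month_num, function(m) sample.int(month_days[m], 1L), 1L)
    ## registry window spans two Oct-Sep years
    year <- ifelse(month_num >= 10,
                   sample(c(2019L, 2020L), n, replace = TRUE),
                   sample(c(2020L, 2021L), n, replace = TRUE))
    hour <- as.integer(sample_cat(n, tbl$hour))
    age_band <- sample_cat(n, tbl$age_band)
    age <- rep(NA_integer_, n)
    known <- age_band != "not recorded"
    lo <- suppressWarnings(as.integer(sub("-.*|\\+", "", age_band)))
    hi <- ifelse(age_band == "80+", 100L,
                 suppressWarnings(as.integer(sub(".*-", "", age_band))))
    age[known] <- lo[known] +
      floor(stats::runif(sum(known)) * (hi[known] - lo[known] + 1))
    sex <- sample_cat(n, tbl$sex)
    occupation <- sample_cat(n, tbl$occupation)
    location <- sample_cat(n, tbl$location)
    bite_site <- sample_cat(n, tbl$bite_site)
    activity <- sample_cat(n, tbl$activity)
    syndrome <- sample_cat(n, tbl$syndrome)
    syndrome[syndrome == "not recorded"] <- NA_character_

    fa_any <- stats::runif(n) < tbl$first_aid_any
    fg <- tbl$first_aid_given_any
    fa_tourniquet <- fa_any & stats::runif(n) < fg[["tourniquet"]]
    fa_incision <- fa_any & stats::runif(n) < fg[["incision"]]
    fa_herbal <- fa_any & stats::runif(n) < fg[["herbal"]]
    fa_bandage <- fa_any & stats::runif(n) < fg[["bandage"]]

    av <- stats::runif(n) < tbl$antivenom
    vial_p <- truncated_geometric_probs(tbl$vials_mean, tbl$vials_max)
    vials <- rep(NA_integer_, n)
    vials[av] <- sample.int(tbl$vials_max, sum(av), replace = TRUE,
                            prob = vial_p)
    adrenaline <- rep(NA, n)
    adrenaline[av] <- stats::runif(sum(av)) < tbl$adrenaline_given_antivenom
    reaction <- rep(NA, n)
    reaction[av] <- stats::runif(sum(av)) < tbl$reaction_given_antivenom
    outcome <- sample_cat(n, tbl$outcome)
    outcome[outcome == "unknown"] <- NA_character_

    out <- data.frame(
      case_id = seq_len(n), ea_id = ea_id,
      date = as.Date(sprintf("%d-%02d-%02d", year, month_num, day)),
      month = month_name, hour = hour, age_band = age_band, age = age,
      sex = sex, occupation = occupation, location = location,
      bite_site = bite_site, activity = activity, syndrome = syndrome,
      first_aid_any = fa_any, fa_tourniquet = fa_tourniquet,
      fa_incision = fa_incision, fa_herbal = fa_herbal,
      fa_bandage = fa_bandage, antivenom = av, vials = vials,
      adrenaline = adrenaline, reaction = reaction, outcome = outcome,
      elevation = truth$mean_elevation[match(ea_id, truth$ea_id)],
      stringsAsFactors = FALSE)
    attr(out, "ea_counts") <- data.frame(ea_id = eas$table$ea_id,
                                         cases = counts)
    out
  })
}

empty_registry <- function() {
  data.frame(case_id = integer(), ea_id = integer(),
             date = as.Date(character()), month = character(),
             hour = integer(), age_band = character(), age = integer(),
             sex = character(), occupation = character(),
             location = character(), bite_site = character(),
             activity = character(), syndrome = character(),
             first_aid_any = logical(), fa_tourniquet = logical(),
             fa_incision = logical(), fa_herbal = logical(),
             fa_bandage = logical(), antivenom = logical(),
             vials = integer(), adrenaline = logical(),
             reaction = logical(), outcome = character(),
             elevation = numeric(), stringsAsFactors = FALSE)
}

#' Simulate the complete synthetic mini-country
#'
#' Runs all five generators in order and returns their outputs in one
#' bundle: rasters, EAs + truth, species suitability layers, facilities
#' and the case registry.
#'
#' @param config a [landscape_config()].
#' @return list with elements `config`, `rasters`, `eas`, `truth`,
#'   `species`, `facilities`, `cases`.
#' @export
simulate_landscape <- function(config = landscape_config()) {
  rasters <- generate_rasters(config)
  ge <- generate_eas(config, rasters)
  species <- generate_species_layers(config, rasters)
  facilities <- generate_facilities(config, ge$eas)
  cases <- generate_cases(config, ge$eas, ge$truth)
  list(config = config, rasters = rasters, eas = ge$eas, truth = ge$truth,
       species = species, facilities = facilities, cases = cases)
}

#' Accumulate replicate registries until a target size
#'
#' Draws independent case registries on one fixed landscape (new Poisson
#' counts and attributes each replicate) until at least `n_target` records
#' exist, then returns the first `n_target`. Used for Monte-Carlo
#' calibration checks of the attribute tables.
#'
#' @param config a [landscape_config()].
#' @param n_target minimum number of case records.
#' @param max_replicates safety cap on replicate draws.
#' @return data.frame of exactly `n_target` case records.
#' @export
simulate_registry <- function(config = landscape_config(),
                              n_target = 10000L, max_replicates = 500L) {
  rasters <- generate_rasters(config)
  ge <- generate_eas(config, rasters)
  out <- list()
  n <- 0L
  r <- 0L
  while (n < n_target) {
    r <- r + 1L
    if (r > max_replicates)
      stop("registry accumulation did not reach n_target; ",
           "increase baseline_rate or max_replicates")
    cc <- generate_cases(config, ge$eas, ge$truth,
                         seed = child_seed(config$rng_seed, 5000L + r))
    out[[r]] <- cc
    n <- n + nrow(cc)
  }
  reg <- do.call(rbind, out)
  reg <- reg[seq_len(n_target), ]
  reg$case_id <- seq_len(n_target)
  rownames(reg) <- NULL
  reg
}
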