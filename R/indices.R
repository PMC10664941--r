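#' Variable specification for a risk index
#'
#' Declares how a raw EA covariate enters an index: its name, its risk
#' orientation (whether larger or smaller raw values are riskier) and the
#' index it belongs to.
#'
#' @param name column name in the EA table.
#' @param orientation "higher-is-worse" or "lower-is-worse".
#' @param index one of "hazard", "exposure", "susceptibility", "scarcity".
#' @return one-row data.frame; rows from several calls can be `rbind`-ed.
#' @export
variable_spec <- function(name, orientation = c("higher-is-worse",
                                                "lower-is-worse"),
                          index = c("hazard", "exposure", "susceptibility",
                                    "scarcity")) {
  data.frame(name = name, orientation = match.arg(orientation),
             index = match.arg(index), stringsAsFactors = FALSE)
}

#' Default variable specifications of the four risk indices
#'
#' Hazard: venomous species richness and reported bite count. Exposure:
#' landcover proportions (trees, cropland, built-up), building density and
#' occupancy, landscape fragmentation (edge density, Shannon diversity)
#' and poultry presence. Susceptibility: proportions of elderly and of
#' children/youth, poverty headcount, and firewood / candle-paraffin use.
#' Scarcity: travel time to the nearest treating facility. All variables
#' are higher-is-worse in these definitions.
#'
#' @return data.frame of [variable_spec()] rows.
#' @export
default_variable_specs <- function() {
  h <- function(n, ix) variable_spec(n, "higher-is-worse", ix)
  rbind(
    h("richness", "hazard"), h("bite_count", "hazard"),
    h("prop_trees", "exposure"), h("prop_cropland", "exposure"),
    h("prop_builtup", "exposure"), h("building_density", "exposure"),
    h("building_occupancy", "exposure"), h("edge_density", "exposure"),
    h("shannon", "exposure"), h("poultry", "exposure"),
    h("prop_elderly", "susceptibility"),
    h("prop_children_youth", "susceptibility"),
    h("poverty", "susceptibility"), h("prop_firewood", "susceptibility"),
    h("prop_candles_paraffin", "susceptibility"),
    h("travel_time", "scarcity"))
}

#' z-standardize matrix columns
#'
#' Subtracts each column's mean and divides by its standard deviation.
#' The population sd (divisor N) is the default; the choice never changes
#' similarity ranks.
#'
#' @param x numeric matrix (N x p), N >= 2.
#' @param sd_type "population" (divisor N) or "sample" (divisor N - 1).
#' @return list: `z` (standardized matrix), `means`, `sds`.
#' @export
zscore_columns <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  means <- colMeans(x)
  n <- nrow(x)
  sds <- apply(x, 2L, stats::sd)
  if (sd_type == "population") sds <- sds * sqrt((n - 1) / n)
  bad <- which(sds == 0)
  if (length(bad))
    stop("constant column(s) cannot be z-standardized: ",
         paste(colnames(x)[bad], collapse = ", "))
  z <- sweep(sweep(x, 2L, means), 2L, sds, "/")
  list(z = z, means = means, sds = sds)
}

#' Build the hypothetical worst-case reference
#'
#' For each variable of an index the reference takes the riskiest observed
#' value: the column maximum for higher-is-worse variables, the column
#' minimum for lower-is-worse ones. The reference is standardized with the
#' same means and sds as the EAs.
#'
#' @param ea_table data.frame with one row per EA.
#' @param specs data.frame of [variable_spec()] rows (a single index).
#' @param sd_type passed to [zscore_columns()].
#' @return list: `raw` (named reference values), `standardized`, plus the
#'   `means`/`sds` used.
#' @export
build_worst_case <- function(ea_table, specs,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  missing_v <- setdiff(specs$name, colnames(ea_table))
  if (length(missing_v))
    stop("EA table lacks variable(s): ", paste(missing_v, collapse = ", "))
  x <- as.matrix(ea_table[, specs$name, drop = FALSE])
  zs <- zscore_columns(x, sd_type)
  raw <- vapply(seq_len(nrow(specs)), function(j) {
    v <- x[, j]
    if (specs$orientation[j] == "higher-is-worse") max(v) else min(v)
  }, numeric(1))
  names(raw) <- specs$name
  list(raw = raw, standardized = (raw - zs$means) / zs$sds,
       means = zs$means, sds = zs$sds)
}

#' Cosine similarity of two vectors
#'
#' `sum(A * B) / (sqrt(sum(A^2)) * sqrt(sum(B^2)))`, in `[-1, 1]`.
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for a zero-norm vector")
  sum(a * b) / (na * nb)
}

#' Similarity-rank risk index
#'
#' The full worst-case ranking pipeline for one index: z-standardize the
#' raw EA variables, build the worst-case reference, compute the cosine
#' similarity of each standardized EA row against the standardized
#' reference, rank EAs from 1 (most similar to the worst case) to N, and
#' map ranks linearly to a normalized score: rank 1 -> 1, rank N -> 0.
#' Ties in similarity are broken first by Euclidean distance to the
#' reference (nearer ranks higher) and then stably by EA id; the distance
#' tie-break makes single-variable indices order exactly by the raw
#' variable in its risk orientation.
#'
#' @param ea_table data.frame with `ea_id` and the index variables.
#' @param specs [variable_spec()] rows for one index.
#' @param name index name.
#' @param sd_type passed to [zscore_columns()].
#' @return a `risk_index`: data.frame `ea_id`, `similarity`, `rank`,
#'   `score` with attributes `index_name`, `variables`, `reference`.
#' @export
similarity_rank_index <- function(ea_table, specs, name = "index",
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(ea_table) < 2L) stop("need at least 2 EAs")
  x <- as.matrix(ea_table[, specs$name, drop = FALSE])
  zs <- zscore_columns(x, sd_type)
  wc <- build_worst_case(ea_table, specs, sd_type)
  ref <- wc$standardized
  n <- nrow(x)
  sim <- rep(NA_real_, n)
  dist_ref <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    zi <- zs$z[i, ]
    dist_ref[i] <- sqrt(sum((zi - ref)^2))
    if (sum(zi^2) > 0 && sum(ref^2) > 0)
      sim[i] <- cosine_similarity(zi, ref)
  }
  if (anyNA(sim))
    warning("zero-norm standardized EA row(s); ranked after all others")
  ord <- order(-sim, dist_ref, ea_table$ea_id, na.last = TRUE)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  score <- (n - rank) / (n - 1)
  out <- data.frame(ea_id = ea_table$ea_id, similarity = sim,
                    rank = rank, score = score)
  attr(out, "index_name") <- name
  attr(out, "variables") <- specs$name
  attr(out, "reference") <- wc
  class(out) <- c("risk_index", "data.frame")
  out
}

#' Landscape fragmentation metrics per EA
#'
#' Shannon diversity `H = -sum(p_k log p_k)` over landcover class
#' proportions within each EA, and edge density: the number of 4-adjacent
#' cell pairs with differing classes (both cells inside the EA) times the
#' cell size, divided by EA area.
#'
#' @param landcover categorical landcover `grid_layer`.
#' @param eas an `ea_set` or EA-id `grid_layer`.
#' @return data.frame: `ea_id`, `shannon`, `edge_density` (m per m^2),
#'   `missing`.
#' @export
landscape_metrics <- function(landcover, eas) {
  ear <- resolve_ea_raster(eas)
  stopifnot_same_grid(landcover, ear)
  lc <- landcover$values
  z <- ear$values
  cs <- landcover$cell_size
  ids <- if (inherits(eas, "ea_set")) eas$table$ea_id
         else sort(unique(as.vector(z)))
  nr <- nrow(lc); nc <- ncol(lc)

  ## horizontal and vertical adjacent pairs inside the same EA
  count_edges <- function(a_lc, b_lc, a_z, b_z) {
    same_ea <- !is.na(a_z) & !is.na(b_z) & a_z == b_z
    diff_lc <- !is.na(a_lc) & !is.na(b_lc) & a_lc != b_lc
    sel <- same_ea & diff_lc
    tapply(rep(1L, sum(sel)), a_z[sel], sum)
  }
  eh <- count_edges(lc[, -nc], lc[, -1], z[, -nc], z[, -1])
  ev <- count_edges(lc[-nr, ], lc[-1, ], z[-nr, ], z[-1, ])

  edges <- rep(0, length(ids))
  for (tt in list(eh, ev)) {
    idx <- match(names(tt), as.character(ids))
    edges[idx[!is.na(idx)]] <- edges[idx[!is.na(idx)]] +
      as.numeric(tt)[!is.na(idx)]
  }
  ncells <- as.numeric(table(factor(as.vector(z), levels = ids)))
  shannon <- vapply(ids, function(e) {
    cls <- lc[!is.na(z) & z == e]
    if (length(cls) == 0L) return(NA_real_)
    p <- table(cls) / length(cls)
    -sum(p * log(p))
  }, numeric(1))
  area <- ncells * cs^2
  data.frame(ea_id = ids, shannon = shannon,
             edge_density = ifelse(ncells > 0, edges * cs / area, NA_real_),
             missing = ncells == 0L)
}

#' Build the four risk indices
#'
#' Assembles the per-EA variable table (richness, reported bite counts,
#' exposure covariates and fragmentation metrics, susceptibility
#' covariates, travel time) and applies [similarity_rank_index()] per
#' index. EAs with missing values in an index's variables are excluded
#' from that index with a warning (no imputation).
#'
#' @param ea_table EA covariate table (from `ea_set$table`).
#' @param richness per-EA mean species richness (data.frame from
#'   [zonal_mean()] or named vector aligned to `ea_id`).
#' @param case_counts data.frame `ea_id`, `cases`.
#' @param travel_time data.frame `ea_id`, `minutes` (or `mean`).
#' @param fragmentation optional data.frame from [landscape_metrics()].
#' @param specs variable specification table
#'   (default [default_variable_specs()]).
#' @return named list of four `risk_index` objects: hazard, exposure,
#'   susceptibility, scarcity.
#' @export
build_all_indices <- function(ea_table, richness, case_counts, travel_time,
                              fragmentation = NULL,
                              specs = default_variable_specs()) {
  tab <- ea_table
  add_col <- function(tab, df, value_col, new_name) {
    if (is.data.frame(df)) {
      idx <- match(tab$ea_id, df$ea_id)
      if (anyNA(idx)) stop("EA id mismatch while joining ", new_name)
      tab[[new_name]] <- df[[value_col]][idx]
    } else tab[[new_name]] <- df[as.character(tab$ea_id)]
    tab
  }
  rc <- if (is.data.frame(richness) && "mean" %in% names(richness))
    "mean" else "richness"
  tab <- add_col(tab, richness, rc, "richness")
  tab <- add_col(tab, case_counts, "cases", "bite_count")
  tc <- if (is.data.frame(travel_time) && "minutes" %in% names(travel_time))
    "minutes" else "mean"
  tab <- add_col(tab, travel_time, tc, "travel_time")
  if (!is.null(fragmentation)) {
    tab <- add_col(tab, fragmentation, "shannon", "shannon")
    tab <- add_col(tab, fragmentation, "edge_density", "edge_density")
  }
  out <- list()
  for (ix in c("hazard", "exposure", "susceptibility", "scarcity")) {
    sp <- specs[specs$index == ix, , drop = FALSE]
    sub <- tab[, c("ea_id", sp$name)]
    ok <- stats::complete.cases(sub)
    if (!all(ok))
      warning(sum(!ok), " EA(s) with missing values excluded from the ",
              ix, " index")
    out[[ix]] <- similarity_rank_index(sub[ok, ], sp, name = ix)
  }
  out
}
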