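#' Stepwise collinearity pruning by variance inflation factor
#'
#' Iteratively removes the covariate with the largest VIF while that VIF
#' exceeds `threshold` (one variable per iteration, as `vifstep` does).
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column
#' `j` on the remaining columns; exact collinearity gives an infinite VIF.
#' Constant columns have no defined VIF and are dropped first with a
#' warning.
#'
#' @param x numeric matrix or data.frame (n rows x p named columns).
#' @param threshold VIF above which a variable is eliminated (default 10).
#' @return character vector of surviving column names, in input order.
#' @export
vif_stepwise <- function(x, threshold = 10) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("columns must be named")
  if (nrow(x) < 2L) stop("need at least 2 rows to compute VIFs")
  keep <- colnames(x)
  const <- keep[apply(x, 2L, function(v) stats::var(v) == 0)]
  if (length(const)) {
    warning("constant column(s) removed (VIF undefined): ",
            paste(const, collapse = ", "))
    keep <- setdiff(keep, const)
  }
  vif_one <- function(j, cols) {
    y <- x[, j]
    others <- x[, setdiff(cols, j), drop = FALSE]
    if (ncol(others) == 0L) return(1)
    fit <- stats::lm.fit(cbind(1, others), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(keep) <= 1L) break
    vifs <- vapply(keep, vif_one, numeric(1), cols = keep)
    worst <- which.max(vifs)
    if (vifs[worst] <= threshold) break
    keep <- keep[-worst]
  }
  keep
}

#' max(sensitivity + specificity) threshold for presence-only scores
#'
#' Among candidate thresholds (the unique pooled scores), returns the
#' smallest candidate `t` maximizing
#' `sensitivity(score >= t) + specificity(score < t)`. Classification is
#' presence when `score >= t` (closed on the presence side); the smallest
#' optimal candidate is returned on ties, making the resulting maps
#' maximally inclusive.
#'
#' @param scores_presence numeric scores at presence points.
#' @param scores_background numeric scores at background points.
#' @return the selected threshold (scalar).
#' @export
max_sss_threshold <- function(scores_presence, scores_background) {
  if (length(scores_presence) == 0L || length(scores_background) == 0L)
    stop("presence and background score sets must be non-empty")
  cand <- sort(unique(c(scores_presence, scores_background)))
  sss <- vapply(cand, function(t)
    mean(scores_presence >= t) + mean(scores_background < t), numeric(1))
  cand[which.max(sss)]   # which.max takes the first (smallest) maximizer
}

#' Binarize suitability layers and stack into species richness
#'
#' Cell richness is the number of species whose suitability meets or
#' exceeds that species' threshold. A cell that is nodata in any layer is
#' nodata in the richness layer.
#'
#' @param suitabilities list of suitability `grid_layer`s on one grid.
#' @param thresholds numeric vector, one threshold per species.
#' @return integer richness `grid_layer` with attribute `species_count`.
#' @export
binarize_and_stack <- function(suitabilities, thresholds) {
  ns <- length(suitabilities)
  if (length(thresholds) != ns)
    stop("need exactly one threshold per species")
  do.call(stopifnot_same_grid, suitabilities)
  ref <- suitabilities[[1L]]
  rich <- matrix(0, nrow(ref$values), ncol(ref$values))
  na_mask <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  for (s in seq_len(ns)) {
    v <- suitabilities[[s]]$values
    na_mask <- na_mask | is.na(v)
    rich <- rich + (!is.na(v) & v >= thresholds[s])
  }
  rich[na_mask] <- NA_real_
  out <- grid_layer(rich, ref$cell_size, ref$origin, name = "richness")
  attr(out, "species_count") <- ns
  out
}

resolve_ea_raster <- function(eas) {
  if (inherits(eas, "ea_set")) eas$raster
  else if (inherits(eas, "grid_layer")) eas
  else stop("`eas` must be an ea_set or an EA-id grid_layer")
}

#' Zonal mean of a raster over enumeration areas
#'
#' Mean of non-nodata cells whose centres fall in each EA. EAs with no
#' covered cells get `NA` and are flagged in the `missing` column.
#'
#' @param layer a `grid_layer`.
#' @param eas an `ea_set` or an EA-id `grid_layer`.
#' @return data.frame: `ea_id`, `mean`, `n_cells`, `missing`.
#' @export
zonal_mean <- function(layer, eas) {
  ear <- resolve_ea_raster(eas)
  stopifnot_same_grid(layer, ear)
  ids <- if (inherits(eas, "ea_set")) eas$table$ea_id
         else sort(unique(as.vector(ear$values)))
  v <- as.vector(layer$values)
  z <- as.vector(ear$values)
  ok <- !is.na(v) & !is.na(z)
  if (!any(ok)) stop("no EA overlaps any non-nodata cell")
  sums <- tapply(v[ok], z[ok], sum)
  ns <- tapply(v[ok], z[ok], length)
  m <- rep(NA_real_, length(ids))
  ncells <- rep(0L, length(ids))
  idx <- match(names(sums), as.character(ids))
  m[idx] <- as.numeric(sums) / as.numeric(ns)
  ncells[idx] <- as.integer(ns)
  data.frame(ea_id = ids, mean = m, n_cells = ncells,
             missing = ncells == 0L)
}

#' Per-species maxSSS thresholds from an occurrence table
#'
#' Convenience wrapper applying [max_sss_threshold()] to each species'
#' presence/background scores in a generator-style occurrence table.
#'
#' @param occurrences data.frame with columns `species`, `type`
#'   ("presence"/"background") and `score`.
#' @return named numeric vector of thresholds, one per species.
#' @export
species_thresholds <- function(occurrences) {
  sp <- sort(unique(occurrences$species))
  th <- vapply(sp, function(s) {
    o <- occurrences[occurrences$species == s, ]
    max_sss_threshold(o$score[o$type == "presence"],
                      o$score[o$type == "background"])
  }, numeric(1))
  names(th) <- sp
  th
}
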