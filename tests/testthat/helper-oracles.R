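# Independent brute-force oracles and tiny fixtures shared by the suite.
# Oracles deliberately avoid the package's own code paths.

tiny_config <- function(seed = 1L, ...) {
  landscape_config(rng_seed = seed, grid_rows = 24L, grid_cols = 24L,
                   n_eas = 16L, n_species = 3L, n_facilities = 3L, ...)
}

# exhaustive Dijkstra on the explicit 8-connected lattice graph,
# array-based, O(n^2) extraction
oracle_dijkstra <- function(friction, facilities) {
  f <- friction$values
  nr <- nrow(f); nc <- ncol(f)
  cs <- friction$cell_size
  dist <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(facilities)))
    dist[facilities[i, 1], facilities[i, 2]] <- 0
  done <- matrix(FALSE, nr, nc)
  nbr <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  step <- sqrt(nbr[, 1]^2 + nbr[, 2]^2) * cs
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    ur <- (u - 1L) %% nr + 1L
    uc <- (u - 1L) %/% nr + 1L
    for (k in 1:8) {
      vr <- ur + nbr[k, 1]; vc <- uc + nbr[k, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      w <- step[k] * (f[ur, uc] + f[vr, vc]) / 2
      alt <- dist[ur, uc] + w
      if (alt < dist[vr, vc]) dist[vr, vc] <- alt
    }
  }
  dist
}

# stepwise VIF elimination recomputed with explicit lm() at every step
oracle_vif_stepwise <- function(x, threshold = 10) {
  keep <- colnames(x)
  repeat {
    if (length(keep) <= 1L) break
    vifs <- sapply(keep, function(j) {
      df <- as.data.frame(x[, keep, drop = FALSE])
      r2 <- suppressWarnings(
        summary(lm(stats::reformulate(setdiff(keep, j), response = j),
                   data = df))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    })
    if (max(vifs) <= threshold) break
    keep <- keep[-which.max(vifs)]
  }
  keep
}

# exhaustive maxSSS search over the pooled-score candidate grid
oracle_max_sss <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  sss <- sapply(cand, function(t) mean(pres >= t) + mean(bg < t))
  best <- max(sss)
  min(cand[abs(sss - best) < 1e-12])
}

# cosine ranking recomputed from first principles (sample-sd z-scores are
# deliberately NOT used: population sd, like the implementation contract)
oracle_cosine_ranks <- function(x, orientation) {
  n <- nrow(x)
  mu <- colMeans(x)
  sdp <- apply(x, 2, function(v) sqrt(sum((v - mean(v))^2) / length(v)))
  z <- sweep(sweep(x, 2, mu), 2, sdp, "/")
  ref_raw <- sapply(seq_len(ncol(x)), function(j)
    if (orientation[j] == "higher-is-worse") max(x[, j]) else min(x[, j]))
  ref <- (ref_raw - mu) / sdp
  cosv <- apply(z, 1, function(a)
    sum(a * ref) / sqrt(sum(a^2) * sum(ref^2)))
  dref <- apply(z, 1, function(a) sqrt(sum((a - ref)^2)))
  ord <- order(-cosv, dref, seq_len(n))
  rk <- integer(n); rk[ord] <- seq_len(n)
  list(cos = cosv, rank = rk, score = (n - rk) / (n - 1))
}

# the pseudo-F double-sum form: R^2 from within/total sums over all
# variables, then the F ratio
oracle_pseudo_f <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); n_c <- length(unique(labels)); n_v <- ncol(x)
  vbar <- colMeans(x)
  sst <- 0; ssw <- 0
  for (i in unique(labels)) {
    xi <- x[labels == i, , drop = FALSE]
    vit <- colMeans(xi)
    for (j in seq_len(nrow(xi)))
      for (k in seq_len(n_v)) {
        ssw <- ssw + (xi[j, k] - vit[k])^2
        sst <- sst + (xi[j, k] - vbar[k])^2
      }
  }
  r2 <- 1 - ssw / sst
  (r2 / (n_c - 1)) / ((1 - r2) / (n - n_c))
}

# exhaustive k-medoids objective over all medoid pairs
oracle_best_medoid_objective <- function(x, k = 2L) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  combos <- utils::combn(n, k)
  best <- Inf
  for (i in seq_len(ncol(combos))) {
    med <- combos[, i]
    best <- min(best, sum(apply(d[, med, drop = FALSE], 1, min)))
  }
  best
}

# exhaustive zonal mean by explicit cell loop
oracle_zonal_mean <- function(layer, ea_raster) {
  v <- layer$values; z <- ea_raster$values
  ids <- sort(unique(as.vector(z)))
  sapply(ids, function(e) {
    vals <- c()
    for (r in seq_len(nrow(v)))
      for (cc in seq_len(ncol(v)))
        if (!is.na(z[r, cc]) && z[r, cc] == e && !is.na(v[r, cc]))
          vals <- c(vals, v[r, cc])
    if (length(vals)) mean(vals) else NA_real_
  })
}

flat_elevation <- function(nr, nc, cell_size = 500)
  grid_layer(matrix(100, nr, nc), cell_size)

generate_cases_fixture <- function() {
  cfg <- tiny_config()
  cfg$baseline_rate <- 5   # enough records on the tiny grid
  ge <- generate_eas(cfg, generate_rasters(cfg))
  generate_cases(cfg, ge$eas, ge$truth)
}
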