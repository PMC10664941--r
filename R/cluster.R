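#' Seed EAs for k-medoids from the risk indices
#'
#' One seed per index: the rank-1 EA of each index in turn. If an EA is
#' already taken, that index contributes its next-ranked EA. When more
#' seeds than indices are requested the indices are cycled, drawing their
#' successive ranks, so a four-cluster solution can be seeded from three
#' indices. Fully deterministic.
#'
#' @param indices list of `risk_index` objects.
#' @param k number of seeds (default: one per index).
#' @return integer vector of seed EA ids, length `k`.
#' @export
assign_seeds <- function(indices, k = length(indices)) {
  n_ea <- nrow(indices[[1L]])
  if (k > n_ea) stop("cannot seed more clusters than EAs")
  ranked <- lapply(indices, function(ix) ix$ea_id[order(ix$rank)])
  seeds <- integer(0)
  pos <- rep(1L, length(indices))
  i <- 0L
  while (length(seeds) < k) {
    i <- i %% length(indices) + 1L
    repeat {
      cand <- ranked[[i]][pos[i]]
      pos[i] <- pos[i] + 1L
      if (!(cand %in% seeds)) break
      if (pos[i] > n_ea) stop("ran out of EAs while deduplicating seeds")
    }
    seeds <- c(seeds, cand)
  }
  seeds
}

#' Seeded k-medoids (PAM) partition
#'
#' Starting from the seed EAs as initial medoids, alternates (i) assigning
#' each EA to its nearest medoid by Euclidean distance and (ii) resetting
#' each cluster's medoid to the member minimizing total within-cluster
#' distance, until labels are stable; a greedy PAM swap phase then
#' repeatedly applies the best objective-improving (medoid, non-medoid)
#' exchange, re-running the alternation after each accepted swap. The
#' objective (total distance of every EA to its nearest medoid) is weakly
#' decreasing throughout; given the seeds the result is fully
#' deterministic (the swap phase makes the greedy heuristic attain the
#' exhaustive-search optimum on small instances). A cluster emptied by
#' reassignment is re-seeded with the EA farthest from its current
#' medoid, with a message.
#'
#' @param features numeric matrix (N x n_v) of feature values with EA ids
#'   as rownames, or a data.frame with an `ea_id` column.
#' @param seeds EA ids of initial medoids (length n_c >= 2).
#' @param max_iter iteration cap.
#' @return object of class `cluster_solution`: list with `labels` (named
#'   by EA id), `medoids` (EA ids), `objective`, `pseudo_f`,
#'   `r2_per_variable`, `profiles` (per-cluster median and quartiles per
#'   variable), `n_c`, `iterations`.
#' @export
kmedoids_partition <- function(features, seeds, max_iter = 100L) {
  fm <- as_feature_matrix(features)
  x <- fm$x; ea_id <- fm$ea_id
  n <- nrow(x)
  n_c <- length(seeds)
  if (n_c < 2L) stop("need at least 2 seeds")
  if (n <= n_c) stop("need more EAs than clusters")
  med <- match(seeds, ea_id)
  if (anyNA(med)) stop("seed EA id(s) not present in the feature matrix")
  d <- as.matrix(stats::dist(x))
  it <- 0L

  alternate <- function(med) {
    labels <- integer(n)
    prev <- rep(-1L, n)
    while (it < max_iter) {
      it <<- it + 1L
      dm <- d[, med, drop = FALSE]
      labels <- max.col(-dm, ties.method = "first")
      ## guard against emptied clusters
      for (c_i in seq_len(n_c)) {
        if (!any(labels == c_i)) {
          far <- which.max(dm[cbind(seq_len(n), labels)])
          labels[far] <- c_i
          med[c_i] <- far
          message("re-seeded emptied cluster ", c_i)
        }
      }
      if (identical(labels, prev)) break
      prev <- labels
      for (c_i in seq_len(n_c)) {
        members <- which(labels == c_i)
        within <- d[members, members, drop = FALSE]
        med[c_i] <- members[which.min(colSums(within))]
      }
    }
    list(med = med, labels = labels)
  }

  obj_of <- function(med)
    sum(Reduce(pmin, lapply(med, function(m) d[, m])))

  st <- alternate(med)
  repeat {
    ## greedy PAM swap: best improving (medoid, non-medoid) exchange
    cur <- obj_of(st$med)
    best <- cur
    best_med <- st$med
    for (c_i in seq_len(n_c)) {
      for (cand in setdiff(seq_len(n), st$med)) {
        trial <- st$med
        trial[c_i] <- cand
        o <- obj_of(trial)
        if (o < best - 1e-12) {
          best <- o
          best_med <- trial
        }
      }
    }
    if (best >= cur - 1e-12 || it >= max_iter) break
    st <- alternate(best_med)
  }
  med <- st$med
  labels <- st$labels
  objective <- sum(d[cbind(seq_len(n), med[labels])])
  r2 <- cluster_r2(x, labels)
  psf <- calinski_harabasz(x, labels)
  structure(list(
    labels = stats::setNames(labels, ea_id), medoids = ea_id[med],
    objective = objective, pseudo_f = psf, r2_per_variable = r2,
    profiles = cluster_profiles(x, labels), n_c = n_c, iterations = it),
    class = "cluster_solution")
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features) && "ea_id" %in% names(features)) {
    ea_id <- features$ea_id
    x <- as.matrix(features[, setdiff(names(features), "ea_id"),
                            drop = FALSE])
  } else {
    x <- as.matrix(features)
    ea_id <- if (!is.null(rownames(x))) type.convert(rownames(x),
                                                     as.is = TRUE)
             else seq_len(nrow(x))
  }
  if (anyNA(x)) stop("feature matrix must have no missing entries")
  list(x = x, ea_id = ea_id)
}

cluster_profiles <- function(x, labels) {
  do.call(rbind, lapply(sort(unique(labels)), function(c_i) {
    xs <- x[labels == c_i, , drop = FALSE]
    do.call(rbind, lapply(colnames(xs) %||% seq_len(ncol(xs)), function(v) {
      q <- stats::quantile(xs[, v], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(cluster = c_i, variable = as.character(v), n = nrow(xs),
                 q1 = q[1], median = q[2], q3 = q[3])
    }))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d clusters, %d EAs, pseudo-F = %.2f\n",
              x$n_c, length(x$labels), x$pseudo_f))
  print(table(x$labels))
  invisible(x)
}

#' Calinski-Harabasz pseudo F-statistic
#'
#' `(R^2 / (n_c - 1)) / ((1 - R^2) / (n - n_c))` with
#' `R^2 = 1 - SSW / SST` pooled over all variables (within-cluster and
#' total sums of squared deviations from cluster / grand means). Equals
#' the classical between/within variance-ratio form. Perfect separation
#' (`SSW = 0`) returns `Inf` with attribute `degenerate = TRUE`.
#'
#' @param features numeric matrix or data.frame (with optional `ea_id`).
#' @param labels integer cluster labels, one per row.
#' @return scalar pseudo-F.
#' @export
calinski_harabasz <- function(features, labels) {
  x <- as_feature_matrix(features)$x
  n <- nrow(x)
  cl <- sort(unique(labels))
  n_c <- length(cl)
  if (n_c < 2L) stop("need at least 2 clusters")
  sst <- sum(sweep(x, 2L, colMeans(x))^2)
  ssw <- sum(vapply(cl, function(c_i) {
    xs <- x[labels == c_i, , drop = FALSE]
    sum(sweep(xs, 2L, colMeans(xs))^2)
  }, numeric(1)))
  if (sst == 0) stop("total sum of squares is zero")
  if (ssw == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r2 <- 1 - ssw / sst
  (r2 / (n_c - 1)) / ((1 - r2) / (n - n_c))
}

#' Per-variable R-squared of a clustering
#'
#' For variable `k`, `R^2_k = 1 - SSW_k / SST_k`: the share of that
#' variable's variation explained by the cluster labels. A variable with
#' zero total variance gets `R^2 = 0` with a warning.
#'
#' @inheritParams calinski_harabasz
#' @return named numeric vector, one `R^2` per variable, in `[0, 1]`.
#' @export
cluster_r2 <- function(features, labels) {
  x <- as_feature_matrix(features)$x
  cl <- sort(unique(labels))
  r2 <- vapply(seq_len(ncol(x)), function(k) {
    v <- x[, k]
    sst <- sum((v - mean(v))^2)
    if (sst == 0) {
      warning("constant variable: R^2 set to 0")
      return(0)
    }
    ssw <- sum(vapply(cl, function(c_i) {
      vs <- v[labels == c_i]
      sum((vs - mean(vs))^2)
    }, numeric(1)))
    1 - ssw / sst
  }, numeric(1))
  names(r2) <- colnames(x)
  r2
}

#' Risk-profile cluster analysis
#'
#' The two profiling analyses: clustering EAs on the normalized hazard,
#' exposure and susceptibility indices (bite-risk analysis), or on those
#' three plus healthcare resource scarcity (outcome analysis). The feature
#' matrix holds the indices' normalized scores; seeds come from
#' [assign_seeds()]; the default cluster count is 4. An optional sweep
#' reports the pseudo-F over a range of cluster counts.
#'
#' @param indices named list of `risk_index` objects including hazard,
#'   exposure, susceptibility and (if used) scarcity.
#' @param include_scarcity include the scarcity index as a feature.
#' @param n_c number of clusters.
#' @param sweep optional integer vector of cluster counts; if given, the
#'   returned object carries a `sweep` data.frame of pseudo-F per count.
#' @return a `cluster_solution` with extra elements `features`
#'   (data.frame of ea_id + index scores) and optionally `sweep`.
#' @export
run_analysis <- function(indices, include_scarcity = FALSE, n_c = 4L,
                         sweep = NULL) {
  wanted <- c("hazard", "exposure", "susceptibility",
              if (include_scarcity) "scarcity")
  if (!all(wanted %in% names(indices)))
    stop("indices must include: ", paste(wanted, collapse = ", "))
  use <- indices[wanted]
  ids <- Reduce(intersect, lapply(use, function(ix) ix$ea_id))
  feats <- data.frame(ea_id = ids)
  for (nm in wanted)
    feats[[nm]] <- use[[nm]]$score[match(ids, use[[nm]]$ea_id)]
  seeds <- assign_seeds(use, k = n_c)
  sol <- kmedoids_partition(feats, seeds)
  sol$features <- feats
  if (!is.null(sweep)) {
    sol$sweep <- do.call(rbind, lapply(sweep, function(k) {
      s <- kmedoids_partition(feats, assign_seeds(use, k = k))
      data.frame(n_c = k, pseudo_f = s$pseudo_f)
    }))
  }
  sol
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 = identical partitions, ~0 = random agreement.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
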