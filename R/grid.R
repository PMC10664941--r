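#' Geo-referenced raster layer
#'
#' Minimal single-band raster container used throughout the package for
#' elevation, landcover, suitability, friction and travel-time surfaces.
#' Values are stored as a numeric matrix with row 1 at the northern edge;
#' all layers taking part in one analysis must share the same grid geometry
#' (dimensions, origin and cell size).
#'
#' @param values numeric matrix (rows = north to south, cols = west to east).
#' @param cell_size cell edge length in metres.
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param nodata value that marks missing cells (stored as `NA` internally
#'   when reading/writing; comparisons use `NA`).
#' @param name optional layer name.
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(values, cell_size, origin = c(0, 0), nodata = -9999,
                       name = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = nodata, name = name),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_layer%s> %d x %d cells, %g m resolution\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              nrow(v), ncol(v), x$cell_size))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  range: [%g, %g], NA cells: %d\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_same_grid <- function(...) {
  layers <- list(...)
  ref <- layers[[1L]]
  for (l in layers[-1L])
    if (!same_grid(ref, l)) stop("grid layers do not share one grid geometry")
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid layer
#'
#' @param layer a `grid_layer`.
#' @return data.frame with columns `row`, `col`, `x`, `y` in grid row-major
#'   order (row index 1 = northern edge).
#' @export
cell_centers <- function(layer) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  cs <- layer$cell_size
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  g$x <- layer$origin[1] + (g$col - 0.5) * cs
  g$y <- layer$origin[2] + (nr - g$row + 0.5) * cs
  g
}

#' Terrain slope in degrees
#'
#' Central-difference gradient magnitude of an elevation layer, converted to
#' slope in degrees. Edge cells use one-sided differences.
#'
#' @param elevation elevation `grid_layer` in metres.
#' @return `grid_layer` of slope (degrees).
#' @export
slope_degrees <- function(elevation) {
  z <- elevation$values
  cs <- elevation$cell_size
  nr <- nrow(z); nc <- ncol(z)
  # column-direction (x) differences
  dzdx <- (z[, c(2:nc, nc)] - z[, c(1, 1:(nc - 1))]) /
    (cs * (outer(rep(1, nr), c(1, rep(2, nc - 2), 1))))
  dzdy <- (z[c(2:nr, nr), ] - z[c(1, 1:(nr - 1)), ]) /
    (cs * (outer(c(1, rep(2, nr - 2), 1), rep(1, nc))))
  sl <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  grid_layer(sl, cs, elevation$origin, name = "slope_deg")
}

#' Write / read a grid layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange (`.asc`): a six-line header followed by
#' rows of cell values, northern row first. `NA` cells are written as the
#' layer's nodata value.
#'
#' @param layer a `grid_layer`.
#' @param path file path.
#' @return `write_grid_asc` returns `path` invisibly; `read_grid_asc`
#'   returns a `grid_layer`.
#' @export
write_grid_asc <- function(layer, path) {
  v <- layer$values
  nod <- layer$nodata
  v[is.na(v)] <- nod
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", layer$origin[1]),
    sprintf("yllcorner %.10g", layer$origin[2]),
    sprintf("cellsize %.10g", layer$cell_size),
    sprintf("NODATA_value %.10g", nod)
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE,
                                                digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  nc <- val(1); nr <- val(2)
  x0 <- val(3); y0 <- val(4); cs <- val(5); nod <- val(6)
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(nrow(m) == nr, ncol(m) == nc)
  m[m == nod] <- NA_real_
  grid_layer(m, cs, c(x0, y0), nodata = nod)
}

## deterministic child seeds: one stream per generator stage, independent of
## call order, kept below 2^31 for 32-bit R integers
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
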