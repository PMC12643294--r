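#' Planar raster grid
#'
#' A minimal georeferenced raster: a numeric matrix with square cells in a
#' planar (projected) coordinate system. Row 1 is the northernmost row;
#' missing cells are `NA`. All distances and areas in this package are planar,
#' so geographic (lon/lat) inputs must be projected before use.
#'
#' @param values numeric matrix (row 1 = north).
#' @param origin_x,origin_y map coordinates of the grid's top-left corner.
#' @param cell_size positive side length of the (square) cells, in map units.
#' @param nodata sentinel value used on disk for missing cells.
#' @param crs_label free-text identifier of the coordinate reference system;
#'   operations that combine layers require matching labels.
#' @return An object of class `raster_grid`.
#' @examples
#' r <- raster_grid(matrix(1:9, 3, 3, byrow = TRUE))
#' raster_values(r)
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = nrow(values),
                        cell_size = 1, nodata = -9999, crs_label = "local-km") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    abort("cell_size must be a single positive number")
  }
  structure(
    list(values = values, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), cell_size = as.numeric(cell_size),
         nodata = as.numeric(nodata), crs_label = as.character(crs_label)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cell_size %g, origin (%g, %g), crs '%s'\n",
              nrow(v), ncol(v), x$cell_size, x$origin_x, x$origin_y, x$crs_label))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: [%g, %g], %d missing\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  } else {
    cat("  all cells missing\n")
  }
  invisible(x)
}

#' @rdname raster_grid
#' @param x a `raster_grid`.
#' @export
raster_values <- function(x) x$values

#' Cell-center coordinates of a raster
#'
#' @param x a `raster_grid`.
#' @return A tibble with `row`, `col`, `x`, `y` and `value` (one row per cell,
#'   row-major from the north-west corner).
#' @export
raster_cells <- function(x) {
  v <- x$values
  nr <- nrow(v); nc <- ncol(v)
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  cx <- x$origin_x + (cols - 0.5) * x$cell_size
  cy <- x$origin_y - (rows - 0.5) * x$cell_size
  tibble(row = rows, col = cols, x = cx, y = cy, value = as.vector(t(v)))
}

#' @exportS3Method tibble::as_tibble
as_tibble.raster_grid <- function(x, ...) raster_cells(x)

#' Do two rasters share the same grid?
#'
#' Aligned means identical origin, cell size, dimensions and CRS label.
#'
#' @param a,b `raster_grid` objects.
#' @export
rasters_aligned <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    a$origin_x == b$origin_x && a$origin_y == b$origin_y &&
    a$cell_size == b$cell_size && a$crs_label == b$crs_label
}

stopifnot_aligned <- function(a, b, what = "rasters") {
  if (!rasters_aligned(a, b)) abort(paste0(what, " are not aligned (origin, cell size, dimensions and crs must match)"))
  invisible(TRUE)
}

#' Locate points on a raster grid
#'
#' @param x a `raster_grid`.
#' @param px,py point coordinates.
#' @return tibble with `row`, `col` (NA where outside the extent).
#' @export
raster_locate <- function(x, px, py) {
  col <- floor((px - x$origin_x) / x$cell_size) + 1
  row <- floor((x$origin_y - py) / x$cell_size) + 1
  bad <- col < 1 | col > ncol(x$values) | row < 1 | row > nrow(x$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble(row = as.integer(row), col = as.integer(col))
}

#' Read / write rasters as plain-text grids
#'
#' Rasters are stored as single-band ESRI ASCII grids (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values from north to south.
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces doubles bit-exactly. The CRS label travels in a `.prj` sidecar
#' text file next to the grid.
#'
#' @param path file path (conventionally ending in `.asc`).
#' @return `read_raster` returns a `raster_grid`; `write_raster` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) abort(paste0("raster file not found: ", path))
  lines <- readLines(path)
  if (length(lines) < 7) abort("not a single-band ASCII grid: header incomplete")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) abort("not a single-band ASCII grid: malformed header")
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) abort("not a single-band ASCII grid: missing header fields")
  if (any(grepl("^(dx|dy)\\b", tolower(lines)))) abort("non-square cells are not supported")
  nc <- hdr$ncols; nr <- hdr$nrows
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) {
    abort(sprintf("grid body has %d values, expected %d x %d; multi-band or truncated files are rejected",
                  length(body), nr, nc))
  }
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == hdr$nodata_value] <- NA_real_
  prj <- sub("\\.[^.]*$", ".prj", path)
  crs <- if (file.exists(prj)) readLines(prj, n = 1) else "local-km"
  raster_grid(v, origin_x = hdr$xllcorner,
              origin_y = hdr$yllcorner + nr * hdr$cellsize,
              cell_size = hdr$cellsize, nodata = hdr$nodata_value,
              crs_label = crs)
}

#' @rdname read_raster
#' @param raster a `raster_grid`.
#' @export
write_raster <- function(raster, path) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  out <- v
  out[is.na(out)] <- raster$nodata
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", raster$origin_x),
    sprintf("yllcorner %.17g", raster$origin_y - nr * raster$cell_size),
    sprintf("cellsize %.17g", raster$cell_size),
    sprintf("NODATA_value %.17g", raster$nodata)
  )
  rows <- apply(out, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(raster$crs_label, sub("\\.[^.]*$", ".prj", path))
  invisible(path)
}

#' Heat-map of a raster grid
#'
#' @param object a `raster_grid`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.raster_grid <- function(object, ...) {
  df <- raster_cells(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
}

#' Environmental layer stack
#'
#' A named list of mutually aligned rasters. Layer names conventionally follow
#' the WorldClim bioclim vocabulary (`BIO1`..`BIO19`, `elevation`) but any
#' unique names are accepted.
#'
#' @param layers named list of `raster_grid` objects.
#' @return an `env_stack`.
#' @export
env_stack <- function(layers) {
  if (length(layers) == 0) abort("env_stack needs at least one layer")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    abort("layers must have unique non-empty names")
  }
  for (i in seq_along(layers)) {
    if (!inherits(layers[[i]], "raster_grid")) abort("all layers must be raster_grid objects")
    stopifnot_aligned(layers[[1]], layers[[i]], "env_stack layers")
  }
  structure(layers, class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Flatten an environmental stack to a cell-by-layer tibble
#'
#' @param env an `env_stack`.
#' @param valid_only drop cells missing in any layer.
#' @return tibble with `row`, `col`, `x`, `y` and one column per layer.
#' @export
env_table <- function(env, valid_only = TRUE) {
  base <- raster_cells(env[[1]]) %>% select("row", "col", "x", "y")
  for (nm in names(env)) base[[nm]] <- as.vector(t(env[[nm]]$values))
  if (valid_only) base <- base[stats::complete.cases(base), ]
  base
}
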