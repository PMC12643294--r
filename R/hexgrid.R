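#' Hexagonal analysis grid
#'
#' Tiles the plane with congruent flat-top regular hexagons and keeps every
#' cell whose polygon intersects the region. The default 5-km edge gives the
#' cell area (3*sqrt(3)/2) * 5^2 = 64.95 km2 used for hexcell summaries.
#' Cells are ordered row-major by center, north to south then west to east,
#' and the tiling is anchored at the region bounding-box top-left corner, so
#' grids are reproducible.
#'
#' @param region a [vector_region()].
#' @param edge_km hexagon edge length in map units (km).
#' @return a `hex_grid`: list with `edge_km`, `cell_area`, `crs_label` and
#'   `cells`, a tibble of `cell_id`, `center_x`, `center_y` and a `vertices`
#'   list-column of 6x2 matrices.
#' @examples
#' reg <- region_rectangle(0, 0, 30, 30)
#' hg <- build_hexgrid(reg, edge_km = 5)
#' hg$cell_area
#' @export
build_hexgrid <- function(region, edge_km) {
  if (!inherits(region, "vector_region")) abort("region must be a vector_region")
  if (!is.numeric(edge_km) || length(edge_km) != 1 || edge_km <= 0) {
    abort("edge_km must be a single positive number")
  }
  e <- edge_km
  bb <- region_bbox(region)
  sq3 <- sqrt(3)
  # flat-top: column spacing 1.5 e, row spacing sqrt(3) e, odd columns shifted
  ncols <- ceiling((bb["xmax"] - bb["xmin"]) / (1.5 * e)) + 2
  nrows <- ceiling((bb["ymax"] - bb["ymin"]) / (sq3 * e)) + 2
  ii <- seq(-1, ncols)
  jj <- seq(-1, nrows)
  centers <- expand.grid(i = ii, j = jj)
  cx <- bb["xmin"] + 1.5 * e * centers$i
  cy <- bb["ymax"] - sq3 * e * centers$j - (centers$i %% 2) * sq3 * e / 2
  ang <- (0:5) * pi / 3
  vx <- e * cos(ang); vy <- e * sin(ang)
  keep <- logical(length(cx))
  verts <- vector("list", length(cx))
  for (k in seq_along(cx)) {
    ring <- cbind(cx[k] + vx, cy[k] + vy)
    ring_closed <- rbind(ring, ring[1, ])
    hit <- FALSE
    for (p in region$polygons) {
      if (rings_intersect(ring_closed, p$coords)) { hit <- TRUE; break }
    }
    if (hit) { keep[k] <- TRUE; verts[[k]] <- ring }
  }
  cx <- cx[keep]; cy <- cy[keep]; verts <- verts[keep]
  if (length(cx) == 0) abort("no hexagons intersect the region")
  ord <- order(-round(cy, 9), round(cx, 9))
  cells <- tibble(
    cell_id = seq_along(ord),
    center_x = cx[ord], center_y = cy[ord],
    vertices = verts[ord]
  )
  structure(list(edge_km = e, cell_area = 3 * sq3 / 2 * e^2,
                 crs_label = region$crs_label, cells = cells),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d cells, edge %g km, cell area %.4f km2\n",
              nrow(x$cells), x$edge_km, x$cell_area))
  invisible(x)
}

#' Zonal statistics of a raster over a hexagonal grid
#'
#' A raster cell belongs to the hexagon containing its center point; missing
#' raster cells are excluded. Hexcells covering no valid raster cell get `NA`.
#'
#' @param raster a `raster_grid`.
#' @param grid a `hex_grid` with the same `crs_label`.
#' @param stat one of `"mean"`, `"sum"`, `"max"`.
#' @return tibble with `cell_id` and `value`.
#' @export
zonal_stat <- function(raster, grid, stat = c("mean", "sum", "max")) {
  stat <- match.arg(stat)
  if (!identical(raster$crs_label, grid$crs_label)) {
    abort("raster and hexgrid use different CRS labels")
  }
  cells <- raster_cells(raster)
  fn <- switch(stat, mean = mean, sum = sum, max = max)
  out <- numeric(nrow(grid$cells))
  for (k in seq_len(nrow(grid$cells))) {
    ring <- grid$cells$vertices[[k]]
    ring_closed <- rbind(ring, ring[1, ])
    bbx <- range(ring[, 1]); bby <- range(ring[, 2])
    cand <- cells$x >= bbx[1] & cells$x <= bbx[2] &
      cells$y >= bby[1] & cells$y <= bby[2] & !is.na(cells$value)
    if (!any(cand)) { out[k] <- NA_real_; next }
    sub <- cells[cand, ]
    inside <- point_in_ring(sub$x, sub$y, ring_closed)
    if (!any(inside)) { out[k] <- NA_real_; next }
    out[k] <- fn(sub$value[inside])
  }
  tibble(cell_id = grid$cells$cell_id, value = out)
}

#' Steep-slope mask from a digital elevation model
#'
#' Computes per-cell terrain slope with Horn's 8-neighbor finite differences
#' (edges replicated) and flags cells whose slope strictly exceeds the
#' threshold. With the 45-degree default this reproduces the permanent
#' preservation area rule for steep private land.
#'
#' @param dem `raster_grid` of elevations; elevation units must equal the
#'   (planar) horizontal map units.
#' @param threshold_deg slope threshold in degrees (strict `>`).
#' @return binary `raster_grid` (1 = steeper than threshold).
#' @export
slope_mask <- function(dem, threshold_deg = 45) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) abort("DEM must be at least 3 x 3")
  pad <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  # neighbours of cell (i, j): rows i..i+2, cols j..j+2 of the padded matrix
  nb <- function(di, dj) pad[(1 + di):(nr + di), (1 + dj):(nc + dj)]
  a <- nb(0, 0); b <- nb(0, 1); cc <- nb(0, 2)
  d <- nb(1, 0);                ee <- nb(1, 2)
  g <- nb(2, 0); h <- nb(2, 1); i9 <- nb(2, 2)
  dzdx <- ((cc + 2 * ee + i9) - (a + 2 * d + g)) / (8 * dem$cell_size)
  dzdy <- ((g + 2 * h + i9) - (a + 2 * b + cc)) / (8 * dem$cell_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  mask <- ifelse(is.na(slope), NA_real_, as.numeric(slope > threshold_deg))
  raster_grid(mask, origin_x = dem$origin_x, origin_y = dem$origin_y,
              cell_size = dem$cell_size, nodata = dem$nodata,
              crs_label = dem$crs_label)
}
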