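#' Vector regions (polygons)
#'
#' Lightweight planar polygon container used for the study-region boundary
#' and protected-area footprints. Each polygon is a closed, non-self-
#' intersecting ring with an id and a free-form attribute list.
#'
#' @param polygons list of elements with `id`, `coords` (closed two-column
#'   matrix of vertices) and optional `attributes` (named list).
#' @param crs_label CRS identifier, matched against rasters/grids.
#' @return a `vector_region`.
#' @export
vector_region <- function(polygons, crs_label = "local-km") {
  if (length(polygons) == 0) abort("region is empty")
  polygons <- lapply(polygons, function(p) {
    xy <- as.matrix(p$coords)
    if (ncol(xy) != 2 || nrow(xy) < 4) abort("polygon rings need at least 3 distinct vertices and must close")
    if (any(xy[1, ] != xy[nrow(xy), ])) abort("polygon ring is not closed")
    if (ring_self_intersects(xy)) abort(paste0("polygon '", p$id, "' is self-intersecting"))
    list(id = p$id, coords = xy,
         attributes = if (is.null(p$attributes)) list() else p$attributes)
  })
  structure(list(polygons = polygons, crs_label = crs_label),
            class = "vector_region")
}

#' @rdname vector_region
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @param id polygon id.
#' @export
region_rectangle <- function(xmin, ymin, xmax, ymax, id = "region",
                             crs_label = "local-km") {
  coords <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                  c(xmin, ymax), c(xmin, ymin))
  vector_region(list(list(id = id, coords = coords)), crs_label = crs_label)
}

#' @export
print.vector_region <- function(x, ...) {
  cat(sprintf("<vector_region> %d polygon(s), crs '%s'\n",
              length(x$polygons), x$crs_label))
  invisible(x)
}

region_bbox <- function(region) {
  xy <- do.call(rbind, lapply(region$polygons, function(p) p$coords))
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

# ray-casting point-in-polygon; boundary points count as inside
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1
  inside <- rep(FALSE, length(px))
  xr <- ring[, 1]; yr <- ring[, 2]
  for (i in seq_len(n)) {
    x1 <- xr[i]; y1 <- yr[i]; x2 <- xr[i + 1]; y2 <- yr[i + 1]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- which(crosses)[xint > px[crosses]]
      inside[hit] <- !inside[hit]
    }
    # boundary: point on segment
    d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    seg <- d <= 1e-12 * max(1, abs(x2 - x1) + abs(y2 - y1)) &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    inside[seg] <- TRUE
  }
  inside
}

#' Test points against a region
#'
#' @param region a `vector_region`.
#' @param px,py coordinates.
#' @return logical vector: inside (or on the boundary of) any polygon.
#' @export
points_in_region <- function(region, px, py) {
  inside <- rep(FALSE, length(px))
  for (p in region$polygons) inside <- inside | point_in_ring(px, py, p$coords)
  inside
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # first and last share the closing vertex
      if (segments_intersect(ring[i, ], ring[i + 1, ], ring[j, ], ring[j + 1, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

rings_intersect <- function(a, b) {
  if (any(point_in_ring(a[, 1], a[, 2], b))) return(TRUE)
  if (any(point_in_ring(b[, 1], b[, 2], a))) return(TRUE)
  na <- nrow(a) - 1; nb <- nrow(b) - 1
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segments_intersect(a[i, ], a[i + 1, ], b[j, ], b[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' Read / write regions as GeoJSON
#'
#' Supports FeatureCollections of Polygons (outer rings only); feature
#' properties become polygon attributes.
#'
#' @param path file path.
#' @param crs_label CRS label attached on read (GeoJSON itself is treated as
#'   already-projected planar coordinates).
#' @export
read_region_geojson <- function(path, crs_label = "local-km") {
  if (!file.exists(path)) abort(paste0("GeoJSON file not found: ", path))
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  polys <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    if (!identical(geom$type, "Polygon")) next
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    props <- if (!is.null(f$properties)) f$properties else list()
    id <- if (!is.null(props$id)) props$id else paste0("poly_", i)
    polys[[length(polys) + 1]] <- list(id = id, coords = ring, attributes = props)
  }
  if (length(polys) == 0) abort("no Polygon features found")
  vector_region(polys, crs_label = crs_label)
}

#' @rdname read_region_geojson
#' @param region a `vector_region`.
#' @export
write_region_geojson <- function(region, path) {
  feats <- lapply(region$polygons, function(p) {
    list(type = "Feature",
         properties = c(list(id = p$id), p$attributes),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(p$coords)), function(i) {
             as.numeric(p$coords[i, ])
           }))
         ))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
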