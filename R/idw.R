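#' IDW configuration
#'
#' @param power inverse-distance exponent `p` (> 0, default 2).
#' @param k number of nearest neighbours used per cell (`Inf` = all points,
#'   the default).
#' @param exact_at_samples return a sample's value exactly when a cell center
#'   coincides with it (within `1e-9 * cell_size`).
#' @export
idw_config <- function(power = 2, k = Inf, exact_at_samples = TRUE) {
  if (power <= 0) abort("power must be positive")
  if (!is.infinite(k) && k < 1) abort("k must be >= 1")
  structure(list(power = power, k = k, exact_at_samples = exact_at_samples),
            class = "idw_config")
}

#' Inverse-distance-weighted interpolation onto a raster template
#'
#' `value(cell) = sum_i w_i v_i / sum_i w_i` with `w_i = d_i^(-p)`. A cell
#' whose center coincides with a sample point takes that sample's value
#' exactly; the surface is bounded by the sample value range (positive
#' weights). Duplicate points with conflicting values are rejected.
#'
#' @param points tibble with `x`, `y`.
#' @param values numeric vector, one per point.
#' @param template `raster_grid` defining the output grid (valid-cell mask is
#'   carried over).
#' @param config an [idw_config()].
#' @return `raster_grid` of interpolated values.
#' @export
idw_interpolate <- function(points, values, template, config = idw_config()) {
  n <- nrow(points)
  if (n == 0) abort("need at least one sample point")
  if (length(values) != n) abort("values must match points")
  eps <- 1e-9 * template$cell_size
  dup <- duplicated(round(cbind(points$x, points$y) / eps))
  if (any(dup)) {
    di <- which(dup)
    for (i in di) {
      twin <- which(abs(points$x - points$x[i]) < eps &
                    abs(points$y - points$y[i]) < eps)
      if (length(unique(values[twin])) > 1) {
        abort("duplicate points with conflicting values")
      }
    }
  }
  cells <- raster_cells(template)
  out <- rep(NA_real_, nrow(cells))
  tgt <- which(!is.na(cells$value) | TRUE) # interpolate everywhere; mask later
  dx <- outer(cells$x, points$x, "-")
  dy <- outer(cells$y, points$y, "-")
  d <- sqrt(dx^2 + dy^2)
  if (!is.infinite(config$k) && config$k < n) {
    # keep only the k nearest samples per cell
    for (i in seq_len(nrow(d))) {
      cut <- sort(d[i, ], partial = config$k)[config$k]
      d[i, d[i, ] > cut] <- Inf
    }
  }
  w <- d^(-config$power)
  hit <- d < eps
  est <- as.vector((w %*% values) / rowSums(w))
  if (config$exact_at_samples && any(hit)) {
    for (i in which(rowSums(hit) > 0)) {
      est[i] <- values[which(hit[i, ])[1]]
    }
  }
  out <- est
  m <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  m[cbind(cells$row, cells$col)] <- out
  m[is.na(template$values)] <- NA_real_
  raster_grid(m, template$origin_x, template$origin_y, template$cell_size,
              crs_label = template$crs_label)
}

#' Contemporary richness surface from the assemblage table
#'
#' IDW of per-site species richness (row sums of the incidence columns) over
#' the region template.
#'
#' @param assemblages assemblage tibble: `site_id`, `x`, `y`, `protection`,
#'   then one binary column per species.
#' @param template `raster_grid`.
#' @param config an [idw_config()].
#' @return `raster_grid` of contemporary richness.
#' @export
contemporary_richness_surface <- function(assemblages, template,
                                          config = idw_config()) {
  inc <- assemblage_incidence(assemblages)
  idw_interpolate(assemblages[, c("x", "y")], rowSums(inc), template, config)
}

#' Contemporary binary surface for one species
#'
#' IDW of the species' 0/1 incidence thresholded at `cutoff` (with `>=`).
#'
#' @param assemblages assemblage tibble.
#' @param species_id one incidence column name.
#' @param template `raster_grid`.
#' @param config an [idw_config()].
#' @param cutoff occupancy threshold (default 0.5).
#' @return binary `raster_grid`.
#' @export
contemporary_species_surface <- function(assemblages, species_id, template,
                                         config = idw_config(), cutoff = 0.5) {
  inc <- assemblage_incidence(assemblages)
  if (!species_id %in% colnames(inc)) {
    abort(paste0("species '", species_id, "' not in the assemblage table"))
  }
  surf <- idw_interpolate(assemblages[, c("x", "y")], inc[, species_id],
                          template, config)
  binarize(surf, cutoff)
}

# incidence matrix from an assemblage tibble (site metadata columns removed)
assemblage_incidence <- function(assemblages) {
  meta <- c("site_id", "x", "y", "protection")
  sp_cols <- setdiff(colnames(assemblages), meta)
  inc <- as.matrix(assemblages[, sp_cols, drop = FALSE])
  if (!all(inc %in% c(0, 1))) abort("incidence columns must be binary")
  rownames(inc) <- assemblages$site_id
  inc
}

#' Summary statistics of an assemblage table
#'
#' Richness mean/SD/range over sites and the distinct species count —
#' the checks used to validate a compiled assemblage table.
#'
#' @param assemblages assemblage tibble.
#' @return one-row tibble: `n_sites`, `n_species`, `mean_richness`,
#'   `sd_richness`, `min_richness`, `max_richness`.
#' @export
assemblage_summary <- function(assemblages) {
  inc <- assemblage_incidence(assemblages)
  rich <- rowSums(inc)
  tibble(
    n_sites = nrow(inc),
    n_species = sum(colSums(inc) > 0),
    mean_richness = mean(rich), sd_richness = sd(rich),
    min_richness = min(rich), max_richness = max(rich)
  )
}
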