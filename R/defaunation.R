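#' Defaunation surface
#'
#' `D = historical - contemporary` richness per cell, with percent loss
#' `100 * D / historical` wherever historical richness is positive. Local
#' gains (negative D) are preserved; percent loss is missing where the
#' historical richness is zero.
#'
#' @param hist,cont aligned richness `raster_grid`s.
#' @return list with `D` and `percent` rasters.
#' @export
defaunation_raster <- function(hist, cont) {
  stopifnot_aligned(hist, cont)
  D <- hist$values - cont$values
  pct <- ifelse(!is.na(hist$values) & hist$values > 0,
                100 * D / hist$values, NA_real_)
  mk <- function(m) raster_grid(m, hist$origin_x, hist$origin_y,
                                hist$cell_size, crs_label = hist$crs_label)
  list(D = mk(D), percent = mk(pct))
}

#' Hexcell records: defaunation response plus driver covariates
#'
#' Zonal mean of the defaunation surface and of each covariate raster per
#' hexcell; records with a missing response are dropped (count reported via
#' a message-free attribute `n_dropped`).
#'
#' @param D defaunation `raster_grid`.
#' @param grid a [build_hexgrid()] grid.
#' @param covariates named list of aligned covariate rasters.
#' @return tibble: `cell_id`, `defaunation`, one column per covariate.
#' @export
defaunation_by_hexcell <- function(D, grid, covariates) {
  out <- zonal_stat(D, grid, "mean") %>% rename(defaunation = "value")
  for (nm in names(covariates)) {
    z <- zonal_stat(covariates[[nm]], grid, "mean")
    out[[nm]] <- z$value
  }
  n0 <- nrow(out)
  out <- out[!is.na(out$defaunation), , drop = FALSE]
  out <- out[stats::complete.cases(out), , drop = FALSE]
  attr(out, "n_dropped") <- n0 - nrow(out)
  out
}

#' Fractions of the region by percent-loss band
#'
#' Default bands follow the reporting convention: severe loss (50, 100],
#' moderate [20, 50), light [0, 20), and gains (< 0). Fractions are over
#' valid cells of the percent-loss raster and the exhaustive bands always
#' partition to 1.
#'
#' @param percent `raster_grid` of percent richness loss.
#' @param bands tibble with `band`, `lo`, `hi`, `lo_open`, `hi_open`
#'   describing interval membership; defaults described above.
#' @return tibble: `band`, `n_cells`, `fraction`.
#' @export
loss_band_summary <- function(percent, bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble(
      band = c("gain", "loss_0_20", "loss_20_50", "loss_over_50"),
      lo = c(-Inf, 0, 20, 50), hi = c(0, 20, 50, Inf),
      lo_open = c(TRUE, FALSE, FALSE, TRUE),
      hi_open = c(TRUE, TRUE, TRUE, FALSE)
    )
  }
  v <- as.vector(percent$values)
  v <- v[!is.na(v)]
  member <- function(lo, hi, lo_open, hi_open) {
    a <- if (lo_open) v > lo else v >= lo
    b <- if (hi_open) v < hi else v <= hi
    a & b
  }
  mm <- mapply(member, bands$lo, bands$hi, bands$lo_open, bands$hi_open)
  mm <- matrix(mm, nrow = length(v))
  if (any(rowSums(mm) > 1)) abort("bands overlap")
  tibble(band = bands$band, n_cells = colSums(mm),
         fraction = colSums(mm) / length(v))
}

#' Species range loss across assemblages, extrapolated to area
#'
#' For each species, compares the assemblages where its historical binary map
#' predicts presence with those where it is actually recorded today:
#' `loss_fraction = 1 - occupied / predicted`, then extrapolates to
#' `lost_area = loss_fraction * historical_area` (cell count x cell area of
#' the binary map). Contemporary records at sites not predicted historically
#' are not part of the loss statistic and are tallied as commission.
#'
#' @param binary_maps named list of per-species historical binary rasters.
#' @param assemblages assemblage tibble (contemporary incidence).
#' @return tibble: one row per species with predicted/occupied counts,
#'   `loss_fraction`, areas (km2 if the CRS unit is km) and flags.
#' @export
species_range_loss <- function(binary_maps, assemblages) {
  inc <- assemblage_incidence(assemblages)
  rows <- lapply(names(binary_maps), function(sp) {
    bm <- binary_maps[[sp]]
    loc <- raster_locate(bm, assemblages$x, assemblages$y)
    pred <- bm$values[cbind(loc$row, loc$col)]
    pred[is.na(pred)] <- 0
    occ <- if (sp %in% colnames(inc)) inc[, sp] else rep(0L, nrow(inc))
    n_pred <- sum(pred > 0)
    n_occ <- sum(occ > 0 & pred > 0)
    commission <- sum(occ > 0 & pred == 0)
    hist_area <- sum(bm$values > 0, na.rm = TRUE) * bm$cell_size^2
    if (n_pred == 0) {
      tibble(species = sp, n_assemblages_predicted = 0L,
             n_assemblages_occupied = 0L, commission = commission,
             loss_fraction = NA_real_, historical_area = hist_area,
             lost_area = NA_real_, assessable = FALSE)
    } else {
      lf <- 1 - n_occ / n_pred
      tibble(species = sp, n_assemblages_predicted = n_pred,
             n_assemblages_occupied = n_occ, commission = commission,
             loss_fraction = lf, historical_area = hist_area,
             lost_area = lf * hist_area, assessable = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Historical composition at the assemblage sites
#'
#' A species is historically present at a site iff its binary map is 1 in the
#' raster cell containing the site.
#'
#' @param binary_maps named list of per-species binary rasters.
#' @param assemblages assemblage tibble (coordinates used).
#' @return integer incidence matrix, sites x species.
#' @export
historical_composition <- function(binary_maps, assemblages) {
  out <- sapply(names(binary_maps), function(sp) {
    bm <- binary_maps[[sp]]
    loc <- raster_locate(bm, assemblages$x, assemblages$y)
    v <- bm$values[cbind(loc$row, loc$col)]
    as.integer(!is.na(v) & v > 0)
  })
  rownames(out) <- assemblages$site_id
  out
}

#' Assemblage downsizing: aggregate and mean body mass, both periods
#'
#' Sums and averages species body masses per site for the historical and
#' contemporary compositions; `retained_fraction` is the contemporary share
#' of historical aggregate mass (it can exceed 1 under commission).
#'
#' @param assemblages contemporary assemblage tibble.
#' @param hist_incidence sites x species matrix from
#'   [historical_composition()].
#' @param mass_kg named numeric vector of body masses in kg (every species in
#'   either composition must be present).
#' @return list: `sites` tibble (one row per site) and `summary` one-row
#'   tibble with regional means/SDs and total biomass loss.
#' @export
downsizing <- function(assemblages, hist_incidence, mass_kg) {
  inc <- assemblage_incidence(assemblages)
  sp_all <- union(colnames(inc), colnames(hist_incidence))
  missing <- setdiff(sp_all, names(mass_kg))
  if (length(missing)) {
    abort(paste0("missing body mass for: ", paste(missing, collapse = ", ")))
  }
  agg <- function(m) as.vector(m %*% mass_kg[colnames(m)])
  mean_mass <- function(m) {
    tot <- agg(m); n <- unname(rowSums(m))
    ifelse(n > 0, tot / n, NA_real_)
  }
  hist_inc <- hist_incidence[assemblages$site_id, , drop = FALSE]
  sites <- tibble(
    site_id = assemblages$site_id,
    protection = assemblages$protection,
    aggregate_hist_kg = agg(hist_inc),
    aggregate_cont_kg = agg(inc),
    mean_mass_hist_kg = mean_mass(hist_inc),
    mean_mass_cont_kg = mean_mass(inc),
    n_hist = rowSums(hist_inc), n_cont = rowSums(inc)
  ) %>%
    mutate(
      retained_fraction = ifelse(.data$aggregate_hist_kg > 0,
                                 .data$aggregate_cont_kg / .data$aggregate_hist_kg,
                                 NA_real_)
    )
  # species lost = historically present but absent today (per site)
  common <- intersect(colnames(hist_inc), colnames(inc))
  lost <- rowSums(hist_inc[, common, drop = FALSE] *
                    (1 - inc[, common, drop = FALSE])) +
    rowSums(hist_inc[, setdiff(colnames(hist_inc), common), drop = FALSE])
  sites$species_lost <- as.numeric(lost)
  summary <- tibble(
    mean_aggregate_hist_kg = mean(sites$aggregate_hist_kg),
    sd_aggregate_hist_kg = sd(sites$aggregate_hist_kg),
    mean_aggregate_cont_kg = mean(sites$aggregate_cont_kg),
    sd_aggregate_cont_kg = sd(sites$aggregate_cont_kg),
    total_biomass_loss_kg = sum(sites$aggregate_hist_kg - sites$aggregate_cont_kg),
    mean_biomass_loss_kg = mean(sites$aggregate_hist_kg - sites$aggregate_cont_kg),
    biomass_decline_pct = 100 * (1 - sum(sites$aggregate_cont_kg) /
                                   sum(sites$aggregate_hist_kg)),
    mean_mass_hist_kg = mean(sites$mean_mass_hist_kg, na.rm = TRUE),
    mean_mass_cont_kg = mean(sites$mean_mass_cont_kg, na.rm = TRUE)
  )
  list(sites = sites, summary = summary)
}

#' Tukey-Kramer pairwise comparison across protection categories
#'
#' One-way ANOVA mean square error with the studentized-range distribution
#' and Kramer's unequal-n adjustment:
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with p-values from the
#' studentized-range CDF on (k groups, N - k df).
#'
#' @param data tibble with the response and grouping columns.
#' @param value,group column names (strings).
#' @param alpha significance level for the `significant` flag.
#' @return tibble: `group1`, `group2`, `mean_diff`, `q`, `p`, `significant`.
#' @export
protection_comparison <- function(data, value, group, alpha = 0.05) {
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2) abort("need at least two groups")
  ns <- tapply(y, g, length)
  if (any(ns < 2)) abort("every group needs at least two observations")
  means <- tapply(y, g, mean)
  N <- length(y)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (N - k)
  combs <- utils::combn(levels(g), 2)
  rows <- apply(combs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(means[[i]] - means[[j]]) / se
    p <- ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
    tibble(group1 = i, group2 = j, mean_diff = means[[j]] - means[[i]],
           q = q, p = p, significant = p < alpha)
  })
  dplyr::bind_rows(rows)
}
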