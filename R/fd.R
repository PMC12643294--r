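#' Gower distance matrix over a trait table
#'
#' Mixed-type Gower dissimilarity with equal trait weights: continuous traits
#' contribute `|x_i - x_j| / range` (range over the whole pool), binary
#' traits a 0/1 mismatch; `d_ij` is the mean over traits. Body mass is
#' log10-transformed by default since masses span orders of magnitude.
#' Constant continuous traits are excluded with a warning (their range-
#' normalized difference is undefined).
#'
#' @param traits tibble: `species_id`, `body_mass_g`, binary `guild_*` and
#'   `loco_*` columns (any other numeric column is treated as continuous if
#'   non-binary, binary otherwise).
#' @param mass_transform function applied to `body_mass_g` (default `log10`;
#'   use `identity` to disable).
#' @return symmetric `dist`-like matrix in `[0, 1]` with species ids as
#'   dimnames.
#' @export
gower_matrix <- function(traits, mass_transform = log10) {
  ids <- traits$species_id
  cols <- setdiff(colnames(traits), "species_id")
  n <- nrow(traits)
  if (n < 2) abort("need at least two species")
  acc <- matrix(0, n, n)
  used <- 0L
  for (cl in cols) {
    v <- traits[[cl]]
    if (cl == "body_mass_g") v <- mass_transform(v)
    if (all(v %in% c(0, 1)) && cl != "body_mass_g") {
      part <- outer(v, v, FUN = function(a, b) as.numeric(a != b))
    } else {
      rng <- diff(range(v))
      if (rng < 1e-300) {
        warn(paste0("constant continuous trait '", cl, "' excluded"))
        next
      }
      part <- abs(outer(v, v, "-")) / rng
    }
    acc <- acc + part
    used <- used + 1L
  }
  if (used == 0L) abort("no usable traits")
  d <- acc / used
  dimnames(d) <- list(ids, ids)
  d
}

#' Principal coordinates analysis of a functional distance matrix
#'
#' Classical scaling: double-center `-1/2 J d^2 J` and eigendecompose. If a
#' negative eigenvalue beyond `-1e-8 * max` appears (non-Euclidean
#' distances), the Cailliez additive correction is applied and the analysis
#' recomputed. Coordinates are eigenvectors scaled by the square root of
#' their (positive) eigenvalues. Embedding quality `R2(m)` is the squared
#' Pearson correlation between the original distances and the Euclidean
#' distances in the first `m` axes.
#'
#' @param d symmetric distance matrix.
#' @return a `pcoa_result`: `coordinates` (species x positive axes),
#'   `eigenvalues` (all, descending), `correction` ("none" or "cailliez"),
#'   `r2` (per axis count).
#' @export
trait_pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("distance matrix must be symmetric")
  }
  n <- nrow(d)
  decomp <- function(dd) {
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (dd^2) %*% J
    eigen((B + t(B)) / 2, symmetric = TRUE)
  }
  ev <- decomp(d)
  correction <- "none"
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    cs <- stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE, add = TRUE)
    dc <- d + cs$ac
    diag(dc) <- 0
    ev <- decomp(dc)
    correction <- "cailliez"
  }
  tol <- 1e-8 * max(abs(ev$values), 1e-300)
  pos <- which(ev$values > tol)
  coords <- if (length(pos)) {
    sweep(ev$vectors[, pos, drop = FALSE], 2, sqrt(ev$values[pos]), "*")
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(d)
  orig <- as.vector(stats::as.dist(d))
  r2 <- vapply(seq_len(ncol(coords)), function(m) {
    emb <- as.vector(dist(coords[, seq_len(m), drop = FALSE]))
    if (sd(emb) < 1e-300 || sd(orig) < 1e-300) return(NA_real_)
    cor(orig, emb)^2
  }, numeric(1))
  structure(list(coordinates = coords, eigenvalues = ev$values,
                 correction = correction, r2 = r2),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d species, %d positive axes, correction: %s\n",
              nrow(x$coordinates), ncol(x$coordinates), x$correction))
  invisible(x)
}

#' Choose the ordination dimensionality by embedding quality
#'
#' Smallest `m` whose `R2(m)` exceeds the threshold, capped at the number of
#' positive axes (with a warning when the threshold is unreachable).
#'
#' @param pcoa a [trait_pcoa()] result.
#' @param quality_threshold required `R2` (default 0.75).
#' @return integer `m`; attribute `threshold_reached` records whether the
#'   quality target was attainable.
#' @export
select_axes <- function(pcoa, quality_threshold = 0.75) {
  if (ncol(pcoa$coordinates) < 1) abort("no positive axes")
  hit <- which(pcoa$r2 > quality_threshold)
  if (length(hit) == 0) {
    warn("quality threshold unreachable; returning all positive axes")
    m <- length(pcoa$r2)
    attr(m, "threshold_reached") <- FALSE
  } else {
    m <- min(hit)
    attr(m, "threshold_reached") <- TRUE
  }
  m
}

# exact convex hull volume of a point matrix (d <= 4)
hull_volume <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) > 4) abort("hull volumes are supported for m <= 4 only")
  if (nrow(points) <= ncol(points)) return(0)
  cpp_hull_volume(points)
}

#' Functional richness of a community
#'
#' Convex-hull volume of the community's species in the first `m` ordination
#' axes, standardized by the pool hull volume in the same axes (so the full
#' pool scores 1). Communities with richness at or below `m` cannot span an
#' `m`-dimensional hull; their hull is computed in the first `richness - 1`
#' axes and standardized against the pool in that same subspace, with a flag.
#'
#' @param community character vector of species ids (subset of the pool).
#' @param pcoa a [trait_pcoa()] result for the pool.
#' @param m ordination axes to use (<= 4).
#' @param pool_volumes optional precomputed pool hull volumes, one per axis
#'   count (a cache used by [fd_by_site()]).
#' @return one-row tibble: `richness`, `m_used`, `fric_raw`, `fric_std`,
#'   `flag` (one of "ok", "reduced_dim", "degenerate").
#' @export
fric <- function(community, pcoa, m, pool_volumes = NULL) {
  if (m > 4) abort("hull volumes are supported for m <= 4 only")
  pool_ids <- rownames(pcoa$coordinates)
  if (!all(community %in% pool_ids)) abort("community must be a subset of the pool")
  r <- length(community)
  if (r < 2) {
    return(tibble(richness = r, m_used = 0L, fric_raw = 0, fric_std = 0,
                  flag = "degenerate"))
  }
  m_used <- min(m, r - 1, ncol(pcoa$coordinates))
  flag <- if (m_used < m) "reduced_dim" else "ok"
  axes <- seq_len(m_used)
  vol <- hull_volume(pcoa$coordinates[community, axes, drop = FALSE])
  pool_vol <- if (!is.null(pool_volumes) && length(pool_volumes) >= m_used) {
    pool_volumes[m_used]
  } else {
    hull_volume(pcoa$coordinates[, axes, drop = FALSE])
  }
  tibble(richness = r, m_used = as.integer(m_used), fric_raw = vol,
         fric_std = if (pool_vol > 0) vol / pool_vol else NA_real_,
         flag = flag)
}

#' Functional diversity loss between two compositions
#'
#' `FD_loss = standardized FRic(historical) - standardized FRic(contemporary)`;
#' negative values (possible under commission) are allowed.
#'
#' @param historical,contemporary character vectors of species ids.
#' @param pcoa,m,pool_volumes as in [fric()].
#' @return one-row tibble with both FRic entries and `fd_loss`.
#' @export
fd_loss <- function(historical, contemporary, pcoa, m, pool_volumes = NULL) {
  h <- fric(historical, pcoa, m, pool_volumes)
  c_ <- fric(contemporary, pcoa, m, pool_volumes)
  tibble(fric_hist = h$fric_std, fric_cont = c_$fric_std,
         fd_loss = h$fric_std - c_$fric_std,
         flag_hist = h$flag, flag_cont = c_$flag)
}

#' Site-level functional diversity analysis
#'
#' Gower distances, PCoA, axis selection and per-site FRic/FD-loss over the
#' historical and contemporary compositions of every assemblage.
#'
#' @param assemblages contemporary assemblage tibble.
#' @param hist_incidence sites x species matrix
#'   ([historical_composition()]).
#' @param traits trait tibble ([traits_table()] schema).
#' @param m axes to use; `NULL` selects by [select_axes()] (capped at 4).
#' @param quality_threshold passed to [select_axes()].
#' @param mass_transform passed to [gower_matrix()].
#' @return list: `pcoa`, `m`, `sites` (tibble with per-site FRic and
#'   `fd_loss`).
#' @export
fd_by_site <- function(assemblages, hist_incidence, traits, m = NULL,
                       quality_threshold = 0.75, mass_transform = log10) {
  d <- gower_matrix(traits, mass_transform = mass_transform)
  pc <- trait_pcoa(d)
  if (is.null(m)) m <- min(4L, as.integer(select_axes(pc, quality_threshold)))
  inc <- assemblage_incidence(assemblages)
  hist_inc <- hist_incidence[assemblages$site_id, , drop = FALSE]
  pool_volumes <- vapply(seq_len(m), function(mm) {
    hull_volume(pc$coordinates[, seq_len(mm), drop = FALSE])
  }, numeric(1))
  rows <- lapply(seq_len(nrow(assemblages)), function(i) {
    hist_sp <- colnames(hist_inc)[hist_inc[i, ] > 0]
    cont_sp <- colnames(inc)[inc[i, ] > 0]
    fd_loss(hist_sp, cont_sp, pc, m, pool_volumes) %>%
      mutate(site_id = assemblages$site_id[i],
             protection = assemblages$protection[i],
             richness_hist = length(hist_sp), richness_cont = length(cont_sp),
             .before = 1)
  })
  list(pcoa = pc, m = m, sites = dplyr::bind_rows(rows))
}

#' Gaussian GLM of functional-diversity loss on drivers
#'
#' Identity-link Gaussian fit (ordinary least squares) of the response on the
#' given predictors, with per-coefficient t-tests. Rank-deficient designs are
#' rejected with the collinear columns named.
#'
#' @param data tibble holding the response and predictors.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @return a `defauna_glm`: list with the `stats::glm` `fit`, tidy
#'   `coefficients` tibble and residual diagnostics.
#' @export
glm_fd <- function(data, response, predictors) {
  if (nrow(data) <= length(predictors) + 1) {
    abort("need more observations than predictors + 1")
  }
  f <- stats::as.formula(paste(response, "~",
                               paste(predictors, collapse = " + ")))
  fit <- stats::glm(f, data = data, family = stats::gaussian())
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                  std_error = unname(sm[, 2]), statistic = unname(sm[, 3]),
                  p_value = unname(sm[, 4]))
  res <- stats::residuals(fit)
  structure(list(fit = fit, coefficients = coefs,
                 diagnostics = tibble(residual_ss = sum(res^2),
                                      residual_sd = sd(res),
                                      shapiro_p = if (length(res) >= 3 && length(res) <= 5000)
                                        stats::shapiro.test(res)$p.value else NA_real_)),
            class = "defauna_glm")
}

#' @export
print.defauna_glm <- function(x, ...) {
  cat("<defauna_glm> Gaussian identity-link fit\n")
  print(x$coefficients)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.defauna_glm <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.defauna_glm <- function(x, ...) {
  tibble(residual_ss = x$diagnostics$residual_ss,
         residual_sd = x$diagnostics$residual_sd,
         aic = stats::AIC(x$fit), n = length(stats::residuals(x$fit)))
}
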