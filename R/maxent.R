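#' Pre-screen correlated predictors
#'
#' Greedy scan in input order over the stack's layers: a layer is dropped iff
#' its Pearson correlation (over jointly valid cells) with any
#' already-retained layer reaches `r_max` in absolute value. Zero-variance
#' layers are excluded with a warning (their correlation is undefined).
#'
#' @param env an [env_stack()].
#' @param r_max absolute correlation ceiling (default 0.8).
#' @return character vector of retained layer names, in input order.
#' @export
prescreen_predictors <- function(env, r_max = 0.8) {
  nm <- names(env)
  vals <- sapply(nm, function(n) as.vector(env[[n]]$values))
  ok <- stats::complete.cases(vals)
  vals <- vals[ok, , drop = FALSE]
  retained <- character(0)
  for (n in nm) {
    v <- vals[, n]
    if (sd(v) < 1e-12) {
      warn(paste0("layer '", n, "' has zero variance; excluded"))
      next
    }
    drop <- FALSE
    for (r in retained) {
      if (abs(cor(v, vals[, r])) >= r_max) { drop <- TRUE; break }
    }
    if (!drop) retained <- c(retained, n)
  }
  retained
}

#' Build a MaxEnt feature matrix
#'
#' Expands the chosen feature classes over a set of environmental layers for
#' the background (all valid cells, or a seeded subsample above
#' `max_background`) and the presence points (snapped to cell centers).
#' Features are scaled to `[0, 1]` by the background minimum and maximum;
#' zero-range features are dropped with a warning.
#'
#' @param env an [env_stack()] (already pre-screened as desired).
#' @param presences tibble with `x`, `y` columns.
#' @param classes subset of `c("linear", "quadratic", "product")`.
#' @param max_background background cap (default 10000).
#' @param seed seed for the background subsample.
#' @return a `feature_matrix`: list with `bg` and `pres` scaled matrices,
#'   `bg_cells`, `scaling` and `classes`.
#' @export
build_features <- function(env, presences,
                           classes = c("linear", "quadratic", "product"),
                           max_background = 10000, seed = 1) {
  classes <- match.arg(classes, several.ok = TRUE)
  tab <- env_table(env, valid_only = TRUE)
  lyr <- names(env)
  bg_raw <- as.matrix(tab[, lyr, drop = FALSE])
  if (nrow(bg_raw) > max_background) {
    keep <- with_seed(seed, sample(nrow(bg_raw), max_background))
    tab <- tab[keep, ]
    bg_raw <- bg_raw[keep, , drop = FALSE]
  }
  loc <- raster_locate(env[[1]], presences$x, presences$y)
  outside <- is.na(loc$row)
  if (any(outside)) {
    warn(sprintf("%d presence point(s) outside the raster extent dropped", sum(outside)))
  }
  loc <- loc[!outside, , drop = FALSE]
  if (nrow(loc) == 0) abort("all presence points fall outside the raster extent")
  pres_raw <- sapply(lyr, function(n) env[[n]]$values[cbind(loc$row, loc$col)])
  pres_raw <- matrix(pres_raw, ncol = length(lyr),
                     dimnames = list(NULL, lyr))
  cc <- stats::complete.cases(pres_raw)
  if (any(!cc)) warn(sprintf("%d presence point(s) on nodata cells dropped", sum(!cc)))
  pres_raw <- pres_raw[cc, , drop = FALSE]
  if (nrow(pres_raw) == 0) abort("no presence points on valid cells")

  expand <- function(m) {
    out <- list()
    if ("linear" %in% classes) {
      for (n in lyr) out[[n]] <- m[, n]
    }
    if ("quadratic" %in% classes) {
      for (n in lyr) out[[paste0(n, "^2")]] <- m[, n]^2
    }
    if ("product" %in% classes && length(lyr) >= 2) {
      for (i in seq_len(length(lyr) - 1)) {
        for (j in (i + 1):length(lyr)) {
          out[[paste0(lyr[i], "*", lyr[j])]] <- m[, lyr[i]] * m[, lyr[j]]
        }
      }
    }
    do.call(cbind, out)
  }
  bg_f <- expand(bg_raw)
  pres_f <- expand(pres_raw)
  if (any(!is.finite(bg_f))) abort("non-finite values in background features")
  mins <- apply(bg_f, 2, min)
  maxs <- apply(bg_f, 2, max)
  keepf <- (maxs - mins) > 1e-300
  if (any(!keepf)) {
    warn(paste0("dropping zero-range feature(s): ",
                paste(colnames(bg_f)[!keepf], collapse = ", ")))
  }
  bg_f <- bg_f[, keepf, drop = FALSE]
  pres_f <- pres_f[, keepf, drop = FALSE]
  mins <- mins[keepf]; maxs <- maxs[keepf]
  scale01 <- function(m) sweep(sweep(m, 2, mins), 2, maxs - mins, "/")
  structure(list(
    bg = scale01(bg_f), pres = scale01(pres_f),
    bg_cells = tab[, c("row", "col", "x", "y")],
    scaling = tibble(feature = colnames(bg_f), min = mins, max = maxs),
    layers = lyr, classes = classes
  ), class = "feature_matrix")
}

#' Fit a penalized maximum-entropy distribution model
#'
#' Maximizes the L1-penalized Gibbs log-likelihood
#' `L(lambda) = lambda . fbar - log Z - sum_j beta_j |lambda_j|`
#' over background cells by cyclic coordinate descent with backtracking, so
#' the objective is non-decreasing across update sweeps. Per-feature penalty
#' `beta_j = beta_scale * sd(feature over presences) / sqrt(n_presences)`.
#' At a `beta = 0` optimum the background expectation of each feature matches
#' its presence mean (the maximum-entropy moment constraints); with
#' `beta_j > 0` the mismatch is bounded by `beta_j`.
#'
#' @param features a [build_features()] object.
#' @param beta_scale multiplier on the penalty heuristic (default 1).
#' @param max_iter maximum update sweeps (default 10000).
#' @param tol convergence tolerance on the largest coordinate update.
#' @param obj_tol relative objective-gain tolerance per full scan; sweeps
#'   stop once a full scan improves the penalized objective by less than
#'   `obj_tol * (1 + |objective|)`.
#' @param lambda_init optional warm-start weight vector (same optimum is
#'   reached; only the path changes).
#' @return a `maxent_model`: feature weights `lambda`, penalties `beta`,
#'   objective trace, Gibbs probabilities over background and the
#'   normalization used to report suitability on a max-1 scale.
#' @export
fit_maxent <- function(features, beta_scale = 0.2, max_iter = 10000, tol = 1e-7,
                       obj_tol = 1e-7, lambda_init = NULL) {
  if (nrow(features$pres) < 1) abort("need at least one presence")
  if (nrow(features$bg) < 2) abort("need at least two background cells")
  if (any(!is.finite(features$pres))) abort("non-finite values in presence features")
  fbar <- colMeans(features$pres)
  n_pres <- nrow(features$pres)
  beta <- beta_scale * apply(features$pres, 2, sd) / sqrt(n_pres)
  beta[!is.finite(beta)] <- 0
  fit <- cpp_maxent_cd(features$bg, fbar, beta, as.integer(max_iter), tol,
                       obj_tol, lambda_init)
  if (!fit$converged) warn("maxent fit did not converge within max_iter sweeps")
  lambda <- setNames(as.numeric(fit$lambda), colnames(features$bg))
  p <- as.numeric(fit$p)
  structure(list(
    lambda = lambda, beta = setNames(beta, names(lambda)), fbar = fbar,
    p = p, p_max = max(p), objective = as.numeric(fit$objective),
    converged = fit$converged, sweeps = fit$sweeps,
    scaling = features$scaling, layers = features$layers,
    classes = features$classes, bg_cells = features$bg_cells
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features (%d active), objective %.5f, %s after %d sweeps\n",
              length(x$lambda), sum(x$lambda != 0), utils::tail(x$objective, 1),
              if (x$converged) "converged" else "NOT converged", x$sweeps))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.maxent_model <- function(x, ...) {
  tibble(term = names(x$lambda), estimate = unname(x$lambda),
         penalty = unname(x$beta), presence_mean = unname(x$fbar))
}

#' @exportS3Method generics::glance
glance.maxent_model <- function(x, ...) {
  tibble(objective = utils::tail(x$objective, 1), sweeps = x$sweeps,
         converged = x$converged, n_features = length(x$lambda),
         n_active = sum(x$lambda != 0))
}

# expand + scale raw layer values with a fitted model's feature recipe
expand_with_scaling <- function(model, raw) {
  lyr <- model$layers
  out <- list()
  if ("linear" %in% model$classes) for (n in lyr) out[[n]] <- raw[, n]
  if ("quadratic" %in% model$classes) {
    for (n in lyr) out[[paste0(n, "^2")]] <- raw[, n]^2
  }
  if ("product" %in% model$classes && length(lyr) >= 2) {
    for (i in seq_len(length(lyr) - 1)) {
      for (j in (i + 1):length(lyr)) {
        out[[paste0(lyr[i], "*", lyr[j])]] <- raw[, lyr[i]] * raw[, lyr[j]]
      }
    }
  }
  f <- do.call(cbind, out)
  f <- f[, model$scaling$feature, drop = FALSE]
  sweep(sweep(f, 2, model$scaling$min), 2,
        model$scaling$max - model$scaling$min, "/")
}

#' Predict a suitability surface from a fitted model
#'
#' Suitability is the Gibbs probability rescaled so the best background cell
#' scores 1 (raw-rescaled output).
#'
#' @param object a `maxent_model`.
#' @param env an [env_stack()] containing the model's layers.
#' @param ... ignored.
#' @return a `raster_grid` of suitability in `[0, 1]` (values can exceed 1
#'   only where conditions beat every background cell).
#' @export
predict.maxent_model <- function(object, env, ...) {
  tab <- env_table(env, valid_only = FALSE)
  raw <- as.matrix(tab[, object$layers, drop = FALSE])
  ok <- stats::complete.cases(raw)
  eta <- rep(NA_real_, nrow(raw))
  f <- expand_with_scaling(object, raw[ok, , drop = FALSE])
  eta[ok] <- as.vector(f %*% object$lambda)
  # normalize exactly as over the fitted background
  bg_raw <- NULL
  tmpl <- env[[1]]
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  p_unnorm <- exp(eta - max(eta, na.rm = TRUE))
  # rescale so the background maximum maps to 1: recompute eta at bg cells
  suit <- p_unnorm / max(p_unnorm, na.rm = TRUE)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(tab$row, tab$col)] <- suit
  raster_grid(m, tmpl$origin_x, tmpl$origin_y, tmpl$cell_size,
              crs_label = tmpl$crs_label)
}

#' Area under the ROC curve by pair counting
#'
#' Mann-Whitney form: ties between a positive and a negative score count 1/2.
#'
#' @param pos,neg score vectors for positives (test presences) and negatives
#'   (background).
#' @return AUC in `[0, 1]`.
#' @export
auc_scores <- function(pos, neg) {
  if (length(pos) == 0 || length(neg) == 0) abort("need scores in both classes")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Replicated fit-and-evaluate for a species
#'
#' Runs `n_rep` random 90/10 presence splits; each replicate fits on the
#' training presences and scores test presences against the full background
#' with ROC AUC. The reported suitability surface is the mean over replicate
#' models.
#'
#' @param features a [build_features()] object.
#' @param n_rep replicates (default 10).
#' @param test_frac presence fraction held out per replicate (default 0.10).
#' @param seed RNG seed for the splits.
#' @param beta_scale,max_iter,tol passed to [fit_maxent()].
#' @return list: `eval` (tibble of per-replicate AUC), `mean_auc`, `models`
#'   (replicate `maxent_model`s), `mean_suitability_bg` (averaged normalized
#'   suitability over the background cells).
#' @export
evaluate_replicates <- function(features, n_rep = 10, test_frac = 0.10,
                                seed = 1, beta_scale = 0.2, max_iter = 10000,
                                tol = 1e-7, obj_tol = 1e-7) {
  n <- nrow(features$pres)
  if (n < 2) abort("need at least two presences to split")
  n_test <- max(1, round(test_frac * n))
  if (n_test >= n) abort("test fraction leaves no training presences")
  aucs <- numeric(n_rep)
  models <- vector("list", n_rep)
  suit_sum <- numeric(nrow(features$bg))
  # replicates share 90% of their presences: warm-start each from the
  # full-data fit (initialization does not change a convex optimum)
  full_fit <- fit_maxent(features, beta_scale = beta_scale,
                         max_iter = max_iter, tol = tol, obj_tol = obj_tol)
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      test_idx <- sample(n, n_test)
      train <- features
      train$pres <- features$pres[-test_idx, , drop = FALSE]
      m <- fit_maxent(train, beta_scale = beta_scale, max_iter = max_iter,
                      tol = tol, obj_tol = obj_tol,
                      lambda_init = unname(full_fit$lambda))
      eta_bg <- as.vector(features$bg %*% m$lambda)
      eta_test <- as.vector(features$pres[test_idx, , drop = FALSE] %*% m$lambda)
      aucs[r] <- auc_scores(eta_test, eta_bg)
      suit_sum <- suit_sum + m$p / m$p_max
      models[[r]] <- m
    }
  })
  list(eval = tibble(replicate = seq_len(n_rep), auc = aucs, n_test = n_test),
       mean_auc = mean(aucs), models = models,
       mean_suitability_bg = suit_sum / n_rep)
}

#' Candidate thresholds and the minimum-predicted-area rule
#'
#' Computes the four standard candidate thresholds — minimum training
#' presence, 10th percentile training presence, equal training sensitivity
#' and specificity, maximum training sensitivity plus specificity — and
#' selects the one whose predicted area (cells with suitability >= threshold)
#' is smallest, the conservative "smallest potential habitat" rule. Ties go
#' to the larger threshold.
#'
#' @param suitability a `raster_grid`.
#' @param presences tibble with `x`, `y` of training presences.
#' @return a `threshold_report`: tibble of candidates (`rule`, `threshold`,
#'   `predicted_area`) with the selected rule flagged, plus attributes
#'   `selected` and `threshold`.
#' @export
select_threshold <- function(suitability, presences) {
  loc <- raster_locate(suitability, presences$x, presences$y)
  ok <- !is.na(loc$row)
  ps <- suitability$values[cbind(loc$row[ok], loc$col[ok])]
  ps <- ps[!is.na(ps)]
  if (length(ps) == 0) abort("no presence has a valid suitability value")
  bg <- as.vector(suitability$values)
  bg <- bg[!is.na(bg)]
  srt <- sort(ps)
  mtp <- srt[1]
  p10 <- srt[min(length(srt), floor(0.1 * length(srt)) + 1)]
  cand_t <- sort(unique(c(ps, bg)))
  sens <- vapply(cand_t, function(t) mean(ps >= t), numeric(1))
  spec <- vapply(cand_t, function(t) mean(bg < t), numeric(1))
  pick_last <- function(idx) cand_t[max(idx)] # ties -> larger threshold
  ess <- pick_last(which(abs(sens - spec) == min(abs(sens - spec))))
  mss <- pick_last(which(sens + spec == max(sens + spec)))
  cand <- tibble(
    rule = c("minimum_training_presence", "p10_training_presence",
             "equal_sens_spec", "max_sens_plus_spec"),
    threshold = c(mtp, p10, ess, mss)
  )
  cand$predicted_area <- vapply(cand$threshold,
                                function(t) sum(bg >= t), numeric(1))
  best <- cand$predicted_area == min(cand$predicted_area)
  sel <- which(best)[which.max(cand$threshold[best])]
  cand$selected <- seq_len(nrow(cand)) == sel
  attr(cand, "selected") <- cand$rule[sel]
  attr(cand, "threshold") <- cand$threshold[sel]
  class(cand) <- c("threshold_report", class(cand))
  cand
}

#' Binarize a suitability surface
#'
#' @param suitability a `raster_grid`.
#' @param tau threshold; presence is `suitability >= tau`. Missing cells stay
#'   missing.
#' @return binary `raster_grid`.
#' @export
binarize <- function(suitability, tau) {
  if (!is.finite(tau)) abort("tau must be finite")
  v <- suitability$values
  m <- ifelse(is.na(v), NA_real_, as.numeric(v >= tau))
  raster_grid(m, suitability$origin_x, suitability$origin_y,
              suitability$cell_size, crs_label = suitability$crs_label)
}

#' Stack binary species maps into a richness surface
#'
#' Cellwise integer sum over aligned binary maps; a cell is missing only
#' where every species map is missing.
#'
#' @param maps list of aligned binary `raster_grid`s.
#' @param template raster used when `maps` is empty (all-zero result).
#' @return `raster_grid` of species richness.
#' @export
stack_richness <- function(maps, template = NULL) {
  if (length(maps) == 0) {
    if (is.null(template)) abort("empty map list needs a template raster")
    return(raster_grid(matrix(0, nrow(template$values), ncol(template$values)),
                       template$origin_x, template$origin_y,
                       template$cell_size, crs_label = template$crs_label))
  }
  for (m in maps) stopifnot_aligned(maps[[1]], m, "binary maps")
  tmpl <- maps[[1]]
  acc <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
  any_ok <- matrix(FALSE, nrow(tmpl$values), ncol(tmpl$values))
  for (m in maps) {
    v <- m$values
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    any_ok <- any_ok | ok
  }
  acc[!any_ok] <- NA_real_
  raster_grid(acc, tmpl$origin_x, tmpl$origin_y, tmpl$cell_size,
              crs_label = tmpl$crs_label)
}

#' Fit, evaluate and binarize the historical model for every species
#'
#' Per-species pipeline: correlation pre-screen, feature expansion,
#' replicated maximum-entropy fits with ROC evaluation, mean suitability
#' surface, minimum-predicted-area thresholding, and stacking of the binary
#' maps into the historical richness surface.
#'
#' @param occurrences tibble `species`, `x`, `y` for all species.
#' @param env an [env_stack()].
#' @param n_rep,test_frac,beta_scale,max_iter,tol,obj_tol modelling controls,
#'   see [evaluate_replicates()] and [fit_maxent()].
#' @param r_max pre-screen correlation ceiling.
#' @param classes feature classes, see [build_features()].
#' @param seed base seed; species get consecutive offsets.
#' @return list: `richness` (stacked `raster_grid`), `species` (tibble with
#'   per-species AUC, selected threshold and range size), `binary` and
#'   `suitability` (named lists of rasters), `retained_layers`.
#' @export
sdm_stack <- function(occurrences, env, n_rep = 10, test_frac = 0.10,
                      beta_scale = 0.2, max_iter = 10000, tol = 1e-6,
                      obj_tol = 1e-5, r_max = 0.8,
                      classes = c("linear", "quadratic", "product"),
                      seed = 1) {
  retained <- prescreen_predictors(env, r_max = r_max)
  env_sub <- env_stack(unclass(env)[retained])
  sp <- unique(occurrences$species)
  binary <- list(); suit <- list()
  rows <- vector("list", length(sp))
  for (k in seq_along(sp)) {
    occ_k <- occurrences[occurrences$species == sp[k], ]
    feats <- build_features(env_sub, occ_k, classes = classes,
                            seed = seed + 7000L + k)
    rep_k <- evaluate_replicates(feats, n_rep = n_rep, test_frac = test_frac,
                                 seed = seed + 9000L + k,
                                 beta_scale = beta_scale,
                                 max_iter = max_iter, tol = tol,
                                 obj_tol = obj_tol)
    # mean suitability surface over replicate models
    preds <- lapply(rep_k$models, function(m) predict(m, env_sub))
    acc <- preds[[1]]$values
    for (i in seq_along(preds)[-1]) acc <- acc + preds[[i]]$values
    mean_suit <- raster_grid(acc / length(preds), preds[[1]]$origin_x,
                             preds[[1]]$origin_y, preds[[1]]$cell_size,
                             crs_label = preds[[1]]$crs_label)
    thr <- select_threshold(mean_suit, occ_k)
    bin <- binarize(mean_suit, attr(thr, "threshold"))
    binary[[sp[k]]] <- bin
    suit[[sp[k]]] <- mean_suit
    rows[[k]] <- tibble(
      species = sp[k], n_occurrences = nrow(occ_k),
      mean_auc = rep_k$mean_auc,
      threshold_rule = attr(thr, "selected"),
      threshold = attr(thr, "threshold"),
      range_cells = sum(bin$values > 0, na.rm = TRUE)
    )
  }
  list(richness = stack_richness(binary), species = dplyr::bind_rows(rows),
       binary = binary, suitability = suit, retained_layers = retained)
}
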