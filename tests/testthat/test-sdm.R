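mk_env <- function(...) {
  layers <- list(...)
  env_stack(lapply(layers, mk_raster))
}

test_that("predictor pre-screen drops layers correlated at or above the ceiling", {
  set.seed(42)
  n <- 30
  a <- matrix(rnorm(n^2), n, n)
  c_ <- matrix(rnorm(n^2), n, n)
  # orthogonalize so pairwise |r| is essentially zero
  c_ <- c_ - mean(a * c_) / mean(a * a) * a
  d_ <- matrix(rnorm(n^2), n, n)
  d_ <- d_ - mean(a * d_) / mean(a * a) * a
  d_ <- d_ - mean(c_ * d_) / mean(c_ * c_) * c_
  # three mutually orthogonal layers are all retained
  expect_identical(prescreen_predictors(mk_env(A = a, B = c_ * 2, C = d_)),
                   c("A", "B", "C"))
  # exact duplicate: keep first, drop copy
  expect_identical(prescreen_predictors(mk_env(A = a, B = a)), "A")
  # engineered r = 0.9 pair: scale noise so cor(A, B) = 0.9 exactly
  za <- as.vector(scale(as.vector(a)))
  zc <- as.vector(scale(as.vector(c_)))
  zc <- as.vector(scale(zc - mean(zc * za) * za))
  b <- matrix(0.9 * za + sqrt(1 - 0.81) * zc, n, n)
  expect_equal(cor(as.vector(a), as.vector(b)), 0.9, tolerance = 1e-6)
  expect_identical(prescreen_predictors(mk_env(A = a, B = b, C = c_)),
                   c("A", "C"))
  # zero-variance layer excluded with a warning
  expect_warning(ret <- prescreen_predictors(mk_env(A = a, Z = a * 0)),
                 "zero variance")
  expect_identical(ret, "A")
})

test_that("feature expansion produces the expected columns in [0, 1]", {
  set.seed(1)
  env <- mk_env(A = matrix(runif(100, 2, 9), 10, 10),
                B = matrix(runif(100, -3, 5), 10, 10))
  pres <- tibble::tibble(x = c(2.5, 5.5), y = c(3.5, 7.5))
  fl <- build_features(env, pres, classes = "linear")
  expect_equal(ncol(fl$bg), 2)
  fq <- build_features(env, pres)
  expect_equal(ncol(fq$bg), 5) # 2 linear + 2 quadratic + 1 product
  expect_true(all(fq$bg >= 0 & fq$bg <= 1))
  # constant layer's features are dropped
  envc <- mk_env(A = matrix(runif(100), 10, 10), K = matrix(4, 10, 10))
  expect_warning(fc <- build_features(envc, pres, classes = "linear"),
                 "zero-range")
  expect_equal(colnames(fc$bg), "A")
  # presences off the grid are dropped, all-off errors
  expect_warning(build_features(env, tibble::tibble(x = c(2.5, 99), y = c(3.5, 99))),
                 "outside")
  expect_error(suppressWarnings(
    build_features(env, tibble::tibble(x = 99, y = 99))), "outside")
})

test_that("maximum-entropy fit matches the closed-form single-constraint solution", {
  # 4 background cells, one binary feature, presence mean 0.75:
  # p = (0.375, 0.375, 0.125, 0.125), lambda = ln 3
  feats <- structure(list(
    bg = matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(NULL, "f")),
    pres = matrix(c(1, 1, 1, 0), 4, 1, dimnames = list(NULL, "f")),
    bg_cells = tibble::tibble(row = 1:4, col = 1L, x = 0, y = 0),
    scaling = tibble::tibble(feature = "f", min = 0, max = 1),
    layers = "f", classes = "linear"
  ), class = "feature_matrix")
  m <- fit_maxent(feats, beta_scale = 0, tol = 1e-12, obj_tol = 1e-14)
  expect_equal(unname(m$lambda), log(3), tolerance = 1e-6)
  expect_equal(m$p, c(0.375, 0.375, 0.125, 0.125), tolerance = 1e-6)
  # penalized objective is non-decreasing across sweeps
  expect_true(all(diff(m$objective) >= -1e-9))

  # presences indistinguishable from background: all weights ~ 0
  featu <- feats
  featu$pres <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(NULL, "f"))
  mu <- fit_maxent(featu, beta_scale = 0, tol = 1e-12, obj_tol = 1e-14)
  expect_equal(unname(mu$lambda), 0, tolerance = 1e-6)
  expect_equal(mu$p, rep(0.25, 4), tolerance = 1e-6)

  # overwhelming L1 penalty shrinks to the uniform model exactly
  mb <- fit_maxent(feats, beta_scale = 1e4, tol = 1e-12)
  expect_identical(unname(mb$lambda), 0)
})

test_that("fitted moments satisfy the KKT conditions within the penalty slack", {
  w <- get_small_world()
  ret <- prescreen_predictors(w$env)
  env_sub <- env_stack(unclass(w$env)[ret])
  occ <- w$occurrences[w$occurrences$species == w$traits$species_id[1], ]
  feats <- build_features(env_sub, occ, classes = c("linear", "quadratic"))
  # beta = 0: expectations match presence means tightly
  m0 <- fit_maxent(feats, beta_scale = 0, tol = 1e-9, obj_tol = 1e-12,
                   max_iter = 20000)
  e0 <- as.vector(t(feats$bg) %*% m0$p)
  expect_lt(max(abs(e0 - colMeans(feats$pres))), 1e-4)
  # beta > 0: mismatch bounded by each feature's penalty
  m1 <- fit_maxent(feats, beta_scale = 1, tol = 1e-9, obj_tol = 1e-12,
                   max_iter = 20000)
  e1 <- as.vector(t(feats$bg) %*% m1$p)
  expect_true(all(abs(e1 - colMeans(feats$pres)) <= m1$beta + 1e-4))
  expect_true(all(diff(m1$objective) >= -1e-9))
})

test_that("ROC AUC counts ranked pairs with the tie rule", {
  expect_equal(auc_scores(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_scores(c(3, 3), c(3, 3, 3)), 0.5)
  # exhaustive pair counting: {0.9, 0.4} vs {0.5, 0.1} -> 3 wins of 4
  expect_equal(auc_scores(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
})

test_that("replicated evaluation splits presences and averages models", {
  w <- get_small_world()
  ret <- prescreen_predictors(w$env)
  env_sub <- env_stack(unclass(w$env)[ret])
  occ <- w$occurrences[w$occurrences$species == w$traits$species_id[1], ]
  feats <- build_features(env_sub, occ, classes = c("linear", "quadratic"))
  er <- evaluate_replicates(feats, n_rep = 3, seed = 5, obj_tol = 1e-4)
  expect_equal(nrow(er$eval), 3)
  expect_true(all(er$eval$auc >= 0 & er$eval$auc <= 1))
  er2 <- evaluate_replicates(feats, n_rep = 3, seed = 5, obj_tol = 1e-4)
  expect_identical(er$eval, er2$eval)
  feats1 <- feats
  feats1$pres <- feats$pres[1, , drop = FALSE]
  expect_error(evaluate_replicates(feats1), "at least two")
})

test_that("threshold selection implements the four rules and minimal area", {
  # presence suitabilities {0.9, 0.7, 0.4}: minimum training presence = 0.4
  suit <- mk_raster(matrix(seq(0.01, 1, length.out = 100), 10, 10, byrow = TRUE))
  cells <- raster_cells(suit)
  pick <- function(vals) cells[match(vals, round(cells$value, 10)), c("x", "y")]
  pres_vals <- c(0.9, 0.7, 0.4)
  pres <- cells[sapply(pres_vals, function(v) which.min(abs(cells$value - v))),
                c("x", "y")]
  rep_ <- select_threshold(suit, pres)
  expect_equal(rep_$threshold[rep_$rule == "minimum_training_presence"],
               min(suit$values[cbind(raster_locate(suit, pres$x, pres$y)$row,
                                     raster_locate(suit, pres$x, pres$y)$col)]))
  # 10th-percentile rule with ten presences: order-statistic oracle
  idx10 <- round(seq(5, 95, length.out = 10))
  pres10 <- cells[idx10, c("x", "y")]
  r10 <- select_threshold(suit, pres10)
  ps <- sort(cells$value[idx10])
  expect_equal(r10$threshold[r10$rule == "p10_training_presence"], ps[2])
  # selected threshold minimizes predicted area
  expect_equal(min(rep_$predicted_area),
               rep_$predicted_area[rep_$selected])
  # constant surface: all candidates coincide, area is the whole region
  constant <- mk_raster(matrix(0.6, 5, 5))
  rc <- select_threshold(constant, tibble::tibble(x = 2.5, y = 2.5))
  expect_true(all(rc$threshold == 0.6))
  expect_true(all(rc$predicted_area == 25))
})

test_that("binarize uses >= and is monotone in the threshold", {
  s <- mk_raster(matrix(c(0.2, 0.5, 0.8, NA), 2, 2))
  expect_equal(sum(binarize(s, 0)$values, na.rm = TRUE), 3)
  expect_equal(sum(binarize(s, 0.9)$values, na.rm = TRUE), 0)
  b <- binarize(mk_raster(matrix(c(0.2, 0.5, 0.8), 1, 3)), 0.5)
  expect_equal(as.vector(b$values), c(0, 1, 1))
  expect_true(is.na(binarize(s, 0.5)$values[2, 2]))
  areas <- sapply(seq(0, 1, 0.1), function(tau)
    sum(binarize(s, tau)$values, na.rm = TRUE))
  expect_true(all(diff(areas) <= 0))
  expect_error(binarize(s, Inf), "finite")
})

test_that("richness stacking sums aligned binary maps cellwise", {
  tmpl <- mk_raster(matrix(0, 1, 2))
  maps <- list(mk_raster(matrix(c(1, 0), 1, 2)),
               mk_raster(matrix(c(1, 1), 1, 2)),
               mk_raster(matrix(c(0, 1), 1, 2)))
  expect_equal(as.vector(stack_richness(maps)$values), c(2, 2))
  expect_equal(as.vector(stack_richness(list(), template = tmpl)$values), c(0, 0))
  # nodata only where every map is missing
  m1 <- mk_raster(matrix(c(1, NA), 1, 2))
  m2 <- mk_raster(matrix(c(NA, NA), 1, 2))
  st <- stack_richness(list(m1, m2))
  expect_equal(st$values[1, 1], 1)
  expect_true(is.na(st$values[1, 2]))
  bad <- mk_raster(matrix(0, 2, 2))
  expect_error(stack_richness(list(m1, bad)), "aligned")
})
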