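#' Train/test split
#'
#' Seeded uniform split without replacement; the training set gets
#' `floor(train_frac * n)` records.
#'
#' @param data tibble of records.
#' @param train_frac training fraction (default 0.75).
#' @param seed RNG seed.
#' @return list with `train` and `test` tibbles.
#' @export
split_data <- function(data, train_frac = 0.75, seed = 1) {
  n <- nrow(data)
  if (n < 8) abort("need at least 8 records to split")
  n_train <- floor(train_frac * n)
  idx <- with_seed(seed, sample(n, n_train))
  list(train = data[idx, , drop = FALSE], test = data[-idx, , drop = FALSE])
}

#' Stochastic gradient boosting of regression trees
#'
#' Stagewise least-squares boosting: starting from the training mean `F0`,
#' each stage fits a depth-limited regression tree to the current residuals
#' on a seeded subsample and adds `shrinkage` times its predictions. Split
#' search is greedy variance reduction with deterministic tie-breaking
#' (lowest feature index, then lowest split value). With `subsample = 1` the
#' training MSE is non-increasing in the number of trees.
#'
#' @param data training tibble.
#' @param response response column name.
#' @param predictors predictor column names (default: all other numeric
#'   columns).
#' @param n_trees,depth,shrinkage,subsample,min_node boosting
#'   hyperparameters.
#' @param seed RNG seed for the subsamples.
#' @return a `defauna_gbm`: trees, `f0`, shrinkage, the training-MSE trace
#'   and the predictor names.
#' @export
fit_gbm <- function(data, response, predictors = NULL, n_trees = 100,
                    depth = 3, shrinkage = 0.1, subsample = 1, min_node = 5,
                    seed = 1) {
  if (is.null(predictors)) {
    predictors <- setdiff(colnames(data)[vapply(data, is.numeric, logical(1))],
                          response)
  }
  y <- data[[response]]
  if (any(is.na(y))) abort("missing responses are not allowed")
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (any(is.na(X))) abort("missing predictor values are not allowed")
  n <- nrow(X)
  f0 <- mean(y)
  trees <- list()
  mse <- numeric(0)
  if (sd(y) < 1e-300) {
    warn("constant response: returning an ensemble of zero trees")
    n_trees <- 0
  }
  Fhat <- rep(f0, n)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      rows <- if (subsample < 1) {
        sample(n, max(2, floor(subsample * n))) - 1L
      } else {
        seq_len(n) - 1L
      }
      resid <- y - Fhat
      tree <- cpp_fit_tree(X, resid, as.integer(rows),
                           as.integer(depth), as.integer(min_node))
      Fhat <- Fhat + shrinkage * cpp_predict_tree(tree, X)
      trees[[t]] <- tree
      mse[t] <- mean((y - Fhat)^2)
    }
  })
  structure(list(trees = trees, f0 = f0, shrinkage = shrinkage,
                 predictors = predictors, response = response,
                 params = list(n_trees = n_trees, depth = depth,
                               shrinkage = shrinkage, subsample = subsample,
                               min_node = min_node),
                 mse_trace = mse),
            class = "defauna_gbm")
}

#' @export
print.defauna_gbm <- function(x, ...) {
  cat(sprintf("<defauna_gbm> %d trees (depth %d, shrinkage %g, subsample %g), training MSE %.4g\n",
              length(x$trees), x$params$depth, x$shrinkage,
              x$params$subsample,
              if (length(x$mse_trace)) utils::tail(x$mse_trace, 1) else NA))
  invisible(x)
}

#' @export
predict.defauna_gbm <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  as.numeric(cpp_predict_forest(object$trees, X, object$f0, object$shrinkage))
}

#' @exportS3Method generics::tidy
tidy.defauna_gbm <- function(x, ...) {
  tibble(tree = seq_along(x$mse_trace), training_mse = x$mse_trace)
}

#' @exportS3Method generics::glance
glance.defauna_gbm <- function(x, ...) {
  tibble(n_trees = length(x$trees), depth = x$params$depth,
         shrinkage = x$shrinkage, subsample = x$params$subsample,
         training_mse = if (length(x$mse_trace)) utils::tail(x$mse_trace, 1) else NA_real_)
}

#' Accuracy of a fitted model on a dataset
#'
#' `R2 = 1 - SS_res / SS_tot` and root-mean-square error. `R2` is reported
#' missing when the response has zero variance.
#'
#' @param model a `defauna_gbm` (anything with a `predict` method works).
#' @param data evaluation tibble.
#' @param response response column name.
#' @return one-row tibble: `r2`, `rmse`, `n`.
#' @export
model_accuracy <- function(model, data, response) {
  if (nrow(data) == 0) abort("no evaluation data")
  y <- data[[response]]
  yhat <- predict(model, data)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble(r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         rmse = sqrt(mean((y - yhat)^2)), n = length(y))
}

#' Random-search hyperparameter tuning with k-fold cross-validation
#'
#' Draws `n_candidates` hyperparameter settings from the candidate space
#' (number of trees and depth uniform over their ranges, shrinkage
#' log-uniform, subsample uniform), scores each by k-fold cross-validated
#' RMSE on the shuffled training set, selects the minimum, and refits the
#' winner on the full training data.
#'
#' @param train training tibble.
#' @param response,predictors as in [fit_gbm()].
#' @param test optional held-out tibble; when given, test R2/RMSE of the
#'   refit model are reported.
#' @param n_candidates random-search budget (default 25).
#' @param k folds (default 10).
#' @param seed RNG seed (candidate draws, fold shuffle, refit subsamples).
#' @param space list with `n_trees` (range), `depth` (choices), `shrinkage`
#'   (range, log-uniform), `subsample` (range), `min_node` (single value).
#' @return a `cv_result`: `candidates` tibble with mean CV RMSE, `selected`
#'   row index, refit `model`, and `metrics` (train and, when available,
#'   test R2/RMSE).
#' @export
tune_random_search <- function(train, response, predictors = NULL, test = NULL,
                               n_candidates = 25, k = 10, seed = 1,
                               space = list(n_trees = c(50, 1000),
                                            depth = c(1, 2, 3, 5),
                                            shrinkage = c(0.01, 0.3),
                                            subsample = c(0.5, 1),
                                            min_node = 5)) {
  if (n_candidates < 1) abort("empty candidate space")
  n <- nrow(train)
  if (n < k) abort("fewer training records than folds")
  cand <- with_seed(seed, tibble(
    candidate = seq_len(n_candidates),
    n_trees = round(runif(n_candidates, space$n_trees[1], space$n_trees[2])),
    depth = sample(space$depth, n_candidates, replace = TRUE),
    shrinkage = exp(runif(n_candidates, log(space$shrinkage[1]),
                          log(space$shrinkage[2]))),
    subsample = runif(n_candidates, space$subsample[1], space$subsample[2])
  ))
  # shuffle, then deal records round-robin into k folds
  folds <- with_seed(seed + 1L, {
    idx <- sample(n)
    split(idx, rep(seq_len(k), length.out = n))
  })
  cv_rmse <- numeric(n_candidates)
  for (i in seq_len(n_candidates)) {
    fold_rmse <- vapply(seq_len(k), function(f) {
      hold <- folds[[f]]
      m <- fit_gbm(train[-hold, , drop = FALSE], response, predictors,
                   n_trees = cand$n_trees[i], depth = cand$depth[i],
                   shrinkage = cand$shrinkage[i], subsample = cand$subsample[i],
                   min_node = space$min_node, seed = seed + 100L + f)
      model_accuracy(m, train[hold, , drop = FALSE], response)$rmse
    }, numeric(1))
    cv_rmse[i] <- mean(fold_rmse)
  }
  cand$mean_cv_rmse <- cv_rmse
  sel <- which.min(cv_rmse)
  model <- fit_gbm(train, response, predictors, n_trees = cand$n_trees[sel],
                   depth = cand$depth[sel], shrinkage = cand$shrinkage[sel],
                   subsample = cand$subsample[sel], min_node = space$min_node,
                   seed = seed + 500L)
  metrics <- model_accuracy(model, train, response) %>%
    mutate(dataset = "train", .before = 1)
  if (!is.null(test) && nrow(test) > 0) {
    metrics <- dplyr::bind_rows(
      metrics,
      model_accuracy(model, test, response) %>% mutate(dataset = "test", .before = 1)
    )
  }
  structure(list(candidates = cand, selected = sel, model = model,
                 metrics = metrics),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$candidates[x$selected, ]
  cat(sprintf("<cv_result> %d candidates; selected: %d trees, depth %d, shrinkage %.3f, subsample %.2f (CV RMSE %.4g)\n",
              nrow(x$candidates), s$n_trees, s$depth, s$shrinkage,
              s$subsample, s$mean_cv_rmse))
  print(x$metrics)
  invisible(x)
}
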