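#' Shapley-value feature attribution for a fitted ensemble
#'
#' Interventional Shapley values: the value of a coalition `S` at point `x`
#' is the mean model prediction with the features in `S` fixed to `x` and
#' the rest drawn from the background rows. With `d <= 12` features all
#' `2^d` coalitions are enumerated, so local accuracy
#' (`base + sum_j phi_j = prediction`) holds to numerical precision; larger
#' feature sets fall back to seeded permutation sampling with `K`
#' permutations.
#'
#' @param model a fitted model with a `predict` method and a `predictors`
#'   field (e.g. `defauna_gbm`).
#' @param data tibble of observations to explain.
#' @param background background tibble (defaults to `data`); a seeded
#'   subsample of at most `max_background` rows is used.
#' @param method `"auto"` (exact up to 12 features), `"exact"`, or
#'   `"sampling"`.
#' @param K permutations for the sampling method.
#' @param max_background background rows retained (default 100).
#' @param seed RNG seed (background subsample, permutations).
#' @return a `shap_explanation`: `values` (long tibble row/feature/phi/x),
#'   `base`, per-feature `importance` (mean |phi|) and `sign_trend`
#'   (correlation of phi with the feature value).
#' @export
shap_values <- function(model, data, background = data,
                        method = c("auto", "exact", "sampling"), K = 200,
                        max_background = 100, seed = 1) {
  method <- match.arg(method)
  feats <- model$predictors
  d <- length(feats)
  if (method == "auto") method <- if (d <= 12) "exact" else "sampling"
  if (method == "exact" && d > 12) abort("exact enumeration supported for d <= 12")
  if (nrow(background) == 0) abort("empty background")
  X <- as.matrix(data[, feats, drop = FALSE])
  B <- as.matrix(background[, feats, drop = FALSE])
  if (nrow(B) > max_background) {
    B <- B[with_seed(seed, sample(nrow(B), max_background)), , drop = FALSE]
  }
  n <- nrow(X); nb <- nrow(B)
  pred_mat <- function(m) { # predict on a plain feature matrix
    df <- as.data.frame(m)
    colnames(df) <- feats
    predict(model, df)
  }
  phi <- matrix(0, n, d, dimnames = list(NULL, feats))

  if (method == "exact") {
    nS <- bitwShiftL(1L, d)
    v <- matrix(0, n, nS)
    # hybrid rows: background block repeated per observation
    bigB <- B[rep(seq_len(nb), times = n), , drop = FALSE]
    obs_of <- rep(seq_len(n), each = nb)
    for (S in 0:(nS - 1L)) {
      inS <- which(bitwAnd(bitwShiftL(1L, 0:(d - 1L)), S) != 0L)
      H <- bigB
      if (length(inS)) H[, inS] <- X[obs_of, inS, drop = FALSE]
      p <- pred_mat(H)
      v[, S + 1L] <- as.vector(tapply(p, obs_of, mean))
    }
    wts <- factorial(0:(d - 1)) * factorial(d - 1 - 0:(d - 1)) / factorial(d)
    for (j in seq_len(d)) {
      bit <- bitwShiftL(1L, j - 1L)
      for (S in 0:(nS - 1L)) {
        if (bitwAnd(S, bit) != 0L) next
        s_size <- sum(bitwAnd(bitwShiftL(1L, 0:(d - 1L)), S) != 0L)
        phi[, j] <- phi[, j] + wts[s_size + 1L] *
          (v[, S + bit + 1L] - v[, S + 1L])
      }
    }
    base <- v[1, 1]
  } else {
    base <- mean(pred_mat(B))
    with_seed(seed + 1L, {
      for (k in seq_len(K)) {
        perm <- sample(d)
        b <- B[sample(nb, 1), , drop = FALSE]
        H <- b[rep(1, n), , drop = FALSE]
        prev <- pred_mat(H)
        for (j in perm) {
          H[, j] <- X[, j]
          cur <- pred_mat(H)
          phi[, j] <- phi[, j] + (cur - prev) / K
          prev <- cur
        }
      }
    })
  }

  values <- tibble(
    row = rep(seq_len(n), times = d),
    feature = rep(feats, each = n),
    phi = as.vector(phi),
    x = as.vector(X)
  )
  importance <- values %>%
    group_by(.data$feature) %>%
    summarise(mean_abs_phi = mean(abs(.data$phi)), .groups = "drop") %>%
    arrange(dplyr::desc(.data$mean_abs_phi))
  sign_trend <- values %>%
    group_by(.data$feature) %>%
    summarise(sign_trend = {
      s1 <- sd(.data$phi); s2 <- sd(.data$x)
      if (!is.na(s1) && !is.na(s2) && s1 > 1e-300 && s2 > 1e-300) {
        cor(.data$phi, .data$x)
      } else 0
    }, .groups = "drop")
  structure(list(values = values, base = base, importance = importance,
                 sign_trend = sign_trend, method = method),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> %s method, base value %.4g\n",
              x$method, x$base))
  print(left_join(x$importance, x$sign_trend, by = "feature"))
  invisible(x)
}

#' Beeswarm-style summary plot of Shapley values
#'
#' @param object a `shap_explanation`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.shap_explanation <- function(object, ...) {
  ord <- object$importance$feature
  df <- object$values %>%
    group_by(.data$feature) %>%
    mutate(x_scaled = if (diff(range(.data$x)) > 0) {
      (.data$x - min(.data$x)) / diff(range(.data$x))
    } else 0.5) %>%
    ungroup() %>%
    mutate(feature = factor(.data$feature, levels = rev(ord)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$feature,
                                   colour = .data$x_scaled)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.7) +
    ggplot2::scale_colour_gradient(low = "#3b4cc0", high = "#b40426",
                                   name = "feature value\n(scaled)") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Shapley value (contribution to defaunation)",
                  y = NULL)
}
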