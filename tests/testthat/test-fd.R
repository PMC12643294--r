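toy_traits <- function() {
  tibble::tibble(
    species_id = c("s1", "s2", "s3", "s4"),
    body_mass_g = c(300, 3000, 30000, 300000),
    guild_omnivore = c(1L, 0L, 1L, 0L),
    guild_frugivore = c(0L, 1L, 0L, 1L),
    loco_terrestrial = c(1L, 1L, 0L, 0L),
    loco_arboreal = c(0L, 0L, 1L, 1L)
  )
}

test_that("Gower distances follow the equal-weight mixed-type definition", {
  tr <- toy_traits()
  d <- gower_matrix(tr)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # identical trait rows are at distance zero
  tr2 <- tr
  tr2[2, -1] <- tr2[1, -1]
  expect_equal(gower_matrix(tr2)["s1", "s2"], 0)
  # two species differing only in mass at the pool extremes: the mass part
  # is 1, averaged over 5 usable traits here
  tr3 <- tr
  tr3[4, 3:6] <- tr3[1, 3:6]
  d3 <- gower_matrix(tr3)
  expect_equal(d3["s1", "s4"], 1 / 5)
  # constant continuous traits are excluded with a warning
  trc <- tr
  trc$body_mass_g <- 1000
  expect_warning(gower_matrix(trc), "constant")
})

test_that("Gower distances agree with the cluster::daisy oracle", {
  skip_if_not_installed("cluster")
  w <- get_small_world()
  tr <- w$traits
  d_pkg <- gower_matrix(tr)
  df <- as.data.frame(tr[, -1])
  df$body_mass_g <- log10(df$body_mass_g)
  d_ref <- as.matrix(suppressWarnings(cluster::daisy(df, metric = "gower")))
  expect_equal(unname(d_pkg), unname(d_ref), tolerance = 1e-10)
})

test_that("Gower matrices satisfy metric axioms on random tables", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    tr <- tibble::tibble(
      species_id = paste0("x", 1:n),
      body_mass_g = 10^runif(n, 2.5, 5.5),
      guild_a = sample(0:1, n, TRUE), guild_b = sample(0:1, n, TRUE),
      loco_a = sample(0:1, n, TRUE)
    )
    d <- suppressWarnings(gower_matrix(tr))
    expect_equal(d, t(d))
    expect_equal(diag(d), rep(0, n), ignore_attr = TRUE)
    trip <- t(utils::combn(n, 3))
    for (i in seq_len(nrow(trip))) {
      a <- trip[i, 1]; b <- trip[i, 2]; c_ <- trip[i, 3]
      expect_lte(d[a, c_], d[a, b] + d[b, c_] + 1e-12)
    }
  }
})

test_that("PCoA reproduces hand-computable eigensystems", {
  # three equidistant points at distance 1: eigenvalues {0.5, 0.5, 0}
  d3 <- matrix(1, 3, 3) - diag(3)
  p3 <- trait_pcoa(d3)
  expect_equal(sort(p3$eigenvalues, decreasing = TRUE)[1:2], c(0.5, 0.5),
               tolerance = 1e-10)
  expect_lt(abs(p3$eigenvalues[3]), 1e-10)
  expect_identical(p3$correction, "none")

  # points already Euclidean in 2-D: distances reproduced exactly
  set.seed(8)
  pts <- cbind(rnorm(6), rnorm(6))
  d2 <- as.matrix(dist(pts))
  p2 <- trait_pcoa(d2)
  expect_equal(ncol(p2$coordinates), 2)
  expect_equal(as.matrix(dist(p2$coordinates)), d2, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(p2$r2[2], 1, tolerance = 1e-9)

  # identical points: all eigenvalues zero, no coordinates
  p0 <- trait_pcoa(matrix(0, 4, 4))
  expect_true(all(abs(p0$eigenvalues) < 1e-12))
  expect_equal(ncol(p0$coordinates), 0)

  expect_error(trait_pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA agrees with the ape::pcoa oracle on Gower distances", {
  skip_if_not_installed("ape")
  w <- get_small_world()
  d <- gower_matrix(w$traits)
  ours <- trait_pcoa(d)
  if (ours$correction == "none") {
    ref <- ape::pcoa(stats::as.dist(d))
    npos <- ncol(ours$coordinates)
    expect_equal(ours$eigenvalues[1:npos], ref$values$Eigenvalues[1:npos],
                 tolerance = 1e-6)
  } else {
    ref <- ape::pcoa(stats::as.dist(d), correction = "cailliez")
    k <- min(4, ncol(ours$coordinates))
    # corrected configurations must induce the same embedded distances
    d_ours <- dist(ours$coordinates[, 1:k])
    d_ref <- dist(ref$vectors.cor[, 1:k])
    expect_equal(as.vector(d_ours), as.vector(d_ref), tolerance = 1e-6)
  }
})

test_that("axis selection tracks embedding quality", {
  set.seed(8)
  pts <- cbind(rnorm(6), rnorm(6))
  p2 <- trait_pcoa(as.matrix(dist(pts)))
  m <- select_axes(p2, 0.75)
  expect_lte(as.integer(m), 2)
  expect_gt(p2$r2[m], 0.75)
  expect_equal(as.integer(select_axes(p2, 0)), 1)
  expect_true(attr(select_axes(p2, 0.5), "threshold_reached"))
  expect_warning(m99 <- select_axes(p2, 1), "unreachable")
})

test_that("functional richness uses exact hull volumes standardized by the pool", {
  sq <- rbind(s1 = c(0, 0), s2 = c(1, 0), s3 = c(1, 1), s4 = c(0, 1))
  pc <- structure(list(coordinates = sq, eigenvalues = c(1, 1),
                       correction = "none", r2 = c(0.8, 1)),
                  class = "pcoa_result")
  full <- fric(rownames(sq), pc, 2)
  expect_equal(full$fric_raw, 1)
  expect_equal(full$fric_std, 1)
  three <- fric(c("s1", "s2", "s3"), pc, 2)
  expect_equal(three$fric_raw, 0.5)
  expect_equal(three$fric_std, 0.5)
  # 5-point standard simplex in 4 axes: volume 1/4! = 1/24
  simp <- rbind(o = rep(0, 4), a = c(1, 0, 0, 0), b = c(0, 1, 0, 0),
                c = c(0, 0, 1, 0), d = c(0, 0, 0, 1))
  pcs <- structure(list(coordinates = simp, eigenvalues = rep(1, 4),
                        correction = "none", r2 = rep(1, 4)),
                   class = "pcoa_result")
  expect_equal(fric(rownames(simp), pcs, 4)$fric_raw, 1 / 24, tolerance = 1e-12)
  # species-poor community drops to richness - 1 axes with a flag
  poor <- fric(c("o", "a", "b"), pcs, 4)
  expect_identical(poor$flag, "reduced_dim")
  expect_equal(poor$m_used, 2L)
  single <- fric("o", pcs, 4)
  expect_identical(single$flag, "degenerate")
  expect_equal(single$fric_raw, 0)
  expect_error(fric(rownames(simp), pcs, 5), "m <= 4")
})

test_that("FRic is monotone under species addition and bounded by the pool", {
  w <- get_small_world()
  d <- gower_matrix(w$traits)
  pc <- trait_pcoa(d)
  m <- min(4, ncol(pc$coordinates))
  ids <- rownames(pc$coordinates)
  set.seed(14)
  for (rep in 1:5) {
    comm <- sample(ids, 6)
    f1 <- fric(comm, pc, m)
    f2 <- fric(c(comm, sample(setdiff(ids, comm), 1)), pc, m)
    expect_gte(f2$fric_raw, f1$fric_raw - 1e-12)
    expect_gte(f1$fric_std, 0)
    expect_lte(f1$fric_std, 1 + 1e-12)
  }
  expect_equal(fric(ids, pc, m)$fric_std, 1, tolerance = 1e-10)
})

test_that("FD loss responds to hull vertices, not interior species", {
  sq <- rbind(s1 = c(0, 0), s2 = c(1, 0), s3 = c(1, 1), s4 = c(0, 1),
              mid = c(0.5, 0.5))
  pc <- structure(list(coordinates = sq, eigenvalues = c(1, 1),
                       correction = "none", r2 = c(0.8, 1)),
                  class = "pcoa_result")
  all_sp <- rownames(sq)
  expect_equal(fd_loss(all_sp, all_sp, pc, 2)$fd_loss, 0)
  expect_gt(fd_loss(all_sp, setdiff(all_sp, "s3"), pc, 2)$fd_loss, 0)
  expect_equal(fd_loss(all_sp, setdiff(all_sp, "mid"), pc, 2)$fd_loss, 0)
})

test_that("the Gaussian GLM on FD loss is ordinary least squares", {
  d <- tibble::tibble(x = 0:4, y = c(1, 3, 5, 7, 9))
  fit <- glm_fd(d, "y", "x")
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_lt(fit$diagnostics$residual_ss, 1e-20)
  # collinear design rejected with the column named
  d2 <- tibble::tibble(y = rnorm(10), a = 1:10, b = 2 * (1:10))
  expect_error(glm_fd(d2, "y", c("a", "b")), "collinear")
  # a pure-noise predictor stays non-significant under the null
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    dd <- tibble::tibble(x = rnorm(40), noise = rnorm(40))
    dd$y <- 2 * dd$x + rnorm(40, sd = 0.5)
    f <- glm_fd(dd, "y", c("x", "noise"))
    f$coefficients$p_value[f$coefficients$term == "noise"] > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
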