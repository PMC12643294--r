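test_that("defaunation surface subtracts rasters with a percent-loss guard", {
  h <- mk_raster(matrix(c(5, 0, 4, 4), 2, 2))
  c_ <- mk_raster(matrix(c(2, 1, 4, 5), 2, 2))
  d <- defaunation_raster(h, c_)
  expect_equal(d$D$values[1, 1], 3)
  expect_equal(d$percent$values[1, 1], 60)
  expect_equal(d$D$values[2, 1], -1)            # local gain preserved
  expect_true(is.na(d$percent$values[2, 1]))    # hist = 0: percent undefined
  expect_equal(d$D$values[1, 2], 0)
  same <- defaunation_raster(h, h)
  expect_true(all(same$D$values == 0))
  expect_error(defaunation_raster(h, mk_raster(matrix(0, 3, 3))), "aligned")
})

test_that("hexcell records take zonal means and drop incomplete rows", {
  reg <- region_rectangle(0, 0, 12, 12)
  hg <- build_hexgrid(reg, edge_km = 2)
  D <- mk_raster(matrix(3, 12, 12))
  cov1 <- mk_raster(matrix(1, 12, 12))
  rec <- defaunation_by_hexcell(D, hg, list(hfp = cov1))
  expect_true(all(rec$defaunation == 3))
  expect_true(all(rec$hfp == 1))
  # checkerboard averages to the midpoint wherever both colors are covered
  cb <- mk_raster(outer(1:12, 1:12, function(i, j) ifelse((i + j) %% 2 == 0, 0, 6)))
  reccb <- defaunation_by_hexcell(cb, hg, list(hfp = cov1))
  big <- reccb[reccb$cell_id %in% rec$cell_id, ]
  inner <- zonal_stat(mk_raster(matrix(1, 12, 12)), hg, "sum")
  full <- inner$cell_id[!is.na(inner$value) & inner$value >= 8]
  expect_true(all(abs(reccb$defaunation[reccb$cell_id %in% full] - 3) <= 1))
  # an all-missing covariate drops every record
  covna <- mk_raster(matrix(NA_real_, 12, 12))
  recna <- defaunation_by_hexcell(D, hg, list(hfp = covna))
  expect_equal(nrow(recna), 0)
})

test_that("loss bands partition the valid cells", {
  pct <- mk_raster(matrix(c(10, 30, 55, 60), 2, 2))
  bands <- loss_band_summary(pct)
  expect_equal(bands$fraction[bands$band == "loss_over_50"], 0.5)
  expect_equal(bands$fraction[bands$band == "loss_20_50"], 0.25)
  expect_equal(sum(bands$fraction), 1)
  zero <- loss_band_summary(mk_raster(matrix(0, 3, 3)))
  expect_equal(zero$fraction[zero$band == "loss_0_20"], 1)
  # random percent rasters always partition to 1
  set.seed(2)
  rnd <- mk_raster(matrix(runif(100, -30, 130), 10, 10))
  expect_equal(sum(loss_band_summary(rnd)$fraction), 1)
  overlap <- tibble::tibble(band = c("a", "b"), lo = c(0, 10), hi = c(20, 30),
                            lo_open = FALSE, hi_open = FALSE)
  expect_error(loss_band_summary(rnd, overlap), "overlap")
})

test_that("species range loss counts assemblages and extrapolates area", {
  # binary map: presence on the left half (columns 1-5) = 50 cells
  bm <- mk_raster(matrix(rep(c(1, 0), each = 50), 10, 10)) # column-major fill
  # ten assemblages inside the predicted half, one outside it
  asm <- tibble::tibble(
    site_id = sprintf("s%02d", 1:11),
    x = c(rep(2.5, 10), 7.5),
    y = c(seq(0.5, 9.5, 1), 5.5),
    protection = "none",
    spA = c(1L, 1L, rep(0L, 8), 1L)
  )
  rl <- species_range_loss(list(spA = bm), asm)
  expect_equal(rl$n_assemblages_predicted, 10)
  expect_equal(rl$n_assemblages_occupied, 2)
  expect_equal(rl$loss_fraction, 0.8)        # 10 predicted, 2 occupied
  expect_equal(rl$historical_area, 50)       # 50 cells x 1 km2
  expect_equal(rl$lost_area, 40)
  expect_equal(rl$commission, 1)             # occupied at an unpredicted site
  # occupied everywhere predicted -> zero loss
  asm2 <- asm
  asm2$spA <- c(rep(1L, 10), 0L)
  expect_equal(species_range_loss(list(spA = bm), asm2)$loss_fraction, 0)
  # never predicted -> not assessable
  bm0 <- mk_raster(matrix(0, 10, 10))
  expect_false(species_range_loss(list(spA = bm0), asm)$assessable)
})

test_that("range loss equals a brute-force recount on a synthetic world", {
  w <- get_small_world()
  maps <- lapply(w$pool, function(p) p$range)
  rl <- species_range_loss(maps, w$assemblages)
  inc <- defauna:::assemblage_incidence(w$assemblages)
  for (i in seq_len(nrow(rl))) {
    sp <- rl$species[i]
    pred <- vapply(seq_len(nrow(w$assemblages)), function(j) {
      loc <- raster_locate(maps[[sp]], w$assemblages$x[j], w$assemblages$y[j])
      maps[[sp]]$values[loc$row, loc$col] > 0
    }, logical(1))
    occ <- inc[, sp] > 0
    if (sum(pred) > 0) {
      expect_equal(rl$loss_fraction[i], 1 - sum(occ & pred) / sum(pred))
    }
  }
})

test_that("downsizing aggregates body mass per site and period", {
  asm <- tibble::tibble(site_id = "s1", x = 1, y = 1, protection = "none",
                        a = 1L, b = 0L, c = 0L)
  hist_inc <- matrix(c(1L, 1L, 1L), 1, 3,
                     dimnames = list("s1", c("a", "b", "c")))
  mass <- c(a = 2, b = 10, c = 300)
  ds <- downsizing(asm, hist_inc, mass)
  s <- ds$sites
  expect_equal(s$aggregate_hist_kg, 312)
  expect_equal(s$aggregate_cont_kg, 2)
  expect_equal(s$mean_mass_hist_kg, 104)
  expect_equal(s$mean_mass_cont_kg, 2)
  expect_equal(s$retained_fraction, 2 / 312)
  expect_equal(s$species_lost, 2)
  # identical compositions: nothing lost
  asm2 <- asm
  asm2$b <- 1L; asm2$c <- 1L
  ds2 <- downsizing(asm2, hist_inc, mass)
  expect_equal(ds2$sites$retained_fraction, 1)
  expect_equal(ds2$sites$species_lost, 0)
  expect_error(downsizing(asm, hist_inc, mass[1:2]), "missing body mass")
  # total loss equals the summed per-site losses (internal consistency)
  expect_equal(ds$summary$total_biomass_loss_kg,
               sum(ds$sites$aggregate_hist_kg - ds$sites$aggregate_cont_kg))
})

test_that("Tukey-Kramer comparison matches its algebraic and simulation oracles", {
  # identical groups: p ~ 1 everywhere
  d0 <- tibble::tibble(v = rep(c(1, 2, 3), 3),
                       g = rep(c("a", "b", "c"), each = 3))
  t0 <- protection_comparison(d0, "v", "g")
  expect_true(all(t0$p > 0.99))
  expect_false(any(t0$significant))

  # two equal-size groups: q = sqrt(2) |t| of the pooled two-sample t
  set.seed(9)
  y1 <- rnorm(8); y2 <- rnorm(8, 1)
  d2 <- tibble::tibble(v = c(y1, y2), g = rep(c("a", "b"), each = 8))
  t2 <- protection_comparison(d2, "v", "g")
  tt <- stats::t.test(y1, y2, var.equal = TRUE)
  expect_equal(t2$q, sqrt(2) * abs(unname(tt$statistic)), tolerance = 1e-10)

  # strongly separated groups reject; permutation oracle agrees
  set.seed(4)
  ya <- rnorm(14); yb <- rnorm(14, 10)
  d3 <- tibble::tibble(v = c(ya, yb), g = rep(c("a", "b"), each = 14))
  t3 <- protection_comparison(d3, "v", "g")
  expect_lt(t3$p, 0.001)
  obs <- abs(mean(ya) - mean(yb))
  pool <- c(ya, yb)
  perm <- replicate(10000, {
    idx <- sample(28, 14)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  expect_lt(mean(perm >= obs), 0.001)

  # unequal-n p-values agree with R's TukeyHSD on the same design
  set.seed(5)
  du <- tibble::tibble(v = c(rnorm(6), rnorm(9, 0.8), rnorm(14, 1.6)),
                       g = rep(c("a", "b", "c"), c(6, 9, 14)))
  tu <- protection_comparison(du, "v", "g")
  hsd <- stats::TukeyHSD(stats::aov(v ~ g, data = du))$g
  expect_equal(tu$p, unname(hsd[, "p adj"]), tolerance = 1e-6)

  expect_error(protection_comparison(d0[d0$g == "a", ], "v", "g"), "two groups")
})
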