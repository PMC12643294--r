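test_that("the virtual world is fully determined by its configuration", {
  cfg <- small_config(seed = 11)
  w1 <- suppressWarnings(simulate_world(cfg))
  w2 <- suppressWarnings(simulate_world(cfg))
  expect_identical(w1$env[["BIO2"]]$values, w2$env[["BIO2"]]$values)
  expect_identical(w1$traits, w2$traits)
  expect_identical(w1$assemblages, w2$assemblages)
  expect_identical(w1$occurrences, w2$occurrences)
})

test_that("environment generator spans both correlated and independent layers", {
  w <- get_small_world()
  vals <- sapply(names(w$env), function(n) as.vector(w$env[[n]]$values))
  cm <- abs(cor(vals))
  diag(cm) <- 0
  expect_true(max(cm) >= 0.8)   # engineered near-duplicate pair
  expect_true(min(cm) < 0.8)    # and genuinely distinct layers
  # infinite correlation length degenerates to constant fields
  ccfg <- world_config(n_rows = 20, n_cols = 20, n_species = 2,
                       corr_length = Inf, seed = 3)
  cenv <- generate_environment(ccfg)
  expect_equal(sd(cenv[[2]]$values), 0)
})

test_that("species pool has valid niches, ranges, masses and one-hot traits", {
  w <- get_small_world()
  tr <- w$traits
  expect_true(all(tr$body_mass_g >= 300 & tr$body_mass_g <= 3e5))
  guild_cols <- grep("^guild_", colnames(tr))
  loco_cols <- grep("^loco_", colnames(tr))
  expect_true(all(rowSums(tr[, guild_cols]) == 1))
  expect_true(all(rowSums(tr[, loco_cols]) == 1))
  for (sp in w$pool) {
    expect_gt(sum(sp$range$values), 0)
    # range is exactly the upper half-maximum suitability set
    expect_identical(sp$range$values,
                     (sp$suitability$values >= 0.5 * max(sp$suitability$values)) + 0)
  }
})

test_that("occurrence sampling follows suitability within the true range", {
  w <- get_small_world()
  sp <- w$pool[[1]]
  expect_equal(nrow(sample_occurrences(sp, 0, seed = 1)), 0)
  occ <- sample_occurrences(sp, 10, seed = 1)
  loc <- raster_locate(sp$range, occ$x, occ$y)
  expect_true(all(sp$range$values[cbind(loc$row, loc$col)] == 1))
  # no duplicates (sampling without replacement)
  expect_equal(anyDuplicated(paste(occ$x, occ$y)), 0)

  # two-cell range with suitability 9:1 -> first draw lands on the likely
  # cell with the binomial frequency
  suit <- matrix(0, 20, 20)
  suit[10, 10] <- 0.9
  suit[10, 11] <- 0.1
  toy <- structure(list(species_id = "toy",
                        suitability = mk_raster(suit),
                        range = mk_raster((suit > 0) + 0)),
                   class = "virtual_species")
  hits <- vapply(1:1000, function(s) {
    sample_occurrences(toy, 1, seed = s)$x[1]
  }, numeric(1))
  frac <- mean(hits == 9.5) # centre x of cell (10, 10)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))
})

test_that("pressure surfaces honour their construction targets", {
  w <- get_default_world()
  pr <- w$pressures$rasters
  for (nm in c("ls", "crop", "past", "hfp")) {
    expect_true(all(pr[[nm]]$values >= 0 & pr[[nm]]$values <= 1))
  }
  expect_true(all(pr$agb$values >= 0))
  # requested corr(ls, hfp) = 0.7 holds on the generated grid
  expect_lt(abs(cor(as.vector(pr$ls$values), as.vector(pr$hfp$values)) -
                  w$config$corr_ls_hfp), 0.1)
  # agb positively tracks the precipitation-like layer
  expect_gt(cor(as.vector(pr$agb$values), as.vector(w$env[["BIO12"]]$values)), 0.5)
  # no reserves requested -> empty pas raster
  cfg0 <- world_config(n_rows = 20, n_cols = 20, n_species = 2, seed = 5,
                       strict_pa_frac = 0, sustainable_pa_frac = 0)
  env0 <- generate_environment(cfg0)
  pr0 <- generate_pressures(cfg0, env0)
  expect_true(all(pr0$rasters$pas$values == 0))
  expect_null(pr0$pa_region)
})

test_that("extirpation process obeys its logistic specification", {
  w <- get_default_world()
  cfg <- w$config
  env <- w$env
  pool <- w$pool
  pressures <- w$pressures
  sites <- w$sites

  # no extirpation: beta0 = -Inf, all other coefficients 0
  cfg0 <- cfg
  cfg0$beta0 <- -Inf
  cfg0$beta_mass <- cfg0$beta_hfp <- cfg0$beta_ls <- cfg0$beta_pa <- 0
  d0 <- apply_defaunation(pool, sites, pressures, cfg0, seed = 1)
  expect_identical(d0$truth$contemporary, d0$truth$historical)

  # total extirpation: every site fails the >= 5 richness rule
  cfg1 <- cfg0
  cfg1$beta0 <- Inf
  expect_error(apply_defaunation(pool, sites, pressures, cfg1, seed = 1),
               "weaken")

  # uniform P = 0.3: realized fraction concentrates at 0.3
  cfg3 <- cfg0
  cfg3$beta0 <- log(0.3 / 0.7)
  d3 <- apply_defaunation(pool, sites, pressures, cfg3, seed = 2)
  n_trials <- sum(d3$truth$historical)
  frac <- sum(d3$truth$extirpated * d3$truth$historical) / n_trials
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n_trials))
})

test_that("defaunation truth shows the built-in mass and protection biases", {
  w <- get_default_world()
  tr <- w$truth
  masses <- log10(w$traits$body_mass_g)
  hist_mat <- tr$historical
  surv_mat <- tr$contemporary
  mean_mass <- function(m) {
    rs <- rowSums(m)
    (m %*% masses)[rs > 0] / rs[rs > 0]
  }
  # survivors are lighter than the historical pool, paired over sites
  expect_lt(mean(mean_mass(surv_mat)), mean(mean_mass(hist_mat)))
  # strict protection retains more richness than unprotected sites
  sd_ <- tr$site_drivers
  ret <- sd_$contemporary_richness / pmax(sd_$historical_richness, 1)
  expect_gt(mean(ret[sd_$protection == "strict"]),
            mean(ret[sd_$protection == "none"]))
})
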