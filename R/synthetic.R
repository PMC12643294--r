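#' Virtual-world configuration
#'
#' Parameters of the synthetic study system: a gridded region with smooth
#' correlated environmental fields, a pool of virtual species with Gaussian
#' niches and log-spread body masses, scattered sample sites, human-pressure
#' surfaces, and a logistic extirpation process biased by body mass, human
#' pressure and protection. Defaults emulate the structure of the real study
#' system: a 100 x 100 km region, 51 species, 73 assemblage sites.
#'
#' The extirpation model for species `s` historically present at site `j` is
#' `P(extirpated) = plogis(beta0 + beta_mass*log10(mass_g) + beta_hfp*hfp_j +
#' beta_ls*ls_j - beta_pa*[j in strict PA])`.
#'
#' @param n_rows,n_cols grid dimensions (>= 20 each).
#' @param cell_size_km cell side length in km.
#' @param n_env_layers number of bioclim-style layers (elevation is added on
#'   top of these).
#' @param n_species,n_sites pool and assemblage sizes.
#' @param seed integer; fixes every random choice in the world.
#' @param corr_length spatial correlation length of the smooth fields, in
#'   cells (`Inf` gives constant layers).
#' @param n_occurrences occurrence records sampled per species.
#' @param beta0,beta_mass,beta_hfp,beta_ls,beta_pa extirpation coefficients
#'   (`beta_mass` per log10 gram; `hfp`/`ls` enter on their 0-1 scale).
#' @param corr_ls_hfp target correlation between the livestock and human
#'   footprint surfaces.
#' @param strict_pa_frac,sustainable_pa_frac approximate area fractions
#'   covered by strict / sustainable-use protected areas.
#' @return a `world_config` list.
#' @export
world_config <- function(n_rows = 100, n_cols = 100, cell_size_km = 1,
                         n_env_layers = 10, n_species = 51, n_sites = 73,
                         seed = 42, corr_length = 25, n_occurrences = 120,
                         beta0 = -4.8, beta_mass = 0.5, beta_hfp = 2.5,
                         beta_ls = 2.5, beta_pa = 2.5, corr_ls_hfp = 0.7,
                         strict_pa_frac = 0.18, sustainable_pa_frac = 0.12) {
  if (n_rows < 20 || n_cols < 20) abort("grid must be at least 20 x 20")
  if (n_species < 2) abort("need at least 2 species")
  cfg <- list(n_rows = n_rows, n_cols = n_cols, cell_size_km = cell_size_km,
              n_env_layers = n_env_layers, n_species = n_species,
              n_sites = n_sites, seed = as.integer(seed),
              corr_length = corr_length, n_occurrences = n_occurrences,
              beta0 = beta0, beta_mass = beta_mass, beta_hfp = beta_hfp,
              beta_ls = beta_ls, beta_pa = beta_pa,
              corr_ls_hfp = corr_ls_hfp,
              strict_pa_frac = strict_pa_frac,
              sustainable_pa_frac = sustainable_pa_frac)
  class(cfg) <- "world_config"
  cfg
}

# run code under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# smooth random field: sum of low-frequency sinusoids + a little white noise
smooth_field <- function(n_rows, n_cols, corr_length, noise_sd = 0.02) {
  if (is.infinite(corr_length)) {
    return(matrix(runif(1), n_rows, n_cols))
  }
  xs <- matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols)
  ys <- matrix(rep(seq_len(n_rows), times = n_cols), n_rows, n_cols)
  f <- matrix(0, n_rows, n_cols)
  for (k in 1:8) {
    wl <- runif(1, corr_length, 4 * corr_length)
    th <- runif(1, 0, 2 * pi)
    ph <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.5, 1)
    f <- f + amp * sin(2 * pi * (cos(th) * xs + sin(th) * ys) / wl + ph)
  }
  f + rnorm(n_rows * n_cols, sd = noise_sd * max(sd(f), 1e-12))
}

rescale01 <- function(m, lo = 0, hi = 1) {
  rng <- range(m)
  if (diff(rng) < 1e-300) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - rng[1]) / diff(rng) * (hi - lo)
}

standardize_field <- function(m) {
  s <- sd(m)
  if (s < 1e-300) return(m * 0)
  (m - mean(m)) / s
}

bioclim_ranges <- function(names) {
  # plausible value ranges per variable family (temperature-, seasonality-,
  # precipitation-like); anything unknown gets [0, 100]
  lookup <- list(
    BIO1 = c(15, 30), BIO2 = c(5, 16), BIO4 = c(100, 600), BIO8 = c(15, 30),
    BIO9 = c(15, 32), BIO12 = c(200, 1200), BIO15 = c(20, 110),
    BIO17 = c(0, 120), BIO18 = c(10, 400), BIO19 = c(10, 350),
    elevation = c(0, 1200)
  )
  lapply(names, function(nm) if (nm %in% names(lookup)) lookup[[nm]] else c(0, 100))
}

#' Generate the synthetic environmental stack
#'
#' Produces `n_env_layers` smooth bioclim-style fields plus elevation, named
#' from the `BIO*` vocabulary and rescaled to plausible value ranges. The
#' first layer is built as a near-copy of the second so the stack always
#' contains at least one pair with |r| >= 0.8, giving the correlation
#' pre-screen genuine work.
#'
#' @param config a [world_config()].
#' @return an [env_stack()].
#' @export
generate_environment <- function(config) {
  nm <- c("BIO1", "BIO2", "BIO4", "BIO8", "BIO9", "BIO12", "BIO15", "BIO17",
          "BIO18", "BIO19")
  if (config$n_env_layers > length(nm)) {
    nm <- c(nm, paste0("BIO", seq(20, 19 + config$n_env_layers - length(nm))))
  }
  nm <- c(nm[seq_len(config$n_env_layers)], "elevation")
  rngs <- bioclim_ranges(nm)
  with_seed(config$seed + 1L, {
    fields <- lapply(seq_along(nm), function(i) {
      smooth_field(config$n_rows, config$n_cols, config$corr_length)
    })
    # engineered collinear pair: layer 1 duplicates layer 2 up to tiny noise
    if (length(fields) >= 2 && !is.infinite(config$corr_length)) {
      fields[[1]] <- standardize_field(fields[[2]]) +
        rnorm(config$n_rows * config$n_cols, sd = 0.05)
    }
    layers <- lapply(seq_along(nm), function(i) {
      raster_grid(rescale01(fields[[i]], rngs[[i]][1], rngs[[i]][2]),
                  origin_x = 0, origin_y = config$n_rows * config$cell_size_km,
                  cell_size = config$cell_size_km)
    })
    names(layers) <- nm
    env_stack(layers)
  })
}

#' Generate the virtual species pool
#'
#' Each species responds to 2-3 randomly chosen layers with Gaussian niches:
#' `suitability(cell) = prod_k exp(-(x_k - mu_k)^2 / (2 sigma_k^2))`, with the
#' optimum drawn from a random cell's conditions and the breadth a fraction of
#' the layer's spatial standard deviation. The true historical range is the
#' set of cells with suitability >= 0.5 * max. Body mass is log-uniform on
#' 300 g - 300 kg; one feeding guild (of 9) and one locomotion mode (of 5)
#' are assigned per species.
#'
#' @param config a [world_config()].
#' @param env the [generate_environment()] output.
#' @param max_retries redraw budget for species whose range comes up empty.
#' @return a `species_pool` (list of `virtual_species`).
#' @export
generate_species_pool <- function(config, env, max_retries = 25) {
  guilds <- c("hypercarnivore", "insectivore", "myrmecophague", "omnivore",
              "piscivore", "frugivore", "folivore", "gummivore", "granivore")
  locos <- c("terrestrial", "semi_fossorial", "scansorial", "semi_aquatic",
             "arboreal")
  layer_names <- names(env)
  with_seed(config$seed + 2L, {
    pool <- vector("list", config$n_species)
    for (s in seq_len(config$n_species)) {
      sp <- NULL
      for (try in seq_len(max_retries)) {
        k <- sample(2:3, 1)
        lyrs <- sample(layer_names, k)
        niche <- lapply(lyrs, function(ln) {
          v <- env[[ln]]$values
          # optima drawn from a random cell's conditions but shrunk toward
          # the regional median: overlapping ranges create the richness
          # gradient (mid-domain hotspots) that real assemblages show
          mu <- 0.65 * v[sample(length(v), 1)] +
            0.35 * stats::median(as.vector(v))
          list(layer = ln, mu = mu,
               sigma = runif(1, 0.5, 1.0) * sd(as.vector(v)))
        })
        suit <- matrix(1, config$n_rows, config$n_cols)
        for (nch in niche) {
          x <- env[[nch$layer]]$values
          suit <- suit * exp(-(x - nch$mu)^2 / (2 * nch$sigma^2))
        }
        rng <- suit >= 0.5 * max(suit)
        if (any(rng)) {
          tmpl <- env[[1]]
          sp <- structure(list(
            species_id = sprintf("sp%02d", s),
            niche = dplyr::bind_rows(lapply(niche, as_tibble)),
            body_mass_g = 10^runif(1, log10(300), log10(3e5)),
            guild = sample(guilds, 1),
            locomotion = sample(locos, 1),
            suitability = raster_grid(suit, tmpl$origin_x, tmpl$origin_y,
                                      tmpl$cell_size, crs_label = tmpl$crs_label),
            range = raster_grid(rng + 0, tmpl$origin_x, tmpl$origin_y,
                                tmpl$cell_size, crs_label = tmpl$crs_label)
          ), class = "virtual_species")
          break
        }
      }
      if (is.null(sp)) abort(sprintf("species %d: empty range after %d redraws", s, max_retries))
      pool[[s]] <- sp
    }
    names(pool) <- vapply(pool, function(p) p$species_id, character(1))
    class(pool) <- "species_pool"
    pool
  })
}

#' Trait table of a species pool
#'
#' @param pool a `species_pool`.
#' @return tibble: `species_id`, `body_mass_g`, nine binary `guild_*` columns
#'   and five binary `loco_*` columns.
#' @export
traits_table <- function(pool) {
  guilds <- c("hypercarnivore", "insectivore", "myrmecophague", "omnivore",
              "piscivore", "frugivore", "folivore", "gummivore", "granivore")
  locos <- c("terrestrial", "semi_fossorial", "scansorial", "semi_aquatic",
             "arboreal")
  out <- tibble(
    species_id = vapply(pool, function(p) p$species_id, character(1)),
    body_mass_g = vapply(pool, function(p) p$body_mass_g, numeric(1))
  )
  for (g in guilds) {
    out[[paste0("guild_", g)]] <-
      as.integer(vapply(pool, function(p) p$guild == g, logical(1)))
  }
  for (l in locos) {
    out[[paste0("loco_", l)]] <-
      as.integer(vapply(pool, function(p) p$locomotion == l, logical(1)))
  }
  out
}

#' Sample occurrence records for one species
#'
#' Cell centers inside the species' true range, drawn without replacement
#' with probability proportional to suitability; if more points are requested
#' than the range holds, every range cell is returned with a warning.
#'
#' @param species a `virtual_species`.
#' @param n_points number of records.
#' @param seed RNG seed.
#' @return tibble: `species`, `x`, `y`.
#' @export
sample_occurrences <- function(species, n_points, seed) {
  cells <- raster_cells(species$suitability)
  rng <- as.vector(t(species$range$values)) > 0
  cand <- cells[rng, ]
  if (nrow(cand) == 0) abort("species has an empty range")
  if (n_points == 0) {
    return(tibble(species = character(), x = numeric(), y = numeric()))
  }
  if (n_points > nrow(cand)) {
    warn(sprintf("%s: requested %d points but range holds %d cells; returning all",
                 species$species_id, n_points, nrow(cand)))
    n_points <- nrow(cand)
  }
  with_seed(seed, {
    idx <- sample(nrow(cand), n_points, replace = FALSE, prob = cand$value)
    tibble(species = species$species_id, x = cand$x[idx], y = cand$y[idx])
  })
}

#' Generate human-pressure surfaces and protected areas
#'
#' Produces correlated smooth driver fields on the environment's grid:
#' `ls` (livestock), `crop` and `past` (cropland/pasture proportions) in
#' `[0, 1]`; `hfp`, a normalized human-footprint index constructed to have
#' sample correlation `corr_ls_hfp` with `ls`; `agb`, aboveground woody
#' biomass (Mg/ha) positively correlated with the precipitation-like layer;
#' and `pas`, the protected area (km2) per cell rasterized from randomly
#' placed rectangular reserves tagged strict or sustainable.
#'
#' @param config a [world_config()].
#' @param env the environmental stack (defines the grid).
#' @return list with `rasters` (named list ls, crop, past, hfp, agb, pas),
#'   `pa_region` (a [vector_region()] of reserves, or NULL when no reserves
#'   were requested) and `pa_table` (tibble of reserve footprints).
#' @export
generate_pressures <- function(config, env) {
  tmpl <- env[[1]]
  nr <- config$n_rows; nc <- config$n_cols
  mk <- function(m) raster_grid(m, tmpl$origin_x, tmpl$origin_y,
                                tmpl$cell_size, crs_label = tmpl$crs_label)
  with_seed(config$seed + 3L, {
    latent <- standardize_field(smooth_field(nr, nc, config$corr_length))
    mix <- function() rescale01(0.75 * latent +
                                0.66 * standardize_field(smooth_field(nr, nc, config$corr_length)))
    ls <- mix(); crop <- mix(); past <- mix()
    # hfp: exact in-sample correlation with ls via orthogonalized noise
    zls <- standardize_field(ls)
    znoise <- standardize_field(smooth_field(nr, nc, config$corr_length))
    znoise <- standardize_field(znoise - mean(znoise * zls) /
                                  mean(zls * zls) * zls)
    rho <- config$corr_ls_hfp
    hfp <- rescale01(rho * zls + sqrt(max(0, 1 - rho^2)) * znoise)
    # agb tracks the wettest conditions
    wet <- if ("BIO12" %in% names(env)) env[["BIO12"]]$values else env[[1]]$values
    zw <- standardize_field(wet)
    za <- standardize_field(smooth_field(nr, nc, config$corr_length))
    za <- standardize_field(za - mean(za * zw) / max(mean(zw * zw), 1e-12) * zw)
    agb <- rescale01(0.7 * zw + 0.3 * za, 0, 300)

    # protected areas: random rectangles until the target area is reached
    w_km <- nc * config$cell_size_km
    h_km <- nr * config$cell_size_km
    total <- w_km * h_km
    draw_pas <- function(frac, tag) {
      polys <- list(); area <- 0; i <- 0
      while (area < frac * total && i < 100) {
        i <- i + 1
        wd <- runif(1, 0.08, 0.2) * w_km
        ht <- runif(1, 0.08, 0.2) * h_km
        x0 <- runif(1, 0, w_km - wd)
        y0 <- runif(1, 0, h_km - ht)
        polys[[i]] <- list(
          id = sprintf("%s_%02d", tag, i),
          coords = rbind(c(x0, y0), c(x0 + wd, y0), c(x0 + wd, y0 + ht),
                         c(x0, y0 + ht), c(x0, y0)),
          attributes = list(protection = tag)
        )
        area <- area + wd * ht
      }
      polys
    }
    polys <- c(draw_pas(config$strict_pa_frac, "strict"),
               draw_pas(config$sustainable_pa_frac, "sustainable"))
    pa_region <- if (length(polys)) vector_region(polys, tmpl$crs_label) else NULL
    pas <- matrix(0, nr, nc)
    if (!is.null(pa_region)) {
      cells <- raster_cells(tmpl)
      inside <- points_in_region(pa_region, cells$x, cells$y)
      pas <- matrix(0, nr, nc)
      pas[cbind(cells$row[inside], cells$col[inside])] <- config$cell_size_km^2
    }
    pa_table <- if (is.null(pa_region)) {
      tibble(id = character(), protection = character())
    } else {
      tibble(
        id = vapply(pa_region$polygons, function(p) p$id, character(1)),
        protection = vapply(pa_region$polygons,
                            function(p) p$attributes$protection, character(1))
      )
    }
    list(rasters = list(ls = mk(ls), crop = mk(crop), past = mk(past),
                        hfp = mk(hfp), agb = mk(agb), pas = mk(pas)),
         pa_region = pa_region, pa_table = pa_table)
  })
}

#' Place assemblage sites
#'
#' Stratified placement with a richness bias: the region is cut into roughly
#' equal blocks, sites are spread round-robin across blocks (so interpolation
#' has spatial coverage everywhere), and within a block each site takes the
#' faunally richest of a handful of candidate cells. The bias emulates how
#' assemblage compilations favor well-surveyed, faunally rich localities; a
#' purely random cell is used when no richness surface is supplied.
#'
#' @param config a [world_config()].
#' @param template a `raster_grid` defining the grid.
#' @param richness optional true species-richness matrix used for the
#'   within-block bias.
#' @param n_candidates candidate cells drawn per site when biasing.
#' @return tibble: `site_id`, `x`, `y`, `row`, `col`.
#' @export
place_sites <- function(config, template, richness = NULL, n_candidates = 6) {
  nb <- ceiling(sqrt(config$n_sites))
  with_seed(config$seed + 4L, {
    blocks <- expand.grid(bi = seq_len(nb), bj = seq_len(nb))
    blocks <- blocks[sample(nrow(blocks)), ]
    rows_per <- config$n_rows / nb
    cols_per <- config$n_cols / nb
    picks <- matrix(0L, config$n_sites, 2)
    taken <- character(0)
    for (s in seq_len(config$n_sites)) {
      b <- blocks[((s - 1) %% nrow(blocks)) + 1, ]
      repeat {
        k <- if (is.null(richness)) 1L else n_candidates
        rs <- pmin(pmax(floor(runif(k, (b$bj - 1) * rows_per, b$bj * rows_per)) + 1,
                        1), config$n_rows)
        cs <- pmin(pmax(floor(runif(k, (b$bi - 1) * cols_per, b$bi * cols_per)) + 1,
                        1), config$n_cols)
        best <- if (is.null(richness)) 1L else which.max(richness[cbind(rs, cs)])
        r <- rs[best]; c <- cs[best]
        key <- paste(r, c)
        if (!key %in% taken) { taken <- c(taken, key); break }
      }
      picks[s, ] <- c(r, c)
    }
    tibble(
      site_id = sprintf("site%02d", seq_len(config$n_sites)),
      x = template$origin_x + (picks[, 2] - 0.5) * template$cell_size,
      y = template$origin_y - (picks[, 1] - 0.5) * template$cell_size,
      row = picks[, 1], col = picks[, 2]
    )
  })
}

#' Apply the ground-truth extirpation process
#'
#' For each species historically present at a site (true range covers the
#' site's cell), extirpation is a Bernoulli draw with the logistic probability
#' described in [world_config()]. Sites whose surviving assemblage holds
#' fewer than five species are dropped, mirroring the inclusion rule for
#' exhaustively sampled assemblages.
#'
#' @param pool a `species_pool`.
#' @param sites tibble from [place_sites()].
#' @param pressures output of [generate_pressures()].
#' @param config a [world_config()] (supplies the coefficients).
#' @param seed RNG seed for the Bernoulli draws.
#' @return list with `assemblages` (site x species incidence tibble with
#'   coordinates and protection) and `truth` (historical incidence,
#'   per-pair extirpation probabilities, realized extirpations, site-level
#'   drivers).
#' @export
apply_defaunation <- function(pool, sites, pressures, config, seed) {
  sp_ids <- names(pool)
  n_s <- nrow(sites); n_sp <- length(pool)
  hist <- matrix(0L, n_s, n_sp, dimnames = list(sites$site_id, sp_ids))
  for (k in seq_len(n_sp)) {
    hist[, k] <- pool[[k]]$range$values[cbind(sites$row, sites$col)]
  }
  cell_idx <- cbind(sites$row, sites$col)
  hfp_j <- pressures$rasters$hfp$values[cell_idx]
  ls_j <- pressures$rasters$ls$values[cell_idx]
  protection <- rep("none", n_s)
  if (!is.null(pressures$pa_region)) {
    for (p in pressures$pa_region$polygons) {
      inside <- point_in_ring(sites$x, sites$y, p$coords)
      tag <- p$attributes$protection
      # strict protection wins where reserves overlap
      protection[inside & (protection == "none" | tag == "strict")] <- tag
    }
  }
  strict <- as.numeric(protection == "strict")
  masses <- vapply(pool, function(p) p$body_mass_g, numeric(1))
  eta <- config$beta0 + config$beta_mass * rep(log10(masses), each = n_s) +
    config$beta_hfp * hfp_j + config$beta_ls * ls_j - config$beta_pa * strict
  p_ext <- matrix(stats::plogis(eta), n_s, n_sp,
                  dimnames = dimnames(hist))
  extirpated <- with_seed(seed, {
    matrix(rbinom(n_s * n_sp, 1, p_ext), n_s, n_sp, dimnames = dimnames(hist))
  })
  contemporary <- hist * (1L - extirpated)
  richness <- rowSums(contemporary)
  keep <- richness >= 5
  if (!any(keep)) {
    abort("no site retains >= 5 species; weaken the extirpation coefficients")
  }
  assemblages <- tibble(
    site_id = sites$site_id[keep], x = sites$x[keep], y = sites$y[keep],
    protection = protection[keep]
  )
  assemblages <- dplyr::bind_cols(
    assemblages, as_tibble(contemporary[keep, , drop = FALSE])
  )
  list(
    assemblages = assemblages,
    truth = list(
      historical = hist, p_extirpation = p_ext, extirpated = extirpated,
      contemporary = contemporary,
      site_drivers = tibble(site_id = sites$site_id, hfp = hfp_j, ls = ls_j,
                            protection = protection,
                            historical_richness = rowSums(hist),
                            contemporary_richness = richness),
      sites_kept = sites$site_id[keep]
    )
  )
}

#' Simulate a complete virtual world
#'
#' One-call wrapper running [generate_environment()],
#' [generate_species_pool()], [generate_pressures()], [place_sites()],
#' [apply_defaunation()] and [sample_occurrences()] for every species under a
#' single configuration. Fully determined by `config` (including its seed).
#'
#' @param config a [world_config()].
#' @return a `defauna_world` list: `config`, `env`, `pool`, `traits`,
#'   `pressures`, `sites`, `assemblages`, `truth`, `occurrences`, `region`.
#' @export
simulate_world <- function(config = world_config()) {
  env <- generate_environment(config)
  pool <- generate_species_pool(config, env)
  pressures <- generate_pressures(config, env)
  tmpl <- env[[1]]
  true_richness <- Reduce(`+`, lapply(pool, function(p) p$range$values))
  sites <- place_sites(config, tmpl, richness = true_richness)
  defa <- apply_defaunation(pool, sites, pressures, config,
                            seed = config$seed + 5L)
  occ <- dplyr::bind_rows(lapply(seq_along(pool), function(k) {
    sample_occurrences(pool[[k]], config$n_occurrences,
                       seed = config$seed + 100L + k)
  }))
  region <- region_rectangle(tmpl$origin_x,
                             tmpl$origin_y - nrow(tmpl$values) * tmpl$cell_size,
                             tmpl$origin_x + ncol(tmpl$values) * tmpl$cell_size,
                             tmpl$origin_y, crs_label = tmpl$crs_label)
  structure(list(config = config, env = env, pool = pool,
                 traits = traits_table(pool), pressures = pressures,
                 sites = sites, assemblages = defa$assemblages,
                 truth = defa$truth, occurrences = occ, region = region),
            class = "defauna_world")
}

#' @export
print.defauna_world <- function(x, ...) {
  cat(sprintf("<defauna_world> %dx%d grid, %d species, %d sites retained (of %d), %d occurrence records\n",
              x$config$n_rows, x$config$n_cols, length(x$pool),
              nrow(x$assemblages), x$config$n_sites, nrow(x$occurrences)))
  invisible(x)
}
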