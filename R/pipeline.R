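#' Pipeline configuration
#'
#' Bundles every stage's parameters and toggles for an end-to-end run over a
#' synthetic world: simulate, sdm, interpolate, defaunate, downsize, fd,
#' drivers. The global `seed` (taken from `world$seed`) is propagated to
#' every stochastic stage with fixed offsets, so a rerun with the same
#' configuration reproduces identical results.
#'
#' @param world a [world_config()].
#' @param stages character subset of the seven stage names to run.
#' @param edge_km hexagonal grid edge length (default 5).
#' @param idw an [idw_config()].
#' @param sdm list of SDM controls passed to [sdm_stack()] (`n_rep`,
#'   `test_frac`, `beta_scale`, `max_iter`, `tol`, `r_max`).
#' @param gbm list of driver-model controls (`train_frac`, `n_candidates`,
#'   `k`, `space`, `max_background`).
#' @param fd list of functional-diversity controls (`m`,
#'   `quality_threshold`).
#' @param out_dir optional directory; when given, stage outputs are written
#'   there (text rasters, CSV tables, GeoJSON) and listed in the manifest.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(world = world_config(),
                            stages = c("simulate", "sdm", "interpolate",
                                       "defaunate", "downsize", "fd",
                                       "drivers"),
                            edge_km = 5, idw = idw_config(),
                            sdm = list(), gbm = list(), fd = list(),
                            out_dir = NULL) {
  sdm_def <- list(n_rep = 10, test_frac = 0.10, beta_scale = 0.2,
                  max_iter = 10000, tol = 1e-6, obj_tol = 1e-5, r_max = 0.8)
  gbm_def <- list(train_frac = 0.75, n_candidates = 25, k = 10,
                  space = list(n_trees = c(50, 1000), depth = c(1, 2, 3, 5),
                               shrinkage = c(0.01, 0.3), subsample = c(0.5, 1),
                               min_node = 5),
                  max_background = 100)
  fd_def <- list(m = NULL, quality_threshold = 0.75)
  structure(list(world = world, stages = stages, edge_km = edge_km,
                 idw = idw, sdm = utils::modifyList(sdm_def, sdm),
                 gbm = utils::modifyList(gbm_def, gbm),
                 fd = utils::modifyList(fd_def, fd), out_dir = out_dir,
                 seed = world$seed),
            class = "pipeline_config")
}

need_stage <- function(results, what, for_stage) {
  if (is.null(results[[what]])) {
    abort(sprintf("stage '%s' requires stage '%s' to run first", for_stage, what))
  }
  invisible(TRUE)
}

#' Run the full defaunation analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic world:
#'
#' 1. `simulate` — virtual world (environment, species, pressures,
#'    assemblages, ground truth);
#' 2. `sdm` — historical distribution models, thresholded and stacked into
#'    historical richness;
#' 3. `interpolate` — contemporary richness surface by IDW from the
#'    assemblage table;
#' 4. `defaunate` — defaunation surface, hexcell records with driver
#'    covariates, loss bands, species range loss;
#' 5. `downsize` — body-mass structure change and the protection-status
#'    comparison;
#' 6. `fd` — functional-diversity loss per site and its Gaussian GLM;
#' 7. `drivers` — gradient-boosted model of hexcell defaunation with Shapley
#'    attribution.
#'
#' @param config a [pipeline_config()].
#' @return list with one entry per executed stage plus `manifest`, a tibble
#'   of stage status, wall time and written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  results <- list()
  manifest <- list()
  outputs <- character(0)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(stage, files) {
    if (length(files)) outputs <<- c(outputs, files)
  }
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    manifest[[stage]] <<- tibble(stage = stage, status = "complete",
                                 elapsed_s = proc.time()[["elapsed"]] - t0)
    val
  }
  seed <- config$seed
  run <- function(s) s %in% config$stages

  if (run("simulate")) {
    results$simulate <- tick("simulate", simulate_world(config$world))
    if (!is.null(out_dir)) {
      w <- results$simulate
      write.csv(w$assemblages, file.path(out_dir, "assemblages.csv"),
                row.names = FALSE)
      write.csv(w$traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
      write.csv(w$occurrences, file.path(out_dir, "occurrences.csv"),
                row.names = FALSE)
      for (nm in names(w$env)) {
        write_raster(w$env[[nm]], file.path(out_dir, paste0("env_", nm, ".asc")))
      }
      for (nm in names(w$pressures$rasters)) {
        write_raster(w$pressures$rasters[[nm]],
                     file.path(out_dir, paste0("driver_", nm, ".asc")))
      }
      if (!is.null(w$pressures$pa_region)) {
        write_region_geojson(w$pressures$pa_region,
                             file.path(out_dir, "protected_areas.geojson"))
      }
      write_region_geojson(w$region, file.path(out_dir, "region.geojson"))
      emit("simulate", list.files(out_dir, full.names = TRUE))
    }
  }

  if (run("sdm")) {
    need_stage(results, "simulate", "sdm")
    w <- results$simulate
    results$sdm <- tick("sdm", do.call(sdm_stack, c(
      list(occurrences = w$occurrences, env = w$env, seed = seed),
      config$sdm
    )))
    if (!is.null(out_dir)) {
      write_raster(results$sdm$richness,
                   file.path(out_dir, "historical_richness.asc"))
      write.csv(results$sdm$species, file.path(out_dir, "sdm_species.csv"),
                row.names = FALSE)
    }
  }

  if (run("interpolate")) {
    need_stage(results, "simulate", "interpolate")
    w <- results$simulate
    template <- w$env[[1]]
    results$interpolate <- tick("interpolate", list(
      richness = contemporary_richness_surface(w$assemblages, template,
                                               config$idw)
    ))
    if (!is.null(out_dir)) {
      write_raster(results$interpolate$richness,
                   file.path(out_dir, "contemporary_richness.asc"))
    }
  }

  if (run("defaunate")) {
    need_stage(results, "sdm", "defaunate")
    need_stage(results, "interpolate", "defaunate")
    w <- results$simulate
    results$defaunate <- tick("defaunate", {
      defa <- defaunation_raster(results$sdm$richness,
                                 results$interpolate$richness)
      hexgrid <- build_hexgrid(w$region, config$edge_km)
      hexcells <- defaunation_by_hexcell(defa$D, hexgrid,
                                         w$pressures$rasters)
      list(defaunation = defa, hexgrid = hexgrid, hexcells = hexcells,
           loss_bands = loss_band_summary(defa$percent),
           range_loss = species_range_loss(results$sdm$binary, w$assemblages))
    })
    if (!is.null(out_dir)) {
      write_raster(results$defaunate$defaunation$D,
                   file.path(out_dir, "defaunation.asc"))
      write.csv(results$defaunate$hexcells, file.path(out_dir, "hexcells.csv"),
                row.names = FALSE)
      write.csv(results$defaunate$range_loss,
                file.path(out_dir, "range_loss.csv"), row.names = FALSE)
    }
  }

  if (run("downsize")) {
    need_stage(results, "sdm", "downsize")
    w <- results$simulate
    results$downsize <- tick("downsize", {
      hist_inc <- historical_composition(results$sdm$binary, w$assemblages)
      mass_kg <- setNames(w$traits$body_mass_g / 1000, w$traits$species_id)
      ds <- downsizing(w$assemblages, hist_inc, mass_kg)
      tk <- protection_comparison(ds$sites, "retained_fraction", "protection")
      list(downsizing = ds, tukey = tk, historical_composition = hist_inc)
    })
    if (!is.null(out_dir)) {
      write.csv(results$downsize$downsizing$sites,
                file.path(out_dir, "downsizing.csv"), row.names = FALSE)
      write.csv(results$downsize$tukey, file.path(out_dir, "tukey.csv"),
                row.names = FALSE)
    }
  }

  if (run("fd")) {
    need_stage(results, "sdm", "fd")
    w <- results$simulate
    results$fd <- tick("fd", {
      hist_inc <- historical_composition(results$sdm$binary, w$assemblages)
      fdres <- fd_by_site(w$assemblages, hist_inc, w$traits,
                          m = config$fd$m,
                          quality_threshold = config$fd$quality_threshold)
      # site-level drivers for the Gaussian GLM
      loc <- raster_locate(w$env[[1]], w$assemblages$x, w$assemblages$y)
      cell <- cbind(loc$row, loc$col)
      glm_data <- fdres$sites %>%
        mutate(agb = w$pressures$rasters$agb$values[cell],
               pas = w$pressures$rasters$pas$values[cell],
               hfp = w$pressures$rasters$hfp$values[cell],
               defaunation = .data$richness_hist - .data$richness_cont)
      fdres$glm <- glm_fd(glm_data, "fd_loss",
                          c("agb", "pas", "hfp", "defaunation"))
      fdres$glm_data <- glm_data
      fdres
    })
    if (!is.null(out_dir)) {
      write.csv(results$fd$sites, file.path(out_dir, "fd_sites.csv"),
                row.names = FALSE)
      write.csv(results$fd$glm$coefficients,
                file.path(out_dir, "fd_glm.csv"), row.names = FALSE)
    }
  }

  if (run("drivers")) {
    need_stage(results, "defaunate", "drivers")
    results$drivers <- tick("drivers", {
      cells <- results$defaunate$hexcells
      preds <- setdiff(colnames(cells), c("cell_id", "defaunation"))
      sp <- split_data(cells, config$gbm$train_frac, seed = seed + 11L)
      cv <- tune_random_search(sp$train, "defaunation", preds, test = sp$test,
                               n_candidates = config$gbm$n_candidates,
                               k = config$gbm$k, seed = seed + 13L,
                               space = config$gbm$space)
      shap <- shap_values(cv$model, cells, background = sp$train,
                          max_background = config$gbm$max_background,
                          seed = seed + 17L)
      list(split = sp, cv = cv, model = cv$model, shap = shap)
    })
    if (!is.null(out_dir)) {
      write.csv(results$drivers$shap$values, file.path(out_dir, "shap.csv"),
                row.names = FALSE)
      write.csv(results$drivers$cv$metrics,
                file.path(out_dir, "gbm_metrics.csv"), row.names = FALSE)
    }
  }

  man <- dplyr::bind_rows(manifest)
  if (!is.null(out_dir)) {
    files <- list.files(out_dir, full.names = TRUE)
    man_files <- tibble(file = basename(files),
                        md5 = as.character(tools::md5sum(files)))
    attr(man, "artifacts") <- man_files
  }
  attr(man, "config") <- config
  results$manifest <- man
  results
}
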