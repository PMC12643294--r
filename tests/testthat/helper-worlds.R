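# shared fixtures, built once per test run and cached

.defauna_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.defauna_cache[[key]])) .defauna_cache[[key]] <- builder()
  .defauna_cache[[key]]
}

# small fast world for unit tests
small_config <- function(seed = 7) {
  # gentler extirpation than the study-scale default: with only a 40 x 40
  # grid the species pool must stay large enough to clear the 5-species
  # assemblage filter
  world_config(n_rows = 40, n_cols = 40, n_species = 40, n_sites = 25,
               n_occurrences = 60, corr_length = 12, seed = seed,
               beta0 = -5.5)
}

get_small_world <- function() {
  memo("small_world", function() suppressWarnings(simulate_world(small_config())))
}

# the default study-scale world (used by the acceptance checks)
get_default_world <- function() {
  memo("default_world", function() suppressWarnings(simulate_world(world_config())))
}

# full pipeline on the default world (heavy; built once)
get_default_pipeline <- function() {
  memo("default_pipeline", function() {
    suppressWarnings(run_pipeline(pipeline_config(
      gbm = list(n_candidates = 10)
    )))
  })
}

# a tiny hand-made raster helper
mk_raster <- function(values, cell_size = 1, crs = "local-km") {
  raster_grid(values, origin_x = 0, origin_y = nrow(values) * cell_size,
              cell_size = cell_size, crs_label = crs)
}

# build a defauna_gbm object from hand-specified stumps:
# each stump is list(feature = 1-based index, split, left_value, right_value)
mk_stump_ensemble <- function(stumps, predictors, f0 = 0, shrinkage = 1) {
  trees <- lapply(stumps, function(s) {
    list(feature = c(s$feature - 1L, -1L, -1L),
         split = c(s$split, 0, 0),
         left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
         value = c(0, s$left_value, s$right_value))
  })
  structure(list(trees = trees, f0 = f0, shrinkage = shrinkage,
                 predictors = predictors, response = "y",
                 params = list(n_trees = length(trees), depth = 1,
                               shrinkage = shrinkage, subsample = 1,
                               min_node = 1),
                 mse_trace = numeric(0)),
            class = "defauna_gbm")
}
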