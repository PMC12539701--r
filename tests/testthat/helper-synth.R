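# Small synthetic datasets shared across test files, generated once per
# session into the tempdir and cached.

.test_cache <- new.env(parent = emptyenv())

# 4 producers x 2 visits x 2 samples x 4 images at 64x64: enough for I/O,
# feature and hygiene tests while staying fast
tiny_dataset <- function() {
  if (is.null(.test_cache$tiny)) {
    cfg <- synth_config(
      n_producers = 4L, n_visits = 2L, samples_per_visit = 2L,
      image_size = c(64L, 64L), grain_radius_range = c(3, 6), seed = 42L
    )
    dir <- file.path(tempdir(), "pollentrace-tiny")
    man <- generate_dataset(cfg, dir)
    .test_cache$tiny <- list(config = cfg, manifest = man, dir = dir)
  }
  .test_cache$tiny
}

# the desk-scale study conditions: 10 producers x 4 visits x 3 samples x 4
# images at 256x256, pipeline on the uv representation with k = 32 and the
# grid restricted to svm_poly degrees {4, 6}; cached per (seed, separation)
acceptance_run <- function(seed, separation = NULL) {
  key <- paste0("accept_", seed, "_", format(separation))
  if (is.null(.test_cache[[key]])) {
    args <- list(n_producers = 10L, n_visits = 4L, samples_per_visit = 3L,
                 image_size = c(256L, 256L), seed = seed)
    if (!is.null(separation)) args$separation <- separation
    cfg <- do.call(synth_config, args)
    man <- generate_dataset(cfg, tempfile(paste0("accept", seed)))
    grid <- default_grid(representations = "uv", ks = 32L,
                         svm_degrees = c(4L, 6L), families = "svm_poly")
    res <- run_pipeline(man, representation = "uv", k = 32L, grid = grid,
                        seed = seed)
    res$manifest <- man
    .test_cache[[key]] <- res
  }
  .test_cache[[key]]
}

# fast tiny-dataset pipeline run used by determinism checks; deliberately
# NOT cached so repeated calls re-execute the full chain
small_pipeline_run <- function(seed) {
  td <- tiny_dataset()
  grid <- default_grid(representations = "uv", ks = 16L,
                       svm_degrees = 4L, families = "svm_poly")
  run_pipeline(td$manifest, representation = "uv", k = 16L, grid = grid,
               n_folds = 5L, seed = seed, max_per_image = 400L)
}

# one rendered image with ground truth, 128x128
tiny_render <- function() {
  if (is.null(.test_cache$render)) {
    cfg <- synth_config(n_producers = 2L, image_size = c(128L, 128L),
                        seed = 9L)
    pal <- make_producer_palettes(cfg)
    .test_cache$render <- list(
      config = cfg, palette = pal[[1L]],
      out = render_sample_image(pal[[1L]], 1L, cfg, 77L)
    )
  }
  .test_cache$render
}
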