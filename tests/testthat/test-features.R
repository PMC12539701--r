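test_that("pixel pooling is deterministic, capped and train-only", {
  td <- tiny_dataset()
  masks <- compute_masks(td$manifest)
  rec <- td$manifest$records
  tr_keys <- rec$image_path[rec$split == "train"]
  mask_sizes <- vapply(masks[tr_keys], sum, integer(1))

  cap <- 150L
  px <- pool_pixels(td$manifest, masks, "uv", max_per_image = cap, seed = 2L)
  expect_identical(nrow(px), sum(pmin(mask_sizes, cap)))
  expect_identical(ncol(px), 2L)
  px2 <- pool_pixels(td$manifest, masks, "uv", max_per_image = cap, seed = 2L)
  expect_identical(px, px2)
  # cap larger than any mask: every masked pixel is included
  big <- pool_pixels(td$manifest, masks, "uv", max_per_image = 10^6L, seed = 2L)
  expect_identical(nrow(big), sum(mask_sizes))
})

test_that("codebook fitting recovers point-mass clusters and the k=1 mean", {
  set.seed(81)
  pts <- matrix(runif(32), ncol = 2)   # 16 distinct points
  x <- pts[rep(seq_len(16), each = 100), ]
  cb <- fit_codebook(x, k = 16L, seed = 4L)
  # independent full-batch Lloyd oracle (stats::kmeans), same data
  km <- stats::kmeans(x, centers = 16L, algorithm = "Lloyd", nstart = 10)
  lex <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(unname(cb$centroids), unname(lex(km$centers)),
               tolerance = 1e-6)
  expect_equal(unname(cb$centroids), unname(lex(pts)), tolerance = 1e-6)
  # k = 1 degenerates to the mean
  cb1 <- fit_codebook(x, k = 1L, enforce_range = FALSE)
  expect_equal(as.vector(cb1$centroids), colMeans(x), tolerance = 1e-9)
  # reproducibility and guards
  cb2 <- fit_codebook(x, k = 16L, seed = 4L)
  expect_identical(cb$centroids, cb2$centroids)
  expect_error(fit_codebook(x[1:10, ], k = 16L), "insufficient")
  expect_error(fit_codebook(x, k = 40L), "16, 35")
})

test_that("fitted codebooks quantize better than random codebooks", {
  set.seed(91)
  x <- matrix(rnorm(4000), ncol = 2)
  cb <- fit_codebook(x, k = 16L, seed = 6L)
  qerr <- function(centers) {
    d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
      2 * x %*% t(centers) + outer(rep(1, nrow(x)), rowSums(centers^2))
    mean(sqrt(pmax(apply(d2, 1, min), 0)))
  }
  rand_cb <- x[sample.int(nrow(x), 16L), ]
  expect_lte(qerr(cb$centroids), qerr(rand_cb))
})

test_that("color assignment matches an exhaustive scan and breaks ties low", {
  set.seed(101)
  cb <- fit_codebook(matrix(runif(6400), ncol = 2), k = 32L, seed = 7L)
  px <- matrix(runif(200), ncol = 2)
  expect_identical(assign_colors(px, cb),
                   as.integer(oracle_assign(px, cb$centroids)))
  # a pixel sitting exactly on centroid j maps to j
  expect_identical(assign_colors(cb$centroids[13, , drop = FALSE], cb), 13L)
  # exact tie between two centroids resolves to the lower index
  cb_tie <- structure(list(
    centroids = rbind(c(0, 0), c(1, 1), c(0, 0)),
    representation = "uv", k = 3L, seed = 1L, scope = "train_only"),
    class = "pollen_codebook")
  expect_identical(assign_colors(matrix(c(0, 0), ncol = 2), cb_tie), 1L)
  expect_error(assign_colors(matrix(runif(9), ncol = 3), cb), "dimension")
})

test_that("histograms are normalized, permutation- and duplication-invariant", {
  td <- tiny_dataset()
  masks <- compute_masks(td$manifest)
  px <- pool_pixels(td$manifest, masks, "uv", max_per_image = 300L)
  cb <- fit_codebook(px, k = 16L, seed = 8L)
  key <- td$manifest$records$image_path[1]
  img <- load_image(manifest_paths(td$manifest)[1])
  h <- histogram_features(img, masks[[key]], cb)
  expect_length(h, 16L)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_true(all(h >= 0))
  # duplicating every pixel (stacking the image side by side) changes nothing
  w <- dim(img)[2]
  img2 <- array(0, dim = c(dim(img)[1], 2 * w, 3))
  img2[, 1:w, ] <- img
  img2[, w + (1:w), ] <- img
  mask2 <- cbind(masks[[key]], masks[[key]])
  expect_equal(histogram_features(img2, mask2, cb), h, tolerance = 1e-12)
  expect_error(histogram_features(img, masks[[key]] & FALSE, cb), "empty")
  # single-centroid degenerate histogram
  cb1 <- fit_codebook(px, k = 1L, enforce_range = FALSE,
                      representation = "uv")
  expect_equal(histogram_features(img, masks[[key]], cb1), 1)
})

test_that("per-image histograms track the generating mixture weights", {
  # codebook placed exactly on the palette colors (k = m), no drift or
  # shadows: the image histogram should approximate the mixture weights,
  # with L1 error shrinking as the image (grain count) grows
  cfg_of <- function(side) {
    synth_config(n_producers = 2L, image_size = c(side, side),
                 palette_size = 16L, shadow_strength = 0,
                 visit_drift = 0, seed = 55L)
  }
  l1_at <- function(side, seed) {
    cfg <- cfg_of(side)
    pal <- make_producer_palettes(cfg)[[1]]
    cb <- structure(list(centroids = transform_pixels(pal$base_colors, "uv"),
                         representation = "uv", k = 16L, seed = 0L,
                         scope = "train_only"),
                    class = "pollen_codebook")
    out <- render_sample_image(pal, 1L, cfg, seed)
    h <- histogram_features(out$image, out$grain_mask, cb)
    sum(abs(h - pal$mixture_weights))
  }
  small <- vapply(1:3, function(s) l1_at(96L, s), numeric(1))
  large <- vapply(1:3, function(s) l1_at(256L, s), numeric(1))
  expect_lt(mean(large), 0.5)
  expect_lt(mean(large), mean(small))
})
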