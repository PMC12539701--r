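#' Synthetic pollen-image generator
#'
#' Generates datasets that emulate the statistical structure of macroscopic
#' corbicular-pollen photographs: each producer's hives forage a stable set
#' of plant species (floral constancy), so a producer is characterized by the
#' *proportions* in which a shared regional pool of grain colors appears in
#' its samples. Images show elliptical grains of palette-drawn colors on a
#' near-uniform gray template, each grain casting a partial achromatic shadow
#' ring; sampling visits perturb the mixture weights slightly (seasonal
#' shifts in the pollen spectrum). Ground-truth grain and shadow masks and
#' the producer palettes are emitted alongside, so segmentation and
#' featurization can be scored against a known answer.
#'
#' @name synth_pollen
NULL

# fold integers into a deterministic 31-bit seed
.derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (x in c(...)) {
    s <- (s * 1000003 + as.double(x) + 1) %% 2147483647
  }
  as.integer(s)
}

.string_seed <- function(x) {
  v <- utf8ToInt(x)
  .derive_seed(7L, sum(v * seq_along(v)))
}

#' Configuration for the synthetic generator
#'
#' Defaults mirror the structure of a full field campaign: 20 producers in 10
#' municipalities (two per municipality), 4 sampling visits, 14 samples per
#' visit and 4 images per sample (two acquisition rounds of two images),
#' giving ~4,480 images at full scale. Tests and examples use smaller
#' explicit values.
#'
#' @param n_producers number of producers (classes).
#' @param municipalities named character vector mapping producer id to
#'   municipality; `NULL` assigns two producers per municipality.
#' @param n_visits number of sampling visits.
#' @param samples_per_visit pollen samples collected per producer per visit.
#' @param images_per_sample images acquired per sample (must be >= 2; the
#'   first half belongs to acquisition round 1, the rest to round 2).
#' @param image_size `c(H, W)` in pixels.
#' @param grain_radius_range `c(min, max)` ellipse semi-axis range in pixels.
#' @param coverage target fraction of pixels covered by grains, in (0, 1).
#' @param shadow_strength relative darkening of shadow rings, in `[0, 1)`;
#'   0 disables shadows.
#' @param background_gray template gray level in `[0, 1]`.
#' @param illumination_jitter half-range of the per-image uniform offset
#'   applied to the background level.
#' @param palette_size number of base colors in the shared regional pool;
#'   must lie in `[16, 35]`, the range of plant species observed per sample
#'   in palynological analysis of this kind of material.
#' @param separation in `[0, 1]`: how far each producer's mixture weights are
#'   pulled from the common weight vector toward a producer-specific mode.
#'   0 makes all producers identical (pure chance for any classifier).
#' @param municipality_affinity in `[0, 1]`: maximum fraction of a
#'   producer's mode shared with the other producers of its municipality.
#'   Nearby apiaries forage overlapping flora, so producers of one
#'   municipality have correlated pollen spectra, and municipalities differ
#'   in how distinctive their local flora are: the municipalities span an
#'   even gradient of affinities from 0 up to this value. This concentrates
#'   misclassifications within a few persistently confusable
#'   same-municipality producer pairs, as observed on real material.
#' @param visit_drift scale of the multiplicative log-normal perturbation of
#'   mixture weights per (producer, visit).
#' @param seed master seed; every random choice derives from it.
#' @return validated `synth_config` list.
#' @export
synth_config <- function(n_producers = 20L,
                         municipalities = NULL,
                         n_visits = 4L,
                         samples_per_visit = 14L,
                         images_per_sample = 4L,
                         image_size = c(256L, 256L),
                         grain_radius_range = c(4, 9),
                         coverage = 0.35,
                         shadow_strength = 0.35,
                         background_gray = 0.8,
                         illumination_jitter = 0.02,
                         palette_size = 24L,
                         separation = 0.35,
                         visit_drift = 0.03,
                         municipality_affinity = 0.9,
                         seed = 1L) {
  if (palette_size < 16L || palette_size > 35L) {
    stop("palette_size must lie in [16, 35]")
  }
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  if (n_visits < 1L) stop("n_visits must be >= 1")
  if (images_per_sample < 2L) stop("images_per_sample must be >= 2")
  if (shadow_strength < 0 || shadow_strength >= 1) {
    stop("shadow_strength must lie in [0, 1)")
  }
  if (separation < 0) stop("separation must be >= 0")
  if (municipality_affinity < 0 || municipality_affinity > 1) {
    stop("municipality_affinity must lie in [0, 1]")
  }
  producers <- sprintf("P%02d", seq_len(n_producers))
  if (is.null(municipalities)) {
    muni <- sprintf("M%02d", ceiling(seq_len(n_producers) / 2))
    municipalities <- stats::setNames(muni, producers)
  } else {
    if (!all(producers %in% names(municipalities))) {
      stop("municipalities must name every producer ",
           paste(producers, collapse = ", "))
    }
    municipalities <- municipalities[producers]
  }
  structure(
    list(n_producers = as.integer(n_producers),
         producers = producers,
         municipalities = municipalities,
         n_visits = as.integer(n_visits),
         samples_per_visit = as.integer(samples_per_visit),
         images_per_sample = as.integer(images_per_sample),
         image_size = as.integer(image_size),
         grain_radius_range = grain_radius_range,
         coverage = coverage,
         shadow_strength = shadow_strength,
         background_gray = background_gray,
         illumination_jitter = illumination_jitter,
         palette_size = as.integer(palette_size),
         separation = separation,
         visit_drift = visit_drift,
         municipality_affinity = municipality_affinity,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Build producer color palettes
#'
#' All producers share one global pool of `palette_size` base colors (the
#' regional flora); producers differ only in their mixture weights. A common
#' weight vector is drawn from a symmetric Dirichlet, and each producer's
#' weights are shifted toward a producer-specific Dirichlet mode by the
#' `separation` fraction: `w_p = (1 - s) w_common + s mode_p`. With
#' `separation = 0` every producer carries the identical weight vector.
#' Each mode is itself a blend of a municipality-level mode and an
#' independent producer draw, weighted by `municipality_affinity`, so
#' producers of one municipality are more alike than producers of different
#' municipalities.
#'
#' @param config a `synth_config`.
#' @return list of palettes, one per producer, each with `producer_id`,
#'   `base_colors` (m x 3 RGB), `mixture_weights` (sums to 1) and
#'   `visit_drift`.
#' @export
make_producer_palettes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  m <- config$palette_size
  set.seed(.derive_seed(config$seed, 101L))
  hue <- ((seq_len(m) - 1) / m + stats::runif(m, 0, 0.5 / m)) %% 1
  sat <- stats::runif(m, 0.45, 0.9)
  val <- stats::runif(m, 0.45, 0.95)
  pool <- t(grDevices::col2rgb(grDevices::hsv(hue, sat, val))) / 255
  colnames(pool) <- c("r", "g", "b")
  w_common <- stats::rgamma(m, shape = 2)
  w_common <- w_common / sum(w_common)
  munis <- unique(unname(config$municipalities))
  aff0 <- config$municipality_affinity
  n_mu <- length(munis)
  muni_modes <- lapply(seq_along(munis), function(mu) {
    set.seed(.derive_seed(config$seed, 909L, mu))
    md <- stats::rgamma(m, shape = 0.5)
    aff <- if (n_mu > 1) aff0 * (mu - 1) / (n_mu - 1) else 0
    list(mode = md / sum(md), affinity = aff)
  })
  names(muni_modes) <- munis
  lapply(seq_len(config$n_producers), function(p) {
    set.seed(.derive_seed(config$seed, 202L, p))
    own <- stats::rgamma(m, shape = 0.5)
    own <- own / sum(own)
    muni <- unname(config$municipalities[config$producers[p]])
    aff <- muni_modes[[muni]]$affinity
    mode_p <- aff * muni_modes[[muni]]$mode + (1 - aff) * own
    w <- (1 - config$separation) * w_common + config$separation * mode_p
    w <- w / sum(w)
    list(producer_id = config$producers[p],
         base_colors = pool,
         mixture_weights = w,
         visit_drift = config$visit_drift)
  })
}

# per-(producer, visit) drifted mixture weights; independent of the image seed
.visit_weights <- function(palette, visit) {
  if (palette$visit_drift <= 0) return(palette$mixture_weights)
  set.seed(.derive_seed(.string_seed(palette$producer_id), visit))
  z <- stats::rnorm(length(palette$mixture_weights))
  w <- palette$mixture_weights * exp(palette$visit_drift * z)
  w / sum(w)
}

#' Render one synthetic pollen-sample image
#'
#' @param palette a producer palette from [make_producer_palettes()].
#' @param visit sampling visit in `1..n_visits`.
#' @param config a `synth_config`.
#' @param seed image-level seed; identical `(palette, visit, config, seed)`
#'   reproduce the image bit for bit.
#' @return list with `image` (H x W x 3 RGB array), `grain_mask` and
#'   `shadow_mask` (H x W logical ground-truth masks).
#' @export
render_sample_image <- function(palette, visit, config, seed) {
  stopifnot(inherits(config, "synth_config"))
  if (visit < 1L || visit > config$n_visits) stop("visit out of range")
  h <- config$image_size[1L]; w <- config$image_size[2L]
  r_max <- max(config$grain_radius_range)
  if (2 * r_max + 6 >= min(h, w)) {
    stop("grain_radius_range too large for image_size")
  }
  wv <- .visit_weights(palette, visit)
  set.seed(.derive_seed(seed, 303L))
  bg <- config$background_gray +
    stats::runif(1, -1, 1) * config$illumination_jitter
  bg <- min(max(bg, 0), 1)
  img <- array(bg, dim = c(h, w, 3L))
  grain <- matrix(FALSE, h, w)
  shadow <- matrix(FALSE, h, w)

  target <- config$coverage * h * w
  mean_area <- pi * mean(config$grain_radius_range)^2
  max_grains <- ceiling(3 * target / mean_area) + 50L
  n_grain_px <- 0
  attempts <- 0L
  while (n_grain_px < target && attempts < 20L * max_grains) {
    attempts <- attempts + 1L
    cy <- stats::runif(1, r_max + 3, h - r_max - 3)
    cx <- stats::runif(1, r_max + 3, w - r_max - 3)
    if (grain[round(cy), round(cx)]) next  # centers must not land on a grain
    a <- stats::runif(1, config$grain_radius_range[1L],
                      config$grain_radius_range[2L])
    b <- stats::runif(1, config$grain_radius_range[1L],
                      config$grain_radius_range[2L])
    th <- stats::runif(1, 0, 2 * pi)
    ci <- sample.int(length(wv), 1L, prob = wv)
    col <- palette$base_colors[ci, ] + stats::rnorm(3, 0, 0.02)
    col <- pmin(pmax(col, 0.02), 1)

    rr <- ceiling(max(a, b))
    ys <- max(1L, floor(cy - rr - 4)):min(h, ceiling(cy + rr + 4))
    xs <- max(1L, floor(cx - rr - 4)):min(w, ceiling(cx + rr + 4))
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    inside <- u * u + v * v <= 1

    if (config$shadow_strength > 0) {
      # partial ring: a ~2.5 px dilation of the ellipse, kept on one side
      sa <- a + 2.5; sb <- b + 2.5
      us <- (dx * cos(th) + dy * sin(th)) / sa
      vs <- (-dx * sin(th) + dy * cos(th)) / sb
      ring <- (us * us + vs * vs <= 1) & !inside
      dir <- stats::runif(1, 0, 2 * pi)
      ring <- ring & (dx * cos(dir) + dy * sin(dir) > 0)
      sh_level <- bg * (1 - config$shadow_strength * stats::runif(1, 0.6, 1))
      idx <- which(ring)
      if (length(idx)) {
        gi <- as.matrix(expand.grid(ys, xs))[idx, , drop = FALSE]
        lin <- gi[, 1L] + (gi[, 2L] - 1L) * h
        new_sh <- lin[!grain[lin]]
        if (length(new_sh)) {
          gnoise <- stats::rnorm(length(new_sh), 0, 0.01)
          gval <- pmin(pmax(sh_level + gnoise, 0), 1)
          for (ch in 1:3) img[new_sh + (ch - 1L) * h * w] <- gval
          shadow[new_sh] <- TRUE
        }
      }
    }

    idx <- which(inside)
    if (length(idx)) {
      gi <- as.matrix(expand.grid(ys, xs))[idx, , drop = FALSE]
      lin <- gi[, 1L] + (gi[, 2L] - 1L) * h
      new_px <- sum(!grain[lin])
      for (ch in 1:3) {
        img[lin + (ch - 1L) * h * w] <-
          pmin(pmax(col[ch] + stats::rnorm(length(lin), 0, 0.015), 0), 1)
      }
      grain[lin] <- TRUE
      n_grain_px <- n_grain_px + new_px
    }
  }
  shadow <- shadow & !grain
  list(image = img, grain_mask = grain, shadow_mask = shadow)
}

.round_of_image <- function(i, images_per_sample) {
  ifelse(i <= ceiling(images_per_sample / 2), 1L, 2L)
}

#' Generate a full synthetic dataset on disk
#'
#' Writes PNG images under `out_dir/images/`, combined ground-truth masks
#' under `out_dir/ground_truth/masks/` (gray PNG: 0 background, 0.5 shadow,
#' 1 grain), palette tables under `out_dir/ground_truth/`, and a manifest CSV
#' at `out_dir/manifest.csv`. Per producer, images are split ~2:1 into
#' train:test stratified across visits, and test images are balanced between
#' the two acquisition rounds (one round-1 and one round-2 image from each
#' selected sample), supporting test-retest evaluation.
#'
#' @param config a `synth_config`.
#' @param out_dir output directory (created if absent).
#' @return the dataset's `pollen_manifest`, invisibly readable back with
#'   [read_manifest()].
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "ground_truth", "masks"), recursive = TRUE,
             showWarnings = FALSE)
  palettes <- make_producer_palettes(config)

  # ground-truth palette table
  gt <- do.call(rbind, lapply(palettes, function(pal) {
    data.frame(producer_id = pal$producer_id,
               color = seq_len(nrow(pal$base_colors)),
               r = pal$base_colors[, 1L], g = pal$base_colors[, 2L],
               b = pal$base_colors[, 3L],
               weight = pal$mixture_weights)
  }))
  utils::write.csv(gt, file.path(out_dir, "ground_truth", "palettes.csv"),
                   row.names = FALSE)

  V <- config$n_visits; S <- config$samples_per_visit
  I <- config$images_per_sample
  n_img_per_producer <- V * S * I

  rows <- vector("list", config$n_producers * n_img_per_producer)
  ri <- 0L
  for (p in seq_len(config$n_producers)) {
    pid <- config$producers[p]
    # choose test (visit, sample) slots, stratified across visits
    n_pairs <- round(n_img_per_producer / 6)
    set.seed(.derive_seed(config$seed, 404L, p))
    per_visit <- rep(n_pairs %/% V, V)
    extra <- n_pairs %% V
    if (extra > 0) {
      bump <- sample.int(V, extra)
      per_visit[bump] <- per_visit[bump] + 1L
    }
    test_slots <- character(0)
    for (v in seq_len(V)) {
      nv <- min(per_visit[v], S)
      if (nv > 0) {
        test_slots <- c(test_slots, paste(v, sample.int(S, nv), sep = "_"))
      }
    }
    for (v in seq_len(V)) for (s in seq_len(S)) {
      slot_is_test <- paste(v, s, sep = "_") %in% test_slots
      # within a test slot, the first image of each round goes to test
      first_r2 <- ceiling(I / 2) + 1L
      for (i in seq_len(I)) {
        rnd <- .round_of_image(i, I)
        split <- if (slot_is_test && (i == 1L || i == first_r2)) "test" else "train"
        name <- sprintf("%s_v%d_s%02d_i%d.png", pid, v, s, i)
        res <- render_sample_image(palettes[[p]], v, config,
                                   .derive_seed(config$seed, p, v, s, i))
        save_image_png(res$image, file.path(out_dir, "images", name))
        gt_mask <- matrix(0, nrow(res$grain_mask), ncol(res$grain_mask))
        gt_mask[res$shadow_mask] <- 0.5
        gt_mask[res$grain_mask] <- 1
        save_image_png(gt_mask,
                       file.path(out_dir, "ground_truth", "masks", name))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          image_path = file.path("images", name),
          producer_id = pid,
          municipality = unname(config$municipalities[pid]),
          visit = v, acquisition_round = rnd, split = split,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- do.call(rbind, rows)
  manifest <- .new_manifest(records, directory = out_dir)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read a ground-truth mask written by [generate_dataset()]
#'
#' @param manifest the dataset manifest.
#' @param image_path an `image_path` entry of the manifest.
#' @return list with logical `grain_mask` and `shadow_mask`.
#' @export
read_ground_truth_mask <- function(manifest, image_path) {
  p <- file.path(manifest$directory, "ground_truth", "masks",
                 basename(image_path))
  if (!file.exists(p)) stop("ground-truth mask not found: ", p)
  m <- png::readPNG(p)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  list(grain_mask = m > 0.75, shadow_mask = m > 0.25 & m <= 0.75)
}
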