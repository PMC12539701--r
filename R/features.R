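#' Color-codebook features
#'
#' Images are reduced to fixed-length color descriptors in two steps: a
#' codebook of k representative colors is learned by mini-batch k-means over
#' pollen-region pixels pooled from the training images, and every image is
#' then summarized by the relative frequency with which its pollen pixels
#' fall nearest to each codebook color. k plays the role of the number of
#' distinguishable pollen (plant-species) colors and is restricted to the
#' range 16-35 observed palynologically for this material; k = 32 is the
#' default.
#'
#' @name features
NULL

#' Segment every image of a manifest
#'
#' Applies [segment_pollen()] followed by [remove_shadows()] to each image.
#'
#' @param manifest a `pollen_manifest`.
#' @param radius entropy radius, see [local_entropy()].
#' @param shadow_rule passed to [remove_shadows()].
#' @return named list of logical masks keyed by `image_path`.
#' @export
compute_masks <- function(manifest, radius = 5L, shadow_rule = "remove_low") {
  paths <- manifest_paths(manifest)
  keys <- manifest$records$image_path
  masks <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    img <- load_image(paths[i])
    raw <- segment_pollen(img, radius = radius)
    masks[[i]] <- if (any(raw)) {
      remove_shadows(img, raw, rule = shadow_rule)
    } else raw
  }
  names(masks) <- keys
  masks
}

#' Pool masked pixels from the training images
#'
#' Uniformly subsamples up to `max_per_image` pollen pixels from every
#' training-split image, transformed to the chosen color representation.
#' Images with an empty mask are skipped with a warning.
#'
#' @param manifest a `pollen_manifest`.
#' @param masks named list of logical masks (see [compute_masks()]).
#' @param representation one of `"hsv"`, `"luv"`, `"hs"`, `"uv"`.
#' @param max_per_image pixel cap per image.
#' @param seed RNG seed for the subsampling.
#' @param split which split to pool from; `"train"` (default) avoids leaking
#'   test pixels into the codebook, `"all"` pools every image.
#' @return n x d numeric matrix of pixels in the representation.
#' @export
pool_pixels <- function(manifest, masks, representation,
                        max_per_image = 2000L, seed = 1L,
                        split = c("train", "all")) {
  split <- match.arg(split)
  rec <- manifest$records
  use <- if (split == "train") rec$split == "train" else rep(TRUE, nrow(rec))
  paths <- manifest_paths(manifest)
  out <- list()
  for (i in which(use)) {
    key <- rec$image_path[i]
    mask <- masks[[key]]
    if (is.null(mask)) stop("no mask for image: ", key)
    n <- sum(mask)
    if (n == 0L) {
      warning("empty mask, skipping image: ", key)
      next
    }
    img <- load_image(paths[i])
    px <- cbind(img[, , 1L][mask], img[, , 2L][mask], img[, , 3L][mask])
    if (n > max_per_image) {
      set.seed(.derive_seed(seed, 505L, i))
      px <- px[sample.int(n, max_per_image), , drop = FALSE]
    }
    out[[length(out) + 1L]] <- transform_pixels(px, representation)
  }
  if (!length(out)) stop("all masks are empty; nothing to pool")
  do.call(rbind, out)
}

# k-means++ seeding (Arthur & Vassilvitskii): probability proportional to
# squared distance to the nearest already-chosen center
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    nd2 <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  centers
}

.nearest_center <- function(x, centers) {
  # n x k squared distances; which.min per row resolves ties to lowest index
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * cross + outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Fit a color codebook by mini-batch k-means
#'
#' Mini-batch k-means (k-means++ seeding; per-center learning rates equal to
#' the reciprocal of the number of samples each center has absorbed) followed
#' by one full-batch Lloyd polish step: a final assignment of all pixels and
#' recomputation of every non-empty center as the exact mean of its pixels.
#' Centroids are stored in canonical (lexicographic) row order, so the
#' codebook is independent of the optimizer's internal labeling.
#'
#' @param pixels n x d matrix of pixels in the target representation.
#' @param k number of centroids, in `[16, 35]` (default 32). Values outside
#'   the range are permitted only via `enforce_range = FALSE` (used by
#'   closed-form tests).
#' @param seed RNG seed; fitting is bit-for-bit reproducible given it.
#' @param batch_size mini-batch size.
#' @param n_iter number of mini-batch iterations.
#' @param representation tag stored with the codebook.
#' @param scope provenance tag (`"train_only"` or `"all"`).
#' @param enforce_range check `k` against `[16, 35]`.
#' @return a `pollen_codebook`: list with `centroids` (k x d, lexicographic),
#'   `representation`, `k`, `seed`, `scope`.
#' @export
fit_codebook <- function(pixels, k = 32L, seed = 1L, batch_size = 4096L,
                         n_iter = 100L, representation = "uv",
                         scope = "train_only", enforce_range = TRUE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (enforce_range && (k < 16L || k > 35L)) {
    stop("k must lie in [16, 35]")
  }
  n <- nrow(pixels)
  if (n < k) stop("insufficient data: ", n, " pixels for k = ", k)
  set.seed(.derive_seed(seed, 606L))
  centers <- .kmeanspp_init(pixels, k)
  counts <- rep(0, k)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, min(batch_size, n))
    batch <- pixels[idx, , drop = FALSE]
    a <- .nearest_center(batch, centers)
    # the sequential per-sample update with rate 1/count is a running mean,
    # so a whole batch collapses to one exact weighted-mean update per center
    sums <- rowsum(batch, a)
    grp <- as.integer(rownames(sums))
    m <- tabulate(a, nbins = k)[grp]
    centers[grp, ] <- (counts[grp] * centers[grp, , drop = FALSE] + sums) /
      (counts[grp] + m)
    counts[grp] <- counts[grp] + m
  }
  # full-batch Lloyd polish: exact means of the final assignment
  a <- .nearest_center(pixels, centers)
  for (j in seq_len(k)) {
    if (any(a == j)) {
      centers[j, ] <- colMeans(pixels[a == j, , drop = FALSE])
    }
  }
  ord <- do.call(order, as.data.frame(centers))
  centers <- centers[ord, , drop = FALSE]
  dimnames(centers) <- NULL
  structure(
    list(centroids = centers, representation = representation,
         k = as.integer(k), seed = seed, scope = scope),
    class = "pollen_codebook"
  )
}

#' @export
print.pollen_codebook <- function(x, ...) {
  cat("pollen_codebook: k =", x$k, "in", x$representation,
      "space (scope:", paste0(x$scope, ")"), "\n")
  invisible(x)
}

#' Assign pixels to their nearest codebook color
#'
#' Minimum Euclidean distance; ties resolve to the lowest centroid index.
#'
#' @param pixels n x d matrix in the codebook's representation.
#' @param codebook a `pollen_codebook`.
#' @return integer vector of centroid indices in `1..k`.
#' @export
assign_colors <- function(pixels, codebook) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (ncol(pixels) != ncol(codebook$centroids)) {
    stop("pixel dimension (", ncol(pixels), ") does not match codebook (",
         ncol(codebook$centroids), ")")
  }
  .nearest_center(pixels, codebook$centroids)
}

#' Color-frequency histogram of one image
#'
#' Transforms the masked pixels to the codebook's representation, assigns
#' each to its nearest centroid and returns relative frequencies (summing
#' to 1), so images with different pollen areas are comparable.
#'
#' @param img H x W x 3 RGB array.
#' @param mask H x W logical mask with at least one `TRUE` pixel.
#' @param codebook a `pollen_codebook`.
#' @return numeric vector of length k summing to 1.
#' @export
histogram_features <- function(img, mask, codebook) {
  if (!any(mask)) stop("mask is empty")
  px <- cbind(img[, , 1L][mask], img[, , 2L][mask], img[, , 3L][mask])
  rp <- transform_pixels(px, codebook$representation)
  a <- assign_colors(rp, codebook)
  tabulate(a, nbins = codebook$k) / length(a)
}

#' Histogram features for every image of a manifest
#'
#' @param manifest a `pollen_manifest`.
#' @param masks named list of masks keyed by `image_path`.
#' @param codebook a `pollen_codebook`.
#' @return matrix (images x k) with rownames set to `image_path`; images with
#'   empty masks are dropped with a warning.
#' @export
dataset_features <- function(manifest, masks, codebook) {
  paths <- manifest_paths(manifest)
  keys <- manifest$records$image_path
  rows <- list()
  for (i in seq_along(paths)) {
    mask <- masks[[keys[i]]]
    if (is.null(mask) || !any(mask)) {
      warning("empty mask, dropping image: ", keys[i])
      next
    }
    img <- load_image(paths[i])
    rows[[keys[i]]] <- histogram_features(img, mask, codebook)
  }
  out <- do.call(rbind, rows)
  out
}
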