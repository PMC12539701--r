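#' Segmentation of the pollen region and shadow cleanup
#'
#' Macroscopic pollen photographs show textured granular pellets on a
#' near-uniform template. Grain regions have high local gray-level entropy
#' while the background is flat, so the pollen region is segmented by
#' thresholding a local-entropy map with Otsu's method. Residual pixels from
#' small grain shadows are then discarded: shadows are near-achromatic, i.e.
#' close to the gray diagonal of the RGB cube, and are identified by their
#' distance to that axis.
#'
#' @name preprocess
NULL

#' Convert an RGB image to grayscale luminance
#'
#' Uses the luminance weights `0.299 R + 0.587 G + 0.114 B` (the Y row of the
#' RGB-to-XYZ matrix), so segmentation and the color model share one
#' definition of lightness.
#'
#' @param img H x W x 3 array of RGB values in `[0, 1]`.
#' @return H x W matrix of gray values in `[0, 1]`.
#' @export
to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  matrix(g, nrow = dim(img)[1L], ncol = dim(img)[2L])
}

#' Local-entropy texture map
#'
#' Per pixel, the Shannon entropy (base 2) of the histogram of quantized gray
#' levels within a circular neighborhood of the given radius. Gray values are
#' quantized to `n_bins` uniform bins on `[0, 1]`; neighborhoods at the image
#' border are truncated to in-bounds pixels.
#'
#' @param gray H x W matrix of gray values in `[0, 1]`.
#' @param radius neighborhood radius in pixels (pixels whose center distance
#'   is at most `radius` belong to the patch). Default 5.
#' @param n_bins number of quantization bins. Default 256.
#' @return H x W matrix of entropies in bits, bounded by `log2(n_bins)`.
#' @export
local_entropy <- function(gray, radius = 5L, n_bins = 256L) {
  gray <- as.matrix(gray)
  if (radius < 1L) stop("radius must be >= 1")
  if (radius > min(dim(gray)) / 2) {
    stop("radius (", radius, ") exceeds half the smallest image dimension")
  }
  if (any(gray < 0 | gray > 1)) stop("gray values must lie in [0, 1]")
  bins <- matrix(pmin(as.integer(floor(gray * n_bins)), n_bins - 1L),
                 nrow = nrow(gray))
  .local_entropy_cpp(bins, as.integer(radius), as.integer(n_bins))
}

#' Otsu threshold over a set of values
#'
#' Quantizes the values to 256 uniform levels spanning their range and
#' returns the cut maximizing the between-class variance of the two-class
#' split; ties are broken toward the lowest qualifying level. The returned
#' threshold is the midpoint between the last level of the low class and the
#' first level of the high class, so it lies strictly between the two
#' classes.
#'
#' @param values numeric vector with at least two distinct quantized levels.
#' @return scalar threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 1e-12 * max(1, abs(hi))) {
    stop("degenerate input: all values identical")
  }
  n_levels <- 256L
  lev <- pmin(as.integer(floor((values - lo) / (hi - lo) * n_levels)),
              n_levels - 1L)
  counts <- tabulate(lev + 1L, nbins = n_levels)
  if (sum(counts > 0) < 2L) stop("degenerate input: fewer than 2 distinct levels")
  centers <- lo + (0:(n_levels - 1L)) / (n_levels - 1L) * (hi - lo)
  n <- sum(counts)
  w0 <- cumsum(counts) / n                       # weight of class <= t
  mu <- cumsum(counts * centers) / n
  mu_t <- mu[n_levels]
  w1 <- 1 - w0
  # between-class variance for thresholds t = 0 .. 254
  valid <- seq_len(n_levels - 1L)
  mu0 <- mu[valid] / w0[valid]
  mu1 <- (mu_t - mu[valid]) / w1[valid]
  bcv <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  bcv[!is.finite(bcv)] <- -Inf
  t_star <- which.max(bcv)                       # which.max takes the lowest tie
  # midpoint between level t_star-1 and the next occupied consideration level
  (centers[t_star] + centers[t_star + 1L]) / 2
}

#' Segment the pollen region of an image
#'
#' Computes the local-entropy map of the grayscale image and thresholds it
#' with Otsu's method; the high-entropy class is the pollen region.
#'
#' @param img H x W x 3 RGB array in `[0, 1]`.
#' @param radius entropy neighborhood radius, see [local_entropy()].
#' @param n_bins entropy quantization bins.
#' @return H x W logical matrix, `TRUE` on pollen pixels.
#' @export
segment_pollen <- function(img, radius = 5L, n_bins = 256L) {
  ent <- local_entropy(to_gray(img), radius = radius, n_bins = n_bins)
  thr <- otsu_threshold(as.vector(ent))
  ent > thr
}

#' Distance of RGB colors to the achromatic axis
#'
#' Euclidean distance of each color P to the gray diagonal of the RGB cube
#' (the line R = G = B), computed as `||U x P|| / ||U||` with `U = (1,1,1)`.
#' Pure grays have distance 0; the distance scales linearly with the color.
#'
#' @param rgb n x 3 matrix of RGB triples (or a single triple).
#' @return numeric vector of n nonnegative distances.
#' @export
#' @examples
#' diagonal_distance(c(1, 0, 0))  # sqrt(2/3)
diagonal_distance <- function(rgb) {
  rgb <- .as_pixel_matrix(rgb)
  r <- rgb[, 1L]; g <- rgb[, 2L]; b <- rgb[, 3L]
  # U x P = (b - g, r - b, g - r)
  sqrt((b - g)^2 + (r - b)^2 + (g - r)^2) / sqrt(3)
}

#' Remove shadow pixels from a segmentation mask
#'
#' Shadows cast by pollen grains are near-achromatic, so among the masked
#' pixels those whose distance to the RGB diagonal falls below one standard
#' deviation of the masked-pixel distances are dropped (`rule =
#' "remove_low"`, the default). `rule = "keep_low"` inverts the comparison
#' and retains only the near-achromatic pixels. If the distances have zero
#' standard deviation the mask is returned unchanged. The refined mask is
#' always a subset of the input mask.
#'
#' @param img H x W x 3 RGB array in `[0, 1]`.
#' @param mask H x W logical matrix with at least one `TRUE` entry.
#' @param rule `"remove_low"` or `"keep_low"`.
#' @return refined H x W logical mask.
#' @export
remove_shadows <- function(img, mask, rule = c("remove_low", "keep_low")) {
  rule <- match.arg(rule)
  stopifnot(length(dim(img)) == 3L, identical(dim(img)[1:2], dim(mask)))
  if (!any(mask)) stop("mask is empty")
  px <- cbind(img[, , 1L][mask], img[, , 2L][mask], img[, , 3L][mask])
  d <- diagonal_distance(px)
  s <- stats::sd(d)
  if (is.na(s) || s == 0) return(mask)
  keep <- if (rule == "remove_low") d >= s else d < s
  out <- mask
  out[mask] <- keep
  out
}
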