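#' Color-space transforms for pollen color featurization
#'
#' Pollen color is the discriminative signal this package exploits: pigments
#' (flavonoids, carotenoids) differ between the plant species each hive
#' forages on, so the mixture of grain colors in a macroscopic photograph
#' carries producer information. Raw RGB confounds chroma with illumination,
#' so pixels are re-expressed either in HSV (hue/saturation are invariant to
#' multiplicative changes in light intensity) or in CIE L*u*v* (approximately
#' perceptually uniform, so Euclidean distances used by the color quantizer
#' track perceived color differences).
#'
#' All functions operate on n x 3 matrices of pixels, one pixel per row.
#' RGB values are expected in [0, 1].
#'
#' @name colorspace
NULL

#' Reference white point for the L*u*v* transform
#'
#' Chromaticity coordinates of the reference white used when converting XYZ
#' to L*u*v*. `u0` and `v0` are the white's chromaticity offsets and `Y0` its
#' luminance; with RGB in [0, 1] the white (1,1,1) maps to Y = 1, so `Y0 = 1`.
#'
#' @param u0,v0 chromaticity of the reference white.
#' @param Y0 luminance of the reference white.
#' @return A list with elements `u0`, `v0`, `Y0`.
#' @export
white_point <- function(u0 = 0.19793943, v0 = 0.46831096, Y0 = 1.0) {
  stopifnot(is.numeric(u0), is.numeric(v0), is.numeric(Y0), Y0 > 0)
  list(u0 = u0, v0 = v0, Y0 = Y0)
}

.as_pixel_matrix <- function(p, d = 3L) {
  if (is.null(dim(p))) p <- matrix(p, ncol = length(p))
  p <- as.matrix(p)
  if (ncol(p) != d) {
    stop("expected a matrix with ", d, " columns, got ", ncol(p))
  }
  storage.mode(p) <- "double"
  p
}

#' RGB to HSV conversion
#'
#' Hue is computed with the two-argument arctangent,
#' `H = atan2(sqrt(3) (G - B), 2R - G - B)`, wrapped to `[0, 2*pi)`; the
#' quadrant-aware form yields the standard hexagonal hue angle, which a
#' single-argument arctangent cannot resolve. Saturation is `C / V` with
#' `C = max - min`, and zero for achromatic pixels (where `H` is set to 0 by
#' convention); value is `max(R, G, B)`.
#'
#' @param rgb n x 3 matrix of RGB pixels in `[0, 1]`.
#' @return n x 3 matrix with columns `h` (radians in `[0, 2*pi)`), `s`, `v`.
#' @export
#' @examples
#' rgb_to_hsv(matrix(c(1, 0, 0), ncol = 3))  # pure red: H = 0, S = 1, V = 1
rgb_to_hsv <- function(rgb) {
  rgb <- .as_pixel_matrix(rgb)
  if (any(rgb < 0 | rgb > 1)) stop("RGB values must lie in [0, 1]")
  r <- rgb[, 1L]; g <- rgb[, 2L]; b <- rgb[, 3L]
  v <- pmax(r, g, b)
  cmin <- pmin(r, g, b)
  ch <- v - cmin
  s <- ifelse(ch == 0, 0, ch / v)
  h <- atan2(sqrt(3) * (g - b), 2 * r - g - b)
  h <- ifelse(ch == 0, 0, h %% (2 * pi))
  out <- cbind(h = h, s = s, v = v)
  rownames(out) <- NULL
  out
}

# Linear RGB -> XYZ primaries matrix (rows X, Y, Z). The Y row doubles as the
# luminance used for grayscale conversion in segmentation.
.rgb_xyz_matrix <- matrix(
  c(0.607, 0.174, 0.200,
    0.299, 0.587, 0.114,
    0.000, 0.066, 1.116),
  nrow = 3, byrow = TRUE
)

#' RGB to XYZ conversion
#'
#' Linear map of RGB onto CIE XYZ tristimulus values.
#'
#' @param rgb n x 3 matrix of RGB pixels in `[0, 1]`.
#' @return n x 3 matrix with columns `x`, `y`, `z`.
#' @export
rgb_to_xyz <- function(rgb) {
  rgb <- .as_pixel_matrix(rgb)
  if (any(rgb < 0 | rgb > 1)) stop("RGB values must lie in [0, 1]")
  out <- rgb %*% t(.rgb_xyz_matrix)
  colnames(out) <- c("x", "y", "z")
  out
}

#' XYZ to CIE L*u*v* conversion
#'
#' Lightness uses the standard two-branch cube-root law on `y = Y / Y0`:
#' `L = 116 y^(1/3) - 16` above `y = 0.008856`, `L = 903.3 y` below (the two
#' branches agree to about 1e-3 at the cut). Chromaticities are taken from
#' `u' = 4X / D` and `v' = 6Y / D` with `D = X + 15Y + 3Z`, giving
#' `u* = 13 L (u' - u0)` and `v* = 13 L (v' - v0)`. The `6Y` numerator is the
#' package's primary convention; `v_prime = "cie1976"` switches to the CIE 1976
#' `9Y / D` definition that the default `v0` constant corresponds to.
#' Black (`D = 0` or `L = 0`) maps to `(0, 0, 0)`.
#'
#' @param xyz n x 3 matrix of nonnegative XYZ pixels.
#' @param wp white point, as from [white_point()].
#' @param v_prime `"as_printed"` (v' = 6Y/D, the default) or `"cie1976"`
#'   (v' = 9Y/D).
#' @return n x 3 matrix with columns `l`, `u`, `v`.
#' @export
xyz_to_luv <- function(xyz, wp = white_point(),
                       v_prime = c("as_printed", "cie1976")) {
  v_prime <- match.arg(v_prime)
  xyz <- .as_pixel_matrix(xyz)
  if (any(xyz < 0)) stop("XYZ values must be nonnegative")
  x <- xyz[, 1L]; y0 <- xyz[, 2L]; z <- xyz[, 3L]
  y <- y0 / wp$Y0
  l <- ifelse(y > 0.008856, 116 * y^(1 / 3) - 16, 903.3 * y)
  d <- x + 15 * y0 + 3 * z
  vnum <- if (v_prime == "as_printed") 6 else 9
  safe_d <- ifelse(d == 0, 1, d)
  u <- 13 * l * (4 * x / safe_d - wp$u0)
  v <- 13 * l * (vnum * y0 / safe_d - wp$v0)
  zero <- d == 0 | l == 0
  u[zero] <- 0
  v[zero] <- 0
  out <- cbind(l = l, u = u, v = v)
  rownames(out) <- NULL
  out
}

.REPRESENTATIONS <- c("hsv", "luv", "hs", "uv")

#' Project a full color space onto a feature representation
#'
#' The pipeline uses four representations: the full `hsv` and `luv` triples,
#' and the chroma-only projections `hs` (hue, saturation) and `uv`
#' (u*, v*), which discard the lightness axis entirely.
#'
#' @param p n x 3 matrix in the full space matching `representation`
#'   (HSV for `"hsv"`/`"hs"`, LUV for `"luv"`/`"uv"`).
#' @param representation one of `"hsv"`, `"luv"`, `"hs"`, `"uv"`.
#' @return n x d matrix, d = 3 for the full spaces and 2 for the projections.
#' @export
project_representation <- function(p, representation) {
  representation <- match.arg(tolower(representation), .REPRESENTATIONS)
  p <- .as_pixel_matrix(p)
  cols <- colnames(p)
  need <- switch(representation,
    hsv = , hs = c("h", "s", "v"),
    luv = , uv = c("l", "u", "v")
  )
  if (!is.null(cols) && !identical(cols, need)) {
    stop("input is tagged '", paste(cols, collapse = ""),
         "' but representation '", representation, "' needs '",
         paste(need, collapse = ""), "'")
  }
  switch(representation,
    hsv = p,
    luv = p,
    hs  = p[, 1:2, drop = FALSE],
    uv  = p[, 2:3, drop = FALSE]
  )
}

#' Transform RGB pixels into a feature representation
#'
#' Convenience composition of [rgb_to_hsv()] / [rgb_to_xyz()] +
#' [xyz_to_luv()] with [project_representation()].
#'
#' @inheritParams rgb_to_hsv
#' @inheritParams project_representation
#' @param wp white point for the LUV route.
#' @param v_prime passed to [xyz_to_luv()].
#' @return n x d matrix in the requested representation.
#' @export
transform_pixels <- function(rgb, representation, wp = white_point(),
                             v_prime = "as_printed") {
  representation <- match.arg(tolower(representation), .REPRESENTATIONS)
  if (representation %in% c("hsv", "hs")) {
    project_representation(rgb_to_hsv(rgb), representation)
  } else {
    project_representation(xyz_to_luv(rgb_to_xyz(rgb), wp, v_prime),
                           representation)
  }
}

#' Dimensionality of a feature representation
#' @inheritParams project_representation
#' @return 2 or 3.
#' @export
representation_dim <- function(representation) {
  representation <- match.arg(tolower(representation), .REPRESENTATIONS)
  if (representation %in% c("hsv", "luv")) 3L else 2L
}
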