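# Independent straight-from-the-definitions oracles, written before the
# package implementations they check. All are deliberately scalar / loop
# based and share no code with the package.

# HSV of one RGB triple
oracle_hsv <- function(r, g, b) {
  v <- max(r, g, b)
  cc <- v - min(r, g, b)
  s <- if (cc == 0) 0 else cc / v
  h <- if (cc == 0) 0 else {
    a <- atan2(sqrt(3) * (g - b), 2 * r - g - b)
    if (a < 0) a + 2 * pi else a
  }
  c(h, s, v)
}

# XYZ of one RGB triple
oracle_xyz <- function(r, g, b) {
  c(0.607 * r + 0.174 * g + 0.200 * b,
    0.299 * r + 0.587 * g + 0.114 * b,
    0.066 * g + 1.116 * b)
}

# L*u*v* of one XYZ triple (v' = 6Y/D convention, Y0 = 1)
oracle_luv <- function(x, y, z, u0 = 0.19793943, v0 = 0.46831096) {
  l <- if (y > 0.008856) 116 * y^(1 / 3) - 16 else 903.3 * y
  d <- x + 15 * y + 3 * z
  if (d == 0 || l == 0) return(c(l, 0, 0))
  c(l, 13 * l * (4 * x / d - u0), 13 * l * (6 * y / d - v0))
}

# distance to the RGB diagonal via the explicit cross product with (1,1,1)
oracle_diag_dist <- function(p) {
  u <- c(1, 1, 1)
  cr <- c(u[2] * p[3] - u[3] * p[2],
          u[3] * p[1] - u[1] * p[3],
          u[1] * p[2] - u[2] * p[1])
  sqrt(sum(cr^2)) / sqrt(sum(u^2))
}

# exhaustive Otsu: maximize between-class variance over all 255 cuts of the
# 256-level quantization; lowest maximizing level wins
oracle_otsu <- function(values) {
  lo <- min(values); hi <- max(values)
  lev <- pmin(floor((values - lo) / (hi - lo) * 256), 255)
  centers <- lo + (0:255) / 255 * (hi - lo)
  best_t <- NA; best_v <- -Inf
  for (t in 0:254) {
    in0 <- lev <= t
    n0 <- sum(in0); n1 <- sum(!in0)
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(lev); w1 <- n1 / length(lev)
    m0 <- mean(centers[lev[in0] + 1]); m1 <- mean(centers[lev[!in0] + 1])
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best_v + 1e-15) { best_v <- v; best_t <- t }
  }
  (centers[best_t + 1] + centers[best_t + 2]) / 2
}

# brute-force nearest centroid (squared Euclidean, lowest index on ties)
oracle_assign <- function(pixels, centroids) {
  apply(pixels, 1, function(p) {
    d <- apply(centroids, 1, function(ct) sum((p - ct)^2))
    which.min(d)
  })
}

# slow per-pixel local entropy with circular truncated neighborhoods
oracle_local_entropy <- function(g, r, nb = 256) {
  h <- nrow(g); w <- ncol(g)
  bins <- pmin(floor(g * nb), nb - 1)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    vals <- integer(0)
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 <= r^2) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          vals <- c(vals, bins[ii, jj])
        }
      }
    }
    p <- table(vals) / length(vals)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}
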