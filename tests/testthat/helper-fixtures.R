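# Hand-constructed planes and small generated fields shared across tests.
# Planes are matrices indexed [y + 1, x + 1]; pixel coords are 0-based.

# 5x5 plus sign: vertical and horizontal 5-pixel lines crossing at (2, 2)
plus_sign_plane <- function() {
  m <- matrix(0L, 5, 5)
  m[3, ] <- 1L  # horizontal line, y = 2
  m[, 3] <- 1L  # vertical line, x = 2
  m
}

# 5x5 X: both diagonals, crossing at (2, 2)
x_cross_plane <- function() {
  m <- matrix(0L, 5, 5)
  for (i in 0:4) {
    m[i + 1L, i + 1L] <- 1L
    m[i + 1L, 5L - i] <- 1L
  }
  m
}

# horizontal line of `len` pixels at row y0 starting at column x0 (0-based)
line_plane <- function(h, w, y0, x0, len) {
  m <- matrix(0L, h, w)
  m[y0 + 1L, (x0 + 1L):(x0 + len)] <- 1L
  m
}

pixel_set <- function(plane) {
  idx <- which(plane == 1L, arr.ind = TRUE)
  s <- sprintf("%d,%d", idx[, 2L] - 1L, idx[, 1L] - 1L)
  sort(s)
}

seg_pixel_strings <- function(seg) {
  sort(sprintf("%d,%d", seg$pixels[, "x"], seg$pixels[, "y"]))
}

# absolute difference on the axial circle, degrees in [0, 90]
axial_delta <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# brute-force orientation oracle: scan 0.001-degree-spaced candidate axes
# for maximal projected variance, then place the vertex of the parabola
# through the three best grid samples (sub-grid interpolation from sampled
# values only). Independent of the atan2/moment route under test.
oracle_axis <- function(pixels, coarse_step = 0.001) {
  x <- pixels[, 1] - mean(pixels[, 1])
  y <- pixels[, 2] - mean(pixels[, 2])
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  grid <- seq(0, 180 - coarse_step, by = coarse_step)
  t <- grid * pi / 180
  v <- cos(t)^2 * sxx + 2 * cos(t) * sin(t) * sxy + sin(t)^2 * syy
  i <- which.max(v)
  n <- length(grid)
  v1 <- v[if (i == 1L) n else i - 1L]
  v2 <- v[i]
  v3 <- v[if (i == n) 1L else i + 1L]
  denom <- v1 - 2 * v2 + v3
  delta <- if (denom == 0) 0 else 0.5 * (v1 - v3) / denom * coarse_step
  (grid[i] + delta) %% 180
}

# fraction of second-moment energy along the preferred axis; ~0 means no
# preferred axis (the oracle's parabola is then numerically flat)
segment_anisotropy <- function(pixels) {
  x <- pixels[, 1] - mean(pixels[, 1])
  y <- pixels[, 2] - mean(pixels[, 2])
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  if (sxx + syy == 0) return(0)
  sqrt((sxx - syy)^2 + 4 * sxy^2) / (sxx + syy)
}

# random real-coordinate pixel cloud with a preferred axis
random_anisotropic_segment <- function(n = 30) {
  ang <- stats::runif(1, 0, 180) * pi / 180
  long <- stats::rnorm(n, 0, 6)
  short <- stats::rnorm(n, 0, 0.8)
  cbind(x = long * cos(ang) - short * sin(ang),
        y = long * sin(ang) + short * cos(ang))
}

two_cluster_field <- function(seed = 11L, n_fibers = 200L, kappa = 100) {
  synthetic_field_spec(
    width = 600L, height = 600L, n_sections = 8L,
    clusters = list(
      cluster_spec(30, kappa, n_fibers, c(30, 30, 280, 570)),
      cluster_spec(120, kappa, n_fibers, c(320, 30, 570, 570))),
    seed = seed, allow_crossings = FALSE)
}
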