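# Planar projective geometry helpers shared by the renderer, the detector
# and the synthetic-scene generator.
#
# Coordinate convention (package-wide): continuous image coordinates in
# pixels, origin at the top-left image corner, x rightward, y downward.
# Pixel (row r, col c) of a frame matrix covers [c-1, c) x [r-1, r); its
# center is (c - 0.5, r - 0.5).

# Fit the 3x3 homography mapping src (n>=4 x 2) to dst (n x 2) by the direct
# linear transform; exact for n = 4 points in general position.
fit_homography <- function(src, dst) {
  stopifnot(nrow(src) >= 4, all(dim(src) == dim(dst)))
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H / H[3, 3]
}

# Apply a homography to an n x 2 point matrix.
apply_homography <- function(H, pts) {
  pts <- rbind2cols(pts)
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

rbind2cols <- function(pts) {
  if (is.null(dim(pts))) matrix(pts, ncol = 2, byrow = TRUE) else pts
}

# Signed polygon area via the shoelace formula. In image coordinates
# (y down) a positive value means the vertices run clockwise on screen.
polygon_area_signed <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(pts) abs(polygon_area_signed(pts))

# Reorder quad vertices clockwise on screen, starting from the vertex
# closest to the top-left (smallest x + y). Deterministic for tests.
order_quad_clockwise <- function(pts) {
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  pts <- pts[order(ang), , drop = FALSE]  # increasing angle = clockwise (y down)
  start <- which.min(pts[, 1] + pts[, 2])
  idx <- ((seq_len(4) + start - 2L) %% 4L) + 1L
  pts[idx, , drop = FALSE]
}

is_convex_quad <- function(pts) {
  z <- numeric(4)
  for (i in 1:4) {
    a <- pts[i, ]; b <- pts[(i %% 4) + 1, ]; cpt <- pts[((i + 1) %% 4) + 1, ]
    z[i] <- (b[1] - a[1]) * (cpt[2] - b[2]) - (b[2] - a[2]) * (cpt[1] - b[1])
  }
  all(z > 0) || all(z < 0)
}

# Distance from each point to a segment [a, b].
dist_point_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

# Minimum distance from each point to the boundary of a polygon.
dist_point_polygon <- function(pts, poly) {
  n <- nrow(poly)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1, ]
    d <- pmin(d, dist_point_segment(pts, a, b))
  }
  d
}

# Intersection of two lines, each given as (point, direction).
line_intersection <- function(p1, d1, p2, d2) {
  A <- cbind(d1, -d2)
  if (abs(det(A)) < 1e-12) return(NULL)
  t <- solve(A, p2 - p1)
  p1 + t[1] * d1
}

# Total-least-squares line through points: returns list(point, direction).
fit_line_tls <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  v <- svd(x, nu = 0, nv = 2)$v[, 1]
  list(point = ctr, dir = v)
}

# Bilinear interpolation of frame values at continuous (x, y) positions.
# Coordinates are clamped to the valid pixel-center range.
bilinear_sample <- function(frame, x, y) {
  h <- nrow(frame); w <- ncol(frame)
  x <- pmin(pmax(x, 0.5), w - 0.5) - 0.5   # to pixel-center grid, 0-based
  y <- pmin(pmax(y, 0.5), h - 0.5) - 0.5
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * h + y0 + 1
  v00 <- frame[i00];         v10 <- frame[i00 + h]
  v01 <- frame[i00 + 1];     v11 <- frame[i00 + h + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# Nearest-pixel lookup at continuous coordinates; returns NA outside frame.
pixel_at <- function(frame, x, y) {
  h <- nrow(frame); w <- ncol(frame)
  cc <- floor(x) + 1L; rr <- floor(y) + 1L
  ok <- cc >= 1L & cc <= w & rr >= 1L & rr <= h
  out <- rep(NA_real_, length(x))
  out[ok] <- frame[cbind(rr[ok], cc[ok])]
  out
}
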