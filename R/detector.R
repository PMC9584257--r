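# Marker detection: adaptive thresholding, candidate-quad extraction,
# perspective unwarping and code matching against the dictionary.

#' Detector parameters
#'
#' Tunables for [detect_markers()] and its stages. All sizes are in pixels
#' unless noted.
#'
#' @param adaptive_window Side of the sliding window used by the adaptive
#'   mean threshold (odd; default 15).
#' @param min_area_frac Minimum candidate quad area as a fraction of the
#'   frame area (default 1e-4).
#' @param max_area_frac Maximum candidate area fraction (default 0.95).
#' @param approx_tol_frac Polygon approximation tolerance as a fraction of
#'   the contour perimeter (default 0.03): contour points may deviate from
#'   the fitted quad by at most this distance.
#' @param aspect_max Maximum ratio of longest to shortest quad edge
#'   (default 4): markers are square, so wildly skewed quads are dropped.
#' @param max_correction Bit-error budget when matching decoded bits against
#'   the dictionary; `NULL` (default) uses
#'   `floor((min_distance - 1) / 2)` of the dictionary in use.
#' @param cell_samples Sample points per axis within each cell's central 50%
#'   area when reading bits (default 3, i.e. a 3 x 3 vote).
#' @param min_contrast Minimum intensity range across the sampled cells for
#'   a candidate to count as a code at all (default 0.1): uniform dark blobs
#'   carry no code structure.
#' @param min_side Minimum quad edge length in pixels (default 8): below
#'   roughly one pixel per marker cell a candidate cannot be decoded, so
#'   smaller blobs are dropped before any fitting.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(adaptive_window = 15L,
                            min_area_frac = 1e-4,
                            max_area_frac = 0.95,
                            approx_tol_frac = 0.03,
                            aspect_max = 4,
                            max_correction = NULL,
                            cell_samples = 3L,
                            min_contrast = 0.1,
                            min_side = 8) {
  structure(list(adaptive_window = as.integer(adaptive_window),
                 min_area_frac = min_area_frac,
                 max_area_frac = max_area_frac,
                 approx_tol_frac = approx_tol_frac,
                 aspect_max = aspect_max,
                 max_correction = max_correction,
                 cell_samples = as.integer(cell_samples),
                 min_contrast = min_contrast,
                 min_side = min_side),
            class = "detector_params")
}

# Sliding-window box mean via integral image; windows are clipped at the
# frame edge and normalized by the true count, so no padding bias.
box_mean <- function(m, w) {
  h <- nrow(m); wd <- ncol(m)
  r <- w %/% 2L
  S <- matrix(0, h + 1L, wd + 1L)
  S[-1L, -1L] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(wd) - r, 1L); c2 <- pmin(seq_len(wd) + r, wd)
  tot <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  tot / cnt
}

#' Adaptive mean threshold
#'
#' Binarizes a grayscale frame by comparing each pixel with the mean of a
#' sliding window centered on it: pixels at or above the local mean map to 1
#' (light), pixels below to 0 (dark). The output is invariant under affine
#' intensity rescaling of the input with positive gain. If the window does
#' not fit in the frame, a global mean threshold is used instead and a
#' warning is raised.
#'
#' @param frame Grayscale matrix.
#' @param params A [detector_params()] list.
#' @return Integer matrix of 0/1, same size as `frame`.
#' @export
threshold_image <- function(frame, params = detector_params()) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0)
    stop("`frame` must be a non-empty numeric matrix")
  w <- params$adaptive_window
  # tolerance absorbs accumulation error in the integral image, so exact
  # ties (uniform regions) land on the light side deterministically
  eps <- 1e-9 * max(1, max(abs(frame)))
  if (w > nrow(frame) || w > ncol(frame)) {
    warning("adaptive window larger than frame; using global threshold")
    return((frame >= mean(frame) - eps) * 1L)
  }
  (frame >= box_mean(frame, w) - eps) * 1L
}

#' Extract candidate quadrilaterals from a binary image
#'
#' Finds connected dark regions, simplifies each outer contour to a
#' quadrilateral (convex-hull vertex reduction followed by a fit-quality
#' check against the full contour), and keeps convex 4-gons within the area
#' and aspect bounds. Corners are ordered clockwise and refined to sub-pixel
#' precision by intersecting total-least-squares lines fitted to the contour
#' edges.
#'
#' @param binary 0/1 matrix from [threshold_image()].
#' @param params A [detector_params()] list.
#' @return List of 4 x 2 corner matrices (columns x, y), possibly empty.
#' @export
extract_quads <- function(binary, params = detector_params()) {
  h <- nrow(binary); w <- ncol(binary)
  frame_area <- h * w
  min_area <- params$min_area_frac * frame_area
  max_area <- params$max_area_frac * frame_area
  dark <- EBImage::Image(t(binary == 0) * 1)
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  min_npix <- max(9, min_area * 0.5, 3 * params$min_side)  # border ring pixels
  keep <- which(sizes >= min_npix & sizes <= max_area)
  if (length(keep) == 0) return(list())
  # drop all other components before contour tracing: noise speckle is
  # plentiful and tracing it dominates runtime otherwise
  drop_idx <- setdiff(seq_along(sizes), keep)
  if (length(drop_idx))
    lab <- EBImage::rmObjects(lab, drop_idx, reenumerate = TRUE)
  contours <- EBImage::ocontour(lab)
  quads <- list()
  for (k in seq_along(contours)) {
    oc <- contours[[k]]
    if (is.null(oc) || nrow(oc) < 8) next
    pts <- cbind(oc[, 1] + 0.5, oc[, 2] + 0.5)  # pixel centers, continuous
    quad <- contour_to_quad(pts, params, min_area, max_area)
    if (is.null(quad)) next
    quads[[length(quads) + 1L]] <- quad
  }
  quads
}

# Reduce a closed contour to a convex quadrilateral, or NULL if the contour
# is not well approximated by one.
contour_to_quad <- function(pts, params, min_area = 0, max_area = Inf) {
  hull_idx <- grDevices::chull(pts)          # counterclockwise in y-up = cw on screen
  hull <- pts[hull_idx, , drop = FALSE]
  if (nrow(hull) < 4) return(NULL)
  # Cheap rejects before any fitting: a near-convex region has contour
  # length close to its hull perimeter; ragged noise blobs are much longer.
  hull_perim <- sum(sqrt(rowSums(
    (hull[c(seq_len(nrow(hull))[-1], 1), , drop = FALSE] - hull)^2)))
  if (nrow(pts) > 1.4 * hull_perim + 8) return(NULL)
  # Iteratively drop the hull vertex whose removal loses the least area.
  while (nrow(hull) > 4) {
    n <- nrow(hull)
    loss <- vapply(seq_len(n), function(i) {
      a <- hull[((i - 2) %% n) + 1, ]
      b <- hull[i, ]
      cpt <- hull[(i %% n) + 1, ]
      abs((b[1] - a[1]) * (cpt[2] - a[2]) - (b[2] - a[2]) * (cpt[1] - a[1])) / 2
    }, numeric(1))
    hull <- hull[-which.min(loss), , drop = FALSE]
  }
  quad <- order_quad_clockwise(hull)
  if (!is_convex_quad(quad)) return(NULL)
  edges <- sqrt(rowSums((quad[c(2, 3, 4, 1), ] - quad)^2))
  if (any(edges < params$min_side)) return(NULL)
  if (max(edges) / min(edges) > params$aspect_max) return(NULL)
  a <- polygon_area(quad)
  if (a < min_area || a > max_area) return(NULL)
  # Quality: the whole contour must hug the quad boundary.
  perim <- sum(edges)
  tol <- max(1.5, params$approx_tol_frac * perim)
  d <- dist_point_polygon(pts, quad)
  if (max(d) > tol) return(NULL)
  refine_quad_corners(pts[d < 1.5, , drop = FALSE], quad)
}

# Sub-pixel corners: fit a line to the contour points backing each edge
# (corners excluded), push each line half a pixel outward (contour points
# are centers of boundary pixels, which sit half a pixel inside the true
# region edge), and intersect adjacent lines.
refine_quad_corners <- function(pts, quad) {
  ctr <- colMeans(quad)
  lines <- vector("list", 4)
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[(i %% 4) + 1, ]
    d <- dist_point_segment(pts, a, b)
    elen <- sqrt(sum((b - a)^2))
    sel <- d < 1.5
    if (sum(sel) >= 4) {
      # drop points near the corners where rasterization rounds the edge
      t <- ((pts[sel, 1] - a[1]) * (b[1] - a[1]) +
            (pts[sel, 2] - a[2]) * (b[2] - a[2])) / elen^2
      core <- t > 0.15 & t < 0.85
      if (sum(core) >= 3) {
        ln <- fit_line_tls(pts[sel, , drop = FALSE][core, , drop = FALSE])
        nrm <- c(-ln$dir[2], ln$dir[1])
        if (sum((ln$point - ctr) * nrm) < 0) nrm <- -nrm  # point outward
        ln$point <- ln$point + 0.5 * nrm
        lines[[i]] <- ln
      }
    }
    if (is.null(lines[[i]])) {
      dir <- (b - a); dir <- dir / sqrt(sum(dir^2))
      lines[[i]] <- list(point = (a + b) / 2, dir = dir)
    }
  }
  out <- quad
  for (i in 1:4) {
    prev <- lines[[((i - 2) %% 4) + 1]]
    cur <- lines[[i]]
    p <- line_intersection(prev$point, prev$dir, cur$point, cur$dir)
    if (!is.null(p) && sqrt(sum((p - quad[i, ])^2)) < 4) out[i, ] <- p
  }
  if (!is_convex_quad(out)) return(quad)
  out
}

#' Decode a candidate quadrilateral
#'
#' Unwarps the quad to the canonical marker square and samples every cell
#' over its central 50% area on the grayscale frame, classifying cells
#' against the midpoint of the sampled intensity range (large solid regions
#' hollow out under adaptive thresholding, so bits are read from intensity,
#' not from the binarized image). The candidate is rejected unless the
#' sampled region has real contrast and the whole border ring is black; the
#' inner bits are matched against all dictionary codes under all four
#' rotations, and the unique best match within the bit-correction budget is
#' accepted. Distance ties between different ids are rejected.
#'
#' @param frame Grayscale matrix.
#' @param quad 4 x 2 corner matrix, clockwise.
#' @param dict A `marker_dictionary`.
#' @param params A [detector_params()] list.
#' @return `NULL` on rejection, else a list with `id`, `hamming` (bits
#'   corrected), and `rotation` (clockwise quarter-turns of the marker
#'   relative to the supplied corner order).
#' @export
decode_quad <- function(frame, quad, dict, params = detector_params()) {
  g <- dict$grid_size
  total <- g + 2L
  S <- total  # canonical square in cell units
  H <- fit_homography(matrix(c(0, 0, S, 0, S, S, 0, S), ncol = 2, byrow = TRUE),
                      quad)
  ns <- params$cell_samples
  off <- (seq_len(ns) - (ns + 1) / 2) / ns * 0.5 + 0.5   # within central 50%
  cell_xy <- expand.grid(cx = seq_len(total) - 1, cy = seq_len(total) - 1)
  samp <- expand.grid(fx = off, fy = off)
  px <- rep(cell_xy$cx, each = nrow(samp)) + samp$fx
  py <- rep(cell_xy$cy, each = nrow(samp)) + samp$fy
  img_pts <- apply_homography(H, cbind(px, py))
  if (any(img_pts[, 1] < 0 | img_pts[, 1] > ncol(frame) |
            img_pts[, 2] < 0 | img_pts[, 2] > nrow(frame)))
    return(NULL)                         # sampling outside the frame
  v <- bilinear_sample(frame, img_pts[, 1], img_pts[, 2])
  means <- colMeans(matrix(v, nrow = nrow(samp)))
  if (max(means) - min(means) < params$min_contrast)
    return(NULL)                         # featureless dark blob, not a code
  thr <- (max(means) + min(means)) / 2
  cellv <- matrix(NA_real_, total, total)
  cellv[cbind(cell_xy$cy + 1L, cell_xy$cx + 1L)] <- means
  cells <- (cellv >= thr) * 1L
  border <- c(cells[1, ], cells[total, ], cells[, 1], cells[, total])
  if (any(border != 0)) return(NULL)     # white edge must isolate a black ring
  observed <- cells[2:(total - 1), 2:(total - 1), drop = FALSE]
  budget <- params$max_correction
  if (is.null(budget)) budget <- max(0L, (dict$min_distance - 1L) %/% 2L)
  best_d <- Inf; best_id <- NA_integer_; best_rot <- NA_integer_; tie <- FALSE
  for (i in seq_along(dict$codes)) {
    for (k in 0:3) {
      d <- sum(observed != rotate_code(dict$codes[[i]], k))
      if (d < best_d) {
        best_d <- d; best_id <- i - 1L; best_rot <- k; tie <- FALSE
      } else if (d == best_d && (i - 1L) != best_id) {
        tie <- TRUE
      }
    }
  }
  if (tie || best_d > budget) return(NULL)
  list(id = best_id, hamming = as.integer(best_d),
       rotation = as.integer(best_rot))
}

#' Detect dictionary markers in a frame
#'
#' Runs the full pipeline: grayscale conversion, adaptive thresholding,
#' candidate-quad extraction, decoding, duplicate suppression (the
#' lowest-Hamming, then largest-area detection wins for overlapping quads of
#' the same id) and deterministic ordering by id, then center y, then x.
#'
#' @param frame Grayscale matrix or H x W x 3 RGB array.
#' @param dict A `marker_dictionary`.
#' @param params A [detector_params()] list.
#' @return A `marker_detections` object: list of detections, each with `id`,
#'   `corners` (4 x 2, clockwise from the marker's decoded top-left),
#'   `center` (mean of corners), and `hamming`. Use `as.data.frame()` for a
#'   tabular view.
#' @export
detect_markers <- function(frame, dict, params = detector_params()) {
  frame <- to_gray(frame)
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0)
    stop("`frame` must be a non-empty numeric matrix or RGB array")
  binary <- threshold_image(frame, params)
  quads <- extract_quads(binary, params)
  dets <- list()
  for (q in quads) {
    dec <- decode_quad(frame, q, dict, params)
    if (is.null(dec)) next
    # rotate corner order so corner 1 is the marker's own top-left
    idx <- ((seq_len(4) - 1 + dec$rotation) %% 4) + 1
    corners <- q[idx, , drop = FALSE]
    dets[[length(dets) + 1L]] <- list(
      id = dec$id, corners = corners,
      center = colMeans(corners), hamming = dec$hamming,
      area = polygon_area(corners))
  }
  dets <- suppress_duplicates(dets)
  dets <- dets[order(vapply(dets, `[[`, numeric(1), "id"),
                     vapply(dets, function(d) d$center[2], numeric(1)),
                     vapply(dets, function(d) d$center[1], numeric(1)))]
  structure(dets, class = "marker_detections")
}

# Two detections are duplicates when their centers are closer than half the
# smaller quad's side; keep the lowest hamming, then the largest area.
suppress_duplicates <- function(dets) {
  if (length(dets) < 2) return(dets)
  keep <- rep(TRUE, length(dets))
  for (i in seq_along(dets)) {
    if (!keep[i]) next
    for (j in seq_along(dets)) {
      if (i == j || !keep[j] || !keep[i]) next
      si <- sqrt(dets[[i]]$area); sj <- sqrt(dets[[j]]$area)
      d <- sqrt(sum((dets[[i]]$center - dets[[j]]$center)^2))
      if (d < 0.5 * min(si, sj)) {
        better_i <- dets[[i]]$hamming < dets[[j]]$hamming ||
          (dets[[i]]$hamming == dets[[j]]$hamming &&
             dets[[i]]$area >= dets[[j]]$area)
        if (better_i) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
  }
  dets[keep]
}

#' @export
print.marker_detections <- function(x, ...) {
  cat(sprintf("%d marker detection(s)\n", length(x)))
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.marker_detections <- function(x, ...) {
  if (length(x) == 0)
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      hamming = integer()))
  data.frame(
    id = vapply(x, `[[`, numeric(1), "id"),
    x = vapply(x, function(d) d$center[1], numeric(1)),
    y = vapply(x, function(d) d$center[2], numeric(1)),
    hamming = vapply(x, `[[`, numeric(1), "hamming"))
}
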