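# Synthetic ground-truth scenes: markers warped onto textured backgrounds at
# known poses, with sensor noise, blur, illumination changes and "fur"
# occlusion, plus simulated human coders. Everything is seeded, so every
# other module can be tested against exact ground truth without recordings.

#' Describe one subject's marker trajectory
#'
#' Builds the per-frame pose table for one collar marker. Scalars are
#' recycled across frames, so a static marker is
#' `subject_track(id, n_frames, x = 80, y = 60, side = 48)`.
#'
#' @param id Dictionary id worn by this subject.
#' @param n_frames Frames in the scene.
#' @param x,y Marker center (pixels).
#' @param side On-screen side of the marker's black border square (pixels).
#' @param theta In-plane rotation (radians, clockwise).
#' @param tilt Out-of-plane tilt (radians) producing perspective.
#' @param visible Logical; `FALSE` marks the marker off-screen that frame.
#' @param using Latent behaviour state: `TRUE` when the subject is actively
#'   using the resource (as opposed to merely being present near it). Kept
#'   separate from visibility because presence without use is a documented
#'   failure mode of ROI-based tracking.
#' @return A data.frame with one row per frame (`frame` is 0-based).
#' @export
subject_track <- function(id, n_frames, x, y, side, theta = 0, tilt = 0,
                          visible = TRUE, using = FALSE) {
  data.frame(frame = seq_len(n_frames) - 1L, id = id,
             x = rep_len(x, n_frames), y = rep_len(y, n_frames),
             side = rep_len(side, n_frames),
             theta = rep_len(theta, n_frames),
             tilt = rep_len(tilt, n_frames),
             visible = rep_len(visible, n_frames),
             using = rep_len(using, n_frames))
}

#' Specify a synthetic scene
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames.
#' @param fps Frames per second (default 30).
#' @param dict Marker dictionary to render from.
#' @param rois List of [roi()] objects (may be empty).
#' @param subjects List of [subject_track()] tables.
#' @param background_level Mean background intensity in \[0, 1\].
#' @param texture_sd Standard deviation of the static background texture.
#' @param bowls Optional list of dark ellipses `list(x, y, rx, ry, level)`
#'   drawn on the background (bowl-like resources).
#' @param noise_sd Per-frame Gaussian sensor noise sd (0 = none).
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param gain,offset Illumination model applied after compositing:
#'   `gain * frame + offset`, then clipped to \[0, 1\].
#' @param occlusions Optional list of episodes
#'   `list(id, from, to, fraction)`: an opaque soft-edged "fur" ellipse
#'   covering `fraction` of the marker's area on frames `from..to` (0-based,
#'   inclusive).
#' @param quiet_zone_cells Quiet-zone rings on the rendered markers.
#' @param seed Integer seed; frames and ground truth are a pure function of
#'   the spec including this seed.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width, height, n_frames, fps = 30, dict,
                       rois = list(), subjects = list(),
                       background_level = 0.62, texture_sd = 0.02,
                       bowls = NULL, noise_sd = 0, blur_sigma = 0,
                       gain = 1, offset = 0, occlusions = NULL,
                       quiet_zone_cells = 1, seed = 1) {
  stopifnot(width >= 8, height >= 8, n_frames >= 0, fps > 0)
  structure(list(width = width, height = height, n_frames = n_frames,
                 fps = fps, dict = dict, rois = rois, subjects = subjects,
                 background_level = background_level, texture_sd = texture_sd,
                 bowls = bowls, noise_sd = noise_sd, blur_sigma = blur_sigma,
                 gain = gain, offset = offset, occlusions = occlusions,
                 quiet_zone_cells = quiet_zone_cells,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Homography mapping marker raster coordinates [0, S]^2 to the frame for a
# pose. The black border square ends up with side `side` px (at tilt 0),
# rotated by theta and tilted about the horizontal axis through the center.
pose_homography <- function(raster_side, quiet_zone_cells, grid_size,
                            x, y, side, theta, tilt) {
  total <- grid_size + 2 + 2 * quiet_zone_cells
  cpx <- raster_side / total
  border_px <- (grid_size + 2) * cpx
  scale <- side / border_px
  f <- 4 * side                       # focal length: moderate perspective
  src <- matrix(c(0, 0, raster_side, 0, raster_side, raster_side,
                  0, raster_side), ncol = 2, byrow = TRUE)
  ctr <- raster_side / 2
  p <- sweep(src, 2, c(ctr, ctr)) * scale
  ct <- cos(theta); st <- sin(theta)
  rot <- cbind(p[, 1] * ct - p[, 2] * st, p[, 1] * st + p[, 2] * ct)
  Z <- rot[, 2] * sin(tilt)
  Y <- rot[, 2] * cos(tilt)
  X <- rot[, 1]
  dst <- cbind(f * X / (f + Z) + x, f * Y / (f + Z) + y)
  fit_homography(src, dst)
}

# True frame coordinates of the border-square corners, clockwise from the
# marker's own top-left (matches the detector's corner convention).
pose_true_corners <- function(H, raster_side, quiet_zone_cells, grid_size) {
  total <- grid_size + 2 + 2 * quiet_zone_cells
  cpx <- raster_side / total
  q <- quiet_zone_cells * cpx
  src <- matrix(c(q, q, raster_side - q, q, raster_side - q, raster_side - q,
                  q, raster_side - q), ncol = 2, byrow = TRUE)
  apply_homography(H, src)
}

# Composite a warped marker raster onto a frame (bilinear, antialiased).
composite_marker <- function(frame, raster, H) {
  corners <- apply_homography(
    H, matrix(c(0, 0, ncol(raster), 0, ncol(raster), nrow(raster),
                0, nrow(raster)), ncol = 2, byrow = TRUE))
  Hi <- solve(H)
  c0 <- max(1L, floor(min(corners[, 1])) - 1L)
  c1 <- min(ncol(frame), ceiling(max(corners[, 1])) + 1L)
  r0 <- max(1L, floor(min(corners[, 2])) - 1L)
  r1 <- min(nrow(frame), ceiling(max(corners[, 2])) + 1L)
  if (c0 > c1 || r0 > r1) return(frame)
  cols <- c0:c1; rows <- r0:r1
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  src <- apply_homography(Hi, cbind(px, py))
  S <- nrow(raster)
  inside <- src[, 1] >= 0 & src[, 1] <= S & src[, 2] >= 0 & src[, 2] <= S
  if (!any(inside)) return(frame)
  vals <- bilinear_sample(raster, src[inside, 1], src[inside, 2])
  block <- frame[rows, cols]
  block[inside] <- vals
  frame[rows, cols] <- block
  frame
}

# Draw an opaque soft-edged ellipse (fur tuft) centered at (x, y).
draw_ellipse <- function(frame, x, y, rx, ry, level, soft = 1.5) {
  c0 <- max(1L, floor(x - rx - soft)); c1 <- min(ncol(frame), ceiling(x + rx + soft))
  r0 <- max(1L, floor(y - ry - soft)); r1 <- min(nrow(frame), ceiling(y + ry + soft))
  if (c0 > c1 || r0 > r1) return(frame)
  cols <- c0:c1; rows <- r0:r1
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  d <- sqrt(((px - x) / rx)^2 + ((py - y) / ry)^2)
  alpha <- pmin(1, pmax(0, (1 + soft / max(rx, ry) - d) / (soft / max(rx, ry))))
  block <- frame[rows, cols]
  frame[rows, cols] <- block * (1 - alpha) + level * alpha
  frame
}

#' Generate a synthetic scene with ground truth
#'
#' Renders each subject's marker into every frame by a per-frame homography,
#' applies occlusion, illumination, blur and sensor noise, and records the
#' exact ground truth (true centers, corner quads, ROI membership by true
#' center, latent behaviour state). Identical specs (including seed) produce
#' bit-identical frames; frames are generated lazily through
#' [scene_frame()], so long clips need no frame storage.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene` with elements `spec`, `truth`
#'   (data.frame: `frame`, `id`, `x`, `y`, `visible`, `occluded`, `rois`
#'   (semicolon-joined indices), `using`), `corners` (list of 4 x 2 true
#'   corner matrices, row-aligned with `truth`), and `n_frames`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  g <- spec$dict$grid_size
  total <- g + 2 + 2 * spec$quiet_zone_cells
  raster_side <- total * 16L  # 16 px per cell: smooth enough for bilinear warp
  rasters <- list()
  truth <- list(); corners <- list()
  for (s in spec$subjects) {
    key <- as.character(s$id[1])
    if (is.null(rasters[[key]]))
      rasters[[key]] <- rasterize_marker(dict_code(spec$dict, s$id[1]),
                                         raster_side, spec$quiet_zone_cells)
    for (i in seq_len(nrow(s))) {
      row <- s[i, ]
      if (row$side > min(spec$width, spec$height) * 2)
        stop("infeasible pose: marker larger than frame")
      occ <- occlusion_fraction(spec$occlusions, row$id, row$frame)
      if (row$visible) {
        H <- pose_homography(raster_side, spec$quiet_zone_cells, g,
                             row$x, row$y, row$side, row$theta, row$tilt)
        cr <- pose_true_corners(H, raster_side, spec$quiet_zone_cells, g)
        ctr <- colMeans(cr)
      } else {
        cr <- matrix(NA_real_, 4, 2)
        ctr <- c(row$x, row$y)
      }
      roi_idx <- assign_rois(ctr, spec$rois)
      truth[[length(truth) + 1L]] <- data.frame(
        frame = row$frame, id = row$id, x = ctr[1], y = ctr[2],
        visible = row$visible, occluded = occ > 0,
        rois = paste(roi_idx, collapse = ";"), using = row$using)
      corners[[length(corners) + 1L]] <- cr
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(), id = integer(), x = numeric(),
               y = numeric(), visible = logical(), occluded = logical(),
               rois = character(), using = logical())
  ord <- order(truth$frame, truth$id)
  structure(list(spec = spec, truth = truth[ord, , drop = FALSE],
                 corners = corners[ord], rasters = rasters,
                 raster_side = raster_side, n_frames = spec$n_frames),
            class = "synthetic_scene")
}

occlusion_fraction <- function(occlusions, id, frame) {
  if (is.null(occlusions)) return(0)
  for (ep in occlusions) {
    if (ep$id == id && frame >= ep$from && frame <= ep$to)
      return(ep$fraction)
  }
  0
}

#' Render one frame of a synthetic scene
#'
#' Pure function of the scene spec and the frame index: the background
#' texture is derived from the scene seed, and per-frame sensor noise from
#' `seed + 7919 * frame`, so lazy and eager generation agree bit for bit.
#'
#' @param scene A `synthetic_scene` from [generate_scene()].
#' @param frame 0-based frame index.
#' @return Grayscale frame matrix in \[0, 1\].
#' @export
scene_frame <- function(scene, frame) {
  spec <- scene$spec
  stopifnot(frame >= 0, frame < spec$n_frames)
  bg <- with_seed(spec$seed, {
    m <- matrix(spec$background_level, spec$height, spec$width)
    if (spec$texture_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, spec$texture_sd),
                      nrow(m), ncol(m))
    m
  })
  f <- bg
  if (!is.null(spec$bowls)) {
    for (b in spec$bowls)
      f <- draw_ellipse(f, b$x, b$y, b$rx, b$ry, b$level)
  }
  g <- spec$dict$grid_size
  for (s in spec$subjects) {
    row <- s[s$frame == frame, ]
    if (nrow(row) == 0 || !row$visible[1]) next
    row <- row[1, ]
    H <- pose_homography(scene$raster_side, spec$quiet_zone_cells, g,
                         row$x, row$y, row$side, row$theta, row$tilt)
    f <- composite_marker(f, scene$rasters[[as.character(row$id)]], H)
    occ <- occlusion_fraction(spec$occlusions, row$id, frame)
    if (occ > 0) {
      r <- row$side * sqrt(occ / pi)  # disc of area occ * side^2
      f <- draw_ellipse(f, row$x, row$y, r, r, level = 0.35)
    }
  }
  f <- spec$gain * f + spec$offset
  if (spec$blur_sigma > 0)
    f <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(f)),
                                             sigma = spec$blur_sigma)))
  if (spec$noise_sd > 0) {
    f <- f + with_seed(spec$seed + 7919L * frame,
                       matrix(stats::rnorm(length(f), 0, spec$noise_sd),
                              nrow(f), ncol(f)))
  }
  pmin(pmax(f, 0), 1)
}

#' Materialize all frames of a scene
#'
#' @param scene A `synthetic_scene`.
#' @return List of frame matrices.
#' @export
scene_frames <- function(scene) {
  lapply(seq_len(scene$n_frames) - 1L, function(i) scene_frame(scene, i))
}

#' Binary ground-truth series for one subject
#'
#' Extracts a per-unit 0/1 series from scene ground truth: either presence
#' of the true marker center in an ROI, or the latent using-the-resource
#' state (defined even while the marker is occluded).
#'
#' @param scene A `synthetic_scene`.
#' @param id Subject (marker) id.
#' @param what `"presence"` (true center inside `roi`) or `"using"` (latent
#'   behaviour state; `roi` then restricts to frames whose true center is in
#'   that ROI, or `NULL` for the raw state).
#' @param roi ROI index, or `NULL`.
#' @param resolution `"frame"` or `"second"`.
#' @return Integer 0/1 vector, unit 0 first (frames, or seconds via
#'   any-presence binning at the scene fps).
#' @export
truth_series <- function(scene, id, what = c("presence", "using"), roi = NULL,
                         resolution = c("frame", "second")) {
  what <- match.arg(what)
  resolution <- match.arg(resolution)
  tr <- scene$truth[scene$truth$id == id, ]
  v <- integer(scene$n_frames)
  if (nrow(tr)) {
    in_roi <- if (is.null(roi)) rep(TRUE, nrow(tr)) else
      vapply(strsplit(tr$rois, ";", fixed = TRUE),
             function(z) as.character(roi) %in% z, logical(1))
    on <- if (what == "presence") in_roi & tr$visible else tr$using & in_roi
    v[tr$frame[on] + 1L] <- 1L
  }
  if (resolution == "second") v <- downsample_any(v, scene$spec$fps)
  v
}

# Any-presence binning of a frame series into seconds.
downsample_any <- function(v, rate) {
  if (length(v) == 0) return(integer())
  sec <- (seq_along(v) - 1L) %/% as.integer(rate)
  as.integer(tapply(v, sec, max))
}

#' Simulate a human coder
#'
#' Corrupts binary ground-truth series the way a human coder errs: each
#' 1-unit is missed independently with `miss_rate`, each 0-unit is falsely
#' scored with `false_alarm_rate`, and each bout boundary shifts by a
#' uniform integer in `[-boundary_jitter, boundary_jitter]` units (bout
#' count is preserved: jittered bouts are clamped so they neither vanish nor
#' merge). Seeded and deterministic.
#'
#' @param truth Integer 0/1 vector, or a named list of them (each column of
#'   an ethogram coding).
#' @param miss_rate,false_alarm_rate Error probabilities in \[0, 1\].
#' @param boundary_jitter Maximum boundary shift in series units (>= 0).
#' @param seed Integer seed.
#' @return Same shape as `truth`: corrupted 0/1 vector, or a data.frame with
#'   `unit` (0-based) plus one column per list element.
#' @export
simulate_coder <- function(truth, miss_rate = 0, false_alarm_rate = 0,
                           boundary_jitter = 0, seed = 1) {
  stopifnot(miss_rate >= 0, miss_rate <= 1,
            false_alarm_rate >= 0, false_alarm_rate <= 1,
            boundary_jitter >= 0)
  if (is.list(truth) && !is.data.frame(truth)) {
    out <- lapply(seq_along(truth), function(i)
      simulate_coder(truth[[i]], miss_rate, false_alarm_rate,
                     boundary_jitter, seed + i))
    names(out) <- names(truth)
    return(data.frame(unit = seq_along(truth[[1]]) - 1L, out))
  }
  v <- as.integer(truth)
  with_seed(seed, {
    if (boundary_jitter > 0) v <- jitter_bouts(v, boundary_jitter)
    ones <- which(v == 1L); zeros <- which(v == 0L)
    if (miss_rate > 0 && length(ones))
      v[ones[stats::runif(length(ones)) < miss_rate]] <- 0L
    if (false_alarm_rate > 0 && length(zeros))
      v[zeros[stats::runif(length(zeros)) < false_alarm_rate]] <- 1L
  })
  v
}

# Shift run boundaries by uniform integers, preserving run count.
jitter_bouts <- function(v, jmax) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values == 1L)
  if (length(on) == 0) return(v)
  out <- integer(length(v))
  prev_end <- 0L
  for (k in seq_along(on)) {
    i <- on[k]
    s <- starts[i] + sample.int(2L * jmax + 1L, 1L) - jmax - 1L
    e <- ends[i] + sample.int(2L * jmax + 1L, 1L) - jmax - 1L
    s <- max(s, prev_end + 2L, 1L)   # keep a gap so bouts never merge
    e <- min(e, length(v))
    if (e < s) e <- s                # never drop a bout
    # avoid swallowing the next bout's start
    if (k < length(on)) e <- min(e, starts[on[k + 1L]] - 2L)
    if (e < s) { s <- min(s, length(v)); e <- s }
    out[s:e] <- 1L
    prev_end <- e
  }
  out
}

#' Deterministic fixtures reproducing documented failure modes
#'
#' Builds small named scenes, each reproducing one failure class observed in
#' deployment: `adjacent_rois` (resources placed so close that one detection
#' falls in two ROIs), `separated_rois` (the corrected layout: no double
#' membership), `drifting_resource` (a lightweight bowl pushed across ROIs,
#' so the marker drifts from its own ROI into a neighbour's),
#' `presence_without_use` (subject occupies the ROI without using the
#' resource: detector presence 1 while latent use 0), and `fur_occlusion`
#' (coat covering the code: detections missed during the episode).
#'
#' @param dict A `marker_dictionary` (ids 0 and 1 are used).
#' @param seed Integer seed.
#' @return Named list of `synthetic_scene` objects.
#' @export
failure_fixtures <- function(dict, seed = 101) {
  n <- 30L
  mk <- function(rois, subjects, occl = NULL, s = 0L)
    generate_scene(scene_spec(width = 200, height = 150, n_frames = n,
                              dict = dict, rois = rois, subjects = subjects,
                              occlusions = occl, texture_sd = 0.015,
                              seed = seed + s))
  far <- list(roi(0, "water", 10, 40, 60, 60),
              roi(1, "dry food", 130, 40, 60, 60))
  in_far <- subject_track(0, n, x = 40, y = 70, side = 44, using = TRUE)
  drift <- subject_track(0, n, x = seq(40, 160, length.out = n), y = 70,
                         side = 44, using = TRUE)
  idle <- subject_track(1, n, x = 40, y = 70, side = 44, using = FALSE)
  occ_track <- subject_track(0, n, x = 40, y = 70, side = 44, using = TRUE)
  list(
    adjacent_rois = mk(list(roi(0, "wet food", 30, 40, 64, 60),
                            roi(1, "dry food", 90, 40, 64, 60)),
                       list(subject_track(0, n, x = 91, y = 70, side = 44,
                                          using = TRUE)), s = 1L),
    separated_rois = mk(far, list(in_far), s = 2L),
    drifting_resource = mk(far, list(drift), s = 3L),
    presence_without_use = mk(far, list(idle), s = 4L),
    fur_occlusion = mk(far, list(occ_track),
                       occl = list(list(id = 0, from = 10L, to = 19L,
                                        fraction = 0.5)), s = 5L)
  )
}
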