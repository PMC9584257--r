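test_that("scene generation is deterministic in the seed", {
  s1 <- single_marker_scene(id = 1, n_frames = 3, noise_sd = 0.02, seed = 9)
  s2 <- single_marker_scene(id = 1, n_frames = 3, noise_sd = 0.02, seed = 9)
  for (i in 0:2) {
    expect_identical(scene_frame(s1, i), scene_frame(s2, i))
  }
  s3 <- single_marker_scene(id = 1, n_frames = 3, noise_sd = 0.02, seed = 10)
  expect_false(identical(scene_frame(s1, 0), scene_frame(s3, 0)))
  # lazy access equals repeated access (per-frame seeding, no state)
  f1 <- scene_frame(s1, 2)
  scene_frame(s1, 0)
  expect_identical(scene_frame(s1, 2), f1)
})

test_that("ground truth is consistent with rendered pixels", {
  dict <- study_dictionary()
  scene <- single_marker_scene(id = 8, side = 48, seed = 14,
                               texture_sd = 0)
  frame <- scene_frame(scene, 0)
  bits <- dict$codes[[9]]
  corners <- scene$corners[[1]]
  # sample the true data-cell centers through the ground-truth geometry
  H <- collartrack:::fit_homography(
    matrix(c(0, 0, 6, 0, 6, 6, 0, 6), ncol = 2, byrow = TRUE), corners)
  for (r in 1:4) for (cc in 1:4) {
    p <- collartrack:::apply_homography(H, cbind(cc + 0.5, r + 0.5))
    val <- frame[floor(p[2]) + 1, floor(p[1]) + 1]
    expect_equal(val >= 0.5, bits[r, cc] == 1,
                 info = sprintf("cell %d,%d", r, cc))
  }
})

test_that("static noise-free markers are recovered in every frame", {
  dict <- study_dictionary()
  scene <- single_marker_scene(id = 11, side = 44, n_frames = 5, seed = 2)
  for (i in 0:4) {
    dets <- detect_markers(scene_frame(scene, i), dict)
    expect_length(dets, 1)
    expect_equal(dets[[1]]$id, 11)
  }
})

test_that("fur occlusion suppresses detection during the episode", {
  dict <- study_dictionary()
  scene <- generate_scene(scene_spec(
    width = 120, height = 120, n_frames = 9, dict = dict,
    subjects = list(subject_track(0, 9, x = 60, y = 60, side = 48,
                                  using = TRUE)),
    occlusions = list(list(id = 0, from = 3L, to = 5L, fraction = 0.5)),
    seed = 33))
  hits <- vapply(0:8, function(i)
    length(detect_markers(scene_frame(scene, i), dict)), integer(1))
  expect_true(all(hits[c(1:3, 7:9)] == 1))
  expect_true(all(hits[4:6] == 0))
  # latent behaviour state stays defined while the marker is occluded
  expect_true(all(scene$truth$using))
  expect_identical(scene$truth$occluded, c(rep(FALSE, 3), rep(TRUE, 3),
                                           rep(FALSE, 3)))
})

test_that("degraded imaging still supports detection at moderate levels", {
  dict <- study_dictionary()
  scene <- single_marker_scene(id = 7, side = 48, seed = 40,
                               noise_sd = 0.04, blur_sigma = 0.8,
                               gain = 0.85, offset = 0.05)
  dets <- detect_markers(scene_frame(scene, 0), dict)
  expect_length(dets, 1)
  expect_equal(dets[[1]]$id, 7)
})

test_that("simulate_coder reproduces truth at zero error", {
  v <- as.integer(c(0, 1, 1, 1, 0, 0, 1, 0, 1, 1))
  expect_identical(simulate_coder(v, 0, 0, 0, seed = 1), v)
  df <- simulate_coder(list(eating = v, drinking = rev(v)), 0, 0, 0, seed = 2)
  expect_identical(df$eating, v)
  expect_identical(df$drinking, rev(v))
  expect_identical(df$unit, 0:9)
})

test_that("simulate_coder error rates land near their nominal values", {
  truth <- collartrack:::with_seed(3, stats::rbinom(2e4, 1, 0.3))
  coded <- simulate_coder(truth, miss_rate = 0.2, false_alarm_rate = 0.05,
                          seed = 4)
  miss_hat <- mean(coded[truth == 1] == 0)
  fa_hat <- mean(coded[truth == 0] == 1)
  expect_lt(abs(miss_hat - 0.2), 0.02)
  expect_lt(abs(fa_hat - 0.05), 0.01)
  # determinism
  expect_identical(coded, simulate_coder(truth, 0.2, 0.05, seed = 4))
})

test_that("boundary jitter preserves bout count while moving edges", {
  v <- integer(400)
  v[21:60] <- 1L; v[141:200] <- 1L; v[301:350] <- 1L
  n_bouts <- function(x) sum(diff(c(0L, x)) == 1L)
  moved <- FALSE
  for (seed in 1:10) {
    j <- simulate_coder(v, 0, 0, boundary_jitter = 5, seed = seed)
    expect_equal(n_bouts(j), 3, info = paste("seed", seed))
    if (!identical(j, v)) moved <- TRUE
  }
  expect_true(moved)
})

test_that("truth_series extracts presence and latent use per ROI", {
  dict <- study_dictionary()
  rois <- list(roi(0, "water", 10, 30, 60, 60),
               roi(1, "food", 95, 30, 60, 60))
  vis <- c(TRUE, TRUE, FALSE, TRUE)
  scene <- generate_scene(scene_spec(
    width = 170, height = 120, n_frames = 4, dict = dict, rois = rois,
    subjects = list(subject_track(5, 4, x = 120, y = 60, side = 40,
                                  visible = vis,
                                  using = c(TRUE, FALSE, FALSE, TRUE))),
    seed = 6))
  expect_identical(truth_series(scene, 5, "presence", roi = 1),
                   c(1L, 1L, 0L, 1L))
  expect_identical(truth_series(scene, 5, "presence", roi = 0),
                   c(0L, 0L, 0L, 0L))
  expect_identical(truth_series(scene, 5, "using", roi = 1),
                   c(1L, 0L, 0L, 1L))
})

test_that("failure fixtures reproduce the documented deployment problems", {
  dict <- study_dictionary()
  fx <- failure_fixtures(dict, seed = 101)
  expect_named(fx, c("adjacent_rois", "separated_rois", "drifting_resource",
                     "presence_without_use", "fur_occlusion"))

  # adjacent ROIs: detections carry two ROI indices
  adj <- fx$adjacent_rois
  dets <- detect_markers(scene_frame(adj, 0), dict)
  expect_length(dets, 1)
  expect_identical(assign_rois(dets[[1]], adj$spec$rois), c(0L, 1L))

  # corrected layout: never more than one ROI per detection
  sep <- fx$separated_rois
  dets2 <- detect_markers(scene_frame(sep, 0), dict)
  expect_length(dets2, 1)
  expect_length(assign_rois(dets2[[1]], sep$spec$rois), 1)
  expect_length(validate_layout(sep$spec$rois), 0)
  expect_gt(length(validate_layout(adj$spec$rois)), 0)

  # drifting resource: ROI membership changes across the scene
  drift <- fx$drifting_resource
  memb <- drift$truth$rois
  expect_gt(length(unique(memb)), 1)

  # presence without use: detector sees the marker, latent use stays 0,
  # so agreement between detection and true use falls below 1
  pwu <- fx$presence_without_use
  expect_true(all(!pwu$truth$using))
  det_pres <- truth_series(pwu, 1, "presence", roi = 0)
  expect_true(any(det_pres == 1))
  use <- truth_series(pwu, 1, "using", roi = 0)
  expect_true(all(use == 0))
})

test_that("infeasible poses are rejected", {
  dict <- study_dictionary()
  expect_error(generate_scene(scene_spec(
    width = 50, height = 50, n_frames = 1, dict = dict,
    subjects = list(subject_track(0, 1, x = 25, y = 25, side = 400)),
    seed = 1)), "infeasible pose")
})
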