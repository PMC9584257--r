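# Shared fixtures, built in code. The 16-marker dictionary matches the
# deployed configuration (16-bit codes, 4x4 grid).

study_dictionary <- local({
  dict <- NULL
  function() {
    if (is.null(dict)) dict <<- generate_dictionary(16, 4, min_distance = 1,
                                                    seed = 7)
    dict
  }
})

# One marker at a fixed pose on a lightly textured background.
single_marker_scene <- function(id = 10, side = 48, theta = 0, tilt = 0,
                                width = 120, height = 120, n_frames = 1,
                                seed = 5, ...) {
  generate_scene(scene_spec(
    width = width, height = height, n_frames = n_frames,
    dict = study_dictionary(),
    subjects = list(subject_track(id, n_frames, x = width / 2,
                                  y = height / 2, side = side,
                                  theta = theta, tilt = tilt)),
    seed = seed, ...))
}

# Brute-force Hamming distance over explicit rotations (test oracle, kept
# independent of rotation_invariant_distance).
oracle_rotation_distance <- function(a, b) {
  rots <- list(b,
               t(b[nrow(b):1, ]),
               t(t(b[nrow(b):1, ])[nrow(b):1, ]),
               t(t(t(b[nrow(b):1, ])[nrow(b):1, ])[nrow(b):1, ]))
  min(vapply(rots, function(r) sum(a != r), numeric(1)))
}
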