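# Marker dictionary: square binary code grids with rotation-invariant
# Hamming-distance guarantees.

#' Rotate a square binary code grid
#'
#' Rotates a marker bit grid clockwise by multiples of 90 degrees. Used both
#' when generating dictionaries (to enforce rotation distinctness) and when
#' matching decoded bits against the dictionary.
#'
#' @param bits Square 0/1 matrix (rows top to bottom, columns left to right).
#' @param quarter_turns Integer in 0..3; number of clockwise 90-degree turns.
#' @return The rotated 0/1 matrix of the same dimensions.
#' @export
#' @examples
#' m <- matrix(0L, 4, 4); m[1, 1] <- 1L
#' rotate_code(m, 1)  # the single set cell moves to row 1, column 4
rotate_code <- function(bits, quarter_turns) {
  stopifnot(is.matrix(bits), nrow(bits) == ncol(bits))
  if (!quarter_turns %in% 0:3)
    stop("`quarter_turns` must be 0, 1, 2 or 3")
  k <- quarter_turns
  out <- bits
  while (k > 0L) {
    out <- t(out[nrow(out):1L, , drop = FALSE])
    k <- k - 1L
  }
  out
}

#' Rotation-invariant Hamming distance between two code grids
#'
#' The minimum, over the four in-plane rotations of `b`, of the bitwise
#' Hamming distance to `a`. This is the distance that matters for a detector
#' that cannot know marker orientation in advance.
#'
#' @param a,b Square 0/1 matrices of equal size, or `marker_code` objects.
#' @return Integer Hamming distance (bits).
#' @export
rotation_invariant_distance <- function(a, b) {
  a <- code_bits(a); b <- code_bits(b)
  stopifnot(all(dim(a) == dim(b)))
  min(vapply(0:3, function(k) sum(a != rotate_code(b, k)), numeric(1)))
}

# Accept either a bits matrix or a marker_code list.
code_bits <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && !is.null(x$bits)) return(x$bits)
  stop("expected a bit matrix or a marker code")
}

# Row-major integer code word, first bit most significant.
word_from_bits <- function(bits) {
  v <- as.integer(t(bits))
  sum(v * 2^(rev(seq_along(v)) - 1L))
}

bits_from_word <- function(word, grid_size) {
  n <- grid_size^2
  v <- as.integer(intToBits(word))[seq_len(n)]   # little-endian
  matrix(rev(v), nrow = grid_size, byrow = TRUE)
}

# All four rotations distinct: otherwise orientation (hence corner order)
# would be ambiguous at detection time.
is_rotation_ambiguous <- function(bits) {
  words <- vapply(1:3, function(k) word_from_bits(rotate_code(bits, k)),
                  numeric(1))
  any(words == word_from_bits(bits)) || anyDuplicated(words) > 0
}

#' Generate a marker dictionary
#'
#' Draws random square code words by rejection sampling until `n_markers`
#' codes satisfy the dictionary invariants: every code has four distinct
#' rotations (so orientation is always resolvable), and every pair of codes
#' is at rotation-invariant Hamming distance of at least `min_distance`.
#' Generation is deterministic for a fixed seed.
#'
#' @param n_markers Number of codes to generate (>= 1).
#' @param grid_size Cells per side of the data grid (default 4, i.e. 16-bit
#'   codes).
#' @param min_distance Minimum rotation-invariant pairwise Hamming distance
#'   (bits, >= 1).
#' @param seed Integer seed controlling the draw.
#' @param max_tries Candidate draws allowed before giving up with an error;
#'   guards against infeasible constraint sets.
#' @return A `marker_dictionary`: list with `codes` (list of bit matrices),
#'   `words` (integer code words), `grid_size`, `min_distance`, `seed`.
#' @export
#' @examples
#' d <- generate_dictionary(16, 4, min_distance = 1, seed = 7)
#' length(d$codes)
generate_dictionary <- function(n_markers, grid_size = 4, min_distance = 1,
                                seed = 1, max_tries = 5000L * n_markers) {
  stopifnot(n_markers >= 1, grid_size >= 2, min_distance >= 1)
  codes <- vector("list", n_markers)
  n_found <- 0L
  tries <- 0L
  with_seed(seed, {
    while (n_found < n_markers) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop(sprintf(paste0(
          "could not generate %d markers (grid %dx%d, min distance %d) ",
          "within %d candidate draws; the constraint set appears infeasible"),
          n_markers, grid_size, grid_size, min_distance, max_tries))
      cand <- matrix(sample(0:1, grid_size^2, replace = TRUE),
                     grid_size, grid_size)
      if (is_rotation_ambiguous(cand)) next
      ok <- TRUE
      for (i in seq_len(n_found)) {
        if (rotation_invariant_distance(codes[[i]], cand) < min_distance) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      n_found <- n_found + 1L
      codes[[n_found]] <- cand
    }
  })
  structure(list(
    codes = codes,
    words = vapply(codes, word_from_bits, numeric(1)),
    grid_size = as.integer(grid_size),
    min_distance = as.integer(min_distance),
    seed = as.integer(seed)
  ), class = "marker_dictionary")
}

#' @export
print.marker_dictionary <- function(x, ...) {
  cat(sprintf(
    "Marker dictionary: %d codes, %dx%d grid (%d bits), min rotation-invariant distance %d, seed %d\n",
    length(x$codes), x$grid_size, x$grid_size, x$grid_size^2,
    x$min_distance, x$seed))
  cat("code words:", paste(format(x$words, scientific = FALSE),
                           collapse = " "), "\n")
  invisible(x)
}

#' @export
length.marker_dictionary <- function(x) length(x$codes)

#' Verify all dictionary invariants exhaustively
#'
#' Checks, by brute force over all code pairs and all four rotations, that
#' every code has four distinct rotations and that every pair is at
#' rotation-invariant distance >= `min_distance`.
#'
#' @param dict A `marker_dictionary`.
#' @return `TRUE` invisibly if all invariants hold; otherwise stops with a
#'   message naming the violated invariant.
#' @export
validate_dictionary <- function(dict) {
  stopifnot(inherits(dict, "marker_dictionary"))
  n <- length(dict$codes)
  for (i in seq_len(n)) {
    bits <- dict$codes[[i]]
    if (!all(dim(bits) == dict$grid_size))
      stop(sprintf("code %d has wrong grid size", i - 1L))
    if (!all(bits %in% 0:1))
      stop(sprintf("code %d is not binary", i - 1L))
    if (word_from_bits(bits) != dict$words[i])
      stop(sprintf("code %d does not match its stored word", i - 1L))
    if (is_rotation_ambiguous(bits))
      stop(sprintf("code %d is rotation-ambiguous", i - 1L))
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        d <- rotation_invariant_distance(dict$codes[[i]], dict$codes[[j]])
        if (d < dict$min_distance)
          stop(sprintf(
            "codes %d and %d at rotation-invariant distance %d < %d",
            i - 1L, j - 1L, d, dict$min_distance))
      }
    }
  }
  invisible(TRUE)
}

#' Write / read a dictionary as plain-text config
#'
#' The dictionary is stored as YAML (or JSON, by file extension) listing the
#' seed, grid size, minimum distance and the integer code words, so a
#' dictionary can be reconstructed and shared without binary files.
#'
#' @param dict A `marker_dictionary`.
#' @param path Output file; `.json` selects JSON, anything else YAML.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   returns the reconstructed `marker_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  obj <- list(grid_size = dict$grid_size, min_distance = dict$min_distance,
              seed = dict$seed, words = as.numeric(dict$words))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  g <- as.integer(obj$grid_size)
  codes <- lapply(as.numeric(obj$words), bits_from_word, grid_size = g)
  structure(list(
    codes = codes,
    words = vapply(codes, word_from_bits, numeric(1)),
    grid_size = g,
    min_distance = as.integer(obj$min_distance),
    seed = as.integer(obj$seed)
  ), class = "marker_dictionary")
}

# Run an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
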