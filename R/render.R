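# Rendering markers and printable collar strips.
#
# Images are numeric matrices in [0, 1], [row = y, col = x], 1 = white.
# A rendered marker is, from outside in: a white quiet zone
# (`quiet_zone_cells` rings), one ring of black border cells, then the
# grid_size x grid_size data cells (bit 1 = white cell).

# Paint a marker at an arbitrary pixel side length by sampling pixel centers
# in cell coordinates. Exact for integer cells-per-pixel ratios because no
# pixel center ever falls on a cell boundary.
rasterize_marker <- function(bits, side_px, quiet_zone_cells = 1) {
  g <- nrow(bits)
  total <- g + 2L + 2L * quiet_zone_cells
  cpp <- side_px / total                      # pixels per cell
  ctr <- (seq_len(side_px) - 0.5) / cpp       # pixel centers in cell units
  cell <- pmin(floor(ctr) + 1L, total)        # cell index per pixel line
  # cell value lookup table: quiet zone white, border black, data per bits
  vals <- matrix(1, total, total)
  b0 <- quiet_zone_cells + 1L                 # border ring start
  b1 <- total - quiet_zone_cells              # border ring end
  vals[b0:b1, b0:b1] <- 0
  d0 <- b0 + 1L; d1 <- b1 - 1L
  vals[d0:d1, d0:d1] <- bits
  vals[cell, cell, drop = FALSE]
}

#' Render a single marker image
#'
#' Produces a grayscale image of one dictionary marker: data cells painted
#' per the code bits (1 = white), surrounded by one ring of black border
#' cells, surrounded by a white quiet zone. The quiet zone realises the
#' requirement that a white edge be visible around the marker for the
#' detector to isolate its contour.
#'
#' @param dict A `marker_dictionary`.
#' @param id Dictionary index (0-based, as printed on collars).
#' @param cell_px Pixels per cell (>= 1).
#' @param quiet_zone_cells White rings around the black border (>= 1).
#' @return Numeric matrix in \[0, 1\] of side
#'   `(grid_size + 2 + 2 * quiet_zone_cells) * cell_px`.
#' @export
render_marker <- function(dict, id, cell_px, quiet_zone_cells = 1) {
  bits <- dict_code(dict, id)
  stopifnot(cell_px >= 1, quiet_zone_cells >= 1)
  total <- dict$grid_size + 2L + 2L * quiet_zone_cells
  rasterize_marker(bits, total * cell_px, quiet_zone_cells)
}

dict_code <- function(dict, id) {
  stopifnot(inherits(dict, "marker_dictionary"))
  if (!(id %in% (seq_along(dict$codes) - 1L)))
    stop(sprintf("unknown marker id %s (dictionary has ids 0..%d)",
                 id, length(dict$codes) - 1L))
  dict$codes[[id + 1L]]
}

#' Render a printable collar strip
#'
#' Tiles a single marker id repeatedly along a sticker strip, so the code
#' stays visible regardless of how the collar sits on the animal's neck.
#' The marker (including its quiet zone) is scaled so its side equals the
#' strip height; repeats are placed side by side, each carrying its own
#' quiet zone, and any remaining length is left white.
#'
#' @param dict A `marker_dictionary`.
#' @param id Dictionary index.
#' @param strip_length_mm,strip_height_mm Physical strip size; defaults are
#'   the 250 x 25 mm collar sticker.
#' @param dpi Print resolution (dots per inch).
#' @param quiet_zone_cells White rings per marker repeat.
#' @return Numeric matrix in \[0, 1\], `round(strip_height_mm / 25.4 * dpi)`
#'   rows by `round(strip_length_mm / 25.4 * dpi)` columns.
#' @export
render_collar_strip <- function(dict, id, strip_length_mm = 250,
                                strip_height_mm = 25, dpi = 300,
                                quiet_zone_cells = 1) {
  bits <- dict_code(dict, id)
  h_px <- max(1L, round(strip_height_mm / 25.4 * dpi))
  w_px <- max(1L, round(strip_length_mm / 25.4 * dpi))
  tile <- rasterize_marker(bits, h_px, quiet_zone_cells)
  n_rep <- max(1L, floor(w_px / h_px))
  strip <- matrix(1, h_px, w_px)
  for (i in seq_len(n_rep)) {
    x0 <- (i - 1L) * h_px
    strip[, (x0 + 1L):(x0 + h_px)] <- tile
  }
  strip
}

#' Write a grayscale image as PNG
#'
#' @param img Numeric matrix in \[0, 1\] (rows = y, columns = x).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read an image as a grayscale matrix
#'
#' PNG and JPEG color inputs are collapsed to intensity with the standard
#' luma weights (0.299, 0.587, 0.114).
#'
#' @param path PNG file path.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  to_gray(a)
}

#' Convert an image array to grayscale
#'
#' @param frame Numeric matrix (returned as is) or H x W x C array with
#'   C >= 3 (RGB collapsed by luma weights; alpha ignored).
#' @return Numeric matrix in \[0, 1\].
#' @export
to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3) {
    if (dim(frame)[3] >= 3)
      return(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
    return(frame[, , 1])
  }
  stop("unsupported frame: expected a matrix or an H x W x C array")
}

# Resample rendered marker bits at data-cell centers; used by invariant
# tests (render -> resample recovers bits without any detector).
resample_bits <- function(img, grid_size, quiet_zone_cells = 1) {
  total <- grid_size + 2L + 2L * quiet_zone_cells
  cpp <- nrow(img) / total
  d0 <- quiet_zone_cells + 1L  # border start cell; data starts one further
  idx <- (d0 + seq_len(grid_size)) - 0.5  # data cell centers in cell units
  px <- round(idx * cpp + 0.5)            # nearest pixel (1-based)
  px <- pmin(pmax(px, 1L), nrow(img))
  m <- img[px, px, drop = FALSE]
  (m >= 0.5) * 1L
}
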