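# Regions of interest: labelled axis-aligned pixel rectangles around
# resources (food bowl, water bowl), and attribution of detections to them.

#' Define a region of interest
#'
#' @param index 0-based integer index, as used in logs ("ROI 0 \[wet food\]").
#' @param label Resource label, e.g. `"water"`, `"dry food"`.
#' @param x,y Top-left corner of the rectangle (pixels).
#' @param w,h Width and height (pixels, > 0).
#' @return A list of class `roi`.
#' @export
roi <- function(index, label, x, y, w, h) {
  stopifnot(w > 0, h > 0, index >= 0)
  structure(list(index = as.integer(index), label = as.character(label),
                 x = x, y = y, w = w, h = h), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI %d [%s]: x=%g y=%g w=%g h=%g\n",
              x$index, x$label, x$x, x$y, x$w, x$h))
  invisible(x)
}

#' Point-in-ROI test
#'
#' Containment is half-open: a point on the left or top edge is inside, a
#' point on the right or bottom edge is not, so adjacent ROIs tile the frame
#' without double-counting boundary pixels.
#'
#' @param point Numeric length-2 `(x, y)`.
#' @param roi An [roi()] object.
#' @return Logical.
#' @export
point_in_roi <- function(point, roi) {
  point[1] >= roi$x && point[1] < roi$x + roi$w &&
    point[2] >= roi$y && point[2] < roi$y + roi$h
}

#' Assign a detection to regions of interest
#'
#' Returns the indices of every ROI whose rectangle contains the detection
#' center, in ascending index order. The result may be empty (detection
#' outside all ROIs) or contain several indices when ROIs overlap or sit
#' close enough that one marker center falls in both.
#'
#' @param detection A detection from [detect_markers()] (any list with a
#'   `center` field), or a bare `(x, y)` point.
#' @param rois List of [roi()] objects.
#' @return Integer vector of ROI indices (possibly empty).
#' @export
assign_rois <- function(detection, rois) {
  pt <- if (is.list(detection) && !is.null(detection$center))
    detection$center else as.numeric(detection)
  idx <- vapply(rois, function(r) r$index, integer(1))
  hit <- vapply(rois, function(r) point_in_roi(pt, r), logical(1))
  sort(idx[hit])
}

#' Check an ROI layout for placement problems
#'
#' Flags ROI pairs that overlap or sit closer than `min_separation` pixels.
#' Resources placed too close to one another cause detections in a
#' neighbouring ROI while an animal uses a different resource, so layouts
#' should be validated before a session.
#'
#' @param rois List of [roi()] objects.
#' @param min_separation Minimum allowed gap between rectangles (pixels).
#' @return Character vector of warnings (empty if the layout is clean).
#' @export
validate_layout <- function(rois, min_separation = 20) {
  warnings <- character()
  n <- length(rois)
  if (n < 2) return(warnings)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      a <- rois[[i]]; b <- rois[[j]]
      gx <- max(a$x - (b$x + b$w), b$x - (a$x + a$w))
      gy <- max(a$y - (b$y + b$h), b$y - (a$y + a$h))
      gap <- max(gx, gy)
      if (gap < 0) {
        warnings <- c(warnings, sprintf(
          "ROIs %d [%s] and %d [%s] overlap",
          a$index, a$label, b$index, b$label))
      } else if (gap < min_separation) {
        warnings <- c(warnings, sprintf(
          "ROIs %d [%s] and %d [%s] are only %g px apart (< %g)",
          a$index, a$label, b$index, b$label, gap, min_separation))
      }
    }
  }
  warnings
}

#' Read / write an ROI layout config
#'
#' Plain-text YAML (or JSON by extension) with one entry per ROI:
#' `{index, label, x, y, w, h}`.
#'
#' @param rois List of [roi()] objects.
#' @param path Config file path.
#' @return `write_rois` returns `path` invisibly; `read_rois` the list of
#'   [roi()] objects sorted by index.
#' @export
write_rois <- function(rois, path) {
  obj <- lapply(rois, function(r)
    list(index = r$index, label = r$label, x = r$x, y = r$y, w = r$w, h = r$h))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rois <- lapply(obj, function(o)
    roi(o$index, o$label, o$x, o$y, o$w, o$h))
  rois[order(vapply(rois, function(r) r$index, integer(1)))]
}
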