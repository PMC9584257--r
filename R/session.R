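# Session runner: drive detection over a frame source in post-event or
# real-time mode, producing the detection log and a session report.
#
# Log schema (CSV): header frame,timestamp,id,x,y,rois
#   frame      0-based frame count
#   timestamp  media time in seconds (frame / fps) for post-event runs;
#              seconds on the simulated or wall clock for real-time runs
#   id         marker id
#   x, y       detection center, pixels (sub-pixel floats)
#   rois       semicolon-joined ROI indices, empty when outside all ROIs

#' Build a frame source
#'
#' Normalizes the ways frames can be supplied into one interface: a list of
#' frame matrices, a directory of PNG frames (sorted by file name), a
#' `synthetic_scene`, or a function `f(i)` returning the 0-based i-th frame
#' together with `n_frames`.
#'
#' @param x List of matrices, directory path, `synthetic_scene`, or function.
#' @param n_frames Required when `x` is a function.
#' @return A list with `get(i)` (0-based) and `n`.
#' @export
frame_source <- function(x, n_frames = NULL) {
  if (inherits(x, "frame_source")) return(x)
  if (inherits(x, "synthetic_scene")) {
    src <- list(get = function(i) scene_frame(x, i), n = x$n_frames)
  } else if (is.list(x) && !is.function(x)) {
    src <- list(get = function(i) to_gray(x[[i + 1L]]), n = length(x))
  } else if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    src <- list(get = function(i) read_image(files[i + 1L]), n = length(files))
  } else if (is.function(x)) {
    if (is.null(n_frames)) stop("`n_frames` is required for a function source")
    src <- list(get = x, n = as.integer(n_frames))
  } else {
    stop("unreadable frame source: expected a list of frames, a directory ",
         "of PNGs, a synthetic scene, or a function")
  }
  structure(src, class = "frame_source")
}

#' Run a post-event (offline) session
#'
#' Decodes and analyzes every frame in order: one log row per detection per
#' frame, timestamps on the media clock (`frame / fps`). Output is a pure
#' function of the input frames and config, so repeated runs give
#' byte-identical logs. A frame that fails to decode is logged as corrupt,
#' skipped, and counted, and processing continues.
#'
#' @param source Anything accepted by [frame_source()].
#' @param dict A `marker_dictionary`.
#' @param rois List of [roi()] objects.
#' @param params A [detector_params()] list.
#' @param fps Frames per second of the source (default 30).
#' @param out_dir Optional output directory: writes `detections.csv` and
#'   `session_report.json` (and annotated frames under `annotated/` when
#'   `annotate = TRUE`).
#' @param annotate Write annotated PNG frames (post-event only; off by
#'   default).
#' @return A list with `log` (data.frame in the schema above) and `report`
#'   (a `session_report`).
#' @export
run_post_event <- function(source, dict, rois = list(),
                           params = detector_params(), fps = 30,
                           out_dir = NULL, annotate = FALSE) {
  src <- frame_source(source)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  rows <- vector("list", src$n)
  corrupt <- 0L
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  for (i in seq_len(src$n) - 1L) {
    frame <- tryCatch(src$get(i), error = function(e) NULL)
    if (is.null(frame)) {
      corrupt <- corrupt + 1L
      warning(sprintf("frame %d unreadable; skipped", i))
      next
    }
    dets <- detect_markers(frame, dict, params)
    rows[[i + 1L]] <- detections_to_rows(dets, i, i / fps, rois)
    if (annotate && !is.null(out_dir)) {
      ann <- annotate_frame(frame, dets, rois)
      write_image(ann, file.path(out_dir, sprintf("frame_%06d.png", i)))
    }
  }
  log <- bind_log_rows(rows)
  report <- session_report(mode = "post_event", frames_total = src$n,
                           frames_analyzed = src$n - corrupt,
                           frames_dropped = 0L, frames_corrupt = corrupt,
                           started = started)
  finish_session(log, report, out_dir)
}

#' Run a simulated real-time session
#'
#' Discrete-event simulation of live monitoring under a processing-time
#' budget: frames arrive at `arrival` times; the detector always takes the
#' most recent frame available when it becomes free, and frames that arrive
#' while it is busy are dropped and counted ("temporal priority supersedes
#' processing every frame"). The accounting identity
#' `frames_analyzed + frames_dropped = frames_total` always holds. Log rows
#' are flushed to `out_dir` incrementally, so a session interrupted
#' mid-stream leaves a valid partial log (the report flags truncation).
#'
#' @param source Anything accepted by [frame_source()].
#' @param dict,rois,params,fps,out_dir As in [run_post_event()].
#' @param proc_time Simulated seconds to process one frame: a scalar or a
#'   function of the 0-based frame index.
#' @param arrival Arrival times (seconds); default `(0:(n-1)) / fps`.
#' @param stop_after Simulate a stream interruption: frames arriving after
#'   this time never arrive (default `Inf`).
#' @return A list with `log` and `report`.
#' @export
run_real_time <- function(source, dict, rois = list(),
                          params = detector_params(), fps = 30,
                          proc_time = 1 / fps, arrival = NULL,
                          out_dir = NULL, stop_after = Inf) {
  src <- frame_source(source)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (is.null(arrival)) arrival <- (seq_len(src$n) - 1L) / fps
  stopifnot(length(arrival) == src$n, !is.unsorted(arrival))
  cost <- if (is.function(proc_time)) proc_time else function(i) proc_time
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  log_path <- if (!is.null(out_dir)) file.path(out_dir, "detections.csv")
  if (!is.null(log_path))
    writeLines("frame,timestamp,id,x,y,rois", log_path)
  truncated <- any(arrival > stop_after)
  avail <- which(arrival <= stop_after)
  rows <- list()
  analyzed <- 0L
  clock <- -Inf
  i <- 1L
  while (i <= length(avail)) {
    # the detector becomes free at `clock`; take the newest arrived frame
    pick_t <- max(clock, arrival[avail[i]])
    ready <- avail[arrival[avail] <= pick_t + 1e-9 & avail >= avail[i]]
    j <- ready[length(ready)]               # newest available; older dropped
    t0 <- max(clock, arrival[j])
    frame <- src$get(j - 1L)
    dets <- detect_markers(frame, dict, params)
    new_rows <- detections_to_rows(dets, j - 1L, t0, rois)
    rows[[length(rows) + 1L]] <- new_rows
    if (!is.null(log_path) && nrow(new_rows) > 0)
      utils::write.table(format_log(new_rows), log_path, append = TRUE,
                         sep = ",", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    analyzed <- analyzed + 1L
    clock <- t0 + cost(j - 1L)
    i <- which(avail > j)[1]
    if (is.na(i)) break
  }
  dropped <- src$n - analyzed
  log <- bind_log_rows(rows)
  report <- session_report(mode = "real_time", frames_total = src$n,
                           frames_analyzed = analyzed,
                           frames_dropped = dropped, frames_corrupt = 0L,
                           started = started, truncated = truncated)
  finish_session(log, report, out_dir, write_log = is.null(log_path))
}

detections_to_rows <- function(dets, frame_idx, timestamp, rois) {
  if (length(dets) == 0)
    return(data.frame(frame = integer(), timestamp = numeric(),
                      id = integer(), x = numeric(), y = numeric(),
                      rois = character()))
  do.call(rbind, lapply(dets, function(d) {
    idx <- assign_rois(d, rois)
    data.frame(frame = frame_idx, timestamp = timestamp, id = d$id,
               x = d$center[1], y = d$center[2],
               rois = paste(idx, collapse = ";"))
  }))
}

bind_log_rows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rows <- rows[vapply(rows, nrow, integer(1)) > 0]
  if (length(rows) == 0)
    return(data.frame(frame = integer(), timestamp = numeric(),
                      id = integer(), x = numeric(), y = numeric(),
                      rois = character()))
  out <- do.call(rbind, rows)
  out[order(out$frame, out$id), , drop = FALSE]
}

session_report <- function(mode, frames_total, frames_analyzed,
                           frames_dropped, frames_corrupt = 0L,
                           started = NA_character_, truncated = FALSE) {
  structure(list(mode = mode, frames_total = frames_total,
                 frames_analyzed = frames_analyzed,
                 frames_dropped = frames_dropped,
                 frames_corrupt = frames_corrupt,
                 started = started,
                 ended = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 truncated = truncated),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("Session (%s): %d frames total, %d analyzed, %d dropped%s%s\n",
              x$mode, x$frames_total, x$frames_analyzed, x$frames_dropped,
              if (x$frames_corrupt > 0)
                sprintf(", %d corrupt", x$frames_corrupt) else "",
              if (isTRUE(x$truncated)) " [truncated stream]" else ""))
  invisible(x)
}

# Fixed-format numbers so logs are byte-identical across runs.
format_log <- function(log) {
  data.frame(frame = log$frame,
             timestamp = formatC(log$timestamp, format = "f", digits = 6),
             id = log$id,
             x = formatC(log$x, format = "f", digits = 3),
             y = formatC(log$y, format = "f", digits = 3),
             rois = log$rois)
}

finish_session <- function(log, report, out_dir, write_log = TRUE) {
  if (!is.null(out_dir)) {
    if (write_log)
      utils::write.csv(format_log(log), file.path(out_dir, "detections.csv"),
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "session_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(log = log, report = report)
}

#' Read a detection log CSV
#'
#' @param path CSV written by [run_post_event()] / [run_real_time()].
#' @return Log data.frame (`rois` kept as character).
#' @export
read_detection_log <- function(path) {
  utils::read.csv(path, colClasses = c(frame = "integer",
                                       timestamp = "numeric",
                                       id = "integer", x = "numeric",
                                       y = "numeric", rois = "character"))
}

#' Overlay ROIs and detections on a frame
#'
#' Draws each ROI rectangle with its index label and, per detection, the
#' quad outline and the text `id=[N]` near the marker. The input frame is
#' not modified; pixels differ from the input only on the drawn overlay.
#'
#' @param frame Grayscale matrix.
#' @param detections A `marker_detections` object (may be empty).
#' @param rois List of [roi()] objects.
#' @return Annotated copy of the frame.
#' @export
annotate_frame <- function(frame, detections = list(), rois = list()) {
  out <- to_gray(frame)
  for (r in rois) {
    out <- draw_rect(out, r$x, r$y, r$w, r$h, level = 1)
    out <- draw_text(out, sprintf("ROI %d", r$index),
                     r$x + 2, r$y + 2, level = 1)
  }
  for (d in detections) {
    out <- draw_polygon(out, d$corners, level = 0)
    out <- draw_text(out, sprintf("id=[%d]", d$id),
                     d$center[1] - 10, min(nrow(out) - 8, d$center[2] +
                                             sqrt(d$area) / 2 + 3), level = 0)
  }
  out
}

draw_rect <- function(img, x, y, w, h, level = 1) {
  h_img <- nrow(img); w_img <- ncol(img)
  c0 <- max(1L, round(x)); c1 <- min(w_img, round(x + w))
  r0 <- max(1L, round(y)); r1 <- min(h_img, round(y + h))
  if (c0 > c1 || r0 > r1) return(img)
  img[r0, c0:c1] <- level; img[r1, c0:c1] <- level
  img[r0:r1, c0] <- level; img[r0:r1, c1] <- level
  img
}

draw_polygon <- function(img, pts, level = 0) {
  n <- nrow(pts)
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[(i %% n) + 1, ]
    steps <- max(2L, ceiling(sqrt(sum((b - a)^2)) * 2))
    t <- seq(0, 1, length.out = steps)
    cc <- pmin(pmax(round(a[1] + t * (b[1] - a[1]) + 0.5), 1), ncol(img))
    rr <- pmin(pmax(round(a[2] + t * (b[2] - a[2]) + 0.5), 1), nrow(img))
    img[cbind(rr, cc)] <- level
  }
  img
}

# 3x5 bitmap font for annotation labels (digits plus the few glyphs used).
annot_font <- function() {
  list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"),
    "i" = c("010", "000", "010", "010", "010"),
    "d" = c("001", "001", "111", "101", "111"),
    "R" = c("110", "101", "110", "101", "101"),
    "O" = c("111", "101", "101", "101", "111"),
    "I" = c("111", "010", "010", "010", "111"),
    "=" = c("000", "111", "000", "111", "000"),
    "[" = c("110", "100", "100", "100", "110"),
    "]" = c("011", "001", "001", "001", "011"),
    " " = c("000", "000", "000", "000", "000"))
}

draw_text <- function(img, text, x, y, level = 0) {
  font <- annot_font()
  cx <- round(x)
  for (ch in strsplit(text, "")[[1]]) {
    glyph <- font[[ch]]
    if (!is.null(glyph)) {
      for (gr in 1:5) {
        bits <- strsplit(glyph[gr], "")[[1]] == "1"
        for (gc in 1:3) {
          if (bits[gc]) {
            rr <- round(y) + gr - 1L; cc <- cx + gc - 1L
            if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img))
              img[rr, cc] <- level
          }
        }
      }
    }
    cx <- cx + 4L
  }
  img
}
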