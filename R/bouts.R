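# Behaviour analytics: detection logs -> per-unit presence series ->
# behaviour bouts -> daily/hourly summaries.
#
# The ethogram's bout rule: engagement separated by at least 60 s of
# non-engagement (1800 frames at 30 fps) counts as a separate event; shorter
# interruptions are merged into one bout.

#' Presence series for one subject in one ROI
#'
#' Converts a detection log into a binary per-unit series. At `"frame"`
#' resolution, unit t is 1 iff the log holds at least one record for
#' `(subject, roi)` at frame t. At `"second"` resolution, second s is 1 iff
#' any such frame falls within second s (any-presence binning at `rate`
#' frames per second).
#'
#' @param log Detection-log data.frame (see [run_post_event()]).
#' @param subject Marker id.
#' @param roi ROI index, or `NULL` for presence anywhere in the frame.
#' @param resolution `"frame"` or `"second"`.
#' @param rate Frames per second (default 30).
#' @param n_frames Series length in frames; defaults to `max(log$frame) + 1`
#'   (pass `report$frames_total` to cover trailing absence).
#' @return Object of class `presence_series`: integer 0/1 vector with
#'   attributes `subject`, `roi`, `resolution`, `rate`, `start` (unit offset
#'   of the first element, 0 here).
#' @export
presence_series <- function(log, subject, roi = NULL,
                            resolution = c("frame", "second"), rate = 30,
                            n_frames = NULL) {
  resolution <- match.arg(resolution)
  stopifnot(rate > 0)
  if (is.null(n_frames))
    n_frames <- if (nrow(log) > 0) max(log$frame) + 1L else 0L
  sel <- log$id == subject
  if (!is.null(roi)) {
    sel <- sel & vapply(strsplit(as.character(log$rois), ";", fixed = TRUE),
                        function(z) as.character(roi) %in% z, logical(1))
  }
  if (nrow(log) > 0 && !any(log$id == subject))
    warning(sprintf("no records for subject %s in log", subject))
  v <- integer(n_frames)
  frames <- log$frame[sel]
  frames <- frames[frames < n_frames]
  v[frames + 1L] <- 1L
  if (resolution == "second") v <- downsample_any(v, rate)
  new_presence_series(v, subject, roi, resolution, rate)
}

new_presence_series <- function(v, subject, roi, resolution, rate,
                                start = 0L) {
  structure(as.integer(v), class = "presence_series", subject = subject,
            roi = roi, resolution = resolution, rate = rate,
            start = as.integer(start))
}

#' @export
print.presence_series <- function(x, ...) {
  cat(sprintf(
    "Presence series: subject %s, ROI %s, %s resolution, %d units (%d on)\n",
    attr(x, "subject"),
    if (is.null(attr(x, "roi"))) "any" else attr(x, "roi"),
    attr(x, "resolution"), length(x), sum(x)))
  invisible(x)
}

#' Segment a presence series into behaviour bouts
#'
#' Merges runs of presence separated by gaps shorter than `gap_threshold`
#' into one bout; a gap of at least `gap_threshold` units of absence starts
#' a new bout. The threshold is in series units: 1800 at frame resolution
#' and 30 fps, 60 at second resolution (one minute of non-engagement either
#' way). Bout `duration = end - start + 1` in units, counting the merged
#' interior gaps as part of the bout.
#'
#' @param series A `presence_series`, or a bare 0/1 vector.
#' @param gap_threshold Minimum separating gap, in series units (> 0).
#'   Defaults to one minute at the series' resolution.
#' @return data.frame of class `behaviour_bouts` with columns `subject`,
#'   `roi`, `start`, `end` (0-based, inclusive), `duration`, `presence`
#'   (units of actual presence inside the bout).
#' @export
segment_bouts <- function(series, gap_threshold = NULL) {
  if (is.null(gap_threshold)) {
    gap_threshold <- if (inherits(series, "presence_series") &&
                         attr(series, "resolution") == "frame")
      60 * attr(series, "rate") else 60
  }
  stopifnot(gap_threshold > 0)
  subject <- attr(series, "subject") %||% NA
  roi_idx <- attr(series, "roi") %||% NA
  start0 <- attr(series, "start") %||% 0L
  v <- as.integer(series)
  on <- which(v == 1L)
  if (length(on) == 0L) {
    return(empty_bouts(subject, roi_idx))
  }
  gaps <- diff(on) - 1L                 # absence run between consecutive 1s
  new_bout <- c(TRUE, gaps >= gap_threshold)
  bout_id <- cumsum(new_bout)
  starts <- tapply(on, bout_id, min) - 1L + start0
  ends <- tapply(on, bout_id, max) - 1L + start0
  pres <- tapply(on, bout_id, length)
  out <- data.frame(subject = subject, roi = roi_idx,
                    start = as.integer(starts), end = as.integer(ends),
                    duration = as.integer(ends - starts + 1L),
                    presence = as.integer(pres))
  rownames(out) <- NULL
  class(out) <- c("behaviour_bouts", "data.frame")
  attr(out, "resolution") <- attr(series, "resolution") %||% "frame"
  attr(out, "rate") <- attr(series, "rate") %||% 30
  out
}

empty_bouts <- function(subject = NA, roi_idx = NA) {
  out <- data.frame(subject = subject[0], roi = roi_idx[0],
                    start = integer(), end = integer(),
                    duration = integer(), presence = integer())
  class(out) <- c("behaviour_bouts", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize bouts per time bin
#'
#' Aggregates bouts into daily or hourly rows: bout count, summed duration,
#' first and last bout times. A bout straddling a bin boundary is split,
#' with its duration conserved across the bins it covers (a split part
#' counts toward the bout count of each bin it touches).
#'
#' @param bouts A `behaviour_bouts` data.frame.
#' @param bin `"day"` or `"hour"`.
#' @param rate Series units per second (30 at frame resolution, 1 at second
#'   resolution); taken from the bouts attributes when present.
#' @param origin POSIXct session start (what unit 0 means); default the Unix
#'   epoch, which is fine for relative summaries.
#' @return data.frame with `subject`, `roi`, `bin`, `n_bouts`,
#'   `duration_s`, `first_start_s`, `last_end_s`.
#' @export
summarize_bouts <- function(bouts, bin = c("day", "hour"), rate = NULL,
                            origin = as.POSIXct("1970-01-01", tz = "UTC")) {
  bin <- match.arg(bin)
  if (is.null(rate)) {
    rate <- if (!is.null(attr(bouts, "resolution")) &&
                attr(bouts, "resolution") == "frame")
      attr(bouts, "rate") %||% 30 else 1
  }
  if (nrow(bouts) == 0)
    return(data.frame(subject = character(), roi = integer(),
                      bin = character(), n_bouts = integer(),
                      duration_s = numeric(), first_start_s = numeric(),
                      last_end_s = numeric()))
  bin_s <- if (bin == "day") 86400 else 3600
  pieces <- list()
  for (i in seq_len(nrow(bouts))) {
    s <- bouts$start[i] / rate            # seconds from origin
    e <- (bouts$end[i] + 1) / rate        # exclusive end
    b0 <- floor(s / bin_s); b1 <- floor((e - 1e-9) / bin_s)
    for (b in b0:b1) {
      ps <- max(s, b * bin_s); pe <- min(e, (b + 1) * bin_s)
      pieces[[length(pieces) + 1L]] <- data.frame(
        subject = bouts$subject[i], roi = bouts$roi[i], bin_index = b,
        dur = pe - ps, start_s = ps, end_s = pe)
    }
  }
  pc <- do.call(rbind, pieces)
  key <- paste(pc$subject, pc$roi, pc$bin_index)  # NA-safe grouping
  agg <- lapply(split(pc, key), function(d) {
    data.frame(subject = d$subject[1], roi = d$roi[1],
               bin = format(origin + d$bin_index[1] * bin_s,
                            if (bin == "day") "%Y-%m-%d" else "%Y-%m-%d %H:00",
                            tz = "UTC"),
               n_bouts = nrow(d), duration_s = sum(d$dur),
               first_start_s = min(d$start_s), last_end_s = max(d$end_s))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$subject, out$roi, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}
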