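#' Keypoint trajectory container
#'
#' A `keypoint_track` holds time-stamped arena coordinates (cm) for a named
#' set of body keypoints sharing one time grid, as exported by video-tracking
#' software. The canonical keypoint set is `nose`, `center`, `forepaws`,
#' `hindpaws`, `tail`; paw keypoints are the midpoint of the respective paw
#' pair. Missing samples (tracker dropouts) are `NA`.
#'
#' @param data data.frame with column `t` (seconds, strictly increasing) and,
#'   for every keypoint `k`, columns `<k>_x` and `<k>_y` in cm.
#' @param frame_rate sampling rate in Hz.
#' @param arena_size numeric length-2, arena width and depth in cm.
#' @return an object of class `keypoint_track`.
#' @examples
#' tr <- keypoint_track(
#'   data.frame(t = c(0, 0.2), center_x = c(1, 2), center_y = c(1, 1)),
#'   frame_rate = 5, arena_size = c(26.5, 26.5)
#' )
#' track_keypoints(tr)
#' @export
keypoint_track <- function(data, frame_rate, arena_size = c(26.5, 26.5)) {
  if (!is.data.frame(data) || !"t" %in% names(data)) {
    stop("`data` must be a data.frame with a `t` column", call. = FALSE)
  }
  if (nrow(data) > 1L && any(diff(data$t) <= 0)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  assert_scalar_num(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  if (length(arena_size) != 2L || any(!is.finite(arena_size)) ||
      any(arena_size <= 0)) {
    stop("`arena_size` must be two positive numbers (cm)", call. = FALSE)
  }
  kps <- track_keypoints_from_names(names(data))
  if (length(kps) == 0L) {
    stop("no `<keypoint>_x` / `<keypoint>_y` column pairs found", call. = FALSE)
  }
  structure(
    list(data = data, frame_rate = frame_rate, arena_size = as.numeric(arena_size)),
    class = "keypoint_track"
  )
}

track_keypoints_from_names <- function(nms) {
  xs <- sub("_x$", "", grep("_x$", nms, value = TRUE))
  ys <- sub("_y$", "", grep("_y$", nms, value = TRUE))
  intersect(xs, ys)
}

#' Keypoints present in a track
#' @param track a `keypoint_track`
#' @return character vector of keypoint names
#' @export
track_keypoints <- function(track) {
  stopifnot(inherits(track, "keypoint_track"))
  track_keypoints_from_names(names(track$data))
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf(
    "<keypoint_track> %d samples @ %.3g Hz, %.4g s, keypoints: %s\n",
    nrow(x$data), x$frame_rate,
    if (nrow(x$data)) diff(range(x$data$t)) + 1 / x$frame_rate else 0,
    paste(track_keypoints(x), collapse = ", ")
  ))
  invisible(x)
}

# x/y matrix (samples x 2) for one keypoint
kp_xy <- function(track, kp) {
  d <- track$data
  cbind(d[[paste0(kp, "_x")]], d[[paste0(kp, "_y")]])
}

#' Labeled epoch set
#'
#' Ordered, non-overlapping labeled time intervals, e.g. the pre-DMF / DMF /
#' post-DMF sessions of an open-field run. Intervals are half-open
#' `[start, end)`.
#'
#' @param labels character vector of epoch labels
#' @param start,end numeric vectors of interval bounds in seconds
#' @return data.frame of class `epoch_set` with columns label, start, end
#' @examples
#' epoch_set(c("pre", "dmf", "post"), c(0, 300, 600), c(300, 600, 900))
#' @export
epoch_set <- function(labels, start, end) {
  if (length(labels) != length(start) || length(start) != length(end)) {
    stop("labels, start and end must have equal length", call. = FALSE)
  }
  if (any(end <= start)) stop("every epoch needs end > start", call. = FALSE)
  o <- order(start)
  labels <- as.character(labels)[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1] < end[-length(end)])) {
    stop("epochs must not overlap", call. = FALSE)
  }
  structure(
    data.frame(label = labels, start = start, end = end,
               stringsAsFactors = FALSE),
    class = c("epoch_set", "data.frame")
  )
}

#' Slice a track into per-epoch tracks
#'
#' Timestamps are preserved, so concatenating the slices restores the covered
#' portion of the track. A sample at time `t` belongs to epoch `[s, e)` iff
#' `s <= t < e`.
#'
#' @param track a `keypoint_track`
#' @param epochs an [epoch_set()]
#' @return named list of `keypoint_track`, one per epoch
#' @export
segment_epochs <- function(track, epochs) {
  stopifnot(inherits(track, "keypoint_track"))
  if (nrow(epochs) == 0L) return(structure(list(), names = character(0)))
  t <- track$data$t
  span <- c(t[1], t[length(t)] + 1 / track$frame_rate)
  if (any(epochs$start < span[1] - 1e-9) || any(epochs$end > span[2] + 1e-9)) {
    stop("epoch outside track span", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(epochs)), function(i) {
    sel <- t >= epochs$start[i] & t < epochs$end[i]
    keypoint_track(track$data[sel, , drop = FALSE], track$frame_rate,
                   track$arena_size)
  })
  names(out) <- epochs$label
  out
}

#' Read / write track CSV
#'
#' The native dialect is a comma-separated table with a header row: column
#' `t`, then `<keypoint>_x`, `<keypoint>_y` per keypoint; missing values
#' blank. [read_ethovision_track()] accepts an EthoVision-like export:
#' semicolon-separated, with metadata preamble lines before the header.
#'
#' @param path file path
#' @param frame_rate sampling rate in Hz; if `NULL`, inferred from the median
#'   time step.
#' @param arena_size arena dimensions in cm
#' @return a `keypoint_track`
#' @export
read_track_csv <- function(path, frame_rate = NULL, arena_size = c(26.5, 26.5)) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(d$t))
  keypoint_track(d, frame_rate, arena_size)
}

#' @rdname read_track_csv
#' @param track a `keypoint_track` to write
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(track$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_track_csv
#' @export
read_ethovision_track <- function(path, frame_rate = NULL,
                                  arena_size = c(26.5, 26.5)) {
  lines <- readLines(path)
  # header = first line whose first field is "t"
  hdr <- which(vapply(strsplit(lines, ";"), function(f) {
    length(f) > 0 && trimws(f[1]) == "t"
  }, logical(1)))[1]
  if (is.na(hdr)) stop("no header row starting with `t` found", call. = FALSE)
  d <- utils::read.csv(text = paste(lines[hdr:length(lines)], collapse = "\n"),
                       sep = ";", check.names = FALSE,
                       na.strings = c("", "NA", "-"))
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(d$t))
  keypoint_track(d, frame_rate, arena_size)
}
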