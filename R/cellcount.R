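#' Segment one image channel: blur, fixed threshold, size filter
#'
#' The quantification scheme of the ImageJ-style counting macro: Gaussian
#' blur (sigma in px), binary threshold at a fixed 8-bit intensity, connected
#' components, then removal of objects smaller than `min_size` pixels to
#' discard speckle and low-signal cells.
#'
#' @param channel numeric matrix in 8-bit range (16-bit inputs are min-max
#'   rescaled to 0-255 with a warning)
#' @param blur_sigma Gaussian blur SD in px
#' @param threshold intensity cutoff (mask keeps pixels `>= threshold`)
#' @param min_size minimum object area, px
#' @return list of class `channel_segmentation`: `labels` (label matrix),
#'   `n` (object count), `objects` (data.frame `id`, `area`, `cx`, `cy`)
#' @export
segment_channel <- function(channel, blur_sigma = 2, threshold = 30,
                            min_size = 20) {
  channel <- as.matrix(channel)
  if (max(channel, na.rm = TRUE) > 255) {
    warning("channel exceeds 8-bit range; rescaling min-max to 0-255")
    rng <- range(channel, na.rm = TRUE)
    channel <- (channel - rng[1]) / (rng[2] - rng[1]) * 255
  }
  blurred <- if (blur_sigma > 0) {
    as.matrix(EBImage::gblur(channel, sigma = blur_sigma))
  } else {
    channel
  }
  mask <- blurred >= threshold
  labels <- EBImage::bwlabel(mask)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0], nbins = max(labels))
    drop <- which(areas < min_size)
    if (length(drop)) labels[labels %in% drop] <- 0L
    # relabel consecutively
    keep <- sort(unique(as.integer(labels[labels > 0])))
    if (length(keep)) {
      remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
      labels[labels > 0] <- remap[as.integer(labels[labels > 0])]
    }
  }
  labels <- matrix(as.integer(labels), nrow(channel), ncol(channel))
  n <- max(labels)
  objects <- if (n > 0) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    data.frame(
      id = seq_len(n),
      area = as.integer(tabulate(lab, nbins = n)),
      cx = as.numeric(tapply(idx[, 1], lab, mean)),
      cy = as.numeric(tapply(idx[, 2], lab, mean))
    )
  } else {
    data.frame(id = integer(0), area = integer(0), cx = numeric(0),
               cy = numeric(0))
  }
  structure(list(labels = labels, n = n, objects = objects),
            class = "channel_segmentation")
}

#' Colocalize c-fos objects with DAPI and marker channels
#'
#' A c-fos object is valid only if its centroid lies within the DAPI mask
#' (clear nuclear colocalization); it is double-positive if that centroid
#' also falls inside a marker object. The headline metric is the percentage
#' of double-positive cells over total marker-expressing cells.
#'
#' @param cfos_seg `channel_segmentation` of the c-fos channel
#' @param dapi_mask logical matrix (e.g. `segment_channel(...)$labels > 0`)
#' @param marker_seg `channel_segmentation` of the transduction marker
#' @return list of class `count_result`: `n_marker`, `n_cfos_dapi`,
#'   `n_double`, `pct_positive`
#' @export
colocalize <- function(cfos_seg, dapi_mask, marker_seg) {
  stopifnot(inherits(cfos_seg, "channel_segmentation"),
            inherits(marker_seg, "channel_segmentation"))
  if (!all(dim(dapi_mask) == dim(cfos_seg$labels))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  if (marker_seg$n == 0L) {
    stop("no marker objects: percent positive undefined", call. = FALSE)
  }
  ob <- cfos_seg$objects
  if (nrow(ob)) {
    ci <- pmin(pmax(round(ob$cx), 1), nrow(dapi_mask))
    cj <- pmin(pmax(round(ob$cy), 1), ncol(dapi_mask))
    valid <- dapi_mask[cbind(ci, cj)]
    dbl <- valid & marker_seg$labels[cbind(ci, cj)] > 0
  } else {
    valid <- dbl <- logical(0)
  }
  structure(list(n_marker = marker_seg$n, n_cfos_dapi = sum(valid),
                 n_double = sum(dbl),
                 pct_positive = 100 * sum(dbl) / marker_seg$n),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d marker cells, %d c-fos+DAPI, %d double (%.2f%%)\n",
              x$n_marker, x$n_cfos_dapi, x$n_double, x$pct_positive))
  invisible(x)
}

#' Full c-fos counting chain on a 3-channel image
#'
#' @param image array width x height x 3 with channels marker, cfos, dapi
#' @param blur_sigma,threshold,min_size passed to [segment_channel()]
#' @param dapi_threshold threshold for the DAPI mask (no size filter)
#' @return a `count_result` (see [colocalize()])
#' @export
count_cfos <- function(image, blur_sigma = 2, threshold = 30, min_size = 20,
                       dapi_threshold = 30) {
  marker <- segment_channel(image[, , 1], blur_sigma, threshold, min_size)
  cfos <- segment_channel(image[, , 2], blur_sigma, threshold, min_size)
  dapi <- segment_channel(image[, , 3], blur_sigma, dapi_threshold,
                          min_size = 1)
  colocalize(cfos, dapi$labels > 0, marker)
}

#' Sample random non-overlapping fixed-size ROIs from an image
#'
#' Crop positions are drawn uniformly over the feasible top-left grid, with
#' rejection of overlapping draws; reproducible for a given seed.
#'
#' @param image matrix or 3-channel array
#' @param n_rois number of crops
#' @param roi_size length-2, crop width and height in px
#' @param seed integer seed
#' @return list of class `roi_samples`: `rois` (list of crops) and
#'   `positions` (data.frame `x0`, `y0` of top-left corners)
#' @export
roi_sampling <- function(image, n_rois = 3, roi_size, seed = 1L) {
  dims <- dim(image)[1:2]
  if (any(roi_size > dims)) stop("roi_size exceeds image", call. = FALSE)
  nx <- dims[1] - roi_size[1] + 1L
  ny <- dims[2] - roi_size[2] + 1L
  if (n_rois > (dims[1] %/% roi_size[1]) * (dims[2] %/% roi_size[2])) {
    stop("infeasible packing: too many ROIs for the image", call. = FALSE)
  }
  with_seed(seed, {
    pos <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pos) < n_rois) {
      cand <- c(sample.int(nx, 1L), sample.int(ny, 1L))
      ok <- nrow(pos) == 0L ||
        all(abs(pos[, 1] - cand[1]) >= roi_size[1] |
              abs(pos[, 2] - cand[2]) >= roi_size[2])
      if (ok) pos <- rbind(pos, cand)
      tries <- tries + 1L
      if (tries > 10000L * n_rois) {
        stop("could not place non-overlapping ROIs", call. = FALSE)
      }
    }
    rois <- lapply(seq_len(nrow(pos)), function(i) {
      xs <- pos[i, 1]:(pos[i, 1] + roi_size[1] - 1L)
      ys <- pos[i, 2]:(pos[i, 2] + roi_size[2] - 1L)
      if (length(dim(image)) == 3L) image[xs, ys, , drop = FALSE]
      else image[xs, ys, drop = FALSE]
    })
    structure(list(rois = rois,
                   positions = data.frame(x0 = pos[, 1], y0 = pos[, 2])),
              class = "roi_samples")
  })
}
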