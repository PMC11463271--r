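#' Parameters for the synthetic 3-channel cell-image generator
#'
#' Emulates an immunofluorescence field of view: a transduction-marker
#' channel (HA/RFP) with one disk per cell, an activity-marker (c-fos)
#' channel lighting up a known fraction of those cells, and a DAPI channel
#' with a nucleus at every cell. Cells are placed by rejection sampling with
#' a minimum center separation so objects never merge under moderate blur.
#'
#' @param image_size pixels, width x height
#' @param n_marker_cells number of marker-positive cells
#' @param positive_fraction fraction of marker cells that are also c-fos
#'   positive, in `[0, 1]`
#' @param cell_radius soma disk radius, px (>= 2)
#' @param nucleus_radius DAPI nucleus radius, px
#' @param intensity_levels named list: `marker_fg`, `cfos_fg`, `dapi_fg`,
#'   `bg` (8-bit intensity values)
#' @param noise_sd additive Gaussian noise SD, intensity units
#' @param min_separation minimum distance between cell centers, px
#' @param n_speckles sub-size bright speckles added to the c-fos channel
#'   (exercise the size filter)
#' @param seed integer seed
#' @return list of class `cell_image_synth_params`
#' @export
cell_image_synth_params <- function(image_size = c(256, 256),
                                    n_marker_cells = 50,
                                    positive_fraction = 0.25,
                                    cell_radius = 6, nucleus_radius = 4,
                                    intensity_levels = list(
                                      marker_fg = 200, cfos_fg = 200,
                                      dapi_fg = 180, bg = 8),
                                    noise_sd = 2, min_separation = 22,
                                    n_speckles = 0, seed = 1L) {
  assert_proportion(positive_fraction, "positive_fraction")
  if (cell_radius < 2) stop("cell_radius must be >= 2 px", call. = FALSE)
  if (n_marker_cells < 0) stop("n_marker_cells must be >= 0", call. = FALSE)
  # conservative feasibility check for rejection packing
  area_per_cell <- (min_separation * 2)^2
  if (n_marker_cells * min_separation^2 > prod(image_size)) {
    stop("impossible packing: too many cells for the image area",
         call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 n_marker_cells = as.integer(n_marker_cells),
                 positive_fraction = positive_fraction,
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 intensity_levels = intensity_levels, noise_sd = noise_sd,
                 min_separation = min_separation,
                 n_speckles = as.integer(n_speckles), seed = as.integer(seed)),
            class = "cell_image_synth_params")
}

draw_disk <- function(img, cx, cy, r, value) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(nrow(img), ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(ncol(img), ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  sub <- img[xs, ys, drop = FALSE]
  sub[d2 <= r^2] <- value
  img[xs, ys] <- sub
  img
}

#' Generate a synthetic 3-channel cell image with known ground truth
#'
#' @param params a [cell_image_synth_params()]
#' @return list of class `synthetic_cell_image`: `image` (array
#'   width x height x 3, channels marker/cfos/dapi, 8-bit range), `truth`
#'   (data.frame `x`, `y`, `cfos_positive`), and `params`
#' @export
generate_cell_image <- function(params) {
  stopifnot(inherits(params, "cell_image_synth_params"))
  p <- params
  with_seed(p$seed, {
    w <- p$image_size[1]; h <- p$image_size[2]
    margin <- p$cell_radius + 4
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < p$n_marker_cells) {
      cand <- c(stats::runif(1, margin, w - margin),
                stats::runif(1, margin, h - margin))
      if (nrow(centers) == 0L ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= p$min_separation) {
        centers <- rbind(centers, cand)
      }
      tries <- tries + 1L
      if (tries > 200L * max(1L, p$n_marker_cells)) {
        stop("impossible packing: could not place cells at this separation",
             call. = FALSE)
      }
    }
    lev <- p$intensity_levels
    marker <- matrix(lev$bg, w, h)
    cfos <- matrix(lev$bg, w, h)
    dapi <- matrix(lev$bg, w, h)
    n_pos <- as.integer(round(p$positive_fraction * p$n_marker_cells))
    pos <- rep(FALSE, p$n_marker_cells)
    if (n_pos > 0L) pos[sample.int(p$n_marker_cells, n_pos)] <- TRUE
    for (i in seq_len(p$n_marker_cells)) {
      marker <- draw_disk(marker, centers[i, 1], centers[i, 2],
                          p$cell_radius, lev$marker_fg)
      dapi <- draw_disk(dapi, centers[i, 1], centers[i, 2],
                        p$nucleus_radius, lev$dapi_fg)
      if (pos[i]) {
        cfos <- draw_disk(cfos, centers[i, 1], centers[i, 2],
                          p$cell_radius, lev$cfos_fg)
      }
    }
    if (p$n_speckles > 0L) {
      for (k in seq_len(p$n_speckles)) {
        cfos <- draw_disk(cfos, stats::runif(1, margin, w - margin),
                          stats::runif(1, margin, h - margin), 1,
                          lev$cfos_fg)
      }
    }
    if (p$noise_sd > 0) {
      marker <- marker + stats::rnorm(w * h, 0, p$noise_sd)
      cfos <- cfos + stats::rnorm(w * h, 0, p$noise_sd)
      dapi <- dapi + stats::rnorm(w * h, 0, p$noise_sd)
    }
    clamp <- function(m) pmin(pmax(m, 0), 255)
    img <- array(0, c(w, h, 3), dimnames = list(NULL, NULL,
                                                c("marker", "cfos", "dapi")))
    img[, , 1] <- clamp(marker); img[, , 2] <- clamp(cfos)
    img[, , 3] <- clamp(dapi)
    truth <- if (p$n_marker_cells > 0L) {
      data.frame(x = centers[, 1], y = centers[, 2], cfos_positive = pos)
    } else {
      data.frame(x = numeric(0), y = numeric(0), cfos_positive = logical(0))
    }
    structure(list(image = img, truth = truth, params = p),
              class = "synthetic_cell_image")
  })
}

#' Write / read a 3-channel cell image as multi-page TIFF
#'
#' Pages are the marker, c-fos and DAPI channels, stored as 8-bit.
#'
#' @param image array width x height x channels in 0-255 range
#' @param path TIFF path
#' @export
write_cell_tiff <- function(image, path) {
  pages <- lapply(seq_len(dim(image)[3]), function(k) {
    # tiff expects row-major [row, col] in [0, 1]
    t(image[, , k]) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_cell_tiff
#' @param channels names assigned to the pages on read
#' @return `read_cell_tiff`: array width x height x channels, 0-255
#' @export
read_cell_tiff <- function(path, channels = c("marker", "cfos", "dapi")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  w <- ncol(pages[[1]]); h <- nrow(pages[[1]])
  img <- array(0, c(w, h, length(pages)))
  for (k in seq_along(pages)) img[, , k] <- t(pages[[k]]) * 255
  if (length(channels) == dim(img)[3]) dimnames(img) <- list(NULL, NULL, channels)
  img
}
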