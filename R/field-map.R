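#' Magnetic field grid over the arena
#'
#' A rectangular grid of field strength (mT) measured with a gaussmeter. The
#' arena y axis points toward the field source, so field strength is highest
#' at the max-y (proximal) edge.
#'
#' @param x_nodes,y_nodes strictly increasing node coordinates, cm
#' @param B matrix of field strength, mT, with `length(x_nodes)` rows and
#'   `length(y_nodes)` columns
#' @return object of class `field_grid`
#' @export
field_grid <- function(x_nodes, y_nodes, B) {
  if (any(diff(x_nodes) <= 0) || any(diff(y_nodes) <= 0)) {
    stop("grid nodes must be strictly increasing", call. = FALSE)
  }
  B <- as.matrix(B)
  if (nrow(B) != length(x_nodes) || ncol(B) != length(y_nodes)) {
    stop("B must be length(x_nodes) x length(y_nodes)", call. = FALSE)
  }
  if (any(!is.finite(B)) || any(B < 0)) {
    stop("field strengths must be finite and >= 0", call. = FALSE)
  }
  structure(list(x_nodes = as.numeric(x_nodes), y_nodes = as.numeric(y_nodes),
                 B = B),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d x %d nodes, B in [%.4g, %.4g] mT\n",
              length(x$x_nodes), length(x$y_nodes), min(x$B), max(x$B)))
  invisible(x)
}

#' Read / write a field grid as long-form CSV (columns x, y, B_mT)
#' @param path file path
#' @return a `field_grid`
#' @export
read_field_grid_csv <- function(path) {
  d <- utils::read.csv(path)
  xs <- sort(unique(d$x)); ys <- sort(unique(d$y))
  B <- matrix(NA_real_, length(xs), length(ys))
  B[cbind(match(d$x, xs), match(d$y, ys))] <- d$B_mT
  if (any(is.na(B))) stop("grid file does not cover a full rectangular grid",
                          call. = FALSE)
  field_grid(xs, ys, B)
}

#' @rdname read_field_grid_csv
#' @param grid a `field_grid` to write
#' @export
write_field_grid_csv <- function(grid, path) {
  d <- expand.grid(x = grid$x_nodes, y = grid$y_nodes)
  d$B_mT <- as.vector(grid$B)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Field strength at a position, by bilinear interpolation
#'
#' Exact at grid nodes; queries outside the grid hull raise an error (no
#' extrapolation).
#'
#' @param grid a [field_grid()]
#' @param x,y query coordinates, cm (vectorized)
#' @return field strength in mT
#' @export
field_at <- function(grid, x, y) {
  xs <- grid$x_nodes; ys <- grid$y_nodes
  if (any(x < xs[1] - 1e-9 | x > xs[length(xs)] + 1e-9 |
          y < ys[1] - 1e-9 | y > ys[length(ys)] + 1e-9, na.rm = TRUE)) {
    stop("query outside the field-grid hull", call. = FALSE)
  }
  ix <- pmin(pmax(findInterval(x, xs), 1L), length(xs) - 1L)
  iy <- pmin(pmax(findInterval(y, ys), 1L), length(ys) - 1L)
  fx <- (x - xs[ix]) / (xs[ix + 1L] - xs[ix])
  fy <- (y - ys[iy]) / (ys[iy + 1L] - ys[iy])
  b00 <- grid$B[cbind(ix, iy)]
  b10 <- grid$B[cbind(ix + 1L, iy)]
  b01 <- grid$B[cbind(ix, iy + 1L)]
  b11 <- grid$B[cbind(ix + 1L, iy + 1L)]
  (1 - fx) * (1 - fy) * b00 + fx * (1 - fy) * b10 +
    (1 - fx) * fy * b01 + fx * fy * b11
}

#' Bin occupancy and freezing time by field strength
#'
#' Each resampled track sample is assigned the interpolated field strength at
#' the center keypoint and contributes one sample step of occupancy to its
#' half-open bin `[low, high)`; samples falling inside a detected freezing
#' bout also contribute freezing time.
#'
#' @param track a resampled `keypoint_track`
#' @param grid a [field_grid()]
#' @param bouts data.frame of freezing bouts (`t_start`, `t_end`), e.g. from
#'   [detect_freezing()]
#' @param bin_edges increasing vector of field-bin edges, mT
#' @return data.frame of class `field_bin_summary`: per bin `B_low`,
#'   `B_high`, `occupancy_time`, `freezing_time`, `freezing_rate`; the
#'   attribute `missing_time` holds seconds spent outside the grid hull or
#'   outside the binned range
#' @export
bin_behavior_by_field <- function(track, grid, bouts, bin_edges) {
  stopifnot(inherits(track, "keypoint_track"))
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be increasing",
                                      call. = FALSE)
  t <- track$data$t
  dt <- 1 / track$frame_rate
  xy <- kp_xy(track, "center")
  xs <- grid$x_nodes; ys <- grid$y_nodes
  inhull <- !is.na(xy[, 1]) & !is.na(xy[, 2]) &
    xy[, 1] >= xs[1] & xy[, 1] <= xs[length(xs)] &
    xy[, 2] >= ys[1] & xy[, 2] <= ys[length(ys)]
  B <- rep(NA_real_, length(t))
  B[inhull] <- field_at(grid, xy[inhull, 1], xy[inhull, 2])
  bin <- findInterval(B, bin_edges, rightmost.closed = FALSE)
  bin[!is.na(bin) & bin == length(bin_edges)] <- NA   # >= last edge
  bin[!is.na(bin) & bin == 0L] <- NA                  # < first edge
  frozen <- rep(FALSE, length(t))
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      frozen <- frozen | (t >= bouts$t_start[i] - 1e-9 &
                            t < bouts$t_end[i] - 1e-9)
    }
  }
  nb <- length(bin_edges) - 1L
  occ <- fz <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- !is.na(bin) & bin == b
    occ[b] <- sum(sel) * dt
    fz[b] <- sum(sel & frozen) * dt
  }
  out <- data.frame(
    B_low = bin_edges[-length(bin_edges)],
    B_high = bin_edges[-1],
    occupancy_time = occ,
    freezing_time = fz,
    freezing_rate = ifelse(occ > 0, fz / occ, NA_real_)
  )
  attr(out, "missing_time") <- sum(is.na(bin)) * dt
  class(out) <- c("field_bin_summary", "data.frame")
  out
}

#' Classify a field range as high DMF, low DMF, or neither
#'
#' High DMF is a region of 0.5 to 1.3 T (500-1300 mT); low DMF is 0.1 to
#' 0.27 T (100-270 mT). A range is labeled when it lies within a definition;
#' anything else is `"none"`.
#'
#' @param B_range numeric length-2, min and max field strength in mT
#' @return `"high"`, `"low"`, or `"none"`
#' @examples
#' classify_regime(c(500, 1300))  # "high"
#' classify_regime(c(100, 270))   # "low"
#' @export
classify_regime <- function(B_range) {
  if (length(B_range) != 2L || any(!is.finite(B_range))) {
    stop("B_range must be two finite numbers (mT)", call. = FALSE)
  }
  if (B_range[2] < B_range[1]) stop("reversed field range", call. = FALSE)
  if (B_range[1] >= 500 && B_range[2] <= 1300) return("high")
  if (B_range[1] >= 100 && B_range[2] <= 270) return("low")
  "none"
}
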