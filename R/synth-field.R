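#' Parameters for the synthetic field-grid generator
#'
#' Emulates a gaussmeter map of the fringe field of a static magnet at the
#' arena's proximal (max-y) edge: field strength decays exponentially with
#' distance from that edge and is constant along x. The map is deterministic;
#' `seed` is accepted for interface symmetry with the other generators but
#' unused.
#'
#' @param arena_size arena width x depth, cm
#' @param grid_spacing node spacing, cm
#' @param peak_mT field strength at the magnet-proximal edge
#' @param decay_length exponential decay length, cm; if `distal_mT` is given
#'   it is solved so the distal edge sits exactly at `distal_mT`
#' @param distal_mT optional field strength at the distal edge
#' @param seed unused; kept for a uniform generator interface
#' @return list of class `field_synth_params`
#' @export
field_synth_params <- function(arena_size = c(26.5, 26.5), grid_spacing = 2.5,
                               peak_mT = 270, decay_length = 10,
                               distal_mT = NULL, seed = 1L) {
  assert_scalar_num(peak_mT, "peak_mT", lower = 0)
  assert_scalar_num(grid_spacing, "grid_spacing", lower = 0, strict_lower = TRUE)
  if (grid_spacing > min(arena_size)) {
    stop("grid_spacing larger than the arena", call. = FALSE)
  }
  if (!is.null(distal_mT)) {
    assert_scalar_num(distal_mT, "distal_mT", lower = 0)
    if (peak_mT > 0 && distal_mT > 0 && distal_mT < peak_mT) {
      decay_length <- arena_size[2] / log(peak_mT / distal_mT)
    } else if (distal_mT == peak_mT) {
      decay_length <- Inf
    } else if (peak_mT > 0) {
      stop("distal_mT must be in (0, peak_mT] to solve the decay length",
           call. = FALSE)
    }
  }
  structure(list(arena_size = as.numeric(arena_size),
                 grid_spacing = grid_spacing, peak_mT = peak_mT,
                 decay_length = decay_length, seed = as.integer(seed)),
            class = "field_synth_params")
}

#' Generate a synthetic gaussmeter field grid
#'
#' @param params a [field_synth_params()]
#' @return a [field_grid()]; field is monotone non-increasing with distance
#'   from the proximal (max-y) edge by construction
#' @examples
#' g <- generate_field_grid(field_synth_params(peak_mT = 270, distal_mT = 100))
#' range(g$B)  # 100 ... 270 mT, the low-DMF titration range
#' @export
generate_field_grid <- function(params) {
  stopifnot(inherits(params, "field_synth_params"))
  p <- params
  xs <- seq(0, p$arena_size[1], by = p$grid_spacing)
  ys <- seq(0, p$arena_size[2], by = p$grid_spacing)
  if (abs(xs[length(xs)] - p$arena_size[1]) > 1e-9) xs <- c(xs, p$arena_size[1])
  if (abs(ys[length(ys)] - p$arena_size[2]) > 1e-9) ys <- c(ys, p$arena_size[2])
  d <- p$arena_size[2] - ys                  # distance from proximal edge
  bcol <- if (is.infinite(p$decay_length)) {
    rep(p$peak_mT, length(ys))
  } else {
    p$peak_mT * exp(-d / p$decay_length)
  }
  B <- matrix(rep(bcol, each = length(xs)), length(xs), length(ys))
  field_grid(xs, ys, B)
}
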