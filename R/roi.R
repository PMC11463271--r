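#' Per-ROI fluorescence trace set
#'
#' Mean-intensity time series for hand-drawn regions of interest plus a
#' background ROI, as produced by time-lapse imaging of calcium (Fluo-4,
#' RCaMP) or chloride (MQAE) indicators. The background trace is subtracted
#' frame-wise before any normalisation; F0 is the mean of the
#' background-subtracted trace over `baseline_window`.
#'
#' @param t time, seconds
#' @param traces numeric matrix or data.frame, one column per ROI
#' @param background background ROI trace (same length), or 0
#' @param baseline_window numeric length-2 `(t0, t1)`: the pre-stimulus
#'   window over which F0 is computed
#' @return object of class `roi_trace_set`
#' @export
roi_trace_set <- function(t, traces, background = 0,
                          baseline_window = c(t[1], t[1] + (t[2] - t[1]) * 5)) {
  traces <- as.matrix(traces)
  if (length(t) != nrow(traces)) stop("t and traces lengths differ",
                                      call. = FALSE)
  if (length(background) == 1L) background <- rep(background, length(t))
  if (length(background) != length(t)) {
    stop("background must be scalar or match t", call. = FALSE)
  }
  if (baseline_window[1] < t[1] - 1e-9 ||
      baseline_window[2] > t[length(t)] + 1e-9 ||
      baseline_window[2] < baseline_window[1]) {
    stop("baseline_window must be a non-decreasing interval within t",
         call. = FALSE)
  }
  if (is.null(colnames(traces))) {
    colnames(traces) <- paste0("roi_", seq_len(ncol(traces)))
  }
  structure(list(t = as.numeric(t), traces = traces,
                 background = as.numeric(background),
                 baseline_window = as.numeric(baseline_window)),
            class = "roi_trace_set")
}

#' Read an ROI trace CSV (columns t, roi_*, optional background)
#' @param path CSV path
#' @param baseline_window passed to [roi_trace_set()]
#' @return a `roi_trace_set`
#' @export
read_roi_csv <- function(path, baseline_window = NULL) {
  d <- utils::read.csv(path)
  bg <- if ("background" %in% names(d)) d$background else 0
  tr <- d[, setdiff(names(d), c("t", "background")), drop = FALSE]
  if (is.null(baseline_window)) {
    roi_trace_set(d$t, tr, bg)
  } else {
    roi_trace_set(d$t, tr, bg, baseline_window)
  }
}

#' Per-ROI dF/F0
#'
#' `dF/F0(t) = (F(t) - F0) / F0` on the background-subtracted trace, with F0
#' the mean over the baseline window. The sign is kept: indicator rises give
#' positive values, chloride quenching of MQAE gives negative values. ROIs
#' whose F0 is not positive are excluded and reported in the
#' `excluded` attribute.
#'
#' @param traces a [roi_trace_set()]
#' @return matrix of dF/F0 traces (time x ROI) of class `dff0_traces`, with
#'   attributes `t` and `excluded`
#' @examples
#' ts <- roi_trace_set(0:10, matrix(c(rep(10, 5), rep(20, 6))),
#'                     baseline_window = c(0, 4))
#' tail(dff0(ts), 1)  # doubling from baseline -> dF/F0 = 1
#' @export
dff0 <- function(traces) {
  stopifnot(inherits(traces, "roi_trace_set"))
  f <- traces$traces - traces$background
  bw <- traces$baseline_window
  sel <- traces$t >= bw[1] - 1e-9 & traces$t <= bw[2] + 1e-9
  f0 <- colMeans(f[sel, , drop = FALSE])
  bad <- !is.finite(f0) | f0 <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d ROI(s) with non-positive baseline: %s",
                    sum(bad), paste(colnames(f)[bad], collapse = ", ")))
  }
  out <- sweep(sweep(f[, !bad, drop = FALSE], 2, f0[!bad], "-"),
               2, f0[!bad], "/")
  structure(out, t = traces$t, excluded = colnames(f)[bad],
            class = c("dff0_traces", class(out)))
}

#' Per-ROI peak dF/F0
#'
#' The maximum dF/F0 per ROI irrespective of when it occurs; in `"quench"`
#' mode the peak is the extremum of largest magnitude (signed value
#' returned). Ties resolve to the earliest time.
#'
#' @param d a `dff0_traces` matrix from [dff0()]
#' @param mode `"rise"` (maximum) or `"quench"` (largest magnitude)
#' @return data.frame with columns `roi`, `peak`, `t_peak`
#' @export
peak_dff0 <- function(d, mode = c("rise", "quench")) {
  mode <- match.arg(mode)
  t <- attr(d, "t")
  rows <- lapply(seq_len(ncol(d)), function(j) {
    v <- d[, j]
    if (all(is.na(v))) stop(sprintf("ROI %s is all-missing", colnames(d)[j]),
                            call. = FALSE)
    i <- if (mode == "rise") which.max(v) else which.max(abs(v))
    data.frame(roi = colnames(d)[j], peak = v[i], t_peak = t[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Windowed area under the dF/F0 curve
#'
#' Trapezoidal integral of each ROI's dF/F0 over `[t0, t1]`; the trace is
#' linearly interpolated at the window endpoints so areas over abutting
#' windows add exactly. The area is signed (negative for a quench).
#'
#' @param d a `dff0_traces` matrix from [dff0()]
#' @param window numeric length-2 `(t0, t1)`, seconds; the magnet-exposure
#'   convention for cumulative calcium responses is 48-180 s
#' @return named numeric vector of areas, one per ROI
#' @export
auc_dff0 <- function(d, window = c(48, 180)) {
  t <- attr(d, "t")
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9 ||
      window[2] <= window[1]) {
    stop("window must be an increasing interval within the trace",
         call. = FALSE)
  }
  inside <- t > window[1] & t < window[2]
  vapply(seq_len(ncol(d)), function(j) {
    v <- d[, j]
    tt <- c(window[1], t[inside], window[2])
    vv <- c(stats::approx(t, v, xout = window[1])$y, v[inside],
            stats::approx(t, v, xout = window[2])$y)
    pracma::trapz(tt, vv)
  }, numeric(1)) |> stats::setNames(colnames(d))
}

#' Group summary of per-ROI (or per-animal) values
#'
#' @param values numeric vector
#' @param groups group labels, same length
#' @return data.frame with per-group `n`, `mean`, `sd`, `sem`; statistical
#'   contrasts are delegated to [welch_t()] / [anova_tukey()]
#' @export
group_summary <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups lengths differ", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  rows <- lapply(split(values, groups), function(v) {
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
               sem = stats::sd(v) / sqrt(length(v)))
  })
  out <- do.call(rbind, rows)
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
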