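#' PET measurement table
#'
#' Validates a per-animal, per-condition table of ROI activity
#' concentrations and dose/weight metadata. Expected columns: `animal`,
#' `condition` (`"baseline"` or `"dmf"`), `c_striatum_L`, `c_striatum_R`,
#' `c_cerebellum` (MBq/ml), `dose_initial`, `dose_residual` (MBq),
#' `weight_g`.
#'
#' @param d data.frame in the layout above
#' @return the validated data.frame, classed `pet_table`
#' @export
pet_table <- function(d) {
  need <- c("animal", "condition", "c_striatum_L", "c_striatum_R",
            "c_cerebellum", "dose_initial", "dose_residual", "weight_g")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(d$dose_residual < 0) || any(d$dose_initial <= d$dose_residual)) {
    stop("need dose_initial > dose_residual >= 0", call. = FALSE)
  }
  conc <- as.matrix(d[, c("c_striatum_L", "c_striatum_R", "c_cerebellum")])
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(d$weight_g <= 0)) stop("weights must be positive", call. = FALSE)
  class(d) <- unique(c("pet_table", class(d)))
  d
}

#' Read a PET measurement CSV
#' @param path CSV path in the [pet_table()] layout
#' @return a `pet_table`
#' @export
read_pet_csv <- function(path) pet_table(utils::read.csv(path))

#' Final injected tracer dose
#'
#' `dose_initial - dose_residual`, per row; the residual is what remained in
#' the syringe after injection.
#'
#' @param m a [pet_table()]
#' @return numeric vector of final doses, MBq
#' @examples
#' m <- pet_table(data.frame(animal = "m1", condition = "baseline",
#'   c_striatum_L = 1, c_striatum_R = 1, c_cerebellum = 1,
#'   dose_initial = 18.5, dose_residual = 0.5, weight_g = 25))
#' final_dose(m)  # 18 MBq
#' @export
final_dose <- function(m) {
  stopifnot(inherits(m, "pet_table"))
  out <- m$dose_initial - m$dose_residual
  if (any(out <= 0)) stop("non-positive final dose", call. = FALSE)
  out
}

#' Percent injected dose per gram of tissue
#'
#' `%ID/g = 100 * C_roi / (final_dose / weight)` under the 1 ml = 1 g tissue
#' density convention. The striatal value is the mean of left and right
#' dorsal striatum.
#'
#' @param m a [pet_table()]
#' @return data.frame with `animal`, `condition`, `idg_striatum`,
#'   `idg_cerebellum` (%ID/g)
#' @export
percent_id_per_g <- function(m) {
  stopifnot(inherits(m, "pet_table"))
  fd <- final_dose(m)
  if (any(m$weight_g <= 0)) stop("zero or negative weight", call. = FALSE)
  per_g <- fd / m$weight_g            # MBq per g of body weight
  striatum <- (m$c_striatum_L + m$c_striatum_R) / 2
  data.frame(animal = m$animal, condition = m$condition,
             idg_striatum = 100 * striatum / per_g,
             idg_cerebellum = 100 * m$c_cerebellum / per_g,
             stringsAsFactors = FALSE)
}

#' Striatum-to-cerebellum reference ratio
#'
#' Averaged striatal uptake divided by cerebellar uptake; the cerebellum
#' lacks D2-type receptors and serves as the reference region. Dose and
#' weight cancel, so the ratio equals the raw concentration ratio and is
#' invariant to global scanner calibration.
#'
#' @param m a [pet_table()]
#' @return data.frame with `animal`, `condition`, `ratio`
#' @export
reference_ratio <- function(m) {
  stopifnot(inherits(m, "pet_table"))
  if (any(m$c_cerebellum <= 0)) stop("zero cerebellum concentration",
                                     call. = FALSE)
  striatum <- (m$c_striatum_L + m$c_striatum_R) / 2
  data.frame(animal = m$animal, condition = m$condition,
             ratio = striatum / m$c_cerebellum, stringsAsFactors = FALSE)
}

#' DMF-over-baseline uptake ratios per animal
#'
#' Matches the two conditions by animal id and reports the field-exposure
#' over baseline ratio of (i) the raw striatal concentration (MBq/ml) and
#' (ii) the cerebellum-referenced uptake.
#'
#' @param m a [pet_table()] containing both conditions
#' @return data.frame with `animal`, `ratio_mbq` and `ratio_ref`
#' @export
dmf_over_baseline <- function(m) {
  stopifnot(inherits(m, "pet_table"))
  bl <- m[m$condition == "baseline", , drop = FALSE]
  df <- m[m$condition == "dmf", , drop = FALSE]
  if (!setequal(bl$animal, df$animal) || anyDuplicated(bl$animal) ||
      anyDuplicated(df$animal)) {
    stop("conditions must contain each animal exactly once", call. = FALSE)
  }
  df <- df[match(bl$animal, df$animal), , drop = FALSE]
  s_bl <- (bl$c_striatum_L + bl$c_striatum_R) / 2
  s_df <- (df$c_striatum_L + df$c_striatum_R) / 2
  if (any(s_bl <= 0)) stop("non-positive baseline striatal uptake",
                           call. = FALSE)
  ref_bl <- s_bl / bl$c_cerebellum
  ref_df <- s_df / df$c_cerebellum
  data.frame(animal = bl$animal, ratio_mbq = s_df / s_bl,
             ratio_ref = ref_df / ref_bl, stringsAsFactors = FALSE)
}

#' Radioactivity unit conversion
#'
#' 1 mCi = 37 MBq exactly.
#'
#' @param x activity values
#' @return converted values
#' @export
mbq_to_uci <- function(x) x * 1000 / 37

#' @rdname mbq_to_uci
#' @export
uci_to_mbq <- function(x) x * 37 / 1000
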