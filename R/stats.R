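#' Welch's two-sample t test
#'
#' Two-tailed t test with Welch's correction (unequal variances,
#' Welch-Satterthwaite degrees of freedom); optionally paired for
#' within-animal baseline-versus-stimulation contrasts.
#'
#' @param a,b numeric vectors (each n >= 2)
#' @param paired paired test (a and b matched per subject)
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`
#' @export
welch_t <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2",
                                             call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && !paired) {
    stop("zero variance in both groups: t undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, paired = paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Pearson correlation with two-tailed p value
#'
#' @param x,y numeric vectors, n >= 3, non-constant
#' @return list with `r`, `p`, `n`
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' One-way ANOVA with Tukey's post hoc comparisons
#'
#' Thin wrapper over `aov()` + `TukeyHSD()` for report formatting of
#' multi-group contrasts.
#'
#' @param values numeric vector
#' @param groups group labels
#' @return list with `anova_p`, `tukey` (data.frame of pairwise contrasts)
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(anova_p = p, tukey = tukey)
}

#' Optional Holm adjustment for a set of per-contrast p values
#'
#' Reported contrasts mirror per-figure tests without multiplicity
#' correction; this exposes Holm's step-down adjustment for users who want
#' it.
#'
#' @param p numeric vector of p values
#' @return adjusted p values
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
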