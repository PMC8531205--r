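#' Two-sample t test on raw group values
#'
#' Welch's t by default; set `pooled = TRUE` for the classical equal-variance
#' Student variant (degrees of freedom `n1 + n2 - 2`). Two-sided.
#'
#' @param group_a,group_b raw values per group, each of length >= 2
#' @param pooled use the pooled-variance Student variant
#' @return list with `t`, `df`, `p`
#' @export
welch_t <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  res <- stats::t.test(group_a, group_b, var.equal = pooled)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Residuals of an allometric (size) regression
#'
#' Ordinary least squares of `y` on `x` (e.g. total length on body mass);
#' the per-animal residuals are returned for downstream group comparison,
#' removing the shared size relationship before testing group effects.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return numeric residuals, in input order
#' @export
allometric_residuals <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  unname(stats::resid(stats::lm(y ~ x)))
}

#' Per-group mean and standard error
#'
#' @param values numeric vector
#' @param group parallel grouping vector
#' @param variable label for the summarized variable (carried through)
#' @return data.frame: `group`, `variable`, `n`, `mean`, `sd`, `sem`
#' @export
group_summary <- function(values, group, variable = NA_character_) {
  sp <- split(values, group)
  data.frame(
    group = names(sp),
    variable = variable,
    n = vapply(sp, length, 1L),
    mean = vapply(sp, mean, 1),
    sd = vapply(sp, stats::sd, 1),
    sem = vapply(sp, function(v) stats::sd(v) / sqrt(length(v)), 1),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
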