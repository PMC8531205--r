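#' Build an aerobic-scope curve from routine and maximum rates
#'
#' Averages routine (rMO2) and maximum (mMO2) mass-specific metabolic rates
#' per test temperature within a group, then computes absolute aerobic scope
#' (AAS = mMO2 - rMO2) and factorial aerobic scope (FAS = mMO2 / rMO2)
#' elementwise on the group means. Scope is computed on group means because
#' routine and maximum rates come from different animals in the underlying
#' design; supply per-animal data and call once per animal for a per-animal
#' variant. Temperatures missing either rate yield missing scope, never an
#' imputed value; FAS is missing where rMO2 is zero.
#'
#' @param rmo2 data.frame with `test_temp_C` and `mo2` columns (routine,
#'   mass-specific, umol O2 per g per h); one row per animal-temperature
#' @param mmo2 same shape, maximum rates
#' @param group group label carried through
#' @return a `scope_curve` data.frame: `test_temp_C`, `rmo2_mean`,
#'   `mmo2_mean`, `aas`, `fas`, `group`
#' @export
build_scope_curve <- function(rmo2, mmo2, group = NA_character_) {
  stopifnot(all(c("test_temp_C", "mo2") %in% names(rmo2)),
            all(c("test_temp_C", "mo2") %in% names(mmo2)))
  rm_means <- tapply(rmo2$mo2, rmo2$test_temp_C, mean, na.rm = TRUE)
  mm_means <- tapply(mmo2$mo2, mmo2$test_temp_C, mean, na.rm = TRUE)
  temps <- sort(unique(c(as.numeric(names(rm_means)),
                         as.numeric(names(mm_means)))))
  shared <- intersect(as.numeric(names(rm_means)),
                      as.numeric(names(mm_means)))
  if (length(shared) < 2) {
    stop("need at least 2 test temperatures with both routine and maximum rates")
  }
  rmean <- rm_means[match(temps, as.numeric(names(rm_means)))]
  mmean <- mm_means[match(temps, as.numeric(names(mm_means)))]
  aas <- as.numeric(mmean - rmean)
  fas <- ifelse(!is.na(rmean) & rmean > 0, as.numeric(mmean / rmean), NA_real_)
  structure(data.frame(test_temp_C = temps,
                       rmo2_mean = as.numeric(rmean),
                       mmo2_mean = as.numeric(mmean),
                       aas = aas, fas = fas, group = group,
                       stringsAsFactors = FALSE),
            class = c("scope_curve", "data.frame"))
}

#' Fit a Gaussian thermal performance curve
#'
#' Nonlinear least squares of `a * exp(-(T - mu)^2 / (2 * sigma^2))`
#' (optionally plus a baseline offset) to scope-versus-temperature points,
#' with multiple starts of `mu` over the observed temperature grid; the best
#' converged start by residual sum of squares wins. Monotone data pin the
#' fitted optimum at or beyond the warmest test temperature; such fits are
#' flagged `boundary`.
#'
#' @param temps test temperatures, degC
#' @param values scope (or any rate) values at those temperatures
#' @param with_baseline fit a 4th baseline parameter (default FALSE)
#' @return a `tpc_fit`: list with `amplitude`, `t_opt_C`, `breadth_C`,
#'   `baseline`, `rss`, `converged`, `boundary`
#' @export
fit_gaussian_tpc <- function(temps, values, with_baseline = FALSE) {
  stopifnot(length(temps) == length(values))
  ok <- is.finite(temps) & is.finite(values)
  temps <- temps[ok]; values <- values[ok]
  n_par <- if (with_baseline) 4L else 3L
  if (length(temps) < n_par + 1L) {
    stop(sprintf("need at least %d points for a %d-parameter fit",
                 n_par + 1L, n_par))
  }
  span <- diff(range(temps))
  mu_grid <- unique(c(temps, mean(temps)))
  best <- NULL
  for (mu0 in mu_grid) {
    start <- list(a = max(values) - if (with_baseline) min(values) else 0,
                  mu = mu0, sigma = span / 3)
    if (with_baseline) start$b <- min(values)
    form <- if (with_baseline) {
      values ~ a * exp(-(temps - mu)^2 / (2 * sigma^2)) + b
    } else {
      values ~ a * exp(-(temps - mu)^2 / (2 * sigma^2))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, start = start,
                        lower = c(a = 0, mu = min(temps) - 10,
                                  sigma = 1e-3,
                                  if (with_baseline) c(b = -Inf)),
                        upper = c(a = Inf, mu = max(temps) + 10,
                                  sigma = Inf,
                                  if (with_baseline) c(b = Inf)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(amplitude = unname(cf["a"]), t_opt_C = unname(cf["mu"]),
                   breadth_C = unname(cf["sigma"]),
                   baseline = if (with_baseline) unname(cf["b"]) else 0,
                   rss = rss, converged = TRUE)
    }
  }
  if (is.null(best)) {
    return(structure(list(amplitude = NA_real_, t_opt_C = NA_real_,
                          breadth_C = NA_real_, baseline = NA_real_,
                          rss = Inf, converged = FALSE, boundary = NA),
                     class = "tpc_fit"))
  }
  best$boundary <- best$t_opt_C >= max(temps) || best$t_opt_C <= min(temps)
  structure(best, class = "tpc_fit")
}

#' Q10 temperature coefficient
#'
#' The factor by which a physiological rate changes over a 10 degC span:
#' `q10 = (rate2 / rate1) ^ (10 / (temp2 - temp1))`.
#'
#' @param rate1,rate2 rates at `temp1_C` and `temp2_C` (both positive)
#' @param temp1_C,temp2_C temperatures, degC (must differ)
#' @return a `q10_result`: list with the inputs and `q10`
#' @export
q10 <- function(rate1, rate2, temp1_C, temp2_C) {
  if (rate1 <= 0 || rate2 <= 0) stop("rates must be positive")
  if (temp1_C == temp2_C) stop("temperatures must differ")
  val <- (rate2 / rate1)^(10 / (temp2_C - temp1_C))
  structure(list(rate1 = rate1, rate2 = rate2,
                 temp1_C = temp1_C, temp2_C = temp2_C, q10 = val),
            class = "q10_result")
}
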