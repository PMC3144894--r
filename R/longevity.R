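# Relating adult longevity to social structure. Per-individual metrics are
# averaged over the adult years (ages two to death), regressed on longevity
# by OLS, and tested by Manly-style randomization of the response because
# age at death is not normally distributed. Residual control removes group
# size / observation effort; a fixed-effects group term checks dependency
# between group-mates.

#' Average a metric over an individual's adult years
#'
#' Social metrics of animals present in multiple years are averaged over
#' all years from age two until death. Years with a missing metric are
#' dropped with a warning; an individual with no adult-year values is
#' signalled for exclusion.
#'
#' @param values Numeric metric values, one per adult year.
#' @param ages Optional ages (years) aligned with `values`; only entries
#'   with `age >= 2` contribute.
#' @return Mean over available adult years.
#' @export
average_adult_metrics <- function(values, ages = NULL) {
  if (!is.null(ages)) values <- values[ages >= 2]
  keep <- !is.na(values)
  if (sum(keep) == 0) {
    abort("No adult-year metric values; exclude this individual.",
          class = "socnetlong_exclude_individual")
  }
  if (any(!keep)) {
    warn(sprintf("Dropping %d missing adult-year value(s) before averaging.",
                 sum(!keep)))
  }
  mean(values[keep])
}

#' Ordinary least squares fit
#'
#' Thin wrapper around [stats::lm()] that names collinear columns instead
#' of silently dropping them.
#'
#' @param data Data frame containing response and predictors.
#' @param formula Model formula.
#' @return The `lm` fit.
#' @export
fit_ols <- function(data, formula) {
  fit <- lm(formula, data = data)
  if (any(is.na(coef(fit)))) {
    abort(sprintf("Rank-deficient design; collinear column(s): %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  fit
}

ols_slope_r2 <- function(y, x) {
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx == 0) return(c(slope = 0, r2 = 0))
  slope <- sum(xc * yc) / sxx
  sst <- sum(yc^2)
  r2 <- if (sst == 0) 0 else slope^2 * sxx / sst
  c(slope = slope, r2 = r2)
}

#' Randomization test for a regression slope
#'
#' Fits `y ~ x` by least squares and computes the p-value of the slope by
#' Manly-style randomization: the response is permuted, the model refit,
#' and the add-one Monte-Carlo p-value is the fraction of permuted slopes
#' at least as extreme as the observed one (two-tailed by default).
#'
#' @param data Data frame.
#' @param formula Two-sided formula `y ~ x` with a single predictor.
#' @param n_perm Number of permutations (>= 100).
#' @param tail `"two"` (default), `"greater"`, or `"less"`.
#' @return A `rand_reg` object with slope, r-squared, p-value, and the null
#'   slope distribution.
#' @export
randomization_regression <- function(data, formula, n_perm = 10000,
                                     tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  if (n_perm < 100) {
    abort("`n_perm` must be at least 100.", class = "socnetlong_config_error")
  }
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (ncol(mf) != 2) abort("Formula must have exactly one predictor.")
  x <- mf[[2]]
  if (length(y) < 5) abort("Need at least 5 observations.")
  obs <- ols_slope_r2(y, x)
  null_slopes <- vapply(seq_len(n_perm), function(i) {
    ols_slope_r2(sample(y), x)[["slope"]]
  }, numeric(1))
  exceed <- switch(tail,
    two = sum(abs(null_slopes) >= abs(obs[["slope"]])),
    greater = sum(null_slopes >= obs[["slope"]]),
    less = sum(null_slopes <= obs[["slope"]])
  )
  p <- (exceed + 1) / (n_perm + 1)
  structure(
    list(slope = unname(obs[["slope"]]), r_squared = unname(obs[["r2"]]),
         p_value = p, n_perm = n_perm, n = length(y), tail = tail,
         null_slopes = null_slopes, formula = formula,
         data = tibble::tibble(y = y, x = x)),
    class = "rand_reg"
  )
}

#' @export
print.rand_reg <- function(x, ...) {
  cat(sprintf(
    "<rand_reg> n=%d: slope=%.4g, r2=%.3f, randomization p=%.4g (%d perms, %s-tailed)\n",
    x$n, x$slope, x$r_squared, x$p_value, x$n_perm, x$tail
  ))
  invisible(x)
}

#' @export
tidy.rand_reg <- function(x, ...) {
  tibble::tibble(term = all.vars(x$formula)[2], estimate = x$slope,
                 p.value = x$p_value)
}

#' @export
glance.rand_reg <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 p.value = x$p_value, n = x$n, n_perm = x$n_perm)
}

#' Scatter plot with fitted line for a randomization regression
#'
#' @param object A `rand_reg`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rand_reg <- function(object, ...) {
  vars <- all.vars(object$formula)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = vars[2], y = vars[1],
      title = sprintf("slope = %.3g, r2 = %.3f, randomization p = %.4g",
                      object$slope, object$r_squared, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Residuals controlling for nuisance covariates
#'
#' Residuals of the OLS regression of `y` on the control columns (with
#' intercept); used to remove group-size and observation-effort effects
#' before regressing on the social predictor of interest.
#'
#' @param y Response vector.
#' @param controls Data frame or matrix of control covariates.
#' @return Residual vector (sums to zero).
#' @export
residual_control <- function(y, controls) {
  df <- as.data.frame(controls)
  fit <- lm(y ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    abort(sprintf("Rank-deficient controls: %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  unname(resid(fit))
}

#' Fixed-effects check for group dependency
#'
#' Adds a group indicator block to the longevity regression and reports
#' partial F tests for the predictor and the group term, to check whether
#' shared group membership (non-independence of group-mates) accounts for
#' the social effect.
#'
#' @param data Data frame with the response, predictor and group label.
#' @param response,predictor,group Column names (strings).
#' @return Tibble with one row per term: `term`, `df`, `df_resid`,
#'   `statistic` (partial F), `p.value`.
#' @export
group_effect_model <- function(data, response, predictor, group) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  sizes <- table(g)
  if (any(sizes == 1)) {
    warn(sprintf("%d group(s) have a single member; retained.",
                 sum(sizes == 1)))
  }
  df <- data.frame(y = data[[response]], x = data[[predictor]], g = g)
  full <- lm(y ~ g + x, data = df)
  no_x <- lm(y ~ g, data = df)
  no_g <- lm(y ~ x, data = df)
  f_of <- function(reduced) {
    a <- anova(reduced, full)
    tibble::tibble(df = a$Df[2], df_resid = a$Res.Df[2],
                   statistic = a$F[2], p.value = a$`Pr(>F)`[2])
  }
  dplyr::bind_rows(
    dplyr::mutate(f_of(no_x), term = predictor, .before = 1),
    dplyr::mutate(f_of(no_g), term = group, .before = 1)
  )
}

#' Aggression rates controlled for group size and observation effort
#'
#' The "controlled" aggression rate is the residual of an OLS regression of
#' agonistic-day counts on group size and observed days (with intercept):
#' positive values mean more aggression than expected for that group size
#' and observation effort.
#'
#' @param counts Number of days with agonistic involvement (individual
#'   level) or agonistic interactions (group level).
#' @param group_size Group size covariate.
#' @param observed_days Days observed covariate.
#' @return Numeric residual vector (sums to zero).
#' @export
aggression_rate <- function(counts, group_size, observed_days) {
  if (any(counts < 0)) abort("`counts` must be nonnegative.")
  if (any(observed_days <= 0)) abort("`observed_days` must be positive.")
  if (all(counts == 0)) return(rep(0, length(counts)))
  residual_control(counts, data.frame(group_size = group_size,
                                      observed_days = observed_days))
}
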