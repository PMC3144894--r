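test_that("adult-lifetime averaging follows the stated rules", {
  expect_equal(average_adult_metrics(c(0.2, 0.3, 0.4), ages = c(2, 3, 4)), 0.3)
  expect_equal(average_adult_metrics(0.7, ages = 2), 0.7)
  expect_warning(
    m <- average_adult_metrics(c(0.2, NA, 0.4), ages = c(2, 3, 4)),
    "missing"
  )
  expect_equal(m, 0.3)
  # juvenile years never contribute
  expect_equal(average_adult_metrics(c(9, 0.2, 0.4), ages = c(1, 2, 3)), 0.3)
  expect_error(average_adult_metrics(c(1, 2), ages = c(0, 1)),
               class = "socnetlong_exclude_individual")
})

test_that("OLS slope and r-squared match hand calculations", {
  df <- data.frame(x = 1:4, y = c(1, 2, 2, 3))
  fit <- fit_ols(df, y ~ x)
  expect_equal(unname(coef(fit)["x"]), 0.6)
  df2 <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(suppressWarnings(summary(fit_ols(df2, y ~ x))$r.squared), 1)
  df3 <- data.frame(x = 1:10, y = rep(2, 10))
  expect_equal(unname(coef(fit_ols(df3, y ~ x))["x"]), 0)
  df4 <- data.frame(x = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(fit_ols(df4, y ~ x + x2), "collinear")
})

test_that("randomization regression recovers exact and degenerate cases", {
  set.seed(81)
  df <- data.frame(x = 1:10, y = 1:10)
  rr <- randomization_regression(df, y ~ x, n_perm = 999)
  expect_equal(rr$slope, 1)
  expect_equal(rr$r_squared, 1)
  expect_equal(rr$p_value, 1 / 1000)
  # constant response: slope 0, p = 1
  dfc <- data.frame(x = 1:8, y = rep(3, 8))
  rrc <- randomization_regression(dfc, y ~ x, n_perm = 199)
  expect_equal(rrc$slope, 0)
  expect_equal(rrc$p_value, 1)
  expect_error(randomization_regression(df, y ~ x, n_perm = 10),
               class = "socnetlong_config_error")
})

test_that("randomization p-values are uniform under the null", {
  set.seed(82)
  ps <- vapply(1:300, function(i) {
    df <- data.frame(x = rnorm(20), y = rnorm(20))
    randomization_regression(df, y ~ x, n_perm = 199)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  rej <- mean(ps < 0.05)
  expect_gt(rej, 0.01); expect_lt(rej, 0.10)
})

test_that("residual control satisfies the Frisch-Waugh-Lovell identity", {
  set.seed(83)
  for (rep in 1:10) {
    n <- 40
    controls <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
    x <- rnorm(n) + 0.5 * controls$c1
    y <- 1.5 * x - 0.8 * controls$c1 + 0.3 * controls$c2 + rnorm(n)
    ry <- residual_control(y, controls)
    rx <- residual_control(x, controls)
    partial <- unname(coef(lm(ry ~ rx))["rx"])
    joint <- unname(coef(lm(y ~ x + c1 + c2,
                            data = cbind(data.frame(x = x, y = y),
                                         controls)))["x"])
    expect_equal(partial, joint, tolerance = 1e-10)
    expect_equal(mean(ry), 0, tolerance = 1e-12)
  }
  # response already in the span of the controls -> zero residuals
  ctr <- data.frame(c1 = 1:10)
  expect_equal(residual_control(2 * (1:10) + 3, ctr), rep(0, 10),
               tolerance = 1e-12)
})

test_that("orthogonal controls leave the slope of interest unchanged", {
  # constructed orthogonality: control orthogonal (and uncorrelated) to x
  x <- rep(c(-1, 1), 10)
  ctrl <- rep(c(-1, -1, 1, 1), 5)
  stopifnot(abs(sum(x * ctrl)) < 1e-12)
  set.seed(84)
  y <- 2 * x + 0.7 * ctrl + rnorm(20, sd = 0.1)
  ry <- residual_control(y, data.frame(ctrl = ctrl))
  expect_equal(unname(coef(lm(ry ~ x))["x"]), unname(coef(lm(y ~ x))["x"]),
               tolerance = 1e-10)
})

test_that("group fixed-effects model separates predictor and group terms", {
  set.seed(85)
  hits_pred <- 0; hits_grp <- 0
  n_rep <- 100
  for (rep in seq_len(n_rep)) {
    g <- factor(sample(rep(1:6, length.out = 34)))
    x <- rnorm(34)
    y <- -0.8 * x + rnorm(34)  # predictor effect, no group effect
    res <- group_effect_model(data.frame(y = y, x = x, g = g), "y", "x", "g")
    hits_pred <- hits_pred + (res$p.value[res$term == "x"] < 0.05)
    hits_grp <- hits_grp + (res$p.value[res$term == "g"] < 0.05)
  }
  expect_gte(hits_pred / n_rep, 0.8)
  expect_lte(hits_grp / n_rep, 0.15)
  # degrees of freedom follow the indicator-block layout
  g <- factor(rep(1:6, length.out = 34))
  res <- group_effect_model(
    data.frame(y = rnorm(34), x = rnorm(34), g = g), "y", "x", "g"
  )
  expect_equal(res$df[res$term == "g"], 5)
  expect_equal(res$df_resid, c(27, 27))
  expect_error(
    group_effect_model(data.frame(y = rnorm(10), x = rnorm(10),
                                  g = factor(rep(1, 10))), "y", "x", "g"),
    "2 groups"
  )
})

test_that("aggression rates are residuals controlling size and effort", {
  set.seed(86)
  size <- runif(20, 5, 20)
  days <- runif(20, 10, 60)
  # counts exactly linear in the controls -> all rates zero
  counts <- 2 + 0.5 * size + 0.1 * days
  expect_equal(aggression_rate(counts, size, days), rep(0, 20),
               tolerance = 1e-10)
  # an individual with excess aggression gets a positive rate
  counts2 <- counts
  counts2[7] <- counts2[7] + 10
  r <- aggression_rate(counts2, size, days)
  expect_gt(r[7], 0)
  expect_equal(sum(r), 0, tolerance = 1e-10)
  expect_equal(aggression_rate(rep(0, 20), size, days), rep(0, 20))
})
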