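hand_pars <- list(S = 0.8, p = 0.5, r = 0.2, R = 0.3, Rp = 0.1,
                  F = 0.9, Fp = 0)

test_that("history constructor enforces event ordering", {
  expect_error(
    encounter_histories(matrix(c(0, 1, 0), 1, 3),
                        matrix(c(1L, 0L), 1, 2)),
    class = "socnetlong_history_error"
  )
  expect_error(
    encounter_histories(matrix(c(1, 0, 1), 1, 3),
                        matrix(c(2L, 0L), 1, 2)),
    class = "socnetlong_history_error"
  )
  expect_error(
    encounter_histories(matrix(c(1, 0, 0), 1, 3),
                        matrix(c(2L, 1L), 1, 2)),
    class = "socnetlong_history_error"
  )
  h <- encounter_histories(matrix(c(1, 1, 0), 1, 3),
                           matrix(c(1L, 2L), 1, 2))
  expect_equal(h$first, 1L)
})

test_that("forward likelihood reproduces the hand-enumerated release", {
  h <- encounter_histories(matrix(c(1, 0), 1, 2), matrix(0L, 1, 1))
  expect_equal(barker_history_probability(h, hand_pars), 0.452,
               tolerance = 1e-12)
  # certain survival, capture, fidelity, no resight: recapture certain
  h2 <- encounter_histories(matrix(c(1, 1), 1, 2), matrix(0L, 1, 1))
  expect_equal(
    barker_history_probability(h2, list(S = 1, p = 1, r = 0, R = 0, Rp = 0,
                                        F = 1, Fp = 0)), 1
  )
})

test_that("forward recursion equals exhaustive path enumeration (T <= 4)", {
  set.seed(91)
  for (rep in 1:20) {
    par <- list(S = runif(1), p = runif(1), r = runif(1), R = runif(1),
                Rp = runif(1), F = runif(1), Fp = runif(1))
    T <- sample(2:4, 1)
    f <- sample(seq_len(T - 1), 1)
    for (hh in enumerate_histories(T, f)) {
      h <- encounter_histories(matrix(hh$caps, 1), matrix(hh$events, 1))
      got <- barker_history_probability(h, par)
      want <- oracle_barker(hh$caps, hh$events, par)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("probabilities over all possible histories sum to one (T <= 3)", {
  set.seed(92)
  for (rep in 1:10) {
    par <- list(S = runif(1), p = runif(1), r = runif(1), R = runif(1),
                Rp = runif(1), F = runif(1), Fp = runif(1))
    for (T in 2:3) {
      for (f in seq_len(T - 1)) {
        tot <- sum(vapply(enumerate_histories(T, f), function(hh) {
          h <- encounter_histories(matrix(hh$caps, 1), matrix(hh$events, 1))
          barker_history_probability(h, par)
        }, numeric(1)))
        expect_equal(tot, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("with r = R = R' = 0, F = 1 the model reduces to CJS", {
  # algebraic reduction on one history
  h <- encounter_histories(matrix(c(1, 0), 1, 2), matrix(0L, 1, 1))
  S <- 0.7; p <- 0.4
  got <- barker_history_probability(
    h, list(S = S, p = p, r = 0, R = 0, Rp = 0, F = 1, Fp = 0)
  )
  expect_equal(got, (1 - S) + S * (1 - p), tolerance = 1e-12)

  # fitted estimates agree with an independent CJS likelihood
  truth <- list(S = 0.75, p = 0.6, r = 0, R = 0, Rp = 0, F = 1, Fp = 0)
  hist <- simulate_encounter_histories(truth, 600, 6, seed = 93)
  fit <- fit_barker(hist, barker_spec(fixed = list(r = 0, R = 0, Rp = 0,
                                                   F = 1, Fp = 0)))
  cjs <- optim(c(0, 0), cjs_negloglik, caps = hist$caps, method = "BFGS")
  expect_equal(
    sort(dplyr::filter(fit$estimates, !fixed)$estimate),
    sort(plogis(cjs$par)), tolerance = 1e-4
  )
})

test_that("QAICc and Akaike weights follow their closed forms", {
  expect_equal(qaicc(-100, 5, 100, 1), 200 + 10 + 60 / 94, tolerance = 1e-12)
  # doubling c-hat halves the deviance term
  expect_equal(qaicc(-100, 5, 100, 2) - (10 + 60 / 94), 100)
  fits <- list(
    a = structure(list(qaicc = 100, K = 4, loglik = -45,
                       c_hat = 1, hist_dim = c(n = 10, T = 4),
                       spec = list(name = "a")), class = "barker_fit"),
    b = structure(list(qaicc = 102, K = 5, loglik = -44,
                       c_hat = 1, hist_dim = c(n = 10, T = 4),
                       spec = list(name = "b")), class = "barker_fit")
  )
  tab <- model_table(fits)
  expect_equal(tab$weight, c(exp(0) / (exp(0) + exp(-1)),
                             exp(-1) / (exp(0) + exp(-1))),
               tolerance = 1e-6)
  expect_equal(round(tab$weight, 3), c(0.731, 0.269))
  expect_equal(model_table(fits["a"])$weight, 1)
  fits$b$qaicc <- 100
  expect_equal(model_table(fits)$weight, c(0.5, 0.5))
})

test_that("model averaging combines estimates and spread", {
  mk <- function(name, q, est, se) {
    structure(list(
      qaicc = q, K = 3, loglik = -q / 2, c_hat = 1,
      hist_dim = c(n = 10, T = 4), spec = list(name = name),
      estimates = tibble::tibble(parameter = "S", stratum = "all",
                                 estimate = est, se = se, fixed = FALSE)
    ), class = "barker_fit")
  }
  fits <- list(m1 = mk("m1", 100, 0.7, 0.02), m2 = mk("m2", 100, 0.8, 0.02))
  avg <- model_average(fits, "S")
  expect_equal(avg$estimate, 0.75)
  expect_gt(avg$se, 0.02)  # between-model spread inflates the SE
  one <- model_average(fits["m1"], "S")
  expect_equal(one$estimate, 0.7)
  expect_equal(one$se, 0.02, tolerance = 1e-12)
  expect_error(model_average(fits, "Fp"), "not estimable")
})

test_that("likelihood ratio test handles identical and nested fits", {
  truth <- list(S = 0.75, p = 0.85, r = 0.1, R = 0.3, Rp = 0.05,
                F = 1, Fp = 0)
  h <- simulate_encounter_histories(truth, 200, 5, seed = 94)
  f1 <- fit_barker(h, barker_spec(fixed = list(F = 1, Fp = 0)))
  expect_equal(likelihood_ratio_test(f1, f1)$p.value, 1)
  f2 <- fit_barker(h, barker_spec(S = ~time, fixed = list(F = 1, Fp = 0)))
  lrt <- likelihood_ratio_test(f1, f2)
  expect_equal(lrt$df, 3)
  expect_gte(lrt$statistic, 0)
  expect_error(likelihood_ratio_test(f2, f1), "not nested")
})

test_that("parameter recovery from simulated constant-model data", {
  truth <- list(S = 0.75, p = 0.85, r = 0.1, R = 0.4, Rp = 0.05,
                F = 0.95, Fp = 0.2)
  hist <- simulate_encounter_histories(truth, 1000, 8, seed = 95)
  fit <- fit_barker(hist, barker_spec())
  expect_true(fit$convergence)
  est <- fit$estimates
  for (pp in c("S", "p", "r", "R", "F")) {
    row <- est[est$parameter == pp, ]
    expect_lt(abs(row$estimate - truth[[pp]]), 3 * row$se + 0.02)
  }
})

test_that("simulated histories are reproducible and respect limits", {
  truth <- list(S = 1, p = 1, r = 0, R = 0, Rp = 0, F = 1, Fp = 0)
  h <- simulate_encounter_histories(truth, 50, 5, seed = 96)
  expect_true(all(h$caps == 1))  # immortal, perfectly detected
  h1 <- simulate_encounter_histories(hand_pars, 100, 4, seed = 97)
  h2 <- simulate_encounter_histories(hand_pars, 100, 4, seed = 97)
  expect_identical(h1$caps, h2$caps)
  expect_identical(h1$events, h2$events)
  # empirical never-seen-again fraction matches the hand value 0.452
  h3 <- simulate_encounter_histories(hand_pars, 10000, 2, seed = 98)
  unseen <- mean(h3$caps[, 2] == 0 & h3$events[, 1] == 0)
  expect_lt(abs(unseen - 0.452), 3 * sqrt(0.452 * 0.548 / 10000))
})

test_that("LD string export interleaves captures and interval events", {
  h <- encounter_histories(matrix(c(1, 1, 0), 1, 3), matrix(c(1L, 2L), 1, 2))
  expect_equal(format_ld_strings(h), "11120")
})
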