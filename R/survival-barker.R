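# Barker joint live-recapture / dead-recovery / live-resight survival model.
#
# Seven probability parameters per interval/occasion:
#   S  survival over interval (i, i+1)
#   p  capture at occasion i, given alive and at risk of capture
#   r  dead recovery: animal dying in the interval is found and reported
#   R  live resight during the interval, given survival to i+1
#   R' live resight before death, for an animal dying in the interval
#   F  fidelity: at risk at i stays at risk at i+1
#   F' re-immigration: off risk at i returns to risk at i+1
#
# The likelihood is computed as a hidden-state forward recursion per animal
# over states {alive at risk, alive off risk, dead-unobserved}, conditioned
# on first release; this is algebraically equivalent to the classical
# multinomial form and is verified against exhaustive path enumeration in
# the tests.

EVENT_CODES <- c(none = 0L, resighted = 1L, found_dead = 2L,
                 resighted_then_dead = 3L)

#' Construct an encounter-history set
#'
#' @param caps Integer 0/1 matrix, animals x occasions: live captures.
#' @param events Integer matrix, animals x (occasions - 1): interval event
#'   codes (0 = none, 1 = resighted alive, 2 = found dead, 3 = resighted
#'   then found dead).
#' @param covariates Optional tibble of per-animal covariates (e.g. `group`,
#'   `age_class`), one row per animal.
#' @return An `encounter_histories` object with elements `caps`, `events`,
#'   `first` (occasion of first capture), `covariates`, `n`, `T`.
#' @export
encounter_histories <- function(caps, events, covariates = NULL) {
  caps <- as.matrix(caps); storage.mode(caps) <- "integer"
  events <- as.matrix(events); storage.mode(events) <- "integer"
  n <- nrow(caps); T <- ncol(caps)
  if (nrow(events) != n || ncol(events) != T - 1) {
    abort("`events` must be animals x (occasions - 1).")
  }
  if (!all(caps %in% c(0L, 1L))) abort("`caps` must be 0/1.")
  if (!all(events %in% EVENT_CODES)) abort("Unknown interval event code.")
  first <- apply(caps, 1, function(x) which(x == 1L)[1])
  if (any(is.na(first))) abort("Every animal must be captured at least once.")
  # no events of any kind before first capture or after a dead recovery
  for (a in seq_len(n)) {
    if (first[a] > 1 && any(events[a, seq_len(first[a] - 1)] != 0L)) {
      abort(sprintf("Animal %d has interval events before first capture.", a),
            class = "socnetlong_history_error")
    }
    dead_at <- which(events[a, ] %in% c(2L, 3L))
    if (length(dead_at)) {
      d <- dead_at[1]
      later_ev <- if (d < T - 1) events[a, (d + 1):(T - 1)] else integer(0)
      later_cap <- if (d < T) caps[a, (d + 1):T] else integer(0)
      if (any(later_ev != 0L) || any(later_cap != 0L) || length(dead_at) > 1) {
        abort(sprintf("Animal %d has events after its dead recovery.", a),
              class = "socnetlong_history_error")
      }
    }
  }
  if (is.null(covariates)) covariates <- tibble::tibble(.rows = n)
  structure(list(caps = caps, events = events, first = as.integer(first),
                 covariates = tibble::as_tibble(covariates),
                 n = n, T = T),
            class = "encounter_histories")
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat(sprintf("<encounter_histories> %d animals, %d occasions\n", x$n, x$T))
  invisible(x)
}

#' Read/write encounter histories as CSV
#'
#' Columns: `id`, any covariate columns, then `cap_1 .. cap_T` (0/1
#' captures) and `ev_1 .. ev_{T-1}` (interval event codes).
#'
#' @param path CSV path.
#' @return An `encounter_histories` object.
#' @export
read_encounter_histories <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  cap_cols <- grep("^cap_", names(df), value = TRUE)
  ev_cols <- grep("^ev_", names(df), value = TRUE)
  cov_cols <- setdiff(names(df), c("id", cap_cols, ev_cols))
  encounter_histories(
    as.matrix(df[cap_cols]), as.matrix(df[ev_cols]),
    covariates = df[cov_cols]
  )
}

#' @rdname read_encounter_histories
#' @param hist An `encounter_histories` object.
#' @export
write_encounter_histories <- function(hist, path) {
  caps <- hist$caps; colnames(caps) <- paste0("cap_", seq_len(ncol(caps)))
  evs <- hist$events; colnames(evs) <- paste0("ev_", seq_len(ncol(evs)))
  df <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("a%04d", seq_len(hist$n))),
    hist$covariates, tibble::as_tibble(caps), tibble::as_tibble(evs)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' MARK-style LD strings (best effort)
#'
#' Interleaves capture and interval-event columns into `LDLD...L` strings
#' (capture flag, then interval code). Provided for eyeballing and rough
#' interchange; bit-exact compatibility with external software input
#' formats is not attempted.
#'
#' @param hist An `encounter_histories` object.
#' @return Character vector of strings, one per animal.
#' @export
format_ld_strings <- function(hist) {
  vapply(seq_len(hist$n), function(a) {
    out <- character(0)
    for (i in seq_len(hist$T)) {
      out <- c(out, hist$caps[a, i])
      if (i < hist$T) out <- c(out, hist$events[a, i])
    }
    paste(out, collapse = "")
  }, character(1))
}

# ---- parameter structures --------------------------------------------------

BARKER_PARS <- c("S", "p", "r", "R", "Rp", "F", "Fp")

#' Specify a Barker model structure
#'
#' Each of the seven parameters gets a formula over per-animal covariates
#' and/or `time` (factor of interval or occasion index), on the logit
#' scale, or a fixed probability via `fixed`. `~1` is the constant
#' structure; `~group` lets the parameter differ by group; `~time` makes it
#' fully time-dependent; `~group + time` is additive.
#'
#' @param S,p,r,R,Rp,F,Fp Formulas (right-hand side) for survival, capture,
#'   dead recovery, resight, resight-before-death, fidelity and
#'   re-immigration.
#' @param fixed Named list of parameters held at fixed probabilities, e.g.
#'   `list(Fp = 0)` for permanent emigration.
#' @param name Optional model label.
#' @return A `barker_spec` object.
#' @export
barker_spec <- function(S = ~1, p = ~1, r = ~1, R = ~1, Rp = ~1,
                        F = ~1, Fp = ~1, fixed = list(), name = NULL) {
  forms <- list(S = S, p = p, r = r, R = R, Rp = Rp, F = F, Fp = Fp)
  if (!all(names(fixed) %in% BARKER_PARS)) {
    abort("`fixed` names must be Barker parameters (S, p, r, R, Rp, F, Fp).")
  }
  for (v in fixed) {
    if (!is.numeric(v) || v < 0 || v > 1) abort("Fixed values must be in [0,1].")
  }
  if (is.null(name)) {
    lab <- vapply(BARKER_PARS, function(pp) {
      if (pp %in% names(fixed)) sprintf("=%g", fixed[[pp]])
      else paste0("(", deparse(forms[[pp]][[2]]), ")")
    }, character(1))
    name <- paste0(BARKER_PARS, lab, collapse = " ")
  }
  structure(list(formulas = forms, fixed = fixed, name = name),
            class = "barker_spec")
}

#' @export
print.barker_spec <- function(x, ...) {
  cat("<barker_spec>", x$name, "\n")
  invisible(x)
}

# Long covariate frame for one parameter: animals x units (intervals for
# all but p; occasions 2..T for p), with `time` as a factor.
barker_design <- function(spec, hist) {
  n <- hist$n; T <- hist$T
  designs <- list()
  for (pp in BARKER_PARS) {
    n_units <- if (pp == "p") T - 1 else T - 1  # p applies to occasions 2..T
    long <- hist$covariates[rep(seq_len(n), times = n_units), , drop = FALSE]
    long$time <- factor(rep(seq_len(n_units), each = n))
    if (pp %in% names(spec$fixed)) {
      designs[[pp]] <- list(fixed = spec$fixed[[pp]], n_units = n_units)
    } else {
      X <- model.matrix(spec$formulas[[pp]], data = long)
      if (qr(X)$rank < ncol(X)) {
        abort(sprintf("Design for %s is rank deficient.", pp))
      }
      designs[[pp]] <- list(X = X, n_units = n_units,
                            long = long[, intersect(names(long),
                                                    all.vars(spec$formulas[[pp]])),
                                        drop = FALSE])
    }
  }
  designs
}

# Coefficients vector -> list of n x n_units probability matrices.
barker_probs <- function(designs, theta, n) {
  out <- list(); pos <- 0
  for (pp in BARKER_PARS) {
    d <- designs[[pp]]
    if (!is.null(d$fixed)) {
      out[[pp]] <- matrix(d$fixed, n, d$n_units)
    } else {
      k <- ncol(d$X)
      eta <- d$X %*% theta[(pos + 1):(pos + k)]
      out[[pp]] <- matrix(plogis(eta), n, d$n_units)
      pos <- pos + k
    }
  }
  out
}

barker_npar <- function(designs) {
  sum(vapply(designs, function(d) if (is.null(d$fixed)) ncol(d$X) else 0L,
             integer(1)))
}

#' Likelihood of encounter histories under given Barker parameters
#'
#' Vectorized hidden-state forward recursion over {alive at risk, alive off
#' risk, dead unobserved}, conditioned on each animal's first release. Per
#' interval: survival, then the resight/recovery emission (R on the
#' survival branch; R' and r on the death branch), the fidelity transition
#' (F from at-risk, F' from off-risk), and the capture emission at the next
#' occasion (p for at-risk animals; off-risk animals cannot be captured).
#'
#' @param hist An `encounter_histories` object.
#' @param probs Named list of probability matrices (`S`, `p`, `r`, `R`,
#'   `Rp`, `F`, `Fp`), each animals x (occasions - 1); column i of `p`
#'   refers to capture at occasion i + 1. Scalars are recycled.
#' @param log Return per-animal log-probabilities?
#' @return Numeric vector of per-animal history probabilities.
#' @export
barker_history_probability <- function(hist, probs, log = FALSE) {
  n <- hist$n; T <- hist$T
  P <- lapply(probs, function(m) {
    if (length(m) == 1) matrix(m, n, T - 1) else as.matrix(m)
  })
  for (nm in BARKER_PARS) {
    if (is.null(P[[nm]])) abort(sprintf("Missing parameter matrix '%s'.", nm))
    if (any(P[[nm]] < 0 | P[[nm]] > 1)) {
      abort(sprintf("Parameter '%s' outside [0, 1].", nm))
    }
  }
  a_risk <- numeric(n); a_off <- numeric(n); a_dead <- numeric(n)
  released <- hist$first == 1L
  a_risk[released] <- 1
  if (T >= 2) {
    for (i in seq_len(T - 1)) {
      S <- P$S[, i]; r <- P$r[, i]; R <- P$R[, i]; Rp <- P$Rp[, i]
      Ff <- P$F[, i]; Fp <- P$Fp[, i]; pc <- P$p[, i]
      e <- hist$events[, i]; y <- hist$caps[, i + 1]
      active <- hist$first <= i

      resighted <- e == 1L | e == 3L
      recovered <- e == 2L | e == 3L
      rp_f <- 1 - Rp; rp_f[resighted] <- Rp[resighted]
      r_f <- 1 - r; r_f[recovered] <- r[recovered]
      die_w <- (1 - S) * rp_f * r_f * (y == 0L)
      srv_emit <- 1 - R
      srv_emit[e == 1L] <- R[e == 1L]
      srv_emit[recovered] <- 0
      surv_w <- S * srv_emit
      cap_risk <- 1 - pc; cap_risk[y == 1L] <- pc[y == 1L]
      dead_emit <- (e == 0L) & (y == 0L)

      new_risk <- (a_risk * Ff + a_off * Fp) * surv_w * cap_risk
      new_off  <- (a_risk * (1 - Ff) + a_off * (1 - Fp)) * surv_w * (y == 0L)
      new_dead <- a_dead * dead_emit + (a_risk + a_off) * die_w

      a_risk[active] <- new_risk[active]
      a_off[active]  <- new_off[active]
      a_dead[active] <- new_dead[active]

      newly <- hist$first == i + 1L
      a_risk[newly] <- 1
    }
  }
  tot <- a_risk + a_off + a_dead
  tot[hist$first == T] <- 1
  if (log) base::log(tot) else tot
}

# ---- fitting ---------------------------------------------------------------

#' QAICc
#'
#' Small-sample, overdispersion-corrected AIC:
#' `-2 lnL / c_hat + 2K + 2K(K + 1)/(n_eff - K - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n_eff Effective sample size (here: number of released animals).
#' @param c_hat Overdispersion coefficient (externally estimated; 1 = none).
#' @return The QAICc value.
#' @export
qaicc <- function(loglik, K, n_eff, c_hat = 1) {
  -2 * loglik / c_hat + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Fit a Barker model by maximum likelihood
#'
#' Maximizes the joint likelihood of the encounter histories over
#' logit-scale design coefficients with BFGS (optionally multi-start), and
#' reports coefficient standard errors from the numerical information
#' matrix plus real-scale estimates by the delta method.
#'
#' @param hist An `encounter_histories` object.
#' @param spec A [barker_spec()].
#' @param c_hat Overdispersion coefficient used in QAICc (default 1).
#'   Externally estimated (e.g. by a median-c-hat procedure); it rescales
#'   model selection, not the likelihood surface.
#' @param n_starts Number of optimizer starts (jittered beyond the first).
#' @param seed Seed for multi-start jitter.
#' @return A `barker_fit` with coefficients, `vcov`, `estimates` (real
#'   scale per parameter and design stratum), `loglik`, `K`, `n_eff`,
#'   `qaicc`, `convergence`, `boundary` flags.
#' @export
fit_barker <- function(hist, spec, c_hat = 1, n_starts = 1, seed = 1) {
  designs <- barker_design(spec, hist)
  K <- barker_npar(designs)
  nll <- function(theta) {
    pr <- barker_probs(designs, theta, hist$n)
    ll <- barker_history_probability(hist, pr, log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }
  starts <- list(rep(0, K))
  if (n_starts > 1) {
    old <- get_rng_state()
    set.seed(seed)
    for (s in seq_len(n_starts - 1)) starts[[s + 1]] <- rnorm(K, 0, 1)
    restore_rng_state(old)
  }
  best <- NULL
  for (st in starts) {
    opt <- optim(st, nll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  hess <- optim(best$par, nll, method = "BFGS", hessian = TRUE,
                control = list(maxit = 5))$hessian
  vc <- tryCatch(solve(hess), error = function(e) {
    warn("Information matrix singular; standard errors unavailable.")
    matrix(NA_real_, K, K)
  })
  theta <- best$par
  boundary <- abs(theta) > 8
  if (any(boundary)) {
    warn(sprintf("%d coefficient(s) at/near the boundary (|logit| > 8).",
                 sum(boundary)))
  }
  fit <- structure(
    list(spec = spec, coefficients = theta, vcov = vc,
         loglik = -best$value, K = K, n_eff = hist$n, c_hat = c_hat,
         qaicc = qaicc(-best$value, K, hist$n, c_hat),
         convergence = best$convergence == 0, boundary = boundary,
         designs = designs, hist_dim = c(n = hist$n, T = hist$T)),
    class = "barker_fit"
  )
  fit$estimates <- barker_real_estimates(fit)
  if (!fit$convergence) warn("Optimizer did not report convergence.")
  fit
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# Real-scale estimates per parameter and distinct design row, delta-method
# standard errors from the coefficient covariance.
barker_real_estimates <- function(fit) {
  rows <- list(); pos <- 0
  for (pp in BARKER_PARS) {
    d <- fit$designs[[pp]]
    if (!is.null(d$fixed)) {
      rows[[pp]] <- tibble::tibble(parameter = pp, stratum = "fixed",
                                   estimate = d$fixed, se = 0, fixed = TRUE)
      next
    }
    k <- ncol(d$X)
    idx <- (pos + 1):(pos + k); pos <- pos + k
    comb <- unique(cbind(as.data.frame(d$long), as.data.frame(d$X)))
    nc <- ncol(d$long)
    ux <- comb[, (nc + 1):ncol(comb), drop = FALSE]
    labs <- if (nc > 0) {
      apply(comb[, seq_len(nc), drop = FALSE], 1, paste, collapse = "/")
    } else rep("all", nrow(ux))
    est <- se <- numeric(nrow(ux))
    V <- fit$vcov[idx, idx, drop = FALSE]
    for (j in seq_len(nrow(ux))) {
      x <- as.numeric(ux[j, ])
      eta <- sum(x * fit$coefficients[idx])
      est[j] <- plogis(eta)
      g <- stats::dlogis(eta)
      se[j] <- if (all(is.finite(V))) sqrt(drop(t(x) %*% V %*% x)) * g
               else NA_real_
    }
    rows[[pp]] <- tibble::tibble(parameter = pp, stratum = labs[seq_len(nrow(ux))],
                                 estimate = est, se = se, fixed = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' @export
print.barker_fit <- function(x, ...) {
  cat(sprintf("<barker_fit> %s\n  logLik = %.3f, K = %d, QAICc = %.3f%s\n",
              x$spec$name, x$loglik, x$K, x$qaicc,
              if (!x$convergence) " [NOT CONVERGED]" else ""))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.barker_fit <- function(x, ...) x$estimates

#' @export
glance.barker_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, K = x$K, n_eff = x$n_eff,
                 c_hat = x$c_hat, QAICc = x$qaicc,
                 converged = x$convergence)
}

#' Real-scale parameter estimates with uncertainty
#'
#' @param object A `barker_fit`.
#' @param ... Unused.
#' @return A ggplot object: point estimates with approximate 95% intervals
#'   per parameter and stratum.
#' @export
autoplot.barker_fit <- function(object, ...) {
  df <- dplyr::filter(object$estimates, !.data$fixed)
  ggplot2::ggplot(df, ggplot2::aes(.data$stratum, .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$estimate - 1.96 * .data$se),
                   ymax = pmin(1, .data$estimate + 1.96 * .data$se)),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "probability",
                  title = "Barker model estimates (approx. 95% CI)") +
    ggplot2::theme_minimal()
}

#' Rank a set of Barker fits by QAICc
#'
#' @param fits Named list of `barker_fit` objects on the same data and
#'   `c_hat`.
#' @return Tibble sorted by QAICc with `delta` and normalized Akaike
#'   `weight` columns (weights sum to 1).
#' @export
model_table <- function(fits) {
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$spec$name, character(1))
  }
  dims <- vapply(fits, function(f) paste(f$hist_dim, collapse = "x"),
                 character(1))
  chats <- vapply(fits, function(f) f$c_hat, numeric(1))
  if (length(unique(dims)) > 1 || length(unique(chats)) > 1) {
    abort("All fits must share the same data dimensions and c_hat.")
  }
  q <- vapply(fits, function(f) f$qaicc, numeric(1))
  delta <- q - min(q)
  w <- exp(-delta / 2); w <- w / sum(w)
  tibble::tibble(
    model = names(fits),
    K = unname(vapply(fits, function(f) f$K, numeric(1))),
    logLik = unname(vapply(fits, function(f) f$loglik, numeric(1))),
    QAICc = unname(q), delta = unname(delta), weight = unname(w)
  ) |> dplyr::arrange(.data$QAICc)
}

#' Model-averaged parameter estimate
#'
#' Akaike-weight-weighted mean of a real-scale parameter across candidate
#' models, with the unconditional standard error combining within-model
#' variance and between-model spread:
#' `sqrt(sum_i w_i (se_i^2 + (theta_i - theta_bar)^2))`.
#'
#' @param fits Named list of `barker_fit` objects.
#' @param parameter One of `"S"`, `"p"`, `"r"`, `"R"`, `"Rp"`, `"F"`,
#'   `"Fp"`.
#' @param stratum Optional stratum label filter; by default each model's
#'   estimates for the parameter are averaged over strata (weighted by
#'   nothing -- a simple mean) before combining across models.
#' @return Tibble with `estimate` and `se`.
#' @export
model_average <- function(fits, parameter, stratum = NULL) {
  tab <- model_table(fits)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$spec$name, character(1))
  }
  w <- setNames(tab$weight, tab$model)
  est <- se <- numeric(length(fits))
  for (i in seq_along(fits)) {
    e <- dplyr::filter(fits[[i]]$estimates, .data$parameter == !!parameter)
    if (!is.null(stratum)) e <- dplyr::filter(e, .data$stratum == !!stratum)
    if (nrow(e) == 0) {
      abort(sprintf("Parameter %s%s not estimable in model '%s'.",
                    parameter,
                    if (is.null(stratum)) "" else paste0("[", stratum, "]"),
                    names(fits)[i]))
    }
    est[i] <- mean(e$estimate)
    se[i] <- sqrt(mean(e$se^2))
  }
  wts <- w[names(fits)]
  avg <- sum(wts * est)
  use <- sqrt(sum(wts * (se^2 + (est - avg)^2)))
  tibble::tibble(parameter = parameter,
                 stratum = stratum %||% "averaged",
                 estimate = avg, se = use)
}

#' Likelihood ratio test between nested Barker fits
#'
#' @param nested,full Two `barker_fit` objects on the same data, with the
#'   nested model's structure a special case of the full model's.
#' @return Tibble with `statistic` (2 * difference in log-likelihood),
#'   `df` (difference in parameter count) and chi-square `p.value`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  if (!identical(nested$hist_dim, full$hist_dim)) {
    abort("Models were fitted to different data.")
  }
  if (nested$K > full$K) {
    abort("`nested` has more parameters than `full`; models not nested.")
  }
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  df <- full$K - nested$K
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p.value = p)
}
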