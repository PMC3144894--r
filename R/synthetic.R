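# Synthetic study generator. Emulates daily focal sampling of a marked,
# group-living population: latent pairwise association propensities with
# within-group gregariousness heterogeneity (the knob that moves the
# within-group centrality SD), daily presence/interaction sampling, a
# discrete yearly longevity model linked to group-level covariates, and
# multi-year encounter histories under known Barker parameters.

#' Population configuration for the synthetic generator
#'
#' Defaults emulate the field regime of a long-term hyrax study: two sites
#' with two social groups each, group sizes around 14 +/- 5, daily focal
#' observation with high detection of marked animals.
#'
#' @param n_groups Number of social groups.
#' @param group_sizes Integer vector of group sizes (recycled/truncated to
#'   `n_groups`).
#' @param sites Site label per group.
#' @param sex_ratio Proportion female.
#' @param within_group_base Baseline within-group daily interaction
#'   propensity (before gregariousness scaling).
#' @param between_group Between-group propensity (same site).
#' @param heterogeneity Log-scale SD of individual gregariousness; one
#'   value per group (recycled). 0 makes all group members equally
#'   gregarious; larger values raise the expected within-group centrality
#'   SD.
#' @param n_days Observation days per period.
#' @param detection_prob Daily probability a marked individual is present
#'   and observable.
#' @return A `population_config` list.
#' @export
population_config <- function(n_groups = 4,
                              group_sizes = c(14, 12, 15, 11),
                              sites = c("A", "A", "B", "B"),
                              sex_ratio = 0.6,
                              within_group_base = 0.25,
                              between_group = 0.01,
                              heterogeneity = c(0.1, 0.25, 0.4, 0.55),
                              n_days = 30,
                              detection_prob = 0.85) {
  stopifnot(n_groups >= 1)
  group_sizes <- rep_len(group_sizes, n_groups)
  sites <- rep_len(sites, n_groups)
  heterogeneity <- rep_len(heterogeneity, n_groups)
  cfg <- list(n_groups = n_groups, group_sizes = group_sizes, sites = sites,
              sex_ratio = sex_ratio, within_group_base = within_group_base,
              between_group = between_group, heterogeneity = heterogeneity,
              n_days = n_days, detection_prob = detection_prob)
  probs <- c(sex_ratio, within_group_base, between_group, detection_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].",
          class = "socnetlong_config_error")
  }
  if (any(group_sizes < 2)) {
    abort("Group sizes must be at least 2.", class = "socnetlong_config_error")
  }
  if (any(heterogeneity < 0)) {
    abort("`heterogeneity` must be nonnegative.",
          class = "socnetlong_config_error")
  }
  structure(cfg, class = "population_config")
}

#' Simulate a population with latent association propensities
#'
#' Each individual gets a gregariousness multiplier drawn lognormally with
#' unit mean and log-scale SD equal to its group's `heterogeneity`. The
#' daily interaction propensity of a pair is the base rate (within- or
#' between-group) times both gregariousness values, clamped to `[0, 1]`.
#' Gregariousness acts multiplicatively because that is the simplest
#' mechanism that spreads centrality within a group without changing the
#' group's mean association much.
#'
#' @param config A [population_config()].
#' @param seed Integer seed; the generator is deterministic given it.
#' @return List with `individuals` (tibble: id, sex, group, site,
#'   gregariousness) and `propensity` (symmetric matrix).
#' @export
simulate_population <- function(config = population_config(), seed = 1) {
  set.seed(seed)
  n <- sum(config$group_sizes)
  ids <- sprintf("ind%03d", seq_len(n))
  grp <- rep(paste0("grp", seq_len(config$n_groups)), config$group_sizes)
  site <- rep(config$sites, config$group_sizes)
  het <- rep(config$heterogeneity, config$group_sizes)
  greg <- rlnorm(n, meanlog = -het^2 / 2, sdlog = het)
  sex <- ifelse(runif(n) < config$sex_ratio, "female", "male")
  same_group <- outer(grp, grp, "==")
  same_site <- outer(site, site, "==")
  base <- matrix(0, n, n)
  base[same_site] <- config$between_group
  base[same_group] <- config$within_group_base
  prop <- base * outer(greg, greg)
  prop[prop > 1] <- 1
  dimnames(prop) <- list(ids, ids)
  diag(prop) <- 0
  list(
    individuals = tibble::tibble(id = ids, sex = sex, group = grp,
                                 site = site, gregariousness = greg),
    propensity = prop,
    config = config
  )
}

#' Simulate daily observation records
#'
#' Per day each individual is present (observable) independently with
#' `detection_prob`; each present pair interacts with its latent
#' propensity, and every realized interaction becomes a two-individual
#' affiliative event in the standard observation schema. Optional
#' contamination adds agonistic and tree-foraging events (to exercise the
#' record filters) and unmarked walk-ons.
#'
#' @param population Output of [simulate_population()].
#' @param start_date First observation day.
#' @param site_label Restrict to one site (default: all sites).
#' @param contaminate Add agonistic/tree-foraging/unmarked records?
#' @param seed Integer seed.
#' @return Observation tibble in the [read_observations()] schema.
#' @export
simulate_observations <- function(population, start_date = as.Date("2001-03-01"),
                                  site_label = NULL, contaminate = FALSE,
                                  seed = 1) {
  set.seed(seed)
  cfg <- population$config
  inds <- population$individuals
  if (!is.null(site_label)) inds <- inds[inds$site == site_label, ]
  prop <- population$propensity
  n_days <- cfg$n_days
  acc <- list(day = integer(0), site = character(0), event = integer(0),
              id = character(0), type = character(0), marked = logical(0))
  ev <- 0L
  sites <- unique(inds$site)
  for (d in seq_len(n_days)) {
    for (s in sites) {
      sids <- inds$id[inds$site == s]
      present <- sids[runif(length(sids)) < cfg$detection_prob]
      if (length(present) < 2) next
      pr <- prop[present, present, drop = FALSE]
      up <- which(upper.tri(pr) & matrix(runif(length(pr)), nrow(pr)) < pr,
                  arr.ind = TRUE)
      m <- nrow(up)
      if (m == 0) next
      type <- sample(c("affiliative_contact", "coordinated_activity"), m,
                     replace = TRUE)
      mark_b <- rep(TRUE, m)
      if (contaminate) {
        neg <- runif(m) < 0.1
        type[neg] <- sample(c("agonistic", "tree_foraging"), sum(neg),
                            replace = TRUE)
        mark_b <- runif(m) >= 0.02
      }
      acc$day <- c(acc$day, rep(d, 2 * m))
      acc$site <- c(acc$site, rep(s, 2 * m))
      acc$event <- c(acc$event, rep(ev + seq_len(m), each = 2))
      acc$id <- c(acc$id,
                  as.vector(rbind(present[up[, 1]], present[up[, 2]])))
      acc$type <- c(acc$type, rep(type, each = 2))
      acc$marked <- c(acc$marked, as.vector(rbind(rep(TRUE, m), mark_b)))
      ev <- ev + m
    }
  }
  tibble::tibble(
    date = start_date + acc$day - 1,
    site = acc$site,
    event_id = sprintf("ev%06d", acc$event),
    individual_id = acc$id,
    interaction_type = acc$type,
    marked = acc$marked
  )
}

#' Longevity configuration
#'
#' Discrete yearly survival from adulthood: each adult year the death
#' probability is logistic in the (standardized) group centrality SD and
#' group size, `plogis(qlogis(baseline_hazard) + beta_sd * z_sd +
#' beta_size * z_size)`. Positive `beta_sd` means animals in groups with
#' more unequal centrality die sooner, giving the negative longevity ~
#' centrality-SD regression slope the analysis should recover.
#'
#' @param baseline_hazard Yearly death probability at average covariates.
#' @param beta_sd Log-odds coefficient on standardized group centrality SD.
#' @param beta_size Log-odds coefficient on standardized group size.
#' @param max_age Cap on age at death (years).
#' @return A `longevity_config` list.
#' @export
longevity_config <- function(baseline_hazard = 0.3, beta_sd = 1.4,
                             beta_size = 0.5, max_age = 12) {
  if (baseline_hazard <= 0 || baseline_hazard >= 1) {
    abort("`baseline_hazard` must be in (0, 1).",
          class = "socnetlong_config_error")
  }
  structure(list(baseline_hazard = baseline_hazard, beta_sd = beta_sd,
                 beta_size = beta_size, max_age = max_age),
            class = "longevity_config")
}

#' Simulate ages at death from group-level covariates
#'
#' @param group_metrics Tibble with one row per (individual, adult year):
#'   columns `individual_id`, `age` (years), `group_sd` (group centrality
#'   SD that year) and `group_size`. Years beyond the last provided row
#'   reuse the last row's covariates.
#' @param config A [longevity_config()].
#' @param seed Integer seed.
#' @return Tibble `individual_id`, `age_at_death` (integer years >= 2; `NA`
#'   for animals surviving past `max_age` is impossible -- the cap forces
#'   death at `max_age`).
#' @export
simulate_longevity <- function(group_metrics, config = longevity_config(),
                               seed = 1) {
  set.seed(seed)
  z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  gm <- group_metrics |>
    dplyr::mutate(z_sd = z(.data$group_sd), z_size = z(.data$group_size))
  out <- gm |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$age, .by_group = TRUE) |>
    dplyr::summarise(age_at_death = {
      zs <- .data$z_sd; zg <- .data$z_size
      age <- NA_integer_
      for (k in seq_len(config$max_age - 2 + 1)) {
        j <- min(k, length(zs))
        pdie <- plogis(qlogis(config$baseline_hazard) +
                         config$beta_sd * zs[j] + config$beta_size * zg[j])
        if (runif(1) < pdie) { age <- 2L + k - 1L; break }
      }
      if (is.na(age)) age <- as.integer(config$max_age)
      age
    }, .groups = "drop")
  out
}

#' Simulate encounter histories under known Barker parameters
#'
#' Forward simulation of the exact generative process the Barker likelihood
#' describes: yearly survival, within-interval resight (R alive / R' before
#' death), dead recovery (r), fidelity transitions (F, F') and capture (p)
#' of at-risk animals, with optional staggered entry.
#'
#' @param params Named list of scalar probabilities `S`, `p`, `r`, `R`,
#'   `Rp`, `F`, `Fp`, or vectors of length `n_animals` for per-animal
#'   (e.g. group-dependent) parameters.
#' @param n_animals Number of released animals.
#' @param T Number of capture occasions.
#' @param staggered If `TRUE`, first capture occasions are spread uniformly
#'   over `1..(T-1)`; otherwise all animals are released at occasion 1.
#' @param covariates Optional per-animal covariate tibble.
#' @param seed Integer seed.
#' @return An [encounter_histories()] object.
#' @export
simulate_encounter_histories <- function(params, n_animals, T,
                                         staggered = FALSE,
                                         covariates = NULL, seed = 1) {
  set.seed(seed)
  gp <- function(nm) rep_len(params[[nm]], n_animals)
  S <- gp("S"); p <- gp("p"); r <- gp("r"); R <- gp("R"); Rp <- gp("Rp")
  Ff <- gp("F"); Fp <- gp("Fp")
  caps <- matrix(0L, n_animals, T)
  events <- matrix(0L, n_animals, T - 1)
  first <- if (staggered) sample.int(T - 1, n_animals, replace = TRUE)
           else rep(1L, n_animals)
  caps[cbind(seq_len(n_animals), first)] <- 1L
  for (a in seq_len(n_animals)) {
    alive <- TRUE; at_risk <- TRUE
    for (i in seq(from = first[a], length.out = T - first[a])) {
      if (!alive) break
      if (runif(1) < S[a]) {
        if (runif(1) < R[a]) events[a, i] <- 1L
        at_risk <- if (at_risk) runif(1) < Ff[a] else runif(1) < Fp[a]
        if (at_risk && runif(1) < p[a]) caps[a, i + 1] <- 1L
      } else {
        alive <- FALSE
        resighted <- runif(1) < Rp[a]
        recovered <- runif(1) < r[a]
        events[a, i] <- if (resighted && recovered) 3L
                        else if (resighted) 1L
                        else if (recovered) 2L else 0L
      }
    }
  }
  encounter_histories(caps, events, covariates = covariates)
}
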