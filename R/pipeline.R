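# End-to-end orchestration: record filtering, per-period network
# construction, permutation gating, community assignment, centrality
# metrics, the longevity panel and its randomization regressions, and
# (optionally) Barker survival model selection.

#' Pipeline configuration
#'
#' @param permute `NULL` to skip the permutation gate, or a list with
#'   `alpha`, `max_perm`, `burn_in`, `swaps_per_sample`, `stabilization_tol`.
#' @param cpmw List with `k` and `threshold` (`NULL` = scan with
#'   [select_threshold()]).
#' @param centrality List with `beta` (`NULL` = `0.5/rho`), `estimator`,
#'   `distance_rule`.
#' @param regression List with `n_perm` for the randomization regressions.
#' @param seed Integer seed recorded in the report and applied before the
#'   stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(permute = list(alpha = 0.05, max_perm = 1000,
                                           burn_in = 500,
                                           swaps_per_sample = 20,
                                           stabilization_tol = 0.01),
                            cpmw = list(k = 3, threshold = NULL),
                            centrality = list(beta = NULL,
                                              estimator = "population",
                                              distance_rule = "inverse_weight"),
                            regression = list(n_perm = 1000),
                            seed = 1) {
  structure(list(permute = permute, cpmw = cpmw, centrality = centrality,
                 regression = regression, seed = seed),
            class = "pipeline_config")
}

# Split records into per-(site, period) networks. A `period` column is
# required; derive it from the observation year when absent.
split_periods <- function(records) {
  if (!"period" %in% names(records)) {
    records$period <- format(records$date, "%Y")
  }
  records$.net <- paste(records$site, records$period, sep = "/")
  split(records, records$.net)
}

#' Individual- and group-level metrics for every network period
#'
#' Builds one association network per (site, period), assigns communities
#' by weighted clique percolation and computes the full centrality table.
#'
#' @param records Filtered observation tibble with a `period` column (the
#'   observation year is used when absent).
#' @param config A [pipeline_config()].
#' @param keep_networks Also return the `assoc_matrix` objects?
#' @return List with `metrics` (tibble: one row per individual per period
#'   with its community, individual measures, and its group's measures) and
#'   optionally `networks`, `communities`.
#' @export
network_metrics_by_period <- function(records, config = pipeline_config(),
                                      keep_networks = FALSE) {
  nets <- split_periods(records)
  metrics <- list(); networks <- list(); communities <- list()
  for (nm in names(nets)) {
    rec <- nets[[nm]]
    am <- association_matrix(rec, period = rec$period[1], site = rec$site[1])
    if (nrow(am) < 3) next
    k <- config$cpmw$k %||% 3
    th <- config$cpmw$threshold
    inv <- clique_inventory(as_cpmw_graph(am), k)
    if (is.null(th)) {
      th <- if (length(inv$cliques)) select_threshold_inv(inv, k) else 0
    }
    comm <- cpmw_from_inventory(inv, k, th)
    ct <- centrality_table(
      am, comm, beta = config$centrality$beta,
      estimator = config$centrality$estimator %||% "population",
      distance_rule = config$centrality$distance_rule %||% "inverse_weight"
    )
    m <- dplyr::left_join(ct$nodes, ct$groups, by = "community") |>
      dplyr::mutate(site = rec$site[1], period = rec$period[1],
                    network = nm, .before = 1) |>
      dplyr::rename(group_size = "n")
    metrics[[nm]] <- m
    if (keep_networks) {
      networks[[nm]] <- am
      communities[[nm]] <- comm
    }
  }
  out <- list(metrics = dplyr::bind_rows(metrics))
  if (keep_networks) {
    out$networks <- networks
    out$communities <- communities
  }
  out
}

GROUP_METRICS <- c("sd_strength", "sd_power", "sd_information",
                   "cohesion", "centralization", "group_size")
INDIVIDUAL_METRICS <- c("strength", "power", "information")

#' Build the longevity panel
#'
#' One row per dead adult of known age: each social metric averaged over
#' the individual's adult years (its periods in a non-solitary community),
#' joined with age at death. Solitary records contribute no group metrics.
#'
#' @param metrics Per-individual-per-period metrics from
#'   [network_metrics_by_period()].
#' @param ages Tibble with `individual_id`, `age_at_death` (years; only
#'   animals dying at age >= 2 enter the panel) and optionally `sex`.
#' @param panel_n Optional cap on panel size; the first `panel_n` eligible
#'   individuals (by id) are kept, emulating a fixed study panel.
#' @return Panel tibble.
#' @export
build_panel <- function(metrics, ages, panel_n = NULL) {
  grouped <- dplyr::filter(metrics, .data$community != "solitary")
  avg <- grouped |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n_adult_years = dplyr::n(),
      dplyr::across(dplyr::all_of(c(INDIVIDUAL_METRICS, GROUP_METRICS)),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  panel <- ages |>
    dplyr::filter(.data$age_at_death >= 2) |>
    dplyr::inner_join(avg, by = "individual_id") |>
    dplyr::arrange(.data$individual_id)
  if (!is.null(panel_n) && nrow(panel) > panel_n) {
    panel <- panel[seq_len(panel_n), ]
  }
  panel
}

#' Randomization regressions of longevity on each social metric
#'
#' For every group-level metric (and the individual centrality measures),
#' regresses age at death on the adult-lifetime average of the metric with
#' a Manly randomization p-value; also reports each group metric after
#' residual control of age at death for mean group size.
#'
#' @param panel Panel tibble from [build_panel()].
#' @param n_perm Permutations per regression.
#' @return Tibble: `metric`, `controlled` (group-size residual control?),
#'   `slope`, `r_squared`, `p_value`, `n`.
#' @export
panel_regressions <- function(panel, n_perm = 1000) {
  mets <- intersect(c(GROUP_METRICS, INDIVIDUAL_METRICS), names(panel))
  rows <- list()
  for (m in mets) {
    dat <- panel[stats::complete.cases(panel[c("age_at_death", m)]), ]
    if (nrow(dat) < 5) next
    rr <- randomization_regression(
      dat, stats::reformulate(m, response = "age_at_death"), n_perm = n_perm
    )
    rows[[paste0(m, "/raw")]] <- tibble::tibble(
      metric = m, controlled = FALSE, slope = rr$slope,
      r_squared = rr$r_squared, p_value = rr$p_value, n = rr$n
    )
    if (m != "group_size" && "group_size" %in% names(dat)) {
      dat <- dat[stats::complete.cases(dat["group_size"]), ]
      if (nrow(dat) < 5) next
      dat$age_resid <- residual_control(dat$age_at_death,
                                        dat["group_size"])
      rc <- randomization_regression(
        dat, stats::reformulate(m, response = "age_resid"), n_perm = n_perm
      )
      rows[[paste0(m, "/ctrl")]] <- tibble::tibble(
        metric = m, controlled = TRUE, slope = rc$slope,
        r_squared = rc$r_squared, p_value = rc$p_value, n = rc$n
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Filters records, builds per-period networks, gates them on the
#' permutation test (optional), assigns communities, computes metrics,
#' builds the longevity panel and its randomization regressions, and
#' optionally runs Barker survival model selection.
#'
#' @param records Raw observation tibble ([read_observations()] schema,
#'   plus an optional `period` column).
#' @param ages Tibble `individual_id`, `age_at_death` for the panel.
#' @param config A [pipeline_config()].
#' @param survival Optional list with `hist` (an [encounter_histories()]),
#'   `specs` (named list of [barker_spec()]) and `c_hat`.
#' @return A `socnet_report`: list with `gates`, `metrics`, `panel`,
#'   `regressions`, `survival`, `config`.
#' @export
run_pipeline <- function(records, ages, config = pipeline_config(),
                         survival = NULL) {
  set.seed(config$seed)
  filtered <- filter_records(records)
  if (!"period" %in% names(filtered)) {
    filtered$period <- format(filtered$date, "%Y")
  }
  gates <- NULL
  if (!is.null(config$permute)) {
    nets <- split_periods(filtered)
    pc <- config$permute
    gates <- purrr::map_dfr(names(nets), function(nm) {
      st <- sampling_structure(nets[[nm]])
      pt <- tryCatch(
        permutation_test(
          st, max_perm = pc$max_perm %||% 1000,
          burn_in = pc$burn_in %||% 500,
          swaps_per_sample = pc$swaps_per_sample %||% 20,
          stabilization_tol = pc$stabilization_tol %||% 0.01
        ),
        socnetlong_not_applicable = function(e) NULL
      )
      tibble::tibble(network = nm,
                     p_value = if (is.null(pt)) NA_real_ else pt$p_value)
    })
    alpha <- pc$alpha %||% 0.05
    gates$retained <- !is.na(gates$p_value) & gates$p_value < alpha
    keep_nets <- gates$network[gates$retained]
    if (length(keep_nets) == 0) {
      warn("Permutation gate retained no networks; stopping after gating.")
      return(structure(list(gates = gates, metrics = NULL, panel = NULL,
                            regressions = NULL, survival = NULL,
                            config = config, status = "gated_out"),
                       class = "socnet_report"))
    }
    filtered$.net <- paste(filtered$site, filtered$period, sep = "/")
    filtered <- dplyr::filter(filtered, .data$.net %in% keep_nets)
    filtered$.net <- NULL
  }
  nm <- network_metrics_by_period(filtered, config, keep_networks = TRUE)
  panel <- build_panel(nm$metrics, ages)
  regressions <- if (nrow(panel) >= 5) {
    panel_regressions(panel, n_perm = config$regression$n_perm %||% 1000)
  } else {
    warn("Panel smaller than 5; regressions skipped.")
    NULL
  }
  if (!is.null(regressions) && nrow(panel) >= 5) {
    agg <- aggression_regression(records, filtered, panel,
                                 n_perm = config$regression$n_perm %||% 1000)
    if (!is.null(agg)) regressions <- dplyr::bind_rows(regressions, agg)
  }
  surv <- NULL
  if (!is.null(survival)) {
    fits <- lapply(survival$specs, function(sp) {
      fit_barker(survival$hist, sp, c_hat = survival$c_hat %||% 1)
    })
    surv <- list(
      fits = fits,
      table = model_table(fits),
      averaged_S = model_average(fits, "S")
    )
  }
  structure(
    list(gates = gates, metrics = nm$metrics, networks = nm$networks,
         communities = nm$communities, panel = panel,
         regressions = regressions, survival = surv, config = config,
         status = "complete"),
    class = "socnet_report"
  )
}

#' @export
print.socnet_report <- function(x, ...) {
  cat("<socnet_report>", x$status, "\n")
  if (!is.null(x$gates)) {
    cat(sprintf("  gate: %d/%d networks retained\n",
                sum(x$gates$retained), nrow(x$gates)))
  }
  if (!is.null(x$panel)) cat(sprintf("  panel: %d dead adults\n", nrow(x$panel)))
  if (!is.null(x$regressions)) {
    cat("  regressions:\n")
    print(x$regressions)
  }
  if (!is.null(x$survival)) {
    cat("  survival model table:\n")
    print(x$survival$table)
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (gates, regressions, survival table, config seed)
#' and CSV tables (`panel.csv`, `metrics.csv`) under `dir`.
#'
#' @param report A `socnet_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    status = report$status,
    seed = report$config$seed,
    gates = report$gates,
    regressions = report$regressions,
    survival_table = if (!is.null(report$survival)) report$survival$table,
    averaged_S = if (!is.null(report$survival)) report$survival$averaged_S
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$panel)) {
    readr::write_csv(report$panel, file.path(dir, "panel.csv"),
                     progress = FALSE)
  }
  if (!is.null(report$metrics)) {
    readr::write_csv(report$metrics, file.path(dir, "metrics.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}

# Longevity (group-size-controlled) against the individual aggression rate:
# days involved in agonistic interactions, residual-adjusted for group size
# and observation effort. Returns NULL when the records hold no agonistic
# interactions for panel members.
aggression_regression <- function(records, filtered, panel, n_perm = 1000) {
  ago <- records[records$interaction_type == "agonistic", ]
  if (nrow(ago) == 0) return(NULL)
  agg_days <- ago |>
    dplyr::distinct(.data$individual_id, .data$date) |>
    dplyr::count(.data$individual_id, name = "agg_days")
  obs_days <- filtered |>
    dplyr::distinct(.data$individual_id, .data$date) |>
    dplyr::count(.data$individual_id, name = "obs_days")
  dat <- panel |>
    dplyr::left_join(agg_days, by = "individual_id") |>
    dplyr::left_join(obs_days, by = "individual_id") |>
    dplyr::mutate(agg_days = dplyr::coalesce(.data$agg_days, 0L)) |>
    dplyr::filter(!is.na(.data$obs_days), !is.na(.data$group_size))
  if (nrow(dat) < 5 || all(dat$agg_days == 0)) return(NULL)
  dat$aggression <- aggression_rate(dat$agg_days, dat$group_size,
                                    dat$obs_days)
  dat$age_resid <- residual_control(dat$age_at_death, dat["group_size"])
  rr <- randomization_regression(dat, age_resid ~ aggression, n_perm = n_perm)
  tibble::tibble(metric = "aggression_individual", controlled = TRUE,
                 slope = rr$slope, r_squared = rr$r_squared,
                 p_value = rr$p_value, n = rr$n)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()]: `permute` (`false`/`null` to
#' skip the gate), `cpmw`, `centrality`, `regression`, `seed`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- pipeline_config()
  if (!is.null(y$permute) && identical(y$permute, FALSE)) {
    base$permute <- NULL
  } else if (is.list(y$permute)) {
    base$permute <- modifyList(base$permute, y$permute)
  }
  for (k in c("cpmw", "centrality", "regression")) {
    if (is.list(y[[k]])) base[[k]] <- modifyList(base[[k]], y[[k]])
  }
  if (!is.null(y$seed)) base$seed <- as.integer(y$seed)
  base
}

# ---- end-to-end synthetic study -------------------------------------------

#' Simulate a complete multi-year study and analyse it
#'
#' Generates a stable population, simulates daily observations for each of
#' `n_periods` field seasons, builds the association networks and group
#' metrics with the real pipeline machinery, draws ages at death from the
#' measured group covariates under the longevity model, and regresses
#' longevity on the adult-lifetime average group centrality SD. All
#' individuals are treated as entering adulthood (age 2) in the first
#' period; animals still alive after the last period are censored and
#' excluded, mirroring the exclusion of still-alive animals from the
#' original panel.
#'
#' @param pop_config A [population_config()].
#' @param longev_config A [longevity_config()].
#' @param n_periods Number of yearly observation periods.
#' @param panel_n Panel size cap (default 34, a realistic number of known
#'   dead adults for a decade-long study of this kind).
#' @param n_perm Randomization-regression permutations.
#' @param seed Integer seed driving every stochastic stage.
#' @param config Pipeline config for the network stages (gating is skipped
#'   here; the generator builds association structure by construction and
#'   gate calibration is a separate analysis).
#' @return List with `panel`, `regressions`, `metrics`, `truth` (latent
#'   generator state).
#' @export
simulate_study <- function(pop_config = population_config(),
                           longev_config = longevity_config(),
                           n_periods = 8, panel_n = 34, n_perm = 500,
                           seed = 1,
                           config = pipeline_config(permute = NULL)) {
  pop <- simulate_population(pop_config, seed = seed)
  all_metrics <- list()
  for (y in seq_len(n_periods)) {
    obs <- simulate_observations(
      pop, start_date = as.Date(sprintf("%d-03-01", 2000 + y)),
      seed = seed * 1000L + y
    )
    if (nrow(obs) == 0) next
    obs$period <- sprintf("Y%02d", y)
    nm <- network_metrics_by_period(filter_records(obs), config)
    all_metrics[[y]] <- nm$metrics
  }
  metrics <- dplyr::bind_rows(all_metrics)
  # measured per-individual-per-year group covariates feed the hazard
  gm <- metrics |>
    dplyr::filter(.data$community != "solitary") |>
    dplyr::transmute(
      individual_id = .data$individual_id,
      age = 2 + as.integer(sub("Y", "", .data$period)) - 1,
      group_sd = .data$sd_strength,
      group_size = .data$group_size
    ) |>
    dplyr::filter(!is.na(.data$group_sd))
  ages <- simulate_longevity(gm, longev_config, seed = seed + 7919L)
  # censor animals reaching the study end or the age cap alive
  max_attainable <- 2L + n_periods - 1L
  ages <- dplyr::filter(ages, .data$age_at_death <= max_attainable,
                        .data$age_at_death < longev_config$max_age)
  # adult years contributing to the average: periods up to the death year
  metrics_adult <- metrics |>
    dplyr::mutate(age = 2 + as.integer(sub("Y", "", .data$period)) - 1) |>
    dplyr::inner_join(ages, by = "individual_id") |>
    dplyr::filter(.data$age <= .data$age_at_death) |>
    dplyr::select(-"age", -"age_at_death")
  panel <- build_panel(metrics_adult, ages, panel_n = panel_n)
  regressions <- if (nrow(panel) >= 5) {
    panel_regressions(panel, n_perm = n_perm)
  } else NULL
  list(panel = panel, regressions = regressions, metrics = metrics,
       truth = list(population = pop, longevity = longev_config,
                    ages = ages, seed = seed))
}
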