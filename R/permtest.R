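# Within-sample (Bejder-style) permutation test for nonrandom long-term
# association. The sampling unit is the day; each day's individuals are
# partitioned into interaction clusters (events merged into connected
# components). The null model swaps individuals between clusters of the same
# day, preserving every cluster's size and every individual's daily sighting
# record, and asks whether the dispersion of dyadic association indices in
# the observed data exceeds what such constrained shuffles produce.

#' Build the daily sampling structure from observation records
#'
#' Each day's retained events are merged into interaction clusters:
#' individuals sharing an event (directly or through chains of shared
#' events) form one cluster. These clusters are the exchangeable units of
#' the permutation null model.
#'
#' @param records Filtered observation tibble (see [filter_records()]).
#' @return A `sampling_structure`: list with `ids` (individuals), `days`
#'   (dates) and `membership`, an individuals-by-days integer matrix of
#'   within-day cluster labels (0 = not seen that day).
#' @export
sampling_structure <- function(records) {
  if (nrow(records) == 0) {
    abort("Cannot build a sampling structure from zero records.")
  }
  ids <- sort(unique(records$individual_id))
  days <- sort(unique(records$date))
  M <- matrix(0L, length(ids), length(days), dimnames = list(ids, NULL))
  for (d in seq_along(days)) {
    recs <- records[records$date == days[d], ]
    pres <- sort(unique(recs$individual_id))
    # union-find over this day's events
    parent <- seq_along(pres); names(parent) <- pres
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (ev in unique(recs$event_id)) {
      mem <- match(unique(recs$individual_id[recs$event_id == ev]), pres)
      if (length(mem) > 1) {
        r <- find(mem[1])
        for (j in mem[-1]) parent[find(j)] <- r
      }
    }
    roots <- vapply(seq_along(pres), find, integer(1))
    M[match(pres, ids), d] <- match(roots, unique(roots))
  }
  structure(list(ids = ids, days = days, membership = M),
            class = "sampling_structure")
}

#' @export
print.sampling_structure <- function(x, ...) {
  cat(sprintf("<sampling_structure> %d individuals, %d days, %d clusters\n",
              length(x$ids), length(x$days),
              sum(apply(x$membership, 2, function(v) length(unique(v[v > 0]))))))
  invisible(x)
}

days_seen_from_membership <- function(M) rowSums(M > 0)

# Association-index vector implied by a membership matrix: days together
# over days either seen (union = seen_i + seen_j - days co-present, and
# co-presence is invariant under within-day swaps). Returns the full dyadic
# matrix.
sri_from_membership <- function(M) {
  n <- nrow(M)
  tog <- matrix(0, n, n)
  for (d in seq_len(ncol(M))) {
    v <- M[, d]
    for (cl in unique(v[v > 0L])) {
      idx <- which(v == cl)
      if (length(idx) > 1) tog[idx, idx] <- tog[idx, idx] + 1
    }
  }
  diag(tog) <- 0
  pres <- (M > 0L) * 1
  copres <- tcrossprod(pres)
  seen <- diag(copres)
  den <- outer(seen, seen, "+") - copres
  ifelse(den > 0, tog / den, 0)
}

perm_stat <- function(M, stat = c("sd", "cv", "mean")) {
  stat <- match.arg(stat)
  sri <- sri_from_membership(M)
  vals <- sri[upper.tri(sri)]
  if (length(vals) < 2) return(0)
  switch(stat,
         sd = sd(vals),
         cv = if (mean(vals) > 0) sd(vals) / mean(vals) else 0,
         mean = mean(vals))
}

# One constrained swap in place on a membership matrix. Days eligible for
# swapping (>= 2 clusters) never change, so they are passed in.
swap_once <- function(M, eligible_days) {
  d <- eligible_days[sample.int(length(eligible_days), 1)]
  v <- M[, d]
  cls <- unique(v[v > 0L])
  pick <- sample(cls, 2)
  i <- which(v == pick[1]); i <- i[sample.int(length(i), 1)]
  j <- which(v == pick[2]); j <- j[sample.int(length(j), 1)]
  M[i, d] <- pick[2]; M[j, d] <- pick[1]
  M
}

#' One checkerboard swap on a sampling structure
#'
#' Exchanges two individuals between two interaction clusters of the same
#' day. Cluster sizes and every individual's set of sighting days are
#' preserved exactly. When no day has two or more clusters the structure is
#' returned unchanged with attribute `noop = TRUE`.
#'
#' @param structure A [sampling_structure()].
#' @return The swapped `sampling_structure` (attribute `noop` flags the
#'   degenerate case).
#' @export
checkerboard_swap <- function(structure) {
  M <- structure$membership
  eligible <- which(apply(M, 2, function(v) length(unique(v[v > 0L]))) >= 2)
  if (length(eligible) == 0) {
    attr(structure, "noop") <- TRUE
    return(structure)
  }
  structure$membership <- swap_once(M, eligible)
  attr(structure, "noop") <- FALSE
  structure
}

#' Permutation test for nonrandom association
#'
#' Runs a Markov chain of within-day checkerboard swaps, recomputing the
#' dispersion of dyadic simple-ratio indices on thinned samples, and reports
#' an add-one Monte-Carlo p-value. A high observed dispersion relative to
#' the constrained null indicates preferred long-term companionships
#' (`alternative = "greater"`, the default); the lower tail tests for
#' avoidance. Permutations accumulate in blocks; the run stops early once
#' the p-value changes by less than `stabilization_tol` between consecutive
#' blocks (set it to 0 to always run `max_perm` permutations).
#'
#' @param structure A [sampling_structure()].
#' @param stat Null statistic over the dyadic association indices: `"sd"`
#'   (default, the network-software convention for companionship tests),
#'   `"cv"` or `"mean"`.
#' @param max_perm Maximum number of retained permutations (>= 100).
#' @param burn_in Swaps applied before the first retained permutation.
#' @param swaps_per_sample Swaps between retained permutations (chain
#'   thinning).
#' @param stabilization_tol Early-stop tolerance on the between-block change
#'   in p.
#' @param block_size Permutations per stabilization block.
#' @param alternative `"greater"` (companionship) or `"less"` (avoidance).
#' @return A `perm_test` object with elements `observed`, `null_stats`,
#'   `p_value`, `n_perm`, `stat`, `stabilized`, `alternative`.
#' @export
permutation_test <- function(structure, stat = c("sd", "cv", "mean"),
                             max_perm = 10000, burn_in = 1000,
                             swaps_per_sample = 100,
                             stabilization_tol = 0.01,
                             block_size = 1000,
                             alternative = c("greater", "less")) {
  stat <- match.arg(stat)
  alternative <- match.arg(alternative)
  if (max_perm < 100) {
    abort("`max_perm` must be at least 100.",
          class = "socnetlong_config_error")
  }
  M <- structure$membership
  if (nrow(M) < 2 || ncol(M) < 2) {
    abort("Degenerate sampling structure: need >= 2 individuals and days.",
          class = "socnetlong_not_applicable")
  }
  observed <- perm_stat(M, stat)
  eligible <- which(apply(M, 2, function(v) length(unique(v[v > 0L]))) >= 2)
  if (length(eligible) == 0) {
    abort("No day has two or more interaction clusters; swaps impossible.",
          class = "socnetlong_not_applicable")
  }
  for (k in seq_len(burn_in)) M <- swap_once(M, eligible)

  null_stats <- numeric(0)
  p_prev <- NA_real_
  stabilized <- FALSE
  count_fun <- if (alternative == "greater") {
    function(ns) sum(ns >= observed)
  } else {
    function(ns) sum(ns <= observed)
  }
  while (length(null_stats) < max_perm) {
    nblk <- min(block_size, max_perm - length(null_stats))
    blk <- numeric(nblk)
    for (b in seq_len(nblk)) {
      for (k in seq_len(swaps_per_sample)) M <- swap_once(M, eligible)
      blk[b] <- perm_stat(M, stat)
    }
    null_stats <- c(null_stats, blk)
    p <- (count_fun(null_stats) + 1) / (length(null_stats) + 1)
    if (!is.na(p_prev) && abs(p - p_prev) < stabilization_tol &&
        stabilization_tol > 0) {
      stabilized <- TRUE
      break
    }
    p_prev <- p
  }
  p <- (count_fun(null_stats) + 1) / (length(null_stats) + 1)
  structure(
    list(observed = observed, null_stats = null_stats, p_value = p,
         n_perm = length(null_stats), stat = stat, stabilized = stabilized,
         alternative = alternative),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> stat=%s observed=%.4f p=%.4g (%d permutations%s, %s tail)\n",
    x$stat, x$observed, x$p_value, x$n_perm,
    if (x$stabilized) ", stabilized" else "",
    if (x$alternative == "greater") "upper" else "lower"
  ))
  invisible(x)
}

#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$observed, p.value = x$p_value,
                 n_perm = x$n_perm, stat = x$stat, stabilized = x$stabilized)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null_stats), null_stat = x$null_stats)
}

#' Null distribution plot for a permutation test
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot object: histogram of null statistics with the observed
#'   value marked.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null_stat = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(.data$null_stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = sprintf("null %s of dyadic association indices", object$stat),
      y = "permutations",
      title = sprintf("Permutation test: p = %.4g (%d permutations)",
                      object$p_value, object$n_perm)
    ) +
    ggplot2::theme_minimal()
}

#' Gate networks on permutation-test significance
#'
#' Retains only the network periods whose association structure differs
#' significantly from the constrained null; nonsignificant periods are
#' reported and dropped from downstream analysis.
#'
#' @param results Tibble with columns `period` and `p_value`, or a named
#'   list of `perm_test` objects (names = period labels).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of retained period labels.
#' @export
gate_networks <- function(results, alpha = 0.05) {
  if (!is.data.frame(results)) {
    results <- tibble::tibble(
      period = names(results),
      p_value = vapply(results, function(r) r$p_value, numeric(1))
    )
  }
  keep <- results$period[results$p_value < alpha]
  drop <- setdiff(results$period, keep)
  if (length(drop)) {
    inform(sprintf("Excluded %d network(s) with p >= %.3g: %s",
                   length(drop), alpha, paste(drop, collapse = ", ")))
  }
  if (length(keep) == 0) {
    warn("No network passed the permutation gate; nothing to analyse.")
  }
  keep
}
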