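# Association networks at one-day resolution. Two individuals count as
# "together" on a day when they co-occur in at least one retained positive
# interaction event that day; the simple ratio index divides days together
# by days on which either was recorded.

#' Filter observation records for network construction
#'
#' Retains only positive interactions (`affiliative_contact`,
#' `coordinated_activity`). Tree-foraging records are dropped because tree
#' crowns force proximity without social context, and agonistic records
#' because they do not express positive association. Whole events that
#' include any unmarked participant are discarded (unmarked animals cannot
#' be identified across days), unless `keep_unmarked = TRUE`.
#'
#' @param records Observation tibble (see [read_observations()]).
#' @param keep_unmarked Keep events containing unmarked individuals?
#' @return Filtered observation tibble.
#' @export
filter_records <- function(records, keep_unmarked = FALSE) {
  out <- dplyr::filter(
    records,
    .data$interaction_type %in% c("affiliative_contact", "coordinated_activity")
  )
  if (!keep_unmarked && nrow(out)) {
    tainted <- unique(out$event_id[!out$marked])
    out <- dplyr::filter(out, !.data$event_id %in% tainted)
  }
  out
}

#' Simple ratio association index for one dyad
#'
#' The proportion of days a pair was recorded together out of all days on
#' which either member was recorded: `|together| / |days_a U days_b|`.
#'
#' @param days_a,days_b Vectors of dates on which each individual was seen.
#' @param days_together Dates on which the pair was seen together; must be a
#'   subset of the days both were seen.
#' @return A number in `[0, 1]`.
#' @export
simple_ratio_index <- function(days_a, days_b, days_together) {
  days_a <- unique(days_a); days_b <- unique(days_b)
  days_together <- unique(days_together)
  if (!all(days_together %in% days_a) || !all(days_together %in% days_b)) {
    abort("`days_together` must be a subset of both individuals' seen days.",
          class = "socnetlong_consistency_error")
  }
  denom <- length(union(days_a, days_b))
  if (denom == 0) {
    abort("Association index undefined: neither individual was ever seen.",
          class = "socnetlong_undefined_index")
  }
  length(days_together) / denom
}

#' Daily presence table
#'
#' One row per (individual, date) with at least one retained record.
#'
#' @param records Filtered observation tibble.
#' @return Tibble with columns `individual_id`, `date`.
#' @export
daily_presence <- function(records) {
  dplyr::distinct(records, .data$individual_id, .data$date)
}

#' Daily co-occurrence table
#'
#' Unordered pairs co-observed in at least one retained interaction event on
#' each day; each pair counts at most once per day regardless of how many
#' events joined them.
#'
#' @param records Filtered observation tibble.
#' @return Tibble with columns `date`, `id_a`, `id_b` (`id_a < id_b`).
#' @export
daily_cooccurrence <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(date = as.Date(character()),
                          id_a = character(), id_b = character()))
  }
  u <- dplyr::distinct(records, .data$date, .data$event_id,
                       .data$individual_id)
  j <- dplyr::inner_join(u, u, by = c("date", "event_id"),
                         relationship = "many-to-many",
                         suffix = c("_a", "_b"))
  j |>
    dplyr::filter(.data$individual_id_a < .data$individual_id_b) |>
    dplyr::distinct(.data$date, id_a = .data$individual_id_a,
                    id_b = .data$individual_id_b)
}

#' Build a simple-ratio association matrix
#'
#' Constructs the symmetric matrix of simple ratio indices for one network
#' period from retained observation records. Individuals seen on zero days
#' in the period do not appear (they have no defined index).
#'
#' @param records Filtered observation tibble for one period (one site, one
#'   season/year); see [filter_records()].
#' @param period Optional label stored as metadata.
#' @param site Optional site label stored as metadata.
#' @return An `assoc_matrix`: a symmetric numeric matrix with zero diagonal,
#'   individual IDs as dimnames, and attributes `days_seen` (named integer
#'   vector), `n_days`, `period`, `site`.
#' @export
association_matrix <- function(records, period = NULL, site = NULL) {
  pres <- daily_presence(records)
  co <- daily_cooccurrence(records)
  ids <- sort(unique(pres$individual_id))
  n <- length(ids)
  days_seen_tbl <- dplyr::count(pres, .data$individual_id)
  days_seen <- setNames(days_seen_tbl$n, days_seen_tbl$individual_id)[ids]
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(co)) {
    bad <- !(co$id_a %in% ids) | !(co$id_b %in% ids)
    if (any(bad)) {
      abort("Co-occurrence involves individuals with no presence records.",
            class = "socnetlong_consistency_error")
    }
    # denominator |days_a U days_b| needs days BOTH were seen (co-presence),
    # which can exceed days together in an interaction event
    P <- matrix(FALSE, n, length(unique(pres$date)),
                dimnames = list(ids, NULL))
    P[cbind(match(pres$individual_id, ids),
            match(pres$date, sort(unique(pres$date))))] <- TRUE
    copres <- tcrossprod(P * 1)
    tog <- dplyr::count(co, .data$id_a, .data$id_b)
    ia <- match(tog$id_a, ids); ib <- match(tog$id_b, ids)
    denom <- days_seen[ia] + days_seen[ib] - copres[cbind(ia, ib)]
    m[cbind(ia, ib)] <- tog$n / denom
    m[cbind(ib, ia)] <- tog$n / denom
  }
  structure(m, class = c("assoc_matrix", "matrix", "array"),
            days_seen = days_seen,
            n_days = length(unique(pres$date)),
            period = period, site = site)
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf(
    "<assoc_matrix> %d individuals over %d days%s%s\n",
    nrow(x), attr(x, "n_days") %||% NA_integer_,
    if (!is.null(attr(x, "site"))) paste0(", site ", attr(x, "site")) else "",
    if (!is.null(attr(x, "period"))) paste0(", period ", attr(x, "period")) else ""
  ))
  print(unclass(x)[, , drop = FALSE], digits = 3)
  invisible(x)
}

#' Tidy an association matrix into a weighted edge list
#'
#' @param x An `assoc_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `id_a`, `id_b`, `weight` for every dyad with
#'   a nonzero index.
#' @export
tidy.assoc_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x) & x > 0, arr.ind = TRUE)
  tibble::tibble(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    weight = x[idx]
  ) |> dplyr::arrange(.data$id_a, .data$id_b)
}

#' Convert an association matrix to an igraph graph
#'
#' @param x An `assoc_matrix` or any symmetric weighted matrix.
#' @return Undirected weighted `igraph` graph (isolates retained).
#' @export
as_igraph <- function(x) {
  igraph::graph_from_adjacency_matrix(unclass(x), mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Export an association matrix
#'
#' @param x An `assoc_matrix`.
#' @param path Output path.
#' @param format `"csv"` (square matrix with ID header), `"edgelist"`
#'   (id_a, id_b, weight), or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_assoc_matrix <- function(x, path, format = c("csv", "edgelist", "graphml")) {
  format <- match.arg(format)
  switch(format,
    csv = {
      df <- tibble::as_tibble(unclass(x), rownames = "id")
      readr::write_csv(df, path, progress = FALSE)
    },
    edgelist = readr::write_csv(tidy.assoc_matrix(x), path, progress = FALSE),
    graphml = igraph::write_graph(as_igraph(x), path, format = "graphml")
  )
  invisible(path)
}

#' Heatmap of an association matrix
#'
#' @param object An `assoc_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_matrix <- function(object, ...) {
  ids <- rownames(object)
  df <- tidyr::expand_grid(id_a = ids, id_b = ids)
  df$weight <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "index",
                  title = "Simple-ratio association matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
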