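# The seven network measures used to relate group social structure to
# longevity: individual strength, Bonacich power and information centrality;
# their within-group standard deviations; distance-based cohesion
# (compactness) and degree-style network centralization.

as_weight_matrix <- function(graph) {
  if (inherits(graph, "igraph")) {
    W <- adjacency_from_graph(as_cpmw_graph(graph))
  } else {
    W <- unclass(graph)
  }
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- as.character(seq_len(nrow(W)))
  }
  if (!isTRUE(all.equal(W, t(W)))) abort("Weight matrix must be symmetric.")
  diag(W) <- 0
  W
}

#' Strength centrality (weighted degree)
#'
#' The sum of all association indices an individual has in the network.
#'
#' @param graph Weighted graph (`assoc_matrix`, matrix, or igraph).
#' @return Named numeric vector of node strengths.
#' @export
strength_centrality <- function(graph) {
  W <- as_weight_matrix(graph)
  rowSums(W)
}

#' Bonacich power centrality
#'
#' Power centrality weights each node's ties by how connected its neighbours
#' are, recursively: `c = (I - beta * W)^{-1} W 1`, equivalently the
#' convergent series `sum_{m>=0} beta^m W^{m+1} 1`. At `beta = 0` it equals
#' strength; positive `beta` lets influence radiate outwards.
#'
#' @param graph Weighted graph.
#' @param beta Attenuation parameter; must satisfy `|beta| < 1/rho(W)` with
#'   `rho` the spectral radius. Default `0.5 / rho(W)`.
#' @param normalize If `TRUE`, scale so the sum of squares equals the number
#'   of nodes (the conventional alpha scaling).
#' @return Named numeric vector.
#' @export
bonacich_power <- function(graph, beta = NULL, normalize = FALSE) {
  W <- as_weight_matrix(graph)
  n <- nrow(W)
  rho <- max(abs(eigen(W, symmetric = TRUE, only.values = TRUE)$values))
  if (is.null(beta)) beta <- if (rho > 0) 0.5 / rho else 0
  if (rho > 0 && abs(beta) >= 1 / rho) {
    abort(sprintf(
      "`beta` = %.4g is at/beyond the divergence bound 1/rho(W) = %.4g.",
      beta, 1 / rho
    ), class = "socnetlong_divergence_error")
  }
  cvec <- solve(diag(n) - beta * W, W %*% rep(1, n))[, 1]
  if (normalize && sum(cvec^2) > 0) cvec <- cvec * sqrt(n / sum(cvec^2))
  out <- setNames(cvec, rownames(W))
  attr(out, "beta") <- beta
  out
}

#' Information centrality
#'
#' Centrality from the harmonic combination of path "information" between a
#' node and all others (Stephenson-Zelen). With `D = diag(strength)`, `J`
#' the all-ones matrix and `C = (D - W + J)^{-1}`, node i's information
#' centrality is `n / (n * C_ii + trace(C) - 2 * rowsum_i(C))`. Weights act
#' as conductances. The graph must be connected; compute per component
#' otherwise.
#'
#' @param graph Weighted connected graph.
#' @return Named numeric vector of strictly positive values.
#' @export
information_centrality <- function(graph) {
  W <- as_weight_matrix(graph)
  n <- nrow(W)
  if (n == 1) return(setNames(NA_real_, rownames(W)))
  comp <- igraph::components(as_igraph(W))
  if (comp$no > 1) {
    abort(paste(
      "Graph is disconnected; information centrality is defined per",
      "component. Split the graph and compute each component separately."
    ), class = "socnetlong_disconnected_error")
  }
  B <- diag(rowSums(W)) - W + matrix(1, n, n)
  C <- solve(B)
  Tr <- sum(diag(C))
  R <- rowSums(C)
  setNames(n / (n * diag(C) + Tr - 2 * R), rownames(W))
}

#' Within-group dispersion of a node measure
#'
#' Standard deviation of member values within each disjoint group -- the
#' group-level inequality measures (strength SD, power SD, information SD).
#'
#' @param values Named numeric vector of per-node values.
#' @param membership Tibble with `individual_id` and `community` columns
#'   (e.g. `tidy()` of [cpmw_communities()]), or a named character vector.
#' @param estimator `"population"` (divide by n; the network-software
#'   convention, default) or `"sample"` (divide by n - 1).
#' @return Tibble with `community`, `n`, `sd`.
#' @export
group_dispersion <- function(values, membership,
                             estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  if (!is.data.frame(membership)) {
    membership <- tibble::tibble(individual_id = names(membership),
                                 community = unname(membership))
  }
  sd_fun <- function(x) {
    if (length(x) < 2) {
      if (estimator == "sample") return(NA_real_)
      return(0)
    }
    if (estimator == "population") {
      sqrt(mean((x - mean(x))^2))
    } else {
      sd(x)
    }
  }
  membership |>
    dplyr::mutate(value = unname(values[.data$individual_id])) |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(n = dplyr::n(), sd = sd_fun(.data$value),
                     .groups = "drop")
}

#' Distance-based cohesion (compactness)
#'
#' The mean inverse shortest-path distance over ordered node pairs:
#' `sum_{i != j} (1 / d_ij) / (n (n - 1))`, with `1/d = 0` for unreachable
#' pairs. Equals 1 for a complete binary graph and 0 for a totally
#' disconnected one.
#'
#' @param graph Weighted graph.
#' @param distance_rule `"inverse_weight"` (edge length `1/w`; default for
#'   weighted association networks) or `"binary"` (every edge length 1).
#' @return A number in `[0, 1]` under the binary rule; under
#'   `inverse_weight` with weights in `(0, 1]` distances are >= 1 so the
#'   value stays in `[0, 1]`.
#' @export
cohesion <- function(graph, distance_rule = c("inverse_weight", "binary")) {
  distance_rule <- match.arg(distance_rule)
  W <- as_weight_matrix(graph)
  n <- nrow(W)
  if (n < 2) abort("Cohesion needs at least 2 nodes.")
  g <- as_igraph(W)
  weights <- if (distance_rule == "inverse_weight") {
    1 / igraph::E(g)$weight
  } else {
    rep(1, igraph::ecount(g))
  }
  d <- igraph::distances(g, weights = weights)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Degree-style network centralization for weighted graphs
#'
#' The degree to which the network is focused on a few central nodes:
#' `sum_i (s_max - s_i) / ((n - 1) (n - 2) w_max)` with `s` the strength
#' vector and `w_max` the largest edge weight. The scaling makes a uniform
#' star score 1 and any weight-regular graph score 0. Absolute values
#' depend on this normalization; comparisons should use networks scored by
#' the same rule.
#'
#' @param graph Weighted graph with at least 3 nodes.
#' @return A number in `[0, 1]`.
#' @export
centralization <- function(graph) {
  W <- as_weight_matrix(graph)
  n <- nrow(W)
  if (n < 3) {
    abort("Centralization is undefined for fewer than 3 nodes.",
          class = "socnetlong_not_applicable")
  }
  s <- rowSums(W)
  w_max <- max(W)
  if (w_max == 0) return(0)
  sum(max(s) - s) / ((n - 1) * (n - 2) * w_max)
}

#' Full centrality table for one network period
#'
#' Computes the individual measures (strength, Bonacich power, information
#' centrality) and the group-level measures (within-group SDs of each,
#' cohesion and centralization of each group's subnetwork) for a network
#' and its disjoint group assignment. Information centrality is computed on
#' each group's subnetwork (connected by construction under clique
#' percolation); nodes whose subnetwork is disconnected or trivial get
#' `NA`.
#'
#' @param graph Weighted graph (typically an [association_matrix()]).
#' @param communities A [cpmw_communities()] object, or a membership tibble.
#' @param beta Bonacich attenuation; default `0.5 / rho(W)` (recorded in
#'   the output attributes).
#' @param estimator SD estimator for [group_dispersion()].
#' @param distance_rule Distance rule for [cohesion()].
#' @return List of class `centrality_table` with `nodes` (tibble:
#'   individual_id, community, strength, power, information) and `groups`
#'   (tibble: community, n, sd_strength, sd_power, sd_information,
#'   cohesion, centralization).
#' @export
centrality_table <- function(graph, communities, beta = NULL,
                             estimator = "population",
                             distance_rule = "inverse_weight") {
  W <- as_weight_matrix(graph)
  membership <- if (inherits(communities, "cpmw_communities")) {
    communities$membership
  } else {
    communities
  }
  s <- strength_centrality(W)
  p <- bonacich_power(W, beta = beta)
  ids <- rownames(W)
  info <- setNames(rep(NA_real_, length(ids)), ids)
  grp_rows <- list()
  groups <- setdiff(unique(membership$community), "solitary")
  for (gname in groups) {
    mem <- membership$individual_id[membership$community == gname]
    mem <- intersect(ids, mem)
    if (length(mem) < 2) next
    sub <- W[mem, mem, drop = FALSE]
    sub_conn <- igraph::components(as_igraph(sub))$no == 1
    if (sub_conn) info[mem] <- information_centrality(sub)
    grp_rows[[gname]] <- tibble::tibble(
      community = gname,
      n = length(mem),
      cohesion = cohesion(sub, distance_rule),
      centralization = if (length(mem) >= 3) centralization(sub) else NA_real_
    )
  }
  nodes <- membership |>
    dplyr::filter(.data$individual_id %in% ids) |>
    dplyr::transmute(
      individual_id = .data$individual_id,
      community = .data$community,
      strength = unname(s[.data$individual_id]),
      power = unname(p[.data$individual_id]),
      information = unname(info[.data$individual_id])
    )
  grp <- if (length(grp_rows)) dplyr::bind_rows(grp_rows) else {
    tibble::tibble(community = character(), n = integer(),
                   cohesion = numeric(), centralization = numeric())
  }
  add_sd <- function(grp, col, label) {
    d <- group_dispersion(setNames(nodes[[col]], nodes$individual_id),
                          membership, estimator = estimator)
    names(d)[names(d) == "sd"] <- label
    dplyr::left_join(grp, d[, c("community", label)], by = "community")
  }
  grp <- grp |> add_sd("strength", "sd_strength") |>
    add_sd("power", "sd_power") |> add_sd("information", "sd_information")
  grp <- grp[, c("community", "n", "sd_strength", "sd_power",
                 "sd_information", "cohesion", "centralization")]
  structure(list(nodes = nodes, groups = grp, beta = attr(p, "beta")),
            class = "centrality_table")
}

#' @export
print.centrality_table <- function(x, ...) {
  cat("<centrality_table>\nNodes:\n")
  print(x$nodes, n = 6)
  cat("Groups:\n")
  print(x$groups)
  invisible(x)
}

#' @export
tidy.centrality_table <- function(x, ...) x$nodes

#' @export
glance.centrality_table <- function(x, ...) x$groups
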