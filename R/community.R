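# Weighted clique percolation (CPMw). A k-clique's intensity is the
# geometric mean of its edge weights; cliques above an intensity threshold
# percolate into communities by chaining cliques that share k-1 nodes.
# Individuals covered by no retained clique are "solitary".

#' Enumerate all k-cliques of a weighted graph
#'
#' Every k-subset of nodes that is fully connected, listed exactly once.
#'
#' @param graph An `igraph` graph, `assoc_matrix`, or symmetric weighted
#'   matrix.
#' @param k Clique size (>= 3).
#' @return List of character vectors of node names (sorted within clique).
#' @export
enumerate_k_cliques <- function(graph, k = 3) {
  if (k < 3) abort("`k` must be at least 3.", class = "socnetlong_config_error")
  g <- as_cpmw_graph(graph)
  cl <- igraph::cliques(g, min = k, max = k)
  nm <- igraph::V(g)$name
  lapply(cl, function(v) sort(nm[as.integer(v)]))
}

as_cpmw_graph <- function(graph) {
  if (inherits(graph, "igraph")) {
    g <- graph
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
    g
  } else {
    as_igraph(graph)
  }
}

adjacency_from_graph <- function(g) {
  igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
}

#' Intensity of a clique: geometric mean of its edge weights
#'
#' For a k-clique with edge weights `w_1 .. w_m` (`m = k(k-1)/2`), the
#' intensity is `(prod w)^(1/m)`; a uniform-weight clique has intensity
#' equal to that weight.
#'
#' @param clique Character vector of node names.
#' @param graph Graph containing the clique.
#' @return Positive number, at most the largest edge weight in the clique.
#' @export
clique_intensity <- function(clique, graph) {
  g <- as_cpmw_graph(graph)
  W <- adjacency_from_graph(g)
  intensity_from_matrix(clique, W)
}

intensity_from_matrix <- function(clique, W) {
  pairs <- combn(clique, 2)
  w <- W[cbind(pairs[1, ], pairs[2, ])]
  if (any(w <= 0)) {
    abort("Not a clique: some node pair has no edge.",
          class = "socnetlong_consistency_error")
  }
  exp(mean(log(w)))
}

# Enumerate cliques once with their intensities; shared by
# cpmw_communities() and select_threshold(). Triangle intensities are
# computed by direct matrix lookup.
clique_inventory <- function(g, k) {
  cl <- enumerate_k_cliques(g, k)
  W <- adjacency_from_graph(g)
  m <- length(cl)
  if (m > 0 && k == 3) {
    M <- matrix(match(unlist(cl), rownames(W)), m, 3, byrow = TRUE)
    lw <- log(W[cbind(M[, 1], M[, 2])]) + log(W[cbind(M[, 1], M[, 3])]) +
      log(W[cbind(M[, 2], M[, 3])])
    intens <- exp(lw / 3)
  } else {
    intens <- vapply(cl, intensity_from_matrix, numeric(1), W = W)
  }
  list(cliques = cl, intensities = intens, W = W,
       nodes = igraph::V(g)$name)
}

# Chain cliques sharing k-1 nodes into components; returns node unions.
# Cliques sharing a (k-1)-subset are unioned via vectorized subset keys,
# O(m * k) instead of O(m^2) pairwise intersection.
percolate_cliques <- function(cliques, k) {
  m <- length(cliques)
  if (m == 0) return(list())
  all_nodes <- sort(unique(unlist(cliques, use.names = FALSE)))
  M <- matrix(0L, m, k)
  for (i in seq_len(m)) M[i, ] <- match(cliques[[i]], all_nodes)
  keys <- character(0); owner <- integer(0)
  for (d in seq_len(k)) {
    sub <- M[, -d, drop = FALSE]
    keys <- c(keys, do.call(paste, c(as.data.frame(sub), sep = ",")))
    owner <- c(owner, seq_len(m))
  }
  parent <- seq_len(m)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (grp in split(owner, keys)) {
    if (length(grp) > 1) {
      r <- find(grp[1])
      for (j in grp[-1]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  unname(lapply(split(seq_len(m), roots),
                function(ix) sort(unique(unlist(cliques[ix])))))
}

#' Weighted clique percolation communities
#'
#' Keeps the k-cliques whose intensity is at least `intensity_threshold`,
#' joins cliques that share `k - 1` nodes, and returns the node-unions of
#' the resulting clique components as (possibly overlapping) communities.
#' Nodes in no retained clique are solitary.
#'
#' @param graph Weighted graph (see [enumerate_k_cliques()]).
#' @param k Clique size, default 3.
#' @param intensity_threshold Minimum clique intensity; 0 keeps every
#'   k-clique (unweighted clique percolation).
#' @return A `cpmw_communities` object: list with `communities` (list of
#'   node-name vectors), `solitary` (node names), `k`,
#'   `intensity_threshold`, and `membership`, a tibble with the disjoint
#'   assignment used downstream (overlapping nodes resolved to the
#'   community where their within-community strength is largest; ties to
#'   the larger community, then lexicographic).
#' @export
cpmw_communities <- function(graph, k = 3, intensity_threshold = 0) {
  if (intensity_threshold < 0) {
    abort("`intensity_threshold` must be nonnegative.",
          class = "socnetlong_config_error")
  }
  g <- as_cpmw_graph(graph)
  inv <- clique_inventory(g, k)
  cpmw_from_inventory(inv, k, intensity_threshold)
}

cpmw_from_inventory <- function(inv, k, intensity_threshold,
                                membership = TRUE) {
  keep <- inv$intensities >= intensity_threshold
  comms <- percolate_cliques(inv$cliques[keep], k)
  covered <- unique(unlist(comms))
  solitary <- setdiff(inv$nodes, covered)
  structure(
    list(communities = comms, solitary = solitary, k = k,
         intensity_threshold = intensity_threshold,
         membership = if (membership) resolve_disjoint(comms, solitary, inv$W)),
    class = "cpmw_communities"
  )
}

# Disjoint group assignment for downstream group-level statistics.
resolve_disjoint <- function(comms, solitary, W) {
  if (length(comms)) {
    ord <- order(-vapply(comms, length, integer(1)),
                 vapply(comms, function(x) paste(x, collapse = ","),
                        character(1)))
    comms_o <- comms[ord]
    all_nodes <- unique(unlist(comms_o))
    assign_to <- vapply(all_nodes, function(nd) {
      cand <- which(vapply(comms_o, function(cc) nd %in% cc, logical(1)))
      if (length(cand) == 1) return(cand)
      strength_in <- vapply(cand, function(ci) {
        others <- setdiff(comms_o[[ci]], nd)
        sum(W[nd, others])
      }, numeric(1))
      # ties already broken by the size/lexicographic ordering of comms_o
      cand[which.max(strength_in)]
    }, integer(1))
    rows <- tibble::tibble(
      individual_id = all_nodes,
      community = paste0("G", assign_to[all_nodes]),
      solitary = FALSE
    )
  } else {
    rows <- tibble::tibble(individual_id = character(),
                           community = character(), solitary = logical())
  }
  dplyr::bind_rows(
    rows,
    tibble::tibble(individual_id = solitary, community = "solitary",
                   solitary = TRUE)
  ) |> dplyr::arrange(.data$individual_id)
}

#' @export
print.cpmw_communities <- function(x, ...) {
  cat(sprintf(
    "<cpmw_communities> k=%d, intensity >= %.3g: %d communit%s, %d solitary\n",
    x$k, x$intensity_threshold, length(x$communities),
    if (length(x$communities) == 1) "y" else "ies", length(x$solitary)
  ))
  invisible(x)
}

#' @export
tidy.cpmw_communities <- function(x, ...) x$membership

#' Scan for a percolation intensity threshold
#'
#' Scans candidate thresholds (the sorted distinct k-clique intensities,
#' thinned to at most 40 quantile points on dense graphs) and returns the
#' largest threshold at which the largest community still covers at least
#' `min_fraction` of all clique-covered nodes -- i.e. the threshold just
#' below the percolation critical point, where communities are as strongly
#' connected as possible without the network shattering.
#'
#' @param graph Weighted graph.
#' @param k Clique size.
#' @param min_fraction Minimum fraction of clique-covered nodes the giant
#'   community must retain (default 0.5).
#' @return The selected threshold, or `NA` with a warning when the graph
#'   has no k-cliques (callers should then fall back to connected
#'   components).
#' @export
select_threshold <- function(graph, k = 3, min_fraction = 0.5) {
  g <- as_cpmw_graph(graph)
  inv <- clique_inventory(g, k)
  if (length(inv$cliques) == 0) {
    warn("Graph has no k-cliques; fall back to connected components.")
    return(NA_real_)
  }
  select_threshold_inv(inv, k, min_fraction)
}

select_threshold_inv <- function(inv, k, min_fraction = 0.5,
                                 max_candidates = 25) {
  intensities <- sort(unique(inv$intensities))
  if (length(intensities) > max_candidates) {
    intensities <- unique(quantile(
      intensities, probs = seq(0, 1, length.out = max_candidates),
      type = 1, names = FALSE
    ))
  }
  covered_all <- length(unique(unlist(inv$cliques)))
  ok <- function(th) {
    comms <- cpmw_from_inventory(inv, k, th, membership = FALSE)$communities
    length(comms) > 0 &&
      max(vapply(comms, length, integer(1))) >= min_fraction * covered_all
  }
  # giant-community size is monotone decreasing in the threshold, so the
  # largest admissible threshold can be found by bisection
  lo <- 1L; hi <- length(intensities)
  if (!ok(intensities[lo])) return(intensities[lo])
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (ok(intensities[mid])) lo <- mid else hi <- mid - 1L
  }
  intensities[lo]
}
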