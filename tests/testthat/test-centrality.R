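path3 <- function(w = c(1, 1)) {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- W["b", "a"] <- w[1]
  W["b", "c"] <- W["c", "b"] <- w[2]
  W
}

star4 <- function(w = 0.5) {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", 2:4] <- W[2:4, "a"] <- w
  W
}

test_that("strength is the weighted row sum", {
  s <- strength_centrality(star4(0.5))
  expect_equal(unname(s), c(1.5, 0.5, 0.5, 0.5))
  set.seed(71)
  W <- random_weighted_graph(6)
  expect_equal(strength_centrality(W), rowSums(W))
  # isolated node has strength 0
  W2 <- rbind(cbind(W, 0), 0)
  rownames(W2)[7] <- colnames(W2)[7] <- "iso"
  expect_equal(strength_centrality(W2)[["iso"]], 0)
})

test_that("Bonacich power matches closed forms and the series oracle", {
  # beta = 0 reduces to strength
  set.seed(72)
  W <- random_weighted_graph(6)
  expect_equal(bonacich_power(W, beta = 0), strength_centrality(W),
               ignore_attr = TRUE)
  # single edge, beta = 0.5: (I - bW)^{-1} W 1 = (2, 2)
  W1 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(bonacich_power(W1, beta = 0.5)), c(2, 2),
               ignore_attr = TRUE)
  # series oracle inside the spectral radius
  for (rep in 1:5) {
    W <- random_weighted_graph(5, p_edge = 0.7)
    rho <- max(abs(eigen(W, symmetric = TRUE, only.values = TRUE)$values))
    beta <- 0.9 / rho
    got <- bonacich_power(W, beta = beta)
    expect_equal(unname(got), oracle_power_series(W, beta), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # divergence guard
  W <- random_weighted_graph(5, p_edge = 0.7)
  rho <- max(abs(eigen(W, symmetric = TRUE, only.values = TRUE)$values))
  expect_error(bonacich_power(W, beta = 1.01 / rho),
               class = "socnetlong_divergence_error")
  # normalization scales to sum of squares = n
  nrm <- bonacich_power(W, normalize = TRUE)
  expect_equal(sum(nrm^2), nrow(W))
})

test_that("information centrality matches the hand-inverted 3-node path", {
  expect_equal(unname(information_centrality(path3())), c(1, 1.5, 1),
               tolerance = 1e-10)
  # complete equal-weight graph: perfect symmetry
  K <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(K) <- 0
  ic <- information_centrality(K)
  expect_equal(max(ic) - min(ic), 0, tolerance = 1e-12)
  # strictly positive on connected graphs
  set.seed(73)
  for (rep in 1:5) {
    W <- random_weighted_graph(6, p_edge = 0.8)
    if (igraph::components(as_igraph(W))$no != 1) next
    expect_true(all(information_centrality(W) > 0))
  }
  # disconnected input is rejected with advice
  D2 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D2["a", "b"] <- D2["b", "a"] <- 1
  D2["c", "d"] <- D2["d", "c"] <- 1
  expect_error(information_centrality(D2),
               class = "socnetlong_disconnected_error")
})

test_that("group dispersion honours the estimator choice", {
  vals <- c(a = 1, b = 1, c = 1)
  mem <- tibble::tibble(individual_id = c("a", "b", "c"),
                        community = "G1")
  expect_equal(group_dispersion(vals, mem)$sd, 0)
  vals2 <- c(a = 0, b = 2)
  mem2 <- tibble::tibble(individual_id = c("a", "b"), community = "G1")
  expect_equal(group_dispersion(vals2, mem2, "population")$sd, 1)
  vals3 <- c(a = 1, b = 2, c = 3, d = 4)
  mem3 <- tibble::tibble(individual_id = letters[1:4], community = "G1")
  expect_equal(group_dispersion(vals3, mem3, "sample")$sd, sd(1:4))
  # singleton group: defined (0) for population, NA for sample
  mem4 <- tibble::tibble(individual_id = c("a", "b", "c"),
                         community = c("G1", "G1", "G2"))
  expect_true(is.na(group_dispersion(vals, mem4, "sample")$sd[2]))
})

test_that("cohesion reproduces hand shortest-path values", {
  expect_equal(cohesion(path3(), "binary"), 5 / 6, tolerance = 1e-10)
  K <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(K) <- 0
  expect_equal(cohesion(K, "binary"), 1)
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(cohesion(D, "binary"), 0)
  # inverse-weight rule: edge length 1/w
  W <- path3(c(0.5, 0.5))  # distances 2, 2, 4
  expect_equal(cohesion(W, "inverse_weight"),
               (2 * (0.5 + 0.5 + 0.25)) / 6, tolerance = 1e-10)
})

test_that("centralization anchors at star = 1 and regular = 0, within [0,1]", {
  expect_equal(centralization(star4(0.7)), 1)
  K <- matrix(0.4, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(K) <- 0
  expect_equal(centralization(K), 0)
  expect_error(centralization(matrix(0, 2, 2)),
               class = "socnetlong_not_applicable")
  set.seed(74)
  for (rep in 1:20) {
    W <- random_weighted_graph(sample(3:9, 1), p_edge = runif(1, 0.3, 1))
    if (max(W) == 0) next
    v <- centralization(W)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("weight scaling acts as expected on each measure", {
  set.seed(75)
  W <- random_weighted_graph(7, p_edge = 0.8) * 0.5
  c0 <- 3
  expect_equal(strength_centrality(W * c0), c0 * strength_centrality(W))
  rho <- max(abs(eigen(W, symmetric = TRUE, only.values = TRUE)$values))
  beta <- 0.4 / rho
  expect_equal(unname(bonacich_power(W * c0, beta = beta / c0)),
               c0 * unname(bonacich_power(W, beta = beta)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(centralization(W * c0), centralization(W), tolerance = 1e-12)
  if (igraph::components(as_igraph(W))$no == 1) {
    r1 <- rank(information_centrality(W))
    r2 <- rank(information_centrality(W * c0))
    expect_equal(r1, r2)
  }
})

test_that("centrality table assembles node and group measures coherently", {
  set.seed(76)
  # two clean 4-cliques
  W <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  for (i in 1:3) for (j in (i + 1):4) W[i, j] <- W[j, i] <- runif(1, 0.3, 0.9)
  for (i in 5:7) for (j in (i + 1):8) W[i, j] <- W[j, i] <- runif(1, 0.3, 0.9)
  comm <- cpmw_communities(W, 3, 0.1)
  ct <- centrality_table(W, comm)
  expect_equal(nrow(ct$nodes), 8)
  expect_equal(nrow(ct$groups), 2)
  expect_equal(ct$nodes$strength,
               unname(strength_centrality(W)[ct$nodes$individual_id]))
  # group SDs equal a naive per-group recomputation
  for (g in ct$groups$community) {
    mem <- ct$nodes$individual_id[ct$nodes$community == g]
    naive <- sqrt(mean((strength_centrality(W)[mem] -
                          mean(strength_centrality(W)[mem]))^2))
    expect_equal(ct$groups$sd_strength[ct$groups$community == g], naive,
                 tolerance = 1e-12)
  }
})
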