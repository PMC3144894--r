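triangle <- function(w = c(1, 1, 1)) {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- W["b", "a"] <- w[1]
  W["a", "c"] <- W["c", "a"] <- w[2]
  W["b", "c"] <- W["c", "b"] <- w[3]
  W
}

test_that("k-clique enumeration finds every fully connected k-subset", {
  expect_length(enumerate_k_cliques(triangle(), 3), 1)
  # complete graph on 5 nodes: C(5,3) = 10 triangles
  K5 <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(K5) <- 0
  expect_length(enumerate_k_cliques(K5, 3), 10)
  # path graph has no triangle
  P4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  P4[cbind(1:3, 2:4)] <- P4[cbind(2:4, 1:3)] <- 1
  expect_length(enumerate_k_cliques(P4, 3), 0)
  expect_error(enumerate_k_cliques(K5, 2), class = "socnetlong_config_error")
})

test_that("clique intensity is the geometric mean of edge weights", {
  expect_equal(clique_intensity(letters[1:3], triangle(c(0.2, 0.2, 0.8))),
               0.032^(1 / 3), tolerance = 1e-12)
  expect_equal(clique_intensity(letters[1:3], triangle(c(0.4, 0.4, 0.4))), 0.4)
  set.seed(5)
  for (i in 1:10) {
    w <- runif(3, 0.01, 1)
    expect_lte(clique_intensity(letters[1:3], triangle(w)), max(w) + 1e-12)
  }
})

test_that("percolation joins cliques sharing k-1 nodes", {
  # two triangles sharing an edge -> one community of 4
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["a", "c"] <- W["b", "c"] <- W["b", "d"] <- W["c", "d"] <- 0.5
  W <- W + t(W)
  cc <- cpmw_communities(W, k = 3, intensity_threshold = 0.1)
  expect_length(cc$communities, 1)
  expect_equal(cc$communities[[1]], letters[1:4])
  expect_length(cc$solitary, 0)

  # two triangles sharing only one node -> two overlapping communities
  W2 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  W2["a", "b"] <- W2["a", "c"] <- W2["b", "c"] <- 0.5
  W2["c", "d"] <- W2["c", "e"] <- W2["d", "e"] <- 0.5
  W2 <- W2 + t(W2)
  cc2 <- cpmw_communities(W2, k = 3, intensity_threshold = 0.1)
  expect_length(cc2$communities, 2)
  expect_true("c" %in% cc2$communities[[1]] && "c" %in% cc2$communities[[2]])
  # the disjoint assignment places c in exactly one group
  expect_equal(sum(cc2$membership$individual_id == "c"), 1)

  # threshold above every weight -> everyone solitary
  cc3 <- cpmw_communities(W2, k = 3, intensity_threshold = 0.9)
  expect_length(cc3$communities, 0)
  expect_setequal(cc3$solitary, letters[1:5])
})

test_that("CPMw equals the brute-force oracle on random small graphs", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    W <- random_weighted_graph(n, p_edge = runif(1, 0.3, 0.8))
    th <- sample(c(0, runif(1, 0.1, 0.8)), 1)
    got <- cpmw_communities(W, k = 3, intensity_threshold = th)
    want <- oracle_cpm(W, k = 3, threshold = th)
    expect_equal(comm_key(got$communities), comm_key(want$communities))
    expect_setequal(got$solitary, want$solitary)
    # no node is ever lost
    expect_setequal(
      c(unlist(got$communities), got$solitary) |> unique(),
      rownames(W)
    )
  }
})

test_that("binary-weight CPMw at threshold 0 equals unweighted percolation", {
  set.seed(62)
  for (rep in 1:10) {
    W <- random_weighted_graph(10, p_edge = 0.4)
    W[W > 0] <- 1
    got <- cpmw_communities(W, k = 3, intensity_threshold = 0)
    want <- oracle_cpm(W, k = 3, threshold = 0)
    expect_equal(comm_key(got$communities), comm_key(want$communities))
  }
})

test_that("raising the threshold never enlarges a community", {
  set.seed(63)
  for (rep in 1:10) {
    W <- random_weighted_graph(10, p_edge = 0.6)
    ths <- seq(0, 1, by = 0.1)
    prev <- NULL
    for (th in ths) {
      cur <- cpmw_communities(W, k = 3, intensity_threshold = th)$communities
      if (!is.null(prev)) {
        # every current community is contained in some previous community
        for (cc in cur) {
          expect_true(any(vapply(prev, function(p) all(cc %in% p),
                                 logical(1))))
        }
      }
      prev <- cur
    }
  }
})

test_that("threshold scan splits well-separated heavy blocks", {
  # two dense blocks with strong internal weights, joined by weak edges
  W <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  for (i in 1:3) for (j in (i + 1):4) W[i, j] <- W[j, i] <- 0.8
  for (i in 5:7) for (j in (i + 1):8) W[i, j] <- W[j, i] <- 0.8
  W[4, 5] <- W[5, 4] <- 0.1
  W[3, 5] <- W[5, 3] <- 0.1
  W[4, 6] <- W[6, 4] <- 0.1
  th <- select_threshold(W, k = 3)
  cc <- cpmw_communities(W, k = 3, intensity_threshold = th)
  sizes <- sort(vapply(cc$communities, length, integer(1)))
  expect_equal(sizes, c(4L, 4L))
  # uniform complete graph percolates whole at any threshold below w
  K <- matrix(0.6, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(K) <- 0
  expect_length(cpmw_communities(K, 3, 0.5)$communities, 1)
  # empty graph signals fallback
  E <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(th0 <- select_threshold(E, 3), "no k-cliques")
  expect_true(is.na(th0))
})
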