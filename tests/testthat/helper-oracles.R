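# Independent brute-force oracles and fixture generators. These deliberately
# share no code with the package implementations they check.

# -- observation fixtures ----------------------------------------------------

make_records <- function(df) {
  tibble::tibble(
    date = as.Date("2001-01-01") + df$day,
    site = df$site %||% "A",
    event_id = df$event_id,
    individual_id = df$individual_id,
    interaction_type = df$interaction_type %||% "affiliative_contact",
    marked = df$marked %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small observation fixture: n individuals, D days, random events of
# random sizes.
random_records <- function(n = 6, D = 8, mean_events = 3) {
  ids <- sprintf("i%02d", seq_len(n))
  rows <- list()
  ev <- 0
  for (d in seq_len(D)) {
    n_ev <- rpois(1, mean_events)
    for (k in seq_len(n_ev)) {
      ev <- ev + 1
      size <- sample(2:min(4, n), 1)
      mem <- sample(ids, size)
      rows[[ev]] <- data.frame(day = d, event_id = sprintf("e%04d", ev),
                               individual_id = mem)
    }
  }
  if (length(rows) == 0) return(NULL)
  make_records(do.call(rbind, rows))
}

# Brute-force simple-ratio recount straight from raw records.
oracle_association <- function(records) {
  ids <- sort(unique(records$individual_id))
  n <- length(ids)
  seen <- lapply(ids, function(i) unique(records$date[records$individual_id == i]))
  names(seen) <- ids
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      ia <- ids[a]; ib <- ids[b]
      together <- 0
      for (d in unique(records$date)) {
        evs_a <- records$event_id[records$individual_id == ia & records$date == d]
        evs_b <- records$event_id[records$individual_id == ib & records$date == d]
        if (length(intersect(evs_a, evs_b)) > 0) together <- together + 1
      }
      denom <- length(union(seen[[ia]], seen[[ib]]))
      m[a, b] <- together / denom
    }
  }
  m
}

# -- clique percolation oracle ----------------------------------------------

# Exhaustive k-clique percolation for small graphs (<= ~12 nodes): subset
# enumeration, geometric-mean intensity filter, pairwise k-1 overlap,
# transitive closure by repeated merging.
oracle_cpm <- function(W, k, threshold = 0) {
  ids <- rownames(W)
  n <- nrow(W)
  if (n < k) return(list(communities = list(), solitary = ids))
  subsets <- combn(n, k, simplify = FALSE)
  cliques <- Filter(function(ss) {
    all(W[t(combn(ss, 2))] > 0)
  }, subsets)
  if (threshold > 0) {
    cliques <- Filter(function(ss) {
      w <- W[t(combn(ss, 2))]
      exp(mean(log(w))) >= threshold
    }, cliques)
  }
  if (length(cliques) == 0) {
    return(list(communities = list(), solitary = ids))
  }
  groups <- lapply(seq_along(cliques), function(i) i)
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      if (merged) break
      for (b in seq_along(groups)) {
        if (a >= b) next
        touch <- any(vapply(groups[[a]], function(i) {
          any(vapply(groups[[b]], function(j) {
            length(intersect(cliques[[i]], cliques[[j]])) >= k - 1
          }, logical(1)))
        }, logical(1)))
        if (touch) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  comms <- lapply(groups, function(g) {
    sort(ids[unique(unlist(cliques[g]))])
  })
  covered <- unique(unlist(comms))
  list(communities = comms, solitary = setdiff(ids, covered))
}

# Canonical form for comparing community sets.
comm_key <- function(comms) {
  sort(vapply(comms, function(x) paste(sort(x), collapse = ","), character(1)))
}

# -- Bonacich series oracle --------------------------------------------------

oracle_power_series <- function(W, beta, terms = 2000) {
  n <- nrow(W)
  acc <- rep(0, n)
  v <- W %*% rep(1, n)
  coef <- 1
  for (m in 0:terms) {
    acc <- acc + coef * v
    v <- W %*% v
    coef <- coef * beta
    if (max(abs(coef * v)) < 1e-14) break
  }
  drop(acc)
}

# -- Barker enumeration oracle ----------------------------------------------

# Exhaustive enumeration over hidden branch sequences for a single animal.
# At each interval an alive animal either dies (emitting R'/r outcomes fixed
# by the observed event) or survives (emitting R) and transitions at-risk /
# off-risk; captures are emitted at occasions. Probability of the observed
# (caps, events) sequence is the sum over all consistent paths.
oracle_barker <- function(caps, events, par) {
  T <- length(caps)
  first <- which(caps == 1)[1]
  if (first == T) return(1)
  recurse <- function(i, state) {
    # state: "risk", "off", "dead"
    if (i > T - 1) return(1)
    e <- events[i]; y <- caps[i + 1]
    tot <- 0
    if (state == "dead") {
      return(if (e == 0 && y == 0) recurse(i + 1, "dead") else 0)
    }
    # death branch
    pe <- switch(as.character(e),
      "0" = (1 - par$Rp) * (1 - par$r),
      "1" = par$Rp * (1 - par$r),
      "2" = (1 - par$Rp) * par$r,
      "3" = par$Rp * par$r
    )
    if (y == 0) tot <- tot + (1 - par$S) * pe * recurse(i + 1, "dead")
    # survival branch (impossible if recovered dead)
    if (e %in% c(0, 1)) {
      emit <- if (e == 1) par$R else 1 - par$R
      stay <- if (state == "risk") par$F else par$Fp
      # to at-risk
      cap_p <- if (y == 1) par$p else 1 - par$p
      tot <- tot + par$S * emit * stay * cap_p * recurse(i + 1, "risk")
      # to off-risk (capture impossible)
      if (y == 0) {
        tot <- tot + par$S * emit * (1 - stay) * recurse(i + 1, "off")
      }
    }
    tot
  }
  recurse(first, "risk")
}

# All observable histories for T occasions with first capture at occasion f.
enumerate_histories <- function(T, f) {
  caps_opts <- expand.grid(rep(list(0:1), T - f))
  ev_opts <- expand.grid(rep(list(0:3), T - 1))
  out <- list()
  for (i in seq_len(nrow(caps_opts))) {
    caps <- c(rep(0, f - 1), 1,
              if (T > f) as.integer(caps_opts[i, ]) else integer(0))
    for (j in seq_len(nrow(ev_opts))) {
      ev <- as.integer(ev_opts[j, ])
      if (f > 1 && any(ev[seq_len(f - 1)] != 0)) next
      dead_at <- which(ev %in% c(2, 3))
      if (length(dead_at) > 1) next
      if (length(dead_at) == 1) {
        d <- dead_at[1]
        if (d < T - 1 && any(ev[(d + 1):(T - 1)] != 0)) next
        if (d < T && any(caps[(d + 1):T] != 0)) next
      }
      out[[length(out) + 1]] <- list(caps = caps, events = ev)
    }
  }
  out
}

# Independent CJS conditional likelihood (constant S, p), direct product
# form per animal.
cjs_negloglik <- function(theta, caps) {
  S <- plogis(theta[1]); p <- plogis(theta[2])
  T <- ncol(caps)
  ll <- 0
  for (a in seq_len(nrow(caps))) {
    h <- caps[a, ]
    f <- which(h == 1)[1]
    l <- max(which(h == 1))
    if (l > f) {
      for (i in (f + 1):l) {
        ll <- ll + log(S) + if (h[i] == 1) log(p) else log(1 - p)
      }
    }
    # chi: probability never seen after l (applied T - l times)
    if (l < T) {
      chi <- 1
      for (i in seq_len(T - l)) chi <- 1 - S + S * (1 - p) * chi
      ll <- ll + log(chi)
    }
  }
  -ll
}

# -- permutation-test fixtures ----------------------------------------------

# Null fixture: random daily presence, random partition into clusters.
null_structure_records <- function(n = 12, D = 12) {
  ids <- sprintf("i%02d", seq_len(n))
  rows <- list()
  for (d in seq_len(D)) {
    present <- ids[runif(n) < 0.8]
    if (length(present) < 4) present <- ids[1:4]
    present <- sample(present)
    ncl <- max(2, length(present) %/% 3)
    cl <- sort(rep_len(seq_len(ncl), length(present)))
    for (ci in unique(cl)) {
      mem <- present[cl == ci]
      if (length(mem) >= 2) {
        rows[[length(rows) + 1]] <- data.frame(
          day = d, event_id = sprintf("d%02dc%d", d, ci),
          individual_id = mem
        )
      }
    }
  }
  make_records(do.call(rbind, rows))
}

# Strong preference fixture: two fixed cliques that always co-occur.
two_clique_records <- function(D = 15) {
  ids <- sprintf("i%02d", 1:8)
  rows <- list()
  for (d in seq_len(D)) {
    rows[[2 * d - 1]] <- data.frame(day = d, event_id = sprintf("d%02da", d),
                                    individual_id = ids[1:4])
    rows[[2 * d]] <- data.frame(day = d, event_id = sprintf("d%02db", d),
                                individual_id = ids[5:8])
  }
  make_records(do.call(rbind, rows))
}

# random weighted graph helper
random_weighted_graph <- function(n = 8, p_edge = 0.5) {
  W <- matrix(0, n, n, dimnames = list(sprintf("n%02d", 1:n),
                                       sprintf("n%02d", 1:n)))
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      if (runif(1) < p_edge) W[a, b] <- W[b, a] <- round(runif(1, 0.05, 1), 3)
    }
  }
  W
}
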