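# Independent oracles used across the suite. These deliberately avoid the
# package's compiled representations: states are evaluated by direct
# substitution into the expression trees, and centralities by explicit
# enumeration of every shortest path.

# Direct evaluation of every node function at a named logical state.
oracle_eval_state <- function(bn, state) {
  env <- as.list(state)
  vapply(bn$nodes, function(v)
    as.logical(eval(bn$functions[[v]], envir = env, enclos = baseenv())),
    logical(1))
}

# All 2^n states of a network as a logical matrix (row r = code r-1).
all_states <- function(bn) {
  n <- length(bn$nodes)
  m <- sapply(0:(n - 1), function(i) ((0:(2^n - 1) %/% 2^i) %% 2) == 1)
  m <- matrix(m, ncol = n, dimnames = list(NULL, bn$nodes))
  m
}

# Full-state truth table (2^n x n) by direct evaluation.
oracle_full_table <- function(bn) {
  st <- all_states(bn)
  t(apply(st, 1L, function(s) oracle_eval_state(bn, s)))
}

# Asynchronous successors of a state by definition.
oracle_async_succ <- function(bn, state) {
  vals <- oracle_eval_state(bn, state)
  out <- list()
  for (i in seq_along(state)) {
    if (vals[i] != state[i]) {
      s2 <- state
      s2[i] <- vals[i]
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

# Random simple digraph (no multi-edges; self-loops excluded) as an igraph.
rand_digraph <- function(n, m, seed) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), min(m, nrow(pairs))), ]
  igraph::graph_from_data_frame(pick, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

# Centralities by brute-force enumeration of all shortest paths (BFS
# distances, then recursive backward path enumeration through predecessors).
oracle_centralities <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- lapply(igraph::as_adj_list(g, mode = "out"),
                function(x) unique(as.integer(x)))
  radj <- lapply(igraph::as_adj_list(g, mode = "in"),
                 function(x) unique(as.integer(x)))
  betw <- stats::setNames(numeric(n), nodes)
  stress <- stats::setNames(numeric(n), nodes)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (w != v && is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    for (t in seq_len(n)) {
      if (t == s || is.infinite(dist[t])) next
      # enumerate all shortest s->t paths backwards
      paths <- list(t)
      repeat {
        heads <- vapply(paths, `[`, integer(1), 1L)
        if (all(heads == s)) break
        nxt <- list()
        for (p in paths) {
          h <- p[1L]
          if (h == s) { nxt[[length(nxt) + 1L]] <- p; next }
          for (u in radj[[h]]) if (u != h && dist[u] == dist[h] - 1)
            nxt[[length(nxt) + 1L]] <- c(u, p)
        }
        paths <- nxt
      }
      sigma <- length(paths)
      for (p in paths) {
        inner <- p[-c(1L, length(p))]
        stress[inner] <- stress[inner] + 1
        betw[inner] <- betw[inner] + 1 / sigma
      }
    }
  }
  list(betweenness = betw, stress = stress)
}

# Small seeded random Boolean network for ensemble tests.
rbn <- function(seed, n = NULL, k = NULL) {
  n <- n %||% (4L + seed %% 9L)          # 4..12
  k <- k %||% (1L + seed %% 3L)          # 1..3
  random_network(generator_spec(n = n, k = min(k, n - 1L), p = 0.5,
                                seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
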