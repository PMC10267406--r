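# Attractor search under five strategies: exhaustive synchronous
# enumeration with basins, SAT-based fixed points and fixed-length cycles,
# SCC-decomposition composition (approximate, with verification flags),
# heuristic synchronous restarts, and asynchronous random walks with
# certified terminal-SCC extraction.

# Attractor constructor. `states` are numeric state codes: a single code for
# steady states, cycle order for synchronous cycles, sorted for complex
# (asynchronous) attractors.
bn_attractor <- function(kind, states, nodes, method,
                         basin_size = NULL, certified = NA,
                         verified = NA, seed = NULL) {
  if (!is.character(states)) states <- as.numeric(states)
  structure(list(kind = kind, states = states, nodes = nodes,
                 method = method, basin_size = basin_size,
                 certified = certified, verified = verified, seed = seed),
            class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, ...) {
  n <- length(x$nodes)
  lab <- if (is.character(x$states)) x$states else
    vapply(x$states, function(cd)
      paste(((cd %/% 2^(0:(n - 1))) %% 2), collapse = ""), character(1))
  cat(x$kind, "attractor (", x$method, "): {", paste(lab, collapse = ", "),
      "}", sep = " ")
  if (!is.null(x$basin_size)) cat(" basin", x$basin_size)
  if (!is.na(x$verified)) cat(" verified:", x$verified)
  if (!is.na(x$certified)) cat(" certified:", x$certified)
  cat("\n")
  invisible(x)
}

# canonical key of an attractor's state set (for deduplication); states may
# be numeric codes or bit-string keys
attractor_key <- function(states) {
  if (is.character(states)) return(paste(sort(states), collapse = ","))
  paste(format(sort(states), scientific = FALSE, trim = TRUE), collapse = ",")
}

# rotate a synchronous cycle so it starts at its smallest state
canonical_cycle <- function(states) {
  k <- which(states == min(states))[1L]
  if (k > 1L) states <- c(states[k:length(states)], states[seq_len(k - 1L)])
  states
}

#' Exhaustive synchronous attractor search with basins
#'
#' Enumerates all `2^n` states, follows the deterministic synchronous
#' successor map and partitions the state space into basins of attraction.
#'
#' @param network a `boolean_network`.
#' @param cap node-count cap for full enumeration (default 24).
#' @return list of attractors (`bn_attractor`), each with `basin_size`;
#'   basin sizes sum to `2^n`. Sorted by decreasing basin size, ties by
#'   smallest state code.
#' @export
exhaustive_sync <- function(network, cap = 24L) {
  n <- length(network$nodes)
  if (n > cap) stop("exhaustive search needs n <= ", cap, " (got ", n, ")")
  codes <- seq(0, 2^n - 1)
  succ <- bn_sync_image(network, codes)
  # pointer doubling: D = succ^(2^n) maps every state into its cycle
  D <- succ
  for (dummy in seq_len(n)) D <- D[D + 1]
  if (n == 0L) D <- succ
  cyclic <- unique(D)
  label <- rep(NA_integer_, length(codes))
  attractors <- list()
  for (c0 in sort(cyclic)) {
    if (!is.na(label[c0 + 1])) next
    cyc <- c0
    nxt <- succ[c0 + 1]
    while (nxt != c0) {
      cyc <- c(cyc, nxt)
      nxt <- succ[nxt + 1]
    }
    id <- length(attractors) + 1L
    label[cyc + 1] <- id
    attractors[[id]] <- bn_attractor(
      kind = if (length(cyc) == 1L) "steady" else "cycle",
      states = canonical_cycle(cyc), nodes = network$nodes,
      method = "exhaustive")
  }
  basin_of <- label[D + 1]
  sizes <- tabulate(basin_of, nbins = length(attractors))
  for (i in seq_along(attractors)) attractors[[i]]$basin_size <- sizes[i]
  ord <- order(-sizes, vapply(attractors, function(a) min(a$states), numeric(1)))
  attractors[ord]
}

#' Synchronous fixed points via SAT
#'
#' Encodes `x_i <-> B_i(x)` for every node as CNF (Tseitin translation) and
#' enumerates all models with iterative blocking clauses. The result equals
#' the set of synchronous steady states.
#'
#' @param network a `boolean_network`.
#' @param limit stop after this many fixed points (default unlimited; note
#'   that a model with `m` unconstrained free inputs has at least `2^m`
#'   fixed points, so a cap is advisable on input-heavy models).
#' @return sorted vector of fixed points: numeric state codes for networks
#'   of up to 48 nodes, bit-string keys (node order) above that, where
#'   numeric codes would lose integer precision. Empty when the constraints
#'   are unsatisfiable.
#' @export
sat_steady_states <- function(network, limit = Inf) {
  cnf <- cnf_fixed_point(network)
  n <- length(network$nodes)
  models <- sat_enumerate(cnf, project = seq_len(n), limit = limit)
  if (!length(models)) {
    return(if (n <= CODE_MAX_N) numeric(0) else character(0))
  }
  if (n <= CODE_MAX_N)
    return(sort(vapply(models, function(m)
      sum(as.numeric(m) * 2^(seq_len(n) - 1)), numeric(1))))
  sort(vapply(models, state_key, character(1)))
}

#' Synchronous cycles of exact length L via SAT
#'
#' Unrolls the update over `L` steps (`x^{t+1} = B(x^t)`, wrap-around), adds
#' pairwise distinctness of the `L` states, and enumerates; each discovered
#' cycle is blocked together with all of its rotations.
#'
#' @param network a `boolean_network`.
#' @param L cycle length (>= 2).
#' @param limit stop after this many cycles (default unlimited).
#' @return list of `bn_attractor` objects of kind `"cycle"` (length-L simple
#'   synchronous cycles, canonical rotation).
#' @export
sat_cycles <- function(network, L, limit = Inf) {
  stopifnot(L >= 2L)
  n <- length(network$nodes)
  cnf <- cnf_new(L * n)
  var_of <- function(t, i) t * n + i      # t in 0..L-1
  for (t in 0:(L - 1)) {
    varmap <- stats::setNames(var_of(t, seq_len(n)), network$nodes)
    tnext <- (t + 1) %% L
    for (i in seq_len(n)) {
      g <- tseitin_expr(network$functions[[i]], varmap, cnf)
      cnf_add(cnf, -var_of(tnext, i), g)
      cnf_add(cnf, var_of(tnext, i), -g)
    }
  }
  for (t in 0:(L - 2)) for (u in (t + 1):(L - 1)) {
    dvars <- integer(n)
    for (i in seq_len(n)) {
      d <- cnf_fresh(cnf)
      dvars[i] <- d
      cnf_add(cnf, -d, var_of(t, i), var_of(u, i))
      cnf_add(cnf, -d, -var_of(t, i), -var_of(u, i))
    }
    cnf_add(cnf, dvars)
  }
  state_vars <- seq_len(L * n)
  clauses <- cnf$clauses
  found <- list()
  repeat {
    model <- dpll_solve(clauses, cnf$nvars)
    if (is.null(model) || length(found) >= limit) break
    codes <- vapply(0:(L - 1), function(t)
      sum(as.numeric(model[var_of(t, seq_len(n))]) * 2^(seq_len(n) - 1)),
      numeric(1))
    found[[length(found) + 1L]] <- bn_attractor(
      "cycle", canonical_cycle(codes), network$nodes, method = "sat")
    # block every rotation of this cycle
    bits <- model[state_vars]
    for (r in 0:(L - 1)) {
      rot <- unlist(lapply(0:(L - 1), function(t) {
        src <- (t + r) %% L
        model[var_of(src, seq_len(n))]
      }))
      block <- ifelse(rot, -state_vars, state_vars)
      clauses[[length(clauses) + 1L]] <- as.integer(block)
    }
  }
  found
}

#' Heuristic attractor search by random restarts
#'
#' Samples `n_starts` initial states, iterates the synchronous step with
#' Brent's cycle-detection algorithm, and deduplicates the attractors
#' reached. Coverage is a lower bound on the true attractor set.
#'
#' @param network a `boolean_network`.
#' @param n_starts number of sampled initial states (>= 1).
#' @param seed RNG seed.
#' @return list of `bn_attractor` objects (kinds `steady`/`cycle`).
#' @export
heuristic_search <- function(network, n_starts = 100L, seed = NULL) {
  stopifnot(n_starts >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(network$nodes)
  found <- list()
  seen <- character(0)
  for (i in seq_len(n_starts)) {
    s0 <- stats::runif(n) < 0.5
    names(s0) <- network$nodes
    cyc <- brent_cycle(function(s) sync_step(network, s), s0,
                       keyf = state_key)
    states <- if (n <= CODE_MAX_N)
      vapply(cyc, key_to_code, numeric(1)) else unlist(cyc)
    key <- attractor_key(states)
    if (key %in% seen) next
    seen <- c(seen, key)
    found[[length(found) + 1L]] <- bn_attractor(
      kind = if (length(states) == 1L) "steady" else "cycle",
      states = canonical_cycle(states), nodes = network$nodes,
      method = "heuristic", seed = seed)
  }
  found[order(vapply(found, function(a) attractor_key(a$states),
                     character(1)))]
}

# Brent's cycle-detection algorithm on a deterministic map f; states are
# compared through `keyf`. Returns the cycle's state KEYS in map order.
brent_cycle <- function(f, x0, keyf) {
  power <- 1L; lam <- 1L
  tortoise <- x0
  hare <- f(x0)
  while (keyf(tortoise) != keyf(hare)) {
    if (power == lam) {
      tortoise <- hare
      power <- power * 2L
      lam <- 0L
    }
    hare <- f(hare)
    lam <- lam + 1L
  }
  # recover a state on the cycle: advance a second pointer by lam, then walk
  tortoise <- x0
  hare <- x0
  for (i in seq_len(lam)) hare <- f(hare)
  while (keyf(tortoise) != keyf(hare)) {
    tortoise <- f(tortoise)
    hare <- f(hare)
  }
  cyc <- list(keyf(tortoise))
  nxt <- f(tortoise)
  while (keyf(nxt) != keyf(tortoise)) {
    cyc[[length(cyc) + 1L]] <- keyf(nxt)
    nxt <- f(nxt)
  }
  cyc
}

#' Asynchronous attractor search by random walks
#'
#' Performs random asynchronous walks (uniform choice among eligible flips)
#' from sampled initial states. A state with no eligible flip is a steady
#' state. A walk that exhausts its step budget triggers a bounded forward
#' closure exploration from its final state: the closure's terminal strongly
#' connected components are certified complex attractors (closed under every
#' asynchronous transition). If the closure exceeds `state_cap`, the walk
#' tail is reported as an uncertified candidate.
#'
#' When the state space is no larger than `n_runs`, initial states are
#' sampled without replacement, so every state — hence every attractor — is
#' visited by some walk.
#'
#' @param network a `boolean_network`.
#' @param n_runs number of walks (>= 1).
#' @param max_steps step budget per walk.
#' @param seed RNG seed.
#' @param state_cap bound on the closure exploration (default 4096 states).
#' @return list of `bn_attractor` objects; complex attractors carry
#'   `certified = TRUE` when their closure was verified.
#' @export
async_random_walk <- function(network, n_runs = 1000L, max_steps = 500L,
                              seed = NULL, state_cap = 4096L) {
  stopifnot(n_runs >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(network$nodes)
  small <- n <= 25L && 2^n <= n_runs
  start_perm <- if (small) sample(seq(0, 2^n - 1)) else NULL
  start_state <- function(i) {
    if (small && i <= length(start_perm))
      return(code_to_state(start_perm[i], network))
    stats::setNames(stats::runif(n) < 0.5, network$nodes)
  }
  to_repr <- function(keys) {
    if (n <= CODE_MAX_N) sort(vapply(keys, key_to_code, numeric(1)))
    else sort(unlist(keys))
  }
  found <- list()
  seen <- character(0)
  known <- new.env(parent = emptyenv())   # state key -> already attributed
  add <- function(att, keys) {
    key <- attractor_key(att$states)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      found[[length(found) + 1L]] <<- att
      if (isTRUE(att$certified))
        for (k in keys) assign(k, TRUE, envir = known)
    }
  }
  for (run in seq_len(n_runs)) {
    state <- start_state(run)
    steady <- FALSE
    hit_known <- FALSE
    for (step in seq_len(max_steps)) {
      if (exists(state_key(state), envir = known, inherits = FALSE)) {
        hit_known <- TRUE
        break
      }
      vals <- bn_node_values(network, state)
      flips <- which(vals != state)
      if (!length(flips)) { steady <- TRUE; break }
      pick <- if (length(flips) == 1L) flips else
        flips[sample.int(length(flips), 1L)]
      state[pick] <- vals[pick]
    }
    if (hit_known) next    # walk entered an already-certified attractor
    if (steady) {
      k <- state_key(state)
      add(bn_attractor("steady", to_repr(k), network$nodes, "async_walk",
                       certified = TRUE, seed = seed), k)
      next
    }
    cl <- async_forward_closure(network, state, state_cap)
    if (is.null(cl)) {
      add(bn_attractor("complex", to_repr(state_key(state)), network$nodes,
                       "async_walk", certified = FALSE, seed = seed),
          character(0))
      next
    }
    for (term in cl)
      add(bn_attractor(if (length(term) == 1L) "steady" else "complex",
                       to_repr(term), network$nodes, "async_walk",
                       certified = TRUE, seed = seed), term)
  }
  found[order(vapply(found, function(a) attractor_key(a$states),
                     character(1)))]
}

# Forward closure of a logical state under asynchronous transitions, bounded
# by `state_cap`; returns the closure's terminal SCCs (lists of state keys)
# or NULL when the cap is exceeded. The closure is complete, so its terminal
# SCCs are genuine attractors of the full system.
async_forward_closure <- function(network, state, state_cap) {
  seen <- new.env(parent = emptyenv())
  k0 <- state_key(state)
  assign(k0, TRUE, envir = seen)
  queue <- list(state)
  n_states <- 1L
  edges <- list()
  while (length(queue)) {
    s <- queue[[1L]]; queue <- queue[-1L]
    vals <- bn_node_values(network, s)
    flips <- which(vals != s)
    from_key <- state_key(s)
    for (i in flips) {
      s2 <- s
      s2[i] <- vals[i]
      k2 <- state_key(s2)
      edges[[length(edges) + 1L]] <- c(from_key, k2)
      if (!exists(k2, envir = seen, inherits = FALSE)) {
        assign(k2, TRUE, envir = seen)
        n_states <- n_states + 1L
        if (n_states > state_cap) return(NULL)
        queue[[length(queue) + 1L]] <- s2
      }
    }
  }
  keys <- ls(seen)
  if (!length(edges)) return(list(k0))   # isolated steady state
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = keys))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  term <- rep(TRUE, comp$no)
  ends <- igraph::as_edgelist(g, names = FALSE)
  cross <- memb[ends[, 1]] != memb[ends[, 2]]
  term[unique(memb[ends[cross, 1]])] <- FALSE
  out <- list()
  for (cmp in which(term))
    out[[length(out) + 1L]] <- sort(names(memb)[memb == cmp])
  out
}

#' Approximate attractor search by SCC decomposition
#'
#' Splits the interaction graph into strongly connected blocks, processes the
#' blocks in topological order, solves each block exhaustively with its
#' upstream nodes frozen to a candidate's context, and composes block
#' attractors phase-aligned (least-common-multiple of the periods). The
#' composition is an approximation: every candidate is checked against the
#' full network's synchronous dynamics and flagged `verified` accordingly.
#'
#' @param network a `boolean_network`.
#' @param block_cap per-block exhaustive cap (default 16 nodes).
#' @return list of `bn_attractor` objects with a logical `verified` field.
#' @export
decomposition_search <- function(network, block_cap = 16L) {
  n <- length(network$nodes)
  g <- igraph::graph_from_data_frame(
    do.call(rbind, lapply(network$nodes, function(v) {
      regs <- bool_expr_vars(network$functions[[v]])
      regs <- setdiff(regs, if (v %in% network$inputs) v else character(0))
      if (!length(regs)) return(NULL)
      data.frame(from = regs, to = v, stringsAsFactors = FALSE)
    })) %||% data.frame(from = character(), to = character()),
    directed = TRUE, vertices = data.frame(name = network$nodes))
  comp <- igraph::components(g, mode = "strong")
  cond <- igraph::contract(g, comp$membership)
  cond <- igraph::simplify(cond)
  topo <- as.integer(igraph::topo_sort(cond, mode = "out"))
  blocks <- split(network$nodes, comp$membership[match(network$nodes,
                                                       igraph::V(g)$name)])
  candidates <- list(list(states = list(stats::setNames(logical(0),
                                                        character(0)))))
  for (b in topo) {
    bnodes <- blocks[[as.character(b)]]
    if (length(bnodes) > block_cap)
      stop("decomposition block of ", length(bnodes),
           " nodes exceeds block_cap = ", block_cap)
    new_cands <- list()
    for (cand in candidates) {
      ctx <- cand$states[[1L]]           # frozen first-phase context
      sub_funs <- lapply(stats::setNames(bnodes, bnodes), function(v) {
        subst <- as.list(ctx)
        keep <- setdiff(names(subst), bnodes)
        bool_validate_expr(
          bool_expr_substitute(network$functions[[v]], subst[keep]))
      })
      sub_bn <- boolean_network(sub_funs)
      atts <- exhaustive_sync(sub_bn)
      for (a in atts) {
        amat <- lapply(a$states, function(cd) code_to_state(cd, sub_bn))
        p1 <- length(cand$states); p2 <- length(amat)
        p <- lcm_int(p1, p2)
        comp_states <- lapply(seq_len(p) - 1L, function(t)
          c(cand$states[[t %% p1 + 1L]], amat[[t %% p2 + 1L]]))
        new_cands[[length(new_cands) + 1L]] <- list(states = comp_states)
      }
    }
    candidates <- new_cands
  }
  out <- list()
  seen <- character(0)
  for (cand in candidates) {
    full <- lapply(cand$states, function(s) s[network$nodes])
    keys <- vapply(full, state_key, character(1))
    # drop duplicate phases (lcm alignment can repeat the same state pattern)
    if (length(keys) > 1L && length(unique(keys)) < length(keys)) {
      k <- which(duplicated(keys))[1L] - 1L
      keys <- keys[seq_len(k)]
      full <- full[seq_len(k)]
    }
    ok <- all(vapply(seq_along(full), function(t) {
      nxt <- sync_step(network, full[[t]])
      state_key(nxt) == keys[if (t == length(keys)) 1L else t + 1L]
    }, logical(1)))
    states <- if (n <= CODE_MAX_N)
      vapply(full, state_code, numeric(1)) else keys
    key <- attractor_key(states)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- bn_attractor(
      kind = if (length(states) == 1L) "steady" else "cycle",
      states = canonical_cycle(states), nodes = network$nodes,
      method = "decomposition", verified = ok)
  }
  out[order(vapply(out, function(a) attractor_key(a$states), character(1)))]
}

lcm_int <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  a * b / gcd(a, b)
}

#' Attractors as a readable table
#'
#' @param attractors list of `bn_attractor` objects.
#' @return data.frame with `kind`, `method`, `length`, `states`
#'   (comma-separated bit-strings in node order), `basin_size`, `verified`,
#'   `certified`.
#' @export
attractor_table <- function(attractors) {
  if (!length(attractors))
    return(data.frame(kind = character(), method = character(),
                      length = integer(), states = character(),
                      basin_size = numeric(), verified = logical(),
                      certified = logical(), stringsAsFactors = FALSE))
  n <- length(attractors[[1L]]$nodes)
  lab <- function(cds) {
    if (is.character(cds)) return(paste(cds, collapse = ","))
    paste(vapply(cds, function(cd)
      paste(((cd %/% 2^(0:(n - 1))) %% 2), collapse = ""), character(1)),
      collapse = ",")
  }
  do.call(rbind, lapply(attractors, function(a) data.frame(
    kind = a$kind, method = a$method, length = length(a$states),
    states = lab(a$states),
    basin_size = a$basin_size %||% NA_real_,
    verified = a$verified, certified = a$certified,
    stringsAsFactors = FALSE)))
}
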