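# Update schemes: synchronous (all nodes recomputed simultaneously),
# asynchronous (one chosen node recomputed), and the state-transition graphs
# they induce.

#' Synchronous update step
#'
#' Every node is simultaneously set to the value of its Boolean function
#' evaluated on the current state.
#'
#' @param network a `boolean_network`.
#' @param state named or ordered logical vector over the network's nodes.
#' @return the successor state (named logical vector).
#' @export
sync_step <- function(network, state) {
  state <- as_state(network, state)
  out <- bn_node_values(network, state)
  names(out) <- network$nodes
  out
}

#' Asynchronous update step
#'
#' Only `node` is recomputed; every other coordinate is untouched.
#'
#' @inheritParams sync_step
#' @param node identifier of the node to update.
#' @return the successor state (named logical vector).
#' @export
async_step <- function(network, state, node) {
  state <- as_state(network, state)
  i <- match(node, network$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  cp <- network$compiled[[i]]
  val <- if (!length(cp$regs)) cp$tt[1L]
         else cp$tt[1L + sum(as.numeric(state[cp$regs]) * 2^(seq_along(cp$regs) - 1))]
  state[i] <- val
  state
}

as_state <- function(network, state) {
  n <- length(network$nodes)
  if (length(state) != n)
    stop("state has ", length(state), " entries, network has ", n, " nodes")
  if (!is.null(names(state))) {
    if (!setequal(names(state), network$nodes))
      stop("state names do not match network nodes")
    state <- state[network$nodes]
  }
  stats::setNames(as.logical(state), network$nodes)
}

# indices of nodes whose update would change the state (code form)
bn_eligible_flips <- function(bn, bits) {
  vals <- bn_node_values(bn, bits)
  which(vals != bits)
}

# asynchronous successor codes of a state code (self-loops omitted)
async_successor_codes <- function(bn, code) {
  bits <- as.numeric(code_to_state(code, bn))
  flips <- bn_eligible_flips(bn, bits == 1)
  if (!length(flips)) return(numeric(0))
  vapply(flips, function(i) code + (1 - 2 * bits[i]) * 2^(i - 1), numeric(1))
}

#' Build a state-transition graph
#'
#' Synchronous STGs contain the edge `s -> sync_step(s)` for every state
#' (out-degree exactly one; fixed points carry their self-loop).
#' Asynchronous STGs contain one edge per node whose update changes the
#' state; no-change self-loops are omitted, so steady states are exactly the
#' sink states.
#'
#' @param network a `boolean_network`.
#' @param scheme `"synchronous"` or `"asynchronous"`.
#' @param init optional vector of initial state codes; when supplied only the
#'   forward-reachable set is built, otherwise all `2^n` states (requires
#'   `n <= cap`).
#' @param cap full-enumeration cap on the node count (default 20).
#' @return an object of class `stg`: list with `scheme`, `nodes`, `states`
#'   (numeric codes) and `edges` (data.frame `from`, `to`).
#' @export
build_stg <- function(network, scheme = c("synchronous", "asynchronous"),
                      init = NULL, cap = 20L) {
  scheme <- match.arg(scheme)
  n <- length(network$nodes)
  if (is.null(init)) {
    if (n > cap)
      stop("full STG needs n <= ", cap, " nodes (got ", n,
           "); supply initial states instead")
    states <- seq(0, 2^n - 1)
    explore <- FALSE
  } else {
    states <- unique(as.numeric(init))
    explore <- TRUE
  }
  succ_of <- function(code) {
    if (scheme == "synchronous") bn_sync_image(network, code)
    else async_successor_codes(network, code)
  }
  if (explore) {
    seen <- new.env(parent = emptyenv())
    for (s in states) assign(format(s, scientific = FALSE), TRUE, envir = seen)
    queue <- states
    edges_from <- list()
    while (length(queue)) {
      code <- queue[[1L]]; queue <- queue[-1L]
      nxt <- succ_of(code)
      edges_from[[format(code, scientific = FALSE)]] <- nxt
      for (t in nxt) {
        key <- format(t, scientific = FALSE)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          queue <- c(queue, t)
          states <- c(states, t)
        }
      }
    }
    from <- rep(as.numeric(names(edges_from)),
                vapply(edges_from, length, integer(1)))
    to <- unlist(edges_from, use.names = FALSE)
  } else if (scheme == "synchronous") {
    from <- states
    to <- bn_sync_image(network, states)
  } else {
    succs <- lapply(states, async_successor_codes, bn = network)
    from <- rep(states, vapply(succs, length, integer(1)))
    to <- unlist(succs, use.names = FALSE)
  }
  if (is.null(to)) to <- numeric(0)
  structure(list(scheme = scheme, nodes = network$nodes,
                 states = sort(unique(states)),
                 edges = data.frame(from = as.numeric(from),
                                    to = as.numeric(to))),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("State-transition graph (", x$scheme, "): ",
      length(x$states), " states, ", nrow(x$edges), " transitions\n", sep = "")
  invisible(x)
}

#' Convert a state-transition graph to igraph
#'
#' Vertex names are the states' bit-strings in network node order (node 1 is
#' the first character).
#'
#' @param stg an object from [build_stg()].
#' @return an igraph object.
#' @export
stg_igraph <- function(stg) {
  n <- length(stg$nodes)
  lab <- function(code) vapply(code, function(cd)
    paste(((cd %/% 2^(0:(n - 1))) %% 2), collapse = ""), character(1))
  igraph::graph_from_data_frame(
    data.frame(from = lab(stg$edges$from), to = lab(stg$edges$to)),
    directed = TRUE, vertices = data.frame(name = lab(stg$states)))
}

# Terminal SCCs of the asynchronous STG: attractors of the async dynamics.
# Returns a list of numeric code vectors (sorted).
stg_terminal_sccs <- function(stg) {
  stopifnot(stg$scheme == "asynchronous")
  g <- stg_igraph(stg)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  term <- rep(TRUE, comp$no)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) {
    cross <- memb[el[, 1]] != memb[el[, 2]]
    term[unique(memb[el[cross, 1]])] <- FALSE
  }
  codes <- stg$states
  names(memb) <- igraph::V(g)$name
  key <- vapply(codes, function(cd)
    paste(((cd %/% 2^(0:(length(stg$nodes) - 1))) %% 2), collapse = ""),
    character(1))
  out <- list()
  for (cmp in which(term)) {
    members <- sort(codes[memb[key] == cmp])
    out[[length(out) + 1L]] <- members
  }
  out[order(vapply(out, min, numeric(1)))]
}
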