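# Knockout/overexpression analysis. A perturbation clamps one node's
# function to a constant; sensitivity compares the unperturbed and perturbed
# attractor landscapes. Both landscapes are summarized as the UNION of their
# attractor states, projected onto all nodes except the perturbed one (the
# clamped coordinate would otherwise register as a trivial difference), and
# compared with two set distances:
#   similarity (Jaccard)  s = |A ∩ B| / |A ∪ B|        (1 = identical)
#   identity distance     d = 1 − |A ∩ B| / |A|        (0 = A preserved)

#' Clamp a node (knockout / overexpression)
#'
#' Replaces the node's Boolean function with the constant 0 (knockout) or 1
#' (overexpression); everything else is untouched.
#'
#' @param network a `boolean_network`.
#' @param node node identifier.
#' @param mode `"knockout"` or `"overexpression"`.
#' @return the clamped `boolean_network`.
#' @export
clamp <- function(network, node, mode = c("knockout", "overexpression")) {
  mode <- match.arg(mode)
  if (!node %in% network$nodes) stop("unknown node: ", node)
  funs <- network$functions
  funs[[node]] <- mode == "overexpression"
  boolean_network(funs, name = network$metadata$name,
                  labels = network$metadata$labels)
}

#' Similarity between two attractor-state sets (Jaccard index)
#'
#' `|A ∩ B| / |A ∪ B|`, exactly as a set similarity; two empty sets count as
#' identical (1).
#'
#' @param a,b numeric vectors of state codes (or character keys); treated as
#'   sets.
#' @return value in `[0, 1]`.
#' @export
similarity_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Identity-based distance between attractor-state sets
#'
#' `1 − |A ∩ B| / |A|`, the fraction of the unperturbed set lost under
#' perturbation. Asymmetric; `A` must be nonempty.
#'
#' @param a unperturbed state set (nonempty).
#' @param b perturbed state set.
#' @return value in `[0, 1]`.
#' @export
identity_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a)) stop("identity distance needs a nonempty unperturbed set")
  1 - length(intersect(a, b)) / length(a)
}

# Union of all attractor states found by the configured search, as
# bit-string state keys over the network's own node order (exact at any
# network size).
attractor_state_union <- function(network, search = attractor_search_config()) {
  n <- length(network$nodes)
  as_keys <- function(states) {
    if (is.character(states)) states
    else vapply(states, code_to_key, character(1), n = n)
  }
  keys <- character(0)
  if ("sat" %in% search$methods)
    keys <- c(keys, as_keys(sat_steady_states(network,
                                              limit = search$sat_limit)))
  if ("async" %in% search$methods) {
    atts <- async_random_walk(network, n_runs = search$n_runs,
                              max_steps = search$max_steps,
                              seed = search$seed)
    keys <- c(keys, unlist(lapply(atts, function(a) as_keys(a$states))))
  }
  if ("exhaustive" %in% search$methods) {
    atts <- exhaustive_sync(network)
    keys <- c(keys, unlist(lapply(atts, function(a) as_keys(a$states))))
  }
  sort(unique(keys))
}

#' Attractor-search configuration for sensitivity analysis
#'
#' @param methods subset of `"sat"` (fixed points), `"async"` (random-walk
#'   complex/steady attractors), `"exhaustive"`. Default: sat + async, the
#'   combination that scales to pathway-sized models.
#' @param n_runs,max_steps,seed forwarded to [async_random_walk()].
#' @param sat_limit cap on SAT fixed-point enumeration (a model with `m`
#'   free inputs has at least `2^m` of them).
#' @return a list of class `attractor_search_config`.
#' @export
attractor_search_config <- function(methods = c("sat", "async"),
                                    n_runs = 200L, max_steps = 250L,
                                    seed = NULL, sat_limit = 10000L) {
  stopifnot(all(methods %in% c("sat", "async", "exhaustive")))
  structure(list(methods = methods, n_runs = n_runs, max_steps = max_steps,
                 seed = seed, sat_limit = sat_limit),
            class = "attractor_search_config")
}

# project state keys (bit-strings over `nodes`) onto nodes minus `drop`:
# returns the set of projected bit patterns.
project_states <- function(keys, nodes, drop) {
  if (!length(keys)) return(character(0))
  drop_idx <- which(nodes %in% drop)
  if (!length(drop_idx)) return(unique(keys))
  unique(vapply(keys, function(k)
    paste(strsplit(k, "", fixed = TRUE)[[1]][-drop_idx], collapse = ""),
    character(1), USE.NAMES = FALSE))
}

#' Sensitivity of the attractor landscape to a single perturbation
#'
#' Computes the unperturbed and perturbed attractor-state unions, projects
#' the perturbed node's coordinate out of both, and reports the similarity
#' (Jaccard) and identity-based distances. The headline scalar sensitivity
#' is the identity-based distance.
#'
#' @param network a `boolean_network`.
#' @param node node to perturb.
#' @param mode `"knockout"` or `"overexpression"`.
#' @param search an [attractor_search_config()].
#' @param unpert_states optional precomputed unperturbed attractor-state
#'   union (state codes), to avoid recomputation across a scan.
#' @return one-row data.frame: `node`, `mode`, `d_sim` (Jaccard similarity),
#'   `dissimilarity` (`1 - d_sim`), `d_id`, `sensitivity` (= `d_id`),
#'   `n_states_unpert`, `n_states_pert`.
#' @export
knockout_sensitivity <- function(network, node,
                                 mode = c("knockout", "overexpression"),
                                 search = attractor_search_config(),
                                 unpert_states = NULL) {
  mode <- match.arg(mode)
  if (is.null(unpert_states))
    unpert_states <- attractor_state_union(network, search)
  pert <- clamp(network, node, mode)
  pert_states <- attractor_state_union(pert, search)
  A <- project_states(unpert_states, network$nodes, node)
  B <- project_states(pert_states, network$nodes, node)
  d_sim <- similarity_distance(A, B)
  d_id <- identity_distance(A, B)
  data.frame(node = node, mode = mode, d_sim = d_sim,
             dissimilarity = 1 - d_sim, d_id = d_id, sensitivity = d_id,
             n_states_unpert = length(A), n_states_pert = length(B),
             stringsAsFactors = FALSE)
}

#' Sensitivity report over many perturbations
#'
#' @param network a `boolean_network`.
#' @param nodes nodes to perturb (default: all).
#' @param modes perturbation modes to apply to each node.
#' @param search an [attractor_search_config()].
#' @return data.frame, one row per (node, mode), columns as in
#'   [knockout_sensitivity()] plus a `seed` column.
#' @export
sensitivity_report <- function(network, nodes = network$nodes,
                               modes = c("knockout", "overexpression"),
                               search = attractor_search_config()) {
  unpert <- attractor_state_union(network, search)
  rows <- list()
  for (v in nodes) for (m in modes)
    rows[[paste(v, m)]] <- knockout_sensitivity(
      network, v, m, search, unpert_states = unpert)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$seed <- search$seed %||% NA_integer_
  out
}

#' Prioritize intervention targets
#'
#' Min–max normalizes betweenness centrality and the identity-based knockout
#' sensitivity to `[0, 1]` and ranks nodes by the mean of the two. Also
#' reports the intersection of the top-`q` sets under each criterion
#' separately (attribute `"top_intersection"`).
#'
#' @param centrality a [centrality_table()].
#' @param sensitivity a [sensitivity_report()] (rows with `mode ==
#'   "knockout"` are used; pass a single-mode report to override).
#' @param q top fraction for the intersection report (default 0.25).
#' @return data.frame sorted by descending `priority`: `node`,
#'   `betweenness`, `sensitivity`, `priority`, `rank`.
#' @export
prioritize_targets <- function(centrality, sensitivity, q = 0.25) {
  stopifnot(nrow(centrality) > 0L, nrow(sensitivity) > 0L)
  sens <- sensitivity
  if ("mode" %in% names(sens) && any(sens$mode == "knockout"))
    sens <- sens[sens$mode == "knockout", , drop = FALSE]
  merged <- merge(centrality[, c("node", "betweenness")],
                  sens[, c("node", "sensitivity")], by = "node")
  if (!nrow(merged)) stop("no common nodes between the two tables")
  minmax <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) rep(0.5, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  merged$priority <- (minmax(merged$betweenness) + minmax(merged$sensitivity)) / 2
  merged <- merged[order(-merged$priority, merged$node), , drop = FALSE]
  merged$rank <- seq_len(nrow(merged))
  rownames(merged) <- NULL
  top_k <- function(x) {
    k <- max(1L, ceiling(q * nrow(merged)))
    merged$node[order(-x)][seq_len(k)]
  }
  attr(merged, "top_intersection") <-
    intersect(top_k(merged$betweenness), top_k(merged$sensitivity))
  merged
}
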