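# Structural statistics used to rank nodes: degrees, feedback loops, and two
# shortest-path centralities on the directed, unweighted interaction graph.
#
# Betweenness of v sums, over ordered pairs (s, t) with s != v != t and at
# least one s->t path, the fraction of shortest s->t paths through v. Stress
# sums the raw counts instead of the fractions, so C_B(v) <= C_S(v) always.
# Both are computed unnormalized on the directed graph; Brandes's single-pass
# accumulation over each source's shortest-path DAG gives the fractional
# dependencies, and a path-count recursion on the same DAG gives stress.

#' Interaction graph of a Boolean network
#'
#' Directed igraph built from the network's regulator -> target pairs (the
#' same edges [sif_edges()] emits), with edge attribute `relation`.
#'
#' @param network a `boolean_network`.
#' @return an igraph object whose vertices are the network's nodes.
#' @export
interaction_graph <- function(network) {
  ed <- sif_edges(network)
  g <- igraph::graph_from_data_frame(
    ed[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = network$nodes))
  igraph::E(g)$relation <- ed$relation
  g
}

as_igraph_input <- function(graph) {
  if (inherits(graph, "boolean_network")) return(interaction_graph(graph))
  if (inherits(graph, "igraph")) return(graph)
  stop("'graph' must be an igraph object or a boolean_network")
}

# BFS shortest-path DAG statistics from each source; callback-free single
# implementation returning both centralities.
path_centralities <- function(g, undirected = FALSE) {
  mode <- if (undirected) "all" else "out"
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  adj <- lapply(igraph::as_adj_list(g, mode = mode), as.integer)
  adj <- lapply(adj, unique)  # parallel edges do not multiply paths
  betw <- stats::setNames(numeric(n), nodes)
  stress <- stats::setNames(numeric(n), nodes)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); sigma <- numeric(n); preds <- vector("list", n)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- s; head <- 1L; order_visited <- integer(0)
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (w == v) next
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)   # Brandes fractional dependency
    for (w in rev(order_visited))
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
    # paths_from[v] = number of shortest-path continuations v -> any t != v
    # within the DAG: sum over DAG successors w of (1 + paths_from[w]);
    # sigma[v] * paths_from[v] then counts shortest s->t paths through v.
    succs <- vector("list", n)
    for (w in order_visited) for (v in preds[[w]])
      succs[[v]] <- c(succs[[v]], w)
    paths_from <- numeric(n)
    for (v in rev(order_visited))
      for (w in succs[[v]])
        paths_from[v] <- paths_from[v] + 1 + paths_from[w]
    inner <- setdiff(order_visited, s)
    betw[inner] <- betw[inner] + delta[inner]
    stress[inner] <- stress[inner] + sigma[inner] * paths_from[inner]
  }
  list(betweenness = betw, stress = stress)
}

#' Betweenness centrality (directed, unnormalized)
#'
#' @param graph an igraph object or a `boolean_network` (its interaction
#'   graph is used).
#' @param undirected treat the graph as undirected.
#' @return named numeric vector of scores.
#' @export
betweenness_centrality <- function(graph, undirected = FALSE) {
  path_centralities(as_igraph_input(graph), undirected)$betweenness
}

#' Stress centrality (directed, unnormalized shortest-path counts)
#'
#' @inheritParams betweenness_centrality
#' @return named numeric vector of scores.
#' @export
stress_centrality <- function(graph, undirected = FALSE) {
  path_centralities(as_igraph_input(graph), undirected)$stress
}

#' Feedback loops of the interaction graph
#'
#' Strongly connected components of size at least two, plus self-loop nodes
#' as singleton loops. Components are ordered by their smallest member
#' identifier; members within a component are sorted.
#'
#' @inheritParams betweenness_centrality
#' @return list of character vectors (node identifiers per loop).
#' @export
feedback_loops <- function(graph) {
  g <- as_igraph_input(graph)
  comp <- igraph::components(g, mode = "strong")
  nodes <- igraph::V(g)$name
  loops <- split(nodes, comp$membership)
  loops <- Filter(function(m) length(m) >= 2L, loops)
  loop_edges <- igraph::E(g)[igraph::which_loop(g)]
  selfies <- if (length(loop_edges))
    unique(igraph::ends(g, loop_edges)[, 1]) else character(0)
  for (s in setdiff(selfies, unlist(loops)))
    loops[[length(loops) + 1L]] <- s
  loops <- lapply(loops, sort)
  loops[order(vapply(loops, min, character(1)))]
}

#' Full centrality table for a network
#'
#' @param network a `boolean_network`.
#' @param undirected compute centralities on the underlying undirected graph.
#' @return data.frame with one row per node: `node`, `in_degree`,
#'   `out_degree`, `betweenness`, `stress`, `in_feedback_loop`.
#' @export
centrality_table <- function(network, undirected = FALSE) {
  g <- as_igraph_input(network)
  cb <- path_centralities(g, undirected)
  fb <- unlist(feedback_loops(g))
  nodes <- igraph::V(g)$name
  data.frame(
    node = nodes,
    in_degree = as.integer(igraph::degree(g, mode = "in")),
    out_degree = as.integer(igraph::degree(g, mode = "out")),
    betweenness = unname(cb$betweenness),
    stress = unname(cb$stress),
    in_feedback_loop = nodes %in% fb,
    stringsAsFactors = FALSE)
}

#' Top-quantile nodes by betweenness
#'
#' Nodes whose betweenness reaches the `(1 - q)` quantile of the *nonzero*
#' betweenness distribution; ties at the threshold are included. With all
#' scores equal, every node is returned.
#'
#' @param table a [centrality_table()] (needs columns `node`, `betweenness`).
#' @param q fraction in (0, 1); default 0.25 = top quartile.
#' @return character vector of node identifiers, sorted by descending score.
#' @export
top_quantile <- function(table, q = 0.25) {
  stopifnot(is.data.frame(table), nrow(table) > 0L, q > 0, q < 1)
  b <- table$betweenness
  nz <- b[b > 0]
  thr <- if (length(nz)) stats::quantile(nz, probs = 1 - q, names = FALSE)
         else 0
  sel <- b >= thr & (b > 0 | length(nz) == 0L)
  table$node[sel][order(-b[sel])]
}
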