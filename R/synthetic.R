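# Seeded generators for test and benchmark networks: classic N-K-p random
# Boolean networks, fixed motifs with known attractor structure, and layered
# pathway-like networks (inputs -> signaling cascade -> phenotype sinks)
# sized to the node/edge scales of curated disease-map pathway models.

#' Specification for a random Boolean network
#'
#' @param n number of nodes (>= 1).
#' @param k regulators per non-input node (0 <= k < n).
#' @param p function bias: probability a truth-table entry is 1.
#' @param input_fraction fraction of nodes kept as free inputs.
#' @param seed RNG seed fixing the entire network.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n, k = 2L, p = 0.5, input_fraction = 0,
                           seed = 1L) {
  stopifnot(n >= 1L, k >= 0L, p >= 0, p <= 1,
            input_fraction >= 0, input_fraction < 1)
  if (k >= n) stop("infeasible spec: k must be smaller than n")
  structure(list(n = as.integer(n), k = as.integer(k), p = p,
                 input_fraction = input_fraction, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a random N-K-p Boolean network
#'
#' Every non-input node receives `k` distinct regulators sampled uniformly
#' (self-regulation allowed) and a random truth table with ON-bias `p`.
#' Nodes designated inputs get the self-identity function. Fully
#' reproducible from the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @return a [boolean_network()].
#' @export
random_network <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n
  nodes <- sprintf("n%02d", seq_len(n))
  n_inputs <- floor(spec$input_fraction * n)
  inputs <- if (n_inputs) sample(nodes, n_inputs) else character(0)
  funs <- stats::setNames(vector("list", n), nodes)
  for (v in nodes) {
    if (v %in% inputs) {
      funs[[v]] <- as.symbol(v)
      next
    }
    if (spec$k == 0L) {
      funs[[v]] <- stats::runif(1) < spec$p    # constant node
      next
    }
    regs <- sample(nodes, spec$k)
    # redraw constant tables so every node depends on its k regulators and
    # the realized in-degree equals k
    repeat {
      tt <- stats::runif(2^spec$k) < spec$p
      if (!all(tt) && any(tt)) break
    }
    funs[[v]] <- truth_table_to_expr(regs, tt)
  }
  boolean_network(funs, name = sprintf("rbn_n%d_k%d_seed%d",
                                       n, spec$k, spec$seed))
}

# Expression for an explicit truth table over ordered regulators (regulator
# j = bit weight 2^(j-1)): disjunction of the ON rows' minterms.
truth_table_to_expr <- function(regs, tt) {
  k <- length(regs)
  on_rows <- which(tt) - 1L
  if (!length(on_rows)) return(FALSE)
  if (length(on_rows) == 2^k) return(TRUE)
  and_join <- function(xs) Reduce(function(a, b) call("&", a, b), xs)
  or_join <- function(xs) Reduce(function(a, b) call("|", a, b), xs)
  minterm <- function(row) {
    lits <- lapply(seq_len(k), function(j) {
      s <- as.symbol(regs[j])
      if ((row %/% 2^(j - 1)) %% 2 == 1) s else call("!", s)
    })
    and_join(lits)
  }
  or_join(lapply(on_rows, minterm))
}

#' Fixed network motifs with known behavior
#'
#' \describe{
#'   \item{`toggle`}{mutual repression `A = !B`, `B = !A`: two steady states
#'     and one synchronous 2-cycle.}
#'   \item{`repressilator`}{three-node negative-feedback ring
#'     `A = !C, B = !A, C = !B`: one complex asynchronous attractor of six
#'     states, no fixed point.}
#'   \item{`maptp`}{kinase/inhibitor switch on tau phosphorylation:
#'     inputs `CDK5_p25`, `PIN1`; `MAPTP = CDK5_p25 & !PIN1`.}
#'   \item{`cascade_phenotype`}{two inputs driving a short signaling cascade
#'     into the phenotype sinks `autophagy` and `neuron_death` (sinks have
#'     no outgoing edges).}
#' }
#'
#' @param name motif name.
#' @return a [boolean_network()].
#' @export
motif <- function(name = c("toggle", "repressilator", "maptp",
                           "cascade_phenotype")) {
  name <- match.arg(name)
  funs <- switch(name,
    toggle = list(A = "!B", B = "!A"),
    repressilator = list(A = "!C", B = "!A", C = "!B"),
    maptp = list(CDK5_p25 = "CDK5_p25", PIN1 = "PIN1",
                 MAPTP = "CDK5_p25 & !PIN1"),
    cascade_phenotype = list(
      growth_signal = "growth_signal",
      stress_signal = "stress_signal",
      kinase1 = "growth_signal",
      kinase2 = "kinase1 & !phosphatase",
      phosphatase = "stress_signal",
      autophagy = "kinase2 | stress_signal",
      neuron_death = "stress_signal & !kinase2"))
  boolean_network(funs, name = name)
}

#' Generate a pathway-like Boolean network
#'
#' Layered input -> signaling -> phenotype topology with a controlled number
#' of feedback edges, sized to match curated pathway-model scales: `small`
#' about 65 nodes / 86 edges, `medium` about 167 / 196, `large` about
#' 391 / 436. Every non-input node's function is built from its incoming
#' edges (activators OR-ed, inhibitors dominant), so the interaction-graph
#' edge count equals the constructed edge count. Phenotype sinks have no
#' outgoing edges and every phenotype is reachable from some input.
#'
#' @param scale `"small"`, `"medium"` or `"large"`.
#' @param seed RNG seed.
#' @param feedback number of added feedback edges (default: 0 for small,
#'   3 for medium, 6 for large).
#' @return a [boolean_network()].
#' @export
pathway_like <- function(scale = c("small", "medium", "large"), seed = 1L,
                         feedback = NULL) {
  scale <- match.arg(scale)
  dims <- switch(scale,
    small = list(n = 65L, e = 86L),
    medium = list(n = 167L, e = 196L),
    large = list(n = 391L, e = 436L))
  if (is.null(feedback))
    feedback <- switch(scale, small = 0L, medium = 3L, large = 6L)
  set.seed(seed)
  n <- dims$n
  n_pheno <- max(2L, round(0.02 * n))
  n_inputs <- max(3L, round(0.15 * n))
  n_mid <- n - n_pheno - n_inputs
  layers <- list(
    inputs = sprintf("input%02d", seq_len(n_inputs)),
    mid = sprintf("sig%03d", seq_len(n_mid)),
    pheno = c("autophagy", "neuron_death",
              if (n_pheno > 2L) sprintf("phenotype%02d", seq_len(n_pheno - 2L))))
  nodes <- unlist(layers, use.names = FALSE)
  depth <- c(rep(0L, n_inputs),
             sort(sample(1:4, n_mid, replace = TRUE)), rep(5L, n_pheno))
  names(depth) <- nodes
  # base edges: each non-input draws one regulator from a shallower layer
  targets <- nodes[depth > 0L]
  edges <- do.call(rbind, lapply(targets, function(v) {
    pool <- nodes[depth < depth[v] & !(nodes %in% layers$pheno)]
    data.frame(from = sample(pool, 1L), to = v, stringsAsFactors = FALSE)
  }))
  # extra forward edges up to the target count (minus reserved feedback)
  want_extra <- dims$e - nrow(edges) - feedback
  tries <- 0L
  while (want_extra > 0L && tries < 50L * dims$e) {
    tries <- tries + 1L
    v <- sample(targets, 1L)
    pool <- nodes[depth < depth[v] & !(nodes %in% layers$pheno)]
    u <- sample(pool, 1L)
    if (!any(edges$from == u & edges$to == v)) {
      edges <- rbind(edges, data.frame(from = u, to = v,
                                       stringsAsFactors = FALSE))
      want_extra <- want_extra - 1L
    }
  }
  # feedback edges: close a genuine cycle by wiring a signaling node back to
  # one of its own ancestors in the forward graph
  added_fb <- 0L
  tries <- 0L
  while (added_fb < feedback && tries < 1000L) {
    tries <- tries + 1L
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = nodes))
    u <- sample(layers$mid, 1L)
    anc <- igraph::V(g)$name[igraph::subcomponent(g, u, mode = "in")]
    anc <- intersect(setdiff(anc, u), layers$mid)
    if (!length(anc)) next
    v <- if (length(anc) == 1L) anc else sample(anc, 1L)
    if (!any(edges$from == u & edges$to == v)) {
      edges <- rbind(edges, data.frame(from = u, to = v,
                                       stringsAsFactors = FALSE))
      added_fb <- added_fb + 1L
    }
  }
  # functions: activators OR-ed; ~15% of regulators act as inhibitors with
  # dominant-negative combination, mirroring the translation semantics
  or_join <- function(xs) Reduce(function(a, b) call("|", a, b), xs)
  funs <- stats::setNames(vector("list", n), nodes)
  for (v in nodes) {
    regs <- edges$from[edges$to == v]
    if (!length(regs)) {
      funs[[v]] <- as.symbol(v)          # free input
      next
    }
    inhib <- regs[stats::runif(length(regs)) < 0.15]
    if (length(inhib) == length(regs)) inhib <- inhib[-1L]
    acts <- setdiff(regs, inhib)
    f <- or_join(lapply(acts, as.symbol))
    if (length(inhib))
      f <- call("&", f, call("!", or_join(lapply(inhib, as.symbol))))
    funs[[v]] <- f
  }
  boolean_network(funs, name = sprintf("pathway_%s_seed%d", scale, seed))
}
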