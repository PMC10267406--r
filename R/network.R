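#' Construct a Boolean network
#'
#' A Boolean network is an ordered set of named nodes, each carrying one
#' Boolean update function over the states of its regulators. Nodes whose
#' function is the identity on themselves (`A = A`) are *free inputs*: their
#' value is never driven by the rest of the network.
#'
#' @param functions named list, one entry per node in the desired node order.
#'   Each entry is either a character string in the rule dialect
#'   (`&`, `|`, `!`, parentheses, `0`/`1`) or a quoted R expression restricted
#'   to that grammar.
#' @param name optional model name stored in the metadata.
#' @param labels optional named character vector mapping node identifiers back
#'   to original display names (kept when identifiers were normalized).
#' @return an object of class `boolean_network` with elements `nodes`,
#'   `functions` (named list of language objects), `inputs` (character vector
#'   of free-input nodes), `metadata`, and a pre-compiled representation used
#'   by the dynamics engines.
#' @examples
#' bn <- boolean_network(list(
#'   CDK5_p25 = "CDK5_p25", PIN1 = "PIN1",
#'   MAPTP = "CDK5_p25 & !PIN1"))
#' bn
#' @export
boolean_network <- function(functions, name = NULL, labels = NULL) {
  if (is.null(names(functions)) || any(!nzchar(names(functions))))
    stop("'functions' must be a fully named list (one entry per node)")
  nodes <- names(functions)
  if (anyDuplicated(nodes))
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  exprs <- lapply(functions, function(f) {
    if (is.character(f)) parse_bool_expr(f) else bool_validate_expr(f)
  })
  names(exprs) <- nodes
  refs <- unique(unlist(lapply(exprs, bool_expr_vars), use.names = FALSE))
  undeclared <- setdiff(refs, nodes)
  if (length(undeclared))
    stop("functions reference undeclared node(s): ",
         paste(undeclared, collapse = ", "))
  inputs <- nodes[vapply(nodes, function(v) identical(exprs[[v]], as.symbol(v)),
                         logical(1))]
  bn <- structure(
    list(nodes = nodes, functions = exprs, inputs = inputs,
         metadata = list(name = name, labels = labels)),
    class = "boolean_network")
  bn$compiled <- bn_compile(bn)
  bn
}

# Pre-compiled form: per node, integer indices of its regulators (in network
# node order of appearance inside the function) and the function's truth table.
bn_compile <- function(bn) {
  idx <- seq_along(bn$nodes)
  names(idx) <- bn$nodes
  lapply(bn$nodes, function(v) {
    regs <- bool_expr_vars(bn$functions[[v]])
    list(regs = unname(idx[regs]),
         tt = bool_expr_truth_table(bn$functions[[v]], regs))
  })
}

#' @export
print.boolean_network <- function(x, ...) {
  nm <- x$metadata$name
  cat("Boolean network", if (!is.null(nm)) paste0("'", nm, "'") else "",
      "with", length(x$nodes), "nodes (",
      length(x$inputs), "free inputs )\n")
  shown <- utils::head(x$nodes, 12L)
  for (v in shown)
    cat("  ", v, " = ", format_bool_expr(x$functions[[v]]), "\n", sep = "")
  if (length(x$nodes) > length(shown))
    cat("  ... and", length(x$nodes) - length(shown), "more\n")
  invisible(x)
}

#' Truth table of one node's update function
#'
#' @param network a `boolean_network`.
#' @param node node identifier.
#' @return list with `regulators` (character) and `table` (logical vector of
#'   length `2^k`; entry `j+1` is the function value when the regulator bit
#'   pattern encodes the integer `j`, first regulator = least significant bit).
#' @export
truth_table <- function(network, node) {
  stopifnot(inherits(network, "boolean_network"))
  if (!node %in% network$nodes) stop("unknown node: ", node)
  regs <- bool_expr_vars(network$functions[[node]])
  list(regulators = regs,
       table = bool_expr_truth_table(network$functions[[node]], regs))
}

# Canonical truth-table fingerprint of every node, used for network equality
# up to expression rewriting. Regulators are sorted by name so the fingerprint
# does not depend on the order symbols appear inside the expression.
bn_truth_fingerprint <- function(bn) {
  lapply(stats::setNames(bn$nodes, bn$nodes), function(v) {
    regs <- sort(bool_expr_vars(bn$functions[[v]]))
    list(regs = regs, tt = bool_expr_truth_table(bn$functions[[v]], regs))
  })
}

#' Test two networks for truth-table equivalence
#'
#' Networks are equivalent when they have the same node set and, node by node,
#' the same regulators and identical truth tables (expressions may differ
#' syntactically).
#'
#' @param a,b `boolean_network` objects.
#' @return logical scalar.
#' @export
bn_equivalent <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  fa <- bn_truth_fingerprint(a)
  fb <- bn_truth_fingerprint(b)
  all(vapply(a$nodes, function(v) {
    identical(fa[[v]]$regs, fb[[v]]$regs) && identical(fa[[v]]$tt, fb[[v]]$tt)
  }, logical(1)))
}

## ---- state representation ----------------------------------------------
# A state is a named logical vector in network node order. Internally states
# are also carried as integer codes in [0, 2^n): node i contributes bit
# weight 2^(i-1). Codes are stored as doubles so n up to 24 stays exact.

#' Convert between states and integer codes
#'
#' Node `i` (in network node order) contributes bit weight `2^(i-1)`.
#'
#' @param state named or unnamed logical vector in network node order.
#' @param network a `boolean_network`.
#' @param code numeric scalar/vector of state codes in `[0, 2^n)`.
#' @return `state_code()` returns a numeric code; `code_to_state()` a named
#'   logical vector (or matrix for several codes).
#' @export
state_code <- function(state, network = NULL) {
  if (!is.null(network) && !is.null(names(state)))
    state <- state[network$nodes]
  sum(as.numeric(state) * 2^(seq_along(state) - 1))
}

#' @rdname state_code
#' @export
code_to_state <- function(code, network) {
  n <- length(network$nodes)
  if (length(code) == 1L) {
    s <- ((code %/% 2^(0:(n - 1))) %% 2) == 1
    names(s) <- network$nodes
    return(s)
  }
  m <- vapply(0:(n - 1), function(i) ((code %/% 2^i) %% 2) == 1,
              logical(length(code)))
  m <- matrix(m, nrow = length(code), dimnames = list(NULL, network$nodes))
  m
}

# Bit-string key of a logical state (node order; "1" = ON). Exact at any n,
# unlike numeric codes which lose integer precision beyond ~48 nodes.
state_key <- function(state) paste(as.integer(state), collapse = "")

key_to_state <- function(key, nodes) {
  stats::setNames(strsplit(key, "", fixed = TRUE)[[1]] == "1", nodes)
}

code_to_key <- function(code, n) {
  paste(((code %/% 2^(0:(n - 1))) %% 2), collapse = "")
}

key_to_code <- function(key) {
  bits <- strsplit(key, "", fixed = TRUE)[[1]] == "1"
  sum(as.numeric(bits) * 2^(seq_along(bits) - 1))
}

# maximum node count for which numeric state codes are exact
CODE_MAX_N <- 48L

# Value of every node's function at a state given as a logical vector.
bn_node_values <- function(bn, state) {
  vapply(seq_along(bn$nodes), function(i) {
    cp <- bn$compiled[[i]]
    if (!length(cp$regs)) return(cp$tt[1L])
    cp$tt[1L + sum(as.numeric(state[cp$regs]) * 2^(seq_along(cp$regs) - 1))]
  }, logical(1))
}

# Vectorized synchronous image over a vector of state codes.
bn_sync_image <- function(bn, codes) {
  n <- length(bn$nodes)
  out <- numeric(length(codes))
  for (i in seq_len(n)) {
    cp <- bn$compiled[[i]]
    if (!length(cp$regs)) {
      val <- rep(as.numeric(cp$tt[1L]), length(codes))
    } else {
      idx <- rep(1, length(codes))
      for (j in seq_along(cp$regs))
        idx <- idx + ((codes %/% 2^(cp$regs[j] - 1)) %% 2) * 2^(j - 1)
      val <- as.numeric(cp$tt[idx])
    }
    out <- out + val * 2^(i - 1)
  }
  out
}
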