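# A small SAT layer: Tseitin translation of Boolean-network constraints to
# CNF and a compiled DPLL solver with unit propagation (src/dpll.cpp).
# Literals are signed integers (DIMACS convention); a CNF is a list of
# integer vectors plus a variable count. The solver branches on the
# lowest-numbered unassigned variable, so placing the n state variables
# first makes gate variables purely derived.

#' @useDynLib boolpath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# mutable CNF builder
cnf_new <- function(nvars = 0L) {
  env <- new.env(parent = emptyenv())
  env$clauses <- list()
  env$nvars <- as.integer(nvars)
  env
}

cnf_add <- function(cnf, ...) {
  cnf$clauses[[length(cnf$clauses) + 1L]] <- as.integer(c(...))
  invisible(cnf)
}

cnf_fresh <- function(cnf) {
  cnf$nvars <- cnf$nvars + 1L
  cnf$nvars
}

# Tseitin-encode an expression; returns the literal equivalent to the
# expression's value. `varmap` maps node identifiers to variable indices.
tseitin_expr <- function(e, varmap, cnf) {
  if (is.symbol(e)) {
    v <- as.character(e)
    if (!v %in% names(varmap)) stop("expression references unmapped node: ", v)
    return(varmap[[v]])
  }
  if (is.logical(e)) {
    v <- cnf_fresh(cnf)
    cnf_add(cnf, if (e) v else -v)
    return(v)
  }
  op <- as.character(e[[1L]])
  if (op == "!") return(-tseitin_expr(e[[2L]], varmap, cnf))
  a <- tseitin_expr(e[[2L]], varmap, cnf)
  b <- tseitin_expr(e[[3L]], varmap, cnf)
  v <- cnf_fresh(cnf)
  if (op == "&") {
    cnf_add(cnf, -v, a); cnf_add(cnf, -v, b); cnf_add(cnf, v, -a, -b)
  } else if (op == "|") {
    cnf_add(cnf, v, -a); cnf_add(cnf, v, -b); cnf_add(cnf, -v, a, b)
  } else stop("unexpected operator in expression: ", op)
  v
}

# Single DPLL solve (compiled backend). Returns a logical assignment of
# length nvars, or NULL when unsatisfiable.
dpll_solve <- function(clauses, nvars) {
  if (!length(clauses)) return(rep(FALSE, nvars))
  dpll_solve_cpp(clauses, as.integer(nvars))
}

# Enumerate all models projected onto `project` variables: solve, record the
# projection, add a blocking clause over the projected literals, repeat
# (blocking happens inside the compiled solver).
sat_enumerate <- function(cnf, project, limit = Inf) {
  if (!length(cnf$clauses)) return(list())
  dpll_enumerate_cpp(cnf$clauses, cnf$nvars, as.integer(project),
                     as.numeric(limit))
}

# CNF for the synchronous fixed-point condition x_i <-> B_i(x).
# State variables are 1..n in network node order.
cnf_fixed_point <- function(bn) {
  n <- length(bn$nodes)
  cnf <- cnf_new(n)
  varmap <- stats::setNames(seq_len(n), bn$nodes)
  for (i in seq_len(n)) {
    g <- tseitin_expr(bn$functions[[i]], varmap, cnf)
    cnf_add(cnf, -i, g)
    cnf_add(cnf, i, -g)
  }
  cnf
}

#' Export a network's fixed-point constraints in DIMACS CNF
#'
#' The first `n` variables are the node states in network order; the
#' remaining variables are Tseitin gates. Any standard SAT solver applied to
#' the output enumerates the network's synchronous fixed points.
#'
#' @param network a `boolean_network`.
#' @param path optional output file.
#' @return the DIMACS lines, invisibly when written.
#' @export
write_dimacs <- function(network, path = NULL) {
  cnf <- cnf_fixed_point(network)
  lines <- c(
    paste("c fixed-point CNF;", length(network$nodes),
          "state variables in node order"),
    paste("p cnf", cnf$nvars, length(cnf$clauses)),
    vapply(cnf$clauses, function(cl) paste(c(cl, 0L), collapse = " "),
           character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
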