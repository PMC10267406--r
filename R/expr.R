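# Boolean expression trees are stored as R language objects restricted to the
# grammar {&, |, !, (, identifier, TRUE, FALSE}. R's own parser produces the
# tree; bool_validate_expr() then rejects anything outside the grammar, so no
# general evaluation can be smuggled in through a model file.

#' Parse a Boolean expression
#'
#' Parses a textual Boolean expression in the rule dialect used throughout the
#' package: `&` (AND), `|` (OR), `!` (NOT), parentheses, node identifiers, and
#' the constants `0`/`1` (also accepted: `TRUE`/`FALSE`). The result is an R
#' language object whose only constants are `TRUE` and `FALSE`.
#'
#' @param text single character string.
#' @return a quoted R expression (language object or logical constant).
#' @examples
#' parse_bool_expr("CDK5_p25 & !PIN1")
#' @export
parse_bool_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(str2lang(text), error = function(err) {
    stop("cannot parse Boolean expression '", text, "': ",
         conditionMessage(err), call. = FALSE)
  })
  bool_validate_expr(e)
}

# Validate and normalize an expression tree: numeric 0/1 -> FALSE/TRUE,
# `(x)` unwrapped. Returns the normalized tree, or stops.
bool_validate_expr <- function(e) {
  if (is.symbol(e)) return(e)
  if (is.logical(e) && length(e) == 1L && !is.na(e)) return(e)
  if (is.numeric(e) && length(e) == 1L) {
    if (e == 0) return(FALSE)
    if (e == 1) return(TRUE)
    stop("numeric constant ", e, " is not a Boolean (use 0 or 1)", call. = FALSE)
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(bool_validate_expr(e[[2L]]))
    if (op == "!") {
      e[[2L]] <- bool_validate_expr(e[[2L]])
      return(e)
    }
    if (op %in% c("&", "|")) {
      e[[2L]] <- bool_validate_expr(e[[2L]])
      e[[3L]] <- bool_validate_expr(e[[3L]])
      return(e)
    }
    stop("operator '", op, "' is not part of the Boolean rule grammar ",
         "(allowed: & | ! parentheses)", call. = FALSE)
  }
  stop("unsupported token in Boolean expression: ", deparse(e), call. = FALSE)
}

# All node identifiers referenced by an expression (unique, in first-use order).
bool_expr_vars <- function(e) {
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    args <- as.list(e)[-1L]
    if (op == "(") args <- args[1L]
    return(unique(unlist(lapply(args, bool_expr_vars), use.names = FALSE)))
  }
  character(0)
}

# Polarity of each referenced variable: does it occur un-negated / negated?
# Returns list(pos = chr, neg = chr). Negation parity is tracked through `!`.
bool_expr_polarity <- function(e, negated = FALSE, acc = NULL) {
  if (is.null(acc)) acc <- new.env(parent = emptyenv())
  if (is.symbol(e)) {
    v <- as.character(e)
    slot <- if (negated) "neg" else "pos"
    assign(paste0(slot, ".", v), TRUE, envir = acc)
  } else if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "!") {
      bool_expr_polarity(e[[2L]], !negated, acc)
    } else if (op == "(") {
      bool_expr_polarity(e[[2L]], negated, acc)
    } else {
      bool_expr_polarity(e[[2L]], negated, acc)
      bool_expr_polarity(e[[3L]], negated, acc)
    }
  }
  keys <- ls(acc)
  list(pos = sub("^pos\\.", "", keys[startsWith(keys, "pos.")]),
       neg = sub("^neg\\.", "", keys[startsWith(keys, "neg.")]))
}

# Deparse with the package's operator spelling and minimal parentheses.
# Precedence: ! > & > |.
format_bool_expr <- function(e) {
  prec <- function(x) {
    if (!is.call(x)) return(4L)
    switch(as.character(x[[1L]]), "!" = 3L, "&" = 2L, "|" = 1L, 4L)
  }
  wrap <- function(x, outer_prec) {
    s <- format_bool_expr(x)
    if (prec(x) < outer_prec) paste0("(", s, ")") else s
  }
  if (is.symbol(e)) return(as.character(e))
  if (is.logical(e)) return(if (e) "1" else "0")
  op <- as.character(e[[1L]])
  if (op == "!") return(paste0("!", wrap(e[[2L]], 3L)))
  if (op == "&") return(paste(wrap(e[[2L]], 2L), "&", wrap(e[[3L]], 2L)))
  if (op == "|") return(paste(wrap(e[[2L]], 1L), "|", wrap(e[[3L]], 1L)))
  stop("unexpected operator in expression: ", op)
}

# Substitute a named list of replacements (logical constants or symbols) for
# symbols in an expression tree.
bool_expr_substitute <- function(e, subst) {
  if (is.symbol(e)) {
    v <- as.character(e)
    if (v %in% names(subst)) return(subst[[v]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- bool_expr_substitute(e[[i]], subst)
    return(e)
  }
  e
}

# Truth table of an expression over an ordered regulator vector: logical vector
# of length 2^k, entry j+1 = value when regulator bits encode integer j
# (regulator r contributes bit weight 2^(r-1) in list order).
bool_expr_truth_table <- function(e, regs) {
  k <- length(regs)
  if (k > 16L)
    stop("refusing to tabulate a function with ", k, " regulators (> 16)")
  if (k == 0L) {
    env <- list()
  } else {
    m <- 0:(2^k - 1)
    env <- lapply(seq_len(k), function(j) ((m %/% 2^(j - 1)) %% 2) == 1)
    names(env) <- regs
  }
  val <- eval(e, envir = env, enclos = baseenv())
  out <- rep_len(as.logical(val), if (k == 0L) 1L else 2^k)
  if (anyNA(out)) stop("Boolean expression evaluated to NA")
  out
}
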