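# Readers/writers for the model formats the pipeline touches: plain-text
# rules, SBML-qual (two-level subset), and SIF edge lists. All text IO is
# UTF-8 with LF line endings; node order follows first appearance in the
# source document so state bit-vectors match the input file's layout.

# Normalize a display name to a rule-grammar-safe identifier: spaces, colons
# and other punctuation map to underscores, runs collapsed.
normalize_identifier <- function(x) {
  id <- gsub("[^A-Za-z0-9_]+", "_", x)
  id <- gsub("_+", "_", id)
  id <- sub("^_", "", sub("_$", "", id))
  ifelse(grepl("^[0-9]", id), paste0("x", id), id)
}

#' Read a Boolean network from plain-text rules
#'
#' One line per node, `target, expression`, with `&`, `|`, `!`, parentheses
#' and the constants `0`/`1`. Blank lines are skipped; `#` starts a comment
#' (full-line or trailing). A node whose expression is its own name becomes a
#' free input. Every identifier referenced must itself be declared as a
#' target.
#'
#' @param path path to a rule file, or a character vector of lines when
#'   `text = TRUE`.
#' @param text logical; interpret `path` as the document content itself.
#' @return a [boolean_network()].
#' @export
read_rules <- function(path, text = FALSE) {
  lines <- if (text) unlist(strsplit(paste(path, collapse = "\n"), "\n"))
           else readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  funs <- list()
  for (ln in keep) {
    line <- trimws(lines[ln])
    m <- regexpr(",", line, fixed = TRUE)
    if (m < 0)
      stop("rule syntax error on line ", ln, ": expected 'target, expression'",
           call. = FALSE)
    target <- trimws(substr(line, 1L, m - 1L))
    rhs <- trimws(substr(line, m + 1L, nchar(line)))
    if (!nzchar(target) || !nzchar(rhs))
      stop("rule syntax error on line ", ln, ": empty target or expression",
           call. = FALSE)
    if (target %in% names(funs))
      stop("duplicate target '", target, "' on line ", ln, call. = FALSE)
    funs[[target]] <- tryCatch(parse_bool_expr(rhs), error = function(e)
      stop("line ", ln, ": ", conditionMessage(e), call. = FALSE))
  }
  if (!length(funs)) stop("no rules found in document")
  boolean_network(funs)
}

#' Write a Boolean network as plain-text rules
#'
#' @param network a `boolean_network`.
#' @param path optional output file; when `NULL` the document is returned as
#'   a character vector of lines.
#' @return the lines, invisibly when written to a file.
#' @export
write_rules <- function(network, path = NULL) {
  stopifnot(inherits(network, "boolean_network"))
  lines <- vapply(network$nodes, function(v)
    paste0(v, ", ", format_bool_expr(network$functions[[v]])), character(1))
  if (is.null(path)) return(unname(lines))
  writeLines(lines, path, useBytes = FALSE)
  invisible(unname(lines))
}

## ---- SIF ----------------------------------------------------------------

#' Interaction edges of a Boolean network
#'
#' One edge per (regulator, target) pair. The relation is `activates` when
#' the regulator occurs only un-negated in the target's function, `inhibits`
#' when only negated, and `interacts` when it occurs with both polarities.
#' Edges are sorted by (source, relation, target) for deterministic output.
#'
#' @param network a `boolean_network`.
#' @return data.frame with columns `source`, `relation`, `target`.
#' @export
sif_edges <- function(network) {
  stopifnot(inherits(network, "boolean_network"))
  rows <- list()
  for (v in network$nodes) {
    if (v %in% network$inputs) next   # self-identity is bookkeeping, not regulation
    pol <- bool_expr_polarity(network$functions[[v]])
    regs <- union(pol$pos, pol$neg)
    if (!length(regs)) next
    rel <- ifelse(regs %in% pol$pos & regs %in% pol$neg, "interacts",
                  ifelse(regs %in% pol$pos, "activates", "inhibits"))
    rows[[v]] <- data.frame(source = regs, relation = rel, target = v,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(source = character(), relation = character(),
                      target = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$source, out$relation, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network's interactions in Simple Interaction Format
#'
#' Three tab-separated columns: source, relation, target.
#'
#' @inheritParams sif_edges
#' @param path optional output file.
#' @return the SIF lines (character vector), invisibly when written.
#' @export
write_sif <- function(network, path = NULL) {
  ed <- sif_edges(network)
  lines <- if (nrow(ed)) paste(ed$source, ed$relation, ed$target, sep = "\t")
           else character(0)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

## ---- SBML-qual ----------------------------------------------------------

# Attribute lookup that ignores namespace prefixes ("qual:id" vs "id").
qual_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(at)) == name)
  if (!length(hit)) NA_character_ else unname(at[hit[1L]])
}

#' Read a Boolean network from SBML-qual
#'
#' Supports the two-level subset of the SBML Level 3 `qual` package: every
#' qualitative species must have `maxLevel` 1; each transition has one output,
#' a default term, and function terms whose MathML uses `and`/`or`/`not`/`eq`
#' over species compared with the levels 0/1 (plus the constants
#' `<true/>`/`<false/>`). Species without a transition become free inputs.
#' Species identifiers are normalized to the rule grammar; original names are
#' kept in the network metadata.
#'
#' @param path path to an SBML-qual XML document (or a literal XML string).
#' @return a [boolean_network()].
#' @export
read_sbml_qual <- function(path) {
  doc <- xml2::read_xml(path)
  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='qualitativeSpecies']")
  if (!length(sp_nodes)) stop("document declares no qualitative species")
  ids <- vapply(sp_nodes, qual_attr, character(1), name = "id")
  maxlev <- vapply(sp_nodes, qual_attr, character(1), name = "maxLevel")
  bad <- which(!is.na(maxlev) & as.numeric(maxlev) > 1)
  if (length(bad))
    stop("multi-level species not supported (maxLevel > 1): ",
         paste(ids[bad], collapse = ", "))
  disp <- vapply(sp_nodes, function(s) {
    nm <- qual_attr(s, "name")
    if (is.na(nm)) qual_attr(s, "id") else nm
  }, character(1))
  norm <- normalize_identifier(ids)
  if (anyDuplicated(norm))
    stop("species identifiers collide after normalization: ",
         paste(unique(norm[duplicated(norm)]), collapse = ", "))
  id_map <- stats::setNames(norm, ids)

  funs <- stats::setNames(vector("list", length(norm)), norm)
  for (tr in xml2::xml_find_all(doc, "//*[local-name()='transition']")) {
    outs <- xml2::xml_find_all(tr, ".//*[local-name()='output']")
    if (length(outs) != 1L)
      stop("transition '", qual_attr(tr, "id"), "' must have exactly one output")
    target_raw <- qual_attr(outs[[1L]], "qualitativeSpecies")
    if (!target_raw %in% names(id_map))
      stop("transition output references unknown species: ", target_raw)
    target <- id_map[[target_raw]]
    if (!is.null(funs[[target]]))
      stop("species '", target_raw, "' has more than one transition")
    def <- xml2::xml_find_all(tr, ".//*[local-name()='defaultTerm']")
    if (length(def) != 1L)
      stop("transition for '", target_raw, "' is missing its default term")
    def_level <- as.numeric(qual_attr(def[[1L]], "resultLevel"))
    fts <- xml2::xml_find_all(tr, ".//*[local-name()='functionTerm']")
    terms1 <- list()   # fire -> level 1
    terms0 <- list()   # fire -> level 0
    for (ft in fts) {
      lev <- as.numeric(qual_attr(ft, "resultLevel"))
      math <- xml2::xml_find_all(ft, ".//*[local-name()='math']")
      if (length(math) != 1L)
        stop("function term without MathML in transition for '", target_raw, "'")
      kids <- xml2::xml_children(math[[1L]])
      if (length(kids) != 1L)
        stop("malformed MathML in transition for '", target_raw, "'")
      e <- mathml_to_expr(kids[[1L]], id_map)
      if (lev == 1) terms1[[length(terms1) + 1L]] <- e
      else terms0[[length(terms0) + 1L]] <- e
    }
    or_join <- function(terms) Reduce(function(a, b) call("|", a, b), terms)
    if (def_level == 0) {
      # ON exactly when some level-1 term fires.
      funs[[target]] <- if (length(terms1)) or_join(terms1) else FALSE
    } else {
      # default ON: OFF exactly when a level-0 term fires (and no level-1 does).
      f <- if (length(terms0)) call("!", or_join(terms0)) else TRUE
      if (length(terms1)) f <- call("|", or_join(terms1), f)
      funs[[target]] <- bool_validate_expr(f)
    }
  }
  for (v in norm) if (is.null(funs[[v]])) funs[[v]] <- as.symbol(v)
  model <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  nm <- if (inherits(model, "xml_node")) qual_attr(model, "id") else NULL
  boolean_network(funs, name = if (is.na(nm)) NULL else nm,
                  labels = stats::setNames(disp, norm))
}

# MathML (apply and/or/not/eq, ci, cn, true, false) -> Boolean expression.
mathml_to_expr <- function(node, id_map) {
  tag <- xml2::xml_name(node)
  if (tag == "true") return(TRUE)
  if (tag == "false") return(FALSE)
  if (tag == "ci") {
    raw <- trimws(xml2::xml_text(node))
    if (!raw %in% names(id_map)) stop("MathML references unknown species: ", raw)
    return(as.symbol(id_map[[raw]]))
  }
  if (tag != "apply") stop("unsupported MathML element: <", tag, ">")
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1L]])
  args <- kids[-1L]
  if (op == "eq") {
    if (length(args) != 2L) stop("malformed <eq> in MathML")
    tags <- vapply(args, xml2::xml_name, character(1))
    if (!("ci" %in% tags) || !("cn" %in% tags))
      stop("<eq> must compare a species to a level")
    ci <- args[[which(tags == "ci")[1L]]]
    cn <- args[[which(tags == "cn")[1L]]]
    lev <- as.numeric(trimws(xml2::xml_text(cn)))
    if (!lev %in% c(0, 1)) stop("species level must be 0 or 1, got ", lev)
    sym <- mathml_to_expr(ci, id_map)
    return(if (lev == 1) sym else call("!", sym))
  }
  if (op == "not") {
    if (length(args) != 1L) stop("malformed <not> in MathML")
    return(call("!", mathml_to_expr(args[[1L]], id_map)))
  }
  if (op %in% c("and", "or")) {
    if (length(args) < 1L) stop("malformed <", op, "> in MathML")
    sub <- lapply(args, mathml_to_expr, id_map = id_map)
    rop <- if (op == "and") "&" else "|"
    return(Reduce(function(a, b) call(rop, a, b), sub))
  }
  stop("MathML operator <", op, "> is outside the supported set ",
       "(and/or/not/eq)")
}

# Boolean expression -> MathML lines (indented), species compared to level 1.
expr_to_mathml <- function(e, indent) {
  pad <- strrep(" ", indent)
  if (is.logical(e)) return(paste0(pad, if (e) "<true/>" else "<false/>"))
  if (is.symbol(e))
    return(paste0(pad, "<apply><eq/><ci> ", as.character(e),
                  " </ci><cn type=\"integer\"> 1 </cn></apply>"))
  op <- as.character(e[[1L]])
  if (op == "!") {
    inner <- e[[2L]]
    if (is.symbol(inner))  # compact negation: species at level 0
      return(paste0(pad, "<apply><eq/><ci> ", as.character(inner),
                    " </ci><cn type=\"integer\"> 0 </cn></apply>"))
    return(c(paste0(pad, "<apply><not/>"),
             expr_to_mathml(inner, indent + 2L),
             paste0(pad, "</apply>")))
  }
  tag <- if (op == "&") "and" else "or"
  c(paste0(pad, "<apply><", tag, "/>"),
    expr_to_mathml(e[[2L]], indent + 2L),
    expr_to_mathml(e[[3L]], indent + 2L),
    paste0(pad, "</apply>"))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a Boolean network as SBML-qual
#'
#' Emits the two-level subset read by [read_sbml_qual()]: one qualitative
#' species per node (`maxLevel` 1), one transition per non-input node with a
#' level-0 default term and a single level-1 function term carrying the
#' node's Boolean function as MathML. Free inputs get no transition. Output
#' ordering is deterministic (network node order).
#'
#' @param network a `boolean_network`.
#' @param path optional output file.
#' @param model_id model identifier written to the document.
#' @return the XML document as a character vector of lines, invisibly when
#'   written to a file.
#' @export
write_sbml_qual <- function(network, path = NULL, model_id = NULL) {
  stopifnot(inherits(network, "boolean_network"))
  if (is.null(model_id))
    model_id <- network$metadata$name %||% "boolean_model"
  labels <- network$metadata$labels
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "level=\"3\" version=\"1\" ",
           "xmlns:qual=\"http://www.sbml.org/sbml/level3/version1/qual/version1\" ",
           "qual:required=\"true\">"),
    paste0("  <model id=\"", xml_escape(normalize_identifier(model_id)), "\">"),
    "    <listOfCompartments>",
    "      <compartment id=\"default\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <qual:listOfQualitativeSpecies>")
  for (v in network$nodes) {
    nm <- if (!is.null(labels) && v %in% names(labels)) labels[[v]] else v
    lines <- c(lines, paste0(
      "      <qual:qualitativeSpecies qual:id=\"", v,
      "\" qual:name=\"", xml_escape(nm),
      "\" qual:compartment=\"default\" qual:constant=\"false\" ",
      "qual:maxLevel=\"1\"/>"))
  }
  lines <- c(lines, "    </qual:listOfQualitativeSpecies>",
             "    <qual:listOfTransitions>")
  for (v in setdiff(network$nodes, network$inputs)) {
    e <- network$functions[[v]]
    regs <- bool_expr_vars(e)
    pol <- bool_expr_polarity(e)
    lines <- c(lines, paste0("      <qual:transition qual:id=\"tr_", v, "\">"))
    if (length(regs)) {
      lines <- c(lines, "        <qual:listOfInputs>")
      for (r in regs) {
        sign <- if (r %in% pol$pos && r %in% pol$neg) "dual"
                else if (r %in% pol$neg) "negative" else "positive"
        lines <- c(lines, paste0(
          "          <qual:input qual:qualitativeSpecies=\"", r,
          "\" qual:transitionEffect=\"none\" qual:sign=\"", sign, "\"/>"))
      }
      lines <- c(lines, "        </qual:listOfInputs>")
    }
    lines <- c(lines,
      "        <qual:listOfOutputs>",
      paste0("          <qual:output qual:qualitativeSpecies=\"", v,
             "\" qual:transitionEffect=\"assignmentLevel\"/>"),
      "        </qual:listOfOutputs>",
      "        <qual:listOfFunctionTerms>",
      "          <qual:defaultTerm qual:resultLevel=\"0\"/>",
      "          <qual:functionTerm qual:resultLevel=\"1\">",
      "            <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
      expr_to_mathml(e, 14L),
      "            </math>",
      "          </qual:functionTerm>",
      "        </qual:listOfFunctionTerms>",
      "      </qual:transition>")
  }
  lines <- c(lines, "    </qual:listOfTransitions>", "  </model>", "</sbml>")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
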