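# Reduction of process-description (PD) reaction graphs to activity-flow
# Boolean networks. A PD graph carries mechanistic reactions (reactants,
# products, signed modifiers); the reduction rewrites it with four rules and
# the logic-inference step then assigns each produced species a Boolean
# function over its remaining regulators.

#' Construct a process-description reaction graph
#'
#' @param species data.frame with columns `id` (unique identifiers), and
#'   optionally `name` (display name), `compartment`, `active` (logical;
#'   `FALSE` marks an inactive form), `receptor` (logical; marks receptor
#'   species for the receptor-ligand rule). Missing optional columns are
#'   filled with defaults (`active = TRUE`, `receptor = FALSE`).
#' @param reactions list; each element a list with `id`, `type` (one of
#'   `"state_transition"`, `"association"`, `"transport"`), `reactants`
#'   (character), `products` (character, at least one), and `modifiers`
#'   (data.frame with columns `species`, `sign` in `"positive"`/`"negative"`,
#'   or `NULL`).
#' @return an object of class `pd_graph`.
#' @export
pd_graph <- function(species, reactions) {
  stopifnot(is.data.frame(species), "id" %in% names(species))
  if (anyDuplicated(species$id))
    stop("duplicate species ids")
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$compartment)) species$compartment <- "default"
  if (is.null(species$active)) species$active <- TRUE
  if (is.null(species$receptor)) species$receptor <- FALSE
  species$active <- as.logical(species$active)
  species$receptor <- as.logical(species$receptor)
  species <- species[, c("id", "name", "compartment", "active", "receptor")]
  empty_mod <- data.frame(species = character(), sign = character(),
                          stringsAsFactors = FALSE)
  reactions <- lapply(reactions, function(r) {
    stopifnot(!is.null(r$id), !is.null(r$type))
    if (!r$type %in% c("state_transition", "association", "transport"))
      stop("unknown reaction type: ", r$type)
    r$reactants <- as.character(r$reactants %||% character())
    r$products <- as.character(r$products)
    if (!length(r$products)) stop("reaction ", r$id, " has no product")
    if (is.null(r$modifiers)) r$modifiers <- empty_mod
    if (!all(r$modifiers$sign %in% c("positive", "negative")))
      stop("modifier signs must be 'positive' or 'negative' (reaction ", r$id, ")")
    parts <- c(r$reactants, r$products, r$modifiers$species)
    unknown <- setdiff(parts, species$id)
    if (length(unknown))
      stop("reaction ", r$id, " references undeclared species: ",
           paste(unknown, collapse = ", "))
    r
  })
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  names(reactions) <- ids
  structure(list(species = species, reactions = reactions), class = "pd_graph")
}

#' @export
print.pd_graph <- function(x, ...) {
  cat("PD graph:", nrow(x$species), "species,", length(x$reactions),
      "reactions\n")
  invisible(x)
}

# how many reactions a species participates in (any role)
pd_participation <- function(pd, id) {
  sum(vapply(pd$reactions, function(r)
    id %in% c(r$reactants, r$products, r$modifiers$species), logical(1)))
}

pd_drop_species_if_orphan <- function(pd, id) {
  if (pd_participation(pd, id) == 0L)
    pd$species <- pd$species[pd$species$id != id, , drop = FALSE]
  pd
}

#' Reduce a PD graph to activity-flow form
#'
#' Applies four rewriting rules, in order and iterated to a fixpoint:
#' \enumerate{
#'   \item In an association where a receptor and a ligand form a complex,
#'     the receptor reactant is removed.
#'   \item In an association where proteins form a complex (no receptor),
#'     the reactants are removed; the reaction's modifiers stay linked to
#'     the product.
#'   \item Inactive forms of a biomolecule participating in a single
#'     reaction are removed.
#'   \item In a transport reaction whose reactant and product denote the
#'     same biomolecule (same display name), the reactant is removed and its
#'     other incident reactions are re-linked to the product.
#' }
#'
#' @param pd a [pd_graph()].
#' @param max_iter iteration cap; exceeded caps raise an error (default
#'   `10 * number of reactions`).
#' @return list with elements `graph` (the reduced `pd_graph`) and `trace`
#'   (a data.frame recording each rule application: `rule`, `reaction`,
#'   `removed`, `rewired`), replayable with [replay_trace()].
#' @export
apply_reduction_rules <- function(pd, max_iter = NULL) {
  stopifnot(inherits(pd, "pd_graph"))
  if (is.null(max_iter)) max_iter <- max(10L, 10L * length(pd$reactions))
  trace <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("reduction did not reach a fixpoint within ", max_iter,
           " iterations")
    step <- pd_reduce_once(pd)
    if (is.null(step)) break
    pd <- step$graph
    trace[[length(trace) + 1L]] <- step$op
  }
  trace_df <- if (length(trace)) {
    do.call(rbind, lapply(trace, function(op)
      data.frame(rule = op$rule, reaction = op$reaction,
                 removed = paste(op$removed, collapse = ","),
                 rewired = op$rewired %||% "", stringsAsFactors = FALSE)))
  } else {
    data.frame(rule = integer(), reaction = character(),
               removed = character(), rewired = character(),
               stringsAsFactors = FALSE)
  }
  list(graph = pd, trace = trace_df)
}

# One rule application (first match in rule order 1..4), or NULL at fixpoint.
pd_reduce_once <- function(pd) {
  recflag <- stats::setNames(pd$species$receptor, pd$species$id)
  actflag <- stats::setNames(pd$species$active, pd$species$id)
  dispname <- stats::setNames(pd$species$name, pd$species$id)

  # Rule 1: receptor-ligand association -> drop the receptor reactant.
  for (rid in names(pd$reactions)) {
    r <- pd$reactions[[rid]]
    if (r$type != "association" || length(r$reactants) < 2L) next
    rec <- r$reactants[recflag[r$reactants]]
    if (!length(rec)) next
    rec <- rec[1L]
    pd$reactions[[rid]]$reactants <- setdiff(r$reactants, rec)
    pd <- pd_drop_species_if_orphan(pd, rec)
    return(list(graph = pd,
                op = list(rule = 1L, reaction = rid, removed = rec)))
  }
  # Rule 2: protein association -> drop all reactants, modifiers stay on the
  # product (they already regulate the producing reaction).
  for (rid in names(pd$reactions)) {
    r <- pd$reactions[[rid]]
    if (r$type != "association" || length(r$reactants) < 2L) next
    gone <- r$reactants
    pd$reactions[[rid]]$reactants <- character()
    for (sp in gone) pd <- pd_drop_species_if_orphan(pd, sp)
    return(list(graph = pd,
                op = list(rule = 2L, reaction = rid, removed = gone)))
  }
  # Rule 3: inactive species in exactly one reaction -> removed.
  for (sp in pd$species$id) {
    if (actflag[sp]) next
    if (pd_participation(pd, sp) != 1L) next
    rid <- names(pd$reactions)[vapply(pd$reactions, function(r)
      sp %in% c(r$reactants, r$products, r$modifiers$species), logical(1))]
    r <- pd$reactions[[rid]]
    r$reactants <- setdiff(r$reactants, sp)
    r$products <- setdiff(r$products, sp)
    r$modifiers <- r$modifiers[r$modifiers$species != sp, , drop = FALSE]
    if (!length(r$products)) {
      pd$reactions[[rid]] <- NULL        # reaction lost its purpose
    } else {
      pd$reactions[[rid]] <- r
    }
    pd$species <- pd$species[pd$species$id != sp, , drop = FALSE]
    return(list(graph = pd,
                op = list(rule = 3L, reaction = rid, removed = sp)))
  }
  # Rule 4: transport of the same biomolecule -> merge reactant into product.
  for (rid in names(pd$reactions)) {
    r <- pd$reactions[[rid]]
    if (r$type != "transport" || length(r$reactants) != 1L ||
        length(r$products) != 1L) next
    from <- r$reactants
    to <- r$products
    if (from == to || dispname[from] != dispname[to]) next
    pd$reactions[[rid]] <- NULL
    for (oid in names(pd$reactions)) {
      o <- pd$reactions[[oid]]
      o$reactants[o$reactants == from] <- to
      o$products[o$products == from] <- to
      o$modifiers$species[o$modifiers$species == from] <- to
      o$reactants <- unique(o$reactants)
      o$products <- unique(o$products)
      o$modifiers <- unique(o$modifiers)
      pd$reactions[[oid]] <- o
    }
    pd$species <- pd$species[pd$species$id != from, , drop = FALSE]
    return(list(graph = pd,
                op = list(rule = 4L, reaction = rid, removed = from,
                          rewired = paste0(from, "->", to))))
  }
  NULL
}

#' Replay a reduction trace
#'
#' Re-applies the recorded rule applications to the original graph; the
#' result reproduces [apply_reduction_rules()]'s output, which makes the
#' reduction auditable.
#'
#' @param pd the original `pd_graph`.
#' @param trace the trace data.frame from [apply_reduction_rules()].
#' @return the reduced `pd_graph`.
#' @export
replay_trace <- function(pd, trace) {
  for (i in seq_len(nrow(trace))) {
    step <- pd_reduce_once(pd)
    if (is.null(step))
      stop("trace replay: graph reached a fixpoint before the trace ended")
    if (step$op$rule != trace$rule[i] || step$op$reaction != trace$reaction[i])
      stop("trace replay diverged at step ", i)
    pd <- step$graph
  }
  pd
}

#' Infer the Boolean network of a reduced PD graph
#'
#' For each species that is the product of at least one reaction, the Boolean
#' function is built as: OR over producing reactions of (AND of the
#' reaction's reactants and positive modifiers), combined with the negative
#' modifiers according to `inhibitor_mode`:
#' \describe{
#'   \item{`"dominant"` (default)}{`(OR of activating routes) & !(OR of all
#'     negative modifiers across the producing reactions)` — any inhibitor
#'     vetoes production.}
#'   \item{`"or"`}{each producing reaction carries its own
#'     `& !(its negative modifiers)` inside the disjunction.}
#' }
#' Species never produced become free inputs. Identifiers are normalized to
#' the rule grammar; original display names are kept in the network metadata.
#'
#' @param pd a reduced [pd_graph()] (see [apply_reduction_rules()]).
#' @param inhibitor_mode `"dominant"` or `"or"`.
#' @return a [boolean_network()].
#' @export
infer_logic <- function(pd, inhibitor_mode = c("dominant", "or")) {
  stopifnot(inherits(pd, "pd_graph"))
  inhibitor_mode <- match.arg(inhibitor_mode)
  ids <- pd$species$id
  norm <- normalize_identifier(ids)
  if (anyDuplicated(norm))
    stop("species identifiers collide after normalization: ",
         paste(unique(norm[duplicated(norm)]), collapse = ", "))
  id_map <- stats::setNames(norm, ids)
  and_join <- function(xs) Reduce(function(a, b) call("&", a, b), xs)
  or_join <- function(xs) Reduce(function(a, b) call("|", a, b), xs)

  funs <- stats::setNames(vector("list", length(norm)), norm)
  for (sp in ids) {
    prod_rs <- Filter(function(r) sp %in% r$products, pd$reactions)
    if (!length(prod_rs)) next
    routes <- list()
    inhibitors <- character()
    for (r in prod_rs) {
      acts <- c(setdiff(r$reactants, sp),
                r$modifiers$species[r$modifiers$sign == "positive"])
      negs <- r$modifiers$species[r$modifiers$sign == "negative"]
      route <- if (length(acts)) and_join(lapply(id_map[acts], as.symbol))
               else TRUE
      if (inhibitor_mode == "or" && length(negs))
        route <- call("&", route,
                      call("!", or_join(lapply(id_map[negs], as.symbol))))
      routes[[length(routes) + 1L]] <- route
      inhibitors <- union(inhibitors, negs)
    }
    f <- or_join(routes)
    if (inhibitor_mode == "dominant" && length(inhibitors))
      f <- call("&", f, call("!", or_join(lapply(id_map[inhibitors], as.symbol))))
    funs[[id_map[[sp]]]] <- bool_validate_expr(f)
  }
  for (v in norm) if (is.null(funs[[v]])) funs[[v]] <- as.symbol(v)
  boolean_network(funs,
                  labels = stats::setNames(pd$species$name, norm))
}

#' Translate a PD graph end to end
#'
#' Convenience wrapper: [apply_reduction_rules()] followed by [infer_logic()].
#'
#' @inheritParams infer_logic
#' @return list with `network`, `reduced` (the reduced graph) and `trace`.
#' @export
translate_pd <- function(pd, inhibitor_mode = c("dominant", "or")) {
  red <- apply_reduction_rules(pd)
  list(network = infer_logic(red$graph, inhibitor_mode),
       reduced = red$graph, trace = red$trace)
}

## ---- structured text exchange format ------------------------------------

#' Read / write PD graphs as structured text
#'
#' A minimal block format: each block starts with a line `species` or
#' `reaction`, followed by indented `key: value` lines. List-valued keys
#' (`reactants`, `products`) are comma-separated; `modifiers` entries are
#' `id:sign` pairs.
#'
#' @param path input file (or character vector of lines with `text = TRUE`).
#' @param text logical; treat `path` as the content.
#' @return a [pd_graph()].
#' @export
read_pd_graph <- function(path, text = FALSE) {
  lines <- if (text) unlist(strsplit(paste(path, collapse = "\n"), "\n"))
           else readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  blocks <- list()
  cur <- NULL
  for (line in lines) {
    if (grepl("^(species|reaction)\\s*$", line)) {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- list(.kind = trimws(line))
    } else if (grepl("^\\s+\\S", line) && grepl(":", line)) {
      if (is.null(cur)) stop("key line outside a block: ", line)
      kv <- regmatches(line, regexec("^\\s+([A-Za-z_]+):\\s*(.*)$", line))[[1]]
      if (length(kv) != 3L) stop("malformed key line: ", line)
      cur[[kv[2]]] <- trimws(kv[3])
    } else stop("malformed PD document line: ", line)
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur

  parse_bool_flag <- function(x, default) {
    if (is.null(x)) default else tolower(x) %in% c("true", "yes", "1")
  }
  split_list <- function(x) {
    if (is.null(x) || !nzchar(x)) character()
    else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  sp_rows <- list()
  rx <- list()
  for (b in blocks) {
    if (b$.kind == "species") {
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        id = b$id, name = b$name %||% b$id,
        compartment = b$compartment %||% "default",
        active = parse_bool_flag(b$active, TRUE),
        receptor = parse_bool_flag(b$receptor, FALSE),
        stringsAsFactors = FALSE)
    } else {
      mods <- split_list(b$modifiers)
      md <- if (length(mods)) {
        parts <- strsplit(mods, ":", fixed = TRUE)
        data.frame(species = vapply(parts, `[`, character(1), 1),
                   sign = vapply(parts, `[`, character(1), 2),
                   stringsAsFactors = FALSE)
      } else NULL
      rx[[length(rx) + 1L]] <- list(
        id = b$id, type = b$type %||% "state_transition",
        reactants = split_list(b$reactants),
        products = split_list(b$products), modifiers = md)
    }
  }
  if (!length(sp_rows)) stop("PD document declares no species")
  pd_graph(do.call(rbind, sp_rows), rx)
}

#' @rdname read_pd_graph
#' @param pd a `pd_graph`.
#' @param path output file, or `NULL` to return the lines.
#' @export
write_pd_graph <- function(pd, path = NULL) {
  stopifnot(inherits(pd, "pd_graph"))
  lines <- character()
  for (i in seq_len(nrow(pd$species))) {
    s <- pd$species[i, ]
    lines <- c(lines, "species",
               paste0("  id: ", s$id),
               paste0("  name: ", s$name),
               paste0("  compartment: ", s$compartment),
               paste0("  active: ", tolower(s$active)),
               paste0("  receptor: ", tolower(s$receptor)))
  }
  for (r in pd$reactions) {
    lines <- c(lines, "reaction",
               paste0("  id: ", r$id),
               paste0("  type: ", r$type),
               paste0("  reactants: ", paste(r$reactants, collapse = ", ")),
               paste0("  products: ", paste(r$products, collapse = ", ")))
    if (nrow(r$modifiers))
      lines <- c(lines, paste0("  modifiers: ",
        paste(paste0(r$modifiers$species, ":", r$modifiers$sign),
              collapse = ", ")))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
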