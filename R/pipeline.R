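# End-to-end orchestration: load/translate -> topology -> attractors ->
# perturbation -> stochastic simulation -> report bundle with a manifest.
# A single global seed fans out deterministically to per-stage seeds
# (seed + 1000 * stage-position in the canonical stage order), so re-running
# one stage reproduces its part of a full run.

pipeline_stages <- c("topology", "attractors", "perturbation", "simulate")

stage_seed <- function(seed, stage) {
  offs <- match(stage, pipeline_stages)
  as.integer((seed + 1000L * offs) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Loads (or accepts) a Boolean network, computes the centrality table,
#' searches attractors, scans single-node perturbation sensitivities, runs
#' the stochastic simulator, and writes every result plus a manifest with
#' content hashes into `out_dir`. Deterministic given `seed`.
#'
#' @param network a `boolean_network`, or `NULL` when `input` is given.
#' @param input optional list `list(path =, format = "rules"|"sbml")` naming
#'   a model file to load.
#' @param stages subset of `c("topology", "attractors", "perturbation",
#'   "simulate")`.
#' @param out_dir output directory (created if needed).
#' @param seed global seed.
#' @param attractor_methods forwarded to [attractor_search_config()].
#' @param perturb_nodes nodes to scan (default all; `NULL` disables the
#'   stage even when listed).
#' @param ctmc a [ctmc_config()] for the `simulate` stage (its seed is
#'   overridden by the fanned-out stage seed).
#' @param scenarios optional scenario list for [scenario_table()]; the table
#'   is written alongside the other outputs.
#' @return invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(network = NULL, input = NULL,
                         stages = pipeline_stages, out_dir, seed = 1L,
                         attractor_methods = c("sat", "async"),
                         perturb_nodes = NULL, ctmc = ctmc_config(),
                         scenarios = NULL) {
  stopifnot(all(stages %in% pipeline_stages))
  if (is.null(network)) {
    if (is.null(input)) stop("supply either 'network' or 'input'")
    network <- switch(input$format,
                      rules = read_rules(input$path),
                      sbml = read_sbml_qual(input$path),
                      stop("unknown input format: ", input$format))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(network = network)
  files <- character(0)

  rules_path <- file.path(out_dir, "model.rules")
  write_rules(network, rules_path)
  files <- c(files, rules_path)

  if ("topology" %in% stages) {
    ct <- centrality_table(network)
    p <- file.path(out_dir, "centrality.tsv")
    utils::write.table(ct, p, sep = "\t", quote = FALSE, row.names = FALSE)
    results$centrality <- ct
    files <- c(files, p)
  }
  if ("attractors" %in% stages) {
    cfg <- attractor_search_config(methods = attractor_methods,
                                   seed = stage_seed(seed, "attractors"))
    atts <- list()
    if ("exhaustive" %in% attractor_methods)
      atts <- c(atts, exhaustive_sync(network))
    if ("sat" %in% attractor_methods)
      atts <- c(atts, lapply(sat_steady_states(network), function(cd)
        bn_attractor("steady", cd, network$nodes, "sat")))
    if ("async" %in% attractor_methods)
      atts <- c(atts, async_random_walk(network, n_runs = cfg$n_runs,
                                        max_steps = cfg$max_steps,
                                        seed = cfg$seed))
    tab <- attractor_table(atts)
    tab <- tab[!duplicated(tab$states), , drop = FALSE]
    p <- file.path(out_dir, "attractors.json")
    jsonlite::write_json(list(nodes = network$nodes, attractors = tab),
                         p, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
    results$attractors <- atts
    results$attractor_table <- tab
    files <- c(files, p)
  }
  if ("perturbation" %in% stages) {
    nodes <- perturb_nodes %||% network$nodes
    cfg <- attractor_search_config(methods = attractor_methods,
                                   seed = stage_seed(seed, "perturbation"))
    rep <- sensitivity_report(network, nodes = nodes, search = cfg)
    p <- file.path(out_dir, "sensitivity.tsv")
    utils::write.table(rep, p, sep = "\t", quote = FALSE, row.names = FALSE)
    results$sensitivity <- rep
    files <- c(files, p)
    if ("topology" %in% stages) {
      pri <- prioritize_targets(results$centrality, rep)
      p2 <- file.path(out_dir, "priorities.tsv")
      utils::write.table(pri, p2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      results$priorities <- pri
      files <- c(files, p2)
    }
  }
  if ("simulate" %in% stages) {
    ctmc$seed <- stage_seed(seed, "simulate")
    est <- simulate_ctmc(network, ctmc)
    traj <- data.frame(time = est$time, est$prob, check.names = FALSE)
    p <- file.path(out_dir, "trajectory.tsv")
    utils::write.table(traj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    results$trajectory <- est
    files <- c(files, p)
    if (!is.null(scenarios)) {
      sc <- scenario_table(network, scenarios,
                           n_traj = ctmc$n_traj, max_time = ctmc$max_time,
                           bin_width = ctmc$bin_width,
                           seed = stage_seed(seed, "simulate"))
      p2 <- file.path(out_dir, "scenarios.tsv")
      utils::write.table(sc, p2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      results$scenarios <- sc
      files <- c(files, p2)
    }
  }
  manifest <- list(
    package = "boolpath",
    version = as.character(utils::packageVersion("boolpath")),
    seed = seed, stages = stages,
    n_nodes = length(network$nodes),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Verify a pipeline output bundle
#'
#' Recomputes the content hash of every file listed in the bundle's manifest.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return logical: all hashes match; mismatching files are reported in a
#'   warning.
#' @export
verify_run <- function(out_dir) {
  mf <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  bad <- character(0)
  for (f in names(mf$files)) {
    path <- file.path(out_dir, f)
    if (!file.exists(path) ||
        unname(tools::md5sum(path)) != mf$files[[f]]$md5)
      bad <- c(bad, f)
  }
  if (length(bad)) {
    warning("manifest mismatch: ", paste(bad, collapse = ", "))
    return(FALSE)
  }
  TRUE
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML document holds the arguments of [run_pipeline()]: `input`
#' (path + format), `stages`, `out_dir`, `seed`, `attractor_methods`,
#' `ctmc` (fields of [ctmc_config()]) and `scenarios`. Paths are resolved
#' relative to the configuration file.
#'
#' @param path YAML configuration file.
#' @return invisibly, the [run_pipeline()] result list.
#' @export
run_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  if (!is.null(cfg$input$path) && !file.exists(cfg$input$path))
    cfg$input$path <- file.path(base, cfg$input$path)
  args <- list(
    input = cfg$input,
    out_dir = if (is.null(cfg$out_dir)) file.path(base, "results")
              else if (startsWith(cfg$out_dir, "/")) cfg$out_dir
              else file.path(base, cfg$out_dir),
    seed = cfg$seed %||% 1L)
  if (!is.null(cfg$stages)) args$stages <- unlist(cfg$stages)
  if (!is.null(cfg$attractor_methods))
    args$attractor_methods <- unlist(cfg$attractor_methods)
  if (!is.null(cfg$ctmc)) args$ctmc <- do.call(ctmc_config, cfg$ctmc)
  if (!is.null(cfg$scenarios))
    args$scenarios <- lapply(cfg$scenarios, function(sc) {
      sc$clamp <- unlist(sc$clamp)
      sc$outputs <- unlist(sc$outputs)
      sc
    })
  do.call(run_pipeline, args)
}

#' Scenario table: clamped inputs versus phenotype probabilities
#'
#' Each scenario clamps named nodes ON or OFF (via [clamp()]) and reports
#' the final-time ON-probability of each named output under the stochastic
#' simulator, with Monte-Carlo standard errors. Unclamped inputs start at
#' ON-probability 0.5.
#'
#' @param network a `boolean_network`.
#' @param scenarios list of scenarios; each a list with `clamp` (named 0/1
#'   vector; may be empty) and `outputs` (character). An optional `name`
#'   labels the row.
#' @param n_traj,max_time,bin_width,seed simulator settings.
#' @return data.frame: one row per scenario with the clamp pattern, and
#'   `<output>` / `<output>_se` columns per requested output.
#' @export
scenario_table <- function(network, scenarios, n_traj = 2000L,
                           max_time = 20, bin_width = 2, seed = 1L) {
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    clamps <- sc$clamp %||% numeric(0)
    if (anyDuplicated(names(clamps)))
      stop("scenario ", si, " clamps a node twice")
    unknown <- setdiff(c(names(clamps), sc$outputs), network$nodes)
    if (length(unknown))
      stop("scenario ", si, " references unknown node(s): ",
           paste(unknown, collapse = ", "))
    net <- network
    for (v in names(clamps))
      net <- clamp(net, v,
                   if (clamps[[v]] == 1) "overexpression" else "knockout")
    est <- simulate_ctmc(net, ctmc_config(
      n_traj = n_traj, max_time = max_time, bin_width = bin_width,
      seed = seed + si))
    final <- est$prob[nrow(est$prob), ]
    fse <- est$se[nrow(est$se), ]
    row <- data.frame(scenario = sc$name %||% paste0("scenario", si),
                      clamps = if (length(clamps))
                        paste(names(clamps), clamps, sep = "=", collapse = ",")
                      else "none",
                      stringsAsFactors = FALSE)
    for (o in sc$outputs) {
      row[[o]] <- unname(final[o])
      row[[paste0(o, "_se")]] <- unname(fse[o])
    }
    rows[[si]] <- row
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA_real_
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
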