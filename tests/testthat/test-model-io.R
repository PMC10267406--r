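test_that("rule text parses into the expected logic", {
  bn <- read_rules(c("# tau phosphorylation fragment",
                     "CDK5_p25, CDK5_p25",
                     "PIN1, PIN1",
                     "MAPTP, CDK5_p25 & !PIN1"), text = TRUE)
  expect_identical(bn$nodes, c("CDK5_p25", "PIN1", "MAPTP"))
  expect_setequal(bn$inputs, c("CDK5_p25", "PIN1"))
  # MAPTP ON iff kinase present and inhibitor absent, all 4 combinations
  for (ck in c(FALSE, TRUE)) for (pi in c(FALSE, TRUE)) {
    s <- c(CDK5_p25 = ck, PIN1 = pi, MAPTP = FALSE)
    expect_identical(unname(sync_step(bn, s)["MAPTP"]), ck && !pi)
  }
})

test_that("a self-referencing rule declares a free input with two fixed points", {
  bn <- read_rules("A, A", text = TRUE)
  expect_identical(bn$inputs, "A")
  expect_identical(sat_steady_states(bn), c(0, 1))
})

test_that("rule reader rejects malformed documents with line numbers", {
  expect_error(read_rules(c("A, B |"), text = TRUE), "line 1")
  expect_error(read_rules(c("A, A", "A, 1"), text = TRUE), "duplicate target")
  expect_error(read_rules(c("A, B"), text = TRUE), "undeclared")
  expect_error(read_rules("A, B ? C", text = TRUE), "line 1")
  expect_error(read_rules("justtext", text = TRUE), "syntax")
})

test_that("rule-text round trip preserves per-node truth tables", {
  for (seed in 1:20) {
    bn <- rbn(seed, n = 4L + seed %% 7L)
    back <- read_rules(write_rules(bn), text = TRUE)
    expect_identical(back$nodes, bn$nodes)
    expect_true(bn_equivalent(bn, back))
  }
  # also via exhaustive full-state evaluation on one instance
  bn <- rbn(99, n = 8L)
  back <- read_rules(write_rules(bn), text = TRUE)
  expect_identical(oracle_full_table(back), oracle_full_table(bn))
})

test_that("SIF export classifies regulator polarity and sorts edges", {
  bn <- boolean_network(list(CDK5_p25 = "CDK5_p25", PIN1 = "PIN1",
                             MAPTP = "CDK5_p25 & !PIN1"))
  ed <- sif_edges(bn)
  expect_identical(ed$relation[ed$source == "CDK5_p25"], "activates")
  expect_identical(ed$relation[ed$source == "PIN1"], "inhibits")

  both <- boolean_network(list(B = "B", A = "B | !B"))
  expect_identical(sif_edges(both)$relation, "interacts")

  const <- boolean_network(list(A = "1", B = "A"))
  expect_identical(nrow(sif_edges(const)), 1L)  # constant node: no incoming

  # exactly one edge per (regulator, target) pair, sorted
  bn2 <- rbn(7)
  ed2 <- sif_edges(bn2)
  expect_false(any(duplicated(ed2[, c("source", "target")])))
  expect_identical(ed2, ed2[order(ed2$source, ed2$relation, ed2$target), ],
                   ignore_attr = TRUE)
  n_lits <- sum(vapply(setdiff(bn2$nodes, bn2$inputs), function(v) {
    p <- boolpath:::bool_expr_polarity(bn2$functions[[v]])
    length(union(p$pos, p$neg))
  }, numeric(1)))
  expect_identical(nrow(ed2), as.integer(n_lits))
})

test_that("SBML-qual round trip is truth-table identical", {
  for (seed in 1:10) {
    bn <- rbn(seed, n = 4L + seed %% 6L)
    doc <- paste(write_sbml_qual(bn), collapse = "\n")
    back <- read_sbml_qual(doc)
    expect_identical(back$nodes, bn$nodes)
    expect_true(bn_equivalent(bn, back))
  }
})

test_that("SBML-qual reader handles simple activation and rejects unsupported content", {
  doc <- paste(write_sbml_qual(boolean_network(list(A = "A", B = "A"))),
               collapse = "\n")
  bn <- read_sbml_qual(doc)
  expect_identical(format(bn$functions$B), "A")

  multi <- sub("qual:maxLevel=\"1\"", "qual:maxLevel=\"2\"", doc)
  expect_error(read_sbml_qual(multi), "maxLevel")

  nodefault <- paste(grep("defaultTerm", strsplit(doc, "\n")[[1]],
                          invert = TRUE, value = TRUE), collapse = "\n")
  expect_error(read_sbml_qual(nodefault), "default term")

  badmath <- sub("<apply><eq/>", "<apply><geq/>", doc, fixed = TRUE)
  expect_error(read_sbml_qual(badmath), "")
})

test_that("species names with spaces and colons are normalized on read", {
  bn <- boolean_network(list(TF_FOXO3_complex_nucleus = "1"),
                        labels = c(TF_FOXO3_complex_nucleus =
                                     "TF FOXO3 complex nucleus"))
  doc <- paste(write_sbml_qual(bn), collapse = "\n")
  doc <- sub("qual:id=\"TF_FOXO3_complex_nucleus\"",
             "qual:id=\"TF_FOXO3_complex_nucleus\"", doc)
  back <- read_sbml_qual(doc)
  expect_identical(unname(back$metadata$labels["TF_FOXO3_complex_nucleus"]),
                   "TF FOXO3 complex nucleus")
  expect_identical(boolpath:::normalize_identifier("TF FOXO3:complex nucleus"),
                   "TF_FOXO3_complex_nucleus")
})

test_that("an input-only network writes a transition-free document", {
  bn <- boolean_network(list(A = "A"))
  doc <- write_sbml_qual(bn)
  expect_false(any(grepl("<qual:transition ", doc)))
  expect_true(bn_equivalent(bn, read_sbml_qual(paste(doc, collapse = "\n"))))
})
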