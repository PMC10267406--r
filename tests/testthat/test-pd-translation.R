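# Fixtures for the four reduction rules and the logic-inference step.

receptor_ligand_pd <- function() {
  pd_graph(
    species = data.frame(id = c("R", "L", "RL", "M"),
                         receptor = c(TRUE, FALSE, FALSE, FALSE)),
    reactions = list(list(
      id = "asc1", type = "association", reactants = c("R", "L"),
      products = "RL",
      modifiers = data.frame(species = "M", sign = "positive"))))
}

test_that("receptor-ligand association drops the receptor reactant", {
  out <- apply_reduction_rules(receptor_ligand_pd())
  r <- out$graph$reactions[["asc1"]]
  expect_identical(r$reactants, "L")
  expect_identical(r$modifiers$species, "M")
  expect_identical(out$trace$rule[1], 1L)
  expect_false("R" %in% out$graph$species$id)
})

test_that("protein association removes reactants and keeps modifiers on the product", {
  pd <- pd_graph(
    species = data.frame(id = c("A", "B", "AB", "M")),
    reactions = list(list(
      id = "asc", type = "association", reactants = c("A", "B"),
      products = "AB",
      modifiers = data.frame(species = "M", sign = "positive"))))
  out <- apply_reduction_rules(pd)
  r <- out$graph$reactions[["asc"]]
  expect_length(r$reactants, 0L)
  expect_identical(r$modifiers$species, "M")
  bn <- infer_logic(out$graph)
  expect_identical(format(bn$functions$AB), "M")
})

test_that("an inactive species in a single reaction is removed", {
  pd <- pd_graph(
    species = data.frame(id = c("X", "Xa", "K"),
                         active = c(FALSE, TRUE, TRUE)),
    reactions = list(list(
      id = "act", type = "state_transition", reactants = "X",
      products = "Xa",
      modifiers = data.frame(species = "K", sign = "positive"))))
  out <- apply_reduction_rules(pd)
  expect_false("X" %in% out$graph$species$id)
  expect_identical(out$trace$rule, 3L)
  expect_identical(format(infer_logic(out$graph)$functions$Xa), "K")
})

test_that("transport of the same biomolecule merges reactant into product", {
  pd <- pd_graph(
    species = data.frame(id = c("P_cyt", "P_nuc", "T"),
                         name = c("P", "P", "T"),
                         compartment = c("cytosol", "nucleus", "cytosol")),
    reactions = list(
      list(id = "tp", type = "transport", reactants = "P_cyt",
           products = "P_nuc"),
      list(id = "mk", type = "state_transition", reactants = "T",
           products = "P_cyt")))
  out <- apply_reduction_rules(pd)
  expect_false("P_cyt" %in% out$graph$species$id)
  expect_identical(out$graph$reactions[["mk"]]$products, "P_nuc")
  expect_match(out$trace$rewired[out$trace$rule == 4L], "P_cyt->P_nuc")
})

test_that("reduction never increases the species count and traces replay exactly", {
  fixtures <- list(receptor_ligand_pd())
  for (pd in fixtures) {
    out <- apply_reduction_rules(pd)
    expect_lte(nrow(out$graph$species), nrow(pd$species))
    replayed <- replay_trace(pd, out$trace)
    expect_identical(replayed$species, out$graph$species)
    expect_identical(replayed$reactions, out$graph$reactions)
  }
})

test_that("logic inference reproduces the kinase/inhibitor switch on all input combinations", {
  pd <- pd_graph(
    species = data.frame(id = c("MAPT", "MAPTP", "CDK5_p25", "PIN1"),
                         active = c(FALSE, TRUE, TRUE, TRUE)),
    reactions = list(list(
      id = "phos", type = "state_transition", reactants = "MAPT",
      products = "MAPTP",
      modifiers = data.frame(species = c("CDK5_p25", "PIN1"),
                             sign = c("positive", "negative")))))
  bn <- translate_pd(pd)$network
  expect_identical(format(bn$functions$MAPTP), "CDK5_p25 & !PIN1")
  for (ck in c(FALSE, TRUE)) for (pi in c(FALSE, TRUE)) {
    s <- c(MAPTP = FALSE, CDK5_p25 = ck, PIN1 = pi)
    expect_identical(unname(sync_step(bn, s)["MAPTP"]), ck && !pi)
  }
})

test_that("two producing reactions disjoin and reactant pairs conjoin", {
  pd <- pd_graph(
    species = data.frame(id = c("P", "A", "B")),
    reactions = list(
      list(id = "r1", type = "state_transition", reactants = "A",
           products = "P"),
      list(id = "r2", type = "state_transition", reactants = "B",
           products = "P")))
  expect_identical(format(infer_logic(pd)$functions$P), "A | B")

  pd2 <- pd_graph(
    species = data.frame(id = c("P", "A", "B", "I1", "I2")),
    reactions = list(list(
      id = "r", type = "state_transition", reactants = c("A", "B"),
      products = "P",
      modifiers = data.frame(species = c("I1", "I2"),
                             sign = c("negative", "negative")))))
  bn <- infer_logic(pd2)
  # 16-row truth table: P' = (A & B) & !(I1 | I2)
  st <- expand.grid(A = c(FALSE, TRUE), B = c(FALSE, TRUE),
                    I1 = c(FALSE, TRUE), I2 = c(FALSE, TRUE))
  for (r in seq_len(nrow(st))) {
    s <- c(P = FALSE, A = st$A[r], B = st$B[r], I1 = st$I1[r], I2 = st$I2[r])
    expect_identical(unname(sync_step(bn, s)["P"]),
                     (st$A[r] && st$B[r]) && !(st$I1[r] || st$I2[r]))
  }
})

test_that("per-reaction inhibitor mode scopes the negation to its route", {
  pd <- pd_graph(
    species = data.frame(id = c("P", "A", "B", "I")),
    reactions = list(
      list(id = "r1", type = "state_transition", reactants = "A",
           products = "P",
           modifiers = data.frame(species = "I", sign = "negative")),
      list(id = "r2", type = "state_transition", reactants = "B",
           products = "P")))
  dom <- infer_logic(pd, inhibitor_mode = "dominant")
  per <- infer_logic(pd, inhibitor_mode = "or")
  s <- c(P = FALSE, A = FALSE, B = TRUE, I = TRUE)
  expect_false(unname(sync_step(dom, s)["P"]))  # inhibitor vetoes everything
  expect_true(unname(sync_step(per, s)["P"]))   # route via B unaffected
})

test_that("species never produced become free inputs", {
  pd <- pd_graph(
    species = data.frame(id = c("S", "P")),
    reactions = list(list(id = "r", type = "state_transition",
                          reactants = "S", products = "P")))
  bn <- infer_logic(pd)
  expect_identical(bn$inputs, "S")
})

test_that("PD text documents round trip", {
  pd <- receptor_ligand_pd()
  txt <- write_pd_graph(pd)
  back <- read_pd_graph(txt, text = TRUE)
  expect_identical(back$species, pd$species)
  expect_identical(lapply(back$reactions, `[`, c("id", "type", "reactants",
                                                 "products")),
                   lapply(pd$reactions, `[`, c("id", "type", "reactants",
                                               "products")))
})
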