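test_that("clamping replaces one function and is reversible", {
  bn <- boolean_network(list(A = "A", B = "A"))
  ko <- clamp(bn, "A", "knockout")
  expect_identical(sat_steady_states(ko), 0)        # only (0,0) survives
  oe <- clamp(boolean_network(list(A = "A", B = "!A")), "A", "overexpression")
  expect_identical(sat_steady_states(oe), 1)        # A=1, B=0
  # clamp then restore the original expression: truth tables recover
  restored <- boolean_network(
    stats::setNames(lapply(bn$nodes, function(v) bn$functions[[v]]),
                    bn$nodes))
  expect_true(bn_equivalent(bn, restored))
  expect_error(clamp(bn, "Z"), "unknown")
})

test_that("similarity distance is the Jaccard index with the empty-set convention", {
  expect_identical(similarity_distance(c(1, 2), c(1, 2)), 1)
  expect_identical(similarity_distance(c(1, 2), c(3, 4)), 0)
  expect_equal(similarity_distance(c(1, 2), c(2, 3)), 1 / 3)
  expect_identical(similarity_distance(numeric(0), numeric(0)), 1)
  # symmetry
  for (i in 1:10) {
    set.seed(i)
    a <- sample(1:8, 4); b <- sample(1:8, 4)
    expect_identical(similarity_distance(a, b), similarity_distance(b, a))
  }
})

test_that("identity distance measures loss of the unperturbed set and is asymmetric", {
  expect_identical(identity_distance(c(1, 2), c(1, 2)), 0)
  expect_identical(identity_distance(c(1, 2), c(3, 4)), 1)
  expect_equal(identity_distance(c(1, 2), c(2, 3)), 0.5)
  expect_error(identity_distance(numeric(0), c(1)), "nonempty")
  expect_false(identity_distance(c(1, 2, 3), c(1)) ==
                 identity_distance(c(1), c(1, 2, 3)))
})

test_that("toggle-switch knockout sensitivity matches hand enumeration", {
  tog <- motif("toggle")
  cfg <- attractor_search_config(methods = c("sat", "async"),
                                 n_runs = 50L, seed = 1)
  row <- knockout_sensitivity(tog, "A", "knockout", cfg)
  # unperturbed attractor states {(1,0),(0,1)} project on B to {0,1};
  # knockout of A leaves only B=1: d_id = 1 - 1/2
  expect_equal(row$d_id, 0.5)
  expect_equal(row$d_sim, 0.5)
})

test_that("clamping a node to its constant attractor value has zero sensitivity", {
  for (seed in c(3, 9, 16)) {
    bn <- rbn(seed, n = 4L + seed %% 4L)
    cfg <- attractor_search_config(methods = "exhaustive")
    states <- boolpath:::attractor_state_union(bn, cfg)   # bit-string keys
    for (i in seq_along(bn$nodes)) {
      bits <- unique(substr(states, i, i))
      if (length(bits) != 1L) next      # node varies across attractors
      mode <- if (bits == "1") "overexpression" else "knockout"
      row <- knockout_sensitivity(bn, bn$nodes[i], mode, cfg)
      expect_identical(row$d_id, 0)
    }
  }
})

test_that("sensitivity is invariant under node relabeling", {
  bn <- boolean_network(list(A = "A", B = "A & !C", C = "C"))
  prm <- boolean_network(list(C = "C", A = "A", B = "A & !C"))
  cfg <- attractor_search_config(methods = "exhaustive")
  for (v in c("A", "C"))
    expect_equal(knockout_sensitivity(bn, v, "knockout", cfg)$d_id,
                 knockout_sensitivity(prm, v, "knockout", cfg)$d_id)
})

test_that("sensitivity report covers each (node, mode) pair once", {
  bn <- motif("cascade_phenotype")
  rep <- sensitivity_report(bn, search = attractor_search_config(
    methods = c("sat", "async"), n_runs = 60L, seed = 2))
  expect_identical(nrow(rep), 2L * length(bn$nodes))
  expect_false(any(duplicated(rep[, c("node", "mode")])))
  expect_true(all(rep$d_sim >= 0 & rep$d_sim <= 1))
  expect_true(all(rep$d_id >= 0 & rep$d_id <= 1))
})

test_that("target prioritization ranks joint extremes first and last", {
  cent <- data.frame(node = letters[1:5],
                     betweenness = c(10, 8, 5, 2, 0))
  sens <- data.frame(node = letters[1:5], mode = "knockout",
                     sensitivity = c(0.9, 0.1, 0.5, 0.2, 0))
  pri <- prioritize_targets(cent, sens)
  expect_identical(pri$node[1], "a")     # maximal in both
  expect_identical(pri$node[5], "e")     # zero in both
  expect_identical(pri$rank, 1:5)
  # centrality-sensitivity inversion is visible as negative rank correlation
  inv <- data.frame(node = letters[1:5], mode = "knockout",
                    sensitivity = c(0.05, 0.1, 0.3, 0.6, 0.9))
  expect_lt(stats::cor(cent$betweenness, inv$sensitivity,
                       method = "spearman"), 0)
  top <- attr(prioritize_targets(cent, inv, q = 0.25), "top_intersection")
  expect_length(top, 0L)                 # disjoint top sets under inversion
})
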