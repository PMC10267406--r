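test_that("exhaustive search on the toggle switch finds all attractors and basins", {
  atts <- exhaustive_sync(motif("toggle"))
  kinds <- vapply(atts, `[[`, character(1), "kind")
  expect_setequal(kinds, c("steady", "cycle"))
  expect_identical(sum(vapply(atts, `[[`, numeric(1), "basin_size")), 4)
  cyc <- atts[[which(kinds == "cycle")]]
  expect_identical(sort(cyc$states), c(0, 3))       # {(0,0),(1,1)}
  steadies <- sort(unlist(lapply(atts[kinds == "steady"], `[[`, "states")))
  expect_identical(steadies, c(1, 2))               # (1,0),(0,1)
})

test_that("a constant network has one steady state with the full basin", {
  bn <- boolean_network(list(A = "1", B = "0", C = "1"))
  atts <- exhaustive_sync(bn)
  expect_length(atts, 1L)
  expect_equal(atts[[1]]$basin_size, 2^3)
  expect_identical(atts[[1]]$states, 5)             # A=1,B=0,C=1
})

test_that("exhaustive basins partition the state space on random networks", {
  for (seed in 1:15) {
    bn <- rbn(seed, n = 4L + seed %% 6L)
    atts <- exhaustive_sync(bn)
    expect_identical(sum(vapply(atts, `[[`, numeric(1), "basin_size")),
                     2^length(bn$nodes))
    states <- unlist(lapply(atts, `[[`, "states"))
    expect_false(any(duplicated(states)))
    # every attractor state is genuinely periodic under sync_step
    for (a in atts) {
      nxt <- boolpath:::bn_sync_image(bn, a$states)
      expect_setequal(nxt, a$states)
    }
  }
})

test_that("SAT fixed points equal the brute-force fixed points", {
  expect_identical(sat_steady_states(motif("toggle")), c(1, 2))
  expect_identical(sat_steady_states(boolean_network(list(A = "!A"))),
                   numeric(0))
  for (seed in 1:25) {
    bn <- rbn(seed)
    codes <- as.numeric(seq(0, 2^length(bn$nodes) - 1))
    brute <- codes[boolpath:::bn_sync_image(bn, codes) == codes]
    expect_identical(sat_steady_states(bn), brute)
  }
})

test_that("SAT cycle search finds exact-length synchronous cycles", {
  neg <- boolean_network(list(A = "!A"))
  c2 <- sat_cycles(neg, 2L)
  expect_length(c2, 1L)
  expect_identical(sort(c2[[1]]$states), c(0, 1))

  tog <- sat_cycles(motif("toggle"), 2L)
  expect_length(tog, 1L)
  expect_identical(sort(tog[[1]]$states), c(0, 3))

  for (seed in c(4, 8, 15)) {
    bn <- rbn(seed, n = 5L + seed %% 4L)
    ex <- exhaustive_sync(bn)
    for (L in 2:4) {
      want <- Filter(function(a) a$kind == "cycle" && length(a$states) == L, ex)
      got <- sat_cycles(bn, L)
      expect_setequal(
        vapply(got, function(a) boolpath:::attractor_key(a$states),
               character(1)),
        vapply(want, function(a) boolpath:::attractor_key(a$states),
               character(1)))
    }
  }
})

test_that("heuristic restarts find what they can and never invent attractors", {
  tog <- motif("toggle")
  atts <- heuristic_search(tog, n_starts = 100L, seed = 1)
  expect_length(atts, 3L)                     # all three basins sampled
  one <- heuristic_search(boolean_network(list(A = "A", B = "A")),
                          n_starts = 1L, seed = 2)
  expect_length(one, 1L)
  for (seed in c(3, 11)) {
    bn <- rbn(seed)
    truth <- vapply(exhaustive_sync(bn), function(a)
      boolpath:::attractor_key(a$states), character(1))
    got <- vapply(heuristic_search(bn, n_starts = 40L, seed = seed),
                  function(a) boolpath:::attractor_key(a$states),
                  character(1))
    expect_true(all(got %in% truth))
  }
})

test_that("async walks find steady states and certify complex attractors", {
  tog <- async_random_walk(motif("toggle"), n_runs = 50L, seed = 5)
  expect_setequal(unlist(lapply(tog, `[[`, "states")), c(1, 2))
  expect_true(all(vapply(tog, `[[`, character(1), "kind") == "steady"))

  rep3 <- async_random_walk(motif("repressilator"), n_runs = 100L, seed = 6)
  expect_length(rep3, 1L)
  expect_identical(rep3[[1]]$kind, "complex")
  expect_length(rep3[[1]]$states, 6L)         # all states but the two fixed... none: 2^3 - 2 antipodal
  expect_true(rep3[[1]]$certified)
  # closure: no asynchronous edge leaves a certified complex attractor
  for (cd in rep3[[1]]$states)
    expect_true(all(boolpath:::async_successor_codes(motif("repressilator"),
                                                     cd) %in%
                      rep3[[1]]$states))
})

test_that("async walk results match the full asynchronous STG ground truth", {
  for (seed in c(1, 7, 12)) {
    bn <- rbn(seed, n = 3L + seed %% 5L)
    truth <- boolpath:::stg_terminal_sccs(build_stg(bn, "asynchronous"))
    got <- async_random_walk(bn, n_runs = 2^length(bn$nodes), seed = seed)
    expect_setequal(
      vapply(got, function(a) boolpath:::attractor_key(a$states),
             character(1)),
      vapply(truth, boolpath:::attractor_key, character(1)))
  }
})

test_that("decomposition composes independent blocks exactly and flags failures", {
  two <- boolean_network(list(A = "!B", B = "!A", C = "!D", D = "!C"))
  atts <- decomposition_search(two)
  steadies <- Filter(function(a) a$kind == "steady", atts)
  expect_length(steadies, 4L)
  expect_true(all(vapply(steadies, `[[`, logical(1), "verified")))

  chain <- boolean_network(list(A = "A", B = "A", C = "B"))
  expect_setequal(
    vapply(decomposition_search(chain), function(a)
      boolpath:::attractor_key(a$states), character(1)),
    vapply(exhaustive_sync(chain), function(a)
      boolpath:::attractor_key(a$states), character(1)))

  # inter-block synchrony broken by freezing: candidate flagged unverified
  lagged <- boolean_network(list(A = "!A", B = "A"))
  atts <- decomposition_search(lagged)
  expect_true(any(!vapply(atts, `[[`, logical(1), "verified")))
})

test_that("verified decomposition candidates are exactly the true attractors", {
  for (seed in c(2, 6, 14)) {
    bn <- rbn(seed, n = 4L + seed %% 5L)
    truth <- vapply(exhaustive_sync(bn), function(a)
      boolpath:::attractor_key(a$states), character(1))
    for (a in decomposition_search(bn)) {
      key <- boolpath:::attractor_key(a$states)
      expect_identical(a$verified, key %in% truth)
    }
  }
})
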