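test_that("synchronous step updates all nodes simultaneously", {
  toggle <- motif("toggle")
  expect_identical(sync_step(toggle, c(A = TRUE, B = FALSE)),
                   c(A = TRUE, B = FALSE))          # fixed point
  expect_identical(sync_step(toggle, c(A = TRUE, B = TRUE)),
                   c(A = FALSE, B = FALSE))         # 2-cycle partner
  neg <- boolean_network(list(A = "!A"))
  expect_identical(unname(sync_step(neg, c(A = FALSE))), TRUE)
  expect_identical(unname(sync_step(neg, sync_step(neg, c(A = FALSE)))),
                   FALSE)                           # period-2 oscillation
})

test_that("synchronous iteration matches direct expression evaluation", {
  bn <- rbn(17, n = 8L)
  st <- all_states(bn)
  set.seed(1)
  s <- st[sample(nrow(st), 1L), ]
  for (i in 1:50) {
    expect_identical(unname(sync_step(bn, s)),
                     unname(oracle_eval_state(bn, s)))
    s <- sync_step(bn, s)
  }
})

test_that("asynchronous step touches only the chosen node and is idempotent at target", {
  toggle <- motif("toggle")
  expect_identical(async_step(toggle, c(A = TRUE, B = TRUE), "A"),
                   c(A = FALSE, B = TRUE))
  # node already at its target value: state unchanged
  expect_identical(async_step(toggle, c(A = TRUE, B = FALSE), "A"),
                   c(A = TRUE, B = FALSE))
  expect_error(async_step(toggle, c(A = TRUE, B = FALSE), "Z"), "unknown")
})

test_that("asynchronous successors equal the definition on every state", {
  for (seed in c(2, 9, 21)) {
    bn <- rbn(seed, n = 3L + seed %% 5L)
    st <- all_states(bn)
    for (r in seq_len(nrow(st))) {
      want <- sort(vapply(oracle_async_succ(bn, st[r, ]), state_code,
                          numeric(1)))
      got <- sort(boolpath:::async_successor_codes(bn, r - 1))
      expect_identical(got, want)
    }
  }
})

test_that("toggle-switch state-transition graphs have the textbook shape", {
  toggle <- motif("toggle")
  sync <- build_stg(toggle, "synchronous")
  expect_length(sync$states, 4L)
  expect_identical(nrow(sync$edges), 4L)            # out-degree exactly 1
  fixed <- sync$edges$from[sync$edges$from == sync$edges$to]
  expect_identical(sort(fixed), c(1, 2))            # (1,0) and (0,1)
  # the 2-cycle {(0,0),(1,1)}
  expect_true(all(c(3, 0) %in% sync$edges$to[sync$edges$from %in% c(0, 3)]))

  async <- build_stg(toggle, "asynchronous")
  out_deg <- table(factor(async$edges$from, levels = 0:3))
  expect_identical(as.integer(out_deg[c("1", "2")]), c(0L, 0L))  # steady sinks
  expect_true(all(as.integer(out_deg) <= 2L))
})

test_that("self-activation gives two fixed points in the synchronous STG", {
  bn <- boolean_network(list(A = "A"))
  stg <- build_stg(bn, "synchronous")
  expect_identical(stg$edges$from, stg$edges$to)
})

test_that("reachable-set STG construction agrees with full enumeration", {
  bn <- rbn(5, n = 6L)
  full <- build_stg(bn, "asynchronous")
  part <- build_stg(bn, "asynchronous", init = seq(0, 2^6 - 1))
  o <- function(e) e[order(e$from, e$to), ]
  expect_identical(o(part$edges), o(full$edges), ignore_attr = TRUE)
})

test_that("CTMC single-node relaxation follows the exponential law", {
  bn <- boolean_network(list(A = "1"))
  est <- simulate_ctmc(bn, ctmc_config(n_traj = 4000L, max_time = 2,
                                       bin_width = 0.5, seed = 11,
                                       init = c(A = 0)))
  theo <- 1 - exp(-est$time)
  dev <- abs(est$prob[, "A"] - theo)
  expect_true(all(dev[-1] <= 3 * est$se[-1, "A"]))
})

test_that("absorbing toggle states capture all mass at long times", {
  toggle <- motif("toggle")
  est <- simulate_ctmc(toggle, ctmc_config(n_traj = 2000L, max_time = 30,
                                           bin_width = 10, seed = 3))
  fp <- est$final_patterns
  absorbed <- sum(fp$prob[fp$pattern %in% c("10", "01")])
  expect_gte(absorbed, 1 - 3 * sqrt(0.5 / 2000))
})

test_that("a steady-state initial condition stays constant in time", {
  toggle <- motif("toggle")
  est <- simulate_ctmc(toggle, ctmc_config(n_traj = 200L, max_time = 5,
                                           bin_width = 1, seed = 4,
                                           init = c(A = 1, B = 0)))
  expect_true(all(est$prob[, "A"] == 1))
  expect_true(all(est$prob[, "B"] == 0))
})

test_that("the exact rate matrix is a proper generator matching eligible flips", {
  bn <- rbn(13, n = 5L)
  Q <- ctmc_rate_matrix(bn)
  expect_equal(rowSums(Q), rep(0, 2^5), tolerance = 1e-12)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
  st <- all_states(bn)
  for (r in sample(1:32, 8)) {
    succ <- vapply(oracle_async_succ(bn, st[r, ]), state_code, numeric(1))
    expect_setequal(which(Q[r, ] > 0) - 1, succ)
  }
})

test_that("identical seeds reproduce the whole estimate", {
  bn <- motif("cascade_phenotype")
  cfg <- ctmc_config(n_traj = 300L, max_time = 5, bin_width = 1, seed = 77)
  a <- simulate_ctmc(bn, cfg)
  b <- simulate_ctmc(bn, cfg)
  expect_identical(a$prob, b$prob)
  expect_identical(a$final_patterns, b$final_patterns)
})
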