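# Continuous-time stochastic Boolean simulation. The model is a
# continuous-time Markov chain on the 2^n states: from state s, every node i
# whose Boolean function disagrees with its current value is an eligible
# flip, with propensity `rate_up[i]` (flipping to ON) or `rate_down[i]`
# (flipping to OFF). Jump times are exponential in the total propensity and
# the flipped node is chosen proportionally — a Gillespie random walk. States
# with no eligible flip are absorbing (asynchronous steady states).

#' Configuration for the stochastic simulator
#'
#' @param n_traj number of Monte-Carlo trajectories (>= 1).
#' @param max_time simulated time horizon (> 0).
#' @param bin_width width of the time grid on which occupancies are
#'   estimated (> 0).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param init initial condition: a named logical/0-1 vector fixing every
#'   node, or a named numeric vector of per-node ON-probabilities (nodes not
#'   named start at probability 0.5), or `NULL` (all nodes Bernoulli(0.5)).
#' @param rate_up,rate_down flip rates towards ON / towards OFF; scalar or
#'   named per-node vectors of positive reals (default 1).
#' @return a list of class `ctmc_config`.
#' @export
ctmc_config <- function(n_traj = 1000L, max_time = 10, bin_width = 0.5,
                        seed = NULL, init = NULL, rate_up = 1,
                        rate_down = 1) {
  stopifnot(n_traj >= 1L, max_time > 0, bin_width > 0,
            all(rate_up > 0), all(rate_down > 0))
  structure(list(n_traj = as.integer(n_traj), max_time = max_time,
                 bin_width = bin_width, seed = seed, init = init,
                 rate_up = rate_up, rate_down = rate_down),
            class = "ctmc_config")
}

resolve_rates <- function(rate, nodes) {
  if (length(rate) == 1L && is.null(names(rate)))
    return(stats::setNames(rep(as.numeric(rate), length(nodes)), nodes))
  out <- stats::setNames(rep(1, length(nodes)), nodes)
  unknown <- setdiff(names(rate), nodes)
  if (length(unknown)) stop("rates name unknown node(s): ",
                            paste(unknown, collapse = ", "))
  out[names(rate)] <- as.numeric(rate)
  out
}

resolve_init_probs <- function(init, nodes) {
  p <- stats::setNames(rep(0.5, length(nodes)), nodes)
  if (is.null(init)) return(p)
  if (is.logical(init) || all(init %in% c(0, 1))) {
    if (is.null(names(init)) && length(init) == length(nodes))
      names(init) <- nodes
  }
  if (is.null(names(init)))
    stop("'init' must be named (or a full-length 0/1 vector)")
  unknown <- setdiff(names(init), nodes)
  if (length(unknown)) stop("'init' names unknown node(s): ",
                            paste(unknown, collapse = ", "))
  vals <- as.numeric(init)
  if (any(vals < 0 | vals > 1)) stop("initial probabilities must lie in [0,1]")
  p[names(init)] <- vals
  p
}

#' Simulate the continuous-time Markov Boolean dynamics
#'
#' Monte-Carlo estimate of the per-node ON-probability on a regular time
#' grid, plus the occupancy of each distinct state pattern at the final
#' time. Fully reproducible from `config$seed`.
#'
#' @param network a `boolean_network`.
#' @param config a [ctmc_config()].
#' @return an object of class `trajectory_estimate`: list with `time`
#'   (grid), `prob` (grid x node matrix of ON-probability estimates), `se`
#'   (matching Monte-Carlo standard errors), `final_patterns` (data.frame
#'   `pattern` (bit-string in node order), `count`, `prob`, `se`),
#'   `n_traj`, and `seed`.
#' @export
simulate_ctmc <- function(network, config = ctmc_config()) {
  stopifnot(inherits(network, "boolean_network"),
            inherits(config, "ctmc_config"))
  nodes <- network$nodes
  n <- length(nodes)
  if (!is.null(config$seed)) set.seed(config$seed)
  up <- resolve_rates(config$rate_up, nodes)
  down <- resolve_rates(config$rate_down, nodes)
  p0 <- resolve_init_probs(config$init, nodes)
  grid <- seq(0, config$max_time, by = config$bin_width)
  G <- length(grid)
  counts <- matrix(0, nrow = G, ncol = n, dimnames = list(NULL, nodes))
  finals <- character(config$n_traj)

  for (tr in seq_len(config$n_traj)) {
    state <- stats::runif(n) < p0
    t_now <- 0
    gi <- 1L
    repeat {
      vals <- bn_node_values(network, state)
      flips <- which(vals != state)
      if (!length(flips)) {
        if (gi <= G) {
          counts[gi:G, ] <- counts[gi:G, , drop = FALSE] +
            rep(as.numeric(state), each = G - gi + 1L)
          gi <- G + 1L
        }
        break
      }
      prop <- ifelse(vals[flips], up[flips], down[flips])
      t_next <- t_now + stats::rexp(1L, sum(prop))
      while (gi <= G && grid[gi] < t_next) {
        counts[gi, ] <- counts[gi, ] + state
        gi <- gi + 1L
      }
      if (gi > G) break
      pick <- if (length(flips) == 1L) flips else
        flips[sample.int(length(flips), 1L, prob = prop)]
      state[pick] <- vals[pick]
      t_now <- t_next
    }
    finals[tr] <- paste(as.integer(state), collapse = "")
  }
  prob <- counts / config$n_traj
  se <- sqrt(prob * (1 - prob) / config$n_traj)
  tab <- sort(table(finals), decreasing = TRUE)
  fp <- data.frame(pattern = names(tab), count = as.integer(tab),
                   prob = as.integer(tab) / config$n_traj,
                   stringsAsFactors = FALSE)
  fp$se <- sqrt(fp$prob * (1 - fp$prob) / config$n_traj)
  structure(list(time = grid, prob = prob, se = se, final_patterns = fp,
                 n_traj = config$n_traj, seed = config$seed, nodes = nodes),
            class = "trajectory_estimate")
}

#' @export
print.trajectory_estimate <- function(x, ...) {
  cat("CTMC trajectory estimate:", x$n_traj, "trajectories,",
      length(x$time), "time bins,", length(x$nodes), "nodes\n")
  tf <- x$prob[nrow(x$prob), ]
  cat("final-time ON probabilities:\n")
  print(round(tf, 3))
  invisible(x)
}

#' Exact transition-rate matrix of the Boolean CTMC
#'
#' Builds the full `2^n x 2^n` generator of the chain simulated by
#' [simulate_ctmc()] (rows = source states in code order `0..2^n-1`).
#' Intended for validation on small networks.
#'
#' @param network a `boolean_network` (`n <= 12`).
#' @param rate_up,rate_down as in [ctmc_config()].
#' @return a dense numeric matrix Q with rows summing to zero.
#' @export
ctmc_rate_matrix <- function(network, rate_up = 1, rate_down = 1) {
  n <- length(network$nodes)
  if (n > 12L) stop("rate matrix limited to n <= 12 nodes")
  up <- resolve_rates(rate_up, network$nodes)
  down <- resolve_rates(rate_down, network$nodes)
  N <- 2^n
  Q <- matrix(0, N, N)
  for (code in 0:(N - 1)) {
    bits <- ((code %/% 2^(0:(n - 1))) %% 2) == 1
    vals <- bn_node_values(network, bits)
    flips <- which(vals != bits)
    for (i in flips) {
      tgt <- code + (1 - 2 * as.numeric(bits[i])) * 2^(i - 1)
      r <- if (vals[i]) up[i] else down[i]
      Q[code + 1, tgt + 1] <- Q[code + 1, tgt + 1] + r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}
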