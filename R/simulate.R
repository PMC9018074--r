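#' Simulation settings for the stochastic engine
#'
#' @param network a [boolean_network()].
#' @param n_trajectories ensemble size (default 5000).
#' @param max_time simulation horizon, model-time units. Long enough
#'   horizons reach the asymptotic regime; a convergence warning is
#'   issued when the last two windows still differ by more than 0.01 in
#'   any tracked marginal.
#' @param time_tick width of the probability windows, model-time units.
#' @param seed root seed; all randomness (initial-state sampling,
#'   waiting times, node choice, drug-mixture variant choice) flows
#'   from it through per-trajectory substreams.
#' @param p0 named per-node Bernoulli probabilities of starting ON.
#'   Defaults: 0 for input nodes, 0.5 for all others. Partial vectors
#'   override the defaults for the named nodes only.
#' @param joint optional list of joint initial-condition assignments,
#'   each `list(nodes=, states=list of 0/1 vectors, probs=)`; joint
#'   assignments override the per-node marginals for their nodes.
#' @param tracked nodes whose window probabilities are recorded;
#'   default the network's outputs (all nodes if none declared).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(network, n_trajectories = 5000L,
                              max_time = 20, time_tick = 1,
                              seed = 42L, p0 = NULL, joint = list(),
                              tracked = NULL) {
  base_p0 <- stats::setNames(rep(0.5, length(network$nodes)), network$nodes)
  base_p0[network$inputs] <- 0
  if (!is.null(p0)) {
    if (is.null(names(p0))) stop("p0 must be named", call. = FALSE)
    if (length(bad <- setdiff(names(p0), network$nodes)))
      stop("p0 names unknown: ", paste(bad, collapse = ", "), call. = FALSE)
    base_p0[names(p0)] <- p0
  }
  if (is.null(tracked))
    tracked <- if (length(network$outputs)) network$outputs else network$nodes
  cfg <- structure(list(
    n_trajectories = as.integer(n_trajectories),
    max_time = max_time,
    time_tick = time_tick,
    seed = as.integer(seed),
    p0 = base_p0,
    joint = joint,
    tracked = tracked
  ), class = "simulation_config")
  validate_config(cfg, network)
  cfg
}

validate_config <- function(config, network) {
  if (config$n_trajectories < 1L)
    stop("n_trajectories must be positive", call. = FALSE)
  if (config$time_tick > config$max_time)
    stop("time_tick must not exceed max_time", call. = FALSE)
  if (any(config$p0 < 0 | config$p0 > 1))
    stop("initial probabilities must lie in [0,1]", call. = FALSE)
  if (length(bad <- setdiff(config$tracked, network$nodes)))
    stop("tracked nodes unknown: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (ja in config$joint) {
    if (length(bad <- setdiff(ja$nodes, network$nodes)))
      stop("joint istate references unknown node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (abs(sum(ja$probs) - 1) > 1e-9)
      stop("joint istate probabilities must sum to 1", call. = FALSE)
    if (any(vapply(ja$states, length, integer(1)) != length(ja$nodes)))
      stop("joint istate state vectors must match the node list",
           call. = FALSE)
  }
  invisible(config)
}

# compile a network (+ per-variant overrides) into the C++ engine's
# variant representation
compile_variant <- function(network, config) {
  idx <- stats::setNames(seq_along(network$nodes), network$nodes)
  joint <- lapply(config$joint, function(ja) {
    list(idx0 = as.integer(idx[ja$nodes] - 1L),
         states = lapply(ja$states, as.integer),
         probs = as.numeric(ja$probs))
  })
  list(code = lapply(network$rules, compile_expr, node_index = idx),
       k_up = unname(network$k_up),
       k_down = unname(network$k_down),
       p0 = unname(config$p0[network$nodes]),
       joint = joint)
}

#' Eligible stochastic transitions from a state
#'
#' Node `i` can flip up at rate `k_up[i]` when it is OFF and its rule
#' evaluates to 1, and down at rate `k_down[i]` when it is ON and its
#' rule evaluates to 0. An empty result means the state is a fixed
#' point of the dynamics.
#'
#' @param network a [boolean_network()].
#' @param state named 0/1 vector over all nodes.
#' @return data.frame with columns `node`, `rate`.
#' @export
eligible_transitions <- function(network, state) {
  if (!setequal(names(state), network$nodes))
    stop("state must cover exactly the network's nodes", call. = FALSE)
  nodes <- character(0); rates <- numeric(0)
  for (nd in network$nodes) {
    target <- evaluate_rule(network$rules[[nd]], state)
    if (state[[nd]] == 0L && target == 1L) {
      nodes <- c(nodes, nd); rates <- c(rates, network$k_up[[nd]])
    } else if (state[[nd]] == 1L && target == 0L) {
      nodes <- c(nodes, nd); rates <- c(rates, network$k_down[[nd]])
    }
  }
  data.frame(node = nodes, rate = rates, stringsAsFactors = FALSE)
}

#' Simulate a single Gillespie trajectory
#'
#' Waiting times are exponential in the total eligible rate; the
#' flipping node is drawn proportionally to its rate. On reaching a
#' fixed point the state holds until `max_time`.
#'
#' @param network a [boolean_network()].
#' @param init named 0/1 initial state.
#' @param config a [simulation_config()] (supplies `max_time`).
#' @param seed trajectory seed (defaults to the config seed).
#' @return data.frame of flip events: `time`, `node`, `value`.
#' @export
run_trajectory <- function(network, init, config, seed = config$seed) {
  if (!setequal(names(init), network$nodes))
    stop("init must cover exactly the network's nodes", call. = FALSE)
  v <- compile_variant(network, config)
  ev <- run_trajectory_cpp(v, as.integer(init[network$nodes]),
                           config$max_time, as.numeric(seed))
  ev$node <- network$nodes[ev$node]
  ev
}

joint_state_labels <- function(tracked) {
  k <- length(tracked)
  keys <- 0:(2^k - 1L)
  vapply(keys, function(key) {
    bits <- bitwAnd(bitwShiftR(key, seq_len(k) - 1L), 1L)
    paste(ifelse(bits == 1L, tracked, paste0("!", tracked)), collapse = " ")
  }, character(1))
}

#' Simulate a trajectory ensemble
#'
#' Runs `config$n_trajectories` Gillespie trajectories and reports, per
#' time window, the trajectory-averaged fraction of time each tracked
#' node is ON (marginals) and each joint tracked-state is occupied.
#' The asymptotic phenotype score of a node is its last-window
#' marginal.
#'
#' @param network a [boolean_network()].
#' @param config a [simulation_config()].
#' @param variants internal: list of `list(network=, config=, prob=)`
#'   mixture components used by the drug machinery; the default is the
#'   single supplied network.
#' @param warn_convergence warn when the last two windows differ by
#'   more than 0.01 in any tracked marginal.
#' @return an object of class `ensemble_result` with elements
#'   `windows` (data.frame `start`,`end`), `marginal` (windows x
#'   tracked matrix), `joint` (windows x joint-state matrix, tracked
#'   sets of up to 12 nodes), `variant_counts`, `tracked`, `outputs`.
#' @export
simulate_ensemble <- function(network, config, variants = NULL,
                              warn_convergence = TRUE) {
  if (is.null(variants))
    variants <- list(list(network = network, config = config, prob = 1))
  probs <- vapply(variants, `[[`, numeric(1), "prob")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("variant probabilities must sum to 1", call. = FALSE)
  compiled <- lapply(variants, function(v)
    compile_variant(v$network, v$config))
  tracked <- config$tracked
  idx <- stats::setNames(seq_along(network$nodes), network$nodes)
  res <- sim_ensemble_cpp(compiled, probs, length(network$nodes),
                          config$n_trajectories, config$max_time,
                          config$time_tick,
                          as.integer(idx[tracked] - 1L),
                          as.numeric(config$seed),
                          TRUE)
  n_win <- nrow(res$marginal)
  starts <- (seq_len(n_win) - 1L) * config$time_tick
  ends <- pmin(starts + config$time_tick, config$max_time)
  marginal <- res$marginal
  dimnames(marginal) <- list(NULL, tracked)
  joint <- NULL
  if (!is.null(res$joint)) {
    joint <- res$joint
    dimnames(joint) <- list(NULL, joint_state_labels(tracked))
  }
  if (warn_convergence && n_win >= 2L) {
    drift <- max(abs(marginal[n_win, ] - marginal[n_win - 1L, ]))
    if (drift > 0.01)
      warning(sprintf(paste0("ensemble may not have reached the asymptotic ",
                             "regime: last two windows differ by %.3f"),
                      drift), call. = FALSE)
  }
  structure(list(
    windows = data.frame(start = starts, end = ends),
    tracked = tracked,
    outputs = network$outputs,
    marginal = marginal,
    joint = joint,
    variant_counts = res$variant_counts,
    config = config
  ), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble result: %d windows, tracked: %s\n",
              nrow(x$windows), paste(x$tracked, collapse = ", ")))
  cat("Asymptotic (last-window) marginals:\n")
  print(round(x$marginal[nrow(x$marginal), ], 4))
  invisible(x)
}

#' Asymptotic phenotype scores
#'
#' Last-window ON-probabilities of the output nodes (or of all tracked
#' nodes when the network declares no outputs).
#'
#' @param result an [simulate_ensemble()] result.
#' @return named numeric vector of probabilities.
#' @export
phenotype_scores <- function(result) {
  if (nrow(result$windows) < 1L)
    stop("result has no windows", call. = FALSE)
  last <- result$marginal[nrow(result$marginal), , drop = TRUE]
  outs <- intersect(result$outputs, result$tracked)
  if (length(outs)) last[outs] else last
}

#' Tidy long-format view of an ensemble result
#'
#' @param x an `ensemble_result`.
#' @param row.names,optional,... unused, for generic consistency.
#' @return data.frame with `window`, `start`, `end`, `entity`,
#'   `probability` (marginals, then joint states).
#' @export
as.data.frame.ensemble_result <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  n_win <- nrow(x$windows)
  m <- data.frame(
    window = rep(seq_len(n_win), times = ncol(x$marginal)),
    start = rep(x$windows$start, times = ncol(x$marginal)),
    end = rep(x$windows$end, times = ncol(x$marginal)),
    kind = "marginal",
    entity = rep(colnames(x$marginal), each = n_win),
    probability = as.vector(x$marginal),
    stringsAsFactors = FALSE)
  if (!is.null(x$joint)) {
    j <- data.frame(
      window = rep(seq_len(n_win), times = ncol(x$joint)),
      start = rep(x$windows$start, times = ncol(x$joint)),
      end = rep(x$windows$end, times = ncol(x$joint)),
      kind = "joint",
      entity = rep(colnames(x$joint), each = n_win),
      probability = as.vector(x$joint),
      stringsAsFactors = FALSE)
    m <- rbind(m, j)
  }
  m
}

# ---------------------------------------------------------------------------
# Exact master-equation oracle for small models

#' Exact window probabilities by master-equation integration
#'
#' Integrates the Kolmogorov forward equation of the continuous-time
#' Markov chain on the full state space (feasible up to ~10 nodes) and
#' returns time-averaged window probabilities in the same layout as
#' [simulate_ensemble()]. This is the independent reference the
#' stochastic engine is validated against.
#'
#' @param network a [boolean_network()] with at most `max_nodes` nodes.
#' @param config a [simulation_config()].
#' @param subdiv quadrature points per window for the time average.
#' @param max_nodes guard on state-space size.
#' @return list with `windows`, `marginal`, `joint` as in
#'   [simulate_ensemble()].
#' @export
master_equation_windows <- function(network, config, subdiv = 20L,
                                    max_nodes = 10L) {
  n <- length(network$nodes)
  if (n > max_nodes)
    stop("master-equation oracle limited to ", max_nodes, " nodes",
         call. = FALSE)
  ns <- 2L^n
  states <- as.matrix(expand.grid(rep(list(0:1), n)))[, seq_len(n),
                                                      drop = FALSE]
  colnames(states) <- network$nodes
  # generator matrix Q: rate s -> s' for single-node flips
  Q <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    st <- stats::setNames(states[s, ], network$nodes)
    el <- eligible_transitions(network, st)
    if (nrow(el) == 0L) next
    for (r in seq_len(nrow(el))) {
      nd <- el$node[r]
      st2 <- st
      st2[[nd]] <- 1L - st2[[nd]]
      s2 <- 1L + sum(st2 * 2L^(seq_len(n) - 1L))
      Q[s, s2] <- Q[s, s2] + el$rate[r]
    }
  }
  diag(Q) <- -rowSums(Q)
  # initial distribution: independent Bernoulli marginals for nodes not
  # covered by a joint assignment, times each assignment's probability
  jnodes <- unlist(lapply(config$joint, `[[`, "nodes"))
  free <- setdiff(seq_len(n), match(jnodes, network$nodes))
  marg_p <- config$p0[network$nodes]
  p0 <- vapply(seq_len(ns), function(s) {
    pf <- prod(ifelse(states[s, free] == 1L, marg_p[free],
                      1 - marg_p[free]))
    for (ja in config$joint) {
      ji <- match(ja$nodes, network$nodes)
      pa <- 0
      for (k in seq_along(ja$probs)) {
        if (all(states[s, ji] == ja$states[[k]])) pa <- pa + ja$probs[k]
      }
      pf <- pf * pa
    }
    pf
  }, numeric(1))
  p0 <- p0 / sum(p0)
  n_win <- as.integer(ceiling(config$max_time / config$time_tick - 1e-9))
  times <- sort(unique(c(outer(
    (seq_len(n_win) - 1L) * config$time_tick,
    seq(0, config$time_tick, length.out = subdiv + 1L), `+`))))
  times <- times[times <= config$max_time + 1e-12]
  sol <- deSolve::ode(y = p0, times = times,
                      func = function(t, y, parms) list(as.vector(y %*% Q)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  pt <- sol[, -1L, drop = FALSE]
  tracked <- config$tracked
  ti <- match(tracked, network$nodes)
  starts <- (seq_len(n_win) - 1L) * config$time_tick
  ends <- pmin(starts + config$time_tick, config$max_time)
  marginal <- matrix(0, n_win, length(tracked),
                     dimnames = list(NULL, tracked))
  jlab <- joint_state_labels(tracked)
  joint <- matrix(0, n_win, length(jlab), dimnames = list(NULL, jlab))
  jkey <- apply(states[, ti, drop = FALSE], 1L, function(row)
    sum(row * 2L^(seq_along(ti) - 1L))) + 1L
  for (w in seq_len(n_win)) {
    sel <- which(sol[, 1L] >= starts[w] - 1e-12 & sol[, 1L] <= ends[w] + 1e-12)
    tw <- sol[sel, 1L]
    pw <- pt[sel, , drop = FALSE]
    wts <- diff(tw)
    avg <- colSums((pw[-1L, , drop = FALSE] +
                    pw[-length(sel), , drop = FALSE]) / 2 * wts) /
           (ends[w] - starts[w])
    for (b in seq_along(ti))
      marginal[w, b] <- sum(avg[states[, ti[b]] == 1L])
    for (k in seq_along(jlab))
      joint[w, k] <- sum(avg[jkey == k])
  }
  list(windows = data.frame(start = starts, end = ends),
       marginal = marginal, joint = joint)
}
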