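test_that("eligible transitions list exactly the permitted flips", {
  net <- boolean_network(list(A = "1"), k_up = c(A = 2))
  el <- eligible_transitions(net, c(A = 0))
  expect_equal(el$node, "A")
  expect_equal(el$rate, 2)
  # ON node whose rule is 0 flips down at k_down
  net2 <- boolean_network(list(A = "0"), k_down = c(A = 0.5))
  el2 <- eligible_transitions(net2, c(A = 1))
  expect_equal(el2$rate, 0.5)
  # fixed point: no transitions
  mt <- make_toy_model("mini_tumour")$network
  fp <- c(GrowthFactor = 0, DeathSignal = 1, MYC = 0, ERK = 0,
          Casp = 1, Proliferation = 0, Apoptosis = 1)
  expect_equal(nrow(eligible_transitions(mt, fp)), 0)
})

test_that("single trajectories follow the exponential waiting-time law", {
  net <- boolean_network(list(A = "1"), k_up = c(A = 2))
  cfg <- simulation_config(net, max_time = 50, tracked = "A")
  # exactly one flip, then absorbed
  ev <- run_trajectory(net, c(A = 0), cfg, seed = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$value, 1)
  # flip-time mean over many trajectories ~ 1/k_up within 3 SE
  n <- 4000
  times <- vapply(seq_len(n), function(s)
    run_trajectory(net, c(A = 0), cfg, seed = s)$time[1], numeric(1))
  se <- 0.5 / sqrt(n)  # exponential sd = mean = 1/2
  expect_lt(abs(mean(times) - 0.5), 3 * se)
  # fixed-point start: zero events
  ev0 <- run_trajectory(net, c(A = 1), cfg, seed = 1)
  expect_equal(nrow(ev0), 0)
  # same seed, same event list
  expect_identical(run_trajectory(net, c(A = 0), cfg, seed = 7),
                   run_trajectory(net, c(A = 0), cfg, seed = 7))
})

test_that("telegraph ensembles match the two-state closed form", {
  settings <- list(c(u = 2, d = 1, p0 = 0),
                   c(u = 0.5, d = 1.5, p0 = 1),
                   c(u = 1, d = 1, p0 = 0.5))
  n <- 10000
  for (s in settings) {
    toy <- make_toy_model("telegraph", u = s[["u"]], d = s[["d"]])
    cfg <- simulation_config(toy$network, n_trajectories = n,
                             max_time = 6, time_tick = 0.5,
                             seed = 11, p0 = c(A = s[["p0"]]))
    res <- simulate_ensemble(toy$network, cfg, warn_convergence = FALSE)
    for (w in seq_len(nrow(res$windows))) {
      exact <- toy$oracle$window_mean(res$windows$start[w],
                                      res$windows$end[w], s[["p0"]])
      expect_lt(abs(res$marginal[w, "A"] - exact),
                3 * mc_se(exact, n) + 1e-9)
    }
    # asymptotic score ~ u/(u+d)
    expect_lt(abs(phenotype_scores(res)[["A"]] - toy$oracle$stationary),
              3 * mc_se(toy$oracle$stationary, n))
  }
})

test_that("pure-birth node matches 1 - exp(-t) windows", {
  net <- boolean_network(list(B = "1"))
  n <- 20000
  cfg <- simulation_config(net, n_trajectories = n, max_time = 3,
                           time_tick = 1, seed = 5, p0 = c(B = 0),
                           tracked = "B")
  res <- simulate_ensemble(net, cfg, warn_convergence = FALSE)
  # window-averaged P(ON) on [t0,t1): 1 - (e^-t0 - e^-t1)/(t1-t0)
  exact <- vapply(seq_len(3), function(w)
    1 - (exp(-(w - 1)) - exp(-w)), numeric(1))
  expect_true(all(abs(res$marginal[, "B"] - exact)
                  < 3 * mc_se(exact, n)))
  # instantaneous P(ON at t=1) = 1 - e^-1 ~ 0.632 sits between the
  # adjacent window averages
  expect_gt(res$marginal[2, "B"], 1 - exp(-1))
  expect_lt(res$marginal[1, "B"], 1 - exp(-1))
})

test_that("small networks match exact master-equation integration", {
  # 3-node cascade with mixed rates, all nodes tracked, incl. joint dist
  casc <- make_toy_model("cascade", k = 2)$network
  casc$k_up[] <- c(1, 2, 0.7)
  casc$k_down[] <- c(1, 0.5, 1.3)
  n <- 8000
  cfg <- simulation_config(casc, n_trajectories = n, max_time = 6,
                           time_tick = 1, seed = 21,
                           p0 = c(Input = 0.6, N1 = 0.2, N2 = 0.9),
                           tracked = casc$nodes)
  sim <- simulate_ensemble(casc, cfg, warn_convergence = FALSE)
  me <- master_equation_windows(casc, cfg)
  expect_true(all(abs(sim$marginal - me$marginal)
                  < 3 * mc_se(me$marginal, n) + 1e-9))
  expect_true(all(abs(sim$joint - me$joint)
                  < 3 * mc_se(me$joint, n) + 1e-9))
  # joint initial conditions are honoured by both engine and oracle
  cfg2 <- simulation_config(casc, n_trajectories = n, max_time = 4,
                            time_tick = 1, seed = 8,
                            p0 = c(Input = 0.5, N1 = 0.5, N2 = 0.5),
                            joint = list(list(
                              nodes = c("N1", "N2"),
                              states = list(c(1L, 1L), c(0L, 0L)),
                              probs = c(0.3, 0.7))),
                            tracked = casc$nodes)
  sim2 <- simulate_ensemble(casc, cfg2, warn_convergence = FALSE)
  me2 <- master_equation_windows(casc, cfg2)
  expect_true(all(abs(sim2$marginal - me2$marginal)
                  < 3 * mc_se(me2$marginal, n) + 1e-9))
})

test_that("joint-state distributions normalise and marginalise correctly", {
  mt <- make_toy_model("mini_tumour")
  cfg <- simulation_config(mt$network, n_trajectories = 2000,
                           max_time = 12, seed = 3,
                           p0 = c(GrowthFactor = 0.5, DeathSignal = 0.5,
                                  MYC = 0.4))
  res <- simulate_ensemble(mt$network, cfg, warn_convergence = FALSE)
  expect_true(all(res$marginal >= 0 & res$marginal <= 1))
  expect_true(all(abs(rowSums(res$joint) - 1) < 1e-9))
  # marginal = sum of joint states with that node ON
  for (b in seq_along(res$tracked)) {
    on_cols <- which(bitwAnd(seq_len(ncol(res$joint)) - 1L,
                             bitwShiftL(1L, b - 1L)) > 0)
    expect_equal(unname(res$marginal[, b]),
                 unname(rowSums(res$joint[, on_cols, drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("identical config and seed give bit-identical results", {
  mt <- make_toy_model("mini_tumour")
  cfg <- simulation_config(mt$network, n_trajectories = 500,
                           max_time = 10, seed = 123,
                           p0 = c(GrowthFactor = 0.5, DeathSignal = 0.5))
  a <- simulate_ensemble(mt$network, cfg, warn_convergence = FALSE)
  b <- simulate_ensemble(mt$network, cfg, warn_convergence = FALSE)
  expect_identical(a$marginal, b$marginal)
  expect_identical(a$joint, b$joint)
  cfg2 <- cfg; cfg2$seed <- 124L
  c2 <- simulate_ensemble(mt$network, cfg2, warn_convergence = FALSE)
  expect_false(identical(a$marginal, c2$marginal))
})

test_that("quiescent conditions give all-zero phenotype scores", {
  mt <- make_toy_model("mini_tumour")
  cfg <- simulation_config(mt$network, n_trajectories = 1000,
                           max_time = 20, seed = 6)  # all inputs OFF
  sc <- phenotype_scores(simulate_ensemble(mt$network, cfg,
                                           warn_convergence = FALSE))
  expect_equal(unname(sc), c(0, 0))
  # and the scores are the last-window joint-consistent marginals
  res <- simulate_ensemble(mt$network, cfg, warn_convergence = FALSE)
  expect_equal(sc, res$marginal[nrow(res$marginal),
                                intersect(res$outputs, res$tracked)])
})

test_that("tidy export carries windows, marginals and joint states", {
  tg <- make_toy_model("telegraph")
  cfg <- simulation_config(tg$network, n_trajectories = 200,
                           max_time = 4, seed = 2, p0 = c(A = 0))
  df <- as.data.frame(simulate_ensemble(tg$network, cfg,
                                        warn_convergence = FALSE))
  expect_setequal(names(df), c("window", "start", "end", "kind",
                               "entity", "probability"))
  expect_true(all(df$probability >= 0 & df$probability <= 1))
  expect_equal(sort(unique(df$kind)), c("joint", "marginal"))
})
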