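test_that("min-max and sigmoid-z normalisation behave per gene", {
  m <- rbind(g1 = c(2, 4, 6), g2 = c(5, 5, 5))
  expect_warning(nm <- normalize_continuous(m, "minmax"), "no variation")
  expect_equal(unname(nm["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(nm["g2", ]), rep(0.5, 3))
  # sigmoid_z maps the median to exactly 0.5
  m2 <- rbind(g = c(1, 3, 9, 27, 81))
  nz <- normalize_continuous(m2, "sigmoid_z")
  expect_equal(unname(nz["g", 3]), 0.5)
  expect_true(all(nz > 0 & nz < 1))
  expect_error(normalize_continuous(m[, 1, drop = FALSE]), "2 samples")
})

test_that("gene values aggregate onto nodes with the declared statistic", {
  map <- node_gene_map(c("AMPK", "AMPK", "CPLX", "CPLX", "GONE"),
                       c("PRKAA1", "PRKAA2", "X1", "X2", "NOPE"),
                       aggregator = c(CPLX = "min"))
  vals <- c(PRKAA1 = 0.2, PRKAA2 = 0.4, X1 = 0.9, X2 = 0.1)
  w <- capture_warnings(agg <- aggregate_node_values(vals, map))
  expect_match(w, "no available gene", all = FALSE)
  expect_match(w, "dropped", all = FALSE)
  expect_equal(agg[["AMPK"]], 0.3)
  expect_equal(agg[["CPLX"]], 0.1)
  expect_false("GONE" %in% names(agg))
})

test_that("discrete forcings follow effect classes and precedence", {
  mt <- make_toy_model("mini_tumour")$network
  map <- node_gene_map(c("MYC", "Casp", "Casp"),
                       c("MYC", "CASP8", "CASP9"))
  rec <- personalisation_recipe()
  # LoF -> 0
  f <- apply_discrete(mt, list(mutations = c(CASP8 = "loss_of_function")),
                      rec, map)
  expect_equal(f[["Casp"]], 0L)
  # amplification -> 1
  f2 <- apply_discrete(mt, list(cna = c(MYC = "amplified")), rec, map)
  expect_equal(f2[["MYC"]], 1L)
  # mutation beats CNA on the same node
  f3 <- apply_discrete(mt, list(mutations = c(MYC = "loss_of_function"),
                                cna = c(MYC = "amplified")), rec, map)
  expect_equal(f3[["MYC"]], 0L)
  # unknown effect ignored with warning
  expect_warning(
    f4 <- apply_discrete(mt, list(mutations = c(MYC = "unknown")),
                         rec, map),
    "unknown effect")
  expect_length(f4, 0)
  # contradictory same-layer calls name the genes
  expect_error(
    apply_discrete(mt, list(mutations = c(CASP8 = "loss_of_function",
                                          CASP9 = "gain_of_function")),
                   rec, map),
    "CASP8.*CASP9")
})

test_that("continuous modulation is neutral at 0.5 and odds-symmetric", {
  mt <- make_toy_model("mini_tumour")$network
  rec <- personalisation_recipe(amplification = 1)
  m <- apply_continuous(mt, c(ERK = 0.5), rec)
  expect_equal(m$k_up[["ERK"]], 1)
  expect_equal(m$k_down[["ERK"]], 1)
  expect_equal(m$p0[["ERK"]], 0.5)
  # x = 0.99 at F = 1: k_up = sqrt(99), k_down its reciprocal
  m2 <- apply_continuous(mt, c(ERK = 0.999), rec)  # clamped to 0.99
  expect_equal(m2$k_up[["ERK"]], sqrt(99), tolerance = 1e-10)
  expect_equal(m2$k_down[["ERK"]], 1 / sqrt(99), tolerance = 1e-10)
  expect_equal(m2$k_up[["ERK"]] * m2$k_down[["ERK"]], 1, tolerance = 1e-12)
  # forced nodes are skipped and recorded
  m3 <- apply_continuous(mt, c(ERK = 0.9, MYC = 0.9), rec, forced = "MYC")
  expect_false("MYC" %in% names(m3$p0))
  expect_equal(m3$skipped, "MYC")
})

test_that("cohort personalisation preserves counts and is deterministic", {
  mt <- make_toy_model("mini_tumour")$network
  spec <- synthetic_cohort_spec(n_samples = 25, seed = 4)
  coh <- generate_cohort(spec)
  rec <- personalisation_recipe()
  pms <- quiet_personalise(mt, coh, rec, coh$map)
  expect_length(pms, 25)
  expect_setequal(names(pms), names(coh$labels))
  pms2 <- quiet_personalise(mt, coh, rec, coh$map)
  expect_identical(pms, pms2)
  # a sample with no usable data yields the generic model plus warning
  empty_cohort <- list(
    mutations = data.frame(sample = character(0), gene = character(0),
                           effect = character(0)),
    cna = data.frame(sample = "s1", gene = "NOT_IN_PANEL",
                     state = "neutral"),
    expression = NULL)
  expect_warning(one <- personalise_cohort(mt, empty_cohort, rec, coh$map),
                 "no usable data")
  expect_length(one[["s1"]]$forced, 0)
  expect_error(personalise_cohort(mt, list(), rec, coh$map), "empty cohort")
})

test_that("higher expression raises an unregulated node's activity", {
  # 1-node model: the driver switch holds its sampled initial value
  net <- boolean_network(list(D = "D"), node_order = "D")
  rec <- personalisation_recipe()
  xs <- seq(0.1, 0.9, by = 0.2)
  scores <- vapply(xs, function(x) {
    mod <- apply_continuous(net, c(D = x), rec)
    cfg <- simulation_config(net, n_trajectories = 2000, max_time = 5,
                             seed = 17, p0 = mod$p0, tracked = "D")
    net2 <- net
    net2$k_up["D"] <- mod$k_up[["D"]]
    net2$k_down["D"] <- mod$k_down[["D"]]
    phenotype_scores(simulate_ensemble(net2, cfg,
                                       warn_convergence = FALSE))[["D"]]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("discrete forcing dominates: forced nodes sit exactly at their value", {
  mt <- make_toy_model("mini_tumour")$network
  map <- node_gene_map("MYC", "MYC")
  for (rec in list(personalisation_recipe(),
                   personalisation_recipe(amplification = 4),
                   personalisation_recipe(continuous_layers = character(0)))) {
    pm <- personalise_model(
      mt, list(mutations = c(MYC = "gain_of_function")),
      expression = c(MYC = 0.2), recipe = rec, map = map)
    rm <- realise_model(pm, simulation_config(
      mt, n_trajectories = 400, max_time = 10, seed = 2,
      tracked = "MYC"))
    res <- simulate_ensemble(rm$network, rm$config,
                             warn_convergence = FALSE)
    expect_equal(unname(res$marginal[, "MYC"]),
                 rep(1, nrow(res$marginal)))
  }
})

test_that("strong synthetic driver signal separates the groups", {
  mt <- make_toy_model("mini_tumour")$network
  rec <- personalisation_recipe()
  cfg <- simulation_config(mt, n_trajectories = 400, max_time = 25,
                           seed = 19,
                           p0 = c(GrowthFactor = 0.3, DeathSignal = 0.3))
  run_auc <- function(spec) {
    coh <- generate_cohort(spec)
    pms <- quiet_personalise(mt, coh, rec, coh$map)
    scores <- vapply(pms, function(pm)
      unname(simulate_personalised(pm, cfg,
                                   warn_convergence = FALSE)["Proliferation"]),
      numeric(1))
    rank_auc(scores, coh$labels[names(pms)] == "B")
  }
  strong <- run_auc(synthetic_cohort_spec(n_samples = 80, seed = 31))
  expect_gt(strong, 0.9)
  null <- run_auc(synthetic_cohort_spec(n_samples = 80, seed = 32,
                                        p_driver_A = 0.05,
                                        p_driver_B = 0.05, delta = 0))
  expect_lt(abs(null - 0.5), 0.1)
})
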