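test_that("mutations replace rules by constants and leave rates alone", {
  mt <- make_toy_model("mini_tumour")$network
  # KO of Casp, the sole Apoptosis activator, silences Apoptosis
  ko <- apply_mutation(mt, perturbation("Casp", 0L))
  cfg <- simulation_config(ko, n_trajectories = 800, max_time = 15,
                           seed = 4, p0 = c(DeathSignal = 1, Casp = 0))
  sc <- phenotype_scores(simulate_ensemble(ko, cfg,
                                           warn_convergence = FALSE))
  expect_equal(sc[["Apoptosis"]], 0)
  expect_equal(ko$k_up, mt$k_up)
  # empty perturbation is the identity
  expect_identical(apply_mutation(mt, perturbation()), mt)
  # OE of an input is the same as switching it ON
  oe <- apply_mutation(mt, perturbation("GrowthFactor", 1L))
  cfg_oe <- simulation_config(oe, n_trajectories = 800, max_time = 15,
                              seed = 4, p0 = c(GrowthFactor = 1))
  cfg_on <- simulation_config(mt, n_trajectories = 800, max_time = 15,
                              seed = 4, p0 = c(GrowthFactor = 1))
  expect_equal(
    phenotype_scores(simulate_ensemble(oe, cfg_oe,
                                       warn_convergence = FALSE)),
    phenotype_scores(simulate_ensemble(mt, cfg_on,
                                       warn_convergence = FALSE)))
  expect_error(perturbation(c("A", "A"), c(0, 1)), "conflicting")
})

test_that("mutant enumeration yields 2n^2 perturbations", {
  for (n in c(1:6, 10)) {
    net <- boolean_network(inputs = paste0("V", seq_len(n)))
    muts <- enumerate_mutants(net, perturbable = paste0("V", seq_len(n)))
    # brute-force count: singles + all distinct ordered value pairs
    expect_length(muts, 2 * n^2)
    expect_equal(sum(vapply(muts, `[[`, integer(1), "order") == 1L), 2 * n)
    labels <- vapply(muts, `[[`, character(1), "label")
    expect_false(anyDuplicated(labels) > 0)
  }
  # the published screen's scale: 127 perturbable nodes
  expect_equal(2 * 127^2, 32258)
})

test_that("drug mixtures interpolate between wild type and knock-out", {
  mt <- make_toy_model("mini_tumour")$network
  cfg <- simulation_config(mt, n_trajectories = 2000, max_time = 12,
                           seed = 9, p0 = c(GrowthFactor = 1, MYC = 0.5))
  # alpha = 1 is bit-identical to the genetic KO under the same seed
  full <- simulate_drug(mt, cfg, drug_spec("ERK", 1))
  p <- perturbation("ERK", 0L)
  ko_net <- apply_mutation(mt, p)
  ko_cfg <- cfg; ko_cfg$p0["ERK"] <- 0
  ko <- simulate_ensemble(ko_net, ko_cfg, warn_convergence = FALSE)
  expect_identical(full$marginal, ko$marginal)
  # alpha = 0 is bit-identical to wild type
  none <- simulate_drug(mt, cfg, drug_spec("ERK", 0))
  wt <- simulate_ensemble(mt, cfg, warn_convergence = FALSE)
  expect_identical(none$marginal, wt$marginal)
})

test_that("joint trajectory fractions follow the product law", {
  mt <- make_toy_model("mini_tumour")$network
  cfg <- simulation_config(mt, n_trajectories = 5000, max_time = 5,
                           seed = 13, p0 = c(GrowthFactor = 1))
  res <- simulate_drug(mt, cfg, drug_spec(c("ERK", "MYC"), 0.5),
                       warn_convergence = FALSE)
  counts <- res$variant_counts
  expect_length(counts, 4)
  expect_equal(sum(counts), 5000)
  # each joint assignment expected at 25%; 99% binomial bounds
  bound <- qnorm(0.995) * sqrt(0.25 * 0.75 * 5000)
  expect_true(all(abs(counts - 1250) < bound))
  # asymmetric levels: P(KO both) = 0.2 * 0.7 etc.
  res2 <- simulate_drug(mt, cfg, drug_spec(c("ERK", "MYC"), c(0.2, 0.7)),
                        warn_convergence = FALSE)
  probs <- c((1 - 0.2) * (1 - 0.7), 0.2 * (1 - 0.7),
             (1 - 0.2) * 0.7, 0.2 * 0.7)
  expect_true(all(abs(res2$variant_counts - 5000 * probs)
                  < qnorm(0.995) * sqrt(probs * (1 - probs) * 5000) + 1))
})

test_that("frozen-mode drugs pin the target at 1 - alpha", {
  mt <- make_toy_model("mini_tumour")$network
  cfg <- simulation_config(mt, n_trajectories = 4000, max_time = 8,
                           seed = 23, p0 = c(GrowthFactor = 1),
                           tracked = c("ERK", "Proliferation"))
  res <- simulate_drug(mt, cfg, drug_spec("ERK", 0.3, "frozen_on_off"))
  erk <- res$marginal[nrow(res$marginal), "ERK"]
  expect_lt(abs(erk - 0.7), 3 * mc_se(0.7, 4000))
})

test_that("dose-response grids span the level grid and respond monotonically", {
  mt <- make_toy_model("mini_tumour")$network
  cfg <- simulation_config(mt, n_trajectories = 1500, max_time = 12,
                           seed = 3, p0 = c(GrowthFactor = 1))
  levels <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  dr <- dose_response(mt, cfg, "GrowthFactor", levels)
  expect_equal(sort(unique(dr$level)), levels)
  expect_equal(nrow(dr), 6 * 2)  # 6 levels x 2 phenotypes
  prolif <- dr$score[dr$phenotype == "Proliferation"]
  # GrowthFactor drives Proliferation (via ERK, with MYC off):
  # inhibition can only lower it, modulo Monte-Carlo jitter
  expect_true(all(diff(prolif) <= 3 * mc_se(prolif[1], 1500)))
  # master-equation oracle confirms the alpha = 1 endpoint
  ko <- apply_mutation(mt, perturbation("GrowthFactor", 0L))
  cfg_ko <- cfg; cfg_ko$p0["GrowthFactor"] <- 0
  me <- master_equation_windows(ko, cfg_ko)
  expect_lt(abs(prolif[6] - me$marginal[nrow(me$marginal),
                                        "Proliferation"]),
            3 * mc_se(0.05, 1500) + 1e-6)
})

test_that("combination grids have the exact published structure", {
  # 17 targets x 6 levels: 136 pairs, 4,998 conditions
  g <- combination_grid(paste0("T", 1:17))
  expect_equal(nrow(g), 4998)
  expect_equal(sum(is.na(g$target_b)), 17 * 6)
  pairs <- unique(g[!is.na(g$target_b), c("target_a", "target_b")])
  expect_equal(nrow(pairs), choose(17, 2))
  expect_equal(choose(17, 2), 136)
  # 2 targets, 2 levels: 2*2 + 1*4 = 8
  expect_equal(nrow(combination_grid(c("A", "B"), c(0, 1))), 8)
})

test_that("pair rows at a partner's alpha 0 equal the single-drug rows", {
  mt <- make_toy_model("mini_tumour")$network
  cfg <- simulation_config(mt, n_trajectories = 2500, max_time = 12,
                           seed = 7, p0 = c(GrowthFactor = 1))
  scr <- combination_screen(mt, cfg, c("ERK", "MYC"), c(0, 0.6))
  pro <- scr[scr$phenotype == "Proliferation", ]
  single <- pro$score[is.na(pro$target_b) & pro$target_a == "ERK" &
                        pro$level_a == 0.6]
  pair0 <- pro$score[!is.na(pro$target_b) & pro$level_a == 0.6 &
                       pro$level_b == 0]
  expect_lt(abs(single - pair0), 4 * mc_se(single, 2500))
})

test_that("rule-robustness scan edits each gate exactly once", {
  net <- parse_boolnet(c("A, B & C", "D, A | (B & C)", "E, !A"),
                       outputs = "E")
  cfg <- simulation_config(net, n_trajectories = 400, max_time = 8,
                           seed = 5, p0 = c(B = 1, C = 1))
  scan <- rule_robustness_scan(net, cfg)
  expect_equal(nrow(scan), 3)  # one AND in A, AND+OR in D, none in E
  expect_setequal(scan$node[scan$from == "and"], c("A", "D"))
  # idempotent operands: swapping B & B for B | B changes nothing
  net2 <- parse_boolnet(c("A, B & B", "E, A"), outputs = "E")
  cfg2 <- simulation_config(net2, n_trajectories = 3000, max_time = 8,
                            seed = 5, p0 = c(B = 0.5))
  scan2 <- suppressWarnings(rule_robustness_scan(net2, cfg2))
  expect_equal(nrow(scan2), 1)
  expect_lt(scan2$shift, 3 * mc_se(0.5, 3000))
  # rules without binary gates generate no edits
  net3 <- parse_boolnet("A, !B")
  cfg3 <- simulation_config(net3, n_trajectories = 100, max_time = 4,
                            seed = 1, tracked = "A")
  expect_equal(nrow(rule_robustness_scan(net3, cfg3)), 0)
})
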