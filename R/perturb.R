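#' A genetic perturbation (knock-out / gain-of-function set)
#'
#' @param nodes character vector of perturbed nodes.
#' @param values 0/1 forcings, same length: 0 = knock-out, 1 =
#'   gain-of-function (overexpression).
#' @return object of class `perturbation` with a canonical `label`
#'   such as `"AKT:0+PI3K:1"`; the empty perturbation is labelled
#'   `"WT"`.
#' @export
perturbation <- function(nodes = character(0), values = integer(0)) {
  stopifnot(length(nodes) == length(values), all(values %in% 0:1))
  if (anyDuplicated(nodes))
    stop("conflicting forcings: node(s) perturbed twice", call. = FALSE)
  o <- order(nodes)
  nodes <- nodes[o]; values <- as.integer(values[o])
  label <- if (length(nodes) == 0L) "WT"
           else paste(sprintf("%s:%d", nodes, values), collapse = "+")
  structure(list(nodes = nodes, values = values,
                 order = length(nodes), label = label),
            class = "perturbation")
}

#' Apply a genetic perturbation to a network
#'
#' Each perturbed node's rule is replaced by the constant forcing;
#' transition rates are untouched. Overexpressing an input node is
#' equivalent to switching that input ON.
#'
#' @param network a [boolean_network()].
#' @param p a [perturbation()].
#' @return the mutated [boolean_network()].
#' @export
apply_mutation <- function(network, p) {
  if (length(bad <- setdiff(p$nodes, network$nodes)))
    stop("unknown perturbed node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (i in seq_along(p$nodes))
    network$rules[[p$nodes[i]]] <- bx_const(p$values[i])
  network
}

# force perturbed nodes' initial conditions to the forcing, so the
# forced value holds from t = 0 (the rule alone would only converge)
force_config <- function(config, p) {
  if (length(p$nodes)) config$p0[p$nodes] <- p$values
  config
}

#' Enumerate single and double mutants
#'
#' All knock-out and gain-of-function perturbations over the
#' perturbable node set: `2n` singles and `4 * choose(n,2)` doubles,
#' `2n^2` in total. By default every node except the outputs is
#' perturbable (inputs included).
#'
#' @param network a [boolean_network()].
#' @param perturbable character vector of perturbable nodes.
#' @param orders subset of `c(1, 2)`.
#' @return list of [perturbation()] objects.
#' @export
enumerate_mutants <- function(network,
                              perturbable = setdiff(network$nodes,
                                                    network$outputs),
                              orders = c(1L, 2L)) {
  if (length(perturbable) == 0L)
    stop("perturbable node set is empty", call. = FALSE)
  if (length(bad <- setdiff(perturbable, network$nodes)))
    stop("unknown perturbable node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- list()
  if (1L %in% orders) {
    for (nd in perturbable) for (v in 0:1)
      out[[length(out) + 1L]] <- perturbation(nd, v)
  }
  if (2L %in% orders && length(perturbable) >= 2L) {
    n <- length(perturbable)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      for (vi in 0:1) for (vj in 0:1)
        out[[length(out) + 1L]] <-
          perturbation(c(perturbable[i], perturbable[j]), c(vi, vj))
  }
  out
}

#' Simulate a set of mutants and tabulate phenotype scores
#'
#' Includes the wild-type reference row (label `"WT"`).
#'
#' @param network a [boolean_network()].
#' @param config a [simulation_config()].
#' @param mutants list of [perturbation()]s, e.g. from
#'   [enumerate_mutants()].
#' @return tidy data.frame: `label`, `order`, `phenotype`, `score`.
#' @export
mutant_screen <- function(network, config, mutants) {
  all_p <- c(list(perturbation()), mutants)
  rows <- lapply(all_p, function(p) {
    net <- apply_mutation(network, p)
    sc <- phenotype_scores(
      simulate_ensemble(net, force_config(config, p),
                        warn_convergence = FALSE))
    data.frame(label = p$label, order = p$order,
               phenotype = names(sc), score = unname(sc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gradual drug inhibition of target nodes
#'
#' @param targets character vector of target nodes.
#' @param alpha inhibition level(s) in `[0,1]`, recycled over targets;
#'   1 is a proper knock-out, 0 no inhibition.
#' @param mode `"mixture_ko_wt"` (default): each trajectory knocks the
#'   target out with probability `alpha` and keeps the intact rule
#'   otherwise, so 0% inhibition is exactly wild type.
#'   `"frozen_on_off"`: the target's rule becomes self-identity and the
#'   trajectory starts (and stays) ON with probability `1 - alpha`.
#' @return object of class `drug_spec`.
#' @export
drug_spec <- function(targets, alpha,
                      mode = c("mixture_ko_wt", "frozen_on_off")) {
  mode <- match.arg(mode)
  alpha <- rep(alpha, length.out = length(targets))
  if (any(alpha < 0 | alpha > 1))
    stop("inhibition levels must lie in [0,1]", call. = FALSE)
  structure(list(targets = targets,
                 alpha = stats::setNames(alpha, targets), mode = mode),
            class = "drug_spec")
}

#' Build the trajectory-mixture (or frozen) model set for a drug
#'
#' In mixture mode each target is knocked out independently per
#' trajectory with probability `alpha`, giving `2^t` network variants
#' whose probabilities follow the product law (e.g. two targets at 50%
#' give 25/25/25/25 over the four joint assignments). In frozen mode a
#' single variant is returned with the target rule frozen to
#' self-identity and initial ON-probability `1 - alpha`.
#'
#' @param network a [boolean_network()].
#' @param config a [simulation_config()].
#' @param spec a [drug_spec()].
#' @return list of `list(network=, config=, prob=, ko=)` variants
#'   consumable by [simulate_ensemble()].
#' @export
apply_drug <- function(network, config, spec) {
  if (length(bad <- setdiff(spec$targets, network$nodes)))
    stop("unknown drug target(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (spec$mode == "frozen_on_off") {
    net <- network
    cfg <- config
    for (tg in spec$targets) {
      net$rules[[tg]] <- bx_var(tg)
      cfg$p0[tg] <- 1 - spec$alpha[[tg]]
    }
    return(list(list(network = net, config = cfg, prob = 1,
                     ko = character(0))))
  }
  t <- length(spec$targets)
  variants <- list()
  for (mask in 0:(2^t - 1L)) {
    ko <- spec$targets[bitwAnd(bitwShiftR(mask, seq_len(t) - 1L), 1L) == 1L]
    prob <- prod(ifelse(spec$targets %in% ko, spec$alpha,
                        1 - spec$alpha))
    p <- perturbation(ko, rep(0L, length(ko)))
    variants[[length(variants) + 1L]] <-
      list(network = apply_mutation(network, p),
           config = force_config(config, p),
           prob = prob, ko = ko)
  }
  # zero-probability components are dropped, so a pure knock-out
  # (alpha = 1) or untreated (alpha = 0) run is bit-identical to the
  # corresponding single-network simulation under the same seed
  variants[vapply(variants, `[[`, numeric(1), "prob") > 0]
}

#' Simulate a drugged model
#'
#' @inheritParams apply_drug
#' @param ... passed to [simulate_ensemble()].
#' @return an `ensemble_result`; `variant_counts` reports how many
#'   trajectories received each joint knock-out assignment (mixture
#'   mode).
#' @export
simulate_drug <- function(network, config, spec, ...) {
  variants <- apply_drug(network, config, spec)
  res <- simulate_ensemble(network, config, variants = variants, ...)
  res$variant_ko <- lapply(variants, `[[`, "ko")
  res
}

# apply a named input preset (assignment over input nodes) to a config
apply_preset <- function(network, config, preset) {
  if (is.null(preset)) return(config)
  if (length(bad <- setdiff(names(preset), network$nodes)))
    stop("preset assigns unknown node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  config$p0[names(preset)] <- preset
  config
}

#' Growth-condition presets over the canonical prostate input nodes
#'
#' The fixed base keeps Nutrients ON and Acidosis, Hypoxia, TGFbeta,
#' Carcinogen and TNFalpha OFF (FGF is also OFF); EGF and Androgen
#' vary across the four named media: `none`, `EGF`, `Androgen`,
#' `EGF+Androgen`.
#'
#' @return named list of named 0/1 input assignments.
#' @export
prostate_presets <- function() {
  base <- c(Nutrients = 1, Acidosis = 0, Hypoxia = 0, TGFbeta = 0,
            Carcinogen = 0, TNFalpha = 0, FGF = 0)
  list(
    none = c(base, EGF = 0, Androgen = 0),
    EGF = c(base, EGF = 1, Androgen = 0),
    Androgen = c(base, EGF = 0, Androgen = 1),
    `EGF+Androgen` = c(base, EGF = 1, Androgen = 1))
}

#' Dose-response grid for one target
#'
#' One simulation per inhibition level (the untreated reference is the
#' `alpha = 0` row).
#'
#' @param network a [boolean_network()].
#' @param config a [simulation_config()].
#' @param target target node.
#' @param levels inhibition levels; default the study's six-point grid.
#' @param preset optional named input assignment (see
#'   [prostate_presets()]).
#' @param preset_name label recorded in the output.
#' @param mode drug semantics, see [drug_spec()].
#' @return tidy data.frame: `target`, `level`, `preset`, `phenotype`,
#'   `score`.
#' @export
dose_response <- function(network, config, target,
                          levels = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                          preset = NULL, preset_name = "base",
                          mode = "mixture_ko_wt") {
  levels <- sort(levels)
  cfg <- apply_preset(network, config, preset)
  rows <- lapply(levels, function(a) {
    sc <- phenotype_scores(
      simulate_drug(network, cfg, drug_spec(target, a, mode),
                    warn_convergence = FALSE))
    data.frame(target = target, level = a, preset = preset_name,
               phenotype = names(sc), score = unname(sc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single + pairwise dose-combination condition grid
#'
#' All single-target level settings plus every unordered target pair
#' on the full level-by-level grid: `t*L + choose(t,2)*L^2` conditions
#' (17 targets and 6 levels give 4,998).
#'
#' @param targets character vector of target nodes.
#' @param levels inhibition levels.
#' @return data.frame: `target_a`, `level_a`, `target_b`, `level_b`
#'   (`NA` for singles).
#' @export
combination_grid <- function(targets, levels = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  levels <- sort(levels)
  singles <- expand.grid(target_a = targets, level_a = levels,
                         stringsAsFactors = FALSE)
  singles$target_b <- NA_character_
  singles$level_b <- NA_real_
  pairs <- list()
  n <- length(targets)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      g <- expand.grid(level_a = levels, level_b = levels)
      pairs[[length(pairs) + 1L]] <-
        data.frame(target_a = targets[i], level_a = g$level_a,
                   target_b = targets[j], level_b = g$level_b,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(list(singles[, c("target_a", "level_a",
                                    "target_b", "level_b")]), pairs))
}

#' Run the single + pairwise drug-combination screen
#'
#' Simulates every condition of [combination_grid()] and reports the
#' asymptotic phenotype scores.
#'
#' @inheritParams dose_response
#' @param targets character vector of target nodes (>= 2).
#' @return tidy data.frame: grid columns plus `preset`, `phenotype`,
#'   `score`.
#' @export
combination_screen <- function(network, config, targets,
                               levels = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                               preset = NULL, preset_name = "base",
                               mode = "mixture_ko_wt") {
  if (length(targets) < 2L)
    stop("combination screen needs at least two targets", call. = FALSE)
  grid <- combination_grid(targets, levels)
  cfg <- apply_preset(network, config, preset)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    spec <- if (is.na(g$target_b))
      drug_spec(g$target_a, g$level_a, mode)
    else
      drug_spec(c(g$target_a, g$target_b), c(g$level_a, g$level_b), mode)
    sc <- phenotype_scores(
      simulate_drug(network, cfg, spec, warn_convergence = FALSE))
    data.frame(g, preset = preset_name, phenotype = names(sc),
               score = unname(sc), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rule-robustness scan (AND/OR gate swaps)
#'
#' Swaps each AND gate for an OR (and vice versa), one gate at a time
#' across all rules, re-simulates, and reports the largest absolute
#' shift in any output score relative to the unedited model.
#'
#' @param network a [boolean_network()].
#' @param config a [simulation_config()].
#' @param baseline optional precomputed [phenotype_scores()] of the
#'   unedited model.
#' @return data.frame: `node`, `gate` (index within the rule), `from`,
#'   `to`, `rule`, `shift`.
#' @export
rule_robustness_scan <- function(network, config, baseline = NULL) {
  if (is.null(baseline))
    baseline <- phenotype_scores(
      simulate_ensemble(network, config, warn_convergence = FALSE))
  rows <- list()
  for (nd in setdiff(network$nodes, network$inputs)) {
    k <- count_binops(network$rules[[nd]])
    if (k == 0L) next
    for (i in seq_len(k)) {
      net2 <- network
      old <- network$rules[[nd]]
      net2$rules[[nd]] <- swap_binop(old, i)
      sc <- phenotype_scores(
        simulate_ensemble(net2, config, warn_convergence = FALSE))
      shift <- max(abs(sc - baseline[names(sc)]))
      # which gate changed, for the report
      gate_from <- find_gate_type(old, i)
      rows[[length(rows) + 1L]] <- data.frame(
        node = nd, gate = i,
        from = gate_from,
        to = if (gate_from == "and") "or" else "and",
        rule = format_bool_expr(net2$rules[[nd]]),
        shift = shift, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(node = character(0), gate = integer(0),
                      from = character(0), to = character(0),
                      rule = character(0), shift = numeric(0)))
  do.call(rbind, rows)
}

find_gate_type <- function(expr, i) {
  k <- 0L
  found <- NULL
  rec <- function(e) {
    if (!is.null(found)) return()
    if (e$type %in% c("and", "or")) {
      k <<- k + 1L
      if (k == i) { found <<- e$type; return() }
      rec(e$lhs); rec(e$rhs)
    } else if (e$type == "not") rec(e$arg)
  }
  rec(expr)
  found
}
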