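#' Map model nodes to gene identifiers
#'
#' A model node can stand for a complex or a gene family, so several
#' genes may feed one node; the per-node aggregator says how their
#' normalised values are combined.
#'
#' @param nodes character vector (repeated node names allowed).
#' @param genes character vector, same length.
#' @param aggregator named character vector over nodes, values in
#'   `mean`, `min`, `max`; unnamed nodes default to `mean`.
#' @return object of class `node_gene_map`: list with `genes` (named
#'   list node -> genes) and `aggregator`.
#' @export
node_gene_map <- function(nodes, genes, aggregator = NULL) {
  stopifnot(length(nodes) == length(genes))
  gl <- split(genes, factor(nodes, levels = unique(nodes)))
  for (nd in names(gl)) {
    if (anyDuplicated(gl[[nd]]))
      stop("duplicate gene for node ", nd, call. = FALSE)
  }
  agg <- stats::setNames(rep("mean", length(gl)), names(gl))
  if (!is.null(aggregator)) {
    if (length(bad <- setdiff(names(aggregator), names(gl))))
      stop("aggregator for unmapped node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!all(aggregator %in% c("mean", "min", "max")))
      stop("aggregator must be mean, min or max", call. = FALSE)
    agg[names(aggregator)] <- aggregator
  }
  structure(list(genes = gl, aggregator = agg), class = "node_gene_map")
}

#' Read a node-gene map from a TSV file
#'
#' Two columns `node`, `gene`, optional third column `aggregator`.
#'
#' @param path TSV file path.
#' @return a [node_gene_map()].
#' @export
read_node_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  agg <- NULL
  if ("aggregator" %in% names(df)) {
    first <- !duplicated(df$node)
    agg <- stats::setNames(df$aggregator[first], df$node[first])
  }
  node_gene_map(df$node, df$gene, agg)
}

#' Normalise a cohort expression matrix to [0,1]
#'
#' @param mat genes x samples numeric matrix.
#' @param method `"minmax"`: per-gene `(x - min)/(max - min)`;
#'   `"sigmoid_z"`: logistic transform of the per-gene robust z-score
#'   `(x - median)/(1.4826 * MAD)`.
#' @return matrix of the same shape with values in `[0,1]`; genes with
#'   no variation map to 0.5 with a warning.
#' @export
normalize_continuous <- function(mat, method = c("minmax", "sigmoid_z")) {
  method <- match.arg(method)
  if (ncol(mat) < 2L)
    stop("cohort normalisation needs at least 2 samples", call. = FALSE)
  out <- mat
  flat <- character(0)
  for (g in seq_len(nrow(mat))) {
    x <- mat[g, ]
    if (method == "minmax") {
      rng <- range(x)
      if (rng[1] == rng[2]) {
        out[g, ] <- 0.5
        flat <- c(flat, rownames(mat)[g] %||% as.character(g))
      } else {
        out[g, ] <- (x - rng[1]) / (rng[2] - rng[1])
      }
    } else {
      med <- stats::median(x)
      s <- stats::mad(x)
      if (s == 0) s <- stats::sd(x)
      if (is.na(s) || s == 0) {
        out[g, ] <- 0.5
        flat <- c(flat, rownames(mat)[g] %||% as.character(g))
      } else {
        out[g, ] <- stats::plogis((x - med) / s)
      }
    }
  }
  if (length(flat))
    warning("gene(s) with no variation mapped to 0.5: ",
            paste(flat, collapse = ", "), call. = FALSE)
  out
}

#' Aggregate normalised gene values onto model nodes
#'
#' @param values named numeric vector of normalised gene values.
#' @param map a [node_gene_map()].
#' @return named numeric vector over the mappable nodes; nodes with no
#'   available gene are absent (logged via warning), missing genes of
#'   partially covered nodes are dropped with a warning.
#' @export
aggregate_node_values <- function(values, map) {
  out <- numeric(0)
  missing_any <- character(0)
  empty <- character(0)
  for (nd in names(map$genes)) {
    gs <- map$genes[[nd]]
    have <- gs[gs %in% names(values)]
    if (length(have) < length(gs))
      missing_any <- c(missing_any, setdiff(gs, have))
    if (length(have) == 0L) {
      empty <- c(empty, nd)
      next
    }
    fn <- switch(map$aggregator[[nd]], mean = mean, min = min, max = max)
    out[nd] <- fn(values[have])
  }
  if (length(missing_any))
    warning("gene(s) absent from values, dropped: ",
            paste(unique(missing_any), collapse = ", "), call. = FALSE)
  if (length(empty))
    warning("node(s) with no available gene left untouched: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out
}

#' Personalisation recipe
#'
#' Which omics layers force node values (discrete) and which modulate
#' the continuous simulation variables, mirroring the recipe retained
#' in the original study: mutations and copy number as discrete
#' forcings, expression as continuous modulation of both transition
#' rates and initial conditions.
#'
#' @param discrete_layers subset of `c("mutations", "cna")`.
#' @param continuous_layers subset of `c("expression")`.
#' @param continuous_targets subset of `c("initial_conditions",
#'   "transition_rates")`.
#' @param amplification exponent `F >= 0` of the odds-power rate
#'   transform (see [rate_transform()]); `F = 0` disables rate
#'   modulation, larger values sharpen it.
#' @param epsilon clamp applied to continuous values before the odds
#'   transform, in `(0, 0.5)`.
#' @param normalisation method handed to [normalize_continuous()].
#' @return object of class `personalisation_recipe`.
#' @export
personalisation_recipe <- function(discrete_layers = c("mutations", "cna"),
                                   continuous_layers = "expression",
                                   continuous_targets =
                                     c("initial_conditions",
                                       "transition_rates"),
                                   amplification = 1,
                                   epsilon = 0.01,
                                   normalisation = "sigmoid_z") {
  discrete_layers <- intersect(discrete_layers, c("mutations", "cna"))
  continuous_layers <- intersect(continuous_layers, "expression")
  continuous_targets <- intersect(continuous_targets,
                                  c("initial_conditions",
                                    "transition_rates"))
  if (length(discrete_layers) + length(continuous_layers) == 0L)
    stop("recipe must enable at least one omics layer", call. = FALSE)
  stopifnot(amplification >= 0, epsilon > 0, epsilon < 0.5)
  structure(list(discrete_layers = discrete_layers,
                 continuous_layers = continuous_layers,
                 continuous_targets = continuous_targets,
                 amplification = amplification,
                 epsilon = epsilon,
                 normalisation = normalisation),
            class = "personalisation_recipe")
}

#' Odds-power transform from a normalised value to transition rates
#'
#' `k_up = (x/(1-x))^(F/2)` and `k_down = (x/(1-x))^(-F/2)`, so the
#' transform is neutral at `x = 0.5`, symmetric around it, and always
#' satisfies `k_up * k_down = 1`. Isolated here so an alternative
#' continuous-to-rate convention can be swapped in at one place.
#'
#' @param x clamped normalised value(s) in `(0,1)`.
#' @param amplification exponent `F`.
#' @return list with numeric `k_up`, `k_down`.
#' @export
rate_transform <- function(x, amplification = 1) {
  odds <- x / (1 - x)
  list(k_up = odds^(amplification / 2),
       k_down = odds^(-amplification / 2))
}

#' Discrete forcings from a sample's mutation and copy-number calls
#'
#' Gain-of-function mutations and amplifications force the node to 1;
#' loss-of-function mutations and deletions force it to 0. Mutations
#' take precedence over copy number when both hit the same node;
#' unknown-effect mutations are ignored with a warning. Contradictory
#' calls within one layer raise an error naming the genes.
#'
#' @param network a [boolean_network()].
#' @param profile list with `mutations` (gene -> effect) and `cna`
#'   (gene -> state) named character vectors (either may be absent).
#' @param recipe a [personalisation_recipe()].
#' @param map a [node_gene_map()].
#' @return named integer vector of forced node values.
#' @export
apply_discrete <- function(network, profile, recipe, map) {
  gene2nodes <- function(gene) {
    names(map$genes)[vapply(map$genes, function(g) gene %in% g, logical(1))]
  }
  layer_forcings <- function(calls, to_value, layer) {
    forced <- list()
    for (gene in names(calls)) {
      val <- to_value(calls[[gene]], gene)
      if (is.na(val)) next
      for (nd in intersect(gene2nodes(gene), network$nodes)) {
        forced[[nd]] <- rbind(forced[[nd]],
                              data.frame(gene = gene, value = val))
      }
    }
    out <- integer(0)
    for (nd in names(forced)) {
      vals <- unique(forced[[nd]]$value)
      if (length(vals) > 1L)
        stop(sprintf("contradictory %s calls for node %s (genes: %s)",
                     layer, nd, paste(forced[[nd]]$gene, collapse = ", ")),
             call. = FALSE)
      out[nd] <- vals
    }
    out
  }
  mut_forced <- integer(0)
  cna_forced <- integer(0)
  if ("mutations" %in% recipe$discrete_layers &&
      length(profile$mutations)) {
    mut_forced <- layer_forcings(profile$mutations, function(eff, gene) {
      switch(eff,
             gain_of_function = 1L,
             loss_of_function = 0L,
             {
               warning(sprintf(
                 "mutation with unknown effect on gene %s ignored", gene),
                 call. = FALSE)
               NA_integer_
             })
    }, "mutation")
  }
  if ("cna" %in% recipe$discrete_layers && length(profile$cna)) {
    cna_forced <- layer_forcings(profile$cna, function(st, gene) {
      switch(st, amplified = 1L, deleted = 0L, neutral = NA_integer_,
             stop(sprintf("unknown CNA state '%s' for gene %s", st, gene),
                  call. = FALSE))
    }, "CNA")
  }
  # mutation wins over CNA on conflict
  forced <- cna_forced
  forced[names(mut_forced)] <- mut_forced
  forced
}

#' Continuous modulation of rates and initial conditions
#'
#' Clamps node values to `[epsilon, 1 - epsilon]`, sets the initial
#' ON-probability to the clamped value, and derives transition rates
#' through [rate_transform()]. Nodes already forced by discrete data
#' are skipped.
#'
#' @param network a [boolean_network()].
#' @param node_values named numeric vector from
#'   [aggregate_node_values()].
#' @param recipe a [personalisation_recipe()].
#' @param forced character vector of discretely forced nodes to skip.
#' @return list with `p0`, `k_up`, `k_down` (named vectors over the
#'   modulated nodes) and `skipped` (forced nodes that had a value).
#' @export
apply_continuous <- function(network, node_values, recipe,
                             forced = character(0)) {
  node_values <- node_values[names(node_values) %in% network$nodes]
  skipped <- intersect(names(node_values), forced)
  node_values <- node_values[setdiff(names(node_values), forced)]
  x <- pmin(pmax(node_values, recipe$epsilon), 1 - recipe$epsilon)
  out <- list(p0 = numeric(0), k_up = numeric(0), k_down = numeric(0),
              skipped = skipped)
  if ("initial_conditions" %in% recipe$continuous_targets)
    out$p0 <- x
  if ("transition_rates" %in% recipe$continuous_targets) {
    kr <- rate_transform(x, recipe$amplification)
    out$k_up <- kr$k_up
    out$k_down <- kr$k_down
  }
  out
}

#' Personalise a network to every sample of a cohort
#'
#' @param network the generic [boolean_network()].
#' @param cohort list with `mutations` (data.frame sample/gene/effect),
#'   `cna` (sample/gene/state), `expression` (genes x samples matrix);
#'   any layer may be empty.
#' @param recipe a [personalisation_recipe()].
#' @param map a [node_gene_map()].
#' @return named list of `personalised_model` objects, one per sample
#'   (union of samples seen in any layer), each carrying `forced`,
#'   `k_up`, `k_down`, `p0` and a provenance data.frame.
#' @export
personalise_cohort <- function(network, cohort, recipe, map) {
  samples <- unique(c(cohort$mutations$sample, cohort$cna$sample,
                      colnames(cohort$expression)))
  if (length(samples) == 0L) stop("empty cohort", call. = FALSE)
  norm <- NULL
  if ("expression" %in% recipe$continuous_layers &&
      !is.null(cohort$expression) && ncol(cohort$expression) >= 2L) {
    norm <- normalize_continuous(cohort$expression, recipe$normalisation)
  }
  lapply(stats::setNames(samples, samples), function(sm) {
    profile <- list(
      mutations = with(cohort$mutations[cohort$mutations$sample == sm, ,
                                        drop = FALSE],
                       stats::setNames(effect, gene)),
      cna = with(cohort$cna[cohort$cna$sample == sm, , drop = FALSE],
                 stats::setNames(state, gene)))
    personalise_model(network, profile,
                      expression = if (!is.null(norm) &&
                                       sm %in% colnames(norm))
                        norm[, sm] else NULL,
                      recipe = recipe, map = map, sample = sm)
  })
}

#' Personalise a network to a single sample
#'
#' @inheritParams personalise_cohort
#' @param profile list of named vectors `mutations`, `cna`.
#' @param expression named numeric vector of cohort-normalised gene
#'   values for this sample (already in `[0,1]`), or `NULL`.
#' @param sample sample identifier for provenance.
#' @return object of class `personalised_model`.
#' @export
personalise_model <- function(network, profile, expression, recipe, map,
                              sample = "sample") {
  forced <- apply_discrete(network, profile, recipe, map)
  prov <- data.frame(layer = character(0), node = character(0),
                     detail = character(0), stringsAsFactors = FALSE)
  for (nd in names(forced))
    prov <- rbind(prov, data.frame(layer = "discrete", node = nd,
                                   detail = sprintf("forced to %d",
                                                    forced[[nd]])))
  cont <- list(p0 = numeric(0), k_up = numeric(0), k_down = numeric(0),
               skipped = character(0))
  if (length(recipe$continuous_layers) && !is.null(expression)) {
    node_values <- suppressWarnings(
      aggregate_node_values(expression, map))
    cont <- apply_continuous(network, node_values, recipe,
                             forced = names(forced))
    for (nd in names(cont$p0))
      prov <- rbind(prov, data.frame(layer = "continuous", node = nd,
                                     detail = sprintf("x = %.4f",
                                                      cont$p0[[nd]])))
    for (nd in cont$skipped)
      prov <- rbind(prov, data.frame(layer = "continuous", node = nd,
                                     detail = "skipped (forced)"))
  }
  if (nrow(prov) == 0L)
    warning(sprintf("sample %s: no usable data; generic model returned",
                    sample), call. = FALSE)
  structure(list(sample = sample, network = network, forced = forced,
                 p0 = cont$p0, k_up = cont$k_up, k_down = cont$k_down,
                 provenance = prov),
            class = "personalised_model")
}

#' @export
print.personalised_model <- function(x, ...) {
  cat(sprintf("Personalised model for %s: %d forced node(s), %d modulated\n",
              x$sample, length(x$forced), length(x$p0)))
  invisible(x)
}

#' Materialise a personalised model for simulation
#'
#' Applies the stored forcings (rules replaced by constants), modified
#' rates and initial-condition probabilities to a simulatable
#' network/config pair.
#'
#' @param pm a `personalised_model`.
#' @param config a [simulation_config()] built on the base network;
#'   defaults to one with standard settings.
#' @return list with `network` and `config`.
#' @export
realise_model <- function(pm, config = NULL) {
  net <- pm$network
  if (is.null(config)) config <- simulation_config(net)
  for (nd in names(pm$forced)) {
    net$rules[[nd]] <- bx_const(pm$forced[[nd]])
    config$p0[nd] <- pm$forced[[nd]]
  }
  if (length(pm$k_up)) net$k_up[names(pm$k_up)] <- pm$k_up
  if (length(pm$k_down)) net$k_down[names(pm$k_down)] <- pm$k_down
  if (length(pm$p0)) config$p0[names(pm$p0)] <- pm$p0
  list(network = net, config = config)
}

#' Simulate a personalised model and return its phenotype scores
#'
#' @param pm a `personalised_model`.
#' @param config optional [simulation_config()] template.
#' @param ... passed to [simulate_ensemble()].
#' @return named numeric vector of asymptotic output probabilities.
#' @export
simulate_personalised <- function(pm, config = NULL, ...) {
  rm <- realise_model(pm, config)
  res <- simulate_ensemble(rm$network, rm$config, ...)
  phenotype_scores(res)
}
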