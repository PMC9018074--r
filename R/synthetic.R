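#' Toy Boolean models with known dynamics
#'
#' Three families used throughout the test-suite and vignette:
#' \describe{
#'   \item{telegraph}{a single self-inhibiting node flipping ON at rate
#'     `u` and OFF at rate `d`; the exact ON-probability is
#'     `p(t) = u/(u+d) + (p0 - u/(u+d)) exp(-(u+d) t)`.}
#'   \item{cascade}{a linear chain Input -> N1 -> ... -> Nk; with the
#'     input ON the all-ON state is the unique attractor.}
#'   \item{mini_tumour}{a 7-node caricature of a growth/death decision:
#'     inputs GrowthFactor and DeathSignal, an unregulated driver node
#'     MYC, intermediates ERK (= GrowthFactor) and Casp (= DeathSignal),
#'     outputs Proliferation = (ERK | MYC) & !Casp and
#'     Apoptosis = Casp. ERK and MYC are redundant Proliferation
#'     activators, so their joint inhibition is synergistic while
#'     either alone is buffered.}
#' }
#'
#' @param kind one of `"telegraph"`, `"cascade"`, `"mini_tumour"`.
#' @param u,d telegraph activation/inhibition rates.
#' @param k cascade chain length.
#' @return list with `network` ([boolean_network()]) and `oracle`, a
#'   machine-readable description of the exact dynamics (closed form
#'   for telegraph, fixed points for the others; small models can also
#'   be handed to [master_equation_windows()]).
#' @export
make_toy_model <- function(kind = c("telegraph", "cascade", "mini_tumour"),
                           u = 1, d = 1, k = 3L) {
  kind <- match.arg(kind)
  if (kind == "telegraph") {
    net <- boolean_network(list(A = "!A"), outputs = "A",
                           k_up = c(A = u), k_down = c(A = d))
    oracle <- list(
      kind = "telegraph", u = u, d = d,
      stationary = u / (u + d),
      p_on = function(t, p0) u / (u + d) + (p0 - u / (u + d)) *
        exp(-(u + d) * t),
      # exact time-average of p_on over [t0, t1)
      window_mean = function(t0, t1, p0) {
        pinf <- u / (u + d)
        pinf + (p0 - pinf) * (exp(-(u + d) * t0) - exp(-(u + d) * t1)) /
          ((u + d) * (t1 - t0))
      })
    return(list(network = net, oracle = oracle))
  }
  if (kind == "cascade") {
    k <- as.integer(k)
    rules <- stats::setNames(
      as.list(c("Input", paste0("N", seq_len(k - 1L)))),
      paste0("N", seq_len(k)))
    net <- boolean_network(rules, inputs = "Input",
                           outputs = paste0("N", k))
    oracle <- list(kind = "cascade", k = k,
                   fixed_point_on = stats::setNames(
                     rep(1L, k + 1L), c("Input", paste0("N", seq_len(k)))),
                   fixed_point_off = stats::setNames(
                     rep(0L, k + 1L), c("Input", paste0("N", seq_len(k)))))
    return(list(network = net, oracle = oracle))
  }
  net <- boolean_network(
    rules = list(
      MYC = "MYC",                       # unregulated driver switch
      ERK = "GrowthFactor",
      Casp = "DeathSignal",
      Proliferation = "(ERK | MYC) & !Casp",
      Apoptosis = "Casp"),
    inputs = c("GrowthFactor", "DeathSignal"),
    outputs = c("Proliferation", "Apoptosis"))
  oracle <- list(
    kind = "mini_tumour",
    # asymptotic scores given input/driver ON-probabilities, from the
    # product structure of the attractor distribution
    asymptotic = function(p_gf, p_death, p_myc) {
      c(Proliferation = (1 - (1 - p_gf) * (1 - p_myc)) * (1 - p_death),
        Apoptosis = p_death)
    })
  list(network = net, oracle = oracle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic stand-in for the published 133-node prostate model
#'
#' The study's curated prostate signalling model (133 nodes, 449
#' influence arcs, 9 environmental inputs, 6 phenotype outputs) is
#' distributed with the original publication and is not bundled here.
#' This generator builds a SYNTHETIC network with exactly those
#' dimensions — the canonical input and output names plus 118
#' deterministic intermediate nodes wired so that every rule literal is
#' semantically effective and the signed influence graph has exactly
#' 449 arcs. It shares only its shape with the published model, not
#' its biology; it exists so structural code paths (parsing, influence
#' analysis, mutant enumeration) can be exercised at full scale.
#'
#' @return a [boolean_network()] with 133 nodes.
#' @export
make_synthetic_prostate_model <- function() {
  inputs <- c("EGF", "FGF", "TGFbeta", "Nutrients", "Hypoxia", "Acidosis",
              "Androgen", "TNFalpha", "Carcinogen")
  outputs <- c("Proliferation", "Apoptosis", "Invasion", "Migration",
               "Metastasis", "DNA_repair")
  inter <- sprintf("S%03d", seq_len(118L))
  # deterministic distinct picks: k consecutive pool entries from a
  # salted offset (always distinct since k <= length(pool))
  pick <- function(pool, k, salt) {
    pool[((salt + seq_len(k) - 1L) %% length(pool)) + 1L]
  }
  rules <- list()
  # 77 intermediates with 4 regulators, 41 with 3: 77*4 + 41*3 = 431
  for (i in seq_along(inter)) {
    pool <- c(inputs, inter[seq_len(i - 1L)])
    if (i <= 77L) {
      r <- pick(pool, 4L, i * 3L)
      rules[[inter[i]]] <- sprintf("(%s & %s) | (%s & !%s)",
                                   r[1], r[2], r[3], r[4])
    } else {
      r <- pick(pool, 3L, i * 5L)
      rules[[inter[i]]] <- sprintf("(%s & %s) | !%s", r[1], r[2], r[3])
    }
  }
  # 6 outputs with 3 regulators each: 18 arcs; total 431 + 18 = 449
  for (o in seq_along(outputs)) {
    r <- pick(inter, 3L, o * 11L)
    rules[[outputs[o]]] <- sprintf("(%s | %s) & !%s", r[1], r[2], r[3])
  }
  boolean_network(rules, inputs = inputs, outputs = outputs)
}

#' Specification of a synthetic two-group omics cohort
#'
#' Emulates a tumour cohort with two latent groups that differ in the
#' mutation frequency of a driver gene and in the expression of
#' driver-linked genes. Defaults follow the study conditions: 488
#' samples (the size of the cohort the original models were
#' personalised to), a strong driver (gain-of-function probability 0.8
#' in group B vs 0.05 in group A) and a standardised expression shift
#' of `delta = 2` on driver-linked genes.
#'
#' @param n_samples cohort size.
#' @param map a [node_gene_map()]; defaults to the mini_tumour panel
#'   (MYC; ERK <- MAPK1, MAPK3; Casp <- CASP8, CASP9) plus ten
#'   passenger genes.
#' @param mixing fraction of samples in group B.
#' @param driver_gene gene carrying the group-B driver alteration.
#' @param driver_effect effect class of the driver mutation.
#' @param p_driver_A,p_driver_B per-group probability that a sample
#'   carries the driver mutation.
#' @param delta standardised expression shift on driver-linked genes in
#'   group B (units of `sigma`).
#' @param sigma per-gene expression noise standard deviation.
#' @param seed integer seed; identical specs give byte-identical
#'   cohorts.
#' @return object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_samples = 488L, map = NULL,
                                  mixing = 0.5,
                                  driver_gene = "MYC",
                                  driver_effect = "gain_of_function",
                                  p_driver_A = 0.05, p_driver_B = 0.8,
                                  delta = 2, sigma = 1, seed = 1L) {
  if (is.null(map)) {
    map <- node_gene_map(
      nodes = c("MYC", "ERK", "ERK", "Casp", "Casp"),
      genes = c("MYC", "MAPK1", "MAPK3", "CASP8", "CASP9"))
  }
  stopifnot(n_samples >= 1L, mixing >= 0, mixing <= 1,
            p_driver_A >= 0, p_driver_A <= 1,
            p_driver_B >= 0, p_driver_B <= 1,
            delta >= 0, sigma >= 0)
  panel <- unique(c(unlist(map$genes), sprintf("PSG%02d", 1:10)))
  if (length(panel) == 0L) stop("empty gene panel", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), map = map,
                 panel = panel, mixing = mixing,
                 driver_gene = driver_gene, driver_effect = driver_effect,
                 p_driver_A = p_driver_A, p_driver_B = p_driver_B,
                 delta = delta, sigma = sigma, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic omics cohort
#'
#' Produces mutation, copy-number and expression tables in the input
#' dialects of [personalise_cohort()], plus the true group labels.
#' Expression is Gaussian per gene with a `delta * sigma` group shift
#' on driver-linked genes only; copy-number is neutral except for
#' sparse random passenger events.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param dir optional directory; when given, `mutations.tsv`,
#'   `cna.tsv` and `expression.tsv` are written there.
#' @return list with `mutations`, `cna` (data.frames), `expression`
#'   (genes x samples matrix), `labels` (named character vector,
#'   `"A"`/`"B"`), `map`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  samples <- sprintf("SAMP%04d", seq_len(spec$n_samples))
  labels <- stats::setNames(
    ifelse(stats::runif(spec$n_samples) < spec$mixing, "B", "A"), samples)
  p_mut <- ifelse(labels == "B", spec$p_driver_B, spec$p_driver_A)
  has_driver <- stats::runif(spec$n_samples) < p_mut
  mutations <- data.frame(sample = samples[has_driver],
                          gene = spec$driver_gene,
                          effect = spec$driver_effect,
                          stringsAsFactors = FALSE)
  # sparse neutral-passenger CNA layer
  cna_rows <- which(stats::runif(spec$n_samples) < 0.1)
  passengers <- grep("^PSG", spec$panel, value = TRUE)
  cna <- if (length(cna_rows) && length(passengers)) {
    data.frame(sample = samples[cna_rows],
               gene = sample(passengers, length(cna_rows), replace = TRUE),
               state = sample(c("amplified", "deleted"), length(cna_rows),
                              replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample = character(0), gene = character(0),
               state = character(0), stringsAsFactors = FALSE)
  }
  driver_nodes <- names(spec$map$genes)[vapply(spec$map$genes, function(g)
    spec$driver_gene %in% g, logical(1))]
  driver_linked <- unique(unlist(spec$map$genes[driver_nodes]))
  expr <- matrix(stats::rnorm(length(spec$panel) * spec$n_samples,
                              sd = spec$sigma),
                 nrow = length(spec$panel),
                 dimnames = list(spec$panel, samples))
  if (length(driver_linked))
    expr[driver_linked, labels == "B"] <-
      expr[driver_linked, labels == "B"] + spec$delta * spec$sigma
  out <- list(mutations = mutations, cna = cna, expression = expr,
              labels = labels, map = spec$map)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(mutations, file.path(dir, "mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cna, file.path(dir, "cna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene = rownames(expr), expr,
                                  check.names = FALSE),
                       file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write a network as a re-parseable fixture
#'
#' @param network a [boolean_network()].
#' @param format `"boolnet"` (single rule-table file) or `"maboss"`
#'   (.bnd/.cfg pair; requires `config`).
#' @param path output path; for maboss the extensions .bnd/.cfg are
#'   appended.
#' @param config a [simulation_config()], used by the maboss format.
#' @return character vector of the files written.
#' @export
write_fixture <- function(network, format = c("boolnet", "maboss"),
                          path, config = NULL) {
  if (!is.character(format) || !format[1] %in% c("boolnet", "maboss"))
    stop("unsupported fixture format '", format[1], "'", call. = FALSE)
  format <- format[1]
  if (format == "boolnet") {
    writeLines(write_boolnet(network), path)
    return(invisible(path))
  }
  if (is.null(config)) config <- simulation_config(network)
  mb <- write_maboss(network, config)
  bnd <- paste0(path, ".bnd"); cfg <- paste0(path, ".cfg")
  writeLines(mb$bnd, bnd)
  writeLines(mb$cfg, cfg)
  invisible(c(bnd, cfg))
}
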