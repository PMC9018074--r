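#' Drug effect on a phenotype probability
#'
#' Normalised efficiency in `[0,1]`: for a desired decrease,
#' `E = max(0, (P_ref - P_treated)/P_ref)`; for an increase,
#' `E = max(0, (P_treated - P_ref)/(1 - P_ref))`. `E = 0` means no
#' change in the desired direction; an undefined denominator gives
#' `NA`.
#'
#' @param p_ref untreated reference probability.
#' @param p_treated treated probability.
#' @param direction `"decrease"` or `"increase"`.
#' @return efficiency in `[0,1]`, or `NA`.
#' @export
drug_effect <- function(p_ref, p_treated,
                        direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (direction == "decrease") {
    if (p_ref <= 0) return(NA_real_)
    max(0, (p_ref - p_treated) / p_ref)
  } else {
    if (p_ref >= 1) return(NA_real_)
    max(0, (p_treated - p_ref) / (1 - p_ref))
  }
}

#' Bliss-independence Combination Index
#'
#' `CI = (Ea + Eb - Ea*Eb) / Eab`: the ratio of the effect predicted
#' under independent drug action to the observed combined effect.
#' `CI < 1` flags synergy, `CI > 1` antagonism.
#'
#' @param ea,eb single-drug efficiencies (from [drug_effect()]).
#' @param eab combined-treatment efficiency.
#' @return the CI, or `NA` when `eab` is 0 or any input is `NA`.
#' @export
bliss_ci <- function(ea, eb, eab) {
  if (anyNA(c(ea, eb, eab)) || eab == 0) return(NA_real_)
  (ea + eb - ea * eb) / eab
}

#' Genetic-interaction null models
#'
#' The four candidate predictions for the double-mutant fitness from
#' the single-mutant fitnesses: additive `x + y`, log
#' `log2((2^x - 1)(2^y - 1) + 1)`, multiplicative `x * y`, and
#' `min(x, y)`.
#'
#' @param x,y single-perturbation fitness values (wild type = 1).
#' @param kind one of `"ADD"`, `"LOG"`, `"MLT"`, `"MIN"`.
#' @return the null-model prediction (vectorised over `x`, `y`).
#' @export
psi_null <- function(x, y, kind = c("ADD", "LOG", "MLT", "MIN")) {
  kind <- match.arg(kind)
  switch(kind,
         ADD = x + y,
         LOG = log2((2^x - 1) * (2^y - 1) + 1),
         MLT = x * y,
         MIN = pmin(x, y))
}

#' Phenotype fitness of a perturbed model
#'
#' `f = P_mutant / P_wildtype`, so the wild type is 1, `f < 1` is
#' deleterious for the phenotype and `f > 1` beneficial. When the
#' wild-type probability is below `floor` the ratio is numerically
#' meaningless and `NA` is returned.
#'
#' @param p_mutant,p_wildtype phenotype probabilities in `[0,1]`.
#' @param floor smallest trusted wild-type probability.
#' @return fitness value(s), `NA` where the wild type underflows.
#' @export
fitness_from_probabilities <- function(p_mutant, p_wildtype,
                                       floor = 1e-4) {
  out <- p_mutant / rep_len(p_wildtype, length(p_mutant))
  out[rep_len(p_wildtype < floor, length(p_mutant))] <- NA_real_
  out
}

#' Epistasis score of a double perturbation
#'
#' `epsilon = f_AB - psi(f_A, f_B)`: 0 exactly when the double mutant
#' matches the null prediction, negative for aggravating and positive
#' for alleviating interactions.
#'
#' @param f_a,f_b single-perturbation fitnesses.
#' @param f_ab double-perturbation fitness.
#' @param kind null model, see [psi_null()].
#' @return the epistasis score (NA inputs propagate).
#' @export
epistasis_score <- function(f_a, f_b, f_ab, kind = "ADD") {
  f_ab - psi_null(f_a, f_b, kind)
}

#' Select the best-fitting null model over all pairs
#'
#' For each candidate psi, the Pearson correlation between the
#' observed double-mutant fitnesses and the null predictions is
#' computed; the psi with the largest correlation wins (ties broken in
#' the fixed order ADD, LOG, MLT, MIN).
#'
#' @param pairs data.frame with columns `f_a`, `f_b`, `f_ab`; rows
#'   with NA are dropped. At least 3 complete pairs are required.
#' @return list with `kind` (selected psi) and `pearson` (named
#'   correlation vector).
#' @export
select_best_psi <- function(pairs) {
  pairs <- pairs[stats::complete.cases(pairs[, c("f_a", "f_b", "f_ab")]), ]
  if (nrow(pairs) < 3L)
    stop("need at least 3 complete pairs to select a null model",
         call. = FALSE)
  if (stats::sd(pairs$f_ab) == 0)
    stop("observed double-mutant fitness has zero variance; ",
         "correlations undefined", call. = FALSE)
  kinds <- c("ADD", "LOG", "MLT", "MIN")
  r <- vapply(kinds, function(k) {
    pred <- psi_null(pairs$f_a, pairs$f_b, k)
    if (stats::sd(pred) == 0) return(NA_real_)
    stats::cor(pairs$f_ab, pred)
  }, numeric(1))
  best <- kinds[which.max(replace(r, is.na(r), -Inf))]
  list(kind = best, pearson = r)
}

#' Epistasis analysis of a mutant screen
#'
#' Converts a [mutant_screen()] table into per-pair fitness values,
#' scores every double against the four null models, and selects the
#' best-fitting psi by Pearson correlation.
#'
#' @param screen tidy data.frame from [mutant_screen()] (must contain
#'   the `"WT"` row and both singles of every double).
#' @param phenotype phenotype to analyse.
#' @param floor wild-type probability floor, see
#'   [fitness_from_probabilities()].
#' @return list with `table` (per-pair data.frame: labels, fitnesses,
#'   `eps_ADD` ... `eps_MIN`), `best_psi`, `pearson`.
#' @export
epistasis_analysis <- function(screen, phenotype, floor = 1e-4) {
  sub <- screen[screen$phenotype == phenotype, ]
  if (nrow(sub) == 0L)
    stop("unknown phenotype '", phenotype, "'", call. = FALSE)
  wt <- sub$score[sub$label == "WT"]
  if (length(wt) != 1L)
    stop("screen must contain exactly one WT row", call. = FALSE)
  f <- stats::setNames(
    fitness_from_probabilities(sub$score, wt, floor), sub$label)
  doubles <- sub[sub$order == 2L, ]
  if (nrow(doubles) == 0L) stop("no double mutants in screen", call. = FALSE)
  parts <- strsplit(doubles$label, "+", fixed = TRUE)
  tab <- data.frame(
    pair = doubles$label,
    single_a = vapply(parts, `[`, character(1), 1L),
    single_b = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE)
  tab$f_a <- unname(f[tab$single_a])
  tab$f_b <- unname(f[tab$single_b])
  tab$f_ab <- unname(f[doubles$label])
  for (k in c("ADD", "LOG", "MLT", "MIN"))
    tab[[paste0("eps_", k)]] <-
      epistasis_score(tab$f_a, tab$f_b, tab$f_ab, k)
  sel <- select_best_psi(tab)
  list(table = tab, best_psi = sel$kind, pearson = sel$pearson)
}

#' Bliss synergy table from a combination screen
#'
#' For every target pair and level combination with both drugs present,
#' computes single efficiencies against the untreated reference (the
#' zero-level rows of the same screen) and the Combination Index.
#'
#' @param grid tidy data.frame from [combination_screen()].
#' @param phenotype phenotype to score.
#' @param direction desired direction of the drug effect, see
#'   [drug_effect()].
#' @return data.frame: `target_a`, `level_a`, `target_b`, `level_b`,
#'   `e_a`, `e_b`, `e_ab`, `ci` (NA where a drug is absent or the
#'   combined effect is 0).
#' @export
synergy_table <- function(grid, phenotype,
                          direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  g <- grid[grid$phenotype == phenotype, ]
  if (nrow(g) == 0L)
    stop("unknown phenotype '", phenotype, "'", call. = FALSE)
  singles <- g[is.na(g$target_b), ]
  ref_rows <- singles[singles$level_a == 0, ]
  if (nrow(ref_rows) == 0L)
    stop("screen lacks the untreated (level 0) reference", call. = FALSE)
  p_ref <- mean(ref_rows$score)
  single_score <- function(tg, lv) {
    s <- singles$score[singles$target_a == tg & singles$level_a == lv]
    if (length(s) != 1L) NA_real_ else s
  }
  pairs <- g[!is.na(g$target_b), ]
  out <- pairs[, c("target_a", "level_a", "target_b", "level_b")]
  out$e_a <- mapply(function(tg, lv)
    drug_effect(p_ref, single_score(tg, lv), direction),
    pairs$target_a, pairs$level_a)
  out$e_b <- mapply(function(tg, lv)
    drug_effect(p_ref, single_score(tg, lv), direction),
    pairs$target_b, pairs$level_b)
  out$e_ab <- vapply(pairs$score, function(s)
    drug_effect(p_ref, s, direction), numeric(1))
  out$ci <- mapply(bliss_ci, out$e_a, out$e_b, out$e_ab)
  # no synergy is defined when either drug is absent
  out$ci[out$level_a == 0 | out$level_b == 0] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Rank interventions by phenotype change
#'
#' Orders a mutant screen by the signed score change relative to wild
#' type in the requested direction; ties are broken lexicographically
#' by perturbation label.
#'
#' @param screen tidy data.frame from [mutant_screen()].
#' @param phenotype phenotype to rank on.
#' @param direction `"decrease"` ranks the strongest depletions first,
#'   `"increase"` the strongest promotions.
#' @param k number of top interventions to return (full ordering if
#'   larger than the table).
#' @return data.frame: `label`, `score`, `change` (score - WT score).
#' @export
rank_interventions <- function(screen, phenotype,
                               direction = c("decrease", "increase"),
                               k = 20L) {
  direction <- match.arg(direction)
  sub <- screen[screen$phenotype == phenotype & screen$label != "WT", ]
  if (nrow(sub) == 0L)
    stop("unknown phenotype '", phenotype, "'", call. = FALSE)
  wt <- screen$score[screen$phenotype == phenotype & screen$label == "WT"]
  if (length(wt) != 1L)
    stop("screen must contain exactly one WT row", call. = FALSE)
  sub$change <- sub$score - wt
  key <- if (direction == "decrease") sub$change else -sub$change
  sub <- sub[order(key, sub$label), c("label", "score", "change")]
  rownames(sub) <- NULL
  utils::head(sub, k)
}

#' Wild-type-centred PCA of a phenotype matrix
#'
#' Centres the conditions-by-outputs matrix by its wild-type row (not
#' by column means) and projects onto principal axes of descending
#' explained variance; the reference condition maps to the origin by
#' construction.
#'
#' @param mat numeric matrix, conditions in rows, phenotype outputs in
#'   columns.
#' @param reference row name or index of the wild-type condition.
#' @return list with `coords` (conditions x components),
#'   `explained_variance` (proportion per component), `rotation`.
#' @export
pca_mutant_map <- function(mat, reference = "WT") {
  if (nrow(mat) < 2L)
    stop("need at least 2 conditions", call. = FALSE)
  ref <- if (is.character(reference)) match(reference, rownames(mat))
         else as.integer(reference)
  if (is.na(ref))
    stop("reference row not found", call. = FALSE)
  centred <- sweep(mat, 2L, mat[ref, ], `-`)
  if (all(abs(centred) < 1e-12))
    stop("constant matrix: no variation to decompose", call. = FALSE)
  pc <- stats::prcomp(centred, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  list(coords = pc$x,
       explained_variance = ev / sum(ev),
       rotation = pc$rotation)
}

#' Rank-based AUC for group separation
#'
#' Probability that a randomly chosen positive-group score exceeds a
#' negative-group one (ties count half), i.e. the Mann-Whitney AUC.
#'
#' @param scores numeric vector.
#' @param labels logical or two-level vector; `TRUE`/second level is
#'   the positive group.
#' @return AUC in `[0,1]`.
#' @export
rank_auc <- function(scores, labels) {
  pos <- as.logical(labels == (if (is.logical(labels)) TRUE
                               else sort(unique(labels))[2]))
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("need both groups", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
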