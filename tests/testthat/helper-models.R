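# shared fixture builders (everything generated in code; no data files)

toy3 <- function() {
  # A regulated by B and C; B, C auto-declared inputs
  parse_boolnet("A, B & !C")
}

# independent sign oracle: evaluate the rule text with base R logic over
# the full truth table and classify each regulator's effect
r_eval_signs <- function(rule_text) {
  e <- str2lang(gsub("!", "!", rule_text, fixed = TRUE))
  vars <- sort(unique(all.vars(e)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(vars)))
  names(grid) <- vars
  vals <- apply(grid, 1L, function(row) {
    env <- as.list(row)
    as.integer(eval(e, envir = env))
  })
  sapply(vars, function(v) {
    on <- vals[grid[[v]]]
    off <- vals[!grid[[v]]]
    pos <- any(on > off); neg <- any(on < off)
    if (pos && neg) "dual" else if (pos) "activator"
    else if (neg) "inhibitor" else "none"
  })
}

quiet_personalise <- function(...) suppressWarnings(personalise_cohort(...))

mc_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
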