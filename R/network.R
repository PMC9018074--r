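#' Construct a Boolean signalling network
#'
#' A `boolean_network` couples logical update rules with per-node
#' activation (`k_up`) and inhibition (`k_down`) transition rates, the
#' ingredients of the continuous-time Markov process simulated by
#' [simulate_ensemble()]. Input nodes are environmental switches: they
#' carry a self-identity rule, so they hold whatever value they are
#' sampled with at time zero. Output nodes are phenotype read-outs
#' (e.g. Proliferation, Apoptosis).
#'
#' @param rules named list of rule strings or parsed expressions, one
#'   per regulated node. Nodes referenced in rules but absent from
#'   `names(rules)` and `inputs` are auto-declared as inputs.
#' @param inputs character vector of input node names (may be empty).
#' @param outputs character vector of output node names; must be
#'   disjoint from `inputs`.
#' @param k_up,k_down named numeric vectors of strictly positive
#'   transition rates, in reciprocal model-time units; unnamed nodes
#'   default to 1.
#' @param node_order optional explicit ordering of all nodes.
#' @return an object of class `boolean_network`.
#' @export
boolean_network <- function(rules = list(), inputs = character(0),
                            outputs = character(0),
                            k_up = numeric(0), k_down = numeric(0),
                            node_order = NULL) {
  parsed <- lapply(rules, function(r) {
    if (is.character(r)) parse_bool_expr(r) else r
  })
  rule_nodes <- names(parsed)
  if (anyDuplicated(rule_nodes))
    stop("duplicate rule for node(s): ",
         paste(unique(rule_nodes[duplicated(rule_nodes)]), collapse = ", "),
         call. = FALSE)
  referenced <- unique(unlist(lapply(parsed, expr_vars)))
  auto_inputs <- setdiff(referenced, c(rule_nodes, inputs))
  inputs <- unique(c(inputs, auto_inputs))
  # a declared rule that is a self-identity or constant makes the node
  # input-like: it is not regulated by anyone else
  self_like <- vapply(rule_nodes, function(nd) {
    e <- parsed[[nd]]
    (e$type == "var" && e$name == nd) || e$type == "const"
  }, logical(1))
  inputs <- unique(c(inputs, rule_nodes[self_like]))
  nodes <- if (!is.null(node_order)) node_order
           else unique(c(rule_nodes, inputs))
  if (!setequal(nodes, union(rule_nodes, inputs)))
    stop("node_order must list exactly the declared nodes", call. = FALSE)
  if (length(bad <- setdiff(outputs, nodes)))
    stop("unknown output node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(bad <- intersect(outputs, inputs)))
    stop("output nodes must be disjoint from inputs: ",
         paste(bad, collapse = ", "), call. = FALSE)
  # every node carries a rule; inputs default to self-identity
  full_rules <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) {
    full_rules[[nd]] <- if (nd %in% rule_nodes) parsed[[nd]] else bx_var(nd)
  }
  # inputs must not be regulated by other nodes
  for (nd in intersect(inputs, nodes)) {
    vs <- expr_vars(full_rules[[nd]])
    if (length(setdiff(vs, nd)))
      stop(sprintf("input node '%s' must not be regulated by other nodes", nd),
           call. = FALSE)
  }
  fill_rates <- function(r, what) {
    out <- stats::setNames(rep(1, length(nodes)), nodes)
    if (length(r)) {
      if (is.null(names(r)))
        stop(what, " must be a named vector", call. = FALSE)
      if (length(bad <- setdiff(names(r), nodes)))
        stop(what, " names unknown: ", paste(bad, collapse = ", "),
             call. = FALSE)
      out[names(r)] <- r
    }
    if (any(out <= 0))
      stop(what, " must be strictly positive", call. = FALSE)
    out
  }
  structure(list(
    nodes = nodes,
    rules = full_rules,
    k_up = fill_rates(k_up, "k_up"),
    k_down = fill_rates(k_down, "k_down"),
    inputs = intersect(nodes, inputs),
    outputs = intersect(nodes, outputs)
  ), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes (%d inputs, %d outputs)\n",
              length(x$nodes), length(x$inputs), length(x$outputs)))
  for (nd in utils::head(x$nodes, 15L)) {
    cat(sprintf("  %s <- %s\n", nd, format_bool_expr(x$rules[[nd]])))
  }
  if (length(x$nodes) > 15L) cat(sprintf("  ... %d more\n", length(x$nodes) - 15L))
  invisible(x)
}

#' Parse a BoolNet-style rule table
#'
#' Reads the two-column `targets, factors` dialect: one rule per line,
#' the node name before the first comma and its Boolean update rule
#' after it. Nodes appearing only on the factor side are auto-declared
#' as inputs, as are nodes whose rule is a constant or their own name.
#'
#' @param text rule text (single string with newlines or a character
#'   vector of lines).
#' @param outputs optional character vector naming output nodes.
#' @return a [boolean_network()].
#' @export
parse_boolnet <- function(text, outputs = character(0)) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  rules <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[[li]])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^targets[[:space:]]*,[[:space:]]*factors$", ln,
              ignore.case = TRUE)) next
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0)
      stop(sprintf("line %d: expected 'target, rule', got '%s'", li, ln),
           call. = FALSE)
    target <- trimws(substr(ln, 1L, comma - 1L))
    rhs <- trimws(substr(ln, comma + 1L, nchar(ln)))
    if (!grepl("^[A-Za-z][A-Za-z0-9_./-]*$", target))
      stop(sprintf("line %d: invalid target name '%s'", li, target),
           call. = FALSE)
    if (!is.null(rules[[target]]))
      stop(sprintf("line %d: duplicate target '%s'", li, target),
           call. = FALSE)
    rules[[target]] <- tryCatch(parse_bool_expr(rhs), error = function(e) {
      stop(sprintf("line %d: %s", li, conditionMessage(e)), call. = FALSE)
    })
  }
  boolean_network(rules, outputs = outputs)
}

#' Serialise a network to BoolNet rule text
#'
#' The BoolNet table carries no transition rates; use [write_maboss()]
#' when rates matter. Parsing the output reproduces the network's node
#' order and rules exactly.
#'
#' @param network a [boolean_network()].
#' @return a single string of `targets, factors` lines.
#' @export
write_boolnet <- function(network) {
  header <- "targets, factors"
  body <- vapply(network$nodes, function(nd) {
    sprintf("%s, %s", nd, format_bool_expr(network$rules[[nd]], "boolnet"))
  }, character(1))
  paste(c(header, body), collapse = "\n")
}

# truth table over a rule's literals; k capped to keep enumeration sane
rule_truth_table <- function(expr, max_regulators = 16L) {
  vars <- expr_vars(expr)
  k <- length(vars)
  if (k > max_regulators)
    stop(sprintf("rule has %d regulators; truth-table analysis capped at %d",
                 k, max_regulators), call. = FALSE)
  if (k == 0L) {
    return(list(vars = character(0),
                grid = matrix(integer(0), nrow = 1L, ncol = 0L),
                values = evaluate_rule(expr, stats::setNames(integer(0),
                                                             character(0)))))
  }
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(grid) <- vars
  values <- apply(grid, 1L, function(row) evaluate_rule(expr, row))
  list(vars = vars, grid = grid, values = as.integer(values))
}

#' Signed influence graph of a network
#'
#' An arc regulator -> target exists iff the regulator appears in the
#' target's rule and flipping it changes the rule's value in at least
#' one context of the remaining regulators. The sign is `activator` if
#' every effective flip is increasing, `inhibitor` if decreasing, and
#' `dual` if both occur. Literals with no semantic effect produce no
#' arc (a warning is issued). Input self-identity rules are
#' bookkeeping, not regulation, and produce no arc.
#'
#' @param network a [boolean_network()].
#' @return a data.frame with columns `regulator`, `target`, `sign`.
#' @export
influence_graph <- function(network) {
  regs <- character(0); tgts <- character(0); signs <- character(0)
  for (nd in network$nodes) {
    if (nd %in% network$inputs) next
    tt <- rule_truth_table(network$rules[[nd]])
    for (v in tt$vars) {
      on <- tt$values[tt$grid[, v] == 1L]
      off <- tt$values[tt$grid[, v] == 0L]
      pos <- any(on > off)
      neg <- any(on < off)
      if (!pos && !neg) {
        warning(sprintf(
          "literal '%s' in rule for '%s' has no semantic effect; no arc",
          v, nd), call. = FALSE)
        next
      }
      regs <- c(regs, v); tgts <- c(tgts, nd)
      signs <- c(signs, if (pos && neg) "dual"
                        else if (pos) "activator" else "inhibitor")
    }
  }
  data.frame(regulator = regs, target = tgts, sign = signs,
             stringsAsFactors = FALSE)
}

#' Summary counts for a network
#'
#' @param network a [boolean_network()].
#' @return a one-row data.frame: `nodes`, `arcs`, `inputs`, `outputs`.
#' @export
network_summary <- function(network) {
  arcs <- suppressWarnings(influence_graph(network))
  data.frame(nodes = length(network$nodes),
             arcs = nrow(arcs),
             inputs = length(network$inputs),
             outputs = length(network$outputs))
}

# ---------------------------------------------------------------------------
# MaBoSS-style .bnd / .cfg dialect (documented subset)

parse_num <- function(s, what) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop(sprintf("%s: not a number: '%s'", what, s), call. = FALSE)
  v
}

parse_rate_field <- function(value, which, node) {
  value <- trimws(value)
  if (grepl("^[0-9.eE+-]+$", value)) return(parse_num(value, which))
  # canonical conditional forms: @logic ? k : 0  (up) / @logic ? 0 : k (down)
  m <- regmatches(value,
    regexec("^@logic[[:space:]]*\\?[[:space:]]*([0-9.eE+-]+)[[:space:]]*:[[:space:]]*([0-9.eE+-]+)$",
            value))[[1]]
  if (length(m) == 3L) {
    a <- parse_num(m[2], which); b <- parse_num(m[3], which)
    if (which == "rate_up" && b == 0) return(a)
    if (which == "rate_down" && a == 0) return(b)
  }
  stop(sprintf("node '%s': unsupported %s expression '%s'", node, which, value),
       call. = FALSE)
}

#' Parse a MaBoSS-style model (.bnd rules + .cfg run settings)
#'
#' Supported .bnd subset: `node NAME { logic = ...; rate_up = ...;
#' rate_down = ...; }` where rates are numeric constants or the
#' canonical `@logic ? k : 0` / `@logic ? 0 : k` conditionals.
#' Supported .cfg subset: `[A].istate = p [1], q [0];` (and joint
#' `[A,B].istate = ...`), `NODE.is_internal = TRUE/FALSE;`, and the
#' scalars `sample_count`, `max_time`, `time_tick`, `seed`. Anything
#' else is rejected rather than silently ignored. A structured comment
#' `// ctboolnet-outputs: A B` in the .bnd declares output nodes.
#'
#' @param bnd_text .bnd content (string or lines).
#' @param cfg_text .cfg content (string or lines); may be `NULL`.
#' @return a list with elements `network` ([boolean_network()]) and
#'   `config` ([simulation_config()]).
#' @export
parse_maboss <- function(bnd_text, cfg_text = NULL) {
  bnd <- if (length(bnd_text) == 1L) strsplit(bnd_text, "\n")[[1]] else bnd_text
  outputs <- character(0)
  out_ln <- grep("^\\s*//\\s*ctboolnet-outputs:", bnd, value = TRUE)
  if (length(out_ln))
    outputs <- strsplit(trimws(sub("^\\s*//\\s*ctboolnet-outputs:", "",
                                   out_ln[[1]])), "[[:space:]]+")[[1]]
  src <- paste(grep("^\\s*//", bnd, invert = TRUE, value = TRUE),
               collapse = "\n")
  rules <- list(); k_up <- numeric(0); k_down <- numeric(0)
  block_re <- "node[[:space:]]+([A-Za-z][A-Za-z0-9_./-]*)[[:space:]]*\\{([^}]*)\\}"
  ms <- gregexpr(block_re, src)[[1]]
  if (ms[1] < 0) stop("no node blocks found in .bnd text", call. = FALSE)
  starts <- as.integer(ms); lens <- attr(ms, "match.length")
  # reject trailing non-block content (unsupported grammar)
  covered <- unlist(mapply(function(s, l) s:(s + l - 1L), starts, lens,
                           SIMPLIFY = FALSE))
  rest <- strsplit(src, "")[[1]]
  rest[covered] <- " "
  if (grepl("[^[:space:]]", paste(rest, collapse = "")))
    stop("unsupported constructs outside node blocks in .bnd text",
         call. = FALSE)
  for (j in seq_along(starts)) {
    blk <- substr(src, starts[j], starts[j] + lens[j] - 1L)
    m <- regmatches(blk, regexec(block_re, blk))[[1]]
    nd <- m[2]; body <- m[3]
    if (!is.null(rules[[nd]]))
      stop(sprintf("duplicate node block '%s'", nd), call. = FALSE)
    stmts <- strsplit(body, ";", fixed = TRUE)[[1]]
    logic <- NULL
    for (st in stmts) {
      st <- trimws(st)
      if (st == "") next
      eq <- regexpr("=", st, fixed = TRUE)
      if (eq < 0) stop(sprintf("node '%s': malformed statement '%s'", nd, st),
                       call. = FALSE)
      key <- trimws(substr(st, 1L, eq - 1L))
      val <- trimws(substr(st, eq + 1L, nchar(st)))
      if (key == "logic") logic <- parse_bool_expr(val)
      else if (key == "rate_up") k_up[nd] <- parse_rate_field(val, "rate_up", nd)
      else if (key == "rate_down")
        k_down[nd] <- parse_rate_field(val, "rate_down", nd)
      else stop(sprintf("node '%s': unsupported field '%s'", nd, key),
                call. = FALSE)
    }
    if (is.null(logic))
      stop(sprintf("node '%s': missing logic", nd), call. = FALSE)
    rules[[nd]] <- logic
  }
  network <- boolean_network(rules, outputs = outputs,
                             k_up = k_up, k_down = k_down)
  config <- simulation_config(network)
  if (!is.null(cfg_text)) config <- parse_maboss_cfg(cfg_text, network, config)
  list(network = network, config = config)
}

parse_maboss_cfg <- function(cfg_text, network, config) {
  lines <- if (length(cfg_text) == 1L) strsplit(cfg_text, "\n")[[1]]
           else cfg_text
  internal <- character(0)
  for (li in seq_along(lines)) {
    ln <- trimws(sub("//.*$", "", lines[[li]]))
    ln <- sub(";\\s*$", "", ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      m <- regmatches(ln, regexec("^\\[([^]]+)\\]\\.istate[[:space:]]*=(.*)$",
                                  ln))[[1]]
      if (length(m) != 3L)
        stop(sprintf("cfg line %d: malformed istate '%s'", li, ln),
             call. = FALSE)
      nds <- trimws(strsplit(m[2], ",", fixed = TRUE)[[1]])
      if (length(bad <- setdiff(nds, network$nodes)))
        stop(sprintf("cfg line %d: istate references unknown node(s) %s",
                     li, paste(bad, collapse = ", ")), call. = FALSE)
      entries <- trimws(strsplit(m[3], ",(?![^[]*\\])", perl = TRUE)[[1]])
      probs <- numeric(0); states <- list()
      for (en in entries) {
        em <- regmatches(en,
          regexec("^([0-9.eE+-]+)[[:space:]]*\\[([01[:space:],]+)\\]$", en))[[1]]
        if (length(em) != 3L)
          stop(sprintf("cfg line %d: malformed istate entry '%s'", li, en),
               call. = FALSE)
        probs <- c(probs, parse_num(em[2], "istate probability"))
        st <- as.integer(trimws(strsplit(em[3], ",", fixed = TRUE)[[1]]))
        if (length(st) != length(nds))
          stop(sprintf("cfg line %d: istate state length mismatch", li),
               call. = FALSE)
        states[[length(states) + 1L]] <- st
      }
      if (abs(sum(probs) - 1) > 1e-9)
        stop(sprintf("cfg line %d: istate probabilities for [%s] sum to %g, not 1",
                     li, paste(nds, collapse = ","), sum(probs)), call. = FALSE)
      if (length(nds) == 1L) {
        p1 <- sum(probs[vapply(states, `[`, integer(1), 1L) == 1L])
        config$p0[nds] <- p1
      } else {
        config$joint[[length(config$joint) + 1L]] <-
          list(nodes = nds, states = states, probs = probs)
      }
    } else if (grepl("\\.is_internal[[:space:]]*=", ln)) {
      m <- regmatches(ln,
        regexec("^([A-Za-z][A-Za-z0-9_./-]*)\\.is_internal[[:space:]]*=[[:space:]]*(TRUE|FALSE|0|1)$",
                ln))[[1]]
      if (length(m) != 3L)
        stop(sprintf("cfg line %d: malformed is_internal '%s'", li, ln),
             call. = FALSE)
      if (!m[2] %in% network$nodes)
        stop(sprintf("cfg line %d: unknown node '%s'", li, m[2]), call. = FALSE)
      if (m[3] %in% c("TRUE", "1")) internal <- c(internal, m[2])
    } else {
      m <- regmatches(ln, regexec("^([A-Za-z_]+)[[:space:]]*=[[:space:]]*([0-9.eE+-]+)$",
                                  ln))[[1]]
      if (length(m) != 3L)
        stop(sprintf("cfg line %d: unsupported construct '%s'", li, ln),
             call. = FALSE)
      key <- m[2]; val <- parse_num(m[3], key)
      if (key == "sample_count") config$n_trajectories <- as.integer(val)
      else if (key == "max_time") config$max_time <- val
      else if (key == "time_tick") config$time_tick <- val
      else if (key == "seed") config$seed <- as.integer(val)
      else stop(sprintf("cfg line %d: unsupported setting '%s'", li, key),
                call. = FALSE)
    }
  }
  if (length(internal))
    config$tracked <- setdiff(config$tracked, internal)
  validate_config(config, network)
  config
}

#' Serialise a network (and optionally a config) to MaBoSS dialect
#'
#' @param network a [boolean_network()].
#' @param config optional [simulation_config()]; when given, a .cfg
#'   text is produced alongside the .bnd.
#' @return list with `bnd` and (if `config` given) `cfg` strings.
#' @export
write_maboss <- function(network, config = NULL) {
  blocks <- vapply(network$nodes, function(nd) {
    paste0("node ", nd, " {\n",
           "  logic = ", format_bool_expr(network$rules[[nd]], "maboss"), ";\n",
           sprintf("  rate_up = @logic ? %.17g : 0;\n", network$k_up[[nd]]),
           sprintf("  rate_down = @logic ? 0 : %.17g;\n", network$k_down[[nd]]),
           "}")
  }, character(1))
  bnd <- paste(c(sprintf("// ctboolnet-outputs: %s",
                         paste(network$outputs, collapse = " ")),
                 blocks), collapse = "\n\n")
  out <- list(bnd = bnd)
  if (!is.null(config)) {
    lines <- c(sprintf("sample_count = %d;", config$n_trajectories),
               sprintf("max_time = %.17g;", config$max_time),
               sprintf("time_tick = %.17g;", config$time_tick),
               sprintf("seed = %d;", config$seed))
    for (nd in network$nodes) {
      p <- config$p0[[nd]]
      lines <- c(lines,
                 sprintf("[%s].istate = %.17g [1], %.17g [0];", nd, p, 1 - p))
    }
    for (ja in config$joint) {
      entries <- vapply(seq_along(ja$probs), function(i) {
        sprintf("%.17g [%s]", ja$probs[i], paste(ja$states[[i]], collapse = ","))
      }, character(1))
      lines <- c(lines, sprintf("[%s].istate = %s;",
                                paste(ja$nodes, collapse = ","),
                                paste(entries, collapse = ", ")))
    }
    for (nd in setdiff(network$nodes, config$tracked)) {
      lines <- c(lines, sprintf("%s.is_internal = TRUE;", nd))
    }
    out$cfg <- paste(lines, collapse = "\n")
  }
  out
}
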