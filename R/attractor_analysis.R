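#' Round a probabilistic rule set to its closest deterministic system
#'
#' Each table entry becomes 1 when the ON-probability is at least 0.5 and
#' 0 otherwise: in the probabilistic state transition system all
#' transitions with probability below 0.5 are absent, so entries at or
#' above 0.5 persist. Exact-0.5 entries (where the deterministic
#' approximation is genuinely ill-defined) round to 1 and are reported in
#' the `ties` attribute and a message.
#'
#' @param rules a [infer_rules()] object, or a plain named list of
#'   [probabilistic_rule()]s.
#' @return list of class `det_rules`: `rules` (named list of
#'   [boolean_rule()]), `sources` (character).
#' @export
round_to_deterministic <- function(rules) {
  plist <- if (inherits(rules, "pbn_rules")) rules$rules else rules
  sources <- if (inherits(rules, "pbn_rules")) rules$sources else character(0)
  ties <- character(0)
  det <- lapply(plist, function(r) {
    if (any(r$probs == 0.5) && length(r$regulators) > 0) {
      ties <<- c(ties, r$target)
    }
    boolean_rule(r$target, r$regulators, as.integer(r$probs >= 0.5))
  })
  names(det) <- vapply(plist, `[[`, "", "target")
  if (length(ties)) {
    message("rounding ties at exactly 0.5 (rounded to 1) in: ",
            paste(unique(ties), collapse = ", "))
  }
  structure(list(rules = det, sources = sources, ties = unique(ties)),
            class = "det_rules")
}

#' Pin source nodes to their condition-average Boolean state
#'
#' A source node is pinned ON for a condition when its mean normalized
#' value across that condition's replicate samples exceeds 0.5, and OFF
#' otherwise (exact 0.5 pins OFF and is reported).
#'
#' @param training node x sample matrix with a `conditions` attribute, as
#'   produced by [build_training_matrix()] (a [normalize_expression()]
#'   object also works).
#' @param condition condition label.
#' @param source_nodes character vector of source node ids.
#' @return list of class `condition_pinning`: `condition`,
#'   `source_values` (named 0/1 integer vector).
#' @export
pin_source_nodes <- function(training, condition, source_nodes) {
  if (inherits(training, "norm_expr")) {
    cond <- training$conditions
    vals <- training$values
  } else {
    cond <- attr(training, "conditions")
    vals <- training
  }
  samples <- names(cond)[cond == condition]
  if (!length(samples)) config_error(sprintf("unknown condition '%s'", condition))
  miss <- setdiff(source_nodes, rownames(vals))
  if (length(miss)) {
    validation_error(paste("no training values for source node(s):",
                           paste(head(miss, 5), collapse = ", ")))
  }
  means <- rowMeans(vals[source_nodes, samples, drop = FALSE])
  ties <- source_nodes[means == 0.5]
  if (length(ties)) {
    message(sprintf("condition '%s': tie at mean 0.5 pinned OFF for: %s",
                    condition, paste(ties, collapse = ", ")))
  }
  structure(list(condition = condition,
                 source_values = setNames(as.integer(means > 0.5), source_nodes)),
            class = "condition_pinning")
}

#' Propagate pinned constants through a deterministic rule set
#'
#' Substitutes the pinned source values into every rule; any rule that
#' becomes constant fixes its node, and propagation repeats until no new
#' node is forced. Substitution is confluent, so the processing order
#' (exposed for testing) does not change the result.
#'
#' @param det a [round_to_deterministic()] object.
#' @param pinning a [pin_source_nodes()] object, or a named 0/1 vector.
#' @param order optional permutation of node ids controlling the sweep
#'   order.
#' @return list of class `reduced_system`: `rules` (free-node
#'   [boolean_rule()]s over free regulators only), `fixed` (named 0/1
#'   vector of pinned plus forced nodes).
#' @export
propagate_constants <- function(det, pinning, order = NULL) {
  fixed <- if (inherits(pinning, "condition_pinning")) {
    pinning$source_values
  } else {
    vapply(pinning, as.integer, integer(1))
  }
  unpinned <- setdiff(det$sources, names(fixed))
  if (length(unpinned)) {
    validation_error(paste("pinning does not cover source node(s):",
                           paste(head(unpinned, 5), collapse = ", ")))
  }
  rules <- det$rules
  ids <- names(rules)
  if (!is.null(order)) {
    ids <- intersect(order, ids)
    if (length(ids) != length(rules)) validation_error("order must permute the rule nodes")
  }
  free <- setdiff(ids, names(fixed))
  repeat {
    changed <- FALSE
    for (id in free) {
      r <- restrict_rule(rules[[id]], fixed)
      rules[[id]] <- r
      vals <- unique(r$table)
      if (length(vals) == 1L) {
        fixed[id] <- vals
        free <- setdiff(free, id)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rules <- lapply(rules[free], restrict_rule, fixed = fixed)
  structure(list(rules = rules, fixed = fixed), class = "reduced_system")
}

# successor table of the general-asynchronous STG: for the 2^m states of
# the free nodes, the next value of each node under its restricted rule.
# Returns an integer matrix (2^m x m) of next values.
stg_next_values <- function(rules, free) {
  m <- length(free)
  states <- 0:(2^m - 1)
  pos <- setNames(seq_len(m) - 1L, free)
  vapply(seq_len(m), function(j) {
    r <- rules[[free[j]]]
    if (length(r$regulators) == 0) {
      rep(r$table[1L], length(states))
    } else {
      idx <- rep(0L, length(states))
      for (k in seq_along(r$regulators)) {
        bit <- bitwAnd(bitwShiftR(states, pos[[r$regulators[k]]]), 1L)
        idx <- idx + bit * 2L^(k - 1L)
      }
      r$table[idx + 1L]
    }
  }, integer(length(states)))
}

#' Find the pseudo-attractors of a reduced deterministic system
#'
#' Builds the general-asynchronous state transition graph (one node
#' updated per step) over the free nodes and finds its terminal strongly
#' connected components. Singleton terminal SCCs are steady states;
#' larger ones report the nodes whose value varies inside the component
#' as oscillating. The pinned/forced assignments are merged back into
#' each attractor. A finite deterministic asynchronous system always has
#' at least one terminal SCC, so at least one attractor is returned.
#'
#' @param reduced a [propagate_constants()] object.
#' @param condition condition label attached to the attractors.
#' @param bound maximum free-node count for the exhaustive search
#'   (default 20); beyond it an error asks for stronger pinning.
#' @return list of `pseudo_attractor` objects: `condition`, `state`
#'   (named 0/1 vector over all nodes, oscillating nodes `NA`),
#'   `oscillating` (character).
#' @export
find_pseudo_attractors <- function(reduced, condition = NA_character_,
                                   bound = 20) {
  free <- names(reduced$rules)
  m <- length(free)
  if (m > bound) {
    config_error(sprintf(
      "%d free nodes exceed the exhaustive bound (%d); pin more sources or raise `bound`",
      m, bound))
  }
  mk <- function(state_bits) {
    st <- c(reduced$fixed, setNames(state_bits, free))
    structure(list(condition = condition, state = st,
                   oscillating = names(st)[is.na(st)]),
              class = "pseudo_attractor")
  }
  if (m == 0) return(list(mk(integer(0))))

  nxt <- stg_next_values(reduced$rules, free)
  states <- 0:(2^m - 1)
  cur <- vapply(seq_len(m), function(j) bitwAnd(bitwShiftR(states, j - 1L), 1L),
                integer(length(states)))
  from <- integer(0); to <- integer(0)
  for (j in seq_len(m)) {
    ch <- which(nxt[, j] != cur[, j])
    from <- c(from, ch)
    to <- c(to, bitwXor(states[ch], 2L^(j - 1L)) + 1L)
  }
  g <- igraph::make_empty_graph(n = length(states), directed = TRUE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  cross <- memb[from] != memb[to]
  nonterminal <- unique(memb[from][cross])
  terminal <- setdiff(seq_len(comp$no), nonterminal)
  lapply(terminal, function(ci) {
    sts <- states[memb == ci]
    bits <- vapply(seq_len(m),
                   function(j) bitwAnd(bitwShiftR(sts, j - 1L), 1L),
                   integer(length(sts)))
    bits <- matrix(bits, nrow = length(sts))
    vals <- bits[1, ]
    osc <- apply(bits, 2, function(b) length(unique(b)) > 1)
    vals[osc] <- NA_integer_
    mk(vals)
  })
}

#' @export
print.pseudo_attractor <- function(x, ...) {
  st <- ifelse(is.na(x$state), "osc", x$state)
  cat(sprintf("<pseudo_attractor> condition=%s  %s\n", x$condition,
              paste(sprintf("%s=%s", names(st), st), collapse = " ")))
  invisible(x)
}

#' Identify pseudo-attractors for every condition
#'
#' Convenience wrapper: rounds the inferred rules, pins the source nodes
#' per condition, propagates constants and runs the exhaustive attractor
#' search.
#'
#' @param rules a [infer_rules()] object.
#' @param conditions condition labels (default: all in the training
#'   matrix's condition map).
#' @param bound exhaustive search bound on free nodes (default 20).
#' @return list of `pseudo_attractor` objects across conditions.
#' @export
pseudo_attractors <- function(rules, conditions = NULL, bound = 20) {
  det <- round_to_deterministic(rules)
  cmap <- attr(rules$training, "conditions")
  if (is.null(conditions)) conditions <- unique(unname(cmap))
  out <- list()
  for (cond in conditions) {
    pin <- pin_source_nodes(rules$training, cond, rules$sources)
    red <- propagate_constants(det, pin)
    out <- c(out, find_pseudo_attractors(red, cond, bound = bound))
  }
  out
}

#' Per-module mean activation of a set of pseudo-attractors
#'
#' For each module and condition, the mean over attractors of the
#' fraction of the module's non-source nodes that are ON; oscillating
#' nodes count 0.5.
#'
#' @param attractors list of `pseudo_attractor` objects.
#' @param modules named character vector node id (or gene) -> module.
#' @param source_nodes nodes excluded from the fraction.
#' @return data frame (condition, module, activation).
#' @export
attractor_module_summary <- function(attractors, modules, source_nodes = character(0)) {
  rows <- list()
  for (att in attractors) {
    st <- att$state
    nodes <- setdiff(names(st), source_nodes)
    mod <- module_of_nodes(nodes, modules)
    for (m in setdiff(unique(mod), NA)) {
      v <- st[nodes[!is.na(mod) & mod == m]]
      frac <- mean(ifelse(is.na(v), 0.5, v))
      rows[[length(rows) + 1L]] <- data.frame(condition = att$condition,
                                              module = m, activation = frac)
    }
  }
  agg <- do.call(rbind, rows)
  out <- stats::aggregate(activation ~ condition + module, agg, mean)
  out[order(out$condition, out$module), ]
}

# map node ids to module labels, falling back to the gene behind a
# split-node suffix; unmapped nodes give NA
module_of_nodes <- function(ids, modules) {
  m <- modules[ids]
  fb <- is.na(m)
  m[fb] <- modules[node_gene(ids[fb])]
  unname(m)
}

#' Average start state of a condition's pseudo-attractors
#'
#' Per node, the mean of its value across the attractors (oscillating
#' counts 0.5), thresholded at strictly greater than 0.5 (ties resolve
#' OFF).
#'
#' @param attractors nonempty list of `pseudo_attractor` objects (one
#'   condition).
#' @return named 0/1 integer vector over all nodes.
#' @export
average_start_state <- function(attractors) {
  if (!length(attractors)) validation_error("need at least one attractor")
  nodes <- names(attractors[[1]]$state)
  sts <- vapply(attractors, function(a) {
    unname(ifelse(is.na(a$state[nodes]), 0.5, a$state[nodes]))
  }, numeric(length(nodes)))
  means <- rowMeans(matrix(sts, nrow = length(nodes)))
  setNames(as.integer(means > 0.5), nodes)
}

#' Write an attractor table
#'
#' One row per attractor, one column per node; values 0, 1 or `"osc"`.
#'
#' @param attractors list of `pseudo_attractor` objects.
#' @param path output CSV path, or `NULL` to just return the table.
#' @return the data frame, invisibly when written.
#' @export
attractor_table <- function(attractors, path = NULL) {
  nodes <- sort(unique(unlist(lapply(attractors, function(a) names(a$state)))))
  rows <- lapply(attractors, function(a) {
    v <- a$state[nodes]
    out <- data.frame(condition = a$condition)
    out[nodes] <- ifelse(is.na(v), "osc", as.character(v))
    out
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
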