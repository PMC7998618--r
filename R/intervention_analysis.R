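#' Necessary/sufficient regulation profile of one edge
#'
#' Quantifies how the source regulator shapes the target's probabilistic
#' rule. `avgON` and `avgOFF` are the unweighted means of the rule output
#' over the `2^(N-1)` configurations of the co-regulators with the source
#' ON and OFF respectively. A positive edge (`avgON > avgOFF`) scores
#' `NON = 1 - avgOFF` (source necessary for target ON) and `SON = avgON`
#' (source sufficient for target ON) with `NOFF = SOFF = 0`; a negative
#' edge scores `NOFF = avgOFF`, `SOFF = 1 - avgON` with `NON = SON = 0`.
#' When `avgON = avgOFF` the edge has no net direction and all four
#' scores are 0.
#'
#' @param rule the target's [probabilistic_rule()].
#' @param source one of the rule's regulators.
#' @return list of class `edge_profile`: `source`, `target`, `avgON`,
#'   `avgOFF`, `sign` (`"positive"`, `"negative"` or `"none"`), `NON`,
#'   `SON`, `NOFF`, `SOFF`.
#' @export
edge_regulation_profile <- function(rule, source) {
  j <- match(source, rule$regulators)
  if (is.na(j)) {
    validation_error(sprintf("'%s' is not a regulator of '%s'", source,
                             rule$target))
  }
  cfg <- config_states(length(rule$regulators))
  on <- cfg[, j] == 1
  avgON <- mean(rule$probs[on])
  avgOFF <- mean(rule$probs[!on])
  if (avgON > avgOFF) {
    sign <- "positive"
    scores <- c(NON = 1 - avgOFF, SON = avgON, NOFF = 0, SOFF = 0)
  } else if (avgON < avgOFF) {
    sign <- "negative"
    scores <- c(NON = 0, SON = 0, NOFF = avgOFF, SOFF = 1 - avgON)
  } else {
    sign <- "none"
    scores <- c(NON = 0, SON = 0, NOFF = 0, SOFF = 0)
  }
  structure(c(list(source = source, target = rule$target, avgON = avgON,
                   avgOFF = avgOFF, sign = sign), as.list(scores)),
            class = "edge_profile")
}

#' Influence index of a node intervention on a module
#'
#' Estimates how well the direct effects of knocking out (KO) or
#' constitutively activating (CA) a node align with an up- or
#' down-regulation goal for a module, by summing necessary/sufficient
#' edge scores over the node's targets inside the module:
#' \itemize{
#'   \item KO, DOWN: `sum (NON - NOFF) + 0.5 (SON - SOFF)`
#'   \item KO, UP:   `sum (NOFF - NON) + 0.5 (SOFF - SON)`
#'   \item CA, DOWN: `sum (SOFF - SON) + 0.5 (NOFF - NON)`
#'   \item CA, UP:   `sum (SON - SOFF) + 0.5 (NON - NOFF)`
#' }
#' Necessary edges weigh more under KO (turning OFF a necessary regulator
#' suffices to turn its target OFF), sufficient edges weigh more under CA.
#' A node with no targets in the module scores 0.
#'
#' @param node the intervened node id.
#' @param mode `"KO"` or `"CA"`.
#' @param module target module label.
#' @param rules a [infer_rules()] object or named list of
#'   [probabilistic_rule()]s.
#' @param modules named character vector node/gene -> module label.
#' @param goal `"UP"` or `"DOWN"`.
#' @return scalar influence index.
#' @export
influence_index <- function(node, mode = c("KO", "CA"), module, rules,
                            modules, goal = c("DOWN", "UP")) {
  mode <- match.arg(mode)
  goal <- match.arg(goal)
  plist <- if (inherits(rules, "pbn_rules")) rules$rules else rules
  total <- 0
  for (rule in plist) {
    if (!(node %in% rule$regulators)) next
    tmod <- module_of_nodes(rule$target, modules)
    if (is.na(tmod) || tmod != module) next
    pr <- edge_regulation_profile(rule, node)
    term <- switch(paste(mode, goal),
      "KO DOWN" = (pr$NON - pr$NOFF) + 0.5 * (pr$SON - pr$SOFF),
      "KO UP"   = (pr$NOFF - pr$NON) + 0.5 * (pr$SOFF - pr$SON),
      "CA DOWN" = (pr$SOFF - pr$SON) + 0.5 * (pr$NOFF - pr$NON),
      "CA UP"   = (pr$SON - pr$SOFF) + 0.5 * (pr$NON - pr$NOFF))
    total <- total + term
  }
  total
}

#' Influence indices for every node/mode/module/goal combination
#'
#' @inheritParams influence_index
#' @param nodes nodes to score (default: every regulator appearing in the
#'   rules).
#' @return data frame (node, mode, module, goal, index) sorted by
#'   decreasing index.
#' @export
influence_table <- function(rules, modules, nodes = NULL) {
  plist <- if (inherits(rules, "pbn_rules")) rules$rules else rules
  if (is.null(nodes)) {
    nodes <- sort(unique(unlist(lapply(plist, `[[`, "regulators"))))
  }
  mods <- setdiff(unique(modules), "unassigned")
  grid <- expand.grid(node = nodes, mode = c("KO", "CA"), module = mods,
                      goal = c("DOWN", "UP"), stringsAsFactors = FALSE)
  grid$index <- mapply(function(n, mo, m, g) {
    influence_index(n, mo, m, rules, modules, g)
  }, grid$node, grid$mode, grid$module, grid$goal)
  grid[order(-grid$index), ]
}

#' Apply KO/CA interventions to a rule set
#'
#' KO nodes are fixed OFF and CA nodes fixed ON: their update rules are
#' replaced by constants and they are added to the held set so that walks
#' never update them. An intervention on a gene that was split into
#' transcript and active forms applies to both forms.
#'
#' @param rules a [infer_rules()] object or named list of
#'   [probabilistic_rule()]s.
#' @param spec data frame with columns `node`, `mode` (`"KO"`/`"CA"`); a
#'   node may appear at most once.
#' @return list: `rules` (with constants substituted), `held` (named 0/1
#'   vector of controlled node values, split forms expanded).
#' @export
apply_intervention <- function(rules, spec) {
  plist <- if (inherits(rules, "pbn_rules")) rules$rules else rules
  if (nrow(spec) == 0) return(list(rules = rules, held = setNames(integer(0), character(0))))
  if (anyDuplicated(spec$node)) {
    validation_error("intervention spec lists a node more than once")
  }
  all_ids <- unique(c(names(plist),
                      unlist(lapply(plist, `[[`, "regulators")),
                      if (inherits(rules, "pbn_rules")) rules$sources))
  held <- integer(0)
  for (i in seq_len(nrow(spec))) {
    gene <- spec$node[i]
    val <- if (spec$mode[i] == "KO") 0L else 1L
    forms <- intersect(c(gene, paste0(gene, "_T"), paste0(gene, "_A")), all_ids)
    if (!length(forms)) {
      validation_error(sprintf("intervention target '%s' is not in the system", gene))
    }
    held[forms] <- val
  }
  for (id in names(held)) {
    if (id %in% names(plist)) {
      plist[[id]] <- probabilistic_rule(id, character(0), held[[id]],
                                        support = NULL, inferred = FALSE)
    }
  }
  if (inherits(rules, "pbn_rules")) rules$rules <- plist else rules <- plist
  list(rules = rules, held = held)
}

# Compile a probabilistic system for walking: node index table, per-node
# regulator indices (0-based) and probability tables. Nodes without a
# rule and not held fall back to the uninformative constant-0.5 prior.
compile_walk_system <- function(rules, held = setNames(integer(0), character(0))) {
  plist <- if (inherits(rules, "pbn_rules")) rules$rules else rules
  nodes <- unique(c(names(plist),
                    unlist(lapply(plist, `[[`, "regulators")),
                    if (inherits(rules, "pbn_rules")) rules$sources,
                    names(held)))
  nodes <- sort(nodes)
  idx <- setNames(seq_along(nodes), nodes)
  reg_idx <- vector("list", length(nodes))
  prob_tab <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    r <- plist[[nodes[i]]]
    if (is.null(r)) {
      reg_idx[[i]] <- integer(0)
      prob_tab[[i]] <- 0.5
    } else {
      reg_idx[[i]] <- unname(idx[r$regulators]) - 1L
      prob_tab[[i]] <- r$probs
    }
  }
  free <- setdiff(nodes, names(held))
  list(nodes = nodes, idx = idx, reg_idx = reg_idx, prob_tab = prob_tab,
       free = free)
}

#' Simulate one asynchronous random walk (reference implementation)
#'
#' At each step one non-held node is chosen uniformly at random and set
#' ON with the probability its rule assigns to the current regulator
#' configuration (OFF otherwise). Held nodes are never selected. This
#' pure-R version returns the full state trajectory and consumes the RNG
#' identically to the compiled core used by [switch_time_experiment()],
#' so the two can be cross-checked under a common seed.
#'
#' @param rules a [infer_rules()] object or named list of
#'   [probabilistic_rule()]s.
#' @param start named 0/1 vector assigning every node.
#' @param held named 0/1 vector of held nodes (interventions and pinned
#'   sources); their start values are overridden by `held`.
#' @param n_steps number of update attempts.
#' @param seed optional integer seed.
#' @return integer matrix with `n_steps + 1` rows (step 0 = start state)
#'   and one column per node.
#' @export
simulate_walk <- function(rules, start, held = setNames(integer(0), character(0)),
                          n_steps = 5000, seed = NULL) {
  sys <- compile_walk_system(rules, held)
  miss <- setdiff(sys$nodes, names(start))
  if (length(miss)) {
    validation_error(paste("start state misses nodes:",
                           paste(head(miss, 5), collapse = ", ")))
  }
  state <- start[sys$nodes]
  state[names(held)] <- held
  if (!is.null(seed)) set.seed(seed)
  free_i <- unname(sys$idx[sys$free])
  traj <- matrix(NA_integer_, nrow = n_steps + 1, ncol = length(sys$nodes),
                 dimnames = list(NULL, sys$nodes))
  traj[1, ] <- state
  for (step in seq_len(n_steps)) {
    j <- free_i[floor(runif(1) * length(free_i)) + 1L]
    regs <- sys$reg_idx[[j]] + 1L
    p <- sys$prob_tab[[j]][config_index(state[regs])]
    state[j] <- as.integer(runif(1) < p)
    traj[step + 1, ] <- state
  }
  traj
}

#' Module activation of a network state
#'
#' The fraction of the module's non-source nodes that are ON, banded as
#' low (`< 1/4`), intermediate (`1/4` to `3/4`, boundaries inclusive) or
#' high (`> 3/4`). Source nodes are excluded because interventions cannot
#' change them.
#'
#' @param state named 0/1 vector.
#' @param module_nodes node ids of the module.
#' @param source_nodes source node ids to exclude.
#' @return list with `fraction` and `band`.
#' @export
module_activation <- function(state, module_nodes, source_nodes = character(0)) {
  members <- setdiff(module_nodes, source_nodes)
  if (!length(members)) {
    validation_error("module has no non-source nodes")
  }
  frac <- mean(state[members])
  band <- if (frac < 0.25) "low" else if (frac <= 0.75) "intermediate" else "high"
  list(fraction = frac, band = band)
}

#' First switching time of a module-activation trajectory
#'
#' @param fractions numeric vector of module activation fractions, one
#'   per step (step 0, the start state, excluded).
#' @param start_band `"low"` or `"intermediate"`.
#' @return the 1-based step of the first band crossing (low starts cross
#'   into intermediate-or-higher, intermediate starts into low), or
#'   `length(fractions) + 1` if the module never switches.
#' @export
first_switch_time <- function(fractions, start_band = c("low", "intermediate")) {
  start_band <- match.arg(start_band)
  bands <- ifelse(fractions < 0.25, "low",
                  ifelse(fractions <= 0.75, "intermediate", "high"))
  hit <- if (start_band == "low") which(bands != "low") else which(bands == "low")
  if (length(hit)) hit[1] else length(fractions) + 1L
}

#' Measure module switching times over repeated random walks
#'
#' Runs `n_walks` independent asynchronous walks from the same start
#' state and records, per tracked module, the first step at which the
#' module's activation crosses out of its start band (low starts cross
#' into intermediate, intermediate starts into low). Walks that never
#' switch are censored at `n_steps + 1`. Modules that start in the high
#' band are dropped with a warning (that transition is not scored). Each
#' walk uses seed `seed + walk_index`.
#'
#' @inheritParams simulate_walk
#' @param module_map named character vector node/gene -> module label.
#' @param source_nodes nodes excluded from activation fractions.
#' @param tracked_modules module labels to track (default: all labels
#'   with at least one non-source member node).
#' @param start_bands optional named vector of `"low"`/`"intermediate"`
#'   overriding the bands computed from the start state (used to keep the
#'   wild-type band definition when simulating an intervention).
#' @param n_walks number of walks (default 100).
#' @param n_steps walk length (default 5000).
#' @param seed master seed.
#' @return data frame (module, start_band, walk, time).
#' @export
switch_time_experiment <- function(rules, start, held = setNames(integer(0), character(0)),
                                   module_map, source_nodes = character(0),
                                   tracked_modules = NULL, start_bands = NULL,
                                   n_walks = 100, n_steps = 5000, seed = 1) {
  sys <- compile_walk_system(rules, held)
  miss <- setdiff(sys$nodes, names(start))
  if (length(miss)) {
    validation_error(paste("start state misses nodes:",
                           paste(head(miss, 5), collapse = ", ")))
  }
  state0 <- start[sys$nodes]
  state0[names(held)] <- held
  node_mod <- module_of_nodes(sys$nodes, module_map)
  if (is.null(tracked_modules)) {
    tracked_modules <- setdiff(sort(unique(node_mod)), "unassigned")
  }
  members <- list()
  bands <- integer(0)
  kept <- character(0)
  for (m in tracked_modules) {
    mem <- sys$nodes[!is.na(node_mod) & node_mod == m]
    mem <- setdiff(mem, source_nodes)
    if (!length(mem)) {
      validation_error(sprintf("module '%s' has no non-source nodes", m))
    }
    band <- if (!is.null(start_bands) && m %in% names(start_bands)) {
      start_bands[[m]]
    } else {
      module_activation(state0, mem)$band
    }
    if (band == "high") {
      warning(sprintf("module '%s' starts in the high band; not tracked", m))
      next
    }
    kept <- c(kept, m)
    members[[length(members) + 1L]] <- unname(sys$idx[mem]) - 1L
    bands <- c(bands, if (band == "low") 0L else 1L)
  }
  if (!length(kept)) validation_error("no trackable modules")
  out <- vector("list", n_walks)
  for (w in seq_len(n_walks)) {
    set.seed(seed + w)
    res <- walk_switch_core(as.integer(state0), sys$reg_idx, sys$prob_tab,
                            unname(sys$idx[sys$free]) - 1L, members, bands,
                            as.integer(n_steps), TRUE)
    out[[w]] <- data.frame(module = kept,
                           start_band = ifelse(bands == 0, "low", "intermediate"),
                           walk = w, time = res$switch_times)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Compare intervention switching times against wild type
#'
#' Two-sided Mann-Whitney U test per (intervention, module) between the
#' wild-type and intervention switching-time distributions, with
#' Benjamini-Hochberg adjustment across the whole batch. Significant
#' interventions (adjusted p below `alpha`) are classified by the
#' direction of the mean shift: a module that starts low and switches
#' more slowly under intervention is being held down (downregulating),
#' while switching faster means upregulating; for intermediate starts the
#' interpretation flips.
#'
#' @param wt_times data frame (module, start_band, walk, time) from
#'   [switch_time_experiment()] of the unperturbed system.
#' @param int_times same format with an extra `intervention` column (one
#'   or several interventions).
#' @param alpha significance level on the adjusted p-values (default
#'   0.05).
#' @return data frame (intervention, module, start_band, p, p_adj,
#'   mean_shift, classification).
#' @export
compare_interventions <- function(wt_times, int_times, alpha = 0.05) {
  if (is.null(int_times$intervention)) int_times$intervention <- "intervention"
  rows <- list()
  for (iv in unique(int_times$intervention)) {
    sub <- int_times[int_times$intervention == iv, ]
    for (m in unique(sub$module)) {
      x <- sub$time[sub$module == m]
      y <- wt_times$time[wt_times$module == m]
      if (!length(y)) next
      if (length(x) != length(y)) {
        validation_error(sprintf("walk counts differ for module '%s'", m))
      }
      band <- wt_times$start_band[wt_times$module == m][1]
      p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
      if (is.nan(p)) p <- 1  # identical constant distributions
      shift <- (mean(x) - mean(y)) / mean(y)
      rows[[length(rows) + 1L]] <- data.frame(
        intervention = iv, module = m, start_band = band, p = p,
        mean_shift = shift)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  slower <- out$mean_shift > 0
  cls <- ifelse(out$start_band == "low",
                ifelse(slower, "downregulating", "upregulating"),
                ifelse(slower, "upregulating", "downregulating"))
  cls[out$mean_shift == 0] <- "none"
  cls[out$p_adj >= alpha] <- "none"
  out$classification <- cls
  out[c("intervention", "module", "start_band", "p", "p_adj", "mean_shift",
        "classification")]
}

#' Run the full intervention analysis for one condition
#'
#' Pins the source nodes for the condition, builds the condition's
#' average start state from its pseudo-attractors, measures wild-type
#' switching times, then repeats under each intervention and classifies
#' the significant effects.
#'
#' @param rules a [infer_rules()] object.
#' @param condition condition label.
#' @param module_map named character vector gene -> module label.
#' @param interventions named list of intervention data frames
#'   (`node`, `mode`), one entry per intervention to test.
#' @param n_walks,n_steps,seed,alpha simulation and test parameters
#'   (defaults 100 walks of 5000 steps, seed 1, alpha 0.05).
#' @param bound exhaustive attractor-search bound.
#' @return list: `start_state`, `wt_times`, `int_times`, `results`.
#' @export
run_intervention_analysis <- function(rules, condition, module_map,
                                      interventions, n_walks = 100,
                                      n_steps = 5000, seed = 1, alpha = 0.05,
                                      bound = 20) {
  atts <- pseudo_attractors(rules, conditions = condition, bound = bound)
  start <- average_start_state(atts)
  pin <- pin_source_nodes(rules$training, condition, rules$sources)
  held_wt <- pin$source_values
  wt <- switch_time_experiment(rules, start, held_wt, module_map,
                               source_nodes = rules$sources,
                               n_walks = n_walks, n_steps = n_steps,
                               seed = seed)
  int_all <- list()
  for (iv in names(interventions)) {
    ap <- apply_intervention(rules, interventions[[iv]])
    held <- held_wt
    held[names(ap$held)] <- ap$held
    wt_bands <- setNames(wt$start_band[!duplicated(wt$module)],
                         wt$module[!duplicated(wt$module)])
    ti <- switch_time_experiment(ap$rules, start, held, module_map,
                                 source_nodes = rules$sources,
                                 tracked_modules = unique(wt$module),
                                 start_bands = wt_bands,
                                 n_walks = n_walks, n_steps = n_steps,
                                 seed = seed)
    ti$intervention <- iv
    int_all[[iv]] <- ti
  }
  int_times <- do.call(rbind, int_all)
  rownames(int_times) <- NULL
  results <- compare_interventions(wt, int_times, alpha = alpha)
  list(start_state = start, wt_times = wt, int_times = int_times,
       results = results)
}
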