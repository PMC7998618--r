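#' The ground-truth rule family
#'
#' Generated networks draw each non-source node's deterministic update
#' rule from a family spanning the functional forms the inference stage
#' must recover: single-regulator identity or negation, two-input AND/OR
#' with random literal signs, and the three-input inhibitory-dominant
#' form `(a1 OR a2) AND NOT i`.
#'
#' @param form one of `"id"`, `"not"`, `"and"`, `"or"`, `"inhdom"`.
#' @param target,regulators node ids; `regulators` length must match the
#'   form (1, 2 or 3).
#' @param signs integer vector of literal signs (+1 activating, -1
#'   inhibiting); ignored for `"id"`/`"not"`/`"inhdom"`, whose signs are
#'   implied.
#' @return a [boolean_rule()] with attributes `form` and `signs`.
#' @export
family_rule <- function(form, target, regulators, signs = NULL) {
  n <- length(regulators)
  cfg <- config_states(n)
  table <- switch(form,
    id = { stopifnot(n == 1); signs <- 1L; cfg[, 1] },
    "not" = { stopifnot(n == 1); signs <- -1L; 1L - cfg[, 1] },
    and = {
      stopifnot(n == 2, length(signs) == 2)
      lit <- sweep_signs(cfg, signs)
      as.integer(lit[, 1] & lit[, 2])
    },
    or = {
      stopifnot(n == 2, length(signs) == 2)
      lit <- sweep_signs(cfg, signs)
      as.integer(lit[, 1] | lit[, 2])
    },
    inhdom = {
      stopifnot(n == 3)
      signs <- c(1L, 1L, -1L)
      as.integer((cfg[, 1] | cfg[, 2]) & !cfg[, 3])
    },
    config_error(sprintf("unknown rule form '%s'", form))
  )
  rule <- boolean_rule(target, regulators, table)
  attr(rule, "form") <- form
  attr(rule, "signs") <- signs
  rule
}

sweep_signs <- function(cfg, signs) {
  out <- cfg
  out[, signs < 0] <- 1L - out[, signs < 0, drop = FALSE]
  out
}

# draw a random family rule with the given regulators
draw_family_rule <- function(target, regulators) {
  n <- length(regulators)
  if (n == 1) {
    family_rule(sample(c("id", "not"), 1), target, regulators)
  } else if (n == 2) {
    family_rule(sample(c("and", "or"), 1), target, regulators,
                signs = sample(c(-1L, 1L), 2, replace = TRUE))
  } else {
    family_rule("inhdom", target, regulators)
  }
}

#' Generate a ground-truth Boolean network model
#'
#' Builds a weakly connected deterministic Boolean network with at least
#' one source node and at least one feedback loop. About 20\% of nodes
#' are sources; every non-source node draws its rule from the
#' [family_rule()] family (in-degree at most `min(max_in_degree, 3)`).
#' Source nodes are guaranteed at least one outgoing edge. Module labels
#' partition the non-source nodes; sources are labeled `"unassigned"`.
#'
#' @param n_nodes number of genes (at least 4).
#' @param n_modules number of module labels besides `"unassigned"`.
#' @param max_in_degree maximum regulators per node (at most 5; the rule
#'   family uses at most 3).
#' @param seed integer RNG seed; identical seeds give identical models.
#' @return an object of class `ground_truth_model`: `nodes`, `modules`
#'   (named character), `tf_flags` (named logical), `rules` (named list
#'   of [boolean_rule()]), `source_nodes`, `seed`.
#' @export
generate_ground_truth_network <- function(n_nodes, n_modules = 3,
                                          max_in_degree = 3, seed = 1) {
  if (n_nodes < 4) config_error("n_nodes must be at least 4")
  if (max_in_degree < 1 || max_in_degree > 5) {
    config_error("max_in_degree must be between 1 and 5")
  }
  if (n_modules < 1 || n_modules > n_nodes) {
    config_error("n_modules must be between 1 and n_nodes")
  }
  kmax <- min(max_in_degree, 3L)
  with_seed(seed, {
    nodes <- sprintf("G%03d", seq_len(n_nodes))
    n_src <- max(1L, round(0.2 * n_nodes))
    if (n_nodes - n_src < 2L) n_src <- n_nodes - 2L
    sources <- nodes[seq_len(n_src)]
    nonsrc <- nodes[(n_src + 1):n_nodes]

    regs <- list()
    for (i in seq_along(nonsrc)) {
      gi <- n_src + i
      # the first regulator of the first non-source node is a source and
      # every later node anchors to an earlier non-source node, so the
      # non-source chain forms one weakly connected tree; the remaining
      # regulators may come from anywhere, making feedback loops
      # plentiful as in real regulatory networks
      k <- sample.int(kmax, 1)
      anchor_pool <- if (i == 1) sources else nonsrc[seq_len(i - 1)]
      first <- sample(anchor_pool, 1)
      pool <- setdiff(nodes, c(nonsrc[i], first))
      rest <- if (k > 1) sample(pool, k - 1) else character(0)
      regs[[nonsrc[i]]] <- c(first, rest)
    }
    # guarantee a feedback loop u -> v -> u between the first two
    # non-source nodes
    u <- nonsrc[1]; v <- nonsrc[2]
    regs[[u]] <- c(sample(sources, 1), v)
    if (!u %in% regs[[v]]) regs[[v]][1] <- u
    regs[[v]] <- unique(regs[[v]])
    # every source must regulate something (no isolated sources)
    used <- unique(unlist(regs))
    for (s in setdiff(sources, used)) {
      open <- nonsrc[vapply(regs[nonsrc], length, 1L) < kmax]
      tgt <- if (length(open)) open[1] else nonsrc[length(nonsrc)]
      if (length(regs[[tgt]]) < kmax) {
        regs[[tgt]] <- c(regs[[tgt]], s)
      } else {
        repl <- regs[[tgt]][!regs[[tgt]] %in% c(u, v)]
        pick <- if (length(repl)) repl[1] else regs[[tgt]][1]
        regs[[tgt]][match(pick, regs[[tgt]])] <- s
      }
    }
    rules <- lapply(setNames(nonsrc, nonsrc), function(id) {
      draw_family_rule(id, regs[[id]])
    })

    mods <- setNames(rep("unassigned", n_nodes), nodes)
    labels <- paste0("M", seq_len(n_modules))
    assign <- sample(labels, length(nonsrc), replace = TRUE)
    # make sure no module label is empty when feasible
    for (lab in setdiff(labels, unique(assign))) {
      slot <- which.max(tabulate(match(assign, labels), length(labels)))
      assign[which(assign == labels[slot])[1]] <- lab
    }
    mods[nonsrc] <- assign
    tf <- setNames(runif(n_nodes) < 0.7, nodes)

    structure(list(nodes = nodes, modules = mods, tf_flags = tf,
                   rules = rules, source_nodes = sources, seed = seed),
              class = "ground_truth_model")
  })
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf("<ground_truth_model> %d nodes (%d sources), %d modules, seed %d\n",
              length(x$nodes), length(x$source_nodes),
              length(setdiff(unique(x$modules), "unassigned")), x$seed))
  invisible(x)
}

#' Specification of a synthetic expression experiment
#'
#' @param n_conditions,n_replicates experiment shape (defaults 6 x 3,
#'   the triplicate six-condition layout the pipeline expects).
#' @param high_range,low_range FPKM intervals for ON and OFF genes
#'   (defaults `[20, 200]` and `[0, 2]`; `high_range` must lie strictly
#'   above `low_range` so the 20th/80th-percentile normalization
#'   separates the two states).
#' @param noise_sd standard deviation of the lognormal replicate noise
#'   (default 0.2).
#' @param dropout_rate probability of zeroing an entry (default 0).
#' @return list of class `synthetic_expression_spec`.
#' @export
synthetic_expression_spec <- function(n_conditions = 6, n_replicates = 3,
                                      high_range = c(20, 200),
                                      low_range = c(0, 2), noise_sd = 0.2,
                                      dropout_rate = 0) {
  if (min(high_range) <= max(low_range)) {
    config_error("high_range must be strictly above low_range")
  }
  if (n_conditions * n_replicates < 2) {
    config_error("need at least 2 samples")
  }
  if (noise_sd < 0 || dropout_rate < 0 || dropout_rate > 1) {
    config_error("noise_sd must be >= 0 and dropout_rate in [0, 1]")
  }
  structure(list(n_conditions = n_conditions, n_replicates = n_replicates,
                 high_range = high_range, low_range = low_range,
                 noise_sd = noise_sd, dropout_rate = dropout_rate),
            class = "synthetic_expression_spec")
}

# asynchronous relaxation of the deterministic model under pinned
# sources; deterministic given the RNG state
relax_to_state <- function(model, pinned, max_sweeps = 200) {
  state <- setNames(integer(length(model$nodes)), model$nodes)
  state[names(pinned)] <- pinned
  nonsrc <- setdiff(model$nodes, model$source_nodes)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (id in sample(nonsrc)) {
      nv <- eval_boolean_rule(model$rules[[id]], state)
      if (nv != state[[id]]) {
        state[[id]] <- nv
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  state
}

#' Generate condition-structured synthetic expression
#'
#' For each condition, pins the model's source nodes to a random Boolean
#' profile, relaxes the deterministic system to a (near-)steady state,
#' and emits FPKM-like values: ON genes draw a base value from
#' `high_range`, OFF genes from `low_range`. Replicates within a
#' condition share the same underlying state and base value and differ
#' only by multiplicative lognormal noise (none when `noise_sd = 0`) and
#' optional dropout.
#'
#' @param model a [generate_ground_truth_network()] model.
#' @param spec a [synthetic_expression_spec()].
#' @param seed integer RNG seed.
#' @return list: `fpkm` (genes x samples matrix), `conditions` (named
#'   character vector sample -> condition), `states` (genes x conditions
#'   0/1 matrix of the underlying attractor states).
#' @export
generate_expression <- function(model, spec = synthetic_expression_spec(),
                                seed = 1) {
  with_seed(seed, {
    conds <- sprintf("cond%d", seq_len(spec$n_conditions))
    samples <- unlist(lapply(conds, function(cn) {
      paste0(cn, "_r", seq_len(spec$n_replicates))
    }))
    cmap <- setNames(rep(conds, each = spec$n_replicates), samples)
    fpkm <- matrix(0, nrow = length(model$nodes), ncol = length(samples),
                   dimnames = list(model$nodes, samples))
    states <- matrix(0L, nrow = length(model$nodes), ncol = length(conds),
                     dimnames = list(model$nodes, conds))
    for (ci in seq_along(conds)) {
      pinned <- setNames(as.integer(runif(length(model$source_nodes)) < 0.5),
                         model$source_nodes)
      st <- relax_to_state(model, pinned)
      states[, ci] <- st[model$nodes]
      base <- ifelse(st[model$nodes] == 1,
                     runif(length(model$nodes), spec$high_range[1], spec$high_range[2]),
                     runif(length(model$nodes), spec$low_range[1], spec$low_range[2]))
      for (r in seq_len(spec$n_replicates)) {
        noise <- exp(rnorm(length(base), 0, spec$noise_sd))
        vals <- base * noise
        drop <- runif(length(base)) < spec$dropout_rate
        vals[drop] <- 0
        fpkm[, (ci - 1) * spec$n_replicates + r] <- vals
      }
    }
    list(fpkm = fpkm, conditions = cmap, states = states)
  })
}

# render a gene name with case/punctuation noise that canonicalization
# undoes ("G003" -> "g-003" etc.)
punct_variant <- function(name) {
  style <- sample(4, 1)
  switch(style,
         tolower(name),
         paste0(substr(name, 1, 1), "-", substring(name, 2)),
         paste0(substr(name, 1, 1), "_", tolower(substring(name, 2))),
         paste0(substr(name, 1, 1), ".", substring(name, 2)))
}

#' Generate noisy multi-resource interaction tables for a model
#'
#' Emits the model's true regulatory edges spread across `n_resources`
#' interaction resources, with gene names perturbed by case/punctuation
#' variants and alias substitutions (recoverable through the emitted
#' alias tables), plus optional decoy edges. Every true edge appears in
#' at least one resource; every record carries a reference count of at
#' least 1 and a confidence in `[0, 1]` (0 for resources that provide
#' none). Decoy edges carry reference count 1 and confidence 0 so that
#' score-based pruning can remove them.
#'
#' @param model a [generate_ground_truth_network()] model.
#' @param n_resources number of resources (at least 1).
#' @param alias_noise probability that a record renders a gene name as a
#'   variant or alias instead of the canonical name.
#' @param decoy_edge_rate decoy edges as a fraction of true edges.
#' @param seed integer RNG seed.
#' @return list: `interactions` (named list of per-resource data frames
#'   with the standard six columns), `aliases` (two-column data frame),
#'   `tf_list` (character), `decoys` (data frame of the planted false
#'   edges, for test assertions), `truth_edges` (data frame
#'   source/target/effect).
#' @export
generate_interaction_databases <- function(model, n_resources = 3,
                                           alias_noise = 0.3,
                                           decoy_edge_rate = 0.1, seed = 1) {
  if (n_resources < 1) config_error("n_resources must be >= 1")
  with_seed(seed, {
    truth <- do.call(rbind, lapply(model$rules, function(r) {
      signs <- attr(r, "signs")
      data.frame(source = r$regulators, target = r$target,
                 effect = ifelse(signs > 0, "+", "-"))
    }))
    rownames(truth) <- NULL

    alias_of <- lapply(setNames(model$nodes, model$nodes), function(g) {
      k <- sample(0:2, 1)
      if (k == 0) character(0) else paste0(g, "ALT", seq_len(k))
    })
    aliases <- do.call(rbind, lapply(names(alias_of), function(g) {
      if (!length(alias_of[[g]])) return(NULL)
      data.frame(name1 = alias_of[[g]], name2 = g)
    }))
    if (is.null(aliases)) aliases <- data.frame(name1 = character(0),
                                                name2 = character(0))

    render <- function(name) {
      if (runif(1) >= alias_noise) return(name)
      opts <- c(alias_of[[name]], punct_variant(name))
      sample(opts, 1)
    }
    resources <- sprintf("resource%d", seq_len(n_resources))
    has_conf <- seq_len(n_resources) %% 2L == 1L
    recs <- list()
    for (i in seq_len(nrow(truth))) {
      incl <- which(runif(n_resources) < 0.6)
      if (!length(incl)) incl <- sample.int(n_resources, 1)
      for (ri in incl) {
        recs[[length(recs) + 1L]] <- data.frame(
          source = render(truth$source[i]), target = render(truth$target[i]),
          effect = truth$effect[i], n_references = 1L + rpois(1, 2),
          confidence = if (has_conf[ri]) round(runif(1, 0.2, 1), 3) else 0,
          resource = resources[ri])
      }
    }

    n_decoy <- round(decoy_edge_rate * nrow(truth))
    decoys <- NULL
    tkey <- paste(truth$source, truth$target)
    made <- 0
    while (made < n_decoy) {
      s <- sample(model$nodes, 1); t <- sample(model$nodes, 1)
      if (paste(s, t) %in% c(tkey, paste(decoys$source, decoys$target))) next
      decoys <- rbind(decoys, data.frame(source = s, target = t))
      made <- made + 1
      recs[[length(recs) + 1L]] <- data.frame(
        source = s, target = t, effect = "?", n_references = 1L,
        confidence = 0, resource = sample(resources, 1))
    }
    all <- do.call(rbind, recs)
    interactions <- lapply(setNames(resources, resources), function(r) {
      out <- all[all$resource == r, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
    list(interactions = interactions, aliases = aliases,
         tf_list = model$nodes[model$tf_flags],
         decoys = decoys %||% data.frame(source = character(0),
                                         target = character(0)),
         truth_edges = truth)
  })
}

#' Build a hub-controlled module model for designed-effect experiments
#'
#' A minimal probabilistic system in which a single source hub `K` is the
#' sole, necessary and sufficient activator of every node of module
#' `"M"`; bystander nodes with uninformative (constant 0.5) rules are in
#' module `"B"` and add update steps that dilute the walk. Knocking out
#' `K` makes module `M` unable to activate.
#'
#' @param n_module_nodes module-M size (default 4).
#' @param n_bystanders bystander count (default 4).
#' @return list: `rules` (named list of [probabilistic_rule()]s),
#'   `modules`, `sources`, `start_state` (all non-hub nodes OFF, hub ON).
#' @export
generate_hub_control_model <- function(n_module_nodes = 4, n_bystanders = 4) {
  m_nodes <- sprintf("M%d", seq_len(n_module_nodes))
  b_nodes <- sprintf("B%d", seq_len(n_bystanders))
  rules <- c(
    lapply(setNames(m_nodes, m_nodes), function(id) {
      probabilistic_rule(id, "K", c(0, 1), inferred = FALSE)
    }),
    lapply(setNames(b_nodes, b_nodes), function(id) {
      probabilistic_rule(id, "K", c(0.5, 0.5), inferred = FALSE)
    })
  )
  modules <- setNames(c(rep("M", n_module_nodes), rep("B", n_bystanders), "unassigned"),
                      c(m_nodes, b_nodes, "K"))
  start <- setNames(c(rep(0L, n_module_nodes + n_bystanders), 1L),
                    c(m_nodes, b_nodes, "K"))
  list(rules = rules, modules = modules, sources = "K", start_state = start)
}

#' Write synthetic pipeline inputs to disk
#'
#' Emits the interaction tables, alias table, TF list, expression matrix,
#' condition map and module map as TSV, plus the ground truth as a JSON
#' sidecar for tests.
#'
#' @param model a [generate_ground_truth_network()] model.
#' @param expr a [generate_expression()] result.
#' @param dbs a [generate_interaction_databases()] result.
#' @param dir output directory.
#' @return invisibly, a named vector of paths.
#' @export
write_synthetic_inputs <- function(model, expr, dbs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (rn in names(dbs$interactions)) {
    p <- file.path(dir, paste0("interactions_", rn, ".tsv"))
    write.table(dbs$interactions[[rn]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[rn] <- p
  }
  wtsv <- function(obj, name, rn = FALSE) {
    p <- file.path(dir, name)
    write.table(obj, p, sep = "\t", quote = FALSE, row.names = rn,
                col.names = if (rn) NA else TRUE)
    p
  }
  paths["aliases"] <- wtsv(dbs$aliases, "aliases.tsv")
  paths["tfs"] <- {
    p <- file.path(dir, "tfs.txt")
    writeLines(dbs$tf_list, p)
    p
  }
  paths["expression"] <- wtsv(as.data.frame(expr$fpkm), "expression.tsv", rn = TRUE)
  paths["conditions"] <- wtsv(
    data.frame(sample = names(expr$conditions), condition = expr$conditions),
    "conditions.tsv")
  paths["modules"] <- wtsv(
    data.frame(gene = names(model$modules), module = model$modules),
    "modules.tsv")
  truth <- list(
    nodes = model$nodes, source_nodes = model$source_nodes,
    modules = as.list(model$modules), tf_flags = as.list(model$tf_flags),
    rules = lapply(model$rules, function(r) {
      list(regulators = r$regulators, table = r$table,
           form = attr(r, "form"))
    }),
    seed = model$seed)
  paths["truth"] <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
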