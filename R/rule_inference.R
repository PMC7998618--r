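#' Log-transform an FPKM expression matrix
#'
#' Applies `log(1 + x)` entry-wise and optionally keeps only rows whose
#' gene symbol is in a whitelist (e.g. genes with a matched HGNC symbol).
#'
#' @param raw nonnegative numeric matrix, genes x samples, with rownames.
#' @param symbol_whitelist optional character vector of gene symbols to
#'   keep; `NULL` keeps all rows.
#' @return the transformed matrix.
#' @export
preprocess_expression <- function(raw, symbol_whitelist = NULL) {
  if (any(raw < 0)) validation_error("FPKM values must be nonnegative")
  out <- log1p(raw)
  if (!is.null(symbol_whitelist)) {
    out <- out[rownames(out) %in% symbol_whitelist, , drop = FALSE]
  }
  out
}

#' Normalize expression to [0, 1] by 20th/80th percentiles
#'
#' Per gene, values at or below the 20th percentile map to 0, values at
#' or above the 80th percentile map to 1, and values in between are
#' linearly interpolated. Percentiles use R's default linear-interpolation
#' convention (`stats::quantile`, type 7). Genes whose two percentiles
#' coincide (near-constant genes) are uninformative; their entries are
#' set to 0.5 with a warning.
#'
#' @param mat numeric matrix, genes x samples.
#' @param conditions named character vector mapping sample (column) name
#'   to condition label; must cover every column.
#' @param p_low,p_high the two percentiles (defaults 0.2 and 0.8).
#' @return an object of class `norm_expr`: list with `values` (matrix in
#'   `[0,1]`), `conditions`, and `transform` tag.
#' @export
normalize_expression <- function(mat, conditions = NULL, p_low = 0.2,
                                 p_high = 0.8) {
  if (ncol(mat) < 2) validation_error("need at least 2 samples to normalize")
  if (!is.null(conditions)) {
    miss <- setdiff(colnames(mat), names(conditions))
    if (length(miss)) {
      validation_error(paste("condition map missing samples:",
                             paste(head(miss, 5), collapse = ", ")))
    }
  }
  vals <- t(apply(mat, 1, function(x) {
    q <- quantile(x, c(p_low, p_high), names = FALSE, type = 7)
    if (q[1] == q[2]) return(rep(NA_real_, length(x)))  # marked, warned below
    pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
  }))
  flat <- which(apply(is.na(vals), 1, all) & !apply(is.na(mat), 1, any))
  if (length(flat)) {
    warning(sprintf("%d near-constant gene(s) set to 0.5: %s",
                    length(flat),
                    paste(head(rownames(mat)[flat], 5), collapse = ", ")))
    vals[flat, ] <- 0.5
  }
  dimnames(vals) <- dimnames(mat)
  structure(list(values = vals,
                 conditions = conditions,
                 transform = "log1p_fpkm"),
            class = "norm_expr")
}

#' @export
print.norm_expr <- function(x, ...) {
  cat(sprintf("<norm_expr> %d genes x %d samples", nrow(x$values),
              ncol(x$values)))
  if (!is.null(x$conditions)) {
    cat(sprintf(", %d conditions", length(unique(x$conditions))))
  }
  cat("\n")
  invisible(x)
}

#' Classify edges as transcriptional or post-translational
#'
#' An edge whose source node is a transcription factor is transcriptional;
#' all other edges are post-translational. Post-translational edges carry
#' an activating/deactivating sign taken from the merged effect
#' annotation; edges without a signed annotation are assumed activating.
#'
#' @param network a [regulatory_network()].
#' @param tf_set transcription-factor node ids; defaults to the network's
#'   own `tf` node flags.
#' @return the network with `regulation_type` filled in and unsigned
#'   post-translational effects defaulted to `"+"`.
#' @export
classify_edge_types <- function(network, tf_set = NULL) {
  if (is.null(tf_set)) tf_set <- network$nodes$id[network$nodes$tf]
  e <- network$edges
  e$regulation_type <- ifelse(e$source %in% tf_set, "transcriptional",
                              "post_translational")
  pt_unsigned <- e$regulation_type == "post_translational" & e$effect == "?"
  e$effect[pt_unsigned] <- "+"
  network$edges <- e
  network$nodes$tf <- network$nodes$id %in% tf_set
  network
}

#' Split post-translationally regulated nodes into transcript and active forms
#'
#' Every node with at least one incoming post-translational edge is split
#' into a transcript node `X_T` (receiving the transcriptional in-edges)
#' and an active-protein node `X_A` (receiving the post-translational
#' in-edges plus a dependency edge `X_T -> X_A`). All outgoing edges are
#' re-sourced to the active form, since only the active protein exerts
#' regulation. Purely transcriptionally regulated nodes are left intact:
#' they are assumed active as long as they are transcribed.
#'
#' @param network a [regulatory_network()] with classified edge types.
#' @return the expanded network; split nodes get roles `"transcript"` and
#'   `"active"`, and the transcript-dependency edges are flagged in an
#'   extra logical column `transcript_link`.
#' @export
split_post_translational_nodes <- function(network) {
  e <- network$edges
  if (any(is.na(e$regulation_type))) {
    validation_error("classify_edge_types() must run before splitting")
  }
  split_ids <- sort(unique(e$target[e$regulation_type == "post_translational"]))
  if (!length(split_ids)) {
    network$edges$transcript_link <- FALSE
    return(network)
  }
  t_of <- setNames(paste0(split_ids, "_T"), split_ids)
  a_of <- setNames(paste0(split_ids, "_A"), split_ids)
  ren <- function(x, map) ifelse(x %in% names(map), map[x], x)

  is_pt <- e$regulation_type == "post_translational"
  e$target <- ifelse(e$target %in% split_ids,
                     ifelse(is_pt, a_of[e$target], t_of[e$target]),
                     e$target)
  e$source <- ren(e$source, a_of)  # out-edges come only from the _A form
  e$transcript_link <- FALSE
  link <- data.frame(source = unname(t_of), target = unname(a_of))
  for (col in setdiff(names(e), c("source", "target"))) {
    link[[col]] <- switch(col,
                          effect = "+",
                          regulation_type = "post_translational",
                          transcript_link = TRUE,
                          NA)
  }
  e <- rbind(e, link[names(e)])

  n <- network$nodes
  keep <- n[!(n$id %in% split_ids), , drop = FALSE]
  base <- n[match(split_ids, n$id), , drop = FALSE]
  tn <- transform(base, id = unname(t_of), role = "transcript")
  an <- transform(base, id = unname(a_of), role = "active")
  nodes <- rbind(keep, tn, an)
  nodes <- nodes[order(nodes$id), ]
  rownames(nodes) <- NULL
  rownames(e) <- NULL
  regulatory_network(nodes, e)
}

# gene behind a (possibly split) node id
node_gene <- function(id) sub("_(T|A)$", "", id)

#' Build the activation equations of a split network
#'
#' One equation per active-protein node: `X_A = X_T * min(sum(activators),
#' 1) * max(1 - sum(inhibitors), 0)`; when a node has no activators the
#' activator factor is dropped so that such nodes are active unless
#' deactivated.
#'
#' @param network a split [regulatory_network()].
#' @return list of `activation_equation` objects (node, transcript_var,
#'   activators, inhibitors, active_var).
#' @export
activation_equations <- function(network) {
  e <- network$edges
  a_nodes <- network$nodes$id[network$nodes$role == "active"]
  lapply(a_nodes, function(a) {
    gene <- node_gene(a)
    ine <- e[e$target == a & !e$transcript_link, , drop = FALSE]
    structure(list(node = gene,
                   transcript_var = paste0(gene, "_T"),
                   activators = ine$source[ine$effect == "+"],
                   inhibitors = ine$source[ine$effect == "-"],
                   active_var = a),
              class = "activation_equation")
  })
}

#' Solve the sloppy-logic protein-activation system
#'
#' For each sample, solves the coupled system of activation equations by
#' damped fixed-point iteration started from `X_A = X_T` (the natural
#' initial guess: fully active transcript). Regulator values reference
#' `_A` variables where those exist, so the equations can be mutually
#' coupled. Solutions are clipped to `[0, 1]` against floating-point
#' error; the algebra itself maps the unit cube into itself.
#'
#' @param normalized a [normalize_expression()] object (or a plain matrix
#'   in `[0,1]` with rownames).
#' @param equations list from [activation_equations()].
#' @param tol residual tolerance (default `1e-9`).
#' @param max_iter iteration budget per sample (default 10000).
#' @param damping step damping in `(0, 1]` (default 0.5).
#' @return matrix of `X_A` values (one row per active node, samples as
#'   columns).
#' @export
solve_protein_activation <- function(normalized, equations, tol = 1e-9,
                                     max_iter = 10000, damping = 0.5) {
  stopifnot(tol > 0)
  vals <- if (inherits(normalized, "norm_expr")) normalized$values else normalized
  if (!length(equations)) {
    return(matrix(numeric(0), nrow = 0, ncol = ncol(vals),
                  dimnames = list(NULL, colnames(vals))))
  }
  a_vars <- vapply(equations, `[[`, "", "active_var")
  out <- matrix(NA_real_, nrow = length(a_vars), ncol = ncol(vals),
                dimnames = list(a_vars, colnames(vals)))

  lookup <- function(var, x_a, sample_vals) {
    if (var %in% names(x_a)) return(x_a[[var]])
    gene <- node_gene(var)
    if (!gene %in% rownames(vals)) {
      validation_error(sprintf("no expression data for regulator '%s'", var))
    }
    sample_vals[[gene]]
  }

  for (s in seq_len(ncol(vals))) {
    sv <- setNames(vals[, s], rownames(vals))
    xt <- vapply(equations, function(eq) {
      gene <- node_gene(eq$transcript_var)
      if (!gene %in% names(sv)) {
        validation_error(sprintf("no expression data for '%s'", gene))
      }
      sv[[gene]]
    }, numeric(1))
    x <- setNames(xt, a_vars)
    g <- function(x) {
      vapply(seq_along(equations), function(i) {
        eq <- equations[[i]]
        act <- if (length(eq$activators)) {
          min(sum(vapply(eq$activators, lookup, numeric(1), x, sv)), 1)
        } else 1
        inh <- if (length(eq$inhibitors)) {
          max(1 - sum(vapply(eq$inhibitors, lookup, numeric(1), x, sv)), 0)
        } else 1
        xt[i] * act * inh
      }, numeric(1))
    }
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      gx <- g(x)
      if (max(abs(gx - x)) < tol) {
        converged <- TRUE
        break
      }
      x <- setNames((1 - damping) * x + damping * gx, a_vars)
    }
    if (!converged) {
      gx <- g(x)
      bad <- a_vars[abs(gx - x) >= tol]
      stop(sprintf("activation solve did not converge in sample '%s' for: %s",
                   colnames(vals)[s] %||% s, paste(bad, collapse = ", ")))
    }
    out[, s] <- pmin(pmax(x, 0), 1)
  }
  out
}

#' Build the node-level training matrix for rule inference
#'
#' Maps every network node to a row of training values: plain and
#' transcript (`_T`) nodes use the gene's normalized transcript values;
#' active (`_A`) nodes use the solved activation values.
#'
#' @param normalized a [normalize_expression()] object.
#' @param network a (possibly split) [regulatory_network()].
#' @param xa matrix from [solve_protein_activation()] (may be empty).
#' @return matrix node x sample with the `conditions` attribute carried
#'   over.
#' @export
build_training_matrix <- function(normalized, network, xa = NULL) {
  vals <- normalized$values
  ids <- network$nodes$id
  rows <- matrix(NA_real_, nrow = length(ids), ncol = ncol(vals),
                 dimnames = list(ids, colnames(vals)))
  for (id in ids) {
    if (endsWith(id, "_A")) {
      if (is.null(xa) || !id %in% rownames(xa)) {
        validation_error(sprintf("no activation values for '%s'", id))
      }
      rows[id, ] <- xa[id, ]
    } else {
      gene <- node_gene(id)
      if (!gene %in% rownames(vals)) {
        validation_error(sprintf("no expression data for node '%s'", id))
      }
      rows[id, ] <- vals[gene, ]
    }
  }
  attr(rows, "conditions") <- normalized$conditions
  rows
}

#' Infer a probabilistic Boolean rule for one target
#'
#' For each regulator configuration `c`, every sample is weighted by how
#' closely its normalized regulator values match `c`
#' (`w = prod_i x_i` for ON bits times `prod_i (1 - x_i)` for OFF bits),
#' and the rule output is the weighted mean of the target's values with a
#' single pseudo-observation of weight `prior_weight` at 0.5:
#' \deqn{f(c) = (0.5 w_0 + \sum_s w_{s,c} y_s) / (w_0 + \sum_s w_{s,c})}
#' Configurations with no sample support therefore return exactly 0.5 --
#' with no data there is a near-50\% chance of the target turning ON or
#' OFF -- and with growing support the estimate converges to the
#' empirical mean.
#'
#' @param target target node id (row of `training`).
#' @param regulators ordered regulator node ids (rows of `training`).
#' @param training node x sample training matrix in `[0, 1]`.
#' @param prior_weight weight of the 0.5 pseudo-observation (default 1).
#' @return a [probabilistic_rule()].
#' @export
infer_probabilistic_rule <- function(target, regulators, training,
                                     prior_weight = 1) {
  n <- length(regulators)
  if (n > 6) {
    warning(sprintf("rule for '%s' has %d regulators; inference above 6 is nearly completely stochastic",
                    target, n))
  }
  miss <- setdiff(c(target, regulators), rownames(training))
  if (length(miss)) {
    validation_error(paste("training matrix lacks rows:",
                           paste(miss, collapse = ", ")))
  }
  y <- training[target, ]
  if (n == 0) {
    return(probabilistic_rule(target, character(0), 0.5, support = 0))
  }
  tx <- t(training[regulators, , drop = FALSE])  # samples x n
  cfg <- config_states(n)
  probs <- numeric(nrow(cfg))
  supp <- numeric(nrow(cfg))
  for (ci in seq_len(nrow(cfg))) {
    bits <- cfg[ci, ]
    m <- tx
    m[, bits == 0] <- 1 - m[, bits == 0, drop = FALSE]
    w <- apply(m, 1, prod)
    supp[ci] <- sum(w)
    probs[ci] <- (0.5 * prior_weight + sum(w * y)) / (prior_weight + supp[ci])
  }
  probabilistic_rule(target, regulators, probs, support = supp)
}

#' Regulator significance of a probabilistic rule
#'
#' The maximum absolute difference in rule output the regulator can make
#' by switching from OFF to ON, over all `2^(N-1)` configurations of the
#' other regulators.
#'
#' @param rule a [probabilistic_rule()].
#' @param regulator one of the rule's regulators.
#' @return scalar in `[0, 1]`.
#' @export
regulator_significance <- function(rule, regulator) {
  j <- match(regulator, rule$regulators)
  if (is.na(j)) validation_error(sprintf("'%s' is not a regulator of '%s'",
                                         regulator, rule$target))
  cfg <- config_states(length(rule$regulators))
  off <- cfg[, j] == 0
  bit <- 2^(j - 1)
  idx_on <- which(off) + bit  # flipping bit j moves the index by 2^(j-1)
  max(abs(rule$probs[idx_on] - rule$probs[off]))
}

#' Infer a rule with iterative regulator-significance pruning
#'
#' Infers the rule, and while any regulator's significance falls below
#' `threshold`, removes the single least significant regulator (ties
#' broken lexicographically by id) and re-infers. A kept regulator must
#' therefore, in at least one configuration of the others, change the
#' output by more than the threshold -- with the default 0.1, the
#' difference between a 0.45-or-less and a 0.55-or-greater output. When
#' no regulator survives, the target becomes a source node for later
#' analyses (constant-0.5 rule flagged `source`).
#'
#' @inheritParams infer_probabilistic_rule
#' @param threshold minimum significance in `(0, 1)` (default 0.1).
#' @return a [probabilistic_rule()] with attribute `source = TRUE` when
#'   all regulators were pruned.
#' @export
prune_insignificant_regulators <- function(target, regulators, training,
                                           threshold = 0.1, prior_weight = 1) {
  stopifnot(threshold > 0, threshold < 1)
  regs <- as.character(regulators)
  repeat {
    rule <- infer_probabilistic_rule(target, regs, training, prior_weight)
    if (!length(regs)) {
      attr(rule, "source") <- TRUE
      return(rule)
    }
    sig <- vapply(regs, function(r) regulator_significance(rule, r), numeric(1))
    if (all(sig >= threshold)) {
      attr(rule, "source") <- FALSE
      attr(rule, "significance") <- sig
      return(rule)
    }
    worst <- sort(names(sig)[sig == min(sig)])[1]
    regs <- setdiff(regs, worst)
  }
}

#' Infer probabilistic rules for every node of a network
#'
#' Orchestrates the inference stage: builds the activation equations of
#' the split network, solves them per sample, assembles the node-level
#' training matrix, then infers a pruned probabilistic rule for every
#' transcriptionally regulated node. Active-protein nodes get the fixed
#' inhibitory-dominant rule; nodes with no in-edges, or whose regulators
#' were all pruned, become source nodes.
#'
#' @param network a classified, split [regulatory_network()].
#' @param normalized a [normalize_expression()] object.
#' @param threshold significance threshold (default 0.1).
#' @param prior_weight pseudo-observation weight (default 1).
#' @return an object of class `pbn_rules`: list with `rules` (named list
#'   of [probabilistic_rule()]), `sources` (character), `nodes` (node
#'   table), and `training` (node x sample matrix).
#' @export
infer_rules <- function(network, normalized, threshold = 0.1,
                        prior_weight = 1) {
  if (is.null(network$edges$transcript_link)) {
    network$edges$transcript_link <- FALSE
  }
  eqs <- activation_equations(network)
  xa <- solve_protein_activation(normalized, eqs)
  training <- build_training_matrix(normalized, network, xa)
  e <- network$edges
  rules <- list()
  sources <- character(0)
  for (id in network$nodes$id) {
    role <- network$nodes$role[network$nodes$id == id]
    if (role == "active") {
      eq <- eqs[[match(id, vapply(eqs, `[[`, "", "active_var"))]]
      rules[[id]] <- inhibitory_dominant_rule(id, eq$transcript_var,
                                              eq$activators, eq$inhibitors)
      next
    }
    regs <- sort(unique(e$source[e$target == id]))
    if (!length(regs)) {
      sources <- c(sources, id)
      next
    }
    rule <- prune_insignificant_regulators(id, regs, training,
                                           threshold = threshold,
                                           prior_weight = prior_weight)
    if (isTRUE(attr(rule, "source"))) {
      sources <- c(sources, id)
    } else {
      rules[[id]] <- rule
    }
  }
  structure(list(rules = rules, sources = sources, nodes = network$nodes,
                 training = training),
            class = "pbn_rules")
}

#' @export
print.pbn_rules <- function(x, ...) {
  cat(sprintf("<pbn_rules> %d rules, %d source nodes\n",
              length(x$rules), length(x$sources)))
  invisible(x)
}

#' Write rule tables and manifest to a directory
#'
#' One CSV per rule (regulator bits, probability, support) plus a
#' `manifest.json` mapping nodes to regulators and source flags.
#'
#' @param rules a [infer_rules()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_rules <- function(rules, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rule in rules$rules) {
    df <- as.data.frame(config_states(length(rule$regulators)))
    if (ncol(df)) names(df) <- rule$regulators
    df$p_on <- rule$probs
    df$support <- if (!is.null(rule$support)) rule$support else NA_real_
    write.table(df, file.path(dir, paste0(rule$target, ".csv")), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    nodes = lapply(rules$rules, function(r) {
      list(regulators = r$regulators, inferred = r$inferred)
    }),
    sources = rules$sources
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
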