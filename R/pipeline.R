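#' Read pipeline input files
#'
#' Plain-TSV readers for the pipeline's input formats.
#'
#' @param path file path.
#' @return `read_interaction_table()`: data frame with the six standard
#'   columns; `read_alias_table()`: two-column data frame;
#'   `read_tf_list()`: character vector; `read_module_map()`: named
#'   character vector gene -> module; `read_expression()`: numeric
#'   matrix; `read_condition_map()`: named character vector
#'   sample -> condition.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_interaction_table <- function(path) {
  check_interaction_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname pipeline_io
#' @export
read_alias_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
read_tf_list <- function(path) readLines(path)

#' @rdname pipeline_io
#' @export
read_module_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df[[2]], df[[1]])
}

#' @rdname pipeline_io
#' @export
read_expression <- function(path) {
  as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
}

#' @rdname pipeline_io
#' @export
read_condition_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df[[2]], df[[1]])
}

#' Pipeline configuration with study defaults
#'
#' Collects every tunable constant of the pipeline, with defaults fixed
#' to the study conditions: 20th/80th percentile normalization, 0.1
#' regulator-significance threshold, reconnecting paths of at most 4
#' nodes, activation bands at 1/4 and 3/4, 100 walks of 5000 steps,
#' alpha 0.05, pseudo-observation weight 1.
#'
#' @param paths named list of input/output paths (see [run_pipeline()]).
#' @param seed master seed for every stochastic stage.
#' @param ... overrides for the numeric knobs: `p_low`, `p_high`,
#'   `significance_threshold`, `max_path_nodes`, `core_component_min`,
#'   `min_component`, `prior_weight`, `exhaustive_bound`, `n_walks`,
#'   `n_steps`, `alpha`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), seed = 1, ...) {
  knobs <- list(p_low = 0.2, p_high = 0.8, significance_threshold = 0.1,
                max_path_nodes = 4, core_component_min = 5, min_component = 4,
                prior_weight = 1.0, exhaustive_bound = 20, n_walks = 100,
                n_steps = 5000, alpha = 0.05)
  over <- list(...)
  bad <- setdiff(names(over), names(knobs))
  if (length(bad)) {
    config_error(paste("unknown config knob(s):", paste(bad, collapse = ", ")))
  }
  knobs <- modifyList(knobs, over)
  with(knobs, {
    if (p_low < 0 || p_high > 1 || p_low >= p_high) {
      config_error("need 0 <= p_low < p_high <= 1")
    }
    if (significance_threshold <= 0 || significance_threshold >= 1) {
      config_error("significance_threshold must be in (0, 1)")
    }
    if (alpha <= 0 || alpha >= 1) config_error("alpha must be in (0, 1)")
    if (n_walks < 2 || n_steps < 1) config_error("need n_walks >= 2, n_steps >= 1")
    if (max_path_nodes < 2) config_error("max_path_nodes must be >= 2")
  })
  for (nm in names(over)) {
    message(sprintf("config: %s = %s (default overridden)", nm,
                    format(knobs[[nm]])))
  }
  structure(c(list(paths = paths, seed = as.integer(seed)), knobs),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with optional `paths`, `seed` and knob entries.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- c(list(paths = y$paths %||% list(), seed = y$seed %||% 1),
            y[setdiff(names(y), c("paths", "seed"))])
  do.call(pipeline_config, args)
}

#' Validate pipeline input files
#'
#' Checks that the input files exist, have the expected columns, contain
#' values in range, and that the condition map covers every expression
#' sample. Failures are collected into a report rather than thrown.
#'
#' @param paths named list with entries `interactions` (character vector),
#'   `aliases`, `tfs`, `modules`, `expression`, `conditions`.
#' @return data frame (input, problem); zero rows when everything checks
#'   out.
#' @export
validate_inputs <- function(paths) {
  fails <- list()
  note <- function(input, problem) {
    fails[[length(fails) + 1L]] <<- data.frame(input = input, problem = problem)
  }
  all_paths <- c(unlist(paths[["interactions"]]),
                 unlist(paths[c("aliases", "tfs", "modules", "expression",
                                "conditions")]))
  for (p in all_paths) {
    if (!file.exists(p)) note(p, "file does not exist")
  }
  for (p in unlist(paths[["interactions"]])) {
    if (!file.exists(p)) next
    tab <- tryCatch(read_interaction_table(p), error = function(e) {
      note(p, conditionMessage(e))
      NULL
    })
  }
  expr <- NULL
  if (!is.null(paths$expression) && file.exists(paths$expression)) {
    expr <- read_expression(paths$expression)
    neg <- which(expr < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      note(paths$expression,
           sprintf("negative FPKM at row '%s', column '%s'",
                   rownames(expr)[neg[1, 1]], colnames(expr)[neg[1, 2]]))
    }
  }
  if (!is.null(paths$conditions) && file.exists(paths$conditions) &&
      !is.null(expr)) {
    cmap <- read_condition_map(paths$conditions)
    miss <- setdiff(colnames(expr), names(cmap))
    for (m in miss) note(paths$conditions, paste("no condition for sample", m))
  }
  if (!length(fails)) {
    return(data.frame(input = character(0), problem = character(0)))
  }
  do.call(rbind, fails)
}

#' Run the full pipeline
#'
#' Orchestrates assemble -> infer -> attractors -> influence ->
#' interventions, writing all artifacts plus a manifest (inputs, seed,
#' knob values, output checksums) into `config$paths$out`. Any stage
#' failure aborts with the stage name in the error.
#'
#' Expected `config$paths` entries: `interactions` (character vector of
#' TSVs), `aliases`, `tfs`, `modules`, `expression`, `conditions`, `out`,
#' and optionally `interventions` (TSV with columns `node`, `mode`) and
#' `condition` (label to simulate; default: first condition).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  out_dir <- p$out %||% config_error("config$paths$out is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- validate_inputs(p)
  if (nrow(report)) {
    config_error(paste("input validation failed:",
                       paste(report$input, report$problem, collapse = "; ")))
  }
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  net <- stage("assemble", {
    net <- assemble_network(
      lapply(p$interactions, read_interaction_table),
      if (!is.null(p$aliases)) list(read_alias_table(p$aliases)) else list(),
      if (!is.null(p$tfs)) read_tf_list(p$tfs) else character(0),
      if (!is.null(p$modules)) read_module_map(p$modules) else character(0),
      max_path_nodes = config$max_path_nodes,
      core_component_min = config$core_component_min,
      min_component = config$min_component)
    write_network(net, graphml = file.path(out_dir, "network.graphml"),
                  edges_tsv = file.path(out_dir, "network_edges.tsv"))
    net
  })

  rules <- stage("infer", {
    if (nrow(net$edges) == 0) {
      stop("assembled network is empty; relax the pruning/component knobs")
    }
    raw <- read_expression(p$expression)
    cmap <- read_condition_map(p$conditions)
    norm <- normalize_expression(preprocess_expression(raw), cmap,
                                 p_low = config$p_low, p_high = config$p_high)
    net2 <- classify_edge_types(net)
    net2 <- split_post_translational_nodes(net2)
    rules <- infer_rules(net2, norm,
                         threshold = config$significance_threshold,
                         prior_weight = config$prior_weight)
    write_rules(rules, file.path(out_dir, "rules"))
    rules
  })

  atts <- stage("attractors", {
    atts <- pseudo_attractors(rules, bound = config$exhaustive_bound)
    attractor_table(atts, file.path(out_dir, "attractors.csv"))
    atts
  })

  modules <- read_module_map(p$modules)
  modules <- setNames(as.character(modules), canonicalize_name(names(modules)))

  stage("influence", {
    inf <- influence_table(rules, modules)
    write.table(inf, file.path(out_dir, "influence_index.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  })

  if (!is.null(p$interventions)) {
    stage("intervene", {
      spec <- read.delim(p$interventions, stringsAsFactors = FALSE)
      ivs <- setNames(
        lapply(seq_len(nrow(spec)), function(i) spec[i, , drop = FALSE]),
        paste0(spec$mode, "_", spec$node))
      cmap <- read_condition_map(p$conditions)
      cond <- p[["condition"]] %||% unname(cmap)[1]
      res <- run_intervention_analysis(
        rules, cond, modules, ivs, n_walks = config$n_walks,
        n_steps = config$n_steps, seed = config$seed, alpha = config$alpha,
        bound = config$exhaustive_bound)
      write.table(res$wt_times, file.path(out_dir, "wt_switch_times.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
      write.table(res$int_times, file.path(out_dir, "intervention_switch_times.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
      write.table(res$results, file.path(out_dir, "intervention_results.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
    })
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    inputs = p[setdiff(names(p), "out")],
    seed = config$seed,
    knobs = config[setdiff(names(config), c("paths", "seed"))],
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               sub(paste0(out_dir, "/?"), "", outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("pipeline complete: ", out_dir)
  invisible(manifest)
}

#' Generate synthetic fixtures and run the pipeline end to end
#'
#' Builds a ground-truth model, emits its expression and interaction
#' tables, then runs every stage on the generated files. Intended as a
#' quick self-contained demonstration; the default problem size (a
#' 12-node model, 25 walks of 1500 steps) keeps the run to well under a
#' minute.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_nodes model size (default 12).
#' @param n_walks,n_steps simulation size overrides for the demo.
#' @return invisibly, the pipeline manifest.
#' @export
run_demo <- function(out_dir, seed = 7, n_nodes = 12, n_walks = 25,
                     n_steps = 1500) {
  model <- generate_ground_truth_network(n_nodes, n_modules = 3,
                                         max_in_degree = 3, seed = seed)
  expr <- generate_expression(model, synthetic_expression_spec(), seed = seed + 1)
  dbs <- generate_interaction_databases(model, n_resources = 3,
                                        alias_noise = 0.3,
                                        decoy_edge_rate = 0, seed = seed + 2)
  in_dir <- file.path(out_dir, "inputs")
  paths <- write_synthetic_inputs(model, expr, dbs, in_dir)
  # demo intervention: KO/CA of the two highest out-degree nodes that
  # survive assembly
  net <- assemble_network(dbs$interactions, list(dbs$aliases), dbs$tf_list,
                          model$modules, core_component_min = 3)
  regs <- table(net$edges$source)
  top <- names(sort(regs, decreasing = TRUE))[1:2]
  iv_path <- file.path(in_dir, "interventions.tsv")
  write.table(data.frame(node = top, mode = c("KO", "CA")), iv_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- pipeline_config(
    paths = list(
      interactions = unname(paths[names(dbs$interactions)]),
      aliases = paths[["aliases"]], tfs = paths[["tfs"]],
      modules = paths[["modules"]], expression = paths[["expression"]],
      conditions = paths[["conditions"]], interventions = iv_path,
      out = file.path(out_dir, "results")),
    seed = seed, n_walks = n_walks, n_steps = n_steps,
    core_component_min = 3)  # a 12-node toy has no 5-node module cores
  run_pipeline(cfg)
}
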