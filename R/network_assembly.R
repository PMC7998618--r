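#' Canonicalize a gene name
#'
#' Interaction resources vary capitalization and interchangeably use the
#' characters `"."`, `"-"` and `"_"` inside gene names. Canonicalization
#' uppercases the name and strips those three characters, so e.g.
#' `"Foo-bar.1"` becomes `"FOOBAR1"`. The operation is idempotent.
#'
#' @param name character vector of gene names.
#' @return character vector of canonical names.
#' @export
canonicalize_name <- function(name) {
  if (length(name) == 0) return(character(0))
  if (any(is.na(name) | !nzchar(name))) {
    validation_error("gene names must be nonempty strings")
  }
  gsub("[._-]", "", toupper(name))
}

#' Build an alias resolver from name-pair tables
#'
#' Constructs the union alias graph over canonicalized names (one edge per
#' alias pair from any table) and takes its connected components: two
#' names refer to the same gene iff any path connects them. Each
#' component is represented by its lexicographically smallest member.
#' Unknown names resolve to themselves (their own singleton component).
#'
#' @param alias_tables a list of two-column data frames (or a single data
#'   frame) of alias pairs; raw names are canonicalized first.
#' @return an object of class `alias_resolver`.
#' @seealso [resolve_alias()]
#' @export
build_alias_resolver <- function(alias_tables = list()) {
  if (is.data.frame(alias_tables)) alias_tables <- list(alias_tables)
  pairs <- lapply(alias_tables, function(tab) {
    if (nrow(tab) == 0) return(NULL)
    cbind(canonicalize_name(as.character(tab[[1]])),
          canonicalize_name(as.character(tab[[2]])))
  })
  pairs <- do.call(rbind, pairs)
  map <- character(0)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    comp <- igraph::components(g)$membership
    nm <- names(comp)
    rep_of <- vapply(split(nm, comp), function(members) min(members), character(1))
    map <- setNames(rep_of[as.character(comp)], nm)
  }
  structure(list(map = map), class = "alias_resolver")
}

#' Resolve names to their alias-component representative
#'
#' @param resolver an [build_alias_resolver()] object.
#' @param names character vector (canonicalized internally).
#' @return character vector of component representatives.
#' @export
resolve_alias <- function(resolver, names) {
  stopifnot(inherits(resolver, "alias_resolver"))
  can <- canonicalize_name(names)
  hit <- resolver$map[can]
  unname(ifelse(is.na(hit), can, hit))
}

#' @export
print.alias_resolver <- function(x, ...) {
  cat(sprintf("<alias_resolver> %d known names, %d components\n",
              length(x$map), length(unique(x$map))))
  invisible(x)
}

interaction_columns <- c("source", "target", "effect", "n_references",
                         "confidence", "resource")

check_interaction_table <- function(tab) {
  miss <- setdiff(interaction_columns, names(tab))
  if (length(miss)) {
    validation_error(paste("interaction table lacks columns:",
                           paste(miss, collapse = ", ")))
  }
  if (any(tab$n_references < 1)) validation_error("n_references must be >= 1")
  if (any(tab$confidence < 0 | tab$confidence > 1)) {
    validation_error("confidence must be in [0, 1]")
  }
  invisible(tab)
}

#' Merge interaction resources into a single edge table
#'
#' Canonicalizes and alias-resolves endpoint names, then groups all
#' records by resolved (source, target) pair. Parallel records collapse
#' into one merged edge that keeps the total reference count, the number
#' of distinct contributing resources, the record count and the mean
#' record confidence. Self-loops are retained. The aggregate effect sign
#' is the majority of signed annotations (`"?"` records abstain; ties or
#' no annotation give `"?"`).
#'
#' @param tables list of interaction data frames with columns
#'   `source, target, effect, n_references, confidence, resource`.
#' @param resolver an [build_alias_resolver()] object.
#' @return a data frame of class `merged_edges` with one row per resolved
#'   edge: `source, target, effect, n_references, n_resources, n_entries,
#'   mean_confidence`.
#' @export
merge_interaction_sources <- function(tables, resolver = build_alias_resolver()) {
  if (is.data.frame(tables)) tables <- list(tables)
  tables <- lapply(tables, check_interaction_table)
  all <- do.call(rbind, lapply(tables, function(t) t[interaction_columns]))
  if (is.null(all) || nrow(all) == 0) {
    out <- data.frame(source = character(0), target = character(0),
                      effect = character(0), n_references = numeric(0),
                      n_resources = integer(0), n_entries = integer(0),
                      mean_confidence = numeric(0))
    class(out) <- c("merged_edges", "data.frame")
    return(out)
  }
  all$source <- resolve_alias(resolver, all$source)
  all$target <- resolve_alias(resolver, all$target)
  key <- paste(all$source, all$target, sep = "\r")
  grp <- split(seq_len(nrow(all)), key)
  rows <- lapply(grp, function(i) {
    sub <- all[i, ]
    pos <- sum(sub$effect == "+")
    neg <- sum(sub$effect == "-")
    eff <- if (pos > neg) "+" else if (neg > pos) "-" else "?"
    data.frame(source = sub$source[1], target = sub$target[1], effect = eff,
               n_references = sum(sub$n_references),
               n_resources = length(unique(sub$resource)),
               n_entries = nrow(sub),
               mean_confidence = mean(sub$confidence))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$source, out$target), ]
  rownames(out) <- NULL
  class(out) <- c("merged_edges", "data.frame")
  out
}

#' Score a merged edge
#'
#' The edge confidence score combines the literature support and resource
#' agreement behind an edge:
#' \deqn{score = (N_{references} + N_{resources} + 10 \bar{c}) \cdot TFMUL}
#' where \eqn{\bar{c}} is the mean record confidence and `TFMUL` is 2 when
#' the source node is a transcription factor and 1 otherwise. Since every
#' edge has at least one reference and one resource, the minimum possible
#' score is 2.
#'
#' @param n_references total reference count of the merged edge.
#' @param n_resources number of distinct resources that contain it.
#' @param mean_confidence mean per-record confidence in `[0, 1]`.
#' @param tf_source logical; is the source node a transcription factor?
#' @return numeric score (vectorized).
#' @export
score_edge <- function(n_references, n_resources, mean_confidence = 0,
                       tf_source = FALSE) {
  (n_references + n_resources + 10 * mean_confidence) * ifelse(tf_source, 2, 1)
}

#' Score every edge of a merged edge table
#'
#' @param merged a [merge_interaction_sources()] table.
#' @param tf_set character vector of transcription-factor gene ids
#'   (canonical/resolved).
#' @return `merged` with logical `tf_source` and numeric `score` columns.
#' @export
score_edges <- function(merged, tf_set = character(0)) {
  merged$tf_source <- merged$source %in% tf_set
  merged$score <- score_edge(merged$n_references, merged$n_resources,
                             merged$mean_confidence, merged$tf_source)
  merged
}

#' Extract the subnetwork induced by focus modules
#'
#' @param edges an edge data frame with `source`/`target` columns.
#' @param modules named character vector mapping resolved gene id to
#'   module label.
#' @param focus_modules character vector of module labels to keep.
#' @return the rows of `edges` whose two endpoints both belong to a focus
#'   module.
#' @export
extract_module_subnetwork <- function(edges, modules, focus_modules) {
  unknown <- setdiff(focus_modules, unique(modules))
  if (length(unknown)) {
    config_error(paste("unknown focus module label(s):",
                       paste(unknown, collapse = ", ")))
  }
  keep_genes <- names(modules)[modules %in% focus_modules]
  edges[edges$source %in% keep_genes & edges$target %in% keep_genes, ,
        drop = FALSE]
}

#' Find short paths reconnecting orphan genes to network components
#'
#' For each orphan gene, searches the full merged network for directed
#' paths of at most `max_path_nodes` total nodes (endpoints included)
#' that run either from the orphan into a component or from a component
#' to the orphan. Only minimum-length qualifying paths are used; when
#' several paths tie for the minimum, the edges of all of them are
#' returned. Orphans with no qualifying path are skipped.
#'
#' @param full_edges edge data frame of the full network (source, target).
#' @param components list of character vectors, the node sets of the
#'   components to connect into.
#' @param orphan_nodes character vector of genes present in `full_edges`
#'   but in no component.
#' @param max_path_nodes maximum number of nodes on a qualifying path
#'   (default 4, i.e. at most 3 edges).
#' @return data frame of unique edges (source, target) to add.
#' @export
find_connecting_paths <- function(full_edges, components, orphan_nodes,
                                  max_path_nodes = 4) {
  comp_nodes <- unique(unlist(components))
  verts <- unique(c(full_edges$source, full_edges$target))
  g <- igraph::graph_from_data_frame(full_edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = verts))
  out <- list()
  targets <- intersect(comp_nodes, verts)
  for (orphan in intersect(orphan_nodes, verts)) {
    d_out <- suppressWarnings(
      igraph::distances(g, v = orphan, to = targets, mode = "out"))[1, ]
    d_in <- suppressWarnings(
      igraph::distances(g, v = orphan, to = targets, mode = "in"))[1, ]
    best <- suppressWarnings(min(c(d_out, d_in), na.rm = TRUE))
    if (!is.finite(best) || best + 1 > max_path_nodes || best < 1) next
    paths <- list()
    for (mode in c("out", "in")) {
      d <- if (mode == "out") d_out else d_in
      ends <- names(d)[is.finite(d) & d == best]
      for (e in ends) {
        sp <- igraph::all_shortest_paths(g, from = orphan, to = e,
                                         mode = mode)$vpaths
        paths <- c(paths, lapply(sp, function(p) {
          nm <- names(p)
          if (mode == "in") nm <- rev(nm)
          nm
        }))
      }
    }
    for (p in paths) {
      out[[length(out) + 1L]] <- data.frame(source = p[-length(p)],
                                            target = p[-1])
    }
  }
  if (!length(out)) return(data.frame(source = character(0), target = character(0)))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Prune the in-edges of one target by score
#'
#' Edges are sorted by descending score (ties broken lexicographically by
#' source id). The up-to-three highest-scoring edges are always retained;
#' each subsequent edge is retained only if its score exceeds the number
#' of edges already retained minus one. The first edge that fails drops,
#' along with every lower-scored edge. The rule keeps all regulators of
#' low in-degree targets while applying an increasingly strict criterion
#' as the in-degree grows.
#'
#' @param scored_in_edges data frame of one target's in-edges with a
#'   `score` column (and optionally `source` for tie-breaking).
#' @return the retained rows, with an attribute `"details"` holding a
#'   data frame (`rank`, `score`, `threshold`, `retained`) that records
#'   the threshold each edge was compared against (`NA` for the
#'   unconditional top three).
#' @export
prune_in_edges <- function(scored_in_edges) {
  n <- nrow(scored_in_edges)
  det <- data.frame(rank = integer(0), score = numeric(0),
                    threshold = numeric(0), retained = logical(0))
  if (is.null(n) || n == 0) {
    out <- scored_in_edges
    attr(out, "details") <- det
    return(out)
  }
  ord <- if (!is.null(scored_in_edges$source)) {
    order(-scored_in_edges$score, scored_in_edges$source)
  } else {
    order(-scored_in_edges$score)
  }
  sorted <- scored_in_edges[ord, , drop = FALSE]
  retained <- rep(FALSE, n)
  thr <- rep(NA_real_, n)
  kept <- 0L
  for (k in seq_len(n)) {
    if (k <= 3L) {
      retained[k] <- TRUE
      kept <- kept + 1L
    } else {
      thr[k] <- kept - 1
      if (sorted$score[k] > thr[k]) {
        retained[k] <- TRUE
        kept <- kept + 1L
      } else {
        break  # this edge and all lower-scored edges are dropped
      }
    }
  }
  det <- data.frame(rank = seq_len(n), score = sorted$score,
                    threshold = thr, retained = retained)
  out <- sorted[retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "details") <- det
  out
}

#' Apply in-degree pruning to every target in an edge table
#'
#' @param scored_edges edge data frame with `source`, `target`, `score`.
#' @return the retained edges.
#' @export
prune_network_in_edges <- function(scored_edges) {
  parts <- split(scored_edges, scored_edges$target)
  out <- do.call(rbind, lapply(parts, prune_in_edges))
  rownames(out) <- NULL
  out
}

#' Regulatory network container
#'
#' @param nodes data frame with columns `id`, `module`, `tf`, `role`.
#' @param edges data frame with columns `source`, `target`, `effect`,
#'   `regulation_type`, `score` (extra columns are kept).
#' @return an object of class `regulatory_network`.
#' @export
regulatory_network <- function(nodes, edges) {
  stopifnot(all(c("id", "module", "tf", "role") %in% names(nodes)))
  stopifnot(all(c("source", "target") %in% names(edges)))
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(missing)) {
    validation_error(paste("edges reference unknown nodes:",
                           paste(head(missing, 5), collapse = ", ")))
  }
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  mods <- table(x$nodes$module)
  cat("  modules:", paste(sprintf("%s=%d", names(mods), mods), collapse = " "), "\n")
  invisible(x)
}

#' Convert a regulatory network to an igraph graph
#'
#' @param network a [regulatory_network()].
#' @return an igraph directed graph with node and edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  nodes <- network$nodes
  names(nodes)[names(nodes) == "id"] <- "name"
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = nodes)
}

# iterative sink removal + small-component filter on an edge data frame;
# returns the surviving edge rows
clean_graph_edges <- function(edges, min_component = 4) {
  repeat {
    if (nrow(edges) == 0) break
    nodes <- unique(c(edges$source, edges$target))
    sinks <- setdiff(nodes, unique(edges$source))
    if (!length(sinks)) break
    edges <- edges[!(edges$target %in% sinks) & !(edges$source %in% sinks), ,
                   drop = FALSE]
  }
  if (nrow(edges) > 0 && min_component > 1) {
    g <- igraph::graph_from_data_frame(edges[, c("source", "target")])
    comp <- igraph::components(g, mode = "weak")
    big <- names(comp$membership)[comp$csize[comp$membership] >= min_component]
    edges <- edges[edges$source %in% big & edges$target %in% big, , drop = FALSE]
  }
  edges
}

#' Finalize an assembled network
#'
#' Removes sink nodes (out-degree zero) iteratively to a fixed point --
#' sinks cannot feed back into the dynamics and removing one can expose
#' another -- then drops weakly connected components with fewer than
#' `min_component` nodes. The result has no sinks and no small
#' components.
#'
#' @param edges edge data frame (source, target, plus any columns).
#' @param modules named character vector gene -> module label.
#' @param tf_set character vector of transcription-factor ids.
#' @param min_component minimum weak-component size (default 4).
#' @return a [regulatory_network()]; empty (with a warning) when nothing
#'   survives.
#' @export
finalize_network <- function(edges, modules = character(0),
                             tf_set = character(0), min_component = 4) {
  edges <- clean_graph_edges(edges, min_component)
  if (nrow(edges) == 0) {
    warning("finalized network is empty")
    nodes <- data.frame(id = character(0), module = character(0),
                        tf = logical(0), role = character(0))
    return(regulatory_network(nodes, edges))
  }
  ids <- sort(unique(c(edges$source, edges$target)))
  mod <- unname(modules[ids])
  mod[is.na(mod)] <- "unassigned"
  nodes <- data.frame(id = ids, module = mod, tf = ids %in% tf_set,
                      role = "plain", stringsAsFactors = FALSE)
  if (is.null(edges$effect)) edges$effect <- "?"
  if (is.null(edges$regulation_type)) edges$regulation_type <- NA_character_
  if (is.null(edges$score)) edges$score <- NA_real_
  rownames(edges) <- NULL
  regulatory_network(nodes, edges)
}

#' Assemble a module-annotated regulatory network from interaction tables
#'
#' Runs the full assembly sequence: canonicalize and alias-resolve names,
#' merge resources, restrict to focus-module genes, reconnect orphan
#' module genes to the large components through short paths in the full
#' merged network, remove sinks, score edges, prune high in-degree nodes
#' and drop small components.
#'
#' @param interaction_tables list of interaction data frames (see
#'   [merge_interaction_sources()]).
#' @param alias_tables list of alias pair data frames.
#' @param tf_list character vector of transcription-factor names.
#' @param module_map named character vector gene -> module label (names
#'   are canonicalized/resolved internally).
#' @param focus_modules module labels to build around; default all labels
#'   in `module_map`.
#' @param max_path_nodes maximum nodes on a reconnecting path (default 4).
#' @param core_component_min minimum size for a module component to count
#'   as a core during reconnection (default 5).
#' @param min_component minimum weak-component size in the final network
#'   (default 4).
#' @return a [regulatory_network()].
#' @export
assemble_network <- function(interaction_tables, alias_tables = list(),
                             tf_list = character(0), module_map = character(0),
                             focus_modules = NULL, max_path_nodes = 4,
                             core_component_min = 5, min_component = 4) {
  resolver <- build_alias_resolver(alias_tables)
  tfs <- unique(resolve_alias(resolver, tf_list))
  modules <- setNames(as.character(module_map),
                      resolve_alias(resolver, names(module_map)))
  merged <- merge_interaction_sources(interaction_tables, resolver)

  if (is.null(focus_modules)) {
    focus_modules <- setdiff(unique(modules), "unassigned")
  }
  sub <- extract_module_subnetwork(merged, modules, focus_modules)

  # reconnect module genes orphaned from the large components via short
  # paths through the full merged network (which may use genes outside
  # the focus modules)
  if (nrow(sub) > 0) {
    g <- igraph::graph_from_data_frame(sub[, c("source", "target")])
    comp <- igraph::components(g, mode = "weak")
    big <- which(comp$csize >= core_component_min)
    components <- lapply(big, function(ci) {
      names(comp$membership)[comp$membership == ci]
    })
  } else {
    components <- list()
  }
  focus_genes <- names(modules)[modules %in% focus_modules]
  orphans <- setdiff(intersect(focus_genes,
                               unique(c(merged$source, merged$target))),
                     unlist(components))
  if (length(components) && length(orphans)) {
    extra <- find_connecting_paths(merged, components, orphans,
                                   max_path_nodes = max_path_nodes)
    if (nrow(extra)) {
      key <- paste(merged$source, merged$target, sep = "\r")
      want <- unique(c(paste(sub$source, sub$target, sep = "\r"),
                       paste(extra$source, extra$target, sep = "\r")))
      sub <- merged[key %in% want, , drop = FALSE]
    }
  }

  sub <- clean_graph_edges(sub, min_component = 1)  # sink fixpoint only
  sub <- score_edges(sub, tfs)
  if (nrow(sub)) sub <- prune_network_in_edges(sub)
  finalize_network(sub, modules, tfs, min_component = min_component)
}

#' Write a regulatory network to GraphML and edge-list TSV
#'
#' @param network a [regulatory_network()].
#' @param graphml,edges_tsv output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, graphml = NULL, edges_tsv = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(network), graphml, format = "graphml")
  }
  if (!is.null(edges_tsv)) {
    write.table(network$edges, edges_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(graphml = graphml, edges_tsv = edges_tsv))
}
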