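#' Enumerate regulator configurations
#'
#' Returns the `2^n` Boolean input configurations of an `n`-regulator rule
#' as a 0/1 integer matrix. Row `i` corresponds to configuration index
#' `i - 1`, with regulator `j` stored in bit `j - 1` (regulator 1 is the
#' least-significant bit). All rule tables in the package share this row
#' order.
#'
#' @param n number of regulators (0 gives a single empty configuration).
#' @return integer matrix with `2^n` rows and `n` columns.
#' @export
config_states <- function(n) {
  stopifnot(n >= 0, n <= 20)
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  idx <- 0:(2^n - 1)
  m <- vapply(seq_len(n), function(j) bitwAnd(bitwShiftR(idx, j - 1L), 1L), integer(2^n))
  matrix(m, nrow = 2^n, ncol = n)
}

# 1-based table index of a Boolean configuration vector (regulator order)
config_index <- function(bits) {
  if (length(bits) == 0) return(1L)
  as.integer(sum(bits * 2^(seq_along(bits) - 1L))) + 1L
}

#' Probabilistic Boolean rule
#'
#' A single target node's ordered regulator list together with its
#' `2^N`-entry table of ON-probabilities and the per-configuration sample
#' support (total sample weight that constrained each entry).
#'
#' @param target target node id.
#' @param regulators character vector of regulator node ids (may be empty).
#' @param probs numeric vector of length `2^N`, entries in `[0, 1]`, in
#'   [config_states()] row order.
#' @param support numeric vector of length `2^N` with per-configuration
#'   sample weight, or `NULL` for rules fixed by construction (such as
#'   active-protein logic).
#' @param inferred logical; whether the rule was estimated from data.
#' @return an object of class `probabilistic_rule`.
#' @export
probabilistic_rule <- function(target, regulators, probs, support = NULL,
                               inferred = TRUE) {
  n <- length(regulators)
  if (length(probs) != 2^n) {
    validation_error(sprintf("rule for '%s': %d probabilities for %d regulators",
                             target, length(probs), n))
  }
  if (any(probs < 0 | probs > 1)) {
    validation_error(sprintf("rule for '%s': probabilities outside [0, 1]", target))
  }
  structure(
    list(target = target, regulators = as.character(regulators),
         probs = as.numeric(probs),
         support = if (!is.null(support)) as.numeric(support),
         inferred = isTRUE(inferred)),
    class = "probabilistic_rule"
  )
}

#' @export
print.probabilistic_rule <- function(x, ...) {
  cat(sprintf("<probabilistic_rule> %s <- {%s}\n", x$target,
              paste(x$regulators, collapse = ", ")))
  df <- as.data.frame(config_states(length(x$regulators)))
  if (ncol(df)) names(df) <- x$regulators
  df$p_on <- round(x$probs, 4)
  if (!is.null(x$support)) df$support <- round(x$support, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Deterministic Boolean rule
#'
#' @param target target node id.
#' @param regulators regulator node ids.
#' @param table integer 0/1 vector of length `2^N` in [config_states()]
#'   row order.
#' @return an object of class `boolean_rule`.
#' @export
boolean_rule <- function(target, regulators, table) {
  n <- length(regulators)
  if (length(table) != 2^n) {
    validation_error(sprintf("boolean rule for '%s': table length %d for %d regulators",
                             target, length(table), n))
  }
  if (!all(table %in% c(0L, 1L))) {
    validation_error(sprintf("boolean rule for '%s': table must be 0/1", target))
  }
  structure(
    list(target = target, regulators = as.character(regulators),
         table = as.integer(table)),
    class = "boolean_rule"
  )
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat(sprintf("<boolean_rule> %s <- {%s} : [%s]\n", x$target,
              paste(x$regulators, collapse = ", "),
              paste(x$table, collapse = "")))
  invisible(x)
}

# Evaluate a boolean_rule on a named Boolean state vector
eval_boolean_rule <- function(rule, state) {
  if (length(rule$regulators) == 0) return(rule$table[1L])
  rule$table[config_index(state[rule$regulators])]
}

#' Inhibitory-dominant activation rule for an active-protein node
#'
#' Builds the Boolean update rule of a split node's active form: the
#' protein is active when its transcript is present, at least one
#' activator is ON (if it has any activators), and no inhibitor is ON.
#' This is the Boolean restriction of the sloppy-logic activation
#' equation `X_A = X_T * min(sum(activators), 1) * max(1 - sum(inhibitors), 0)`.
#'
#' @param target id of the active-form node (e.g. `"X_A"`).
#' @param transcript id of the transcript node (e.g. `"X_T"`).
#' @param activators,inhibitors regulator ids (either may be empty).
#' @return a [probabilistic_rule()] with probabilities in `{0, 1}` and
#'   `inferred = FALSE`.
#' @export
inhibitory_dominant_rule <- function(target, transcript, activators,
                                     inhibitors) {
  regs <- c(transcript, activators, inhibitors)
  cfg <- config_states(length(regs))
  colnames(cfg) <- regs
  xt <- cfg[, transcript]
  act <- if (length(activators)) pmin(rowSums(cfg[, activators, drop = FALSE]), 1) else 1
  inh <- if (length(inhibitors)) pmax(1 - rowSums(cfg[, inhibitors, drop = FALSE]), 0) else 1
  probabilistic_rule(target, regs, as.numeric(xt * act * inh),
                     support = NULL, inferred = FALSE)
}

# Restrict a boolean_rule by fixing some regulators to constants.
# `fixed` is a named 0/1 vector; regulators not named stay free.
restrict_rule <- function(rule, fixed) {
  keep <- !(rule$regulators %in% names(fixed))
  if (all(keep)) return(rule)
  cfg <- config_states(length(rule$regulators))
  ok <- rep(TRUE, nrow(cfg))
  for (j in which(!keep)) {
    ok <- ok & cfg[, j] == fixed[[rule$regulators[j]]]
  }
  boolean_rule(rule$target, rule$regulators[keep], rule$table[ok])
}
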