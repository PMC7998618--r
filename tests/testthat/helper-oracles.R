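# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with the package internals: the state
# transition graph is built by per-state evaluation and terminal SCCs
# are found with a hand-written iterative Kosaraju, whereas the package
# vectorizes the STG and uses igraph's strong components.

# successor lists (changed general-asynchronous transitions) of a named
# list of boolean_rule covering every node
oracle_succ <- function(rules) {
  nodes <- names(rules)
  m <- length(nodes)
  lapply(0:(2^m - 1), function(s) {
    bits <- setNames(as.integer(intToBits(s))[seq_len(m)], nodes)
    out <- integer(0)
    for (j in seq_len(m)) {
      r <- rules[[j]]
      v <- if (length(r$regulators)) {
        idx <- sum(bits[r$regulators] * 2^(seq_along(r$regulators) - 1)) + 1
        r$table[idx]
      } else {
        r$table[1]
      }
      if (v != bits[j]) out <- c(out, bitwXor(s, 2^(j - 1)))
    }
    out + 1L
  })
}

# terminal strongly connected components (lists of 1-based state ids)
oracle_terminal_sccs <- function(succ) {
  n <- length(succ)
  pred <- vector("list", n)
  for (v in seq_len(n)) {
    for (w in succ[[v]]) pred[[w]] <- c(pred[[w]], v)
  }
  visited <- logical(n)
  finish <- integer(n)
  nf <- 0L
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack <- s
    ptr <- 0L
    visited[s] <- TRUE
    while (length(stack)) {
      top <- length(stack)
      v <- stack[top]
      ptr[top] <- ptr[top] + 1L
      nbrs <- succ[[v]]
      if (ptr[top] <= length(nbrs)) {
        w <- nbrs[ptr[top]]
        if (!visited[w]) {
          visited[w] <- TRUE
          stack <- c(stack, w)
          ptr <- c(ptr, 0L)
        }
      } else {
        nf <- nf + 1L
        finish[nf] <- v
        stack <- stack[-top]
        ptr <- ptr[-top]
      }
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (v in rev(finish)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      x <- queue[1]
      queue <- queue[-1]
      for (w in pred[[x]]) {
        if (comp[w] == 0L) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  leaving <- unlist(lapply(seq_len(n), function(v) {
    if (any(comp[succ[[v]]] != comp[v])) comp[v]
  }))
  terminal <- setdiff(seq_len(cid), unique(leaving))
  lapply(terminal, function(ci) which(comp == ci))
}

# attractor signature of a terminal SCC: per node its fixed value, or NA
# when it varies within the component
oracle_signature <- function(states, nodes) {
  m <- length(nodes)
  bits <- vapply(states - 1L, function(s) as.integer(intToBits(s))[seq_len(m)],
                 integer(m))
  bits <- matrix(bits, nrow = m)
  sig <- bits[, 1]
  sig[apply(bits, 1, function(b) length(unique(b)) > 1)] <- NA_integer_
  setNames(sig, nodes)
}

# canonical string form of a set of signatures, for multiset comparison
signature_key <- function(sigs) {
  sort(vapply(sigs, function(s) {
    paste(ifelse(is.na(s[sort(names(s))]), "osc", s[sort(names(s))]),
          collapse = "")
  }, character(1)))
}

# random deterministic Boolean system (every node regulated)
random_boolean_system <- function(n_nodes, max_k = 3) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  rules <- lapply(setNames(nodes, nodes), function(id) {
    k <- sample.int(max_k, 1)
    regs <- sample(nodes, k)
    boolean_rule(id, regs, sample(0:1, 2^k, replace = TRUE))
  })
  structure(list(rules = rules, sources = character(0)), class = "det_rules")
}

# independent deterministic-rule evaluation on a named state vector
eval_boolean_rule_for_test <- function(rule, state) {
  if (!length(rule$regulators)) return(rule$table[[1]])
  idx <- sum(state[rule$regulators] * 2^(seq_along(rule$regulators) - 1)) + 1
  rule$table[[idx]]
}

# brute-force regulator significance straight from the rule table
oracle_significance <- function(rule, regulator) {
  n <- length(rule$regulators)
  j <- match(regulator, rule$regulators)
  best <- 0
  for (c in 0:(2^n - 1)) {
    if (bitwAnd(bitwShiftR(c, j - 1L), 1L) == 1L) next
    d <- abs(rule$probs[c + bitwShiftL(1L, j - 1L) + 1L] - rule$probs[c + 1L])
    best <- max(best, d)
  }
  best
}
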