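# Shared fixtures built in code.

# probabilistic rule for f(A,B,C) = A or (B and C), the canonical worked
# example for necessary/sufficient edge scoring
worked_rule <- function(target = "D") {
  cfg <- config_states(3)
  probabilistic_rule(target, c("A", "B", "C"),
                     as.numeric(cfg[, 1] | (cfg[, 2] & cfg[, 3])))
}

# exhaustive noiseless Boolean training for a ground-truth rule: one
# sample per regulator configuration, target set to the rule output
exhaustive_training <- function(rule) {
  cfg <- config_states(length(rule$regulators))
  tr <- rbind(t(cfg), rule$table)
  rownames(tr) <- c(rule$regulators, rule$target)
  colnames(tr) <- paste0("s", seq_len(ncol(tr)))
  tr
}

# two-node mutual-inhibition toggle as a deterministic system
toggle_system <- function() {
  structure(list(rules = list(A = boolean_rule("A", "B", c(1, 0)),
                              B = boolean_rule("B", "A", c(1, 0))),
                 sources = character(0)),
            class = "det_rules")
}

no_pin <- setNames(integer(0), character(0))

# small classified network with one post-translationally regulated node:
# TF1 -|> X (transcriptional), KIN -> X (post-translational activator),
# PHO -| X (post-translational inhibitor), X -> OUT
split_fixture_network <- function() {
  nodes <- data.frame(
    id = c("TF1", "KIN", "PHO", "X", "OUT"),
    module = c("unassigned", "unassigned", "unassigned", "M1", "M1"),
    tf = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    role = "plain")
  edges <- data.frame(
    source = c("TF1", "KIN", "PHO", "X"),
    target = c("X", "X", "X", "OUT"),
    effect = c("+", "+", "-", "+"),
    regulation_type = NA_character_,
    score = 2)
  classify_edge_types(regulatory_network(nodes, edges))
}
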