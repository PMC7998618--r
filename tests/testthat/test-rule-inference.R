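test_that("expression preprocessing log-transforms and filters by whitelist", {
  raw <- matrix(c(0, 1, 3, 7), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  out <- preprocess_expression(raw)
  expect_equal(out, log1p(raw))
  expect_equal(rownames(preprocess_expression(raw, "A")), "A")
  expect_error(preprocess_expression(matrix(-1)),
               class = "boolmod_validation_error")
})

test_that("20/80 normalization maps percentiles to 0/1 with linear middle", {
  x <- matrix(0:10, nrow = 1, dimnames = list("g", paste0("s", 0:10)))
  norm <- normalize_expression(rbind(x, x + 100))  # two informative genes
  expect_equal(norm$values["g", "s2"], 0)   # p20 = 2
  expect_equal(norm$values["g", "s5"], 0.5)
  expect_equal(norm$values["g", "s8"], 1)   # p80 = 8
  expect_equal(norm$values["g", "s0"], 0)
  expect_equal(norm$values["g", "s10"], 1)

  flat <- matrix(5, 1, 4, dimnames = list("c1", paste0("s", 1:4)))
  expect_warning(nf <- normalize_expression(rbind(flat, x[, 1:4, drop = FALSE])),
                 "near-constant")
  expect_true(all(nf$values["c1", ] == 0.5))
})

test_that("edge classification follows TF status and defaults unknown signs", {
  net <- split_fixture_network()
  e <- net$edges
  expect_equal(e$regulation_type[e$source == "TF1"], "transcriptional")
  expect_equal(e$regulation_type[e$source == "KIN"], "post_translational")
  expect_equal(e$effect[e$source == "PHO"], "-")
  # unsigned non-TF edge defaults positive
  nodes <- data.frame(id = c("K1", "Z"), module = "m", tf = FALSE, role = "plain")
  edges <- data.frame(source = "K1", target = "Z", effect = "?",
                      regulation_type = NA, score = 2)
  net2 <- classify_edge_types(regulatory_network(nodes, edges))
  expect_equal(net2$edges$effect, "+")
  expect_equal(net2$edges$regulation_type, "post_translational")
})

test_that("post-translational targets split into _T and _A forms", {
  net <- split_post_translational_nodes(split_fixture_network())
  expect_true(all(c("X_T", "X_A") %in% net$nodes$id))
  expect_false("X" %in% net$nodes$id)
  e <- net$edges
  # transcriptional edge lands on the transcript form
  expect_equal(e$target[e$source == "TF1"], "X_T")
  # post-translational edges land on the active form
  expect_setequal(e$target[e$source %in% c("KIN", "PHO")], "X_A")
  # out-edges re-sourced to the active form
  expect_equal(e$source[e$target == "OUT"], "X_A")
  # dependency edge X_T -> X_A present and flagged
  expect_true(any(e$source == "X_T" & e$target == "X_A" & e$transcript_link))
  # node count grows by exactly the number of split nodes
  expect_equal(nrow(net$nodes), 5 + 1)
  # purely transcriptional targets stay unsplit
  expect_true("OUT" %in% net$nodes$id)
})

test_that("activation solve matches the sloppy-logic algebra on single nodes", {
  eq <- structure(list(node = "X", transcript_var = "X_T",
                       activators = "J", inhibitors = character(0),
                       active_var = "X_A"), class = "activation_equation")
  vals <- matrix(c(0.8, 1), 2, 1, dimnames = list(c("X", "J"), "s1"))
  expect_equal(solve_protein_activation(vals, list(eq))["X_A", 1], 0.8)

  eq2 <- structure(list(node = "X", transcript_var = "X_T",
                        activators = character(0), inhibitors = "M",
                        active_var = "X_A"), class = "activation_equation")
  vals2 <- matrix(c(0.8, 0.25), 2, 1, dimnames = list(c("X", "M"), "s1"))
  expect_equal(solve_protein_activation(vals2, list(eq2))["X_A", 1], 0.6)
})

test_that("coupled activation equations converge with small residuals", {
  eqs <- list(
    structure(list(node = "X", transcript_var = "X_T",
                   activators = character(0), inhibitors = "Y_A",
                   active_var = "X_A"), class = "activation_equation"),
    structure(list(node = "Y", transcript_var = "Y_T",
                   activators = character(0), inhibitors = "X_A",
                   active_var = "Y_A"), class = "activation_equation"))
  vals <- matrix(c(1, 1), 2, 1, dimnames = list(c("X", "Y"), "s1"))
  xa <- solve_protein_activation(vals, eqs, tol = 1e-10)
  x <- xa["X_A", 1]; y <- xa["Y_A", 1]
  expect_true(all(c(x, y) >= 0 & c(x, y) <= 1))
  expect_lt(abs(x - max(1 - y, 0)), 1e-8)
  expect_lt(abs(y - max(1 - x, 0)), 1e-8)
})

test_that("raising an inhibitor never raises the solved activation", {
  eq <- structure(list(node = "X", transcript_var = "X_T",
                       activators = "J", inhibitors = "M",
                       active_var = "X_A"), class = "activation_equation")
  prev <- Inf
  for (m in seq(0, 1, by = 0.1)) {
    vals <- matrix(c(0.9, 0.8, m), 3, 1, dimnames = list(c("X", "J", "M"), "s1"))
    cur <- solve_protein_activation(vals, list(eq))["X_A", 1]
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("rule estimator returns 0.5 with no support and converges with data", {
  # single regulator, all samples at A=1: the A=0 configuration has
  # (almost) no support and stays near the uninformative prior
  tr <- rbind(A = rep(1, 100), B = rep(1, 100))
  r <- infer_probabilistic_rule("B", "A", tr)
  expect_equal(r$probs[1], 0.5)
  expect_equal(r$support[1], 0)
  expect_equal(r$probs[2], 100.5 / 101)
  expect_equal(r$support[2], 100)
})

test_that("probabilities stay in [0,1] and zero support pins 0.5 exactly", {
  withr::local_seed(21)
  for (trial in 1:10) {
    n <- sample(1:3, 1)
    regs <- paste0("R", 1:n)
    tr <- matrix(runif((n + 1) * 6), n + 1, 6,
                 dimnames = list(c(regs, "T"), paste0("s", 1:6)))
    # make half the regulator entries hard 0/1 so some configs lose support
    tr[1:n, ] <- round(tr[1:n, ])
    r <- infer_probabilistic_rule("T", regs, tr)
    expect_true(all(r$probs >= 0 & r$probs <= 1))
    expect_true(all(r$probs[r$support == 0] == 0.5))
  }
})

test_that("adding an ON observation never decreases the rule output", {
  withr::local_seed(22)
  regs <- c("R1", "R2")
  tr <- matrix(runif(3 * 8), 3, 8, dimnames = list(c(regs, "T"), paste0("s", 1:8)))
  base <- infer_probabilistic_rule("T", regs, tr)
  for (ci in 1:4) {
    bits <- config_states(2)[ci, ]
    extra <- cbind(tr, s9 = c(bits, 1))
    grown <- infer_probabilistic_rule("T", regs, extra)
    expect_gte(grown$probs[ci], base$probs[ci] - 1e-12)
  }
})

test_that("identity rules are recovered from exhaustive Boolean training", {
  rule <- family_rule("id", "B", "A")
  r <- infer_probabilistic_rule("B", "A", exhaustive_training(rule))
  expect_equal(as.integer(r$probs >= 0.5), rule$table)
})

test_that("every <=3-input family rule is recovered from noiseless training", {
  for (seed in 1:100) {
    rule <- with_seed(seed, {
      k <- sample(1:3, 1)
      draw_family_rule("T", paste0("R", seq_len(k)))
    })
    tr <- exhaustive_training(rule)
    fit <- prune_insignificant_regulators("T", rule$regulators, tr)
    expect_setequal(fit$regulators, rule$regulators)
    # reorder the inferred table into the generating regulator order
    perm <- match(rule$regulators, fit$regulators)
    cfg <- config_states(length(rule$regulators))
    idx <- apply(cfg, 1, function(bits) {
      sum(bits[perm] * 2^(seq_along(bits) - 1)) + 1
    })
    expect_equal(as.integer(fit$probs[idx] >= 0.5), rule$table,
                 info = paste("seed", seed, attr(rule, "form")))
  }
})

test_that("regulator significance matches brute force and flags symmetry", {
  r <- worked_rule()
  expect_equal(regulator_significance(r, "A"), 1)
  for (reg in r$regulators) {
    expect_equal(regulator_significance(r, reg), oracle_significance(r, reg))
  }
  # a rule ignoring its regulator has significance 0
  flat <- probabilistic_rule("T", c("A", "B"), c(0.3, 0.3, 0.9, 0.9))
  expect_equal(regulator_significance(flat, "A"), 0)
  expect_equal(regulator_significance(flat, "B"), 0.6)
  ident <- probabilistic_rule("T", "A", c(0, 1))
  expect_equal(regulator_significance(ident, "A"), 1)
})

test_that("pruning removes spurious regulators and can empty a rule", {
  # target copies A; S is noise uncorrelated with the target
  tr <- rbind(A = c(0, 0, 1, 1), S = c(0, 1, 0, 1), T = c(0, 0, 1, 1))
  colnames(tr) <- paste0("s", 1:4)
  fit <- prune_insignificant_regulators("T", c("A", "S"), tr)
  expect_equal(fit$regulators, "A")
  expect_false(attr(fit, "source"))

  # all regulators spurious: the node becomes a source
  tr2 <- rbind(S1 = c(0, 1, 0, 1), S2 = c(0, 0, 1, 1), T = c(0.5, 0.5, 0.5, 0.5))
  colnames(tr2) <- paste0("s", 1:4)
  fit2 <- prune_insignificant_regulators("T", c("S1", "S2"), tr2)
  expect_length(fit2$regulators, 0)
  expect_true(attr(fit2, "source"))
  expect_equal(fit2$probs, 0.5)
})

test_that("rule inference warns above six regulators", {
  regs <- paste0("R", 1:7)
  tr <- matrix(0.5, 8, 4, dimnames = list(c(regs, "T"), paste0("s", 1:4)))
  expect_warning(infer_probabilistic_rule("T", regs, tr), "stochastic")
})

test_that("infer_rules handles a split network end to end", {
  net <- split_post_translational_nodes(split_fixture_network())
  withr::local_seed(30)
  genes <- c("TF1", "KIN", "PHO", "X", "OUT")
  raw <- matrix(runif(length(genes) * 12, 0, 100), length(genes), 12,
                dimnames = list(genes, paste0("s", 1:12)))
  cmap <- setNames(rep(paste0("c", 1:4), each = 3), colnames(raw))
  norm <- normalize_expression(preprocess_expression(raw), cmap)
  rules <- infer_rules(net, norm, threshold = 0.05)
  expect_s3_class(rules, "pbn_rules")
  # the active form carries the fixed inhibitory-dominant rule
  xa <- rules$rules[["X_A"]]
  expect_false(is.null(xa))
  expect_false(xa$inferred)
  expect_true(all(xa$probs %in% c(0, 1)))
  expect_setequal(xa$regulators, c("X_T", "KIN", "PHO"))
  # regulator-less nodes are sources
  expect_true(all(c("TF1", "KIN", "PHO") %in% rules$sources))
  dir <- withr::local_tempdir()
  write_rules(rules, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
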