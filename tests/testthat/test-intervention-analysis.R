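test_that("the worked edge profile for f = A or (B and C) is reproduced", {
  p <- edge_regulation_profile(worked_rule(), "A")
  expect_equal(p$avgON, 1)
  expect_equal(p$avgOFF, 0.25)
  expect_equal(p$sign, "positive")
  expect_equal(p$NON, 0.75)
  expect_equal(p$SON, 1)
  expect_equal(p$NOFF, 0)
  expect_equal(p$SOFF, 0)
})

test_that("negative and tied edges take the mirror and zero branches", {
  neg <- probabilistic_rule("B", "A", c(1, 0))  # f = NOT A
  p <- edge_regulation_profile(neg, "A")
  expect_equal(p$avgON, 0)
  expect_equal(p$avgOFF, 1)
  expect_equal(p$sign, "negative")
  expect_equal(c(p$NOFF, p$SOFF, p$NON, p$SON), c(1, 1, 0, 0))
  flat <- probabilistic_rule("B", "A", c(0.4, 0.4))
  pf <- edge_regulation_profile(flat, "A")
  expect_equal(c(pf$NON, pf$SON, pf$NOFF, pf$SOFF), c(0, 0, 0, 0))
  expect_error(edge_regulation_profile(neg, "Z"),
               class = "boolmod_validation_error")
})

test_that("edge profiles keep scores in [0,1] with one active branch", {
  withr::local_seed(61)
  for (trial in 1:20) {
    n <- sample(1:3, 1)
    r <- probabilistic_rule("T", paste0("R", 1:n), runif(2^n))
    p <- edge_regulation_profile(r, "R1")
    sc <- c(p$NON, p$SON, p$NOFF, p$SOFF)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_true(p$NON + p$SON == 0 || p$NOFF + p$SOFF == 0)
  }
})

test_that("influence index matches hand-evaluated identity-edge cases", {
  rules <- list(M1 = probabilistic_rule("M1", "K", c(0, 1)))
  mods <- c(M1 = "M", K = "unassigned")
  # identity edge: NON = SON = 1 -> KO/DOWN = 1.5, antisymmetric for UP
  expect_equal(influence_index("K", "KO", "M", rules, mods, "DOWN"), 1.5)
  expect_equal(influence_index("K", "KO", "M", rules, mods, "UP"), -1.5)
  expect_equal(influence_index("K", "CA", "M", rules, mods, "UP"), 1.5)
  # no targets in the module
  expect_equal(influence_index("K", "KO", "other", rules,
                               c(M1 = "other2", K = "unassigned"), "DOWN"), 0)
})

test_that("influence index is antisymmetric in the goal for random rules", {
  withr::local_seed(62)
  for (trial in 1:10) {
    rules <- lapply(setNames(paste0("T", 1:4), paste0("T", 1:4)), function(id) {
      n <- sample(1:3, 1)
      probabilistic_rule(id, sample(c("K", paste0("R", 1:3)), n), runif(2^n))
    })
    mods <- setNames(rep("M", 4), paste0("T", 1:4))
    for (mode in c("KO", "CA")) {
      up <- influence_index("K", mode, "M", rules, mods, "UP")
      dn <- influence_index("K", mode, "M", rules, mods, "DOWN")
      expect_equal(up, -dn)
    }
  }
})

test_that("interventions fix both forms of a split gene and reject duplicates", {
  rules <- list(
    X_T = probabilistic_rule("X_T", "TF1", c(0.2, 0.9)),
    X_A = inhibitory_dominant_rule("X_A", "X_T", "KIN", character(0)),
    OUT = probabilistic_rule("OUT", "X_A", c(0.1, 0.8)))
  ap <- apply_intervention(rules, data.frame(node = "X", mode = "KO"))
  expect_equal(ap$held, c(X_T = 0L, X_A = 0L))
  expect_equal(ap$rules$X_T$probs, 0)
  expect_equal(ap$rules$X_A$probs, 0)
  expect_identical(ap$rules$OUT, rules$OUT)

  ca <- apply_intervention(rules, data.frame(node = "OUT", mode = "CA"))
  expect_equal(ca$held, c(OUT = 1L))

  expect_error(apply_intervention(rules, data.frame(node = c("X", "X"),
                                                    mode = c("KO", "CA"))),
               class = "boolmod_validation_error")
  empty <- apply_intervention(rules, data.frame(node = character(0),
                                                mode = character(0)))
  expect_length(empty$held, 0)
})

test_that("walks respect absorbing states and held nodes", {
  rules <- list(A = probabilistic_rule("A", character(0), 1),
                B = probabilistic_rule("B", "A", c(0, 1)))
  start <- c(A = 1L, B = 1L)
  traj <- simulate_walk(rules, start, n_steps = 50, seed = 1)
  expect_true(all(traj[, "A"] == 1) && all(traj[, "B"] == 1))

  # held KO node stays OFF even under a constant-ON rule
  rules2 <- list(K = probabilistic_rule("K", character(0), 1),
                 B = probabilistic_rule("B", "K", c(0.5, 0.5)))
  traj2 <- simulate_walk(rules2, c(K = 1L, B = 0L), held = c(K = 0L),
                         n_steps = 200, seed = 2)
  expect_true(all(traj2[, "K"] == 0))
})

test_that("a lone f = 0.5 node matches its sampling contract", {
  rules <- list(N = probabilistic_rule("N", character(0), 0.5))
  traj <- simulate_walk(rules, c(N = 0L), n_steps = 10000, seed = 3)
  frac <- mean(traj[-1, "N"])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000) + 0.01)
  # flip frequency consistent with p = 0.5 (chi-square on ON/OFF counts)
  counts <- table(factor(traj[-1, "N"], levels = 0:1))
  expect_gt(suppressWarnings(stats::chisq.test(counts)$p.value), 0.01)
})

test_that("module activation bands use inclusive intermediate boundaries", {
  state <- c(a = 0L, b = 0L, c = 0L, d = 0L, s = 1L)
  expect_equal(module_activation(state, c("a", "b", "c", "d", "s"), "s"),
               list(fraction = 0, band = "low"))
  state[c("a", "b")] <- 1L
  expect_equal(module_activation(state, c("a", "b", "c", "d", "s"), "s")$band,
               "intermediate")
  expect_equal(module_activation(c(a = 1L, b = 0L, c = 0L, d = 0L),
                                 letters[1:4])$band, "intermediate")  # 0.25
  expect_equal(module_activation(c(a = 1L, b = 1L, c = 1L, d = 1L),
                                 letters[1:4])$band, "high")
  expect_error(module_activation(state, "s", "s"),
               class = "boolmod_validation_error")
})

test_that("switch times censor at n_steps + 1 and respect the prefix property", {
  expect_equal(first_switch_time(c(0.5, 0.1), "low"), 1)
  expect_equal(first_switch_time(rep(0.1, 10), "low"), 11)
  expect_equal(first_switch_time(c(0.5, 0.5, 0.1), "intermediate"), 3)
  fr <- c(0.1, 0.1, 0.5, 0.1, 0.6)
  full <- first_switch_time(fr, "low")
  trunc <- first_switch_time(fr[1:2], "low")
  expect_true(trunc >= full || trunc == 3)  # truncation only adds censoring
})

test_that("compiled walk core agrees with the pure-R reference walk", {
  hub <- generate_hub_control_model(4, 3)
  members <- setdiff(names(hub$modules)[hub$modules == "M"], "K")
  for (s in c(10, 20)) {
    times <- switch_time_experiment(hub$rules, hub$start_state,
                                    held = c(K = 1L), hub$modules,
                                    source_nodes = "K",
                                    tracked_modules = "M",
                                    n_walks = 1, n_steps = 400, seed = s)
    traj <- simulate_walk(hub$rules, hub$start_state, held = c(K = 1L),
                          n_steps = 400, seed = s + 1)
    fr <- rowMeans(traj[-1, members, drop = FALSE])
    expect_equal(times$time, first_switch_time(fr, "low"))
  }
})

test_that("extreme switching-time separations classify per start band", {
  wt <- data.frame(module = "M", start_band = "low", walk = 1:100,
                   time = rep(100, 100))
  slow <- data.frame(intervention = "ko", module = "M", start_band = "low",
                     walk = 1:100, time = rep(5001, 100))
  res <- compare_interventions(wt, slow)
  expect_lt(res$p_adj, 0.05)
  expect_equal(res$classification, "downregulating")

  fast <- slow
  fast$time <- 10
  expect_equal(compare_interventions(wt, fast)$classification, "upregulating")

  # intermediate starts flip the interpretation
  wt_i <- transform(wt, start_band = "intermediate")
  slow_i <- transform(slow, start_band = "intermediate")
  expect_equal(compare_interventions(wt_i, slow_i)$classification,
               "upregulating")

  same <- transform(slow, time = wt$time)
  expect_equal(compare_interventions(wt, same)$classification, "none")

  expect_error(compare_interventions(wt, slow[1:50, ]),
               class = "boolmod_validation_error")
})

test_that("BH adjustment is monotone and never below the raw p-value", {
  withr::local_seed(63)
  wt <- data.frame(module = rep(paste0("m", 1:4), each = 50),
                   start_band = "low", walk = rep(1:50, 4),
                   time = sample(1:500, 200, replace = TRUE))
  int <- wt
  int$intervention <- "iv"
  int$time <- wt$time + rep(c(0, 30, 300, 3000), each = 50)
  res <- compare_interventions(wt, int)
  expect_true(all(res$p_adj >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
})

test_that("a necessary-hub knockout is detected as downregulating its module", {
  hub <- generate_hub_control_model()
  # the hub is by construction necessary and sufficient for every module node
  for (id in names(hub$modules)[hub$modules == "M"]) {
    p <- edge_regulation_profile(hub$rules[[id]], "K")
    expect_equal(c(p$NON, p$SON), c(1, 1))
  }
  wt <- switch_time_experiment(hub$rules, hub$start_state, held = c(K = 1L),
                               hub$modules, source_nodes = "K",
                               n_walks = 40, n_steps = 1000, seed = 5)
  ko <- apply_intervention(hub$rules, data.frame(node = "K", mode = "KO"))
  kt <- switch_time_experiment(ko$rules, hub$start_state, held = ko$held,
                               hub$modules, source_nodes = "K",
                               tracked_modules = unique(wt$module),
                               n_walks = 40, n_steps = 1000, seed = 5)
  kt$intervention <- "KO_K"
  res <- compare_interventions(wt, kt)
  m_row <- res[res$module == "M", ]
  expect_equal(m_row$classification, "downregulating")
  expect_true(all(kt$time[kt$module == "M"] == 1001))  # fully censored
})
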