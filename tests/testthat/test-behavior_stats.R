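test_that("score_recall is strict positional matching", {
  expect_equal(score_recall(c("ba", "da"), c("ba", "da")), c(TRUE, TRUE))
  expect_equal(score_recall(c("ba", "da", "ga", "ba"),
                            c("ba", "ga", "ga", "da")),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_error(score_recall(c("ba", "da"), "ba"), "equal length")
  # random responding converges to chance = 1/3
  set.seed(10)
  n <- 12000
  t_syl <- sample(c("ba", "da", "ga"), n, replace = TRUE)
  r_syl <- sample(c("ba", "da", "ga"), n, replace = TRUE)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(mean(score_recall(t_syl, r_syl)) - 1 / 3), 3 * se)
})

make_toy_cohort <- function() {
  # 8-trial toy design, hand-checkable counts
  design <- data.frame(
    subject = rep("S1", 8), trial = 0:7,
    room = rep(c("anechoic", "reverberant"), each = 4),
    interrupted = rep(c(TRUE, FALSE), 4))
  # position 1 always correct, position 2 correct only when uninterrupted
  resp <- do.call(rbind, lapply(0:7, function(tr) {
    inter <- design$interrupted[design$trial == tr]
    data.frame(subject = "S1", trial = tr, position = 1:2,
               target = c("ba", "da"),
               response = c("ba", if (inter) "ga" else "da"))
  }))
  list(design = design, resp = resp)
}

test_that("accuracy_table matches hand counts and is order-invariant", {
  toy <- make_toy_cohort()
  acc <- accuracy_table(toy$resp, toy$design)
  expect_equal(nrow(acc), 8)  # 1 subject x 2 rooms x 2 interruption x 2 pos
  expect_true(all(acc$accuracy[acc$position == 1] == 1))
  expect_equal(acc$accuracy[acc$position == 2],
               ifelse(acc$interrupted[acc$position == 2], 0, 1))
  expect_true(all(acc$n_trials == 2))
  perm <- toy$resp[sample(nrow(toy$resp)), ]
  expect_equal(accuracy_table(perm, toy$design), acc)
  # missing cells are reported
  expect_error(accuracy_table(toy$resp[toy$resp$trial < 4, ], toy$design),
               "empty design cells")
})

test_that("interruption_effect is the uninterrupted-minus-interrupted delta", {
  toy <- make_toy_cohort()
  acc <- accuracy_table(toy$resp, toy$design)
  eff <- interruption_effect(acc)
  expect_equal(eff$effect[eff$position == 1], c(0, 0))
  expect_equal(eff$effect[eff$position == 2], c(1, 1))
  expect_error(interruption_effect(acc[!acc$interrupted, ]), "both")
})

test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  set.seed(33)
  grid <- expand.grid(subject = paste0("S", 1:6),
                      interrupted = c(TRUE, FALSE),
                      room = c("anechoic", "reverberant"),
                      position = 1:4, stringsAsFactors = FALSE)
  grid$accuracy <- runif(nrow(grid))
  got <- rm_anova(grid)
  oracle <- oracle_rm_anova(grid, "accuracy",
                            c("interrupted", "room", "position"), "subject")
  expect_equal(nrow(got), 7)
  for (i in seq_len(nrow(oracle))) {
    want <- oracle[i, ]
    parts <- strsplit(want$effect, ":")[[1]]
    hit <- which(vapply(strsplit(got$effect, ":"), function(g)
      setequal(g, parts), logical(1)))
    expect_length(hit, 1)
    expect_equal(got$F[hit], want$F, tolerance = 1e-8)
    expect_equal(got$df1[hit], want$df1)
    expect_equal(got$df2[hit], want$df2)
    expect_equal(got$p[hit], want$p, tolerance = 1e-8)
  }
})

test_that("rm_anova F is invariant to location and scale", {
  set.seed(7)
  grid <- expand.grid(subject = paste0("S", 1:5),
                      interrupted = c(TRUE, FALSE),
                      room = c("anechoic", "reverberant"),
                      position = 1:4, stringsAsFactors = FALSE)
  grid$accuracy <- runif(nrow(grid))
  f0 <- rm_anova(grid)$F
  g1 <- grid; g1$accuracy <- grid$accuracy + 5
  expect_equal(rm_anova(g1)$F, f0, tolerance = 1e-8)
  g2 <- grid; g2$accuracy <- grid$accuracy * 3.2
  expect_equal(rm_anova(g2)$F, f0, tolerance = 1e-8)
  expect_error(rm_anova(grid[-1, ]), "incomplete")
})

test_that("posthoc_paired matches the closed-form paired t and Bonferroni", {
  set.seed(21)
  pairs <- lapply(1:4, function(i)
    list(x = rnorm(5, mean = 0.1 * i), y = rnorm(5)))
  names(pairs) <- paste0("cmp", 1:4)
  got <- posthoc_paired(pairs)
  for (i in 1:4) {
    d <- pairs[[i]]$x - pairs[[i]]$y
    t_direct <- mean(d) / (sd(d) / sqrt(5))
    p_direct <- 2 * pt(-abs(t_direct), 4)
    expect_equal(got$t[i], t_direct, tolerance = 1e-10)
    expect_equal(got$p[i], p_direct, tolerance = 1e-10)
    expect_equal(got$p_adj[i], min(1, 4 * p_direct), tolerance = 1e-10)
  }
  # identical vectors: t = 0, adjusted p = 1
  one <- posthoc_paired(list(same = list(x = 1:5, y = 1:5)))
  expect_equal(one$t, 0)
  expect_equal(one$p_adj, 1)
  # m = 1: adjusted p equals raw p
  single <- posthoc_paired(pairs["cmp1"])
  expect_equal(single$p_adj, single$p)
  expect_error(posthoc_paired(list(bad = list(x = 1, y = 2))), "pairs")
})

test_that("ANOVA detects generated penalties and is calibrated under null", {
  # detection with the default penalty structure (scaled-down cohort;
  # effect sizes untouched)
  detect <- vapply(1:8, function(sd_) {
    cohort <- lapply(1:14, function(s) {
      cfg <- design_config(n_trials = 80, n_blocks = 4,
                          seed = s + 100 * sd_)
      bp <- behavior_gen_params(seed = s + 100 * sd_ + 50000L)
      d <- build_design(cfg)
      b <- simulate_behavior(d, bp)
      b$subject <- d$subject <- sprintf("S%02d", s)
      list(d = d, b = b)
    })
    acc <- accuracy_table(do.call(rbind, lapply(cohort, `[[`, "b")),
                          do.call(rbind, lapply(cohort, `[[`, "d")))
    an <- rm_anova(acc)
    all(an$p[an$effect %in% c("interrupted", "room")] < 0.05)
  }, logical(1))
  expect_gte(mean(detect), 7 / 8)

  # null generator: rejection rate of each main effect ~ alpha
  null_p <- t(vapply(1:220, function(sim) {
    cohort <- lapply(1:10, function(s) {
      cfg <- design_config(n_trials = 32, n_blocks = 2,
                          seed = sim * 31 + s)
      bp <- behavior_gen_params(rep(0.7, 4), rep(0, 4), 0,
                                seed = sim * 37 + s)
      d <- build_design(cfg)
      b <- simulate_behavior(d, bp)
      b$subject <- d$subject <- sprintf("S%02d", s)
      list(d = d, b = b)
    })
    acc <- accuracy_table(do.call(rbind, lapply(cohort, `[[`, "b")),
                          do.call(rbind, lapply(cohort, `[[`, "d")))
    an <- rm_anova(acc)
    c(interrupted = an$p[an$effect == "interrupted"],
      room = an$p[an$effect == "room"])
  }, numeric(2)))
  n_sim <- nrow(null_p)
  band <- 3 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(null_p[, "interrupted"] < 0.05) - 0.05), band)
  expect_lt(abs(mean(null_p[, "room"] < 0.05) - 0.05), band)
})
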