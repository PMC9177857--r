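test_that("auROC matches brute-force pair counting and known values", {
  expect_equal(auroc(c(2, 3), c(1, 2)), 0.875)
  expect_equal(auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auroc(c(10, 11, 12), c(1, 2, 3)), 1.0)
  expect_equal(auroc(c(1, 2, 3), c(10, 11, 12)), 0.0)
  set.seed(341)
  for (k in 1:30) {
    x <- sample(0:5, 8, replace = TRUE)
    y <- sample(0:5, 11, replace = TRUE)
    expect_equal(auroc(x, y), oracle_auroc(x, y), tolerance = 1e-12)
  }
})

test_that("auROC is invariant to monotone transforms and complements", {
  set.seed(351)
  x <- stats::rexp(10); y <- stats::rexp(15)
  a <- auroc(x, y)
  expect_equal(auroc(exp(2 * x), exp(2 * y)), a)
  expect_equal(auroc(rank(c(x, y))[1:10], rank(c(x, y))[11:25]), a)
  expect_equal(auroc(y, x), 1 - a, tolerance = 1e-12)
})

test_that("responsiveness labels strong effects and ignores flat units", {
  set.seed(361)
  s <- generate_trial_sequence(task_config(60))
  n_tr <- nrow(s)
  flat <- do.call(rbind, lapply(seq_len(n_tr), function(i)
    poisson_trial_spikes(i, 3, c(-3, 6))))
  excited <- do.call(rbind, lapply(seq_len(n_tr), function(i) rbind(
    poisson_trial_spikes(i, 3, c(-3, 0)),
    poisson_trial_spikes(i, 8, c(0, 1)),
    poisson_trial_spikes(i, 3, c(1, 6)))))
  silent <- data.frame(trial = integer(0), time = numeric(0))
  rs <- make_raster_set(list(flat, excited, silent), s)
  res <- test_responsiveness(rs)
  lab <- function(u, w) res$label[res$unit == u & res$window == w]
  expect_true(all(lab("u003", "CS") == "none"))      # all-zero unit
  expect_true(any(lab("u002", "CS") == "excited"))
  expect_true(all(lab("u002", "wait") == "none"))
  expect_true(all(lab("u001", "CS") == "none"))
})

test_that("null units are flagged at roughly the nominal rate pre-correction", {
  set.seed(371)
  s <- generate_trial_sequence(task_config(60))
  units <- lapply(1:40, function(u)
    do.call(rbind, lapply(seq_len(nrow(s)), function(i)
      poisson_trial_spikes(i, 4, c(-3, 6)))))
  rs <- make_raster_set(units, s)
  res <- test_responsiveness(rs)
  rate <- mean(res$p < 0.05)
  expect_lt(rate, 0.10)    # ~5% nominal; generous upper bound
  expect_true(all(res$label[res$p_adj >= 0.05] == "none"))
})

test_that("profile clustering separates planted archetypes with purity", {
  set.seed(381)
  s <- generate_trial_sequence(task_config(90))
  p <- population_params(mix = c(transient = 0.5, ramping = 0.5,
                                 inhibited = 0, sustained = 0),
                         dominant_fraction = 0)
  rs <- simulate_population(s, 50, params = p, seed = 9)
  truth <- vapply(rs$units, `[[`, character(1), "archetype")
  prof <- auroc_profile(rs)
  cl <- cluster_units(prof)
  tab <- table(truth, cl$group)
  purity <- sum(apply(tab, 1, max)) / length(truth)
  expect_gte(purity, 0.95)
  # planted inhibited units land in the inhibited group
  p2 <- population_params(mix = c(transient = 0.5, ramping = 0.2,
                                  inhibited = 0.3, sustained = 0))
  rs2 <- simulate_population(s, 40, params = p2, seed = 10)
  truth2 <- vapply(rs2$units, `[[`, character(1), "archetype")
  cl2 <- cluster_units(auroc_profile(rs2))
  inh <- truth2 == "inhibited"
  expect_gte(mean(cl2$group[inh] == "inhibited"), 0.9)
})

test_that("a homogeneous population maps to a single functional group", {
  set.seed(391)
  s <- generate_trial_sequence(task_config(90))
  p <- population_params(mix = c(transient = 1, ramping = 0,
                                 inhibited = 0, sustained = 0),
                         dominant_fraction = 0)
  rs <- simulate_population(s, 20, params = p, seed = 11)
  cl <- cluster_units(auroc_profile(rs))
  # tree-cut granularity on a homogeneous population is noise-driven, but
  # every flat cluster must classify to the same functional group
  expect_equal(unique(cl$group), "transient")
})

test_that("monotonic RP and dominance labels follow the rank-sum rules", {
  set.seed(401)
  mono <- test_monotonic_rp(r0 = stats::rnorm(20, 1, 0.3),
                            r50 = stats::rnorm(20, 4, 0.3),
                            r100 = stats::rnorm(20, 8, 0.3))
  expect_equal(mono$label, "monotonic")
  same <- test_monotonic_rp(rep(2, 20), rep(2, 20), rep(2, 20))
  expect_equal(same$label, "neither")
  dom <- test_monotonic_rp(r0 = stats::rnorm(20, 1, 0.3),
                           r50 = stats::rnorm(20, 8, 0.3),
                           r100 = stats::rnorm(20, 1.1, 0.3))
  expect_equal(dom$label, "dominant")
  expect_equal(dom$dominant_cs, "CS50")
  # inverted test for inhibited clusters
  inh <- test_monotonic_rp(r0 = stats::rnorm(20, 8, 0.3),
                           r50 = stats::rnorm(20, 4, 0.3),
                           r100 = stats::rnorm(20, 1, 0.3),
                           inhibited = TRUE)
  expect_equal(inh$label, "monotonic")
  few <- test_monotonic_rp(1:3, 4:6, 7:9)
  expect_equal(few$label, "neither")
  expect_true(few$flagged)
  # labels invariant to unit-wide rate scaling
  sc <- test_monotonic_rp(2.5 * stats::rnorm(20, 1, 0.3),
                          2.5 * stats::rnorm(20, 4, 0.3),
                          2.5 * stats::rnorm(20, 8, 0.3))
  expect_equal(sc$label, "monotonic")
})

test_that("non-monotonic single-CS responders are monotonic as a population", {
  set.seed(411)
  n_tr <- 90
  cs <- rep(c("CS0", "CS50", "CS100"), each = n_tr / 3)
  # dominant responders; unit counts scale with reward probability
  pref <- c(rep("CS100", 6), rep("CS50", 3), rep("CS0", 1))
  rate_mat <- t(vapply(pref, function(p)
    stats::rpois(n_tr, ifelse(cs == p, 8, 1)), numeric(n_tr)))
  mono_flags <- rep(FALSE, length(pref))
  out <- distributed_coding_test(rate_mat, cs, mono_flags)
  expect_true(out$population_monotonic)
  expect_equal(out$ordering, c("CS0", "CS50", "CS100"))
  # pure-noise remainder is not monotonic
  noise_mat <- matrix(stats::rpois(10 * n_tr, 3), nrow = 10)
  out2 <- distributed_coding_test(noise_mat, cs, rep(FALSE, 10))
  expect_false(out2$population_monotonic)
  expect_warning(distributed_coding_test(noise_mat, cs, rep(TRUE, 10)),
                 "undefined")
})

test_that("reward surprise requires a larger CS50 jump than CS100", {
  set.seed(421)
  d50 <- stats::rnorm(25, 4, 1); d100 <- stats::rnorm(25, 1, 1)
  expect_true(test_reward_surprise(d50, d100)$surprise)
  same <- stats::rnorm(25, 2, 1)
  expect_false(test_reward_surprise(same, same + 1e-9)$surprise)
  # inverted criteria for inhibited units
  expect_true(test_reward_surprise(-d50, -d100,
                                   inhibited = TRUE)$surprise)
  expect_false(test_reward_surprise(-d50, -d100)$surprise)
  # either window suffices
  flat <- stats::rnorm(25, 0, 1)
  out <- test_reward_surprise(flat, flat, d50_b = d50, d100_b = d100)
  expect_true(out$surprise)
  expect_equal(out$window, "B")
})

test_that("outcome discrimination is one-directional", {
  set.seed(431)
  r <- stats::rnorm(25, 6, 1); n <- stats::rnorm(25, 2, 1)
  expect_true(test_outcome_discrimination(r, n)$discriminates)
  expect_false(test_outcome_discrimination(n, n + 1e-9)$discriminates)
  # significant but opposite-direction effect is not scored
  expect_false(test_outcome_discrimination(n, r)$discriminates)
  expect_true(test_outcome_discrimination(n, r,
                                          inhibited = TRUE)$discriminates)
})

test_that("chance level for a specific ordering is n_discriminative / 6", {
  set.seed(441)
  units <- lapply(1:12, function(u) list(r0 = stats::rnorm(20, 1, 0.2),
                                         r50 = stats::rnorm(20, 3, 0.2),
                                         r100 = stats::rnorm(20, 5, 0.2)))
  out <- chance_level_monotonic(units)
  expect_equal(out$n_discriminative, 12L)
  expect_equal(out$expected_per_ordering, 2)
  expect_equal(unname(out$observed[["CS100>CS50>CS0"]]), 12L)
  none <- chance_level_monotonic(lapply(1:5, function(u)
    list(r0 = rep(1, 20), r50 = rep(1, 20), r100 = rep(1, 20))))
  expect_equal(none$n_discriminative, 0L)
  expect_equal(none$expected_per_ordering, 0)
})

test_that("ordering counts are exchangeable under cue-label permutation", {
  set.seed(451)
  # null units that discriminate cues with random intensities: each of the
  # six orderings should appear with roughly equal frequency
  counts <- integer(0)
  for (rep_i in 1:150) {
    mus <- sample(c(1, 3, 5))
    u <- list(r0 = stats::rnorm(25, mus[1], 0.3),
              r50 = stats::rnorm(25, mus[2], 0.3),
              r100 = stats::rnorm(25, mus[3], 0.3))
    out <- chance_level_monotonic(list(u))
    if (out$n_discriminative == 1)
      counts <- c(counts, names(out$observed))
  }
  tab <- table(counts)
  expect_equal(length(tab), 6L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("history and satiety contrasts pick up the planted modulations", {
  set.seed(461)
  s <- generate_trial_sequence(task_config(150))
  # planted: +2 Hz after rewarded CS50 history, no satiety effect
  i50 <- which(s$cs == "CS50")
  hist_sign <- rep(0, nrow(s))
  hist_sign[i50[-1]] <- ifelse(s$rewarded[i50][-length(i50)], 1, -1)
  values <- stats::rnorm(nrow(s), 5 + 2 * hist_sign, 0.5)
  out <- history_satiety_effects(values, s)
  expect_lt(out$history[["p"]], 0.01)
  expect_gt(out$history[["diff"]], 0)
  expect_gt(out$satiety[["p"]], 0.05)
  # planted satiety only
  prior_rew <- c(FALSE, s$rewarded[-nrow(s)])
  values2 <- stats::rnorm(nrow(s), 5 - 2 * prior_rew, 0.5)
  out2 <- history_satiety_effects(values2, s)
  expect_lt(out2$satiety[["p"]], 0.01)
  expect_lt(out2$satiety[["diff"]], 0)
})
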