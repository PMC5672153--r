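# Seeded generators for counts and trial-level experiments; outlier trim.

test_that("simulated counts are reproducible and match analytic probabilities", {
  m <- build_ebpm_model()
  th <- c(P = 0.4, M = 0.9, C1 = 0.5, C2 = 0.7)
  c1 <- simulate_counts(m, th, 1000, seed = 10)
  c2 <- simulate_counts(m, th, 1000, seed = 10)
  expect_identical(c1, c2)
  expect_false(identical(c1, simulate_counts(m, th, 1000, seed = 11)))
  # large-sample proportions stay within three binomial standard errors
  big <- simulate_counts(m, th, 1e6, seed = 12)
  pm <- category_probabilities(m, th)
  for (i in seq_len(nrow(big))) {
    p <- pm[big$tree[i], big$category[i]]
    se <- sqrt(p * (1 - p) / 1e6)
    expect_lt(abs(big$count[i] / 1e6 - p), 3 * se + 1e-8)
  }
  # degenerate generating point: every target response is "pm"
  all_pm <- simulate_counts(m, c(P = 1, M = 1, C1 = 1, C2 = 1), 100,
                            seed = 1)
  tm <- all_pm[all_pm$tree == "target_match", ]
  expect_equal(tm$count[tm$category == "pm"], 100)
})

test_that("cue trials are placed deterministically by the duration design", {
  des <- condition_design(3, 3, n_participants = 2, trial_rate = 20)
  sim <- simulate_experiment(des, generator_config(seed = 5))
  p1 <- sim$trials[sim$trials$participant == 1, ]
  # first cue at 3 min x 20 trials/min = trial 60, second 2 min later,
  # task ends 2 min after the second cue
  expect_identical(which(p1$is_cue), c(60L, 100L))
  expect_identical(nrow(p1), 140L)
  expect_true(all(p1$trial_type[p1$is_cue] %in%
                    c("target_match", "target_nonmatch")))
  # non-cue trials split evenly between match and non-match distractors
  tt <- table(p1$trial_type[!p1$is_cue])
  expect_equal(unname(tt["distractor_match"]),
               unname(tt["distractor_nonmatch"]))
  expect_error(condition_design(3, 0, n_participants = 2),
               "cue placement")
})

test_that("the experiment generator is deterministic in its seed", {
  des <- ebpm_design_grid(n_participants = rep(3, 9))
  s1 <- simulate_experiment(des, generator_config(seed = 77))
  s2 <- simulate_experiment(des, generator_config(seed = 77))
  expect_identical(s1, s2)
  expect_error(generator_config(), "seed")
})

test_that("perfect processes yield perfect accuracy; ratings stay on the 1-5 scale", {
  cfg <- generator_config(theta = function(f, o) {
    c(P = 1, M = 1, C1 = 1, C2 = 1)
  }, gamma = 0, seed = 3)
  sim <- simulate_experiment(condition_design(3, 3, 20), cfg)
  expect_true(all(sim$participants$accuracy == 1))
  expect_true(all(sim$participants$self_reminding %in% 1:5))
  expect_true(all(sim$participants$discriminability %in% 1:5))
  expect_true(all(sim$trials$rt_ms > 0))
})

test_that("trial-level and count-level generators agree in distribution", {
  m <- build_ebpm_model()
  th <- default_condition_theta(3, 3)
  cfg <- generator_config(theta = function(f, o) th, gamma = 0, seed = 21)
  sim <- simulate_experiment(condition_design(3, 3, 300), cfg)
  agg <- counts_from_trials(sim$trials)
  direct <- simulate_counts(m, th, 5000, seed = 22)
  # per tree, compare the two response distributions with a two-sample
  # chi-square test; they come from the same multinomial
  for (tr in ebpm_tree_names()) {
    a <- agg[agg$tree == tr, ]
    b <- direct[direct$tree == tr, ]
    cats <- union(a$response, b$category)
    tab <- rbind(a$count[match(cats, a$response)],
                 b$count[match(cats, b$category)])
    tab[is.na(tab)] <- 0
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("aggregated trials from a large cohort recover the generating parameters", {
  m <- build_ebpm_model()
  th <- default_condition_theta(3, 3)
  cfg <- generator_config(theta = function(f, o) th, gamma = 0, seed = 11)
  big <- simulate_experiment(condition_design(3, 3, 10000), cfg)
  fit <- fit_mle(m, counts_from_trials(big$trials)[, c("tree", "response",
                                                       "count")],
                 n_starts = 3, seed = 1, ci = FALSE)
  expect_lt(max(abs(fit$estimates[names(th)] - th)), 0.01)
})

test_that("the outlier trim applies a single mean +/- 3 SD pass", {
  # brute force on the canonical example: mean 20.8, SD 44.27, so 100 lies
  # inside the 3 SD band and the input is returned unchanged
  x <- c(1, 1, 1, 1, 100)
  expect_true(100 < mean(x) + 3 * stats::sd(x))
  expect_identical(trim_outliers(x), x)
  # a genuinely extreme point is removed
  set.seed(7)
  y <- c(rnorm(50), 1e6)
  expect_identical(trim_outliers(y), y[-51])
  # constant input (zero SD) is returned unchanged
  expect_identical(trim_outliers(rep(2, 5)), rep(2, 5))
  # standard-normal tail mass: about 0.27% removed in large samples
  set.seed(8)
  z <- rnorm(1e5)
  removed <- 1 - length(trim_outliers(z)) / length(z)
  expect_gt(removed, 0.001)
  expect_lt(removed, 0.005)
  expect_error(trim_outliers(1), "length")
})

test_that("default generating parameters blend the marginal duration estimates", {
  th <- default_condition_theta(3, 9)
  tab <- ebpm_theta_table()
  ft3 <- tab[tab$task == "ft" & tab$minutes == 3, c("P", "M", "C1", "C2")]
  ot9 <- tab[tab$task == "ot" & tab$minutes == 9, c("P", "M", "C1", "C2")]
  expect_equal(unname(th), unname((as.numeric(ft3) + as.numeric(ot9)) / 2))
  expect_error(default_condition_theta(3, 6), "3, 9 and 15")
  # design grid covers the 3 x 3 layout with the study's cell sizes
  grid <- ebpm_design_grid()
  expect_identical(length(grid), 9L)
  expect_identical(sum(vapply(grid, `[[`, numeric(1), "n_participants")),
                   223)
})
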