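# Maximum-likelihood fitting, G-squared, and confidence intervals.

test_that("G-squared matches direct evaluation and is additive over trees", {
  # single tree, observed (30, 70) against fifty-fifty expectations
  obs <- data.frame(tree = "t", category = c("yes", "no"),
                    count = c(30, 70))
  probs <- matrix(c(0.5, 0.5), 1, dimnames = list("t", c("yes", "no")))
  expect_equal(g_squared(obs, probs),
               2 * (30 * log(0.6) + 70 * log(1.4)), tolerance = 1e-12)
  expect_equal(g_squared(obs, probs), 16.4566, tolerance = 1e-4)
  # observed exactly at expectation gives zero
  obs0 <- data.frame(tree = "t", category = c("yes", "no"),
                     count = c(50, 50))
  expect_equal(g_squared(obs0, probs), 0)
  # two trees: statistic sums over trees
  obs2 <- rbind(obs, within(obs, tree <- "u"))
  probs2 <- rbind(t = c(0.5, 0.5), u = c(0.5, 0.5))
  colnames(probs2) <- c("yes", "no")
  expect_equal(g_squared(obs2, probs2), 2 * g_squared(obs, probs),
               tolerance = 1e-12)
  # a zero count contributes nothing
  obs3 <- data.frame(tree = "t", category = c("yes", "no"),
                     count = c(100, 0))
  expect_equal(g_squared(obs3, probs), 2 * 100 * log(2), tolerance = 1e-12)
  # positive count on a zero-probability cell: infinite, with a warning
  probs4 <- matrix(c(1, 0), 1, dimnames = list("t", c("yes", "no")))
  expect_warning(v <- g_squared(obs, probs4), "infinite")
  expect_identical(v, Inf)
})

test_that("the MLE equals the closed form on a one-parameter binomial tree", {
  m <- binomial_model()
  for (n_yes in c(3, 41, 77)) {
    cts <- data.frame(tree = "t", category = c("yes", "no"),
                      count = c(n_yes, 100 - n_yes))
    fit <- fit_mle(m, cts, n_starts = 3, seed = 1, ci = FALSE)
    expect_equal(unname(fit$estimates["a"]), n_yes / 100,
                 tolerance = 1e-6)
  }
})

test_that("fitting expected frequencies recovers the generating point exactly", {
  m <- build_ebpm_model()
  theta <- c(P = 0.5, M = 0.9, C1 = 0.6, C2 = 0.8)
  fit <- fit_mle(m, expected_counts(m, theta, 1000), n_starts = 5,
                 seed = 1, ci = FALSE)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates[names(theta)] - theta)), 1e-4)
  expect_lt(fit$g_squared, 1e-6)
  expect_identical(fit$df, 4L)
})

test_that("estimates and G-squared are invariant to row order of the counts", {
  m <- build_ebpm_model()
  cts <- simulate_counts(m, c(P = 0.4, M = 0.9, C1 = 0.5, C2 = 0.7),
                         n_per_tree = 500, seed = 5)
  perm <- cts[rev(seq_len(nrow(cts))), ]
  f1 <- fit_mle(m, cts, n_starts = 3, seed = 2, ci = FALSE)
  f2 <- fit_mle(m, perm, n_starts = 3, seed = 2, ci = FALSE)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-9)
  expect_equal(f1$g_squared, f2$g_squared, tolerance = 1e-9)
})

test_that("degenerate counts give a boundary estimate with a truncated interval", {
  m <- binomial_model()
  cts <- data.frame(tree = "t", category = c("yes", "no"),
                    count = c(100, 0))
  fit <- fit_mle(m, cts, n_starts = 3, seed = 1)
  expect_true(fit$converged)
  expect_gt(fit$estimates[["a"]], 1 - 1e-5)
  expect_identical(unname(fit$ci_method["a"]), "profile")
  expect_equal(unname(fit$ci95["a", "upper"]), 1)
  # profile lower bound: G2(v) = -200 log v rises by 3.84 at v = exp(-0.0192)
  expect_equal(unname(fit$ci95["a", "lower"]),
               exp(-stats::qchisq(0.95, 1) / 200), tolerance = 1e-3)
})

test_that("Wald interval width shrinks like one over the square root of N", {
  m <- build_ebpm_model()
  theta <- c(P = 0.5, M = 0.8, C1 = 0.6, C2 = 0.7)
  w <- sapply(c(1e3, 1e5), function(N) {
    fit <- fit_mle(m, expected_counts(m, theta, N), n_starts = 3,
                   seed = 1)
    mean(fit$ci95[, "upper"] - fit$ci95[, "lower"])
  })
  expect_equal(w[1] / w[2], sqrt(1e5 / 1e3), tolerance = 0.05)
})

test_that("fixed parameters get no interval and missing data are rejected", {
  m <- build_ebpm_model()
  cts <- simulate_counts(m, c(P = 0.4, M = 0.9, C1 = 0.5, C2 = 0.7),
                         n_per_tree = 500, seed = 6)
  fit <- fit_mle(m, cts, n_starts = 3, seed = 1)
  expect_setequal(rownames(fit$ci95), c("P", "M", "C1", "C2"))
  expect_false(any(c("g", "c") %in% rownames(fit$ci95)))
  empty <- data.frame(tree = "target_match", category = "pm", count = 0)
  expect_error(fit_mle(m, empty, n_starts = 2, seed = 1), "empty")
  bad <- data.frame(tree = "no_such_tree", category = "pm", count = 5)
  expect_error(fit_mle(m, bad, n_starts = 2, seed = 1), "unknown")
})

test_that("fitting does not disturb the caller's random-number stream", {
  m <- binomial_model()
  cts <- data.frame(tree = "t", category = c("yes", "no"),
                    count = c(40, 60))
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(fit_mle(m, cts, n_starts = 5, seed = 3, ci = FALSE))
  expect_identical(stats::runif(1), before)
})
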