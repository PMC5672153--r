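# Joint fits across conditions and delta-G-squared equality tests.

test_that("a joint fit with nothing shared reduces to independent fits", {
  m <- build_ebpm_model()
  th <- c(P = 0.46, M = 0.96, C1 = 0.56, C2 = 0.73)
  a <- simulate_counts(m, th, 2000, seed = 1)
  b <- simulate_counts(m, th, 2000, seed = 2)
  single <- fit_mle(m, a, n_starts = 3, seed = 1, ci = FALSE)
  # two identical datasets: joint G2 doubles, per-dataset estimates agree
  j2 <- fit_joint(m, list(x = a, y = a), n_starts = 3, seed = 1)
  expect_equal(j2$g_squared, 2 * single$g_squared, tolerance = 1e-6)
  expect_equal(j2$estimates["x", ], j2$estimates["y", ], tolerance = 1e-5)
  expect_equal(unname(j2$estimates["x", names(th)]),
               unname(single$estimates[names(th)]), tolerance = 1e-4)
  # one dataset: identical to fit_mle
  j1 <- fit_joint(m, list(only = a), n_starts = 3, seed = 1)
  expect_equal(j1$g_squared, single$g_squared, tolerance = 1e-8)
  expect_identical(j1$df, 4L)
  # different tree structure is a structural error
  bad <- data.frame(tree = "weird_tree", category = "pm", count = 4)
  expect_error(fit_joint(m, list(a = a, b = bad)), "unknown")
})

test_that("the pooled nine-condition fit has 36 trees and 68 degrees of freedom", {
  m <- build_ebpm_model()
  th <- c(P = 0.4, M = 0.95, C1 = 0.55, C2 = 0.78)
  sets <- lapply(1:9, function(i) simulate_counts(m, th, 800, seed = i))
  names(sets) <- paste0("cond", 1:9)
  jf <- fit_joint(m, sets, equate = c("P", "M", "C1", "C2"),
                  n_starts = 3, seed = 1)
  expect_identical(length(jf$model$trees) * 9L, 36L)
  expect_identical(jf$df, 68L)
  expect_true(jf$converged)
  # all-shared estimates are identical across conditions
  expect_equal(max(apply(jf$estimates, 2, stats::sd)), 0, tolerance = 1e-12)
  # statistic decomposes over datasets
  expect_equal(sum(jf$per_dataset_g2), jf$g_squared, tolerance = 1e-8)
})

test_that("equating a parameter between identical datasets changes nothing", {
  m <- build_ebpm_model()
  th <- c(P = 0.4, M = 0.9, C1 = 0.5, C2 = 0.7)
  a <- simulate_counts(m, th, 3000, seed = 11)
  cmp <- delta_g2_test(m, a, a, "P", n_starts = 3, seed = 1)
  expect_lt(abs(cmp$delta_g2), 1e-4)
  expect_false(cmp$significant)
  expect_identical(cmp$df, 1L)
  expect_equal(cmp$critical_value, stats::qchisq(0.95, 1), tolerance = 1e-12)
})

test_that("the constrained fit never beats the free fit (nesting) and the test is symmetric", {
  m <- build_ebpm_model()
  th_a <- c(P = 0.46, M = 0.96, C1 = 0.56, C2 = 0.73)
  th_b <- c(P = 0.30, M = 0.96, C1 = 0.56, C2 = 0.73)
  set.seed(31)
  for (i in 1:5) {
    a <- simulate_counts(m, th_a, 1500, seed = 100 + i)
    b <- simulate_counts(m, th_b, 1500, seed = 200 + i)
    par <- sample(c("P", "M", "C1", "C2"), 1)
    ab <- delta_g2_test(m, a, b, par, n_starts = 2, seed = 1)
    ba <- delta_g2_test(m, b, a, par, n_starts = 2, seed = 1)
    expect_gte(ab$delta_g2, -1e-9)
    expect_equal(ab$delta_g2, ba$delta_g2, tolerance = 1e-3)
  }
})

test_that("a true difference in P between durations is detected with high power", {
  # generating contrast: P = 0.46 vs 0.30 with the other parameters shared
  m <- build_ebpm_model()
  th_a <- c(P = 0.46, M = 0.96, C1 = 0.56, C2 = 0.73)
  th_b <- c(P = 0.30, M = 0.96, C1 = 0.56, C2 = 0.73)
  hits <- 0L
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    a <- simulate_counts(m, th_a, 5000, seed = 1000 + i)
    b <- simulate_counts(m, th_b, 5000, seed = 5000 + i)
    cmp <- delta_g2_test(m, a, b, "P", n_starts = 2, seed = 1)
    if (isTRUE(cmp$significant)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("the pairwise comparison table reports every pair and the test count", {
  m <- build_ebpm_model()
  th <- c(P = 0.4, M = 0.9, C1 = 0.5, C2 = 0.7)
  cs <- list(A = simulate_counts(m, th, 1500, seed = 41),
             B = simulate_counts(m, th, 1500, seed = 42))
  tab <- compare_conditions(m, cs, parameters = c("P", "M"),
                            n_starts = 2, seed = 1)
  expect_identical(nrow(tab), 2L)
  expect_identical(attr(tab, "n_tests"), 2L)
  expect_true(all(tab$p_adjusted == tab$p_value))  # no correction by default
  tab_b <- compare_conditions(m, cs, parameters = c("P", "M"),
                              p_adjust = "bonferroni", n_starts = 2,
                              seed = 1)
  expect_true(all(tab_b$p_adjusted >= tab_b$p_value))
})
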