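# Core MPT representation: parameter resolution, category probabilities,
# parameter counting, degrees of freedom, serialization.

test_that("parameter declarations validate fixed values and equality chains", {
  p <- mpt_parameters(free = c("P", "M"), fixed = c(g = 0.1),
                      equated = c(M2 = "M"))
  expect_s3_class(p, "mpt_parameters")
  expect_error(mpt_parameters(fixed = c(g = 1.2)), "\\[0, 1\\]")
  expect_error(mpt_parameters(free = "a", equated = c(b = "c")),
               "not declared")
  expect_error(mpt_parameters(equated = c(a = "b", b = "a")), "cyclic")
  expect_error(mpt_parameters(free = c("a", "a")), "duplicated")
})

test_that("category probabilities follow the branch products and sum to one", {
  m <- build_ebpm_model()
  # all processes succeed: every target trial ends in a PM response
  p1 <- category_probabilities(m, c(P = 1, M = 1, C1 = 1, C2 = 1))
  expect_equal(p1["target_match", "pm"], 1)
  expect_equal(p1["target_match", "match"], 0)
  expect_equal(p1["target_match", "nonmatch"], 0)
  # no preparatory attention prunes every PM branch; detected color wins
  p2 <- category_probabilities(m, c(P = 0, M = 0.3, C1 = 1, C2 = 1))
  expect_equal(p2["target_match", "match"], 1)
  # fitted parameters for the shortest filler duration: p(pm) on target
  # trees equals P * (M + (1 - M) * g)
  p3 <- category_probabilities(m, c(P = 0.36, M = 0.97, C1 = 0.52,
                                    C2 = 0.78))
  expect_equal(p3["target_match", "pm"], 0.35028, tolerance = 1e-12)
  expect_equal(unname(rowSums(p3)), rep(1, 4), tolerance = 1e-12)
})

test_that("normalization holds across random admissible parameter vectors", {
  m <- build_ebpm_model()
  set.seed(421)
  for (theta in random_ebpm_theta(300, lo = 0.001, hi = 0.999)) {
    s <- rowSums(category_probabilities(m, theta))
    expect_true(all(abs(s - 1) < 1e-12))
  }
})

test_that("malformed inputs raise named structural errors", {
  m <- build_ebpm_model()
  expect_error(category_probabilities(m, c(P = 0.5, M = 0.5, C1 = 0.5)),
               "C2")
  expect_error(
    mpt_model(data.frame(tree = "t", factors = "z+", outcome = "x"),
              mpt_parameters(free = "a")),
    "undeclared")
  # a tree that does not normalize is rejected at construction
  expect_error(
    mpt_model(data.frame(tree = "t", factors = c("a+", "a+"),
                         outcome = c("x", "y")),
              mpt_parameters(free = "a")),
    "normalize")
})

test_that("free-parameter counting resolves constraints", {
  expect_identical(free_parameter_count(build_ebpm_model()), 4L)
  expect_identical(
    free_parameter_count(build_ebpm_model(constrained = FALSE)), 7L)
  all_fixed <- mpt_model(
    data.frame(tree = "t", factors = c("a+", "a-"),
               outcome = c("x", "y")),
    mpt_parameters(fixed = c(a = 0.3)))
  expect_identical(free_parameter_count(all_fixed), 0L)
})

test_that("degrees of freedom follow the counting rule", {
  m <- build_ebpm_model()
  expect_identical(degrees_of_freedom(m), 4L)
  expect_identical(degrees_of_freedom(saturated_model()), 0L)
  expect_identical(degrees_of_freedom(m, n_datasets = 9, n_equated = 4),
                   68L)
  # 9 conditions, nothing shared: 72 - 36 = 36
  expect_identical(degrees_of_freedom(m, n_datasets = 9), 36L)
  # negative df is an identifiability error
  over <- mpt_model(
    data.frame(tree = "t", factors = c("a+ b+", "a+ b-", "a-"),
               outcome = c("x", "y", "x")),
    mpt_parameters(free = c("a", "b", "c"), equated = c(d = "c")),
    check_normalization = FALSE)
  expect_error(degrees_of_freedom(over), "identifiable")
})

test_that("model declarations round-trip losslessly through the text dialect", {
  m <- build_ebpm_model()
  tf <- withr::local_tempfile(fileext = ".mpt")
  write_mpt_model(m, tf)
  m2 <- read_mpt_model(tf)
  expect_identical(m2$parameters, m$parameters)
  expect_identical(m2$branches$tree, m$branches$tree)
  expect_identical(m2$branches$outcome, m$branches$outcome)
  th <- c(P = 0.3, M = 0.9, C1 = 0.5, C2 = 0.7)
  expect_equal(category_probabilities(m2, th),
               category_probabilities(m, th), tolerance = 1e-15)
  # the packaged declaration matches the built-in constructor
  shipped <- read_mpt_model(system.file("extdata", "ebpm_model.mpt",
                                        package = "ebpmtree"))
  expect_equal(category_probabilities(shipped, th),
               category_probabilities(m, th), tolerance = 1e-15)
})
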