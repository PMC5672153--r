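# Shared fixtures: tiny reference models and an independent Monte-Carlo
# simulator of the EBPM trees (coded from the process description, not from
# the package's branch tables, so it can serve as an oracle for them).

# One tree, one parameter: p(yes) = a, p(no) = 1 - a. Closed-form MLE is
# n_yes / N.
binomial_model <- function() {
  mpt_model(
    data.frame(tree = "t", factors = c("a+", "a-"),
               outcome = c("yes", "no")),
    mpt_parameters(free = "a")
  )
}

# One tree, three categories, two free parameters: as many free parameters
# as independent category proportions (a saturated model, df = 0).
saturated_model <- function() {
  mpt_model(
    data.frame(tree = "t",
               factors = c("a+", "a- b+", "a- b-"),
               outcome = c("c1", "c2", "c3")),
    mpt_parameters(free = c("a", "b"))
  )
}

# Random admissible free-parameter vectors for the constrained EBPM model.
random_ebpm_theta <- function(n, lo = 0.05, hi = 0.95) {
  lapply(seq_len(n), function(i) {
    stats::setNames(stats::runif(4, lo, hi), c("P", "M", "C1", "C2"))
  })
}

# Independent Monte-Carlo traversal of one EBPM tree. Implements the
# process logic directly: a "pm" response requires preparatory attention
# plus recognition (or a g-guess); otherwise color detection yields the
# correct ongoing response, and failed detection falls back to a c-guess.
# `th` is the full parameter vector (P, M1, M2, C1, C2, g, c).
mc_tree_responses <- function(tree, th, n) {
  is_target <- startsWith(tree, "target")
  is_match <- endsWith(tree, "_match")
  Cp <- if (is_match) th[["C1"]] else th[["C2"]]
  Mp <- if (is_target) th[["M1"]] else th[["M2"]]
  correct <- if (is_match) "match" else "nonmatch"
  C <- stats::runif(n) < Cp
  P <- stats::runif(n) < th[["P"]]
  M <- stats::runif(n) < Mp
  g <- stats::runif(n) < th[["g"]]
  cc <- stats::runif(n) < th[["c"]]
  pm <- if (is_target) P & (M | g) else P & !M & g
  ifelse(pm, "pm", ifelse(C, correct, ifelse(cc, "match", "nonmatch")))
}

# Full parameter vector for the constrained model.
full_theta <- function(theta, g = 0.1, c = 0.5) {
  c(P = theta[["P"]], M1 = theta[["M"]], M2 = theta[["M"]],
    C1 = theta[["C1"]], C2 = theta[["C2"]], g = g, c = c)
}

# Expected-frequency counts table for a model at theta.
expected_counts <- function(model, theta, n_per_tree) {
  pm <- category_probabilities(model, theta)
  data.frame(tree = rep(rownames(pm), each = ncol(pm)),
             category = rep(colnames(pm), nrow(pm)),
             count = as.vector(t(pm)) * n_per_tree,
             stringsAsFactors = FALSE)
}
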