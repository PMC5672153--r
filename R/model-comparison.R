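#' Joint multi-condition fit with cross-condition equality constraints
#'
#' Fits one MPT parameter vector per dataset (condition), with the symbols
#' named in `equate` shared across all datasets. The joint `G^2` is the sum
#' of the per-dataset statistics; degrees of freedom follow
#' [degrees_of_freedom()] under the same constraint scheme. With
#' `equate = character(0)` the joint fit decomposes into independent
#' per-condition fits; with all free parameters equated it is the fully
#' pooled model (for the four-parameter EBPM model over nine conditions,
#' 36 trees and `df = 68`).
#'
#' @param model An [mpt_model()].
#' @param datasets Named list of [category_counts()] tables, one per
#'   condition. All must cover the same tree structure.
#' @param equate Character vector of free-parameter symbols shared across
#'   all conditions (default none).
#' @param n_starts,seed,tol,max_iter As in [fit_mle()].
#' @param extra_starts Optional list of full joint start vectors.
#'
#' @return Object of class `mpt_fit_joint`: `estimates` (matrix, rows =
#'   datasets, columns = free parameters), `g_squared`, `per_dataset_g2`,
#'   `df`, `p_value`, `converged`, `equate`, `n_starts_used`, `seed`.
#' @export
fit_joint <- function(model, datasets, equate = character(),
                      n_starts = 20, seed = 1L, tol = 1e-9,
                      max_iter = 1000, extra_starts = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  cm <- .compile_mpt(model)
  bad <- setdiff(equate, cm$free)
  if (length(bad)) {
    stop("equate names non-free parameter(s): ", paste(bad, collapse = ", "))
  }
  aligned <- lapply(datasets, function(d) .align_counts(cm, d))
  K <- length(datasets)
  shared <- sort(unique(equate))
  other <- setdiff(cm$free, shared)
  n_par <- length(shared) + K * length(other)
  # map joint parameter vector -> per-dataset free vectors (model order)
  idx <- lapply(seq_len(K), function(d) {
    m <- integer(cm$k)
    m[match(shared, cm$free)] <- seq_along(shared)
    m[match(other, cm$free)] <-
      length(shared) + (d - 1) * length(other) + seq_along(other)
    m
  })
  objs <- lapply(aligned, function(a) .g2_objective(cm, a$n, a$Ntree))
  fn <- function(par) {
    tot <- 0
    for (d in seq_len(K)) {
      v <- objs[[d]]$fn(par[idx[[d]]])
      tot <- tot + v
    }
    tot
  }
  gr <- function(par) {
    g <- rep(0, n_par)
    for (d in seq_len(K)) {
      gd <- objs[[d]]$gr(par[idx[[d]]])
      g[idx[[d]]] <- g[idx[[d]]] + gd
    }
    g
  }
  starts <- .make_starts(n_par, n_starts, seed, extra_starts, NULL)
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, fn, gr, method = "L-BFGS-B",
                   lower = 1e-6, upper = 1 - 1e-6,
                   control = list(maxit = max_iter,
                                  factr = tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) stop("all optimizer starts failed")
  est <- t(vapply(seq_len(K), function(d) best$par[idx[[d]]],
                  numeric(cm$k)))
  dimnames(est) <- list(names(datasets), cm$free)
  per_g2 <- vapply(seq_len(K), function(d) objs[[d]]$fn(best$par[idx[[d]]]),
                   numeric(1))
  names(per_g2) <- names(datasets)
  df <- degrees_of_freedom(model, n_datasets = K,
                           n_equated = length(shared))
  structure(
    list(estimates = est, g_squared = best$value, per_dataset_g2 = per_g2,
         df = df, p_value = stats::pchisq(best$value, df,
                                          lower.tail = FALSE),
         converged = converged, equate = shared,
         n_starts_used = length(starts), seed = seed,
         model = model, compiled = cm, idx = idx, n_par = n_par),
    class = "mpt_fit_joint")
}

#' @export
print.mpt_fit_joint <- function(x, ...) {
  cat("Joint MPT fit over", nrow(x$estimates), "conditions\n")
  if (length(x$equate)) {
    cat("  equated across conditions:", paste(x$equate, collapse = ", "),
        "\n")
  }
  cat(sprintf("  G^2(%d) = %.3f, p = %.3f%s\n", x$df, x$g_squared,
              x$p_value, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$estimates, 3))
  invisible(x)
}

#' Delta-G-squared test for a parameter difference between two conditions
#'
#' Tests whether one free parameter differs between two conditions by
#' comparing the per-condition ("free") fits, in which all free parameters
#' may differ between conditions, against a joint fit with a single
#' cross-condition equality constraint on `parameter`. The statistic
#' `delta G^2 = G^2(constrained) - G^2(free)` is referred to chi-square with
#' 1 degree of freedom; the difference is called significant when it
#' exceeds the 0.95 quantile, 3.84.
#'
#' To guarantee the nesting inequality numerically, the constrained fit is
#' seeded with the free solution (equated parameter set to the mean of the
#' two free estimates) in addition to its random starts, and vice versa.
#'
#' @param model An [mpt_model()].
#' @param data_a,data_b [category_counts()] tables for the two conditions.
#' @param parameter Free-parameter symbol to test.
#' @param alpha Significance level (default 0.05; critical value reported).
#' @param n_starts,seed As in [fit_mle()].
#' @return Object of class `mpt_comparison`: `parameter`, `delta_g2`, `df`
#'   (1), `p_value`, `significant`, `critical_value`, `converged`, plus the
#'   two free fits and the constrained fit.
#' @export
delta_g2_test <- function(model, data_a, data_b, parameter,
                          alpha = 0.05, n_starts = 20, seed = 1L) {
  cm <- .compile_mpt(model)
  if (!(parameter %in% cm$free)) {
    stop("'", parameter, "' is not a free parameter of the model")
  }
  con <- fit_joint(model, list(a = data_a, b = data_b), equate = parameter,
                   n_starts = n_starts, seed = seed)
  # free baseline: all parameters may differ (independent fits), each also
  # started from the constrained solution
  ex_a <- list(con$estimates["a", ])
  ex_b <- list(con$estimates["b", ])
  fit_a <- fit_mle(model, data_a, n_starts = n_starts, seed = seed,
                   ci = FALSE, extra_starts = ex_a)
  fit_b <- fit_mle(model, data_b, n_starts = n_starts, seed = seed + 1,
                   ci = FALSE, extra_starts = ex_b)
  # re-seed the constrained fit from the free solution
  shared_i <- match(parameter, cm$free)
  joint_par <- function(est_a, est_b) {
    par <- numeric(con$n_par)
    par[con$idx[[1]]] <- est_a
    par[con$idx[[2]]] <- est_b
    par[con$idx[[1]][shared_i]] <-
      (est_a[shared_i] + est_b[shared_i]) / 2
    par
  }
  con2 <- fit_joint(model, list(a = data_a, b = data_b),
                    equate = parameter, n_starts = 1, seed = seed,
                    extra_starts = list(
                      joint_par(fit_a$estimates, fit_b$estimates)))
  if (con2$g_squared < con$g_squared) con <- con2
  converged <- fit_a$converged && fit_b$converged && con$converged
  delta <- con$g_squared - (fit_a$g_squared + fit_b$g_squared)
  crit <- stats::qchisq(1 - alpha, 1)
  structure(
    list(parameter = parameter, delta_g2 = delta, df = 1L,
         p_value = stats::pchisq(max(delta, 0), 1, lower.tail = FALSE),
         significant = if (converged) delta > crit else NA,
         critical_value = crit, converged = converged,
         fit_free = list(a = fit_a, b = fit_b), fit_constrained = con),
    class = "mpt_comparison")
}

#' @export
print.mpt_comparison <- function(x, ...) {
  cat(sprintf("Delta G^2 test for parameter %s\n", x$parameter))
  cat(sprintf("  delta G^2(1) = %.3f, p = %.3f (critical value %.2f)\n",
              x$delta_g2, x$p_value, x$critical_value))
  if (is.na(x$significant)) {
    cat("  no verdict: a component fit did not converge\n")
  } else {
    cat("  conditions differ", if (x$significant) "significantly\n"
        else "non-significantly\n")
  }
  invisible(x)
}

#' Pairwise parameter-difference matrix across conditions
#'
#' Runs [delta_g2_test()] for each requested parameter and condition pair
#' and assembles a long-format table (one row per pair x parameter) with
#' delta-G^2 values, p-values and significance stars. No multiple-testing
#' correction is applied by default; the number of tests performed is
#' recorded so users can judge, and Bonferroni adjustment is available.
#'
#' @param model An [mpt_model()].
#' @param counts_by_condition Named list of [category_counts()] tables.
#' @param parameters Free parameters to test (default: all).
#' @param pairs Two-column character matrix of condition pairs; default all
#'   unordered pairs.
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @param n_starts,seed As in [fit_mle()].
#' @return Data frame of class `mpt_comparison_table` with columns
#'   `condition_a`, `condition_b`, `parameter`, `delta_g2`, `p_value`,
#'   `p_adjusted`, `significant`, `stars`; attribute `n_tests`.
#' @export
compare_conditions <- function(model, counts_by_condition,
                               parameters = NULL, pairs = NULL,
                               p_adjust = c("none", "bonferroni"),
                               n_starts = 10, seed = 1L) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.list(counts_by_condition),
            !is.null(names(counts_by_condition)))
  cm <- .compile_mpt(model)
  if (is.null(parameters)) parameters <- cm$free
  conds <- names(counts_by_condition)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(conds, 2))
  }
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    for (par in parameters) {
      cmp <- delta_g2_test(model, counts_by_condition[[a]],
                           counts_by_condition[[b]], par,
                           n_starts = n_starts, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        condition_a = a, condition_b = b, parameter = par,
        delta_g2 = cmp$delta_g2, p_value = cmp$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_adjusted < 0.05
  out$stars <- cut(out$p_adjusted, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("mpt_comparison_table", "data.frame")
  out
}
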