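#' Response-category counts for MPT fitting
#'
#' A container for observed (or simulated) counts per tree and response
#' category. Counts may be non-integer so that expected-frequency tables can
#' be fitted directly.
#'
#' @param x Data frame with columns `tree`, `category` (or `response`) and
#'   `count`; duplicate (tree, category) cells are summed.
#' @return Data frame of class `category_counts` with columns `tree`,
#'   `category`, `count`.
#' @export
category_counts <- function(x) {
  stopifnot(is.data.frame(x))
  if ("response" %in% names(x) && !("category" %in% names(x))) {
    x$category <- x$response
  }
  stopifnot(all(c("tree", "category", "count") %in% names(x)))
  x$tree <- as.character(x$tree)
  x$category <- .canonical_category(x$category)
  x$count <- as.numeric(x$count)
  if (any(!is.finite(x$count)) || any(x$count < 0)) {
    stop("counts must be finite and non-negative")
  }
  agg <- stats::aggregate(count ~ tree + category, data = x, FUN = sum)
  agg <- agg[order(agg$tree, agg$category), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("category_counts", "data.frame")
  agg
}

# ---- compiled model representation ------------------------------------

# Turn an mpt_model into matrices for fast repeated evaluation:
#   branch prob = const * prod_k theta_k^A[b,k] * (1-theta_k)^B[b,k]
# over free parameters (equated symbols resolved to their roots; fixed
# symbols folded into `const`), plus a cells x branches aggregation matrix.
.compile_mpt <- function(model) {
  p <- model$parameters
  free <- p$name[p$status == "free"]
  k <- length(free)
  root <- stats::setNames(
    vapply(p$name, function(s) .resolve_root(p, s), character(1)), p$name)
  nb <- nrow(model$branches)
  A <- matrix(0, nb, k, dimnames = list(NULL, free))
  B <- matrix(0, nb, k, dimnames = list(NULL, free))
  const <- rep(1, nb)
  for (b in seq_len(nb)) {
    f <- model$parsed[[b]]
    for (j in seq_len(nrow(f))) {
      r <- root[[f$symbol[j]]]
      i <- match(r, p$name)
      if (p$status[i] == "free") {
        if (f$complement[j]) B[b, r] <- B[b, r] + 1
        else A[b, r] <- A[b, r] + 1
      } else {
        v <- p$value[i]
        const[b] <- const[b] * if (f$complement[j]) 1 - v else v
      }
    }
  }
  trees <- model$trees
  cats <- model$categories
  cell_tree <- rep(trees, each = length(cats))
  cell_cat <- rep(cats, times = length(trees))
  cell_key <- paste(cell_tree, cell_cat, sep = "\r")
  br_cell <- match(paste(model$branches$tree, model$branches$outcome,
                         sep = "\r"), cell_key)
  Agg <- matrix(0, length(cell_key), nb)
  Agg[cbind(br_cell, seq_len(nb))] <- 1
  list(A = A, B = B, const = const, Agg = Agg, free = free,
       cell_tree = cell_tree, cell_cat = cell_cat, k = k)
}

# Cell probabilities for a free-parameter vector (interior values only).
.cell_probs <- function(cm, par) {
  br <- cm$const * exp(cm$A %*% log(par) + cm$B %*% log1p(-par))
  as.vector(cm$Agg %*% br)
}

# Align a category_counts object to the compiled cell order; unseen cells
# get zero counts. Unknown trees/categories are structural errors.
.align_counts <- function(cm, counts) {
  counts <- category_counts(counts)
  key <- paste(cm$cell_tree, cm$cell_cat, sep = "\r")
  idx <- match(paste(counts$tree, counts$category, sep = "\r"), key)
  if (anyNA(idx)) {
    bad <- paste(counts$tree[is.na(idx)], counts$category[is.na(idx)],
                 sep = "/")
    stop("counts refer to unknown tree/category cell(s): ",
         paste(unique(bad), collapse = ", "))
  }
  n <- rep(0, length(key))
  n[idx] <- counts$count
  Ntree <- tapply(n, cm$cell_tree, sum)[cm$cell_tree]
  list(n = n, Ntree = as.numeric(Ntree))
}

# G-squared of aligned counts against cell probabilities (0*log0 = 0).
.g2_of <- function(n, Ntree, p) {
  pos <- n > 0
  if (any(p[pos] <= 0)) {
    warning("expected probability 0 for a cell with a positive count; ",
            "G-squared is infinite")
    return(Inf)
  }
  2 * sum(n[pos] * (log(n[pos]) - log(Ntree[pos] * p[pos])))
}

# Objective and analytic gradient of G^2 in the free parameters.
.g2_objective <- function(cm, n, Ntree) {
  pos <- n > 0
  npos <- n[pos]
  lnN <- log(npos) - log(Ntree[pos])
  Aggp <- cm$Agg[pos, , drop = FALSE]
  fn <- function(par) {
    br <- cm$const * exp(cm$A %*% log(par) + cm$B %*% log1p(-par))
    p <- as.vector(Aggp %*% br)
    if (any(p <= 0) || any(!is.finite(p))) return(1e12)
    2 * sum(npos * (lnN - log(p)))
  }
  gr <- function(par) {
    br <- as.vector(cm$const * exp(cm$A %*% log(par) + cm$B %*% log1p(-par)))
    p <- as.vector(Aggp %*% br)
    if (any(p <= 0) || any(!is.finite(p))) return(rep(0, cm$k))
    W <- (br * cm$A) %*% diag(1 / par, cm$k) -
      (br * cm$B) %*% diag(1 / (1 - par), cm$k)
    dP <- Aggp %*% W
    -2 * as.vector(crossprod(dP, npos / p))
  }
  list(fn = fn, gr = gr)
}

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards (fits never perturb user-level randomness).
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' G-squared goodness-of-fit statistic
#'
#' The likelihood-ratio statistic
#' `G^2 = 2 * sum n * log(n / (N_tree * p))`, summed over all trees and
#' response categories, where `n` is the observed count, `N_tree` the tree
#' total and `p` the model category probability. Cells with `n = 0`
#' contribute zero (the `0 * log 0 = 0` convention). The statistic is
#' additive over trees, and is asymptotically chi-square distributed under
#' the model.
#'
#' @param observed A [category_counts()] table (or coercible data frame).
#' @param expected_probs Matrix of category probabilities as returned by
#'   [category_probabilities()] (rows = trees, columns = categories), or any
#'   matrix with matching dimnames. Rows must each sum to one.
#' @return The statistic (possibly `Inf`, with a warning, if a cell with a
#'   positive count has model probability zero).
#' @examples
#' m <- build_ebpm_model()
#' th <- c(P = 0.4, M = 0.95, C1 = 0.55, C2 = 0.75)
#' pr <- category_probabilities(m, th)
#' obs <- simulate_counts(m, th, n_per_tree = 200, seed = 1)
#' g_squared(obs, pr)
#' @export
g_squared <- function(observed, expected_probs) {
  observed <- category_counts(observed)
  stopifnot(is.matrix(expected_probs), !is.null(rownames(expected_probs)),
            !is.null(colnames(expected_probs)))
  if (any(abs(rowSums(expected_probs) - 1) > 1e-8)) {
    stop("expected probabilities must sum to one within each tree")
  }
  colnames(expected_probs) <- .canonical_category(colnames(expected_probs))
  i <- match(observed$tree, rownames(expected_probs))
  j <- match(observed$category, colnames(expected_probs))
  if (anyNA(i)) {
    stop("observed counts refer to tree(s) absent from expected_probs: ",
         paste(unique(observed$tree[is.na(i)]), collapse = ", "))
  }
  if (anyNA(j)) {
    stop("observed counts refer to category(ies) absent from expected_probs: ",
         paste(unique(observed$category[is.na(j)]), collapse = ", "))
  }
  Ntree <- tapply(observed$count, observed$tree, sum)[observed$tree]
  if (all(Ntree == 0)) stop("all tree totals are zero")
  p <- expected_probs[cbind(i, j)]
  .g2_of(observed$count, as.numeric(Ntree), p)
}

#' Maximum-likelihood fit of an MPT model
#'
#' Estimates the free parameters by minimizing `G^2` (the same argmin as the
#' multinomial maximum likelihood) with a bounded quasi-Newton optimizer
#' (`L-BFGS-B`, analytic gradient) run from multiple starting points.
#' Parameters are kept in `[1e-6, 1 - 1e-6]` during the search to avoid log
#' singularities; the first start is the centre of the cube, the remainder
#' are drawn uniformly on `(0.05, 0.95)` from a seeded generator that does
#' not disturb the caller's RNG state.
#'
#' @param model An [mpt_model()].
#' @param data A [category_counts()] table (or coercible data frame).
#' @param n_starts Number of multistart runs (default 20).
#' @param seed Seed for the start-point generator; recorded in the result.
#' @param tol Objective convergence tolerance (default 1e-9).
#' @param max_iter Maximum iterations per start (default 500).
#' @param ci Compute 95% confidence intervals (default `TRUE`); see
#'   [confidence_intervals()].
#' @param extra_starts Optional list of additional start vectors (each a
#'   named or ordered numeric vector of free parameters); used internally by
#'   the nested-model tests to guarantee the nesting inequality.
#'
#' @return An object of class `mpt_fit`: list with `estimates` (named
#'   vector), `ci95` (matrix with columns `lower`, `upper`), `g_squared`,
#'   `df`, `p_value`, `converged`, `n_starts_used`, `seed`, `log_lik`, plus
#'   the model and aligned data for downstream use.
#' @examples
#' m <- build_ebpm_model()
#' cts <- simulate_counts(m, c(P = 0.5, M = 0.9, C1 = 0.6, C2 = 0.8),
#'                        n_per_tree = 1000, seed = 7)
#' fit <- fit_mle(m, cts, n_starts = 5, seed = 1)
#' fit
#' @export
fit_mle <- function(model, data, n_starts = 20, seed = 1L, tol = 1e-9,
                    max_iter = 500, ci = TRUE, extra_starts = NULL) {
  cm <- .compile_mpt(model)
  if (cm$k == 0) stop("model has no free parameters to estimate")
  al <- .align_counts(cm, data)
  if (all(al$n == 0)) stop("counts table is empty (all totals zero)")
  df <- degrees_of_freedom(model)
  obj <- .g2_objective(cm, al$n, al$Ntree)
  starts <- .make_starts(cm$k, n_starts, seed, extra_starts, cm$free)
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj$fn, obj$gr, method = "L-BFGS-B",
                   lower = 1e-6, upper = 1 - 1e-6,
                   control = list(maxit = max_iter,
                                  factr = tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) stop("all optimizer starts failed")
  est <- stats::setNames(best$par, cm$free)
  g2 <- best$value
  p_cell <- .cell_probs(cm, best$par)
  pos <- al$n > 0
  log_lik <- sum(al$n[pos] * log(p_cell[pos])) +
    sum(lgamma(tapply(al$n, cm$cell_tree, sum) + 1)) -
    sum(lgamma(al$n[pos] + 1))
  fit <- structure(
    list(estimates = est, ci95 = NULL, g_squared = g2, df = df,
         p_value = stats::pchisq(g2, df, lower.tail = FALSE),
         converged = converged, n_starts_used = length(starts),
         seed = seed, log_lik = log_lik, model = model,
         compiled = cm, aligned = al, ci_method = NULL),
    class = "mpt_fit")
  if (ci) {
    civ <- confidence_intervals(fit)
    fit$ci95 <- civ
    fit$ci_method <- attr(civ, "method")
  }
  fit
}

.make_starts <- function(k, n_starts, seed, extra_starts, free) {
  stopifnot(n_starts >= 1)
  starts <- list(rep(0.5, k))
  if (n_starts > 1) {
    rnd <- .with_seed(seed, stats::runif((n_starts - 1) * k, 0.05, 0.95))
    starts <- c(starts, split(rnd, rep(seq_len(n_starts - 1), each = k)))
  }
  for (ex in extra_starts) {
    v <- if (!is.null(names(ex))) ex[free] else ex
    starts <- c(starts, list(pmin(pmax(as.numeric(v), 1e-6), 1 - 1e-6)))
  }
  starts
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat("MPT maximum-likelihood fit\n")
  cat(sprintf("  G^2(%d) = %.3f, p = %.3f%s\n", x$df, x$g_squared,
              x$p_value, if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = round(x$estimates, 3))
  if (!is.null(x$ci95)) {
    tab$ci95 <- sprintf("(%.2f-%.2f)", x$ci95[, "lower"], x$ci95[, "upper"])
    tab$method <- x$ci_method
  }
  print(tab)
  cat(sprintf("  starts: %d, seed: %s\n", x$n_starts_used,
              format(x$seed)))
  invisible(x)
}

#' 95% confidence intervals for MPT parameter estimates
#'
#' Wald intervals from the inverse observed information (central-difference
#' Hessian of the multinomial log-likelihood, step 1e-5), truncated to
#' `[0, 1]`. For estimates at (or within 1e-4 of) the boundary, where the
#' Wald approximation degenerates, profile-likelihood bounds are used
#' instead (the parameter value at which the profiled `G^2` rises by the
#' 0.95 chi-square(1) quantile). A singular information matrix yields an
#' `undetermined` interval for the affected parameter(s).
#'
#' @param fit An `mpt_fit` from [fit_mle()].
#' @return Matrix with columns `lower` and `upper`, one row per free
#'   parameter; attribute `method` records `"wald"`, `"profile"` or
#'   `"undetermined"` per parameter.
#' @export
confidence_intervals <- function(fit) {
  stopifnot(inherits(fit, "mpt_fit"))
  cm <- fit$compiled
  al <- fit$aligned
  est <- fit$estimates
  k <- cm$k
  pos <- al$n > 0
  ll <- function(par) {
    par <- pmin(pmax(par, 1e-9), 1 - 1e-9)
    p <- .cell_probs(cm, par)
    if (any(p[pos] <= 0)) return(-Inf)
    sum(al$n[pos] * log(p[pos]))
  }
  h <- 1e-5
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- rep(0, k); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (ll(est + ei) - 2 * ll(est) + ll(est - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (ll(est + ei + ej) - ll(est + ei - ej) -
             ll(est - ei + ej) + ll(est - ei - ej)) / (4 * h^2)
      }
    }
  }
  out <- matrix(NA_real_, k, 2,
                dimnames = list(cm$free, c("lower", "upper")))
  method <- stats::setNames(rep("undetermined", k), cm$free)
  info <- -H
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(cov)) {
    se <- suppressWarnings(sqrt(diag(cov)))
    ok <- is.finite(se) & se > 0
    out[ok, "lower"] <- pmax(0, est[ok] - 1.959964 * se[ok])
    out[ok, "upper"] <- pmin(1, est[ok] + 1.959964 * se[ok])
    method[ok] <- "wald"
  }
  at_boundary <- est < 1e-4 | est > 1 - 1e-4
  for (i in which(at_boundary | method == "undetermined")) {
    b <- .profile_bounds(fit, i)
    out[i, ] <- b
    method[i] <- "profile"
  }
  attr(out, "method") <- method
  out
}

# Profile-likelihood 95% bounds for one free parameter: the values at which
# the profiled G^2 exceeds the minimum by qchisq(0.95, 1).
.profile_bounds <- function(fit, i) {
  cm <- fit$compiled
  al <- fit$aligned
  est <- fit$estimates
  target <- fit$g_squared + stats::qchisq(0.95, 1)
  k <- cm$k
  prof <- function(v) {
    par0 <- est
    par0[i] <- v
    if (k == 1) return(.g2_objective(cm, al$n, al$Ntree)$fn(par0))
    obj <- .g2_objective(cm, al$n, al$Ntree)
    fn_sub <- function(ps) {
      p <- est; p[-i] <- ps; p[i] <- v; obj$fn(p)
    }
    gr_sub <- function(ps) {
      p <- est; p[-i] <- ps; p[i] <- v; obj$gr(p)[-i]
    }
    stats::optim(est[-i], fn_sub, gr_sub, method = "L-BFGS-B",
                 lower = 1e-6, upper = 1 - 1e-6)$value
  }
  root_on <- function(lo, hi) {
    f <- function(v) prof(v) - target
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  }
  lower <- if (est[i] <= 1e-6) 0 else {
    r <- root_on(1e-6, est[i]); if (is.na(r)) 0 else r
  }
  upper <- if (est[i] >= 1 - 1e-6) 1 else {
    r <- root_on(est[i], 1 - 1e-6); if (is.na(r)) 1 else r
  }
  c(lower, upper)
}
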