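#' Sobel test of an indirect (mediated) effect
#'
#' Tests the product `a * b` of the mediator path coefficients (X -> W and
#' W -> Y | X) with the delta-method standard error:
#' `z = a * b / sqrt(a^2 * se_b^2 + b^2 * se_a^2)`.
#'
#' Both tail conventions are reported and labeled: `p_one` is the one-tailed
#' upper-normal probability of `|z|` (0.5 when `z = 0`), `p_two` the
#' two-tailed probability. When both `a` and `b` are zero the statistic is 0
#' by convention.
#'
#' @param a,se_a Coefficient and standard error of the X -> W path.
#' @param b,se_b Coefficient and standard error of the W -> Y | X path.
#' @return List with `z`, `p_one`, `p_two`.
#' @examples
#' sobel_test(a = 0.5, se_a = 0.1, b = 0.4, se_b = 0.1)  # z ~ 3.123
#' @export
sobel_test <- function(a, se_a, b, se_b) {
  stopifnot(is.finite(a), is.finite(b))
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive")
  denom <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  z <- if (denom == 0) 0 else a * b / denom
  p_one <- stats::pnorm(abs(z), lower.tail = FALSE)
  list(z = z, p_one = p_one, p_two = 2 * p_one)
}

#' Baron-Kenny three-step mediation analysis with Sobel tests
#'
#' Ordinary-least-squares regressions on standardized (zero-mean,
#' unit-variance) variables:
#' step 1 fits `Y ~ X` (total effect, path c); step 2 fits `W_j ~ X`
#' separately for each mediator (paths a_j); step 3 fits
#' `Y ~ X + W_1 + ... + W_m` (paths b_j and the direct effect c').
#' Each mediator's indirect effect `a_j * b_j` is then tested with
#' [sobel_test()].
#'
#' @param data Data frame with one row per participant.
#' @param x Name of the predictor column (e.g. task duration in minutes,
#'   used as a numeric predictor).
#' @param mediators Character vector of mediator column names (1-5 Likert
#'   ratings in the EBPM design; one or two mediators are typical).
#' @param y Name of the outcome column (EBPM accuracy in `[0, 1]`).
#' @return Object of class `mediation_result`: `paths` (data frame with
#'   columns `step`, `response`, `term`, `coefficient`, `se`, `t`,
#'   standardized scale), `sobel` (data frame with `mediator`, `a`, `se_a`,
#'   `b`, `se_b`, `z`, `p_one`, `p_two`), and `n`.
#' @examples
#' d <- data.frame(x = rep(c(3, 9, 15), each = 20),
#'                 w = rnorm(60), y = rnorm(60))
#' d$w <- d$w + 0.1 * d$x
#' baron_kenny(d, x = "x", mediators = "w", y = "y")
#' @export
baron_kenny <- function(data, x = "x", mediators = "w", y = "y") {
  stopifnot(is.data.frame(data), length(mediators) >= 1)
  vars <- c(x, mediators, y)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 complete cases")
  for (v in vars) {
    if (stats::sd(d[[v]]) == 0) {
      stop("variable '", v, "' has zero variance")
    }
    d[[v]] <- as.numeric(scale(d[[v]]))
  }
  if (length(unique(d[[x]])) < 2) stop("predictor must take >= 2 values")

  coef_row <- function(fit, term, step, response) {
    s <- summary(fit)$coefficients
    data.frame(step = step, response = response, term = term,
               coefficient = s[term, "Estimate"],
               se = s[term, "Std. Error"],
               t = s[term, "t value"], stringsAsFactors = FALSE)
  }
  paths <- list()
  # step 1: total effect of X on Y (path c)
  f1 <- stats::lm(stats::reformulate(x, y), data = d)
  paths[[1]] <- coef_row(f1, x, 1L, y)
  # step 2: X on each mediator (paths a_j)
  step2 <- lapply(mediators, function(w) {
    f <- stats::lm(stats::reformulate(x, w), data = d)
    coef_row(f, x, 2L, w)
  })
  paths <- c(paths, step2)
  # step 3: Y on X and all mediators jointly (c' and b_j)
  f3 <- stats::lm(stats::reformulate(c(x, mediators), y), data = d)
  paths[[length(paths) + 1]] <- coef_row(f3, x, 3L, y)
  for (w in mediators) {
    paths[[length(paths) + 1]] <- coef_row(f3, w, 3L, y)
  }
  paths <- do.call(rbind, paths)
  rownames(paths) <- NULL

  sobel <- do.call(rbind, lapply(mediators, function(w) {
    a_row <- paths[paths$step == 2 & paths$response == w, ]
    b_row <- paths[paths$step == 3 & paths$term == w, ]
    s <- sobel_test(a_row$coefficient, a_row$se,
                    b_row$coefficient, b_row$se)
    data.frame(mediator = w, a = a_row$coefficient, se_a = a_row$se,
               b = b_row$coefficient, se_b = b_row$se,
               z = s$z, p_one = s$p_one, p_two = s$p_two,
               stringsAsFactors = FALSE)
  }))
  rownames(sobel) <- NULL
  structure(list(paths = paths, sobel = sobel, n = nrow(d),
                 x = x, y = y, mediators = mediators),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Baron-Kenny mediation (n = %d), standardized variables\n",
              x$n))
  p <- x$paths
  lab <- c("1 (total c)", "2 (a paths)", "3 (c' and b)")
  for (s in 1:3) {
    rows <- p[p$step == s, ]
    cat(" step", lab[s], "\n")
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("   %s ~ %s: coef = %+.3f, SE = %.3f, t = %+.2f\n",
                  rows$response[i], rows$term[i], rows$coefficient[i],
                  rows$se[i], rows$t[i]))
    }
  }
  cat(" Sobel tests (one- and two-tailed p, both labeled):\n")
  for (i in seq_len(nrow(x$sobel))) {
    cat(sprintf("   %s: z = %+.3f, p(one-tailed) = %.3f, p(two-tailed) = %.3f\n",
                x$sobel$mediator[i], x$sobel$z[i], x$sobel$p_one[i],
                x$sobel$p_two[i]))
  }
  invisible(x)
}
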