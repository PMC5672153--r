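#' Declare the parameter set of an MPT model
#'
#' Each parameter of a multinomial processing tree (MPT) model is either
#' freely estimated, fixed at a known probability, or equated to another
#' parameter. Equality chains must resolve (without cycles) to exactly one
#' free or fixed parameter.
#'
#' @param free Character vector of freely estimated parameter symbols.
#' @param fixed Named numeric vector of parameters fixed at probabilities in
#'   `[0, 1]`, e.g. `c(g = 0.1, c = 0.5)`.
#' @param equated Named character vector mapping a parameter symbol to the
#'   symbol it is constrained equal to, e.g. `c(M2 = "M1")`.
#'
#' @return A data frame with columns `name`, `status` (`"free"`, `"fixed"` or
#'   `"equated"`), `value` (fixed value or `NA`) and `to` (equality target or
#'   `NA`), of class `mpt_parameters`.
#' @examples
#' mpt_parameters(free = c("P", "M"), fixed = c(g = 0.1), equated = c(M2 = "M"))
#' @export
mpt_parameters <- function(free = character(), fixed = numeric(),
                           equated = character()) {
  fixed_names <- names(fixed)
  equated_names <- names(equated)
  if (length(fixed) && is.null(fixed_names)) {
    stop("`fixed` must be a named numeric vector")
  }
  if (length(equated) && is.null(equated_names)) {
    stop("`equated` must be a named character vector")
  }
  nm <- c(free, fixed_names, equated_names)
  if (anyDuplicated(nm)) {
    stop("duplicated parameter name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (length(fixed) && (any(fixed < 0) || any(fixed > 1))) {
    stop("fixed parameter values must lie in [0, 1]")
  }
  params <- data.frame(
    name = nm,
    status = rep(c("free", "fixed", "equated"),
                 c(length(free), length(fixed), length(equated))),
    value = c(rep(NA_real_, length(free)), unname(fixed),
              rep(NA_real_, length(equated))),
    to = c(rep(NA_character_, length(free) + length(fixed)),
           unname(equated)),
    stringsAsFactors = FALSE
  )
  # every equality target must resolve, acyclically, to a free/fixed root
  for (s in equated_names) {
    .resolve_root(params, s)
  }
  class(params) <- c("mpt_parameters", "data.frame")
  params
}

# Follow an equality chain to its free or fixed root symbol.
.resolve_root <- function(params, symbol) {
  seen <- character()
  cur <- symbol
  repeat {
    i <- match(cur, params$name)
    if (is.na(i)) {
      stop("parameter '", cur, "' (reached from '", symbol,
           "') is not declared")
    }
    if (params$status[i] != "equated") {
      return(cur)
    }
    if (cur %in% seen) {
      stop("cyclic equality constraint involving parameter '", cur, "'")
    }
    seen <- c(seen, cur)
    cur <- params$to[i]
  }
}

# Parse a factor string like "C1+ P+ M1-" into symbol/complement columns.
# Tokens are whitespace- or comma-separated; a trailing "-" marks the
# complement (1 - theta), "+" (or nothing) the direct probability.
.parse_factors <- function(s) {
  tokens <- strsplit(trimws(s), "[,[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("branch has no factors: '", s, "'")
  complement <- grepl("-$", tokens)
  symbol <- sub("[+-]$", "", tokens)
  if (any(!nzchar(symbol))) stop("malformed factor token in '", s, "'")
  data.frame(symbol = symbol, complement = complement,
             stringsAsFactors = FALSE)
}

.canonical_category <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9_]", "", x)
}

#' Construct an MPT model from a branch table
#'
#' An MPT model is a set of processing trees, one per trial type. Each branch
#' is a product of parameters (direct, `theta`) or their complements
#' (`1 - theta`) terminating in a response category; the probability of a
#' response category within a tree is the sum of its branch probabilities.
#' Branches are explicit data so that normalization (branch probabilities
#' summing to one for every admissible parameter vector) can be verified.
#'
#' @param branches Data frame with columns `tree` (trial-type label),
#'   `factors` (ordered factor string, e.g. `"C1+ P+ M1-"`, where a trailing
#'   `-` denotes the complement `1 - theta`) and `outcome` (response-category
#'   label; matched case-insensitively and stored lowercase).
#' @param parameters An [mpt_parameters()] table covering every symbol used
#'   in `factors`.
#' @param check_normalization If `TRUE` (default), verify that each tree's
#'   branch probabilities sum to one. Because each branch probability is a
#'   polynomial in the parameters, a tree whose branches never repeat a
#'   symbol is multilinear, and checking all 0/1 corners of the parameter
#'   cube is an exact symbolic proof; trees with repeated symbols are checked
#'   at random interior points instead.
#'
#' @return An object of class `mpt_model` with elements `parameters`,
#'   `branches` (with parsed factor lists), `trees` and `categories`.
#' @seealso [build_ebpm_model()] for the packaged EBPM color-matching model.
#' @export
mpt_model <- function(branches, parameters, check_normalization = TRUE) {
  stopifnot(is.data.frame(branches),
            all(c("tree", "factors", "outcome") %in% names(branches)))
  branches <- as.data.frame(branches, stringsAsFactors = FALSE)
  branches$tree <- as.character(branches$tree)
  branches$outcome <- .canonical_category(branches$outcome)
  parsed <- lapply(branches$factors, .parse_factors)
  symbols <- unique(unlist(lapply(parsed, `[[`, "symbol")))
  unknown <- setdiff(symbols, parameters$name)
  if (length(unknown)) {
    stop("branch references undeclared parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  model <- structure(
    list(
      parameters = parameters,
      branches = branches,
      parsed = parsed,
      trees = unique(branches$tree),
      categories = sort(unique(branches$outcome))
    ),
    class = "mpt_model"
  )
  if (check_normalization) .check_normalization(model)
  model
}

#' @export
print.mpt_model <- function(x, ...) {
  cat("MPT model:", length(x$trees), "trees,",
      nrow(x$branches), "branches\n")
  cat("Trees:", paste(x$trees, collapse = ", "), "\n")
  cat("Categories:", paste(x$categories, collapse = ", "), "\n")
  k <- free_parameter_count(x)
  p <- x$parameters
  cat("Parameters:", nrow(p), "declared,", k, "free\n")
  fx <- p[p$status == "fixed", ]
  if (nrow(fx)) {
    cat("  fixed:", paste(sprintf("%s = %g", fx$name, fx$value),
                          collapse = ", "), "\n")
  }
  eq <- p[p$status == "equated", ]
  if (nrow(eq)) {
    cat("  equated:", paste(sprintf("%s = %s", eq$name, eq$to),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# Exact (corner-based) or numeric normalization check per tree.
.check_normalization <- function(model, n_random = 25, tol = 1e-9) {
  free <- model$parameters$name[model$parameters$status == "free"]
  multilinear <- all(vapply(model$parsed, function(f) {
    !anyDuplicated(f$symbol)
  }, logical(1)))
  thetas <- list()
  if (multilinear && length(free) <= 12) {
    corners <- expand.grid(rep(list(c(0, 1)), length(free)))
    thetas <- lapply(seq_len(nrow(corners)), function(i) {
      stats::setNames(as.numeric(corners[i, ]), free)
    })
  } else {
    thetas <- lapply(seq_len(n_random), function(i) {
      v <- ((i * 7 + seq_along(free) * 3) %% 17 + 1) / 19
      stats::setNames(v, free)
    })
  }
  for (theta in thetas) {
    pm <- category_probabilities(model, theta)
    s <- rowSums(pm)
    if (any(abs(s - 1) > tol)) {
      bad <- rownames(pm)[which.max(abs(s - 1))]
      stop("tree '", bad, "' does not normalize: branch probabilities sum to ",
           format(s[which.max(abs(s - 1))], digits = 12))
    }
  }
  invisible(TRUE)
}

# Full named parameter vector: free from theta, fixed from the declaration,
# equated resolved to their roots.
.resolve_theta <- function(model, theta) {
  p <- model$parameters
  out <- stats::setNames(rep(NA_real_, nrow(p)), p$name)
  free <- p$name[p$status == "free"]
  missing <- setdiff(free, names(theta))
  if (length(missing)) {
    stop("missing value for free parameter '",
         paste(missing, collapse = "', '"), "'")
  }
  th <- unlist(theta)
  if (any(th < 0 | th > 1)) stop("parameter values must lie in [0, 1]")
  out[free] <- th[free]
  out[p$status == "fixed"] <- p$value[p$status == "fixed"]
  for (s in p$name[p$status == "equated"]) {
    out[s] <- out[.resolve_root(p, s)]
  }
  out
}

#' Category probabilities of an MPT model
#'
#' Evaluates, for each tree, the probability of every response category as
#' the sum of its branch probabilities (products of `theta` or `1 - theta`
#' along each branch).
#'
#' @param model An [mpt_model()].
#' @param theta Named vector (or list) supplying every free parameter, values
#'   in `[0, 1]`. Fixed and equated parameters are resolved automatically.
#'
#' @return A numeric matrix, rows = trees, columns = response categories;
#'   each row sums to one.
#' @examples
#' m <- build_ebpm_model()
#' category_probabilities(m, c(P = 0.36, M = 0.97, C1 = 0.52, C2 = 0.78))
#' @export
category_probabilities <- function(model, theta) {
  full <- .resolve_theta(model, theta)
  br <- vapply(model$parsed, function(f) {
    v <- full[f$symbol]
    prod(ifelse(f$complement, 1 - v, v))
  }, numeric(1))
  out <- matrix(0, nrow = length(model$trees),
                ncol = length(model$categories),
                dimnames = list(model$trees, model$categories))
  for (i in seq_along(br)) {
    out[model$branches$tree[i], model$branches$outcome[i]] <-
      out[model$branches$tree[i], model$branches$outcome[i]] + br[i]
  }
  out
}

#' Number of free parameters after resolving constraints
#'
#' Counts parameters whose status is `free`; equated parameters collapse onto
#' their roots and fixed parameters are excluded.
#'
#' @param model An [mpt_model()].
#' @return Integer count of free parameters.
#' @examples
#' free_parameter_count(build_ebpm_model())              # 4
#' free_parameter_count(build_ebpm_model(constrained = FALSE))  # 7
#' @export
free_parameter_count <- function(model) {
  sum(model$parameters$status == "free")
}

#' Degrees of freedom of the G-squared goodness-of-fit test
#'
#' Each tree with `k` response categories contributes `k - 1` independent
#' category proportions. For a joint fit over `n_datasets` conditions in
#' which `n_equated` of the free parameters are shared across all
#' conditions, the effective number of free parameters is
#' `n_datasets * k_free - (n_datasets - 1) * n_equated`.
#'
#' @param model An [mpt_model()].
#' @param n_datasets Number of conditions fitted jointly (default 1).
#' @param n_equated Number of free parameters equated across all conditions
#'   (default 0; ignored when `n_datasets == 1`).
#' @return Integer degrees of freedom.
#' @examples
#' m <- build_ebpm_model()
#' degrees_of_freedom(m)                      # 8 - 4 = 4
#' degrees_of_freedom(m, n_datasets = 9, n_equated = 4)  # 72 - 4 = 68
#' @export
degrees_of_freedom <- function(model, n_datasets = 1, n_equated = 0) {
  stopifnot(n_datasets >= 1, n_equated >= 0)
  k <- free_parameter_count(model)
  if (n_equated > k) stop("n_equated exceeds the number of free parameters")
  ncat <- table(model$branches$tree[!duplicated(
    paste(model$branches$tree, model$branches$outcome))])
  cells <- sum(ncat - 1) * n_datasets
  n_free <- n_datasets * k - (n_datasets - 1) * n_equated
  df <- as.integer(cells - n_free)
  if (df < 0) {
    stop("negative degrees of freedom (", df,
         "): model is not identifiable by the counting condition")
  }
  df
}

#' Write an MPT model declaration to a text file
#'
#' The dialect is line-oriented: `param <name> free`,
#' `param <name> fixed <value>`, `param <name> equated <target>`, then one
#' `branch <tree> <factor-list> <outcome>` line per branch, with factors
#' comma-separated and oriented by a trailing `+` (direct) or `-`
#' (complement). Round-tripping through [read_mpt_model()] is lossless.
#'
#' @param model An [mpt_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mpt_model <- function(model, path) {
  p <- model$parameters
  lines <- c("# mpt model declaration v1")
  for (i in seq_len(nrow(p))) {
    lines <- c(lines, switch(
      p$status[i],
      free = paste("param", p$name[i], "free"),
      fixed = paste("param", p$name[i], "fixed",
                    format(p$value[i], digits = 17)),
      equated = paste("param", p$name[i], "equated", p$to[i])
    ))
  }
  for (i in seq_len(nrow(model$branches))) {
    f <- model$parsed[[i]]
    fl <- paste0(f$symbol, ifelse(f$complement, "-", "+"), collapse = ",")
    lines <- c(lines, paste("branch", model$branches$tree[i], fl,
                            model$branches$outcome[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an MPT model declaration from a text file
#'
#' @param path File written by [write_mpt_model()] (or hand-authored in the
#'   same dialect).
#' @param check_normalization Passed to [mpt_model()].
#' @return An [mpt_model()].
#' @export
read_mpt_model <- function(path, check_normalization = TRUE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  free <- character(); fixed <- numeric(); equated <- character()
  btree <- character(); bfac <- character(); bout <- character()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "param") {
      if (length(tok) < 3) stop("malformed param line: '", ln, "'")
      switch(tok[3],
        free = { free <- c(free, tok[2]) },
        fixed = {
          v <- as.numeric(tok[4])
          fixed <- c(fixed, stats::setNames(v, tok[2]))
        },
        equated = {
          equated <- c(equated, stats::setNames(tok[4], tok[2]))
        },
        stop("unknown parameter status '", tok[3], "' in '", ln, "'")
      )
    } else if (tok[1] == "branch") {
      if (length(tok) != 4) stop("malformed branch line: '", ln, "'")
      btree <- c(btree, tok[2]); bfac <- c(bfac, tok[3])
      bout <- c(bout, tok[4])
    } else {
      stop("unknown record type '", tok[1], "' in model file")
    }
  }
  mpt_model(
    data.frame(tree = btree, factors = bfac, outcome = bout,
               stringsAsFactors = FALSE),
    mpt_parameters(free = free, fixed = fixed, equated = equated),
    check_normalization = check_normalization
  )
}
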