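#' Read a counts file
#'
#' Comma-separated, UTF-8, with header `condition,tree,response,count`.
#'
#' @param path File path.
#' @return Named list of [category_counts()] tables, one per condition (in
#'   file order of first appearance).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "tree", "response", "count")
  if (!all(need %in% names(df))) {
    stop("counts file must have header: ", paste(need, collapse = ","))
  }
  if (nrow(df) == 0) stop("counts file is empty: ", path)
  conds <- unique(df$condition)
  out <- lapply(conds, function(cc) {
    category_counts(df[df$condition == cc, c("tree", "response", "count")])
  })
  stats::setNames(out, conds)
}

#' Write a counts file
#'
#' @param counts Either a data frame with columns
#'   `condition,tree,response,count` (e.g. from [counts_from_trials()]) or a
#'   named list of [category_counts()] tables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  if (is.data.frame(counts)) {
    df <- counts[, c("condition", "tree", "response", "count")]
  } else {
    stopifnot(is.list(counts), !is.null(names(counts)))
    df <- do.call(rbind, lapply(names(counts), function(cc) {
      x <- category_counts(counts[[cc]])
      data.frame(condition = cc, tree = x$tree, response = x$category,
                 count = x$count, stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a participant table
#'
#' Comma-separated with header `participant,condition_filler,
#' condition_ongoing,accuracy,self_reminding,discriminability` (extra
#' columns are kept).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("participant file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "condition_filler", "condition_ongoing",
            "accuracy", "self_reminding", "discriminability")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("participant file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write a participant table
#' @param participants Data frame (see [read_participants()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stable-key JSON writer (keys sorted recursively).
.write_json <- function(x, path) {
  sort_keys <- function(v) {
    if (is.data.frame(v)) {
      v[, order(names(v)), drop = FALSE]   # keep row structure
    } else if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sort_keys)
    } else v
  }
  jsonlite::write_json(sort_keys(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Summaries of one or more fits as a JSON-ready list
#'
#' @param fits Named list of `mpt_fit` objects.
#' @return List (condition -> estimates, ci95, g_squared, df, p_value,
#'   converged, ci_method); keys are stable-ordered on write.
#' @export
fit_summaries <- function(fits) {
  lapply(fits, function(f) {
    ci <- if (is.null(f$ci95)) NULL else {
      stats::setNames(lapply(rownames(f$ci95), function(p) {
        list(lower = unname(f$ci95[p, "lower"]),
             upper = unname(f$ci95[p, "upper"]))
      }), rownames(f$ci95))
    }
    list(estimates = as.list(f$estimates), ci95 = ci,
         ci_method = as.list(f$ci_method),
         g_squared = f$g_squared, df = f$df, p_value = f$p_value,
         converged = f$converged, n_starts = f$n_starts_used,
         seed = f$seed)
  })
}

#' Human-readable estimates table (one row pair per condition)
#'
#' Mirrors the conventional layout for MPT parameter reports: point
#' estimates with 95% intervals in parentheses underneath.
#'
#' @param fits Named list of `mpt_fit` objects.
#' @return Character matrix (printed with [cat()] by callers).
#' @export
format_estimates_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  pars <- names(fits[[1]]$estimates)
  rows <- list()
  for (cc in names(fits)) {
    f <- fits[[cc]]
    est <- sprintf("%.2f", f$estimates[pars])
    ci <- if (!is.null(f$ci95)) {
      sprintf("(%.2f-%.2f)", f$ci95[pars, "lower"], f$ci95[pars, "upper"])
    } else rep("", length(pars))
    rows[[length(rows) + 1]] <- c(cc, est)
    rows[[length(rows) + 1]] <- c("", ci)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("Condition", pars)
  out
}
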