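#' The four-tree EBPM color-matching MPT model
#'
#' Builds the multinomial processing tree model for event-based prospective
#' memory (EBPM) embedded in a color-matching ongoing task. There are four
#' trial types (trees): PM target with matching color (`target_match`), PM
#' target with non-matching color (`target_nonmatch`), distractor with
#' matching color (`distractor_match`) and distractor with non-matching
#' color (`distractor_nonmatch`); each trial has three response options,
#' `match`, `nonmatch` and `pm`.
#'
#' Parameters:
#' \describe{
#'   \item{P}{probability of engaging preparatory attentional processes (the
#'     prospective component);}
#'   \item{M1, M2}{probability of discriminating PM targets from non-targets
#'     (the retrospective component) on target and distractor trials
#'     respectively;}
#'   \item{C1}{probability of detecting that the colors match;}
#'   \item{C2}{probability of detecting that the colors do not match;}
#'   \item{g}{probability of guessing that an item is a PM target;}
#'   \item{c}{probability of guessing that the colors match.}
#' }
#'
#' The unconstrained model has seven parameters but only eight independent
#' category proportions (4 trees x 2), so it is not identifiable. The
#' default constraints `M1 = M2` (reported as the single symbol `M`),
#' `c = 0.5`, `g = 0.1` leave the four free parameters `P`, `M`, `C1`, `C2`.
#'
#' Useful closed forms implied by the branch tables: on both target trees
#' `p(pm) = P * (M + (1 - M) * g)`, and on both distractor trees the
#' false-alarm probability is `p(pm) = P * (1 - M) * g`, independent of
#' `C1` and `C2`.
#'
#' @param g Fixed guessing-a-target probability (default 0.1).
#' @param c Fixed guessing-color-match probability (default 0.5).
#' @param constrained If `TRUE` (default) apply `M1 = M2` and fix `g` and
#'   `c`, giving the identifiable four-parameter model; if `FALSE` all seven
#'   parameters are free (useful only for structural checks: the
#'   unconstrained model is not identifiable).
#'
#' @return An [mpt_model()] with trees `target_match`, `target_nonmatch`,
#'   `distractor_match`, `distractor_nonmatch` and categories `match`,
#'   `nonmatch`, `pm`.
#' @examples
#' m <- build_ebpm_model()
#' free_parameter_count(m)
#' category_probabilities(m, c(P = 0.5, M = 0.9, C1 = 0.6, C2 = 0.8))
#' @export
build_ebpm_model <- function(g = 0.1, c = 0.5, constrained = TRUE) {
  stopifnot(g >= 0, g <= 1, c >= 0, c <= 1)
  branches <- ebpm_branch_table()
  params <- if (constrained) {
    mpt_parameters(
      free = c("P", "M", "C1", "C2"),
      fixed = c(g = g, c = c),
      equated = c(M1 = "M", M2 = "M")
    )
  } else {
    mpt_parameters(free = c("C1", "C2", "P", "M1", "M2", "g", "c"))
  }
  mpt_model(branches, params)
}

#' Branch table of the EBPM color-matching model
#'
#' The explicit branch enumeration behind [build_ebpm_model()]: one row per
#' processing path, with factor strings in the [mpt_model()] dialect
#' (trailing `-` marks the complement). Exposed as data so the structure can
#' be inspected, diffed or modified; the same table ships as a model file in
#' `system.file("extdata", "ebpm_model.mpt", package = "ebpmtree")`.
#'
#' @return Data frame with columns `tree`, `factors`, `outcome`.
#' @export
ebpm_branch_table <- function() {
  rows <- list(
    # PM target, colors match: color detection succeeds with C1.
    c("target_match", "C1+ P+ M1+",          "pm"),
    c("target_match", "C1+ P+ M1- g+",       "pm"),
    c("target_match", "C1+ P+ M1- g-",       "match"),
    c("target_match", "C1+ P-",              "match"),
    c("target_match", "C1- P+ M1+",          "pm"),
    c("target_match", "C1- P+ M1- g+",       "pm"),
    c("target_match", "C1- P+ M1- g- c+",    "match"),
    c("target_match", "C1- P+ M1- g- c-",    "nonmatch"),
    c("target_match", "C1- P- c+",           "match"),
    c("target_match", "C1- P- c-",           "nonmatch"),
    # PM target, colors do not match: detection succeeds with C2 and the
    # correct ongoing response is "nonmatch".
    c("target_nonmatch", "C2+ P+ M1+",       "pm"),
    c("target_nonmatch", "C2+ P+ M1- g+",    "pm"),
    c("target_nonmatch", "C2+ P+ M1- g-",    "nonmatch"),
    c("target_nonmatch", "C2+ P-",           "nonmatch"),
    c("target_nonmatch", "C2- P+ M1+",       "pm"),
    c("target_nonmatch", "C2- P+ M1- g+",    "pm"),
    c("target_nonmatch", "C2- P+ M1- g- c+", "match"),
    c("target_nonmatch", "C2- P+ M1- g- c-", "nonmatch"),
    c("target_nonmatch", "C2- P- c+",        "match"),
    c("target_nonmatch", "C2- P- c-",        "nonmatch"),
    # Distractor, colors match: discriminating the item as a non-target
    # (M2) routes to the ongoing color response.
    c("distractor_match", "C1+ P+ M2+",          "match"),
    c("distractor_match", "C1+ P+ M2- g+",       "pm"),
    c("distractor_match", "C1+ P+ M2- g-",       "match"),
    c("distractor_match", "C1+ P-",              "match"),
    c("distractor_match", "C1- P+ M2+ c+",       "match"),
    c("distractor_match", "C1- P+ M2+ c-",       "nonmatch"),
    c("distractor_match", "C1- P+ M2- g+",       "pm"),
    c("distractor_match", "C1- P+ M2- g- c+",    "match"),
    c("distractor_match", "C1- P+ M2- g- c-",    "nonmatch"),
    c("distractor_match", "C1- P- c+",           "match"),
    c("distractor_match", "C1- P- c-",           "nonmatch"),
    # Distractor, colors do not match.
    c("distractor_nonmatch", "C2+ P+ M2+",          "nonmatch"),
    c("distractor_nonmatch", "C2+ P+ M2- g+",       "pm"),
    c("distractor_nonmatch", "C2+ P+ M2- g-",       "nonmatch"),
    c("distractor_nonmatch", "C2+ P-",              "nonmatch"),
    c("distractor_nonmatch", "C2- P+ M2+ c+",       "match"),
    c("distractor_nonmatch", "C2- P+ M2+ c-",       "nonmatch"),
    c("distractor_nonmatch", "C2- P+ M2- g+",       "pm"),
    c("distractor_nonmatch", "C2- P+ M2- g- c+",    "match"),
    c("distractor_nonmatch", "C2- P+ M2- g- c-",    "nonmatch"),
    c("distractor_nonmatch", "C2- P- c+",           "match"),
    c("distractor_nonmatch", "C2- P- c-",           "nonmatch")
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("tree", "factors", "outcome")
  out
}

#' Names of the four EBPM trial-type trees
#' @return Character vector in canonical order.
#' @export
ebpm_tree_names <- function() {
  c("target_match", "target_nonmatch", "distractor_match",
    "distractor_nonmatch")
}
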