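#' Marginal EBPM parameter estimates by task duration
#'
#' The fitted four free parameters of the EBPM model by filler-task
#' duration (`ft`) and ongoing-task duration (`ot`), used as the generating
#' values of the synthetic-data module.
#'
#' @return Data frame with columns `task` (`"ft"`/`"ot"`), `minutes`, `P`,
#'   `M`, `C1`, `C2`.
#' @export
ebpm_theta_table <- function() {
  data.frame(
    task = rep(c("ft", "ot"), each = 3),
    minutes = rep(c(3, 9, 15), 2),
    P  = c(0.36, 0.29, 0.47, 0.46, 0.30, 0.43),
    M  = c(0.97, 0.96, 0.99, 0.96, 0.97, 0.99),
    C1 = c(0.52, 0.57, 0.56, 0.56, 0.46, 0.61),
    C2 = c(0.78, 0.79, 0.80, 0.73, 0.78, 0.83),
    stringsAsFactors = FALSE
  )
}

#' Default generating parameters for one duration condition
#'
#' Only marginal estimates (by filler duration and by ongoing duration) are
#' available, so the generator's default for a cell of the 3 x 3 design is
#' the mean of the corresponding filler-task and ongoing-task rows of
#' [ebpm_theta_table()].
#'
#' @param filler,ongoing Durations in minutes, each in `{3, 9, 15}`.
#' @return Named vector `c(P, M, C1, C2)`.
#' @export
default_condition_theta <- function(filler, ongoing) {
  tab <- ebpm_theta_table()
  f <- tab[tab$task == "ft" & tab$minutes == filler, c("P", "M", "C1", "C2")]
  o <- tab[tab$task == "ot" & tab$minutes == ongoing, c("P", "M", "C1", "C2")]
  if (nrow(f) != 1 || nrow(o) != 1) {
    stop("default theta is tabulated only for durations 3, 9 and 15 min; ",
         "supply theta explicitly for other designs")
  }
  stats::setNames((as.numeric(f) + as.numeric(o)) / 2,
                  c("P", "M", "C1", "C2"))
}

#' Describe one cell of the duration design
#'
#' The ongoing task runs until 2 minutes after the last PM cue; the first
#' cue appears `ongoing_duration` minutes after the ongoing task starts and
#' subsequent cues follow at `cue_spacing`-minute intervals. Half of the
#' non-cue trials are color-match trials and half non-match.
#'
#' @param filler_duration Filler-task duration in minutes.
#' @param ongoing_duration Ongoing-task duration (start to first cue) in
#'   minutes.
#' @param n_participants Participants in this cell.
#' @param trial_rate Ongoing-task trials per minute (default 20; one trial
#'   comprises a 500 ms color display, a 250 ms interstimulus interval and
#'   the word/response interval).
#' @param n_pm_cues Number of PM cue trials (default 2).
#' @param cue_spacing Minutes between successive cues (default 2).
#' @return List of class `condition_design`.
#' @export
condition_design <- function(filler_duration, ongoing_duration,
                             n_participants, trial_rate = 20,
                             n_pm_cues = 2, cue_spacing = 2) {
  stopifnot(filler_duration > 0, n_participants >= 1, trial_rate > 0,
            n_pm_cues >= 1, cue_spacing > 0)
  if (ongoing_duration <= 0 || ongoing_duration * trial_rate < 1) {
    stop("ongoing_duration is shorter than the first cue placement")
  }
  structure(list(filler_duration = filler_duration,
                 ongoing_duration = ongoing_duration,
                 n_participants = n_participants,
                 trial_rate = trial_rate, n_pm_cues = n_pm_cues,
                 cue_spacing = cue_spacing),
            class = "condition_design")
}

#' The full 3 x 3 duration design
#'
#' @param n_participants Vector of 9 cell sizes in row-major order over
#'   filler duration (3, 9, 15) by ongoing duration (3, 9, 15); the default
#'   is the study's cell sizes (total 223).
#' @param ... Passed to [condition_design()] (e.g. `trial_rate`).
#' @return Named list of nine [condition_design()] objects, names like
#'   `"ft3_ot9"`.
#' @export
ebpm_design_grid <- function(n_participants = c(29, 33, 22, 29, 25, 24,
                                                21, 19, 21), ...) {
  stopifnot(length(n_participants) == 9)
  grid <- expand.grid(ongoing = c(3, 9, 15), filler = c(3, 9, 15))
  grid <- grid[, c("filler", "ongoing")]
  grid <- grid[order(grid$filler, grid$ongoing), ]
  out <- lapply(seq_len(9), function(i) {
    condition_design(grid$filler[i], grid$ongoing[i], n_participants[i],
                     ...)
  })
  names(out) <- sprintf("ft%d_ot%d", grid$filler, grid$ongoing)
  out
}

#' Generator configuration for the synthetic experiment
#'
#' Defaults emulate the study conditions: per-condition MPT parameters from
#' [default_condition_theta()]; self-reminding ratings increasing weakly
#' with filler duration; discriminability ratings decreasing with ongoing
#' duration; and a mediation coupling by which a participant's prospective
#' component P is shifted by the within-condition residual of their latent
#' discriminability (so discriminability carries a real indirect path to
#' accuracy while self-reminding does not).
#'
#' Rating model (latent scores, standard-normal noise, then rounded and
#' clamped to the 1-5 scale):
#' `d1 = alpha1 + beta1 * filler_min + e1` (self-reminding),
#' `d2 = alpha2 + beta2 * ongoing_min + e2` (discriminability);
#' participant-level `P_i = clamp(P_cond + gamma * e2, 0.001, 0.999)`.
#'
#' @param theta Function `(filler, ongoing) -> c(P, M, C1, C2)`; default
#'   [default_condition_theta()].
#' @param rating List with `alpha1`, `beta1`, `alpha2`, `beta2` (latent
#'   intercepts and per-minute slopes; defaults 3, 0.02, 3, -0.06).
#' @param gamma Mediation coupling of P to the discriminability residual
#'   (default 0.2; 0 switches mediation off).
#' @param rt Lognormal reaction-time parameters `meanlog`, `sdlog`
#'   (milliseconds; defaults give a median of about 650 ms).
#' @param seed Mandatory integer seed; all randomness in
#'   [simulate_experiment()] flows from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(theta = default_condition_theta,
                             rating = list(alpha1 = 3, beta1 = 0.02,
                                           alpha2 = 3, beta2 = -0.06),
                             gamma = 0.2,
                             rt = list(meanlog = log(650), sdlog = 0.25),
                             seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("generator_config requires an integer seed")
  }
  stopifnot(is.function(theta))
  structure(list(theta = theta, rating = rating, gamma = gamma, rt = rt,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Static branch bookkeeping for trial sampling: per-tree row indices,
# outcomes and latent factor strings (computed once per model).
.branch_layout <- function(model) {
  latent <- vapply(seq_along(model$parsed), function(i) {
    f <- model$parsed[[i]]
    paste0(f$symbol, ifelse(f$complement, "-", "+"), collapse = ",")
  }, character(1))
  list(idx = split(seq_len(nrow(model$branches)), model$branches$tree),
       outcome = model$branches$outcome, latent = latent)
}

# Branch probability vector at theta (in branch-table order).
.branch_prob_values <- function(model, theta) {
  full <- .resolve_theta(model, theta)
  vapply(model$parsed, function(f) {
    v <- full[f$symbol]
    prod(ifelse(f$complement, 1 - v, v))
  }, numeric(1))
}

#' Simulate category counts from an MPT model
#'
#' Draws, for each tree, `n_per_tree` responses from the model's category
#' probabilities (one multinomial draw per tree).
#'
#' @param model An [mpt_model()].
#' @param theta Named free-parameter vector.
#' @param n_per_tree Responses per tree (scalar or named vector over trees).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A [category_counts()] table.
#' @export
simulate_counts <- function(model, theta, n_per_tree, seed) {
  stopifnot(all(n_per_tree >= 1))
  pm <- category_probabilities(model, theta)
  if (length(n_per_tree) == 1) {
    n_per_tree <- stats::setNames(rep(n_per_tree, nrow(pm)), rownames(pm))
  }
  counts <- .with_seed(seed, {
    do.call(rbind, lapply(rownames(pm), function(tr) {
      k <- stats::rmultinom(1, n_per_tree[[tr]], pm[tr, ])
      data.frame(tree = tr, category = colnames(pm), count = as.numeric(k),
                 stringsAsFactors = FALSE)
    }))
  })
  category_counts(counts)
}

#' Simulate the trial-level EBPM experiment
#'
#' Generates, for each participant in each design cell, the full ongoing
#' task trial sequence: PM cue trials placed deterministically at
#' `ongoing_duration + (k - 1) * cue_spacing` minutes (trial index =
#' time x trial rate), the remaining trials split evenly between color-match
#' and non-match distractors, responses sampled branch-by-branch from the
#' EBPM trees at the participant's parameter vector, lognormal reaction
#' times, Likert ratings, and accuracy as the proportion of cue trials
#' answered "pm".
#'
#' @param design A [condition_design()] or a (named) list of them, e.g.
#'   [ebpm_design_grid()].
#' @param config A [generator_config()] (the seed lives here).
#' @param model The MPT model to sample from; default [build_ebpm_model()].
#' @return List with `trials` (one row per trial: `participant`,
#'   `condition`, `trial`, `trial_type`, `is_cue`, `latent`, `response`,
#'   `rt_ms`) and `participants` (one row per participant: `participant`,
#'   `condition`, `condition_filler`, `condition_ongoing`, `accuracy`,
#'   `self_reminding`, `discriminability`).
#' @export
simulate_experiment <- function(design, config,
                                model = build_ebpm_model()) {
  stopifnot(inherits(config, "generator_config"))
  designs <- if (inherits(design, "condition_design")) {
    list(condition = design)
  } else {
    stopifnot(length(design) >= 1,
              all(vapply(design, inherits, logical(1), "condition_design")))
    if (is.null(names(design))) {
      names(design) <- paste0("condition", seq_along(design))
    }
    design
  }
  layout <- .branch_layout(model)
  .with_seed(config$seed, {
    trial_rows <- list()
    part_rows <- list()
    pid <- 0L
    for (cond in names(designs)) {
      ds <- designs[[cond]]
      theta0 <- config$theta(ds$filler_duration, ds$ongoing_duration)
      cue_idx <- round(ds$trial_rate *
                         (ds$ongoing_duration +
                            (seq_len(ds$n_pm_cues) - 1) * ds$cue_spacing))
      n_trials <- round(ds$trial_rate *
                          (ds$ongoing_duration +
                             (ds$n_pm_cues - 1) * ds$cue_spacing + 2))
      if (any(cue_idx < 1) || any(cue_idx > n_trials)) {
        stop("cue placement falls outside the trial sequence")
      }
      for (i in seq_len(ds$n_participants)) {
        pid <- pid + 1L
        e1 <- stats::rnorm(1)
        e2 <- stats::rnorm(1)
        d1 <- config$rating$alpha1 +
          config$rating$beta1 * ds$filler_duration + e1
        d2 <- config$rating$alpha2 +
          config$rating$beta2 * ds$ongoing_duration + e2
        w1 <- min(max(round(d1), 1), 5)
        w2 <- min(max(round(d2), 1), 5)
        theta_i <- theta0
        theta_i["P"] <- min(max(theta0[["P"]] + config$gamma * e2,
                                0.001), 0.999)
        pr <- .branch_prob_values(model, theta_i)
        trial_type <- character(n_trials)
        is_cue <- seq_len(n_trials) %in% cue_idx
        trial_type[is_cue] <- sample(c("target_match", "target_nonmatch"),
                                     sum(is_cue), replace = TRUE)
        n_dist <- n_trials - sum(is_cue)
        half <- rep(c("distractor_match", "distractor_nonmatch"),
                    length.out = n_dist)
        trial_type[!is_cue] <- sample(half)
        # sample a full branch (latent process record) per trial
        latent <- character(n_trials)
        response <- character(n_trials)
        for (tt in unique(trial_type)) {
          sel <- trial_type == tt
          rows <- layout$idx[[tt]]
          bi <- rows[sample.int(length(rows), sum(sel), replace = TRUE,
                                prob = pr[rows])]
          latent[sel] <- layout$latent[bi]
          response[sel] <- layout$outcome[bi]
        }
        rt <- stats::rlnorm(n_trials, config$rt$meanlog, config$rt$sdlog)
        trial_rows[[pid]] <- list(
          participant = rep(pid, n_trials), condition = rep(cond, n_trials),
          trial = seq_len(n_trials), trial_type = trial_type,
          is_cue = is_cue, latent = latent, response = response, rt_ms = rt)
        part_rows[[pid]] <- list(
          participant = pid, condition = cond,
          condition_filler = ds$filler_duration,
          condition_ongoing = ds$ongoing_duration,
          accuracy = mean(response[is_cue] == "pm"),
          self_reminding = w1, discriminability = w2)
      }
    }
    col <- function(rows, name) unlist(lapply(rows, `[[`, name),
                                       use.names = FALSE)
    trials <- data.frame(
      participant = col(trial_rows, "participant"),
      condition = col(trial_rows, "condition"),
      trial = col(trial_rows, "trial"),
      trial_type = col(trial_rows, "trial_type"),
      is_cue = col(trial_rows, "is_cue"),
      latent = col(trial_rows, "latent"),
      response = col(trial_rows, "response"),
      rt_ms = col(trial_rows, "rt_ms"), stringsAsFactors = FALSE)
    participants <- data.frame(
      participant = col(part_rows, "participant"),
      condition = col(part_rows, "condition"),
      condition_filler = col(part_rows, "condition_filler"),
      condition_ongoing = col(part_rows, "condition_ongoing"),
      accuracy = col(part_rows, "accuracy"),
      self_reminding = col(part_rows, "self_reminding"),
      discriminability = col(part_rows, "discriminability"),
      stringsAsFactors = FALSE)
    list(trials = trials, participants = participants)
  })
}

#' Aggregate simulated trials into per-condition category counts
#'
#' @param trials The `trials` component of [simulate_experiment()].
#' @return Data frame with columns `condition`, `tree`, `response`,
#'   `count` (the counts-file dialect); split by condition and pass cells
#'   through [category_counts()] for fitting.
#' @export
counts_from_trials <- function(trials) {
  stopifnot(all(c("condition", "trial_type", "response") %in%
                  names(trials)))
  agg <- stats::aggregate(
    rep(1, nrow(trials)),
    by = list(condition = trials$condition, tree = trials$trial_type,
              response = trials$response), FUN = sum)
  names(agg)[4] <- "count"
  agg[order(agg$condition, agg$tree, agg$response), , drop = FALSE]
}

#' One-pass outlier trim at mean plus or minus 3 SD
#'
#' Removes values outside `mean(x) +/- 3 * sd(x)`, with mean and SD computed
#' once on the full input (no iterative re-trimming). Constant input (SD
#' zero) is returned unchanged.
#'
#' @param values Numeric vector, length at least 2.
#' @return The retained values, order preserved.
#' @export
trim_outliers <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(values)
  values[values >= m - 3 * s & values <= m + 3 * s]
}
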