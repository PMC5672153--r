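#' Default pipeline configuration
#'
#' @param stages Stages to run, in order, a subset of
#'   `c("simulate", "fit", "compare", "mediate", "report")`.
#' @param n_participants Cell sizes for [ebpm_design_grid()].
#' @param compare_parameters Parameters for the `compare` stage (default all
#'   four free parameters).
#' @param mediators Mediator columns for the `mediate` stage.
#' @param mediation_x Predictor column for the `mediate` stage (default the
#'   ongoing-task duration).
#' @param n_starts Multistart count for fitting stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "fit", "compare",
                                       "mediate", "report"),
                            n_participants = c(29, 33, 22, 29, 25, 24,
                                               21, 19, 21),
                            compare_parameters = c("P", "M", "C1", "C2"),
                            mediators = c("self_reminding",
                                          "discriminability"),
                            mediation_x = "condition_ongoing",
                            n_starts = 10) {
  known <- c("simulate", "fit", "compare", "mediate", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, n_participants = n_participants,
                 compare_parameters = compare_parameters,
                 mediators = mediators, mediation_x = mediation_x,
                 n_starts = n_starts),
            class = "pipeline_config")
}

# Deterministic per-stage seeds fanned out from one top-level seed.
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, fit = 202L, compare = 303L, mediate = 404L,
            report = 505L)
  as.integer((seed * 7 + offs[[stage]]) %% .Machine$integer.max)
}

#' Run the simulate / fit / compare / mediate / report pipeline
#'
#' Executes the requested stages in order inside `out_dir`, each stage
#' reading the files its predecessor declared, and writes a run manifest
#' (`manifest.json`) with the command, configuration hash, seeds, package
#' version, timestamps and MD5 digests of every input and output file.
#' Identical configuration and seed give byte-identical data files and
#' digests.
#'
#' Stage outputs: `simulate` writes `counts.csv`, `participants.csv`,
#' `trials.csv`; `fit` writes `fits.json` and `estimates.txt`; `compare`
#' writes `comparisons.csv`; `mediate` writes `mediation.json`; `report`
#' writes `report.txt` summarizing the others.
#'
#' @param config A [pipeline_config()] (or NULL for defaults).
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level integer seed; per-stage seeds are derived from it
#'   deterministically.
#' @param log_level `"info"` (progress messages) or `"quiet"`.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1L,
                         log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(config)) config <- pipeline_config()
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (log_level == "info") message(...)
  pth <- function(f) file.path(out_dir, f)
  outputs <- character()
  inputs <- character()

  cfg_file <- pth("config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  outputs <- c(outputs, cfg_file)

  model <- build_ebpm_model()
  need <- function(f, stage) {
    if (!file.exists(pth(f))) {
      stop("stage '", stage, "' requires missing upstream file: ", pth(f))
    }
    inputs <<- c(inputs, pth(f))
    pth(f)
  }

  for (stage in config$stages) {
    say("stage: ", stage)
    if (stage == "simulate") {
      gc_ <- generator_config(seed = .stage_seed(seed, "simulate"))
      sim <- simulate_experiment(
        ebpm_design_grid(config$n_participants), gc_)
      write_counts(counts_from_trials(sim$trials), pth("counts.csv"))
      write_participants(sim$participants, pth("participants.csv"))
      utils::write.csv(sim$trials, pth("trials.csv"), row.names = FALSE,
                       quote = FALSE)
      outputs <- c(outputs, pth(c("counts.csv", "participants.csv",
                                  "trials.csv")))
    } else if (stage == "fit") {
      counts <- read_counts(need("counts.csv", stage))
      fits <- lapply(counts, function(cc) {
        fit_mle(model, cc, n_starts = config$n_starts,
                seed = .stage_seed(seed, "fit"))
      })
      .write_json(fit_summaries(fits), pth("fits.json"))
      tab <- format_estimates_table(fits)
      utils::write.table(tab, pth("estimates.txt"), row.names = FALSE,
                         col.names = TRUE, quote = FALSE, sep = "\t")
      for (cc in names(fits)) {
        say(sprintf("  %s: G^2(%d) = %.2f, p = %.2f", cc, fits[[cc]]$df,
                    fits[[cc]]$g_squared, fits[[cc]]$p_value))
      }
      outputs <- c(outputs, pth(c("fits.json", "estimates.txt")))
    } else if (stage == "compare") {
      counts <- read_counts(need("counts.csv", stage))
      cmp <- compare_conditions(model, counts,
                                parameters = config$compare_parameters,
                                n_starts = config$n_starts,
                                seed = .stage_seed(seed, "compare"))
      utils::write.csv(cmp, pth("comparisons.csv"), row.names = FALSE,
                       quote = FALSE)
      say("  ", attr(cmp, "n_tests"),
          " tests run (no multiplicity correction by default)")
      outputs <- c(outputs, pth("comparisons.csv"))
    } else if (stage == "mediate") {
      parts <- read_participants(need("participants.csv", stage))
      med <- baron_kenny(parts, x = config$mediation_x,
                         mediators = config$mediators, y = "accuracy")
      .write_json(list(paths = med$paths, sobel = med$sobel, n = med$n),
                  pth("mediation.json"))
      for (i in seq_len(nrow(med$sobel))) {
        say(sprintf("  Sobel %s: z = %.2f", med$sobel$mediator[i],
                    med$sobel$z[i]))
      }
      outputs <- c(outputs, pth("mediation.json"))
    } else if (stage == "report") {
      lines <- c("EBPM MPT pipeline report", "")
      if (file.exists(pth("fits.json"))) {
        inputs <- c(inputs, pth("fits.json"))
        fj <- jsonlite::read_json(pth("fits.json"))
        lines <- c(lines, "Per-condition fits:")
        for (cc in names(fj)) {
          lines <- c(lines, sprintf(
            "  %s: G^2(%d) = %.2f, p = %.2f", cc, fj[[cc]]$df,
            fj[[cc]]$g_squared, fj[[cc]]$p_value))
        }
      }
      if (file.exists(pth("mediation.json"))) {
        inputs <- c(inputs, pth("mediation.json"))
        mj <- jsonlite::read_json(pth("mediation.json"),
                                  simplifyVector = TRUE)
        lines <- c(lines, "", "Sobel tests:")
        for (i in seq_len(nrow(mj$sobel))) {
          lines <- c(lines, sprintf(
            "  %s: z = %.2f, p(one-tailed) = %.3f, p(two-tailed) = %.3f",
            mj$sobel$mediator[i], mj$sobel$z[i], mj$sobel$p_one[i],
            mj$sobel$p_two[i]))
        }
      }
      writeLines(lines, pth("report.txt"))
      outputs <- c(outputs, pth("report.txt"))
    }
  }

  outputs <- unique(outputs)
  inputs <- unique(inputs)
  digest <- function(files) {
    as.list(stats::setNames(unname(tools::md5sum(files)),
                            basename(files)))
  }
  manifest <- list(
    command = paste("run_pipeline:", paste(config$stages, collapse = ",")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = seed,
    stage_seeds = as.list(stats::setNames(
      vapply(config$stages, function(s) .stage_seed(seed, s), integer(1)),
      config$stages)),
    package_version = as.character(utils::packageVersion("ebpmtree")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = digest(inputs),
    outputs = digest(setdiff(outputs, pth("manifest.json")))
  )
  .write_json(manifest, pth("manifest.json"))
  invisible(manifest)
}
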