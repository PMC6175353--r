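#' Fitted-model report
#'
#' Fits the requested dose-toxicity specification, prints the coefficients,
#' the fitted per-dose DLT probabilities per subgroup and the TD100theta
#' estimate(s), and returns the pieces invisibly.
#'
#' @param data a [ToxicityData-class] (e.g. from [readToxicityData()]).
#' @param spec a [ModelSpec-class].
#' @param grid a [DoseGrid-class].
#' @param policy an [EscalationPolicy-class] supplying theta.
#' @return invisibly, list(fit, probs, td).
#' @examples
#' fitReport(nicholsonData(), modelSpec(), defaultDoseGrid(),
#'           escalationPolicy())
#' @export
fitReport <- function(data, spec = modelSpec(), grid = defaultDoseGrid(),
                      policy = escalationPolicy()) {
  fit <- fitDoseToxicity(data, spec, grid)
  show(fit)
  groups <- if (spec@beta2 || spec@beta3) 0:1 else 0L
  probs <- t(vapply(groups,
                    function(g) predictProb(fit, grid@doses, g),
                    numeric(length(grid@doses))))
  dimnames(probs) <- list(paste0("subgroup", groups), grid@doses)
  cat("Fitted DLT probabilities:\n")
  print(round(probs, 3L))
  td <- vapply(groups, function(g)
    tryCatch(tdEstimate(fit, policy@theta, g), error = function(e) NA_real_),
    numeric(1L))
  names(td) <- paste0("subgroup", groups)
  cat(sprintf("TD%d estimate(s), mg/m2:\n", round(100 * policy@theta)))
  print(round(td))
  invisible(list(fit = fit, probs = probs, td = td))
}

#' Run one trial and write its trajectory and result to files
#'
#' @param config a [TrialConfig-class].
#' @param truth a [ScenarioTruth-class].
#' @param seed integer seed.
#' @param outDir output directory (created if needed).
#' @return the [TrialResult-class], invisibly. Writes
#'   \code{trajectory.csv} (cohort, subgroup, dose, outcome, chosen spec,
#'   inclusion probabilities) and \code{result.json}.
#' @export
runTrialToFiles <- function(config, truth, seed, outDir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("runTrialToFiles needs the 'jsonlite' package")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- runTrial(config, truth, seed)
  utils::write.csv(res@cohortLog, file.path(outDir, "trajectory.csv"),
                   row.names = FALSE)
  rec <- as.list(res@recommended)
  jsonlite::write_json(
    list(recommended = lapply(rec, function(x) if (is.na(x)) NULL else x),
         verdict = res@verdict,
         patients = as.list(res@patients), dlts = as.list(res@dlts),
         stop_reasons = as.list(res@stopReasons),
         fallback_used = res@fallbackUsed, seed = res@seed),
    file.path(outDir, "result.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(res)
}

#' Run a study and write its summary files
#'
#' @param config a [TrialConfig-class].
#' @param scenarios named list of [ScenarioTruth-class].
#' @param nReplicates trials per scenario.
#' @param rootSeed root seed.
#' @param outDir output directory.
#' @param fast logical: shorten the method-2 chains to the fast profile
#'   (5000 iterations, 1000 burn-in); flagged in the provenance header.
#' @return the [StudySummary-class], invisibly. Writes \code{summary.csv}
#'   (tidy, one row per scenario x statistic) and \code{summary.txt} (a
#'   human-readable table with a provenance header).
#' @export
runStudyToFiles <- function(config, scenarios, nReplicates, rootSeed, outDir,
                            fast = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (fast && config@method == "method2")
    config@ssConfig <- spikeSlabConfig(
      5000L, 1000L, config@ssConfig@priorInclusion,
      config@ssConfig@inclusionBound)
  summary <- runStudy(config, scenarios, nReplicates, rootSeed)
  utils::write.csv(tidyStudySummary(summary),
                   file.path(outDir, "summary.csv"), row.names = FALSE)
  txt <- c(sprintf("# doseslab %s | method %s | %d replicates | seed %d | %s",
                   as.character(utils::packageVersion("doseslab")),
                   config@method, nReplicates, rootSeed,
                   if (fast) "fast MCMC profile" else "full profile"),
           utils::capture.output(show(summary)))
  writeLines(txt, file.path(outDir, "summary.txt"))
  invisible(summary)
}

#' Read a run configuration file
#'
#' A flat YAML file mirroring [trialConfig()] plus study options. Recognised
#' keys (all optional, defaults are the simulation-study setup): \code{doses},
#' \code{reference_dose}, \code{theta}, \code{delta}, \code{method},
#' \code{max_patients}, \code{accuracy_stop}, \code{min_at_dose},
#' \code{ci_level}, \code{ci_width_bound}, \code{n_iterations},
#' \code{burn_in}, \code{prior_inclusion}, \code{inclusion_bound},
#' \code{slab_scale}, \code{pseudo_data} (path to a pseudo-data CSV with
#' columns subgroup, dose, proportion, weight), \code{scenarios} (integer
#' vector 1..6), \code{n_replicates}, \code{root_seed}, \code{fast},
#' \code{out_dir}.
#'
#' @param file path to the YAML config.
#' @return list(config = [TrialConfig-class], scenarios, nReplicates,
#'   rootSeed, fast, outDir).
#' @export
readRunConfig <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("readRunConfig needs the 'yaml' package")
  y <- yaml::read_yaml(file)
  known <- c("doses", "reference_dose", "theta", "delta", "method",
             "max_patients", "accuracy_stop", "min_at_dose", "ci_level",
             "ci_width_bound", "n_iterations", "burn_in", "prior_inclusion",
             "inclusion_bound", "slab_scale", "pseudo_data", "scenarios",
             "n_replicates", "root_seed", "fast", "out_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  get <- function(key, default) y[[key]] %||% default

  grid <- DoseGrid(unlist(get("doses", c(100, 150, 180, 215, 245, 260))),
                   get("reference_dose", 200))
  policy <- escalationPolicy(get("theta", 0.16), get("delta", 0.35))
  pseudo <- if (!is.null(y$pseudo_data)) {
    df <- utils::read.csv(y$pseudo_data)
    pseudoDataSpec(df$subgroup, df$dose, df$proportion, df$weight)
  } else defaultPseudoData()
  ss <- spikeSlabConfig(get("n_iterations", 20000L), get("burn_in", 5000L),
                        unlist(get("prior_inclusion", c(0.5, 0.5))),
                        get("inclusion_bound", 0.25))
  config <- trialConfig(grid, policy, pseudo,
                        method = get("method", "baseline"),
                        maxPatients = get("max_patients", 60L),
                        accuracyStop = get("accuracy_stop", FALSE),
                        minAtDose = get("min_at_dose", 5L),
                        ciLevel = get("ci_level", 0.95),
                        ciWidthBound = get("ci_width_bound", 5),
                        ssConfig = ss, slabScale = get("slab_scale", 1))
  all <- buildScenarios(grid = grid)
  idx <- unlist(get("scenarios", 1:6))
  if (!all(idx %in% 1:6)) stop("'scenarios' must be integers in 1..6")
  list(config = config, scenarios = all[idx],
       nReplicates = as.integer(get("n_replicates", 1000L)),
       rootSeed = as.integer(get("root_seed", 1L)),
       fast = isTRUE(get("fast", FALSE)),
       outDir = get("out_dir", "doseslab-out"))
}
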