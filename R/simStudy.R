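#' Recommendation frequency table
#'
#' Per subgroup, the proportion of trials recommending each grid dose, with
#' the proportion declaring no dose as its own first column ("none"). All
#' proportions are out of the full set of trials, so each row sums to 1.
#'
#' @param results list of [TrialResult-class] objects.
#' @param grid a [DoseGrid-class].
#' @return 2 x (ndose + 1) matrix, rows "0" and "1".
#' @export
summariseRecommendations <- function(results, grid) {
  stopifnot(length(results) > 0L)
  lev <- c(NA, grid@doses)
  freq <- matrix(0, 2L, length(lev),
                 dimnames = list(c("0", "1"), c("none", grid@doses)))
  for (g in c("0", "1")) {
    rec <- vapply(results, function(r) r@recommended[g], numeric(1L))
    freq[g, 1L] <- mean(is.na(rec))
    for (j in seq_along(grid@doses))
      freq[g, j + 1L] <- mean(!is.na(rec) & rec == grid@doses[j])
  }
  freq
}

#' Run a replicated operating-characteristics study
#'
#' Simulates \code{nReplicates} independent trials per scenario (replicate
#' \code{r} uses seed \code{rootSeed + r}, so a study split across seed
#' offsets and pooled reproduces the full study exactly) and aggregates
#' sample sizes, DLT proportions, subgroup-effect verdicts, recommendation
#' frequencies and stop reasons.
#'
#' @param config a [TrialConfig-class].
#' @param scenarios named list of [ScenarioTruth-class] objects.
#' @param nReplicates trials per scenario.
#' @param rootSeed integer root seed.
#' @return a [StudySummary-class].
#' @export
runStudy <- function(config, scenarios, nReplicates = 1000L, rootSeed = 1L) {
  stopifnot(nReplicates >= 1L)
  if (is(scenarios, "ScenarioTruth")) scenarios <- list(scenarios)
  rows <- list(); recFreq <- list(); stopReasons <- list()
  failures <- 0L

  for (si in seq_along(scenarios)) {
    truth <- scenarios[[si]]
    results <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
      results[[r]] <- tryCatch(
        runTrial(config, truth, seed = as.integer(rootSeed + r)),
        error = function(e) e)
    }
    bad <- vapply(results, inherits, logical(1L), what = "error")
    if (any(bad)) {
      failures <- failures + sum(bad)
      warning(sum(bad), " trial(s) failed in scenario ", si, ": ",
              conditionMessage(results[[which(bad)[1L]]]))
      results <- results[!bad]
    }
    pat <- t(vapply(results, slot, numeric(2L), name = "patients"))
    dlt <- t(vapply(results, slot, numeric(2L), name = "dlts"))
    verdict <- vapply(results, slot, integer(1L), name = "verdict")
    propOf <- function(num, den) mean(ifelse(den > 0, num / den, NA),
                                      na.rm = TRUE)
    rows[[si]] <- data.frame(
      scenario = names(scenarios)[si] %||% as.character(si),
      label = truth@label,
      avgPatients = mean(rowSums(pat)),
      avgPatientsNeg = mean(pat[, 1L]),
      avgPatientsPos = mean(pat[, 2L]),
      avgDltProp = propOf(rowSums(dlt), rowSums(pat)),
      avgDltPropNeg = propOf(dlt[, 1L], pat[, 1L]),
      avgDltPropPos = propOf(dlt[, 2L], pat[, 2L]),
      verdict0 = sum(verdict == 0L),
      verdict1 = sum(verdict == 1L),
      verdict2 = sum(verdict == 2L),
      fallbacks = sum(vapply(results, slot, logical(1L),
                             name = "fallbackUsed")),
      nTrials = length(results))
    recFreq[[si]] <- summariseRecommendations(results, config@grid)
    sr <- matrix(0, 2L, 3L, dimnames = list(c("0", "1"),
                                            c("safety", "max", "accuracy")))
    for (g in c("0", "1")) {
      reasons <- vapply(results, function(r) r@stopReasons[g], character(1L))
      for (rs in colnames(sr)) sr[g, rs] <- mean(reasons == rs)
    }
    stopReasons[[si]] <- sr
  }
  names(recFreq) <- names(stopReasons) <-
    names(scenarios) %||% as.character(seq_along(scenarios))

  new("StudySummary", summary = do.call(rbind, rows), recFreq = recFreq,
      stopReasons = stopReasons, method = config@method,
      nReplicates = as.integer(nReplicates), rootSeed = as.integer(rootSeed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "StudySummary", function(object) {
  cat(sprintf("StudySummary: method %s, %d replicates (root seed %d)\n",
              object@method, object@nReplicates, object@rootSeed))
  df <- object@summary
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = 2L)
  print(df, row.names = FALSE)
  cat("\nRecommendation frequencies (rows: subgroup; first column: none):\n")
  for (nm in names(object@recFreq)) {
    cat(" ", nm, "\n")
    print(round(object@recFreq[[nm]], 3L))
  }
  invisible(object)
})

#' Tidy export of a study summary
#'
#' One row per scenario x statistic, suitable for CSV export.
#'
#' @param summary a [StudySummary-class].
#' @return a data.frame with columns scenario, statistic, subgroup, value.
#' @export
tidyStudySummary <- function(summary) {
  df <- summary@summary
  out <- list()
  add <- function(scenario, statistic, subgroup, value)
    out[[length(out) + 1L]] <<- data.frame(
      scenario = scenario, statistic = statistic, subgroup = subgroup,
      value = value)
  for (i in seq_len(nrow(df))) {
    sc <- df$scenario[i]
    add(sc, "avg_patients", "all", df$avgPatients[i])
    add(sc, "avg_patients", "0", df$avgPatientsNeg[i])
    add(sc, "avg_patients", "1", df$avgPatientsPos[i])
    add(sc, "avg_dlt_prop", "all", df$avgDltProp[i])
    add(sc, "avg_dlt_prop", "0", df$avgDltPropNeg[i])
    add(sc, "avg_dlt_prop", "1", df$avgDltPropPos[i])
    for (v in 0:2) add(sc, paste0("verdict", v), "all",
                       df[[paste0("verdict", v)]][i])
    rf <- summary@recFreq[[i]]
    for (g in c("0", "1"))
      for (j in colnames(rf))
        add(sc, paste0("rec_", j), g, rf[g, j])
    sr <- summary@stopReasons[[i]]
    for (g in c("0", "1"))
      for (j in colnames(sr))
        add(sc, paste0("stop_", j), g, sr[g, j])
  }
  do.call(rbind, out)
}
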