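#' The default dose grid of the simulation study
#'
#' Six doses 100--260 mg/m2 with reference dose 200 mg/m2 (the adult
#' recommended dose).
#' @return a [DoseGrid-class].
#' @export
defaultDoseGrid <- function() {
  DoseGrid(c(100, 150, 180, 215, 245, 260), referenceDose = 200)
}

#' Construct a trial configuration
#'
#' Defaults reproduce the simulation-study setup: six-dose grid, theta 0.16,
#' delta 0.35, the default pseudo-data prior (three patients' worth per
#' subgroup), cohorts of two (one patient per subgroup), at most 60 patients
#' (30 per subgroup), accuracy stopping off.
#'
#' @param grid a [DoseGrid-class].
#' @param policy an [EscalationPolicy-class].
#' @param pseudo a [PseudoDataSpec-class] (per-subgroup prior, methods 1/2).
#' @param pseudoPooled a [PseudoDataSpec-class]: the pooled-population prior
#'   the baseline design fits (its top-dose DLT proportion is elicited at 1).
#' @param method "baseline", "method1" or "method2".
#' @param cohortSize patients per cohort (only 2 supported).
#' @param maxPatients overall sample-size cap (even; half per subgroup).
#' @param accuracyStop enable the accuracy stopping rule.
#' @param minAtDose accuracy rule: minimum subgroup patients at the advised
#'   dose.
#' @param ciLevel accuracy rule: interval level.
#' @param ciWidthBound accuracy rule: the TD interval must be strictly
#'   narrower than this many mg/m2.
#' @param ssConfig a [SpikeSlabConfig-class] (method2).
#' @param slabScale slab covariance multiplier (method2).
#' @return a [TrialConfig-class].
#' @export
trialConfig <- function(grid = defaultDoseGrid(), policy = escalationPolicy(),
                        pseudo = defaultPseudoData(),
                        pseudoPooled = defaultPooledPseudoData(),
                        method = "baseline",
                        cohortSize = 2L, maxPatients = 60L,
                        accuracyStop = FALSE, minAtDose = 5L, ciLevel = 0.95,
                        ciWidthBound = 5, ssConfig = spikeSlabConfig(),
                        slabScale = 1) {
  new("TrialConfig", grid = grid, policy = policy, pseudo = pseudo,
      pseudoPooled = pseudoPooled,
      method = method, cohortSize = as.integer(cohortSize),
      maxPatients = as.integer(maxPatients), accuracyStop = accuracyStop,
      minAtDose = as.integer(minAtDose), ciLevel = ciLevel,
      ciWidthBound = ciWidthBound, ssConfig = ssConfig,
      slabScale = slabScale)
}

#' Advise the next dose for each subgroup
#'
#' One model update of the chosen design on the accumulated data (pseudo-data
#' plus observed patients): the baseline design fits the pooled two-parameter
#' model and advises one dose for everybody; method 1 fits the four-parameter
#' model and advises per subgroup; method 2 first chooses the model by
#' spike-and-slab variable selection, then refits the chosen specification by
#' maximum likelihood. After a one-sided safety stop (\code{soloSubgroup}
#' set), the surviving subgroup is advised from the two-parameter model fitted
#' to that subgroup's data only. An \code{NA} dose signals that no grid dose
#' satisfies the safety criterion for that subgroup (safety stop).
#'
#' @param data accumulated [ToxicityData-class] (pseudo + trial records).
#' @param config a [TrialConfig-class].
#' @param soloSubgroup 0 or 1 when only that subgroup remains after the other
#'   stopped for safety; NA otherwise.
#' @param slab a [SlabPrior-class] (method2; derived from the config's pseudo
#'   data when NULL).
#' @param chainSeed seed for the method2 chain (NA: current RNG state).
#' @return list with \code{dose} (named numeric, "0" and "1", NA = no safe
#'   dose), \code{spec} (the [ModelSpec-class] used), \code{fits} (per-subgroup
#'   [DoseToxicityFit-class] used for the advice), and \code{w} (posterior
#'   inclusion probabilities, NA except under method2).
#' @export
adviseNextDoses <- function(data, config, soloSubgroup = NA, slab = NULL,
                            chainSeed = NA_integer_) {
  grid <- config@grid; policy <- config@policy
  w <- c(w2 = NA_real_, w3 = NA_real_)

  if (!is.na(soloSubgroup)) {
    g <- as.integer(soloSubgroup)
    fit <- fitDoseToxicity(subgroupData(data, g), modelSpec(), grid)
    dose <- c("0" = NA_real_, "1" = NA_real_)
    dose[as.character(g)] <- selectDose(fit, grid, policy, g)
    fits <- list(fit, fit)
    return(list(dose = dose, spec = modelSpec(), fits = fits, w = w))
  }

  spec <- switch(config@method,
    baseline = modelSpec(),
    method1 = modelSpec(TRUE, TRUE),
    method2 = {
      if (is.null(slab))
        slab <- deriveSlab(config@pseudo, grid, config@slabScale,
                           config@ssConfig@priorInclusion)
      sscfg <- config@ssConfig
      sscfg@seed <- as.integer(chainSeed)
      post <- runSpikeSlab(data, slab, grid, sscfg)
      w <- inclusionProb(post)
      chooseModel(post, sscfg)
    })

  fit <- fitDoseToxicity(data, spec, grid)
  if (!fit@identifiable) {  # cannot happen with the pseudo-data present,
    spec <- modelSpec()     # but never advise from a degenerate fit
    fit <- fitDoseToxicity(data, spec, grid)
  }
  dose <- if (config@method == "baseline") {
    d <- selectDose(fit, grid, policy, 0L)
    c("0" = d, "1" = d)
  } else {
    c("0" = selectDose(fit, grid, policy, 0L),
      "1" = selectDose(fit, grid, policy, 1L))
  }
  list(dose = dose, spec = spec, fits = list(fit, fit), w = w)
}

#' Accuracy stopping check for one subgroup
#'
#' TRUE when at least \code{minAtDose} of the subgroup's trial patients have
#' been treated at the dose advised for the next cohort and the delta-method
#' interval (at the configured level) for the subgroup's TD100theta estimate
#' is strictly narrower than \code{ciWidthBound} mg/m2. An undefined interval
#' (degenerate fit) never triggers a stop.
#'
#' @param data accumulated [ToxicityData-class].
#' @param config a [TrialConfig-class].
#' @param subgroup 0 or 1.
#' @param advisedDose the dose advised for the subgroup's next cohort.
#' @param fit the [DoseToxicityFit-class] that produced the advice.
#' @return logical.
#' @export
checkAccuracyStop <- function(data, config, subgroup, advisedDose, fit) {
  if (!config@accuracyStop || is.na(advisedDose)) return(FALSE)
  tr <- trialData(data)
  atDose <- tr@subgroup == as.integer(subgroup) & tr@dose == advisedDose
  nAt <- sum(tr@dltWeight[atDose] + tr@noDltWeight[atDose])
  if (nAt < config@minAtDose) return(FALSE)
  ci <- tdInterval(fit, config@policy@theta, subgroup, config@ciLevel)
  if (anyNA(ci)) return(FALSE)
  unname(ci["upper"] - ci["lower"]) < config@ciWidthBound
}

## final-recommendation helper: frequentist fit on trial data only, falling
## back to the MAP fit (pseudo-data included) when the trial-only fit is
## non-identifiable or separated. Returns dose + fallback flag.
.recommendFrom <- function(dataTrial, dataMap, spec, grid, policy, subgroup,
                           allowed) {
  if (length(allowed) == 0L) return(list(dose = NA_real_, fallback = FALSE))
  fit <- if (length(dataTrial) > 0L)
    fitDoseToxicity(dataTrial, spec, grid) else NULL
  if (!is.null(fit) && fit@identifiable && fit@converged && !fit@boundary)
    return(list(dose = selectDose(fit, grid, policy, subgroup, allowed),
                fallback = FALSE))
  mapFit <- fitDoseToxicity(dataMap, spec, grid)
  if (!mapFit@identifiable) {
    mapFit <- fitDoseToxicity(dataMap, modelSpec(), grid)
  }
  list(dose = selectDose(mapFit, grid, policy, subgroup, allowed),
       fallback = TRUE)
}

#' Simulate one dose-escalation trial
#'
#' Conducts a complete trial under the configured design against a true
#' dose-toxicity scenario: cohorts of two (one patient per subgroup while both
#' are active; both from the survivor after a one-sided stop), a model update
#' and dose selection before each cohort, stopping for safety, for the
#' subgroup sample-size cap, or (optionally) for accuracy, and the final
#' frequentist dose recommendation from trial data only.
#'
#' A single root seed drives the trial; patient outcomes and the method-2
#' Markov chains use separate deterministic streams, so a fixed seed gives an
#' identical [TrialResult-class] on re-run.
#'
#' @param config a [TrialConfig-class].
#' @param truth a [ScenarioTruth-class].
#' @param seed integer root seed.
#' @return a [TrialResult-class].
#' @examples
#' cfg <- trialConfig(method = "baseline")
#' sc <- buildScenarios(grid = cfg@grid)
#' res <- runTrial(cfg, sc[[1]], seed = 1L)
#' recommendedDoses(res)
#' @export
runTrial <- function(config, truth, seed) {
  stopifnot(is(config, "TrialConfig"), is(truth, "ScenarioTruth"))
  seed <- as.integer(seed)
  grid <- config@grid; policy <- config@policy
  gridDoses <- grid@doses
  pseudo <- expandPseudoData(
    if (config@method == "baseline") config@pseudoPooled else config@pseudo)
  slab <- if (config@method == "method2")
    deriveSlab(pseudo, grid, config@slabScale,
               config@ssConfig@priorInclusion) else NULL

  cap <- config@maxPatients %/% 2L
  status <- c("0" = "active", "1" = "active")
  n <- c("0" = 0, "1" = 0)
  dlts <- c("0" = 0, "1" = 0)
  maxAdm <- c("0" = NA_real_, "1" = NA_real_)
  staggered <- FALSE
  recDose <- recGrp <- recDlt <- recCoh <- numeric(0)
  logRows <- list()
  cohort <- 0L
  chainCalls <- 0L

  truthProb <- function(dose, g)
    truth@probs[g + 1L, match(dose, gridDoses)]
  curData <- function() {
    if (length(recDose) == 0L) return(pseudo)
    c(pseudo, ToxicityData(recDose, recGrp, recDlt, 1 - recDlt, FALSE))
  }
  active <- function() names(status)[status == "active"]

  set.seed(seed)  # outcome stream

  repeat {
    for (gch in active()) if (n[gch] >= cap) status[gch] <- "max"
    if (length(active()) == 0L) break

    solo <- NA
    oth <- c("0" = "1", "1" = "0")
    if (length(active()) == 1L) {
      g <- active()
      if (status[oth[g]] == "safety") solo <- as.integer(g)
    }
    chainCalls <- chainCalls + 1L
    chainSeed <- as.integer((as.numeric(seed) * 1009 + chainCalls) %%
                            2147483647)
    adv <- adviseNextDoses(curData(), config, soloSubgroup = solo,
                           slab = slab, chainSeed = chainSeed)

    ## safety-stop signals
    for (gch in active()) {
      if (is.na(adv$dose[gch])) {
        status[gch] <- "safety"
        if (config@method == "baseline") status[oth[gch]] <- "safety"
      }
    }
    ## a one-sided safety stop switches the survivor to its own
    ## two-parameter model immediately
    if (length(active()) == 1L && is.na(solo)) {
      g <- active()
      if (status[oth[g]] == "safety") {
        staggered <- TRUE
        adv <- adviseNextDoses(curData(), config,
                               soloSubgroup = as.integer(g))
        if (is.na(adv$dose[g])) status[g] <- "safety"
      }
    }
    if (length(active()) == 0L) break

    if (config@accuracyStop) {
      for (gch in active()) {
        gi <- as.integer(gch)
        if (checkAccuracyStop(curData(), config, gi, adv$dose[gch],
                              adv$fits[[gi + 1L]]))
          status[gch] <- "accuracy"
      }
      if (length(active()) == 0L) break
    }

    ## allocate the next cohort
    cohort <- cohort + 1L
    act <- active()
    alloc <- if (length(act) == 2L) c("0", "1") else
      rep(act, min(config@cohortSize, cap - n[act]))
    for (gch in alloc) {
      gi <- as.integer(gch)
      d <- unname(adv$dose[gch])
      out <- as.numeric(stats::runif(1L) < truthProb(d, gi))
      recDose <- c(recDose, d); recGrp <- c(recGrp, gi)
      recDlt <- c(recDlt, out); recCoh <- c(recCoh, cohort)
      n[gch] <- n[gch] + 1
      dlts[gch] <- dlts[gch] + out
      maxAdm[gch] <- max(maxAdm[gch], d, na.rm = TRUE)
      logRows[[length(logRows) + 1L]] <- data.frame(
        cohort = cohort, subgroup = gi, dose = d, dlt = out,
        spec = paste0(as.integer(adv$spec@beta2), as.integer(adv$spec@beta3)),
        w2 = unname(adv$w["w2"]), w3 = unname(adv$w["w3"]))
    }
  }

  ## ---- final recommendation (frequentist, trial data only) ----
  tr <- if (length(recDose)) ToxicityData(recDose, recGrp, recDlt,
                                          1 - recDlt, FALSE) else
    ToxicityData(numeric(0), integer(0), numeric(0), numeric(0), logical(0))
  full <- curData()
  recommended <- c("0" = NA_real_, "1" = NA_real_)
  fallback <- FALSE
  safety <- status == "safety"

  allowedFor <- function(m) if (is.na(m)) numeric(0) else
    gridDoses[gridDoses <= m]

  finalSpecChoice <- NULL
  if (config@method == "baseline") {
    verdict <- 0L
    if (!any(safety)) {
      r <- .recommendFrom(tr, full, modelSpec(), grid, policy, 0L,
                          allowedFor(max(maxAdm, na.rm = TRUE)))
      recommended[] <- r$dose; fallback <- r$fallback
    }
  } else if (any(safety)) {
    if (all(safety)) {
      verdict <- if (staggered) 2L else 1L
      if (config@method == "method2" && !staggered) {
        chainSeed <- as.integer((as.numeric(seed) * 1009 + chainCalls + 1L) %%
                                2147483647)
        sscfg <- config@ssConfig; sscfg@seed <- chainSeed
        post <- runSpikeSlab(full, slab, grid, sscfg)
        finalSpecChoice <- chooseModel(post, sscfg)
        verdict <- if (finalSpecChoice@beta2 || finalSpecChoice@beta3) 1L
                   else 0L
      }
    } else {
      verdict <- 2L
      g <- as.integer(names(status)[!safety])
      r <- .recommendFrom(subgroupData(tr, g), subgroupData(full, g),
                          modelSpec(), grid, policy, g,
                          allowedFor(maxAdm[as.character(g)]))
      recommended[as.character(g)] <- r$dose; fallback <- r$fallback
    }
  } else {
    if (config@method == "method2") {
      chainSeed <- as.integer((as.numeric(seed) * 1009 + chainCalls + 1L) %%
                              2147483647)
      sscfg <- config@ssConfig; sscfg@seed <- chainSeed
      post <- runSpikeSlab(full, slab, grid, sscfg)
      finalSpecChoice <- chooseModel(post, sscfg)
    }
    pooledFinal <- config@method == "method2" &&
      !finalSpecChoice@beta2 && !finalSpecChoice@beta3
    if (pooledFinal) {
      verdict <- 0L
      r <- .recommendFrom(tr, full, modelSpec(), grid, policy, 0L,
                          allowedFor(max(maxAdm, na.rm = TRUE)))
      recommended[] <- r$dose; fallback <- r$fallback
    } else {
      verdict <- 1L
      for (g in 0:1) {
        r <- .recommendFrom(tr, full, modelSpec(TRUE, TRUE), grid, policy, g,
                            allowedFor(maxAdm[as.character(g)]))
        recommended[as.character(g)] <- r$dose
        fallback <- fallback || r$fallback
      }
    }
  }

  cohortLog <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(cohort = integer(0), subgroup = integer(0), dose = numeric(0),
               dlt = numeric(0), spec = character(0), w2 = numeric(0),
               w3 = numeric(0))

  new("TrialResult", recommended = recommended, verdict = verdict,
      patients = n, dlts = dlts, stopReasons = status,
      cohortLog = cohortLog, fallbackUsed = fallback, seed = seed)
}

#' @describeIn runTrial recommended doses of a result
#' @param object a [TrialResult-class].
#' @export
setMethod("recommendedDoses", "TrialResult",
          function(object) object@recommended)

setMethod("show", "TrialResult", function(object) {
  fmt <- function(x) ifelse(is.na(x), "none", format(x))
  cat("TrialResult:\n")
  cat(sprintf("  recommended: %s (biomarker-) / %s (biomarker+)\n",
              fmt(object@recommended["0"]), fmt(object@recommended["1"])))
  cat(sprintf("  verdict: %d  patients: %g + %g  DLTs: %g + %g\n",
              object@verdict, object@patients["0"], object@patients["1"],
              object@dlts["0"], object@dlts["1"]))
  cat(sprintf("  stopped: %s / %s%s\n", object@stopReasons["0"],
              object@stopReasons["1"],
              if (object@fallbackUsed) "  [MAP fallback used]" else ""))
  invisible(object)
})
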