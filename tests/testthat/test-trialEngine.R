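scenariosTE <- buildScenarios(pooledFit, theGrid)
noTox <- scenarioTruth("no toxicity anywhere",
                       matrix(1e-6, 2, 6), theGrid)

test_that("under a no-DLT path escalation never skips a dose level", {
  for (m in c("baseline", "method1", "method2")) {
    cfg <- trialConfig(method = m,
                       ssConfig = spikeSlabConfig(2000L, 500L))
    res <- runTrial(cfg, noTox, seed = 1L)
    for (g in 0:1) {
      path <- res@cohortLog$dose[res@cohortLog$subgroup == g]
      expect_equal(path[1L], 100)  # the advised start dose
      ## never escalate past an untried dose level
      steps <- match(path, theGrid@doses)
      highest <- cummax(steps)
      expect_true(all(steps[-1L] <= highest[-length(steps)] + 1L),
                  label = paste("no skipped dose under", m))
    }
  }
})

test_that("trials are deterministic given the seed", {
  cfg <- trialConfig(method = "method2",
                     ssConfig = spikeSlabConfig(1500L, 300L))
  r1 <- runTrial(cfg, scenariosTE$scenario3, seed = 77L)
  r2 <- runTrial(cfg, scenariosTE$scenario3, seed = 77L)
  expect_identical(r1@cohortLog, r2@cohortLog)
  expect_identical(r1@recommended, r2@recommended)
  expect_identical(r1@verdict, r2@verdict)
})

test_that("sample-size accounting and dose caps hold on simulated trials", {
  cfg <- trialConfig(method = "method1")
  for (seed in 1:25) {
    sc <- scenariosTE[[1L + seed %% 6L]]
    res <- runTrial(cfg, sc, seed = seed)
    expect_lte(sum(res@patients), cfg@maxPatients)
    expect_true(all(res@patients <= cfg@maxPatients / 2))
    log <- res@cohortLog
    for (g in 0:1) {
      gch <- as.character(g)
      expect_equal(sum(log$subgroup == g), unname(res@patients[gch]))
      ## recommended dose never exceeds the subgroup's max administered dose
      if (!is.na(res@recommended[gch]))
        expect_lte(res@recommended[gch], max(log$dose[log$subgroup == g]))
      ## a stopped subgroup receives no further patients: its last cohort is
      ## no later than the overall last only when it stopped at the end
      if (res@stopReasons[gch] == "safety" && any(log$subgroup == g))
        expect_true(max(log$cohort[log$subgroup == g]) <= max(log$cohort))
    }
    ## verdict 2 requires a safety stop
    if (res@verdict == 2L)
      expect_true(any(res@stopReasons == "safety"))
  }
})

test_that("without early stops the full sample size is used", {
  cfg <- trialConfig(method = "baseline")
  res <- runTrial(cfg, noTox, seed = 3L)
  expect_equal(unname(res@patients), c(30, 30))
  expect_equal(unname(res@stopReasons), c("max", "max"))
  expect_equal(res@verdict, 0L)
})

test_that("an intolerable truth stops both subgroups for safety early", {
  cfg <- trialConfig(method = "method1")
  stops <- vapply(1:10, function(s) {
    res <- runTrial(cfg, scenariosTE$scenario6, seed = s)
    sum(res@patients)
  }, numeric(1L))
  expect_lt(mean(stops), 30)
  res <- runTrial(cfg, scenariosTE$scenario6, seed = 2L)
  expect_true(all(is.na(res@recommended)) ||
              any(res@stopReasons != "safety"))
})

test_that("the accuracy rule needs both the patient count and a tight interval", {
  fit <- fitDoseToxicity(c(thePseudoExpanded,
                           simulateFromModel(c(-7.1, 7.7, 0, 0), 30L)),
                         modelSpec(), theGrid)
  width <- diff(tdInterval(fit, 0.16, 0L, 0.95))
  mkcfg <- function(bound) trialConfig(method = "baseline",
                                       accuracyStop = TRUE,
                                       ciWidthBound = bound)
  advised <- 215
  fewAt <- c(thePseudoExpanded,
             ToxicityData(rep(advised, 4), rep(0L, 4), rep(0, 4), rep(1, 4)))
  manyAt <- c(thePseudoExpanded,
              ToxicityData(rep(advised, 6), rep(0L, 6), rep(0, 6), rep(1, 6)))
  ## 4 patients at the advised dose: never stops, whatever the interval
  expect_false(checkAccuracyStop(fewAt, mkcfg(1e6), 0L, advised, fit))
  ## 6 patients and a bound wider than the interval: stops
  expect_true(checkAccuracyStop(manyAt, mkcfg(width + 1), 0L, advised, fit))
  ## the comparison is strict: a bound equal to the width does not stop
  expect_false(checkAccuracyStop(manyAt, mkcfg(width), 0L, advised, fit))
  ## an undefined interval never stops
  badFit <- fitDoseToxicity(ToxicityData(c(100, 100), c(0L, 0L), c(1, 0),
                                         c(0, 1)), modelSpec(), theGrid)
  expect_false(checkAccuracyStop(manyAt, mkcfg(1e6), 0L, advised, badFit))
})

test_that("accuracy stopping shortens trials and is recorded", {
  ## the TD interval narrows from ~300 to ~70 mg/m2 over a full trial, so a
  ## bound inside that range must trigger stops that the default bound of
  ## 5 mg/m2 (too tight to be reachable at these sample sizes) cannot
  cfg <- trialConfig(method = "method1", accuracyStop = TRUE,
                     ciWidthBound = 90)
  res <- lapply(1:8, function(s) runTrial(cfg, scenariosTE$scenario1,
                                          seed = s))
  n <- vapply(res, function(r) sum(r@patients), numeric(1L))
  cfg0 <- trialConfig(method = "method1")
  n0 <- vapply(1:8, function(s)
    sum(runTrial(cfg0, scenariosTE$scenario1, seed = s)@patients),
    numeric(1L))
  expect_lt(mean(n), mean(n0))
  reasons <- unlist(lapply(res, slot, "stopReasons"))
  expect_true(any(reasons == "accuracy"))
  ## stopped-for-accuracy subgroups still get a final recommendation
  acc <- res[vapply(res, function(r) any(r@stopReasons == "accuracy"),
                    logical(1L))]
  expect_true(all(vapply(acc, function(r)
    any(!is.na(r@recommended)), logical(1L))))
})

test_that("prior-only advice matches the published start dose for all methods", {
  for (m in c("baseline", "method1", "method2")) {
    cfg <- trialConfig(method = m, ssConfig = spikeSlabConfig(3000L, 500L))
    pseudo <- expandPseudoData(
      if (m == "baseline") cfg@pseudoPooled else cfg@pseudo)
    adv <- adviseNextDoses(pseudo, cfg, chainSeed = 1L)
    expect_equal(unname(adv$dose), c(100, 100))
  }
})
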