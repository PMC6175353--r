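scenariosSS <- buildScenarios(pooledFit, theGrid)

test_that("recommendation frequencies normalise over doses plus none", {
  mkres <- function(rec0, rec1) new("TrialResult",
    recommended = c("0" = as.numeric(rec0), "1" = as.numeric(rec1)),
    verdict = 0L,
    patients = c("0" = 30, "1" = 30), dlts = c("0" = 3, "1" = 3),
    stopReasons = c("0" = "max", "1" = "max"),
    cohortLog = data.frame(), fallbackUsed = FALSE, seed = 1L)
  all215 <- replicate(5, mkres(215, 215), simplify = FALSE)
  f <- summariseRecommendations(all215, theGrid)
  expect_equal(unname(f["0", "215"]), 1)
  expect_equal(sum(f["0", ]), 1)
  mixed <- list(mkres(215, NA), mkres(180, 100), mkres(NA, NA), mkres(215, 215))
  f <- summariseRecommendations(mixed, theGrid)
  expect_equal(rowSums(f), c("0" = 1, "1" = 1))
  expect_equal(unname(f["0", "none"]), 0.25)
  expect_equal(unname(f["1", "none"]), 0.5)
})

test_that("a single-replicate study recodes the single trial", {
  cfg <- trialConfig(method = "baseline")
  s <- runStudy(cfg, scenariosSS["scenario1"], nReplicates = 1L,
                rootSeed = 5L)
  r <- runTrial(cfg, scenariosSS$scenario1, seed = 6L)  # rootSeed + 1
  expect_equal(s@summary$avgPatients, sum(r@patients))
  expect_equal(s@summary$avgDltProp, sum(r@dlts) / sum(r@patients))
  expect_equal(s@summary$verdict0 + s@summary$verdict1 + s@summary$verdict2,
               1L)
  rf <- s@recFreq$scenario1
  expect_equal(unname(rf["0", as.character(r@recommended["0"])]), 1)
})

test_that("a study split by seed offset and pooled equals the full study", {
  cfg <- trialConfig(method = "baseline")
  full <- runStudy(cfg, scenariosSS["scenario6"], nReplicates = 20L,
                   rootSeed = 100L)
  h1 <- runStudy(cfg, scenariosSS["scenario6"], nReplicates = 10L,
                 rootSeed = 100L)
  h2 <- runStudy(cfg, scenariosSS["scenario6"], nReplicates = 10L,
                 rootSeed = 110L)
  expect_equal(full@summary$avgPatients,
               (h1@summary$avgPatients + h2@summary$avgPatients) / 2)
  expect_equal(full@summary$verdict0,
               h1@summary$verdict0 + h2@summary$verdict0)
  expect_equal(full@recFreq$scenario6,
               (h1@recFreq$scenario6 + h2@recFreq$scenario6) / 2)
})

test_that("study-level Monte-Carlo noise shrinks with replicate count", {
  ## study-to-study SD of the average sample size should shrink roughly as
  ## 1/sqrt(n); checked on the short-running intolerable scenario
  cfg <- trialConfig(method = "baseline")
  avg <- function(n, base) vapply(1:8, function(k)
    runStudy(cfg, scenariosSS["scenario6"], nReplicates = n,
             rootSeed = base + k * n)@summary$avgPatients, numeric(1L))
  sdSmall <- stats::sd(avg(15L, 1000L))
  sdLarge <- stats::sd(avg(60L, 5000L))
  expect_lt(sdLarge, sdSmall)
})

test_that("tidy export covers every statistic once", {
  cfg <- trialConfig(method = "baseline")
  s <- runStudy(cfg, scenariosSS["scenario6"], nReplicates = 5L,
                rootSeed = 3L)
  td <- tidyStudySummary(s)
  expect_true(all(c("scenario", "statistic", "subgroup", "value") %in%
                  names(td)))
  expect_equal(sum(td$statistic == "avg_patients"), 3L)
  recRows <- td[grepl("^rec_", td$statistic) & td$subgroup == "0", ]
  expect_equal(sum(recRows$value), 1)
})
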