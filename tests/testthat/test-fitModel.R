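test_that("the anchor-trial fits reproduce the published TD16 values", {
  fn <- fitDoseToxicity(subgroupData(theData, 0L), modelSpec(), theGrid)
  fp <- fitDoseToxicity(subgroupData(theData, 1L), modelSpec(), theGrid)
  expect_equal(round(tdEstimate(fn, 0.16)), 244)
  expect_equal(round(tdEstimate(fp, 0.16)), 181)
  expect_equal(round(tdEstimate(pooledFit, 0.16)), 206)
  ## the biomarker-negative data are quasi-separated: flagged, not silent
  expect_true(fn@boundary)
  expect_false(fp@boundary)
  expect_true(pooledFit@converged)
})

test_that("predicted probabilities follow the inverse-logit model", {
  fit0 <- new("DoseToxicityFit",
              coef = c(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0),
              spec = modelSpec(TRUE, TRUE), vcov = diag(4),
              converged = TRUE, boundary = FALSE, identifiable = TRUE,
              grid = theGrid)
  expect_equal(predictProb(fit0, theGrid@doses, 0L), rep(0.5, 6))
  expect_equal(predictProb(fit0, theGrid@doses, 1L), rep(0.5, 6))
  ## without subgroup terms both subgroups share one curve
  expect_equal(predictProb(pooledFit, theGrid@doses, 0L),
               predictProb(pooledFit, theGrid@doses, 1L))
  ## the pooled curve at 215 matches the published 2-dp value
  expect_equal(round(predictProb(pooledFit, 215), 2), 0.18)
  ## monotone in dose for a positive slope
  expect_true(all(diff(predictProb(pooledFit, theGrid@doses)) > 0))
})

test_that("TD estimation inverts the fitted curve", {
  fit <- new("DoseToxicityFit",
             coef = c(beta0 = 0, beta1 = 1, beta2 = NA, beta3 = NA),
             spec = modelSpec(), vcov = diag(2), converged = TRUE,
             boundary = FALSE, identifiable = TRUE, grid = theGrid)
  expect_equal(tdEstimate(fit, 0.5), 0)  # logit(0.5) = 0 at dose 0
  for (g in 0:1) {
    td <- tdEstimate(pooledFit, 0.16, g)
    expect_equal(predictProb(pooledFit, td, g), 0.16, tolerance = 1e-10)
  }
  bad <- new("DoseToxicityFit",
             coef = c(beta0 = 0, beta1 = -1, beta2 = NA, beta3 = NA),
             spec = modelSpec(), vcov = diag(2), converged = TRUE,
             boundary = FALSE, identifiable = TRUE, grid = theGrid)
  expect_error(tdEstimate(bad, 0.16), "slope")
})

test_that("pooled fits ignore subgroup labels", {
  flipped <- theData
  flipped@subgroup <- 1L - flipped@subgroup
  f2 <- fitDoseToxicity(flipped, modelSpec(), theGrid)
  expect_equal(f2@coef, pooledFit@coef, tolerance = 1e-10)
})

test_that("weight linearity: splitting a record in half leaves the fit alone", {
  d <- theData
  half <- ToxicityData(d@dose, d@subgroup, d@dltWeight / 2,
                       d@noDltWeight / 2, d@isPseudo)
  doubled <- c(half, half)
  f2 <- fitDoseToxicity(doubled, modelSpec(), theGrid)
  expect_equal(unname(f2@coef[1:2]), unname(pooledFit@coef[1:2]),
               tolerance = 1e-8)
})

test_that("non-identifiable designs are flagged, never silent", {
  oneDose <- ToxicityData(c(100, 100), c(0L, 0L), c(1, 0), c(1, 2))
  f <- fitDoseToxicity(oneDose, modelSpec(), theGrid)
  expect_false(f@identifiable)
  expect_false(f@converged)
  expect_error(predictProb(f, 100), "identifiable")
})

test_that("dose selection maximises gain subject to the safety criterion", {
  mkfit <- function(b0, b1) new("DoseToxicityFit",
    coef = c(beta0 = b0, beta1 = b1, beta2 = NA, beta3 = NA),
    spec = modelSpec(), vcov = diag(2), converged = TRUE, boundary = FALSE,
    identifiable = TRUE, grid = theGrid)

  ## exact hit: probabilities (0.05, 0.16, 0.30) -> middle dose
  g3 <- DoseGrid(c(50, 100, 150), 100)
  z3 <- standardiseDose(g3@doses, g3)
  cf <- solve(cbind(1, z3[c(1, 3)]), stats::qlogis(c(0.05, 0.30)))
  ## adjust so the middle dose sits exactly on theta
  fitMid <- new("DoseToxicityFit",
    coef = c(beta0 = stats::qlogis(0.16) - cf[2] * z3[2], beta1 = cf[2],
             beta2 = NA, beta3 = NA),
    spec = modelSpec(), vcov = diag(2), converged = TRUE, boundary = FALSE,
    identifiable = TRUE, grid = g3)
  expect_equal(selectDose(fitMid, g3, thePolicy), 100)
  expect_equal(predictProb(fitMid, 100), 0.16, tolerance = 1e-12)
  expect_gt(patientGain(fitMid, 100, thePolicy), 1e12)

  ## everything unsafe -> NA (safety-stop signal)
  hot <- mkfit(2, 1)
  expect_true(all(predictProb(hot, theGrid@doses) >= 0.35))
  expect_true(is.na(selectDose(hot, theGrid, thePolicy)))

  ## brute-force oracle: selection == argmin |p - theta| over safe doses,
  ## ties resolved to the lower dose
  set.seed(42)
  for (i in 1:200) {
    fit <- mkfit(stats::rnorm(1, -4, 2), stats::runif(1, 0.5, 8))
    p <- predictProb(fit, theGrid@doses)
    safe <- p < thePolicy@delta
    expected <- if (!any(safe)) NA_real_ else {
      d <- theGrid@doses[safe]
      crit <- abs(p[safe] - thePolicy@theta)
      d[which(crit == min(crit))[1L]]
    }
    expect_identical(selectDose(fit, theGrid, thePolicy), expected)
  }
  expect_error(selectDose(hot, theGrid, thePolicy, allowed = c(105)),
               "subset")
})

test_that("coefficients are recovered from large simulated samples", {
  beta <- c(-7.1, 7.7, 0.1, 2.5)
  dat <- simulateFromModel(beta, nPer = 5000L, seed = 99L)
  fit <- fitDoseToxicity(dat, modelSpec(TRUE, TRUE), theGrid)
  se <- sqrt(diag(fit@vcov))
  expect_true(all(abs(fit@coef - beta) < 3 * se))
})
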