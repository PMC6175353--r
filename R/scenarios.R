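#' Construct a scenario truth
#'
#' @param label scenario label.
#' @param probs 2 x ndose matrix of true per-subgroup DLT probabilities
#'   (rows: biomarker-negative, biomarker-positive).
#' @param grid a [DoseGrid-class].
#' @param coef optional generating coefficients (beta0..beta3) of the
#'   four-parameter model; when supplied, the tabulated probabilities must
#'   agree with the model evaluation to within 2-dp rounding (0.005).
#' @return a [ScenarioTruth-class].
#' @export
scenarioTruth <- function(label, probs, grid, coef = numeric(0)) {
  dimnames(probs) <- list(c("0", "1"), grid@doses)
  obj <- new("ScenarioTruth", label = label, probs = probs,
             coef = as.numeric(coef), grid = grid)
  if (length(coef) == 4L) {
    z <- standardiseDose(grid@doses, grid)
    for (g in 0:1) {
      p <- stats::plogis(coef[1] + coef[2] * z + g * (coef[3] + coef[4] * z))
      err <- abs(p - probs[g + 1L, ])
      if (any(err > 0.005 + 1e-12))
        stop("tabulated probabilities disagree with the generating model at ",
             "subgroup ", g, ", dose(s) ",
             paste(grid@doses[err > 0.005], collapse = ", "))
    }
  }
  obj
}

## Tabulated target probabilities for the biomarker-positive subgroup in the
## subgroup-effect scenarios and the shared curve of the no-tolerated-dose
## scenario, as published (2 dp).
.scenarioTargets <- function() {
  list(positive = rbind(
         s2 = c(0.02, 0.08, 0.14, 0.26, 0.38, 0.45),
         s3 = c(0.03, 0.13, 0.24, 0.42, 0.58, 0.65),
         s4 = c(0.09, 0.36, 0.60, 0.81, 0.90, 0.93),
         s5 = c(0.42, 0.90, 0.97, 0.99, 1.00, 1.00)),
       intolerable = c(0.38, 0.67, 0.79, 0.88, 0.93, 0.94))
}

## Recover (beta2, beta3) whose four-parameter curve reproduces a printed
## biomarker-positive row to 2 dp: least squares on the logit scale for a
## start, then a minimax polish on the probability scale. Cells printed as
## 1.00 only constrain the fitted value to be >= 0.995.
.solveSubgroupCoef <- function(b0, b1, target, z) {
  interior <- target >= 0.01 & target <= 0.99
  resid <- stats::qlogis(target[interior]) - (b0 + b1 * z[interior])
  start <- stats::coef(stats::lm(resid ~ z[interior]))
  obj <- function(b) {
    p <- stats::plogis(b0 + b1 * z + b[1L] + b[2L] * z)
    err <- abs(p - target)
    hi <- target >= 0.995
    err[hi] <- pmax(0, 0.995 - p[hi])
    max(err)
  }
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = 5000L, reltol = 1e-12))
  unname(o$par)
}

#' Build the six simulation scenarios
#'
#' Scenario truths are generated from the four-parameter dose-toxicity model:
#' \eqn{\beta_0, \beta_1} are the pooled two-parameter fit to the anchor
#' trial data (the no-subgroup-effect curve), and \eqn{\beta_2, \beta_3} are
#' recovered per scenario so that the biomarker-positive curve reproduces the
#' published per-dose probabilities to 2 dp. Scenario 1 has no subgroup
#' effect; scenarios 2--4 shift the positive-subgroup recommended dose down
#' by one to three levels; scenario 5 leaves no tolerated dose in the
#' positive subgroup; scenario 6 (tabulated directly, identical in both
#' subgroups) has no tolerated dose at all.
#'
#' @param pooledFit the pooled two-parameter [DoseToxicityFit-class]
#'   (default: fitted to [nicholsonData()]).
#' @param grid a [DoseGrid-class].
#' @return named list of six [ScenarioTruth-class] objects.
#' @examples
#' sc <- buildScenarios()
#' sc[["scenario1"]]@probs["0", "215"]  # 0.18 to 2 dp
#' @export
buildScenarios <- function(pooledFit = NULL, grid = defaultDoseGrid()) {
  if (is.null(pooledFit))
    pooledFit <- fitDoseToxicity(nicholsonData(), modelSpec(), grid)
  b <- pooledFit@coef
  b0 <- unname(b["beta0"]); b1 <- unname(b["beta1"])
  z <- standardiseDose(grid@doses, grid)
  neg <- stats::plogis(b0 + b1 * z)
  tg <- .scenarioTargets()

  out <- list(scenario1 = scenarioTruth(
    "no subgroup effect", rbind(neg, neg), grid, coef = c(b0, b1, 0, 0)))
  labels <- c("small subgroup effect (one level)",
              "medium subgroup effect (two levels)",
              "medium subgroup effect (three levels)",
              "no safe dose in the positive subgroup")
  for (i in 1:4) {
    target <- tg$positive[i, ]
    b23 <- .solveSubgroupCoef(b0, b1, target, z)
    pos <- stats::plogis(b0 + b1 * z + b23[1L] + b23[2L] * z)
    err <- abs(pos - target)
    err[target >= 0.995] <- pmax(0, 0.995 - pos[target >= 0.995])
    if (any(err > 0.005 + 1e-12))
      stop("scenario ", i + 1L, ": reconstructed curve misses the published ",
           "probabilities at dose(s) ",
           paste(grid@doses[err > 0.005], collapse = ", "))
    out[[paste0("scenario", i + 1L)]] <- scenarioTruth(
      labels[i], rbind(neg, pos), grid, coef = c(b0, b1, b23))
  }
  out$scenario6 <- scenarioTruth("no safe dose in either subgroup",
                                 rbind(tg$intolerable, tg$intolerable), grid)
  out
}

setMethod("show", "ScenarioTruth", function(object) {
  cat("ScenarioTruth:", object@label, "\n")
  print(round(object@probs, 2L))
  invisible(object)
})
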