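#' @import methods
NULL

#' Discrete dose grid with a reference dose
#'
#' The ordered set of doses available for administration in the trial, together
#' with the reference dose \eqn{d^*} used to standardise dose in the
#' dose-toxicity model via \eqn{\log(x/d^* + 1)}.
#'
#' @slot doses strictly increasing positive numeric vector of doses (mg/m2).
#' @slot referenceDose positive scalar, the reference dose \eqn{d^*} (mg/m2).
#'
#' @seealso [DoseGrid()], [standardiseDose()]
#' @export
setClass("DoseGrid",
  representation(doses = "numeric", referenceDose = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@doses) < 1L || anyNA(object@doses))
      msg <- c(msg, "'doses' must be a non-empty numeric vector without NA")
    if (any(object@doses <= 0))
      msg <- c(msg, "all doses must be positive")
    if (is.unsorted(object@doses, strictly = TRUE))
      msg <- c(msg, "doses must be strictly increasing")
    if (length(object@referenceDose) != 1L || is.na(object@referenceDose) ||
        object@referenceDose <= 0)
      msg <- c(msg, "'referenceDose' must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Escalation policy: target and unacceptable toxicity levels
#'
#' @slot theta target probability of dose-limiting toxicity (the TD100theta is
#'   the dose with DLT probability \code{theta}).
#' @slot delta unacceptable DLT probability; only doses with estimated DLT
#'   probability strictly below \code{delta} may be administered.
#'
#' @export
setClass("EscalationPolicy",
  representation(theta = "numeric", delta = "numeric"),
  validity = function(object) {
    if (length(object@theta) != 1L || length(object@delta) != 1L)
      return("'theta' and 'delta' must be scalars")
    if (!(object@theta > 0 && object@theta < object@delta && object@delta < 1))
      return("must have 0 < theta < delta < 1")
    TRUE
  })

#' Dose-toxicity model specification
#'
#' Which subgroup terms enter the logistic dose-toxicity model. The intercept
#' \eqn{\beta_0} and dose slope \eqn{\beta_1} are always included; the subgroup
#' intercept shift \eqn{\beta_2} and subgroup slope shift \eqn{\beta_3} are
#' optional, giving four legal specifications.
#'
#' @slot beta2 logical, include the subgroup intercept term.
#' @slot beta3 logical, include the subgroup slope term.
#'
#' @export
setClass("ModelSpec",
  representation(beta2 = "logical", beta3 = "logical"),
  validity = function(object) {
    if (length(object@beta2) != 1L || length(object@beta3) != 1L ||
        anyNA(c(object@beta2, object@beta3)))
      return("'beta2' and 'beta3' must be single non-NA logicals")
    TRUE
  })

#' Weighted binomial toxicity records
#'
#' Per-record DLT and no-DLT weights at a dose for one subgroup. Fractional
#' weights are permitted (the pseudo-data prior is expressed as fractions of
#' patients); records flagged \code{isPseudo} carry the prior and are excluded
#' from the trial-data-only view used for final dose recommendations.
#'
#' @slot dose numeric, dose administered (mg/m2).
#' @slot subgroup integer 0/1, biomarker-negative / biomarker-positive.
#' @slot dltWeight nonnegative numeric, (fractional) number of DLTs.
#' @slot noDltWeight nonnegative numeric, (fractional) number without DLT.
#' @slot isPseudo logical, prior pseudo-data flag.
#'
#' @seealso [ToxicityData()], [trialData()], [readToxicityData()]
#' @export
setClass("ToxicityData",
  representation(dose = "numeric", subgroup = "integer",
                 dltWeight = "numeric", noDltWeight = "numeric",
                 isPseudo = "logical"),
  validity = function(object) {
    n <- length(object@dose)
    msg <- character()
    if (any(lengths(list(object@subgroup, object@dltWeight,
                         object@noDltWeight, object@isPseudo)) != n))
      msg <- c(msg, "all slots must have equal length")
    else {
      if (any(object@dose <= 0)) msg <- c(msg, "doses must be positive")
      if (!all(object@subgroup %in% c(0L, 1L)))
        msg <- c(msg, "subgroup must be 0 or 1")
      if (any(object@dltWeight < 0) || any(object@noDltWeight < 0))
        msg <- c(msg, "weights must be nonnegative")
      if (n > 0 && any(object@dltWeight + object@noDltWeight <= 0))
        msg <- c(msg, "each record needs dltWeight + noDltWeight > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Pseudo-data prior specification
#'
#' The prior on the dose-toxicity model parameters, expressed as a prior
#' proportion of DLTs among a (possibly fractional) number of pseudo-patients
#' at two prior doses per subgroup.
#'
#' @slot subgroup integer 0/1 per row.
#' @slot dose prior dose (mg/m2) per row.
#' @slot proportion prior proportion of DLTs at that dose, in [0, 1].
#' @slot weight positive number of pseudo-patients carrying that proportion.
#'
#' @seealso [pseudoDataSpec()], [expandPseudoData()], [defaultPseudoData()]
#' @export
setClass("PseudoDataSpec",
  representation(subgroup = "integer", dose = "numeric",
                 proportion = "numeric", weight = "numeric"),
  validity = function(object) {
    n <- length(object@dose)
    msg <- character()
    if (any(lengths(list(object@subgroup, object@proportion,
                         object@weight)) != n))
      msg <- c(msg, "all slots must have equal length")
    else {
      if (!all(object@subgroup %in% c(0L, 1L)))
        msg <- c(msg, "subgroup must be 0 or 1")
      if (any(object@proportion < 0 | object@proportion > 1))
        msg <- c(msg, "proportions must lie in [0, 1]")
      if (any(object@weight <= 0)) msg <- c(msg, "weights must be positive")
      for (g in unique(object@subgroup)) {
        if (length(unique(object@dose[object@subgroup == g])) != 2L)
          msg <- c(msg, sprintf("subgroup %d needs exactly two prior doses", g))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Fitted logistic dose-toxicity model
#'
#' Maximum-likelihood (equivalently, MAP when pseudo-data are included) fit of
#' the two- to four-parameter logistic dose-toxicity model. Coefficients of
#' terms excluded by the [ModelSpec-class] are \code{NA} and treated as zero in
#' prediction.
#'
#' @slot coef named numeric length 4 (beta0, beta1, beta2, beta3); NA = excluded.
#' @slot spec the [ModelSpec-class] fitted.
#' @slot vcov observed-information covariance of the active coefficients.
#' @slot converged logical, optimiser convergence.
#' @slot boundary logical, separation / fitted probabilities at 0 or 1.
#' @slot identifiable logical, design matrix of full column rank.
#' @slot grid the [DoseGrid-class] providing the dose standardisation.
#'
#' @seealso [fitDoseToxicity()], [predictProb()], [tdEstimate()]
#' @export
setClass("DoseToxicityFit",
  representation(coef = "numeric", spec = "ModelSpec", vcov = "matrix",
                 converged = "logical", boundary = "logical",
                 identifiable = "logical", grid = "DoseGrid"))

#' Slab component of the spike-and-slab prior
#'
#' Normal slab over the four dose-toxicity coefficients, derived from the
#' four-parameter fit to the pseudo-data alone, together with the prior
#' inclusion probabilities of the subgroup terms (the spike weights).
#'
#' @slot mean numeric length 4, slab means for (beta0, beta1, beta2, beta3).
#' @slot cov 4x4 symmetric positive-definite slab covariance.
#' @slot spikeWeights numeric length 2, prior inclusion probabilities
#'   (w2, w3) of the subgroup terms; beta0 and beta1 are implicitly always in.
#'
#' @seealso [deriveSlab()]
#' @export
setClass("SlabPrior",
  representation(mean = "numeric", cov = "matrix", spikeWeights = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mean) != 4L) msg <- c(msg, "'mean' must have length 4")
    if (!all(dim(object@cov) == c(4L, 4L)))
      msg <- c(msg, "'cov' must be 4x4")
    else {
      if (max(abs(object@cov - t(object@cov))) > 1e-8)
        msg <- c(msg, "'cov' must be symmetric")
      ev <- tryCatch(eigen(object@cov, symmetric = TRUE,
                           only.values = TRUE)$values, error = function(e) -1)
      if (min(ev) <= 0) msg <- c(msg, "'cov' must be positive definite")
    }
    if (length(object@spikeWeights) != 2L ||
        any(object@spikeWeights < 0 | object@spikeWeights > 1))
      msg <- c(msg, "'spikeWeights' must be two probabilities")
    if (length(msg)) msg else TRUE
  })

#' MCMC settings for spike-and-slab variable selection
#'
#' @slot nIterations total Markov chain length.
#' @slot burnIn iterations discarded before computing inclusion probabilities.
#' @slot priorInclusion prior inclusion probabilities (w2, w3).
#' @slot inclusionBound threshold: a subgroup term enters the escalation model
#'   when its posterior inclusion probability strictly exceeds this bound.
#' @slot seed integer RNG seed, or NA to use the current RNG state.
#'
#' @seealso [spikeSlabConfig()], [runSpikeSlab()], [chooseModel()]
#' @export
setClass("SpikeSlabConfig",
  representation(nIterations = "integer", burnIn = "integer",
                 priorInclusion = "numeric", inclusionBound = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
    if (object@burnIn < 0L || object@burnIn >= object@nIterations)
      msg <- c(msg, "need 0 <= burnIn < nIterations")
    if (length(object@priorInclusion) != 2L ||
        any(object@priorInclusion < 0 | object@priorInclusion > 1))
      msg <- c(msg, "'priorInclusion' must be two probabilities")
    if (length(object@inclusionBound) != 1L || object@inclusionBound <= 0 ||
        object@inclusionBound >= 1)
      msg <- c(msg, "'inclusionBound' must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Posterior draws from the spike-and-slab dose-toxicity model
#'
#' Retained MCMC draws of the coefficients and inclusion indicators, with the
#' marginal posterior inclusion probabilities of the subgroup terms. Draws with
#' indicator zero carry coefficient exactly zero (Dirac spike).
#'
#' @slot draws matrix with columns beta0..beta3, gamma2, gamma3 (retained
#'   iterations only).
#' @slot inclusionProb named numeric (w2, w3), fraction of retained draws with
#'   the corresponding indicator equal to 1.
#' @slot config the [SpikeSlabConfig-class] used.
#'
#' @seealso [runSpikeSlab()], [inclusionProb()]
#' @export
setClass("SpikeSlabPosterior",
  representation(draws = "matrix", inclusionProb = "numeric",
                 config = "SpikeSlabConfig"))

#' True dose-toxicity curves for a simulation scenario
#'
#' Per-subgroup true DLT probabilities at each grid dose, optionally backed by
#' generating coefficients of the four-parameter model.
#'
#' @slot label scenario label.
#' @slot probs 2 x ndose matrix of true DLT probabilities, rows "0" and "1".
#' @slot coef generating coefficients (length 4) or numeric(0) when the truth
#'   is tabulated directly.
#' @slot grid the [DoseGrid-class].
#'
#' @seealso [buildScenarios()], [scenarioTruth()]
#' @export
setClass("ScenarioTruth",
  representation(label = "character", probs = "matrix", coef = "numeric",
                 grid = "DoseGrid"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@probs) != 2L ||
        ncol(object@probs) != length(object@grid@doses))
      msg <- c(msg, "'probs' must be 2 x ndose")
    if (any(object@probs < 0 | object@probs > 1))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(apply(object@probs, 1L, is.unsorted)))
      msg <- c(msg, "probabilities must be nondecreasing in dose")
    if (!length(object@coef) %in% c(0L, 4L))
      msg <- c(msg, "'coef' must have length 0 or 4")
    if (length(msg)) msg else TRUE
  })

#' Full configuration of a dose-escalation trial
#'
#' @slot grid available doses and reference dose.
#' @slot policy target and unacceptable toxicity probabilities.
#' @slot pseudo per-subgroup pseudo-data prior specification (methods 1, 2).
#' @slot pseudoPooled pooled-population pseudo-data prior used by the
#'   baseline design.
#' @slot method escalation design: "baseline" (pooled two-parameter model),
#'   "method1" (four-parameter subgroup model throughout), or "method2"
#'   (spike-and-slab variable selection each update).
#' @slot cohortSize patients per cohort (2: one per subgroup while both are
#'   active, both from the survivor after a one-sided stop).
#' @slot maxPatients overall cap; each subgroup is capped at half of it.
#' @slot accuracyStop enable the accuracy stopping rule.
#' @slot minAtDose minimum patients of the subgroup at the advised dose before
#'   accuracy stopping can trigger.
#' @slot ciLevel level of the interval used by the accuracy rule.
#' @slot ciWidthBound the interval for the TD100theta estimate (mg/m2 scale)
#'   must be strictly narrower than this for an accuracy stop.
#' @slot ssConfig spike-and-slab MCMC settings (method2 only).
#' @slot slabScale multiplier on the pseudo-data-fit covariance when deriving
#'   the slab.
#'
#' @seealso [trialConfig()], [runTrial()]
#' @export
setClass("TrialConfig",
  representation(grid = "DoseGrid", policy = "EscalationPolicy",
                 pseudo = "PseudoDataSpec", pseudoPooled = "PseudoDataSpec",
                 method = "character",
                 cohortSize = "integer", maxPatients = "integer",
                 accuracyStop = "logical", minAtDose = "integer",
                 ciLevel = "numeric", ciWidthBound = "numeric",
                 ssConfig = "SpikeSlabConfig", slabScale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("baseline", "method1", "method2"))
      msg <- c(msg, "method must be baseline, method1 or method2")
    if (object@maxPatients < 2L || object@maxPatients %% 2L != 0L)
      msg <- c(msg, "maxPatients must be an even number >= 2")
    if (object@cohortSize != 2L)
      msg <- c(msg, "only cohorts of size 2 (one patient per subgroup) are supported")
    if (length(msg)) msg else TRUE
  })

#' Result of one simulated (or conducted) trial
#'
#' @slot recommended named numeric length 2 ("0", "1"): recommended dose per
#'   subgroup, NA when no dose is declared.
#' @slot verdict integer: 0 no subgroup effect, 1 significant subgroup effect,
#'   2 defaulted to a subgroup effect after a one-sided safety stop.
#' @slot patients named numeric length 2, patients treated per subgroup.
#' @slot dlts named numeric length 2, DLTs observed per subgroup.
#' @slot stopReasons named character length 2: "safety", "max" or "accuracy".
#' @slot cohortLog data.frame of per-patient allocations and per-cohort model
#'   choices (cohort, subgroup, dose, dlt, spec, w2, w3).
#' @slot fallbackUsed logical: the final frequentist fit was degenerate and the
#'   MAP fallback produced the recommendation.
#' @slot seed the root seed used.
#'
#' @seealso [runTrial()], [recommendedDoses()]
#' @export
setClass("TrialResult",
  representation(recommended = "numeric", verdict = "integer",
                 patients = "numeric", dlts = "numeric",
                 stopReasons = "character", cohortLog = "data.frame",
                 fallbackUsed = "logical", seed = "integer"))

#' Aggregated operating characteristics across simulated trials
#'
#' @slot summary data.frame, one row per scenario: average patients and DLT
#'   proportions (overall and per subgroup), verdict counts, fallback count.
#' @slot recFreq list (one element per scenario) of 2 x (ndose + 1) matrices of
#'   recommendation frequencies per subgroup; first column "none".
#' @slot stopReasons list per scenario of 2 x 3 matrices (safety, max,
#'   accuracy) of per-subgroup stop-reason proportions.
#' @slot method escalation method simulated.
#' @slot nReplicates replicates per scenario.
#' @slot rootSeed root seed (replicate r uses rootSeed + r).
#'
#' @seealso [runStudy()]
#' @export
setClass("StudySummary",
  representation(summary = "data.frame", recFreq = "list",
                 stopReasons = "list", method = "character",
                 nReplicates = "integer", rootSeed = "integer"))
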