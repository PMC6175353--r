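#' Doses of a grid-bearing object
#' @param object a [DoseGrid-class] or object containing one.
#' @return numeric vector of doses (mg/m2).
#' @export
setGeneric("doses", function(object) standardGeneric("doses"))

#' Reference dose of a grid-bearing object
#' @param object a [DoseGrid-class] or object containing one.
#' @return the reference dose (mg/m2).
#' @export
setGeneric("referenceDose", function(object) standardGeneric("referenceDose"))

#' Fitted DLT probability
#'
#' Inverse-logit of the linear predictor of a fitted dose-toxicity model, with
#' the subgroup terms applied only for biomarker-positive patients and only
#' when included in the fitted specification.
#'
#' @param fit a [DoseToxicityFit-class].
#' @param x dose(s) in mg/m2 (vectorised).
#' @param subgroup 0 or 1.
#' @return fitted DLT probabilities in (0, 1).
#' @export
setGeneric("predictProb",
           function(fit, x, subgroup = 0L) standardGeneric("predictProb"))

#' Estimated TD100theta
#'
#' The continuous dose with fitted DLT probability \code{theta}, obtained by
#' inverting the logit analytically:
#' \eqn{x = d^* (\exp[(\mathrm{logit}\,\theta - a)/s] - 1)} where \eqn{a} and
#' \eqn{s} are the subgroup-specific intercept and slope.
#'
#' @param fit a [DoseToxicityFit-class].
#' @param theta target DLT probability.
#' @param subgroup 0 or 1.
#' @return dose in mg/m2 (full precision; round for reporting).
#' @export
setGeneric("tdEstimate",
           function(fit, theta, subgroup = 0L) standardGeneric("tdEstimate"))

#' Posterior inclusion probabilities of the subgroup terms
#' @param object a [SpikeSlabPosterior-class].
#' @return named numeric (w2, w3).
#' @export
setGeneric("inclusionProb", function(object) standardGeneric("inclusionProb"))

#' Recommended dose(s) of a trial result
#' @param object a [TrialResult-class].
#' @return named numeric length 2 ("0", "1"); NA means no dose declared.
#' @export
setGeneric("recommendedDoses",
           function(object) standardGeneric("recommendedDoses"))
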