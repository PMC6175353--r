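#' Construct a pseudo-data prior specification
#'
#' The prior on the dose-toxicity model is encoded as a prior proportion of
#' DLTs among a (fractional) number of pseudo-patients at two prior doses per
#' subgroup, typically weighted to a tenth of the planned subgroup sample
#' size. Incorporated into the model like trial data, the MAP estimate equals
#' the weighted MLE on the augmented dataset.
#'
#' @param subgroup 0/1 per row.
#' @param dose prior dose (mg/m2) per row; two distinct doses per subgroup.
#' @param proportion prior proportion of DLTs at that dose, in [0, 1].
#' @param weight positive pseudo-patient weight per row.
#' @return a [PseudoDataSpec-class].
#' @export
pseudoDataSpec <- function(subgroup, dose, proportion, weight) {
  new("PseudoDataSpec", subgroup = as.integer(subgroup),
      dose = as.numeric(dose), proportion = as.numeric(proportion),
      weight = as.numeric(weight))
}

#' The default prior of the simulation study
#'
#' Two pseudo-patients at 100 mg/m2 with DLT proportion 1/6 and one at
#' 260 mg/m2 with proportion 1/2, identically in both subgroups: three
#' patients' worth of prior per subgroup, a tenth of the planned 30. Under
#' this prior the escalation rule advises a 100 mg/m2 start dose.
#'
#' @return a [PseudoDataSpec-class] read from the packaged fixture.
#' @export
defaultPseudoData <- function() {
  df <- utils::read.csv(system.file("extdata", "prior_pseudo.csv",
                                    package = "doseslab", mustWork = TRUE))
  pseudoDataSpec(df$subgroup, df$dose, df$proportion, df$weight)
}

#' @describeIn defaultPseudoData the pooled-population prior used by the
#'   baseline design: four pseudo-patients at 100 mg/m2 with DLT proportion
#'   1/6 and two at 260 mg/m2 with proportion 1 (six patients' worth, a tenth
#'   of the planned 60). The top-dose proportion is elicited at the boundary,
#'   which is permitted in data expansion (the record simply has no no-DLT
#'   weight).
#' @export
defaultPooledPseudoData <- function() {
  df <- utils::read.csv(system.file("extdata", "prior_pseudo_pooled.csv",
                                    package = "doseslab", mustWork = TRUE))
  pseudoDataSpec(df$subgroup, df$dose, df$proportion, df$weight)
}

#' Expand a pseudo-data specification into weighted records
#'
#' Each (dose, proportion p, weight n) row becomes a toxicity record with
#' \code{dltWeight = n p} and \code{noDltWeight = n (1 - p)}, flagged as
#' pseudo-data. E.g. two pseudo-patients at DLT proportion 1/6 expand to 1/3
#' of a patient with a toxicity and 5/3 without.
#'
#' @param spec a [PseudoDataSpec-class].
#' @return a [ToxicityData-class] of pseudo records.
#' @export
expandPseudoData <- function(spec) {
  stopifnot(is(spec, "PseudoDataSpec"))
  ToxicityData(spec@dose, spec@subgroup,
               dltWeight = spec@weight * spec@proportion,
               noDltWeight = spec@weight * (1 - spec@proportion),
               isPseudo = TRUE)
}

#' Derive the slab component of the spike-and-slab prior
#'
#' Fits the four-parameter dose-toxicity model to the pseudo-data alone; the
#' coefficient estimates become the slab means and \code{slabScale} times the
#' inverse observed information becomes the slab covariance, so by default the
#' slab carries exactly the pseudo-data prior's strength. The spike weights
#' (prior inclusion probabilities of the subgroup terms) are attached from
#' configuration.
#'
#' @param pseudo a [ToxicityData-class] of pseudo records (see
#'   [expandPseudoData()]), or a [PseudoDataSpec-class].
#' @param grid a [DoseGrid-class].
#' @param slabScale positive multiplier on the covariance (default 1).
#' @param priorInclusion prior inclusion probabilities (w2, w3).
#' @return a [SlabPrior-class].
#' @export
deriveSlab <- function(pseudo, grid, slabScale = 1,
                       priorInclusion = c(0.5, 0.5)) {
  if (is(pseudo, "PseudoDataSpec")) pseudo <- expandPseudoData(pseudo)
  stopifnot(is(pseudo, "ToxicityData"), slabScale > 0)
  fit <- fitDoseToxicity(pseudo, modelSpec(TRUE, TRUE), grid)
  if (!fit@identifiable) {
    ## name the deficient term(s) for the error message
    bad <- character()
    if (!any(pseudo@subgroup == 1L)) bad <- c(bad, "beta2", "beta3")
    else {
      for (g in 0:1)
        if (length(unique(pseudo@dose[pseudo@subgroup == g])) < 2L)
          bad <- c(bad, if (g == 0L) "beta1" else "beta3")
    }
    if (!length(bad)) bad <- "beta2/beta3"
    stop("pseudo-data do not identify: ", paste(unique(bad), collapse = ", "),
         " (need two doses in each subgroup)")
  }
  if (anyNA(fit@vcov)) stop("singular information in the pseudo-data fit")
  new("SlabPrior", mean = unname(fit@coef), cov = slabScale * unname(fit@vcov),
      spikeWeights = priorInclusion)
}

#' Prior-only advised start dose
#'
#' The dose the escalation rule advises before any patient is treated: the
#' gain-maximising safe dose under the pooled two-parameter fit to the
#' pseudo-data alone.
#'
#' @param pseudo a [PseudoDataSpec-class] or expanded [ToxicityData-class].
#' @param grid a [DoseGrid-class].
#' @param policy an [EscalationPolicy-class].
#' @return a dose (mg/m2), or \code{NA} if no grid dose is safe under the
#'   prior.
#' @export
priorAdvisedStartDose <- function(pseudo, grid, policy) {
  if (is(pseudo, "PseudoDataSpec")) pseudo <- expandPseudoData(pseudo)
  fit <- fitDoseToxicity(pseudo, modelSpec(), grid)
  selectDose(fit, grid, policy)
}

setMethod("show", "PseudoDataSpec", function(object) {
  cat("PseudoDataSpec:\n")
  print(data.frame(subgroup = object@subgroup, dose = object@dose,
                   proportion = object@proportion, weight = object@weight))
  invisible(object)
})

setMethod("show", "SlabPrior", function(object) {
  cat("SlabPrior: mean =", sprintf("%.4g", object@mean), "\n")
  cat("  prior inclusion (w2, w3) =",
      paste(object@spikeWeights, collapse = ", "), "\n")
  invisible(object)
})
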