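#' Construct spike-and-slab MCMC settings
#'
#' @param nIterations total chain length (default 20000).
#' @param burnIn discarded iterations (default 5000).
#' @param priorInclusion prior inclusion probabilities (w2, w3), default
#'   (0.5, 0.5): a relatively non-informative belief that one of the two
#'   subgroup predictors is significant.
#' @param inclusionBound threshold on the posterior inclusion probability for
#'   a term to enter the escalation model (default 0.25; strict inequality).
#' @param seed integer RNG seed, or NA to sample from the current RNG state.
#' @return a [SpikeSlabConfig-class].
#' @export
spikeSlabConfig <- function(nIterations = 20000L, burnIn = 5000L,
                            priorInclusion = c(0.5, 0.5),
                            inclusionBound = 0.25, seed = NA_integer_) {
  new("SpikeSlabConfig", nIterations = as.integer(nIterations),
      burnIn = as.integer(burnIn), priorInclusion = as.numeric(priorInclusion),
      inclusionBound = inclusionBound, seed = as.integer(seed))
}

## Aggregate records to (dose, subgroup) support points: the binomial
## likelihood only depends on the summed weights, and the Polya-Gamma
## augmentation cost is linear in the number of rows.
.aggregateRecords <- function(data) {
  key <- paste(data@dose, data@subgroup)
  idx <- !duplicated(key)
  agg <- function(w) as.numeric(tapply(w, key, sum)[key[idx]])
  list(dose = data@dose[idx], s = as.numeric(data@subgroup[idx]),
       dlt = agg(data@dltWeight), nodlt = agg(data@noDltWeight))
}

#' Run the spike-and-slab Markov chain
#'
#' Samples the posterior of the four-parameter logistic dose-toxicity model
#' under Dirac-spike / normal-slab priors on the subgroup terms, by
#' Polya-Gamma data augmentation with Gibbs updates: conditional on the
#' augmentation the likelihood is Gaussian, so each inclusion indicator is
#' updated from its closed-form marginal-likelihood ratio (coefficients
#' integrated out) and the active coefficients from their Gaussian full
#' conditional. Fractional binomial weights enter as non-integer Polya-Gamma
#' shape parameters. The chain starts at the slab mean with both subgroup
#' terms included.
#'
#' @param data a [ToxicityData-class] (pseudo-data plus any observed
#'   patients).
#' @param slab a [SlabPrior-class].
#' @param grid a [DoseGrid-class].
#' @param config a [SpikeSlabConfig-class]; its \code{priorInclusion}
#'   overrides the slab's spike weights when not NA.
#' @return a [SpikeSlabPosterior-class].
#' @examples
#' grid <- DoseGrid(c(100, 150, 180, 215, 245, 260), 200)
#' pseudo <- expandPseudoData(defaultPseudoData())
#' slab <- deriveSlab(pseudo, grid)
#' post <- runSpikeSlab(pseudo, slab, grid,
#'                      spikeSlabConfig(2000L, 500L, seed = 1L))
#' inclusionProb(post)
#' @export
runSpikeSlab <- function(data, slab, grid, config = spikeSlabConfig()) {
  stopifnot(is(data, "ToxicityData") || length(data) == 0L,
            is(slab, "SlabPrior"), is(grid, "DoseGrid"),
            is(config, "SpikeSlabConfig"))
  w <- config@priorInclusion
  if (anyNA(w)) w <- slab@spikeWeights

  if (length(data) > 0L) {
    a <- .aggregateRecords(data)
    z <- standardiseDose(a$dose, grid)
    X <- cbind(1, z, a$s, a$s * z)
    ntr <- a$dlt + a$nodlt
    kappa <- a$dlt - ntr / 2
  } else {
    X <- matrix(numeric(0), 0L, 4L)
    ntr <- kappa <- numeric(0)
  }

  runChain <- function() {
    .spikeSlabChainCpp(X, kappa, ntr, slab@mean, slab@cov, w[1L], w[2L],
                       config@nIterations, config@burnIn)
  }
  draws <- if (is.na(config@seed)) runChain() else
    .withSeed(config@seed, runChain())
  colnames(draws) <- c("beta0", "beta1", "beta2", "beta3", "gamma2", "gamma3")

  new("SpikeSlabPosterior", draws = draws,
      inclusionProb = c(w2 = mean(draws[, "gamma2"]),
                        w3 = mean(draws[, "gamma3"])),
      config = config)
}

## evaluate expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  hasState <- exists(".Random.seed", envir = globalenv())
  if (hasState) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (hasState) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' @describeIn runSpikeSlab marginal posterior inclusion probabilities
#' @param object a [SpikeSlabPosterior-class].
#' @export
setMethod("inclusionProb", "SpikeSlabPosterior",
          function(object) object@inclusionProb)

#' Choose the escalation model from posterior inclusion probabilities
#'
#' A subgroup term is non-zero in the fitted escalation model exactly when its
#' posterior inclusion probability strictly exceeds the prespecified bound
#' (ties at the bound exclude). The intercept and dose slope are always
#' included.
#'
#' @param posterior a [SpikeSlabPosterior-class].
#' @param config a [SpikeSlabConfig-class] supplying the bound (defaults to
#'   the posterior's own config).
#' @return a [ModelSpec-class].
#' @export
chooseModel <- function(posterior, config = posterior@config) {
  wb <- config@inclusionBound
  w <- posterior@inclusionProb
  modelSpec(beta2 = unname(w["w2"] > wb), beta3 = unname(w["w3"] > wb))
}

setMethod("show", "SpikeSlabPosterior", function(object) {
  cat(sprintf(
    "SpikeSlabPosterior: %d retained draws; inclusion w2 = %.3f, w3 = %.3f\n",
    nrow(object@draws), object@inclusionProb["w2"],
    object@inclusionProb["w3"]))
  invisible(object)
})

#' Plain-text MCMC diagnostics report
#'
#' Posterior summaries and switch rates of the inclusion indicators, for
#' convergence checking.
#'
#' @param posterior a [SpikeSlabPosterior-class].
#' @param file optional path; when given the report is written there.
#' @return the report lines, invisibly.
#' @export
spikeSlabDiagnostics <- function(posterior, file = NULL) {
  d <- posterior@draws
  qs <- t(apply(d[, 1:4, drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.5, 0.975)))
  switchRate <- function(g) if (nrow(d) < 2L) 0 else mean(diff(g) != 0)
  lines <- c(
    sprintf("retained draws: %d", nrow(d)),
    sprintf("inclusion: w2 = %.4f, w3 = %.4f",
            posterior@inclusionProb["w2"], posterior@inclusionProb["w3"]),
    sprintf("indicator switch rates: gamma2 = %.3f, gamma3 = %.3f",
            switchRate(d[, "gamma2"]), switchRate(d[, "gamma3"])),
    "coefficient quantiles (2.5%, 50%, 97.5%):",
    utils::capture.output(print(round(qs, 4L))))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
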