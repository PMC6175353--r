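## shared fixtures: the published trial grid, policy and priors
theGrid <- defaultDoseGrid()
thePolicy <- escalationPolicy(theta = 0.16, delta = 0.35)
theData <- nicholsonData()
thePseudo <- defaultPseudoData()
thePseudoExpanded <- expandPseudoData(thePseudo)

## Eq.-style reference curves used in several files
pooledFit <- fitDoseToxicity(theData, modelSpec(), theGrid)

## small helper: aggregated binomial data simulated from the four-parameter
## model with known coefficients, nPer patients per subgroup spread evenly
## over the grid
simulateFromModel <- function(beta, nPer, grid = theGrid, seed = 1L) {
  set.seed(seed)
  z <- standardiseDose(grid@doses, grid)
  nDose <- length(grid@doses)
  per <- rep(floor(nPer / nDose), nDose)
  per[seq_len(nPer - sum(per))] <- per[seq_len(nPer - sum(per))] + 1L
  rows <- list()
  for (g in 0:1) {
    p <- stats::plogis(beta[1] + beta[2] * z + g * (beta[3] + beta[4] * z))
    dlt <- stats::rbinom(nDose, per, p)
    rows[[g + 1L]] <- ToxicityData(grid@doses, rep(g, nDose), dlt, per - dlt)
  }
  c(rows[[1L]], rows[[2L]])
}
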