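#' Construct a dose grid
#'
#' @param doses strictly increasing positive doses (mg/m2).
#' @param referenceDose the reference dose \eqn{d^*} used in the
#'   \eqn{\log(x/d^*+1)} standardisation.
#' @return a [DoseGrid-class].
#' @examples
#' grid <- DoseGrid(c(100, 150, 180, 215, 245, 260), referenceDose = 200)
#' standardiseDose(200, grid)  # log(2)
#' @export
DoseGrid <- function(doses, referenceDose) {
  new("DoseGrid", doses = as.numeric(doses),
      referenceDose = as.numeric(referenceDose))
}

#' Standardised dose
#'
#' The transformed, standardised dose \eqn{\log(x/d^* + 1)} entering the
#' logistic dose-toxicity model. Strictly increasing in \code{x} and zero at a
#' zero dose, so the model intercept is interpretable as the log-odds of
#' toxicity at dose zero.
#'
#' @param x dose(s), nonnegative (mg/m2).
#' @param grid a [DoseGrid-class].
#' @return numeric vector of standardised doses.
#' @export
standardiseDose <- function(x, grid) {
  stopifnot(is(grid, "DoseGrid"))
  if (any(x < 0)) stop("doses must be nonnegative")
  log(x / grid@referenceDose + 1)
}

#' @describeIn DoseGrid doses of the grid
#' @param object a [DoseGrid-class].
#' @export
setMethod("doses", "DoseGrid", function(object) object@doses)

#' @describeIn DoseGrid reference dose of the grid
#' @export
setMethod("referenceDose", "DoseGrid", function(object) object@referenceDose)

setMethod("show", "DoseGrid", function(object) {
  cat("DoseGrid:", paste(object@doses, collapse = ", "),
      "mg/m2 (reference", object@referenceDose, "mg/m2)\n")
  invisible(object)
})

#' Construct an escalation policy
#'
#' @param theta target DLT probability (the TD100theta target).
#' @param delta unacceptable DLT probability (safety criterion
#'   \eqn{\hat\pi(d) < \delta}).
#' @return an [EscalationPolicy-class].
#' @export
escalationPolicy <- function(theta = 0.16, delta = 0.35) {
  new("EscalationPolicy", theta = theta, delta = delta)
}

setMethod("show", "EscalationPolicy", function(object) {
  cat(sprintf("EscalationPolicy: theta = %.3g, delta = %.3g\n",
              object@theta, object@delta))
  invisible(object)
})

#' Construct a model specification
#'
#' @param beta2 include the subgroup intercept shift.
#' @param beta3 include the subgroup slope shift.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(beta2 = FALSE, beta3 = FALSE) {
  new("ModelSpec", beta2 = beta2, beta3 = beta3)
}

setMethod("show", "ModelSpec", function(object) {
  terms <- c("beta0", "beta1",
             if (object@beta2) "beta2", if (object@beta3) "beta3")
  cat("ModelSpec:", paste(terms, collapse = " + "), "\n")
  invisible(object)
})
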