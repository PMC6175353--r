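## Internal: two-row-per-record weighted coding of a ToxicityData and the
## design matrix of the requested specification. The logistic likelihood with
## fractional DLT / no-DLT weights is exactly the weighted Bernoulli likelihood
## of this coding, so a standard binomial GLM fit maximises it; with the
## pseudo-data included the MLE is the MAP estimate under the pseudo-data prior.
.designMatrix <- function(z, s, spec) {
  X <- cbind(beta0 = 1, beta1 = z)
  if (spec@beta2) X <- cbind(X, beta2 = s)
  if (spec@beta3) X <- cbind(X, beta3 = s * z)
  X
}

.expandRows <- function(data) {
  y <- rep(c(1, 0), each = length(data@dose))
  w <- c(data@dltWeight, data@noDltWeight)
  keep <- w > 0
  list(y = y[keep], w = w[keep],
       dose = rep(data@dose, 2L)[keep],
       s = as.numeric(rep(data@subgroup, 2L))[keep])
}

#' Fit the logistic dose-toxicity model
#'
#' Weighted maximum-likelihood fit of the two- to four-parameter logistic
#' dose-toxicity model
#' \deqn{\mathrm{logit}\,\pi(d) = \beta_0 + \beta_1 \log(x/d^*+1) +
#'   I^+\{\beta_2 + \beta_3 \log(x/d^*+1)\}}
#' to a weighted binomial dataset. Fractional success/failure weights (the
#' pseudo-data prior) are supported; with pseudo-data included the maximum
#' likelihood estimate equals the modal a posteriori estimate, so no MCMC is
#' needed for escalation under the baseline and subgroup-covariate designs.
#'
#' Non-identifiable designs (fewer distinct (dose, subgroup) support points
#' than free parameters) and separated fits are flagged, never returned
#' silently: check \code{converged}, \code{identifiable} and \code{boundary}
#' slots. The coefficient covariance is the inverse observed information at
#' the optimum.
#'
#' @param data a [ToxicityData-class].
#' @param spec a [ModelSpec-class]; the default is the pooled two-parameter
#'   model.
#' @param grid a [DoseGrid-class].
#' @param control a [stats::glm.control()] list; the default is the standard
#'   GLM deviance criterion.
#' @return a [DoseToxicityFit-class].
#' @examples
#' grid <- DoseGrid(c(100, 150, 180, 215, 245, 260), 200)
#' fit <- fitDoseToxicity(nicholsonData(), modelSpec(), grid)
#' round(tdEstimate(fit, 0.16))  # pooled TD16
#' @export
fitDoseToxicity <- function(data, spec = modelSpec(), grid,
                            control = stats::glm.control(epsilon = 1e-8,
                                                         maxit = 50L)) {
  stopifnot(is(data, "ToxicityData"), is(spec, "ModelSpec"),
            is(grid, "DoseGrid"))
  if (length(data) == 0L) stop("empty dataset")
  rows <- .expandRows(data)
  z <- standardiseDose(rows$dose, grid)
  X <- .designMatrix(z, rows$s, spec)

  ## identifiability: distinct (dose, subgroup) support vs free parameters
  sup <- unique(cbind(z, rows$s))
  Xs <- .designMatrix(sup[, 1L], sup[, 2L], spec)
  identifiable <- qr(Xs)$rank == ncol(X)

  coefFull <- c(beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
                beta3 = NA_real_)
  if (!identifiable) {
    return(new("DoseToxicityFit", coef = coefFull, spec = spec,
               vcov = matrix(NA_real_, 0L, 0L), converged = FALSE,
               boundary = FALSE, identifiable = FALSE, grid = grid))
  }

  gf <- suppressWarnings(
    stats::glm.fit(X, rows$y, weights = rows$w, family = stats::binomial(),
                   control = control))
  beta <- gf$coefficients
  coefFull[colnames(X)] <- beta

  p <- gf$fitted.values
  boundary <- any(p < 1e-10 | p > 1 - 1e-10) || gf$boundary

  W <- rows$w * p * (1 - p)
  info <- crossprod(X, W * X)
  vc <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X), dimnames = list(colnames(X),
                                                       colnames(X))))
  dimnames(vc) <- list(colnames(X), colnames(X))

  new("DoseToxicityFit", coef = coefFull, spec = spec, vcov = vc,
      converged = gf$converged && !any(is.na(beta)), boundary = boundary,
      identifiable = TRUE, grid = grid)
}

#' @describeIn predictProb fitted DLT probability of a dose-toxicity fit
#' @export
setMethod("predictProb", "DoseToxicityFit", function(fit, x, subgroup = 0L) {
  b <- fit@coef
  if (anyNA(b[c("beta0", "beta1")]))
    stop("fit has no usable coefficients (non-identifiable)")
  b[is.na(b)] <- 0
  z <- standardiseDose(x, fit@grid)
  g <- as.numeric(subgroup)
  unname(stats::plogis(b["beta0"] + b["beta1"] * z +
                       g * (b["beta2"] + b["beta3"] * z)))
})

#' @describeIn tdEstimate analytic TD100theta of a dose-toxicity fit
#' @export
setMethod("tdEstimate", "DoseToxicityFit", function(fit, theta, subgroup = 0L) {
  ab <- .interceptSlope(fit, subgroup)
  if (!is.finite(ab["slope"]) || ab["slope"] <= 0)
    stop("no solution: non-positive effective slope")
  unname(fit@grid@referenceDose *
         (exp((stats::qlogis(theta) - ab["intercept"]) / ab["slope"]) - 1))
})

.interceptSlope <- function(fit, subgroup) {
  b <- fit@coef
  b[is.na(b)] <- 0
  g <- as.numeric(subgroup)
  c(intercept = unname(b["beta0"] + g * b["beta2"]),
    slope = unname(b["beta1"] + g * b["beta3"]))
}

#' Patient gain of a dose
#'
#' The escalation criterion \eqn{1/\{\hat\pi(d)-\theta\}^2}, infinite when the
#' fitted probability hits the target exactly. Maximising the gain over safe
#' doses is equivalent to minimising \eqn{|\hat\pi(d)-\theta|}, which is how
#' [selectDose()] implements the selection (no division by zero).
#'
#' @param fit a [DoseToxicityFit-class].
#' @param dose dose(s) in mg/m2.
#' @param policy an [EscalationPolicy-class].
#' @param subgroup 0 or 1.
#' @return numeric gain values (possibly \code{Inf}).
#' @export
patientGain <- function(fit, dose, policy, subgroup = 0L) {
  1 / (predictProb(fit, dose, subgroup) - policy@theta)^2
}

#' Gain-maximising safe dose
#'
#' Among the allowed doses whose fitted DLT probability is strictly below
#' \code{delta}, returns the one maximising the patient gain, i.e. the safe
#' dose with fitted probability closest to \code{theta}. Ties (two doses
#' equidistant from the target) resolve to the lower dose. Returns \code{NA}
#' when no allowed dose is safe, which signals a safety stop.
#'
#' @param fit a [DoseToxicityFit-class].
#' @param grid a [DoseGrid-class].
#' @param policy an [EscalationPolicy-class].
#' @param subgroup 0 or 1.
#' @param allowed candidate doses, a subset of the grid (default: full grid).
#' @return a dose (mg/m2) or \code{NA_real_}.
#' @export
selectDose <- function(fit, grid, policy, subgroup = 0L,
                       allowed = doses(grid)) {
  if (!all(allowed %in% grid@doses))
    stop("'allowed' must be a subset of the dose grid")
  if (length(allowed) == 0L) return(NA_real_)
  p <- predictProb(fit, allowed, subgroup)
  safe <- p < policy@delta
  if (!any(safe)) return(NA_real_)
  cand <- allowed[safe]
  cand[which.min(abs(p[safe] - policy@theta))]
}

#' Delta-method confidence interval for the TD100theta
#'
#' Normal approximation of the TD100theta estimator on the dose scale, using
#' the gradient of the analytic inverse and the fit's observed-information
#' covariance. Used by the accuracy stopping rule.
#'
#' @param fit a [DoseToxicityFit-class].
#' @param theta target DLT probability.
#' @param subgroup 0 or 1.
#' @param level interval level (default 0.95).
#' @return numeric c(lower, upper), or c(NA, NA) when the interval is
#'   undefined (degenerate fit or non-positive slope).
#' @export
tdInterval <- function(fit, theta, subgroup = 0L, level = 0.95) {
  out <- c(lower = NA_real_, upper = NA_real_)
  if (!fit@identifiable || anyNA(fit@vcov)) return(out)
  ab <- .interceptSlope(fit, subgroup)
  if (!is.finite(ab["slope"]) || ab["slope"] <= 0) return(out)
  a <- unname(ab["intercept"]); s <- unname(ab["slope"])
  u <- (stats::qlogis(theta) - a) / s
  dstar <- fit@grid@referenceDose
  td <- dstar * (exp(u) - 1)
  dA <- -dstar * exp(u) / s        # d TD / d intercept
  dS <- -dstar * exp(u) * u / s    # d TD / d slope
  g <- as.numeric(subgroup)
  full <- c(beta0 = dA, beta1 = dS, beta2 = g * dA, beta3 = g * dS)
  grad <- full[rownames(fit@vcov)]
  v <- drop(grad %*% fit@vcov %*% grad)
  if (!is.finite(v) || v < 0) return(out)
  half <- stats::qnorm(1 - (1 - level) / 2) * sqrt(v)
  c(lower = td - half, upper = td + half)
}

setMethod("show", "DoseToxicityFit", function(object) {
  act <- !is.na(object@coef)
  cat("DoseToxicityFit:",
      paste(sprintf("%s=%.4g", names(object@coef)[act], object@coef[act]),
            collapse = ", "), "\n")
  cat(sprintf("  converged: %s  identifiable: %s  boundary: %s\n",
              object@converged, object@identifiable, object@boundary))
  invisible(object)
})
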