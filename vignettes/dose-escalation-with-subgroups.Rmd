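---
title: "Dose-escalation designs with subgroup-aware variable selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-escalation designs with subgroup-aware variable selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doseslab)
```

## The problem and the model

A phase-I dose-escalation trial chooses, from a discrete dose set, the dose
whose probability of causing a dose-limiting toxicity (DLT) in a patient's
first treatment cycle is closest to a target θ — the TD100θ. When the
population splits into biomarker-positive and biomarker-negative subgroups
that may tolerate the treatment differently, a pooled analysis recommends a
compromise dose that can underdose one subgroup and overdose the other.

All machinery in this package rests on the logistic dose-toxicity model on
the standardised dose. With reference dose $d^*$ and subgroup indicator
$\mathbb{1}^+$,

$$\mathrm{logit}\,\pi(d) \;=\; \beta_0 + \beta_1 \log(x/d^*+1)
  \;+\; \mathbb{1}^+\{\beta_2 + \beta_3 \log(x/d^*+1)\}.$$

The standardisation makes $\beta_0$ the log-odds of toxicity at dose zero
and keeps the transformed dose positive and increasing. Three designs are
implemented:

* **baseline** — the two-parameter pooled model throughout;
* **method 1** — the four-parameter model throughout: subgroup-specific
  escalation and recommendations, no inference about whether the subgroup
  terms are needed;
* **method 2** — spike-and-slab variable selection on $\beta_2, \beta_3$
  before every cohort, so escalation pools exactly when the data say the
  subgroups behave alike.

Toxicity is assumed monotone nondecreasing in dose within each subgroup,
DLT outcomes are binary and immediate (one per patient), and subgroup
membership is known without error at study entry.

## The pseudo-data prior

The prior on the model coefficients is expressed as *pseudo-data*: at two
prior doses per subgroup, a prior proportion of DLTs among a possibly
fractional number of pseudo-patients, weighted in total to a tenth of the
planned sample size (three patients' worth per subgroup here). Fitted
together with real data by weighted maximum likelihood, the MAP estimate is
available in closed form from a standard GLM fit — no MCMC during ordinary
escalation. The packaged default places 2 pseudo-patients at 100 mg/m² with
DLT proportion 1/6 and 1 at 260 mg/m² with proportion 1/2, identically in
both subgroups; under it the escalation rule advises a 100 mg/m² start dose
and, on a DLT-free path, climbs one dose level at a time.

The baseline design fits the pooled population and uses the pooled prior.
The published prior table prints the pooled top-dose proportion in a form
that taken literally (proportion 1 among 2 pseudo-patients) makes every dose
above the start dose permanently unsafe — escalation would never leave
100 mg/m², contradicting the published baseline operating characteristics.
The per-subgroup rows aggregate exactly to proportion 1/2 among 2 patients,
and the pooled low-dose row is exactly the per-subgroup aggregation, so this
package reads the pooled prior as that aggregation
(`defaultPooledPseudoData()`). Both priors are configuration inputs, not
constants.

## Escalation, safety and stopping

Before each cohort the current design's model is refitted to pseudo-data
plus accumulated outcomes, and each active subgroup is advised the dose
maximising the patient gain $1/\{\hat\pi(d)-\theta\}^2$ among doses
satisfying the safety criterion $\hat\pi(d) < \delta$. Gain maximisation is
implemented as the equivalent $\arg\min |\hat\pi(d)-\theta|$ over safe doses
(no division by zero at an exact hit), with ties broken toward the lower
dose — conservative and deterministic. Cohorts hold two patients: one per
subgroup while both are active, both from the survivor after a one-sided
stop. Each subgroup is capped at half the overall sample-size cap
(30 of 60 by default).

A subgroup with no safe dose stops for safety. If the other subgroup is
still active, escalation continues there using the two-parameter model
fitted to that subgroup's own data (plus its pseudo-data). The final
recommendation is frequentist — fitted to trial data only, never the
pseudo-data — and is restricted to doses at or below the maximum
administered in the relevant subgroup. When the trial-only fit is
non-identifiable or separated (every patient at one dose is the common
case: under a strong subgroup effect escalation can pin at the lowest
dose), the recommendation falls back to the MAP fit with pseudo-data
included, and the result records that the fallback fired. Refusing to
recommend in those trials would distort the operating characteristics far
more than the weakly-informative prior does.

Each trial reports a subgroup-effect verdict: 0 (none), 1 (significant), or
2 (defaulted after a safety stop in exactly one subgroup). The baseline
design always reports 0; method 1 reports 1 unless a one-sided safety stop
forces 2; method 2 reruns the variable-selection step on the complete data
at trial end and reports 0 only when both subgroup terms drop out.

### The accuracy stopping rule

The optional accuracy rule stops a subgroup when at least 5 of its patients
sit at the currently advised dose *and* the 95% interval for that
subgroup's TD100θ is strictly narrower than 5 mg/m². The interval is a
delta-method normal approximation on the dose scale, from the
observed-information covariance of the current (pseudo + trial) fit; a
posterior-draw interval could be substituted via the same config surface.
Measured on simulated trials, this interval narrows from roughly 300 mg/m²
after the first cohorts to 60–80 mg/m² at 30 patients per subgroup, so the
5 mg/m² bound essentially never triggers at realistic sample sizes. The
published description of the rule it follows does not pin down the scale or
quantity behind its threshold; this package keeps the literal reading as
the default and leaves both the bound and the interval level as
configuration knobs. The rule's mechanics (both clauses, strictness at the
bound, undefined intervals never stopping) are tested at bounds inside the
observed width range.

## The spike-and-slab step

Method 2 places on each subgroup coefficient a two-component prior: a Dirac
point mass at zero (the spike — exactly zero, so draws with the term
excluded carry coefficient 0) and a normal slab. The slab is derived by
fitting the four-parameter model to the pseudo-data alone: the coefficient
estimates become the slab mean (zero for the subgroup terms under the
symmetric default prior), and `slabScale` × the inverse observed information
becomes the slab covariance. With the default `slabScale = 1` the slab
carries exactly the prior's six-patient strength. The reference
implementation this design was originally run on uses a much more diffuse
default slab; posterior inclusion probabilities — and therefore the verdict
composition in weak-data scenarios — are sensitive to this choice, which is
why the prior inclusion probabilities, the inclusion bound and `slabScale`
are all exposed.

Sampling uses Pólya-Gamma data augmentation: conditional on the
augmentation variables the likelihood is Gaussian, so each inclusion
indicator is updated by a closed-form marginal-likelihood ratio with the
coefficients integrated out, and the active coefficients by their Gaussian
full conditional. Fractional binomial weights enter as non-integer PG shape
parameters, which is why PG draws use the truncated sum-of-gammas
representation (20 terms plus the deterministic mean of the dropped tail;
the tail's variance share is $O(K^{-3})$, negligible at $K=20$) rather than
an integer-shape-only exact sampler. The chain starts at the slab mean with
both subgroup terms included, runs 20 000 iterations with 5 000 burn-in by
default, and is bit-reproducible under a fixed seed because all randomness
flows through R's RNG. The test suite checks the sampler against exact
model enumeration by Gauss–Hermite quadrature on a tiny instance, against
the prior with an empty dataset, and against PG moment identities.

A term enters the escalation model when its posterior inclusion probability
strictly exceeds the bound (default 0.25; ties exclude, following the
strict reading of "greater than"). The chosen specification is then
refitted by maximum likelihood for dose selection.

## Scenario truths and what the simulator does (not) emulate

Simulation scenarios are generated from the four-parameter model, not from
rounded probability tables: $\beta_0, \beta_1$ come from the pooled
two-parameter fit to the packaged anchor-trial data, and per scenario
$(\beta_2, \beta_3)$ are recovered so the biomarker-positive curve
reproduces the published per-dose probabilities to 2 decimal places.
Ordinary least squares on the logit of rounded 2-dp cells leaves errors up
to 0.02, so the recovery polishes the least-squares start with a minimax
(Nelder–Mead) criterion on the probability scale; cells printed as 1.00
only constrain the curve to at least 0.995, since their logit is infinite.
`buildScenarios()` errors, naming the offending doses, if any cell misses
by more than 0.005. The no-tolerated-dose scenario does not follow the
shared $\beta_0,\beta_1$ curve and is tabulated directly, identically in
both subgroups.

The simulator draws independent Bernoulli DLTs at the true per-dose,
per-subgroup probability. It does not emulate late-onset or cumulative
toxicity, patient dropout, biomarker misclassification, between-patient
covariates beyond the biomarker, or clinical overrides of model advice —
so passing operating-characteristics tests shows the designs behave as
intended under the stated model, not that they are robust to those
real-world features.

## Numerical choices

* **Fitter**: `stats::glm` (binomial), with each weighted record expanded to
  a success row and a failure row so fractional weights are exact. Standard
  GLM deviance convergence (1e-8, up to 50 iterations). The anchor trial's
  biomarker-negative stratum is quasi-completely separated — its MLE lies at
  infinity and any reported TD16 for it is a property of the stopping rule;
  the fit is flagged (`boundary`), and the standard stopping point is what
  the worked example prints.
* **Identifiability**: the design matrix over distinct (dose, subgroup)
  support points must have full column rank, otherwise the fit is flagged
  non-identifiable and prediction refuses to run.
* **Covariance**: inverse observed information at the optimum (the accuracy
  rule's interval needs it).
* **Reproducibility**: one root seed per trial; patient outcomes and the
  method-2 chains use separate deterministic streams, and replicate $r$ of
  a study uses root seed $+ r$, so a study split across seed offsets and
  pooled is identical to the full run.
* **Problem sizes**: the default test run uses 200 replicates for the
  baseline operating characteristics, 150 replicates with a shortened
  chain (2 500/500) for the method-2 subgroup-effect detection rate, and
  the acceptance script uses 1 000 baseline replicates for the sample-size
  averages and, for the safety-stopping scenario, 2 000 replicates for each
  closed-form design and 400 (5 000/1 000 chains) for the spike-and-slab
  design; Monte-Carlo tolerances are computed at those counts.

## Known limitations

* The slab's strength drives the verdict composition in weak-data
  scenarios; with the default pseudo-data-strength slab, the
  spike-and-slab design keeps the subgroup terms more often than a diffuse
  slab would, so "no subgroup effect" conclusions in homogeneous scenarios
  are rarer than under the reference implementation's diffuse default.
* The accuracy stopping rule's published threshold is not reachable on the
  scale implemented here (see above); reproducing published
  accuracy-stopping tables requires choosing a bound appropriate to the
  interval actually used.
* Only two disjoint subgroups are supported; ordinal or continuous
  biomarkers, differing targets θ per subgroup, and efficacy-driven
  extensions are out of scope.
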