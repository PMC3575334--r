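---
title: "Latent class models for test accuracy without a gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class models for test accuracy without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(genolcm)
library(dplyr)
```

## The problem

Several laboratory methods can type the p53 codon 72 polymorphism
(rs1042522) into Arg/Arg, Arg/Pro or Pro/Pro, and they disagree for roughly
one woman in ten. None of them is an error-free reference, so neither the
accuracy of any single method nor the association between the *true*
genotype and disease can be read directly off the data: empirical
prevalences and odds ratios computed from any one method's calls are biased
by its misclassification. `genolcm` implements the latent class approach to
this situation: the unobserved true genotype is a latent variable, every
method is treated as fallible, and the ensemble of methods identifies both
the accuracy of each one and the corrected genotype–disease association.

## Model 1: conditional independence

Let $X \in \{1, \dots, C\}$ be the true class with prevalences $\pi_c$, and
let test $t$ report $r_t$ with classification probabilities
$\theta_t[r \mid c] = P(r_t = r \mid X = c)$. Assuming test errors are
independent given $X$ (conditional independence), a subject contributes

$$ L = \sum_{c=1}^{C} \pi_c \prod_{t \,\text{observed}} \theta_t[r_t \mid c], $$

and the sample log-likelihood is the count-weighted sum of $\log L$ over the
distinct observed response patterns. Missing calls are simply skipped, which
is the maximum-likelihood treatment when missingness is MCAR (the package's
working assumption; informative missingness is not modelled). With $C$-level
tests and no constraints the model needs at least three tests per subject to
be identified, and the counting check `free parameters <= distinct
observable patterns - 1` is enforced with a warning.

Estimation is by EM. The E-step computes posterior class memberships per
response pattern; the M-step is closed-form reweighting, which keeps every
iterate on the probability simplex and makes the log-likelihood provably
non-decreasing (asserted per iteration in the test-suite). Because latent
class likelihoods are multimodal, every fit runs from one moment-style start
(near-diagonal classification matrices, modal-vote prevalences) plus
`n_restarts` random starts (default 20) and keeps the best local maximum.
All restart randomness derives from a single integer seed (default
20130218), so fits are exactly reproducible.

### Numerical choices

* **Convergence**: relative log-likelihood change below `rel_tol` (default
  `1e-8`), at most `max_iter = 5000` iterations per start.
* **Label switching**: after fitting, classes are permuted to maximise the
  total correct-classification mass $\sum_t \sum_c \theta_t[c \mid c]$, with
  ties broken by descending prevalence. This is what licenses reading class
  $c$ as "true category $c$".
* **Boundaries**: probabilities may legitimately converge to 0 (some
  misclassifications never happen in the data). Internally they are floored
  at $10^{-12}$ for log-safety; in output they are reported as 0 with
  standard error 0 and a boundary flag, because the information-matrix
  approximation is unreliable there.
* **Standard errors**: numerically observed information in a minimal
  log-ratio parameterization (last level as reference), inverted and
  delta-transformed to the probability scale. A rank-deficient information
  matrix (boundary or weakly identified parameters) falls back to a
  pseudo-inverse with a warning.
* **Degenerate fits**: a model whose free parameters exceed the identifiable
  cell count is reported with `converged = FALSE` — the likelihood then has
  no unique maximum, so no EM trajectory can be said to have converged to
  *the* MLE.

## Model 2: linking the latent genotype to disease

`fit_lcm_outcome()` appends the binary cytology outcome (SIL within two
years, coded 2) to the panel as one more conditionally independent variable
whose class-conditional distribution is Bernoulli with risk $\rho_c$. This
assumes test accuracy is independent of outcome status — the stratified
model below exists to probe that assumption. The fit reports $\rho_c$ with
standard errors and the misclassification-corrected odds ratios

$$ \mathrm{OR}_c = \frac{\rho_c / (1 - \rho_c)}{\rho_{\mathrm{ref}} /
(1 - \rho_{\mathrm{ref}})}, $$

against the Pro/Pro reference class by default. Confidence intervals are
symmetric on the OR scale by default — the convention the motivating study
printed — with the usual log-scale Wald interval available via
`or_scale = "log"`; the delta-method variance uses the full covariance of
$(\rho_c, \rho_{\mathrm{ref}})$. With no outcome column the function returns
exactly the Model 1 fit.

## Robustness machinery

* **Equal accuracy across tests** (`constraint = "equal_accuracy"`): one
  shared $\theta$ for all tests, the natural null for "are the methods
  interchangeable?". Tested against the free model by
  `likelihood_ratio_test()`.
* **Accuracy stratified by outcome** (`fit_lcm_stratified()`): separate
  $\theta$ per outcome stratum, shared or per-stratum prevalences. The
  parameter count doubles, and a thin case stratum typically cannot support
  it: the fit then completes but carries `converged = FALSE`, mirroring how
  such models fail in practice rather than crashing.
* **Pairwise conditional dependence** (`fit_lcm_dependent()`): for a flagged
  pair, the within-class joint cell table becomes the independence product
  times $e^{\lambda}$ on the agreement diagonal, renormalised — one
  log-linear association parameter per pair (shared across classes by
  default, per-class optional, matching the one-parameter-per-pair degrees
  of freedom a pairwise-correlation screen implies). $\lambda = 0$ reduces
  exactly to Model 1, and the `lambda_fixed = 0` path literally *is* the
  independence fit. Free-$\lambda$ fits start from the independence solution
  and maximise the full likelihood by quasi-Newton; $\lambda$ is boxed at
  $\pm 8$ because beyond odds multipliers of $e^8 \approx 3000$ the profile
  likelihood is flat to machine precision and unbounded drift in a boundary
  direction would be reported as a spuriously extreme association.
  `dependence_screen()` tests every pair and reports Bonferroni-adjusted
  p-values alongside the raw ones — with six pairwise tests on four tests, a
  multiplicity adjustment is the difference between a borderline finding and
  noise. Bonferroni was chosen as the most conservative standard choice.
* **Category collapsing** (`collapse_categories()`): Arg/Arg-vs-others or
  Pro/Pro-vs-others regroupings, which trade resolution for stability when
  three-level cells run thin.

Boundary parameters make the $\chi^2$ reference for the LRT approximate;
results then carry `boundary_warning = TRUE` rather than a silent p-value.

## The packaged panel and what it can and cannot reproduce

Only the six pairwise cross-tabulations of the four main methods (by
cytology stratum) were published; the four-way joint table was not.
`load_table1_fixture()` therefore ships a *synthetic* subject-level panel —
911 women, 850 cytology-negative, 61 with SIL, one missing RFLP-2 call —
found once by integer constraint satisfaction over the $3^4$ complete
response patterns per stratum and frozen
(`inst/extdata/table1_patterns.csv`). Every pairwise quantity computed from
it (crude agreement, kappas, empirical prevalences, empirical odds ratios)
equals the published values exactly, because those depend only on the
pairwise margins. Latent class fits depend on the unpublished three- and
four-way cells, so model estimates from this panel are *not* expected to
equal the published model results, and the package makes no such claim:
model-level validation is done by parameter recovery on synthetic data
instead.

## The generator and the simulation studies

`simulate_panel()` inverts the likelihood into a sampler: true class from
$\pi$, outcome from $\rho_X$, calls from $\theta_t[\cdot \mid X]$
(jointly for flagged dependent pairs, using exactly the fitter's
parameterization), then MCAR masking. `p53_defaults()` fixes the study
conditions: the four methods' published classification probabilities
(column-renormalised so each column is an exact simplex — one published
column sums to 1.023 from rounding), SIL risks (0.090, 0.054, 0.050),
genotype prevalences (0.38, 0.45, 0.17, the range observed among
outcome-negative women; the study never printed its fitted prevalences), and
the study's scale of 911 women with about 61 expected cases.

The simulations the tests and the acceptance script run, with the problem
sizes chosen as the package's own study conditions:

* Model 1 recovery at $n = 5000$ (every $\theta$ entry within 0.03, $\pi$
  within 0.02) and Model 2 risk recovery at $n = 20000$ ($\rho$ within
  0.015).
* Size of the pairwise-dependence LRT over 200 independent-truth replicates
  at $n = 2000$ (realised size close to, and in practice slightly below, the
  nominal 0.05 — the shared-$\lambda$ alternative sits partly on a boundary).
* Rejection of the equal-accuracy constraint at $n = 5000$ under the
  unequal published accuracies.
* Detection of within-class dependence: under the near-perfect default
  accuracies an agreement-inflating association adds little on an already
  dominant diagonal, so the association parameter is weakly identified and
  power is modest. The detection property is therefore exercised on a
  moderate-accuracy panel (diagonal 0.85), where $\lambda = 1.5$ is
  estimated without visible bias and detected essentially always at
  $n = 5000$.

What passing these simulations does *not* show: robustness to informative
missingness, to outcome-dependent accuracy beyond the stratified variant, to
more-than-pairwise error dependence, or to latent structure with more
classes than categories. Real genotyping data may violate any of these.

## Known limitations

* Standard errors are information-based; profile-likelihood or bootstrap
  intervals are not provided, and boundary-adjacent SEs should be read as
  qualitative.
* The dependence model allows each test in at most one flagged pair;
  overlapping pair structures would need a full log-linear within-class
  model.
* No covariate adjustment (age, ancestry) of prevalences or risks; the
  model operates on the cross-sectional panel alone.
* The equal-accuracy constraint shares whole classification matrices;
  partial sharing (e.g. equal sensitivity only) is not implemented.
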