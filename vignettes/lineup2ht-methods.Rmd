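---
title: "The 2-HT eyewitness identification model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The 2-HT eyewitness identification model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineup2ht)
```

## The model

Lineup experiments produce, per condition, two multinomial observations:
the culprit-present tree (culprit identification / filler identification /
rejection) and the culprit-absent tree (innocent-suspect identification /
filler identification / rejection).  The two-high-threshold (2-HT)
eyewitness identification model is a multinomial processing tree over these
six categories with four latent-process probabilities: culprit-presence
detection `dP`, culprit-absence detection `dA`, biased suspect selection
`b`, and guessing-based selection `g`.  Detection is a discrete
("high-threshold") state: when it occurs it fully determines the response
(culprit identification, or rejection of a culprit-absent lineup).  When it
does not, the non-detection processes `b` and `g` operate identically in
both tree types — the witness has no access to ground truth.  Guessing
selects the suspect with probability `1/k` in a lineup of size `k` and a
filler with probability `(k-1)/k`; these weights are structural constants
of the design, not parameters.

```{r}
category_probabilities(c(dP = .5, b = .2, g = .5, dA = .1), lineup_size = 6)
```

Two structural facts drive identifiability.  First, each tree contributes
two independent categories, so a single condition supports at most four
free parameters: the saturated per-condition model has zero degrees of
freedom.  Second, unlike old/new recognition designs, the lineup design
lets `dP` and `dA` vary freely; fixing `dA = 0` (via `fix_parameters()`)
yields the one-high-threshold variant as a testable special case.

Hypotheses are expressed as bindings (`ht_spec()`): every
condition-parameter slot is tied to a named free parameter — shared names
encode equality restrictions — or to a constant.  A restricted model is
nested in a general one exactly when its bindings arise by merging free
parameters and/or fixing them, which `is_nested()` checks structurally
before any likelihood-ratio test is allowed.  Lineup sizes deliberately
live in the data object only, not in the specification, so there is a
single source of truth and mismatches are impossible; the fit validates
that specification and data refer to the same conditions.

## Estimation

Parameters are estimated by maximum likelihood for the product-multinomial
likelihood, equivalently by minimizing the log-likelihood-ratio statistic

`G² = 2 · Σ O · ln(O / E)`,

with `0 · ln 0 := 0`; a positive observed count in a zero-probability
category makes `G²` infinite and is reported as a non-fit rather than
being patched over.

The optimizer is the expectation-maximization scheme for multinomial
processing trees.  The E-step distributes each observed category count over
the root-to-leaf paths ending in that category, proportionally to the path
probabilities; the M-step sets each free parameter to expected successes
over expected trials, aggregated over every branch that the parameter
governs (the `1/k` weights stay fixed).  Each EM iteration provably does
not decrease the likelihood, which the test suite verifies on every bundled
data set and on randomly generated instances.

Controls (`ht_control()`), with defaults:

* `restarts = 10` uniform-random starting vectors plus one heuristic start
  (detection parameters at .5, `b` and `dA` at .1, `g` at .5); the lowest
  G² wins, first-found winning ties within 1e-9.
* `tol = 1e-10`: stop when the log-likelihood improves by less than this
  per iteration, or after `max_iter = 1e5` iterations (non-convergence is
  flagged, never silent).
* `seed = 20220804` feeds the random restarts; the user's RNG state is
  saved and restored, so fits are reproducible and side-effect free.
* A quasi-Newton (BFGS) pass on logit-transformed parameters re-minimizes
  G² from the EM solution.  Its role is a cross-check — the absolute G²
  agreement is recorded in the diagnostics and is required to be below
  1e-4 in the tests — but when it strictly improves on EM (it typically
  sharpens the last few decimals near an interior optimum, since EM's
  stopping rule is on the likelihood, not the parameters) the refined
  solution is kept.
* Restarts disagreeing in G² by more than 1e-3 trigger a multimodality
  warning and are counted in `n_restarts_agreeing`.

EM keeps parameters inside `(0, 1)` by construction; estimates within 1e-4
of a boundary are flagged.  Reported values rounded to two decimals
therefore print as `.00` for solutions that are effectively at zero, which
is how boundary estimates are conventionally displayed in this literature.

Standard errors are square roots of the diagonal of the inverse observed
Fisher information of the product-multinomial log-likelihood kernel in the
free parameters, computed by finite differences at the estimates.  For
boundary estimates the evaluation point is moved inward by 1e-3 so the
difference stencil stays inside the unit cube; such SEs are reported but
flagged, since curvature at a boundary optimum is not a pure sampling
variance.  Whether reference implementations of MPT software use observed
or expected information is not documented; the package uses observed
information, and the bundled published SEs are matched to ±0.02 rather
than exactly for that reason.  A singular information matrix yields
undefined SEs plus an identifiability warning — values are never
fabricated.  `identifiability_check()` complements this with the rank of
the numerical Jacobian of the independent category probabilities (only
trees with observations count; boundary points are perturbed inward by
1e-3 before differentiation).

Degrees of freedom are independent categories (two per non-empty tree)
minus free parameters.  For studies without a designated innocent suspect
the suspect column of the culprit-absent tree is reconstructed (below), and
one can argue such trees carry one fewer independent category.  The default
keeps the full count — the ΔG² tests, which are the quantities of
scientific interest, are unaffected because the correction cancels in the
difference — and `strict_df = TRUE` applies the correction for sensitivity
analysis.

## Bundled reanalyses and data-reconstruction conventions

Eight published lineup experiments are bundled (`fixture_names()`), each
with its frequency tables stored as literal integers exactly as printed in
the source, the comparison-standard specification used for that study, and
one nested specification per published test.  Conventions baked into the
fixtures:

* **Innocent-suspect split.** Studies with filler-only culprit-absent
  lineups get their suspect count as
  `round_half_up(total false identifications / k)`
  (`split_false_identifications()`), the standard convention; it assumes a
  fair lineup.  Rounding must be half-up: one bundled cell is `9/6 = 1.5`
  and is printed as 2 in the source.  These trees carry
  `reconstructed_ca = TRUE` for the `strict_df` variant.
* **Equal cell sizes** (`equal_cell_counts()`) where a source reports only
  group totals under balanced assignment.  One bundled study's total is
  not divisible by its six conditions; its printed per-condition tables
  (which imply totals of 164–167) are stored verbatim instead, and the
  function refuses non-divisible totals rather than guessing.
* **Wildcard responses count as lineup rejections**, the scoring used for
  that study's design, and the two designated innocent suspects of one
  fairness study are aggregated into a single culprit-absent tree.
* One study uses a five-person lineup; all others use six.  The `1/k`
  weights are ordinary double-precision ratios; against exact rationals
  the difference is below 1e-16 and numerically irrelevant.

`reproduce_analyses()` refits everything and tabulates recomputed G², ΔG²,
estimates and SEs next to the published values with pass/fail columns at
the package's comparison tolerances (±0.05 on G²-type statistics, ±0.01 on
estimates, ±0.02 on SEs).

## The simulator

`simulate_lineup()` and `sample_dataset()` draw the two trees of each
condition from multinomials at the model's category probabilities, with
fixed tree totals taken from a template data set — i.e., they emulate the
fixed-`n` between-subjects designs of the bundled studies, one decision
per witness.  Replicate streams are seeded as a deterministic function of
the study seed and the replicate index, so a replicate can be regenerated
in isolation and results do not depend on execution order.  The simulator
does **not** model participant-level heterogeneity in the parameters,
confidence ratings, sequential-lineup position effects, or random
condition sizes; recovery results therefore speak to the estimator under
the model's own assumptions, not to robustness against misspecification.

`recovery_study()` reports bias and RMSE per free parameter; replicates at
a boundary are retained (and counted) rather than discarded, since
discarding them would bias the summary exactly where boundaries matter.
Non-convergent replicates are excluded and counted.  `lrt_error_rate()`
simulates under a restricted model and measures how often the ΔG² test
rejects the (true) restriction.

Problem sizes used by the packaged simulation studies, chosen to make the
asymptotic claims checkable while keeping the default test run quick:
parameter recovery at the wildcard study's estimates uses 10,000 witnesses
per tree and 20 replicates (interior parameters recover with |bias| <
0.01); the test-calibration study uses 2,000 replicates of a two-condition
design with 200 witnesses per tree at interior parameters, where the
ΔG²(1) rejection rate at nominal .05 falls within [0.03, 0.07].

## Numerical choices and degenerate inputs

* Parameters are clamped to `[1e-12, 1 - 1e-12]` inside EM and the
  likelihood is evaluated in logs, so zero-probability paths cannot produce
  NaNs.
* Empty trees (total 0) contribute no independent categories and nothing
  to G²; a condition with both trees empty is rejected at construction.
* An EM start that places probability zero on an observed category cannot
  recover (the likelihood is `-Inf` throughout); such runs are abandoned
  and noted in the diagnostics, and the random restarts make them
  inconsequential.
* `compare_fits()` clips tiny negative ΔG² (within 1e-6, from finite
  tolerances) to zero and warns beyond that; Δdf must be positive, so
  comparing a model with itself is refused rather than reported as a
  trivial pass.
* p-values are upper-tail χ²; the saturated model (df 0) reports `NA`
  rather than a misleading number.

## Known limitations

* G² and ΔG² rely on χ² asymptotics; two bundled studies have around 50
  witnesses per tree, where exact tests would be preferable in principle.
* Boundary estimates (`b` or `dA` at 0 occur in several bundled studies)
  make the nominal SE an approximation; the flag is the honest signal.
* The innocent-suspect split rule presumes lineup fairness; for unfair
  lineups without a designated innocent suspect the reconstruction, and
  with it parameter `b`, would be distorted.  Studies with designated
  innocent suspects are unaffected.
* The engine is specialized to the two lineup trees; it is not a general
  MPT toolbox, and showup (single-person) designs are out of scope.
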