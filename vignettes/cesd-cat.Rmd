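---
title: "Adaptive measurement of depressive symptoms with the CES-D: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive measurement of depressive symptoms with the CES-D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesdcat)
```

# The measurement model

The CES-D asks how often each of 20 depressive symptoms occurred during the
past week, on four ordered categories (coded 0–3 internally; files coded 1–4
are handled by the loader's `coding_offset`). `cesdcat` models each item with
Samejima's graded response model on the **logistic metric**:

$$P^*_k(\theta) = \frac{1}{1 + e^{-a(\theta - b_k)}},\qquad
  P_k(\theta) = P^*_k(\theta) - P^*_{k+1}(\theta),$$

with $P^*_0 \equiv 1$, $P^*_m \equiv 0$. The slope $a > 0$ measures how
sharply the item discriminates along the latent severity $\theta$ (a
z-score); the ordered thresholds $b_1 < b_2 < b_3$ locate the categories on
that scale. No 1.702 scaling constant appears in the probabilities. The
constant enters exactly once, in the loading conversion
$\lambda = (a/1.702)\big/\sqrt{(a/1.702)^2 + 1}$: this is the only convention
that reproduces the published standardized loadings of the packaged bank
(e.g. $a = 3.70 \mapsto \lambda = 0.91$, $a = 1.13 \mapsto \lambda = 0.55$),
which pins down the metric of the published slopes.

Item information is the Samejima form
$I_i(\theta) = \sum_k (P^{*\prime}_k - P^{*\prime}_{k+1})^2 / P_k$ with
$P^{*\prime}_k = a P^*_k (1 - P^*_k)$; test information sums over items and
$SE(\theta) = 1/\sqrt{I(\theta)}$.

The packaged 17-item bank (`cesd_bank()`) carries the published calibration
of the CES-D after three unscalable items (2, 11, 15 of the original
numbering) were removed.

# Scale evaluation

* **Cronbach's α** by the variance-ratio formula.
* **One-factor CFA** treats the 0–3 scores as continuous and minimizes the
  normal-theory ML discrepancy. Uniquenesses are optimized on the log scale
  with the loading vector profiled out through the leading eigenpair of
  $\Psi^{-1/2} R \Psi^{-1/2}$; $\chi^2 = (n-1)F$, CFI/TLI use the
  independence baseline and are truncated to $[0, 1]$, and the RMSEA 90% CI
  inverts the noncentral $\chi^2$. Heywood cases are handled by a uniqueness
  floor of 0.005 (flagged in the result). Polychoric CFA is deliberately out
  of scope: the estimator mirrors the continuous-ML convention of the
  original analysis.
* **Mokken scalability**: $H_{ij} = \sigma_{ij}/\sigma^{\max}_{ij}$ where
  $\sigma^{\max}_{ij}$ is the covariance of the comonotonically coupled
  marginals (computed by sorting both columns; verified in the tests against
  an independent Hoeffding-representation oracle). Item and scale $H$ are
  ratios of sums. Item-removal iterates one item at a time — always the
  lowest $H_i$ below the 0.30 floor, recomputing after each removal — the
  conservative reading of a procedure whose batch-vs-sequential order was
  not documented. Item standard errors use a first-order influence-function
  (delta-method) approximation that holds the maximum covariances fixed;
  this is simpler than the full ratio-delta method and accurate to the 0.01
  displayed in practice (the SEs are descriptive here, no decision rests on
  them).

# Calibration and diagnostics

`fit_grm()` maximizes the marginal likelihood under a standard-normal latent
density by EM: 41 equally spaced quadrature nodes on $[-5, 5]$ weighted by
the normal density (re-normalized), per-item quasi-Newton M-steps on the
order-preserving parameterization $(\log a, b_1, \log \Delta b)$, stopping
when the largest absolute parameter change falls below $10^{-4}$ (500
iteration cap; the EM log-likelihood trace is returned and is asserted
non-decreasing in the tests). Standard errors come from the empirical
cross-product of per-person marginal score vectors. Categories never
observed are collapsed into their lower neighbour with a warning; `NA`
responses simply drop out of the likelihood (the DIF-adjusted refit relies
on this). Parameter recovery at $n = 1000$ (slopes within $\pm 3$ SE for at
least 85% of items) is part of the acceptance suite.

**Local dependence.** `yen_q3()` conditions on Bayesian modal trait
estimates — not ML — so all-floor/all-ceiling responders stay finite, forms
residuals $x_{pi} - E[x_i \mid \hat\theta_p]$, and correlates them; $|Q3| >
0.20$ flags a pair. Flagged pairs can be summed into a testlet
(`form_testlet()`), refit as a single graded super-item with
$\sum_i (m_i - 1) + 1$ categories, and re-screened; banks may therefore mix
category counts (trailing `NA` thresholds mark absent categories).

**Item fit.** No specific statistic was prescribed for the original
analysis, so the package makes its own choice: a stratified Pearson $\chi^2$
in which, for each item, persons are stratified by the **leave-one-out
posterior mean** of $\theta$ and the expected category counts average the
model probabilities over that same leave-one-out posterior. Early versions
that conditioned on the full-vector point estimate were badly miscalibrated
(the item's own response contaminates both the stratum assignment and the
reference distribution); the leave-one-out form brings the null
false-positive rate close to nominal, which the tests assert. Degrees of
freedom are `cells − strata − item parameters`, floored at 1 — an
approximation, slightly liberal in small strata. Cells with expected count
below 5 are pooled downward; strata under 30 persons are merged.

**DIF.** Three proportional-odds models per item (`MASS::polr` with explicit
cumulative-logit starting values, since the default start search fails for
very steep items): `~theta`, `~theta + group`, `~theta * group`, with the
pooled-calibration Bayesian modal score as the matching variable and no
iterative purification (none was described for the original procedure).
Flagging uses the relative change in the trait coefficient between the first
two models (> 1%, the documented operating rule); the McFadden pseudo-$R^2$
change between the first and third models is reported for severity grading
against the conventional 0.13 cut rather than folded into the flag — the two
published rules conflict for at least one item, so both thresholds stay
exposed as parameters. McFadden's variant was chosen because it is monotone
in the likelihood ratio and needs nothing beyond the fitted log-likelihoods.
`dif_adjusted_scores()` frees the flagged items' parameters per group by
duplicating their columns with the other group's entries missing, refits,
rescores each person with their own group's parameters, and reports the
Pearson correlation and Welch *t* against the pooled scores.

# The adaptive test

`run_cat()` starts at the prior mean (0), selects the unadministered item
with maximum Fisher information at the current estimate (ties break to the
lowest bank index), administers it, re-estimates, and checks the stopping
rule after each response. Scoring bounds are $\pm 4$, consistent with the
observed decile range of the trait. Defaults: stop at $SE \le 0.32$
(reliability $\approx 0.90$), prior N(0, 1).

Two conventions deserve explanation:

* **Interim estimator and stopping SE.** The default interim estimator is
  Bayesian modal throughout, with the stopping rule applied to its
  posterior-precision SE, $1/\sqrt{I(\hat\theta) + 1}$; the final reported
  estimate is maximum likelihood (Bayesian modal fallback when every
  response is at the floor or ceiling), with the Fisher SE
  $1/\sqrt{I(\hat\theta)}$. This choice is forced by arithmetic: with the
  packaged bank, stopping on the *ML* SE would require information
  $\ge 1/0.32^2 = 9.77$ from administered items alone, which even ideal
  greedy selection cannot reach at, say, $\theta = -0.7$ with 11 items —
  yet the published simulation stopped there after 11 items on average, and
  its reported mean standard errors (0.33–0.34, *above* the 0.32 rule)
  match exactly what the final ML SE looks like when the *Bayesian* SE was
  the one driving the stop. The literal reading — switch to ML as soon as
  the pattern is mixed and stop on the ML SE — is available as
  `cat_config(interim = "ml_mixed")` and yields tests about 2.5 items
  longer. `update_estimate()` exposes the mixed-pattern ML/MAP switch
  directly; "mixed" is operationalized as the exact finiteness condition
  for the graded-model ML estimate.
* **Final estimate.** Recomputed from scratch at termination rather than
  carried over from the last interim step, so the reported score never
  depends on the estimator used for stopping.

## Simulation studies

`simulation_one()` draws $n$ true traits from N(0, 1) (fresh draws: the
published decile means match standard-normal order statistics), simulates
each respondent item-by-item from the model, runs the adaptive test, and
summarizes by deciles of true $\theta$: mean $\theta$, RMSE, mean bias, mean
test length, mean final SE. A master seed spawns per-person substreams, so
results do not depend on evaluation order. `simulation_two()` replays the
adaptive test against fixed full response vectors; the reference score is
the full-bank ML estimate (Bayesian modal fallback), deciles are assigned by
it, and RMSE/bias are against it — a deliberate, documented definition,
since the published post-hoc table reports error magnitudes that cannot
arise from comparing adaptive to full-bank scores of the same responses
(r = 0.98 there) and whose actual definition is not recoverable.

# The synthetic-data generator

`make_study_dataset()` emulates the calibration study's stated world: two
independent groups of about 1018 (evaluation) and 1042 (validation) persons,
$\theta \sim N(0, 1)$, graded responses from the packaged bank, and a
66/34 female/male split. Sampling goes through latent propensities
$z_i = \theta + e_i/a_i$ with logistic noise $e_i$ (`x = #\{k : z_i > b_k\}`),
which makes controlled violations simple to inject **before**
categorization:

* *Off-dimension items* replace $\theta$ with
  $\sqrt{1-\lambda_2^2}\,\theta + \lambda_2\,\theta_2$, one shared second
  trait for all such items — a compensatory two-dimensional structure that
  keeps total variance comparable across items.
* *Locally dependent pairs* add a shared standard-normal shock scaled by
  $\sqrt{\rho/(1-\rho)}\,(\pi/\sqrt{3})/a_i$ to both propensities, giving
  residual correlation $\approx \rho$; the marginal noise inflation this
  causes (slightly flatter effective slopes) is accepted as the price of a
  controllable Q3 expectation.
* *DIF items* use $b + \delta$ (uniform) and $a\kappa$ (non-uniform) for the
  named group only.

With no injections the generator is bit-identical to plain model sampling
from the same RNG stream, which the tests assert.

What the generator does **not** emulate: real response styles, the
demographic structure of the original samples, or the mild multidimensionality
real CES-D data show. A green synthetic CFA therefore says the *code* is
correct, not that the real CES-D is unidimensional — on the real data the
initial 20-item CFA fit poorly, which is precisely why the Mokken screen and
item removal exist.

# Reproduction status and known limitations

Running the packaged bank through this implementation reproduces the
published loading conversion exactly and the simulated-respondent study's
qualitative structure — U-shaped test-length profile, extreme-decile mean
lengths (~14 items), mean decile RMSE ~0.33, near-zero bias, mean final SEs
0.33–0.34. Two published quantities resist reproduction from the printed
parameters, coherently with each other:

* the reported test-information maximum (18.71) is about a third higher
  than what the standard Samejima information yields from the printed bank
  (14.07 at $\theta = 0.43$) under the only metric convention consistent
  with the printed loadings; and
* the central-decile mean test lengths (8.3 at the median decile) are
  correspondingly shorter than this implementation produces (~10), exactly
  as one would expect if the original engine's information function ran
  higher near the centre of the scale; the tail deciles, where the curves
  evidently agree, match within tolerance.

No standard formula variant examined (boundary-information sums,
score-information, 1.702-scaled or probit forms) reproduces the published
curve, so the package keeps the textbook definition and reports the
difference rather than calibrating toward the published numbers.

Other limitations: the item-fit degrees of freedom are approximate; Mokken
item SEs use a simplified delta method; polychoric CFA, exposure control,
content balancing and empirically derived DIF thresholds are out of scope.
The command-line surface is deliberately omitted — the exported functions,
the acceptance script and this vignette are the interface.
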