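---
title: "A mechanistic negative binomial model of per-occasion drinking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic negative binomial model of per-occasion drinking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbdrink)
```

## The model

A drinking occasion (a drinking day) is treated as a run of *mini drinking
episodes*.  Within an episode the drinker consumes successive drinks, each
time stopping with probability $p$; the episode length is therefore
geometric (number of failures before the first success).  An occasion
comprises $r$ such episodes, so the occasion total $Y$ — the number of
drinks consumed that day — is negative binomial in the
failures-before-the-$r$-th-success parameterization:

$$P(Y = y \mid r, p) = \frac{\Gamma(y + r)}{\Gamma(r)\, y!}\, p^r (1-p)^y,
\qquad E[Y] = \frac{r\,(1-p)}{p}.$$

Two observation features shape the likelihood:

* **Zero truncation.**  Only people who drank at least once in the past 30
  days are modelled, so all probabilities condition on $Y \ge 1$.
* **Right censoring.**  Survey instruments top-code the last-occasion
  count, here at 20 drinks; a report of 20 contributes the tail mass
  $P(Y \ge 20 \mid Y \ge 1)$ rather than a point mass.

Both parameters are linked to four items available in almost any
alcohol-use survey — age band, gender, usual drinks per drinking day $K$
(1–24) and drinking days in the past 30 days $M$ (1–30):

$$r_j = 1 + \exp(x_{rj}'\beta_r), \qquad p_j = \mathrm{logit}^{-1}(x_{pj}'\beta_p),$$

where each design vector holds an intercept, eight age-band dummies
(reference 20–25 years), a female indicator, and the drinking-norm
transforms $\ln(1/K)$, $(\ln(1/K))^2$, $\ln M$, $(\ln M)^2$.  The $1 +
\exp(\cdot)$ link keeps $r > 1$ (an occasion has at least one episode,
plus a continuous surplus); the logistic link keeps $p \in (0,1)$.
Intuitively, $K$ approximates the mean occasion size $r(1-p)/p$ and $M/30$
approximates the drinking propensity $P(Y \ge 1)$, which is why these two
items carry most of the signal.

## Estimation

`nbdrink()` maximises the summed conditional log likelihood

$$\ln L = \sum_j \ln \ell_j, \qquad
\ell_j = \begin{cases}
P(Y = y_j \mid r_j, p_j)/(1 - P(Y = 0 \mid r_j, p_j)) & y_j < 20\\[2pt]
P(Y \ge 20 \mid r_j, p_j)/(1 - P(Y = 0 \mid r_j, p_j)) & y_j = 20
\end{cases}$$

by BFGS with an analytic gradient (digamma terms for $r$; the censored
tail is differentiated through its finite head sum).  Standard errors are
Wald, from the inverse observed information (numerical Hessian at the
optimum); 95% intervals are $\hat\beta \pm 1.96\,\mathrm{SE}$.

Numerical choices that matter:

* All probability arithmetic is in log space; the truncation divisor uses
  a stable $\log(1 - e^x)$ so small $p^r$ never cancels.
* The $r$ linear predictor is capped at 50 before exponentiation and $p$
  is clamped to $(10^{-12}, 1 - 10^{-12})$; outside-parameter states are
  rejected with a large objective value rather than propagating NaN.
* Starting values: intercepts are moment-matched from the raw outcome
  (ignoring truncation — adequate for a starting point), slopes start at
  0.  If BFGS stops without clean convergence or the Hessian is not
  positive definite, the fit restarts once from the incumbent, which
  rebuilds the curvature approximation; persistent failure is reported
  via `converged = FALSE` and a warning, never silently.
* The fit refuses cohorts with fewer than 10 records per active term.

**Term elimination** (`eliminate = TRUE`) mirrors the backward procedure
used to arrive at the reference coefficient set: fit the full model,
remove *every* removable unit with Wald $p \ge \alpha$ in one sweep, refit,
and repeat until all remaining units are significant.  The eight age
dummies are one unit, tested by a joint Wald chi-square and kept or
removed as a block — individual bands can be non-significant while the
category matters, and a block test is the only coherent way to retain the
full dummy set in that case.  Intercepts are never candidates.

Because age and gender enter both predictors as the same binary/dummy
columns, their $r$ and $p$ coefficients are close to collinear (estimate
correlations near 0.98 in full-model fits): the *difference* in how a
shift in $\log(r-1)$ versus $\mathrm{logit}(p)$ deforms the truncated
distribution is subtle.  Elimination resolves this by dropping whichever
side the data cannot support; in the shipped reference set age and gender
survive only in the $r$ predictor.

No survey weights enter the likelihood; coefficient estimates from a
weighted survey design should be interpreted accordingly (a limitation,
not an option that was declined lightly: the reference estimates were
produced unweighted).

## Prediction

From a fitted model (or any coefficient set), `predict_risk()` composes
the link with the conditional exceedance

$$P(Y \ge t \mid Y \ge 1) = \frac{1 - \sum_{y < t} P(Y = y)}{1 - P(Y = 0)},$$

and multiplies by the respondent's drinking days $M$ to give the expected
number of days per 30 on which consumption reaches $t$ drinks — the count
of such days is Binomial$(M, P(Y \ge t \mid Y \ge 1))$ under the model,
so the product is its mean.  The default threshold set is 2–12 drinks
(the discrimination cutoffs) plus 4 and 5 (the conventional risky-day
levels).  No cap is applied beyond the arithmetic one ($\le M$), and
expected days are returned at full precision.  `conversion_table()`
tabulates the same quantities over a $(K, M)$ grid, the form practitioners
can use as a look-up calculator.

## Validation

Two procedures, both exposed through `validate_model()`:

* **Cutoff-wise AUROC** (`auroc_pipeline()`): for each cutoff $i \in
  \{2,\dots,12\}$ the binary outcome $G_i = 1\{y \ge i\}$ is scored by the
  log of the model probability $P(Y \ge i \mid Y \ge 1)$; a univariate
  logistic regression fitted on the training sample transports that score
  to the test sample, and AUROC is the midrank Mann–Whitney statistic.
  Since AUROC is invariant to monotone transforms, the logistic refit
  cannot change the training AUROC — it is retained because the fitted
  score is what is applied to the test sample.
* **Slope-only calibration** (`slope_only_calibration()`): observed
  risky-day counts are regressed on predicted counts with no intercept;
  the slope ($\sum o_i p_i / \sum p_i^2$, classical 95% CI) should be near
  1 and the uncentered $R^2 = 1 - \sum(o - \hat\beta p)^2/\sum o^2$ high.
  The uncentered definition is the standard no-intercept convention and
  the only one guaranteed to stay in $[0,1]$ here.  Classical rather than
  heteroskedasticity-robust standard errors are used; because the
  binomial residual variance grows with the prediction, the classical CI
  undercovers slightly, which is visible as occasional near misses of 1
  in finite samples even under the true model.

## The synthetic cohort generator

`simulate_cohort()` produces microdata with *exactly* the structure the
model assumes: covariates from configurable marginals, $(r_j, p_j)$ via
the link, last-occasion counts from the zero-truncated negative binomial
(inverse-cdf sampling, then top-coding at 20), and risky-day counts drawn
Binomial$(M, \cdot)$ from the same exceedance probabilities — so
calibration slopes have a ground truth of exactly 1 and parameter-recovery
experiments have a known answer.

Default covariate marginals are fixture choices, documented as such and
not estimates of any survey population: age weights roughly uniform over
adult bands with small minor-band mass, $P(\text{female}) = 0.5$,
$K \sim 1 + \mathrm{Poisson}(2)$ truncated at 24, and
$M \sim 1 + \mathrm{Binomial}(29, 0.25)$.  Under these marginals censoring
at 20 drinks is rare (heavy usual drinkers are uncommon), as it is in
general-population surveys.

What passing simulation-based tests shows — and does not.  The generator
satisfies every model assumption by construction: independence of days,
a binomial day count sharing the occasion exceedance probability, no
reporting error, no survey design effects.  Green recovery and
calibration tests therefore certify the estimation and prediction
machinery, not the model's adequacy for any real survey population.

Problem sizes used by the shipped tests: single-fit recovery and
elimination checks run at $n = 30{,}000$ (comparable to the reference
training sample), recovery coverage across 10 replicates, elimination
frequency across 20 replicates, distributional fidelity at
$10^5$–$2\times10^5$ draws.

## Known limitations and open edges

* The usual-drinks bound of 24 is a covariate recode only; only the
  last-occasion bound of 20 enters the likelihood as censoring.
* Gender is modelled as the two categories the source instruments code;
  other values are rejected explicitly rather than silently dropped.
* Predictions carry no uncertainty intervals (coefficient uncertainty is
  available but not propagated through the exceedance chain).
* The reference coefficients describe the 2010–2011 US general
  population; for other populations the model should be refitted, not
  transported.
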