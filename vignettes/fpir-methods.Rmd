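---
title: "Estimating fractional-power interactions: model, search, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fractional-power interactions: model, search, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpir)
```

## The model

The classical way to let two continuous predictors interact in a linear
model is the product term:

$$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_1 X_2 + \varepsilon.$$

This fixes the *shape* of the interaction: the simple slope of $Y$ on $X_1$
is the linear function $\beta_1 + \beta_3 X_2$. Many ecological and
epidemiological relationships are not like that — the moderating effect of
$X_2$ saturates, accelerates, or acts only near the upper end of its range.
The model this package fits generalizes the product term to a
fractional-power form,

$$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_1^M X_2^N + \varepsilon,$$

with real-valued exponents $M$ and $N$ estimated from the data. The simple
slope becomes the nonlinear family
$\beta_1 + \beta_3 M X_1^{M-1} X_2^N$ (available as
`interaction_slope()`), and the classical model is recovered exactly at
$M = N = 1$. Because the model stays linear in its coefficients, every
candidate $(M, N)$ is an ordinary least-squares fit: four coefficients,
interpretable tests, and honest degrees of freedom — in contrast to
polynomial, additive or tree-based models that buy flexibility with many
more parameters.

The exponents also carry meaning of their own: their relative size ranks
the two predictors' contributions to the interaction, and $M$ or $N$ near
zero flattens the corresponding predictor out of the term entirely.

## The two-stage grid search

$M$ and $N$ enter the model nonlinearly, so they are estimated by explicit
search rather than by gradient methods (the $R^2$ landscape is cheap to
evaluate, multimodal at extreme exponents, and a grid makes the estimator
deterministic and auditable).

**Stage 1.** Each exponent ranges over 55 candidate values spanning
$[-52.5, 52.5]$, denser near zero where most real exponents live. The
positive half is the power-scaled sequence
$52.5\,(i/27)^{\gamma}$, $i = 1,\dots,27$, with
$\gamma = \log(52.5)/\log(27/4) \approx 2.074$; the negative half mirrors
it and 0 is included. We chose $\gamma$ so that the value 1 falls *exactly*
on the grid (at $i = 4$) without any post-hoc snapping: a snapped grid
would violate the monotone-spacing property near the snap, and containing 1
exactly is what guarantees the searched model can never fit worse than the
regular regression. All $55 \times 55 = 3025$ pairs are scored by $R^2$.

**Stage 2.** The winning pair is refined: each exponent gets 10 evenly
spaced values spanning a $\pm 3.5$ window around its stage-1 value (step
$7/9$), giving 100 further models. The final estimate is the
highest-$R^2$ valid candidate from either stage. Over all 55 possible
centers the stage-2 windows reach 550 distinct values per exponent within
$[-56, 56]$ — 302,500 reachable pairs — and the window width is the unique
simple choice consistent with those totals, which is why we fixed it at
$\pm 3.5$ rather than scaling it with the local grid spacing (a
half-spacing neighborhood cannot reach $\pm 56$ from the extreme centers).

Details that matter in practice:

* **Selection criterion.** Within a stage every candidate has the same
  number of coefficients, so ranking by $R^2$, adjusted $R^2$ or AIC is
  equivalent; plain $R^2$ is used, as the simplest statement of the rule.
* **Ties** (exact, as happen with noiseless data) go to the pair closest to
  $(1, 1)$ in $|M-1| + |N-1|$, then lexicographically — parsimony toward
  the classical model.
* **Invalid candidates.** On 0–1 standardized predictors, a zero value
  raised to a negative exponent is infinite, and extreme exponents can make
  the interaction column numerically collinear with the main effects (or
  overflow). Such candidates are skipped with a reason code
  (`nonfinite`, `collinear`, `overflow`) in the returned candidate table,
  never silently and never fatally unless *every* candidate fails.
* **Scoring path.** All candidates in a stage share their non-interaction
  columns, so each candidate's $R^2$ is computed by projecting the
  interaction column and the response onto the orthogonal complement of
  the shared columns (the Frisch–Waugh identity), vectorized across the
  grid. The winning model and the $(1,1)$ baseline are then refit in full
  by the OLS engine; the test suite checks the shortcut against a
  brute-force per-candidate `lm()` loop.
* **Estimator resolution.** The estimate lives on a fixed lattice, so its
  natural error unit is one tuned-grid step ($7/9 \approx 0.78$); recovery
  experiments report the fraction of replicates within one step. No
  confidence interval is attached to $(M, N)$.

The three-way form
$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_3 + \beta_4 X_1^M X_2^N X_3^K + \varepsilon$
uses the same scheme. Its stage 1 scans, by default, a coarsened sub-grid —
every other initial value plus $\{-1, 0, 1\}$, 31 values per exponent
($31^3$ = 29,791 triples) — because the full $55^3$ scan costs 5–6 times
more for little gain at stage-1 resolution. The values $\{-1, 0, 1\}$ are
kept so the classical $(1,1,1)$ candidate stays reachable and the
dominance guarantee survives coarsening; `coarse = FALSE` restores the full
scan. Stage 2 tunes all three exponents jointly ($10^3$ models).

## The OLS engine

`ols_fit()` reports, per model: coefficients with standard errors and
two-sided $t$ p-values, RSS/TSS, $R^2$ and adjusted $R^2$, residual
degrees of freedom, and the sequential (Type I) sum of squares of each term
in declared order — the SS of term $j$ is the RSS drop when it joins the
model holding terms $1..j{-}1$, so the non-intercept SS plus the final RSS
reconstruct the TSS exactly. The interaction's sequential share of TSS
(term order $X_1$, $X_2$, interaction) is the `interaction_share` reported
with every search result.

Two AIC values are reported under the Gaussian likelihood
$n\log(2\pi\,\mathrm{RSS}/n) + n + 2(p+1)$:

* `aic_naive` counts only the $k$ linear coefficients ($p = k$);
* `aic_adjusted` additionally counts the grid-searched exponents
  ($p = k + 2$, or $k + 3$ for three-way), i.e. it charges the search for
  the flexibility it used. The two differ by exactly 4 for a two-way fit.

Reporting both makes the parameter-counting convention explicit instead of
burying it; model comparisons should use `aic_adjusted` when the exponents
were estimated and `aic_naive` when they were fixed a priori.

Numerical choices: the design is fit on unit-norm-scaled columns so that
rank detection and the factorization are invariant to column scaling
(fractional-power columns can span dozens of orders of magnitude);
rank deficiency means a relative singular value below $10^{-10}$, and the
error names the collinear terms. The grid scorer applies the same relative
tolerance to the projected candidate column; in the rare boundary case
where a scored winner is still rejected at refit, it is invalidated and the
next-best candidate is taken.

## Comparators

* `fit_regular()` — the product-interaction model, identical to the
  candidate at $(1,1)$ (asserted to $10^{-10}$ in the tests).
* `fit_polynomial()` — the full bivariate basis of total degree $\le$
  `order`: all $X_1^a X_2^b$ with $a + b \le$ `order`, i.e.
  $(\text{order}+1)(\text{order}+2)/2$ terms — 15 at the default order 4.
  The per-variable-degree-4 reading (25 terms) is rejected: it is the
  total-degree basis that matches a 15-parameter model on the residual
  degrees of freedom.
* `fit_fpirp()` — the quadratic-augmented variant, appending $X_1^2$ and
  $X_2^2$ to *every* candidate and re-running the whole search, so the
  selected exponents are estimated in the presence of the quadratics
  rather than inherited from the plain search. Each augmented candidate
  nests the plain one, giving the ordering
  $R^2(\text{regular}) \le R^2(\text{fpir}) \le R^2(\text{fpirp})$ on any
  dataset.
* `compare_models()` — one call fitting all four and assembling a
  comparison table plus per-term detail (coefficient, SE, p, sequential
  SS) for the regular and fractional-power fits.

## The synthetic-data generator

`simulate_fpir_data()` draws from exactly the generative structure the
model assumes: predictors on $(\ell, h] \subseteq (0, 1]$ — mirroring 0–1
standardized covariates — and
$Y = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_1^M X_2^N + \varepsilon$
with Gaussian noise. Defaults describe a strong, clean two-way
interaction: $n = 500$, $\beta = (0.25, 0.1, 0.9, 9.8)$,
$(M, N) = (4.9, 2.6)$, noise SD 0.05, predictors uniform on $(0.05, 1)$.
The lower bound 0.05 keeps negative candidate exponents well-defined
during the search; the exponents and coefficients are of the magnitude the
method is designed to detect. A `lognormal` predictor law (right-skewed,
rescaled to the same range) is available because real environmental
covariates are typically concentrated at small values; uniform remains the
default for clean recovery behaviour.

`recovery_experiment()` repeats simulate-then-fit with replicate seeds
derived deterministically from the spec seed
(`(seed + 10007*rep) mod (2^31 - 1)`) — every reported number is a pure
function of the spec. It summarizes per-exponent bias, RMSE, the fraction
of replicates within one tuned-grid step of the truth, and the mean $R^2$
gain over the regular model.

What the generator does *not* emulate — and hence what passing recovery
tests do not establish about field data: correlated or spatially
structured predictors, non-Gaussian or heteroscedastic errors, measurement
error in $X$, model misspecification (a true surface outside the
fractional-power family), and zeros in the predictors (real 0–1
standardized data contain exact zeros, which invalidate negative-exponent
candidates; the search handles this by skipping, but the recovery rates
reported here do not cover that regime).

## Validation experiments and their sizes

The test suite and the acceptance script rerun, from scratch:

* the grid identities (55 values, 3025 + 100 models, 550 reachable values
  in $[-56, 56]$, 302,500 pairs), exactly;
* the engine against an independent normal-equations solve on 50 random
  small problems (agreement to $10^{-8}$ relative, observed near machine
  precision);
* the scoring path against a brute-force `lm()` double loop on reduced
  $11 \times 11$ grids;
* exponent recovery at true $(3, 2)$ with $n = 500$, noise SD 0.05, 20
  replicates — both exponents land within one tuned step in every
  replicate, and noiseless on-grid truth is recovered with zero error;
* the null case $\beta_3 = 0$ at $n = 1000$, 20 replicates — the mean
  $R^2$ advantage of the searched model over the regular one is about
  $10^{-3}$, an order of magnitude under the 0.02 bound we consider
  practically negligible. This quantifies the main worry about maximizing
  $R^2$ over 3125 candidates: the selection overfit is real but tiny at
  these sample sizes;
* the nesting order and sequential-SS conservation on 20 seeded datasets.

These sizes ($n$ of 120–1000, 20 replicates) were chosen as the smallest
designs at which the checked properties are stable across seeds; all run
in about a minute in total.

## Known limitations

Continuous predictors only — categorical moderators do not fit the
power-term form. One interaction term per model (one two-way or one
three-way). Exponent estimates are lattice-valued with no uncertainty
interval; when the interaction is weak the selected exponents are close to
noise (as the null experiment shows) even though the $R^2$ cost of that
freedom is small, so the exponents should be interpreted only when the
interaction term itself is convincing. Selection by in-sample $R^2$ means
the reported $R^2$ of the winner is optimistically biased by the search;
`aic_adjusted` is the provided counterweight, and out-of-sample checks
remain the user's responsibility.
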