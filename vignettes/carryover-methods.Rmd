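---
title: "Simulating and analysing aggregated N-of-1 trials with carry-over"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing aggregated N-of-1 trials with carry-over}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nofonesim)
```

This vignette is the package's account of its models: what the simulator
generates and why, what each estimator assumes, which parameters matter,
and where the design was genuinely open and a choice had to be made. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## The scientific setting

An N-of-1 trial crosses a single patient over between two treatments;
aggregating many such trials estimates a population-average treatment
effect difference with each patient acting as their own control. Without
wash-out phases in the design, **carry-over** — the residual effect of the
previous treatment — contaminates the contrast between treatment periods,
and time-varying covariates can both modify the treatment effect and be
affected by past treatment. The package simulates exactly this situation
for a study of two daily exercise regimens against chronic nonspecific low
back pain, and implements five analysis strategies whose bias and
efficiency can be compared under controlled conditions, because in
simulation the truth (an effect difference of 2 pain-scale points) is
known.

## Data-generating model

### Structural equations on a causal graph

Every variable $Z_i$ at day $t$ is a weighted sum of its parents plus
Gaussian noise,
$$Z^{t}_{i} = \sum_j \sum_{l \ge 0} w^{l}_{j,i}\, Z^{t-l}_{j} + \varepsilon_i,
  \qquad \varepsilon_i \sim N(\mu_i, \sigma_i^2),$$
where $l$ indexes lags (a lagged value before day 1 counts as zero).
Binary variables are produced by thresholding: $Z \mapsto 1\{Z \ge
\lambda\}$. Parent-free variables are drawn from declared distributions
(Gaussian, Bernoulli, Poisson or uniform) — once per patient for constant
baseline variables, freshly each day for time-varying ones. The graph,
distributions, weights and thresholds are declared in a YAML/JSON schema
(`inst/extdata/backpain_graph.yaml`) or imported from a plain `"A -> B"`
edge list; `parse_graph()` validates acyclicity of the instantaneous
subgraph, node references, and variance signs.

### The study graph and its default parameters

The packaged graph has twelve nodes: demographics; the constant binaries
education, work, previous diagnosis, chronic diseases; daily medication
use (binary), activity, stress and quality of sleep (Gaussian); treatment;
the pain outcome; and the latent underlying state. Demographics acts only
through proxies (education, work, activity, medication, previous
diagnosis, chronic diseases) — there is no direct demographics→pain edge —
and eight covariates are direct parents of pain.

The only weights fixed by the study description are the treatment effects
on pain: −2 (treatment 1) and −4 (treatment 2) versus no treatment, an
effect difference of 2. All other weights are package defaults, chosen
once at moderate size (|w| between 0.1 and 0.5 on standardised or binary
parents) so that covariate adjustment matters without dominating the
outcome; the pain equation's noise has mean 6 — the baseline intercept —
and SD 0.4, keeping both treatment arms well inside the 0–10 scale so
truncation (below) is rare. These defaults are declared, not inferred
from the original study.

Two conventions govern edges touching the categorical treatment node:

* an **instantaneous** treatment→covariate edge (treatment→stress,
  treatment→quality-of-sleep) is a treatment-*presence* effect, weight
  times $E_1^t + E_2^t$: every study day is under some treatment, so these
  always-on edges shift both arms equally and create no arm contrast —
  which is what makes *all* estimators unbiased in the scenario without
  carry-over or interaction;
* a **lagged** treatment→covariate edge is an arm contrast, weight times
  $1\{T^{t-l} = 2\}$; these edges (treatment→activity and
  treatment→quality-of-sleep at lag 1) exist only in the interaction
  scenarios and make the activity distribution differ between arms.

### Carry-over

Treatment reaches the outcome through exponential-decay exposure
indicators with wash-in $\tau_k \ge 1$ and wash-out $\gamma_k \ge 1$:
$$E_k^{t} = E_k^{t-1} + \frac{1-E_k^{t-1}}{\tau_k} T_k^{t}
  - \frac{E_k^{t-1}}{\gamma_k}\,(1-T_k^{t}), \qquad E_k^0 = 0,$$
so under sustained treatment $1 - E_k^t = (1-1/\tau_k)^t$ exactly, and the
outcome's treatment term is $\sum_k \beta_k E_k^t$. With $\tau = \gamma =
1$ the exposure equals the binary indicator and the machinery disappears.
The same recursion serves both generation and the COAPM analysis; the
generation side is a modelling choice here, made so that the analysis
model is *correctly specified up to the ordinal rounding* — the
deliberate, mild misspecification discussed next.

### Ordinal outcome, underlying state, drift

The continuous outcome $O^t = Z^t_{\text{pain}} + U^t + \varepsilon_o$ is
truncated to $[0, 10]$ and rounded to integers before it is emitted,
emulating a daily ordinal pain score; every analysis model then treats the
score as continuous Gaussian. This reproduces a misspecification that is
near-universal in practice. Tests that need exactness switch it off via
`ordinal_outcome = FALSE`.

The underlying state $U^t$ is a discrete-time Wiener process,
$U^t = U^{t-1} + N(\mu, \sigma^2)$ with $U^0 = 0$. Defaults are $\mu = 0$
(no systematic time trend, so unbiasedness statements are about the
treatment term) and $\sigma = 0.05$ per day, which accumulates to an SD of
about 0.5 over the 112-day study — visible autocorrelated wandering that
no analysis model adjusts for, but no drift large enough to push scores
against the scale bounds.

### Design, scenarios, cohorts

The crossover design is 2 blocks × two 28-day periods (16 weeks, 112
days); within each block the period order is drawn uniformly from
{AB, BA}, independently per patient. Four scenarios cross two switches:

| | no activity interaction | activity interaction |
|---|---|---|
| **no carry-over** | scenario 1: $\tau=\gamma=1$, $w_{A,T}=0$ | scenario 3 |
| **carry-over** | scenario 2: $\tau_1=6, \gamma_1=3, \tau_2=5, \gamma_2=4$ | scenario 4 |

In scenarios 3/4 the treatment contribution becomes
$(\beta_k + w_{A,T}(A^t - \bar A))\,E_k^t$ with $w_{A,T} = 0.3$, and the
lag-1 treatment edges into activity and quality of sleep are active. The
modifier is **centred** at the theoretical mean of activity
($\bar A = 0.5\,w^{l}_{T,A}$, since a day's predecessor is under treatment
2 with long-run probability 1/2), so the population-average effect
difference remains 2 — without centring, the interaction would silently
change the estimand that all methods are graded against.

A cohort (default 1000 patients) gives every patient an independent design
randomisation and an independent RNG sub-stream derived from the master
seed by a Lehmer-style integer hash (`derive_seed()`), making cohorts
bit-reproducible and patients exchangeable.

### Missingness

Two drop-out mechanisms mark whole days missing (row-wise across all
measurements; the treatment schedule columns survive, being design
quantities):

1. *random drop-out with increasing hazard*: day $t$ of an $n$-day record
   is deleted with probability $p_t = 2\,r\,t/(n+1)$, linear in time and
   calibrated so the expected deleted fraction is $r$ (default 10%). The
   linear ramp is the package's choice; only "increasing over time" is
   externally constrained.
2. *vacation*: one block of exactly 10 consecutive days, uniformly placed.

Analyses are complete-case throughout; no imputation is attempted.

## The estimators

All estimators report the treatment effect difference oriented so the
simulated truth is +2 (treatment 2 lowers pain more than treatment 1).

**Sample mean** — difference of pooled day-level means between arms. No
adjustment; its standard error is supplied only at the Monte-Carlo layer
(empirical SD across replicate samples), as is done for all methods
without a model-based SE.

**Linear model** — pooled OLS of pain on a treatment-2 indicator and the
eight direct covariate parents of pain, assuming independent
observations. Rank-deficient designs raise an error naming the collinear
columns rather than silently dropping them; in tiny samples a constant
binary covariate can therefore abort a replicate, which the Monte-Carlo
harness counts and reports instead of hiding.

**COAPM** — OLS on the decay-transformed exposures:
$$O^t = \beta_0 + \beta_1 E_1^t(\tau_1,\gamma_1)
  + \beta_2 E_2^t(\tau_2,\gamma_2) + \textstyle\sum_j \beta_{3,j} C_j^t
  + \varepsilon.$$
$(\tau_k, \gamma_k)$ are unknown and selected by maximising $R^2$ over the
integer grid $1..10$ per parameter. The package scans the **full joint
4-D grid by default**: after projecting the intercept-plus-covariate block
out of the outcome and out of each candidate exposure column
(Frisch–Waugh–Lovell), every candidate costs only a bivariate regression,
and the joint scan is both faster than coordinate-wise sweeps (the
residualisation dominates the runtime) and immune to the local optima the
coordinate scheme can stall in; the coordinate scheme remains available
via `joint = FALSE`. Ties break toward the lexicographically smallest
$(\tau_1,\gamma_1,\tau_2,\gamma_2)$; candidates with rank-deficient
designs are skipped — notably $\tau=\gamma=1$ for both treatments, where
$E_1 + E_2 \equiv 1$ collides with the intercept. The exposure recursion
runs **through** missing days using the known treatment schedule
(toggleable via `evolve_through_missing`); only masked rows leave the
regression. Coefficient SEs come from the selected model's OLS output.

**G-estimation** — a structural nested mean model with a single parameter.
Because the design has no untreated days, treatment is coded as a binary
contrast ($T = 1$ for treatment 2), making $\psi$ the average effect of
treatment 2 versus treatment 1 (truth −2; the reported estimate is
$-\hat\psi$). For candidate $\psi$, $H(\psi) = O - \psi T$ enters the
propensity model
$\text{logit}\,P(T = 1 \mid H(\psi), C) = \theta_0 + \theta_1 H(\psi) +
\sum_j \theta_{2,j} C_j$, fitted by GEE with an independence or AR1
working correlation; conditional exchangeability makes $\theta_1(\psi) =
0$ at the truth. The root is found by Brent's method over $[-10, 10]$
after probing the interval on a coarse grid — at extreme $\psi$ the term
$\psi T$ separates the propensity fit, so failed endpoint fits are treated
as unusable rather than fatal — with a 0.01-step grid scan as fallback
and a tolerance of $10^{-4}$ on $|\theta_1|$ at the solution. The GEE
solver is implemented in the package (Fisher scoring; AR1 parameter
re-estimated each step from lag-1 Pearson-residual autocorrelation; the
AR1 working inverse applied in closed tridiagonal form); under
independence it reproduces ordinary logistic maximum likelihood, which the
tests verify against `glm`.

**Bayesian networks** — every node of the assumed DAG (observed variables
only; the underlying state is latent and excluded) is fitted as a Bayesian
linear regression on its parents, all variables — including 0/1 binaries
and the 1/2-coded treatment — modelled as Gaussian. The prior is a weak
unit-information Gaussian equivalent to `prior_weight` pseudo-observations
(default 1): posterior-mean coefficients are the OLS solution shrunk by
$n/(n+w)$, reducing to OLS as $w \to 0$. The homogeneous Gaussian
treatment of mixed variables is a documented simplification that keeps the
intervention distribution tractable and path-tracing identities testable.
The effect difference is estimated by **intervention sampling**: 1000
forward samples per arm from the mutilated graph with the treatment node
clamped (for a point intervention this coincides with likelihood weighting
on point evidence), confounders sampled from their fitted models so both
arms share one confounder distribution, and the difference of mean
outcomes reported. The *time-adjusted* variant adds lag-1 nodes for
treatment and pain, created in preprocessing (each patient's first day is
dropped). The lag wiring is an interpretation the package documents and
defends: `pain_lag` is modelled on `treatment_lag` plus pain's covariate
parents, and `treatment_lag` is clamped together with `treatment` during
sampling. Under this wiring the attenuation of the current-treatment
coefficient caused by conditioning on the lagged outcome is exactly
compensated by the lagged outcome's own arm shift when there is no
carry-over (so the time-adjusted network stays unbiased in scenario 1),
while multi-day exponential carry-over — which a single lag cannot
represent — still biases it downward, as expected.

## Monte-Carlo harness

`run_scenario()` simulates one population per scenario (default 1000
patients), draws `replicates` (default 100) samples per sample size
**without replacement**, independently re-drawn per replicate (the
resampling-from-one-population reading; re-simulating populations per
replicate is the other defensible reading and would only widen the
spread), runs every requested method, and summarises the mean estimate
(bias) and the empirical SD of the estimates across replicates — the
study's efficiency measure and the "empirical standard error" referred to
throughout the package. Per-replicate seeds derive from (master seed,
scenario, missingness, size, replicate), so any cell can be reproduced in
isolation. Method failures on a replicate are caught, counted, and
excluded from the summaries; a cell with more than 10% failures is
flagged `degraded`. `full_study()` crosses all scenarios with and without
drop-out and renders the summary figure (`autoplot()`: estimate ±
empirical SE versus sample size, reference line at 2).

## Numerical choices and degenerate inputs

* Grid-search ties: strict $R^2$ improvement in lexicographic scan order,
  so exact ties resolve to the smallest parameters.
* Rank checks: explicit QR rank tests with errors naming offending
  columns; candidate-level deficiency inside the COAPM grid is skipped,
  and only an all-deficient grid errors.
* GEE: convergence at step size $10^{-8}$, maximum 50 iterations; the AR1
  parameter is clamped to $(-0.99, 0.99)$; divergence and separation abort
  with a condition class the root-finder can catch.
* Exposure recursion requires $\tau, \gamma \ge 1$ (values below 1 would
  overshoot $[0,1]$) and a 0/1 treatment series without NA.
* `derive_seed()` keeps all derived seeds below $2^{31}-1$ using only
  exact-double arithmetic.

## What the tests do and do not show

The test suite and acceptance script run at the study's own desk scale:
100 samples of 25 patients from one 1000-patient population per scenario,
2000 seeded applications of the drop-out mechanism, 10000 design
randomisations. These sizes were chosen as the package's own evaluation
conditions; at them, the unbiasedness checks use the empirical SD across
the 100 samples as the yardstick (a "within 3 empirical SEs" band), which
also absorbs the finite-population error of simulating one shared
population per scenario.

Passing tests show that the estimators behave as designed **on data whose
generating process matches the package's own simulator**: linear
structural equations, Gaussian noise, exponential-decay carry-over, a
single-dimension effect-modifier, missingness independent of unobserved
values. They do not show robustness to non-linear dependence, random
effects across patients (every patient shares the same structural
weights), informative drop-out, serially correlated measurement error
beyond the Wiener drift, or floor effects stronger than the mild
truncation simulated here. The COAPM's unbiasedness under carry-over, in
particular, reflects that its exposure model coincides with the
generator's; on real data the exponential-decay family is an assumption
like any other.

## Known limitations

* Fixed effects only; no between-patient heterogeneity in treatment
  effects or weights.
* The Bayesian network is linear-Gaussian throughout; binary nodes are
  modelled as Gaussian, so its per-node residual SDs are descriptive, not
  generative, for those nodes.
* G-estimation assumes conditional additive rank preservation and a
  correctly specified propensity model; only a single scalar $\psi$ is
  estimated.
* The CLI and I/O layer handle the package's own long CSV schema; they are
  not general trial-data importers.
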