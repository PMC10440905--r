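# nofonesim

Simulation and causal analysis of **aggregated N-of-1 trials with
carry-over**.

N-of-1 trials are multi-crossover studies in which each patient alternates
between treatments and serves as their own control; a *series* of such
trials can be analysed jointly to estimate a population-level treatment
effect. Two features make that analysis hard in practice: **carry-over**
(one treatment's effect persisting into the next period when the design has
no wash-out phases) and **treatment–covariate dependence** (the effect
being modified by, and temporally entangled with, time-varying covariates
such as physical activity). This package provides, for biostatisticians
studying such designs:

* a **simulator** for cohorts of per-day N-of-1 trajectories generated from
  a causal DAG with time-varying linear structural equations, emulating a
  two-block, four-period (4 × 28 days) crossover study on chronic
  nonspecific low back pain with treatment effects −2 and −4 on a 0–10
  pain scale;
* five **estimators** of the average treatment effect difference (truth
  +2): the naive sample-mean contrast, covariate-adjusted OLS, a
  carry-over adjusted parametric model (COAPM), G-estimation of a
  structural nested mean model with GEE propensity fits (independence or
  AR1 working correlation), and linear-Gaussian Bayesian-network
  estimation with optional lag-1 time adjustment;
* a **Monte-Carlo harness** comparing bias and efficiency of all methods
  across scenarios, sample sizes, and drop-out conditions.

## The models in brief

**Data generation.** Each variable follows
`Z_i^t = Σ_j Σ_l w_{j,i}^l · Z_j^{t−l} + ε_i` with Gaussian noise, optional
step-function binarisation, and a latent underlying state `U^t` following a
discrete-time Wiener process. Treatment enters the outcome through
exponential-decay exposure indicators: while treatment `k` is given,
`E_k^t` relaxes towards 1 at wash-in rate `1/τ_k`; while it is not,
towards 0 at wash-out rate `1/γ_k`:

```
E_k^t = E_k^{t−1} + (1 − E_k^{t−1})/τ_k · T_k^t − E_k^{t−1}/γ_k · (1 − T_k^t),   E_k^0 = 0
```

so the outcome's treatment term is `Σ_k β_k · E_k^t` with `β_1 = −2`,
`β_2 = −4`. Four scenarios cross carry-over
(`τ_1 = 6, γ_1 = 3, τ_2 = 5, γ_2 = 4` vs `τ = γ = 1`) with an
activity–treatment interaction (`w_{A,T} ≠ 0` plus lag-1 effects of
treatment on activity and sleep quality).

**COAPM.** OLS of the outcome on `E_1^t`, `E_2^t` and the covariates, with
`(τ_k, γ_k)` chosen by an R²-maximising grid search over the integer grid
1..10; `β̂_1 − β̂_2` is the carry-over adjusted effect-difference estimate.

**G-estimation.** With `T = 1` coding treatment 2, find `ψ` such that the
residualised outcome `H(ψ) = O − ψT` carries no information about treatment
in the propensity model
`logit P(T=1 | H(ψ), C) = θ_0 + θ_1 H(ψ) + Σ_j θ_{2,j} C_j`
(root of `θ_1(ψ)`, GEE fit with independence or AR1 working correlation).

**Bayesian network.** Every node of the assumed DAG is fitted as a
Bayesian linear regression on its parents; the effect difference is the
difference of mean outcomes between two 1000-draw forward samples with the
treatment node clamped to each arm.

## Worked example

Simulate 25 patients under scenario 2 (strong carry-over, complete data)
and compare estimators:

```r
library(nofonesim)
cfg <- scenario_config(2)               # tau = (6, 5), gamma = (3, 4)
co  <- simulate_cohort(cfg, n_patients = 25, seed = 12)

tidy(sample_mean_estimate(co))
#> # A tibble: 1 × 3
#>   method      estimate    se
#>   <chr>          <dbl> <dbl>
#> 1 sample_mean     1.60    NA

coapm_grid_search(co)
#> <coapm_fit> effect difference: 2.02 (SE 0.0261 )
#>   beta1: -1.898 | beta2: -3.918 | R^2: 0.7526
#>   selected tau/gamma: 6 3 (trt 1); 5 4 (trt 2) in 1 sweep(s)

glance(g_estimate(co, correlation = "ar1"))[, c("method", "estimate")]
#> # A tibble: 1 × 2
#>   method   estimate
#>   <chr>       <dbl>
#> 1 gest_ar1    0.427
```

The naive contrast (1.60) underestimates the true difference of 2 because
the slowly washing-in effect never reaches full strength on most treated
days; AR1 G-estimation (0.43) is hit hardest because exponential-decay
carry-over violates its working correlation; COAPM recovers both the
generating wash-in/wash-out parameters (6, 3 and 5, 4) and the effect
difference (2.02), with per-treatment effects near −2 and −4.

The full comparison (all scenarios × methods × sample sizes, with and
without drop-out) runs via `full_study()` or the bundled CLI:

```sh
Rscript inst/cli/nof1.R evaluate --scenarios 1,2,3,4 --replicates 100 --seed 1 --out results/
```

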