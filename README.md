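# cpssd — Bayesian sample size determination with commensurate predictive priors

`cpssd` computes fully Bayesian sample sizes for experiments comparing two
group means, where relevant pre-experimental information — historical
studies or elicited expert opinion, possibly from several sources of
varying relevance — is folded into a robust prior used for both the design
and the analysis. The package is aimed at statisticians planning
experiments in which frequentist power calculations are infeasible or
wasteful, the canonical case being rare-disease clinical trials with
elicited expert priors on a log-odds-ratio scale.

## The model

Each of K sources summarizes its evidence about the effect as a normal
summary θ_k | y_k ~ N(m_k, s_k²), together with a prior probability of
incommensurability w_k ∈ [0, 1] (w_k = 1: no borrowing; w_k = 0: no
robustification). The source's parameter is projected to the scale of the
new experiment through a commensurate predictive distribution

  θ̃_k | θ_k, ν_k ~ N(θ_k, 1/ν_k),
  ν_k ~ w_k · Gamma(a01, b01) + (1 − w_k) · Gamma(a02, b02),

with the first Gamma component concentrated on small precisions
(down-weighting) and the second on large precisions (borrowing).
Marginally θ̃_k | θ_k is a two-component mixture of nonstandardized t
distributions; its moment-matched normal approximation has variance
inflation w_k·b01/(a01−1) + (1−w_k)·b02/(a02−1), requiring a01, a02 > 1.
The K approximated predictive priors are combined linearly with softmax
synthesis weights

  p_k ∝ exp(−w_k²/s0),

giving the normal collective prior μ_Δ ~ N(Σ p_k m_k, Σ p_k² ξ_k²) with
ξ_k² = s_k² + inflation(w_k). The new experiment's data enter through the
difference in sample means X̄_Δ ~ N(μ_Δ, (1/n_A + 1/n_B)σ0²).

Sample sizes are the smallest designs meeting one of three pre-posterior
criteria, averaged over the predictive distribution of the data:

* **ACC** — the average coverage of the length-ℓ0 HPD interval centred at
  the posterior mean is at least 1 − α; known σ0² gives the closed form
  n_A n_B/(n_A + n_B) ≥ (4 z²_{α/2}/ℓ0² − 1/Σp_k²ξ_k²)·σ0².
* **ALC** — the average length of the 1 − α0 credible interval is at most
  ℓ (identical to the ACC when σ0² is known).
* **APVC** — the average posterior variance is at most ε0:
  n_A n_B/(n_A + n_B) ≥ (1/ε0 − 1/Σp_k²ξ_k²)·σ0².

When σ0² is unknown it carries the prior Inv-Gamma(c/2, c·Σp_k²ξ_k²/2)
anchored to the collective prior; the ACC and APVC substitute
E[σ0²] = cV/(c − 2) (c > 2), while the ALC has no closed form and is
solved by an integer search with quadrature over the variance prior.

## Worked example

Five expert opinions about a log-odds ratio of remission, summarized as
N(−0.26, 0.25), N(−0.24, 0.23), N(−0.37, 0.22), N(−0.34, 0.36),
N(−0.32, 0.26) with incommensurability weights 0.15, 0.20, 0.17, 0.13,
0.20:

```r
library(cpssd)

experts <- as_historical_summaries(data.frame(
  label = paste0("expert", 1:5),
  mean = c(-0.26, -0.24, -0.37, -0.34, -0.32),
  variance = c(0.25, 0.23, 0.22, 0.36, 0.26),
  w = c(0.15, 0.20, 0.17, 0.13, 0.20)))

prior <- collective_prior(experts)   # Gamma(2,2)/Gamma(18,3), s0 = 0.05
prior
#> Collective prior: mu_Delta ~ N(-0.309, 0.154)  [K = 5 sources]
#>     label     w     p lambda   xi2
#> 1 expert1 0.150 0.227  -0.26 0.700
#> 2 expert2 0.200 0.160  -0.24 0.771
#> ...

acc_known(prior, l0 = 0.65, alpha = 0.05, sigma0_sq = 0.35)
#> ACC sample size (allocation ratio 1):
#>   continuous total: 41.8  (n_A = 20.92, n_B = 20.92)
#>   integer total:    42  (n_A = 21, n_B = 21)

vp <- variance_prior_from_collective(prior, c = 5)
vp
#> Unknown common variance: sigma0^2 ~ Inv-Gamma(2.5, 0.3855)  [c = 5]
#>   E[sigma0^2] = 0.257

acc_unknown(prior, l0 = 0.65, alpha = 0.05, vp)$continuous_total   # 30.72
alc_unknown(prior, l = 0.65, alpha0 = 0.05, vp)$integer_total      # 24
apvc_unknown(prior, eps0 = 0.03, vp)$continuous_total              # 27.60
```

So borrowing the expert opinion, a 95% average-coverage HPD interval of
length 0.65 needs 42 subjects with a known variance of 0.35, but only
30.7 (continuous; ACC) or 24 (ALC) when the unknown variance is itself
informed by the collective prior with c = 5.

The returned ALC design (12 per group) can be verified by Monte Carlo —
its average 95% interval length indeed stays below 0.65:

```r
simulate_average_properties(prior, design_spec(12), vp, l0 = 0.65,
                            reps = 1e5, seed = 20220328)
#> Monte-Carlo average posterior properties (100000 reps, seed 20220328)
#>   design: n_A = 12, n_B = 12
#>   avg coverage of length-0.65 HPD: 0.9378 (SE 0.00021)
#>   avg 95% interval length:     0.6485 (SE 0.00058)
#>   avg posterior variance:        0.02955 (SE 5.6e-05)
```

(The 0.9378 average coverage shows why the ACC asks for ~31 subjects
rather than 24: coverage at the smaller ALC design falls short of 95%.)

Comparison modes (`comparison_modes()`) recompute a criterion with no
robustification (all w_k = 0), no borrowing (all w_k = 1), a single
most-informative source, and the perfect-commensurability benchmark;
`sensitivity_sweep()` tabulates any criterion over grids of c, targets
and the borrowing Gamma component. A thin command-line interface wraps
these functions:

```sh
Rscript inst/cli/ssd.R ssd --scenario expert5 --criterion acc \
    --variance known --sigma0-sq 0.35 --l0 0.65 --alpha 0.05
Rscript inst/cli/ssd.R compare --scenario config3_RWI --criterion acc \
    --variance unknown --c 3
```

Configuration-file driven runs (JSON or YAML) with JSON/CSV reports are
available through `load_config()` / `run_ssd()`.

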