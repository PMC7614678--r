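---
title: "Sample size determination with commensurate predictive priors: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample size determination with commensurate predictive priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpssd)
```

## The inferential problem

A new two-group experiment will compare means $\mu_A$ and $\mu_B$ with a
common sampling variance $\sigma_0^2$; the estimand is
$\mu_\Delta = \mu_A - \mu_B$. Before any data exist, $K$ pre-experimental
sources (historical studies, or experts whose elicited opinions have been
summarized probabilistically) each supply a normal summary
$\theta_k \mid y_k \sim N(m_k, s_k^2)$ of their own version of the
effect, together with a weight $w_k \in [0,1]$ expressing the prior
probability that $\theta_k$ is *incommensurate* with $\mu_\Delta$. The
design question is the smallest $(n_A, n_B)$ for which the posterior of
$\mu_\Delta$, averaged over the data that might be observed, is
adequately concentrated. This is the natural formulation when frequentist
power is unattainable — the motivating case being rare-disease trials,
where the effect scale is typically a log-odds ratio of response
(`log_odds_summary()` converts a 2×2 count table, with the
Haldane–Anscombe 0.5 correction when a cell is empty).

## From per-source summaries to a collective prior

Each source is projected to the new experiment's parameter space through
a commensurate predictive distribution
$\tilde\theta_k \mid \theta_k, \nu_k \sim N(\theta_k, 1/\nu_k)$ whose
precision has the two-component mixture prior
$\nu_k \sim w_k\,\mathrm{Ga}(a_{01}, b_{01}) + (1-w_k)\,\mathrm{Ga}(a_{02}, b_{02})$.
Integrating $\nu_k$ out gives a two-component mixture of nonstandardized
$t$ distributions with common location $\theta_k$, degrees of freedom
$2a_{01}$ and $2a_{02}$ and scales $\sqrt{b_{01}/a_{01}}$,
$\sqrt{b_{02}/a_{02}}$ (`predictive_density()`). For tractable synthesis
the mixture is replaced by its moment-matched normal, whose variance is
exactly the mixture variance
$w_k b_{01}/(a_{01}-1) + (1-w_k) b_{02}/(a_{02}-1)$
(`predictive_inflation()`; this is why both shapes must exceed 1).
`normal_approximation_error()` quantifies the cost of the approximation —
sup-norm and Kolmogorov distances between the $t$-mixture and the normal
on a dense grid — so a user can check it for their own hyperparameters
before trusting the closed forms downstream.

The sources are then combined as $\mu_\Delta = \sum_k p_k \tilde\theta_k$
with softmax synthesis weights $p_k \propto \exp(-w_k^2/s_0)$
(`synthesis_weights()`), yielding the collective prior
$\mu_\Delta \sim N(\sum_k p_k m_k, \sum_k p_k^2 \xi_k^2)$,
$\xi_k^2 = s_k^2 + \text{inflation}(w_k)$ (`collective_prior()`).

### Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| $a_{01}, b_{01}$ | down-weighting Gamma component (small precisions) | Gamma(2, 2) | adds variance $b_{01}/(a_{01}-1) = 2$ at $w=1$: a source believed incommensurate contributes almost nothing |
| $a_{02}, b_{02}$ | borrowing component (large precisions) | Gamma(18, 3) | adds only $3/17 \approx 0.18$ at $w=0$: near-full pooling |
| $s_0$ | synthesis concentration | 0.05 | small relative to typical $w_k$, so modest differences in $w_k$ translate into clearly differentiated $p_k$; $s_0 \to \infty$ gives uniform weights, $s_0 \to 0^+$ lets the smallest $w_k$ dominate (exact ties split equally — forced by the softmax form) |
| $w_k$ | prior probability of incommensurability | — (user input) | elicited; `hellinger_matrix()` reports pairwise Hellinger distances between the source summaries as an aid, but no automatic distance-to-$w$ mapping is imposed, since any such rule would be an additional modelling assumption |
| $c$ | variance-prior degrees of freedom | — (user input) | see below |

Validation is deliberately asymmetric: $a_{0j} \le 1$ is a hard error
(the moment match is undefined), while a component-1 mean inflation not
exceeding component 2's is only a warning — the model remains
well-defined, but the down-weighting/borrowing interpretation of $w_k$
inverts, which the user must consciously accept.

## Posterior, predictive, and the three criteria

The likelihood enters through the sufficient statistic
$\bar X_\Delta \sim N(\mu_\Delta, (1/n_A + 1/n_B)\sigma_0^2)$; all
formulas depend on the design only through the effective size
$e = n_A n_B/(n_A+n_B)$ (`effective_size()`; $e = N/4$ under equal
allocation with total $N$). With $V = \sum p_k^2\xi_k^2$:

* known $\sigma_0^2$: conjugate normal posterior with precision
  $1/V + e/\sigma_0^2$ (`posterior_known_variance()`);
* unknown $\sigma_0^2 \sim \text{Inv-Gamma}(c/2,\ cV/2)$
  (`variance_prior_from_collective()`; equivalently
  $cV/\sigma_0^2 \sim \chi^2(c)$): the marginal posterior is proportional
  to a normal × nonstandardized-$t$ kernel product
  (`marginal_posterior_unknown_variance()`), normalized numerically.

The three pre-posterior criteria and their solvers:

* **ACC** (`acc_known()`, `acc_unknown()`): average coverage of the
  length-$\ell_0$ HPD interval centred at the posterior mean $\ge 1-\alpha$.
  Known variance: $e \ge (4z_{\alpha/2}^2/\ell_0^2 - 1/V)\sigma_0^2$.
  Unknown: $\sigma_0^2$ is replaced by its prior mean $cV/(c-2)$, so
  $c \le 2$ is a hard error (the required moment does not exist), not a
  silent fallback.
* **ALC** (`alc_known()`, `alc_unknown()`): average $1-\alpha_0$ credible
  length $\le \ell$. Known variance: identical to the ACC (the length is
  deterministic given the design), implemented as an exact delegation.
  Unknown: no closed form; see the search below.
* **APVC** (`apvc_known()`, `apvc_unknown()`): average posterior variance
  $\le \varepsilon_0$; same structure with $1/\varepsilon_0 - 1/V$.

When the right-hand side of an inequality is non-positive, the prior
alone already meets the target; the result is reported as zero with a
`binding` flag rather than a negative size.

## Numerical choices

* **ALC expectation.** The quantity needed is
  $E_{\sigma_0^2}[(1/V + e/\sigma_0^2)^{-1/2}]$. Substituting the
  precision $u = 1/\sigma_0^2 \sim \mathrm{Ga}(c/2, cV/2)$ bounds the
  integrand by $\sqrt V$; integrating over the probability scale
  ($u = F^{-1}(p)$, $p \in (0,1)$, absolute tolerance $10^{-10}$) keeps
  the quadrature accurate for *every* $c > 0$, including near-degenerate
  priors ($c \sim 10^6$) used as known-variance benchmarks, where a naive
  integral over $(0, \infty)$ misses the spike entirely.
* **ALC integer search.** The average length is strictly decreasing in
  the total $N$, so the solver bisects over integer totals, bracketed
  above by the ACC solution when $c > 2$ (the ALC never needs more
  subjects than the ACC at matching targets, by Jensen's inequality
  applied to $E[\sigma_N] \le \sqrt{E[\sigma_N^2]}$) and by geometric
  expansion otherwise. The default granularity is *one* in the total with
  effective size $NR/(1+R)^2$: odd totals are admissible, consistent with
  reporting the tightest integer design; `step = 2` restricts to
  per-group-integer designs under equal allocation. The result records
  the average length at $N$ and at $N - \text{step}$, so the boundary is
  auditable.
* **Marginal-posterior normalization** uses adaptive quadrature on a
  window of ±15 combined scales around the prior mean and the observed
  statistic (absolute tolerance $10^{-10}$); non-convergence is raised as
  an error with the integrator's diagnostics, never silently truncated.
* **Approximation diagnostic grid**: location ±12 combined scales, 4001
  points, locally refined around the largest discrepancy — wide enough to
  capture the heavy $t$ tails at 4 degrees of freedom.
* **Continuous vs integer reporting.** Closed-form criteria report the
  continuous total (matching the 1-d.p. convention of the worked
  examples) plus per-group ceilings; the ALC reports integers only.
  $z$-quantiles are computed at full double precision.
* **General allocation.** All solvers accept a ratio $R = n_B/n_A$,
  inverted through `groups_from_effective()`; the default $R = 1$ covers
  the standard equal-allocation case.

## The Monte-Carlo evaluator and what it does (not) show

`simulate_average_properties()` verifies a returned design by direct
simulation of the design-stage model: per replicate it draws
$\sigma_0^2$ from its prior (unknown mode), then
$\bar x_\Delta \sim N(\text{prior mean}, \sigma_0^2/e + V)$, forms the
conditional-normal posterior, and records the HPD coverage, the credible
length and the posterior variance; averages carry standard errors
(sample SD/$\sqrt{\text{reps}}$; default $10^5$ replicates,
seed 20220328, bit-reproducible for fixed inputs). Coverage is evaluated
under the conditional-normal representation given the drawn variance —
the representation from which the closed-form criteria are derived — with
a `marginal = TRUE` flag to cross-check against the variance-integrated
posterior by quadrature. Both representations are exposed because
reported credible intervals in an eventual analysis could legitimately
use either.

The generator emulates exactly the study conditions of the built-in
scenarios (`builtin_scenarios()`): a five-expert elicited example and
four historical-data configurations, each under two robust weight sets,
spanning consistent/divergent sources and high/low informativeness. What
it does *not* emulate: non-normal raw outcomes (only the asymptotic
normal summary statistic is simulated), analysis under the exact
$t$-mixture prior rather than its normal approximation, per-subject
accrual, and prior–data conflict in the realized trial. Passing checks
therefore validate the design calculus given the model, not robustness of
the model itself to misspecified summaries.

Problem sizes used by the default test-bed: $10^5$ Monte-Carlo replicates
for the criterion checks ($10^6$ for the convergence-to-quadrature
check), dense grids of $2$–$4 \times 10^5$ points for density oracles —
sizes at which the Monte-Carlo standard errors are an order of magnitude
below the tolerances being asserted.

## Design choices where the design was open

* **Comparison modes** (`comparison_modes()`): in unknown-variance mode
  each strategy (robust / no-robustification / no-borrowing /
  single-source / optimal) anchors the inverse-gamma prior to *its own*
  collective variance, so "no borrowing" forgoes historical information
  through the variance channel too — matching the interpretation of the
  benchmark comparisons. The optimal benchmark equates $\sigma_0^2$ with
  the robust collective variance (known mode) or uses $c = 10^6$
  (unknown mode).
* **Single-source mode** uses the source with the smallest $s_k^2$
  directly as $N(m_k, s_k^2)$, with no commensurability inflation — it
  represents the alternative of trusting one dataset outright.
* **Ties at $s_0 \to 0^+$** split the limiting synthesis weight equally
  among the minimizing sources; the softmax functional form forces this
  and it is documented rather than configurable.
* **Elicitation of $w_k$** is supported only descriptively (the
  Hellinger-distance matrix); imposing a functional $H \mapsto w$ map was
  rejected as an unfounded extra assumption.
* **Configuration interface**: one structured key-value document (JSON
  and YAML both accepted), builtin-scenario labels, CSV summaries or
  inline sources; reports echo every input (audit trail) and identical
  configurations yield byte-identical JSON reports.

## Known limitations

* The collective prior relies on the normal approximation of the
  $t$-mixture predictives; with very small $a_{0j}$ (heavy tails) the
  approximation error reported by `normal_approximation_error()` grows,
  and the closed-form sizes inherit it.
* Unknown-variance ACC/APVC require $c > 2$; designs wanting an even
  vaguer variance prior must use the ALC, which is defined for all
  $c > 0$.
* A common variance across arms is assumed throughout; unequal-variance
  designs are out of scope.
* The criteria control *average* posterior properties; they do not
  control frequentist type-I error, and no interim re-estimation of
  $w_k$ is provided.

```{r example}
prior <- collective_prior(get_scenario("expert5")$sources)
vp <- variance_prior_from_collective(prior, c = 5)
c(acc = acc_unknown(prior, 0.65, 0.05, vp)$continuous_total,
  alc = alc_unknown(prior, 0.65, 0.05, vp)$integer_total,
  apvc = apvc_unknown(prior, 0.03, vp)$continuous_total)
```
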