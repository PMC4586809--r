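---
title: "Modelling ethnic disparities in areal cancer incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ethnic disparities in areal cancer incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(arealdisp)
```

## The problem

Cancer registries report case counts by area (county), year and ethnic
group. The scientific question `arealdisp` addresses is whether a focal
group (here: a Hispanic population, against a non-Hispanic reference)
carries systematically higher incidence than the reference group, whether
that disparity varies over space, and where it clusters. Raw standardized
incidence ratios (SIRs) answer none of this reliably: most counties are
small, many focal-group county-years record zero cases, and the SIR of a
county-year with one expected case is mostly noise. Hierarchical Bayesian
disease mapping borrows strength across neighbouring areas and across years
to produce stable, smoothed risk and disparity estimates.

## Indirect standardization

For county $i$, year $j$, group $k$ the observed SIR is
$\mathrm{SIR}_{ijk} = y_{ijk}/e_{ijk}$ with expected counts computed under
an equal-risk assumption: $e_{ijk} = n_{ijk} \, r_k$, where $r_k$ is the
group's statewide rate pooled over the whole study period (all cases over
all person-years). Rates are computed per group *and* per cancer type;
cancer types are independent strata throughout and share no parameters.
Person-years are populations summed over years with no mid-year
adjustment — the package makes no interpolation assumption. `sir_ratio_by_year()`
summarizes the observed disparity per year as a ratio of group-wise county
means; the ratio-of-means is the default because it is robust to
zero-denominator counties (the mean-of-ratios variant is available via
`method = "mean_of_ratios"`).

## The three models

Counts are Poisson: $y_{Cijk} \mid \theta_{Cijk} \sim
\mathrm{Poisson}(e_{Cijk}\,\theta_{Cijk})$, with the log relative risk

$$\ln(\theta_{Cijk}) = \alpha_C + \delta_{Ci}\,\mathrm{eth}_{k} +
\textstyle\sum_m \beta_{Cm} x_{im} + u_{Ci} + v_{Ci} + t_{Cj} + \psi_{Cij}.$$

The convolution $u + v$ is the Besag–York–Mollié prior: $u$ is an intrinsic
CAR (ICAR) effect whose full conditional centres each county on the mean of
its contiguity neighbours with conditional variance $1/(\tau_u n_i)$, and
$v$ is exchangeable Gaussian heterogeneity. $t_j$ is an exchangeable year
effect and $\psi_{ij}$ an independent space–time interaction (the simplest,
"Type I", interaction structure). The three models differ only in the
disparity coefficient multiplying the focal-group indicator:

* **Model 1** — a single statewide $\delta_0$ (fixed disparity);
* **Model 2** — $\delta_0 + \delta_i$ with exchangeable $\delta_i \sim
  N(0, \tau_\delta)$ (unstructured random slopes);
* **Model 3** — $\delta_0 + \delta_i$ with ICAR-distributed $\delta_i$
  (a spatially varying coefficient, smoothing the disparity over neighbours).

All normal priors are parameterized by mean and *precision*
($\tau = 1/\sigma^2$). Fixed effects carry vague $N(0, 10^{-4})$ precision
priors, the intercept an improper flat prior, and every precision a
$\mathrm{Gamma}(0.5, 0.0005)$ prior (prior mean 1000), with a flat
$\mathrm{Uniform}(0, 10^5]$ alternative used by the sensitivity harness.

### Reading the ICAR notation

Conditional autoregressive priors are sometimes written with their second
argument ambiguous between a variance and a precision. Taken literally as a
conditional *precision*, $\tau_u/n_i$ would make an area's conditional
variance grow with its neighbour count, inverting the usual information
pooling. The package implements the conventional Besag form — conditional
variance $1/(\tau_u n_i)$ — which is the behaviour of standard ICAR
implementations and the only reading consistent with the BYM model the
specification cites. Equivalently the joint (improper) density is
$\exp\{-\tfrac{\tau}{2}\sum_{i\sim j}(x_i-x_j)^2\}$, a degenerate Gaussian
with precision matrix $\tau(D-W)$.

### Identifiability

The ICAR prior is improper (constant shifts are unpenalized) and the
exchangeable year and disparity-deviation blocks are weakly confounded with
the intercept and $\delta_0$. The package imposes sum-to-zero constraints on
$u$, $t$ and (Models 2–3) $\delta_i$ by recentering after every sampler
sweep, absorbing the removed means into $\alpha$ and $\delta_0$ so the
linear predictor — and hence the likelihood — is unchanged by the move.
Model 2's disparity is parameterized as a fixed mean $\delta_0$ plus
zero-centred deviations (the mean-plus-deviation reading of a random-slope
model). Areas with no neighbours get $u_i$ fixed at zero; their spatial
signal is absorbed by $v_i$. Covariates are z-scored by default
(`standardize_covariates` in `model_spec()`) so coefficient scales are
comparable across covariates; effect magnitudes on raw proportions are not
directly comparable to analyses that scaled differently.

## Inference

`fit_model()` runs an adaptive Metropolis-within-Gibbs sampler:

* $\alpha$ is drawn exactly from its conjugate conditional (a log-Gamma
  distribution, available because the prior is flat);
* $\delta_0$ and each $\beta$ use Gaussian random-walk steps;
* random-effect blocks use element-wise random-walk steps. Exchangeable
  blocks ($v$, $t$, $\psi$, Model 2 $\delta$) have mutually independent full
  conditionals and are proposed and accepted simultaneously; ICAR blocks
  ($u$, Model 3 $\delta$) are updated simultaneously within colour classes
  of a greedy proper colouring of the contiguity graph, so no two
  interacting sites ever move together;
* precisions are drawn from conjugate Gamma conditionals (ICAR blocks use
  rank $n - c$ degrees of freedom, $c$ the number of graph components;
  constrained exchangeable blocks lose one degree of freedom). Under the
  flat prior the conditional is an upper-truncated Gamma, sampled by
  inverse CDF;
* each hierarchical block additionally gets a joint scaling move
  $(x, \tau) \to (c\,x, \tau/c^2)$ per sweep. The Gaussian prior density
  times the Jacobian reduces to $c^{-2}$ for any block rank, so the
  acceptance ratio involves only the likelihood and the $\tau$ hyperprior.
  Without it, a block can fall into a quasi-absorbing regime — effects
  collapsed at zero, precision at the top of its prior range — that
  element-wise updates with adapted step sizes cannot leave (a failure mode
  the flat precision prior makes especially sticky).

Proposal scales adapt toward 44% acceptance during burn-in only and are
frozen afterwards, preserving detailed balance for the retained draws.
Initialization: $\alpha = \log(\sum y / \sum e)$, random effects at small
random values (exactly-zero starts make the first conjugate precision draw
degenerate), precisions at their prior mean with updates held for a short
warm-up. Chains use seeds derived from the configured seed, so identical
configurations reproduce bitwise-identical output. Cells with $e = 0$ (zero population at risk) are retained in the
panel but excluded from the likelihood, since the log link is undefined
there. Summaries are posterior means with equal-tailed 95% credible
intervals.

Defaults (`mcmc_config()`): 2 chains, 10,000 sweeps, 5,000 burn-in,
thinning 5. The package's own validation experiments use one or two shorter
chains (3,000–4,000 sweeps) at panel sizes of 254 areas × 9 years and
100 × 5; at those sizes the mean disparity's posterior mean is recovered
within ±0.05 and its 95% interval covers the truth at the nominal rate
(see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`, which
recompute these rates from scratch).

A practical mixing note: $\tau_u$ and $\tau_v$ are jointly weakly
identified (the classic BYM confounding between correlated and uncorrelated
heterogeneity), so their individual chains mix slowly even when the fitted
risk surface, $\delta_0$ and the DIC are stable. `convergence()` reports
split-$\hat R$ and effective sample sizes so this is visible.

## Model comparison and cluster detection

`dic()` computes $\bar D$ (posterior mean deviance), a plug-in deviance at
the posterior mean of each cell's *log* relative risk (the canonical
scale — the standard Spiegelhalter construction), $p_D = \bar D - \hat D$
and $\mathrm{DIC} = \bar D + p_D$. Lower is better; `compare_models()`
ranks fits and reports $\Delta$DIC. Because the plug-in differs slightly
between implementations (e.g., approximation-based fitters), DIC values are
comparable within a fitter, not across fitters. Negative $p_D$ is flagged,
never hidden.

`exceedence()` reports $\Pr(\theta > \theta^*)$ from the retained draws.
The default level is the per-area disparity relative risk
$e^{\delta_0+\delta_i}$ — "where is focal-group risk more than
$\theta^* = 1.25$ times reference risk?" — because that is the
cluster-detection question for disparities; cell-level fitted-SIR
exceedence is available for year-by-year risk maps (`level = "cell"`,
requires `keep_eta = TRUE`). Probabilities are banded at 0.8 and 0.95 for
presentation; 0.95–1 is conventionally read as a significant cluster.

## The synthetic generator

`gen_config()` defaults define the package's reference study conditions:

* 254 areas × 9 years × 2 groups per cancer type, two independent cancer
  strata (digestive, respiratory) with separate truths;
* area populations log-normal (median 20,000, sdlog 1.6 — county sizes
  spanning hamlets to metropolitan cores), constant over years;
* focal-group share Beta(1.2, 3.8): most areas have small focal
  populations, a few are majority-focal. This — not zero-inflation — is
  what produces realistic focal zero-count sparsity: at the default rates,
  25–46% of focal county-years record zero cases, matching the range
  reported for Hispanic county-year zero counts in the Texas registry
  panel the generator emulates;
* group reference rates chosen at registry magnitudes (digestive:
  9.5/4.6 cases per 10,000 person-years for reference/focal; respiratory:
  8.8/2.9) — the focal crude rates are lower, consistent with a younger
  focal population, while the modelled disparity acts on *standardized*
  risk;
* truth values: $\delta_0 = 0.15$, intercepts and covariate effects at
  fitted-model magnitudes, precisions $\tau_u = 429$, $\tau_v = 93$,
  $\tau_t = 478$, $\tau_\psi = 297$, $\tau_\delta = 16$ for the digestive
  stratum (respiratory analogues in `gen_config()`), i.e., a pronounced
  spatially varying disparity over a mild convolution surface.

The ICAR truth is simulated exactly on the sum-to-zero subspace via the
spectral decomposition of $D - W$ (the conditional specification alone does
not define a proper joint). Expected counts returned by the generator apply
the configured group rates to the simulated populations — the
indirect-standardization construction with the generator's statewide rates
taken as known. Re-deriving rates internally from a simulated panel would
fold the average disparity into the focal group's rate (both groups'
SIRs would average one by construction), leaving $\delta_0$ identified only
through the covariance of risk with population weights; fixing the
reference rates keeps the recovery target well-defined. `statewide_rates()`
remains the right construction for real registry panels, where the
analyst has no external rates.

What the generator does *not* emulate: real county geography (graphs are
lattices or random planar triangulations), population growth, migration,
age structure and age-specific rates, registry suppression rules, or
reporting delay. Passing recovery tests therefore demonstrates correctness
of the inferential machinery under the stated model, not robustness to the
ways real registry data violate it.

## Numerical and design choices

* Queen/rook contiguity from polygons uses exact coordinate matching after
  snapping to a $10^{-9}$ grid: queen requires a shared snapped vertex,
  rook a shared boundary segment. Administrative boundary files have
  exactly coincident shared vertices, and snapping makes graph construction
  deterministic; the package deliberately does no geometry repair.
* Graph colouring for the ICAR updates is greedy (largest degree first);
  any proper colouring is valid, the colouring only affects update order.
* The linear predictor is maintained incrementally during sampling and
  recomputed exactly every 250 sweeps to cap floating-point drift; a test
  verifies the incremental state against the exact predictor.
* Panels with all-zero counts cannot be fit (the intercept's conditional
  is then improper); `fit_model()` refuses them with an error.
* Degenerate fits for validation: `components = "none"` reduces the model
  to the intercept (plus covariates), which has a closed-form posterior
  against which the sampler is checked.
* DIC's plug-in uses the posterior mean of $\log\theta$, not of $\theta$;
  on the $\theta$ scale Jensen's inequality would shift $p_D$.

## Known limitations

* The sampler is single-machine, in-R; fits at registry scale take seconds
  to tens of seconds, and the package favours clarity over raw speed.
* $\tau_u$/$\tau_v$ mixing is slow (see above); report the convolution sum
  $u + v$, or run longer chains, when the split matters.
* Only the Type I (independent) space–time interaction is provided;
  structured interactions and random-walk time priors are out of scope, as
  are zero-inflated likelihoods — the sparsity in the reference conditions
  is reproduced by small populations under a plain Poisson model.
* Exceedence maps inherit posterior uncertainty from the model; they are a
  decision aid, not a hypothesis test.
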