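---
title: "Measuring use-of-force disparities for persons with serious mental illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring use-of-force disparities for persons with serious mental illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Persons with serious mental illness (PwSMI) may face sharply elevated risk
of experiencing police use of force, but two measurement gaps make the
disparity hard to quantify: force records rarely identify mental-health
status, and no census counts PwSMI at the neighborhood level. This package
implements a three-stage pipeline that addresses both gaps and estimates
the disparity as a relative risk:

1. **Case definition** — a rule-based serious-mental-illness classification
   applied to structured survey items (`classify_smi()`).
2. **Synthetic small-area estimation** — a logistic regression of SMI on
   demographics, fit on national survey microdata and projected onto
   area-level census covariate profiles to estimate each area's SMI and
   non-SMI adult population (`fit_smi_logit()`, `project_all()`).
3. **Disparity estimation** — a Bayesian hierarchical negative-binomial
   model of force/injury counts with the estimated populations as exposure
   offsets (`fit_disparity()`), yielding relative risks with 95% credible
   intervals, plus the analogous race-benchmark model
   (`fit_race_disparity()`).

Because the administrative data this design targets are restricted, the
package ships a first-class synthetic-data generator
(`make_paper_like_fixture()`) that runs the full generative model forward
with known parameters, so every stage — and the pipeline end to end — is
validated by parameter recovery rather than by fiat.

## The SMI case definition

A respondent is classified as having SMI iff all three criteria hold:

* **A. Diagnosis** — at least one of eleven catalogue items (bipolar I/II,
  mania, hypomania, major depressive disorder, agoraphobia, generalized
  anxiety disorder, PTSD, specific phobia, social phobia, or a serious
  suicide attempt in the past 12 months).
* **B. Impairment** — unable to function at least 120 of the past 365
  days, *or* role impairment (work, home, relationships, social life)
  rated at least 7 of 10.
* **C. Duration** — the disorder has lasted at least 12 months.

All thresholds are inclusive. The impairment-rating clause is genuinely
ambiguous between "any domain ≥ 7" and "all domains ≥ 7"; we default to
**any** (the maximum over domains), which matches common severe-role-
impairment codings and is the more sensitive reading, and expose
`impairment_rule = "any" | "all"` so the stricter reading is one argument
away. A single duration field applies to the qualifying disorder as a
whole; the suicide-attempt item is treated as an ordinary member of the
criterion-A catalogue, with B and C applying uniformly.

## Synthetic small-area estimation

With `smi` labels in hand, stage 2 fits
$$\operatorname{logit} \Pr(\text{SMI}_j = 1) = \beta_0 + x_j^\top \beta$$
by unpenalized maximum likelihood (IRLS, convergence tolerance $10^{-8}$
on the deviance, 100 iterations max; rank deficiency and separation are
errors, not silent results). Covariates are age band, gender, race,
marital status, employment status, education, and the income-to-poverty
ratio. A `coding_scheme` registry pins level sets, reference levels, and
design-column names so microdata and aggregate profiles are coded
identically — the alignment the projection depends on.

The projection is the **plug-in** estimator: an area's covariate summary
vector $\bar{x}_a$ (indicator proportions and continuous means) is pushed
through the individual-level linear predictor,
$$\hat p_a = \operatorname{logit}^{-1}(\hat\beta_0 + \bar{x}_a^\top \hat\beta),
\qquad \hat n^{\text{SMI}}_a = \hat p_a \cdot \text{pop}_a .$$
This is deliberately the crude classical form rather than cell-based
post-stratification over the joint covariate distribution: the joint
distribution is not observed at the tract level, and the plug-in is the
estimator this design is built around. Its known nonlinearity (Jensen)
bias is small at prevalences of a few percent; the test suite documents
the direction of the gap. Precinct and city profiles, when not supplied,
are population-weighted averages of member tracts. Uncertainty from the
logistic fit is *not* propagated downstream — projected populations enter
the count model as fixed offsets — so disparity intervals are conditional
on the exposure estimates. Survey weights are carried but default to 1.

## The disparity model

For counts $y_{gti}$ (group $g$, year $t$, area $i$) with exposure
$n_{gti}$:
$$y_{gti} \sim \mathrm{NB}\!\left(n_{gti}\, e^{u + \alpha_g + \delta_t + \beta_i},\ \phi\right),
\qquad \beta_i \sim \mathrm{Normal}(0, \sigma_\beta^2),$$
in the mean–shape parameterization (variance $\mu + \mu^2/\phi$), with
the reference group (non-SMI, or White) and the earliest year absorbed
into the intercept. $e^{\alpha_g}$ is the relative risk reported in the
summaries; the point estimate is the posterior median of $e^{\alpha_g}$
(switchable to the mean) with an equal-tailed 2.5–97.5% percentile
interval.

Priors are weakly informative and overridable via `disparity_config()`:
$u, \alpha, \delta \sim \mathrm{N}(0, 5^2)$;
$\sigma_\beta \sim \text{half-Student-}t(3, 0, 2.5)$;
$\phi \sim \mathrm{Gamma}(0.01, 0.01)$. Sampling runs in JAGS (via
**rjags**) with a non-centered parameterization of the area effects
($\beta_i = \sigma_\beta z_i$, $z_i \sim \mathrm{N}(0,1)$) to avoid the
funnel geometry that a centered parameterization produces when
$\sigma_\beta$ is weakly identified. Default MCMC settings are 4 chains of
2000 iterations (1000 warmup); the bundled analyses use 2 chains with
explicit seeds so every run is exactly reproducible. Split R-hat is
computed for every reported parameter and effective sample sizes come
from **coda**; any split R-hat above 1.05 raises a warning flag on the
output rather than an error, since the group coefficients typically mix
much faster than the global intercept.

Numerical edge cases: cells with non-positive exposure have no defined
log-offset and are dropped with a counted warning (an `exposure_floor`
mode retains them for sensitivity analysis); a model needs at least two
areas for $\sigma_\beta$ to be identified, and at least one case and one
non-case for the logistic stage. The NB log-pmf (`nb_log_pmf()`) is
evaluated from its log-gamma closed form and is property-tested for
normalization and its Poisson limit.

## The synthetic-data generator

`scenario_config()` fixes every generating parameter; the defaults are
the package's reference scenario:

| parameter | default | meaning |
|---|---|---|
| `n_respondents` | 5493 | survey size |
| `n_cities`, `tracts_per_city` | 9, 12 | area layout |
| `years` | 2011–2017 | study window |
| intercept of `true_logit_coefs` | −3.55 | sets plug-in prevalence ≈ 2% |
| `true_rr_smi` | 11.6 | SMI vs non-SMI relative risk |
| `true_rr_race` | Black 3.1, Latinx 1.0, Other 1.0 | race benchmark truths |
| `sigma_beta_true` | 1.5 | SD of area log-rate effects |
| `phi_true` | 1.2 | NB dispersion |
| `base_rate` | 0.0016 | force events per reference person-year, median area |
| `injury_rate_scale` | 0.3 | injury baseline relative to force |
| `tract_jitter` | 0.15 | tract-level covariate dispersion |

The headline truths (RR 11.6; race 3.1/1.0; prevalence in the 1–3% band)
make recovered values recognizably "paper-like"; they are generator
settings, not reproduction claims. The survey generator draws latent SMI
from the true logistic model and **back-fills** the diagnostic,
impairment, and duration items so that `classify_smi()` reproduces the
latent label exactly — the classification stage is thereby testable in
isolation. An optional `label_noise` parameter injects false-negative-
heavy misclassification into the incident table (officers under-identify
SMI), for sensitivity experiments only; it breaks the exact
incident/count aggregation identity by design. Tract covariate profiles
are log-perturbations of the survey distribution, held constant across
years; adult populations are uniform on 1,200–8,000. Event counts are
drawn from the NB model itself, with one area effect shared across
outcomes and groupings.

What the generator does **not** emulate: real spatial geography and
spatial correlation of area effects, survey design weights and
nonresponse, drift between the survey era and the study window,
systematic (rather than random) officer misclassification, and homeless
populations invisible to household frames (the `homeless_per_city` field
and `adjust_prevalence_homeless()` treat that last one as an explicit
sensitivity analysis with an assumed 40% SMI rate). Passing recovery
tests therefore demonstrates internal statistical validity of the
estimator chain, not robustness to these real-data failure modes.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle and the
chain end to end:

* the logistic fit against a quasi-Newton maximization of the
  hand-written log-likelihood (agreement to $10^{-6}$);
* the NB pmf against enumeration (normalization to $10^{-8}$) and the
  Poisson limit at $\phi = 10^6$, where the Bayesian fixed effects are
  also checked against a Poisson GLM with offset within 3 posterior SDs;
* offset equivariance (scaling exposures by 10 shifts only the intercept
  by $-\log 10$, within Monte Carlo error);
* end-to-end recovery on the reference fixture (9 cities × 12 tracts ×
  7 years: posterior-median RRs within ±20% of 11.6 / 3.1 / 1.0 with
  covering credible intervals), and null calibration (RR = 1) across 20
  replicate datasets of 50 areas × 3 years, requiring ≥ 18/20 interval
  coverage.

The replicate and calibration sizes are chosen to keep the whole suite at
useful statistical power while remaining comfortably runnable on a single
CPU; the fixture's 12 tracts per city likewise balances area-effect
identifiability against sampler cost.

## Known limitations

* Exposure uncertainty is ignored downstream, so credible intervals are
  conditional on the small-area estimates; an unlucky logistic fit shifts
  the RR beyond what its interval acknowledges.
* The plug-in projection inherits ecological assumptions: coefficients
  estimated on individuals are applied to aggregate margins.
* Area effects are exchangeable, not spatial (no CAR/ICAR structure),
  and year effects do not interact with group, mirroring the target
  design.
* The race model takes census race counts as exposures directly and
  shares the area-effect structure; differential exposure to police
  within areas is not modeled.
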