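---
title: "Estimating sex differences in total fertility rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sex differences in total fertility rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malefert)
```

## Why male fertility has to be estimated

The total fertility rate (TFR) — the number of children a person would have
over a reproductive lifetime under a given year's age-specific rates — is
routinely published for women but not for men. Yet the two can diverge
substantially: fertility is births relative to the population *exposed*,
so when reproductive-age men outnumber reproductive-age women (or vice
versa), the per-capita rates of the two sexes must differ even if every
birth has one mother and one father. `malefert` provides the machinery to
quantify that divergence: an indirect regression estimator of the male TFR,
a standardization that isolates the population-structure effect, a
decomposition of the structure into its birth and mortality drivers, and
trend analytics for the crossover from higher male to higher female
fertility.

## The regression model

The estimator exploits that the male TFR tracks the female TFR closely,
with deviations driven by the adult sex ratio:

$$\log(\mathrm{TFR}_m) = \alpha + \beta_1 \log(\mathrm{TFR}_w) +
  \beta_2 \log(\mathrm{SR}) + \varepsilon .$$

All logarithms in the package are natural. $\beta_1$ is the elasticity of
male to female fertility (close to but above 1: male fertility falls
faster than female fertility as the level declines), and $\beta_2 < 0$
captures the dilution of male rates when men are abundant. Three variants
differ only in the age windows of SR:

| variant | male ages | female ages |
|---|---|---|
| baseline | 20–39 | 20–39 |
| postponement | 25–44 | 25–44 |
| age_gap | 25–44 | 20–39 |

Ages are completed years and all ranges are closed (20–39 means 20 through
39 inclusive). The age-gap variant encodes that fathers are on average
older than mothers, and is the default throughout the package.

`fit_male_tfr()` is pooled, unweighted OLS on the log scale across all
country-years, with classical (non-clustered) standard errors and the
residual scale on $n-3$ degrees of freedom. No weighting or fixed effects
are applied: the estimator is deliberately a single global coefficient set.
The shipped `default_coefficients()` are published point estimates from a
fit to roughly four thousand harmonized country-year observations of male
TFR; for the age-gap variant, $\alpha=-0.078$, $\beta_1=1.101$,
$\beta_2=-0.661$.

### Prediction intervals

`predict_male_tfr()` builds the standard OLS prediction interval on the log
scale — $t_{n-3}$ quantile times $\sqrt{x'Vx + \hat\sigma^2}$, i.e.
parameter variance plus residual variance — and exponentiates it. As $n$
grows the width tends to the residual-only asymptote
$\exp(\pm z \hat\sigma)$, which the tests verify. When a fit is constructed
from bare published coefficients (no covariance, no residual scale) the
interval cannot be reconstructed honestly, so `pi_low`/`pi_high` are `NA`
rather than an approximation — a deliberate design choice: points from
published coefficients, intervals only from actual fits. For the same
reason the package treats published interval endpoints as non-reproducible
and validates its interval construction only on synthetic data, via
coverage (a well-specified 90% interval should cover 87–93% of a
1,000-observation holdout, the 3σ binomial band).

## Standardization

The standardized male TFR applies the observed births by maternal age to
the male population structure,

$$\mathrm{TFR}_{std} = \sum_{x=15}^{55} \frac{B_x}{P^m_x},$$

with ages 15–55 inclusive — the reproductive range wide enough to cover
male fertility too. Dividing by the female TFR computed from the same
births and the female structure yields `ratio_std`, which is exactly $1/k$
when the male population is $k$ times the female population at every
fertile age: the statistic is harmonic in structure and answers "how much
of the male–female TFR gap is population structure alone", under the
deliberate simplification that both sexes share one fertility schedule.
Births must be by single age; `split_grouped_births()` spreads 5-year
groups uniformly when only grouped data exist. Ages with zero births
contribute zero regardless of population; a positive birth count at an age
with zero male population is an error, not a silent skip.

## Decomposing the population sex ratio

`decompose_sex_ratio()` explains the age profile of the sex ratio in a
given period with a synthetic cohort: set the male radix to the sex ratio
at birth (male births per 100 female births), the female radix to 100, and
survive both forward with the year's sex-specific single-age survival
probabilities:

$$SR_t(x) = \underbrace{100\,\frac{B_{m,t}}{B_{w,t}}}_{\text{birth}}
  \times \underbrace{\frac{\prod_{i=0}^{x-1} p_{m,t}(i)}
  {\prod_{i=0}^{x-1} p_{w,t}(i)}}_{\text{mortality}} .$$

Two conventions matter and are fixed deliberately:

* **The survivorship product runs from birth to exact age $x$** (empty
  product at $x=0$). Including $p(x)$ itself would make $SR_t(0)$ differ
  from the sex ratio at birth and contradict the radix construction, so the
  package uses the birth-to-exact-age reading and documents it here
  prominently.
* **Period rates throughout** — all $p(i)$ come from year $t$'s life table.
  This is a synthetic cohort, not the lived experience of any real cohort;
  cohort life tables are intentionally unsupported.

Migration is absent from the identity by construction, which is exactly its
point: it isolates what births and mortality alone would do to the sex
composition. The output also carries the per-age factor $p_m(x)/p_w(x)$
(`survival_ratio_increment`) so that bar-style displays can show either the
cumulative or the incremental mortality contribution. `crossover_age()`
reports the first age where the ratio falls strictly below parity; a ratio
exactly at parity never counts as crossed.

## Crossover analytics

`percent_difference()` uses the female TFR as base, so positive values mean
higher male fertility. `detect_crossover()` finds the first year with
$\mathrm{TFR}_m < \mathrm{TFR}_w$ strictly — ties are "not crossed",
because the zero line is the equilibrium itself. `share_summary()` counts
regions with strictly higher male TFR and weights the below-threshold share
by total population; the 5% threshold is implemented strictly
(`pct_diff < -5`), so a region at exactly −5% is *not* counted as "more
than 5% lower" — the boundary convention is documented and tested.
`counterfactual_ratio_decomposition()` rewrites the model as
$\log(\mathrm{TFR}_m/\mathrm{TFR}_w) = \alpha + (\beta_1 - 1)
\log \mathrm{TFR}_w + \beta_2 \log \mathrm{SR}$ and splits a change in the
log ratio between two states into the two addends. This is an exact,
order-independent decomposition in logs — a deliberately simple stepwise
design chosen because it makes the components sum to the total identically,
at the cost of ignoring interaction paths a sequential counterfactual could
attribute differently.

## The synthetic-data generator

`generate_scenario()` emulates the kind of internally consistent
population/births/life-table/fertility system that national-accounts style
demographic estimates provide, via a migration-free cohort-component
projection:

* **Balancing equation, exactly.** $P(a{+}1, t{+}1) = P(a,t)\,p(a,t)$ for
  every age, year and sex; newborns enter at age 0 of their birth year;
  births by maternal age are $\mathrm{ASFR}(a,t) \cdot P_w(a,t)$; male over
  female births equal $\mathrm{SRB}(t)/100$. These identities are exact in
  floating point, which is what makes the generator usable as an oracle.
* **Fertility schedule**: a symmetric-beta density over ages 15–55
  parameterized by mean (default 28 years) and spread (default 6 years),
  normalized so the ASFRs sum to the year's TFR. Any smooth unimodal
  schedule would do for testing; the beta keeps it to two interpretable
  parameters.
* **Mortality**: Gompertz hazard $a e^{bx}$ (defaults $a=10^{-4}$,
  $b=0.09$) with a multiplicative male gap (default 1.5) and an additive
  infant component $0.01\,e^{-x}$, converted to survival by
  $p(x) = e^{-h(x)}$ — monotone, controllable, and broadly life-table
  shaped. Shocks multiply the hazard for a year range, sex and age range,
  emulating conflict or maternal-mortality episodes.
* **Sex ratio at birth**: defaults to 105 male births per 100 female
  births, the center of the natural 103–107 range; paths can ramp higher to
  emulate sex-selective abortion regimes.
* **Initial population**: the stationary population of the first year's
  survival schedule (cohort size × survivorship). With rates constant in
  time this makes the period population sex ratio equal the synthetic-cohort
  ratio at every age from year 0 — the key cross-module identity linking
  the generator to the decomposition, tested at tolerance 1e-9.

Counts are expected values, not Poisson draws, and there is no migration,
union formation, or parity structure. Consequently the generator shows that
the pipeline's algebra is right under its own assumptions; passing tests do
*not* show robustness to migration flows (the known failure mode of the
regression estimator in, e.g., labor-migration states), to stochastic
small-population noise, or to real-world schedule shapes. The only
stochastic component anywhere is `generate_regression_panel()`, which draws
covariates ($\log \mathrm{TFR}_w \sim U(\ln 0.8, \ln 8)$,
$\log \mathrm{SR} \sim N(0, 0.15^2)$) and log-scale Gaussian noise from a
single seeded generator.

## Numerical choices and degenerate inputs

* CSV interchange writes doubles with 17 significant digits, so
  `read_frame(write_frame(x))` is exact.
* Strictly positive inputs are required wherever a log is taken; zero
  female populations, zero female births, and empty holdouts are domain
  errors with named offenders, and region-years that cannot be processed in
  panel operations are reported in a `skipped` attribute, never dropped
  silently.
* The open age interval "100+" is stored as age 100; life tables must be
  contiguous from age 0.
* Rank-deficient regression designs (e.g., a constant sex ratio series)
  raise a singularity error instead of returning a pseudo-inverse fit.
* Exact interpolation (noiseless panels) is supported; the usual
  "essentially perfect fit" warning is deliberately muffled for that case.

## Problem sizes in the test suite

The suite exercises scenarios of 10–50 years with 101 single ages and
regression panels of up to 4,000 observations; the elasticity-recovery
check uses 100 replications of the n = 4,000 panel and the
confidence-interval coverage check 400 replications, with a 3σ binomial
band around the nominal level. These sizes were chosen to make
Monte-Carlo bands tight enough to be informative while keeping the whole
suite in the tens of seconds on a laptop.

## Limitations

The regression approach assumes the historical relationship between female
fertility, sex ratios and male fertility transfers to the prediction
target; it is known to mislead where population structure moves without
fertility consequences (male-dominated labor migration). The
standardization assumes identical fertility schedules for both sexes,
understating differences where parental age gaps are large. The
decomposition is a period construct and neutralizes migration by design.
The shipped coefficients are point estimates without covariance, so
interval-bearing predictions require refitting on the user's own training
compilation.
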