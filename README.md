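# malefert

Statistical offices report fertility for women; the total fertility rate of
men is rarely published, even though it can differ from the female TFR by
tens of percent when the reproductive-age population is skewed toward one
sex. `malefert` is an R package for studying those sex differences in
fertility: it estimates male TFRs indirectly, isolates how much of the
male–female gap is due to population structure, decomposes the structure
itself into its demographic drivers, and tracks when and where female
fertility overtakes male fertility.

## The models

**Indirect male-TFR estimation.** The male TFR is tied to the overall
fertility level and to the sex composition of the reproductive-age
population through a log-log regression,

```
log(TFRm) = α + β₁ · log(TFRw) + β₂ · log(SR) + ε,
```

where `TFRw` is the female TFR and `SR` is an adult sex ratio (male over
female population, summed over age windows). Three variants differ only in
the windows: *baseline* (both sexes 20–39), *postponement* (both 25–44),
and *age gap* (men 25–44 over women 20–39, reflecting that fathers are
typically older than mothers). Fits are pooled, unweighted OLS on the log
scale with classical standard errors; predictions come with 90% log-scale
normal-theory prediction intervals. A published coefficient set for each
variant ships with the package (for the age-gap variant:
α = −0.078, β₁ = 1.101, β₂ = −0.661), so male TFRs can be estimated
without refitting.

**Standardization.** The standardized male TFR applies the observed births
by maternal age `B_x` to the male population structure,
`TFR_std = Σ_x B_x / P_x^male` over ages 15–55. Because the fertility
schedule is identical for both sexes by construction, the ratio of
`TFR_std` to the female TFR computed from the same inputs isolates the pure
sex-ratio effect.

**Sex-ratio decomposition.** The period age-specific population sex ratio is
factored, synthetic-cohort style, into a birth and a mortality component:

```
SR_t(x) = 100 · (B_m / B_w) · Π_{i=0}^{x-1} p_m(i) / Π_{i=0}^{x-1} p_w(i)
```

with the male radix set to the sex ratio at birth and the female radix
to 100. The survivorship product runs from birth to exact age `x`, so the
identity `sr_total = birth_contribution × mortality_contribution` is exact
at every age.

**Crossover analytics.** Percent differences
`100 · (TFRm − TFRw) / TFRw`, first-crossing detection (strict inequality;
ties do not cross), per-year country shares, population-weighted shares of
people living where the male TFR is more than 5% below the female TFR, and
an exact log-additive counterfactual decomposition of TFR-ratio changes
into a fertility-level and a sex-ratio component.

**Synthetic scenarios.** A migration-free cohort-component generator
produces internally consistent population, births, life-table and fertility
tables with known ground truth (sex ratio at birth path, Gompertz mortality
with a male gap factor, symmetric-beta fertility schedule, transient
conflict-style hazard shocks). It exists so every stage of the pipeline can
be tested against construction-exact identities without downloading data.

## Worked example

```r
library(malefert)

fit <- male_tfr_fit_from_coefficients(default_coefficients("age_gap"))
predict_male_tfr(fit, tfr_female = 2.1, sex_ratio = c(0.5, 1, 2))
#> # A tibble: 3 × 5
#>   point pi_low pi_high log_point log_se
#>   <dbl>  <dbl>   <dbl>     <dbl>  <dbl>
#> 1  3.31     NA      NA     1.20      NA
#> 2  2.09     NA      NA     0.739     NA
#> 3  1.32     NA      NA     0.281     NA
```

At replacement-level female fertility (2.1 births per woman) and a balanced
population the model predicts 2.09 births per man; with twice as many women
as men at reproductive ages (SR = 0.5) male fertility rises to 3.31, and
with twice as many men (SR = 2) it drops to 1.32. Intervals are `NA`
because a bare published coefficient set carries no covariance; a fitted
model provides them:

```r
panel <- generate_regression_panel(4000, default_coefficients("age_gap"),
                                   noise_sd = 0.05, seed = 1)
refit <- fit_male_tfr(panel, "age_gap")
refit
#> <male_tfr_fit> variant: age_gap
#>   log(TFRm) = -0.0801 +1.1028 log(TFRw) -0.6645 log(SR)
#>   n = 4000, resid sd = 0.0501, R2 = 0.9956 (adj 0.9956)
predict_male_tfr(refit, 2.1, 2)
#> # A tibble: 1 × 5
#>   point pi_low pi_high log_point log_se
#>   <dbl>  <dbl>   <dbl>     <dbl>  <dbl>
#> 1  1.32   1.22    1.43     0.277 0.0503
```

The decomposition, on a flat life table with a male survival disadvantage
(p = 0.995 vs 0.999 per year) and a sex ratio at birth of 106:

```r
d <- decompose_sex_ratio(births, lifetables, "R", 2000, max_age = 60)
d[d$age %in% c(0, 25, 50), c("age", "sr_total", "mortality_contribution")]
#>     age sr_total mortality_contribution
#> 1     0    106                  1
#> 2    25     95.9                0.905
#> 3    50     86.7                0.818
crossover_age(d)   # women outnumber men from age 15 on
#> [1] 15
```

A full pipeline run (simulate → fit → estimate → standardize → decompose →
crossover) from a YAML config:

```sh
Rscript scripts/pipeline.R --config config.yml --out-dir run --seed 5
```

which writes `estimated.csv`, `standardized.csv`, `decomposition.csv`,
`crossover.csv`, `shares.csv` and a `manifest.json` with input checksums
and per-stage row counts; identical config and seed give byte-identical
outputs.

## Mapping WPP-style data

The package reads four long-format CSVs (schemas in `?read_frame`):
`population.csv` (region_id, year, age, sex, count), `births.csv`
(region_id, year, sex_of_child, mother_age, count — single ages;
`split_grouped_births()` spreads 5-year groups), `lifetable.csv`
(region_id, year, sex, age, p) and `fertility.csv` (region_id, year,
tfr_female, tfr_male). To use UN World Population Prospects exports, select
the medium-variant single-age tables, rename the location column to
`region_id`, recode sex labels to lower case, map the life-table `px`
column to `p`, and store the open age interval 100+ as age 100.
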