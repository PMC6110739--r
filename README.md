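# survmeta

Metadata-driven survival analysis for clinical tabular data.

Clinical cohort tables arrive as flat CSVs whose columns mean different
things in every study: which column is the follow-up time, which is the death
flag, which raw tokens (`1`, `m`, `M`) encode which category. `survmeta`
makes those conventions explicit in a three-layer metadata codebook and then
drives a complete right-censored survival workflow off it:

1. **Metadata** — layer 1 names the time/event/id columns (and can alias raw
   names to canonical ones such as `TimeOS`, `EventDeath`); layer 2 records
   each variable's measurement scale (nominal / ordinal / interval / ratio),
   which determines whether it is analysed as categorical or continuous;
   layer 3 is the dictionary mapping raw categorical tokens to integer codes
   (e.g. `{1, m, M} -> 1 "male"`). Bundles can be read, written,
   auto-generated from a raw table and validated against one.
2. **ETL** — recoding and type coercion under the bundle, per-cell
   missingness accounting, and conjunctive inclusion/exclusion filters with
   first-failure attribution of excluded rows.
3. **Demographics** — an automatic test-selection flow for the baseline
   characteristics ("Table 1"): data type → number of strata → normality
   (Shapiro–Wilk up to n = 5000, Anderson–Darling above) → Welch t-test /
   one-way ANOVA / Wilcoxon rank-sum / Kruskal–Wallis for continuous
   variables, Pearson chi-square (flagged Fisher exact fallback on sparse
   2×2) for categorical ones.
4. **Survival core** — implemented from first principles:
   * Kaplan–Meier product-limit estimator
     S(t₍ₙ₎) = S(t₍ₙ₋₁₎) · P̂r(T > t₍ₙ₎ | T ≥ t₍ₙ₎), with Greenwood variance
     and log(−log) confidence bands;
   * log-rank test, two-group (O₂−E₂)²/Var(O₂−E₂) with per-event-time
     hypergeometric variance, generalised to k groups (df = k−1) and strata;
   * Cox proportional hazards log h(t)/h₀(t) = β₁X₁ + … + β_pX_p, maximised
     by Newton–Raphson on the partial likelihood with Efron (default) or
     Breslow tie handling, stratified baseline hazards, Wald intervals on
     hazard ratios exp(β).
5. **Simulation** — colon-trial-shaped synthetic cohorts with known ground
   truth (inverse-transform event times under proportional hazards,
   independent censoring to a target fraction), written out as
   `Dataset.csv` + the three layer CSVs so the whole pipeline is testable
   without any external download.
6. **Reporting** — CSV/markdown Table 1 rendering, right-continuous KM step
   plots with censor ticks and confidence bands, p-value floor display
   (`<0.001`).

## Worked example

```r
library(survmeta)

# a 900-subject synthetic trial: treatment (HR 0.7), age, nodal count,
# sex/differentiation/extent as null covariates, ~50% censoring
res    <- simulate_cohort(colon_like_spec(n = 900, seed = 20))
paths  <- make_fixture_files(res, "fixtures")
bundle <- read_metadata(paths["layer1"], paths["layer2"], paths["layer3"])
ds     <- load_dataset(paths["dataset"], bundle)

out <- apply_filters(ds, list("age >= 40", "nodes not-missing"))
#> Filter outcome: 848 included, 52 excluded
#>   excluded per criterion (first failure): 52, 0

build_table1(out$included, "rx")
#> Demographic table stratified by rx
#>   group sizes: 0=419, 1=429
#>   continuous
#>     age          wilcoxon_rank_sum  p = 0.587
#>     nodes        t_test             p = 0.0801
#>   categorical
#>     sex          chi_square         p = 0.341
#>     differ       chi_square         p = 0.279
#>     extent       chi_square         p = 0.657

km_by_formula(out$included, survival_formula("TimeOS", "EventDeath", "rx"))
#> Kaplan-Meier curve [rx=0]
#>   n = 419 , events = 226 , median = 18.4131
#> Kaplan-Meier curve [rx=1]
#>   n = 429 , events = 198 , median = 26.97424
#> Log-rank test
#>   group observed expected
#> 1  rx=0      226   196.81
#> 2  rx=1      198   227.19
#>   chi-square = 8.1288 on 1 df, p = 0.004357

fit <- coxph_by_formula(out$included,
                        survival_formula("TimeOS", "EventDeath",
                                         c("rx", "age", "nodes"),
                                         strata = "sex"))
summary(fit)
#>              beta          se        hr  hr_lower  hr_upper         z            p
#> rx    -0.25965914 0.098705344 0.7713145 0.6356431 0.9359435 -2.630649 8.522194e-03
#> age    0.01406173 0.004576804 1.0141611 1.0051043 1.0232994  3.072390 2.123518e-03
#> nodes  0.10441694 0.015535987 1.1100632 1.0767712 1.1443845  6.720972 1.805159e-11
#> Likelihood ratio = 63.485, p = 1.06e-13; score at 0 = 62.902
```

Reading the output: the filter excluded 52 subjects younger than 40 (none
failed the second criterion once the first had been applied); at baseline no
covariate differs materially between arms, as designed; the treated arm's
median overall survival is 27.0 months against 18.4 under control, the
log-rank test rejects equality of the survival curves (p ≈ 0.004), and the
sex-stratified Cox fit estimates a treatment hazard ratio of 0.77
(95% CI 0.64–0.94) against a simulated truth of 0.70, with the adverse age
and nodal-burden effects recovered alongside.

A command-line front end wrapping the same functions ships in
`inst/cli/survmeta.R`:

```sh
Rscript inst/cli/survmeta.R simulate --n 900 --seed 20 -o fixtures/
Rscript inst/cli/survmeta.R coxph fixtures/Dataset.csv --metadata fixtures \
    --covariates rx,age,nodes --strata sex -o cox
```

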