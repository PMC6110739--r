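---
title: "Methods: metadata-driven survival analysis with survmeta"
author: "survmeta authors"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical procedures `survmeta` implements, the
modelling assumptions behind them, the defaults and numerical conventions
chosen where the methodology left genuine freedom, and what the simulation
-backed guarantees do and do not establish about real data.

## The data model

`survmeta` analyses right-censored time-to-event data: each subject
contributes an observed time `T_obs = min(T, C)` and an event flag
`event = 1{T <= C}`, where `T` is the latent event time and `C` an
independent censoring time. Left censoring, left truncation, interval
censoring, time-varying covariates and competing risks are out of scope.

The three-layer metadata codebook makes the mapping from a raw CSV to this
model explicit:

* **Layer 1 (roles)** names the time and event columns and may alias raw
  names to canonical ones (`OS_months` → `TimeOS`). Exactly one time and one
  event role must exist.
* **Layer 2 (measurement)** assigns each column one of the classical
  measurement scales. The scale determines the analysis class
  deterministically: interval/ratio → continuous, nominal/ordinal →
  categorical. The time variable must be continuous and the event variable
  categorical.
* **Layer 3 (dictionary)** maps raw tokens to integer codes, one row per
  (variable, code), tokens pipe-separated. Matching is case-sensitive and
  whitespace-trimmed — `m` and `M` are distinct tokens that may share a code
  — and the token sets of different codes must be disjoint. After mapping,
  the event flag uses the canonical coding 0 = censored/alive, 1 =
  event/dead.

The physical schema of the three files (headered CSVs
`layer1.csv (role, raw_column, canonical_name)`,
`layer2.csv (name, measurement, role)`,
`layer3.csv (variable, code, tokens, display)`) is this package's own
design; it was chosen to be minimal and diff-friendly, and `write_metadata`
emits it in a normalised order (layer 3 sorted by variable then code) so
that a write–read–write round trip is byte-stable.

**Auto-generation rule.** `generate_metadata` must classify columns without
guidance. The rule: a numeric column with more than `k` distinct non-missing
values is ratio/continuous, otherwise nominal/categorical with an auto-built
dictionary; `k = 6` by default, configurable. Six was chosen because
clinical codebooks rarely carry ordered scales with more than six levels
(tumour grade, performance status), while genuinely continuous measurements
essentially always exceed it. Time and event roles are found by
case-insensitive name matching (`time`; `event`/`status`/`death`) when not
given explicitly; explicit arguments and per-column overrides always win.
Code assignment preserves numeric tokens when they are unambiguous small
integers, otherwise codes are 0-based in sorted token order — so
auto-generated metadata over the same table is deterministic.

## ETL and filtering semantics

Cells that fail to parse (continuous) or fail to map (categorical) become
missing *and are counted per variable*, never silently dropped; a negative
time aborts the load as corrupt data, while unmappable event tokens warn
with a count. Filters are conjunctive, applied in order, and each excluded
row is attributed to the **first** criterion it fails — so the per-criterion
counts read like a cohort-diagram exclusion flow and always sum to the total
excluded. Missing cells fail every criterion except `missing`/`not-missing`;
this conservative semantics means filtering can only remove rows with
affirmatively disqualifying values or unknowns, never retain a row on an
unverifiable comparison. Complete-case elimination for the statistical
procedures happens inside each procedure (per variable for Table 1, per
model for Cox), not at load time, so one variable's missingness never costs
another variable its observations.

## The demographic test-selection flow

For each covariate the selection is a total, deterministic function of
(analysis class, number of strata, normality):

| class | strata | normal | test |
|---|---|---|---|
| continuous | 2 | yes | Welch t-test |
| continuous | >2 | yes | one-way ANOVA |
| continuous | 2 | no | Wilcoxon rank-sum |
| continuous | >2 | no | Kruskal–Wallis |
| categorical | any | — | Pearson chi-square |

Decisions taken and recorded in the rationale trace:

* **Normality routing.** Shapiro–Wilk for 3 ≤ n ≤ 5000 (its implementation
  limit), Anderson–Darling above, at α = 0.05. The screen is applied **per
  group**, and the parametric branch requires *every* group to pass: a
  comparison is only as parametric as its least normal arm. A group too
  small to screen (n < 3) or constant is treated as non-normal — a constant
  vector carries no evidence of normality, and the rank tests remain valid.
* **Welch by default.** The two-group t-test does not pool variances unless
  asked (`var_equal = TRUE`); the one-way ANOVA is the classical
  equal-variance F (via `oneway.test(var.equal = TRUE)`).
* **Kruskal–Wallis** is the >2-group generalisation of the Wilcoxon branch;
  the Wilcoxon itself uses the normal approximation without continuity
  correction.
* **Chi-square without continuity correction**; on a 2×2 table with any
  expected count below 5 the Fisher exact test replaces it and the result is
  flagged (`fisher_exact` in the test choice) — the fallback is never
  silent.
* All tests are two-sided; each variable is reduced to complete cases
  against the stratifier independently. No multiple-testing adjustment is
  applied across the table's rows, and no post-hoc pairwise tests follow an
  ANOVA.

An untestable covariate (fully missing, or collapsing to one level) stays in
the table flagged `untestable` with the reason, rather than disappearing.

## The survival core

### Kaplan–Meier

At each distinct time `t` with `d` events out of `n` at risk the estimator
multiplies on the conditional survival fraction `1 − d/n`:
`S(t) = Π_{t_i ≤ t} (1 − d_i/n_i)`. Conventions:

* Subjects censored at `t` remain in the risk set for events at `t`
  (standard convention).
* Greenwood variance `Var S(t) = S(t)² Σ d_i/(n_i(n_i−d_i))`; when the
  curve hits zero the summand is undefined and the variance is reported as
  the degenerate limit 0 (the reference implementation prints NaN there; the
  estimate itself is degenerate either way).
* The pointwise band is computed on the log(−log) scale by default, which
  keeps it inside [0, 1]; a plain linear Greenwood band is available.
* A sample with zero events yields the constant curve 1 with a warning.
* The median is the smallest event time with `S ≤ 0.5` (so a curve touching
  exactly 0.5 has reached its median), reported "not reached" otherwise.

### Log-rank

At each distinct event time the vector of per-group event counts is
hypergeometric given the margins: expectation `d·n_g/n`, covariance
`d(n−d)/(n−1)·(n_g/n)(δ_gh − n_h/n)`. O − E and the covariance are summed
over event times (and over strata, when given, with per-stratum risk sets),
and the statistic is the quadratic form over any k−1 groups against
χ²(k−1); for two groups this reduces to `(O₂−E₂)²/Var(O₂−E₂)`. A risk set
of size one contributes zero variance (the `n−1` denominator is degenerate).
If the covariance submatrix is singular — possible when a group is empty
over part of the time axis — a pseudo-inverse via SVD is used.

### Cox proportional hazards

The model is `log h(t|x)/h₀(t) = β'x`; the baseline hazard is eliminated by
the partial likelihood, maximised by Newton–Raphson:

* **Ties**: Efron's correction by default (the more accurate standard
  choice); Breslow available, and needed for the exact score/log-rank
  identity below.
* **Initialisation** at β = 0; **convergence** when the score sup-norm
  falls below `tol = 1e-9` or the relative log-likelihood change does;
  `max_iter = 50`. Step halving guarantees the partial likelihood never
  decreases across iterations, and the trace is kept on the fit object.
* **Safeguards**: covariates are centred internally (β is
  translation-invariant; this only conditions the exponentials), the linear
  predictor is max-shifted before exponentiation, a coefficient passing
  |β| > 15 aborts with a monotone-likelihood/separation diagnostic, constant
  covariates and singular information matrices abort with identifiability
  errors, and non-convergence reports the iteration trace.
* Standard errors come from the inverse observed information at the
  optimum; hazard ratios are `exp(β)` with Wald intervals. The score
  statistic at β = 0 is kept on the fit: for a single binary covariate with
  Breslow ties and no tied deaths it equals the log-rank statistic, which
  the tests verify to 1e-8 — a structural identity linking the two
  implementations.
* Strata give each stratum its own risk sets (its own baseline hazard); the
  same semantics serve the stratified log-rank.
* Missing values are eliminated model-wise (complete cases over time, event,
  covariates and strata) before fitting.

The formula interface expands the covariates of a Kaplan–Meier request over
the combinations of their observed unique values — including numeric
covariates, deliberately, so a three-valued numeric grade yields three
curves — but refuses more than 20 groups to guard against expanding a truly
continuous variable. An `endpoint_level` recodes the event flag on the fly
(`event := raw == endpoint_level`); without it the canonical 0/1 coding
applies.

## The cohort simulator

Event times are drawn by inverse transform under proportional hazards:
`T = H₀⁻¹(−log U / exp(β'x))` with an exponential (`H₀(t) = λt`) or Weibull
(`H₀(t) = (t/scale)^shape`) baseline. Effects are applied to
mean-centred covariates so the baseline rate stays interpretable at the
cohort average. Censoring is administrative, exponential with a given rate,
or solved to a **target fraction**: the exponential censoring rate `c` is
found by `uniroot` so that the mean of `exp(−c·T_i)` over the drawn latent
times equals the target event fraction — an unbiased conditional
expectation, so the realised censoring fraction concentrates on the target
at Monte-Carlo rate.

The default `colon_like_spec()` emulates the shape of a classic adjuvant
colon-cancer trial: n = 900; overall-survival time in months under an
exponential baseline hazard of 0.03/month (median ≈ 23 months); a treatment
arm with hazard ratio 0.7 (a clinically meaningful adjuvant effect); age
(normal, 60 ± 12 years, +1.5%/year hazard); nodal count (normal, 3.7 ± 3.5,
+8%/node); sex, differentiation (3 levels) and extent (4 levels) as null
covariates; censoring targeted at 50%, typical of trials with substantial
administrative censoring. These values are the package's fixed study
conditions, chosen once as realistic for the field. The nodal count is
drawn normal (so occasionally negative) rather than from a count law — it
is a covariate, not an outcome, and only its linear effect matters to the
model under test.

What the simulator does *not* emulate: dependent or informative censoring,
non-proportional hazards, measurement error, correlated covariates, and
count-valued or heavy-tailed covariate laws. Passing the recovery and
calibration tests therefore shows the estimators are correct *under the
model*, not that the model fits any particular real dataset.

## Problem sizes and calibration checks

The package's statistical guarantees are exercised at these sizes, chosen to
keep Monte-Carlo error far below the tolerance being asserted:

* Kaplan–Meier vs the design law: one cohort of n = 10 000 without
  censoring, sup-norm tolerance 0.02 (empirical-process error at this n is
  ≈ 0.007).
* Log-rank type-I error: 2000 replicates of two exponential arms of 100
  each; acceptance band 0.04–0.06 (±2 binomial SE around the ≈ 0.052 true
  finite-sample level of the χ² approximation at this n).
* Cox recovery: 500 replicates of n = 2000 with true hazard ratio 2 and 30%
  censoring; mean β̂ within 0.05 of log 2 and Wald coverage within
  0.93–0.97.
* Cox vs brute force: n ≤ 20, one binary covariate, no ties; the grid oracle
  scans β at step 1e-3 over [−3, 3] then refines at 1e-5, and the Newton
  estimate must agree to 1e-4.
* Demographic null calibration: 800 replicates per comparison, tolerance 3
  binomial standard errors around α = 0.05.

`scripts/acceptance.R` recomputes all of these from a single `--seed` and
writes them as JSON; the test suite asserts them with fixed seeds.

## Known limitations

* The normality screen's per-group, all-groups-must-pass rule is a design
  choice; screening the pooled sample would route borderline variables
  differently. The choice is recorded per variable in the rationale trace.
* The Wilcoxon/Kruskal branch tests distributional equality, not mean
  equality; under strong variance heterogeneity its null calibration for
  means degrades, as for any rank test.
* Wald intervals for the Cox model are first-order; profile-likelihood
  intervals are not implemented.
* The layer-3 dictionary accepts only integer codes; free-text categorical
  harmonisation beyond token mapping is out of scope.
* Baseline-hazard export, Schoenfeld-residual diagnostics and time-varying
  covariates are out of scope for the survival core.
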