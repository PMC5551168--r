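---
title: "Methods: tract-level risk-factor modeling by spatial microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tract-level risk-factor modeling by spatial microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`tractrisk` estimates the prevalence of modifiable health behaviors and
outcomes — any exercise in the past 30 days, eating five or more daily
servings of fruit and vegetables, body mass index (BMI), and diagnosed
diabetes — at census-tract resolution, where direct survey estimates do not
exist. It does so in four linked steps:

1. **Spatial microsimulation.** Individual survey microdata are available
   only at coarse geography (a public-use microdata area), while small-area
   census products publish tract-level marginal and cross-tabulated counts.
   The package reconstructs a tract-resolved synthetic population by
   selecting, for every tract, a multiset of microdata households whose
   tabulation best matches that tract's constraint tables, by simulated
   annealing.
2. **Outcome models.** Multivariable logistic models (exercise, fruit and
   vegetable consumption, diabetes) and a linear model (BMI) are fitted from
   behavioral-surveillance survey records by block-wise backward selection,
   in a fixed chain order in which each outcome may use earlier outcomes as
   predictors.
3. **Chained prediction.** The fitted (or ingested published) models are
   applied to every synthetic individual aged 21 and older, drawing each
   binary outcome in chain order and categorizing predicted BMI.
4. **Monte Carlo uncertainty.** The prediction chain is replicated (1000
   replicates by default) to give each tract a prevalence distribution per
   outcome, summarized as a mean, a 2.5/97.5 percentile interval, and a
   coefficient of variation.

Because the real constraint tables and survey extracts are restricted, the
package carries a first-class synthetic-data generator with *known* truth:
every stage can be validated against the population and coefficient vectors
that generated its inputs.

## The synthetic city

`gen_params()` describes a city of `n_tracts` (default 31) tracts averaging
roughly 3,000 residents each at the default 1,270 households per tract and
mean household size 2.4 — about 95,000 people, the scale of the mid-sized
city this methodology targets. Two independent spatial patterns drive
between-tract contrast:

* a monotone **socioeconomic gradient**: the probability that a household is
  in the low-SES latent class rises linearly across the tract index (0.20 to
  0.65 by default). Income band, tenure, education, and race/ethnicity are
  drawn conditional on this class, which also induces realistic
  within-household correlation between income, education, and tenure;
* a non-monotone **age pattern** (the share of older adults peaks mid-city),
  so that age-driven outcomes (diabetes) map differently over the city than
  SES-driven behaviors — mirroring the common empirical finding that
  diabetes hot-spots do not coincide with behavioral risk hot-spots.

Households are built person by person: the first member is always an adult
drawn from the tract's adult age profile; later members are children with
probability 0.4, otherwise additional adults. The household head is defined
as the *oldest member* — headship is otherwise arbitrary, and this rule
makes the head-age constraint tables deterministic and testable. Under-18
and 18–20 individuals are generated on purpose: they exercise the age-21
eligibility filter downstream.

Income is generated on eight fine bands and collapsed to three
(`<$25k`, `$25–35k`, `>=$35k`) for modeling and constraints, reflecting how
sparse categories are collapsed in survey practice.

### Generating models (the "truth")

`true_model_set()` holds one generating model per chain stage:

smoking → alcohol → exercise → fruit/vegetable → BMI → diabetes.

Smoking is generated as two nested binaries (ever-smoker, then
current-vs-former among ever-smokers) and reassembled into the three-level
status used as a predictor; how the upstream smoking/alcohol fields were
originally attached to real microdata is not documented in the surveillance
literature we emulate, so the nested-binary choice is ours and is confined
to this generator. Coefficients are on the logit scale (kg/m² for BMI, with
Gaussian residual sd 4.5); directions follow the epidemiological literature
(lower income and education reduce health-promoting behaviors and raise BMI
and diabetes risk; diabetes risk rises steeply with age; current smokers
exercise less but weigh less), and magnitudes were fixed once at
realistic-strong values so that tract-level prevalence contrasts clearly
exceed sampling noise in a simulation of this size.

What the generator does **not** emulate: survey non-response and weighting,
measurement error in self-reports, undercounted subpopulations (e.g.
undocumented immigrants), within-tract spatial structure, and secular time
trends. Passing tests therefore demonstrate that the *algorithms* recover
known structure under clean conditions — not that real-data estimates would
be unbiased.

## The annealer

For one tract, the state is a multiset of microdata household ids (repeats
allowed — sampling with replacement). The objective is the **total absolute
error** (TAE): the sum over all 13 constraint tables (8 individual-level, 5
household-level) of the absolute cell-wise difference between the selected
households' tabulation and the target counts, optionally weighted per table
(default weight 1). TAE is zero exactly on a perfect match and scales
linearly in the weights.

The **unit of assignment is the household**: members travel together.
Assigning severed individuals would make the household-level tables
(tenure, income by head age) untabulatable. Individual-level tables are
evaluated over the members of the selected households.

Moves and schedule:

* **Proposals.** With probability 0.7 a replacement (one uniformly chosen
  selected household is swapped for one uniformly chosen pool household),
  with probability 0.15 an insertion, and 0.15 a deletion. Insertions and
  deletions are essential, not cosmetic: the household-level tables pin the
  number of selected households (their cells sum to the tract's household
  count), and a replacement never changes that number, so a run initialized
  with an overshoot could never reach a perfect fit under replacements
  alone. We verified this directly — replacement-only runs stall at TAE
  13–52 on a toy city whose perfect fit is achievable; with the mixed move
  set they reach 0.
* **Acceptance.** Metropolis: improving *or TAE-neutral* moves are always
  accepted (the objective is integer-valued and plateaus are wide; neutral
  drift explores them), worsening moves with probability exp(−Δ/T).
* **Cooling.** Geometric, T ← 0.99·T every 100 proposals. T0 is
  auto-calibrated from 200 probe moves so that about 80% of initially
  worsening moves would be accepted. A run stops after 50,000 proposals, or
  2,000 proposals without a best-so-far improvement; on a stall the
  temperature can be reset to T0 up to `reheats` times (default 2),
  resuming from the best state. The best-so-far assignment is returned, so
  the reported TAE trace is non-increasing by construction.
* **Initialization.** Households are drawn uniformly with replacement until
  the materialized person count first reaches the tract's person target,
  defined as the sum of the sex table (every person appears in it exactly
  once).
* **Seeding.** Each tract derives its own seed from the master seed and the
  tract id, so tracts are order-independent and reproducible in isolation.

The published methodology this re-implements names only "probabilistic
reweighting using simulated annealing"; the fitness, schedule, move mix,
and integer combinatorial selection are this package's own choices, all
configurable through `anneal_config()` and echoed in diagnostics.

## Outcome models and backward selection

`fit_logistic()`/`fit_linear()` fit maximum-likelihood logistic (IRLS,
log-likelihood tolerance 1e-8, max 100 iterations, Wald standard errors
from the observed information) and least-squares linear models on
reference-cell dummy designs built by `encode_design()`. Complete
separation, degenerate responses, and rank-deficient designs raise
diagnostic errors naming the offending columns.

Backward selection (`backward_select()`) treats the **whole categorical
variable (block)** as the unit of removal: the block-level statistic is a
Wald chi-square that all of the block's coefficients are zero (df = number
of non-reference categories; 1 for binary/continuous terms). At each step
the retained block with the largest block p-value is removed if that
p-value exceeds 0.05, and the model is refitted; ties break to the earliest
block. This matches how published coefficient tables annotate entire
variables as "NS", and avoids the interpretational mess of pruning
individual categories. The Wald form (rather than likelihood-ratio) is
standard, cheap, and equivalent to first order. Missing data are handled
complete-case per model over the full candidate set, so every refit sees
the same observations; fitting is unweighted.

`fit_chain()` fits the four models in chain order; during fitting the
*observed* survey values of earlier outcomes (not predictions) serve as
predictors, and a spec that references a later-stage outcome is rejected.

### Ingesting a published coefficient table

`model_from_table()` builds the same model objects from a packaged
transcription of a published main-effects coefficient table (exercise,
fruit/vegetable, BMI — linear, diabetes). Published tables print no
intercepts, so ingested models are flagged **uncalibrated** and every
prediction path refuses them until `calibrate_intercept()` (or
`calibrate_chain()`) sets the intercept so the population-mean predicted
probability matches a user-supplied target prevalence. The mean predicted
probability is strictly increasing in the intercept, so bisection finds the
unique solution (tolerance 1e-6 on the mean).

Two caveats are deliberate. First, the published BMI coefficients are far
too small for raw kg/m² (e.g. 0.036 for male sex), implying an undocumented
outcome transformation; the transcription stores them verbatim, the model
scale is treated as opaque, and the chain calibrates the BMI intercept
against a target *mean* on whatever scale the user asserts. Second, no
standard errors are printed, so coefficient-draw Monte Carlo is unavailable
for ingested models.

## Prediction and Monte Carlo

`eligible_population()` keeps individuals aged **21 and older** (inclusive)
— the models involve alcohol consumption, so prediction is restricted to
those of legal drinking age. Smoking and alcohol status are carried on the
synthetic population from the microdata (the default), since the emulated
workflow inherits them from prior microdata work; drawing them from
upstream models is also supported.

`chain_predict()` evaluates, per individual: the exercise probability; a
Bernoulli exercise draw; the fruit/vegetable probability conditional on the
drawn exercise; a draw; the BMI value **deterministically** (no residual
draw — BMI uncertainty is not propagated, matching the emulated design);
its category (underweight < 18.5 ≤ normal < 25 ≤ overweight < 30 ≤ obese);
and the diabetes probability conditional on the drawn behaviors and BMI
category.

`monte_carlo()` repeats this chain `n_reps` times (default 1000) and
records every tract's realized prevalence per replicate (**outcome-draw
mode**, the default — the uncertainty is the Bernoulli realization of each
individual's risk). A **coefficient-draw mode** instead perturbs every
coefficient by an independent normal draw at its standard error and records
tract mean probabilities, holding one fixed realization of the upstream
drawn fields; the emulated methodology's description ("each model was
simulated") does not disambiguate the two, so both are first-class and
results are labelled with their mode. All replicates derive their seeds
from (master seed, mode, replicate index).

`summarize_tracts()` reports per tract and outcome the replicate mean, the
2.5/97.5 percentile interval (type-7 linear-interpolation quantiles), and
the coefficient of variation (sample sd / mean; defined 0 when the spread
or the mean is zero). `citywide_summary()` weights tract prevalences by
tract population within each replicate — so the citywide value per
replicate is exactly the population-weighted tract mean — then summarizes
across replicates. Normality is never assumed; percentile intervals were
chosen because the replicate distributions of small-tract prevalences are
visibly discrete and skewed. `ci_overlap()` implements the closed-interval
overlap rule (shared endpoints overlap) used for consistency checks against
published city and state estimates; `export_geo()` writes one GeoJSON
FeatureCollection per outcome for mapping.

## Validation design and problem sizes

The package's correctness claims are established at these scales (chosen to
keep the full validation suite within a few minutes on one CPU, while
remaining faithful scaled-down copies of the default study conditions):

* **Annealer optimality** against exhaustive multiset enumeration: 8
  candidate single-person households, person target 4, one sex table (330
  enumerable multisets); the annealer attains the enumerated minimum in at
  least 9 of 10 seeds at default settings.
* **Self-recovery**: a 4-tract city of 12 households per tract, microdata =
  the full ground-truth pool; every tract reaches TAE 0 and the
  materialized tract marginals equal the truth exactly.
* **Parameter recovery**: 20 surveys of n = 15,814 drawn from the known
  coefficients; at least 93% of coefficient-replicate pairs fall within 2
  fitted standard errors of truth.
* **Selection behavior**: a pure-noise 3-level block appended to a strong
  model (n = 5,000) is removed in 90–98% of 200 replicates at α = 0.05.
* **Monte Carlo consistency**: 1,000 individuals at known heterogeneous
  probabilities, 1,000 replicates; the replicate mean sits within 3
  analytic standard errors of the mean probability and the replicate
  variance within 20% of the Poisson-binomial value.
* **End-to-end recovery**: a 31-tract city of 400 households per tract
  (about 10,000 eligible adults), a 35% microdata sample, a survey of
  15,814, and 200 replicates; the Spearman correlation between pipeline
  tract prevalences and the ground-truth *expected* tract prevalences
  exceeds 0.8 for every binary outcome.

On the last point, "ground truth" deserves care. The realized 0/1 outcome
rates of a tract are one stochastic draw: at a few hundred eligible adults
per tract their binomial noise (sd ≈ 0.02) is comparable to the true
between-tract spread (sd ≈ 0.013–0.027 across outcomes), so even the exact
generating probabilities cannot rank realized rates much better than
Spearman 0.7–0.85. The estimand of the pipeline is the *expected*
prevalence given tract composition, so recovery is judged against the
per-tract mean of the generating models' probabilities
(`tract_truth_prevalence(type = "expected")`); both notions are exposed,
and the realized-rate comparison is reported alongside in the acceptance
script's diagnostics for transparency.

## Numerical and degenerate-input choices

* Equal-TAE annealing moves count as improving (plateau drift); stalls
  reheat at most `reheats` times; a tract with person target 0 yields an
  empty assignment with a warning rather than an error.
* Logistic separation is detected (coefficients diverging with fitted
  probabilities at machine 0/1) and reported as a diagnostic error, as is
  IRLS non-convergence within 100 iterations.
* Backward selection returning an empty model yields an intercept-only fit
  with a warning.
* Calibration requires a target strictly inside (0, 1) and a bracketed
  solution; the bisection runs to 1e-6 on the mean probability.
* All randomness flows through `derive_seed(master, labels...)`, a
  deterministic string hash into [1, 2^31); identical configurations and
  master seeds reproduce every output byte for byte (verified by manifest
  digests).

## Known limitations

* The annealer optimizes tracts independently; it does not constrain the
  city-wide total use of any microdata household, and no multi-tract
  simultaneous optimization (or IPF/GREGWT-style calibration) is provided.
* Survey-design variance (strata, PSU, weights) is not propagated into the
  fitted standard errors; an unweighted fit is the default and only fit.
* BMI uncertainty is deliberately not propagated, so diabetes uncertainty
  understates the contribution of BMI model error.
* The synthetic generator's clean-data assumptions mean validation results
  bound algorithmic, not epidemiological, error.
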