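---
title: "Methods: matched-cohort PheWAS and disease-trajectory construction"
author: "phetraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-cohort PheWAS and disease-trajectory construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`phetraj` implements a registry-style comorbidity analysis of an index
condition (the running example is hyperthyroidism, PheCodes 242/242.1/242.2,
ICD-10 E05.x, self-report codes 1225/1522) in longitudinal diagnosis
records: cohort assembly by propensity-score matching, a phenome-wide
survival screen, competing-risk screening of causes of death, landmark
(time-window) hazard estimation, and construction of directed
disease-trajectory graphs. Because registry data of this kind cannot be
redistributed, the package ships a synthetic-EHR generator with planted
ground truth; every stage is validated by recovering what was planted.

## Data model and preprocessing

Inputs are four delimited tables: diagnosis events (person, code, coding
system, date, source), persons (birth year, gender, BMI, Townsend
deprivation index, education, smoking, alcohol, physical activity, region,
optional loss-to-follow-up date), deaths (date plus one of 16 system-level
underlying-cause categories), and an ICD-10-to-PheCode map.

* **Mapping.** ICD-10 codes are mapped to PheCodes by longest-prefix
  lookup (an `E05.9` event matches an `E05` map row when no finer row
  exists), mirroring how published PheCode maps mix 3- and 4-character
  codes. Self-reported diagnoses map through a separate two-column table
  and must carry an explicit date; the package does not impute interview
  dates. Events in the pregnancy/childbirth, congenital-anomaly and
  external-cause injury/poisoning categories are excluded.
* **Deduplication.** Only the first record per (person, PheCode) is kept.
  Mapping precedes deduplication, so two ICD variants of one PheCode
  collapse to the earlier date.
* **Exposure.** A person is exposed at their earliest exposure-PheCode
  date (the index date). Cases indexed on or before 1997-01-01 are
  dropped (records completeness), as are cases who died on the diagnosis
  day.
* **Time.** Dates are whole days; analysis time is years computed as
  days/365.25. One consequence: ten calendar years spans 3652 days =
  9.9986 analysis years, and tests assert the days/365.25 value.

## Matched cohort

The propensity model is a main-effects logistic regression of exposure on
the eight baseline covariates. Matching is greedy 1:4 nearest-neighbour
without replacement on the logit of the score, with cases processed in a
seeded random order and a caliper of 0.2 SD of the logit score — the
standard Austin recommendation, adopted here as a package default and
config-overridable, since the source design for this analysis type leaves
the estimator details open. Distance ties resolve toward the lower score,
then the lexicographically smaller person id, making runs reproducible.
Sets that keep fewer than four (but at least one) controls are retained.
Post-match exclusions remove controls who died or were lost before the
set's index date and controls carrying a treatment/surgery flag; sets left
without controls are dropped entirely. Balance is reported as standardized
mean differences (pooled-SD denominator; per-level for categoricals; a
zero pooled SD reports SMD 0 with a degeneracy flag).

## Phenome-wide screen

Candidate phenotypes are those diagnosed in at least 20 exposed persons
(all-time by default; a flag restricts counting to post-index). Each
matched set is a stratum; follow-up runs from the index date to the
earliest of phenotype onset, death, loss to follow-up, or the region's
administrative censoring date (England 2022-10-31, Scotland 2022-08-31,
Wales 2022-05-31). Members whose onset is on or before the index date are
excluded as prevalent — onset *on* the index day is treated as prevalent
because a zero follow-up time is not a valid survival record; this is the
one place the package sharpens the "prior to the index date" rule, and it
is deterministic. A same-day tie between onset and death counts as an
event (onset wins), maximising event capture.

The per-phenotype model is a stratified Cox fit (one baseline hazard per
matched set) of the exposure indicator only, with the Efron tie
approximation — appropriate for day-granular data, and fixed rather than
configurable. Screens never abort: a phenotype with no informative
stratum (at least one event and both exposure arms) is flagged
non-estimable. Family-wise control is Bonferroni with m equal to the
number of candidates actually tested, significance at adjusted p < 0.05.

Cause-specific mortality is screened with Fine-Gray subdistribution
models (via censoring-distribution weighting) for causes with at least 20
exposed deaths. Because standard subdistribution software does not
stratify on thousands of small matched sets, this screen is unstratified
and instead adjusts for the eight matching covariates — a deliberate,
documented deviation from the matched-strata design. With a single event
type the fit reduces exactly to the cause-specific Cox model, which the
tests assert.

## Landmark analysis

Windows are [0,2), [2,5), [5,10), [10,∞) years from the index date,
closed-open: an event at exactly a boundary belongs to the later window.
At each landmark the risk set is rebuilt — members with a prior event,
death, loss or censoring before the point are excluded — observation is
administratively terminated at the window end, and the same stratified
Cox model is refit. An event falling exactly on a landmark point would
have zero within-window follow-up; its duration is floored at half a day
(impossible in practice on a day grid, but the degenerate input is
handled deterministically). With the single window [0,∞) the landmark
estimate is *identical* to the overall screen estimate, an exact identity
the tests check.

## Trajectory construction

Among exposed persons only, in four steps:

1. **Pairs.** All ordered phenotype pairs (D1, D2) co-diagnosed in at
   least 10 persons. Diagnoses are counted post-index by default
   (configurable to all-time). Same-day co-diagnoses carry no ordering
   information: they are excluded from the trial count and reported
   separately.
2. **Directionality.** One-sided exact binomial tail
   p = P(X ≥ n_D1-first | n, ½). Bonferroni is applied within the family
   of unordered pairs tested (a pair and its reverse are one hypothesis:
   their one-sided p-values are the two tails of the same trial).
3. **Odds ratio.** Logistic regression of ever-D2 on ever-D1 adjusted
   for gender and age at index; the pair passes with Bonferroni-adjusted
   p < 0.05 and OR > 1. Quasi-separated fits are flagged and dropped.
4. **Mediation.** For coexisting validated pairs D1→D2, D2→D3, D1→D3,
   the indirect effect is the product of logistic coefficients (a from
   D2 ~ D1 + covariates; b from D3 ~ D2 + D1 + covariates) with a seeded
   percentile bootstrap CI (default 1,000 resamples); the triple is
   validated when the CI excludes 0 at a Bonferroni-adjusted confidence
   level over the triples tested. The estimator and CI method are
   package choices; the analysis type names neither.

Validated pairs become graph edges; overlapping validated triples
concatenate into longer trajectories (A→B→C plus B→C→D gives A→B→C→D);
weakly connected components are reported as clusters seeded by the
phenotypes directly associated with the exposure. Mortality trajectories
repeat the machinery per cause of death: phenotypes pass an adjusted
logistic gate against death from that cause (Bonferroni over phenotypes
tested, OR > 1) and feed a sink node. Graphs export as Sankey-ready JSON
and Graphviz DOT; no rendering is done.

Bonferroni families are per gate (pairs for the direction test, pairs for
the OR gate, triples for mediation, phenotypes for each death cause): the
source design states Bonferroni control globally without assigning
families, and per-gate families are the strictest reading that keeps the
gates independent.

## Synthetic cohort generator

The generator emulates the study conditions of a UK registry cohort: 77%
female; exposure prevalence 1.5% by default, assigned by a logistic
propensity model whose intercept is calibrated by fixed-seed Monte Carlo
to hit the target marginal; exposure onsets uniform over 1997–2015;
region mix ~89/7/4% England/Scotland/Wales with the regions' 2022
censoring dates; covariate distributions (BMI 28.1 ± 5.4, Townsend
−1.0 ± 3.2, category frequencies) set to the baseline table of a cohort
of this kind. Phenotype and death-cause onsets are exponential
(piecewise-exponential when landmark-window effects are planted) with
hazards multiplied by exp(effect) from exposure onset, and by chain
effects from upstream-disease onset; deaths are the minimum of competing
cause-specific latent times; records truncate at death, exponential loss
to follow-up (0.005/person-year) and regional censoring.

All randomness derives from one seeded stream laid out in fixed-size
per-person blocks indexed by person position, so enlarging a cohort never
perturbs existing persons — the tests assert this extension property.
Covariates are sampled independently: propensity coefficients already
supply the exposure–covariate confounding that matching must remove, so
a covariance structure would add nothing the tests consume. Controls'
counterfactual index dates are not simulated; they arise from matching,
as in the real design.

What the generator deliberately does not emulate: real-world marginal
disease frequencies, coding noise and miscoding, covariate measurement
error, informative loss to follow-up, and calendar trends in incidence.
Passing recovery tests therefore demonstrates that the estimators recover
what the design assumes, not that the assumptions hold in any particular
registry.

Two distributional facts about the generator matter when interpreting
null scenarios. First, among persons co-diagnosed with two *independent*
diseases of unequal incidence, the higher-rate disease tends to come
first, so the directionality test's null only holds under exchangeable
onset distributions (equal rates); the calibration test is built that
way. Second, "ever diagnosed" indicators of independent diseases
correlate positively through variable follow-up length, so an
unadjusted-for-follow-up OR gate can pass on independent diseases in
large cohorts — a real epidemiological artifact of the analysis type,
visible here because the truth is known.

## Calibration studies and problem sizes

Four replicated studies validate the pipeline end to end; the test suite
and `scripts/acceptance.R` run them at the following sizes, chosen so
each study's Monte-Carlo error is small relative to the property being
checked while a full run stays within an ordinary desktop budget:

* **Coverage**: 20,000 persons per replicate, planted HR 2.0 for one
  phenotype, full matched analysis per replicate; 200 replicates in the
  tests (150 in the acceptance script). Nominal 95% CI coverage is
  accepted within a binomial 3-SE band.
* **Landmark recovery**: planted HR 3.0 on [0,2) and 1.0 after; 20,000
  persons; 100 replicates (80 in the script). The scenario uses a
  phenotype incidence of 0.03/person-year and enrolment 1997–2008 so the
  first window holds ~80 events and the last window remains populated —
  a power-driven design choice made from the closed-form Wald power
  calculation.
* **Family-wise error**: global null with m = 100 candidate phenotypes,
  1,200 persons and 10% exposure per replicate (cohort size is free in
  this study; what matters is the null), 500 replicates (250 in the
  script).
* **Chain recovery**: planted D1→D2→D3 with hazard multipliers 3
  (plus a weaker direct D1→D3 path) among 20,000 exposed persons, 20
  replicates (12 in the script), mediation bootstrap 199 resamples.

## Numerical choices

* Logistic fits in bootstrap loops use `glm.fit` on prebuilt model
  matrices (IRLS, convergence 1e-10); coefficients with |b| > 10 or
  failed convergence mark a fit quasi-separated.
* The piecewise-exponential sampler inverts the cumulative hazard
  exactly; the vectorised form sorts each person's changepoints by
  repeated row-minimum extraction (changepoint counts are ≤ ~6).
* Wald CIs and p-values throughout; Fine-Gray uses robust (sandwich)
  standard errors clustered on person.
* Propensity-intercept calibration solves the marginal-prevalence
  equation by `uniroot` over a fixed-seed Monte-Carlo sample of 40,000
  covariate draws, independent of cohort size and scenario seed.

## Limitations

* Trajectory arrows are sequence, not causation; diagnostic-delay and
  surveillance artifacts propagate into edges exactly as in the source
  analysis type.
* The stratified Cox screen is exposure-only within strata; residual
  confounding beyond the matched covariates is not adjusted.
* The Fine-Gray screen abandons the matched strata (covariate adjustment
  instead); estimates are population-averaged rather than within-set.
* The OR and mediation gates do not adjust for follow-up duration (the
  analysis type does not), which inflates associations between common
  long-follow-up diagnoses; see the generator notes above.
* The bundled PheCode map is a ~50-row demonstration; real analyses must
  supply a complete map.
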