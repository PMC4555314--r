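---
title: "Methods: ICF standardization, monitoring and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ICF standardization, monitoring and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icfmonitor)
```

## The problem

People in the chronic phase of acquired brain injury (ABI) rehabilitation are
assessed once a year with a battery of validated questionnaires — Barthel
index, CIQ, PCRS/PCRSi, Rancho, DRS, GOSE and institution-specific social
scales. The same underlying construct (say, independence in eating) is
captured by different instruments with different scales, which blocks
interoperability and longitudinal comparison. `icfmonitor` standardizes these
heterogeneous responses into profiles coded with the WHO International
Classification of Functioning, Disability and Health (ICF), where every
category carries an ordered severity qualifier — 0 (no problem), 1 (mild),
2 (moderate), 3 (severe), 4 (complete) — plus two sentinels, 8 (not
specified) and 9 (not applicable), which are excluded from all arithmetic.

## The standardization pipeline

Four steps turn one person-year of raw responses into an ICF snapshot:

1. **Attribute normalization.** A declarative crosswalk maps each
   (instrument, item) pair to one ICF code; e.g. Barthel *feeding* maps to
   eating (d550).
2. **Value normalization.** The same crosswalk maps each admissible raw value
   to a qualifier; Barthel feeding scores 10/5/0 map to 0/2/4. Higher ICF
   qualifier always means worse functioning, so instruments scored in the
   opposite direction invert explicitly in the map — direction is never
   inferred.
3. **Aggregation.** When several items target one code (Barthel feeding and
   CIQ competences-at-home/feeding both target d550), their qualifiers reduce
   to one. The default policy is the arithmetic mean of the ordered values
   with halves rounded toward the worse end; worst-case (max) and best-case
   (min) policies are selectable. The rounding choice is clinically
   conservative: when the evidence is equivocal, the profile errs toward
   flagging a problem.
4. **Hierarchical inference.** A parent category without a value (e.g.
   self-care, d5) gains the rounded average of its immediate children that
   have ordered values. Passes run bottom-up — fourth level fills third,
   third fills second, second fills chapters — so inference propagates
   without ever skipping a level, never overwrites measured or aggregated
   data, and is idempotent. A code whose only evidence is sentinels records
   8. The hierarchy itself is derived purely from code text (component letter
   plus digit-count rule: 1 digit = chapter, 3 = second level, 4 = third,
   5 = fourth), so no external taxonomy file is needed; well-formed "other
   specified" codes such as d5308 are placed by the same rule and are
   included in parent averaging.

Every datum keeps provenance (`measured`, `aggregated`, `inferred`) and its
contributing sources, so any cell of a monitoring plot can be audited back to
instrument items.

```{r pipeline-example}
cw <- load_crosswalk(bundled_crosswalk_path())
obs <- tibble::tibble(person_id = "p1", year = 2013,
                      instrument = c("Barthel", "CIQ"),
                      item = c("feeding", "home_feeding"),
                      value = c(10, 0))
standardize(obs, cw)
```

Only the Barthel feeding row of the bundled crosswalk is a published ground
truth; the CIQ/PCRS/DRS rows are clearly-labelled illustrative fixtures that
let the pipeline run end-to-end. They are not clinically validated mappings.

## Monitoring representations

The individual view is a code-by-year matrix of qualifiers with the standard
severity colours (blue/0, green/1, yellow/2, orange/3, red/4; grey for
sentinels and missing). Population views give, for one code and year, the
percentage of the cohort at each severity level. Missing data get an explicit
bin by default — silently dropping them would overstate the observed
severities — and a complete-case flag renormalizes over ordered values when
that convention is wanted. The default time axis is the calendar year of the
evaluation; an alternate axis in years since diagnosis is available for
individual matrices. Correctness is asserted on the returned data; plots are
presentation only.

## Prognosis

The decision-support component predicts the next qualifier of one target
category (5 classes). Eligibility requires at least 3 distinct measurement
years and an ordered value of the target at the label year — the last
measurement, which serves to validate the prediction. Two temporal feature
representations are built on top of the five demographic features (age,
gender, years from diagnosis, disease, origin):

* **full time-series** — one feature per (code, predictor year) pair over all
  codes present in the eligible cohort and all years before the label year;
* **previous state** — one feature per code: the most recent pre-label
  ordered value (chosen over the strictly-preceding calendar year because
  the year-wise missingness of these registries would leave that mostly
  empty).

Label-year values never enter the features, and sentinel qualifiers are
treated as missing, not as ordinal levels. Learners are k-nearest neighbours
(k = 7), naive Bayes, an RBF-kernel support vector machine and a CART
decision tree (`"j48"` is accepted as an alias for the tree learner).
Evaluation is stratified 10-fold cross-validation under a fixed seed — the
original evaluation protocol behind the published benchmark is not stated, so
the common default was chosen and is recorded in the report metadata. Naive
Bayes and the tree consume missing values natively (the qualifier features
are given to naive Bayes as nominal attributes, since Gaussian
class-conditionals degenerate on sparse year-columns); for KNN and SVM,
median/mode imputation is computed within training folds only.

Metrics come from the pooled out-of-fold confusion matrix: accuracy,
precision, recall (sensitivity) and specificity. Each class is scored
one-vs-rest with the textbook formulas and combined by support-weighted
averaging (macro averaging by flag); reported accuracy is the overall
fraction correct, which equals support-weighted recall algebraically. A
per-class ratio with zero denominator scores 0 and the class is flagged.
Attribute importance is impurity importance from a random forest, reported
as percentages — an in-repo ranking device, not a reproduction of any
external service's algorithm or percentages.

## Economics

No published formula ties ICF qualifiers to health utility, so the utility
policy is explicit and pluggable. The default is linear disutility,
`1 - mean(ordered qualifiers)/4` over a configurable code set: all-0 profiles
have utility 1, all-4 profiles utility 0. QALYs gained are the signed utility
change times the interval in years; DALYs averted convert 1:1 by default
(configurable factor; discounting and age-weighting deliberately off);
savings are the monetary value of the DALYs averted minus the cost of the
rehabilitation process. All economic outputs are policy-dependent and
labelled as such.

## The synthetic cohort

No clinical registry ships with the package, so a generator emulates the
registry structure the platform was built for, per prognosis target
(emotional functions b152, measured directly; executive functions b164,
obtained by hierarchical inference from organization-and-planning b1641):

* ages truncated-normal within 17–90 (mean 46.7/47.2, sd 15.5/15.6);
* male:female about 1.8:1; disease and origin drawn from the registry's
  marginal frequencies;
* series of 3–7 consecutive annual evaluations ending 2013; lengths follow a
  discretized normal solved once to give mean 4.2 and sd 1.0 exactly;
* the target attribute is censored missing-completely-at-random per year
  (e.g. 99% in 2007 falling to 0% in 2013 for the emotional preset), and the
  label-year value is never missing;
* raw values are emitted at the instrument level (Barthel, CIQ, PCRS-style
  items) and pushed through the crosswalk, so generation exercises the whole
  standardization pipeline, including aggregation and rollup;
* the label follows a configurable transition model: persist (label = last
  observed previous state with probability 1 − noise, default noise 0.3) or
  uniform (chance level).

`plant_signal()` rewrites labels of an existing cohort under a stated
transition model for parameter-recovery tests: in the noiseless persist limit
a previous-state decision tree should approach perfect accuracy, and with
uniform labels accuracy should sit at 1/5. The transition conditions on an
observed previous state, so replanting uncensors the most recent pre-label
value for the (few) persons whose entire pre-label series was censored;
`generate_cohort()` itself never uncensors, keeping the schedule intact.

What the generator does **not** emulate: joint dependence between
demographics and outcomes, informative (non-random) missingness beyond an
optional mode, instrument-specific measurement error, and the real registry's
label distribution conditional on history. Tests passing on synthetic data
therefore validate the machinery — filters, representations, metrics,
reproducibility — not clinical performance; the published per-learner
benchmark values would require the original 730-person registry and are out
of scope.

## Numerical and design choices

* **Rounding**: means round to the nearest integer, exact halves toward the
  worse end (`floor(x + 0.5)`), both in aggregation and inference.
* **Ties and determinism**: observations are sorted by code and source before
  aggregation, so results are independent of input order; duplicate
  observations of one item keep the last by input order with a warning; all
  stochastic steps (generation, fold assignment, forests) flow from explicit
  seeds.
* **Degenerate inputs**: empty observation sets for a person-year are an
  error in `standardize()` (there is no snapshot to build) but an empty
  *table* harmonizes to an empty result; a benchmark with fewer than two
  label classes is an explicit error; a snapshot with no ordered qualifier
  has undefined utility and errors rather than returning a silent value.
* **Problem sizes in the test suite**: property tests use 1,000 random
  snapshots/confusion tables; signal-recovery runs use n = 500 persons; the
  missingness-schedule check uses n = 5,000 so that the sparse early years
  (reached only by 6–7-year series, about 11% of persons) have denominators
  compatible with a percentage-point comparison.
* **Chance-level checks** use the uniform label model, making the expected
  chance accuracy exactly 1/5 regardless of the preset's label distribution.

## Known limitations

The crosswalk ships with one validated row; real deployments must supply
their instruments' full mappings. The hierarchy is structural only — it does
not know ICF inclusion/exclusion notes, so a code placed by prefix may not be
a clinically sensible child in edge cases. Multiclass averaging and the
cross-validation protocol are reasonable defaults, not reconstructions of the
original platform's unpublished choices. Economic outputs depend entirely on
the utility policy and cost parameters supplied.
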