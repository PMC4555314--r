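# icfmonitor

Monitoring and prognosis of functioning profiles coded with the WHO
International Classification of Functioning, Disability and Health (ICF),
for people in the chronic phase of acquired brain injury (ABI)
rehabilitation.

Rehabilitation centres assess their patients once a year with heterogeneous
validated questionnaires (Barthel index, CIQ, PCRS, DRS, GOSE, ...). The same
construct is measured by different instruments on different scales, which
blocks interoperability and longitudinal comparison. `icfmonitor`:

* **standardizes** raw questionnaire responses into ICF category/qualifier
  profiles through a declarative crosswalk — attribute normalization, value
  normalization, cross-instrument aggregation, and hierarchical inference of
  missing parent categories as the rounded average of the lower categories
  that have a value;
* **monitors** individuals (code × year severity matrices with the standard
  colour coding: blue/0 no problem … red/4 complete problem) and populations
  (percentage of a cohort at each severity level of a category, at an instant
  or over time), with demographic cohort filters;
* **predicts** the next qualifier of a target category (5 ordered classes)
  with a cross-validated benchmark of four learners (KNN with k = 7, naive
  Bayes, SVM, decision tree) over two temporal feature representations — the
  full time-series and the previous state — scored by accuracy, precision,
  recall and specificity from the pooled confusion matrix, plus a random
  forest attribute-importance ranking;
* **quantifies burden**: health utility from ICF profiles (pluggable policy;
  default linear disutility `1 − mean(qualifiers)/4`), QALYs gained, DALYs
  averted, and savings = value of DALYs averted − rehabilitation cost;
* **generates synthetic cohorts** with the structure of an ABI registry
  (ages 17–90, ~1.8:1 male:female, 3–7 annual evaluations with mean length
  4.2, year-wise missingness of the target attribute vanishing in the final
  year, 5-class label distribution), emitted as raw instrument responses so
  the whole pipeline is exercised without clinical data.

The severity scale is the ICF qualifier: 0 no, 1 mild, 2 moderate, 3 severe,
4 complete deficiency/limitation/restriction, with sentinels 8 (not
specified) and 9 (not applicable) excluded from all arithmetic. Confusion
matrices are scored one-vs-rest with

    accuracy = (TP + TN) / (TP + FP + FN + TN)    precision = TP / (TP + FP)
    recall   = TP / (TP + FN)                     specificity = TN / (TN + FP)

and support-weighted averaging across the five classes (weighted recall
equals overall accuracy).

## Worked example

```r
library(icfmonitor)

# --- standardize one person-year ---------------------------------------
cw <- load_crosswalk(bundled_crosswalk_path())
obs <- tibble::tibble(person_id = "p1", year = 2013,
                      instrument = c("Barthel", "CIQ"),
                      item = c("feeding", "home_feeding"),
                      value = c(5, 0))
standardize(obs, cw)
#> <icf_snapshot> person p1, year 2013: 2 ICF data
#>   code  qualifier provenance
#> 1 d550          3 aggregated
#> 2 d5            3 inferred
```

Barthel feeding 5 normalizes to qualifier 2 (moderate) and CIQ
home-feeding 0 to qualifier 4 (complete); both target eating (d550), so they
aggregate to the rounded mean 3, and the parent self-care category (d5),
unmeasured, is inferred from its only valued child.

```r
# --- synthetic cohort, full prognosis benchmark ------------------------
gen <- generate_cohort(cohort_config("emotional", n = 200, seed = 42))
res <- run_prognosis(gen$observations, gen$demographics, target_code = "b152",
                     seed = 42)
res$report
#>   representation learner accuracy precision recall specificity
#> 1 full           knn        0.330     0.314  0.330       0.774
#> 2 full           nb         0.525     0.525  0.525       0.875
#> 3 full           svm        0.370     0.300  0.370       0.793
#> 4 full           tree       0.490     0.488  0.490       0.851
#> 5 previous       knn        0.315     0.300  0.315       0.784
#> 6 previous       nb         0.655     0.649  0.655       0.905
#> 7 previous       svm        0.430     0.413  0.430       0.818
#> 8 previous       tree       0.710     0.705  0.710       0.919
```

The generator plants a persistence signal (the next emotional-functions
qualifier mostly repeats the last observed one, 30% noise), so learners that
exploit the previous state beat chance (0.2 for five classes) by a wide
margin — the numbers characterize the synthetic signal, not clinical
performance.

```r
attribute_importance(res$features$previous, top_n = 5, seed = 42)
#>   feature              importance_pct
#> 1 prev_b152                      28.1
#> 2 prev_b1                        26.1
#> 3 age                            16.1
#> 4 years_from_diagnosis           15.6
#> 5 disease                        14.2
```

The previous state of the target itself (and of its chapter rollup b1) ranks
first, as it should under a persistence signal.

Monitoring and economics:

```r
h <- harmonize_cohort(gen$observations, gen$demographics)
population_snapshot(h$cohort, "b152", 2013)     # % per severity level
individual_evolution(h$cohort[[1]], c("b152", "d550", "d5"))
economic_summary(h$cohort[[1]], cost_per_daly = 30000, rehab_cost = 25000)
```

A command-line wrapper for the whole pipeline ships at `inst/cli/icf-tool`
(subcommands `synth`, `harmonize`, `monitor`, `prognosis`, `economics`).

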