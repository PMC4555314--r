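# End-to-end convenience wrappers tying the modules together.

#' Harmonize a synthetic (or real) observation set into a cohort of profiles
#'
#' Runs the observations through the crosswalk pipeline and assembles
#' [person_profile()] objects.
#'
#' @param observations long observations tibble (`person_id`, `year`,
#'   `instrument`, `item`, `value`).
#' @param demographics demographics tibble (`person_id`, `age`, `gender`,
#'   `years_from_diagnosis`, `disease`, `origin`).
#' @param cw a crosswalk; defaults to the bundled one.
#' @param policy aggregation policy.
#' @return list with `cohort` (profiles), `icf_long` (long ICF tibble) and
#'   `unmapped` (skipped items).
#' @export
harmonize_cohort <- function(observations, demographics,
                             cw = load_crosswalk(bundled_crosswalk_path()),
                             policy = "mean") {
  icf_long <- harmonize_observations(observations, cw, policy = policy)
  list(cohort = build_profiles(icf_long, demographics),
       icf_long = icf_long,
       unmapped = attr(icf_long, "unmapped"))
}

#' Run the full prognosis benchmark on an observation set
#'
#' Harmonizes, filters to the eligible cohort, builds the requested temporal
#' representations and benchmarks the learners.
#'
#' @inheritParams harmonize_cohort
#' @param target_code ICF code to predict.
#' @param representations subset of `c("full", "previous")`.
#' @param learners learner names, see [benchmark()].
#' @param min_years eligibility threshold, see [cohort_spec()].
#' @param label_year optional fixed label year.
#' @param seed benchmark seed.
#' @param ... further arguments to [benchmark()].
#' @return list with `report` (the [benchmark()] tibble), `eligible_n`,
#'   `features` (the representation matrices) and `spec`.
#' @export
run_prognosis <- function(observations, demographics, target_code,
                          cw = load_crosswalk(bundled_crosswalk_path()),
                          representations = c("full", "previous"),
                          learners = c("knn", "nb", "svm", "tree"),
                          min_years = 3, label_year = NULL, seed = 1, ...) {
  representations <- match.arg(representations, several.ok = TRUE)
  h <- harmonize_cohort(observations, demographics, cw = cw)
  spec <- cohort_spec(target_code, label_year = label_year,
                      min_years = min_years)
  eligible <- select_cohort(h$cohort, spec)
  if (length(eligible) == 0) {
    stop("no eligible profiles for target ", target_code, call. = FALSE)
  }
  fms <- list()
  if ("full" %in% representations) {
    fms$full <- features_full_series(eligible, spec)
  }
  if ("previous" %in% representations) {
    fms$previous <- features_previous_state(eligible, spec)
  }
  report <- benchmark(fms, learners = learners, seed = seed, ...)
  list(report = report, eligible_n = length(eligible), features = fms,
       spec = spec)
}
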