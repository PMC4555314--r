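# Containers: per-year ICF snapshots, person profiles, cohorts.
#
# A snapshot holds the standardized ICF data of one person in one evaluation
# year; a profile holds a person's demographics plus their year-indexed
# snapshots; a cohort is a list of profiles.

#' Construct an ICF snapshot
#'
#' One person-year of standardized ICF data. Each datum records its
#' provenance: `measured` (one instrument item), `aggregated` (two or more
#' items targeting the same code) or `inferred` (average of child categories).
#'
#' @param person_id person identifier.
#' @param year evaluation (calendar) year.
#' @param data tibble with columns `code` (ICF code), `qualifier` (integer in
#'   `{0,...,4,8,9}`), `provenance` (`"measured"|"aggregated"|"inferred"`) and
#'   `sources` (list-column of character: item keys or child codes). At most
#'   one datum per code.
#' @return an object of class `icf_snapshot`.
#' @export
icf_snapshot <- function(person_id, year,
                         data = tibble::tibble(code = character(),
                                               qualifier = integer(),
                                               provenance = character(),
                                               sources = list())) {
  stopifnot(length(person_id) == 1L, length(year) == 1L)
  data <- tibble::as_tibble(data)
  if (nrow(data) > 0) {
    parse_icf_code(data$code)
    validate_qualifier(data$qualifier)
    if (anyDuplicated(data$code)) {
      stop("snapshot has more than one datum for code(s): ",
           paste(unique(data$code[duplicated(data$code)]), collapse = ", "),
           call. = FALSE)
    }
    stopifnot(all(data$provenance %in% c("measured", "aggregated", "inferred")))
    data$qualifier <- as.integer(data$qualifier)
    if (!"sources" %in% names(data)) data$sources <- rep(list(character()), nrow(data))
  }
  structure(list(person_id = person_id, year = as.integer(year), data = data),
            class = "icf_snapshot")
}

#' @export
print.icf_snapshot <- function(x, ...) {
  cat("<icf_snapshot> person ", x$person_id, ", year ", x$year, ": ",
      nrow(x$data), " ICF data\n", sep = "")
  if (nrow(x$data) > 0) print(x$data[, c("code", "qualifier", "provenance")])
  invisible(x)
}

# qualifier of one code in a snapshot, NA if absent
snapshot_qualifier <- function(snapshot, code) {
  hit <- snapshot$data$code == code
  if (!any(hit)) NA_integer_ else snapshot$data$qualifier[which(hit)[1]]
}

#' Construct a person profile
#'
#' @param person_id person identifier.
#' @param demographics a one-row data frame or named list with fields `age`,
#'   `gender`, `years_from_diagnosis`, `disease`, `origin`.
#' @param snapshots list of [icf_snapshot()] objects for this person, one per
#'   year; stored sorted by year.
#' @return an object of class `person_profile`.
#' @export
person_profile <- function(person_id, demographics, snapshots) {
  stopifnot(length(snapshots) >= 1L)
  years <- vapply(snapshots, function(s) s$year, integer(1))
  if (anyDuplicated(years)) {
    stop("profile for ", person_id, " has duplicate snapshot years",
         call. = FALSE)
  }
  snapshots <- snapshots[order(years)]
  names(snapshots) <- sort(years)
  structure(list(person_id = person_id,
                 demographics = as.list(demographics),
                 snapshots = snapshots),
            class = "person_profile")
}

#' @export
print.person_profile <- function(x, ...) {
  cat("<person_profile> ", x$person_id, ": years ",
      paste(profile_years(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Measurement years of a profile
#'
#' @param profile a [person_profile()].
#' @return sorted integer vector of snapshot years.
#' @export
profile_years <- function(profile) {
  sort(vapply(profile$snapshots, function(s) s$year, integer(1)))
}

#' Convert a cohort of profiles to a long-format ICF table
#'
#' @param cohort list of [person_profile()] objects.
#' @return tibble with columns `person_id`, `year`, `code`, `qualifier`,
#'   `provenance`, `sources` (sources collapsed to a `;`-separated string).
#' @export
cohort_to_long <- function(cohort) {
  rows <- purrr::map_dfr(cohort, function(p) {
    purrr::map_dfr(p$snapshots, function(s) {
      if (nrow(s$data) == 0) return(NULL)
      tibble::tibble(
        person_id = p$person_id, year = s$year,
        code = s$data$code, qualifier = s$data$qualifier,
        provenance = s$data$provenance,
        sources = vapply(s$data$sources, paste, character(1), collapse = ";")
      )
    })
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(person_id = character(), year = integer(),
                           code = character(), qualifier = integer(),
                           provenance = character(), sources = character())
  }
  rows
}

#' Build profiles from a long-format ICF table plus demographics
#'
#' Inverse of [cohort_to_long()]: used after [harmonize_observations()] to
#' assemble the per-person containers that the monitoring and prognosis
#' modules consume.
#'
#' @param icf_long tibble with columns `person_id`, `year`, `code`,
#'   `qualifier` and optionally `provenance`, `sources`.
#' @param demographics tibble with columns `person_id`, `age`, `gender`,
#'   `years_from_diagnosis`, `disease`, `origin`.
#' @return list of [person_profile()] objects (a cohort), ordered by
#'   `person_id`.
#' @export
build_profiles <- function(icf_long, demographics) {
  icf_long <- tibble::as_tibble(icf_long)
  if (!"provenance" %in% names(icf_long)) icf_long$provenance <- "measured"
  if (!"sources" %in% names(icf_long)) icf_long$sources <- ""
  ids <- unique(demographics$person_id)
  missing_demo <- setdiff(unique(icf_long$person_id), ids)
  if (length(missing_demo) > 0) {
    stop("persons without demographics: ",
         paste(utils::head(missing_demo, 5), collapse = ", "), call. = FALSE)
  }
  cohort <- lapply(ids, function(id) {
    demo <- demographics[demographics$person_id == id, , drop = FALSE][1, ]
    rows <- icf_long[icf_long$person_id == id, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    snaps <- lapply(split(rows, rows$year), function(yr) {
      icf_snapshot(id, yr$year[1], tibble::tibble(
        code = yr$code, qualifier = as.integer(yr$qualifier),
        provenance = yr$provenance,
        sources = strsplit(ifelse(is.na(yr$sources), "", yr$sources), ";",
                           fixed = TRUE)
      ))
    })
    person_profile(id, demo[setdiff(names(demo), "person_id")], snaps)
  })
  purrr::compact(cohort)
}

#' Filter a cohort by demographic criteria
#'
#' Profiles must satisfy all given criteria; omitting every criterion returns
#' the cohort unchanged, so filters compose and adding a criterion can never
#' enlarge the result.
#'
#' @param cohort list of [person_profile()] objects.
#' @param disease,gender,origin optional exact-match values.
#' @param age_range optional numeric length-2 vector `c(min, max)`, inclusive.
#' @return the filtered cohort (possibly empty list).
#' @export
filter_cohort <- function(cohort, disease = NULL, gender = NULL,
                          age_range = NULL, origin = NULL) {
  if (!is.null(age_range)) {
    if (length(age_range) != 2 || !is.numeric(age_range) ||
        any(is.na(age_range)) || age_range[1] > age_range[2]) {
      stop("age_range must be a numeric c(min, max) with min <= max",
           call. = FALSE)
    }
  }
  keep <- vapply(cohort, function(p) {
    d <- p$demographics
    (is.null(disease) || identical(as.character(d$disease), as.character(disease))) &&
      (is.null(gender) || identical(as.character(d$gender), as.character(gender))) &&
      (is.null(origin) || identical(as.character(d$origin), as.character(origin))) &&
      (is.null(age_range) ||
         (!is.null(d$age) && d$age >= age_range[1] && d$age <= age_range[2]))
  }, logical(1))
  cohort[keep]
}
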