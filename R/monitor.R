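# Monitoring representations: individual evolution matrices, population
# qualifier distributions at an instant, and population evolution across
# years, with the standard severity colour coding.

#' Colour of a qualifier value
#'
#' The fixed severity colour scale used in all monitoring plots: blue for 0
#' (no problem), green for 1 (mild), yellow for 2 (moderate), orange for 3
#' (severe), red for 4 (complete). Sentinels (8, 9) and missing values render
#' in a neutral grey.
#'
#' @param q integer vector of qualifiers (NA allowed).
#' @return character vector of colour names.
#' @examples
#' color_of(c(0, 4, 8, NA))
#' @export
color_of <- function(q) {
  validate_qualifier(q, allow_na = TRUE)
  scale <- c(`0` = "blue", `1` = "green", `2` = "yellow",
             `3` = "orange", `4` = "red", `8` = "grey", `9` = "grey")
  out <- unname(scale[as.character(q)])
  out[is.na(q)] <- "grey"
  out
}

#' Individual evolution matrix
#'
#' One row per requested ICF code, one column per measurement year of the
#' profile; cells hold the qualifier observed (or inferred) that year, `NA`
#' where the code has no datum. This is the per-person colour-matrix view of
#' the evolution of functioning.
#'
#' @param profile a [person_profile()].
#' @param codes character vector of ICF codes (row order preserved).
#' @param time_axis `"year"` (calendar year of the evaluation, default) or
#'   `"since_diagnosis"` (columns relabelled as years elapsed since
#'   diagnosis, using the demographic `years_from_diagnosis` at the last
#'   evaluation).
#' @return integer matrix with rownames = codes and colnames = time labels.
#' @export
individual_evolution <- function(profile, codes,
                                 time_axis = c("year", "since_diagnosis")) {
  time_axis <- match.arg(time_axis)
  years <- profile_years(profile)
  m <- matrix(NA_integer_, nrow = length(codes), ncol = length(years),
              dimnames = list(codes, years))
  for (j in seq_along(years)) {
    snap <- profile$snapshots[[as.character(years[j])]]
    for (i in seq_along(codes)) {
      m[i, j] <- snapshot_qualifier(snap, codes[i])
    }
  }
  if (time_axis == "since_diagnosis") {
    yfd <- profile$demographics$years_from_diagnosis
    if (is.null(yfd) || is.na(yfd)) {
      stop("profile has no years_from_diagnosis; cannot relabel time axis",
           call. = FALSE)
    }
    colnames(m) <- years - max(years) + round(yfd)
  }
  m
}

#' Population qualifier distribution at an instant
#'
#' Percentage of the population at each severity level of one ICF code in one
#' year. People who have a snapshot that year but no datum for the code are
#' counted in an explicit `missing` bin by default; `complete_cases = TRUE`
#' switches to percentages over people with an ordered value only. People
#' with no snapshot that year are outside the denominator either way.
#'
#' @param cohort non-empty list of [person_profile()] objects.
#' @param code a single ICF code.
#' @param year evaluation year.
#' @param complete_cases drop the missing bin and renormalize.
#' @return tibble with columns `code`, `year`, `qualifier` (`"0"`..`"4"`,
#'   `"missing"`), `n` and `pct`; `pct` sums to 100.
#' @export
population_snapshot <- function(cohort, code, year, complete_cases = FALSE) {
  if (length(cohort) == 0) {
    stop("population_snapshot() requires a non-empty cohort", call. = FALSE)
  }
  vals <- vapply(cohort, function(p) {
    snap <- p$snapshots[[as.character(year)]]
    if (is.null(snap)) return(NA_integer_)
    q <- snapshot_qualifier(snap, code)
    # sentinels carry no severity: bin with missing
    if (!is.na(q) && !is_ordered_qualifier(q)) q <- NA_integer_
    q
  }, integer(1))
  in_year <- vapply(cohort, function(p) !is.null(p$snapshots[[as.character(year)]]),
                    logical(1))
  vals <- vals[in_year]
  bins <- c(as.character(0:4), "missing")
  lab <- ifelse(is.na(vals), "missing", as.character(vals))
  counts <- table(factor(lab, levels = bins))
  out <- tibble::tibble(code = code, year = as.integer(year),
                        qualifier = bins, n = as.integer(counts))
  if (complete_cases) {
    out <- out[out$qualifier != "missing", , drop = FALSE]
  }
  total <- sum(out$n)
  out$pct <- if (total > 0) 100 * out$n / total else 0
  out
}

#' Population evolution across years
#'
#' One [population_snapshot()] distribution per year, with the same cohort
#' membership rule throughout, showing how the severity mix of one ICF code
#' shifts over time.
#'
#' @inheritParams population_snapshot
#' @param years integer vector of years.
#' @return tibble stacking the per-year distributions.
#' @export
population_evolution <- function(cohort, code, years, complete_cases = FALSE) {
  purrr::map_dfr(years, function(y) {
    population_snapshot(cohort, code, y, complete_cases = complete_cases)
  })
}

#' Plot an individual evolution matrix
#'
#' Renders the severity colour matrix. Correctness lives in the data returned
#' by [individual_evolution()]; this is presentation only.
#'
#' @param m matrix from [individual_evolution()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_individual_evolution <- function(m, title = "Individual evolution") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- tibble::tibble(
    code = rep(rownames(m), times = ncol(m)),
    year = rep(colnames(m), each = nrow(m)),
    qualifier = as.integer(m)
  )
  df$color <- color_of(df$qualifier)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$code)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$color), color = "white") +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(title = title, x = "year", y = "ICF category") +
    ggplot2::theme_minimal()
}

#' Plot a population distribution or evolution
#'
#' @param dist tibble from [population_snapshot()] or
#'   [population_evolution()].
#' @param title plot title.
#' @return a ggplot object (stacked percentage bars per year).
#' @export
plot_population <- function(dist, title = "Population distribution") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  fill <- c(`0` = "blue", `1` = "green", `2` = "yellow", `3` = "orange",
            `4` = "red", missing = "grey")
  ggplot2::ggplot(dist, ggplot2::aes(x = factor(.data$year), y = .data$pct,
                                     fill = .data$qualifier)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = fill) +
    ggplot2::labs(title = title, x = "year", y = "% of population",
                  fill = "qualifier") +
    ggplot2::theme_minimal()
}
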