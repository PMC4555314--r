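# Socio-economic burden indicators derived from ICF profiles: utility,
# QALYs gained over a rehabilitation interval, DALYs averted, and savings
# (cost of the DALYs averted minus the cost of the rehabilitation process).
#
# No published formula ties ICF qualifiers to utility, so the utility policy
# is explicit and pluggable; all downstream quantities are policy-dependent.

#' Health utility of an ICF snapshot
#'
#' Default policy `"linear"`: utility = 1 - (mean ordered qualifier)/4 over
#' the selected code set, i.e. linear disutility on the 0-4 deficiency scale
#' (all qualifiers 0 gives utility 1, all 4 gives 0). Sentinel qualifiers
#' (8, 9) are excluded. Alternative policies can be supplied as a function
#' mapping the ordered qualifier vector to a value in `[0, 1]`.
#'
#' @param snapshot an [icf_snapshot()].
#' @param codes optional ICF codes restricting the computation (default: all
#'   codes in the snapshot).
#' @param policy `"linear"` or a `function(qualifiers) -> utility`.
#' @return utility in `[0, 1]`.
#' @export
utility_of <- function(snapshot, codes = NULL, policy = "linear") {
  stopifnot(inherits(snapshot, "icf_snapshot"))
  data <- snapshot$data
  if (!is.null(codes)) data <- data[data$code %in% codes, , drop = FALSE]
  q <- data$qualifier[is_ordered_qualifier(data$qualifier)]
  if (length(q) == 0) {
    stop("undefined utility: snapshot has no ordered qualifier",
         if (!is.null(codes)) " in the selected codes" else "", call. = FALSE)
  }
  u <- if (is.function(policy)) policy(q) else
    switch(policy,
           linear = 1 - mean(q) / 4,
           stop("unknown utility policy: ", policy, call. = FALSE))
  if (is.na(u) || u < 0 || u > 1) {
    stop("utility policy returned a value outside [0, 1]", call. = FALSE)
  }
  u
}

#' QALYs gained between two snapshots
#'
#' (utility after - utility before) x duration in years. Signed:
#' deterioration yields negative QALYs.
#'
#' @param before,after [icf_snapshot()] objects with defined utility.
#' @param years duration of the interval in years (> 0).
#' @inheritParams utility_of
#' @return QALYs gained (can be negative).
#' @export
qalys_gained <- function(before, after, years, codes = NULL,
                         policy = "linear") {
  stopifnot(is.numeric(years), years > 0)
  (utility_of(after, codes, policy) - utility_of(before, codes, policy)) * years
}

#' DALYs averted from QALYs gained
#'
#' Default conversion factor 1: one QALY gained counts as one DALY averted.
#' Discounting and age-weighting are deliberately off; a different factor can
#' encode them if required.
#'
#' @param qalys QALYs gained.
#' @param factor conversion factor (default 1).
#' @return DALYs averted.
#' @export
dalys_averted <- function(qalys, factor = 1) {
  stopifnot(is.numeric(factor), factor >= 0)
  qalys * factor
}

#' Monetary savings of a rehabilitation process
#'
#' Cost of the DALYs averted minus the cost of the rehabilitation process.
#'
#' @param dalys DALYs averted.
#' @param cost_per_daly monetary value of one averted DALY (>= 0).
#' @param rehab_cost cost of the rehabilitation process (>= 0).
#' @return savings in currency units (negative when rehabilitation cost
#'   exceeds the value of the DALYs averted).
#' @export
savings <- function(dalys, cost_per_daly, rehab_cost) {
  stopifnot(is.numeric(cost_per_daly), cost_per_daly >= 0,
            is.numeric(rehab_cost), rehab_cost >= 0)
  dalys * cost_per_daly - rehab_cost
}

#' Economic summary of one person's rehabilitation interval
#'
#' Convenience wrapper combining [utility_of()], [qalys_gained()],
#' [dalys_averted()] and [savings()] between a person's first and last
#' snapshot. All values are policy-dependent.
#'
#' @param profile a [person_profile()].
#' @param cost_per_daly,rehab_cost see [savings()].
#' @param codes,policy see [utility_of()].
#' @param daly_factor see [dalys_averted()].
#' @return named list: `utility_before`, `utility_after`, `years`,
#'   `qalys_gained`, `dalys_averted`, `savings`.
#' @export
economic_summary <- function(profile, cost_per_daly, rehab_cost,
                             codes = NULL, policy = "linear",
                             daly_factor = 1) {
  years <- profile_years(profile)
  if (length(years) < 2) {
    stop("economic summary needs at least two evaluation years", call. = FALSE)
  }
  before <- profile$snapshots[[as.character(min(years))]]
  after <- profile$snapshots[[as.character(max(years))]]
  span <- max(years) - min(years)
  q <- qalys_gained(before, after, span, codes = codes, policy = policy)
  d <- dalys_averted(q, factor = daly_factor)
  list(
    utility_before = utility_of(before, codes, policy),
    utility_after = utility_of(after, codes, policy),
    years = span,
    qalys_gained = q,
    dalys_averted = d,
    savings = savings(d, cost_per_daly, rehab_cost)
  )
}
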