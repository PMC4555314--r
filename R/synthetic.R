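# Synthetic cohort generator.
#
# Emulates the demographic and longitudinal structure of an acquired brain
# injury rehabilitation registry: ages 17-90, roughly 1.8:1 male:female,
# annual series of length 3-7 (mean 4.2, sd 1.0) ending in 2013, a per-year
# missingness schedule for the predicted attribute that vanishes in the final
# year, and a 5-class label distribution over qualifiers 0-4. Raw
# observations are generated at the instrument level (Barthel, CIQ,
# PCRS-style items) and pushed through the crosswalk, so the whole
# standardization pipeline is exercised on realistic inputs.

TABLE_PRESETS <- list(
  emotional = list(
    n = 419,
    target_code = "b152",
    target_instrument = "PCRS", target_item = "emotional_control",
    age_range = c(17, 90), age_mean = 46.7, age_sd = 15.5,
    gender_probs = c(male = 274, female = 145) / 419,
    yfd_range = c(4, 67), yfd_mean = 17.9, yfd_sd = 15.7,
    disease_freq = c(
      "not assigned" = 2, "Guillain-Barre" = 18, "polio" = 14, "plexus" = 5,
      "mielomeningocele" = 20, "traumatic brain injury" = 213,
      "multiple sclerosis" = 43, "other progressive diseases" = 22,
      "children cerebral palsy" = 103, "hemorrhagic stroke" = 122,
      "thrombotic stroke" = 26, "embolic stroke" = 12,
      "undetermined ischemic brain stroke" = 24,
      "other ischemic brain stroke" = 9,
      "other degenerative diseases not traumatic" = 84,
      "muscular dystrophy" = 1, "poliradiculoneuritis" = 7, "other" = 4),
    origin_freq = c(traumatic = 131, medic = 208, undefined = 80),
    missing_schedule = c(`2007` = 0.99, `2008` = 0.80, `2009` = 0.54,
                         `2010` = 0.42, `2011` = 0.39, `2012` = 0.52,
                         `2013` = 0.00),
    label_dist = c(`0` = 120, `1` = 130, `2` = 112, `3` = 39, `4` = 18) / 419
  ),
  executive = list(
    n = 477,
    target_code = "b164",
    target_instrument = "PCRS", target_item = "organization_planning",
    age_range = c(17, 90), age_mean = 47.2, age_sd = 15.6,
    gender_probs = c(male = 313, female = 164) / 477,
    yfd_range = c(2, 72), yfd_mean = 19.0, yfd_sd = 17.0,
    disease_freq = c(
      "not assigned" = 2, "Guillain-Barre" = 14, "polio" = 7, "plexus" = 3,
      "mielomeningocele" = 14, "traumatic brain injury" = 133,
      "multiple sclerosis" = 23, "other progressive diseases" = 13,
      "children cerebral palsy" = 73, "hemorrhagic stroke" = 87,
      "thrombotic stroke" = 22, "embolic stroke" = 10,
      "undetermined brain stroke" = 14, "other ischemic brain stroke" = 5,
      "other degenerative diseases not traumatic" = 51,
      "muscular dystrophy" = 1, "poliradiculoneuritis" = 3, "other" = 2),
    origin_freq = c(traumatic = 134, medic = 231, undefined = 112),
    missing_schedule = c(`2007` = 0.77, `2008` = 0.69, `2009` = 0.69,
                         `2010` = 0.45, `2011` = 0.37, `2012` = 0.47,
                         `2013` = 0.00),
    label_dist = c(`0` = 100, `1` = 69, `2` = 103, `3` = 91, `4` = 114) / 477
  )
)

# Discretized-normal probabilities on {3..7} fitted so the series-length
# distribution has mean 4.2 and sd 1.0 (solved once numerically).
SERIES_PROBS <- c(`3` = 0.2796, `4` = 0.3644, `5` = 0.2494,
                  `6` = 0.0897, `7` = 0.0169)

#' Solve a discrete series-length distribution for a target mean and sd
#'
#' Fits a discretized normal over the support so that its mean and standard
#' deviation match the targets. Used to derive the default length
#' distribution on 3..7 (mean 4.2, sd 1.0).
#'
#' @param support integer support (e.g. `3:7`).
#' @param mean,sd target moments; `mean` must lie inside the support range.
#' @return named probability vector over `support`.
#' @export
solve_series_probs <- function(support, mean, sd) {
  if (mean < min(support) || mean > max(support)) {
    stop("infeasible series-length configuration: mean ", mean,
         " lies outside the support [", min(support), ", ", max(support), "]",
         call. = FALSE)
  }
  obj <- function(par) {
    p <- stats::dnorm(support, par[1], exp(par[2]))
    p <- p / sum(p)
    m <- sum(support * p)
    s <- sqrt(sum((support - m)^2 * p))
    (m - mean)^2 + (s - sd)^2
  }
  fit <- stats::optim(c(mean, log(max(sd, 1e-3))), obj)
  p <- stats::dnorm(support, fit$par[1], exp(fit$par[2]))
  stats::setNames(p / sum(p), support)
}

#' Configuration of a synthetic cohort
#'
#' Defaults come from a preset describing one of the two prognosis targets
#' (emotional functions, target code b152 measured directly; or executive
#' functions, target code b164 inferred from its child b1641): sample size,
#' age and years-from-diagnosis distributions, gender/disease/origin
#' frequencies, the per-year missingness schedule of the predicted attribute
#' (0 in the final year 2013), and the 5-class label distribution. Series
#' lengths are drawn on support 3-7 with mean 4.2 and sd 1.0.
#'
#' @param preset `"emotional"` or `"executive"`.
#' @param n number of persons (preset default: 419 / 477).
#' @param seed integer seed; the whole generation is reproducible given it.
#' @param signal planted transition model for the label: a list with `model`
#'   (`"persist"`: label equals the previous observed state with probability
#'   `1 - noise`, otherwise uniform over 0-4; or `"uniform"`: label uniform
#'   regardless) and `noise` in `[0, 1]`.
#' @param series_support,series_mean,series_sd series-length distribution
#'   parameters; the probabilities are solved with [solve_series_probs()]
#'   when the moments differ from the defaults.
#' @param ... overrides for any preset field (`age_mean`, `gender_probs`,
#'   `missing_schedule`, `label_dist`, ...).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(preset = c("emotional", "executive"), n = NULL,
                          seed = 1,
                          signal = list(model = "persist", noise = 0.3),
                          series_support = 3:7, series_mean = 4.2,
                          series_sd = 1.0, ...) {
  preset <- match.arg(preset)
  cfg <- TABLE_PRESETS[[preset]]
  cfg$preset <- preset
  if (!is.null(n)) cfg$n <- n
  cfg$seed <- as.integer(seed)
  cfg$signal <- signal
  if (any(series_support < 3) || any(series_support > 7)) {
    stop("series-length support must lie within 3..7", call. = FALSE)
  }
  cfg$series_support <- series_support
  cfg$series_probs <- if (identical(series_support, 3:7) &&
                          series_mean == 4.2 && series_sd == 1.0) {
    SERIES_PROBS
  } else {
    solve_series_probs(series_support, series_mean, series_sd)
  }
  cfg$last_year <- 2013L
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  for (nm in c("gender_probs", "label_dist")) {
    cfg[[nm]] <- cfg[[nm]] / sum(cfg[[nm]])
  }
  if (cfg$n < 0) stop("n must be >= 0", call. = FALSE)
  if (!cfg$signal$model %in% c("persist", "uniform")) {
    stop("unknown signal model: ", cfg$signal$model, call. = FALSE)
  }
  if (cfg$signal$noise < 0 || cfg$signal$noise > 1) {
    stop("signal noise must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= range[1] & draw <= range[2]
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# random walk on 0..4: stay 0.6, step +/-1 with 0.2 each (clamped)
walk_step <- function(q) {
  u <- stats::runif(length(q))
  q <- ifelse(u < 0.2, q - 1L, ifelse(u < 0.4, q + 1L, q))
  pmin(pmax(q, 0L), 4L)
}

draw_label <- function(prev, signal) {
  if (signal$model == "uniform" ||
      (signal$model == "persist" && stats::runif(1) < signal$noise) ||
      is.na(prev)) {
    sample(0:4, 1)
  } else {
    prev
  }
}

# Inverse value maps of the bundled crosswalk rules used by the generator:
# latent qualifier -> raw instrument score.
raw_from_qualifier <- list(
  barthel = function(q) c(`0` = 10, `1` = 10, `2` = 5, `3` = 5, `4` = 0)[as.character(q)],
  ciq = function(q) c(`0` = 2, `1` = 2, `2` = 1, `3` = 1, `4` = 0)[as.character(q)],
  pcrs = function(q) 5 - q
)

#' Generate a synthetic cohort of raw observations
#'
#' Draws demographics, a series of consecutive annual evaluation years ending
#' in 2013, a latent trajectory of the target attribute (initialized from the
#' label distribution, evolving by a small random walk), and raw
#' instrument-level observations consistent with the bundled crosswalk:
#' Barthel feeding/dressing, CIQ items, and a PCRS-style item carrying the
#' target. Pre-label target observations are censored per the year-wise
#' missingness schedule; the label-year (2013) value is never missing. The
#' label-year value follows the configured transition model (see
#' [plant_signal()]): by default it persists the last observed previous state
#' with 30% noise.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort`: `observations` (long tibble:
#'   `person_id`, `year`, `instrument`, `item`, `value`), `demographics`
#'   (tibble), `truth` (latent target qualifier per person-year with an
#'   `observed` flag) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n
  empty <- function() list(
    observations = tibble::tibble(person_id = character(), year = integer(),
                                  instrument = character(), item = character(),
                                  value = numeric()),
    demographics = tibble::tibble(person_id = character(), age = numeric(),
                                  gender = character(),
                                  years_from_diagnosis = numeric(),
                                  disease = character(), origin = character()),
    truth = tibble::tibble(person_id = character(), year = integer(),
                           qualifier = integer(), observed = logical()),
    config = config
  )
  if (n == 0) return(structure(empty(), class = "synthetic_cohort"))

  ids <- sprintf("P%04d", seq_len(n))
  demographics <- tibble::tibble(
    person_id = ids,
    age = round(rtrunc_norm(n, config$age_mean, config$age_sd,
                            config$age_range)),
    gender = sample(names(config$gender_probs), n, replace = TRUE,
                    prob = config$gender_probs),
    years_from_diagnosis = round(rtrunc_norm(n, config$yfd_mean, config$yfd_sd,
                                             config$yfd_range)),
    disease = sample(names(config$disease_freq), n, replace = TRUE,
                     prob = config$disease_freq / sum(config$disease_freq)),
    origin = sample(names(config$origin_freq), n, replace = TRUE,
                    prob = config$origin_freq / sum(config$origin_freq))
  )

  lengths <- sample(config$series_support, n, replace = TRUE,
                    prob = config$series_probs)
  obs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    yrs <- seq(config$last_year - lengths[i] + 1L, config$last_year)
    k <- length(yrs)
    # latent target trajectory over pre-label years
    tq <- integer(k)
    tq[1] <- sample(0:4, 1, prob = config$label_dist)
    for (j in seq_len(k - 1)[-1]) tq[j] <- walk_step(tq[j - 1])
    # censoring of pre-label target observations per the schedule
    miss_p <- config$missing_schedule[as.character(yrs)]
    miss_p[is.na(miss_p)] <- 0
    observed <- stats::runif(k) >= miss_p
    observed[k] <- TRUE
    # label follows the transition model from the last observed previous state
    prev_obs <- which(observed[-k])
    prev <- if (length(prev_obs) > 0) tq[max(prev_obs)] else NA_integer_
    tq[k] <- draw_label(prev, config$signal)

    # context trajectories (exercise aggregation and hierarchy rollup)
    cq <- integer(k)  # self-care severity for Barthel/CIQ items
    cq[1] <- sample(0:4, 1)
    for (j in seq_len(k - 1)[-1]) cq[j] <- walk_step(cq[j - 1])
    cq[k] <- walk_step(cq[max(1, k - 1)])

    inst <- c(rep(config$target_instrument, k), rep("Barthel", 2 * k),
              rep("CIQ", 2 * k))
    item <- c(rep(config$target_item, k), rep("feeding", k),
              rep("dressing", k), rep("family_relationships", k),
              rep("recreation_leisure", k))
    val <- c(raw_from_qualifier$pcrs(tq),
             unname(raw_from_qualifier$barthel(cq)),
             unname(raw_from_qualifier$barthel(walk_step(cq))),
             unname(raw_from_qualifier$ciq(walk_step(cq))),
             unname(raw_from_qualifier$ciq(walk_step(cq))))
    seen <- c(observed, stats::runif(4 * k) >= 0.15)
    obs[[i]] <- tibble::tibble(
      person_id = ids[i], year = rep(yrs, 5), instrument = inst,
      item = item, value = as.numeric(val)
    )[seen, , drop = FALSE]
    truth[[i]] <- tibble::tibble(person_id = ids[i], year = yrs,
                                 qualifier = tq, observed = observed)
  }
  observations <- dplyr::bind_rows(obs)[, c("person_id", "year", "instrument",
                                            "item", "value")]
  structure(list(observations = observations, demographics = demographics,
                 truth = dplyr::bind_rows(truth), config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> preset ", x$config$preset, ": ",
      nrow(x$demographics), " persons, ", nrow(x$observations),
      " observations, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Rewrite labels of a generated cohort per a transition model
#'
#' Replaces every person's label-year target value according to the stated
#' stochastic transition: `model = "persist"` sets the label to the previous
#' observed state with probability `1 - noise` and to a uniform draw over 0-4
#' otherwise; `model = "uniform"` draws uniformly regardless, which is the
#' chance-level (noise 1) limit. The transition conditions on an observed
#' previous state: where the missingness schedule censored every pre-label
#' value of the target, the most recent one is uncensored so the planted
#' transition is well-defined for every person. Used for parameter-recovery
#' tests of the prognosis module (in the noiseless persist limit a
#' previous-state decision tree should approach perfect accuracy).
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param signal list with `model` (`"persist"` or `"uniform"`) and `noise`.
#' @param seed integer seed for the rewriting.
#' @return the cohort with `observations` and `truth` rewritten.
#' @export
plant_signal <- function(cohort, signal = list(model = "persist", noise = 0),
                         seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  signal$noise <- signal$noise %||% 0
  if (!signal$model %in% c("persist", "uniform")) {
    stop("unknown signal model: ", signal$model, call. = FALSE)
  }
  set.seed(seed)
  cfg <- cohort$config
  truth <- cohort$truth
  obs <- cohort$observations
  for (id in unique(truth$person_id)) {
    rows <- which(truth$person_id == id)
    yrs <- truth$year[rows]
    label_row <- rows[which.max(yrs)]
    pre <- rows[yrs < max(yrs)]
    pre_obs <- pre[truth$observed[pre]]
    if (length(pre_obs) == 0 && length(pre) > 0) {
      # uncensor the most recent pre-label value
      reveal <- pre[which.max(truth$year[pre])]
      truth$observed[reveal] <- TRUE
      obs <- dplyr::bind_rows(obs, tibble::tibble(
        person_id = id, year = truth$year[reveal],
        instrument = cfg$target_instrument, item = cfg$target_item,
        value = unname(raw_from_qualifier$pcrs(truth$qualifier[reveal]))))
      pre_obs <- reveal
    }
    prev <- if (length(pre_obs) > 0)
      truth$qualifier[pre_obs[which.max(truth$year[pre_obs])]] else NA_integer_
    new_label <- draw_label(prev, signal)
    truth$qualifier[label_row] <- new_label
    hit <- obs$person_id == id & obs$year == max(yrs) &
      obs$instrument == cfg$target_instrument & obs$item == cfg$target_item
    obs$value[hit] <- unname(raw_from_qualifier$pcrs(new_label))
  }
  cohort$truth <- truth
  cohort$observations <- dplyr::arrange(obs, .data$person_id, .data$year,
                                        .data$instrument, .data$item)
  cohort
}
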