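# Standardization pipeline for one person-year: (1) attribute normalization,
# (2) value normalization, (3a) aggregation of values when several items map
# to the same ICF code, (3b) hierarchical inference of parent categories from
# the average of the lower categories that have a value.

#' Aggregate several qualifiers observed for one ICF code
#'
#' When two or more instrument items target the same ICF code in the same
#' year (e.g. Barthel *feeding* and CIQ *competences at home/feeding*, both
#' standardized to eating d550), their qualifiers must be reduced to one.
#' Sentinels (8, 9) carry no ordered information and are excluded; if only
#' sentinels are present the result is 8 (not specified).
#'
#' @param values integer vector of qualifiers, length >= 1.
#' @param policy `"mean"` (default; arithmetic mean of the ordered values,
#'   halves rounded toward the worse end), `"worst"` (max) or `"best"` (min).
#' @return a single integer qualifier.
#' @export
aggregate_qualifiers <- function(values, policy = c("mean", "worst", "best")) {
  policy <- match.arg(policy)
  if (length(values) == 0) {
    stop("aggregate_qualifiers() requires at least one value", call. = FALSE)
  }
  validate_qualifier(values)
  ordered <- values[is_ordered_qualifier(values)]
  if (length(ordered) == 0) return(8L)
  switch(policy,
    mean  = round_toward_worse(mean(ordered)),
    worst = as.integer(max(ordered)),
    best  = as.integer(min(ordered))
  )
}

#' Infer missing parent categories from their children
#'
#' Every code that is absent from the snapshot but has at least one immediate
#' child carrying an ordered value gains an inferred datum equal to the
#' rounded mean of those children. Passes run bottom-up (fourth level feeds
#' third, third feeds second, second feeds chapters) so inferences propagate
#' without skipping levels. Measured and aggregated data are never
#' overwritten, and the operation is idempotent.
#'
#' @param snapshot an [icf_snapshot()] that has been through normalization and
#'   aggregation.
#' @param policy rounding/aggregation policy passed to
#'   [aggregate_qualifiers()].
#' @return the snapshot with inferred data added.
#' @export
infer_missing <- function(snapshot, policy = "mean") {
  stopifnot(inherits(snapshot, "icf_snapshot"))
  data <- snapshot$data
  # children with d digits fill parents; deepest first
  for (child_digits in c(5L, 4L, 3L)) {
    if (nrow(data) == 0) break
    is_child <- (nchar(data$code) - 1L) == child_digits &
      is_ordered_qualifier(data$qualifier)
    if (!any(is_child)) next
    kids <- data[is_child, ]
    kids$parent <- icf_parent(kids$code)
    for (par in unique(kids$parent)) {
      if (par %in% data$code) next
      contrib <- kids[kids$parent == par, ]
      data <- dplyr::bind_rows(data, tibble::tibble(
        code = par,
        qualifier = aggregate_qualifiers(contrib$qualifier, policy = policy),
        provenance = "inferred",
        sources = list(contrib$code)
      ))
    }
  }
  icf_snapshot(snapshot$person_id, snapshot$year, data)
}

#' Standardize one person-year of raw observations into an ICF snapshot
#'
#' Composition of the four standardization steps: items are mapped to ICF
#' codes (attribute normalization), raw values to qualifiers (value
#' normalization), multiple items targeting one code are aggregated, and
#' absent parent categories are inferred from the average of the lower
#' categories that have a value.
#'
#' Items absent from the crosswalk are skipped, not fatal: they are collected
#' in the `"unmapped"` attribute of the result (and signalled as a warning).
#' Duplicate observations of the same item keep the last by input order.
#'
#' @param observations tibble with columns `person_id`, `year`, `instrument`,
#'   `item`, `value`, all rows sharing one person and year.
#' @param cw a [load_crosswalk()] crosswalk.
#' @param policy aggregation policy, see [aggregate_qualifiers()].
#' @param infer if `FALSE`, skip the hierarchical-inference step.
#' @return an [icf_snapshot()]; attribute `"unmapped"` holds a tibble of
#'   skipped (instrument, item) pairs.
#' @export
standardize <- function(observations, cw, policy = "mean", infer = TRUE) {
  observations <- tibble::as_tibble(observations)
  need <- c("person_id", "year", "instrument", "item", "value")
  stopifnot(all(need %in% names(observations)))
  if (nrow(observations) == 0) {
    stop("standardize() needs a person and year; got zero observations",
         call. = FALSE)
  }
  if (length(unique(observations$person_id)) != 1L ||
      length(unique(observations$year)) != 1L) {
    stop("standardize() handles one person-year at a time", call. = FALSE)
  }
  pid <- observations$person_id[1]
  year <- observations$year[1]

  # deduplicate: keep the last observation of each item by input order
  key <- paste(observations$instrument, observations$item, sep = "\r")
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate observation(s) for ",
            paste(unique(sub("\r", "/", key[dup])), collapse = ", "),
            "; keeping the last of each", call. = FALSE)
    observations <- observations[!dup, , drop = FALSE]
  }

  mapped <- vector("list", nrow(observations))
  unmapped <- list()
  for (i in seq_len(nrow(observations))) {
    o <- observations[i, ]
    rule <- find_rule(cw, o$instrument, o$item)
    if (is.null(rule)) {
      unmapped[[length(unmapped) + 1L]] <-
        tibble::tibble(instrument = o$instrument, item = o$item)
      next
    }
    mapped[[i]] <- tibble::tibble(
      code = rule$icf_code,
      qualifier = normalize_value(o$instrument, o$item, o$value, cw),
      source = paste(o$instrument, o$item, sep = "/")
    )
  }
  mapped <- dplyr::bind_rows(mapped)
  unmapped <- dplyr::bind_rows(unmapped)
  if (nrow(unmapped) > 0) {
    warning("skipped ", nrow(unmapped), " observation(s) with unmapped items: ",
            paste(unique(paste(unmapped$instrument, unmapped$item, sep = "/")),
                  collapse = ", "), call. = FALSE)
  }

  if (nrow(mapped) == 0) {
    snap <- icf_snapshot(pid, year)
  } else {
    # deterministic regardless of observation input order
    mapped <- mapped[order(mapped$code, mapped$source), ]
    per_code <- lapply(split(mapped, mapped$code), function(g) {
      tibble::tibble(
        code = g$code[1],
        qualifier = aggregate_qualifiers(g$qualifier, policy = policy),
        provenance = if (nrow(g) > 1) "aggregated" else "measured",
        sources = list(g$source)
      )
    })
    snap <- icf_snapshot(pid, year, dplyr::bind_rows(per_code))
    if (infer) snap <- infer_missing(snap, policy = policy)
  }
  attr(snap, "unmapped") <- unmapped
  snap
}

#' Restrict a snapshot to a profile definition
#'
#' The selector of the pipeline: keeps only the listed codes (e.g. a
#' condition-specific core set), in the listed order.
#'
#' @param snapshot an [icf_snapshot()].
#' @param codes character vector of ICF codes defining the view.
#' @param keep_missing if `TRUE`, codes requested but absent from the
#'   snapshot are recorded in the `"missing"` attribute of the result; if
#'   `FALSE` (default) they are silently omitted.
#' @return the restricted [icf_snapshot()].
#' @export
select_view <- function(snapshot, codes, keep_missing = FALSE) {
  stopifnot(inherits(snapshot, "icf_snapshot"))
  present <- snapshot$data[match(codes, snapshot$data$code), , drop = FALSE]
  present <- present[!is.na(present$code), , drop = FALSE]
  out <- icf_snapshot(snapshot$person_id, snapshot$year, present)
  if (keep_missing) {
    attr(out, "missing") <- setdiff(codes, present$code)
  }
  out
}

#' Harmonize a full observation table into long-format ICF data
#'
#' Vectorized equivalent of applying [standardize()] to every person-year in
#' the table and binding the results (the equivalence is asserted in the test
#' suite). Warnings about unmapped items are collected once.
#'
#' @param observations tibble with columns `person_id`, `year`, `instrument`,
#'   `item`, `value` (any number of persons and years).
#' @inheritParams standardize
#' @return long-format tibble (`person_id`, `year`, `code`, `qualifier`,
#'   `provenance`, `sources`); attribute `"unmapped"` aggregates skipped
#'   items.
#' @export
harmonize_observations <- function(observations, cw, policy = "mean",
                                   infer = TRUE) {
  observations <- tibble::as_tibble(observations)
  need <- c("person_id", "year", "instrument", "item", "value")
  stopifnot(all(need %in% names(observations)))
  empty <- tibble::tibble(person_id = character(), year = integer(),
                          code = character(), qualifier = integer(),
                          provenance = character(), sources = character())
  no_unmapped <- tibble::tibble(instrument = character(), item = character())
  if (nrow(observations) == 0) {
    attr(empty, "unmapped") <- no_unmapped
    return(empty)
  }

  key <- paste(observations$person_id, observations$year,
               observations$instrument, observations$item, sep = "\r")
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate observation(s) for ",
            length(unique(key[dup])), " (person, year, item) group(s); ",
            "keeping the last of each", call. = FALSE)
    observations <- observations[!dup, , drop = FALSE]
  }

  obs <- dplyr::left_join(
    observations,
    cw$rules[, c("instrument", "item", "icf_code")],
    by = c("instrument", "item")
  )
  unmapped <- dplyr::distinct(obs[is.na(obs$icf_code),
                                  c("instrument", "item"), drop = FALSE])
  if (nrow(unmapped) > 0) {
    warning("unmapped items skipped during harmonization: ",
            paste(paste(unmapped$instrument, unmapped$item, sep = "/"),
                  collapse = ", "), call. = FALSE)
    obs <- obs[!is.na(obs$icf_code), , drop = FALSE]
  }
  if (nrow(obs) == 0) {
    attr(empty, "unmapped") <- unmapped
    return(empty)
  }

  # value normalization, vectorized per crosswalk rule
  obs$qualifier <- NA_integer_
  rule_key <- paste(obs$instrument, obs$item, sep = "\r")
  for (rk in unique(rule_key)) {
    sel <- rule_key == rk
    rule <- find_rule(cw, obs$instrument[sel][1], obs$item[sel][1])
    q <- lookup_qualifiers(rule$values[[1]], obs$value[sel])
    if (any(is.na(q))) {
      stop("value-domain error: raw value(s) ",
           paste(unique(obs$value[sel][is.na(q)]), collapse = ", "),
           " not admissible for ", obs$instrument[sel][1], "/",
           obs$item[sel][1], call. = FALSE)
    }
    obs$qualifier[sel] <- q
  }

  agg_fun <- function(q) aggregate_qualifiers(q, policy = policy)
  obs$source <- paste(obs$instrument, obs$item, sep = "/")
  obs <- dplyr::arrange(obs, .data$person_id, .data$year, .data$icf_code,
                        .data$source)
  long <- dplyr::summarise(
    dplyr::group_by(obs, .data$person_id, .data$year, code = .data$icf_code),
    qualifier = agg_fun(.data$qualifier),
    provenance = if (dplyr::n() > 1) "aggregated" else "measured",
    sources = paste(.data$source, collapse = ";"),
    .groups = "drop"
  )
  long$year <- as.integer(long$year)

  if (infer) {
    for (child_digits in c(5L, 4L, 3L)) {
      kids <- long[(nchar(long$code) - 1L) == child_digits &
                     is_ordered_qualifier(long$qualifier), , drop = FALSE]
      if (nrow(kids) == 0) next
      kids$child <- kids$code
      kids$parent <- icf_parent(kids$code)
      kids <- dplyr::arrange(kids, .data$person_id, .data$year, .data$parent,
                             .data$child)
      inferred <- dplyr::summarise(
        dplyr::group_by(kids, .data$person_id, .data$year,
                        code = .data$parent),
        qualifier = agg_fun(.data$qualifier),
        provenance = "inferred",
        sources = paste(.data$child, collapse = ";"),
        .groups = "drop"
      )
      inferred <- dplyr::anti_join(inferred, long,
                                   by = c("person_id", "year", "code"))
      long <- dplyr::bind_rows(long, inferred)
    }
  }
  long <- dplyr::arrange(long, .data$person_id, .data$year, .data$code)
  attr(long, "unmapped") <- unmapped
  long
}

# vectorized value-map lookup: exact matches first, then closed intervals;
# NA where the raw value is outside the domain
lookup_qualifiers <- function(vmap, raw) {
  q <- rep(NA_integer_, length(raw))
  ex <- vmap[!is.na(vmap$raw), , drop = FALSE]
  if (nrow(ex) > 0) {
    q <- ex$qualifier[match(as.character(raw), ex$raw)]
  }
  iv <- vmap[!is.na(vmap$from), , drop = FALSE]
  if (nrow(iv) > 0 && any(is.na(q))) {
    iv <- iv[order(iv$from), , drop = FALSE]
    todo <- which(is.na(q))
    rn <- suppressWarnings(as.numeric(raw[todo]))
    pos <- findInterval(rn, iv$from)
    hit <- !is.na(rn) & pos >= 1 & rn <= iv$to[pmax(pos, 1L)]
    q[todo[hit]] <- iv$qualifier[pos[hit]]
  }
  q
}

#' Read a long-format observations CSV
#'
#' Expected columns: `person_id`, `year`, `instrument`, `item`, `value`.
#' Lines starting with `#` are metadata and skipped.
#'
#' @param path CSV path.
#' @return tibble of observations.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("person_id", "year", "instrument", "item", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("observations file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$person_id <- as.character(df$person_id)
  df$year <- as.integer(df$year)
  tibble::as_tibble(df)
}
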