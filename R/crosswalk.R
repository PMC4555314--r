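# Declarative crosswalk: questionnaire items -> ICF codes, raw values ->
# qualifiers. This is the attribute-normalization and value-normalization
# stage of the standardization pipeline.
#
# File format (YAML):
#   version: "1.0"
#   instruments:
#     - instrument: Barthel
#       items:
#         - item: feeding
#           icf_code: d550
#           values:
#             - {raw: 10, qualifier: 0}
#             - {raw: 5,  qualifier: 2}
#             - {raw: 0,  qualifier: 4}
#
# A value entry is either an exact match ({raw, qualifier}) or a closed
# numeric interval ({from, to, qualifier}); intervals of one item must not
# overlap. Direction is always explicit in the map, never inferred: for
# instruments where a higher raw score means better functioning (Barthel) the
# map inverts, because a higher ICF qualifier means worse functioning.

#' Load a crosswalk from a YAML configuration file
#'
#' Validates the schema: every rule must carry an item key, a well-formed ICF
#' code and a value map whose qualifiers lie in `{0,1,2,3,4,8,9}`; duplicate
#' (instrument, item) pairs are rejected. An empty rule list is a valid (if
#' useless) crosswalk and only warns.
#'
#' @param path path to the YAML crosswalk file.
#' @return a `crosswalk` object: a tibble of rules (columns `instrument`,
#'   `item`, `icf_code`, `values` list-column) plus a version tag.
#' @seealso [normalize_attribute()], [normalize_value()], [write_crosswalk()]
#' @export
load_crosswalk <- function(path) {
  if (!file.exists(path)) stop("crosswalk file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  build_crosswalk(doc, source = path)
}

build_crosswalk <- function(doc, source = "<config>") {
  version <- doc$version %||% "unversioned"
  instruments <- doc$instruments %||% list()
  rules <- list()
  idx <- 0L
  for (inst in instruments) {
    if (is.null(inst$instrument) || !nzchar(inst$instrument)) {
      stop("crosswalk schema violation in ", source,
           ": instrument block without an 'instrument' name", call. = FALSE)
    }
    for (it in inst$items %||% list()) {
      idx <- idx + 1L
      for (field in c("item", "icf_code", "values")) {
        if (is.null(it[[field]])) {
          stop("crosswalk schema violation in ", source, ": rule #", idx,
               " (", inst$instrument, ") is missing field '", field, "'",
               call. = FALSE)
        }
      }
      parse_icf_code(it$icf_code)
      vmap <- parse_value_map(it$values, rule = idx, source = source)
      rules[[idx]] <- tibble::tibble(
        instrument = inst$instrument, item = it$item,
        icf_code = it$icf_code, values = list(vmap)
      )
    }
  }
  if (idx == 0L) {
    warning("crosswalk '", source, "' contains no rules", call. = FALSE)
    rules_tbl <- tibble::tibble(
      instrument = character(), item = character(),
      icf_code = character(), values = list()
    )
  } else {
    rules_tbl <- dplyr::bind_rows(rules)
    dup <- duplicated(rules_tbl[, c("instrument", "item")])
    if (any(dup)) {
      stop("duplicate crosswalk rule(s) for: ",
           paste(rules_tbl$instrument[dup], rules_tbl$item[dup],
                 sep = "/", collapse = ", "), call. = FALSE)
    }
  }
  structure(list(rules = rules_tbl, version = version), class = "crosswalk")
}

# each entry -> one row of tibble(raw, from, to, qualifier); exact matches are
# stored as character so categorical raw values work too
parse_value_map <- function(entries, rule, source) {
  if (length(entries) == 0) {
    stop("crosswalk schema violation in ", source, ": rule #", rule,
         " has an empty value map", call. = FALSE)
  }
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    q <- e$qualifier
    if (is.null(q) || length(q) != 1 || is.na(suppressWarnings(as.integer(q))) ||
        !(as.integer(q) %in% ICF_QUALIFIERS)) {
      stop("crosswalk validation error in ", source, ": rule #", rule,
           " value entry ", i, " has qualifier '",
           if (is.null(q)) "<missing>" else q,
           "' outside {0,1,2,3,4,8,9}", call. = FALSE)
    }
    if (!is.null(e$raw)) {
      tibble::tibble(raw = as.character(e$raw), from = NA_real_, to = NA_real_,
                     qualifier = as.integer(q))
    } else if (!is.null(e$from) && !is.null(e$to)) {
      if (as.numeric(e$from) > as.numeric(e$to)) {
        stop("crosswalk validation error in ", source, ": rule #", rule,
             " interval entry ", i, " has from > to", call. = FALSE)
      }
      tibble::tibble(raw = NA_character_, from = as.numeric(e$from),
                     to = as.numeric(e$to), qualifier = as.integer(q))
    } else {
      stop("crosswalk schema violation in ", source, ": rule #", rule,
           " value entry ", i, " needs either 'raw' or 'from'/'to'",
           call. = FALSE)
    }
  })
  vmap <- dplyr::bind_rows(rows)
  iv <- vmap[!is.na(vmap$from), ]
  if (nrow(iv) > 1) {
    iv <- iv[order(iv$from), ]
    if (any(iv$from[-1] <= iv$to[-nrow(iv)])) {
      stop("crosswalk validation error in ", source, ": rule #", rule,
           " has overlapping intervals", call. = FALSE)
    }
  }
  vmap
}

#' @export
print.crosswalk <- function(x, ...) {
  cat("<crosswalk> version ", x$version, ": ", nrow(x$rules), " rules, ",
      length(unique(x$rules$instrument)), " instruments, ",
      length(unique(x$rules$icf_code)), " target ICF codes\n", sep = "")
  invisible(x)
}

find_rule <- function(cw, instrument, item) {
  stopifnot(inherits(cw, "crosswalk"))
  hit <- cw$rules$instrument == instrument & cw$rules$item == item
  if (!any(hit)) return(NULL)
  cw$rules[hit, ][1, ]
}

#' Normalize a questionnaire item to its ICF code
#'
#' Attribute normalization: e.g. the Barthel index item *feeding* maps to the
#' ICF category *eating* (d550).
#'
#' @param instrument instrument name, e.g. `"Barthel"`.
#' @param item item key within the instrument, e.g. `"feeding"`.
#' @param cw a [load_crosswalk()] object.
#' @return the target ICF code (character scalar).
#' @export
normalize_attribute <- function(instrument, item, cw) {
  rule <- find_rule(cw, instrument, item)
  if (is.null(rule)) {
    stop("unmapped attribute: instrument '", instrument, "', item '", item,
         "' not present in crosswalk", call. = FALSE)
  }
  rule$icf_code
}

#' Normalize a raw item value to an ICF qualifier
#'
#' Value normalization: e.g. Barthel feeding scores 10, 5 and 0 map to
#' qualifiers 0 (no involvement), 2 (moderate impairment) and 4 (complete).
#' Exact matches take precedence over interval matches.
#'
#' @inheritParams normalize_attribute
#' @param raw the raw item value (numeric or categorical).
#' @return an integer qualifier in `{0,1,2,3,4,8,9}`.
#' @export
normalize_value <- function(instrument, item, raw, cw) {
  rule <- find_rule(cw, instrument, item)
  if (is.null(rule)) {
    stop("unmapped attribute: instrument '", instrument, "', item '", item,
         "' not present in crosswalk", call. = FALSE)
  }
  vmap <- rule$values[[1]]
  exact <- !is.na(vmap$raw) & vmap$raw == as.character(raw)
  if (any(exact)) return(vmap$qualifier[which(exact)[1]])
  rawn <- suppressWarnings(as.numeric(raw))
  if (!is.na(rawn)) {
    iv <- !is.na(vmap$from) & vmap$from <= rawn & rawn <= vmap$to
    if (any(iv)) return(vmap$qualifier[which(iv)[1]])
  }
  stop("value-domain error: raw value '", raw, "' is not admissible for ",
       instrument, "/", item, call. = FALSE)
}

#' Flatten a crosswalk to a tibble for audit
#'
#' @param cw a crosswalk object.
#' @return tibble with one row per value-map entry: `instrument`, `item`,
#'   `icf_code`, `raw`, `from`, `to`, `qualifier`.
#' @export
crosswalk_table <- function(cw) {
  stopifnot(inherits(cw, "crosswalk"))
  if (nrow(cw$rules) == 0) {
    return(tibble::tibble(instrument = character(), item = character(),
                          icf_code = character(), raw = character(),
                          from = double(), to = double(),
                          qualifier = integer()))
  }
  tidyr::unnest(cw$rules, "values")
}

#' Serialize a crosswalk back to YAML
#'
#' Round trip: `load_crosswalk(write_crosswalk(cw, f))` is equivalent to `cw`.
#'
#' @param cw a crosswalk object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(cw, path) {
  stopifnot(inherits(cw, "crosswalk"))
  inst_order <- factor(cw$rules$instrument, levels = unique(cw$rules$instrument))
  insts <- lapply(split(cw$rules, inst_order), function(rt) {
    list(
      instrument = rt$instrument[1],
      items = lapply(seq_len(nrow(rt)), function(i) {
        vm <- rt$values[[i]]
        list(
          item = rt$item[i], icf_code = rt$icf_code[i],
          values = lapply(seq_len(nrow(vm)), function(j) {
            if (!is.na(vm$raw[j])) {
              list(raw = vm$raw[j], qualifier = vm$qualifier[j])
            } else {
              list(from = vm$from[j], to = vm$to[j], qualifier = vm$qualifier[j])
            }
          })
        )
      })
    )
  })
  yaml::write_yaml(list(version = cw$version, instruments = unname(insts)),
                   path)
  invisible(path)
}

#' Path to the bundled acquired-brain-injury crosswalk
#'
#' Contains the published worked example (Barthel feeding scores 10/5/0 to
#' eating d550 qualifiers 0/2/4) plus illustrative rules for CIQ and
#' PCRS-style items so the pipeline runs end-to-end. Only the Barthel feeding
#' row is asserted as ground truth; the rest are plausible fixtures, not
#' clinically validated mappings.
#'
#' @return path to the YAML file shipped with the package.
#' @export
bundled_crosswalk_path <- function() {
  system.file("extdata", "crosswalk-abi.yaml", package = "icfmonitor",
              mustWork = TRUE)
}
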