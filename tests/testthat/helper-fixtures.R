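# Shared fixtures: snapshots, profiles and cohorts built in code.

snap <- function(person_id, year, quals, provenance = "measured") {
  icf_snapshot(person_id, year, tibble::tibble(
    code = names(quals),
    qualifier = as.integer(quals),
    provenance = provenance,
    sources = as.list(names(quals))
  ))
}

demo_row <- function(age = 45, gender = "male", yfd = 10,
                     disease = "traumatic brain injury",
                     origin = "traumatic") {
  list(age = age, gender = gender, years_from_diagnosis = yfd,
       disease = disease, origin = origin)
}

profile_from_years <- function(person_id, year_quals, demographics = demo_row()) {
  snaps <- lapply(names(year_quals), function(y) {
    snap(person_id, as.integer(y), year_quals[[y]])
  })
  person_profile(person_id, demographics, snaps)
}

# cohort for the eligibility filter: series lengths 2-5 ending 2013, the
# target b152 present every observed year except that some persons have an
# empty (absent or sentinel) last-year value; every person-year also carries
# d550 so the year counts as a measurement even when the target is missing
eligibility_cohort <- function(n = 120, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    len <- sample(2:5, 1)
    years <- seq(2013 - len + 1, 2013)
    label_state <- sample(c("present", "absent", "sentinel"), 1,
                          prob = c(0.6, 0.25, 0.15))
    snaps <- lapply(years, function(y) {
      quals <- c(d550 = sample(0:4, 1))
      if (y < 2013 || label_state == "present") {
        quals <- c(quals, b152 = sample(0:4, 1))
      } else if (label_state == "sentinel") {
        quals <- c(quals, b152 = 8L)
      }
      snap(sprintf("E%03d", i), y, quals)
    })
    person_profile(sprintf("E%03d", i), demo_row(), snaps)
  })
}

# independent brute-force oracle for hierarchical inference: recursive
# descendant enumeration over the ancestor closure of the measured codes
oracle_infer <- function(measured) {
  closure <- names(measured)
  repeat {
    parents <- stats::na.omit(unique(icf_parent(closure)))
    new <- setdiff(parents, closure)
    if (length(new) == 0) break
    closure <- c(closure, new)
  }
  value_of <- function(code) {
    if (code %in% names(measured)) return(measured[[code]])
    kids <- closure[!is.na(icf_parent(closure)) & icf_parent(closure) == code]
    vals <- vapply(kids, value_of, integer(1))
    vals <- vals[!is.na(vals) & vals %in% 0:4]
    if (length(vals) == 0) return(NA_integer_)
    as.integer(floor(mean(vals) + 0.5))
  }
  out <- vapply(closure, value_of, integer(1))
  out[!is.na(out)]
}

random_measured_snapshot <- function() {
  pool <- c("b152", "b1641", "b16410", "d550", "d540", "d5308", "d530",
            "d920", "d9201", "e340", "d8700", "d230")
  codes <- sample(pool, sample(1:6, 1))
  quals <- sample(c(0:4, 8L, 9L), length(codes), replace = TRUE,
                  prob = c(rep(0.18, 5), 0.05, 0.05))
  stats::setNames(as.integer(quals), codes)
}

tiny_crosswalk_yaml <- function(path = tempfile(fileext = ".yaml")) {
  writeLines(c(
    "version: 'test'",
    "instruments:",
    "  - instrument: Barthel",
    "    items:",
    "      - item: feeding",
    "        icf_code: d550",
    "        values:",
    "          - {raw: 10, qualifier: 0}",
    "          - {raw: 5, qualifier: 2}",
    "          - {raw: 0, qualifier: 4}"
  ), path)
  path
}
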