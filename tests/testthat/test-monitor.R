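test_that("the severity colour scale is the fixed bijection on 0-4", {
  expect_equal(color_of(0:4), c("blue", "green", "yellow", "orange", "red"))
  expect_equal(color_of(c(8, 9, NA)), c("grey", "grey", "grey"))
  # bijection: distinct colours, invertible on 0-4
  expect_equal(anyDuplicated(color_of(0:4)), 0L)
})

test_that("individual evolution matrices restate the profile data", {
  p <- profile_from_years("p1", list(`2010` = c(d550 = 2), `2011` = c(d550 = 1)))
  m <- individual_evolution(p, "d550")
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(unname(m["d550", ]), c(2L, 1L))

  m2 <- individual_evolution(p, c("d550", "b152"))
  expect_true(all(is.na(m2["b152", ])))   # never observed -> missing row

  m3 <- individual_evolution(p, character(0))
  expect_equal(nrow(m3), 0L)
})

test_that("the time axis can be relabelled as years since diagnosis", {
  p <- profile_from_years("p1", list(`2010` = c(d550 = 2), `2013` = c(d550 = 1)),
                          demographics = demo_row(yfd = 26))
  m <- individual_evolution(p, "d550", time_axis = "since_diagnosis")
  expect_equal(colnames(m), c("23", "26"))
})

test_that("population snapshots count qualifiers into percentage bins", {
  cohort <- list(
    profile_from_years("a", list(`2012` = c(d550 = 0))),
    profile_from_years("b", list(`2012` = c(d550 = 0))),
    profile_from_years("c", list(`2012` = c(d550 = 2))),
    profile_from_years("d", list(`2012` = c(d550 = 4)))
  )
  d <- population_snapshot(cohort, "d550", 2012)
  pct <- stats::setNames(d$pct, d$qualifier)
  expect_equal(unname(pct[c("0", "2", "4")]), c(50, 25, 25))
  expect_equal(sum(d$pct), 100, tolerance = 1e-9)

  # nobody has the code that year -> 100% missing bin
  d2 <- population_snapshot(cohort, "b152", 2012)
  expect_equal(d2$pct[d2$qualifier == "missing"], 100)

  # complete-case mode renormalizes over ordered values
  cohort2 <- c(cohort, list(profile_from_years("e", list(`2012` = c(d920 = 1)))))
  d3 <- population_snapshot(cohort2, "d550", 2012, complete_cases = TRUE)
  expect_false("missing" %in% d3$qualifier)
  expect_equal(sum(d3$pct), 100, tolerance = 1e-9)

  expect_error(population_snapshot(list(), "d550", 2012), "non-empty")
})

test_that("population evolution tracks per-year distributions", {
  p <- profile_from_years("a", list(`2011` = c(b152 = 3), `2012` = c(b152 = 2)))
  d <- population_evolution(list(p), "b152", c(2011, 2012))
  y1 <- d[d$year == 2011, ]
  y2 <- d[d$year == 2012, ]
  expect_equal(y1$pct[y1$qualifier == "3"], 100)
  expect_equal(y2$pct[y2$qualifier == "2"], 100)
  expect_equal(sum(y1$pct), 100, tolerance = 1e-9)
  expect_equal(sum(y2$pct), 100, tolerance = 1e-9)
  expect_equal(nrow(population_evolution(list(p), "b152", integer(0))), 0)
})

test_that("distributions sum to 100% on random cohorts", {
  set.seed(3)
  cohort <- lapply(1:40, function(i) {
    profile_from_years(paste0("r", i),
                       list(`2012` = c(d550 = sample(c(0:4, 8), 1))))
  })
  for (cc in c(TRUE, FALSE)) {
    d <- population_snapshot(cohort, "d550", 2012, complete_cases = cc)
    expect_equal(sum(d$pct), 100, tolerance = 1e-9)
  }
})

test_that("cohort filtering is conjunctive, monotone and commutative", {
  cohort <- list(
    profile_from_years("a", list(`2012` = c(d550 = 1)),
                       demo_row(age = 30, disease = "traumatic brain injury",
                                gender = "male")),
    profile_from_years("b", list(`2012` = c(d550 = 1)),
                       demo_row(age = 60, disease = "multiple sclerosis",
                                gender = "female")),
    profile_from_years("c", list(`2012` = c(d550 = 1)),
                       demo_row(age = 44, disease = "traumatic brain injury",
                                gender = "female"))
  )
  expect_length(filter_cohort(cohort), 3)   # identity with no criteria
  tbi <- filter_cohort(cohort, disease = "traumatic brain injury")
  expect_setequal(vapply(tbi, `[[`, character(1), "person_id"), c("a", "c"))

  ab <- filter_cohort(filter_cohort(cohort, disease = "traumatic brain injury"),
                      gender = "female")
  ba <- filter_cohort(filter_cohort(cohort, gender = "female"),
                      disease = "traumatic brain injury")
  expect_equal(vapply(ab, `[[`, character(1), "person_id"),
               vapply(ba, `[[`, character(1), "person_id"))
  expect_lte(length(ab), length(tbi))      # adding criteria never enlarges

  expect_length(filter_cohort(cohort, age_range = c(17, 90)), 3)
  expect_error(filter_cohort(cohort, age_range = c(90, 17)), "age_range")
})

test_that("plots are produced from the data without error", {
  skip_if_not_installed("ggplot2")
  p <- profile_from_years("p1", list(`2010` = c(d550 = 2), `2011` = c(d550 = 1)))
  g1 <- plot_individual_evolution(individual_evolution(p, "d550"))
  expect_s3_class(g1, "ggplot")
  g2 <- plot_population(population_evolution(list(p), "d550", 2010:2011))
  expect_s3_class(g2, "ggplot")
})
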