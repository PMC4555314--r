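# brute-force metric oracle: enumerate every cell of the table per class
oracle_eval <- function(cm) {
  total <- sum(cm)
  K <- nrow(cm)
  prec <- rec <- spec <- 0
  correct <- 0
  for (k in seq_len(K)) {
    TP <- FP <- FN <- TN <- 0
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        n <- cm[i, j]
        if (i == k && j == k) TP <- TP + n
        else if (i == k) FN <- FN + n
        else if (j == k) FP <- FP + n
        else TN <- TN + n
      }
    }
    w <- (TP + FN) / total
    prec <- prec + w * (if (TP + FP == 0) 0 else TP / (TP + FP))
    rec <- rec + w * (if (TP + FN == 0) 0 else TP / (TP + FN))
    spec <- spec + w * (if (TN + FP == 0) 0 else TN / (TN + FP))
  }
  for (i in seq_len(K)) correct <- correct + cm[i, i]
  list(accuracy = correct / total, precision = prec, recall = rec,
       specificity = spec)
}

make_fm <- function(n = 100, seed = 1, label_from_feature = TRUE) {
  set.seed(seed)
  fm <- tibble::tibble(
    person_id = sprintf("m%03d", seq_len(n)),
    age = round(runif(n, 17, 90)),
    gender = factor(sample(c("male", "female"), n, replace = TRUE)),
    years_from_diagnosis = round(runif(n, 2, 40)),
    disease = factor(sample(c("tbi", "stroke"), n, replace = TRUE)),
    origin = factor(sample(c("traumatic", "medic"), n, replace = TRUE)),
    prev_b152 = sample(0:4, n, replace = TRUE),
    prev_d550 = sample(0:4, n, replace = TRUE)
  )
  fm$label <- factor(if (label_from_feature) fm$prev_b152 else
    sample(0:4, n, replace = TRUE), levels = 0:4)
  attr(fm, "representation") <- "previous"
  fm
}

test_that("eligibility keeps >=3 measurement years and an ordered label", {
  spec <- cohort_spec("b152", min_years = 3)
  two_years <- profile_from_years("a", list(`2011` = c(b152 = 1),
                                            `2012` = c(b152 = 2)))
  label_missing <- profile_from_years("b", list(`2011` = c(b152 = 1),
                                                `2012` = c(b152 = 2),
                                                `2013` = c(d550 = 1)))
  label_sentinel <- profile_from_years("c", list(`2011` = c(b152 = 1),
                                                 `2012` = c(b152 = 2),
                                                 `2013` = c(b152 = 8)))
  ok <- profile_from_years("d", list(`2011` = c(b152 = 1),
                                     `2012` = c(b152 = 2),
                                     `2013` = c(b152 = 2)))
  kept <- select_cohort(list(two_years, label_missing, label_sentinel, ok), spec)
  expect_equal(vapply(kept, `[[`, character(1), "person_id"), "d")
})

test_that("eligibility is monotone in the minimum series length", {
  cohort <- eligibility_cohort(n = 80, seed = 4)
  sizes <- vapply(2:5, function(m) {
    length(select_cohort(cohort, cohort_spec("b152", min_years = m)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(cohort_spec("b152", min_years = 1), ">= 2")
})

test_that("full-series features are code x predictor-year plus demographics", {
  p <- profile_from_years("x", list(
    `2011` = c(b152 = 1, d550 = 2),
    `2012` = c(b152 = 2, d540 = 3),
    `2013` = c(b152 = 2)
  ))
  spec <- cohort_spec("b152")
  fm <- features_full_series(list(p), spec)
  temporal <- setdiff(names(fm), c("person_id", "age", "gender",
                                   "years_from_diagnosis", "disease",
                                   "origin", "label"))
  expect_length(temporal, 6)  # 3 codes x 2 predictor years
  expect_setequal(temporal, c("b152_2011", "b152_2012", "d550_2011",
                              "d550_2012", "d540_2011", "d540_2012"))
  expect_equal(fm$b152_2011, 1)
  expect_true(is.na(fm$d540_2011))
  expect_equal(as.character(fm$label), "2")
  # label-year values are never features
  expect_false(any(grepl("2013", names(fm))))
})

test_that("previous-state features take the last ordered pre-label value", {
  p <- profile_from_years("x", list(
    `2010` = c(b152 = 1),
    `2012` = c(b152 = 3),
    `2013` = c(b152 = 2)
  ))
  spec <- cohort_spec("b152")
  fm <- features_previous_state(list(p), spec)
  expect_equal(fm$prev_b152, 3)
  expect_equal(as.character(fm$label), "2")

  const <- profile_from_years("y", list(
    `2011` = c(b152 = 2), `2012` = c(b152 = 2), `2013` = c(b152 = 0)
  ))
  expect_equal(features_previous_state(list(const), spec)$prev_b152, 2)

  # a code observed only in the label year yields a missing previous state
  only_label <- profile_from_years("z", list(
    `2011` = c(b152 = 1), `2012` = c(b152 = 1),
    `2013` = c(b152 = 1, d550 = 4)
  ))
  fm3 <- features_previous_state(list(only_label), spec)
  expect_true(is.na(fm3$prev_d550))

  # sentinel pre-label values are skipped, not used as ordinal levels
  sentinel <- profile_from_years("w", list(
    `2011` = c(b152 = 1), `2012` = c(b152 = 8), `2013` = c(b152 = 2)
  ))
  expect_equal(features_previous_state(list(sentinel), spec)$prev_b152, 1)
})

test_that("binary metrics reduce to the textbook formulas verbatim", {
  perfect <- evaluate(c(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  specificity = 1))
  m <- evaluate(c(TP = 2, FP = 1, FN = 1, TN = 6))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
})

test_that("a diagonal multiclass table scores 1 everywhere", {
  m <- evaluate(diag(c(3, 3, 3)))
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1,
                            specificity = 1))
})

test_that("multiclass metrics match brute-force counting on random tables", {
  set.seed(21)
  for (i in 1:1000) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, lambda = sample(1:8, 1)), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    got <- evaluate(cm)
    want <- oracle_eval(cm)
    for (metric in names(want)) {
      expect_equal(got[[metric]], want[[metric]], tolerance = 1e-12)
    }
    # support-weighted recall equals overall accuracy (algebraic identity)
    expect_equal(got$recall, got$accuracy, tolerance = 1e-12)
    expect_true(all(unlist(got) >= 0 & unlist(got) <= 1))
  }
})

test_that("zero-denominator classes are scored 0 and flagged", {
  cm <- matrix(c(5, 0, 3, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))  # b never predicted, never true? row b: 3,0
  m <- evaluate(cm)
  expect_false(any(is.na(unlist(m))))
  expect_true(!is.null(attr(m, "degenerate_classes")))
})

test_that("the benchmark is reproducible and conserves instance counts", {
  fm <- make_fm(n = 120, seed = 8)
  r1 <- benchmark(fm, learners = c("tree", "nb"), seed = 5)
  r2 <- benchmark(fm, learners = c("tree", "nb"), seed = 5)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  cms <- attr(r1, "confusions")
  totals <- vapply(cms, sum, numeric(1))
  expect_true(all(totals == nrow(fm)))    # every instance evaluated once
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
})

test_that("a single-class label vector is rejected as degenerate", {
  fm <- make_fm(n = 30, seed = 2)
  fm$label <- factor(rep(2, 30), levels = 0:4)
  expect_error(benchmark(fm, learners = "tree"), "degenerate")
})

test_that("all four learners run on pipeline features", {
  gen <- generate_cohort(cohort_config("emotional", n = 80, seed = 31))
  res <- run_prognosis(gen$observations, gen$demographics, "b152",
                       learners = c("knn", "nb", "svm", "tree"), seed = 9)
  expect_equal(nrow(res$report), 8)  # 2 representations x 4 learners
  expect_setequal(unique(res$report$representation), c("full", "previous"))
  metrics <- unlist(res$report[, c("accuracy", "precision", "recall",
                                   "specificity")])
  expect_true(all(metrics >= 0 & metrics <= 1))
})

test_that("a planted previous-state signal is recovered by the tree", {
  gen <- generate_cohort(cohort_config("emotional", n = 150, seed = 17))
  noiseless <- plant_signal(gen, list(model = "persist", noise = 0), seed = 18)
  res <- run_prognosis(noiseless$observations, noiseless$demographics, "b152",
                       representations = "previous", learners = "tree",
                       seed = 19)
  expect_gte(res$report$accuracy, 0.9)
})

test_that("importance ranks a copied-label feature first", {
  fm <- make_fm(n = 300, seed = 13, label_from_feature = TRUE)
  imp <- attribute_importance(fm, top_n = 10, seed = 3)
  expect_equal(imp$feature[1], "prev_b152")
  expect_gt(imp$importance_pct[1], 50)
  expect_equal(sum(imp$importance_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(imp$importance_pct) <= 1e-9))  # descending

  # pure-noise labels: no feature dominates
  fm2 <- make_fm(n = 300, seed = 14, label_from_feature = FALSE)
  imp2 <- attribute_importance(fm2, top_n = 10, seed = 3)
  expect_lt(imp2$importance_pct[1], 50)

  # requesting more features than exist returns what exists
  imp3 <- attribute_importance(fm, top_n = 50, seed = 3)
  expect_lte(nrow(imp3), 7)
})
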