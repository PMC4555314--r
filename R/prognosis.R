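# Clinical decision support: predict the next qualifier of a target ICF
# category. Eligibility filtering (at least `min_years` annual measurements
# and a non-empty target value in the last measurement, which serves as the
# label), two temporal feature representations (full time-series vs previous
# state), a multi-learner cross-validated benchmark with four
# confusion-matrix metrics, and attribute-importance ranking.

#' Specification of a prognosis cohort
#'
#' @param target_code the ICF code whose next qualifier is predicted (e.g.
#'   `"b152"` emotional functions, `"b164"` executive functions).
#' @param label_year the year whose value is predicted and used for
#'   validation; `NULL` (default) uses each person's last measurement year.
#' @param min_years minimum number of distinct annual measurements required
#'   for eligibility; must be >= 2 (the label year plus at least one
#'   predictor year). Default 3.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(target_code, label_year = NULL, min_years = 3L) {
  parse_icf_code(target_code)
  if (min_years < 2) {
    stop("min_years must be >= 2 (label plus at least one predictor year)",
         call. = FALSE)
  }
  structure(list(target_code = target_code,
                 label_year = if (is.null(label_year)) NULL else as.integer(label_year),
                 min_years = as.integer(min_years)),
            class = "cohort_spec")
}

label_year_of <- function(profile, spec) {
  if (is.null(spec$label_year)) max(profile_years(profile)) else spec$label_year
}

# ordered target qualifier at a year; NA if absent, sentinel, or no snapshot
target_at <- function(profile, code, year) {
  snap <- profile$snapshots[[as.character(year)]]
  if (is.null(snap)) return(NA_integer_)
  q <- snapshot_qualifier(snap, code)
  if (is.na(q) || !is_ordered_qualifier(q)) NA_integer_ else q
}

#' Filter a cohort to prognosis-eligible profiles
#'
#' Keeps exactly the profiles with at least `min_years` distinct measurement
#' years and an ordered (0-4) value of the target code in the label year
#' (the last measurement, used to validate the prediction).
#'
#' @param cohort list of [person_profile()] objects.
#' @param spec a [cohort_spec()].
#' @return the eligible sub-cohort.
#' @export
select_cohort <- function(cohort, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  keep <- vapply(cohort, function(p) {
    years <- profile_years(p)
    ly <- label_year_of(p, spec)
    length(years) >= spec$min_years &&
      ly %in% years &&
      !is.na(target_at(p, spec$target_code, ly))
  }, logical(1))
  cohort[keep]
}

demographic_features <- function(profile) {
  d <- profile$demographics
  tibble::tibble(
    age = as.numeric(d$age %||% NA),
    gender = as.character(d$gender %||% NA),
    years_from_diagnosis = as.numeric(d$years_from_diagnosis %||% NA),
    disease = as.character(d$disease %||% NA),
    origin = as.character(d$origin %||% NA)
  )
}

codes_in_scope <- function(cohort) {
  sort(unique(unlist(lapply(cohort, function(p) {
    unlist(lapply(p$snapshots, function(s) s$data$code))
  }))))
}

finalize_feature_matrix <- function(fm, representation, spec) {
  for (col in c("gender", "disease", "origin")) {
    fm[[col]] <- factor(fm[[col]])
  }
  fm$label <- factor(fm$label, levels = 0:4)
  if (any(is.na(fm$label))) {
    stop("internal contract violation: missing label after eligibility filter",
         call. = FALSE)
  }
  attr(fm, "representation") <- representation
  attr(fm, "spec") <- spec
  fm
}

#' Full time-series feature representation
#'
#' One feature per (ICF code, predictor year) pair, over all codes present in
#' at least one eligible profile and all years strictly before each person's
#' label year, plus the five demographic features (age, gender, years from
#' diagnosis, disease, origin). Label-year values never enter the features.
#' Cells without an ordered value are missing (`NA`); sentinel qualifiers 8/9
#' are treated as missing, not as ordinal levels.
#'
#' @param cohort an eligibility-filtered cohort (see [select_cohort()]).
#' @param spec the [cohort_spec()] used for filtering.
#' @return a tibble (one row per person) with `person_id`, demographic
#'   columns, temporal columns named `<code>_<year>`, and a 5-level factor
#'   `label`; attribute `"representation"` is `"full"`.
#' @export
features_full_series <- function(cohort, spec) {
  stopifnot(length(cohort) > 0)
  codes <- codes_in_scope(cohort)
  label_years <- vapply(cohort, label_year_of, integer(1), spec = spec)
  all_years <- sort(unique(unlist(lapply(cohort, profile_years))))
  pred_years <- all_years[all_years < max(label_years)]
  if (length(pred_years) == 0) {
    stop("contract violation: no predictor years before the label year",
         call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    ly <- label_years[i]
    if (all(profile_years(p) >= ly)) {
      stop("contract violation: profile ", p$person_id,
           " has no measurements before its label year", call. = FALSE)
    }
    cells <- lapply(pred_years, function(y) {
      if (y >= ly) return(stats::setNames(rep(NA_real_, length(codes)),
                                          paste0(codes, "_", y)))
      v <- vapply(codes, function(cd) {
        q <- target_at(p, cd, y)
        if (is.na(q)) NA_real_ else as.numeric(q)
      }, numeric(1))
      stats::setNames(v, paste0(codes, "_", y))
    })
    dplyr::bind_cols(
      tibble::tibble(person_id = p$person_id),
      demographic_features(p),
      tibble::as_tibble(as.list(unlist(cells))),
      tibble::tibble(label = target_at(p, spec$target_code, ly))
    )
  })
  finalize_feature_matrix(rows, "full", spec)
}

#' Previous-state feature representation
#'
#' The temporal block reduces to one feature per ICF code: the qualifier at
#' the most recent pre-label year in which that code has an ordered value
#' (missing if there is none). Demographics as in [features_full_series()].
#'
#' @inheritParams features_full_series
#' @return a tibble with `person_id`, demographic columns, temporal columns
#'   named `prev_<code>`, and factor `label`; attribute `"representation"` is
#'   `"previous"`.
#' @export
features_previous_state <- function(cohort, spec) {
  stopifnot(length(cohort) > 0)
  codes <- codes_in_scope(cohort)
  rows <- purrr::map_dfr(cohort, function(p) {
    ly <- label_year_of(p, spec)
    years <- profile_years(p)
    prev_years <- sort(years[years < ly], decreasing = TRUE)
    v <- vapply(codes, function(cd) {
      for (y in prev_years) {
        q <- target_at(p, cd, y)
        if (!is.na(q)) return(as.numeric(q))
      }
      NA_real_
    }, numeric(1))
    dplyr::bind_cols(
      tibble::tibble(person_id = p$person_id),
      demographic_features(p),
      tibble::as_tibble(as.list(stats::setNames(v, paste0("prev_", codes)))),
      tibble::tibble(label = target_at(p, spec$target_code, ly))
    )
  })
  finalize_feature_matrix(rows, "previous", spec)
}

#' Build a confusion matrix from truth and predictions
#'
#' @param truth,pred factors (or vectors coercible to factors with common
#'   levels).
#' @return a K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred) {
  lev <- union(levels(factor(truth)), levels(factor(pred)))
  as.matrix(table(factor(truth, levels = lev), factor(pred, levels = lev)))
}

#' Confusion-matrix metrics: accuracy, precision, recall, specificity
#'
#' For a binary table given as explicit counts (a list or named vector with
#' `TP`, `FP`, `FN`, `TN`) the four metrics are the textbook formulas
#' verbatim: accuracy (TP+TN)/(TP+FP+FN+TN), precision TP/(TP+FP), recall
#' TP/(TP+FN), specificity TN/(TN+FP).
#'
#' For a K x K table each class is scored one-vs-rest with the same formulas
#' and the per-class values are combined by support-weighted averaging
#' (default; `average = "macro"` gives the unweighted mean). Accuracy is the
#' overall fraction of correct predictions, which algebraically equals the
#' support-weighted recall. A per-class ratio with zero denominator is
#' defined as 0 and the class is flagged in the `"degenerate_classes"`
#' attribute.
#'
#' @param cm a K x K matrix/table (rows = truth) or named TP/FP/FN/TN counts.
#' @param average `"weighted"` (default) or `"macro"`; ignored for explicit
#'   binary counts.
#' @return named list with `accuracy`, `precision`, `recall`, `specificity`,
#'   all in `[0,1]`.
#' @export
evaluate <- function(cm, average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (!is.matrix(cm) && !is.table(cm) &&
      all(c("TP", "FP", "FN", "TN") %in% names(cm))) {
    cm <- as.list(cm)
    total <- cm$TP + cm$FP + cm$FN + cm$TN
    stopifnot(total > 0)
    return(list(
      accuracy = (cm$TP + cm$TN) / total,
      precision = safe_ratio(cm$TP, cm$TP + cm$FP),
      recall = safe_ratio(cm$TP, cm$TP + cm$FN),
      specificity = safe_ratio(cm$TN, cm$TN + cm$FP)
    ))
  }
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  per <- vapply(seq_len(k), function(i) {
    TP <- cm[i, i]
    FN <- sum(cm[i, -i])
    FP <- sum(cm[-i, i])
    TN <- total - TP - FN - FP
    c(precision = safe_ratio(TP, TP + FP),
      recall = safe_ratio(TP, TP + FN),
      specificity = safe_ratio(TN, TN + FP),
      support = TP + FN,
      degenerate = as.numeric((TP + FP) == 0 || (TP + FN) == 0))
  }, numeric(5))
  w <- if (average == "weighted") per["support", ] / total else rep(1 / k, k)
  out <- list(
    accuracy = sum(diag(cm)) / total,
    precision = sum(w * per["precision", ]),
    recall = sum(w * per["recall", ]),
    specificity = sum(w * per["specificity", ])
  )
  deg <- which(per["degenerate", ] == 1)
  if (length(deg) > 0) {
    attr(out, "degenerate_classes") <- rownames(cm)[deg] %||% deg
  }
  out
}

safe_ratio <- function(num, den) {
  if (den == 0) 0 else num / den
}

# ---- learners --------------------------------------------------------------

# Per-fold preprocessing. Imputation statistics come from the training fold
# only; the decision tree and naive Bayes consume missing values natively.
impute_stats <- function(x) {
  lapply(x, function(col) {
    if (is.numeric(col)) {
      m <- stats::median(col, na.rm = TRUE)
      if (is.na(m)) m <- 0
      m
    } else {
      m <- mode_of(as.character(col))
      if (is.na(m)) m <- "(missing)"
      m
    }
  })
}

apply_impute <- function(x, stats) {
  for (nm in names(x)) {
    col <- x[[nm]]
    if (is.factor(col)) col <- as.character(col)
    col[is.na(col)] <- stats[[nm]]
    x[[nm]] <- col
  }
  x
}

# one-hot encode with factor levels fixed from train+test union
to_numeric_matrix <- function(train, test) {
  both <- dplyr::bind_rows(train, test)
  for (nm in names(both)) {
    if (!is.numeric(both[[nm]])) both[[nm]] <- factor(both[[nm]])
  }
  mm <- stats::model.matrix(~ . - 1, data = both)
  list(train = mm[seq_len(nrow(train)), , drop = FALSE],
       test = mm[nrow(train) + seq_len(nrow(test)), , drop = FALSE])
}

fit_predict <- function(learner, x_train, y_train, x_test, k = 7) {
  lev <- levels(y_train)
  pred <- switch(learner,
    knn = {
      st <- impute_stats(x_train)
      mats <- to_numeric_matrix(apply_impute(x_train, st),
                                apply_impute(x_test, st))
      mu <- colMeans(mats$train)
      sdv <- apply(mats$train, 2, stats::sd)
      sdv[sdv == 0 | is.na(sdv)] <- 1
      tr <- scale(mats$train, center = mu, scale = sdv)
      te <- scale(mats$test, center = mu, scale = sdv)
      class::knn(tr, te, cl = y_train, k = min(k, nrow(tr)), use.all = TRUE)
    },
    nb = {
      dtr <- as.data.frame(x_train)
      dte <- as.data.frame(x_test)
      yd <- droplevels(y_train)
      # qualifier features are ordinal categories: give them to naive Bayes
      # as nominal attributes (frequency tables) rather than Gaussians, which
      # degenerate on sparse year-columns
      for (nm in names(dtr)) {
        col <- dtr[[nm]]
        if (is.numeric(col) && all(col[!is.na(col)] %in% 0:4)) {
          dtr[[nm]] <- factor(col, levels = 0:4)
          dte[[nm]] <- factor(dte[[nm]], levels = 0:4)
        }
      }
      # remaining numeric columns need a positive class-conditional variance
      keep <- vapply(dtr, function(col) {
        if (is.numeric(col)) {
          sds <- tapply(col, yd, function(v) stats::sd(v, na.rm = TRUE))
          all(!is.na(sds) & sds > 0)
        } else {
          length(unique(col[!is.na(col)])) > 1
        }
      }, logical(1))
      if (!any(keep)) keep[1] <- TRUE
      dtr <- dtr[, keep, drop = FALSE]
      dtr$label <- yd
      fit <- e1071::naiveBayes(label ~ ., data = dtr)
      stats::predict(fit, dte[, keep, drop = FALSE])
    },
    svm = {
      st <- impute_stats(x_train)
      mats <- to_numeric_matrix(apply_impute(x_train, st),
                                apply_impute(x_test, st))
      keep <- apply(mats$train, 2, function(cc) stats::sd(cc) > 0)
      if (!any(keep)) keep[1] <- TRUE
      fit <- e1071::svm(x = mats$train[, keep, drop = FALSE],
                        y = droplevels(y_train), kernel = "radial")
      stats::predict(fit, mats$test[, keep, drop = FALSE])
    },
    tree = ,
    j48 = {
      dtr <- as.data.frame(x_train)
      dtr$label <- y_train
      fit <- rpart::rpart(label ~ ., data = dtr, method = "class")
      stats::predict(fit, as.data.frame(x_test), type = "class")
    },
    stop("unknown learner: ", learner, call. = FALSE)
  )
  factor(as.character(pred), levels = lev)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) > 0) {
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  }
  fold
}

#' Cross-validated prognosis benchmark
#'
#' Runs each learner on each temporal representation under stratified k-fold
#' cross-validation (a fixed seed makes the whole benchmark reproducible),
#' pools the out-of-fold predictions into one confusion matrix per
#' (representation, learner), and scores it with [evaluate()].
#'
#' Learners: `"knn"` (k-nearest neighbours, k = 7 by default), `"nb"` (naive
#' Bayes), `"svm"` (support vector machine, radial kernel) and `"tree"` (CART
#' decision tree; `"j48"` is accepted as an alias). Naive Bayes and the tree
#' consume missing values natively; for KNN and SVM, median/mode imputation
#' is computed within training folds only.
#'
#' @param fms a feature matrix from [features_full_series()] /
#'   [features_previous_state()], or a list of them (one row group per
#'   representation in the report).
#' @param learners character vector of learner names.
#' @param k neighbours for KNN (default 7).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment and any stochastic
#'   learner internals.
#' @param average metric averaging passed to [evaluate()].
#' @return a `benchmark_report` tibble with columns `representation`,
#'   `learner`, `accuracy`, `precision`, `recall`, `specificity`; the
#'   evaluation configuration is stored in the `"config"` attribute and the
#'   pooled confusion matrices in `"confusions"`.
#' @export
benchmark <- function(fms, learners = c("knn", "nb", "svm", "tree"),
                      k = 7, folds = 10, seed = 1,
                      average = "weighted") {
  if (inherits(fms, "data.frame")) {
    fms <- stats::setNames(list(fms), attr(fms, "representation") %||% "features")
  }
  rows <- list()
  confusions <- list()
  for (rep_name in names(fms)) {
    fm <- fms[[rep_name]]
    y <- fm$label
    if (length(unique(as.character(y[!is.na(y)]))) < 2) {
      stop("degenerate benchmark input: fewer than 2 label classes present",
           call. = FALSE)
    }
    x <- fm[setdiff(names(fm), c("person_id", "label"))]
    for (learner in learners) {
      set.seed(seed)
      fold <- stratified_folds(y, folds)
      pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
      for (f in sort(unique(fold))) {
        te <- fold == f
        if (!any(te) || all(te)) next
        pred[te] <- fit_predict(learner, x[!te, , drop = FALSE], y[!te],
                                x[te, , drop = FALSE], k = k)
      }
      cm <- confusion_matrix(y, pred)
      key <- paste(rep_name, learner, sep = "/")
      confusions[[key]] <- cm
      m <- evaluate(cm, average = average)
      rows[[key]] <- tibble::tibble(
        representation = rep_name, learner = learner,
        accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, specificity = m$specificity
      )
    }
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "config") <- list(k = k, folds = folds, seed = seed,
                                 average = average,
                                 protocol = "stratified cross-validation")
  attr(report, "confusions") <- confusions
  class(report) <- c("benchmark_report", class(report))
  report
}

#' Rank features by importance for the prognosis
#'
#' Impurity-based importance from an ensemble of decision trees (random
#' forest), reported as percentages that sum to 100 over the returned
#' features, in descending order. Missing cells are median/mode imputed
#' before fitting.
#'
#' @param fm a feature matrix (see [features_full_series()]).
#' @param top_n number of features to report (default 10; fewer if the matrix
#'   has fewer features).
#' @param seed integer seed for the forest.
#' @param num_trees ensemble size.
#' @return tibble with columns `feature` and `importance_pct`, descending.
#' @export
attribute_importance <- function(fm, top_n = 10, seed = 1, num_trees = 500) {
  y <- droplevels(fm$label)
  x <- fm[setdiff(names(fm), c("person_id", "label"))]
  x <- apply_impute(x, impute_stats(x))
  d <- as.data.frame(x, stringsAsFactors = TRUE)
  for (nm in names(d)) if (is.character(d[[nm]])) d[[nm]] <- factor(d[[nm]])
  d$label <- y
  fit <- ranger::ranger(label ~ ., data = d, importance = "impurity",
                        num.trees = num_trees, seed = seed,
                        respect.unordered.factors = "order")
  imp <- pmax(fit$variable.importance, 0)
  pct <- if (sum(imp) > 0) 100 * imp / sum(imp) else
    rep(100 / length(imp), length(imp))
  out <- tibble::tibble(feature = names(imp), importance_pct = unname(pct))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance_pct))
  out <- utils::head(out, top_n)
  out$importance_pct <- 100 * out$importance_pct / sum(out$importance_pct)
  out
}
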