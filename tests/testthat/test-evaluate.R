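test_that("confusion counts follow the worse-positive convention", {
  allw <- confusion_counts(rep(1, 6), rep(1, 6))
  expect_identical(allw$FP + allw$FN, 0L)
  expect_identical(allw$TP, 6L)
  y_true <- c(rep(1, 10), rep(0, 10))
  y_pred <- y_true
  y_pred[10] <- 0       # one worse day missed
  y_pred[20] <- 1       # one better day flagged
  cm <- confusion_counts(y_true, y_pred)
  expect_identical(cm[c("TP", "FN", "TN", "FP")],
                   list(TP = 9L, FN = 1L, TN = 9L, FP = 1L))
  ## swapping truth and prediction swaps FP and FN
  sw <- confusion_counts(y_pred, y_true)
  expect_identical(sw$FP, cm$FN)
  expect_identical(sw$FN, cm$FP)
  expect_error(confusion_counts(1, c(1, 0)), "equal length")
})

test_that("metric percentages match hand evaluation and the harmonic-mean
           identity", {
  m <- compute_metrics(list(TP = 9, FN = 1, FP = 2, TN = 8))
  expect_equal(m$REC, 90)
  expect_equal(m$PRE, 100 * 9 / 11)
  expect_equal(m$FPR, 20)
  expect_equal(m$ACC, 85)
  expect_equal(m$Fscore, 2 * m$REC * m$PRE / (m$REC + m$PRE))
  perfect <- compute_metrics(list(TP = 50, FN = 0, FP = 0, TN = 50))
  expect_equal(unlist(perfect[c("REC", "PRE", "ACC", "Fscore")]),
               c(REC = 100, PRE = 100, ACC = 100, Fscore = 100))
  expect_equal(perfect$FPR, 0)
  ## random sweep: identities hold whenever denominators are nonzero
  set.seed(71)
  for (r in 1:50) {
    cm <- as.list(setNames(sample(0:20, 4, replace = TRUE),
                           c("TP", "TN", "FP", "FN")))
    met <- compute_metrics(cm)
    tot <- cm$TP + cm$TN + cm$FP + cm$FN
    if (tot > 0) expect_equal(met$ACC, 100 * (cm$TP + cm$TN) / tot)
    if (!is.na(met$REC) && !is.na(met$PRE) && met$REC + met$PRE > 0)
      expect_equal(met$Fscore, 2 * met$REC * met$PRE / (met$REC + met$PRE))
  }
  ## zero denominators are undefined, never silent zeros
  none <- compute_metrics(list(TP = 0, FN = 0, FP = 3, TN = 7))
  expect_true(is.na(none$REC))
})

test_that("AUC equals the pairwise-concordance (Mann-Whitney) oracle", {
  concordance_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  set.seed(72)
  for (r in 1:50) {
    n <- sample(10:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(rnorm(n) + y, sample(c(1, 8), 1))  # sometimes heavy ties
    expect_equal(roc_and_auc(y, s)$auc, concordance_auc(y, s))
  }
  ## perfectly separated scores
  expect_equal(roc_and_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_error(roc_and_auc(c(1, 1), c(0.2, 0.3)), "single-class")
})

test_that("AUC is invariant under strictly monotone score transforms and
           near 0.5 for label-free scores", {
  set.seed(73)
  y <- sample(0:1, 400, replace = TRUE)
  s <- rnorm(400)
  a1 <- roc_and_auc(y, s)$auc
  expect_equal(roc_and_auc(y, exp(3 * s) + 2)$auc, a1)
  y2 <- c(rep(0, 1000), rep(1, 1000))
  expect_lt(abs(roc_and_auc(y2, rnorm(2000))$auc - 0.5), 0.045)
})

test_that("cross-check against an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  y <- sample(0:1, 80, replace = TRUE)
  s <- rnorm(80) + 0.8 * y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_and_auc(y, s)$auc, ref, tolerance = 1e-12)
})

test_that("fold plans partition the grouping units with both classes per
           fold and are reproducible", {
  set.seed(75)
  groups <- rep(sprintf("S1:%d", 1:20), each = 5)
  y_unit <- rep(c(0, 1), 10)
  y <- rep(y_unit, each = 5)
  p1 <- cv_plan(groups, y, k = 5, seed = 9)
  p2 <- cv_plan(groups, y, k = 5, seed = 9)
  expect_identical(p1$unit_fold, p2$unit_fold)
  expect_identical(sort(unique(p1$fold)), 1:5)
  ## partition: every unit in exactly one fold; rows follow their unit
  expect_identical(length(p1$unit_fold), 20L)
  for (f in 1:5)
    expect_identical(length(unique(y[p1$fold == f])), 2L)
  ## no straddling: all rows of a unit share the fold
  expect_true(all(tapply(p1$fold, groups, function(v)
    length(unique(v))) == 1))
  ## leave-one-unit-out degenerate case runs (class constraint relaxed
  ## only through resampling; here every unit is single-class, so expect
  ## the both-classes constraint to fail loudly)
  expect_error(cv_plan(groups, y, k = 20, seed = 1), "both conditions")
  expect_error(cv_plan(groups, y, k = 21, seed = 1), "exceeds")
})

test_that("grouped cross-validation never leaks a subject-day across the
           split and pools counts over folds", {
  d <- toy_segments(n = 120, len = 12, sep = 2, seed = 76)
  groups <- rep(sprintf("g%02d", 1:30), each = 4)
  ## make labels constant within groups (as segments of one day are)
  y <- rep(rep(0:1, 15), each = 4)
  d$x <- d$x - 2 * d$y + 2 * y       # rebuild separation on group labels
  cv <- kfold_cross_validate("svm", d$x, y, groups, k = 5, seed = 77,
                             gamma = 0.05)
  expect_identical(nrow(cv$folds), 5L)
  counts <- cv$aggregate$counts
  expect_identical(counts$TP + counts$TN + counts$FP + counts$FN, 120L)
  expect_gt(cv$aggregate$ACC, 90)
  expect_gt(cv$auc, 0.95)
  ## plan audit: train and test units disjoint in every fold
  for (f in seq_len(cv$plan$k)) {
    te_units <- unique(groups[cv$plan$fold == f])
    tr_units <- unique(groups[cv$plan$fold != f])
    expect_length(intersect(te_units, tr_units), 0)
  }
})

test_that("row-level fold mode is available for leakage comparison", {
  d <- toy_segments(n = 60, len = 12, sep = 2, seed = 78)
  cv <- kfold_cross_validate("svm", d$x, d$y,
                             groups = rep("one-day", 60), k = 3, seed = 79,
                             level = "row", gamma = 0.05)
  expect_identical(nrow(cv$folds), 3L)
})
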