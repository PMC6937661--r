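#' Confusion counts with worse (1) as the positive class
#'
#' @param y_true,y_pred Integer vectors of conditions (0 better / 1 worse),
#'   equal length.
#' @return List of class `wellcast_confusion` with `TP` (worse predicted
#'   worse), `TN` (better predicted better), `FP` (better predicted worse),
#'   `FN` (worse predicted better).
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("conditions must be binary 0/1", call. = FALSE)
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "wellcast_confusion")
}

#' Classification metrics from confusion counts
#'
#' Recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, false-positive rate
#' `FP/(FP+TN)`, accuracy `(TP+TN)/total` and the F-score (harmonic mean of
#' recall and precision), all expressed as percentages. A metric whose
#' denominator is zero is reported as `NA` (undefined), never silently 0.
#'
#' @param counts A `wellcast_confusion` (or list with `TP`, `TN`, `FP`,
#'   `FN`).
#' @return List of class `wellcast_metrics` with `REC`, `PRE`, `FPR`,
#'   `ACC`, `Fscore` (percent) and the `counts`.
#' @examples
#' m <- compute_metrics(list(TP = 9, FN = 1, FP = 2, TN = 8))
#' m$REC   # 90
#' @export
compute_metrics <- function(counts) {
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  REC <- rate(TP, TP + FN)
  PRE <- rate(TP, TP + FP)
  FPR <- rate(FP, FP + TN)
  ACC <- rate(TP + TN, TP + TN + FP + FN)
  Fscore <- if (is.na(REC) || is.na(PRE) || (REC + PRE) == 0) NA_real_
            else 2 * REC * PRE / (REC + PRE)
  structure(list(REC = REC, PRE = PRE, FPR = FPR, ACC = ACC,
                 Fscore = Fscore, counts = counts),
            class = "wellcast_metrics")
}

#' @export
print.wellcast_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat(sprintf("REC %s  PRE %s  FPR %s  ACC %s  Fscore %s\n",
              fmt(x$REC), fmt(x$PRE), fmt(x$FPR), fmt(x$ACC), fmt(x$Fscore)))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the classification threshold over the unique worse-class scores,
#' records the (FPR, TPR) operating points and sums the area under the
#' curve by the trapezoidal rule. The resulting AUC equals the
#' Mann-Whitney pairwise-concordance probability (ties counted half).
#'
#' @param y_true Conditions (0 better / 1 worse); both classes required.
#' @param scores Continuous worse-class scores (finite), higher = more
#'   worse.
#' @return List of class `wellcast_roc` with `fpr`, `tpr`, `thresholds`
#'   (decreasing) and `auc` (fraction in `[0, 1]`).
#' @export
roc_and_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("y_true and scores must have equal length", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(y_true)) < 2)
    stop("single-class truth: ROC undefined", call. = FALSE)
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  ## cumulative counts at each distinct threshold (predict worse if
  ## score >= threshold)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[last_of_tie]
  fp <- cumsum(y == 0)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last_of_tie]), auc = auc),
            class = "wellcast_roc")
}

#' Grouped cross-validation fold plan
#'
#' Assigns grouping units (subject-days by default, so overlapping segments
#' of one recording never straddle train and test) to `k` folds at random
#' under a fixed seed. Assignments are redrawn (up to `max_tries`) until
#' every fold's test set contains both conditions.
#'
#' @param groups Grouping unit per dataset row.
#' @param y Conditions per row.
#' @param k Number of folds (default 10; must not exceed the number of
#'   units).
#' @param seed Seed for the assignment stream.
#' @param max_tries Redraw budget for the both-classes constraint.
#' @return List of class `wellcast_cv_plan`: `fold` (integer per row),
#'   `unit_fold` (named integer per unit), `k`, `seed`.
#' @export
cv_plan <- function(groups, y, k = 10, seed = 1, max_tries = 200) {
  units <- unique(groups)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > length(units))
    stop("k = ", k, " exceeds the number of grouping units (",
         length(units), ")", call. = FALSE)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    unit_fold <- stats::setNames(
      sample(rep_len(seq_len(k), length(units))), units)
    fold <- unit_fold[groups]
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) == 2, logical(1)))
    if (ok)
      return(structure(list(fold = unname(fold), unit_fold = unit_fold,
                            k = k, seed = seed),
                       class = "wellcast_cv_plan"))
  }
  stop("could not build a fold plan with both conditions in every fold",
       call. = FALSE)
}

#' Grouped, label-stratified holdout split
#'
#' Splits grouping units (subject-days) into train and test so that no
#' unit straddles the split, stratifying by the unit's label so both sides
#' keep the cohort's class balance.
#'
#' @param groups Grouping unit per row.
#' @param y Conditions per row (constant within a unit).
#' @param test_frac Fraction of units held out (default 0.3).
#' @param seed Seed.
#' @return List with logical row masks `train` and `test`.
#' @export
grouped_holdout_split <- function(groups, y, test_frac = 0.3, seed = 1) {
  unit_y <- tapply(y, groups, function(v) v[1])
  set.seed(seed)
  test_units <- unlist(lapply(split(names(unit_y), unit_y), function(u) {
    n_test <- max(1L, round(length(u) * test_frac))
    sample(u, n_test)
  }), use.names = FALSE)
  test <- groups %in% test_units
  list(train = !test, test = test)
}

#' Grouped k-fold cross-validation of one model family
#'
#' Trains and evaluates a model on each fold of a grouped plan: folds are
#' split at the subject-day level by default (`level = "group"`), so the
#' overlapping 5-s segments of one recording never leak across the split;
#' `level = "row"` switches to segment-level folds for comparison. Reports
#' per-fold metrics, the pooled (micro) aggregate over all folds'
#' confusion counts and scores, and the per-fold (macro) means.
#'
#' @param model Model family (see [train_model()]).
#' @param x,y Labeled segments.
#' @param groups Grouping unit per row.
#' @param k Folds (default 10).
#' @param seed Seed for the fold plan.
#' @param plan Optional pre-built [cv_plan()] (overrides `k`/`seed`).
#' @param level `"group"` (leakage-safe, default) or `"row"`.
#' @param ... Arguments passed to [train_model()] (hidden_size, config,
#'   C, gamma, ...).
#' @return List of class `wellcast_cv` with `folds` (per-fold metric data
#'   frame), `aggregate` (pooled `wellcast_metrics`), `auc` (pooled),
#'   `macro` (mean per-fold metrics), `auc_macro`, and `plan`. When the
#'   pooled and macro AUC differ by more than 0.05 the result carries
#'   `auc_divergence = TRUE`.
#' @export
kfold_cross_validate <- function(model, x, y, groups, k = 10, seed = 1,
                                 plan = NULL, level = c("group", "row"),
                                 ...) {
  level <- match.arg(level)
  if (level == "row") groups <- as.character(seq_along(y))
  if (is.null(plan)) plan <- cv_plan(groups, y, k = k, seed = seed)
  k <- plan$k
  fold_rows <- plan$fold
  fold_metrics <- vector("list", k)
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  all_scores <- numeric(0)
  all_truth <- integer(0)
  fold_aucs <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold_rows == f
    fit <- train_model(model, x[!te, , drop = FALSE], y[!te], ...)
    pred <- predict(fit, x[te, , drop = FALSE], type = "class")
    score <- predict(fit, x[te, , drop = FALSE], type = "score")
    cm <- confusion_counts(y[te], pred)
    met <- compute_metrics(cm)
    fold_aucs[f] <- if (length(unique(y[te])) == 2)
      roc_and_auc(y[te], score)$auc else NA_real_
    fold_metrics[[f]] <- data.frame(fold = f, REC = met$REC, PRE = met$PRE,
                                    FPR = met$FPR, ACC = met$ACC,
                                    Fscore = met$Fscore, AUC = fold_aucs[f],
                                    n = sum(te))
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cm[[nm]]
    all_scores <- c(all_scores, score)
    all_truth <- c(all_truth, y[te])
  }
  folds <- do.call(rbind, fold_metrics)
  aggregate <- compute_metrics(pooled)
  auc_pooled <- roc_and_auc(all_truth, all_scores)$auc
  macro <- colMeans(folds[, c("REC", "PRE", "FPR", "ACC", "Fscore")],
                    na.rm = TRUE)
  auc_macro <- mean(fold_aucs, na.rm = TRUE)
  structure(list(folds = folds, aggregate = aggregate, auc = auc_pooled,
                 macro = as.list(macro), auc_macro = auc_macro,
                 auc_divergence = abs(auc_pooled - auc_macro) > 0.05,
                 plan = plan, model = model),
            class = "wellcast_cv")
}

#' @export
print.wellcast_cv <- function(x, ...) {
  cat("wellcast ", x$plan$k, "-fold CV, model ", toupper(x$model),
      " (pooled):\n", sep = "")
  print(x$aggregate)
  cat(sprintf("AUC %.3f (pooled), %.3f (macro)\n", x$auc, x$auc_macro))
  invisible(x)
}
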