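#' Extract BiLSTM concatenated hidden features
#'
#' Captures, for each segment, the pre-softmax concatenation of the two
#' directions' final hidden states (width `2 * hidden_size`; 512 at the
#' default hidden size 256). Deterministic given the fitted model and data.
#'
#' @param fit A fitted BiLSTM `wellcast_model`.
#' @param x Segment matrix (rows = examples).
#' @return Numeric matrix, one row per segment, `2 * hidden_size` columns.
#' @export
extract_hidden_features <- function(fit, x) {
  if (!inherits(fit, "wellcast_model") || fit$model != "bilstm")
    stop("model is not bidirectional: hidden-feature extraction needs a ",
         "fitted BiLSTM", call. = FALSE)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0) stop("empty dataset", call. = FALSE)
  bilstm_forward(x, fit$params, return_features = TRUE)$features
}

#' Principal-component projection of a feature matrix
#'
#' Centers the columns (no scaling: hidden activations share a scale) and
#' projects onto the top `k` eigenvectors of the covariance matrix. The
#' sign of each component is fixed so its largest-magnitude loading is
#' positive. Explained-variance ratios are reported for all components
#' (non-negative, sorted, summing to 1).
#'
#' @param features Numeric matrix (rows = observations).
#' @param k Target dimension (default 2; must be below both `nrow` and the
#'   matrix rank).
#' @return List with `scores` (`n x k`), `loadings`, `explained` (ratios,
#'   all components) and `explained_k` (sum of the top-k ratios).
#' @export
pca_project <- function(features, k = 2) {
  if (nrow(features) <= k)
    stop("need more than k = ", k, " rows", call. = FALSE)
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev > ev[1] * 1e-12) < k)
    stop("feature matrix rank below k = ", k, call. = FALSE)
  ratios <- ev / sum(ev)
  load_k <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- load_k[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  load_k <- sweep(load_k, 2, flip, `*`)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  list(scores = scores, loadings = load_k, explained = ratios,
       explained_k = sum(ratios[seq_len(k)]))
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `g1 * sqrt(n (n - 1)) / (n - 2)` where
#' `g1 = m3 / m2^(3/2)` is the third standardized sample moment. The
#' diagnostic used to show that rank-based inverse-normal transformation
#' removes the asymmetry of raw health-index scores.
#'
#' @param values Numeric vector (`n >= 3`).
#' @return Scalar skewness; `NA` for constant input.
#' @examples
#' skewness(c(-1, 0, 1))   # 0
#' @export
skewness <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((values - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Filtering ablation: training curves with and without the EWMA
#'
#' Builds the labeled dataset twice from the same cohort -- once with EWMA
#' denoising, once from the raw signals -- and trains the same model with
#' the same seed and configuration on each, returning the paired
#' epoch-indexed training curves and held-out accuracy. On noisy cohorts
#' the filtered arm is expected to reach at least the unfiltered arm's
#' accuracy; on clean cohorts the arms are statistically indistinguishable.
#'
#' @param cohort A `wellcast_cohort`.
#' @param model Model family (default `"bilstm"`).
#' @param hidden_size,input_size,config Passed to [train_model()].
#' @param test_frac Held-out fraction of subject-days.
#' @param split_seed Seed of the holdout split (shared by both arms).
#' @param ... Passed to [build_dataset()] (e.g. `ewma_n`).
#' @return List of class `wellcast_ablation` with `history` (data frame:
#'   `arm`, `epoch`, `lr`, `loss`, `accuracy`) and `test_accuracy` (named
#'   vector for arms `ewma` and `raw`).
#' @export
ewma_ablation <- function(cohort, model = "bilstm", hidden_size = 32,
                          input_size = 100, config = NULL, test_frac = 0.3,
                          split_seed = 1, ...) {
  arms <- list(ewma = TRUE, raw = FALSE)
  history <- list()
  test_acc <- c(ewma = NA_real_, raw = NA_real_)
  for (arm in names(arms)) {
    ds <- build_dataset(cohort, use_ewma = arms[[arm]], ...)
    sp <- grouped_holdout_split(ds$group, ds$y, test_frac, split_seed)
    fit <- train_model(model, ds$x[sp$train, , drop = FALSE],
                       ds$y[sp$train], hidden_size = hidden_size,
                       input_size = input_size, config = config)
    pred <- predict(fit, ds$x[sp$test, , drop = FALSE], type = "class")
    test_acc[arm] <- mean(pred == ds$y[sp$test])
    h <- fit$history
    h$arm <- arm
    history[[arm]] <- h
  }
  structure(list(history = do.call(rbind, history),
                 test_accuracy = test_acc),
            class = "wellcast_ablation")
}

#' Plot helpers for the diagnostic artifacts
#'
#' Base-graphics renderings of the pipeline's standard figures: ROC
#' overlay across models, the two-dimensional PCA embedding of BiLSTM
#' features colored by condition, and paired training-accuracy curves from
#' the filtering ablation.
#'
#' @param rocs Named list of `wellcast_roc` objects.
#' @param ... Passed to the underlying plot call.
#' @return Invisibly, the object plotted.
#' @export
plot_roc_overlay <- function(rocs, ...) {
  plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
       xlab = "False positive rate", ylab = "True positive rate", ...)
  cols <- seq_along(rocs) + 1
  for (i in seq_along(rocs))
    lines(rocs[[i]]$fpr, rocs[[i]]$tpr, col = cols[i], lwd = 2)
  legend("bottomright", bty = "n", lwd = 2, col = cols,
         legend = sprintf("%s (AUC %.2f)", names(rocs),
                          vapply(rocs, function(r) r$auc, numeric(1))))
  invisible(rocs)
}

#' @rdname plot_roc_overlay
#' @param projection Result of [pca_project()].
#' @param y Conditions aligned with the projected rows.
#' @export
plot_pca_features <- function(projection, y, ...) {
  plot(projection$scores, col = ifelse(y == 1, "red", "blue"), pch = 16,
       cex = 0.6, xlab = "PC1", ylab = "PC2", ...)
  legend("topright", bty = "n", pch = 16, col = c("blue", "red"),
         legend = c("better", "worse"))
  invisible(projection)
}

#' @rdname plot_roc_overlay
#' @param ablation Result of [ewma_ablation()].
#' @export
plot_ablation <- function(ablation, ...) {
  h <- ablation$history
  plot(range(h$epoch), range(h$accuracy), type = "n", xlab = "Epoch",
       ylab = "Training accuracy", ...)
  for (arm in unique(h$arm)) {
    hh <- h[h$arm == arm, ]
    lines(hh$epoch, hh$accuracy, col = ifelse(arm == "ewma", "forestgreen",
                                              "grey40"), lwd = 2)
  }
  legend("bottomright", bty = "n", lwd = 2,
         col = c("forestgreen", "grey40"), legend = c("with EWMA", "raw"))
  invisible(ablation)
}
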