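#' Radial basis function kernel
#'
#' Gaussian similarity `k(x1, x2) = exp(-||x1 - x2||^2 / (2 * sigma^2))`:
#' symmetric, in `(0, 1]`, equal to 1 exactly at zero distance. The
#' alternative coefficient parameterization `gamma` (as in the SVM
#' configuration) relates to the bandwidth by `gamma = 1 / (2 * sigma^2)`.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param sigma Kernel bandwidth (> 0).
#' @return Scalar similarity.
#' @examples
#' rbf_kernel(1:3, 1:3, sigma = 2)       # 1
#' @export
rbf_kernel <- function(x1, x2, sigma) {
  if (length(x1) != length(x2))
    stop("x1 and x2 must have equal dimension", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  exp(-sum((x1 - x2)^2) / (2 * sigma^2))
}

#' Convert an RBF kernel coefficient to a bandwidth
#' @param gamma Kernel coefficient (> 0).
#' @return Bandwidth `sigma = sqrt(1 / (2 * gamma))`.
#' @export
gamma_to_sigma <- function(gamma) {
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  sqrt(1 / (2 * gamma))
}

#' Fit a soft-margin RBF-kernel SVM
#'
#' Maximum-margin classifier with slack (penalty `C`) and Gaussian kernel
#' (coefficient `gamma`), solved by the established SMO-type dual solver in
#' \pkg{e1071}/libsvm. The contract pinned here is the decision function:
#' `f(x) = sum_i alpha_i y_i k(x_i, x) + b` with `y in {-1, +1}` mapping
#' worse to +1 and better to -1, classifying by `sign(f)`.
#'
#' @param x Numeric matrix, rows = training examples.
#' @param y Integer conditions (0 better / 1 worse); both classes must be
#'   present.
#' @param C Penalty parameter (> 0, default 10).
#' @param gamma RBF kernel coefficient (> 0, default 0.01).
#' @param tolerance Stopping tolerance of the dual solver (default 1e-3).
#' @return List of class `wellcast_svm` with the fitted \pkg{e1071} model,
#'   the hyperparameters, and the orientation sign that makes positive
#'   decision values mean worse.
#' @export
svm_fit <- function(x, y, C = 10, gamma = 0.01, tolerance = 1e-3) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("single-class data: both conditions must be present", call. = FALSE)
  if (C <= 0 || gamma <= 0) stop("C and gamma must be > 0", call. = FALSE)
  yf <- factor(ifelse(y == 1, "worse", "better"), levels = c("worse", "better"))
  fit <- e1071::svm(x, yf, scale = FALSE, kernel = "radial", cost = C,
                    gamma = gamma, tolerance = tolerance)
  ## libsvm orients decision values towards the first class seen in
  ## training order; pin the orientation so that score > 0 <=> worse
  pr <- predict(fit, x[1:min(nrow(x), 20), , drop = FALSE],
                decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  agree <- sign(dv) == ifelse(pr == "worse", 1, -1)
  agree <- agree[dv != 0]
  orientation <- if (length(agree) == 0 || mean(agree) >= 0.5) 1 else -1
  structure(list(fit = fit, C = C, gamma = gamma, tolerance = tolerance,
                 sigma = gamma_to_sigma(gamma), orientation = orientation),
            class = "wellcast_svm")
}

#' Predict conditions and margin scores from a fitted SVM
#'
#' @param object A `wellcast_svm` from [svm_fit()].
#' @param x Numeric matrix of examples (rows).
#' @return List with `condition` (0/1) and `score` (signed margin, positive
#'   towards worse; used for ROC curves).
#' @export
svm_predict <- function(object, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  pr <- predict(object$fit, x, decision.values = TRUE)
  score <- object$orientation * drop(attr(pr, "decision.values"))
  list(condition = as.integer(pr == "worse"), score = score)
}
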