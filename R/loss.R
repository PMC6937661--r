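#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of the true conditions under the predicted
#' probabilities:
#' `L = -(1/m) * sum(y * log(p) + (1 - y) * log(1 - p))`,
#' where `p` is the predicted probability of the worse condition (class 1).
#' Non-negative; zero only for perfectly confident correct predictions.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` so exactly-saturated
#' predictions do not produce `log(0)`.
#'
#' @param y_true Integer vector of conditions (0 better / 1 worse).
#' @param prob Predicted probabilities: either a vector of worse-class
#'   probabilities or a two-column matrix (columns better, worse) as
#'   returned by the model forward passes.
#' @return Scalar loss.
#' @examples
#' cross_entropy_loss(c(0, 1), c(0.5, 0.5))  # log(2)
#' @export
cross_entropy_loss <- function(y_true, prob) {
  if (is.matrix(prob)) {
    if (ncol(prob) != 2) stop("prob matrix must have 2 columns", call. = FALSE)
    prob <- prob[, 2]
  }
  if (length(y_true) != length(prob))
    stop("y_true and prob must have equal length", call. = FALSE)
  if (!all(y_true %in% c(0, 1)))
    stop("y_true must be binary 0/1", call. = FALSE)
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}
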