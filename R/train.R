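#' Training configuration for the neural models
#'
#' Plain minibatch stochastic gradient descent on the cross-entropy loss
#' with one of two learning-rate schedules:
#' \describe{
#'   \item{plateau}{multiply the rate by `decay_factor` when the epoch loss
#'     has not improved by a relative `improvement_tol` for `patience`
#'     consecutive epochs (recurrent-model default: `eta0 = 0.6`,
#'     `f = 0.1`, patience 10).}
#'   \item{step}{multiply by `decay_factor` every `step_every` epochs
#'     (ANN default: `eta0 = 0.01`, `f = 0.01`, every 100 epochs).}
#' }
#' The rate never drops below `lr_floor`. Gradients are clipped to a global
#' L2 norm of `clip_norm` for stability at the large default rate. All
#' randomness (initialization and minibatch shuffling) flows from `seed`,
#' so identical configurations reproduce identical fits.
#'
#' @param learning_rate Initial learning rate `eta0` (> 0).
#' @param decay_factor Multiplicative decay `f` in (0, 1).
#' @param schedule `"plateau"` or `"step"`.
#' @param patience Plateau patience in epochs.
#' @param step_every Step-schedule period in epochs.
#' @param epochs Total training epochs `N` (default 500).
#' @param batch_size Minibatch size (default 32).
#' @param improvement_tol Relative loss decrease below which an epoch does
#'   not count as improving (default 1e-4).
#' @param lr_floor Minimum learning rate (default 1e-6).
#' @param clip_norm Global gradient-norm cap (default 5; `Inf` disables).
#' @param seed Integer seed for initialization and shuffling.
#' @return List of class `wellcast_train_config`.
#' @export
train_config <- function(learning_rate = 0.6, decay_factor = 0.1,
                         schedule = c("plateau", "step"), patience = 10,
                         step_every = 100, epochs = 500, batch_size = 32,
                         improvement_tol = 1e-4, lr_floor = 1e-6,
                         clip_norm = 5, seed = 1) {
  schedule <- match.arg(schedule)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (decay_factor <= 0 || decay_factor >= 1)
    stop("decay_factor must be in (0, 1)", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, decay_factor = decay_factor,
                 schedule = schedule, patience = patience,
                 step_every = step_every, epochs = epochs,
                 batch_size = batch_size, improvement_tol = improvement_tol,
                 lr_floor = lr_floor, clip_norm = clip_norm, seed = seed),
            class = "wellcast_train_config")
}

#' Family defaults for the training configuration
#'
#' Recurrent models (LSTM, BiLSTM): `eta0 = 0.6`, plateau decay by 0.1 with
#' patience 10. ANN: `eta0 = 0.01`, step decay by 0.01 every 100 epochs.
#'
#' @param model `"lstm"`, `"bilstm"` or `"ann"`.
#' @param ... Overrides passed to [train_config()].
#' @return A `wellcast_train_config`.
#' @export
default_train_config <- function(model, ...) {
  args <- list(...)
  base <- if (model == "ann")
    list(learning_rate = 0.01, decay_factor = 0.01, schedule = "step",
         step_every = 100)
  else
    list(learning_rate = 0.6, decay_factor = 0.1, schedule = "plateau",
         patience = 10)
  do.call(train_config, utils::modifyList(base, args))
}

.clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  flat <- flatten_params(grads)
  nrm <- sqrt(sum(flat^2))
  if (nrm <= clip_norm) return(grads)
  unflatten_params(flat * (clip_norm / nrm), grads)
}

#' Train a one-day-forward wellness forecasting model
#'
#' Fits one of the four classifier families on labeled ECG segments.
#' Neural families (`"lstm"`, `"bilstm"`, `"ann"`) are trained by minibatch
#' SGD on the cross-entropy loss with the configured learning-rate schedule;
#' `"svm"` delegates to the soft-margin RBF dual solver ([svm_fit()]).
#' Training is deterministic under a fixed `config$seed` (fixed
#' initialization and shuffling stream).
#'
#' @param model `"lstm"`, `"bilstm"`, `"ann"` or `"svm"`.
#' @param x Segment matrix (rows = examples).
#' @param y Conditions (0 better / 1 worse); both classes required.
#' @param hidden_size Hidden width (per direction for recurrent models).
#'   Defaults: 256 recurrent, 100 ANN.
#' @param input_size Per-step slice width for recurrent models (default
#'   100; segment length must be a multiple).
#' @param config A [train_config()]; `NULL` uses the family default.
#' @param C,gamma,tolerance SVM hyperparameters (see [svm_fit()]).
#' @return Object of class `wellcast_model` with elements `model`,
#'   `params` (or `svm`), and for neural fits `history` (per-epoch data
#'   frame: `epoch`, `lr`, `loss`, `accuracy` over the shuffled training
#'   stream).
#' @export
train_model <- function(model = c("lstm", "bilstm", "ann", "svm"), x, y,
                        hidden_size = NULL, input_size = 100, config = NULL,
                        C = 10, gamma = 0.01, tolerance = 1e-3) {
  model <- match.arg(model)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0 || length(y) != nrow(x))
    stop("x and y must be non-empty with matching sizes", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both conditions must be present in the training data",
         call. = FALSE)
  if (model == "svm") {
    fit <- svm_fit(x, y, C = C, gamma = gamma, tolerance = tolerance)
    return(structure(list(model = "svm", svm = fit), class = "wellcast_model"))
  }
  if (is.null(config)) config <- default_train_config(model)
  set.seed(config$seed)
  if (model == "ann") {
    if (is.null(hidden_size)) hidden_size <- 100
    params <- init_ann_params(ncol(x), hidden_size)
    grad_fun <- ann_loss_grad
  } else {
    if (is.null(hidden_size)) hidden_size <- 256
    params <- init_recurrent_params(input_size, hidden_size,
                                    bidirectional = (model == "bilstm"))
    grad_fun <- if (model == "bilstm") bilstm_loss_grad else lstm_loss_grad
  }
  n <- nrow(x)
  lr <- config$learning_rate
  best_loss <- Inf
  stall <- 0L
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    ep_correct <- 0
    for (b0 in starts) {
      idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
      res <- grad_fun(params, x[idx, , drop = FALSE], y[idx])
      if (!is.finite(res$loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             "; reduce the learning rate", call. = FALSE)
      grads <- .clip_gradients(res$grads, config$clip_norm)
      params <- unflatten_params(
        flatten_params(params) - lr * flatten_params(grads), params)
      ep_loss <- ep_loss + res$loss * length(idx)
      ep_correct <- ep_correct +
        sum((res$prob[, 2] > 0.5) == (y[idx] == 1))
    }
    ep_loss <- ep_loss / n
    history[[epoch]] <- data.frame(epoch = epoch, lr = lr, loss = ep_loss,
                                   accuracy = ep_correct / n)
    ## learning-rate schedule
    if (config$schedule == "step") {
      if (epoch %% config$step_every == 0)
        lr <- max(lr * config$decay_factor, config$lr_floor)
    } else {
      if (ep_loss < best_loss * (1 - config$improvement_tol)) {
        best_loss <- ep_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) {
          lr <- max(lr * config$decay_factor, config$lr_floor)
          stall <- 0L
        }
      }
    }
  }
  structure(list(model = model, params = params, config = config,
                 input_size = if (model == "ann") ncol(x) else input_size,
                 hidden_size = hidden_size,
                 history = do.call(rbind, history)),
            class = "wellcast_model")
}

#' Predict conditions, probabilities or scores
#'
#' @param object A `wellcast_model`.
#' @param x Segment matrix (rows = examples) or a single segment vector.
#' @param type `"class"` (0/1 conditions), `"prob"` (n x 2 probability
#'   matrix, columns better/worse) or `"score"` (continuous worse-class
#'   score: worse-class probability for the neural families, signed margin
#'   for the SVM; the ROC input).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.wellcast_model <- function(object, x,
                                   type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (object$model == "svm") {
    pr <- svm_predict(object$svm, x)
    return(switch(type, class = pr$condition, score = pr$score,
                  prob = {  # logistic squash of the margin, for uniformity
                    p1 <- 1 / (1 + exp(-pr$score))
                    cbind(1 - p1, p1)
                  }))
  }
  prob <- switch(object$model,
                 lstm = lstm_forward(x, object$params),
                 bilstm = bilstm_forward(x, object$params),
                 ann = ann_forward(x, object$params))
  switch(type, prob = prob, score = prob[, 2],
         class = as.integer(prob[, 2] > 0.5))
}

#' @export
print.wellcast_model <- function(x, ...) {
  cat("wellcast", toupper(x$model), "model")
  if (x$model == "svm")
    cat(" (C =", x$svm$C, ", gamma =", x$svm$gamma, ")\n")
  else
    cat(" (hidden", x$hidden_size, ", trained",
        max(x$history$epoch), "epochs, final loss",
        signif(x$history$loss[nrow(x$history)], 4), ")\n")
  invisible(x)
}

#' Hyperparameter grids used for model selection
#'
#' `ann_hidden_grid()` spans hidden sizes 100 to 1000 in steps of 10;
#' `svm_default_grid()` crosses penalty `C` and kernel coefficient `gamma`
#' over the decades `10^-8` to `10^8` (17 x 17 = 289 combinations).
#'
#' @return A data frame of hyperparameter combinations, ordered by
#'   increasing model size (the grid-search tie-break).
#' @export
svm_default_grid <- function() {
  g <- expand.grid(C = 10^(-8:8), gamma = 10^(-8:8))
  g[order(g$C, g$gamma), , drop = FALSE]
}

#' @rdname svm_default_grid
#' @export
ann_hidden_grid <- function() data.frame(hidden_size = seq(100, 1000, by = 10))

#' Exhaustive grid search with cross-validated F-score selection
#'
#' Evaluates every hyperparameter combination with the grouped k-fold
#' cross-validation of [kfold_cross_validate()] and returns the combination
#' with the highest aggregate F-score; ties go to the earlier (smaller)
#' grid row, so grids ordered by model size prefer the smaller model.
#'
#' @param model Model family (see [train_model()]).
#' @param x,y Labeled segments.
#' @param groups Grouping unit per row (subject-day identifiers).
#' @param grid Data frame of hyperparameter columns (e.g. `hidden_size`,
#'   or `C` and `gamma`).
#' @param k Folds (default 10).
#' @param seed Seed for the fold plan.
#' @param ... Further fixed arguments to [train_model()].
#' @return List with `best` (one-row data frame), `scores` (grid plus an
#'   `Fscore` column) and `best_index`.
#' @export
grid_search <- function(model, x, y, groups, grid, k = 10, seed = 1, ...) {
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- c(list(model = model, x = x, y = y, groups = groups, k = k,
                   seed = seed), as.list(grid[i, , drop = FALSE]),
              list(...))
    cv <- do.call(kfold_cross_validate, args)
    scores[i] <- cv$aggregate$Fscore
  }
  best_index <- which.max(scores)  # first max: smaller model wins ties
  out <- cbind(grid, Fscore = scores)
  list(best = grid[best_index, , drop = FALSE], scores = out,
       best_index = best_index)
}
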