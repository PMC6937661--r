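## Neural building blocks: LSTM / BiLSTM / single-hidden-layer ANN with
## hand-derived analytic gradients (verified against central finite
## differences in the test suite).

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Row-wise softmax
#' @param logits Numeric matrix, one row per example.
#' @return Matrix of probabilities, rows summing to 1.
#' @keywords internal
softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

.runif_mat <- function(nr, nc, bound) matrix(runif(nr * nc, -bound, bound), nr, nc)

#' Initialize LSTM parameters
#'
#' One direction of a recurrent network: per gate g in \{input `i`, forget
#' `f`, output `o`, candidate `c`\}, an input weight matrix `Wx[[g]]`
#' (input_size x hidden_size), a recurrent weight matrix `Wh[[g]]`
#' (hidden_size x hidden_size) and two bias vectors `bx[[g]]`, `bh[[g]]`
#' (the input-side and hidden-side biases of the gate's affine form). All
#' entries are drawn uniformly from `(-1/sqrt(h), 1/sqrt(h))` from the
#' current RNG stream.
#'
#' @param input_size Length of each per-step input slice (default 100).
#' @param hidden_size Hidden state width (default 256).
#' @param forget_bias Constant added to the forget gate's input-side bias
#'   at initialization (default 0, the plain uniform initialization).
#'   Setting it to ~1 starts with mostly-open forget gates, a common
#'   remedy for slow learning of long-range structure; on this package's
#'   short (25-step) sequences it mainly accelerates overfitting, so it is
#'   off by default.
#' @return List with `Wx`, `Wh`, `bx`, `bh` (each a 4-element named list),
#'   `input_size`, `hidden_size`.
#' @export
init_lstm_direction <- function(input_size = 100, hidden_size = 256,
                                forget_bias = 0) {
  b <- 1 / sqrt(hidden_size)
  gates <- c("i", "f", "o", "c")
  mk <- function(nr) stats::setNames(lapply(gates, function(g)
    .runif_mat(nr, hidden_size, b)), gates)
  mkb <- function() stats::setNames(lapply(gates, function(g)
    runif(hidden_size, -b, b)), gates)
  p <- list(Wx = mk(input_size), Wh = mk(hidden_size), bx = mkb(),
            bh = mkb(), input_size = input_size, hidden_size = hidden_size)
  p$bx$f <- p$bx$f + forget_bias
  p
}

#' Initialize a full recurrent classifier
#'
#' @param input_size Per-step input width.
#' @param hidden_size Hidden width per direction.
#' @param bidirectional If TRUE, independent forward and backward directions
#'   are created and the softmax readout consumes their concatenated final
#'   hidden states (width `2 * hidden_size`).
#' @param seed Optional seed for the initialization stream.
#' @param forget_bias See [init_lstm_direction()].
#' @return List of class `wellcast_params` with elements `forward`
#'   (and `backward` if bidirectional), `Wout`, `bout`, plus sizes.
#' @export
init_recurrent_params <- function(input_size = 100, hidden_size = 256,
                                  bidirectional = FALSE, seed = NULL,
                                  forget_bias = 0) {
  if (!is.null(seed)) set.seed(seed)
  p <- list(forward = init_lstm_direction(input_size, hidden_size,
                                          forget_bias))
  if (bidirectional)
    p$backward <- init_lstm_direction(input_size, hidden_size, forget_bias)
  out_in <- hidden_size * (1L + bidirectional)
  b <- 1 / sqrt(hidden_size)
  p$Wout <- .runif_mat(out_in, 2L, b)
  p$bout <- runif(2L, -b, b)
  p$input_size <- input_size
  p$hidden_size <- hidden_size
  p$bidirectional <- bidirectional
  class(p) <- "wellcast_params"
  p
}

#' Initialize single-hidden-layer ANN parameters
#'
#' Sigmoid hidden layer, linear two-unit output (probabilities via softmax).
#'
#' @param input_size Flattened input width (default 2500).
#' @param hidden_size Hidden units (default 100).
#' @param seed Optional seed.
#' @return List with `W1`, `b1`, `W2`, `b2` and sizes.
#' @export
init_ann_params <- function(input_size = 2500, hidden_size = 100,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- 1 / sqrt(hidden_size)
  p <- list(W1 = .runif_mat(input_size, hidden_size, b),
            b1 = runif(hidden_size, -b, b),
            W2 = .runif_mat(hidden_size, 2L, b),
            b2 = runif(2L, -b, b),
            input_size = input_size, hidden_size = hidden_size)
  class(p) <- "wellcast_params"
  p
}

#' One LSTM cell step
#'
#' Applies the gated update: sigmoid input/forget/output gates, tanh
#' candidate, `c_t = f_t * c_{t-1} + i_t * cand_t`,
#' `h_t = o_t * tanh(c_t)` (all products elementwise).
#'
#' @param x_t Input slice: numeric vector of length `input_size` or a
#'   batch matrix (rows = examples).
#' @param h_prev,c_prev Previous hidden and cell state, same batch shape
#'   with `hidden_size` columns.
#' @param params One direction's parameters ([init_lstm_direction()]).
#' @return List with `h`, `c` and `gates` (list `i`, `f`, `o`, `cand`).
#' @export
lstm_cell_forward <- function(x_t, h_prev, c_prev, params) {
  if (is.null(dim(x_t))) x_t <- matrix(x_t, nrow = 1)
  if (is.null(dim(h_prev))) h_prev <- matrix(h_prev, nrow = 1)
  if (is.null(dim(c_prev))) c_prev <- matrix(c_prev, nrow = 1)
  if (ncol(x_t) != params$input_size)
    stop("x_t has ", ncol(x_t), " columns; expected input_size = ",
         params$input_size, call. = FALSE)
  if (ncol(h_prev) != params$hidden_size || ncol(c_prev) != params$hidden_size)
    stop("state width does not match hidden_size = ", params$hidden_size,
         call. = FALSE)
  nb <- nrow(x_t)
  aff <- function(g) x_t %*% params$Wx[[g]] + h_prev %*% params$Wh[[g]] +
    rep(params$bx[[g]] + params$bh[[g]], each = nb)
  i_t <- sigmoid(aff("i"))
  f_t <- sigmoid(aff("f"))
  o_t <- sigmoid(aff("o"))
  cand <- tanh(aff("c"))
  c_t <- f_t * c_prev + i_t * cand
  h_t <- o_t * tanh(c_t)
  list(h = h_t, c = c_t, gates = list(i = i_t, f = f_t, o = o_t, cand = cand))
}

#' Reshape a flat segment into the recurrent input sequence
#'
#' Cuts a length-`L` segment into `T = L / input_size` consecutive
#' non-overlapping slices, each fed to one recurrent step (2500 samples at
#' `input_size = 100` give T = 25 steps).
#'
#' @param x Numeric vector (one segment) or matrix (batch, rows = segments).
#' @param input_size Per-step slice width.
#' @return For a vector: a `T x input_size` matrix (row t = slice t). For a
#'   batch: a list of `T` matrices of shape `batch x input_size`.
#' @export
reshape_segment <- function(x, input_size) {
  if (is.null(dim(x))) {
    if (length(x) %% input_size != 0)
      stop("segment length ", length(x), " is not divisible by input_size ",
           input_size, "; pad or crop the segment to a multiple first",
           call. = FALSE)
    return(matrix(x, ncol = input_size, byrow = TRUE))
  }
  if (ncol(x) %% input_size != 0)
    stop("segment length ", ncol(x), " is not divisible by input_size ",
         input_size, "; pad or crop the segments to a multiple first",
         call. = FALSE)
  T_steps <- ncol(x) %/% input_size
  lapply(seq_len(T_steps), function(t)
    x[, ((t - 1L) * input_size + 1L):(t * input_size), drop = FALSE])
}

## run one direction over a list of T input slices; optionally keep the
## per-step cache needed for backpropagation through time
.lstm_run <- function(x_list, prm, keep_cache = FALSE) {
  nb <- nrow(x_list[[1]])
  h <- matrix(0, nb, prm$hidden_size)
  cc <- matrix(0, nb, prm$hidden_size)
  T_steps <- length(x_list)
  cache <- if (keep_cache) vector("list", T_steps) else NULL
  for (t in seq_len(T_steps)) {
    st <- lstm_cell_forward(x_list[[t]], h, cc, prm)
    if (keep_cache)
      cache[[t]] <- list(gates = st$gates, c_prev = cc, h_prev = h,
                         tanh_c = tanh(st$c))
    h <- st$h
    cc <- st$c
  }
  list(h_final = h, cache = cache)
}

.as_seq <- function(x, input_size) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  reshape_segment(x, input_size)
}

#' LSTM forward pass
#'
#' Runs the cell over the `T` slices of each segment from a zero initial
#' state and maps the final hidden state through an affine readout and a
#' softmax to a probability pair over \{better (0), worse (1)\}.
#'
#' @param x One segment (vector) or a batch matrix (rows = segments), of
#'   width `T * input_size`.
#' @param params From [init_recurrent_params()] with
#'   `bidirectional = FALSE`.
#' @return Matrix of probabilities (`n x 2`, columns better/worse).
#' @export
lstm_forward <- function(x, params) {
  x_list <- .as_seq(x, params$input_size)
  if (length(x_list) == 0) stop("empty sequence", call. = FALSE)
  run <- .lstm_run(x_list, params$forward)
  softmax_rows(run$h_final %*% params$Wout +
                 rep(params$bout, each = nrow(run$h_final)))
}

#' BiLSTM forward pass
#'
#' Runs one direction over the sequence and an independent direction over
#' the reversed sequence; their final hidden states are concatenated
#' (forward final first) into a `2 * hidden_size` feature vector feeding
#' the softmax readout.
#'
#' @inheritParams lstm_forward
#' @param params From [init_recurrent_params()] with `bidirectional = TRUE`.
#' @param return_features If TRUE, also return the concatenated hidden
#'   features.
#' @return Probability matrix as in [lstm_forward()]; if
#'   `return_features`, a list with `prob` and `features` (`n x 2h`).
#' @export
bilstm_forward <- function(x, params, return_features = FALSE) {
  if (!isTRUE(params$bidirectional))
    stop("params are not bidirectional", call. = FALSE)
  x_list <- .as_seq(x, params$input_size)
  if (length(x_list) == 0) stop("empty sequence", call. = FALSE)
  fwd <- .lstm_run(x_list, params$forward)
  bwd <- .lstm_run(rev(x_list), params$backward)
  h_con <- cbind(fwd$h_final, bwd$h_final)
  prob <- softmax_rows(h_con %*% params$Wout +
                         rep(params$bout, each = nrow(h_con)))
  if (return_features) list(prob = prob, features = h_con) else prob
}

#' ANN forward pass
#'
#' Sigmoid hidden layer over the flattened segment, linear two-unit output,
#' softmax for the probability pair.
#'
#' @param x One flattened segment (vector) or batch matrix.
#' @param params From [init_ann_params()].
#' @return Probability matrix (`n x 2`, columns better/worse).
#' @export
ann_forward <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != params$input_size)
    stop("input has ", ncol(x), " columns; expected ", params$input_size,
         call. = FALSE)
  nb <- nrow(x)
  h <- sigmoid(x %*% params$W1 + rep(params$b1, each = nb))
  softmax_rows(h %*% params$W2 + rep(params$b2, each = nb))
}

## ---- analytic gradients (verified by finite differences in tests) -------

## gradient of mean cross-entropy w.r.t. logits, plus readout grads
.readout_backward <- function(feat, y, Wout, bout) {
  nb <- nrow(feat)
  logits <- feat %*% Wout + rep(bout, each = nb)
  p <- softmax_rows(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(nb), y + 1L)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(nb), y + 1L)] <-
    dlogits[cbind(seq_len(nb), y + 1L)] - 1
  dlogits <- dlogits / nb
  list(loss = loss, prob = p,
       dWout = crossprod(feat, dlogits), dbout = colSums(dlogits),
       dfeat = dlogits %*% t(Wout))
}

## backprop through time for one direction given d(final hidden)
.lstm_backward <- function(x_list, cache, prm, dh_final) {
  zero_like <- function(tmpl) lapply(tmpl, function(m) m * 0)
  g <- list(Wx = zero_like(prm$Wx), Wh = zero_like(prm$Wh),
            bx = zero_like(prm$bx), bh = zero_like(prm$bh))
  dh <- dh_final
  dc <- dh * 0
  for (t in rev(seq_along(x_list))) {
    cc <- cache[[t]]
    i_t <- cc$gates$i; f_t <- cc$gates$f; o_t <- cc$gates$o
    cand <- cc$gates$cand; tc <- cc$tanh_c
    d_o <- dh * tc * o_t * (1 - o_t)
    dc <- dc + dh * o_t * (1 - tc^2)
    d_f <- dc * cc$c_prev * f_t * (1 - f_t)
    d_i <- dc * cand * i_t * (1 - i_t)
    d_cand <- dc * i_t * (1 - cand^2)
    dc <- dc * f_t
    das <- list(i = d_i, f = d_f, o = d_o, c = d_cand)
    dh <- dh * 0
    for (k in names(das)) {
      g$Wx[[k]] <- g$Wx[[k]] + crossprod(x_list[[t]], das[[k]])
      g$Wh[[k]] <- g$Wh[[k]] + crossprod(cc$h_prev, das[[k]])
      db <- colSums(das[[k]])
      g$bx[[k]] <- g$bx[[k]] + db
      g$bh[[k]] <- g$bh[[k]] + db
      dh <- dh + das[[k]] %*% t(prm$Wh[[k]])
    }
  }
  g
}

## loss + gradients for each family; x is a batch matrix, y in {0,1}
lstm_loss_grad <- function(params, x, y) {
  x_list <- .as_seq(x, params$input_size)
  run <- .lstm_run(x_list, params$forward, keep_cache = TRUE)
  ro <- .readout_backward(run$h_final, y, params$Wout, params$bout)
  grads <- list(forward = .lstm_backward(x_list, run$cache, params$forward,
                                         ro$dfeat),
                Wout = ro$dWout, bout = ro$dbout)
  list(loss = ro$loss, prob = ro$prob, grads = grads)
}

bilstm_loss_grad <- function(params, x, y) {
  x_list <- .as_seq(x, params$input_size)
  rev_list <- rev(x_list)
  fwd <- .lstm_run(x_list, params$forward, keep_cache = TRUE)
  bwd <- .lstm_run(rev_list, params$backward, keep_cache = TRUE)
  h <- params$hidden_size
  feat <- cbind(fwd$h_final, bwd$h_final)
  ro <- .readout_backward(feat, y, params$Wout, params$bout)
  grads <- list(
    forward = .lstm_backward(x_list, fwd$cache, params$forward,
                             ro$dfeat[, 1:h, drop = FALSE]),
    backward = .lstm_backward(rev_list, bwd$cache, params$backward,
                              ro$dfeat[, (h + 1):(2 * h), drop = FALSE]),
    Wout = ro$dWout, bout = ro$dbout)
  list(loss = ro$loss, prob = ro$prob, grads = grads)
}

ann_loss_grad <- function(params, x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nb <- nrow(x)
  hid <- sigmoid(x %*% params$W1 + rep(params$b1, each = nb))
  ro <- .readout_backward(hid, y, params$W2, params$b2)
  dhid <- ro$dfeat * hid * (1 - hid)
  grads <- list(W1 = crossprod(x, dhid), b1 = colSums(dhid),
                W2 = ro$dWout, b2 = ro$dbout)
  list(loss = ro$loss, prob = ro$prob, grads = grads)
}

## ---- parameter vector utilities (SGD updates, finite-difference checks) --

.param_leaves <- c("Wx", "Wh", "bx", "bh", "W1", "b1", "W2", "b2",
                   "Wout", "bout", "forward", "backward")

#' Flatten trainable parameters to a numeric vector
#' @param params A `wellcast_params` (or a gradient list of the same shape).
#' @return Numeric vector of all trainable entries, in a fixed order.
#' @keywords internal
flatten_params <- function(params) {
  grab <- function(x) {
    if (is.list(x))
      return(unlist(lapply(x[names(x) %in% .param_leaves | names(x) %in%
                               c("i", "f", "o", "c")], grab),
                    use.names = FALSE))
    as.numeric(x)
  }
  grab(params)
}

#' Rebuild a parameter object from a flat vector
#' @keywords internal
unflatten_params <- function(flat, skeleton) {
  pos <- 1L
  fill <- function(x) {
    if (is.list(x)) {
      for (nm in names(x)) {
        if (nm %in% .param_leaves || nm %in% c("i", "f", "o", "c"))
          x[[nm]] <- fill(x[[nm]])
      }
      return(x)
    }
    n <- length(x)
    out <- flat[pos:(pos + n - 1L)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  fill(skeleton)
}
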