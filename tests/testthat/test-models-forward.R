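test_that("LSTM cell at zero parameters gives half-open gates and zero
           state", {
  p <- init_recurrent_params(4, 3, seed = 1)
  zero <- wellcast:::unflatten_params(
    0 * wellcast:::flatten_params(p), p)
  st <- lstm_cell_forward(rnorm(4), numeric(3), numeric(3), zero$forward)
  expect_equal(as.numeric(st$gates$i), rep(0.5, 3))
  expect_equal(as.numeric(st$gates$f), rep(0.5, 3))
  expect_equal(as.numeric(st$gates$o), rep(0.5, 3))
  expect_equal(as.numeric(st$gates$cand), rep(0, 3))
  expect_equal(as.numeric(st$c), rep(0, 3))
  expect_equal(as.numeric(st$h), rep(0, 3))
  ## and the full forward is the symmetric coin
  expect_equal(as.numeric(lstm_forward(rnorm(8), zero)), c(0.5, 0.5))
})

test_that("scalar LSTM cell matches a hand-evaluated trace of the gate
           equations", {
  ## i = h = 1 with hand-picked weights; trace the equations directly
  p <- init_lstm_direction(1, 1)
  p$Wx <- list(i = matrix(0.5), f = matrix(-0.3), o = matrix(0.8),
               c = matrix(1.1))
  p$Wh <- list(i = matrix(0.2), f = matrix(0.4), o = matrix(-0.6),
               c = matrix(0.9))
  p$bx <- list(i = 0.1, f = 0.2, o = -0.1, c = 0.05)
  p$bh <- list(i = 0.05, f = -0.1, o = 0.3, c = -0.2)
  x_t <- 0.7; h_prev <- 0.3; c_prev <- -0.2
  sig <- function(z) 1 / (1 + exp(-z))
  i_t <- sig(0.5 * 0.7 + 0.1 + 0.2 * 0.3 + 0.05)
  f_t <- sig(-0.3 * 0.7 + 0.2 + 0.4 * 0.3 - 0.1)
  o_t <- sig(0.8 * 0.7 - 0.1 - 0.6 * 0.3 + 0.3)
  cand <- tanh(1.1 * 0.7 + 0.05 + 0.9 * 0.3 - 0.2)
  c_t <- f_t * c_prev + i_t * cand
  h_t <- o_t * tanh(c_t)
  st <- lstm_cell_forward(x_t, h_prev, c_prev, p)
  expect_equal(as.numeric(st$h), h_t, tolerance = 1e-12)
  expect_equal(as.numeric(st$c), c_t, tolerance = 1e-12)
  expect_equal(as.numeric(st$gates$i), i_t, tolerance = 1e-12)
})

test_that("gate activations stay in their ranges over random parameter
           sweeps", {
  set.seed(33)
  for (r in 1:200) {
    p <- init_lstm_direction(3, 2)
    for (g in c("i", "f", "o", "c")) {
      p$Wx[[g]][] <- runif(6, -10, 10)
      p$Wh[[g]][] <- runif(4, -10, 10)
      p$bx[[g]][] <- runif(2, -10, 10)
      p$bh[[g]][] <- runif(2, -10, 10)
    }
    st <- lstm_cell_forward(runif(3, -5, 5), runif(2, -1, 1),
                            runif(2, -2, 2), p)
    ## mathematically open intervals; saturation can hit the bound in
    ## double precision, so the sweep asserts the closed envelope
    expect_true(all(st$gates$i >= 0 & st$gates$i <= 1))
    expect_true(all(st$gates$f >= 0 & st$gates$f <= 1))
    expect_true(all(st$gates$o >= 0 & st$gates$o <= 1))
    expect_true(all(st$gates$cand >= -1 & st$gates$cand <= 1))
  }
  ## strict interior at moderate pre-activations
  p <- init_lstm_direction(3, 2)
  st <- lstm_cell_forward(runif(3, -1, 1), runif(2, -1, 1),
                          runif(2, -1, 1), p)
  for (g in c("i", "f", "o"))
    expect_true(all(st$gates[[g]] > 0 & st$gates[[g]] < 1))
  expect_true(all(st$gates$cand > -1 & st$gates$cand < 1))
})

test_that("segment reshaping partitions and reassembles exactly", {
  x <- rnorm(2500)
  sl <- reshape_segment(x, 100)
  expect_identical(dim(sl), c(25L, 100L))
  expect_identical(as.numeric(t(sl)), x)           # partition identity
  expect_identical(nrow(reshape_segment(x, 2500)), 1L)
  expect_error(reshape_segment(rnorm(2501), 100), "divisible")
  ## batch form: list of T slices
  xb <- matrix(rnorm(3 * 12), 3, 12)
  lb <- reshape_segment(xb, 4)
  expect_length(lb, 3)
  expect_identical(lb[[2]], xb[, 5:8])
})

test_that("forward passes return normalized probability pairs and the
           LSTM is order-sensitive", {
  set.seed(44)
  p <- init_recurrent_params(4, 6, seed = 2)
  x <- matrix(rnorm(5 * 12), 5, 12)
  pr <- lstm_forward(x, p)
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(rowSums(pr), rep(1, 5))
  ## permuting time steps changes generic outputs
  xp <- x[, c(9:12, 1:8)]
  expect_gt(max(abs(lstm_forward(xp, p) - pr)), 1e-8)
})

test_that("BiLSTM concatenates the two directions' final states", {
  p <- init_recurrent_params(4, 6, bidirectional = TRUE, seed = 3)
  x <- matrix(rnorm(2 * 12), 2, 12)
  out <- bilstm_forward(x, p, return_features = TRUE)
  expect_identical(ncol(out$features), 12L)        # 2h
  expect_equal(rowSums(out$prob), rep(1, 2))
  ## palindromic input with tied directional parameters gives identical
  ## forward and backward hidden states
  p$backward <- p$forward
  pal <- c(1:4, 9:12, 1:4)
  feats <- bilstm_forward(pal, p, return_features = TRUE)$features
  expect_equal(feats[, 1:6], feats[, 7:12], tolerance = 1e-12)
  expect_error(bilstm_forward(x, init_recurrent_params(4, 6, seed = 1)),
               "not bidirectional")
})

test_that("BiLSTM with a silenced backward direction reproduces the LSTM", {
  p1 <- init_recurrent_params(4, 5, seed = 7)
  p2 <- init_recurrent_params(4, 5, bidirectional = TRUE, seed = 8)
  p2$forward <- p1$forward
  ## zero the backward direction and its readout rows; copy the forward
  ## readout block
  flatb <- wellcast:::flatten_params(p2$backward)
  p2$backward <- wellcast:::unflatten_params(0 * flatb, p2$backward)
  p2$Wout <- rbind(p1$Wout, matrix(0, 5, 2))
  p2$bout <- p1$bout
  x <- matrix(rnorm(4 * 12), 4, 12)
  ## backward h stays 0 (zero candidate), so the readout sees only h_fwd
  expect_equal(bilstm_forward(x, p2), lstm_forward(x, p1),
               tolerance = 1e-12)
})

test_that("ANN forward matches a hand-computed 2-input/1-hidden example
           and keeps activations in range", {
  p <- init_ann_params(2, 1, seed = 4)
  p$W1 <- matrix(c(0.3, -0.7), 2, 1)
  p$b1 <- 0.1
  p$W2 <- matrix(c(1.2, -0.4), 1, 2)
  p$b2 <- c(0.05, -0.05)
  x <- c(0.5, -1)
  h <- 1 / (1 + exp(-(0.3 * 0.5 + (-0.7) * (-1) + 0.1)))
  logits <- c(1.2 * h + 0.05, -0.4 * h - 0.05)
  want <- exp(logits) / sum(exp(logits))
  expect_equal(as.numeric(ann_forward(x, p)), want, tolerance = 1e-12)
  ## zero parameters: hidden all 0.5, symmetric output
  pz <- wellcast:::unflatten_params(0 * wellcast:::flatten_params(p), p)
  expect_equal(as.numeric(ann_forward(c(3, -9), pz)), c(0.5, 0.5))
})

test_that("RBF kernel is a unit-diagonal symmetric similarity", {
  expect_equal(rbf_kernel(1:5, 1:5, 3), 1)
  ## squared distance equal to 2 sigma^2 gives exp(-1)
  sigma <- 0.7
  x1 <- c(0, 0)
  x2 <- c(sqrt(2) * sigma, 0)
  expect_equal(rbf_kernel(x1, x2, sigma), exp(-1), tolerance = 1e-12)
  set.seed(55)
  for (r in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(rbf_kernel(a, b, 1.3), rbf_kernel(b, a, 1.3))
    expect_true(rbf_kernel(a, b, 1.3) > 0 && rbf_kernel(a, b, 1.3) <= 1)
  }
  expect_error(rbf_kernel(1:2, 1:2, 0), "sigma")
  expect_error(rbf_kernel(1:2, 1:3, 1), "dimension")
  expect_equal(gamma_to_sigma(0.01), sqrt(50))
})

test_that("cross-entropy loss has its closed-form landmarks", {
  expect_equal(cross_entropy_loss(c(0, 1, 1, 0), rep(0.5, 4)), log(2))
  expect_lt(cross_entropy_loss(1, 1 - 1e-12), 1e-10)
  ## monotone decrease as the prediction approaches the truth
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(p) cross_entropy_loss(1, p), numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_gte(cross_entropy_loss(c(1, 0), c(0.9, 0.2)), 0)
  ## matrix form uses the worse-class column
  expect_equal(cross_entropy_loss(c(1, 0), cbind(c(0.1, 0.8), c(0.9, 0.2))),
               cross_entropy_loss(c(1, 0), c(0.9, 0.2)))
  ## saturated inputs are clamped, not infinite
  expect_true(is.finite(cross_entropy_loss(c(1, 0), c(0, 1))))
})
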