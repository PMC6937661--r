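test_that("training is deterministic under a fixed seed", {
  d <- toy_segments(n = 40, len = 12, sep = 1, seed = 81)
  cfg <- train_config(learning_rate = 0.3, epochs = 5, batch_size = 8,
                      seed = 5)
  f1 <- train_model("lstm", d$x, d$y, hidden_size = 4, input_size = 4,
                    config = cfg)
  f2 <- train_model("lstm", d$x, d$y, hidden_size = 4, input_size = 4,
                    config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(wellcast:::flatten_params(f1$params),
                   wellcast:::flatten_params(f2$params))
})

test_that("every neural family overfits a small strongly separable set", {
  d <- toy_segments(n = 60, len = 12, sep = 2, seed = 82)
  cfg <- train_config(learning_rate = 0.5, epochs = 40, batch_size = 16,
                      seed = 6)
  for (fam in c("lstm", "bilstm")) {
    fit <- train_model(fam, d$x, d$y, hidden_size = 8, input_size = 4,
                       config = cfg)
    expect_gte(mean(predict(fit, d$x) == d$y), 0.95)
  }
  cfg_a <- train_config(learning_rate = 0.5, epochs = 60, batch_size = 16,
                        schedule = "step", decay_factor = 0.1, seed = 6)
  fit_a <- train_model("ann", d$x, d$y, hidden_size = 8, config = cfg_a)
  expect_gte(mean(predict(fit_a, d$x) == d$y), 0.95)
})

test_that("label-shuffled data trains to chance-level held-out accuracy", {
  set.seed(83)
  d <- toy_segments(n = 120, len = 12, sep = 2, seed = 83)
  y_shuf <- sample(d$y)
  cfg <- train_config(learning_rate = 0.3, epochs = 10, batch_size = 16,
                      seed = 7)
  fit <- train_model("lstm", d$x[1:80, ], y_shuf[1:80], hidden_size = 4,
                     input_size = 4, config = cfg)
  acc <- mean(predict(fit, d$x[81:120, ]) == y_shuf[81:120])
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / 40) + 0.05)
})

test_that("learning-rate schedules decay as configured", {
  d <- toy_segments(n = 20, len = 8, sep = 0, seed = 84)
  cfg_step <- train_config(learning_rate = 0.1, decay_factor = 0.5,
                           schedule = "step", step_every = 3, epochs = 7,
                           batch_size = 10, seed = 1)
  fit <- train_model("ann", d$x, d$y, hidden_size = 3, config = cfg_step)
  expect_equal(fit$history$lr, 0.1 * 0.5^c(0, 0, 0, 1, 1, 1, 2))
  ## plateau: flat loss (zero-signal data, tiny lr) must trigger decay
  ## after `patience` stalled epochs and respect the floor
  cfg_pl <- train_config(learning_rate = 1e-6, decay_factor = 0.1,
                         schedule = "plateau", patience = 2, epochs = 6,
                         batch_size = 10, lr_floor = 1e-7, seed = 1)
  fit2 <- train_model("ann", d$x, d$y, hidden_size = 3, config = cfg_pl)
  expect_lte(fit2$history$lr[6], 1e-6)
  expect_gte(min(fit2$history$lr), 1e-7)
  expect_error(train_config(learning_rate = 0),
               "learning_rate")
  expect_error(train_config(decay_factor = 1), "decay_factor")
})

test_that("single-class data and shape mismatches are rejected", {
  d <- toy_segments(n = 20, len = 12, seed = 85)
  expect_error(svm_fit(d$x, rep(1, 20)), "single-class")
  expect_error(train_model("lstm", d$x, rep(0, 20)), "both conditions")
  fit <- train_model("svm", d$x, d$y, gamma = 0.05)
  expect_error(predict(fit, matrix(0, 2, 5)), regexp = ".")
})

test_that("SVM separates the separable and solves XOR with the RBF kernel", {
  d <- toy_segments(n = 40, len = 12, sep = 3, seed = 86)
  fit <- train_model("svm", d$x, d$y, gamma = 0.05)
  expect_equal(mean(predict(fit, d$x) == d$y), 1)
  ## XOR corners: linearly inseparable, RBF-separable
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  xor_y <- c(0L, 1L, 1L, 0L)
  fx <- svm_fit(xor_x, xor_y, C = 100, gamma = 1)
  expect_identical(svm_predict(fx, xor_x)$condition, xor_y)
  ## margin scores are finite and sign-consistent with the class
  pr <- svm_predict(fx, xor_x)
  expect_true(all(is.finite(pr$score)))
  expect_identical(as.integer(pr$score > 0), pr$condition)
})

test_that("SVM decision values reproduce the explicit kernel expansion", {
  d <- toy_segments(n = 30, len = 6, sep = 1.5, seed = 87)
  fit <- svm_fit(d$x, d$y, C = 10, gamma = 0.2)
  sv <- fit$fit$SV
  coefs <- fit$fit$coefs          # alpha_i * y_i in libsvm's orientation
  rho <- fit$fit$rho
  xq <- matrix(rnorm(5 * 6), 5, 6)
  manual <- vapply(seq_len(5), function(i) {
    k <- vapply(seq_len(nrow(sv)), function(j)
      rbf_kernel(xq[i, ], sv[j, ], fit$sigma), numeric(1))
    sum(coefs * k) - rho
  }, numeric(1))
  got <- unname(svm_predict(fit, xq)$score)
  expect_equal(abs(got), abs(manual), tolerance = 1e-10)
  ## orientation: positive score means predicted worse
  expect_identical(as.integer(got > 0), svm_predict(fit, xq)$condition)
})

test_that("grid search enumerates the documented grids and recovers a
           planted optimum", {
  expect_identical(nrow(svm_default_grid()), 289L)
  expect_identical(nrow(ann_hidden_grid()), 91L)
  expect_equal(range(ann_hidden_grid()$hidden_size), c(100, 1000))
  ## planted optimum: gamma far off-scale fails, the matched one wins
  d <- toy_segments(n = 48, len = 6, sep = 2, seed = 88)
  groups <- rep(sprintf("u%d", 1:12), each = 4)
  y <- rep(rep(0:1, 6), each = 4)
  d$x <- d$x - 2 * d$y + 2 * y
  grid <- data.frame(gamma = c(1e-8, 0.05, 1e+6))
  gs <- grid_search("svm", d$x, y, groups, grid, k = 3, seed = 2, C = 10)
  expect_equal(gs$best$gamma, 0.05)
  expect_identical(nrow(gs$scores), 3L)
  ## singleton grid returns its only point
  gs1 <- grid_search("svm", d$x, y, groups,
                     data.frame(gamma = 0.05), k = 3, seed = 2, C = 10)
  expect_equal(gs1$best$gamma, 0.05)
  expect_error(grid_search("svm", d$x, y, groups, data.frame()), "empty")
})
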