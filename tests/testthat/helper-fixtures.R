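## Shared in-code fixtures: tiny cohorts and datasets, sized for speed.

tiny_cohort <- function(n_subjects = 2, n_days = 8, effect_size = 1,
                        seed = 11, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, n_days = n_days,
                                duration_range = c(6, 7),
                                effect_size = effect_size, seed = seed, ...))
}

## small separable 2-class dataset in segment format (for cheap model tests):
## class-dependent mean on a short "segment" divisible by input_size 4
toy_segments <- function(n = 60, len = 12, sep = 2, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * len), n, len) + sep * y
  list(x = x, y = y)
}

## brute-force heart-rate oracle: dominant beat period by autocorrelation
## after running-median baseline removal -- robust to wave-amplitude
## lability, baseline wander and smoothing
rate_feature <- function(ecg, fs) {
  x <- ecg - stats::runmed(ecg, 201)
  n <- length(x)
  lags <- round(0.4 * fs):round(1.5 * fs)
  ac <- vapply(lags, function(L) sum(x[1:(n - L)] * x[(L + 1):n]),
               numeric(1))
  60 / (lags[which.max(ac)] / fs)
}

## central finite-difference gradient check; returns max relative error
## over a random probe of parameter coordinates
fd_gradient_error <- function(loss_grad, params, x, y, n_probe = 50,
                              h = 1e-5, seed = 1) {
  res <- loss_grad(params, x, y)
  ana <- wellcast:::flatten_params(res$grads)
  flat <- wellcast:::flatten_params(params)
  set.seed(seed)
  idx <- sort(sample(length(flat), min(n_probe, length(flat))))
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + h
    dn <- flat; dn[i] <- dn[i] - h
    (loss_grad(wellcast:::unflatten_params(up, params), x, y)$loss -
       loss_grad(wellcast:::unflatten_params(dn, params), x, y)$loss) / (2 * h)
  }, numeric(1))
  max(abs(num - ana[idx]) / pmax(abs(num) + abs(ana[idx]), 1e-8))
}
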