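#' EWMA window weights
#'
#' Geometric weights of a trailing exponentially weighted moving average of
#' window length `n`, normalized to sum to one (unit DC gain): the weight of
#' the sample at lag `k` (k = 0 is the current sample) is proportional to
#' `(1 - alpha)^k` with `alpha = 2 / (1 + n)`.
#'
#' @param n Window length in samples (>= 1).
#' @return Numeric vector of length `n`, weights by increasing lag.
#' @export
ewma_weights <- function(n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  alpha <- 2 / (1 + n)
  w <- (1 - alpha)^(0:(n - 1))
  w / sum(w)
}

#' Exponentially weighted moving-average filter
#'
#' Causal low-pass filter: each output sample is the weighted mean of the
#' trailing `n` input samples with geometrically declining weights
#' (`alpha = 2 / (1 + n)`), normalized to unit sum so a constant signal maps
#' to itself and amplitude is preserved. At the left edge the window is
#' truncated to the available samples and its weights renormalized (no
#' padding, no startup transient).
#'
#' With the default `n = 40` at 500 Hz this strongly attenuates
#' high-frequency noise while keeping the beat-scale structure of an ECG.
#'
#' @param x Numeric vector of samples (non-empty, finite).
#' @param n Window length in samples. Default 40.
#' @return Filtered vector, same length as `x`.
#' @examples
#' ewma_filter(rep(3, 10))        # constant in, constant out
#' @export
ewma_filter <- function(x, n = 40) {
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite samples",
                               call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  N <- length(x)
  alpha <- 2 / (1 + n)
  g <- (1 - alpha)^(0:(n - 1))        # unnormalized weight at lag k
  out <- numeric(N)
  head_len <- min(n - 1L, N)
  if (head_len > 0) {
    csum <- cumsum(g)
    for (t in seq_len(head_len))      # truncated, renormalized window
      out[t] <- sum(g[1:t] * x[t:1]) / csum[t]
  }
  if (N >= n) {
    full <- stats::filter(x, g / sum(g), method = "convolution", sides = 1)
    out[n:N] <- as.numeric(full[n:N])
  }
  out
}

#' Cut a signal into fixed-length overlapping segments
#'
#' Slides a `window_s`-second window with `stride_s`-second steps over the
#' signal. Two counting conventions are provided: the default (`"drop_last"`)
#' yields `K = max(1, floor((L - w) / s))` segments, omitting the final
#' full-coverage window (a 20 s trace at 5 s / 1 s gives 15 segments); the
#' `"all"` convention keeps it, `K = floor((L - w) / s) + 1` (16 segments
#' for the same trace).
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling frequency in Hz.
#' @param window_s Window length in seconds (default 5).
#' @param stride_s Stride in seconds (default 1).
#' @param convention `"drop_last"` (default) or `"all"`.
#' @return A numeric matrix, one row per segment (`round(window_s * fs)`
#'   columns), with attribute `start_s` giving each segment's offset in
#'   seconds within the source signal.
#' @examples
#' nrow(segment_signal(numeric(10000), fs = 500))  # 15
#' @export
segment_signal <- function(x, fs, window_s = 5, stride_s = 1,
                           convention = c("drop_last", "all")) {
  convention <- match.arg(convention)
  if (window_s <= 0 || stride_s <= 0)
    stop("window_s and stride_s must be > 0", call. = FALSE)
  w <- round(window_s * fs)
  s <- round(stride_s * fs)
  N <- length(x)
  if (N < w)
    stop("signal duration (", N / fs, " s) is shorter than the window (",
         window_s, " s)", call. = FALSE)
  n_strides <- floor((N - w) / s)
  K <- if (convention == "drop_last") max(1L, n_strides) else n_strides + 1L
  starts <- (seq_len(K) - 1L) * s            # 0-based sample offsets
  seg <- matrix(0, nrow = K, ncol = w)
  for (k in seq_len(K)) seg[k, ] <- x[(starts[k] + 1L):(starts[k] + w)]
  attr(seg, "start_s") <- starts / fs
  seg
}

#' Min-max scale a segment to the unit interval
#'
#' Affine map `(x - min) / (max - min)` so the output attains 0 and 1 and
#' the order of samples is preserved. A constant segment (max == min) is
#' mapped to all zeros with a warning rather than an error, so batch
#' pipelines survive flatline artifacts.
#'
#' @param x Numeric vector (non-empty).
#' @return Scaled vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(0, 5, 10))
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0) stop("empty segment", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant segment: min-max scaling undefined, returning zeros")
    return(numeric(length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Min-max scale each row of a segment matrix
#'
#' @param segments Matrix, one segment per row (as from [segment_signal()]).
#' @return Matrix of the same shape with each row scaled to `[0, 1]`;
#'   constant rows become zeros (one warning reports how many).
#' @export
normalize_segments <- function(segments) {
  lo <- apply(segments, 1, min)
  hi <- apply(segments, 1, max)
  flat <- hi == lo
  if (any(flat))
    warning(sum(flat), " constant segment(s): min-max scaling undefined, ",
            "returning zeros")
  span <- ifelse(flat, 1, hi - lo)
  out <- (segments - lo) / span
  out[flat, ] <- 0
  attr(out, "start_s") <- attr(segments, "start_s")
  out
}

#' Preprocess one raw trace into model-ready segments
#'
#' Applies the pipeline's preprocessing order: EWMA filtering (optional),
#' sliding-window segmentation, per-segment min-max scaling.
#'
#' @param x Numeric vector of raw samples.
#' @param fs Sampling frequency in Hz.
#' @param use_ewma Apply the EWMA filter first (default TRUE; FALSE feeds
#'   the filtering ablation).
#' @param ewma_n EWMA window length in samples.
#' @inheritParams segment_signal
#' @return Matrix of scaled segments (rows), with `start_s` attribute.
#' @export
preprocess_signal <- function(x, fs, use_ewma = TRUE, ewma_n = 40,
                              window_s = 5, stride_s = 1,
                              convention = c("drop_last", "all")) {
  if (use_ewma) x <- ewma_filter(x, ewma_n)
  seg <- segment_signal(x, fs, window_s, stride_s, match.arg(convention))
  normalize_segments(seg)
}
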