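#' Fisher-Yates (rank-based inverse-normal) normalization
#'
#' Replaces each score by the standard-normal quantile of its midrank:
#' `qnorm(r / (I + 1))`, where `r` is the average rank of the score within
#' the series of length `I`. Applied per subject, the transform removes both
#' the skew of the raw ordinal distribution and any subject-specific scoring
#' bias, since it depends only on the within-subject ranks. Tied scores
#' share one midrank and therefore one transformed value.
#'
#' @param scores Numeric vector of ordinal scores for one subject (length
#'   `I >= 1`).
#' @return Numeric vector of normalized scores (ties-free series of odd
#'   length center at 0; an all-tied series maps to all zeros).
#' @examples
#' fisher_yates_normalize(c(3, 4, 5))   # qnorm(c(1,2,3)/4)
#' @export
fisher_yates_normalize <- function(scores) {
  if (length(scores) == 0) stop("empty score series", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  qnorm(r / (length(scores) + 1))
}

#' Dichotomize a normalized score into a binary wellness condition
#'
#' Scores strictly greater than 0 map to 0 (better condition); all others,
#' including exactly 0, map to 1 (worse condition).
#'
#' @param fy_score Numeric vector of Fisher-Yates normalized scores.
#' @return Integer vector of 0 (better) / 1 (worse).
#' @examples
#' dichotomize(c(0.449, -0.627, 0))  # 0 1 1
#' @export
dichotomize <- function(fy_score) {
  if (!all(is.finite(fy_score))) stop("scores must be finite", call. = FALSE)
  ifelse(fy_score > 0, 0L, 1L)
}

#' Per-subject score series with ranks, normalized scores and conditions
#'
#' Convenience constructor bundling the label pipeline for one subject.
#'
#' @param day_indices Integer vector of (sorted, distinct) day indices.
#' @param hi_scores Ordinal health-index scores in 1-5, same length.
#' @param subject_id Optional identifier attached as an attribute.
#' @return Data frame with columns `day_index`, `hi_score`, `rank`,
#'   `fy_score`, `condition`.
#' @export
score_series <- function(day_indices, hi_scores, subject_id = NA_character_) {
  if (length(day_indices) != length(hi_scores))
    stop("day_indices and hi_scores must have equal length", call. = FALSE)
  if (anyDuplicated(day_indices)) stop("duplicated day indices", call. = FALSE)
  if (!all(hi_scores %in% 1:5))
    stop("hi_scores must be ordinal integers in 1..5", call. = FALSE)
  o <- order(day_indices)
  day_indices <- day_indices[o]
  hi_scores <- hi_scores[o]
  fy <- fisher_yates_normalize(hi_scores)
  out <- data.frame(day_index = day_indices, hi_score = hi_scores,
                    rank = rank(hi_scores, ties.method = "average"),
                    fy_score = fy, condition = dichotomize(fy))
  attr(out, "subject_id") <- subject_id
  out
}

#' Align each day's ECG with the next day's condition
#'
#' Emits one forecast pair per day `d` whose successor `d + 1` is also
#' present: the pair carries day `d` (the predictor ECG's day) and the
#' binary condition of day `d + 1` as its label. Days whose successor is
#' missing are dropped; pairs never cross subjects (call per subject).
#'
#' @param day_indices Integer vector of a subject's observed day indices.
#' @param conditions Binary conditions (0/1) aligned with `day_indices`.
#' @return Data frame with columns `ecg_day`, `label_day`, `label`
#'   (possibly zero rows).
#' @examples
#' shift_one_day_forward(c(0, 2, 3), c(1, 0, 1))  # only the 2 -> 3 pair
#' @export
shift_one_day_forward <- function(day_indices, conditions) {
  if (length(day_indices) != length(conditions))
    stop("day_indices and conditions must have equal length", call. = FALSE)
  o <- order(day_indices)
  day_indices <- day_indices[o]
  conditions <- conditions[o]
  has_next <- (day_indices + 1L) %in% day_indices
  d <- day_indices[has_next]
  nxt <- match(d + 1L, day_indices)
  data.frame(ecg_day = as.integer(d), label_day = as.integer(d + 1),
             label = as.integer(conditions[nxt]))
}

#' Propagate forecast labels to a day's segments
#'
#' Every segment cut from the ECG of day `d` inherits the binary condition
#' of day `d + 1` (training-set enlargement: one labeled day yields one
#' labeled row per sliding window).
#'
#' @param pairs Data frame of forecast pairs (from
#'   [shift_one_day_forward()]), with an additional `subject_id` column if
#'   several subjects are mixed.
#' @param segments_by_day Named list mapping `"subject_id:ecg_day"` (or
#'   plain `ecg_day` when `pairs` has no `subject_id`) to a segment matrix.
#' @return List with `x` (row-bound segment matrix), `y` (integer labels)
#'   and `meta` (data frame: `subject_id`, `ecg_day`, `start_s`).
#' @export
propagate_labels_to_segments <- function(pairs, segments_by_day) {
  keyed <- "subject_id" %in% names(pairs)
  xs <- list(); metas <- list(); ys <- list()
  for (i in seq_len(nrow(pairs))) {
    sid <- if (keyed) pairs$subject_id[i] else NA_character_
    key <- if (keyed) paste0(sid, ":", pairs$ecg_day[i])
           else as.character(pairs$ecg_day[i])
    seg <- segments_by_day[[key]]
    if (is.null(seg) || nrow(seg) == 0)
      stop("no segments for record ", key, call. = FALSE)
    xs[[i]] <- seg
    ys[[i]] <- rep(pairs$label[i], nrow(seg))
    st <- attr(seg, "start_s")
    if (is.null(st)) st <- rep(NA_real_, nrow(seg))
    metas[[i]] <- data.frame(subject_id = sid, ecg_day = pairs$ecg_day[i],
                             start_s = st)
  }
  list(x = do.call(rbind, xs), y = unlist(ys),
       meta = do.call(rbind, metas))
}

#' Build the labeled segment dataset from a cohort
#'
#' End-to-end data preparation: per subject, ordinal HI scores are
#' Fisher-Yates normalized and dichotomized, each observed day is paired
#' with its successor's condition, and each pair's ECG is preprocessed
#' (optional EWMA, segmentation, min-max scaling) into labeled rows.
#'
#' @param cohort A `wellcast_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @inheritParams preprocess_signal
#' @return Object of class `wellcast_dataset`: list with `x` (segments x
#'   samples matrix), `y` (0 better / 1 worse), `meta` (subject, day,
#'   offset) and `group` (subject-day identifier per row, the unit at which
#'   evaluation splits are made).
#' @export
build_dataset <- function(cohort, use_ewma = TRUE, ewma_n = 40,
                          window_s = 5, stride_s = 1,
                          convention = c("drop_last", "all")) {
  convention <- match.arg(convention)
  manifest <- as.data.frame(cohort)
  sids <- unique(manifest$subject_id)
  rec_key <- vapply(cohort$records, function(r)
    paste0(r$subject_id, ":", r$day_index), character(1))
  xs <- list(); ys <- list(); metas <- list()
  for (sid in sids) {
    sub <- manifest[manifest$subject_id == sid, ]
    ser <- score_series(sub$day_index, sub$hi_score, sid)
    pairs <- shift_one_day_forward(ser$day_index, ser$condition)
    if (nrow(pairs) == 0) next
    pairs$subject_id <- sid
    segs <- list()
    for (d in pairs$ecg_day) {
      rec <- cohort$records[[match(paste0(sid, ":", d), rec_key)]]
      segs[[paste0(sid, ":", d)]] <- preprocess_signal(
        rec$ecg, rec$fs, use_ewma, ewma_n, window_s, stride_s, convention)
    }
    part <- propagate_labels_to_segments(pairs, segs)
    xs[[sid]] <- part$x; ys[[sid]] <- part$y; metas[[sid]] <- part$meta
  }
  if (length(xs) == 0)
    stop("cohort yields no forecast pairs (no consecutive days)",
         call. = FALSE)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  structure(list(x = do.call(rbind, xs), y = unlist(ys, use.names = FALSE),
                 meta = meta,
                 group = paste0(meta$subject_id, ":", meta$ecg_day)),
            class = "wellcast_dataset")
}

#' @export
print.wellcast_dataset <- function(x, ...) {
  cat("wellcast labeled dataset:", nrow(x$x), "segments x", ncol(x$x),
      "samples;", length(unique(x$group)), "subject-days;",
      sum(x$y == 1), "worse /", sum(x$y == 0), "better\n")
  invisible(x)
}
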