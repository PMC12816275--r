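#' @name preprocessing
#' @title Gaze preprocessing: blink removal, gap interpolation, trial QC
#'
#' @description Raw gaze streams are cleaned in a fixed order: blink
#' classification first (so blinks are never "filled"), then linear
#' interpolation of short non-blink gaps, then trial-level quality control
#' on the remaining missing fraction.
#'
#' A *gap* is a maximal run of invalid samples. Its duration is measured
#' between the last valid sample before and the first valid sample after
#' the run, minus one inter-sample interval, which is robust to timestamp
#' jitter.
NULL

trial_dt <- function(trial) {
  hz <- attr(trial, "sampling_hz")
  if (!is.null(hz)) return(1000 / hz)
  stats::median(diff(trial$t_ms))
}

ensure_preproc_cols <- function(trial) {
  if (!"removed" %in% names(trial)) trial$removed <- FALSE
  if (!"interpolated" %in% names(trial)) trial$interpolated <- FALSE
  trial
}

invalid_runs <- function(trial) {
  bad <- !trial$valid | trial$removed
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Classify and remove blink artifacts
#'
#' Validity-0 runs whose duration falls inside the blink window are marked
#' `removed`, together with a margin of adjacent samples (blink onset and
#' offset contaminate neighbouring gaze estimates). Removed samples are
#' excluded from gap interpolation and from event detection.
#'
#' @param trial A `gaze_trial`.
#' @param blink_min_ms,blink_max_ms Blink duration window (ms).
#' @param margin_samples Samples removed on each side of a blink run.
#' @return The trial with a logical `removed` column set.
#' @export
remove_blinks <- function(trial, blink_min_ms = 75, blink_max_ms = 500,
                          margin_samples = 1L) {
  trial <- ensure_preproc_cols(trial)
  dt <- trial_dt(trial)
  runs <- invalid_runs(trial)
  if (!nrow(runs)) return(trial)
  n <- nrow(trial)
  for (i in seq_len(nrow(runs))) {
    dur <- (trial$t_ms[runs$end[i]] - trial$t_ms[runs$start[i]]) + dt
    if (dur >= blink_min_ms && dur <= blink_max_ms) {
      a <- max(1L, runs$start[i] - margin_samples)
      b <- min(n, runs$end[i] + margin_samples)
      trial$removed[a:b] <- TRUE
    }
  }
  trial
}

#' Linearly interpolate short gaps
#'
#' Every maximal run of invalid samples strictly shorter than `max_gap_ms`
#' (gap duration measured between flanking valid samples minus one sample
#' interval) that is flanked by valid samples on both sides is filled by
#' linear interpolation of x and y between the flanks. Longer gaps, edge
#' gaps, and samples removed as blinks are left untouched. Valid samples
#' are never altered, and the operation is idempotent.
#'
#' @param trial A `gaze_trial`.
#' @param max_gap_ms Maximum (exclusive) gap duration eligible for filling.
#' @return The trial with filled samples flagged `interpolated` and
#'   `valid = TRUE`.
#' @export
interpolate_gaps <- function(trial, max_gap_ms = 75) {
  trial <- ensure_preproc_cols(trial)
  if (!any(trial$valid)) {
    warning("trial has no valid samples; returned unchanged")
    return(trial)
  }
  dt <- trial_dt(trial)
  bad <- !trial$valid & !trial$removed
  r <- rle(bad | trial$removed)  # runs of anything-not-valid
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- nrow(trial)
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    if (any(trial$removed[s:e])) next           # blink-contaminated run
    if (s == 1L || e == n) next                 # no flanking valid sample
    if (!trial$valid[s - 1L] || !trial$valid[e + 1L]) next
    gap <- (trial$t_ms[e + 1L] - trial$t_ms[s - 1L]) - dt
    if (gap >= max_gap_ms) next
    tt <- trial$t_ms[c(s - 1L, e + 1L)]
    trial$x_px[s:e] <- stats::approx(tt, trial$x_px[c(s - 1L, e + 1L)],
                                     xout = trial$t_ms[s:e])$y
    trial$y_px[s:e] <- stats::approx(tt, trial$y_px[c(s - 1L, e + 1L)],
                                     xout = trial$t_ms[s:e])$y
    trial$valid[s:e] <- TRUE
    trial$interpolated[s:e] <- TRUE
  }
  trial
}

#' Trial-level quality control
#'
#' Computes the fraction of samples still missing (invalid or removed)
#' relative to the expected sample count at the nominal rate over the trial
#' span, and flags the trial for dropping when the fraction strictly
#' exceeds `max_missing_frac`.
#'
#' @param trial A preprocessed `gaze_trial`.
#' @param max_missing_frac Maximum tolerated missing fraction.
#' @return List with `keep` (logical) and `missing_frac`.
#' @export
qc_trial <- function(trial, max_missing_frac = 0.20) {
  trial <- ensure_preproc_cols(trial)
  dt <- trial_dt(trial)
  span <- diff(range(trial$t_ms)) + dt
  expected <- max(round(span / dt), nrow(trial))
  n_ok <- sum(trial$valid & !trial$removed)
  frac <- (expected - n_ok) / expected
  list(keep = frac <= max_missing_frac, missing_frac = frac)
}

#' Preprocess one trial (blinks, gaps, QC)
#'
#' @inheritParams remove_blinks
#' @inheritParams interpolate_gaps
#' @inheritParams qc_trial
#' @return The cleaned trial with attribute `qc` (the [qc_trial()] result).
#' @export
preprocess_trial <- function(trial, max_gap_ms = 75, blink_min_ms = 75,
                             blink_max_ms = 500, margin_samples = 1L,
                             max_missing_frac = 0.20) {
  trial <- remove_blinks(trial, blink_min_ms, blink_max_ms, margin_samples)
  trial <- interpolate_gaps(trial, max_gap_ms)
  attr(trial, "qc") <- qc_trial(trial, max_missing_frac)
  trial
}

#' Preprocess every trial of a cohort and apply QC drops
#'
#' @param cohort A `gaze_cohort` (or long gaze tibble).
#' @param ... Passed to [preprocess_trial()].
#' @return List with `trials` (kept, cleaned `gaze_trial`s), `dropped`
#'   (tibble of dropped trials with missing fractions) and `subjects`.
#' @export
preprocess_cohort <- function(cohort, ...) {
  trials <- split_trials(cohort)
  cleaned <- lapply(trials, preprocess_trial, ...)
  keep <- vapply(cleaned, function(x) attr(x, "qc")$keep, logical(1))
  frac <- vapply(cleaned, function(x) attr(x, "qc")$missing_frac, numeric(1))
  dropped <- tibble::tibble(
    key = names(cleaned)[!keep],
    missing_frac = frac[!keep]
  )
  list(
    trials = cleaned[keep],
    dropped = dropped,
    missing_frac = frac,
    subjects = if (inherits(cohort, "gaze_cohort")) cohort$subjects else NULL
  )
}
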