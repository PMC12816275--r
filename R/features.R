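#' @name oculomotor-features
#' @title Per-trial oculomotor features
#'
#' @description Eleven per-trial features in three families.
#' Saccadic: mean vectorial saccade velocity (deg/s), mean vectorial
#' amplitude (deg), inflection count, mean vectorial peak velocity (deg/s),
#' velocity waveform indicator (regression slope relating per-saccade mean
#' and peak velocity). Fixation: mean fixation duration (ms), fixation
#' count, regions of interest (data-driven fixation clusters receiving
#' concentrated attention). Scanpath: Shannon entropy of gaze dispersion
#' over a screen grid (bits), scanpath length (deg) and scanpath area
#' (deg^2, convex hull of fixation centroids).
#'
#' Features that are undefined on a trial (e.g. saccade means with zero
#' saccades) are reported as `NA`, never as zero.
NULL

#' Feature family membership
#'
#' @return Named list mapping family (`saccadic`, `fixation`, `scanpath`)
#'   to feature column names.
#' @export
feature_families <- function() {
  list(
    saccadic = c("mean_saccade_velocity", "mean_saccade_amplitude",
                 "inflection_count", "mean_saccade_peak_velocity",
                 "velocity_waveform_indicator"),
    fixation = c("mean_fixation_duration", "fixation_count", "roi_count"),
    scanpath = c("shannon_entropy", "scanpath_length", "scanpath_area")
  )
}

#' Saccade summary features
#'
#' Arithmetic means of per-saccade mean velocity, amplitude and peak
#' velocity. All three are `NA` when the trial has no saccades.
#'
#' @param events An `oculomotor_events` object (or its `saccades` tibble).
#' @return Named numeric vector `mean_velocity`, `mean_amplitude`,
#'   `mean_peak_velocity`.
#' @export
saccade_summary <- function(events) {
  s <- if (inherits(events, "oculomotor_events")) events$saccades else events
  if (!NROW(s)) {
    return(c(mean_velocity = NA_real_, mean_amplitude = NA_real_,
             mean_peak_velocity = NA_real_))
  }
  c(mean_velocity = mean(s$mean_velocity),
    mean_amplitude = mean(s$amplitude),
    mean_peak_velocity = mean(s$peak_velocity))
}

#' Velocity waveform indicator
#'
#' Ordinary least-squares slope (with intercept) relating per-saccade mean
#' and peak velocity. The default regresses mean velocity on peak velocity,
#' which yields the sub-unity slopes typical of group summaries of this
#' statistic; `orientation = "peak_on_mean"` swaps the axes.
#'
#' @param saccades Saccade tibble or `oculomotor_events`.
#' @param orientation `"mean_on_peak"` (default) or `"peak_on_mean"`.
#' @return Slope, or `NA` with fewer than 3 saccades or a degenerate
#'   predictor.
#' @export
velocity_waveform_indicator <- function(saccades,
                                        orientation = c("mean_on_peak",
                                                        "peak_on_mean")) {
  orientation <- match.arg(orientation)
  s <- if (inherits(saccades, "oculomotor_events")) saccades$saccades else saccades
  if (NROW(s) < 3) return(NA_real_)
  if (orientation == "mean_on_peak") {
    xx <- s$peak_velocity; yy <- s$mean_velocity
  } else {
    xx <- s$mean_velocity; yy <- s$peak_velocity
  }
  ok <- is.finite(xx) & is.finite(yy)
  xx <- xx[ok]; yy <- yy[ok]
  # a predictor spread below 1% of its level is degenerate: the slope is
  # dominated by noise and can take arbitrarily extreme values
  if (length(xx) < 3 || stats::sd(xx) <= 0.01 * abs(mean(xx))) {
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(yy ~ xx))[2])
}

#' Inflection count
#'
#' Number of directional changes across consecutive saccades: sign changes
#' of the horizontal displacement component plus sign changes of the
#' vertical component. Components with magnitude below `jitter_floor_px`
#' inherit the preceding sign, so tracker noise does not create spurious
#' reversals.
#'
#' @param saccades Saccade tibble or `oculomotor_events`.
#' @param jitter_floor_px Magnitude below which a component inherits the
#'   previous sign.
#' @return Integer count (0 with fewer than 2 saccades).
#' @export
inflection_count <- function(saccades, jitter_floor_px = 1) {
  s <- if (inherits(saccades, "oculomotor_events")) saccades$saccades else saccades
  if (NROW(s) < 2) return(0L)
  count_changes <- function(comp) {
    sg <- ifelse(abs(comp) < jitter_floor_px, 0L, sign(comp))
    # zeros inherit the previous sign
    for (i in seq_along(sg)) {
      if (sg[i] == 0L) sg[i] <- if (i > 1) sg[i - 1] else 0L
    }
    sg <- sg[sg != 0L]
    if (length(sg) < 2) return(0L)
    sum(diff(sg) != 0L)
  }
  count_changes(s$dx) + count_changes(s$dy)
}

#' Fixation summary features
#'
#' @param events An `oculomotor_events` object (or its `fixations` tibble).
#' @return Named vector `mean_duration` (ms; `NA` with zero fixations) and
#'   `count`.
#' @export
fixation_summary <- function(events) {
  f <- if (inherits(events, "oculomotor_events")) events$fixations else events
  if (!NROW(f)) return(c(mean_duration = NA_real_, count = 0))
  c(mean_duration = mean(f$duration), count = NROW(f))
}

#' Regions of interest receiving concentrated attention
#'
#' Single-linkage clustering of fixation centroids at `link_radius_deg`;
#' counts clusters containing at least `min_members` fixations. This is a
#' data-driven feature, distinct from the fixed reliability AOI rectangle.
#'
#' @param fixations Fixation tibble or `oculomotor_events`.
#' @param link_radius_deg Single-linkage merge radius (deg).
#' @param min_members Minimum cluster size to count as a region.
#' @param geom A [screen_geometry()].
#' @return Integer count of regions.
#' @export
roi_count <- function(fixations, link_radius_deg = 2.0, min_members = 2L,
                      geom = screen_geometry()) {
  f <- if (inherits(fixations, "oculomotor_events")) fixations$fixations else fixations
  n <- NROW(f)
  if (n == 0) return(0L)
  if (n == 1) return(as.integer(1L >= min_members))
  ppd <- deg_to_px(1, geom)  # small-angle planar degree coordinates
  cl <- stats::cutree(stats::hclust(stats::dist(cbind(f$x, f$y) / ppd),
                                    method = "single"),
                      h = link_radius_deg)
  sum(table(cl) >= min_members)
}

#' Shannon entropy of gaze dispersion
#'
#' The screen is partitioned into a `grid[1] x grid[2]` array of equal
#' cells; with `p_i` the fraction of fixations in cell `i`, the entropy is
#' `-sum(p_i log2 p_i)` over occupied cells. Higher values indicate more
#' dispersed, irregular exploration.
#'
#' @param fixations Fixation tibble or `oculomotor_events`.
#' @param grid `c(rows, cols)` partition of the screen.
#' @param geom A [screen_geometry()].
#' @return Entropy in bits (`NA` with zero fixations).
#' @export
shannon_entropy <- function(fixations, grid = c(8L, 8L),
                            geom = screen_geometry()) {
  f <- if (inherits(fixations, "oculomotor_events")) fixations$fixations else fixations
  if (!NROW(f)) return(NA_real_)
  rows <- grid[1]; cols <- grid[2]
  cx <- pmin(pmax(ceiling(f$x / (geom$width_px / cols)), 1L), cols)
  cy <- pmin(pmax(ceiling(f$y / (geom$height_px / rows)), 1L), rows)
  p <- as.numeric(table(paste(cy, cx))) / NROW(f)
  -sum(p * log2(p))
}

#' Scanpath length
#'
#' Sum of vectorial (Euclidean) distances between consecutive fixation
#' centroids, in degrees.
#'
#' @inheritParams shannon_entropy
#' @return Length in deg (0 with fewer than 2 fixations).
#' @export
scanpath_length <- function(fixations, geom = screen_geometry()) {
  f <- if (inherits(fixations, "oculomotor_events")) fixations$fixations else fixations
  n <- NROW(f)
  if (n < 2) return(0)
  sum(px_to_deg(diff(f$x), diff(f$y), geom))
}

#' Scanpath area
#'
#' Area of the convex hull of the fixation centroids, in squared degrees
#' (small-angle planar coordinates about the screen centre). Zero for
#' fewer than 3 non-collinear fixations.
#'
#' @inheritParams shannon_entropy
#' @return Area in deg^2.
#' @export
scanpath_area <- function(fixations, geom = screen_geometry()) {
  f <- if (inherits(fixations, "oculomotor_events")) fixations$fixations else fixations
  n <- NROW(f)
  if (n < 3) return(0)
  px_per_deg <- deg_to_px(1, geom)
  x <- f$x / px_per_deg
  y <- f$y / px_per_deg
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  shoelace(x[h], y[h])
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Compute the 11 per-trial features from detected events
#'
#' @param events An `oculomotor_events` object.
#' @param geom A [screen_geometry()].
#' @param units `"deg"` (default) or `"px"`. Velocity, amplitude, length
#'   and area features are reported in the chosen unit system (`px`,
#'   `px/s`, `px^2`); durations, counts and entropy are unit-free.
#' @param entropy_grid,roi_link_deg,roi_min_members,vwi_orientation
#'   Feature tuning knobs, see the individual feature functions.
#' @return One-row tibble with the 11 feature columns.
#' @export
trial_features <- function(events, geom = screen_geometry(),
                           units = c("deg", "px"),
                           entropy_grid = c(8L, 8L),
                           roi_link_deg = 2.0, roi_min_members = 2L,
                           vwi_orientation = "mean_on_peak") {
  units <- match.arg(units)
  sac <- saccade_summary(events)
  fix <- fixation_summary(events)
  px_per_deg <- deg_to_px(1, geom)
  u <- if (units == "px") px_per_deg else 1
  tibble::tibble(
    mean_saccade_velocity = sac[["mean_velocity"]] * u,
    mean_saccade_amplitude = sac[["mean_amplitude"]] * u,
    inflection_count = inflection_count(events),
    mean_saccade_peak_velocity = sac[["mean_peak_velocity"]] * u,
    velocity_waveform_indicator =
      velocity_waveform_indicator(events, vwi_orientation),
    mean_fixation_duration = fix[["mean_duration"]],
    fixation_count = fix[["count"]],
    roi_count = roi_count(events, roi_link_deg, roi_min_members, geom),
    shannon_entropy = shannon_entropy(events, entropy_grid, geom),
    scanpath_length = scanpath_length(events, geom) * u,
    scanpath_area = scanpath_area(events, geom) * u^2
  )
}

#' Extract per-trial features for a whole cohort
#'
#' Runs preprocessing, event detection and feature computation over every
#' trial and returns a tidy feature table.
#'
#' @param cohort A `gaze_cohort`, long gaze tibble, or the result of
#'   [preprocess_cohort()].
#' @param geom A [screen_geometry()].
#' @param preprocess Apply [preprocess_cohort()] first (set `FALSE` if
#'   `cohort` is already preprocessed).
#' @param detect_args,preprocess_args,feature_args Named lists of extra
#'   arguments for [detect_events()], [preprocess_cohort()] and
#'   [trial_features()].
#' @return Tibble with `subject_id`, `trial_id`, `stimulus_id`, the 11
#'   features, and `n_fixations`/`n_saccades` bookkeeping columns. The
#'   detected events are attached as `attr(, "events")` (named list).
#' @export
extract_features <- function(cohort, geom = screen_geometry(),
                             preprocess = TRUE,
                             detect_args = list(),
                             preprocess_args = list(),
                             feature_args = list()) {
  pp <- if (inherits(cohort, "gaze_cohort") || is.data.frame(cohort)) {
    if (preprocess) {
      do.call(preprocess_cohort, c(list(cohort), preprocess_args))
    } else {
      list(trials = split_trials(cohort), subjects = NULL)
    }
  } else {
    cohort  # already a preprocess_cohort() result
  }
  trials <- pp$trials
  events <- lapply(trials, function(tr) {
    do.call(detect_events, c(list(tr, geom = geom), detect_args))
  })
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    ft <- do.call(trial_features, c(list(events[[i]], geom = geom),
                                    feature_args))
    dplyr::bind_cols(
      tibble::tibble(subject_id = tr$subject_id[1],
                     trial_id = tr$trial_id[1],
                     stimulus_id = tr$stimulus_id[1]),
      ft,
      tibble::tibble(n_fixations = nrow(events[[i]]$fixations),
                     n_saccades = nrow(events[[i]]$saccades))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "events") <- stats::setNames(events, names(trials))
  out
}
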