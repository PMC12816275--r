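#' Segment a gaze trial into fixations and saccades
#'
#' Velocity-threshold identification (I-VT): point-to-point angular
#' velocities are computed by central differences on usable samples and
#' compared against `velocity_threshold_deg_s`. Contiguous sub-threshold
#' runs become fixation candidates (retained when their duration reaches
#' `min_fixation_ms`; centroid = mean position); the intervals between
#' consecutive retained fixations become saccades, with amplitude defined
#' centroid-to-centroid, mean velocity = amplitude / duration and peak
#' velocity = the maximum point velocity inside the interval. Candidates
#' separated by removed (blink) or lost samples never merge across the gap.
#' Adjacent retained fixations closer than `merge_dist_deg` and separated
#' by less than `merge_gap_ms` are merged, which suppresses splits caused
#' by single noisy velocity samples at low sampling rates.
#'
#' A dispersion-based detector (I-DT) is available via `detector = "idt"`:
#' windows whose x+y dispersion stays below `dispersion_threshold_deg` and
#' whose duration reaches `min_fixation_ms` become fixations.
#'
#' @param trial A preprocessed `gaze_trial`.
#' @param geom A [screen_geometry()].
#' @param velocity_threshold_deg_s I-VT velocity threshold (deg/s).
#' @param min_fixation_ms Minimum fixation duration (ms).
#' @param detector `"ivt"` (default) or `"idt"`.
#' @param dispersion_threshold_deg I-DT dispersion threshold (deg).
#' @param merge_dist_deg,merge_gap_ms Post-hoc fixation merge rule.
#' @param reattach_dist_deg Positional tolerance for reclaiming boundary
#'   samples whose velocity estimate was contaminated by an adjacent
#'   saccade (central differences span the ramp) but whose position still
#'   lies on the fixation.
#' @return An `oculomotor_events` object: list with `fixations`
#'   (onset, offset, duration, x, y, n_samples) and `saccades`
#'   (onset, offset, duration, dx, dy, amplitude, mean_velocity,
#'   peak_velocity; amplitudes in degrees).
#' @export
detect_events <- function(trial, geom = screen_geometry(),
                          velocity_threshold_deg_s = 30,
                          min_fixation_ms = 60,
                          detector = c("ivt", "idt"),
                          dispersion_threshold_deg = 1,
                          merge_dist_deg = 0.7, merge_gap_ms = 75,
                          reattach_dist_deg = 0.05) {
  detector <- match.arg(detector)
  trial <- ensure_preproc_cols(trial)
  dt <- trial_dt(trial)
  ok <- trial$valid & !trial$removed
  if (sum(ok) < 2) {
    warning("fewer than 2 usable samples; no events detected")
    return(empty_events())
  }
  # segments of consecutive usable samples (events never span a gap)
  seg_id <- cumsum(c(TRUE, diff(which(ok)) > 1L))
  idx_ok <- which(ok)
  segs <- split(idx_ok, seg_id)

  fixes <- list(); sacs <- list()
  for (seg in segs) {
    if (length(seg) < 3) next
    t <- trial$t_ms[seg]; x <- trial$x_px[seg]; y <- trial$y_px[seg]
    res <- if (detector == "ivt") {
      segment_ivt(t, x, y, dt, geom, velocity_threshold_deg_s,
                  min_fixation_ms, merge_dist_deg, merge_gap_ms,
                  reattach_dist_deg)
    } else {
      segment_idt(t, x, y, dt, geom, dispersion_threshold_deg,
                  min_fixation_ms)
    }
    fixes[[length(fixes) + 1L]] <- res$fixations
    sacs[[length(sacs) + 1L]] <- res$saccades
  }
  fixations <- dplyr::bind_rows(fixes)
  saccades <- dplyr::bind_rows(sacs)
  structure(list(fixations = tibble::as_tibble(fixations),
                 saccades = tibble::as_tibble(saccades),
                 detector = detector),
            class = "oculomotor_events")
}

empty_events <- function() {
  structure(list(
    fixations = tibble::tibble(onset = numeric(0), offset = numeric(0),
                               duration = numeric(0), x = numeric(0),
                               y = numeric(0), n_samples = integer(0)),
    saccades = tibble::tibble(onset = numeric(0), offset = numeric(0),
                              duration = numeric(0), dx = numeric(0),
                              dy = numeric(0), amplitude = numeric(0),
                              mean_velocity = numeric(0),
                              peak_velocity = numeric(0)),
    detector = NA_character_
  ), class = "oculomotor_events")
}

#' @export
print.oculomotor_events <- function(x, ...) {
  cat(sprintf("<oculomotor_events> %d fixations, %d saccades (%s)\n",
              nrow(x$fixations), nrow(x$saccades), x$detector))
  invisible(x)
}

point_velocity_deg_s <- function(t, x, y, geom) {
  n <- length(t)
  v <- numeric(n)
  if (n >= 3) {
    i <- 2:(n - 1)
    v[i] <- px_to_deg(x[i + 1] - x[i - 1], y[i + 1] - y[i - 1], geom) /
      ((t[i + 1] - t[i - 1]) / 1000)
  }
  v[1] <- px_to_deg(x[2] - x[1], y[2] - y[1], geom) / ((t[2] - t[1]) / 1000)
  v[n] <- px_to_deg(x[n] - x[n - 1], y[n] - y[n - 1], geom) /
    ((t[n] - t[n - 1]) / 1000)
  v
}

segment_ivt <- function(t, x, y, dt, geom, vthr, min_fix_ms,
                        merge_dist_deg, merge_gap_ms, reattach_dist_deg) {
  v <- point_velocity_deg_s(t, x, y, geom)
  sub <- v < vthr
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(cand)) {
    cand$onset <- t[cand$start]
    cand$offset <- t[cand$end] + dt
    cand <- cand[cand$offset - cand$onset >= min_fix_ms, , drop = FALSE]
  }
  # merge adjacent candidates split by transient velocity noise
  if (nrow(cand) >= 2) {
    keep <- TRUE
    i <- 1L
    merged <- cand[0, ]
    curr <- cand[1, ]
    for (j in seq_len(nrow(cand))[-1]) {
      cx1 <- mean(x[curr$start:curr$end]); cy1 <- mean(y[curr$start:curr$end])
      cx2 <- mean(x[cand$start[j]:cand$end[j]])
      cy2 <- mean(y[cand$start[j]:cand$end[j]])
      gap <- cand$onset[j] - curr$offset
      if (gap < merge_gap_ms &&
          px_to_deg(cx2 - cx1, cy2 - cy1, geom) < merge_dist_deg) {
        curr$end <- cand$end[j]
        curr$offset <- cand$offset[j]
      } else {
        merged <- rbind(merged, curr)
        curr <- cand[j, ]
      }
    }
    cand <- rbind(merged, curr)
  }
  # boundary reattachment: a sample flanking a retained run carries a
  # velocity estimate contaminated by the adjacent saccade (central
  # difference spans the ramp) even when its position still lies on the
  # fixation; reclaim such samples by position so durations are unbiased
  if (nrow(cand)) {
    thr_px <- deg_to_px(reattach_dist_deg, geom)
    n <- length(t)
    for (i in seq_len(nrow(cand))) {
      cx_ <- mean(x[cand$start[i]:cand$end[i]])
      cy_ <- mean(y[cand$start[i]:cand$end[i]])
      lo_lim <- if (i > 1) cand$end[i - 1] + 1L else 1L
      while (cand$start[i] > lo_lim &&
             sqrt((x[cand$start[i] - 1L] - cx_)^2 +
                    (y[cand$start[i] - 1L] - cy_)^2) < thr_px) {
        cand$start[i] <- cand$start[i] - 1L
      }
      hi_lim <- if (i < nrow(cand)) cand$start[i + 1] - 1L else n
      while (cand$end[i] < hi_lim &&
             sqrt((x[cand$end[i] + 1L] - cx_)^2 +
                    (y[cand$end[i] + 1L] - cy_)^2) < thr_px) {
        cand$end[i] <- cand$end[i] + 1L
      }
    }
    cand$onset <- t[cand$start]
    cand$offset <- t[cand$end] + dt
  }
  events_from_candidates(cand, t, x, y, v, geom)
}

segment_idt <- function(t, x, y, dt, geom, disp_thr, min_fix_ms) {
  n <- length(t)
  min_len <- max(2L, ceiling(min_fix_ms / dt))
  in_fix <- rep(FALSE, n)
  i <- 1L
  cand <- data.frame(start = integer(0), end = integer(0))
  while (i + min_len - 1L <= n) {
    j <- i + min_len - 1L
    win <- i:j
    disp <- function(w) px_to_deg(diff(range(x[w])), 0, geom) +
      px_to_deg(diff(range(y[w])), 0, geom)
    if (disp(win) <= disp_thr) {
      while (j < n && disp(i:(j + 1L)) <= disp_thr) j <- j + 1L
      cand <- rbind(cand, data.frame(start = i, end = j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (nrow(cand)) {
    cand$onset <- t[cand$start]
    cand$offset <- t[cand$end] + dt
  }
  v <- point_velocity_deg_s(t, x, y, geom)
  events_from_candidates(cand, t, x, y, v, geom)
}

events_from_candidates <- function(cand, t, x, y, v, geom) {
  if (!nrow(cand)) {
    e <- empty_events()
    return(list(fixations = e$fixations, saccades = e$saccades))
  }
  fx <- vapply(seq_len(nrow(cand)),
               function(i) mean(x[cand$start[i]:cand$end[i]]), numeric(1))
  fy <- vapply(seq_len(nrow(cand)),
               function(i) mean(y[cand$start[i]:cand$end[i]]), numeric(1))
  fixations <- tibble::tibble(
    onset = cand$onset, offset = cand$offset,
    duration = cand$offset - cand$onset,
    x = fx, y = fy, n_samples = cand$end - cand$start + 1L
  )
  k <- nrow(fixations)
  if (k < 2) {
    return(list(fixations = fixations, saccades = empty_events()$saccades))
  }
  i <- seq_len(k - 1L)
  onset <- fixations$offset[i]
  offset <- fixations$onset[i + 1L]
  dur <- offset - onset
  dx <- fx[i + 1L] - fx[i]
  dy <- fy[i + 1L] - fy[i]
  amp <- px_to_deg(dx, dy, geom)
  meanv <- amp / (dur / 1000)
  # the window includes the flanking fixation-boundary samples: their
  # central-difference velocities span the ramp and carry the peak
  peakv <- vapply(seq_len(k - 1L), function(j) {
    max(v[cand$end[j]:cand$start[j + 1L]])
  }, numeric(1))
  saccades <- tibble::tibble(
    onset = onset, offset = offset, duration = dur, dx = dx, dy = dy,
    amplitude = amp, mean_velocity = meanv, peak_velocity = peakv
  )
  # boundary reattachment can close a gap completely; a zero-length
  # transition is not a saccade
  saccades <- saccades[saccades$duration > 0, , drop = FALSE]
  list(fixations = fixations, saccades = saccades)
}
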