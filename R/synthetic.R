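#' Specification of a synthetic two-cohort free-viewing experiment
#'
#' Bundles every tunable of the gaze simulator: cohort sizes, trial timing,
#' sampling rate, the multiplicative group effects applied to the impaired
#' cohort, artifact rates, and the spatial layout parameters that control
#' where fixations land on the (face-like) stimulus.
#'
#' Group effects are expressed as multiplicative factors applied to the
#' impaired ("case") group: a fixation-duration factor above 1 lengthens
#' fixations, a saccade-amplitude factor below 1 makes the anchor-to-anchor
#' walk more local (smaller saccades, shorter scanpaths), a saccade-rate
#' factor below 1 suppresses saccade initiation (fewer, longer fixations),
#' an exploration-extent factor below 1 contracts the stimulus layout about
#' the screen centre (smaller scanpath area), a saccade-speed factor below 1
#' slows saccades (lower velocities), and a velocity-shape factor below 1
#' flattens the saccadic velocity profile (raising the mean-to-peak velocity
#' ratio). Defaults follow the ratios of the printed group means of the
#' clinical comparison the simulator emulates; see the package vignette.
#'
#' @param n_subjects_per_group Subjects per group; length 1 (both groups) or
#'   2 (`c(control, case)`).
#' @param n_trials Trials (= stimuli) per subject.
#' @param trial_duration_ms Trial length in ms.
#' @param sampling_hz Nominal sampling rate.
#' @param group_effects Named list of multiplicative factors for the case
#'   group (see Details); partial lists are merged over the defaults.
#' @param blink_rate_per_s Poisson rate of blink artifacts (100-300 ms
#'   validity-0 runs).
#' @param missing_frac Fraction of additional samples dropped at random,
#'   in `[0, 1)`.
#' @param base_fixation_ms Median-scale fixation duration of the control
#'   group (log-normal mean).
#' @param fixation_sigma Log-normal sdlog of fixation durations.
#' @param n_anchors Number of gaze anchor points on the stimulus.
#' @param subject_offset_sd_px SD of per-subject idiosyncratic anchor
#'   offsets (drives intra- over inter-individual scanpath similarity).
#' @param stimulus_jitter_sd_px SD of per-stimulus anchor perturbations.
#' @param locality_scale_deg Spatial scale of the anchor-to-anchor walk;
#'   larger values give more uniform exploration.
#' @param noise_sd_px Within-fixation sample jitter SD (tracker noise).
#' @param refix_scatter_px SD of the per-fixation landing scatter around an
#'   anchor.
#' @param subject_sd Log-scale SD of the per-subject random effects on
#'   fixation duration, walk locality and saccade speed.
#' @param seed Integer seed; identical spec + seed gives identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group = 20L,
                        n_trials = 10L,
                        trial_duration_ms = 10000,
                        sampling_hz = 90,
                        group_effects = list(),
                        blink_rate_per_s = 0.15,
                        missing_frac = 0.02,
                        base_fixation_ms = 280,
                        fixation_sigma = 0.35,
                        n_anchors = 14L,
                        subject_offset_sd_px = 130,
                        subject_shift_sd_px = 40,
                        stimulus_jitter_sd_px = 30,
                        locality_scale_deg = 2.5,
                        extent_knee_px = 260,
                        noise_sd_px = 6,
                        refix_scatter_px = 25,
                        subject_sd = 0.15,
                        seed = 1L) {
  defaults <- list(
    fixation_duration  = 1.08,  # longer fixations in the impaired group
    saccade_amplitude  = 0.86,  # smaller saccades / shorter scanpaths
    saccade_rate       = 0.97,  # fewer saccades per second
    exploration_extent = 0.65,  # compressed peripheral exploration
    saccade_speed      = 0.80,  # slower saccades
    velocity_shape     = 0.37,  # flatter velocity waveform
    heterogeneity      = 2.5,   # more idiosyncratic spatial layouts
    landing_scatter    = 1.30   # larger fixation landing error
  )
  unknown <- setdiff(names(group_effects), names(defaults))
  if (length(unknown)) {
    stop("unknown group_effects: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ge <- utils::modifyList(defaults, group_effects)

  n_grp <- rep_len(as.integer(n_subjects_per_group), 2L)
  spec <- list(
    n_subjects_per_group = n_grp,
    n_trials = as.integer(n_trials),
    trial_duration_ms = trial_duration_ms,
    sampling_hz = sampling_hz,
    group_effects = ge,
    blink_rate_per_s = blink_rate_per_s,
    missing_frac = missing_frac,
    base_fixation_ms = base_fixation_ms,
    fixation_sigma = fixation_sigma,
    n_anchors = as.integer(n_anchors),
    subject_offset_sd_px = subject_offset_sd_px,
    subject_shift_sd_px = subject_shift_sd_px,
    stimulus_jitter_sd_px = stimulus_jitter_sd_px,
    locality_scale_deg = locality_scale_deg,
    extent_knee_px = extent_knee_px,
    noise_sd_px = noise_sd_px,
    refix_scatter_px = refix_scatter_px,
    subject_sd = subject_sd,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(
    all(spec$n_subjects_per_group > 0), spec$n_trials > 0,
    spec$trial_duration_ms > 0, spec$sampling_hz > 0,
    spec$n_anchors > 0, spec$base_fixation_ms > 0, spec$fixation_sigma > 0,
    spec$blink_rate_per_s >= 0,
    spec$missing_frac >= 0, spec$missing_frac < 1,
    all(unlist(spec$group_effects) > 0)
  )
  worst_fix <- spec$base_fixation_ms * max(1, spec$group_effects$fixation_duration)
  if (worst_fix >= spec$trial_duration_ms) {
    stop("impossible schedule: mean fixation duration >= trial duration",
         call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d + %d subjects, %d trials x %.1f s at %g Hz, seed %d\n",
    x$n_subjects_per_group[1], x$n_subjects_per_group[2],
    x$n_trials, x$trial_duration_ms / 1000, x$sampling_hz, x$seed
  ))
  ge <- unlist(x$group_effects)
  cat("  case-group effects:",
      paste(sprintf("%s=%.2f", names(ge), ge), collapse = ", "), "\n")
  invisible(x)
}

# Canonical face-like anchor layout (px offsets from screen centre, y down):
# eyes, brows, nose, mouth corners and centre, chin, forehead. Shared across
# stimuli so a viewer meets a comparable layout on every face.
face_template <- function(k = 10L) {
  pts <- matrix(c(
    -110,  -70,   # left eye
     110,  -70,   # right eye
    -110, -130,   # left brow
     110, -130,   # right brow
       0,   10,   # nose
     -70,  110,   # left mouth corner
      70,  110,   # right mouth corner
       0,  120,   # mouth centre
       0,  190,   # chin
       0, -185    # forehead
  ), ncol = 2, byrow = TRUE) * 1.25
  if (k <= nrow(pts)) return(pts[seq_len(k), , drop = FALSE])
  extra <- k - nrow(pts)
  ang <- seq(0, 2 * pi, length.out = extra + 1L)[-1L]
  rbind(pts, cbind(290 * cos(ang), 250 * sin(ang)))
}

resolve_effects <- function(spec, group) {
  ge <- spec$group_effects
  if (identical(group, "case")) {
    list(dur = ge$fixation_duration, amp = ge$saccade_amplitude,
         rate = ge$saccade_rate, extent = ge$exploration_extent,
         speed = ge$saccade_speed, shape = 3 * ge$velocity_shape,
         scatter = ge$landing_scatter)
  } else {
    list(dur = 1, amp = 1, rate = 1, extent = 1, speed = 1, shape = 3,
         scatter = 1)
  }
}

# het > 1 amplifies the subject-specific whole-layout translation
# (case-group lesion heterogeneity: individual exploration patterns
# diverge more across subjects without widening any one subject's own
# spatial coverage)
draw_subject_params <- function(spec, het = 1) {
  k <- spec$n_anchors
  shift <- stats::rnorm(2, 0, spec$subject_shift_sd_px * het)
  list(
    offsets = matrix(stats::rnorm(2L * k, 0, spec$subject_offset_sd_px),
                     ncol = 2) + rep(shift, each = k),
    weights = {
      w <- stats::rexp(k) + 0.25
      w / sum(w)
    },
    dur = stats::rlnorm(1, -spec$subject_sd^2 / 2, spec$subject_sd),
    loc = stats::rlnorm(1, -spec$subject_sd^2 / 2, spec$subject_sd),
    speed = stats::rlnorm(1, -spec$subject_sd^2 / 2, spec$subject_sd)
  )
}

draw_stimulus_params <- function(spec) {
  k <- spec$n_anchors
  matrix(stats::rnorm(2L * k, 0, spec$stimulus_jitter_sd_px), ncol = 2)
}

# Core single-trial generator. Each trial's fixation anchors are drawn
# i.i.d. from the subject's anchor-preference weights, so the spatial
# occupancy distribution is identical in law across groups (the dispersion
# null the downstream entropy comparison relies on). The drawn multiset is
# then ordered by a greedy locality tour (next target chosen among the
# remaining draws with probability decaying in distance), so the
# saccade-amplitude factor shapes sequencing -- saccade sizes, scanpath
# length -- without touching where gaze mass lands. Consecutive draws of
# the same anchor collapse into one prolonged fixation, and the
# saccade-rate factor suppresses saccade initiation by merging scheduled
# fixations into their predecessor.
sim_trial_impl <- function(spec, eff, subj, stim_jitter, geom,
                           subject_id, trial_id, stimulus_id) {
  dt <- 1000 / spec$sampling_hz
  n <- floor(spec$trial_duration_ms / dt)
  t <- (seq_len(n) - 1L) * dt
  cx <- geom$width_px / 2
  cy <- geom$height_px / 2

  anchors <- face_template(spec$n_anchors) + stim_jitter + subj$offsets
  # the extent factor compresses eccentricity beyond a knee radius about
  # the layout centroid: peripheral excursions (which define the scanpath
  # hull) contract while the central fixation mass -- and with it the
  # grid-cell occupancy that drives gaze entropy -- is left in place
  if (eff$extent != 1) {
    ctr <- colMeans(anchors)
    rel <- sweep(anchors, 2, ctr)
    r <- sqrt(rowSums(rel^2))
    knee <- spec$extent_knee_px
    sc <- ifelse(r <= knee | r == 0, 1,
                 (knee + (r - knee) * eff$extent) / r)
    anchors <- sweep(rel * sc, 2, ctr, "+")
  }
  anchors <- cbind(cx + anchors[, 1], cy + anchors[, 2])
  k <- nrow(anchors)
  # quadratic response calibrates the amplitude factor to transfer roughly
  # one-to-one onto the measured mean saccade amplitude
  lambda_px <- max(deg_to_px(spec$locality_scale_deg, geom) *
                     eff$amp^2 * subj$loc, 1)

  mean_fix <- spec$base_fixation_ms * eff$dur * subj$dur
  meanlog <- log(mean_fix) - spec$fixation_sigma^2 / 2
  mean_sac <- 35 / (eff$speed * subj$speed)  # scheduling approximation

  # duration schedule: fixation count m emerges from durations and the
  # saccade-rate factor
  fdur <- numeric(0)
  elapsed <- 0
  while (elapsed < spec$trial_duration_ms) {
    d <- stats::rlnorm(1, meanlog, spec$fixation_sigma)
    if (length(fdur) && stats::runif(1) > eff$rate) {
      fdur[length(fdur)] <- fdur[length(fdur)] + d   # prolonged fixation
      elapsed <- elapsed + d
    } else {
      fdur <- c(fdur, d)
      elapsed <- elapsed + d + mean_sac
    }
  }
  m <- length(fdur)

  # i.i.d. anchor draws, then greedy locality ordering; repeated draws of
  # an anchor stay separate fixations (refixations within a region)
  draws <- sample.int(k, m, replace = TRUE, prob = subj$weights)
  if (m > 1) {
    pos <- anchors[draws, , drop = FALSE]
    ord <- integer(m)
    remaining <- seq_len(m)
    pick <- sample.int(m, 1)
    for (i in seq_len(m)) {
      ord[i] <- pick
      remaining <- remaining[remaining != pick]
      if (!length(remaining)) break
      dd <- sqrt((pos[remaining, 1] - pos[pick, 1])^2 +
                   (pos[remaining, 2] - pos[pick, 2])^2)
      # refixations (duplicate draws of the current anchor) are scheduled
      # neutrally, so their adjacency does not depend on the locality scale
      if (any(dd >= 1)) dd[dd < 1] <- stats::median(dd[dd >= 1])
      w <- exp(-dd / lambda_px)
      pick <- remaining[sample.int(length(remaining), 1,
                                   prob = w / sum(w))]
    }
    draws <- draws[ord]
  }
  targets <- anchors[draws, , drop = FALSE] +
    matrix(stats::rnorm(2L * m, 0, spec$refix_scatter_px * eff$scatter),
           ncol = 2)
  fx <- targets[, 1]; fy <- targets[, 2]

  # actual saccade durations from the realized amplitudes (main sequence)
  amp_deg <- if (m > 1) px_to_deg(diff(fx), diff(fy), geom) else numeric(0)
  sdur <- c((2.2 * amp_deg + 21) / (eff$speed * subj$speed), 0)
  # truncate the event sequence at the trial boundary
  ends <- cumsum(fdur + sdur)
  last <- which(ends - sdur >= spec$trial_duration_ms)[1]
  if (!is.na(last)) {
    fx <- fx[seq_len(last)]; fy <- fy[seq_len(last)]
    fdur <- fdur[seq_len(last)]; sdur <- sdur[seq_len(last)]
    sdur[last] <- 0
    fdur[last] <- min(fdur[last],
                      spec$trial_duration_ms - (ends[last] - sdur[last] -
                                                  fdur[last]))
  }

  # lay the schedule onto the sample grid
  x <- y <- rep(NA_real_, n)
  onset <- cumsum(c(0, fdur + sdur))[seq_along(fdur)]
  shape <- max(eff$shape, 1.05)
  for (i in seq_along(fdur)) {
    in_fix <- t >= onset[i] & t < onset[i] + fdur[i]
    nf <- sum(in_fix)
    if (nf) {
      x[in_fix] <- fx[i] + stats::rnorm(nf, 0, spec$noise_sd_px)
      y[in_fix] <- fy[i] + stats::rnorm(nf, 0, spec$noise_sd_px)
    }
    if (sdur[i] > 0 && i < length(fdur)) {
      in_sac <- t >= onset[i] + fdur[i] & t < onset[i] + fdur[i] + sdur[i]
      ns <- sum(in_sac)
      if (ns) {
        tau <- (t[in_sac] - onset[i] - fdur[i]) / sdur[i]
        s <- stats::pbeta(tau, shape, shape)  # symmetric velocity profile
        x[in_sac] <- fx[i] + s * (fx[i + 1] - fx[i])
        y[in_sac] <- fy[i] + s * (fy[i + 1] - fy[i])
      }
    }
  }
  # trailing samples (saccade truncated by trial end) hold the last target
  tail_na <- is.na(x)
  x[tail_na] <- fx[length(fx)]
  y[tail_na] <- fy[length(fy)]
  x <- pmin(pmax(x, 1), geom$width_px)
  y <- pmin(pmax(y, 1), geom$height_px)

  valid <- rep(TRUE, n)
  n_blink <- stats::rpois(1, spec$blink_rate_per_s *
                            spec$trial_duration_ms / 1000)
  if (n_blink > 0) {
    for (b in seq_len(n_blink)) {
      b0 <- stats::runif(1, 0, spec$trial_duration_ms)
      bdur <- stats::runif(1, 100, 300)
      valid[t >= b0 & t < b0 + bdur] <- FALSE
    }
  }
  if (spec$missing_frac > 0) {
    drop <- stats::runif(n) < spec$missing_frac
    valid[drop] <- FALSE
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_

  out <- tibble::tibble(
    subject_id = subject_id, trial_id = trial_id, stimulus_id = stimulus_id,
    t_ms = t, x_px = x, y_px = y, valid = valid
  )
  attr(out, "sampling_hz") <- spec$sampling_hz
  attr(out, "schedule") <- tibble::tibble(
    x = fx, y = fy, onset = onset, duration = fdur, saccade_ms = sdur
  )
  class(out) <- c("gaze_trial", class(out))
  out
}

#' Simulate a single gaze trial
#'
#' Generates one raw 90 Hz-style sample stream alternating fixations
#' (log-normal durations, anchor position plus isotropic jitter) and
#' saccades (symmetric beta-profile position ramps with a main-sequence
#' duration-amplitude rule), with Poisson blink artifacts and random sample
#' loss. The generating fixation schedule is attached as
#' `attr(trial, "schedule")`.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"case"`; the case group receives the
#'   spec's multiplicative group effects.
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param geom A [screen_geometry()].
#' @return A `gaze_trial` tibble with columns `subject_id`, `trial_id`,
#'   `stimulus_id`, `t_ms`, `x_px`, `y_px`, `valid`.
#' @export
simulate_trial <- function(spec, group = c("control", "case"),
                           seed = spec$seed, geom = screen_geometry()) {
  group <- match.arg(group)
  validate_cohort_spec(spec)
  with_seed(seed, {
    subj <- draw_subject_params(spec)
    stim <- draw_stimulus_params(spec)
    sim_trial_impl(spec, resolve_effects(spec, group), subj, stim, geom,
                   subject_id = "S01", trial_id = "T01",
                   stimulus_id = "FACE01")
  })
}

#' Simulate a two-cohort free-viewing experiment
#'
#' Generates `n_subjects_per_group[1]` control and `[2]` case subjects, each
#' viewing the same `n_trials` stimuli. Subjects carry idiosyncratic anchor
#' offsets, anchor-preference weights and multiplicative random effects on
#' fixation duration, walk locality and saccade speed, so that a subject's
#' scanpaths resemble each other across stimuli more than two subjects'
#' scanpaths on the same stimulus.
#'
#' @param spec A [cohort_spec()].
#' @param geom A [screen_geometry()].
#' @return A `gaze_cohort`: list with `samples` (one long gaze tibble),
#'   `subjects` (tibble of `subject_id`, `group`) and the `spec`.
#' @examples
#' spec <- cohort_spec(n_subjects_per_group = 2, n_trials = 2)
#' coh <- simulate_cohort(spec)
#' table(coh$subjects$group)
#' @export
simulate_cohort <- function(spec, geom = screen_geometry()) {
  validate_cohort_spec(spec)
  simulate_cohort_impl(spec, geom)
}

simulate_cohort_impl <- function(spec, geom) {
  on.exit(NULL)
  res <- with_seed(spec$seed, simulate_cohort_body(spec, geom))
  res
}

simulate_cohort_body <- function(spec, geom) {
  n1 <- spec$n_subjects_per_group[1]
  n2 <- spec$n_subjects_per_group[2]
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n1 + n2)),
    group = rep(c("control", "case"), c(n1, n2))
  )
  stims <- lapply(seq_len(spec$n_trials), function(i) draw_stimulus_params(spec))
  trials <- vector("list", nrow(subjects) * spec$n_trials)
  idx <- 1L
  for (s in seq_len(nrow(subjects))) {
    het <- if (subjects$group[s] == "case") {
      spec$group_effects$heterogeneity
    } else 1
    subj <- draw_subject_params(spec, het)
    eff <- resolve_effects(spec, subjects$group[s])
    for (tr in seq_len(spec$n_trials)) {
      trials[[idx]] <- sim_trial_impl(
        spec, eff, subj, stims[[tr]], geom,
        subject_id = subjects$subject_id[s],
        trial_id = sprintf("T%02d", tr),
        stimulus_id = sprintf("FACE%02d", tr)
      )
      idx <- idx + 1L
    }
  }
  samples <- dplyr::bind_rows(lapply(trials, function(x) {
    attributes(x)[c("schedule")] <- NULL
    as.data.frame(x)
  }))
  structure(
    list(samples = tibble::as_tibble(samples), subjects = subjects,
         spec = spec, sampling_hz = spec$sampling_hz),
    class = "gaze_cohort"
  )
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat(sprintf("<gaze_cohort> %d subjects (%s), %d trials, %d samples\n",
              nrow(x$subjects),
              paste(table(x$subjects$group), collapse = " + "),
              length(unique(x$samples$trial_id)), nrow(x$samples)))
  invisible(x)
}

#' Split a gaze cohort (or gaze table) into per-trial objects
#'
#' @param x A `gaze_cohort` or a long gaze tibble.
#' @param sampling_hz Nominal sampling rate attached to each trial.
#' @return Named list of `gaze_trial` tibbles (one per subject x trial).
#' @export
split_trials <- function(x, sampling_hz = NULL) {
  samples <- if (inherits(x, "gaze_cohort")) x$samples else x
  hz <- sampling_hz %||%
    (if (inherits(x, "gaze_cohort")) x$sampling_hz else infer_hz(samples$t_ms))
  key <- paste(samples$subject_id, samples$trial_id, sep = "|")
  parts <- split(samples, factor(key, levels = unique(key)))
  lapply(parts, function(p) {
    p <- tibble::as_tibble(p)
    attr(p, "sampling_hz") <- hz
    class(p) <- c("gaze_trial", class(p))
    p
  })
}

infer_hz <- function(t_ms) {
  dt <- stats::median(diff(sort(unique(t_ms[seq_len(min(2000, length(t_ms)))]))))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate")
  1000 / dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
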