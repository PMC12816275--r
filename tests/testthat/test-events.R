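geom <- make_geom()
dt <- 1000 / 90

test_that("a constant-position trial yields one fixation, no saccades", {
  tr <- build_trial((0:449) * dt, rep(960, 450), rep(540, 450))
  ev <- detect_events(tr, geom)
  expect_equal(nrow(ev$fixations), 1L)
  expect_equal(nrow(ev$saccades), 0L)
  expect_equal(ev$fixations$x, 960)
  expect_equal(ev$fixations$y, 540)
})

test_that("a two-fixation ramp trial is segmented analytically", {
  centers <- rbind(c(800, 500), c(1000, 500))
  tr <- schedule_trial(centers, c(500, 500), sac_ms = 40)
  ev <- detect_events(tr, geom)
  expect_equal(nrow(ev$fixations), 2L)
  expect_equal(nrow(ev$saccades), 1L)
  expect_equal(ev$saccades$dx, 200, tolerance = 1)
  expect_equal(ev$saccades$amplitude, px_to_deg(200, 0, geom),
               tolerance = 0.05)
  # hand-computed peak: central difference across the steepest ramp samples
  x <- tr$x_px; t <- tr$t_ms
  v_hand <- max(px_to_deg(x[-(1:2)] - x[1:(length(x) - 2)], 0, geom) /
                  ((t[-(1:2)] - t[1:(length(t) - 2)]) / 1000))
  expect_equal(ev$saccades$peak_velocity, v_hand, tolerance = 1e-6)
})

test_that("continuous fast motion yields no fixations", {
  n <- 60
  tr <- build_trial((seq_len(n) - 1) * dt, seq(100, 1800, length.out = n),
                    rep(500, n))
  # ~57 deg/s sweep: above the 30 deg/s threshold throughout
  ev <- suppressWarnings(detect_events(tr, geom))
  expect_equal(nrow(ev$fixations), 0L)
})

test_that("fewer than two usable samples yields empty events with a warning", {
  tr <- build_trial(c(0, dt), c(100, NA), c(100, NA),
                    valid = c(TRUE, FALSE))
  expect_warning(ev <- detect_events(tr, geom), "usable")
  expect_equal(nrow(ev$fixations), 0L)
})

test_that("noise-free schedules are recovered exactly", {
  set.seed(21)
  for (r in 1:10) {
    k <- sample(3:6, 1)
    centers <- cbind(runif(k, 400, 1500), runif(k, 200, 900))
    # keep consecutive centers well separated
    for (i in 2:k) {
      while (sqrt(sum((centers[i, ] - centers[i - 1, ])^2)) < 150) {
        centers[i, ] <- c(runif(1, 400, 1500), runif(1, 200, 900))
      }
    }
    durs <- runif(k, 200, 500)
    tr <- schedule_trial(centers, durs, sac_ms = 40)
    ev <- detect_events(tr, geom)
    expect_equal(nrow(ev$fixations), k)
    expect_lt(max(abs(ev$fixations$x - centers[, 1])), 0.5)
    expect_lt(max(abs(ev$fixations$y - centers[, 2])), 0.5)
    expect_lt(max(abs(ev$fixations$duration - durs)), dt + 1e-6)
  }
})

test_that("event segmentation never crosses a removed (blink) gap", {
  n1 <- 40; nb <- 14; n2 <- 40
  n <- n1 + nb + n2
  tr <- build_trial((seq_len(n) - 1) * dt, rep(900, n), rep(500, n),
                    valid = c(rep(TRUE, n1), rep(FALSE, nb), rep(TRUE, n2)))
  tr <- remove_blinks(tr)            # ~155 ms gap -> blink
  ev <- detect_events(tr, geom)
  expect_equal(nrow(ev$fixations), 2L)   # same position, but not merged
  expect_equal(nrow(ev$saccades), 0L)    # no saccade across the blink
})

test_that("event counts and durations respect the trial envelope", {
  spec <- cohort_spec(n_subjects_per_group = 1, n_trials = 1, seed = 13)
  tr <- preprocess_trial(simulate_trial(spec, "control", seed = 13))
  ev <- detect_events(tr, geom)
  expect_lte(abs(nrow(ev$fixations) - nrow(ev$saccades)), 1L)
  expect_lte(sum(ev$fixations$duration) + sum(ev$saccades$duration),
             10000 + dt)
  expect_true(all(ev$saccades$peak_velocity > 0 &
                    ev$saccades$mean_velocity > 0))
  expect_true(all(ev$fixations$offset > ev$fixations$onset))
})

test_that("raising the velocity threshold never shrinks total fixation time", {
  spec <- cohort_spec(n_subjects_per_group = 1, n_trials = 1, seed = 17)
  tr <- preprocess_trial(simulate_trial(spec, "case", seed = 17))
  tot <- sapply(c(15, 30, 60, 120), function(th) {
    ev <- detect_events(tr, geom, velocity_threshold_deg_s = th)
    sum(ev$fixations$duration)
  })
  expect_true(all(diff(tot) >= -1e-9))
})

test_that("the dispersion-based detector agrees on clean schedules", {
  centers <- rbind(c(700, 400), c(1100, 600), c(900, 800))
  tr <- schedule_trial(centers, c(400, 350, 450), sac_ms = 40)
  ev <- detect_events(tr, geom, detector = "idt")
  expect_equal(nrow(ev$fixations), 3L)
  expect_lt(max(abs(ev$fixations$x - centers[, 1])), 0.5)
})
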