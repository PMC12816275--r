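geom <- make_geom()

fix_tbl <- function(x, y, duration = 250) {
  tibble::tibble(onset = seq_along(x) * 300, offset = seq_along(x) * 300 + duration,
                 duration = rep_len(duration, length(x)), x = x, y = y,
                 n_samples = 10L)
}

sac_tbl <- function(dx, dy, amplitude = NULL, mean_velocity = NULL,
                    peak_velocity = NULL) {
  n <- length(dx)
  amplitude <- amplitude %||% (sqrt(dx^2 + dy^2) / 44)
  mean_velocity <- mean_velocity %||% (amplitude * 20)
  peak_velocity <- peak_velocity %||% (mean_velocity * 1.8)
  tibble::tibble(onset = seq_len(n) * 300, offset = seq_len(n) * 300 + 40,
                 duration = 40, dx = dx, dy = dy, amplitude = amplitude,
                 mean_velocity = mean_velocity, peak_velocity = peak_velocity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("saccade summaries are plain means and missing without saccades", {
  s <- sac_tbl(c(100, -50), c(0, 30), amplitude = c(4, 6),
               mean_velocity = c(90, 110), peak_velocity = c(170, 190))
  out <- saccade_summary(s)
  expect_equal(unname(out), c(100, 5, 180))
  one <- saccade_summary(sac_tbl(10, 0, amplitude = 5, mean_velocity = 100,
                                 peak_velocity = 180))
  expect_equal(unname(one), c(100, 5, 180))
  none <- saccade_summary(sac_tbl(numeric(0), numeric(0)))
  expect_true(all(is.na(none)))
})

test_that("velocity waveform indicator is the OLS slope with guards", {
  s <- sac_tbl(1:5 * 10, rep(0, 5), mean_velocity = 0.2 * (50 + 1:5 * 20),
               peak_velocity = 50 + 1:5 * 20)
  expect_equal(velocity_waveform_indicator(s), 0.2, tolerance = 1e-12)
  # degenerate predictor
  s2 <- sac_tbl(1:4 * 10, rep(0, 4), mean_velocity = runif(4, 50, 80),
                peak_velocity = rep(120, 4))
  expect_true(is.na(velocity_waveform_indicator(s2)))
  expect_true(is.na(velocity_waveform_indicator(s[1:2, ])))
  # orientation swap
  expect_equal(velocity_waveform_indicator(s, "peak_on_mean"), 5,
               tolerance = 1e-9)
})

test_that("inflection counting follows the sign-change rule", {
  expect_equal(inflection_count(sac_tbl(c(50, 60, 40, 70), c(30, 20, 40, 25))), 0L)
  alt <- sac_tbl(c(50, -50, 50, -50, 50, -50), rep(20, 6))
  expect_equal(inflection_count(alt), 5L)
  expect_equal(inflection_count(sac_tbl(50, 20)), 0L)
  # sub-floor jitter inherits the previous sign
  jit <- sac_tbl(c(50, 0.5, 50), c(20, 20, 20))
  expect_equal(inflection_count(jit), 0L)
})

test_that("fixation summaries are exact", {
  f <- fix_tbl(c(100, 200), c(100, 200), duration = c(200, 400))
  expect_equal(unname(fixation_summary(f)), c(300, 2))
  expect_equal(unname(fixation_summary(fix_tbl(1, 1, 250))), c(250, 1))
  empty <- fixation_summary(fix_tbl(numeric(0), numeric(0)))
  expect_true(is.na(empty[["mean_duration"]]))
  expect_equal(empty[["count"]], 0)
})

test_that("roi_count clusters fixations by single linkage", {
  # all within 0.1 deg of one point
  expect_equal(roi_count(fix_tbl(rep(900, 5) + runif(5, 0, 2),
                                 rep(500, 5) + runif(5, 0, 2)), geom = geom), 1L)
  # two tight triplets ~10 deg apart + 1 isolated fixation
  f <- fix_tbl(c(500, 505, 510, 950, 955, 960, 1700),
               c(500, 505, 500, 500, 505, 500, 900))
  expect_equal(roi_count(f, geom = geom), 2L)
  expect_equal(roi_count(fix_tbl(numeric(0), numeric(0)), geom = geom), 0L)
})

test_that("gaze entropy matches the direct formula", {
  # all fixations in a single cell
  expect_equal(shannon_entropy(fix_tbl(rep(100, 6), rep(100, 6)), geom = geom), 0)
  # equal counts across exactly 4 cells -> 2 bits (cells are 240 x 135 px)
  f4 <- fix_tbl(c(100, 100, 400, 400, 100, 100, 400, 400),
                c(100, 100, 100, 100, 300, 300, 300, 300))
  expect_equal(shannon_entropy(f4, geom = geom), 2)
  # arbitrary counts {5,3,2}
  f <- fix_tbl(c(rep(100, 5), rep(400, 3), rep(700, 2)), rep(100, 10))
  expect_equal(shannon_entropy(f, geom = geom), entropy_oracle(c(5, 3, 2)))
  expect_true(is.na(shannon_entropy(fix_tbl(numeric(0), numeric(0)),
                                    geom = geom)))
})

test_that("scanpath length and area match closed-form cases", {
  expect_equal(scanpath_length(fix_tbl(500, 500), geom), 0)
  two <- fix_tbl(c(500, 500 + 200), c(500, 500))
  expect_equal(scanpath_length(two, geom), px_to_deg(200, 0, geom))
  expect_equal(scanpath_area(fix_tbl(c(100, 200, 300), c(100, 200, 300)),
                             geom), 0)
  ppd <- 700 * tan(pi / 180) / geom$mm_per_px
  sq <- fix_tbl(c(500, 500 + ppd, 500 + ppd, 500),
                c(500, 500, 500 + ppd, 500 + ppd))
  expect_equal(scanpath_area(sq, geom), 1, tolerance = 1e-9)
})

test_that("all continuous features agree with brute-force oracles", {
  for (r in 1:25) {
    ev <- random_events(n_fix = sample(4:18, 1), n_sac = sample(3:15, 1),
                        seed = 1000 + r)
    f <- ev$fixations; s <- ev$saccades
    expect_equal(saccade_summary(ev)[["mean_amplitude"]],
                 mean_oracle(s$amplitude), tolerance = 1e-12)
    expect_equal(velocity_waveform_indicator(ev),
                 ols_slope_oracle(s$peak_velocity, s$mean_velocity),
                 tolerance = 1e-9)
    expect_equal(inflection_count(ev), inflection_oracle(s$dx, s$dy))
    expect_equal(fixation_summary(ev)[["mean_duration"]],
                 mean_oracle(f$duration), tolerance = 1e-12)
    # roi via graph components
    ppd <- deg_to_px_test(geom)
    comp <- single_linkage_oracle(cbind(f$x / ppd, f$y / ppd), 2.0)
    expect_equal(roi_count(ev, geom = geom),
                 sum(table(comp) >= 2))
    # scanpath length by explicit summation
    len <- 0
    for (i in 2:nrow(f)) {
      len <- len + px_to_deg(f$x[i] - f$x[i - 1], f$y[i] - f$y[i - 1], geom)
    }
    expect_equal(scanpath_length(ev, geom), len, tolerance = 1e-9)
    expect_equal(scanpath_area(ev, geom),
                 jarvis_hull_area(f$x / ppd, f$y / ppd), tolerance = 1e-9)
  }
})

test_that("feature invariants hold", {
  ev <- random_events(10, 9, seed = 4)
  ev$fixations$x <- runif(10, 300, 1500)   # keep on-screen after the shift
  base <- trial_features(ev, geom)
  # translation by one full entropy cell leaves every feature unchanged
  shifted <- ev
  shifted$fixations$x <- shifted$fixations$x + 240
  sh <- trial_features(shifted, geom)
  expect_equal(as.numeric(sh), as.numeric(base), tolerance = 1e-9)
  # single fixation: degenerate scanpath
  one <- random_events(1, 0, seed = 5)
  expect_equal(scanpath_length(one, geom), 0)
  expect_equal(scanpath_area(one, geom), 0)
  expect_lte(roi_count(one, geom = geom), 1L)
  # entropy bound
  expect_lte(shannon_entropy(ev, geom = geom), log2(64))
})

test_that("pixel unit mode rescales spatial features consistently", {
  ev <- random_events(8, 7, seed = 6)
  d <- trial_features(ev, geom, units = "deg")
  p <- trial_features(ev, geom, units = "px")
  ppd <- deg_to_px_test(geom)
  expect_equal(p$mean_saccade_amplitude, d$mean_saccade_amplitude * ppd)
  expect_equal(p$scanpath_area, d$scanpath_area * ppd^2)
  expect_equal(p$mean_fixation_duration, d$mean_fixation_duration)
  expect_equal(p$shannon_entropy, d$shannon_entropy)
})
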