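# Shared fixtures and independent oracles. The oracles deliberately use
# different algorithms from the package implementation (explicit loops,
# normal equations, graph search, gift wrapping, alignment enumeration).

make_geom <- function() screen_geometry()

# gaze_trial from raw vectors
build_trial <- function(t, x, y, valid = TRUE, hz = 90,
                        subject = "S01", trial = "T01", stim = "FACE01") {
  n <- length(t)
  tr <- tibble::tibble(
    subject_id = subject, trial_id = trial, stimulus_id = stim,
    t_ms = t, x_px = x, y_px = y, valid = rep_len(valid, n)
  )
  tr$x_px[!tr$valid] <- NA_real_
  tr$y_px[!tr$valid] <- NA_real_
  attr(tr, "sampling_hz") <- hz
  class(tr) <- c("gaze_trial", class(tr))
  tr
}

# noise-free piecewise trial from an explicit fixation schedule:
# centers (k x 2 px), durations (ms), linear ramps of sac_ms between them
schedule_trial <- function(centers, durations, sac_ms = 40, hz = 90) {
  dt <- 1000 / hz
  t <- c(); x <- c(); y <- c()
  t0 <- 0
  for (i in seq_len(nrow(centers))) {
    tt <- seq(t0, t0 + durations[i] - 1e-9, by = dt)
    t <- c(t, tt)
    x <- c(x, rep(centers[i, 1], length(tt)))
    y <- c(y, rep(centers[i, 2], length(tt)))
    t0 <- t0 + durations[i]
    if (i < nrow(centers)) {
      ts <- seq(t0, t0 + sac_ms - 1e-9, by = dt)
      frac <- (ts - t0) / sac_ms
      t <- c(t, ts)
      x <- c(x, centers[i, 1] + frac * (centers[i + 1, 1] - centers[i, 1]))
      y <- c(y, centers[i, 2] + frac * (centers[i + 1, 2] - centers[i, 2]))
      t0 <- t0 + sac_ms
    }
  }
  # snap onto the regular sample grid
  tg <- seq(0, max(t), by = dt)
  xi <- approx(t, x, xout = tg)$y
  yi <- approx(t, y, xout = tg)$y
  build_trial(tg, xi, yi)
}

# random oculomotor_events object
random_events <- function(n_fix, n_sac = max(n_fix - 1L, 0L), seed = 1) {
  set.seed(seed)
  fixations <- tibble::tibble(
    onset = cumsum(runif(n_fix, 100, 400)),
    duration = runif(n_fix, 80, 500),
    x = runif(n_fix, 200, 1700),
    y = runif(n_fix, 100, 950)
  )
  fixations$offset <- fixations$onset + fixations$duration
  fixations$n_samples <- pmax(2L, round(fixations$duration / 11.1))
  sac_amp <- runif(n_sac, 0.5, 12)
  sac_dur <- runif(n_sac, 20, 80)
  saccades <- tibble::tibble(
    onset = cumsum(runif(n_sac, 100, 400)),
    duration = sac_dur,
    dx = rnorm(n_sac, 0, 150),
    dy = rnorm(n_sac, 0, 100),
    amplitude = sac_amp,
    mean_velocity = sac_amp / (sac_dur / 1000)
  )
  saccades$offset <- saccades$onset + saccades$duration
  saccades$peak_velocity <- saccades$mean_velocity * runif(n_sac, 1.2, 2.2)
  structure(list(fixations = fixations, saccades = saccades,
                 detector = "ivt"), class = "oculomotor_events")
}

# --- independent oracles -------------------------------------------------

deg_to_px_test <- function(geom) tan(pi / 180) *
  geom$viewing_distance_mm / geom$mm_per_px

mean_oracle <- function(v) {
  s <- 0
  for (el in v) s <- s + el
  s / length(v)
}

ols_slope_oracle <- function(x, y) {
  # normal equations on the augmented design
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  beta[2]
}

# connected components of the <=h distance graph (single linkage)
single_linkage_oracle <- function(xy, h) {
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        dij <- sqrt(sum((xy[i, ] - xy[j, ])^2))
        if (dij <= h && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  as.integer(factor(comp))
}

entropy_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  h <- 0
  for (pi in p) h <- h - pi * log2(pi)
  h
}

# gift-wrapping convex hull + shoelace
jarvis_hull_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    q <- if (p == n) 1L else p + 1L
    for (r in seq_len(n)) {
      cross <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
               (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      if (r != p && cross < 0) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) break
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  m <- length(hx)
  a <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    a <- a + hx[i] * hy[j] - hx[j] * hy[i]
  }
  abs(a) / 2
}

# exhaustive enumeration of all global alignments of two fixation
# sequences under the duration-weighted, distance-modulated cost scheme
scasim_brute <- function(a, b, modulation = 0.83) {
  sub_cost <- function(i, j) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
    sim <- modulation^d
    sim * abs(a$duration[i] - b$duration[j]) +
      (1 - sim) * (a$duration[i] + b$duration[j])
  }
  rec <- function(i, j) {
    if (i > nrow(a) && j > nrow(b)) return(0)
    best <- Inf
    if (i <= nrow(a) && j <= nrow(b)) {
      best <- min(best, sub_cost(i, j) + rec(i + 1, j + 1))
    }
    if (i <= nrow(a)) best <- min(best, a$duration[i] + rec(i + 1, j))
    if (j <= nrow(b)) best <- min(best, b$duration[j] + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

random_scanpath <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scanpath(x = runif(n, -15, 15), y = runif(n, -8, 8),
           duration = runif(n, 80, 500))
}

# count of inflections by direct enumeration over the sign sequence
inflection_oracle <- function(dx, dy, floor_px = 1) {
  one_axis <- function(v) {
    signs <- c()
    last <- 0
    for (el in v) {
      s <- if (abs(el) < floor_px) last else sign(el)
      if (s != 0) signs <- c(signs, s)
      last <- s
    }
    n <- 0
    if (length(signs) >= 2) {
      for (i in 2:length(signs)) if (signs[i] != signs[i - 1]) n <- n + 1
    }
    n
  }
  one_axis(dx) + one_axis(dy)
}
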