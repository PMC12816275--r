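test_that("dissimilarity is zero for identical paths and symmetric", {
  for (r in 1:10) {
    a <- random_scanpath(sample(2:6, 1), seed = 100 + r)
    b <- random_scanpath(sample(2:6, 1), seed = 200 + r)
    expect_equal(scanpath_dissimilarity(a, a), 0)
    expect_equal(scanpath_dissimilarity(a, b), scanpath_dissimilarity(b, a),
                 tolerance = 1e-12)
    expect_gte(scanpath_dissimilarity(a, b), 0)
  }
  expect_error(scanpath_dissimilarity(random_scanpath(2),
                                      random_scanpath(0)), "empty")
})

test_that("the alignment minimum matches exhaustive enumeration", {
  for (r in 1:30) {
    a <- random_scanpath(sample(1:4, 1), seed = 300 + r)
    b <- random_scanpath(sample(1:4, 1), seed = 400 + r)
    expect_equal(scanpath_dissimilarity(a, b), scasim_brute(a, b),
                 tolerance = 1e-9)
  }
})

test_that("matched fixations at zero distance cost their duration difference", {
  a <- scanpath(0, 0, 300)
  b <- scanpath(0, 0, 420)
  expect_equal(scanpath_dissimilarity(a, b), 120)
  # far apart: cost approaches the sum of durations
  far <- scanpath(1000, 0, 420)
  expect_equal(scanpath_dissimilarity(a, far), 720, tolerance = 1e-6)
})

test_that("similarity is an order-reversing map into [0, 1]", {
  expect_equal(to_similarity(0, 1000), 1)
  expect_equal(to_similarity(1000, 1000), 0)
  set.seed(8)
  d <- runif(20, 0, 500)
  s <- to_similarity(d, 500)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(rank(s), rank(-d))
})

test_that("intra-individual similarity averages within-subject pairs", {
  p1 <- random_scanpath(4, seed = 11)
  set <- structure(list(
    paths = list(p1, p1, p1),
    meta = tibble::tibble(subject_id = "S01", trial_id = c("T1", "T2", "T3"),
                          stimulus_id = c("F1", "F2", "F3"))
  ), class = "scanpath_set")
  out <- intra_individual_similarity(set)
  expect_equal(out$similarity, 1)

  paths <- list(random_scanpath(3, seed = 21), random_scanpath(4, seed = 22),
                random_scanpath(5, seed = 23))
  set2 <- structure(list(
    paths = paths,
    meta = tibble::tibble(subject_id = "S01", trial_id = c("T1", "T2", "T3"),
                          stimulus_id = c("F1", "F2", "F3"))
  ), class = "scanpath_set")
  pair <- function(a, b) {
    to_similarity(scanpath_dissimilarity(a, b),
                  sum(a$duration) + sum(b$duration))
  }
  hand <- mean(c(pair(paths[[1]], paths[[2]]), pair(paths[[1]], paths[[3]]),
                 pair(paths[[2]], paths[[3]])))
  expect_equal(intra_individual_similarity(set2)$similarity, hand)

  # single trial -> missing
  set3 <- structure(list(
    paths = paths[1],
    meta = tibble::tibble(subject_id = "S01", trial_id = "T1",
                          stimulus_id = "F1")
  ), class = "scanpath_set")
  expect_true(is.na(intra_individual_similarity(set3)$similarity))
})

test_that("inter-individual similarity averages subject pairs per stimulus", {
  p <- random_scanpath(4, seed = 31)
  subjects <- tibble::tibble(subject_id = c("S01", "S02", "S03"),
                             group = "control")
  set <- structure(list(
    paths = list(p, p),
    meta = tibble::tibble(subject_id = c("S01", "S02"),
                          trial_id = "T1", stimulus_id = "F1")
  ), class = "scanpath_set")
  out <- inter_individual_similarity(set, subjects)
  expect_equal(out$similarity, 1)

  paths <- list(random_scanpath(3, seed = 41), random_scanpath(4, seed = 42),
                random_scanpath(5, seed = 43))
  set2 <- structure(list(
    paths = paths,
    meta = tibble::tibble(subject_id = c("S01", "S02", "S03"),
                          trial_id = "T1", stimulus_id = "F1")
  ), class = "scanpath_set")
  pair <- function(a, b) {
    to_similarity(scanpath_dissimilarity(a, b),
                  sum(a$duration) + sum(b$duration))
  }
  hand <- mean(c(pair(paths[[1]], paths[[2]]), pair(paths[[1]], paths[[3]]),
                 pair(paths[[2]], paths[[3]])))
  out2 <- inter_individual_similarity(set2, subjects)
  expect_equal(out2$similarity, hand)
  expect_equal(out2$n_pairs, 3L)

  # disjoint single-fixation paths at far corners sit near the floor
  corners <- list(scanpath(-20, -11, 300), scanpath(20, 11, 300))
  set3 <- structure(list(
    paths = corners,
    meta = tibble::tibble(subject_id = c("S01", "S02"),
                          trial_id = "T1", stimulus_id = "F1")
  ), class = "scanpath_set")
  expect_lt(inter_individual_similarity(set3, subjects)$similarity, 0.01)
})
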