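#' Construct a scanpath
#'
#' A scanpath is the time-ordered sequence of fixations of one trial,
#' carried as positions in degrees plus durations in ms.
#'
#' @param x,y Fixation positions in degrees.
#' @param duration Fixation durations in ms (all > 0).
#' @param subject_id,trial_id,stimulus_id Optional identifiers.
#' @return A `scanpath` tibble.
#' @export
scanpath <- function(x, y, duration, subject_id = NA_character_,
                     trial_id = NA_character_, stimulus_id = NA_character_) {
  stopifnot(length(x) == length(y), length(x) == length(duration),
            all(is.finite(duration)), all(duration > 0))
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        duration = as.numeric(duration))
  attr(out, "subject_id") <- subject_id
  attr(out, "trial_id") <- trial_id
  attr(out, "stimulus_id") <- stimulus_id
  class(out) <- c("scanpath", class(out))
  out
}

#' Convert detected events to a scanpath
#'
#' @param events An `oculomotor_events` object.
#' @param geom A [screen_geometry()].
#' @param subject_id,trial_id,stimulus_id Identifiers to attach.
#' @return A [scanpath()] (positions converted to degrees about the screen
#'   centre), or `NULL` when the trial has no fixations.
#' @export
as_scanpath <- function(events, geom = screen_geometry(),
                        subject_id = NA_character_,
                        trial_id = NA_character_,
                        stimulus_id = NA_character_) {
  f <- events$fixations
  if (!NROW(f)) return(NULL)
  ppd <- deg_to_px(1, geom)
  scanpath((f$x - geom$width_px / 2) / ppd,
           (f$y - geom$height_px / 2) / ppd,
           f$duration, subject_id, trial_id, stimulus_id)
}

#' Duration-weighted scanpath alignment dissimilarity
#'
#' Global sequence alignment of two fixation sequences by dynamic
#' programming. Substituting fixation `i` for fixation `j` costs
#' `sim * |d_i - d_j| + (1 - sim) * (d_i + d_j)` where
#' `sim = modulation^distance_deg`: perfectly co-located fixations cost
#' their duration difference, far-apart fixations cost their combined
#' duration. Inserting or deleting a fixation costs its duration. The
#' result is the minimal total alignment cost (0 for identical paths).
#'
#' @param a,b Non-empty [scanpath()] objects (or tibbles with `x`, `y` in
#'   degrees and `duration` in ms).
#' @param modulation Spatial decay base per degree of separation, in
#'   (0, 1); smaller values make spatial mismatch more expensive.
#' @param normalize If `TRUE`, divide by the total duration of both paths
#'   (the resulting value lies in `[0, 1]`).
#' @return Non-negative alignment cost.
#' @export
scanpath_dissimilarity <- function(a, b, modulation = 0.83,
                                   normalize = FALSE) {
  if (!NROW(a) || !NROW(b)) stop("empty scanpath", call. = FALSE)
  stopifnot(modulation > 0, modulation < 1)
  n <- NROW(a); m <- NROW(b)
  da <- a$duration; db <- b$duration
  # substitution costs
  dist_ij <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  sim <- modulation^dist_ij
  sub <- sim * abs(outer(da, db, "-")) + (1 - sim) * outer(da, db, "+")
  d <- matrix(0, n + 1L, m + 1L)
  d[, 1L] <- cumsum(c(0, da))
  d[1L, ] <- cumsum(c(0, db))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j] + sub[i, j],
                               d[i, j + 1L] + da[i],
                               d[i + 1L, j] + db[j])
    }
  }
  cost <- d[n + 1L, m + 1L]
  if (normalize) cost <- cost / (sum(da) + sum(db))
  cost
}

#' Map dissimilarity to a similarity score in [0, 1]
#'
#' The default transform is `s = 1 - cost / (total duration of both
#' paths)`, a monotone-decreasing map with `s = 1` for identical paths.
#'
#' @param dissimilarity Alignment cost(s) from [scanpath_dissimilarity()]
#'   (un-normalized).
#' @param total_duration Combined duration of the two scanpaths (same
#'   length as `dissimilarity`, or scalar).
#' @return Similarity in `[0, 1]`.
#' @export
to_similarity <- function(dissimilarity, total_duration) {
  stopifnot(all(dissimilarity >= 0), all(total_duration > 0))
  pmin(pmax(1 - dissimilarity / total_duration, 0), 1)
}

scanpath_pair_similarity <- function(a, b, modulation = 0.83) {
  to_similarity(scanpath_dissimilarity(a, b, modulation),
                sum(a$duration) + sum(b$duration))
}

#' Build the scanpath set of a cohort
#'
#' @param features Result of [extract_features()] (its `"events"`
#'   attribute is used), or a named list of `oculomotor_events`.
#' @param meta Tibble with `subject_id`, `trial_id`, `stimulus_id` per
#'   event list entry (taken from `features` when available).
#' @param geom A [screen_geometry()].
#' @return A `scanpath_set`: list with `paths` (list of scanpaths) and
#'   `meta` (tibble; rows with no fixations are dropped).
#' @export
cohort_scanpaths <- function(features, meta = NULL,
                             geom = screen_geometry()) {
  events <- if (is.list(features) && is.null(attr(features, "events"))) {
    features
  } else {
    attr(features, "events")
  }
  if (is.null(meta)) {
    meta <- features[, c("subject_id", "trial_id", "stimulus_id")]
  }
  stopifnot(length(events) == nrow(meta))
  paths <- lapply(seq_along(events), function(i) {
    as_scanpath(events[[i]], geom, meta$subject_id[i], meta$trial_id[i],
                meta$stimulus_id[i])
  })
  keep <- !vapply(paths, is.null, logical(1))
  structure(list(paths = paths[keep], meta = meta[keep, , drop = FALSE]),
            class = "scanpath_set")
}

#' Intra-individual scanpath similarity
#'
#' For each subject, the mean pairwise similarity of their scanpaths
#' across different trials (stimuli): the stability of an individual's
#' exploration pattern.
#'
#' @param set A `scanpath_set` from [cohort_scanpaths()].
#' @param modulation Spatial decay base, see [scanpath_dissimilarity()].
#' @return Tibble with `subject_id`, `n_trials`, `similarity` (`NA` with
#'   fewer than 2 retained trials).
#' @export
intra_individual_similarity <- function(set, modulation = 0.83) {
  subj <- unique(set$meta$subject_id)
  rows <- lapply(subj, function(s) {
    idx <- which(set$meta$subject_id == s)
    if (length(idx) < 2) {
      return(tibble::tibble(subject_id = s, n_trials = length(idx),
                            similarity = NA_real_))
    }
    pairs <- utils::combn(idx, 2)
    sims <- apply(pairs, 2, function(p) {
      scanpath_pair_similarity(set$paths[[p[1]]], set$paths[[p[2]]],
                               modulation)
    })
    tibble::tibble(subject_id = s, n_trials = length(idx),
                   similarity = mean(sims))
  })
  dplyr::bind_rows(rows)
}

#' Inter-individual scanpath similarity
#'
#' For each stimulus and group, the mean pairwise similarity between
#' different subjects' scanpaths on that same stimulus: the consistency of
#' exploration across individuals. Stimuli seen by fewer than 2 subjects
#' of a group are skipped.
#'
#' @param set A `scanpath_set` from [cohort_scanpaths()].
#' @param subjects Tibble with `subject_id` and `group`.
#' @param modulation Spatial decay base.
#' @return Tibble with `stimulus_id`, `group`, `n_pairs`, `similarity`.
#'   The per-group mean over stimuli is attached as
#'   `attr(, "group_means")`.
#' @export
inter_individual_similarity <- function(set, subjects, modulation = 0.83) {
  meta <- set$meta
  meta$group <- subjects$group[match(meta$subject_id, subjects$subject_id)]
  combos <- unique(meta[, c("stimulus_id", "group")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    idx <- which(meta$stimulus_id == combos$stimulus_id[i] &
                   meta$group == combos$group[i])
    idx <- idx[!duplicated(meta$subject_id[idx])]
    if (length(idx) < 2) return(NULL)
    pairs <- utils::combn(idx, 2)
    sims <- apply(pairs, 2, function(p) {
      scanpath_pair_similarity(set$paths[[p[1]]], set$paths[[p[2]]],
                               modulation)
    })
    tibble::tibble(stimulus_id = combos$stimulus_id[i],
                   group = combos$group[i],
                   n_pairs = ncol(pairs), similarity = mean(sims))
  })
  out <- dplyr::bind_rows(rows)
  gm <- stats::aggregate(similarity ~ group, data = as.data.frame(out), mean)
  attr(out, "group_means") <- stats::setNames(gm$similarity, gm$group)
  out
}
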