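#' Fixed rectangular area of interest
#'
#' A standardized rectangle (default 600 x 450 px, centred on the screen)
#' enclosing the core facial features of a face stimulus.
#'
#' @param center_x,center_y Rectangle centre in px.
#' @param width,height Rectangle size in px.
#' @param geom Optional [screen_geometry()] used to check that the
#'   rectangle lies on-screen.
#' @return An `aoi_rect` object.
#' @export
aoi_rect <- function(center_x = 960, center_y = 540,
                     width = 600, height = 450, geom = NULL) {
  stopifnot(width > 0, height > 0)
  r <- structure(
    list(center_x = center_x, center_y = center_y,
         width = width, height = height,
         x0 = center_x - width / 2, x1 = center_x + width / 2,
         y0 = center_y - height / 2, y1 = center_y + height / 2),
    class = "aoi_rect"
  )
  if (!is.null(geom)) {
    stopifnot(r$x0 >= 0, r$y0 >= 0,
              r$x1 <= geom$width_px, r$y1 <= geom$height_px)
  }
  r
}

#' Proportion of fixations and fixation time inside an AOI
#'
#' Centroids exactly on the rectangle boundary count as inside.
#'
#' @param fixations Fixation tibble (px centroids) or `oculomotor_events`.
#' @param aoi An [aoi_rect()].
#' @return Named vector `prop_count`, `prop_duration` (both `NA` with zero
#'   fixations).
#' @export
aoi_proportions <- function(fixations, aoi = aoi_rect()) {
  f <- if (inherits(fixations, "oculomotor_events")) fixations$fixations else fixations
  if (!NROW(f)) return(c(prop_count = NA_real_, prop_duration = NA_real_))
  inside <- f$x >= aoi$x0 & f$x <= aoi$x1 & f$y >= aoi$y0 & f$y <= aoi$y1
  c(prop_count = mean(inside),
    prop_duration = sum(f$duration[inside]) / sum(f$duration))
}

#' Intraclass correlation coefficient of a subjects x trials matrix
#'
#' Balanced two-way decomposition (one observation per cell): with
#' between-subject mean square MSR, between-trial mean square MSC and
#' residual mean square MSE over `k` trials and `n` subjects,
#' \describe{
#'   \item{ICC(3,k)}{`(MSR - MSE) / MSR` — two-way mixed, consistency,
#'     average of k measures (the default: internal consistency of the
#'     trial-mean score).}
#'   \item{ICC(3,1)}{`(MSR - MSE) / (MSR + (k-1) MSE)`.}
#'   \item{ICC(2,1)}{`(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#'     — two-way random, absolute agreement, single measure.}
#'   \item{ICC(2,k)}{`(MSR - MSE) / (MSR + (MSC - MSE) / n)`.}
#' }
#' Values are clipped below at -1. A matrix with (numerically) zero total
#' variance is perfectly consistent: the ICC is reported as 1 with
#' attribute `degenerate = TRUE`.
#'
#' @param mat Numeric matrix, subjects in rows, trials in columns, no
#'   missing cells.
#' @param form One of `"ICC3k"`, `"ICC31"`, `"ICC21"`, `"ICC2k"`.
#' @return ICC value in `[-1, 1]`.
#' @export
icc <- function(mat, form = c("ICC3k", "ICC31", "ICC21", "ICC2k")) {
  form <- match.arg(form)
  mat <- as.matrix(mat)
  stopifnot(is.numeric(mat), !anyNA(mat), nrow(mat) >= 2, ncol(mat) >= 2)
  n <- nrow(mat); k <- ncol(mat)
  g <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sse <- sum((mat - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + g)^2)
  sst <- ssr + ssc + sse
  if (sst < 1e-12 * max(1, g^2)) {
    return(structure(1, degenerate = TRUE))
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- switch(form,
    ICC3k = (msr - mse) / msr,
    ICC31 = (msr - mse) / (msr + (k - 1) * mse),
    ICC21 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC2k = (msr - mse) / (msr + (msc - mse) / n)
  )
  max(val, -1)
}

#' ICC reliability over trial subsets
#'
#' For each subset size `k`, each feature's per-trial values are arranged
#' into a subjects x k matrix using each subject's first `k` retained
#' trials in presentation order (subjects with fewer than `k` retained
#' trials are excluded for that subset), and the ICC is computed.
#'
#' @param features Per-trial feature tibble from [extract_features()].
#' @param feature_names Features to assess (default: all 11).
#' @param subsets Trial-subset sizes.
#' @param form ICC form, see [icc()].
#' @return Tibble with `feature`, `k`, `n_subjects`, `icc`.
#' @export
icc_trial_subsets <- function(features,
                              feature_names = unlist(feature_families(),
                                                     use.names = FALSE),
                              subsets = c(3L, 5L, 7L),
                              form = "ICC3k") {
  features <- features[order(features$subject_id, features$trial_id), ]
  rows <- list()
  for (feat in feature_names) {
    vals <- split(features[[feat]], features$subject_id)
    vals <- lapply(vals, function(v) v[!is.na(v)])
    for (k in subsets) {
      mat <- do.call(rbind, lapply(vals, function(v) {
        if (length(v) >= k) v[seq_len(k)] else NULL
      }))
      if (is.null(mat) || nrow(mat) < 5) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          feature = feat, k = k, n_subjects = NROW(mat) %||% 0L,
          icc = NA_real_)
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        feature = feat, k = k, n_subjects = nrow(mat),
        icc = as.numeric(icc(mat, form)))
    }
  }
  dplyr::bind_rows(rows)
}
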