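#' Build the subject-level wide feature table
#'
#' Arranges per-trial features into one row per subject with one column
#' per (feature, trial) pair, which keeps all of a subject's data on one
#' side of any cross-validation split. Trials are indexed per subject in
#' presentation order; subjects with fewer retained trials than
#' `n_trials` have the missing cells imputed with the within-subject
#' median of that feature (falling back to the across-subject median when
#' a subject has no value at all). Subjects with zero retained trials are
#' excluded.
#'
#' @param features Per-trial feature tibble from [extract_features()].
#' @param subjects Tibble with `subject_id`, `group`.
#' @param n_trials Number of trial columns (default: the maximum retained
#'   trial count over subjects).
#' @param family `"multi"` (all 11 features) or one of
#'   `names(feature_families())`.
#' @return A `feature_table`: list with `x` (numeric matrix, subjects x
#'   (features x trials)), `y` (factor `control`/`case`),
#'   `subject_id`, `feature_set`.
#' @export
build_feature_table <- function(features, subjects, n_trials = NULL,
                                family = c("multi", "saccadic",
                                           "fixation", "scanpath")) {
  family <- match.arg(family)
  fams <- feature_families()
  feats <- if (family == "multi") unlist(fams, use.names = FALSE)
           else fams[[family]]
  features <- features[order(features$subject_id, features$trial_id), ]
  sid <- sort(unique(features$subject_id))
  counts <- table(features$subject_id)
  if (is.null(n_trials)) n_trials <- max(counts)

  col_names <- as.vector(t(outer(feats, seq_len(n_trials),
                                 function(f, t) sprintf("%s_t%02d", f, t))))
  x <- matrix(NA_real_, nrow = length(sid), ncol = length(col_names),
              dimnames = list(sid, col_names))
  for (s in sid) {
    rows <- features[features$subject_id == s, ]
    for (f in feats) {
      v <- rows[[f]][seq_len(min(nrow(rows), n_trials))]
      v <- c(v, rep(NA_real_, n_trials - length(v)))
      med <- stats::median(v, na.rm = TRUE)
      v[is.na(v)] <- med
      x[s, sprintf("%s_t%02d", f, seq_len(n_trials))] <- v
    }
  }
  # across-subject fallback for features missing in every trial of a subject
  for (j in seq_len(ncol(x))) {
    if (anyNA(x[, j])) {
      cm <- stats::median(x[, j], na.rm = TRUE)
      x[is.na(x[, j]), j] <- if (is.finite(cm)) cm else 0
    }
  }
  grp <- subjects$group[match(sid, subjects$subject_id)]
  keep <- !is.na(grp)
  structure(
    list(x = x[keep, , drop = FALSE],
         y = factor(grp[keep], levels = c("control", "case")),
         subject_id = sid[keep], feature_set = family,
         n_trials = n_trials),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d columns (%s), groups %s\n",
              nrow(x$x), ncol(x$x), x$feature_set,
              paste(table(x$y), collapse = "/")))
  invisible(x)
}

scale_fit <- function(x) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  list(mu = mu, sd = sd_)
}
scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

# run code under a private RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' LASSO selection of exactly k columns
#'
#' L1-regularized logistic regression (glmnet); the penalty is located by
#' bisection on lambda so that exactly `k` coefficients are nonzero. When
#' a plateau in the regularization path makes exactly-k unattainable, the
#' nearest achievable count below `k` is returned with attribute
#' `flag = "plateau"`. With at most `k` columns available, all columns
#' are returned (`flag = "all_columns"`).
#'
#' @param x Numeric matrix (rows = subjects), already standardized or raw
#'   (columns are standardized internally for the selection fit).
#' @param y Two-level factor.
#' @param k Target number of selected columns.
#' @param seed Seed (the procedure is deterministic; the seed guards any
#'   tie-breaking).
#' @return Character vector of selected column names, with attributes
#'   `lambda` and `flag`.
#' @export
lasso_select <- function(x, y, k = 10L, seed = 1L) {
  stopifnot(is.matrix(x), nlevels(factor(y)) == 2)
  if (ncol(x) <= k) {
    return(structure(colnames(x), lambda = NA_real_, flag = "all_columns"))
  }
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  yb <- as.integer(y == levels(factor(y))[2])
  nnz_at <- function(lam) {
    # small LOOCV training folds routinely trip glmnet's small-class warning
    fit <- suppressWarnings(
      glmnet::glmnet(xs, yb, family = "binomial", lambda = lam,
                     standardize = FALSE))
    cf <- as.matrix(fit$beta)
    nz <- cf[, 1] != 0
    list(n = sum(nz), cols = rownames(cf)[nz], beta = cf[nz, 1])
  }
  path <- suppressWarnings(
    glmnet::glmnet(xs, yb, family = "binomial", nlambda = 100,
                   standardize = FALSE))
  df <- path$df; lam <- path$lambda
  if (any(df == k)) {
    best <- max(lam[df == k])
    sel <- nnz_at(best)
    if (sel$n == k) {
      return(structure(sel$cols, lambda = best, flag = "exact"))
    }
  }
  hi <- suppressWarnings(min(lam[df < k]))   # stronger penalty, fewer cols
  lo <- suppressWarnings(max(lam[df > k]))   # weaker penalty, more cols
  if (!is.finite(hi)) hi <- max(lam)
  if (!is.finite(lo)) lo <- min(lam) / 10
  best_below <- NULL
  for (it in seq_len(50)) {
    mid <- sqrt(hi * lo)
    sel <- nnz_at(mid)
    if (sel$n == k) {
      return(structure(sel$cols, lambda = mid, flag = "exact"))
    }
    if (sel$n < k) {
      if (is.null(best_below) || sel$n > length(best_below$cols)) {
        best_below <- list(cols = sel$cols, lambda = mid)
      }
      hi <- mid
    } else {
      lo <- mid
    }
  }
  if (is.null(best_below) || !length(best_below$cols)) {
    # a plateau that jumps from 0 straight past k: take the k strongest
    # coefficients at the weak-penalty side
    sel <- nnz_at(lo)
    if (length(sel$cols)) {
      ord <- order(abs(sel$beta), decreasing = TRUE)
      return(structure(sel$cols[ord][seq_len(min(k, length(ord)))],
                       lambda = lo, flag = "plateau"))
    }
    # glmnet selects nothing at any penalty (degenerate fit): fall back to
    # a univariate correlation screen so downstream models always receive
    # a non-empty design
    sc_cor <- abs(as.vector(stats::cor(xs, yb)))
    sc_cor[!is.finite(sc_cor)] <- 0
    ord <- order(sc_cor, decreasing = TRUE)[seq_len(min(k, ncol(xs)))]
    return(structure(colnames(xs)[ord], lambda = NA_real_,
                     flag = "screen_fallback"))
  }
  structure(best_below$cols, lambda = best_below$lambda, flag = "plateau")
}

fit_classifier <- function(model, x, y, seed) {
  switch(model,
    svm = {
      fit <- e1071::svm(x, y, kernel = "radial", probability = TRUE,
                        scale = FALSE)
      function(newx) {
        p <- attr(stats::predict(fit, newx, probability = TRUE),
                  "probabilities")
        p[, "case"]
      }
    },
    extra_trees = {
      fit <- ranger::ranger(
        x = as.data.frame(x), y = y, probability = TRUE,
        splitrule = "extratrees", num.random.splits = 1L,
        replace = FALSE, sample.fraction = 1, num.trees = 300L,
        min.node.size = 1L,
        seed = as.integer(seed), num.threads = 1L
      )
      function(newx) {
        stats::predict(fit, as.data.frame(newx),
                       num.threads = 1L)$predictions[, "case"]
      }
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(x, label = as.integer(y == "case"),
                                  nthread = 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3L,
                      eta = 0.1, min_child_weight = 0, nthread = 1L),
        data = dtr, nrounds = 120L, verbose = 0
      )
      function(newx) {
        stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1L))
      }
    },
    dart = {
      dtr <- xgboost::xgb.DMatrix(x, label = as.integer(y == "case"),
                                  nthread = 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", booster = "dart",
                      rate_drop = 0.1, max_depth = 3L, eta = 0.1,
                      min_child_weight = 0, nthread = 1L),
        data = dtr, nrounds = 120L, verbose = 0
      )
      function(newx) {
        stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1L))
      }
    },
    stop("unknown model family: ", model, call. = FALSE)
  )
}

#' Leave-one-out cross-validated classification
#'
#' Each subject is held out once; scaling, LASSO selection and the
#' classifier are re-fit on the remaining subjects only (no leakage), and
#' the held-out subject is scored. Accuracy and F1 (positive class =
#' `case`) are computed from the pooled hard predictions at a 0.5
#' probability threshold; AUROC and AUCPR from the pooled continuous
#' scores.
#'
#' @param table A [build_feature_table()] result.
#' @param model One of `"svm"`, `"extra_trees"`, `"xgboost"`, `"dart"`
#'   (the last two are the gradient-boosted variants).
#' @param k Number of LASSO-selected columns per fold.
#' @param seed Seed applied to every stochastic fit.
#' @param select Apply per-fold LASSO selection (`TRUE`, default). The
#'   global (leaky) variant of selecting once on all data is available
#'   via `select = "global"` for comparison only.
#' @return A `cv_report` tibble (one row: model, feature_set, accuracy,
#'   f1, auroc, aucpr, n_folds) with per-fold predictions in
#'   `attr(, "folds")` and per-fold selections in `attr(, "selected")`.
#' @export
loocv_evaluate <- function(table, model = "svm", k = 10L, seed = 1L,
                           select = TRUE) {
  x <- table$x; y <- table$y
  n <- nrow(x)
  stopifnot(min(table(y)) >= 2)
  global_sel <- NULL
  if (identical(select, "global")) {
    global_sel <- lasso_select(x, y, k, seed)
  }
  raw <- score <- rep(NA_real_, n)
  selections <- vector("list", n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) next  # single-class training fold
    sc <- scale_fit(xtr)
    xs <- scale_apply(xtr, sc)
    sel <- if (!is.null(global_sel)) global_sel
           else if (isTRUE(select)) lasso_select(xtr, ytr, k, seed)
           else colnames(x)
    selections[[i]] <- sel
    pred_fun <- with_seed(seed, {
      fit_classifier(model, xs[, sel, drop = FALSE],
                     factor(ytr, levels = levels(y)), seed)
    })
    xte <- scale_apply(x[i, , drop = FALSE], sc)[, sel, drop = FALSE]
    raw[i] <- pred_fun(xte)
    # pooled-curve scores are centred by the fold's mean training score:
    # naive pooling is anti-ordered under the null because each fold's
    # training class balance shifts its score scale
    score[i] <- raw[i] - mean(pred_fun(xs[, sel, drop = FALSE]))
  }
  ok <- !is.na(score)
  truth <- y[ok]
  pred <- factor(ifelse(raw[ok] >= 0.5, "case", "control"),
                 levels = levels(y))
  out <- tibble::tibble(
    model = model, feature_set = table$feature_set,
    accuracy = 100 * mean(pred == truth),
    f1 = 100 * f1_score(truth, pred, positive = "case"),
    auroc = auroc(truth == "case", score[ok]),
    aucpr = aucpr(truth == "case", score[ok]),
    n_folds = sum(ok)
  )
  attr(out, "folds") <- tibble::tibble(
    subject_id = table$subject_id[ok], truth = as.character(truth),
    probability = raw[ok], score = score[ok], pred = as.character(pred)
  )
  attr(out, "selected") <- selections
  class(out) <- c("cv_report", class(out))
  out
}

f1_score <- function(truth, pred, positive = "case") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

auroc <- function(is_pos, score) {
  r <- pROC::roc(response = as.integer(is_pos), predictor = score,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Average precision: sum over unique score thresholds of
# (recall step) x precision, ties handled jointly.
aucpr <- function(is_pos, score) {
  np <- sum(is_pos)
  if (np == 0 || np == length(is_pos)) return(NA_real_)
  thr <- sort(unique(score), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (th in thr) {
    sel <- score >= th
    prec <- sum(is_pos & sel) / sum(sel)
    rec <- sum(is_pos & sel) / np
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

#' Evaluate every feature set with every model family
#'
#' Runs [loocv_evaluate()] for the three single-family feature sets and
#' the combined multi-type set across the four classifier families.
#'
#' @param features Per-trial feature tibble from [extract_features()].
#' @param subjects Tibble with `subject_id`, `group`.
#' @param models Model families to run.
#' @param feature_sets Feature sets to run.
#' @param k,seed,n_trials Passed through.
#' @return Tibble with one row per (feature set, model) combination.
#' @export
evaluate_feature_sets <- function(features, subjects,
                                  models = c("svm", "extra_trees",
                                             "xgboost", "dart"),
                                  feature_sets = c("saccadic", "fixation",
                                                   "scanpath", "multi"),
                                  k = 10L, seed = 1L, n_trials = NULL) {
  grid <- list()
  for (fs in feature_sets) {
    tab <- build_feature_table(features, subjects, n_trials, family = fs)
    for (m in models) {
      grid[[length(grid) + 1L]] <-
        loocv_evaluate(tab, model = m, k = k, seed = seed)
    }
  }
  dplyr::bind_rows(grid)
}
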