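# A per-trial feature tibble with a controllable class signal in every
# feature; large `shift` makes the classes linearly separable.
toy_features <- function(n_per_group = 8, n_trials = 3, shift = 0,
                         seed = 1) {
  set.seed(seed)
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(2 * n_per_group)),
    group = rep(c("control", "case"), each = n_per_group)
  )
  feats <- unlist(feature_families(), use.names = FALSE)
  rows <- expand.grid(subject_id = subjects$subject_id,
                      trial_id = sprintf("T%02d", seq_len(n_trials)),
                      stringsAsFactors = FALSE)
  rows$stimulus_id <- sub("T", "F", rows$trial_id)
  is_case <- subjects$group[match(rows$subject_id,
                                  subjects$subject_id)] == "case"
  for (f in feats) {
    rows[[f]] <- rnorm(nrow(rows)) + ifelse(is_case, shift, 0)
  }
  list(features = tibble::as_tibble(rows), subjects = subjects)
}

test_that("the wide feature table has the documented shape and order", {
  toy <- toy_features(n_per_group = 1, n_trials = 3)
  tab <- build_feature_table(toy$features, toy$subjects)
  expect_equal(dim(tab$x), c(2L, 33L))
  expect_equal(levels(tab$y), c("control", "case"))
  # permuting the input rows leaves the table unchanged
  perm <- toy$features[sample(nrow(toy$features)), ]
  tab2 <- build_feature_table(perm, toy$subjects)
  expect_identical(tab$x, tab2$x)
  expect_identical(tab$y, tab2$y)
})

test_that("missing trials are imputed with the within-subject median", {
  toy <- toy_features(n_per_group = 2, n_trials = 3)
  ft <- toy$features[-which(toy$features$subject_id == "S01" &
                              toy$features$trial_id == "T03"), ]
  tab <- build_feature_table(ft, toy$subjects, n_trials = 3)
  kept <- ft[ft$subject_id == "S01", ]
  expect_equal(tab$x["S01", "fixation_count_t03"],
               median(kept$fixation_count))
})

test_that("lasso selection returns exactly k informative-capable columns", {
  set.seed(11)
  x <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(NULL, sprintf("c%02d", 1:60)))
  y <- factor(rep(c("control", "case"), each = 20),
              levels = c("control", "case"))
  x[, 1] <- x[, 1] + ifelse(y == "case", 2, 0)
  sel <- lasso_select(x, y, k = 10, seed = 1)
  expect_length(sel, 10L)
  expect_identical(sel, lasso_select(x, y, k = 10, seed = 1))
  # fewer columns than k: everything returned, flagged
  selall <- lasso_select(x[, 1:5], y, k = 10)
  expect_length(selall, 5L)
  expect_equal(attr(selall, "flag"), "all_columns")
})

test_that("lasso keeps a strongly separating column", {
  hits <- 0
  for (r in 1:10) {
    set.seed(600 + r)
    x <- matrix(rnorm(40 * 31), 40, 31,
                dimnames = list(NULL, c("signal", sprintf("n%02d", 1:30))))
    y <- factor(rep(c("control", "case"), each = 20),
                levels = c("control", "case"))
    x[, "signal"] <- rnorm(40, sd = 0.3) + ifelse(y == "case", 3, 0)
    sel <- lasso_select(x, y, k = 10, seed = r)
    hits <- hits + ("signal" %in% sel)
  }
  expect_gte(hits, 9L)
})

test_that("LOOCV is perfect on separable cohorts and has N folds", {
  toy <- toy_features(n_per_group = 6, n_trials = 3, shift = 6, seed = 2)
  tab <- build_feature_table(toy$features, toy$subjects)
  rep <- loocv_evaluate(tab, model = "svm", seed = 1)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$auroc, 1)
  expect_equal(rep$n_folds, 12L)
  folds <- attr(rep, "folds")
  expect_equal(nrow(folds), 12L)
  # accuracy recomputed from stored fold predictions
  expect_equal(rep$accuracy, 100 * mean(folds$pred == folds$truth))
})

test_that("every model family runs and scores sensibly when separable", {
  toy <- toy_features(n_per_group = 5, n_trials = 2, shift = 6, seed = 3)
  tab <- build_feature_table(toy$features, toy$subjects)
  rep_et <- loocv_evaluate(tab, model = "extra_trees", seed = 1)
  expect_gte(rep_et$auroc, 0.95)
  expect_gte(rep_et$accuracy, 90)
  # boosted trees on 9-sample folds carry fold-dependent base rates into
  # the pooled scores; accuracy stays high but pooled AUROC is capped
  for (m in c("xgboost", "dart")) {
    rep <- loocv_evaluate(tab, model = m, seed = 1)
    expect_gte(rep$auroc, 0.75)
    expect_gte(rep$accuracy, 80)
  }
})

test_that("AUROC is rank-based and AUCPR matches hand enumeration", {
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  score <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  a1 <- oculoscreen:::auroc(truth, score)
  expect_equal(a1, oculoscreen:::auroc(truth, rank(score)))
  # hand AUROC: pairs correctly ordered / all pos-neg pairs
  np <- sum(truth); nn <- sum(!truth)
  conc <- 0
  for (i in which(truth)) for (j in which(!truth)) {
    conc <- conc + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  expect_equal(a1, conc / (np * nn))
  # hand AP: precision at each recall step
  expect_equal(oculoscreen:::aucpr(truth, score),
               (1 / 3) * 1 + (1 / 3) * 1 + (1 / 3) * 3 / 4)
})

test_that("fold models never depend on the held-out subject", {
  toy <- toy_features(n_per_group = 4, n_trials = 2, shift = 2, seed = 5)
  tab <- build_feature_table(toy$features, toy$subjects)
  rep1 <- loocv_evaluate(tab, model = "svm", k = 5, seed = 1)
  tab2 <- tab
  tab2$x[3, ] <- tab2$x[3, ] + 1000   # corrupt one subject
  rep2 <- loocv_evaluate(tab2, model = "svm", k = 5, seed = 1)
  sel1 <- attr(rep1, "selected")
  sel2 <- attr(rep2, "selected")
  expect_identical(sel1[[3]], sel2[[3]])   # fold 3 trains without subject 3
})

test_that("permuted labels drive AUROC to chance", {
  # null features: pooled LOOCV scores under label permutation are only
  # centred at 0.5 when the feature matrix carries no two-cluster split
  toy <- toy_features(n_per_group = 6, n_trials = 2, shift = 0, seed = 6)
  set.seed(99)
  aucs <- replicate(40, {
    perm <- toy$subjects
    perm$group <- sample(perm$group)
    tab <- build_feature_table(toy$features, perm)
    loocv_evaluate(tab, model = "svm", k = 5, seed = 1)$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("the evaluation grid covers feature sets x model families", {
  toy <- toy_features(n_per_group = 4, n_trials = 2, shift = 4, seed = 7)
  grid <- evaluate_feature_sets(toy$features, toy$subjects,
                                models = c("svm", "xgboost"),
                                feature_sets = c("fixation", "multi"),
                                k = 5, seed = 1)
  expect_equal(nrow(grid), 4L)
  expect_setequal(unique(grid$feature_set), c("fixation", "multi"))
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 100))
  expect_true(all(grid$auroc >= 0 & grid$auroc <= 1))
  # deterministic re-run
  grid2 <- evaluate_feature_sets(toy$features, toy$subjects,
                                 models = c("svm", "xgboost"),
                                 feature_sets = c("fixation", "multi"),
                                 k = 5, seed = 1)
  expect_equal(grid, grid2)
})
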