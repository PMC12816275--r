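#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk tests are run on each group; when both are compatible with
#' normality (p >= `alpha_normality`) an independent two-sample t-test
#' (pooled variance by default) is used with Cohen's d as effect size,
#' otherwise a Mann-Whitney U test with the rank-biserial correlation
#' `r = 1 - 2U / (n_a n_b)`. All p values are two-tailed. The 95%
#' confidence interval of the effect size is obtained by seeded percentile
#' bootstrap.
#'
#' @param values_a,values_b Numeric observations for the two groups
#'   (NAs dropped; at least 3 per group).
#' @param alpha_normality Shapiro-Wilk gate level.
#' @param var_equal Pooled-variance t-test (`TRUE`, default) or Welch.
#' @param n_boot Bootstrap resamples for the effect-size CI (0 disables).
#' @param conf CI coverage.
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `test`, `statistic`, `p`, `effect`,
#'   `effect_name`, `ci_lo`, `ci_hi`, group means and SEMs, the two
#'   Shapiro p values, and a `flag` (`"ok"`, `"zero_variance"`).
#' @examples
#' compare_groups(rnorm(10), rnorm(12, 1), n_boot = 200, seed = 1)
#' @export
compare_groups <- function(values_a, values_b, alpha_normality = 0.05,
                           var_equal = TRUE, n_boot = 10000,
                           conf = 0.95, seed = 1L) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  stopifnot(length(a) >= 3, length(b) >= 3)
  base <- tibble::tibble(
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
    mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b))
  )
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(test = NA_character_, statistic = NA_real_,
                     p = NA_real_, effect = NA_real_,
                     effect_name = NA_character_, ci_lo = NA_real_,
                     ci_hi = NA_real_, shapiro_p_a = NA_real_,
                     shapiro_p_b = NA_real_, flag = "zero_variance"),
      base))
  }
  sw <- function(v) {
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }
  pa <- sw(a); pb <- sw(b)
  normal <- pa >= alpha_normality && pb >= alpha_normality

  if (normal) {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    eff_fun <- cohens_d
    test <- "t"; effect_name <- "cohens_d"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    eff_fun <- rank_biserial
    test <- "mann-whitney"; effect_name <- "rank_biserial_r"
  }
  eff <- eff_fun(a, b)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      eff_fun(sample(a, replace = TRUE), sample(b, replace = TRUE))
    }, numeric(1)))
    ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  dplyr::bind_cols(
    tibble::tibble(test = test,
                   statistic = unname(ht$statistic),
                   p = ht$p.value,
                   effect = eff, effect_name = effect_name,
                   ci_lo = ci[1], ci_hi = ci[2],
                   shapiro_p_a = pa, shapiro_p_b = pb, flag = "ok"),
    base)
}

cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

# Mann-Whitney U computed from ranks (ties averaged); r = 1 - 2U/(na*nb)
# with U the count of (a, b) pairs where a > b.
rank_biserial <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  1 - 2 * u / (na * nb)
}

#' Compare every feature between groups
#'
#' @param features Per-trial feature tibble from [extract_features()].
#' @param subjects Tibble with `subject_id`, `group` (groups `"control"`
#'   and `"case"`; group a = control).
#' @param unit `"subject"` (default; per-subject trial means are the
#'   observations — statistically preferred as trials are nested in
#'   subjects) or `"trial"` (every trial is an observation).
#' @param feature_names Features to test (default: all 11).
#' @param ... Passed to [compare_groups()].
#' @return Tibble, one row per feature, with the [compare_groups()]
#'   columns.
#' @export
compare_features <- function(features, subjects,
                             unit = c("subject", "trial"),
                             feature_names = unlist(feature_families(),
                                                    use.names = FALSE),
                             ...) {
  unit <- match.arg(unit)
  grp <- subjects$group[match(features$subject_id, subjects$subject_id)]
  rows <- lapply(feature_names, function(feat) {
    v <- features[[feat]]
    if (unit == "subject") {
      means <- tapply(v, features$subject_id, mean, na.rm = TRUE)
      g <- subjects$group[match(names(means), subjects$subject_id)]
      a <- means[g == "control"]; b <- means[g == "case"]
    } else {
      a <- v[grp == "control"]; b <- v[grp == "case"]
    }
    dplyr::bind_cols(tibble::tibble(feature = feat, unit = unit),
                     compare_groups(a, b, ...))
  })
  dplyr::bind_rows(rows)
}
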