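#' Read a raw gaze table
#'
#' Reads a delimited gaze file with the documented vendor-neutral header:
#' `subject_id, trial_id, stimulus_id, t_ms, x_px, y_px, valid` (an
#' optional `group` column attaches cohort labels). Rows are grouped into
#' per-(subject, trial) streams; trials whose timestamps are not strictly
#' increasing are rejected with a message, the rest are loaded.
#'
#' @param path File path.
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @return A `gaze_cohort`-like list with `samples`, `subjects` (group
#'   column `NA` when absent), `rejected` (keys of rejected trials) and
#'   `sampling_hz`.
#' @export
read_gaze_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  required <- c("subject_id", "trial_id", "stimulus_id", "t_ms",
                "x_px", "y_px", "valid")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("t_ms", "x_px", "y_px")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  bad_rows <- which(!is.finite(raw$t_ms))
  if (length(bad_rows)) {
    message("dropping ", length(bad_rows), " malformed row(s): lines ",
            paste(utils::head(bad_rows + 1L, 10), collapse = ", "))
    raw <- raw[-bad_rows, ]
  }
  raw$valid <- as.logical(raw$valid) |
    (is.numeric(raw$valid) & raw$valid != 0)

  key <- paste(raw$subject_id, raw$trial_id, sep = "|")
  keep <- rep(TRUE, nrow(raw))
  rejected <- character(0)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    if (any(diff(raw$t_ms[idx]) <= 0)) {
      keep[idx] <- FALSE
      rejected <- c(rejected, kk)
      message("rejecting trial ", kk, ": timestamps not strictly increasing")
    }
  }
  samples <- tibble::as_tibble(raw[keep, c(required,
                                           intersect("group", names(raw)))])
  subjects <- unique(samples[, c("subject_id",
                                 intersect("group", names(samples)))])
  if (!"group" %in% names(subjects)) subjects$group <- NA_character_
  samples$group <- NULL
  structure(
    list(samples = samples, subjects = tibble::as_tibble(subjects),
         rejected = rejected, sampling_hz = infer_hz(samples$t_ms)),
    class = "gaze_cohort"
  )
}

#' Write a gaze table
#'
#' @param cohort A `gaze_cohort` (or long gaze tibble).
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_gaze_table <- function(cohort, path, sep = ",") {
  samples <- if (inherits(cohort, "gaze_cohort")) cohort$samples else cohort
  if (inherits(cohort, "gaze_cohort") &&
      !all(is.na(cohort$subjects$group))) {
    samples$group <-
      cohort$subjects$group[match(samples$subject_id,
                                  cohort$subjects$subject_id)]
  }
  utils::write.table(samples, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested list mirroring the analysis stages; every block's keys are
#' validated, unknown keys are rejected. Defaults are the package's
#' documented analysis defaults.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    geometry = list(screen_width_px = 1920L, screen_height_px = 1080L,
                    screen_diagonal_mm = 23.8 * 25.4,
                    viewing_distance_mm = 700),
    preprocessing = list(max_gap_ms = 75, blink_min_ms = 75,
                         blink_max_ms = 500, blink_margin_samples = 1L,
                         max_missing_frac = 0.20),
    detection = list(velocity_threshold_deg_s = 30, min_fixation_ms = 60,
                     detector = "ivt"),
    features = list(units = "deg", entropy_rows = 8L, entropy_cols = 8L,
                    roi_link_deg = 2.0, roi_min_members = 2L,
                    vwi_orientation = "mean_on_peak"),
    similarity = list(modulation = 0.83),
    reliability = list(aoi_center_x = 960, aoi_center_y = 540,
                       aoi_width = 600, aoi_height = 450,
                       icc_subsets = c(3L, 5L, 7L), icc_form = "ICC3k"),
    stats = list(unit = "subject", n_boot = 2000L, var_equal = TRUE),
    ml = list(k = 10L, models = c("svm", "extra_trees", "xgboost", "dart"),
              feature_sets = c("saccadic", "fixation", "scanpath", "multi")),
    simulate = list(n_subjects_control = 20L, n_subjects_case = 20L,
                    n_trials = 10L),
    seed = 1L
  )
}

#' Load and validate a YAML pipeline configuration
#'
#' User values are merged over [default_config()]; unknown keys anywhere
#' in the tree cause an error.
#'
#' @param path YAML file (or `NULL` for pure defaults).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    check_keys <- function(user, template, prefix = "") {
      unknown <- setdiff(names(user), names(template))
      if (length(unknown)) {
        stop("unknown config key(s): ",
             paste0(prefix, unknown, collapse = ", "), call. = FALSE)
      }
      for (nm in names(user)) {
        if (is.list(template[[nm]]) && is.list(user[[nm]])) {
          check_keys(user[[nm]], template[[nm]], paste0(prefix, nm, "."))
        }
      }
    }
    check_keys(user, cfg)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

config_geom <- function(config) {
  g <- config$geometry
  screen_geometry(g$screen_width_px, g$screen_height_px,
                  g$screen_diagonal_mm, g$viewing_distance_mm)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> event detection -> features ->
#' {group statistics, scanpath similarity, reliability, classification}
#' on a gaze cohort (read from `gaze_path`, or simulated from the config's
#' `simulate` block when no path is given) and writes the report bundle:
#' `features.csv`, `events.csv`, `stats.csv`, `similarity_intra.csv`,
#' `similarity_inter.csv`, `reliability.json`, `classification.json` and
#' `run_log.txt`. Every output carries the configuration hash.
#'
#' @param config Configuration list from [load_config()].
#' @param out_dir Output directory (created if needed).
#' @param gaze_path Optional gaze CSV; when `NULL` a synthetic cohort is
#'   generated.
#' @param stages Subset of `c("stats", "similarity", "reliability", "ml")`
#'   to run after feature extraction.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         gaze_path = NULL,
                         stages = c("stats", "similarity",
                                    "reliability", "ml")) {
  hash <- config_hash(config)
  geom <- config_geom(config)
  log_lines <- c(sprintf("oculoscreen %s",
                         as.character(utils::packageVersion("oculoscreen"))),
                 sprintf("config_md5 %s", hash),
                 sprintf("seed %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("input", {
    if (!is.null(gaze_path)) {
      read_gaze_table(gaze_path)
    } else {
      sim <- config$simulate
      spec <- cohort_spec(
        n_subjects_per_group = c(sim$n_subjects_control,
                                 sim$n_subjects_case),
        n_trials = sim$n_trials, seed = config$seed
      )
      simulate_cohort(spec, geom)
    }
  })

  pre <- config$preprocessing
  pp <- stage("preprocess", preprocess_cohort(
    cohort, max_gap_ms = pre$max_gap_ms, blink_min_ms = pre$blink_min_ms,
    blink_max_ms = pre$blink_max_ms,
    margin_samples = pre$blink_margin_samples,
    max_missing_frac = pre$max_missing_frac
  ))
  log_lines <- c(log_lines,
                 sprintf("trials_kept %d", length(pp$trials)),
                 sprintf("trials_dropped %d", nrow(pp$dropped)),
                 sprintf("qc_drop %s frac=%.3f",
                         pp$dropped$key, pp$dropped$missing_frac))

  det <- config$detection
  fea <- config$features
  features <- stage("features", extract_features(
    pp, geom,
    detect_args = list(velocity_threshold_deg_s = det$velocity_threshold_deg_s,
                       min_fixation_ms = det$min_fixation_ms,
                       detector = det$detector),
    feature_args = list(units = fea$units,
                        entropy_grid = c(fea$entropy_rows, fea$entropy_cols),
                        roi_link_deg = fea$roi_link_deg,
                        roi_min_members = fea$roi_min_members,
                        vwi_orientation = fea$vwi_orientation)
  ))
  subjects <- cohort$subjects

  results <- list(config = config, hash = hash, features = features,
                  subjects = subjects, dropped = pp$dropped)

  if ("stats" %in% stages) {
    st <- config$stats
    results$stats <- stage("stats", compare_features(
      features, subjects, unit = st$unit, n_boot = st$n_boot,
      var_equal = st$var_equal, seed = config$seed
    ))
  }
  if ("similarity" %in% stages) {
    set <- cohort_scanpaths(features, geom = geom)
    mod <- config$similarity$modulation
    results$similarity_intra <-
      stage("similarity", intra_individual_similarity(set, mod))
    results$similarity_inter <-
      stage("similarity", inter_individual_similarity(set, subjects, mod))
  }
  if ("reliability" %in% stages) {
    rel <- config$reliability
    aoi <- aoi_rect(rel$aoi_center_x, rel$aoi_center_y,
                    rel$aoi_width, rel$aoi_height)
    ev <- attr(features, "events")
    props <- t(vapply(ev, function(e) aoi_proportions(e, aoi), numeric(2)))
    results$aoi <- tibble::tibble(
      key = rownames(props),
      prop_count = props[, 1], prop_duration = props[, 2]
    )
    results$icc <- stage("reliability", icc_trial_subsets(
      features, subsets = rel$icc_subsets, form = rel$icc_form
    ))
  }
  if ("ml" %in% stages) {
    ml <- config$ml
    results$classification <- stage("ml", evaluate_feature_sets(
      features, subjects, models = ml$models,
      feature_sets = ml$feature_sets, k = ml$k, seed = config$seed
    ))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      p <- file.path(out_dir, name)
      con <- file(p, "w")
      writeLines(sprintf("# config_md5 %s", hash), con)
      utils::write.table(as.data.frame(df), con, sep = ",",
                         row.names = FALSE, quote = FALSE)
      close(con)
    }
    wcsv(features, "features.csv")
    ev <- attr(features, "events")
    events_df <- dplyr::bind_rows(lapply(names(ev), function(k) {
      e <- ev[[k]]
      dplyr::bind_rows(
        dplyr::mutate(e$fixations, type = "fixation", key = k),
        dplyr::mutate(e$saccades, type = "saccade", key = k)
      )
    }))
    wcsv(events_df, "events.csv")
    if (!is.null(results$stats)) wcsv(results$stats, "stats.csv")
    if (!is.null(results$similarity_intra)) {
      wcsv(results$similarity_intra, "similarity_intra.csv")
      wcsv(results$similarity_inter, "similarity_inter.csv")
    }
    if (!is.null(results$icc)) {
      jsonlite::write_json(
        list(config_md5 = hash,
             aoi = results$aoi, icc = results$icc),
        file.path(out_dir, "reliability.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(results$classification)) {
      jsonlite::write_json(
        list(config_md5 = hash, grid = results$classification),
        file.path(out_dir, "classification.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA
      )
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(results)
}
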