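#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. All values are
#' echoed into the run manifest so a results bundle is self-describing.
#'
#' @param plaque_counts Character vector of plaque-count CSV paths.
#' @param plate_measurements,plate_layout Optional growth-plate CSVs.
#' @param dialect Measurement dialect, `"long"` or `"wide"`.
#' @param col_map Optional column mapping applied to the plaque-count
#'   files (see [read_plaque_counts()]).
#' @param countable_range Countable plaque window for titering.
#' @param survival A [survival_config()] of reference rules.
#' @param decay_main_effect Named logical: per stressor, whether the
#'   ANCOVA includes a pooled duration main effect before the interaction.
#'   The heat-gradient model has none (per-stratum slopes only); the
#'   solute models include it.
#' @param direction One-tailed slope-test direction (`"less"` = decay).
#' @param bonferroni_m Bonferroni family size for slope tests; `NULL`
#'   uses the number of estimable strata per stressor.
#' @param smoothing_method,smoothing_window,prominence Growth-curve
#'   settings (see [extract_peaks()]).
#' @param target_pfu Dosing target for the exclusion flag.
#' @param alpha Significance level for Tukey letters.
#' @param out_dir Output directory for the results bundle.
#' @return A `run_config` object.
#' @export
run_config <- function(plaque_counts,
                       plate_measurements = NULL, plate_layout = NULL,
                       dialect = "long", col_map = NULL,
                       countable_range = c(3, 300),
                       survival = survival_config(),
                       decay_main_effect = c(heat = FALSE, urea = TRUE,
                                             saline = TRUE, none = FALSE),
                       direction = "less",
                       bonferroni_m = NULL,
                       smoothing_method = "moving_median",
                       smoothing_window = 5,
                       prominence = NULL,
                       target_pfu = 200,
                       alpha = 0.05,
                       out_dir = tempfile("phagestress_run_")) {
  paths <- c(plaque_counts, plate_measurements, plate_layout)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0) {
    abort(paste0("input file(s) not found: ",
                 paste(missing_files, collapse = ", ")),
          class = "phagestress_io_error")
  }
  structure(list(plaque_counts = plaque_counts,
                 plate_measurements = plate_measurements,
                 plate_layout = plate_layout,
                 dialect = dialect, col_map = col_map,
                 countable_range = countable_range,
                 survival = survival,
                 decay_main_effect = decay_main_effect,
                 direction = direction,
                 bonferroni_m = bonferroni_m,
                 smoothing_method = smoothing_method,
                 smoothing_window = smoothing_window,
                 prominence = prominence,
                 target_pfu = target_pfu,
                 alpha = alpha,
                 out_dir = out_dir),
            class = "run_config")
}

#' Decay analysis for one stressor's survival observations
#'
#' Handles the bookkeeping around [fit_stratified_decay()] for real
#' experiments: strata whose observations are entirely censored (or have
#' fewer than two distinct uncensored durations) cannot carry a slope and
#' are reported as NA rows rather than errors, mirroring the
#' "temperatures at which every measure fell below detection" case.
#'
#' @param observations Survival rows for one stressor.
#' @param stratum,include_main_effect See [fit_stratified_decay()].
#' @param direction,n_tests See [slope_tests()].
#' @return List: `fit` (`decay_fit`), `slopes` (slope-test tibble with NA
#'   rows for inestimable strata), `ancova`, `dropped_levels`.
#' @export
decay_analysis <- function(observations, stratum = "level",
                           include_main_effect = FALSE,
                           direction = "less", n_tests = NULL) {
  all_levels <- sort(unique(observations[[stratum]]))
  unc <- observations[!observations$censored, , drop = FALSE]
  n_dur <- tapply(unc$duration_min, unc[[stratum]],
                  function(v) length(unique(v)))
  estimable <- names(n_dur)[!is.na(n_dur) & n_dur >= 2]
  dropped <- setdiff(as.character(all_levels), estimable)
  keep <- as.character(observations[[stratum]]) %in% estimable
  fit <- fit_stratified_decay(observations[keep, , drop = FALSE],
                              stratum = stratum,
                              include_main_effect = include_main_effect)
  slopes <- slope_tests(fit, direction = direction,
                        n_tests = if (is.null(n_tests)) length(estimable)
                                  else n_tests,
                        all_levels = as.character(all_levels))
  anc <- ancova_table(observations[keep, , drop = FALSE], stratum = stratum,
                      include_main_effect = include_main_effect)
  list(fit = fit, slopes = slopes, ancova = anc, dropped_levels = dropped)
}

#' Run the full analysis pipeline
#'
#' Reads raw plaque-count (and optionally growth-plate) data, titers every
#' sample with LOD censoring, normalizes to percent survival, fits the
#' per-stressor decay models with slope tests and sequential ANCOVA, runs
#' the growth-curve fitness comparison, and writes the results bundle:
#' `survival.csv`, `slope_tests.csv`, `ancova.csv`, and (with plate data)
#' `peaks.csv` and `fitness_stats.json`, plus a `manifest.json` echoing
#' the configuration, input checksums and exclusion counts. The pipeline
#' uses no random numbers: rerunning a config on the same inputs
#' reproduces the bundle byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the result tables (`survival`, `slopes`,
#'   `ancova`, `peaks`, `fitness`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- with_stage("read_plaque_counts", {
    dplyr::bind_rows(purrr::map(config$plaque_counts, read_plaque_counts,
                                col_map = config$col_map))
  })
  titers <- with_stage("titering", {
    titer_table(counts, countable_range = config$countable_range)
  })
  survival <- with_stage("survival", {
    survival_table(titers, config$survival)
  })
  survival_out <- survival[, c("sample_id", "stressor", "level",
                               "duration_min", "stock_id", "pfu_per_ml",
                               "lod_pfu_per_ml", "percent_survival",
                               "log10_percent", "censored", "reference_id")]
  write_results(survival_out, file.path(config$out_dir, "survival.csv"))

  stressors <- setdiff(unique(survival$stressor), "none")
  slopes <- anc <- NULL
  analyses <- list()
  for (s in stressors) {
    res <- with_stage(paste0("decay_fit[", s, "]"), {
      decay_analysis(
        survival[survival$stressor == s, , drop = FALSE],
        include_main_effect = isTRUE(config$decay_main_effect[[s]]),
        direction = config$direction,
        n_tests = config$bonferroni_m
      )
    })
    analyses[[s]] <- res
    slopes <- dplyr::bind_rows(slopes,
                               dplyr::mutate(res$slopes, stressor = s,
                                             .before = 1))
    anc <- dplyr::bind_rows(anc,
                            dplyr::mutate(res$ancova, stressor = s,
                                          .before = 1))
  }
  write_results(slopes, file.path(config$out_dir, "slope_tests.csv"))
  write_results(anc, file.path(config$out_dir, "ancova.csv"))

  peaks <- fitness <- NULL
  if (!is.null(config$plate_measurements)) {
    plate <- with_stage("read_plate_timeseries", {
      read_plate_timeseries(config$plate_measurements, config$plate_layout,
                            config$dialect)
    })
    peaks <- with_stage("extract_peaks", {
      extract_peaks(plate, method = config$smoothing_method,
                    window = config$smoothing_window,
                    prominence = config$prominence,
                    target_pfu = config$target_pfu)
    })
    write_results(peaks, file.path(config$out_dir, "peaks.csv"))
    fitness <- with_stage("fitness_comparison", {
      fitness_comparison(peaks, alpha = config$alpha)
    })
    jsonlite::write_json(
      list(anova = fitness$anova, tukey = fitness$tukey,
           letters = fitness$letters, group_means = fitness$group_means,
           welch = fitness$welch, mse = fitness$mse,
           df_resid = fitness$df_resid, n_excluded = fitness$n_excluded),
      file.path(config$out_dir, "fitness_stats.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
  }

  manifest <- list(
    package = "phagestress",
    package_version = as.character(utils::packageVersion("phagestress")),
    inputs = lapply(
      setNames(nm = c(config$plaque_counts, config$plate_measurements,
                      config$plate_layout)),
      function(p) unname(tools::md5sum(p))
    ),
    config = config_manifest(config),
    counts = list(
      n_plates = nrow(counts),
      n_samples = nrow(titers),
      n_censored = sum(survival$censored),
      n_survival = nrow(survival),
      dropped_strata = lapply(analyses, function(a) a$dropped_levels),
      n_wells_excluded = if (!is.null(fitness)) fitness$n_excluded else 0
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(survival = survival_out, slopes = slopes, ancova = anc,
                 peaks = peaks, fitness = fitness, manifest = manifest,
                 analyses = analyses))
}

# every tunable that affects output, in plain-JSON form
config_manifest <- function(config) {
  list(
    dialect = config$dialect,
    col_map = as.list(config$col_map),
    countable_range = config$countable_range,
    survival = unclass(config$survival),
    decay_main_effect = as.list(config$decay_main_effect),
    direction = config$direction,
    bonferroni_m = config$bonferroni_m,
    smoothing_method = config$smoothing_method,
    smoothing_window = config$smoothing_window,
    prominence = config$prominence,
    target_pfu = config$target_pfu,
    alpha = config$alpha
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage ", stage, ": ", conditionMessage(e)),
          class = class(e)[1])
  })
}

#' Mapping of an archived-study directory onto the pipeline inputs
#'
#' Describes where each cleaned data table lives inside an archive
#' directory and how its columns map onto the package's canonical names.
#' Each entry is `NULL` (analysis skipped) or
#' `list(file = "name.csv", col_map = c(canonical = "archived"))`.
#' Expected canonical columns: survival tables need the stratifier
#' (`level` or `stock_id`), `duration_min`, `log10_percent` (or
#' `percent_survival`) and optionally `censored`; the fitness table needs
#' `treatment`, `stock_id`, `peak_od` and optionally `control_type`,
#' `excluded`.
#'
#' @param heat_gradient,heat_timecourse,fitness,saline,urea Entries as
#'   described above. Defaults assume canonical file names and columns.
#' @return A `reproduce_mapping` list.
#' @export
reproduce_mapping <- function(
    heat_gradient = list(file = "heat_gradient_survival.csv"),
    heat_timecourse = list(file = "heat_timecourse_survival.csv"),
    fitness = list(file = "fitness_peaks.csv"),
    saline = list(file = "saline_survival.csv"),
    urea = list(file = "urea_survival.csv")) {
  structure(list(heat_gradient = heat_gradient,
                 heat_timecourse = heat_timecourse,
                 fitness = fitness, saline = saline, urea = urea),
            class = "reproduce_mapping")
}

#' The study's printed statistics used as reproduction targets
#'
#' Per-temperature decay slopes and one-tailed t statistics with their
#' Bonferroni-adjusted p-values, the ANCOVA F statistics of the heat,
#' saline and urea analyses, the long-time-course slopes, the fitness
#' ANOVA treatment F, and the Welch control contrast, each with the
#' number of decimals at which it was reported.
#'
#' @return Tibble: `quantity`, `printed`, `decimals`.
#' @export
printed_statistics <- function() {
  tibble::tribble(
    ~quantity,                  ~printed, ~decimals,
    "slope_55",                   0.0008,        4,
    "slope_60",                   0.0005,        4,
    "slope_65",                  -0.0028,        4,
    "slope_70",                  -0.0182,        4,
    "t_55",                         0.98,        2,
    "t_60",                         0.58,        2,
    "t_65",                        -3.35,        2,
    "t_70",                       -22.08,        2,
    "p_bonf_55",                       1,        2,
    "p_bonf_60",                       1,        2,
    "p_bonf_65",                   0.020,        3,
    "heat_interaction_F",         125.01,        2,
    "timecourse_duration_F",       519.1,        1,
    "timecourse_stock_F",           2.54,        2,
    "timecourse_interaction_F",     0.95,        2,
    "slope_70_timecourse_ref",   -0.0167,        4,
    "slope_stockA_timecourse",   -0.0161,        4,
    "fitness_treatment_F",          14.2,        1,
    "welch_t",                     -4.18,        2,
    "welch_df",                     8.86,        2,
    "saline_interaction_F",         5.57,        2,
    "urea_interaction_F",           1.19,        2
  )
}

#' Recompute the study's statistics from an archived data directory
#'
#' Runs the decay and fitness analyses on cleaned archived data tables
#' (mapped by a [reproduce_mapping()]) and compares every recomputed
#' statistic with its printed value at printed precision. Analyses whose
#' entry is `NULL` or whose file is missing are reported as `NA` rows
#' rather than errors, so partial archives still produce a report.
#'
#' @param archive_dir Directory holding the archived CSVs.
#' @param mapping A [reproduce_mapping()].
#' @return List: `report` (tibble `quantity`, `computed`, `printed`,
#'   `decimals`, `pass`) and `details` (the fitted tables per analysis).
#' @export
reproduce_study <- function(archive_dir, mapping = reproduce_mapping()) {
  stopifnot(inherits(mapping, "reproduce_mapping"))
  computed <- list()
  details <- list()

  surv <- function(entry) {
    path <- file.path(archive_dir, entry$file)
    if (!file.exists(path)) return(NULL)
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    x <- apply_col_map(x, entry$col_map)
    if (!"log10_percent" %in% names(x)) {
      if (!"percent_survival" %in% names(x)) {
        abort(paste0("cannot map ", entry$file,
                     ": need log10_percent or percent_survival"),
              class = "phagestress_schema_error")
      }
      x$log10_percent <- log10(x$percent_survival)
    }
    if (!"censored" %in% names(x)) x$censored <- FALSE
    x
  }

  if (!is.null(mapping$heat_gradient)) {
    hg <- surv(mapping$heat_gradient)
    if (!is.null(hg)) {
      res <- decay_analysis(hg, stratum = "level",
                            include_main_effect = FALSE, n_tests = 4)
      details$heat_gradient <- res
      sl <- res$slopes
      for (lv in c(55, 60, 65, 70)) {
        i <- match(as.character(lv), sl$level)
        computed[[paste0("slope_", lv)]] <- sl$slope[i]
        computed[[paste0("t_", lv)]] <- sl$t_value[i]
      }
      computed$p_bonf_55 <- sl$p_bonferroni[match("55", sl$level)]
      computed$p_bonf_60 <- sl$p_bonferroni[match("60", sl$level)]
      computed$p_bonf_65 <- sl$p_bonferroni[match("65", sl$level)]
      icol <- grepl(":", res$ancova$term)
      computed$heat_interaction_F <- res$ancova$statistic[icol][1]
    }
  }
  if (!is.null(mapping$heat_timecourse)) {
    tc <- surv(mapping$heat_timecourse)
    if (!is.null(tc)) {
      res <- decay_analysis(tc, stratum = "stock_id",
                            include_main_effect = TRUE)
      details$heat_timecourse <- res
      a <- res$ancova
      computed$timecourse_stock_F <- a$statistic[a$term == "stock_id"]
      computed$timecourse_duration_F <- a$statistic[a$term == "duration_min"]
      computed$timecourse_interaction_F <-
        a$statistic[grepl(":", a$term)][1]
      first_stock <- res$slopes$level[1]
      computed$slope_stockA_timecourse <-
        res$slopes$slope[res$slopes$level == first_stock]
    }
  }
  if (!is.null(mapping$fitness)) {
    path <- file.path(archive_dir, mapping$fitness$file)
    if (file.exists(path)) {
      pk <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      pk <- apply_col_map(pk, mapping$fitness$col_map)
      if (!"control_type" %in% names(pk)) pk$control_type <- NA_character_
      if (!"excluded" %in% names(pk)) pk$excluded <- FALSE
      fc <- fitness_comparison(pk)
      details$fitness <- fc
      computed$fitness_treatment_F <-
        fc$anova$statistic[fc$anova$term == "treatment"]
      if (!is.null(fc$welch)) {
        computed$welch_t <- fc$welch$t
        computed$welch_df <- fc$welch$df
      }
    }
  }
  for (s in c("saline", "urea")) {
    if (is.null(mapping[[s]])) next
    x <- surv(mapping[[s]])
    if (is.null(x)) next
    res <- decay_analysis(x, stratum = "level", include_main_effect = TRUE)
    details[[s]] <- res
    computed[[paste0(s, "_interaction_F")]] <-
      res$ancova$statistic[grepl(":", res$ancova$term)][1]
  }
  if (!is.null(details$heat_gradient)) {
    # per-stratum refit of the hottest estimable gradient condition alone,
    # the comparison the time-course section quotes
    hg <- surv(mapping$heat_gradient)
    sub <- hg[hg$level == 70 & !hg$censored, , drop = FALSE]
    if (nrow(sub) >= 3) {
      x <- cbind(`(Intercept)` = 1, duration = sub$duration_min)
      computed$slope_70_timecourse_ref <-
        fit_ols(x, sub$log10_percent)$coefficients[["duration"]]
    }
  }

  report <- printed_statistics()
  report$computed <- vapply(report$quantity, function(q) {
    v <- computed[[q]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }, numeric(1))
  report$pass <- !is.na(report$computed) &
    abs(round(report$computed, report$decimals) - report$printed) <
      10^-(report$decimals + 6)
  list(report = report[, c("quantity", "computed", "printed",
                           "decimals", "pass")],
       details = details)
}
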