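#' Read and validate a plaque-count table
#'
#' Reads a CSV of raw plaque-assay plate counts. Each row is one plate:
#' the sample it came from, the stress condition applied to that sample,
#' the serial dilution the plate received (`dilution_exponent` d means the
#' plate was inoculated with a `10^-d` dilution of the sample), the plated
#' volume, and the plaque count. Units are fixed package-wide: minutes for
#' durations, mL for volumes, mol/L for solute concentrations, degrees C
#' for temperatures.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(plaques = "plaque_count")`. Columns not mentioned are taken as-is.
#' @return A tibble with columns `sample_id`, `stressor`, `level`,
#'   `duration_min`, `stock_id`, `dilution_exponent`, `volume_ml`,
#'   `plaques`, and `plate` (within-sample plate replicate index, created
#'   if absent), in file row order.
#' @seealso [titer_table()] to turn plate counts into PFU/mL titers.
#' @export
#' @examples
#' path <- system.file("extdata", "example_plaque_counts.csv",
#'                     package = "phagestress")
#' read_plaque_counts(path)
read_plaque_counts <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "phagestress_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- apply_col_map(raw, col_map)
  as_plaque_counts(raw)
}

#' Validate an in-memory plaque-count table
#'
#' Applies the schema and invariant checks of [read_plaque_counts()] to a
#' data frame already in memory (e.g. simulator output).
#'
#' @param x A data frame with the plaque-count columns.
#' @return A validated tibble (see [read_plaque_counts()]).
#' @export
as_plaque_counts <- function(x) {
  required <- c("sample_id", "stressor", "level", "duration_min",
                "stock_id", "dilution_exponent", "volume_ml", "plaques")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("plaque-count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phagestress_schema_error")
  }
  x <- tibble::as_tibble(x)
  x$sample_id <- as.character(x$sample_id)
  x$stock_id <- as.character(x$stock_id)
  x$stressor <- as.character(x$stressor)

  bad_stressor <- !x$stressor %in% c("heat", "urea", "saline", "none")
  if (any(bad_stressor)) {
    abort(row_msg("unknown stressor", which(bad_stressor)),
          class = "phagestress_validation_error")
  }
  check_rows(x, is.finite(x$level), "non-finite level")
  check_rows(x, is.finite(x$duration_min) & x$duration_min >= 0,
             "negative or non-finite duration_min")
  check_rows(x, is.finite(x$dilution_exponent) &
               x$dilution_exponent >= 0 &
               x$dilution_exponent == round(x$dilution_exponent),
             "dilution_exponent must be a non-negative integer")
  check_rows(x, is.finite(x$volume_ml) & x$volume_ml > 0,
             "volume_ml must be finite and positive")
  check_rows(x, is.finite(x$plaques) & x$plaques >= 0 &
               x$plaques == round(x$plaques),
             "plaques must be a non-negative integer")
  x$dilution_exponent <- as.integer(round(x$dilution_exponent))
  # counts on barely-diluted plates of a dense lysate can exceed the
  # 32-bit integer range; keep those as integer-valued doubles
  if (max(x$plaques) < .Machine$integer.max) {
    x$plaques <- as.integer(round(x$plaques))
  } else {
    x$plaques <- round(x$plaques)
  }

  if (!"plate" %in% names(x)) {
    x <- x |>
      dplyr::group_by(.data$sample_id, .data$dilution_exponent) |>
      dplyr::mutate(plate = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  keys <- paste(x$sample_id, x$dilution_exponent, x$plate, sep = "\r")
  if (anyDuplicated(keys) > 0) {
    abort(row_msg("duplicate (sample_id, dilution_exponent, plate) key",
                  which(duplicated(keys))),
          class = "phagestress_validation_error")
  }
  x
}

#' Read plate-reader OD600 time series with a well layout
#'
#' Reads optical-density measurements for a multi-well plate together with
#' a layout table describing each well (treatment label, phage stock,
#' inoculated PFU, target MOI, control type). Two measurement dialects are
#' supported: `"long"` (`well_id,time_min,od600`) and `"wide"` (a
#' `time_min` column plus one column per well). Both yield identical
#' results for equivalent content.
#'
#' Phage-free control wells may leave `inoculated_pfu`/`target_moi` empty.
#'
#' @param measurements_path CSV of OD600 readings (long or wide).
#' @param layout_path CSV with columns `well_id`, `treatment`, `stock_id`,
#'   `inoculated_pfu`, `target_moi` and optionally `control_type`.
#' @param dialect `"long"` or `"wide"`.
#' @return A tibble with one row per (well, timepoint): the layout columns
#'   joined to `time_min` and `od600`, ordered by well then time.
#' @seealso [extract_peaks()] for the downstream peak statistic.
#' @export
read_plate_timeseries <- function(measurements_path, layout_path,
                                  dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  for (p in c(measurements_path, layout_path)) {
    if (!file.exists(p)) {
      abort(paste0("file not found: ", p), class = "phagestress_io_error")
    }
  }
  layout <- readr::read_csv(layout_path, show_col_types = FALSE,
                            progress = FALSE)
  meas <- readr::read_csv(measurements_path, show_col_types = FALSE,
                          progress = FALSE)
  if (dialect == "wide") {
    if (!"time_min" %in% names(meas)) {
      abort("wide measurements need a 'time_min' column",
            class = "phagestress_schema_error")
    }
    meas <- tidyr::pivot_longer(meas, -"time_min",
                                names_to = "well_id", values_to = "od600")
  }
  as_plate_timeseries(meas, layout)
}

#' Assemble a validated plate time-series table from in-memory parts
#'
#' @param measurements Data frame with `well_id`, `time_min`, `od600`.
#' @param layout Data frame with `well_id`, `treatment`, `stock_id`,
#'   `inoculated_pfu`, `target_moi`, optionally `control_type`.
#' @return Joined, validated tibble as in [read_plate_timeseries()].
#' @export
as_plate_timeseries <- function(measurements, layout) {
  need_layout <- c("well_id", "treatment", "stock_id", "inoculated_pfu",
                   "target_moi")
  missing_cols <- setdiff(need_layout, names(layout))
  if (length(missing_cols) > 0) {
    abort(paste0("layout is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phagestress_schema_error")
  }
  if (!"control_type" %in% names(layout)) layout$control_type <- NA_character_
  need_meas <- c("well_id", "time_min", "od600")
  missing_cols <- setdiff(need_meas, names(measurements))
  if (length(missing_cols) > 0) {
    abort(paste0("measurements are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phagestress_schema_error")
  }
  layout <- tibble::as_tibble(layout)
  measurements <- tibble::as_tibble(measurements)
  layout$well_id <- as.character(layout$well_id)
  measurements$well_id <- as.character(measurements$well_id)

  unknown <- setdiff(unique(measurements$well_id), layout$well_id)
  if (length(unknown) > 0) {
    abort(paste0("measurement well(s) absent from layout: ",
                 paste(unknown, collapse = ", ")),
          class = "phagestress_validation_error")
  }
  if (anyDuplicated(layout$well_id) > 0) {
    abort("duplicate well_id in layout",
          class = "phagestress_validation_error")
  }
  if (!all(is.finite(measurements$od600))) {
    abort("non-finite od600 value(s) in measurements",
          class = "phagestress_validation_error")
  }
  measurements <- dplyr::arrange(measurements, .data$well_id, .data$time_min)
  non_mono <- measurements |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(ok = !anyDuplicated(.data$time_min) &&
                       !is.unsorted(.data$time_min, strictly = TRUE),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(non_mono) > 0) {
    abort(paste0("non-monotone time_min within well(s): ",
                 paste(non_mono$well_id, collapse = ", ")),
          class = "phagestress_validation_error")
  }
  dplyr::inner_join(layout, measurements, by = "well_id") |>
    dplyr::arrange(.data$well_id, .data$time_min)
}

#' Write a result table to CSV
#'
#' Writes any pipeline result table with a header, UTF-8, "." decimal
#' separator, at full double precision so that reading the file back
#' reproduces the values to at least 12 significant digits.
#'
#' @param x A nonempty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (!is.data.frame(x) || nrow(x) == 0) {
    abort("refusing to write an empty result table",
          class = "phagestress_io_error")
  }
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

# rename file columns to canonical names; col_map is c(canonical = "in_file")
apply_col_map <- function(x, col_map) {
  if (is.null(col_map)) return(x)
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  for (canonical in names(col_map)) {
    from <- col_map[[canonical]]
    if (!from %in% names(x)) {
      abort(paste0("mapped column '", from, "' (for '", canonical,
                   "') not found in file"),
            class = "phagestress_schema_error")
    }
    names(x)[names(x) == from] <- canonical
  }
  x
}

check_rows <- function(x, ok, what) {
  ok[is.na(ok)] <- FALSE
  if (!all(ok)) {
    abort(row_msg(what, which(!ok)), class = "phagestress_validation_error")
  }
  invisible(x)
}

row_msg <- function(what, rows) {
  shown <- head(rows, 5)
  paste0(what, " in row(s) ", paste(shown, collapse = ", "),
         if (length(rows) > 5) ", ...")
}
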