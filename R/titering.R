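#' Limit of detection of a plaque assay
#'
#' The smallest titer observable for a sample: the PFU/mL implied by a
#' single plaque on the least-dilute plate actually plated. Samples whose
#' plates all show zero plaques are censored at this value. A protocol
#' dilution applied before plating (e.g. a 200-fold dilution used to
#' terminate a stress exposure) scales the LOD by the same factor.
#'
#' @param lowest_dilution_exponent Smallest serial-dilution exponent
#'   plated for the sample (0 = undiluted).
#' @param volume_ml Volume plated, mL.
#' @param pre_dilution_factor Fold-dilution applied to the sample before
#'   the serial dilutions (>= 1, default 1).
#' @return LOD in PFU/mL.
#' @export
#' @examples
#' limit_of_detection(1, 0.1)        # 100 PFU/mL
#' limit_of_detection(0, 1)          # 1 PFU/mL
#' limit_of_detection(0, 0.1, 200)   # stress terminated by 200-fold dilution
limit_of_detection <- function(lowest_dilution_exponent, volume_ml,
                               pre_dilution_factor = 1) {
  if (any(!is.finite(volume_ml) | volume_ml <= 0)) {
    abort("volume_ml must be positive", class = "phagestress_domain_error")
  }
  if (any(pre_dilution_factor < 1)) {
    abort("pre_dilution_factor must be >= 1",
          class = "phagestress_domain_error")
  }
  pre_dilution_factor / (volume_ml * 10^(-lowest_dilution_exponent))
}

#' Estimate a PFU/mL titer from the plates of one sample
#'
#' Each plate gives an estimate `plaques / (volume_ml * 10^-d *
#' 1/pre_dilution_factor)`. The sample titer is the arithmetic mean over
#' plates whose raw count falls in `countable_range`. If no plate is
#' countable but some plaques were seen, the plate with the largest count
#' at the highest dilution showing plaques is used and the estimate is
#' flagged `out_of_range`. If every plate shows zero plaques the sample is
#' censored at its limit of detection.
#'
#' @param plates Plaque-count rows for a single sample
#'   (see [read_plaque_counts()]).
#' @param countable_range Integer vector `c(lo, hi)`; plates with counts in
#'   this closed range are used for the mean. Default `c(3, 300)`, the
#'   standard plaque-assay convention.
#' @param pre_dilution_factor Protocol dilution before plating (see
#'   [limit_of_detection()]).
#' @return One-row tibble: `sample_id`, `pfu_per_ml`, `lod_pfu_per_ml`,
#'   `censored`, `n_plates_used`, `out_of_range`, plus a `plate_estimates`
#'   list-column of the per-plate estimates that entered the mean.
#' @export
#' @examples
#' plates <- tibble::tibble(
#'   sample_id = "s", stressor = "none", level = 0, duration_min = 0,
#'   stock_id = "A", dilution_exponent = 6L, volume_ml = 0.1,
#'   plaques = c(28L, 30L, 35L), plate = 1:3
#' )
#' estimate_titer(plates)  # mean of 2.8e8, 3.0e8, 3.5e8
estimate_titer <- function(plates, countable_range = c(3, 300),
                           pre_dilution_factor = 1) {
  if (nrow(plates) == 0) {
    abort("estimate_titer needs at least one plate",
          class = "phagestress_domain_error")
  }
  if (length(countable_range) != 2 ||
      countable_range[1] > countable_range[2] || countable_range[1] < 1) {
    abort("countable_range must be c(lo, hi) with 1 <= lo <= hi",
          class = "phagestress_domain_error")
  }
  sample_id <- if ("sample_id" %in% names(plates)) {
    unique(as.character(plates$sample_id))
  } else "<unnamed>"
  if (length(sample_id) != 1) {
    abort("estimate_titer received plates from more than one sample",
          class = "phagestress_domain_error")
  }
  per_plate <- plates$plaques * pre_dilution_factor /
    (plates$volume_ml * 10^(-plates$dilution_exponent))
  lod <- limit_of_detection(min(plates$dilution_exponent),
                            plates$volume_ml[which.min(plates$dilution_exponent)],
                            pre_dilution_factor)
  countable <- plates$plaques >= countable_range[1] &
    plates$plaques <= countable_range[2]

  if (any(countable)) {
    pfu <- mean(per_plate[countable])
    used <- sum(countable)
    censored <- FALSE
    out_of_range <- FALSE
    estimates <- per_plate[countable]
  } else if (any(plates$plaques > 0)) {
    # no plate in range: fall back to the most informative nonzero plate
    nz <- plates$plaques > 0
    top_dil <- max(plates$dilution_exponent[nz])
    cand <- which(nz & plates$dilution_exponent == top_dil)
    best <- cand[which.max(plates$plaques[cand])]
    pfu <- per_plate[best]
    used <- 1L
    censored <- FALSE
    out_of_range <- TRUE
    estimates <- per_plate[best]
  } else {
    pfu <- lod
    used <- 0L
    censored <- TRUE
    out_of_range <- FALSE
    estimates <- numeric(0)
  }
  tibble::tibble(
    sample_id = sample_id,
    pfu_per_ml = pfu,
    lod_pfu_per_ml = lod,
    censored = censored,
    n_plates_used = as.integer(used),
    out_of_range = out_of_range,
    plate_estimates = list(estimates)
  )
}

#' Titer every sample in a plaque-count table
#'
#' Groups a plaque-count table by `sample_id`, carries the condition
#' metadata through, and applies [estimate_titer()] per sample.
#'
#' @param counts A validated plaque-count table ([read_plaque_counts()]).
#' @param countable_range,pre_dilution_factor Passed to
#'   [estimate_titer()]. `pre_dilution_factor` may instead be supplied as
#'   a column of `counts` (constant within each sample) when different
#'   protocols were used for different samples.
#' @return A tibble with one row per sample: condition metadata
#'   (`stressor`, `level`, `duration_min`, `stock_id`) plus the
#'   [estimate_titer()] columns.
#' @export
titer_table <- function(counts, countable_range = c(3, 300),
                        pre_dilution_factor = 1) {
  has_pdf_col <- "pre_dilution_factor" %in% names(counts)
  meta_cols <- c("stressor", "level", "duration_min", "stock_id")
  counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(g, key) {
      meta <- unique(g[, intersect(meta_cols, names(g))])
      if (nrow(meta) != 1) {
        abort(paste0("inconsistent condition metadata within sample ",
                     key$sample_id),
              class = "phagestress_validation_error")
      }
      pdf <- if (has_pdf_col) unique(g$pre_dilution_factor) else
        pre_dilution_factor
      if (length(pdf) == 1 && is.na(pdf)) pdf <- pre_dilution_factor
      if (length(pdf) != 1) {
        abort(paste0("pre_dilution_factor varies within sample ",
                     key$sample_id),
              class = "phagestress_validation_error")
      }
      g$sample_id <- key$sample_id
      est <- estimate_titer(g, countable_range, pdf)
      dplyr::bind_cols(meta, est[, setdiff(names(est), "sample_id")])
    }) |>
    dplyr::ungroup()
}

#' Configuration of survival-normalization references
#'
#' Chooses, per stressor, which sample serves as the 100%-survival
#' reference. Defaults follow the heat-gradient protocol (reference is the
#' mildest treatment, 55 degrees C after 5 minutes of exposure) and the
#' solute protocols (reference is the growth-medium control concentration
#' at 0 minutes: LB is 0.17 M saline; urea control is 0 M). For a
#' single-temperature time course use `heat = list(duration_min = 0)` so
#' the unexposed source stock is the reference. References are matched
#' within phage stock when `per_stock = TRUE` (default), so biological
#' replicates are each normalized to their own baseline.
#'
#' @param heat,saline,urea,none Lists with optional elements `level` and
#'   `duration_min`; a `NULL` element matches any value.
#' @param per_stock Match references within `stock_id`?
#' @return A `survival_config` list.
#' @export
survival_config <- function(heat = list(level = 55, duration_min = 5),
                            saline = list(level = 0.17, duration_min = 0),
                            urea = list(level = 0, duration_min = 0),
                            none = list(duration_min = 0),
                            per_stock = TRUE) {
  structure(list(heat = heat, saline = saline, urea = urea, none = none,
                 per_stock = isTRUE(per_stock)),
            class = "survival_config")
}

#' Percent survival of one titer relative to a reference titer
#'
#' `100 * obs / reference`, with the observation's censoring flag carried
#' through so below-LOD values can be excluded from model fits downstream
#' while still being plotted at their LOD-implied value.
#'
#' @param obs One-or-more-row titer tibble ([estimate_titer()] output).
#' @param reference One-row titer tibble; must be uncensored.
#' @return `obs` rows with `percent_survival`, `log10_percent`,
#'   `censored`, `reference_id` appended.
#' @export
percent_survival <- function(obs, reference) {
  if (nrow(reference) != 1) {
    abort("reference must be a single titer row",
          class = "phagestress_domain_error")
  }
  if (isTRUE(reference$censored)) {
    abort(paste0("cannot normalize against censored reference sample ",
                 reference$sample_id),
          class = "phagestress_reference_error")
  }
  pct <- 100 * obs$pfu_per_ml / reference$pfu_per_ml
  out <- obs
  out$percent_survival <- pct
  out$log10_percent <- log10(pct)
  out$reference_id <- reference$sample_id
  out
}

#' Percent-survival table for a full experiment
#'
#' For each (stressor, stock) group, finds the configured reference sample
#' and expresses every titer as percent survival relative to it. Censored
#' titers keep their LOD-implied percent but stay flagged; downstream
#' model fits exclude them.
#'
#' @param titers Output of [titer_table()].
#' @param config A [survival_config()].
#' @param per_plate If `TRUE`, emit one survival row per countable plate
#'   (per-plate titer estimate over the reference mean titer) instead of
#'   one row per sample.
#' @return Tibble of survival observations: condition metadata,
#'   `percent_survival`, `log10_percent`, `censored`, `reference_id`.
#' @export
survival_table <- function(titers, config = survival_config(),
                           per_plate = FALSE) {
  stopifnot(inherits(config, "survival_config"))
  group_cols <- if (config$per_stock) c("stressor", "stock_id") else "stressor"
  titers |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(g, key) {
      rule <- config[[key$stressor[1]]]
      if (is.null(rule)) {
        abort(paste0("no reference rule for stressor ", key$stressor[1]),
              class = "phagestress_reference_error")
      }
      sel <- rep(TRUE, nrow(g))
      if (!is.null(rule$level)) sel <- sel & g$level == rule$level
      if (!is.null(rule$duration_min)) {
        sel <- sel & g$duration_min == rule$duration_min
      }
      if (sum(sel) != 1) {
        abort(paste0(if (sum(sel) == 0) "no" else "ambiguous",
                     " reference sample for ",
                     paste(unlist(key), collapse = "/"),
                     " under the configured rule"),
              class = "phagestress_reference_error")
      }
      ref <- g[sel, ]
      res <- percent_survival(g, ref)
      if (per_plate) {
        res <- res |>
          dplyr::filter(!.data$censored) |>
          tidyr::unnest("plate_estimates") |>
          dplyr::mutate(
            percent_survival = 100 * .data$plate_estimates / ref$pfu_per_ml,
            log10_percent = log10(.data$percent_survival)
          ) |>
          dplyr::select(-"plate_estimates")
      }
      res[, setdiff(names(res), "plate_estimates"), drop = FALSE]
    }) |>
    dplyr::ungroup()
}
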