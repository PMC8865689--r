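#' OD600-to-CFU standard curve
#'
#' Linear calibration on the log scale: `log10(CFU/mL) = intercept +
#' slope * OD600`, valid over a stated OD range. Conversions outside the
#' range are extrapolations and are flagged.
#'
#' @param intercept log10 CFU/mL at OD 0.
#' @param slope log10 CFU/mL per OD unit (> 0).
#' @param valid_od_range `c(lo, hi)` of the calibrated OD range.
#' @return A `standard_curve` object.
#' @export
standard_curve <- function(intercept, slope, valid_od_range = c(0.01, 1)) {
  if (slope <= 0) {
    abort("standard-curve slope must be positive",
          class = "phagestress_domain_error")
  }
  if (valid_od_range[1] >= valid_od_range[2]) {
    abort("valid_od_range must be c(lo, hi) with lo < hi",
          class = "phagestress_domain_error")
  }
  structure(list(intercept = intercept, slope = slope,
                 valid_od_range = valid_od_range),
            class = "standard_curve")
}

#' Convert OD600 to CFU/mL (and back)
#'
#' @param od Optical density value(s).
#' @param curve A [standard_curve()].
#' @return CFU/mL, `10^(intercept + slope * od)`, with a logical attribute
#'   `extrapolated` marking values outside the curve's valid range (a
#'   warning is raised when any are).
#' @export
od_to_cfu <- function(od, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  extrapolated <- od < curve$valid_od_range[1] | od > curve$valid_od_range[2]
  if (any(extrapolated)) {
    warn("OD value(s) outside the standard curve's valid range; extrapolating")
  }
  structure(10^(curve$intercept + curve$slope * od),
            extrapolated = extrapolated)
}

#' @rdname od_to_cfu
#' @param cfu_per_ml Cell density value(s).
#' @return For `cfu_to_od`, the OD600 implied by the curve.
#' @export
cfu_to_od <- function(cfu_per_ml, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  (log10(cfu_per_ml) - curve$intercept) / curve$slope
}

#' Dosing specification for growth-curve wells
#'
#' Defaults follow the fitness-assay protocol: 200 PFU per well at a
#' multiplicity of infection of 1e-5 in 200 uL wells, so each well gets
#' 2e7 bacterial cells.
#'
#' @param target_pfu_per_well Phage particles per well.
#' @param target_moi Phage-to-bacteria ratio at inoculation.
#' @param well_volume_ml Total well volume, mL.
#' @param max_phage_volume_ml Largest phage-suspension volume that can be
#'   added to a well, mL.
#' @param min_pipette_ml Smallest accurately pipettable volume, mL;
#'   smaller requirements trigger an intermediate tenfold dilution.
#' @return A `dose_spec` object.
#' @export
dose_spec <- function(target_pfu_per_well = 200, target_moi = 1e-5,
                      well_volume_ml = 0.2, max_phage_volume_ml = 0.1,
                      min_pipette_ml = 0.002) {
  vals <- c(target_pfu_per_well, target_moi, well_volume_ml,
            max_phage_volume_ml, min_pipette_ml)
  if (any(!is.finite(vals) | vals <= 0)) {
    abort("all dose_spec values must be positive",
          class = "phagestress_domain_error")
  }
  structure(list(target_pfu_per_well = target_pfu_per_well,
                 target_moi = target_moi, well_volume_ml = well_volume_ml,
                 max_phage_volume_ml = max_phage_volume_ml,
                 min_pipette_ml = min_pipette_ml),
            class = "dose_spec")
}

#' Plan the phage and bacteria additions for one stock's wells
#'
#' Normalizes a titered phage stock to a fixed PFU dose per well at a
#' constant MOI: picks the intermediate tenfold dilution (if any) that
#' brings the required phage volume into the pipettable window, and sizes
#' the bacterial inoculum as `achieved_pfu / target_moi` so the MOI is
#' constant even when a low-titer stock cannot supply the full dose. Wells
#' that cannot receive the target PFU are flagged `insufficient` and are
#' excluded from the treatment ANOVA downstream.
#'
#' @param titer One-row titer tibble ([estimate_titer()]); must be
#'   uncensored.
#' @param culture_od OD600 of the bacterial culture used to seed wells.
#' @param curve [standard_curve()] for the OD-to-CFU conversion.
#' @param spec A [dose_spec()].
#' @return One-row tibble: `phage_dilution_exponent`, `phage_volume_ml`,
#'   `achieved_pfu`, `achieved_moi`, `bacteria_cells_per_well`,
#'   `bacteria_volume_ml`, `insufficient`.
#' @export
dose_wells <- function(titer, culture_od, curve, spec = dose_spec()) {
  stopifnot(inherits(spec, "dose_spec"))
  if (nrow(titer) != 1) {
    abort("dose_wells takes a single titer row",
          class = "phagestress_domain_error")
  }
  if (isTRUE(titer$censored)) {
    abort(paste0("cannot dose from censored titer ", titer$sample_id),
          class = "phagestress_domain_error")
  }
  pfu_ml <- titer$pfu_per_ml
  target <- spec$target_pfu_per_well
  v0 <- target / pfu_ml
  if (v0 > spec$max_phage_volume_ml) {
    # stock too dilute to supply the full dose
    d <- 0L
    v <- spec$max_phage_volume_ml
    achieved <- pfu_ml * v
    insufficient <- TRUE
  } else {
    d <- 0L
    v <- v0
    while (v < spec$min_pipette_ml) {
      d <- d + 1L
      v <- target / (pfu_ml * 10^(-d))
    }
    achieved <- pfu_ml * 10^(-d) * v
    insufficient <- FALSE
  }
  cells <- achieved / spec$target_moi
  cfu_ml <- as.numeric(od_to_cfu(culture_od, curve))
  tibble::tibble(
    sample_id = titer$sample_id,
    phage_dilution_exponent = d,
    phage_volume_ml = v,
    achieved_pfu = achieved,
    achieved_moi = spec$target_moi,
    bacteria_cells_per_well = cells,
    bacteria_volume_ml = cells / cfu_ml,
    insufficient = insufficient
  )
}

#' Smooth a growth-curve series
#'
#' Moving median (default) or moving average with an odd window; at the
#' series edges the window shrinks symmetrically, so the output has the
#' same length as the input and a window of 1 is the identity.
#'
#' @param od Numeric series.
#' @param method `"moving_median"` or `"moving_average"`.
#' @param window Odd integer window width, `<= length(od)`.
#' @return Smoothed numeric series, same length.
#' @export
smooth_curve <- function(od, method = c("moving_median", "moving_average"),
                         window = 5) {
  method <- match.arg(method)
  n <- length(od)
  if (window %% 2 == 0 || window < 1) {
    abort("window must be a positive odd integer",
          class = "phagestress_domain_error")
  }
  if (window > n) {
    abort("window longer than the series", class = "phagestress_domain_error")
  }
  if (window == 1) return(od)
  half <- (window - 1) / 2
  stat <- if (method == "moving_median") median else mean
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    stat(od[(i - h):(i + h)])
  }, numeric(1))
}

#' First local maximum of a smoothed growth curve
#'
#' The phage-fitness proxy: the earliest point that is at least as high as
#' both neighbours and after which the series drops by at least
#' `prominence`. Plateau ties go to the earliest index. If no interior
#' maximum qualifies (e.g. a still-rising culture, or noise never followed
#' by a real decline), the global maximum is returned with
#' `boundary_flag = TRUE`. Higher peaks mean the phage suppressed growth
#' less, i.e. lower phage fitness.
#'
#' @param smoothed Smoothed OD series (length >= 3).
#' @param time_grid Times (minutes) matching `smoothed`.
#' @param prominence Required subsequent drop below the candidate peak.
#'   `NULL` uses a data-driven noise floor: 3 times the median absolute
#'   successive difference of the series up to its global maximum.
#' @return One-row tibble: `peak_od`, `peak_time_min`, `peak_index`,
#'   `prominence`, `boundary_flag`.
#' @export
first_peak <- function(smoothed, time_grid, prominence = NULL) {
  n <- length(smoothed)
  if (n < 3) {
    abort("series must have at least 3 points",
          class = "phagestress_domain_error")
  }
  if (length(time_grid) != n) {
    abort("time_grid must match the series length",
          class = "phagestress_domain_error")
  }
  if (is.null(prominence)) prominence <- auto_prominence(smoothed)
  peak_i <- NA_integer_
  for (i in 2:(n - 1)) {
    if (smoothed[i] >= smoothed[i - 1] && smoothed[i] >= smoothed[i + 1] &&
        min(smoothed[i:n]) <= smoothed[i] - prominence) {
      peak_i <- i
      break
    }
  }
  boundary <- is.na(peak_i)
  if (boundary) peak_i <- which.max(smoothed)
  tibble::tibble(
    peak_od = smoothed[peak_i],
    peak_time_min = time_grid[peak_i],
    peak_index = as.integer(peak_i),
    prominence = prominence,
    boundary_flag = boundary
  )
}

# noise floor for peak prominence: 3 x median |successive difference|
# over the rising part of the series (up to the global maximum)
auto_prominence <- function(smoothed) {
  gmax <- which.max(smoothed)
  pre <- smoothed[seq_len(max(gmax, 2))]
  3 * median(abs(diff(pre)))
}

#' Peak statistics for every well of a plate
#'
#' Smooths each well's OD600 series and extracts its first local maximum.
#' Wells whose inoculated PFU fell short of the dosing target are flagged
#' `excluded` (they stay in the table for reporting but are left out of
#' the treatment ANOVA); phage-free control wells are never `excluded` but
#' carry their `control_type` so [fitness_comparison()] can route them to
#' the control contrast.
#'
#' @param plate Plate time-series tibble ([read_plate_timeseries()]).
#' @param method,window Passed to [smooth_curve()].
#' @param prominence Passed to [first_peak()] (`NULL` = data-driven).
#' @param target_pfu Dosing target used for the exclusion flag.
#' @param dose_tolerance Relative shortfall tolerated before exclusion.
#' @return Tibble: one row per well with layout metadata, `peak_od`,
#'   `peak_time_min`, `boundary_flag`, `excluded`, and the smoothing
#'   settings used.
#' @export
extract_peaks <- function(plate, method = "moving_median", window = 5,
                          prominence = NULL, target_pfu = 200,
                          dose_tolerance = 0.01) {
  plate |>
    dplyr::group_by(.data$well_id, .data$treatment, .data$stock_id,
                    .data$inoculated_pfu, .data$target_moi,
                    .data$control_type) |>
    dplyr::group_modify(function(g, key) {
      sm <- smooth_curve(g$od600, method, window)
      pk <- first_peak(sm, g$time_min, prominence)
      pk$smoothing_method <- method
      pk$smoothing_window <- as.integer(window)
      pk
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      excluded = !is.na(.data$inoculated_pfu) &
        .data$inoculated_pfu < target_pfu * (1 - dose_tolerance)
    )
}

#' Compare phage fitness across treatments from peak statistics
#'
#' Fits peak OD as a function of heat-shock treatment (factor), phage
#' stock, and their interaction (sequential ANOVA, term order as listed;
#' stock terms are dropped automatically when only one stock is present),
#' then runs Tukey HSD over treatment levels using the model's residual
#' mean square and summarizes them as compact letters. If two phage-free
#' control groups are present (distinct `control_type` values), their peak
#' ODs are compared with a Welch unequal-variance t-test.
#'
#' @param peaks Output of [extract_peaks()].
#' @param alpha Family-wise level for Tukey significance and letters.
#' @return A `fitness_comparison` object: list with `anova`, `tukey`,
#'   `letters`, `welch` (or `NULL`), `group_means`, `mse`, `df_resid`,
#'   `n_excluded`, `alpha`, and the analysis `peaks`.
#' @export
fitness_comparison <- function(peaks, alpha = 0.05) {
  is_control <- !is.na(peaks$control_type)
  analysis <- peaks[!is_control & !peaks$excluded, , drop = FALSE]
  trt_n <- table(analysis$treatment)
  if (length(trt_n) < 2) {
    abort("need at least two treatments with analysable wells",
          class = "phagestress_domain_error")
  }
  if (any(trt_n < 2)) {
    abort(paste0("treatment(s) with fewer than 2 wells: ",
                 paste(names(trt_n)[trt_n < 2], collapse = ", ")),
          class = "phagestress_domain_error")
  }
  f_trt <- factor(analysis$treatment)
  f_stk <- factor(analysis$stock_id)
  y <- analysis$peak_od
  n <- length(y)
  one_stock <- nlevels(f_stk) < 2

  x_null <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  x_trt <- cbind(x_null, dummy_cols(f_trt, "treatment"))
  fits <- list(fit_ols(x_null, y), fit_ols(x_trt, y))
  terms <- "treatment"
  if (!one_stock) {
    x_stk <- cbind(x_trt, dummy_cols(f_stk, "stock"))
    inter <- interaction_cols(f_trt, f_stk)
    x_full <- cbind(x_stk, inter)
    fits <- c(fits, list(fit_ols(x_stk, y), fit_ols(x_full, y)))
    terms <- c(terms, "stock", "treatment:stock")
  }
  anova_tbl <- sequential_anova(fits, terms)
  full <- fits[[length(fits)]]
  mse <- full$residual_ss / full$residual_df

  means <- tapply(y, f_trt, mean)
  ns <- tapply(y, f_trt, length)
  tukey <- tukey_hsd(setNames(as.numeric(means), names(means)),
                     setNames(as.integer(ns), names(ns)),
                     mse, full$residual_df, alpha)
  letters_v <- compact_letters(tukey, levels(f_trt), alpha)

  welch <- NULL
  ctrl <- peaks[is_control, , drop = FALSE]
  ctypes <- sort(unique(ctrl$control_type))
  if (length(ctypes) == 2 &&
      all(table(ctrl$control_type) >= 2)) {
    welch <- welch_t(ctrl$peak_od[ctrl$control_type == ctypes[1]],
                     ctrl$peak_od[ctrl$control_type == ctypes[2]])
    welch$group_a <- ctypes[1]
    welch$group_b <- ctypes[2]
  }
  structure(
    list(anova = anova_tbl, tukey = tukey,
         letters = tibble::tibble(treatment = names(letters_v),
                                  letters = unname(letters_v)),
         welch = welch,
         group_means = tibble::tibble(treatment = names(means),
                                      mean_peak_od = as.numeric(means),
                                      n = as.integer(ns)),
         mse = mse, df_resid = full$residual_df,
         n_excluded = sum(peaks$excluded), alpha = alpha,
         peaks = analysis),
    class = "fitness_comparison"
  )
}

dummy_cols <- function(f, prefix) {
  lv <- levels(f)[-1]
  m <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
  m <- matrix(m, nrow = length(f))
  colnames(m) <- paste0(prefix, "_", lv)
  m
}

interaction_cols <- function(f1, f2) {
  l1 <- levels(f1)[-1]; l2 <- levels(f2)[-1]
  cols <- list()
  for (a in l1) for (b in l2) {
    cols[[paste0("trt", a, ":stk", b)]] <- as.numeric(f1 == a & f2 == b)
  }
  do.call(cbind, cols)
}

#' @export
print.fitness_comparison <- function(x, ...) {
  cat("Phage-fitness comparison (peak bacterial density)\n\nANOVA:\n")
  print(x$anova)
  cat("\nTreatment means and Tukey letters (alpha =", x$alpha, "):\n")
  print(dplyr::left_join(x$group_means, x$letters, by = "treatment"))
  if (!is.null(x$welch)) {
    cat("\nWelch control contrast (", x$welch$group_a, "vs",
        x$welch$group_b, "): t =", format(x$welch$t, digits = 4),
        ", df =", format(x$welch$df, digits = 4),
        ", p =", format(x$welch$p_two_sided, digits = 3), "\n")
  }
  if (x$n_excluded > 0) {
    cat("\n", x$n_excluded, "under-dosed well(s) excluded from the ANOVA\n")
  }
  invisible(x)
}

#' @describeIn fitness_comparison Tukey pairwise table.
#' @param x A `fitness_comparison`.
#' @param ... Unused.
#' @method tidy fitness_comparison
#' @export
tidy.fitness_comparison <- function(x, ...) x$tukey

#' @describeIn fitness_comparison One-row summary (treatment F and p,
#'   residual df, excluded wells).
#' @method glance fitness_comparison
#' @export
glance.fitness_comparison <- function(x, ...) {
  trt <- x$anova[x$anova$term == "treatment", ]
  tibble::tibble(
    statistic_treatment = trt$statistic,
    df_treatment = trt$df,
    df_resid = x$df_resid,
    p_treatment = trt$p.value,
    mse = x$mse,
    n_wells = nrow(x$peaks),
    n_excluded = x$n_excluded
  )
}

#' @describeIn fitness_comparison Peak OD by treatment with Tukey letters.
#' @param object A `fitness_comparison`.
#' @method autoplot fitness_comparison
#' @export
autoplot.fitness_comparison <- function(object, ...) {
  d <- object$peaks
  lab <- dplyr::left_join(object$group_means, object$letters, by = "treatment")
  lab$y <- max(d$peak_od) * 1.05
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment, y = .data$peak_od)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(y = .data$y, label = .data$letters)) +
    ggplot2::labs(x = "treatment", y = "peak OD600 (smoothed)")
}
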