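#' Fit a stratified log-linear decay model
#'
#' Ordinary least squares of `log10(percent survival)` with one intercept
#' and one exposure-duration slope per stratum (temperature, solute
#' concentration, or phage stock as a factor): the model
#' `log10_percent ~ 0 + stratum + stratum:duration`. There is no pooled
#' duration main effect by default, so each stratum's slope is its own
#' decay rate in log10 percent per minute. Censored (below limit of
#' detection) observations are excluded before fitting and retained on the
#' returned object for plotting.
#'
#' @param observations Survival table ([survival_table()]); needs the
#'   response, stratifying and covariate columns plus `censored`.
#' @param stratum Name of the stratifying column (default `"level"`;
#'   use `"stock_id"` for a time course across biological replicates).
#' @param covariate Name of the duration column (default `"duration_min"`).
#' @param response Name of the response column (default `"log10_percent"`).
#' @param include_main_effect If `TRUE`, fit the conventional
#'   factor-plus-covariate-plus-interaction parametrization instead
#'   (sensitivity analysis); slopes per stratum are identical, sequential
#'   sums of squares differ.
#' @return A `decay_fit` object: the [fit_ols()] fit plus bookkeeping
#'   (strata, data used, censored rows excluded). Methods: [tidy()],
#'   [glance()], [autoplot()], [slope_tests()].
#' @export
fit_stratified_decay <- function(observations,
                                 stratum = "level",
                                 covariate = "duration_min",
                                 response = "log10_percent",
                                 include_main_effect = FALSE) {
  needed <- c(stratum, covariate, response)
  missing_cols <- setdiff(needed, names(observations))
  if (length(missing_cols) > 0) {
    abort(paste0("observations are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phagestress_schema_error")
  }
  censored_rows <- if ("censored" %in% names(observations)) {
    observations[observations$censored, , drop = FALSE]
  } else observations[0, , drop = FALSE]
  used <- if ("censored" %in% names(observations)) {
    observations[!observations$censored, , drop = FALSE]
  } else observations
  if (nrow(used) == 0) {
    abort("no uncensored observations to fit",
          class = "phagestress_domain_error")
  }
  if (!all(is.finite(used[[response]]))) {
    abort("non-finite response among uncensored observations",
          class = "phagestress_domain_error")
  }
  f <- factor(used[[stratum]])
  t_cov <- used[[covariate]]
  thin <- tapply(t_cov, f, function(v) length(unique(v)) < 2)
  if (any(thin)) {
    abort(paste0("stratum with fewer than 2 distinct durations: ",
                 paste(names(thin)[thin], collapse = ", ")),
          class = "phagestress_domain_error")
  }
  design <- decay_design(f, t_cov, include_main_effect)
  fit <- fit_ols(design, used[[response]])
  structure(
    list(fit = fit,
         data = used,
         censored = censored_rows,
         stratum = stratum, covariate = covariate, response = response,
         include_main_effect = include_main_effect,
         levels = levels(f)),
    class = "decay_fit"
  )
}

# per-stratum intercepts and slopes; main-effect variant uses treatment
# contrasts so the pooled slope is the reference stratum's
decay_design <- function(f, t_cov, include_main_effect) {
  lv <- levels(f)
  icpt <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
  colnames(icpt) <- paste0("stratum_", lv)
  if (!include_main_effect) {
    slp <- icpt * t_cov
    colnames(slp) <- paste0("slope_", lv)
    cbind(icpt, slp)
  } else {
    base <- cbind(`(Intercept)` = rep(1, length(f)),
                  icpt[, -1, drop = FALSE], duration = t_cov)
    inter <- icpt[, -1, drop = FALSE] * t_cov
    colnames(inter) <- paste0("slope_diff_", lv[-1])
    cbind(base, inter)
  }
}

# slope estimate and SE per stratum from a decay_fit
decay_slopes <- function(object) {
  lv <- object$levels
  co <- object$fit$coefficients
  cv <- object$fit$cov_matrix
  if (!object$include_main_effect) {
    nm <- paste0("slope_", lv)
    tibble::tibble(level = lv, slope = as.numeric(co[nm]),
                   std_err = unname(sqrt(diag(cv)[nm])))
  } else {
    slope <- se <- numeric(length(lv))
    for (i in seq_along(lv)) {
      sel <- if (i == 1) "duration" else
        c("duration", paste0("slope_diff_", lv[i]))
      slope[i] <- sum(co[sel])
      se[i] <- unname(sqrt(sum(cv[sel, sel])))
    }
    tibble::tibble(level = lv, slope = slope, std_err = se)
  }
}

#' One-tailed slope tests with Bonferroni adjustment
#'
#' For each stratum of a [fit_stratified_decay()] model, tests the decay
#' slope against zero with a one-tailed t-test (`direction = "less"`
#' detects increased decay, the default) and adjusts the p-values by a
#' Bonferroni factor of `n_tests`.
#'
#' @param fit A `decay_fit`.
#' @param direction `"less"` (slope < 0, i.e. decay) or `"greater"`.
#' @param n_tests Bonferroni family size; default is the number of strata
#'   with an estimable slope.
#' @param all_levels Optional vector of stratum levels to report.
#'   Levels without an estimable slope (e.g. every observation below the
#'   limit of detection) are emitted as NA rows rather than dropped, so
#'   the output has the familiar "per-condition decay table" shape.
#' @return Tibble: `level`, `slope` (log10 percent per minute), `std_err`,
#'   `t_value`, `df`, `p_one_tailed`, `p_bonferroni`, `n_tests`.
#' @export
slope_tests <- function(fit, direction = c("less", "greater"),
                        n_tests = NULL, all_levels = NULL) {
  stopifnot(inherits(fit, "decay_fit"))
  direction <- match.arg(direction)
  perfect_tol <- 1e-10 * (1 + sum(fit$fit$fitted^2))
  if (fit$fit$residual_ss <= perfect_tol || fit$fit$residual_df == 0) {
    abort("zero residual variance: slope tests are undefined (perfect fit)",
          class = "phagestress_domain_error")
  }
  sl <- decay_slopes(fit)
  if (is.null(n_tests)) n_tests <- nrow(sl)
  if (n_tests < nrow(sl)) {
    abort("n_tests must be at least the number of estimable strata",
          class = "phagestress_domain_error")
  }
  df <- fit$fit$residual_df
  t_val <- sl$slope / sl$std_err
  p1 <- if (direction == "less") pt(t_val, df) else
    pt(t_val, df, lower.tail = FALSE)
  out <- tibble::tibble(
    level = sl$level, slope = sl$slope, std_err = sl$std_err,
    t_value = t_val, df = as.integer(df),
    p_one_tailed = p1, p_bonferroni = bonferroni(p1, n_tests),
    n_tests = as.integer(n_tests)
  )
  if (!is.null(all_levels)) {
    all_levels <- as.character(all_levels)
    na_lv <- setdiff(all_levels, out$level)
    if (length(na_lv) > 0) {
      out <- dplyr::bind_rows(
        out,
        tibble::tibble(level = na_lv, slope = NA_real_, std_err = NA_real_,
                       t_value = NA_real_, df = NA_integer_,
                       p_one_tailed = NA_real_, p_bonferroni = NA_real_,
                       n_tests = as.integer(n_tests))
      )
    }
    out <- out[order(match(out$level, all_levels)), ]
  }
  out
}

#' Sequential ANCOVA table for a stratified decay model
#'
#' Type I (sequential) analysis of covariance in the fixed term order of
#' the decay model: the stratifying factor first, then (optionally) the
#' pooled duration main effect, then the factor-by-duration interaction.
#' Censored observations are excluded first. F statistics use the full
#' model's residual mean square; because the decomposition is sequential,
#' the table depends on this term order by construction.
#'
#' @inheritParams fit_stratified_decay
#' @return Tibble with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value` (one row per term plus `Residuals`).
#' @export
ancova_table <- function(observations,
                         stratum = "level",
                         covariate = "duration_min",
                         response = "log10_percent",
                         include_main_effect = FALSE) {
  full <- fit_stratified_decay(observations, stratum, covariate, response,
                               include_main_effect)
  used <- full$data
  f <- factor(used[[stratum]])
  t_cov <- used[[covariate]]
  y <- used[[response]]
  n <- length(y)
  icpt_full <- decay_design(f, t_cov, include_main_effect = TRUE)

  null_fit <- fit_ols(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), y)
  factor_cols <- c("(Intercept)", paste0("stratum_", levels(f)[-1]))
  factor_fit <- fit_ols(icpt_full[, factor_cols, drop = FALSE], y)
  if (include_main_effect) {
    main_fit <- fit_ols(icpt_full[, c(factor_cols, "duration"), drop = FALSE], y)
    full_fit <- fit_ols(icpt_full, y)
    terms <- c(stratum, covariate, paste0(stratum, ":", covariate))
    fits <- list(null_fit, factor_fit, main_fit, full_fit)
  } else {
    full_fit <- full$fit
    terms <- c(stratum, paste0(stratum, ":", covariate))
    fits <- list(null_fit, factor_fit, full_fit)
  }
  sequential_anova(fits, terms)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Stratified log-linear decay fit\n")
  cat("  response:", x$response, "~", x$stratum, "+",
      paste0(x$stratum, ":", x$covariate),
      if (x$include_main_effect) paste0("(+ ", x$covariate, ")"), "\n")
  cat("  strata:", paste(x$levels, collapse = ", "), "\n")
  cat("  n used:", nrow(x$data), " censored excluded:", nrow(x$censored), "\n")
  cat("  residual df:", x$fit$residual_df,
      " residual SS:", format(x$fit$residual_ss, digits = 6), "\n")
  print(decay_slopes(x))
  invisible(x)
}

#' @describeIn fit_stratified_decay Broom-style coefficient table: one row
#'   per stratum intercept and slope with standard errors.
#' @param x,object A `decay_fit`.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  sl <- decay_slopes(x)
  co <- x$fit$coefficients
  cv <- sqrt(diag(x$fit$cov_matrix))
  ic <- if (!x$include_main_effect) {
    nm <- paste0("stratum_", x$levels)
    tibble::tibble(level = x$levels, role = "intercept",
                   estimate = as.numeric(co[nm]), std.error = as.numeric(cv[nm]))
  } else {
    tibble::tibble(level = x$levels[1], role = "intercept",
                   estimate = as.numeric(co["(Intercept)"]),
                   std.error = as.numeric(cv["(Intercept)"]))
  }
  dplyr::bind_rows(
    ic,
    tibble::tibble(level = sl$level, role = "slope",
                   estimate = sl$slope, std.error = sl$std_err)
  )
}

#' @describeIn fit_stratified_decay One-row model summary.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  y <- x$data[[x$response]]
  tss <- sum((y - mean(y))^2)
  tibble::tibble(
    r.squared = if (tss > 0) 1 - x$fit$residual_ss / tss else NA_real_,
    sigma = if (x$fit$residual_df > 0)
      sqrt(x$fit$residual_ss / x$fit$residual_df) else 0,
    df.residual = x$fit$residual_df,
    nobs = nrow(x$data),
    n_censored_excluded = nrow(x$censored),
    n_strata = length(x$levels)
  )
}

#' @describeIn fit_stratified_decay Survival data with fitted decay lines;
#'   censored observations are drawn as asterisks at their LOD-implied
#'   values and do not influence the lines.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  d <- object$data
  d$.stratum <- factor(d[[object$stratum]])
  d$.t <- d[[object$covariate]]
  d$.y <- d[[object$response]]
  sl <- decay_slopes(object)
  ic <- tidy.decay_fit(object)
  ic <- ic[ic$role == "intercept", ]
  lines <- tibble::tibble(
    .stratum = factor(sl$level, levels = levels(d$.stratum)),
    intercept = if (object$include_main_effect)
      rep(ic$estimate[1], nrow(sl)) else ic$estimate[match(sl$level, ic$level)],
    slope = sl$slope
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$.t, y = .data$.y,
                                       colour = .data$.stratum)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$.stratum)
    ) +
    ggplot2::labs(x = paste0(object$covariate), y = object$response,
                  colour = object$stratum)
  if (nrow(object$censored) > 0) {
    cd <- object$censored
    cd$.stratum <- factor(cd[[object$stratum]], levels = levels(d$.stratum))
    cd$.t <- cd[[object$covariate]]
    cd$.y <- cd[[object$response]]
    p <- p + ggplot2::geom_point(data = cd, shape = 8)
  }
  p
}
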