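noise_free_obs <- function() {
  d <- tidyr::expand_grid(level = c("cool", "hot"),
                          duration_min = c(0, 30, 60, 90))
  d$log10_percent <- ifelse(d$level == "cool",
                            2 - 0.01 * d$duration_min,
                            2 - 0.02 * d$duration_min)
  d$censored <- FALSE
  d
}

test_that("noise-free strata are recovered exactly with zero residual variance", {
  fit <- fit_stratified_decay(noise_free_obs())
  sl <- phagestress:::decay_slopes(fit)
  expect_equal(sl$slope[sl$level == "cool"], -0.01, tolerance = 1e-12)
  expect_equal(sl$slope[sl$level == "hot"], -0.02, tolerance = 1e-12)
  expect_equal(fit$fit$residual_ss, 0, tolerance = 1e-20)
  # tests are undefined on a perfect fit
  expect_error(slope_tests(fit), "perfect fit",
               class = "phagestress_domain_error")
})

test_that("slope tests match closed-form simple regression per stratum", {
  # single stratum, 3 points: compare against textbook OLS formulas
  d <- tibble::tibble(level = "a", duration_min = c(0, 30, 60),
                      log10_percent = c(2.0, 1.6, 1.5), censored = FALSE)
  fit <- fit_stratified_decay(d)
  st <- slope_tests(fit, n_tests = 1)
  t_c <- d$duration_min - mean(d$duration_min)
  slope_hat <- sum(t_c * d$log10_percent) / sum(t_c^2)
  resid <- d$log10_percent - mean(d$log10_percent) - slope_hat * t_c
  se_hat <- sqrt(sum(resid^2) / 1 / sum(t_c^2))
  expect_equal(st$slope, slope_hat, tolerance = 1e-10)
  expect_equal(st$std_err, se_hat, tolerance = 1e-10)
  expect_equal(st$t_value, slope_hat / se_hat, tolerance = 1e-10)
  expect_equal(st$p_one_tailed, pt(st$t_value, 1), tolerance = 1e-12)
})

test_that("an exactly-zero slope gives one-tailed p = 0.5 and Bonferroni 1", {
  # symmetric responses around the duration midpoint: slope exactly 0,
  # residual variance positive
  d <- tibble::tibble(level = "a", duration_min = c(0, 30, 60),
                      log10_percent = c(1, 2, 1), censored = FALSE)
  fit <- fit_stratified_decay(d)
  st <- slope_tests(fit, n_tests = 4)
  expect_equal(st$slope, 0, tolerance = 1e-14)
  expect_equal(st$p_one_tailed, 0.5, tolerance = 1e-12)
  expect_equal(st$p_bonferroni, 1)
})

test_that("t-value equals slope over its standard error on noisy fits", {
  set.seed(12)
  obs <- random_survival_data(4, 4)
  st <- slope_tests(fit_stratified_decay(obs))
  expect_equal(st$t_value, st$slope / st$std_err, tolerance = 1e-10)
  expect_equal(st$p_bonferroni, pmin(1, st$n_tests * st$p_one_tailed))
})

test_that("censored rows never influence coefficients, SS or p-values", {
  set.seed(77)
  for (i in 1:10) {
    obs <- random_survival_data()
    extra <- obs[sample(nrow(obs), 5), ]
    extra$log10_percent <- extra$log10_percent - runif(5, 1, 3)
    extra$censored <- TRUE
    with_cens <- dplyr::bind_rows(obs, extra)

    f1 <- fit_stratified_decay(obs)
    f2 <- fit_stratified_decay(with_cens)
    expect_equal(f1$fit$coefficients, f2$fit$coefficients)
    expect_equal(ancova_table(obs), ancova_table(with_cens))
    expect_equal(slope_tests(f1), slope_tests(f2))
  }
})

test_that("relabeling strata permutes but does not change slope estimates", {
  set.seed(13)
  obs <- random_survival_data(3, 4)
  relab <- obs
  map <- c(s1 = "zebra", s2 = "ant", s3 = "mouse")
  relab$level <- unname(map[relab$level])
  a <- slope_tests(fit_stratified_decay(obs))
  b <- slope_tests(fit_stratified_decay(relab))
  b <- b[match(unname(map[a$level]), b$level), ]
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
  expect_equal(a$std_err, b$std_err, tolerance = 1e-12)
})

test_that("sequential ANCOVA equals brute-force nested refits and base anova", {
  set.seed(14)
  for (i in 1:10) {
    obs <- random_survival_data(3, 5)
    obs$f <- factor(obs$level)
    ours <- ancova_table(obs)
    # base R fits the identical sequential decomposition
    ref <- anova(lm(log10_percent ~ f + f:duration_min, data = obs))
    expect_equal(ours$sumsq, ref[["Sum Sq"]], tolerance = 1e-10)
    expect_equal(ours$df, ref[["Df"]])
    expect_equal(ours$statistic[1:2], ref[["F value"]][1:2],
                 tolerance = 1e-10)
    # and brute-force nested RSS differences
    ss <- nested_rss_anova(list(log10_percent ~ 1,
                                log10_percent ~ f,
                                log10_percent ~ f + f:duration_min), obs)
    expect_equal(ours$sumsq[1:2], unname(ss), tolerance = 1e-10)
    # total decomposition
    expect_equal(sum(ours$sumsq),
                 sum((obs$log10_percent - mean(obs$log10_percent))^2),
                 tolerance = 1e-10)
  }
})

test_that("the main-effect parametrization changes SS but not the slopes", {
  set.seed(15)
  obs <- random_survival_data(3, 4)
  sl0 <- slope_tests(fit_stratified_decay(obs))
  sl1 <- slope_tests(fit_stratified_decay(obs, include_main_effect = TRUE))
  expect_equal(sl0$slope, sl1$slope, tolerance = 1e-10)
  a1 <- ancova_table(obs, include_main_effect = TRUE)
  ref <- anova(lm(log10_percent ~ f + duration_min + f:duration_min,
                  data = dplyr::mutate(obs, f = factor(level))))
  expect_equal(a1$sumsq, ref[["Sum Sq"]], tolerance = 1e-10)
  expect_equal(a1$df, ref[["Df"]])
})

test_that("strata with too few distinct durations are rejected by name", {
  obs <- noise_free_obs()
  obs <- obs[!(obs$level == "hot" & obs$duration_min > 0), ]
  expect_error(fit_stratified_decay(obs), "hot",
               class = "phagestress_domain_error")
})

test_that("decay_analysis reports inestimable strata as NA rows", {
  obs <- noise_free_obs()
  obs$log10_percent <- obs$log10_percent + c(0.01, -0.01)  # break perfect fit
  below <- tidyr::expand_grid(level = "inferno",
                              duration_min = c(0, 30, 60, 90))
  below$log10_percent <- -6
  below$censored <- TRUE
  res <- decay_analysis(dplyr::bind_rows(obs, below))
  expect_equal(res$dropped_levels, "inferno")
  na_row <- res$slopes[res$slopes$level == "inferno", ]
  expect_true(is.na(na_row$slope) && is.na(na_row$t_value) &&
                is.na(na_row$p_bonferroni))
  expect_equal(sum(!is.na(res$slopes$slope)), 2)
})

test_that("slopes are recovered across simulated decay experiments", {
  # moderate-size parameter recovery run; the full acceptance-scale run
  # lives in the acceptance suite
  set.seed(16)
  true_slope <- -0.01
  hits <- 0
  n_runs <- 30
  for (i in 1:n_runs) {
    d <- tibble::tibble(level = "a",
                        duration_min = rep(c(5, 30, 60, 90), 2),
                        censored = FALSE)
    d$log10_percent <- 2 + true_slope * d$duration_min + rnorm(8, 0, 0.1)
    st <- slope_tests(fit_stratified_decay(d), n_tests = 1)
    ci <- st$slope + c(-1, 1) * qt(0.975, st$df) * st$std_err
    if (ci[1] <= true_slope && true_slope <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_runs - 3)
})

test_that("tidy, glance and autoplot work on a decay fit", {
  set.seed(18)
  obs <- random_survival_data(3, 4)
  fit <- fit_stratified_decay(obs)
  td <- tidy(fit)
  expect_setequal(unique(td$role), c("intercept", "slope"))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$df.residual, nrow(obs) - 6)
  expect_s3_class(autoplot(fit), "ggplot")
})
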