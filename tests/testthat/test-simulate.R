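test_that("identical seeds give identical simulated tables", {
  cfg <- decay_sim_config(stocks = 2, seed = 33)
  a <- simulate_decay_assay(cfg)
  b <- simulate_decay_assay(cfg)
  expect_identical(a, b)
  c2 <- simulate_decay_assay(decay_sim_config(stocks = 2, seed = 34))
  expect_false(identical(a$plaques, c2$plaques))

  lay <- growth_layout(stocks = "stock_A", replicates = 1)
  gcfg <- growth_sim_config(seed = 33, duration_min = 120)
  g1 <- simulate_growth_curves(gcfg, lay)
  g2 <- simulate_growth_curves(gcfg, lay)
  expect_identical(g1, g2)
})

test_that("zero decay in noise-free mode titers to exactly 100% survival", {
  counts <- simulate_decay_assay(decay_sim_config(
    conditions = tibble::tibble(label = "flat", stressor = "heat",
                                level = 55, k1 = 0),
    durations_min = c(5, 30, 60, 90), stocks = 1, stock_sd = 0,
    poisson_noise = FALSE, seed = 1
  ))
  surv <- survival_table(titer_table(counts),
                         survival_config(heat = list(duration_min = 5)))
  expect_equal(surv$percent_survival, rep(100, 4))
  expect_equal(surv$log10_percent, rep(2, 4))
})

test_that("plaque counts are Poisson around the dilution-implied mean", {
  # 1000 replicate plates at expected count 30
  cfg <- decay_sim_config(
    n0_pfu_per_ml = 30 / 0.1 * 1e6,
    conditions = tibble::tibble(label = "x", stressor = "none",
                                level = 0, k1 = 0),
    durations_min = 0, stocks = 1, stock_sd = 0,
    dilution_exponents = 6, n_plates = 1000, seed = 44
  )
  counts <- simulate_decay_assay(cfg)
  expect_equal(nrow(counts), 1000)
  expect_lt(abs(mean(counts$plaques) - 30), 3 * sqrt(30 / 1000))
  expect_gt(var(counts$plaques), 30 * 0.7)  # dispersion consistent with Poisson
  expect_lt(var(counts$plaques), 30 * 1.4)
})

test_that("between-stock variation appears as a lognormal titer offset", {
  cfg <- decay_sim_config(
    conditions = tibble::tibble(label = "x", stressor = "none",
                                level = 0, k1 = 0),
    durations_min = 0, stocks = 50, stock_sd = 0.3,
    poisson_noise = FALSE, seed = 9
  )
  truth <- attr(simulate_decay_assay(cfg), "true_titers")
  lt <- log10(truth$true_titer) - 10
  expect_lt(abs(sd(lt) - 0.3), 0.12)
  expect_lt(abs(mean(lt)), 0.15)
})

test_that("phage-free noise-free wells grow logistically to carrying capacity", {
  cfg <- growth_sim_config(od_noise_sd = 0, seed = 1)
  lay <- tibble::tibble(well_id = "A01", treatment = "ctrl",
                        stock_id = "none", damage_factor = 1,
                        dose_pfu = 0, k_factor = 1,
                        control_type = "ctrl")
  plate <- simulate_growth_curves(cfg, lay)
  pk <- first_peak(plate$od600, plate$time_min, prominence = 0.001)
  expect_true(pk$boundary_flag)
  expect_equal(pk$peak_time_min, cfg$duration_min)
  expect_equal(pk$peak_od, cfg$od_blank + cfg$od_per_cell * cfg$K,
               tolerance = 1e-3)
  # logistic closed form at a mid timepoint
  b0 <- cfg$dose_pfu / cfg$target_moi / cfg$well_volume_ml
  t_mid <- 180
  b_exact <- cfg$K / (1 + (cfg$K / b0 - 1) * exp(-cfg$r * t_mid))
  od_mid <- plate$od600[plate$time_min == t_mid]
  expect_equal(od_mid, cfg$od_blank + cfg$od_per_cell * b_exact,
               tolerance = 1e-4)
})

test_that("phage-challenged cultures rise, peak and decline; total cells stay below K", {
  cfg <- growth_sim_config(od_noise_sd = 0, seed = 1)
  lay <- tibble::tibble(well_id = "A01", treatment = "0",
                        stock_id = "A", damage_factor = 1,
                        dose_pfu = 200, k_factor = 1,
                        control_type = NA_character_)
  plate <- simulate_growth_curves(cfg, lay)
  pk <- first_peak(plate$od600, plate$time_min, prominence = 0.01)
  expect_false(pk$boundary_flag)
  expect_lt(pk$peak_time_min, cfg$duration_min)
  expect_gt(pk$peak_od, cfg$od_blank + 5 * 0.005)
  # conservation: OD never implies more cells than carrying capacity
  max_cells <- (max(plate$od600) - cfg$od_blank) / cfg$od_per_cell
  expect_lte(max_cells, cfg$K * (1 + 1e-6))
  # late decline well below the peak
  late <- plate$od600[plate$time_min > 600]
  expect_lt(min(late), pk$peak_od * 0.8)
})

test_that("peak OD is non-increasing in burst size (noise-free sweep)", {
  peaks <- vapply(c(10, 50, 100, 200, 400), function(b) {
    cfg <- growth_sim_config(burst = b, od_noise_sd = 0, seed = 1)
    lay <- tibble::tibble(well_id = "A01", treatment = "0", stock_id = "A",
                          damage_factor = 1, dose_pfu = 200, k_factor = 1,
                          control_type = NA_character_)
    plate <- simulate_growth_curves(cfg, lay)
    first_peak(plate$od600, plate$time_min, prominence = 0.01)$peak_od
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("heat damage strictly raises the bacterial peak at equal dose", {
  peak_at <- function(damage) {
    cfg <- growth_sim_config(od_noise_sd = 0, seed = 1)
    lay <- tibble::tibble(well_id = "A01", treatment = "x", stock_id = "A",
                          damage_factor = damage, dose_pfu = 200,
                          k_factor = 1, control_type = NA_character_)
    plate <- simulate_growth_curves(cfg, lay)
    first_peak(plate$od600, plate$time_min, prominence = 0.01)$peak_od
  }
  expect_gt(peak_at(0.2), peak_at(1.0))
})

test_that("log-linear fits recover mono-exponential decay but not biphasic decay", {
  mono <- simulate_decay_assay(decay_sim_config(
    conditions = tibble::tibble(label = "m", stressor = "heat", level = 70,
                                k1 = -0.02),
    durations_min = seq(0, 150, by = 30), stocks = 1, stock_sd = 0,
    poisson_noise = FALSE, seed = 2
  ))
  biph <- simulate_decay_assay(decay_sim_config(
    conditions = tibble::tibble(label = "b", stressor = "heat", level = 70,
                                k1 = -0.2, k2 = -0.002, fraction_fast = 0.9),
    durations_min = seq(0, 150, by = 30), stocks = 1, stock_sd = 0,
    poisson_noise = FALSE, seed = 2
  ))
  fit_rss <- function(counts) {
    surv <- survival_table(titer_table(counts),
                           survival_config(heat = list(duration_min = 0)))
    fit_stratified_decay(surv)$fit$residual_ss
  }
  # the mono fit is log-linear up to plate-count rounding; the biphasic
  # curve leaves orders-of-magnitude larger systematic curvature
  expect_lt(fit_rss(mono), 0.01)
  expect_gt(fit_rss(biph), 0.1)
})

test_that("the fixture bundle is self-consistent and exercises censoring", {
  with_tmpdir(function(dir) {
    files <- make_fixture_bundle(dir, seed = 5)
    expect_true(all(file.exists(files)))
    counts <- dplyr::bind_rows(
      read_plaque_counts(files[["heat_plaque_counts"]]),
      read_plaque_counts(files[["solute_plaque_counts"]])
    )
    plate <- read_plate_timeseries(files[["growth_measurements"]],
                                   files[["growth_layout"]], "long")
    expect_gt(nrow(plate), 0)
    surv <- survival_table(titer_table(counts))
    # the 75C condition is driven below the limit of detection
    cens <- surv[surv$censored, ]
    expect_gt(nrow(cens), 0)
    expect_true(all(cens$level == 75))
    # and censored rows are excluded from the heat fit
    res <- decay_analysis(surv[surv$stressor == "heat", ])
    expect_equal(res$dropped_levels, "75")
  })
})
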