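test_that("standard-curve conversions follow the log-linear calibration", {
  curve <- standard_curve(8, 1, c(0.01, 1))
  expect_equal(as.numeric(od_to_cfu(0.5, curve)), 10^8.5)
  expect_equal(as.numeric(suppressWarnings(od_to_cfu(0, curve))), 1e8)
  expect_warning(od_to_cfu(0.001, curve), "extrapolat")
  # inverse round trip
  od <- c(0.05, 0.2, 0.9)
  back <- cfu_to_od(as.numeric(od_to_cfu(od, curve)), curve)
  expect_equal(back, od, tolerance = 1e-12)
  expect_error(standard_curve(8, -1), class = "phagestress_domain_error")
})

fake_titer <- function(pfu, id = "s") {
  tibble::tibble(sample_id = id, pfu_per_ml = pfu, lod_pfu_per_ml = 10,
                 censored = FALSE, n_plates_used = 3L, out_of_range = FALSE)
}

test_that("dosing hits 200 PFU at MOI 1e-5 with 2e7 cells per well", {
  curve <- standard_curve(8.5, 1)
  plan <- dose_wells(fake_titer(1e7), culture_od = 0.5, curve = curve)
  expect_equal(plan$bacteria_cells_per_well, 200 / 1e-5)
  expect_equal(plan$achieved_pfu, 200, tolerance = 1e-9)
  expect_false(plan$insufficient)
})

test_that("high-titer stocks get an intermediate dilution; volumes stay pipettable", {
  curve <- standard_curve(8.5, 1)
  spec <- dose_spec()
  plan <- dose_wells(fake_titer(1e9), culture_od = 0.5, curve = curve,
                     spec = spec)
  expect_gt(plan$phage_dilution_exponent, 0)
  expect_gte(plan$phage_volume_ml, spec$min_pipette_ml)
  expect_lte(plan$phage_volume_ml, spec$max_phage_volume_ml)
  expect_equal(plan$achieved_pfu, 200, tolerance = 200 * 0.01)
})

test_that("low-titer stocks are flagged insufficient with the attainable dose", {
  curve <- standard_curve(8.5, 1)
  plan <- dose_wells(fake_titer(1e3), culture_od = 0.5, curve = curve)
  expect_true(plan$insufficient)
  expect_equal(plan$achieved_pfu, 100)   # 1e3 PFU/mL x 0.1 mL max
  # MOI held constant by shrinking the bacterial inoculum
  expect_equal(plan$achieved_moi, 1e-5)
  cen <- fake_titer(10); cen$censored <- TRUE
  expect_error(dose_wells(cen, 0.5, curve), class = "phagestress_domain_error")
})

test_that("smoothing leaves constants alone, is identity at window 1, kills spikes", {
  const <- rep(0.3, 20)
  expect_equal(smooth_curve(const, "moving_median", 5), const)
  expect_equal(smooth_curve(const, "moving_average", 5), const)
  x <- runif(15)
  expect_equal(smooth_curve(x, "moving_median", 1), x)
  expect_error(smooth_curve(x, window = 4), class = "phagestress_domain_error")
  expect_error(smooth_curve(x[1:3], window = 5),
               class = "phagestress_domain_error")

  flat <- rep(0.2, 21); flat[11] <- 0.2 + 5
  sm <- smooth_curve(flat, "moving_median", 5)
  expect_equal(sm, rep(0.2, 21))
})

test_that("smoothing matches a brute-force windowed oracle and stays bounded", {
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(sample(10:40, 1))
    w <- sample(c(3, 5, 7), 1)
    expect_equal(smooth_curve(x, "moving_median", w),
                 running_stat_scan(x, w, median))
    avg <- smooth_curve(x, "moving_average", w)
    expect_equal(avg, running_stat_scan(x, w, mean))
    expect_true(all(avg >= min(x) & avg <= max(x)))
  }
})

test_that("first_peak handles boundary, unimodal and bimodal series", {
  tg <- seq(0, 95, by = 5)
  rising <- seq(0.1, 1, length.out = 20)
  pk <- first_peak(rising, tg, prominence = 0.01)
  expect_true(pk$boundary_flag)
  expect_equal(pk$peak_index, 20L)

  unimodal <- c(seq(0.1, 1, length.out = 10), seq(0.95, 0.3, length.out = 10))
  pk2 <- first_peak(unimodal, tg, prominence = 0.05)
  expect_false(pk2$boundary_flag)
  expect_equal(pk2$peak_index, which.max(unimodal))

  # first hump lower than the second but prominent: first is chosen
  bimodal <- c(0.1, 0.4, 0.6, 0.4, 0.2, 0.5, 0.9, 0.6, 0.3, 0.1,
               rep(0.1, 10))
  pk3 <- first_peak(bimodal, tg, prominence = 0.1)
  expect_equal(pk3$peak_index, 3L)
  expect_false(pk3$boundary_flag)

  expect_error(first_peak(c(1, 2), c(0, 5)),
               class = "phagestress_domain_error")
})

test_that("first_peak equals the exhaustive scan of its definition", {
  set.seed(24)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    s <- cumsum(rnorm(n, 0, 0.1)) + dnorm(seq(-2, 4, length.out = n)) * 2
    prom <- runif(1, 0, 0.5)
    got <- first_peak(s, seq_len(n), prominence = prom)
    want <- first_peak_scan(s, prom)
    expect_equal(got$peak_index, want$index)
    expect_equal(got$boundary_flag, want$boundary)
  }
})

test_that("peak extraction is shift-equivariant in time and scale-equivariant in OD", {
  set.seed(25)
  n <- 40
  s <- c(seq(0.1, 0.8, length.out = 25), seq(0.78, 0.3, length.out = 15)) +
    rnorm(n, 0, 0.01)
  tg <- seq(0, by = 5, length.out = n)
  sm <- smooth_curve(s, "moving_median", 5)
  base <- first_peak(sm, tg, prominence = 0.05)
  shifted <- first_peak(sm, tg + 120, prominence = 0.05)
  expect_equal(shifted$peak_time_min, base$peak_time_min + 120)
  scaled <- first_peak(3 * smooth_curve(3 * s, "moving_median", 5), tg,
                       prominence = 0.05 * 9)
  expect_equal(scaled$peak_od, 9 * base$peak_od, tolerance = 1e-12)
  expect_equal(scaled$peak_index, base$peak_index)
})

test_that("fitness comparison reproduces the two-group Tukey/t identity end-to-end", {
  set.seed(26)
  peaks <- tibble::tibble(
    well_id = sprintf("W%02d", 1:12),
    treatment = rep(c("0", "90"), each = 6),
    stock_id = "A",
    inoculated_pfu = 200, target_moi = 1e-5,
    control_type = NA_character_,
    peak_od = c(rnorm(6, 0.5, 0.03), rnorm(6, 0.65, 0.03)),
    excluded = FALSE
  )
  fc <- fitness_comparison(peaks)
  tt <- t.test(peak_od ~ treatment, data = peaks, var.equal = TRUE)
  expect_lt(abs(fc$tukey$p_adj - tt$p.value), 1e-8)
  expect_equal(fc$anova$df, c(1L, 10L))
})

test_that("fitness comparison excludes under-dosed wells and tests controls", {
  set.seed(27)
  peaks <- tibble::tibble(
    well_id = sprintf("W%02d", 1:22),
    treatment = c(rep(c("0", "5", "90"), each = 4), rep("ctrl", 5),
                  rep("ctrl_shock", 5)),
    stock_id = rep(c("A", "B"), 11),
    inoculated_pfu = c(rep(200, 10), 40, 200, rep(NA, 10)),
    target_moi = 1e-5,
    control_type = c(rep(NA, 12), rep("ctrl", 5), rep("ctrl_shock", 5)),
    peak_od = c(rnorm(4, 0.45, 0.02), rnorm(8, 0.6, 0.02),
                rnorm(5, 0.75, 0.02), rnorm(5, 0.7, 0.02)),
    excluded = FALSE
  )
  peaks$excluded <- !is.na(peaks$inoculated_pfu) & peaks$inoculated_pfu < 198
  fc <- fitness_comparison(peaks)
  expect_equal(fc$n_excluded, 1)
  expect_equal(nrow(fc$peaks), 11)
  expect_false(is.null(fc$welch))
  ref <- t.test(peaks$peak_od[peaks$control_type == "ctrl"],
                peaks$peak_od[peaks$control_type == "ctrl_shock"])
  expect_equal(fc$welch$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fc$welch$df, unname(ref$parameter), tolerance = 1e-12)
  # letters partition: 0 differs from the damaged treatments
  ltr <- setNames(fc$letters$letters, fc$letters$treatment)
  expect_false(ltr[["0"]] == ltr[["5"]])
  expect_s3_class(autoplot(fc), "ggplot")
  expect_equal(tidy(fc), fc$tukey)
  expect_equal(glance(fc)$n_excluded, 1)
})

test_that("Tukey letter sharing equals non-significance on fitness output", {
  set.seed(28)
  peaks <- tibble::tibble(
    well_id = sprintf("W%02d", 1:24),
    treatment = rep(c("0", "5", "90", "180"), each = 6),
    stock_id = "A",
    inoculated_pfu = 200, target_moi = 1e-5, control_type = NA_character_,
    peak_od = rnorm(24, rep(c(0.45, 0.62, 0.63, 0.64), each = 6), 0.03),
    excluded = FALSE
  )
  fc <- fitness_comparison(peaks)
  ltr <- setNames(fc$letters$letters, fc$letters$treatment)
  for (i in seq_len(nrow(fc$tukey))) {
    shares <- any(strsplit(ltr[[fc$tukey$level_a[i]]], "")[[1]] %in%
                    strsplit(ltr[[fc$tukey$level_b[i]]], "")[[1]])
    expect_equal(shares, fc$tukey$p_adj[i] >= fc$alpha)
  }
})
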