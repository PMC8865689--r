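#' Configuration for simulated decay/plaque-assay experiments
#'
#' Describes a stress-exposure experiment observed through a plaque assay:
#' per-condition (optionally biphasic) exponential decay of the true titer
#' on the log10 scale, lognormal between-stock variation, and Poisson
#' plaque counting through a serial-dilution scheme. Defaults reproduce
#' the heat-gradient design: four temperatures with decay rates equal to
#' the study's per-temperature estimates, durations 5/30/60/90 minutes,
#' and triplicate 0.1 mL platings across a tenfold dilution series.
#'
#' @param n0_pfu_per_ml True starting titer of the stock lysate.
#' @param conditions Data frame with columns `label`, `level`, `stressor`,
#'   `k1` (log10 units per minute; the decay slope), and optionally `k2`
#'   and `fraction_fast` for biphasic decay (`fraction_fast = 1` is
#'   mono-exponential). Small positive `k1` values are allowed: estimated
#'   slopes of stable conditions scatter around zero.
#' @param durations_min Exposure durations sampled.
#' @param stocks Number of biological replicate stocks.
#' @param stock_sd Between-stock variation, sd of a log10-scale normal
#'   multiplicative offset.
#' @param volume_ml Plated volume.
#' @param dilution_exponents Serial dilutions plated per sample.
#' @param n_plates Replicate plates per dilution (triplicate by default).
#' @param pre_dilution_factor Protocol dilution applied before the serial
#'   dilutions (200 for the stress-termination protocol of the solute
#'   assays).
#' @param poisson_noise `FALSE` yields noise-free rounded expected counts.
#' @param seed RNG seed (used by [simulate_decay_assay()]).
#' @return A `decay_sim_config` object.
#' @export
decay_sim_config <- function(n0_pfu_per_ml = 1e10,
                             conditions = heat_gradient_conditions(),
                             durations_min = c(5, 30, 60, 90),
                             stocks = 1,
                             stock_sd = 0.1,
                             volume_ml = 0.1,
                             dilution_exponents = 0:9,
                             n_plates = 3,
                             pre_dilution_factor = 1,
                             poisson_noise = TRUE,
                             seed = 1L) {
  conditions <- tibble::as_tibble(conditions)
  if (!all(c("label", "level", "stressor", "k1") %in% names(conditions))) {
    abort("conditions needs columns label, level, stressor, k1",
          class = "phagestress_domain_error")
  }
  if (!"k2" %in% names(conditions)) conditions$k2 <- conditions$k1
  if (!"fraction_fast" %in% names(conditions)) conditions$fraction_fast <- 1
  if (any(!is.finite(conditions$k1)) || any(!is.finite(conditions$k2))) {
    abort("non-finite decay rate", class = "phagestress_domain_error")
  }
  if (any(conditions$fraction_fast < 0 | conditions$fraction_fast > 1)) {
    abort("fraction_fast must be in [0, 1]",
          class = "phagestress_domain_error")
  }
  if (length(durations_min) == 0) {
    abort("durations_min must be nonempty", class = "phagestress_domain_error")
  }
  structure(list(n0_pfu_per_ml = n0_pfu_per_ml, conditions = conditions,
                 durations_min = durations_min, stocks = stocks,
                 stock_sd = stock_sd, volume_ml = volume_ml,
                 dilution_exponents = dilution_exponents,
                 n_plates = n_plates,
                 pre_dilution_factor = pre_dilution_factor,
                 poisson_noise = isTRUE(poisson_noise),
                 seed = as.integer(seed)),
            class = "decay_sim_config")
}

#' Study-design condition tables for the decay simulator
#'
#' `heat_gradient_conditions()` encodes the heat-gradient design with
#' per-temperature log10-percent-per-minute decay rates set to the study's
#' estimates (near-zero at 55 and 60 degrees C, moderate at 65, fast at
#' 70), plus an optional very-fast stratum representing temperatures at
#' which every measurement falls below the limit of detection.
#' `solute_conditions()` encodes the urea/saline designs (no saline
#' effect; urea decay above 2 M).
#'
#' @param include_below_lod Add the 75 degrees C below-LOD stratum?
#' @return Tibble usable as `conditions` in [decay_sim_config()].
#' @export
heat_gradient_conditions <- function(include_below_lod = FALSE) {
  base <- tibble::tibble(
    label = c("55C", "60C", "65C", "70C"),
    stressor = "heat",
    level = c(55, 60, 65, 70),
    k1 = c(0.0008, 0.0005, -0.0028, -0.0182)
  )
  if (include_below_lod) {
    base <- dplyr::bind_rows(
      base,
      tibble::tibble(label = "75C", stressor = "heat", level = 75, k1 = -2)
    )
  }
  base
}

#' @rdname heat_gradient_conditions
#' @param stressor `"urea"` or `"saline"`.
#' @export
solute_conditions <- function(stressor = c("urea", "saline")) {
  stressor <- match.arg(stressor)
  if (stressor == "urea") {
    tibble::tibble(
      label = paste0(c(0, 1, 2, 3, 4), "M_urea"), stressor = "urea",
      level = c(0, 1, 2, 3, 4),
      k1 = c(0, 0, 0, -0.01, -0.029)
    )
  } else {
    tibble::tibble(
      label = paste0(c(0, 0.17, 0.5, 3, 5), "M_saline"), stressor = "saline",
      level = c(0, 0.17, 0.5, 3, 5),
      k1 = 0
    )
  }
}

#' Simulate a plaque-count table from a decay experiment
#'
#' For each condition, stock and duration the true titer is
#' `N(t) = N0 * m_stock * (f * 10^(k1 t) + (1 - f) * 10^(k2 t))` with
#' `m_stock = 10^Normal(0, stock_sd)`; each plate's count is Poisson with
#' mean `N(t) / pre_dilution_factor * volume * 10^-d`. The same seed and
#' config always give an identical table.
#'
#' @param config A [decay_sim_config()].
#' @return A validated plaque-count tibble ([as_plaque_counts()]), with a
#'   `pre_dilution_factor` column when the protocol dilution is not 1 and
#'   a hidden attribute `true_titers` (tibble of the noise-free titers)
#'   for parameter-recovery checks.
#' @export
simulate_decay_assay <- function(config) {
  stopifnot(inherits(config, "decay_sim_config"))
  set.seed(config$seed)
  cond <- config$conditions
  stock_ids <- paste0("stock_", if (config$stocks <= 26) {
    LETTERS[seq_len(config$stocks)]
  } else {
    sprintf("%03d", seq_len(config$stocks))
  })
  stock_mult <- 10^rnorm(config$stocks, 0, config$stock_sd)
  grid <- tidyr::expand_grid(
    ci = seq_len(nrow(cond)),
    si = seq_len(config$stocks),
    duration_min = config$durations_min
  )
  n_true <- config$n0_pfu_per_ml * stock_mult[grid$si] *
    (cond$fraction_fast[grid$ci] * 10^(cond$k1[grid$ci] * grid$duration_min) +
       (1 - cond$fraction_fast[grid$ci]) *
       10^(cond$k2[grid$ci] * grid$duration_min))
  samples <- tibble::tibble(
    sample_id = paste(cond$label[grid$ci], stock_ids[grid$si],
                      grid$duration_min, sep = "_"),
    stressor = cond$stressor[grid$ci],
    level = cond$level[grid$ci],
    duration_min = grid$duration_min,
    stock_id = stock_ids[grid$si],
    true_titer = n_true
  )
  plates <- tidyr::expand_grid(
    samples,
    dilution_exponent = as.integer(config$dilution_exponents),
    plate = seq_len(config$n_plates)
  )
  lambda <- plates$true_titer / config$pre_dilution_factor *
    config$volume_ml * 10^(-plates$dilution_exponent)
  plates$plaques <- if (config$poisson_noise) {
    # normal approximation for huge means (uncountable lawn plates), where
    # rpois overflows; indistinguishable from Poisson at these counts
    big <- lambda > 1e7
    counts <- numeric(length(lambda))
    counts[!big] <- rpois(sum(!big), lambda[!big])
    counts[big] <- pmax(0, round(rnorm(sum(big), lambda[big],
                                       sqrt(lambda[big]))))
    counts
  } else {
    round(lambda)
  }
  plates$volume_ml <- config$volume_ml
  if (config$pre_dilution_factor != 1) {
    plates$pre_dilution_factor <- config$pre_dilution_factor
  }
  out <- as_plaque_counts(plates[, setdiff(names(plates), "true_titer")])
  attr(out, "true_titers") <- samples
  out
}

#' Configuration for simulated phage-bacteria growth curves
#'
#' Parameters of a stage-structured predation model: logistic bacterial
#' growth, mass-action phage adsorption, an Erlang-distributed latent
#' period (`n_stages` sequential infected classes), and burst release.
#' A `damage_factor` below 1 multiplies the adsorption rate (or burst
#' size) of heat-damaged phage, lowering per-particle fitness without
#' changing the inoculated PFU. Defaults describe an overnight 96-well
#' assay: 5-minute reads for 12 hours, wells seeded at MOI 1e-5 with 200
#' PFU, a ~30-minute bacterial doubling time and a carrying capacity of
#' 1e9 cells/mL read as OD through `od_per_cell`.
#'
#' @param r Bacterial growth rate, 1/min.
#' @param K Carrying capacity, cells/mL.
#' @param adsorption Adsorption rate constant, mL/(cell x min).
#' @param burst Burst size, phage per lysed cell.
#' @param latent_min Mean latent period, minutes.
#' @param n_stages Erlang stages of the latent period.
#' @param od_per_cell OD600 per (cell/mL).
#' @param od_blank Blank OD added to every reading.
#' @param od_noise_sd Additive Gaussian read noise (OD units); 0 for
#'   noise-free curves.
#' @param damage_target `"adsorption"` or `"burst"`: which per-particle
#'   parameter the damage factor multiplies.
#' @param dose_pfu Default phage dose per well.
#' @param target_moi Phage-to-bacteria ratio at inoculation.
#' @param well_volume_ml Well volume.
#' @param duration_min,step_min Measurement span and read interval.
#' @param seed RNG seed for the read noise.
#' @return A `growth_sim_config` object.
#' @export
growth_sim_config <- function(r = log(2) / 30, K = 1e9,
                              adsorption = 1e-9, burst = 100,
                              latent_min = 40, n_stages = 5,
                              od_per_cell = 1e-9, od_blank = 0.04,
                              od_noise_sd = 0.005,
                              damage_target = c("adsorption", "burst"),
                              dose_pfu = 200, target_moi = 1e-5,
                              well_volume_ml = 0.2,
                              duration_min = 720, step_min = 5,
                              seed = 1L) {
  damage_target <- match.arg(damage_target)
  pos <- c(r = r, K = K, adsorption = adsorption, burst = burst,
           latent_min = latent_min, n_stages = n_stages,
           od_per_cell = od_per_cell, well_volume_ml = well_volume_ml,
           target_moi = target_moi, duration_min = duration_min,
           step_min = step_min)
  if (any(!is.finite(pos) | pos <= 0)) {
    abort("all growth rates/sizes must be positive",
          class = "phagestress_domain_error")
  }
  structure(list(r = r, K = K, adsorption = adsorption, burst = burst,
                 latent_min = latent_min, n_stages = as.integer(n_stages),
                 od_per_cell = od_per_cell, od_blank = od_blank,
                 od_noise_sd = od_noise_sd, damage_target = damage_target,
                 dose_pfu = dose_pfu, target_moi = target_moi,
                 well_volume_ml = well_volume_ml,
                 duration_min = duration_min, step_min = step_min,
                 seed = as.integer(seed)),
            class = "growth_sim_config")
}

#' Default well layout for a simulated fitness assay
#'
#' Heat-shock duration treatments (0 minutes = undamaged reference; longer
#' shocks share a reduced per-particle fitness, reflecting the saturating
#' damage seen after any exposure), replicated across stocks, plus two
#' phage-free control groups (plain medium and heat-shocked medium, the
#' latter with a slightly reduced carrying capacity).
#'
#' @param treatments Tibble with `treatment`, `damage_factor`, and
#'   optionally `dose_pfu` and `k_factor` (carrying-capacity multiplier).
#' @param stocks Stock labels replicated over treatments.
#' @param replicates Wells per treatment x stock.
#' @param controls Tibble with `control_type`, `k_factor`, `replicates`.
#' @return Layout tibble for [simulate_growth_curves()].
#' @export
growth_layout <- function(treatments = tibble::tibble(
                            treatment = c("0", "5", "90", "180"),
                            damage_factor = c(1, 0.25, 0.25, 0.25)
                          ),
                          stocks = c("stock_A", "stock_B"),
                          replicates = 3,
                          controls = tibble::tibble(
                            control_type = c("ctrl", "ctrl_shock"),
                            k_factor = c(1, 0.9),
                            replicates = 6
                          )) {
  if (!"dose_pfu" %in% names(treatments)) treatments$dose_pfu <- NA_real_
  if (!"k_factor" %in% names(treatments)) treatments$k_factor <- 1
  trt <- tidyr::expand_grid(treatments, stock_id = stocks,
                            rep = seq_len(replicates))
  trt$control_type <- NA_character_
  ctl <- controls |>
    dplyr::rowwise() |>
    dplyr::reframe(control_type = .data$control_type,
                   k_factor = .data$k_factor,
                   rep = seq_len(.data$replicates))
  ctl$treatment <- ctl$control_type
  ctl$damage_factor <- 1
  ctl$dose_pfu <- 0
  ctl$stock_id <- "none"
  out <- dplyr::bind_rows(trt, ctl)
  out$well_id <- sprintf("%s%02d", rep(LETTERS[1:8], length.out = nrow(out)),
                         (seq_len(nrow(out)) - 1) %/% 8 + 1)
  out[, c("well_id", "treatment", "stock_id", "damage_factor", "dose_pfu",
          "k_factor", "control_type", "rep")]
}

#' Simulate bacterial growth curves under phage predation
#'
#' Integrates, per well, the stage-structured predation model
#' `dB/dt = r B (1 - (B + sum I_j)/K) - a B P`;
#' `dI_1/dt = a B P - (n/lambda) I_1`;
#' `dI_j/dt = (n/lambda)(I_(j-1) - I_j)`;
#' `dP/dt = burst (n/lambda) I_n - a B P`,
#' with `a = adsorption * damage_factor` (or
#' `burst * damage_factor` when `damage_target = "burst"`), using an
#' adaptive stiff ODE solver (maximum internal step `step_min / 4`; the
#' system is stiff once the phage population amplifies), reading OD600
#' every `step_min` as
#' `od_blank + od_per_cell * (B + sum I_j)` plus Gaussian noise. Wells are
#' seeded at constant MOI: `B0 = dose_pfu / target_moi / volume`,
#' `P0 = dose_pfu / volume`; phage-free wells get the same `B0`.
#'
#' @param config A [growth_sim_config()].
#' @param layout A [growth_layout()]-style tibble (columns `well_id`,
#'   `treatment`, `stock_id`, `damage_factor`, optional `dose_pfu`,
#'   `k_factor`, `control_type`).
#' @return A plate time-series tibble ([as_plate_timeseries()]) with
#'   layout columns `inoculated_pfu` and `target_moi` filled in.
#' @export
simulate_growth_curves <- function(config = growth_sim_config(),
                                   layout = growth_layout()) {
  stopifnot(inherits(config, "growth_sim_config"))
  set.seed(config$seed)
  if (!"dose_pfu" %in% names(layout)) layout$dose_pfu <- NA_real_
  if (!"k_factor" %in% names(layout)) layout$k_factor <- 1
  if (!"control_type" %in% names(layout)) layout$control_type <- NA_character_
  times <- seq(0, config$duration_min, by = config$step_min)
  b0_ref <- config$dose_pfu / config$target_moi / config$well_volume_ml

  meas <- purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    w <- layout[i, ]
    dose <- if (is.na(w$dose_pfu)) config$dose_pfu else w$dose_pfu
    p0 <- dose / config$well_volume_ml
    cells <- integrate_predation(
      b0 = b0_ref, p0 = p0,
      r = config$r, K = config$K * w$k_factor,
      a = config$adsorption *
        if (config$damage_target == "adsorption") w$damage_factor else 1,
      burst = config$burst *
        if (config$damage_target == "burst") w$damage_factor else 1,
      latent = config$latent_min, n_stages = config$n_stages,
      times = times, step = config$step_min / 4
    )
    od <- config$od_blank + config$od_per_cell * cells
    if (config$od_noise_sd > 0) {
      od <- od + rnorm(length(od), 0, config$od_noise_sd)
    }
    tibble::tibble(well_id = w$well_id, time_min = times, od600 = od)
  })
  lay <- layout
  lay$inoculated_pfu <- ifelse(is.na(lay$dose_pfu), config$dose_pfu,
                               lay$dose_pfu)
  lay$target_moi <- ifelse(lay$inoculated_pfu > 0, config$target_moi, NA_real_)
  lay$inoculated_pfu[!is.na(lay$control_type)] <- NA_real_
  as_plate_timeseries(
    meas,
    lay[, c("well_id", "treatment", "stock_id", "inoculated_pfu",
            "target_moi", "control_type")]
  )
}

# Integrates the predation ODE with an adaptive stiff solver (lsoda);
# the system turns stiff once the phage population amplifies (adsorption
# x phage density can exceed 100/min), which no practical fixed step can
# follow. Returns uninfected + infected cells/mL at `times`.
integrate_predation <- function(b0, p0, r, K, a, burst, latent, n_stages,
                                times, step) {
  deriv <- function(t, y, parms) {
    b <- y[1]; p <- y[2]; infected <- y[-(1:2)]
    total <- b + sum(infected)
    infection <- a * b * p
    stage_rate <- n_stages / latent
    # stage flows: in from previous stage, out to next
    d_stages <- stage_rate * (c(0, infected[-n_stages]) - infected)
    d_stages[1] <- d_stages[1] + infection
    list(c(
      r * b * (1 - total / K) - infection,
      burst * stage_rate * infected[n_stages] - infection,
      d_stages
    ))
  }
  y0 <- c(B = b0, P = p0, setNames(rep(0, n_stages),
                                   paste0("I", seq_len(n_stages))))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-4 * b0,
                      hmax = step, maxsteps = 50000)
  if (any(!is.finite(sol[, -1])) ||
      any(sol[, "B"] < -1e-3 * K)) {
    abort("growth-curve integration failed; check rates or reduce step_min",
          class = "phagestress_domain_error")
  }
  cells <- sol[, "B"] + rowSums(sol[, paste0("I", seq_len(n_stages)),
                                    drop = FALSE])
  pmax(cells, 0)
}

#' Write a self-consistent synthetic fixture bundle
#'
#' Generates, with one seed, a complete small experiment exercising every
#' pipeline stage, in the package's CSV schemas: a heat-gradient
#' plaque-count table (4 informative temperatures x 4 durations x 2
#' stocks, plus a 75 degrees C condition driven entirely below the limit
#' of detection), urea and saline plaque counts (5 concentrations x
#' {0, 45, 90} minutes x 3 stocks, 200-fold termination dilution), and one
#' growth plate (layout plus long-format OD600 measurements).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling every random draw.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixture_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  heat <- simulate_decay_assay(decay_sim_config(
    conditions = heat_gradient_conditions(include_below_lod = TRUE),
    durations_min = c(5, 30, 60, 90),
    stocks = 2, stock_sd = 0.1, seed = seed
  ))
  solute <- dplyr::bind_rows(
    simulate_decay_assay(decay_sim_config(
      conditions = solute_conditions("urea"),
      durations_min = c(0, 45, 90), stocks = 3, stock_sd = 0.1,
      pre_dilution_factor = 200, seed = seed + 1L
    )),
    simulate_decay_assay(decay_sim_config(
      conditions = solute_conditions("saline"),
      durations_min = c(0, 45, 90), stocks = 3, stock_sd = 0.1,
      pre_dilution_factor = 200, seed = seed + 2L
    ))
  )
  plate <- simulate_growth_curves(growth_sim_config(seed = seed + 3L),
                                  growth_layout())
  layout <- plate |>
    dplyr::distinct(.data$well_id, .data$treatment, .data$stock_id,
                    .data$inoculated_pfu, .data$target_moi,
                    .data$control_type)
  measurements <- plate[, c("well_id", "time_min", "od600")]

  files <- c(
    heat_plaque_counts = file.path(dir, "heat_plaque_counts.csv"),
    solute_plaque_counts = file.path(dir, "solute_plaque_counts.csv"),
    growth_layout = file.path(dir, "growth_layout.csv"),
    growth_measurements = file.path(dir, "growth_measurements.csv")
  )
  write_results(heat, files["heat_plaque_counts"])
  write_results(solute, files["solute_plaque_counts"])
  write_results(layout, files["growth_layout"])
  write_results(measurements, files["growth_measurements"])
  invisible(files)
}
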