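#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the design of the study the package models: 66
#' colonies with 6 replicate fragments each (4 across 4 heat tanks, 2
#' across 2 procedural-control tanks), a 5-week (35-day) heatwave
#' emulation ramping at ~0.8 degrees C per week to +3.5 degrees C above
#' the local climatological baseline after a 7-day ambient
#' acclimatisation, 16 health surveys, colony diameters 24 +/- 8 cm, 4.9
#' +/- 1.4 eggs per polyp, and a mean egg volume of 0.11 mm3. Mean
#' critical DHW is 6.7 +/- 1.1 degree heating weeks across colonies.
#'
#' The couplings are the scientifically interesting dials: they set the
#' latent correlation between a colony's thermal threshold and its growth
#' (or fecundity), embodying the energetic-continuum hypothesis that
#' resource-rich colonies do everything well. Coupling 0 generates the
#' no-association null.
#'
#' @param n_colonies,n_heat_fragments,n_control_fragments,n_tanks_heat,n_tanks_control Design counts.
#' @param mean_diameter_cm,sd_diameter_cm Initial colony diameter distribution.
#' @param mean_eggs_per_polyp,sd_eggs_per_polyp Per-polyp egg count distribution.
#' @param mean_egg_volume_mm3 Target mean egg volume.
#' @param mean_critical_dhw,sd_critical_dhw Latent colony thermal thresholds (degree heating weeks).
#' @param mean_livesa_growth,sd_livesa_growth,mean_vol_growth,sd_vol_growth Annual growth distributions (cm2/yr, cm3/yr).
#' @param tolerance_growth_coupling,tolerance_fecundity_coupling Latent correlations in `[-1, 1]`.
#' @param ramp_rate_c_per_week,peak_anomaly_c,assay_days,acclim_days Heatwave profile.
#' @param n_surveys Number of health survey timepoints.
#' @param baseline_c Ambient baseline (MMM_adj) in degrees C.
#' @param diel_amplitude_c,noise_sd_c Daily cycle amplitude and logger noise.
#' @param fragment_threshold_sd Fragment-level SD around the colony threshold (degree heating weeks).
#' @param category_offsets DHW offsets past the fragment threshold at
#'   which it advances to bleached, partial mortality, and dead.
#' @param handling_death_prob Per-colony probability that one control
#'   fragment dies of handling (exercises the exclusion rule).
#' @param n_polyps_per_colony Dissected polyps per colony (two fragments of ten).
#' @param mean_polyp_density,sd_polyp_density Polyps per cm2.
#' @param seed Integer seed; every table derives its substream from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_colonies = 66, n_heat_fragments = 4, n_control_fragments = 2,
                         n_tanks_heat = 4, n_tanks_control = 2,
                         mean_diameter_cm = 24, sd_diameter_cm = 8,
                         mean_eggs_per_polyp = 4.9, sd_eggs_per_polyp = 1.4,
                         mean_egg_volume_mm3 = 0.11,
                         mean_critical_dhw = 6.7, sd_critical_dhw = 1.1,
                         mean_livesa_growth = 216, sd_livesa_growth = 722,
                         mean_vol_growth = 404, sd_vol_growth = 647,
                         tolerance_growth_coupling = 0.4,
                         tolerance_fecundity_coupling = 0,
                         ramp_rate_c_per_week = 0.8, peak_anomaly_c = 3.5,
                         assay_days = 35, acclim_days = 7, n_surveys = 16,
                         baseline_c = 29.5,
                         diel_amplitude_c = 0.4, noise_sd_c = 0.12,
                         fragment_threshold_sd = 0.5,
                         category_offsets = c(bleached = 1.0, partial_mortality = 1.75, dead = 2.5),
                         handling_death_prob = 2 / 66,
                         n_polyps_per_colony = 20,
                         mean_polyp_density = 50, sd_polyp_density = 10,
                         seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_colonies", "n_heat_fragments", "n_control_fragments",
              "n_tanks_heat", "n_tanks_control", "n_surveys", "n_polyps_per_colony")
  for (nm in counts) {
    if (cfg[[nm]] < 1) rlang::abort(sprintf("%s must be a positive count", nm), class = "coralheat_config_error")
  }
  for (nm in c("tolerance_growth_coupling", "tolerance_fecundity_coupling")) {
    if (abs(cfg[[nm]]) > 1) {
      rlang::abort(sprintf("%s must lie in [-1, 1]", nm), class = "coralheat_config_error")
    }
  }
  stopifnot(length(category_offsets) == 3, all(diff(c(0, category_offsets)) > 0),
            cfg$handling_death_prob >= 0, cfg$handling_death_prob <= 1)
  structure(cfg, class = "synth_config")
}

# named substreams keyed off the master seed keep each table reproducible
# independently of whether the others were generated
substream_seed <- function(seed, name) {
  offset <- c(temperature = 101L, population = 211L, health = 307L,
              replicate = 401L)[[name]]
  (as.integer(seed) %% 1000003L) * 1009L + offset
}

colony_ids <- function(n) sprintf("A%02d", seq_len(n))

#' Generate tank temperature logger series
#'
#' Heat tanks hold the ambient baseline through an acclimatisation
#' period, ramp linearly at the configured rate up to baseline + peak
#' anomaly, and hold that plateau until the end of the assay; control
#' tanks stay at ambient throughout. A diel sinusoid (afternoon peak) and
#' Gaussian logger noise are superimposed, at a 10-minute cadence.
#'
#' @param config A [synth_config()].
#' @return A temperature tibble (`tank_id`, `timestamp`, `temp_c`).
#' @export
generate_tank_temperatures <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(substream_seed(config$seed, "temperature"))
  start <- as.POSIXct("2018-08-01 00:00:00", tz = "UTC")
  total_days <- config$acclim_days + config$assay_days
  tmins <- seq(0, total_days * 24 * 60 - 10, by = 10)
  t_days <- tmins / (24 * 60)
  day_frac <- t_days - floor(t_days)
  ramp_days <- config$peak_anomaly_c / config$ramp_rate_c_per_week * 7
  anomaly <- pmin(pmax(t_days - config$acclim_days, 0) * config$ramp_rate_c_per_week / 7,
                  config$peak_anomaly_c)
  stopifnot(ramp_days <= config$assay_days)
  diel <- config$diel_amplitude_c * sin(2 * pi * (day_frac - 0.25))
  tanks <- c(sprintf("H%d", seq_len(config$n_tanks_heat)),
             sprintf("C%d", seq_len(config$n_tanks_control)))
  purrr::map_dfr(tanks, function(tk) {
    heat <- grepl("^H", tk)
    mu <- config$baseline_c + if (heat) anomaly else 0
    tibble::tibble(
      tank_id = tk,
      timestamp = start + tmins * 60,
      temp_c = mu + diel + stats::rnorm(length(tmins), 0, config$noise_sd_c)
    )
  })
}

#' Generate a synthetic colony population with coupled traits
#'
#' Draws latent colony states on an energetic continuum: a standard
#' normal tolerance score sets each colony's true critical DHW, and
#' growth and fecundity scores are correlated with it at the configured
#' couplings, so that `cor(true_growth, true_critical_dhw)` equals the
#' growth coupling in expectation. From the latent state it derives the
#' observable tables: repeat 3D-model size surveys (hemispherical
#' geometry, diameters Normal(24, 8) truncated above 5 cm), per-polyp
#' dissection records (egg counts rounded Normal, truncated at 0; egg
#' axis diameters lognormal calibrated so the mean egg volume matches the
#' configured 0.11 mm3), polyp densities, and ITS2 symbiont profiles (96%
#' of colonies single-profile, 70% carrying the modal profile).
#'
#' @param config A [synth_config()].
#' @return A list of tibbles: `latent`, `sizes`, `dissections`,
#'   `polyp_density`, `symbionts`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(substream_seed(config$seed, "population"))
  n <- config$n_colonies
  ids <- colony_ids(n)
  z_tol <- stats::rnorm(n)
  mix <- function(rho) rho * z_tol + sqrt(1 - rho^2) * stats::rnorm(n)
  z_g1 <- mix(config$tolerance_growth_coupling)
  z_g2 <- mix(config$tolerance_growth_coupling)
  z_f <- mix(config$tolerance_fecundity_coupling)
  true_critical <- pmax(config$mean_critical_dhw + config$sd_critical_dhw * z_tol, 0.5)
  growth_la <- config$mean_livesa_growth + config$sd_livesa_growth * z_g1
  growth_v <- config$mean_vol_growth + config$sd_vol_growth * z_g2

  # initial sizes: truncated-normal diameters, hemispherical geometry
  d0 <- stats::qnorm(stats::runif(n, stats::pnorm(5, config$mean_diameter_cm, config$sd_diameter_cm), 1),
                     config$mean_diameter_cm, config$sd_diameter_cm)
  r0 <- d0 / 2
  sa0 <- 2 * pi * r0^2
  live_frac0 <- stats::rbeta(n, 40, 2)  # most tissue alive at baseline
  livesa0 <- sa0 * live_frac0
  vol0 <- 2 / 3 * pi * r0^3

  survey_dates <- as.Date(c("2017-11-15", "2018-05-15", "2019-02-15"))
  n_surv <- sample(c(2, 3), n, replace = TRUE, prob = c(21, 24) / 45)
  sizes <- purrr::map_dfr(seq_len(n), function(i) {
    dates <- if (n_surv[i] == 3) survey_dates else survey_dates[c(1, 3)]
    dt <- as.numeric(dates - dates[1]) / 365.25
    la <- livesa0[i] + growth_la[i] * dt
    vo <- vol0[i] + growth_v[i] * dt
    la <- pmax(la, 1)
    vo <- pmax(vo, 1)
    sa <- pmax(sa0[i] + growth_la[i] * dt, la)
    tibble::tibble(
      colony_id = ids[i], survey_date = dates,
      diameter_cm = c(d0[i], rep(NA_real_, length(dates) - 1)),
      sa_cm2 = sa, livesa_cm2 = la, volume_cm3 = vo,
      partial_mortality = growth_la[i] < 0
    )
  })
  # a few colonies lack the tape-measured diameter entirely
  no_d <- sample(n, min(3, n))
  sizes$diameter_cm[sizes$colony_id %in% ids[no_d]] <- NA_real_

  # fecundity: colony-level mean egg count shifts along the latent axis,
  # within-colony polyp noise makes the marginal Normal(mean, sd)
  s_colony <- config$sd_eggs_per_polyp * 0.5
  s_polyp <- sqrt(config$sd_eggs_per_polyp^2 - s_colony^2)
  colony_ec <- config$mean_eggs_per_polyp + s_colony * z_f
  # egg axis diameters lognormal; meanlog solved so E[volume] = target
  sdlog <- 0.15
  meanlog <- (log(6 * config$mean_egg_volume_mm3 / pi) - 4.5 * sdlog^2) / 3
  dissections <- purrr::map_dfr(seq_len(n), function(i) {
    counts <- pmax(0, round(stats::rnorm(config$n_polyps_per_colony, colony_ec[i], s_polyp)))
    diam_cells <- vapply(counts, function(k) {
      if (k == 0) return("")
      gmd <- stats::rlnorm(k, meanlog, sdlog)
      asym <- exp(stats::rnorm(k, 0, 0.03))
      paste(sprintf("%.4gx%.4g", gmd * asym, gmd / asym), collapse = ";")
    }, character(1))
    tibble::tibble(
      colony_id = ids[i],
      fragment_id = paste0(ids[i], "-F",
                           ifelse(seq_along(counts) <= ceiling(length(counts) / 2), 1L, 2L)),
      polyp_index = seq_along(counts),
      egg_count = as.integer(counts),
      egg_diameters_mm = diam_cells
    )
  })

  pd <- pmax(stats::rnorm(n, config$mean_polyp_density, config$sd_polyp_density), 10)
  polyp_density <- tibble::tibble(colony_id = ids, polyps_per_cm2 = pd)

  symbionts <- generate_symbionts(ids)

  ev_mean <- pi / 6 * exp(3 * meanlog + 4.5 * sdlog^2)
  latent <- tibble::tibble(
    colony_id = ids,
    energy_budget = exp(0.4 * z_tol),
    true_critical_dhw = true_critical,
    true_growth_livesa = growth_la,
    true_growth_vol = growth_v,
    true_tep = colony_ec * pd * livesa0,
    true_tev = colony_ec * pd * livesa0 * ev_mean / 1000
  )
  list(latent = latent, sizes = sizes, dissections = dissections,
       polyp_density = polyp_density, symbionts = symbionts)
}

generate_symbionts <- function(ids) {
  n <- length(ids)
  modal <- "C40-C3-C115-C40h"
  minor <- c("C40-C3-C115", "C40-C3", "C3-C40-C115", "D1/D4-D4c-D1c-D1h-D2")
  n_modal <- round(0.70 * n)
  n_mixed <- max(round(0.04 * n), if (n >= 25) 1 else 0)
  single <- c(rep(modal, n_modal),
              sample(minor[1:3], n - n_modal - n_mixed, replace = TRUE))
  assign <- sample(n)  # shuffle which colony gets which community
  single_ids <- ids[assign[seq_along(single)]]
  mixed_ids <- ids[assign[seq.int(length(single) + 1, length.out = n_mixed)]]
  out <- tibble::tibble(colony_id = single_ids, its2_profile = single, relative_abundance = 1)
  if (n_mixed > 0) {
    minor_frac <- stats::runif(n_mixed, 0.25, 0.35)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(colony_id = rep(mixed_ids, 2),
                     its2_profile = c(rep(modal, n_mixed),
                                      sample(minor, n_mixed, replace = TRUE)),
                     relative_abundance = c(1 - minor_frac, minor_frac))
    )
  }
  dplyr::arrange(out, colony_id, dplyr::desc(relative_abundance))
}

#' Generate fragment health trajectories under the tank heat stress
#'
#' Each heat fragment carries a bleaching threshold — the colony's true
#' critical DHW plus fragment-level noise — and degrades through the five
#' ordinal categories as its tank's accumulated DHW crosses the threshold
#' and the fixed category offsets beyond it; states never recover within
#' the assay. Fragments are dispersed one per tank. Control fragments stay
#' healthy apart from a configurable handling-death probability, which
#' feeds the procedural-control exclusion rule downstream.
#'
#' @param population Output of [generate_population()].
#' @param stress Per-tank daily DHW from [compute_dhw()], covering all
#'   heat tanks.
#' @param config The [synth_config()] used to generate the population.
#' @return A fragment health tibble (`colony_id`, `fragment_id`,
#'   `tank_id`, `survey_time`, `category`).
#' @export
generate_health_trajectories <- function(population, stress, config) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(substream_seed(config$seed, "health"))
  heat_tanks <- sprintf("H%d", seq_len(config$n_tanks_heat))
  control_tanks <- sprintf("C%d", seq_len(config$n_tanks_control))
  missing <- setdiff(heat_tanks, unique(stress$tank_id))
  if (length(missing)) {
    rlang::abort(sprintf("no DHW series for heat tank(s): %s", paste(missing, collapse = ", ")))
  }
  latent <- population$latent
  n <- nrow(latent)
  dates <- sort(unique(stress$date))
  assay_start <- dates[1] + config$acclim_days
  if (config$n_surveys > config$assay_days) {
    rlang::abort("n_surveys cannot exceed assay_days (daily surveys at most)",
                 class = "coralheat_config_error")
  }
  survey_days <- distinct_survey_days(config$assay_days, config$n_surveys)
  survey_dates <- assay_start + survey_days
  survey_times <- as.POSIXct(paste(survey_dates, "12:00:00"), tz = "UTC")

  dhw_at <- function(tank, when) {
    s <- stress[stress$tank_id == tank, ]
    idx <- findInterval(as.numeric(when), as.numeric(s$date))
    ifelse(idx == 0, 0, s$dhw_c_weeks[pmax(idx, 1)])
  }
  offsets <- c(0, config$category_offsets)  # half_bleached, bleached, partial_mortality, dead
  # a colony's BSI reaches the 0.75 onset only once its slowest fragment is
  # half-bleached, i.e. at the max of the fragment thresholds; centre the
  # fragment distribution so that this max sits at true_critical_dhw on
  # average, keeping the latent threshold interpretable as the colony onset
  onset_shift <- config$fragment_threshold_sd *
    expected_max_std_normal(config$n_heat_fragments)

  heat <- purrr::map_dfr(seq_len(n), function(i) {
    frag_tanks <- heat_tanks[seq_len(config$n_heat_fragments) %% length(heat_tanks) + 1]
    purrr::map_dfr(seq_len(config$n_heat_fragments), function(j) {
      thr <- max(latent$true_critical_dhw[i] - onset_shift +
                   stats::rnorm(1, 0, config$fragment_threshold_sd), 0.1)
      dhw <- dhw_at(frag_tanks[j], survey_dates)
      stage <- findInterval(dhw, thr + offsets)  # 0 = healthy .. 4 = dead
      tibble::tibble(
        colony_id = latent$colony_id[i],
        fragment_id = sprintf("%s-H%d", latent$colony_id[i], j),
        tank_id = frag_tanks[j],
        survey_time = survey_times,
        category = health_levels()[stage + 1]
      )
    })
  })
  control <- purrr::map_dfr(seq_len(n), function(i) {
    frag_tanks <- control_tanks[seq_len(config$n_control_fragments) %% length(control_tanks) + 1]
    dies <- stats::runif(1) < config$handling_death_prob
    death_frag <- sample(config$n_control_fragments, 1)
    death_survey <- sample(seq(4, config$n_surveys), 1)
    purrr::map_dfr(seq_len(config$n_control_fragments), function(j) {
      cat <- rep("healthy", config$n_surveys)
      if (dies && j == death_frag) cat[seq(death_survey, config$n_surveys)] <- "dead"
      tibble::tibble(
        colony_id = latent$colony_id[i],
        fragment_id = sprintf("%s-C%d", latent$colony_id[i], j),
        tank_id = frag_tanks[j],
        survey_time = survey_times,
        category = cat
      )
    })
  })
  dplyr::arrange(dplyr::bind_rows(heat, control), colony_id, fragment_id, survey_time)
}

# E[max of k iid standard normals], by quadrature
expected_max_std_normal <- function(k) {
  stats::integrate(function(x) x * k * stats::dnorm(x) * stats::pnorm(x)^(k - 1),
                   -Inf, Inf)$value
}

# n distinct integer survey days in [0, assay_days - 1], ends included
distinct_survey_days <- function(assay_days, n_surveys) {
  days <- round(seq(0, assay_days - 1, length.out = n_surveys))
  while (any(duplicated(days))) {
    free <- setdiff(0:(assay_days - 1), days)
    days[duplicated(days)][1] <- free[1]
    days <- sort(days)
  }
  days
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining temperature, DHW, population, and health
#' generation, optionally writing the six input tables plus the
#' latent-state ground truth to a directory as CSV.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory for the CSV tables.
#' @return A list: `config`, `temperatures`, `stress`, `population`
#'   (latent + observable tables), `health`.
#' @export
generate_study <- function(config = synth_config(), dir = NULL) {
  temps <- generate_tank_temperatures(config)
  stress <- compute_dhw(temps, config$baseline_c)
  pop <- generate_population(config)
  health <- generate_health_trajectories(pop, stress, config)
  out <- list(config = config, temperatures = temps, stress = stress,
              population = pop, health = health)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_coral_table(temps, file.path(dir, "temperature.csv"))
    write_coral_table(health, file.path(dir, "health.csv"))
    write_coral_table(pop$sizes, file.path(dir, "size.csv"))
    write_coral_table(pop$dissections, file.path(dir, "dissection.csv"))
    write_coral_table(pop$symbionts, file.path(dir, "symbiont.csv"))
    write_coral_table(pop$polyp_density, file.path(dir, "polyp_density.csv"))
    write_coral_table(pop$latent, file.path(dir, "ground_truth.csv"))
  }
  out
}
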