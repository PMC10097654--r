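#' Calibrate the satellite climatological baseline to in-situ conditions
#'
#' Satellite sea-surface temperature products and in-tank/in-situ loggers
#' rarely agree exactly, so the satellite-derived maximum of monthly means
#' (MMM) is adjusted through the ordinary-least-squares relationship
#' between overlapping daily series: regressing in-situ on satellite
#' temperature gives `mmm_adj = intercept + slope * mmm`, the baseline
#' against which experimental heat stress is accumulated.
#'
#' @param daily A data frame with columns `date`, `satellite_c`, and
#'   `insitu_c` (daily means, degrees C). At least 30 complete overlapping
#'   days are required.
#' @param mmm Satellite maximum of monthly means (degrees C).
#' @return An object of class `climatology_baseline`: a list with `mmm`,
#'   `intercept`, `slope`, `mmm_adj`, and `n_days`.
#' @export
#' @examples
#' d <- data.frame(date = as.Date("2018-01-01") + 0:59,
#'                 satellite_c = 28 + sin(1:60 / 9))
#' d$insitu_c <- d$satellite_c + 0.7
#' fit_baseline_adjustment(d, mmm = 29.2)$mmm_adj  # 29.9
fit_baseline_adjustment <- function(daily, mmm) {
  stopifnot(is.data.frame(daily))
  need <- c("date", "satellite_c", "insitu_c")
  missing <- setdiff(need, names(daily))
  if (length(missing)) stop_schema(paste("baseline input missing column(s):", paste(missing, collapse = ", ")))
  ok <- stats::complete.cases(daily[c("satellite_c", "insitu_c")])
  d <- daily[ok, ]
  if (nrow(d) < 30) {
    rlang::abort(sprintf("baseline calibration needs >= 30 overlapping days, got %d", nrow(d)),
                 class = "coralheat_insufficient_data")
  }
  if (stats::sd(d$satellite_c) < 1e-12) {
    rlang::abort("satellite series has zero variance; baseline fit is degenerate",
                 class = "coralheat_degenerate_fit")
  }
  fit <- stats::lm(insitu_c ~ satellite_c, data = d)
  co <- stats::coef(fit)
  out <- list(
    mmm = mmm,
    intercept = unname(co[1]),
    slope = unname(co[2]),
    mmm_adj = unname(co[1] + co[2] * mmm),
    n_days = nrow(d)
  )
  class(out) <- "climatology_baseline"
  out
}

#' @export
print.climatology_baseline <- function(x, ...) {
  cat(sprintf("Climatological baseline: MMM %.2f C -> MMM_adj %.2f C\n", x$mmm, x$mmm_adj))
  cat(sprintf("  in-situ = %.3f + %.3f x satellite (n = %d days)\n", x$intercept, x$slope, x$n_days))
  invisible(x)
}

#' Accumulate degree heating weeks per tank
#'
#' Collapses a logger series to calendar-day means, forms the daily
#' hotspot — the anomaly above the adjusted baseline, retained only when
#' it exceeds 1 degree C (strictly, by default) — and accumulates degree
#' heating weeks as the trailing 84-day (12-week) sum of hotspots divided
#' by 7. Days before the log starts contribute zero stress.
#'
#' @param temps Temperature log tibble (`tank_id`, `timestamp`, `temp_c`).
#' @param baseline A `climatology_baseline`, or a single numeric baseline
#'   temperature in degrees C.
#' @param hotspot_rule `"gt"` retains anomalies strictly greater than
#'   1 degree C (the default); `"ge"` is the operational variant that also
#'   counts anomalies of exactly 1.
#' @param window_days Trailing accumulation window (default 84).
#' @return A tibble with one row per tank-day: `tank_id`, `date`,
#'   `daily_mean_c`, `hotspot_c`, `dhw_c_weeks`.
#' @export
compute_dhw <- function(temps, baseline, hotspot_rule = c("gt", "ge"), window_days = 84) {
  hotspot_rule <- match.arg(hotspot_rule)
  mmm_adj <- if (inherits(baseline, "climatology_baseline")) baseline$mmm_adj else as.numeric(baseline)
  stopifnot(is.finite(mmm_adj), is.data.frame(temps))
  temps |>
    dplyr::group_by(tank_id) |>
    dplyr::group_modify(~ dhw_one_tank(.x, mmm_adj, hotspot_rule, window_days)) |>
    dplyr::ungroup()
}

dhw_one_tank <- function(log, mmm_adj, hotspot_rule, window_days) {
  ts <- log$timestamp
  gaps <- diff(as.numeric(ts)) / 3600
  if (any(gaps > 24)) {
    i <- which(gaps > 24)
    rlang::abort(sprintf("logger gap > 24 h between %s and %s",
                         format(ts[i[1]]), format(ts[i[1] + 1])),
                 class = "coralheat_gap_error")
  }
  day <- as.Date(ts, tz = "UTC")
  counts <- table(day)
  keep_days <- names(counts)
  # drop partial first/last calendar days so daily means are unbiased
  if (length(counts) > 2) {
    modal <- stats::median(as.numeric(counts[2:(length(counts) - 1)]))
    if (counts[1] < modal) keep_days <- keep_days[-1]
    if (counts[length(counts)] < modal) keep_days <- keep_days[-length(keep_days)]
  }
  keep <- day %in% as.Date(keep_days)
  daily <- tapply(log$temp_c[keep], as.character(day[keep]), mean)
  dates <- as.Date(names(daily))
  anomaly <- as.numeric(daily) - mmm_adj
  hot <- if (hotspot_rule == "gt") ifelse(anomaly > 1, anomaly, 0) else ifelse(anomaly >= 1, anomaly, 0)
  csum <- cumsum(hot)
  lag <- c(rep(0, min(window_days, length(hot))), csum)[seq_along(hot)]
  dhw <- (csum - lag) / 7
  tibble::tibble(date = dates, daily_mean_c = as.numeric(daily),
                 hotspot_c = hot, dhw_c_weeks = dhw)
}

#' Build a fixed grid of DHW levels shared across tanks
#'
#' Tanks accumulate heat stress at slightly different rates, so fragment
#' health is compared at fixed DHW values rather than fixed dates. The
#' grid spans 0 to the minimum, across heat tanks, of the final
#' accumulated DHW, in `n_levels` evenly spaced values, guaranteeing that
#' every heat tank reaches every level.
#'
#' @param stress Per-tank daily DHW tibble from [compute_dhw()].
#' @param n_levels Number of grid levels (default 21).
#' @param heat_tanks Optional character vector naming the heat tanks;
#'   by default tanks whose final DHW exceeds 0 are treated as heated.
#' @return Numeric vector of strictly increasing, evenly spaced DHW levels.
#' @export
dhw_grid <- function(stress, n_levels = 21, heat_tanks = NULL) {
  finals <- stress |>
    dplyr::group_by(tank_id) |>
    dplyr::summarise(final = dplyr::last(dhw_c_weeks), .groups = "drop")
  if (is.null(heat_tanks)) heat_tanks <- finals$tank_id[finals$final > 0]
  if (length(heat_tanks) == 0) rlang::abort("no heat tanks: all final DHW are zero")
  top <- min(finals$final[finals$tank_id %in% heat_tanks])
  seq(0, top, length.out = n_levels)
}

#' Interpolate fragment health status onto the DHW grid
#'
#' For each fragment and grid level `x`, looks up the first day on which
#' the fragment's tank reached DHW `>= x` and takes the fragment's most
#' recent surveyed category at or before that day (step interpolation on
#' the DHW axis). This aligns tanks with lagged heating profiles so that
#' colonies are compared at identical accumulated stress, not identical
#' dates. Tanks that never accumulate stress (procedural controls) are
#' dropped silently; a heated tank that fails to reach the grid maximum is
#' an error, since the grid should have been built to prevent it.
#'
#' @param health Fragment health tibble (`colony_id`, `fragment_id`,
#'   `tank_id`, `survey_time`, `category`), normally after
#'   [apply_control_exclusion()].
#' @param stress Per-tank daily DHW tibble from [compute_dhw()].
#' @param grid Numeric DHW levels from [dhw_grid()].
#' @return A tibble with one row per fragment and grid level: `colony_id`,
#'   `fragment_id`, `tank_id`, `dhw_level`, `category`.
#' @export
interpolate_health_at_grid <- function(health, stress, grid) {
  stopifnot(is.numeric(grid), !is.unsorted(grid, strictly = TRUE))
  finals <- stress |>
    dplyr::group_by(tank_id) |>
    dplyr::summarise(final = max(dhw_c_weeks), .groups = "drop")
  missing_tanks <- setdiff(unique(health$tank_id), finals$tank_id)
  if (length(missing_tanks)) {
    rlang::abort(sprintf("no heat-stress series for tank(s): %s", paste(missing_tanks, collapse = ", ")))
  }
  hot <- finals$tank_id[finals$final > 0]
  short <- finals$tank_id[finals$final > 0 & finals$final < max(grid) - 1e-9]
  if (length(short)) {
    rlang::abort(sprintf("heated tank(s) never reach the grid maximum %.2f: %s",
                         max(grid), paste(short, collapse = ", ")))
  }
  health <- health[health$tank_id %in% hot, ]
  # per tank: the first time dhw reaches x, for each grid level. Each day's
  # DHW value is attained at the end of that day; within a day the series
  # is interpolated linearly, so a level crossed mid-day is reached before
  # that day's survey is scored against it.
  reach <- stress |>
    dplyr::filter(tank_id %in% hot) |>
    dplyr::group_by(tank_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$date), ]
      day_end <- as.numeric(d$date) + 1
      tibble::tibble(dhw_level = grid,
                     reach_time = first_crossing_time(d$dhw_c_weeks, day_end, grid))
    }) |>
    dplyr::ungroup()
  health |>
    dplyr::group_by(colony_id, fragment_id, tank_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$survey_time), ]
      rt <- reach$reach_time[reach$tank_id == key$tank_id]
      survey_end <- as.numeric(as.Date(d$survey_time, tz = "UTC")) + 1
      idx <- findInterval(rt + 1e-9, survey_end)
      idx[idx == 0] <- 1L  # before the first survey: fragments enter as first scored
      tibble::tibble(dhw_level = grid, category = d$category[idx])
    }) |>
    dplyr::ungroup() |>
    dplyr::select(colony_id, fragment_id, tank_id, dhw_level, category)
}

# first time the piecewise-linear series (value dhw[i] attained at time[i])
# reaches each level; levels at or below the first value are reached at the
# first timepoint
first_crossing_time <- function(dhw, time, levels) {
  vapply(levels, function(x) {
    idx <- which(dhw >= x - 1e-12)[1]
    if (is.na(idx)) return(NA_real_)
    if (idx == 1 || dhw[idx - 1] >= x - 1e-12) return(time[idx])
    time[idx - 1] + (x - dhw[idx - 1]) / (dhw[idx] - dhw[idx - 1]) *
      (time[idx] - time[idx - 1])
  }, numeric(1))
}
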