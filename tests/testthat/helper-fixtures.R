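# fixtures built in code; all randomness under explicit seeds

make_temperature_log <- function(tank_id = "H1", days = 3, cadence_min = 10,
                                 temp = 29.5, start = "2018-08-01") {
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            by = cadence_min * 60, length.out = days * 24 * 60 / cadence_min)
  tibble::tibble(tank_id = tank_id, timestamp = ts,
                 temp_c = rep_len(temp, length(ts)))
}

# a tank log whose daily means equal `daily` exactly (constant within day)
log_from_daily_means <- function(daily, tank_id = "H1", start = "2018-08-01",
                                 cadence_min = 60) {
  per_day <- 24 * 60 / cadence_min
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            by = cadence_min * 60, length.out = length(daily) * per_day)
  tibble::tibble(tank_id = tank_id, timestamp = ts,
                 temp_c = rep(daily, each = per_day))
}

# brute-force DHW oracle: trailing-window daily summation, no vectorization
dhw_oracle <- function(daily_means, mmm_adj, window = 84, rule = ">") {
  n <- length(daily_means)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (s in max(1, t - window + 1):t) {
      a <- daily_means[s] - mmm_adj
      hit <- if (rule == ">") a > 1 else a >= 1
      if (hit) acc <- acc + a
    }
    out[t] <- acc / 7
  }
  out
}

make_health <- function(colony_id, fragment_id, tank_id, days, categories,
                        start = "2018-08-08") {
  tibble::tibble(
    colony_id = colony_id, fragment_id = fragment_id, tank_id = tank_id,
    survey_time = as.POSIXct(paste(as.Date(start) + days, "12:00:00"), tz = "UTC"),
    category = categories
  )
}

small_config <- function(...) {
  synth_config(n_colonies = 12, handling_death_prob = 0, ...)
}
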