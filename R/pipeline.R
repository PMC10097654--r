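#' Read and validate a run configuration
#'
#' A run is driven by one YAML file with either an `inputs:` block naming
#' the six study tables (keys `temperature`, `health`, `size`,
#' `dissection`, `symbiont`, `polyp_density`, optionally a
#' `column_mapping:` block renaming file columns to the canonical schema
#' names) or a `synth:` block of [synth_config()] overrides; plus
#' `baseline` (either `value:` in degrees C or `mmm:` with a daily
#' calibration file), `grid: {n_levels}`, `control_tanks`, `prior`,
#' `sensitivity` toggles, `output_dir`, and `seed`.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$inputs) && is.null(cfg$synth)) {
    rlang::abort("run config needs either an 'inputs' block or a 'synth' block",
                 class = "coralheat_config_error")
  }
  if (!is.null(cfg$inputs)) {
    need <- schema_names()
    missing <- setdiff(need, names(cfg$inputs))
    missing <- setdiff(missing, "column_mapping")
    if (length(missing)) {
      rlang::abort(sprintf("inputs block missing file(s): %s", paste(missing, collapse = ", ")),
                   class = "coralheat_config_error")
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$grid <- cfg$grid %||% list(n_levels = 21)
  cfg$control_tanks <- cfg$control_tanks %||% c("C1", "C2")
  cfg$sensitivity <- cfg$sensitivity %||% list(exclude_shrinkage = FALSE,
                                               exclude_max_fecundity = FALSE)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_baseline <- function(cfg, synth_cfg = NULL) {
  b <- cfg$baseline
  if (is.null(b)) {
    if (!is.null(synth_cfg)) return(synth_cfg$baseline_c)
    rlang::abort("config has no baseline and no synth block", class = "coralheat_config_error")
  }
  if (!is.null(b$value)) return(as.numeric(b$value))
  daily <- read_baseline_daily(b$calibration_file)
  fit_baseline_adjustment(daily, mmm = as.numeric(b$mmm))
}

read_baseline_daily <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("date", "satellite_c", "insitu_c")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop_schema(paste("baseline calibration file missing:", paste(missing, collapse = ", ")))
  d$date <- as.Date(d$date)
  d
}

#' Run the full trade-off analysis end to end
#'
#' Chains every stage from raw (or synthesized) tables to the trade-off
#' posteriors: input reading/generation, per-tank DHW accumulation, the
#' fixed DHW grid and health interpolation, procedural-control exclusion,
#' colony BSI trajectories and tolerance summaries, size-corrected growth
#' and whole-colony fecundity, overall Bayesian trade-off regressions and
#' the per-level slope progression, plus the symbiont and
#' partial-mortality confounder tests. All stage tables are written as
#' CSV to the output directory along with a JSON run summary (colony
#' counts, exclusions, final DHW, mean critical DHW, per-trait
#' `p_positive`) and a plain-text log with stage timings.
#'
#' @param config A `run_config` (see [read_run_config()]), a path to one,
#'   or a list accepted by it.
#' @return Invisibly, a list with all stage outputs and the `summary`
#'   list that was serialized to JSON.
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  out_dir <- config$output_dir %||% tempfile("coralheat_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), parent = e)
    })
    logf("stage %s done in %.2f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  logf("run starting, seed %d", config$seed)

  synth_cfg <- NULL
  if (!is.null(config$synth)) {
    args <- config$synth
    args$seed <- args$seed %||% config$seed
    synth_cfg <- do.call(synth_config, args)
  }

  dat <- stage("data", {
    if (!is.null(synth_cfg)) {
      study <- generate_study(synth_cfg)
      list(temps = study$temperatures, health = study$health,
           sizes = study$population$sizes,
           dissections = study$population$dissections,
           symbionts = study$population$symbionts,
           polyp_density = study$population$polyp_density,
           latent = study$population$latent)
    } else {
      ins <- config$inputs
      list(
        temps = read_coral_table(ins$temperature, "temperature"),
        health = read_coral_table(ins$health, "health"),
        sizes = read_coral_table(ins$size, "size"),
        dissections = read_coral_table(ins$dissection, "dissection"),
        symbionts = read_coral_table(ins$symbiont, "symbiont"),
        polyp_density = read_coral_table(ins$polyp_density, "polyp_density"),
        latent = NULL
      )
    }
  })

  baseline <- stage("baseline", resolve_baseline(config, synth_cfg))
  stress <- stage("dhw", compute_dhw(dat$temps, baseline,
                                     hotspot_rule = config$hotspot_rule %||% "gt"))
  grid <- dhw_grid(stress, n_levels = config$grid$n_levels %||% 21)

  excl <- stage("exclusion", apply_control_exclusion(dat$health, config$control_tanks))
  grid_cats <- stage("interpolation", interpolate_health_at_grid(excl$records, stress, grid))
  traj <- stage("bsi", colony_trajectories(grid_cats))
  tol <- summarize_tolerance(traj)

  traits <- stage("traits", {
    growth <- annual_growth(dat$sizes)
    initial <- dat$sizes |>
      dplyr::group_by(colony_id) |>
      dplyr::arrange(survey_date, .by_group = TRUE) |>
      dplyr::summarise(diameter_cm = diameter_cm[1], sa_cm2 = sa_cm2[1],
                       livesa_cm2 = livesa_cm2[1], .groups = "drop")
    afs <- adjustment_factors(initial)
    gr <- growth_records(growth, afs)
    fec <- colony_fecundity(dat$dissections, dat$polyp_density,
                            initial[c("colony_id", "livesa_cm2")])
    list(growth = gr, fecundity = fec,
         colony_data = tol |>
           dplyr::left_join(gr, by = "colony_id") |>
           dplyr::left_join(fec, by = "colony_id"))
  })

  tradeoff <- stage("tradeoff", {
    overall <- overall_tradeoff_analysis(
      traits$colony_data,
      exclude_shrinkage = isTRUE(config$sensitivity$exclude_shrinkage),
      exclude_max_fecundity = isTRUE(config$sensitivity$exclude_max_fecundity)
    )
    progression <- dplyr::bind_rows(lapply(
      intersect(c("corrected_livesa_growth", "corrected_vol_growth", "tep", "tev"),
                names(traits$colony_data)),
      function(tr) slope_progression(traj, traits$colony_data, tr)
    ))
    list(overall = overall, progression = progression)
  })

  group_tests <- stage("group_tests", {
    sym <- symbiont_effect_test(traj |> dplyr::semi_join(tol, by = "colony_id"), dat$symbionts)
    conf <- suppressWarnings(confounder_tests(
      traits$colony_data |>
        dplyr::left_join(dplyr::distinct(dat$sizes, colony_id, partial_mortality), by = "colony_id"),
      traits = intersect(c("average_bsi", "corrected_livesa_growth", "corrected_vol_growth",
                           "tep", "tev"), names(traits$colony_data))
    ))
    pca <- tryCatch(its2_pca(dat$symbionts, tol), coralheat_degenerate_fit = function(e) NULL)
    list(symbiont = sym, confounders = conf, pca = pca)
  })

  for (pair in list(list(stress, "heat_stress.csv"), list(traj, "bsi_trajectories.csv"),
                    list(tol, "tolerance_summary.csv"), list(traits$growth, "growth_records.csv"),
                    list(traits$fecundity, "fecundity_records.csv"),
                    list(tradeoff$overall, "tradeoff_overall.csv"),
                    list(tradeoff$progression, "tradeoff_progression.csv"))) {
    if (nrow(pair[[1]]) > 0) write_coral_table(pair[[1]], file.path(out_dir, pair[[2]]))
  }
  if (nrow(group_tests$confounders %||% tibble::tibble()) > 0) {
    write_coral_table(group_tests$confounders, file.path(out_dir, "confounder_tests.csv"))
  }
  if (nrow(group_tests$symbiont$contrasts) > 0) {
    write_coral_table(group_tests$symbiont$contrasts, file.path(out_dir, "symbiont_contrasts.csv"))
  }

  p_pos <- stats::setNames(as.list(tradeoff$overall$p_positive), tradeoff$overall$trait)
  summary <- list(
    seed = config$seed,
    n_colonies_scored = length(unique(tol$colony_id)),
    n_colonies_excluded = length(excl$excluded),
    excluded_colonies = excl$excluded,
    final_dhw_c_weeks = max(stress$dhw_c_weeks),
    grid_max_c_weeks = max(grid),
    mean_average_bsi = mean(tol$average_bsi),
    mean_critical_dhw = mean(tol$critical_dhw, na.rm = TRUE),
    p_positive = p_pos
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("run complete: %d colonies scored, %d excluded", summary$n_colonies_scored,
       summary$n_colonies_excluded)
  invisible(list(stress = stress, grid = grid, trajectories = traj, tolerance = tol,
                 traits = traits, tradeoff = tradeoff, group_tests = group_tests,
                 summary = summary, output_dir = out_dir, latent = dat$latent))
}
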