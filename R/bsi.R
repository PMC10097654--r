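#' Bleaching survival index from category proportions
#'
#' The bleaching and mortality index (BMI) is the weighted mean of the
#' five ordinal fragment categories, weights 0 (healthy) through 4 (dead),
#' normalised by N - 1 = 4; the bleaching survival index is its
#' complement, BSI = 1 - BMI, so that higher values mean healthier
#' colonies. A colony with all fragments healthy scores 1, all dead scores
#' 0, and all half-bleached scores 0.75 — the onset-threshold state.
#'
#' @param proportions Either a numeric vector of length 5 (proportions of
#'   replicate fragments in categories healthy, half_bleached, bleached,
#'   partial_mortality, dead) or a matrix / data frame with five such
#'   columns, one row per colony-level observation.
#' @return Numeric BSI value(s) in `[0, 1]`.
#' @export
#' @examples
#' compute_bsi(c(1, 0, 0, 0, 0))        # 1
#' compute_bsi(c(0, 1, 0, 0, 0))        # 0.75
#' compute_bsi(c(0.25, 0, 0.75, 0, 0))  # 0.625
compute_bsi <- function(proportions) {
  p <- if (is.data.frame(proportions)) as.matrix(proportions) else proportions
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 5) stop_validation("proportions must have 5 categories")
  if (any(p < -1e-12 | p > 1 + 1e-12)) stop_validation("proportions must lie in [0, 1]")
  sums <- rowSums(p)
  if (any(abs(sums - 1) > 1e-9)) {
    stop_validation(sprintf("category proportions must sum to 1 (got %.6f)", sums[which(abs(sums - 1) > 1e-9)[1]]))
  }
  bmi <- as.numeric(p %*% (0:4)) / 4
  1 - bmi
}

#' Remove colonies that died in the procedural control tanks
#'
#' Mortality in an unheated control tank indicates a handling artefact
#' rather than heat stress, so such a colony cannot be assigned a heat
#' tolerance score: all of its records (heat and control) are removed.
#' A colony with no control fragments is retained with a warning.
#'
#' @param health Fragment health tibble (`colony_id`, `fragment_id`,
#'   `tank_id`, `survey_time`, `category`).
#' @param control_tanks Character vector of procedural-control tank ids.
#' @return A list with `records` (the filtered tibble) and `excluded`
#'   (character vector of excluded colony ids).
#' @export
apply_control_exclusion <- function(health, control_tanks) {
  is_control <- health$tank_id %in% control_tanks
  no_control <- setdiff(unique(health$colony_id), unique(health$colony_id[is_control]))
  if (length(no_control)) {
    rlang::warn(sprintf("colony(ies) without procedural-control fragments retained unchecked: %s",
                        paste(no_control, collapse = ", ")))
  }
  dead_in_control <- unique(health$colony_id[is_control & health$category == "dead"])
  list(
    records = health[!(health$colony_id %in% dead_in_control), ],
    excluded = dead_in_control
  )
}

#' Colony BSI trajectories over the DHW grid
#'
#' Converts grid-aligned fragment categories to colony-level category
#' proportions and BSI at each DHW level, using the colony's heat-tank
#' fragments. A fragment scored dead stays dead at all later levels
#' (mortality is irreversible within the assay), which is enforced here
#' regardless of raw scoring noise.
#'
#' @param grid_categories Tibble from [interpolate_health_at_grid()].
#' @return A tibble with one row per colony and grid level: `colony_id`,
#'   `dhw_level`, `n_fragments`, proportions `c1`-`c5`, and `bsi`.
#' @export
colony_trajectories <- function(grid_categories) {
  idx <- category_index(grid_categories$category)
  df <- grid_categories
  df$cat_idx <- idx
  # absorb the dead state: once index 5, always 5 at higher levels
  df <- df |>
    dplyr::arrange(colony_id, fragment_id, dhw_level) |>
    dplyr::group_by(colony_id, fragment_id) |>
    dplyr::mutate(cat_idx = ifelse(cummax(cat_idx == 5L) > 0L, 5L, cat_idx)) |>
    dplyr::ungroup()
  traj <- df |>
    dplyr::group_by(colony_id, dhw_level) |>
    dplyr::summarise(
      n_fragments = dplyr::n(),
      c1 = mean(cat_idx == 1), c2 = mean(cat_idx == 2), c3 = mean(cat_idx == 3),
      c4 = mean(cat_idx == 4), c5 = mean(cat_idx == 5),
      .groups = "drop"
    )
  traj$bsi <- compute_bsi(traj[c("c1", "c2", "c3", "c4", "c5")])
  traj
}

#' Per-colony heat tolerance summaries
#'
#' A colony's overall heat tolerance is the unweighted mean of its BSI
#' across the fixed DHW grid; the critical DHW is the first grid level at
#' which BSI falls to 0.75 or below, marking the onset of the bleaching
#' and mortality response (a tie at exactly 0.75 counts as onset), and is
#' absent for colonies that never reach it. Tolerance categories follow
#' the convention high (average BSI >= 0.8), medium (>= 0.7), low
#' (otherwise), boundaries inclusive.
#'
#' @param trajectories Tibble from [colony_trajectories()].
#' @param onset_bsi Onset threshold on BSI (default 0.75).
#' @return A tibble with one row per colony: `colony_id`, `average_bsi`,
#'   `critical_dhw` (NA if onset never occurs), `tolerance_category`.
#' @export
summarize_tolerance <- function(trajectories, onset_bsi = 0.75) {
  trajectories |>
    dplyr::group_by(colony_id) |>
    dplyr::arrange(dhw_level, .by_group = TRUE) |>
    dplyr::summarise(
      average_bsi = mean(bsi),
      critical_dhw = if (any(bsi <= onset_bsi)) dhw_level[which(bsi <= onset_bsi)[1]] else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(tolerance_category = tolerance_category(average_bsi))
}

#' Classify average BSI into broad tolerance categories
#' @param average_bsi Numeric vector of per-colony average BSI values.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
tolerance_category <- function(average_bsi) {
  cut(average_bsi, breaks = c(-Inf, 0.7, 0.8, Inf),
      labels = c("low", "medium", "high"), right = FALSE)
}
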