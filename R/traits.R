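#' Raw annual growth rates from repeat size surveys
#'
#' Annual growth in live surface area and volume is the change in size
#' between successive photogrammetry surveys divided by the interval in
#' years; colonies surveyed three times get the mean of their two interval
#' rates. Shrinkage (negative growth through partial mortality or
#' breakage) is a real outcome and is preserved. Intervals of 30 days or
#' less are rejected as too short to measure annual growth; colonies with
#' fewer than two usable surveys are omitted with a warning.
#'
#' @param sizes Colony size tibble (`colony_id`, `survey_date`,
#'   `livesa_cm2`, `volume_cm3`, ...).
#' @param min_interval_days Minimum usable interval (default 30).
#' @return A tibble per colony: `raw_livesa_growth` (cm2/yr),
#'   `raw_vol_growth` (cm3/yr), `n_intervals`.
#' @export
annual_growth <- function(sizes, min_interval_days = 30) {
  res <- sizes |>
    dplyr::arrange(colony_id, survey_date) |>
    dplyr::group_by(colony_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble::tibble(raw_livesa_growth = NA_real_,
                                             raw_vol_growth = NA_real_, n_intervals = 0L))
      dt_years <- diff(as.numeric(d$survey_date)) / 365.25
      ok <- diff(as.numeric(d$survey_date)) > min_interval_days
      if (!any(ok)) return(tibble::tibble(raw_livesa_growth = NA_real_,
                                          raw_vol_growth = NA_real_, n_intervals = 0L))
      la <- diff(d$livesa_cm2)[ok] / dt_years[ok]
      vo <- diff(d$volume_cm3)[ok] / dt_years[ok]
      tibble::tibble(raw_livesa_growth = mean(la), raw_vol_growth = mean(vo),
                     n_intervals = sum(ok))
    }) |>
    dplyr::ungroup()
  dropped <- res$colony_id[res$n_intervals == 0]
  if (length(dropped)) {
    rlang::warn(sprintf("colony(ies) without two usable size surveys omitted: %s",
                        paste(dropped, collapse = ", ")))
  }
  res[res$n_intervals > 0, ]
}

#' Predict maximum diameter from initial surface area
#'
#' For colonies lacking a tape-measured maximum diameter D, D is predicted
#' from the initial 3D-model surface area through the fitted log-log
#' relationship `log(D) = -0.738 + 0.537 * log(SA)` (natural logs by
#' default; a log10 variant is provided since the convention is not
#' universal — note the printed coefficients are only valid under one
#' base).
#'
#' @param initial_sa Initial total surface area, cm2 (> 0).
#' @param intercept,slope Regression coefficients on the log scale.
#' @param base `"ln"` (default) or `"log10"`.
#' @return Predicted diameter(s), cm.
#' @export
#' @examples
#' predict_diameter_from_sa(100)  # ~5.67 cm
predict_diameter_from_sa <- function(initial_sa, intercept = -0.738, slope = 0.537,
                                     base = c("ln", "log10")) {
  base <- match.arg(base)
  if (any(!is.finite(initial_sa) | initial_sa <= 0)) {
    stop_validation("initial surface area must be positive")
  }
  if (base == "ln") exp(intercept + slope * log(initial_sa))
  else 10^(intercept + slope * log10(initial_sa))
}

#' Size-bias adjustment factors for growth rates
#'
#' For identical linear extension, large colonies accrue more area and
#' volume per year than small ones, biasing raw growth rates. Each
#' colony's growth is therefore multiplied by a dimensionless adjustment
#' factor (AF): the ratio of the population-mean initial size to the
#' colony's initial size, taken one dimension below the growth metric.
#' Areal growth is corrected by `mean(D) / D_i`; volumetric growth by
#' `mean(A) / A_i` with the initial vertical cross-section
#' `A_i = D_i * (D_i / 2)` (height assumed D/2). Colonies lacking a
#' measured D get one predicted from initial SA via
#' [predict_diameter_from_sa()].
#'
#' @param initial A tibble with one row per colony: `colony_id`,
#'   `diameter_cm` (NA allowed), and `sa_cm2` (initial total surface
#'   area, used only to predict missing diameters).
#' @return A tibble per colony: `diameter_cm` (as used), `d_predicted`
#'   (logical), `areal_af`, `volumetric_af`.
#' @export
adjustment_factors <- function(initial) {
  stopifnot(all(c("colony_id", "diameter_cm") %in% names(initial)))
  d <- initial$diameter_cm
  pred <- is.na(d)
  if (any(pred)) {
    if (!"sa_cm2" %in% names(initial)) {
      stop_validation("colonies lack diameter_cm and no sa_cm2 column is available to predict it")
    }
    d[pred] <- predict_diameter_from_sa(initial$sa_cm2[pred])
  }
  if (any(!is.finite(d) | d <= 0)) stop_validation("diameters must be positive")
  a <- d^2 / 2
  tibble::tibble(
    colony_id = initial$colony_id,
    diameter_cm = d,
    d_predicted = pred,
    areal_af = mean(d) / d,
    volumetric_af = mean(a) / a
  )
}

#' Size-corrected growth records
#'
#' Joins raw annual growth with per-colony adjustment factors and applies
#' the correction `corrected = raw x AF`.
#'
#' @param growth Output of [annual_growth()].
#' @param afs Output of [adjustment_factors()].
#' @return A growth-record tibble with raw, AF, and corrected columns.
#' @export
growth_records <- function(growth, afs) {
  growth |>
    dplyr::inner_join(afs, by = "colony_id") |>
    dplyr::mutate(
      corrected_livesa_growth = raw_livesa_growth * areal_af,
      corrected_vol_growth = raw_vol_growth * volumetric_af
    )
}

#' Egg volume from geometric mean diameter
#'
#' Eggs are treated as spheres of the geometric mean diameter:
#' `EV = 4/3 * pi * (GMD / 2)^3`.
#'
#' @param gmd Geometric mean diameter(s), mm (>= 0).
#' @return Egg volume(s), mm3.
#' @export
#' @examples
#' egg_volume(1)      # pi/6 ~ 0.524 mm3
#' egg_volume(0.594)  # ~0.110 mm3
egg_volume <- function(gmd) {
  if (any(gmd < 0, na.rm = TRUE)) stop_validation("geometric mean diameter must be >= 0")
  4 / 3 * pi * (gmd / 2)^3
}

#' Whole-colony fecundity from polyp dissections
#'
#' Scales dissection-derived per-polyp fecundity to the whole colony:
#' mean egg count per polyp (EC) times polyp density (PD, polyps/cm2)
#' times live surface area gives total egg production
#' `TEP = EC x PD x LiveSA`; total egg volume is `TEV = EV x TEP`,
#' with the mean egg volume EV computed per egg from the geometric mean
#' of its measured perpendicular diameters and converted from mm3 to cm3
#' once, at TEV.
#'
#' @param dissections Dissection tibble (`colony_id`, `polyp_index`,
#'   `egg_count`, `egg_diameters_mm` serialized as in
#'   [parse_egg_diameters()]).
#' @param polyp_density Tibble (`colony_id`, `polyps_per_cm2`).
#' @param livesa Tibble (`colony_id`, `livesa_cm2`), the colony's live
#'   surface area.
#' @return A tibble per colony: `ec_mean` (eggs/polyp), `gmd_mean` (mm),
#'   `ev_mean` (mm3; NA when the colony had no eggs), `pd`, `livesa_cm2`,
#'   `tep` (eggs/colony), `tev` (cm3/colony).
#' @export
colony_fecundity <- function(dissections, polyp_density, livesa) {
  per_colony <- dissections |>
    dplyr::group_by(colony_id) |>
    dplyr::group_modify(function(d, key) {
      eggs <- unlist(lapply(parse_egg_diameters(d$egg_diameters_mm),
                            function(polyp) lapply(polyp, function(ax) exp(mean(log(ax))))),
                     use.names = FALSE)
      gmd <- if (length(eggs)) unlist(eggs) else numeric(0)
      tibble::tibble(
        n_polyps = nrow(d),
        ec_mean = mean(d$egg_count),
        gmd_mean = if (length(gmd)) mean(gmd) else NA_real_,
        ev_mean = if (length(gmd)) mean(egg_volume(gmd)) else NA_real_
      )
    }) |>
    dplyr::ungroup()
  per_colony |>
    dplyr::inner_join(polyp_density, by = "colony_id") |>
    dplyr::inner_join(livesa, by = "colony_id") |>
    dplyr::rename(pd = polyps_per_cm2) |>
    dplyr::mutate(
      tep = ec_mean * pd * livesa_cm2,
      tev = dplyr::if_else(tep == 0, 0, ev_mean * tep / 1000)  # mm3 -> cm3
    )
}

#' Test growth metrics for residual size dependence
#'
#' After AF correction, growth should no longer depend on initial colony
#' size; this fits the ordinary linear regression of a growth column on
#' initial diameter and reports the slope with its two-sided p-value.
#'
#' @param growth Growth-record tibble including `diameter_cm`.
#' @param metric Name of the growth column to test.
#' @return A one-row tibble: `metric`, `slope`, `se`, `p_value`, `n`.
#' @export
size_dependence_test <- function(growth, metric = "corrected_livesa_growth") {
  d <- growth[stats::complete.cases(growth[c(metric, "diameter_cm")]), ]
  if (nrow(d) < 10) {
    rlang::abort(sprintf("size-dependence test needs >= 10 colonies, got %d", nrow(d)),
                 class = "coralheat_insufficient_data")
  }
  if (stats::sd(d$diameter_cm) < 1e-12 || stats::sd(d[[metric]]) < 1e-12) {
    rlang::abort("degenerate variance in size-dependence test", class = "coralheat_degenerate_fit")
  }
  fit <- stats::lm(stats::reformulate("diameter_cm", metric), data = d)
  sm <- summary(fit)$coefficients
  tibble::tibble(metric = metric, slope = sm[2, 1], se = sm[2, 2],
                 p_value = sm[2, 4], n = nrow(d))
}
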