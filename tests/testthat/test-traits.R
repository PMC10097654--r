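make_sizes <- function(colony_id, dates, livesa, vol, d0 = 20) {
  tibble::tibble(colony_id = colony_id, survey_date = as.Date(dates),
                 diameter_cm = c(d0, rep(NA, length(dates) - 1)),
                 sa_cm2 = livesa * 1.1, livesa_cm2 = livesa, volume_cm3 = vol,
                 partial_mortality = FALSE)
}

test_that("annual growth is size change per year, averaged over intervals", {
  # exactly one year: rate equals the raw difference
  s <- make_sizes("A01", c("2017-11-15", "2018-11-15"), c(1000, 1500), c(2000, 2400))
  g <- annual_growth(s)
  expect_equal(g$raw_livesa_growth, 500 / (365 / 365.25), tolerance = 1e-6)
  # two intervals with rates 400 and 600 average to 500
  dt1 <- 365.25
  s <- tibble::tibble(
    colony_id = "A02",
    survey_date = as.Date("2017-11-15") + c(0, dt1, 2 * dt1),
    diameter_cm = NA, sa_cm2 = c(1100, 1540, 2200),
    livesa_cm2 = c(1000, 1400, 2000), volume_cm3 = c(500, 900, 1200),
    partial_mortality = FALSE
  )
  g <- annual_growth(s)
  expect_equal(g$raw_livesa_growth, 500, tolerance = 1e-3)
  expect_equal(g$n_intervals, 2L)
  # shrinkage is preserved as negative growth
  s <- make_sizes("A03", c("2017-11-15", "2018-11-15"), c(1000, 800), c(2000, 1900))
  expect_lt(annual_growth(s)$raw_livesa_growth, 0)
})

test_that("annual growth drops short intervals and single-survey colonies", {
  s <- make_sizes("A01", c("2017-11-15", "2017-11-25"), c(1000, 1010), c(2000, 2010))
  expect_warning(g <- annual_growth(s), regexp = "A01")
  expect_equal(nrow(g), 0)
  s <- make_sizes("A02", "2017-11-15", 1000, 2000)
  expect_warning(g <- annual_growth(s), regexp = "A02")
  expect_equal(nrow(g), 0)
})

test_that("adjustment factors follow the mean-over-individual size ratios", {
  init <- tibble::tibble(colony_id = c("A01", "A02", "A03"),
                         diameter_cm = c(20, 20, 20), sa_cm2 = c(600, 600, 600))
  af <- adjustment_factors(init)
  expect_equal(af$areal_af, rep(1, 3))     # every colony at the mean
  expect_equal(af$volumetric_af, rep(1, 3))
  init$diameter_cm <- c(10, 20, 30)
  af <- adjustment_factors(init)
  expect_equal(af$areal_af, 20 / c(10, 20, 30))
  # A = D^2 / 2
  expect_equal(af$volumetric_af, mean(c(10, 20, 30)^2 / 2) / (c(10, 20, 30)^2 / 2))
  # a colony at twice the mean diameter has areal AF one half
  init <- tibble::tibble(colony_id = c("A", "B", "C"), diameter_cm = c(10, 20, 30) * 0,
                         sa_cm2 = 1)
  init$diameter_cm <- c(15, 15, 30)  # mean 20; A03 = 2 x ... not needed
  af <- adjustment_factors(init)
  expect_equal(af$areal_af[3], mean(init$diameter_cm) / 30)
})

test_that("mean of areal_af weighted by relative diameter is exactly one", {
  set.seed(61)
  init <- tibble::tibble(colony_id = sprintf("A%02d", 1:30),
                         diameter_cm = runif(30, 8, 40), sa_cm2 = runif(30, 300, 3000))
  af <- adjustment_factors(init)
  expect_equal(mean(af$areal_af * af$diameter_cm / mean(af$diameter_cm)), 1)
})

test_that("missing diameters are predicted from initial surface area", {
  expect_equal(predict_diameter_from_sa(100), exp(-0.738 + 0.537 * log(100)))
  expect_equal(predict_diameter_from_sa(100), 5.67, tolerance = 1e-3)
  expect_equal(predict_diameter_from_sa(1), exp(-0.738))
  expect_error(predict_diameter_from_sa(-5), class = "coralheat_validation_error")
  init <- tibble::tibble(colony_id = c("A01", "A02"), diameter_cm = c(20, NA),
                         sa_cm2 = c(600, 100))
  af <- adjustment_factors(init)
  expect_identical(af$d_predicted, c(FALSE, TRUE))
  expect_equal(af$diameter_cm[2], predict_diameter_from_sa(100))
})

test_that("refitting the log-log diameter regression recovers its coefficients", {
  set.seed(62)
  sa <- exp(runif(60, log(50), log(5000)))
  d <- exp(-0.738 + 0.537 * log(sa) + rnorm(60, 0, 0.15))
  fit <- stats::lm(log(d) ~ log(sa))
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(coef(fit)[1] - (-0.738)), 2 * se[1])
  expect_lt(abs(coef(fit)[2] - 0.537), 2 * se[2])
})

test_that("egg volume is the sphere volume of the geometric mean diameter", {
  expect_equal(egg_volume(0), 0)
  expect_equal(egg_volume(1), pi / 6)
  expect_equal(egg_volume(0.594), 0.110, tolerance = 1e-2)
  expect_error(egg_volume(-1), class = "coralheat_validation_error")
})

test_that("whole-colony fecundity scales dissection data by density and area", {
  diss <- tibble::tibble(
    colony_id = "A01", fragment_id = "A01-F1", polyp_index = 1:2,
    egg_count = c(5L, 5L),
    egg_diameters_mm = c(paste(rep("0.594x0.594", 5), collapse = ";"),
                         paste(rep("0.594x0.594", 5), collapse = ";"))
  )
  pd <- tibble::tibble(colony_id = "A01", polyps_per_cm2 = 50)
  la <- tibble::tibble(colony_id = "A01", livesa_cm2 = 1000)
  f <- colony_fecundity(diss, pd, la)
  expect_equal(f$ec_mean, 5)
  expect_equal(f$tep, 5 * 50 * 1000)       # 250,000 eggs
  expect_equal(f$gmd_mean, 0.594)
  expect_equal(f$tev, f$ev_mean * f$tep / 1000)
  expect_equal(f$tev, 27.5, tolerance = 0.2)  # ~0.11 mm3 x 250k eggs
})

test_that("a colony with no eggs gets zero production and undefined egg volume", {
  diss <- tibble::tibble(colony_id = "A01", fragment_id = "F1", polyp_index = 1:3,
                         egg_count = 0L, egg_diameters_mm = "")
  f <- colony_fecundity(diss, tibble::tibble(colony_id = "A01", polyps_per_cm2 = 50),
                        tibble::tibble(colony_id = "A01", livesa_cm2 = 500))
  expect_equal(f$tep, 0)
  expect_true(is.na(f$ev_mean))
  expect_equal(f$tev, 0)
})

test_that("tev / tep equals the unit-converted mean egg volume for every colony", {
  cfg <- small_config(seed = 63)
  pop <- generate_population(cfg)
  initial <- pop$sizes |>
    dplyr::group_by(colony_id) |>
    dplyr::summarise(livesa_cm2 = livesa_cm2[1], .groups = "drop")
  f <- colony_fecundity(pop$dissections, pop$polyp_density, initial)
  has_eggs <- f$tep > 0
  expect_true(any(has_eggs))
  expect_equal(f$tev[has_eggs] / f$tep[has_eggs], f$ev_mean[has_eggs] / 1000,
               tolerance = 1e-12)
})

test_that("AF correction removes the size bias of hemispherical geometry", {
  # colonies with identical linear extension but diameters 10-40 cm:
  # raw areal growth rises with D; corrected growth does not
  set.seed(64)
  d0 <- seq(10, 40, length.out = 24)
  r0 <- d0 / 2
  delta <- 1.5  # cm/yr linear extension, identical across colonies
  # instantaneous areal growth of a hemisphere: d(2 pi r^2)/dt = 2 pi D delta
  raw <- 2 * pi * d0 * delta + rnorm(24, 0, 8)
  init <- tibble::tibble(colony_id = sprintf("A%02d", 1:24), diameter_cm = d0,
                         sa_cm2 = 2 * pi * r0^2)
  af <- adjustment_factors(init)
  growth <- tibble::tibble(colony_id = init$colony_id, raw_livesa_growth = raw,
                           raw_vol_growth = raw, n_intervals = 1L)
  gr <- growth_records(growth, af)
  uncorrected <- stats::lm(raw_livesa_growth ~ diameter_cm, data = gr)
  corrected <- stats::lm(corrected_livesa_growth ~ diameter_cm, data = gr)
  expect_lt(summary(uncorrected)$coefficients[2, 4], 0.05)  # raw: significant size bias
  ci <- confint(corrected)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)                       # corrected: CI covers zero
})

test_that("size-dependence test recovers null and injected slopes", {
  set.seed(65)
  d <- tibble::tibble(colony_id = sprintf("A%02d", 1:40),
                      diameter_cm = runif(40, 10, 40))
  # null: growth independent of size
  d$corrected_livesa_growth <- rnorm(40, 200, 50)
  res <- size_dependence_test(d)
  expect_gt(res$p_value, 0.001)
  expect_lt(abs(res$slope), 3 * res$se)
  # injected dependence: sign recovered
  d$corrected_livesa_growth <- 500 - 10 * d$diameter_cm + rnorm(40, 0, 20)
  res <- size_dependence_test(d)
  expect_lt(res$slope, 0)
  expect_lt(res$p_value, 0.01)
  # too few colonies
  expect_error(size_dependence_test(d[1:2, ]), class = "coralheat_insufficient_data")
})
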