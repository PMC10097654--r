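test_that("conjugate posterior quantiles match the dense-grid integration oracle", {
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  cases <- list(list(seed = 42, n = 12, sd = 0.4),
                list(seed = 99, n = 8, sd = 0.8),
                list(seed = 7, n = 20, sd = 0.2))
  for (cs in cases) {
    set.seed(cs$seed)
    x <- rnorm(cs$n, 10, 3)
    y <- 0.5 + 0.1 * x + rnorm(cs$n, 0, cs$sd)
    fit <- fit_bayes_lm(y, x)
    impl_q <- fit$beta1_location + fit$beta1_scale * qt(probs, df = fit$df)
    oracle <- grid_posterior_beta1(y, x, probs = probs)
    expect_equal(impl_q, oracle$quantiles_raw, tolerance = 1e-3)
    expect_equal(fit$p_positive, oracle$p_positive, tolerance = 1e-3)
  }
})

test_that("p_positive respects the reflection identity under trait negation", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    x <- rnorm(n); y <- rnorm(n, 0.2 * x)
    p1 <- fit_bayes_lm(y, x)$p_positive
    p2 <- fit_bayes_lm(y, -x)$p_positive
    expect_equal(p1 + p2, 1, tolerance = 1e-9)
  }
})

test_that("the diffuse posterior concentrates on the least-squares line", {
  x <- seq(1, 10)
  vanishing <- bayes_prior(beta_scale = 1e8, a0 = 1e-6, b0 = 1e-12)
  fit <- fit_bayes_lm(2 * x, x, prior = vanishing)
  expect_equal(fit$beta1_location, 2, tolerance = 1e-5)
  expect_equal(fit$beta0_location, 0, tolerance = 1e-4)
  ci <- fit$intervals_beta1
  expect_lt(max(ci$upper - ci$lower), 1e-3)  # noise-free: intervals collapse
  # with noise, medians match OLS under the diffuse prior
  set.seed(92)
  y <- 2 * x + rnorm(10, 0, 0.5)
  fit <- fit_bayes_lm(y, x)
  expect_equal(fit$beta1_location, unname(coef(lm(y ~ x))[2]), tolerance = 1e-4)
})

test_that("credible intervals are nested and ordered", {
  set.seed(93)
  x <- rnorm(15); y <- rnorm(15, 0.3 * x)
  fit <- fit_bayes_lm(y, x)
  iv <- fit$intervals_beta1[order(fit$intervals_beta1$level), ]
  expect_true(all(diff(iv$lower) <= 0))
  expect_true(all(diff(iv$upper) >= 0))
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "slope"))
  expect_lt(td$conf.low.95[2], td$conf.low.50[2])
  g <- glance(fit)
  expect_identical(g$n, 15L)
  expect_false(g$degenerate)
})

test_that("regression preconditions are enforced", {
  expect_error(fit_bayes_lm(rnorm(4), rnorm(4)), class = "coralheat_insufficient_data")
  expect_error(fit_bayes_lm(rnorm(10), rep(3, 10)), class = "coralheat_degenerate_fit")
})

test_that("a null simulation centres p_positive on one half", {
  set.seed(94)
  p <- replicate(80, {
    x <- rnorm(30); y <- rnorm(30)
    fit_bayes_lm(y, x)$p_positive
  })
  expect_lt(abs(mean(p) - 0.5), 0.06)
})

test_that("overall trade-off analysis recovers the generator's coupling direction", {
  cfg <- synth_config(n_colonies = 64, tolerance_growth_coupling = 0.5,
                      tolerance_fecundity_coupling = 0, handling_death_prob = 0,
                      seed = 95)
  study <- generate_study(cfg)
  tol <- summarize_tolerance(colony_trajectories(
    interpolate_health_at_grid(study$health, study$stress, dhw_grid(study$stress))))
  d <- tol |>
    dplyr::inner_join(study$population$latent, by = "colony_id")
  res <- overall_tradeoff_analysis(d, traits = c("true_growth_livesa", "true_growth_vol",
                                                 "true_tep"))
  growth_rows <- res[grepl("growth", res$trait), ]
  expect_true(all(growth_rows$beta1_median > 0))
  expect_true(all(growth_rows$p_positive > 0.8))
  # dropping a colony changes n by exactly one
  d2 <- d[-1, ]
  res2 <- overall_tradeoff_analysis(d2, traits = "true_growth_livesa")
  expect_equal(res2$n_colonies, res$n_colonies[1] - 1L)
})

test_that("sensitivity refits exclude shrinkage colonies and the most fecund colony", {
  set.seed(96)
  d <- tibble::tibble(colony_id = sprintf("A%02d", 1:30),
                      average_bsi = runif(30, 0.5, 1),
                      corrected_livesa_growth = rnorm(30, 100, 300),
                      tep = rlnorm(30, 12, 0.5))
  base <- overall_tradeoff_analysis(d, traits = c("corrected_livesa_growth", "tep"))
  sens <- overall_tradeoff_analysis(d, traits = c("corrected_livesa_growth", "tep"),
                                    exclude_shrinkage = TRUE, exclude_max_fecundity = TRUE)
  n_shrink <- sum(d$corrected_livesa_growth < 0)
  expect_gt(n_shrink, 0)
  expect_equal(sens$n_colonies[1], base$n_colonies[1] - n_shrink)
  expect_equal(sens$n_colonies[2], base$n_colonies[2] - 1L)
})

test_that("slope progression peaks near bleaching onset under positive coupling", {
  cfg <- synth_config(n_colonies = 64, tolerance_growth_coupling = 0.7,
                      handling_death_prob = 0, seed = 97)
  study <- generate_study(cfg)
  grid <- dhw_grid(study$stress)
  traj <- colony_trajectories(
    interpolate_health_at_grid(study$health, study$stress, grid))
  prog <- slope_progression(traj, study$population$latent, "true_growth_livesa")
  expect_equal(nrow(prog), 21)
  # pre-stress levels are degenerate (everyone healthy): slope pinned at zero
  expect_true(prog$degenerate[1])
  expect_equal(prog$beta1_median[1], 0, tolerance = 1e-9)
  expect_equal(prog$p_positive[1], 0.5, tolerance = 1e-6)
  # p_positive rises from the symmetric null to near-certainty as colonies
  # spread out around bleaching onset
  expect_gt(max(prog$p_positive), 0.9)
  expect_lt(prog$p_positive[2], max(prog$p_positive))
  # the slope itself peaks near the mean onset DHW and declines afterwards
  # as responses re-align (p_positive saturates at 1 over the peak region,
  # so the peak location is read from the slope median)
  peak_level <- prog$dhw_level[which.max(prog$beta1_median)]
  onset <- mean(summarize_tolerance(traj)$critical_dhw, na.rm = TRUE)
  expect_lt(abs(peak_level - onset), 2.5)
  expect_lt(dplyr::last(prog$beta1_median), max(prog$beta1_median))
})

test_that("negating the trait negates every level's slope posterior exactly", {
  cfg <- small_config(seed = 98)
  study <- generate_study(cfg)
  grid <- dhw_grid(study$stress, n_levels = 11)
  traj <- colony_trajectories(
    interpolate_health_at_grid(study$health, study$stress, grid))
  traits <- study$population$latent
  prog_pos <- slope_progression(traj, traits, "true_growth_livesa")
  traits$true_growth_livesa <- -traits$true_growth_livesa
  prog_neg <- slope_progression(traj, traits, "true_growth_livesa")
  expect_equal(prog_neg$beta1_median, -prog_pos$beta1_median, tolerance = 1e-9)
  expect_equal(prog_neg$ci95_lower, -prog_pos$ci95_upper, tolerance = 1e-9)
  expect_equal(prog_neg$p_positive, 1 - prog_pos$p_positive, tolerance = 1e-9)
})

test_that("single-colony symbiont groups are flagged and not tested", {
  traj <- tidyr::expand_grid(colony_id = sprintf("A%02d", 1:7),
                             dhw_level = seq(0, 8, by = 2)) |>
    dplyr::mutate(bsi = pmax(0, pmin(1, 1 - dhw_level / 10 + rnorm(dplyr::n(), 0, 0.05))),
                  n_fragments = 4L)
  profiles <- tibble::tibble(
    colony_id = sprintf("A%02d", 1:7),
    its2_profile = c(rep("C40-C3", 3), rep("C40-C115", 3), "D1-D4"),
    relative_abundance = 1
  )
  withr::local_seed(101)
  res <- suppressMessages(symbiont_effect_test(traj, profiles))
  expect_identical(res$flagged, "D1-D4")
  expect_false(any(grepl("D1-D4", res$contrasts$contrast)))
  expect_equal(nrow(res$contrasts), 1)  # one testable pair
  expect_true(all(res$contrasts$adjusted_p >= res$contrasts$raw_p - 1e-12))
})

test_that("identical symbiont groups yield no significant contrasts", {
  withr::local_seed(102)
  traj <- tidyr::expand_grid(colony_id = sprintf("A%02d", 1:12),
                             dhw_level = seq(0, 8, by = 1)) |>
    dplyr::mutate(bsi = pmax(0.01, pmin(0.99, 1 - dhw_level / 10 + rnorm(dplyr::n(), 0, 0.08))),
                  n_fragments = 4L)
  profiles <- tibble::tibble(colony_id = sprintf("A%02d", 1:12),
                             its2_profile = rep(c("C40-C3", "C40-C115", "C3"), each = 4),
                             relative_abundance = 1)
  res <- symbiont_effect_test(traj, profiles)
  expect_equal(nrow(res$contrasts), 3)
  expect_true(all(res$contrasts$adjusted_p > 0.05))
})

test_that("confounder tests pick the right branch and adjust correctly", {
  withr::local_seed(103)
  d <- tibble::tibble(
    colony_id = sprintf("A%02d", 1:45),
    partial_mortality = rep(c("none", "partial", "severe"), each = 15),
    normal_trait = rnorm(45, 10, 2),
    heavy_trait = rcauchy(45)
  )
  res <- confounder_tests(d, traits = c("normal_trait", "heavy_trait"))
  expect_identical(unique(res$branch[res$trait == "normal_trait"]), "parametric")
  expect_identical(unique(res$branch[res$trait == "heavy_trait"]), "nonparametric")
  # identical distributions: omnibus p not small
  expect_gt(res$raw_p[res$trait == "normal_trait" & res$contrast == "omnibus"], 0.01)
  # bonferroni adjustment is min(1, raw * n_comparisons)
  pw <- res[res$test_name == "pairwise_wilcoxon", ]
  expect_equal(pw$adjusted_p, pmin(1, pw$raw_p * 3))
})

test_that("ITS2 PCA separates two-profile compositions on one axis", {
  profiles <- tibble::tibble(
    colony_id = rep(sprintf("A%02d", 1:6), each = 2),
    its2_profile = rep(c("C40", "C15"), 6),
    relative_abundance = as.vector(rbind(seq(0.2, 0.9, length.out = 6),
                                         1 - seq(0.2, 0.9, length.out = 6)))
  )
  pc <- its2_pca(profiles)
  expect_gt(pc$variance_explained[1], 1 - 1e-9)  # compositional: rank one
  # colony order does not change the scores
  pc2 <- its2_pca(profiles[order(rev(seq_len(nrow(profiles)))), ])
  sc1 <- pc$scores[order(pc$scores$colony_id), ]
  sc2 <- pc2$scores[order(pc2$scores$colony_id), ]
  expect_equal(abs(sc1$PC1), abs(sc2$PC1), tolerance = 1e-9)
  # identical profiles across colonies are degenerate
  constant <- tibble::tibble(colony_id = sprintf("A%02d", 1:5),
                             its2_profile = "C40", relative_abundance = 1)
  expect_error(its2_pca(dplyr::bind_rows(constant,
                                         dplyr::mutate(constant, its2_profile = "C15",
                                                       relative_abundance = 0))),
               class = "coralheat_degenerate_fit")
})
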