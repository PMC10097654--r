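#' Dominant ITS2 profile per colony
#'
#' Assigns each colony the ITS2 type profile with the highest relative
#' abundance (most colonies host a single profile; the handful with mixed
#' communities get their majority profile).
#'
#' @param profiles Symbiont tibble (`colony_id`, `its2_profile`,
#'   `relative_abundance`).
#' @return Tibble with `colony_id`, `dominant_profile`, `n_profiles`,
#'   `dominant_abundance`.
#' @export
dominant_profiles <- function(profiles) {
  profiles |>
    dplyr::group_by(colony_id) |>
    dplyr::summarise(
      dominant_profile = its2_profile[which.max(relative_abundance)],
      dominant_abundance = max(relative_abundance),
      n_profiles = dplyr::n(),
      .groups = "drop"
    )
}

#' Test for a symbiont-community effect on the bleaching response
#'
#' Fits a binomial-family GLM of the colony BSI-DHW response (BSI as a
#' proportion, weighted by the number of replicate fragments) on DHW and
#' dominant ITS2 profile, then tests all pairwise profile contrasts with
#' a family-wise Tukey adjustment. Because colony BSI is a weighted
#' proportion rather than integer successes, the quasibinomial family is
#' used; point estimates match the binomial fit. Profiles represented by
#' a single colony are reported but flagged as having insufficient
#' statistical power, and are excluded from the contrasts.
#'
#' @param trajectories Colony BSI trajectories from
#'   [colony_trajectories()].
#' @param profiles Symbiont tibble (see [dominant_profiles()]).
#' @return A list with `contrasts` (tibble: groups, estimate, raw and
#'   Tukey-adjusted p), `flagged` (profiles with one colony), and `model`.
#'   When fewer than two testable groups remain, `contrasts` is empty.
#' @export
symbiont_effect_test <- function(trajectories, profiles) {
  dom <- dominant_profiles(profiles)
  d <- trajectories |>
    dplyr::inner_join(dom[c("colony_id", "dominant_profile")], by = "colony_id")
  counts <- d |>
    dplyr::distinct(colony_id, dominant_profile) |>
    dplyr::count(dominant_profile, name = "n_colonies")
  flagged <- counts$dominant_profile[counts$n_colonies < 2]
  testable <- counts$dominant_profile[counts$n_colonies >= 2]
  if (length(flagged)) {
    rlang::inform(sprintf("profile(s) with a single colony flagged, insufficient statistical power: %s",
                          paste(flagged, collapse = ", ")))
  }
  dt <- d[d$dominant_profile %in% testable, ]
  if (length(testable) < 2) {
    return(list(contrasts = empty_contrasts(), flagged = flagged, model = NULL))
  }
  dt$dominant_profile <- factor(dt$dominant_profile)
  fit <- stats::glm(bsi ~ dhw_level + dominant_profile, family = stats::quasibinomial(),
                    data = dt, weights = n_fragments)
  em <- emmeans::emmeans(fit, "dominant_profile")
  tuk <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  raw <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  contrasts <- tibble::tibble(
    test_name = "symbiont_its2_effect",
    contrast = tuk$contrast,
    estimate = tuk$estimate,
    statistic = tuk$t.ratio,
    raw_p = raw$p.value,
    adjusted_p = pmax(tuk$p.value, raw$p.value),
    adjustment_method = "tukey"
  )
  list(contrasts = contrasts, flagged = flagged, model = fit)
}

empty_contrasts <- function() {
  tibble::tibble(test_name = character(), contrast = character(),
                 estimate = double(), statistic = double(), raw_p = double(),
                 adjusted_p = double(), adjustment_method = character())
}

#' Test traits for confounding by partial mortality
#'
#' For each trait, compares its distribution across partial-mortality
#' classes: one-way ANOVA with Tukey HSD contrasts when the ANOVA
#' residuals pass a Shapiro-Wilk normality check, otherwise
#' Kruskal-Wallis with pairwise Bonferroni-corrected Wilcoxon tests.
#' Classes with fewer than two observations are dropped with a warning.
#'
#' @param colony_data Tibble with the trait columns and a grouping column.
#' @param traits Character vector of trait column names.
#' @param group Name of the grouping column (default
#'   `"partial_mortality"`).
#' @param shapiro_alpha Normality-test level deciding the branch
#'   (default 0.05).
#' @return Tibble with one row per trait and pairwise comparison plus an
#'   omnibus row per trait; columns `test_name`, `trait`, `contrast`,
#'   `statistic`, `raw_p`, `adjusted_p`, `adjustment_method`, `branch`.
#' @export
confounder_tests <- function(colony_data, traits, group = "partial_mortality",
                             shapiro_alpha = 0.05) {
  purrr::map_dfr(traits, function(tr) {
    d <- colony_data[stats::complete.cases(colony_data[c(tr, group)]), ]
    d$grp <- factor(d[[group]])
    sizes <- table(d$grp)
    small <- names(sizes)[sizes < 2]
    if (length(small)) {
      rlang::warn(sprintf("trait %s: dropping class(es) with n < 2: %s", tr,
                          paste(small, collapse = ", ")))
      d <- d[!(d$grp %in% small), , drop = FALSE]
      d$grp <- droplevels(d$grp)
    }
    if (nlevels(d$grp) < 2) return(NULL)
    form <- stats::reformulate("grp", tr)
    fit <- stats::aov(form, data = d)
    sw_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value, error = function(e) 0)
    if (sw_p >= shapiro_alpha) {
      om <- summary(fit)[[1]]
      tuk <- as.data.frame(stats::TukeyHSD(fit)$grp)
      dplyr::bind_rows(
        tibble::tibble(test_name = "anova", trait = tr, contrast = "omnibus",
                       statistic = om$`F value`[1], raw_p = om$`Pr(>F)`[1],
                       adjusted_p = om$`Pr(>F)`[1], adjustment_method = "none",
                       branch = "parametric"),
        tibble::tibble(test_name = "tukey_hsd", trait = tr, contrast = rownames(tuk),
                       statistic = tuk$diff, raw_p = NA_real_, adjusted_p = tuk$`p adj`,
                       adjustment_method = "tukey", branch = "parametric")
      )
    } else {
      kw <- stats::kruskal.test(form, data = d)
      prs <- utils::combn(levels(d$grp), 2, simplify = FALSE)
      pw <- purrr::map_dfr(prs, function(pp) {
        a <- d[[tr]][d$grp == pp[1]]; b <- d[[tr]][d$grp == pp[2]]
        wt <- suppressWarnings(stats::wilcox.test(a, b))
        tibble::tibble(test_name = "pairwise_wilcoxon", trait = tr,
                       contrast = paste(pp, collapse = " - "),
                       statistic = unname(wt$statistic), raw_p = wt$p.value,
                       adjusted_p = min(1, wt$p.value * length(prs)),
                       adjustment_method = "bonferroni", branch = "nonparametric")
      })
      dplyr::bind_rows(
        tibble::tibble(test_name = "kruskal_wallis", trait = tr, contrast = "omnibus",
                       statistic = unname(kw$statistic), raw_p = kw$p.value,
                       adjusted_p = kw$p.value, adjustment_method = "none",
                       branch = "nonparametric"),
        pw
      )
    }
  })
}

#' Principal component analysis of ITS2 type-profile composition
#'
#' Centred PCA of the colony x profile relative-abundance matrix, with
#' scores labelled by broad tolerance category so overlap among
#' high/medium/low-tolerance colonies can be inspected.
#'
#' @param profiles Symbiont tibble (`colony_id`, `its2_profile`,
#'   `relative_abundance`).
#' @param tolerance Tibble with `colony_id` and `tolerance_category`
#'   (e.g. from [summarize_tolerance()]); optional.
#' @return A list of class `its2_pca`: `scores` (tibble with colony_id,
#'   PCs, tolerance_category), `loadings`, `variance_explained`.
#' @export
its2_pca <- function(profiles, tolerance = NULL) {
  wide <- profiles |>
    tidyr::pivot_wider(id_cols = colony_id, names_from = its2_profile,
                       values_from = relative_abundance, values_fill = 0,
                       values_fn = sum)
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (nrow(m) < 3 || ncol(m) < 2) {
    rlang::abort("ITS2 PCA needs >= 3 colonies and >= 2 profiles", class = "coralheat_insufficient_data")
  }
  if (all(apply(m, 2, stats::sd) < 1e-12)) {
    rlang::abort("ITS2 profile matrix is constant across colonies; PCA is degenerate",
                 class = "coralheat_degenerate_fit")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  scores <- tibble::as_tibble(pc$x) |>
    dplyr::mutate(colony_id = wide$colony_id, .before = 1)
  if (!is.null(tolerance)) {
    scores <- dplyr::left_join(scores, tolerance[c("colony_id", "tolerance_category")],
                               by = "colony_id")
  }
  structure(list(
    scores = scores,
    loadings = pc$rotation,
    variance_explained = pc$sdev^2 / sum(pc$sdev^2)
  ), class = "its2_pca")
}

#' @export
print.its2_pca <- function(x, ...) {
  cat(sprintf("ITS2 profile PCA: %d colonies, %d profiles; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings),
              100 * x$variance_explained[1],
              100 * ifelse(length(x$variance_explained) > 1, x$variance_explained[2], 0)))
  invisible(x)
}
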