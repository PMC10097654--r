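#' Weakly-informative conjugate prior for the trade-off regressions
#'
#' Normal-inverse-gamma prior for the two-coefficient Gaussian linear
#' model: coefficients `beta | sigma2 ~ N(0, beta_scale * sigma2 * I)` and
#' `sigma2 ~ InvGamma(a0, b0)`. The defaults (`beta_scale = 1e6`,
#' `a0 = b0 = 0.01`) are diffuse on the standardized-predictor scale, so
#' the posterior essentially reproduces the likelihood, matching the
#' non-informative intent of the study design while keeping the posterior
#' proper at degenerate levels (e.g. a constant response before bleaching
#' onset).
#'
#' @param beta_scale Prior variance multiplier for the coefficients.
#' @param a0,b0 Inverse-gamma shape and rate for the residual variance.
#' @return A list of class `bayes_prior`.
#' @export
bayes_prior <- function(beta_scale = 1e6, a0 = 0.01, b0 = 0.01) {
  stopifnot(beta_scale > 0, a0 > 0, b0 > 0)
  structure(list(beta_scale = beta_scale, a0 = a0, b0 = b0), class = "bayes_prior")
}

#' Exact Bayesian simple linear regression
#'
#' Fits `y = beta0 + beta1 * x + e` under the conjugate
#' normal-inverse-gamma prior, for which the joint posterior is available
#' in closed form: the marginal posterior of each coefficient is a
#' location-scale Student-t, so medians, central credible intervals at any
#' level, and the probability of a positive slope `P(beta1 > 0)` are
#' computed from exact t quantiles — no sampling, no approximation. With a
#' vanishingly diffuse prior the posterior mean equals the least-squares
#' estimate.
#'
#' The predictor is standardized internally (the raw trait scales differ
#' from the response by orders of magnitude, e.g. growth in the thousands
#' of cm2/yr against BSI in tenths) and the posterior is transformed back
#' to the raw scale for reporting; `p_positive` is invariant to this
#' positive rescaling.
#'
#' @param y Response vector (colony heat tolerance or instantaneous BSI).
#' @param x Predictor vector (a colony-level trait); must have nonzero
#'   variance.
#' @param prior A [bayes_prior()].
#' @param levels Central credible-interval levels (default 0.5, 0.75,
#'   0.95).
#' @return An object of class `bayes_lm` with elements `coefficients`
#'   (posterior medians on the raw scale), `p_positive`, `df`, interval
#'   tables, `sigma_median`, `n`, and `degenerate` (TRUE when the
#'   response had zero variance).
#' @export
fit_bayes_lm <- function(y, x, prior = bayes_prior(), levels = c(0.5, 0.75, 0.95)) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 5) {
    rlang::abort(sprintf("Bayesian regression needs n >= 5, got %d", n),
                 class = "coralheat_insufficient_data")
  }
  sx <- stats::sd(x)
  if (sx < 1e-12) {
    rlang::abort("predictor has zero variance", class = "coralheat_degenerate_fit")
  }
  mx <- mean(x)
  z <- (x - mx) / sx
  X <- cbind(1, z)
  # conjugate update: V0 = beta_scale * I
  V0_inv <- diag(2) / prior$beta_scale
  Vn_inv <- V0_inv + crossprod(X)
  Vn <- solve(Vn_inv)
  mn <- Vn %*% crossprod(X, y)
  an <- prior$a0 + n / 2
  bn <- prior$b0 + 0.5 * (sum(y^2) - drop(t(mn) %*% Vn_inv %*% mn))
  bn <- max(bn, .Machine$double.xmin)
  df <- 2 * an
  # marginal t for (intercept_z, slope_z); back-transform to raw x scale:
  # beta1 = slope_z / sx ; beta0 = intercept_z - slope_z * mx / sx
  scale_mat <- (bn / an) * Vn
  b1_loc <- mn[2] / sx
  b1_scale <- sqrt(scale_mat[2, 2]) / sx
  cvec <- c(1, -mx / sx)
  b0_loc <- drop(cvec %*% mn)
  b0_scale <- sqrt(drop(t(cvec) %*% scale_mat %*% cvec))
  ci <- function(loc, scl) {
    do.call(rbind, lapply(levels, function(lv) {
      q <- stats::qt(c((1 - lv) / 2, 1 - (1 - lv) / 2), df = df)
      tibble::tibble(level = lv, lower = loc + scl * q[1], upper = loc + scl * q[2])
    }))
  }
  p_pos <- if (b1_scale > 0) stats::pt(b1_loc / b1_scale, df = df) else as.numeric(b1_loc > 0) + 0.5 * (b1_loc == 0)
  # posterior median of sigma from the inverse-gamma marginal
  sigma_median <- sqrt(bn / stats::qgamma(0.5, shape = an))
  out <- list(
    coefficients = c(beta0 = b0_loc, beta1 = b1_loc),
    beta1_location = b1_loc, beta1_scale = b1_scale, df = df,
    beta0_location = b0_loc, beta0_scale = b0_scale,
    intervals_beta1 = ci(b1_loc, b1_scale),
    intervals_beta0 = ci(b0_loc, b0_scale),
    p_positive = p_pos,
    sigma_median = sigma_median,
    n = n,
    degenerate = stats::sd(y) < 1e-12,
    prior = prior,
    an = an, bn = bn, mn = drop(mn), Vn = Vn, x_center = mx, x_scale = sx
  )
  class(out) <- "bayes_lm"
  out
}

#' Posterior probability that the slope is positive
#'
#' The probability of "no trade-off": the proportion of the slope's
#' posterior distribution exceeding zero, `P(beta1 > 0)`, from the exact
#' Student-t marginal. A value near 0.5 means the data cannot tell a
#' trade-off from a co-benefit; values near 1 indicate the traits act in
#' concert.
#'
#' @param fit A `bayes_lm` object.
#' @return Probability in `[0, 1]`.
#' @export
prob_positive_slope <- function(fit) {
  stopifnot(inherits(fit, "bayes_lm"))
  fit$p_positive
}

#' @export
print.bayes_lm <- function(x, ...) {
  ci95 <- x$intervals_beta1[x$intervals_beta1$level == max(x$intervals_beta1$level), ]
  cat(sprintf("Bayesian linear regression (n = %d, exact conjugate posterior)\n", x$n))
  cat(sprintf("  beta1 median %.4g  [%.0f%% CI %.4g, %.4g]  P(beta1 > 0) = %.3f\n",
              x$beta1_location, 100 * ci95$level, ci95$lower, ci95$upper, x$p_positive))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Bayesian regression fit
#'
#' @param x A `bayes_lm` object.
#' @param ... Unused.
#' @return One row per coefficient: posterior median, posterior scale,
#'   and credible-interval bounds at each requested level (columns
#'   `conf.low.50` etc.).
#' @method tidy bayes_lm
#' @export
tidy.bayes_lm <- function(x, ...) {
  row <- function(term, loc, scl, ints) {
    out <- tibble::tibble(term = term, estimate = loc, std.error = scl)
    for (i in seq_len(nrow(ints))) {
      lv <- round(100 * ints$level[i])
      out[[paste0("conf.low.", lv)]] <- ints$lower[i]
      out[[paste0("conf.high.", lv)]] <- ints$upper[i]
    }
    out
  }
  dplyr::bind_rows(
    row("(Intercept)", x$beta0_location, x$beta0_scale, x$intervals_beta0),
    row("slope", x$beta1_location, x$beta1_scale, x$intervals_beta1)
  )
}

#' Glance at a Bayesian regression fit
#' @param x A `bayes_lm` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `sigma_median`, `p_positive`, `df`,
#'   `degenerate`.
#' @method glance bayes_lm
#' @export
glance.bayes_lm <- function(x, ...) {
  tibble::tibble(n = x$n, sigma_median = x$sigma_median,
                 p_positive = x$p_positive, df = x$df, degenerate = x$degenerate)
}

slope_posterior_row <- function(fit, trait, level) {
  iv <- fit$intervals_beta1
  pick <- function(lv, side) iv[[side]][abs(iv$level - lv) < 1e-9]
  tibble::tibble(
    trait = trait, dhw_level = level,
    beta0_median = fit$beta0_location, beta1_median = fit$beta1_location,
    ci50_lower = pick(0.50, "lower"), ci50_upper = pick(0.50, "upper"),
    ci75_lower = pick(0.75, "lower"), ci75_upper = pick(0.75, "upper"),
    ci95_lower = pick(0.95, "lower"), ci95_upper = pick(0.95, "upper"),
    sigma_median = fit$sigma_median,
    p_positive = fit$p_positive,
    n_colonies = fit$n,
    degenerate = fit$degenerate
  )
}

#' Overall tolerance-trait trade-off regressions
#'
#' Regresses colony heat tolerance (average BSI) on each colony-level
#' trait in turn, dropping colonies missing either value pairwise, and
#' reports the exact slope posterior with `P(beta1 > 0)`. A negative slope
#' would indicate a trade-off; `p_positive` near 1 indicates tolerance and
#' the trait act in concert. Sensitivity switches re-fit excluding
#' shrinkage colonies (negative values of the trait, for growth traits) or
#' the single most fecund colony (for fecundity traits).
#'
#' @param colony_data Tibble with `colony_id`, `average_bsi`, and the
#'   trait columns.
#' @param traits Character vector of trait column names.
#' @param prior A [bayes_prior()].
#' @param exclude_shrinkage Drop colonies with negative trait values
#'   (growth traits only, i.e. traits whose name contains "growth").
#' @param exclude_max_fecundity Drop the colony with the largest trait
#'   value (fecundity traits only, names containing "tep"/"tev").
#' @return A slope-posterior tibble, one row per trait, `dhw_level =
#'   "overall"` column omitted in favour of `dhw_level = NA`.
#' @export
overall_tradeoff_analysis <- function(colony_data,
                                      traits = c("corrected_livesa_growth",
                                                 "corrected_vol_growth", "tep", "tev"),
                                      prior = bayes_prior(),
                                      exclude_shrinkage = FALSE,
                                      exclude_max_fecundity = FALSE) {
  stopifnot("average_bsi" %in% names(colony_data))
  purrr::map_dfr(traits, function(tr) {
    d <- colony_data[stats::complete.cases(colony_data[c("average_bsi", tr)]), ]
    if (exclude_shrinkage && grepl("growth", tr)) d <- d[d[[tr]] >= 0, ]
    if (exclude_max_fecundity && grepl("te[pv]", tr)) d <- d[-which.max(d[[tr]]), ]
    fit <- fit_bayes_lm(d$average_bsi, d[[tr]], prior = prior)
    slope_posterior_row(fit, tr, NA_real_)
  })
}

#' Slope progression across DHW levels
#'
#' At each level of the fixed DHW grid, fits an independent Bayesian
#' regression of the colonies' instantaneous BSI on a colony-level trait,
#' tracing how the tolerance-trait relationship develops as heat stress
#' accumulates (the machine-readable counterpart of a slope-progression
#' figure). Levels where every colony shares one BSI value (e.g. all 1.0
#' before any bleaching) are degenerate: the slope posterior centres on
#' zero and the row is flagged.
#'
#' @param trajectories Colony BSI trajectories from
#'   [colony_trajectories()].
#' @param colony_traits Tibble with `colony_id` and the trait column.
#' @param trait Name of the trait column.
#' @param prior A [bayes_prior()].
#' @return A slope-posterior tibble, one row per grid level.
#' @export
slope_progression <- function(trajectories, colony_traits, trait, prior = bayes_prior()) {
  d <- trajectories |>
    dplyr::inner_join(colony_traits[c("colony_id", trait)], by = "colony_id") |>
    dplyr::filter(is.finite(.data[[trait]]), is.finite(bsi))
  purrr::map_dfr(sort(unique(d$dhw_level)), function(x) {
    dl <- d[d$dhw_level == x, ]
    fit <- fit_bayes_lm(dl$bsi, dl[[trait]], prior = prior)
    slope_posterior_row(fit, trait, x)
  })
}
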