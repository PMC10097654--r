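# coralheat

Does heat tolerance cost corals their growth or fecundity? `coralheat`
is an R package for answering that question from marine heatwave
emulation experiments on tagged colony populations. It converts ordinal
fragment bleaching scores into colony-level tolerance phenotypes on an
accumulated-heat-stress axis, computes size-corrected whole-colony
growth and fecundity traits, and tests for trait trade-offs with exact
Bayesian regressions. It is written for coral ecophysiologists and
restoration scientists who run tank-based thermal assays alongside reef
monitoring of the same colonies.

## The method in brief

**Heat stress.** Tank logger series are reduced to daily means and
accumulated as degree heating weeks against an adjusted climatological
baseline (MMM_adj, calibrated from satellite-to-in-situ daily
regression): hotspots are anomalies strictly above 1 °C, and
DHW(t) = Σ(hotspots over the trailing 84 days) / 7, in °C-weeks.

**Tolerance.** Replicate fragments are scored into five ordinal
categories (healthy, half bleached, bleached, partial mortality, dead).
With c₁…c₅ the per-colony category proportions and N = 5,

    BMI = (0c₁ + 1c₂ + 2c₃ + 3c₄ + 4c₅) / (N − 1),   BSI = 1 − BMI

so BSI runs from 1 (all healthy) to 0 (all dead). Fragment health is
step-interpolated onto a fixed grid of 21 DHW levels shared across
tanks; a colony's heat tolerance is its average BSI over the grid, and
its critical DHW is the first level with BSI ≤ 0.75 (an average
health status of half-bleached — the onset of the bleaching and
mortality response). Colonies losing a fragment in the unheated
procedural-control tanks are excluded as handling artefacts.

**Traits.** Annual growth from repeat 3D-model surveys is corrected for
initial size with dimensionless adjustment factors AF_areal = D̄/Dᵢ and
AF_vol = Ā/Aᵢ (A = D²/2); missing diameters are predicted from
log D = −0.738 + 0.537 log SA. Whole-colony fecundity scales polyp
dissections: EV = 4/3 π (GMD/2)³, TEP = EC × PD × LiveSA,
TEV = EV × TEP.

**Inference.** Each tolerance-trait regression
y = β₀ + β₁x + ε is fitted with a conjugate normal-inverse-gamma prior,
so slope medians, 50/75/95% credible intervals, and P(β₁ > 0) — the
posterior probability of *no trade-off* — are exact Student-t
quantiles. The same machinery runs at every DHW level separately
(`slope_progression()`), tracing when in the exposure the
tolerance-trait relationship is expressed. Symbiont (ITS2 profile) and
partial-mortality confounders are tested with binomial-family GLM +
Tukey contrasts and ANOVA/Tukey or Wilcoxon/Bonferroni branches.

A synthetic-data generator (`generate_study()`) emulates a complete
study — logger series, health surveys, 3D sizes, dissections, symbiont
profiles — with configurable tolerance-trait couplings, so the entire
pipeline is testable without any field data.

## Worked example

Generate a synthetic study under the default design (66 colonies × 6
fragments, 35-day heatwave emulation ramping 0.8 °C/week to +3.5 °C),
score tolerance, and test for a growth trade-off:

```r
library(coralheat)

study <- generate_study(synth_config(seed = 11))
excl  <- apply_control_exclusion(study$health, c("C1", "C2"))
grid  <- dhw_grid(study$stress, n_levels = 21)
traj  <- colony_trajectories(
           interpolate_health_at_grid(excl$records, study$stress, grid))
tol   <- summarize_tolerance(traj)
tol
#> # A tibble: 63 × 4
#>   colony_id average_bsi critical_dhw tolerance_category
#>   <chr>           <dbl>        <dbl> <fct>
#> 1 A01             0.970         9.17 high
#> 2 A02             0.905         8.25 high
#> 3 A03             0.842         6.88 high
#> 4 A04             0.935         8.25 high
#> # ℹ 59 more rows
```

Three colonies (`A11`, `A26`, `A61`) lost a control fragment and were
excluded; the emulation accumulated a final DHW of 9.19 °C-weeks and the
population's mean critical DHW is 7.27 °C-weeks. Regressing tolerance on
the generator's ground-truth traits:

```r
d <- dplyr::inner_join(tol, study$population$latent, by = "colony_id")
fit_bayes_lm(d$average_bsi, d$true_growth_livesa)
#> Bayesian linear regression (n = 63, exact conjugate posterior)
#>   beta1 median 3.208e-05  [95% CI 3.41e-06, 6.074e-05]  P(beta1 > 0) = 0.986
```

The slope looks tiny only because growth is measured in hundreds of
cm²/yr against a BSI in tenths; what matters is its sign and
uncertainty. Here P(β₁ > 0) = 0.986: under the generator's positive
tolerance-growth coupling (default 0.4), tolerance and growth act in
concert — no trade-off — while a zero-coupling trait gives odds near
50:50 (`true_tep` in the same run: P = 0.37). `tidy()`, `glance()`,
`autoplot()` and `plot_slope_progression()` work on these results, and
`run_full_analysis()` chains every stage from a single YAML or list
config, writing stage CSVs plus a JSON run summary.

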