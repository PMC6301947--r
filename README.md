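# saltmig

Quantitative analysis of heterogeneous, saltatory ("pause and burst")
tumor-cell migration from time-lapse centroid tracks.

Invasive tumor cells — glioma cells in brain tissue being the motivating
system — migrate intermittently: long stationary probing interrupted by
short bursts of rapid movement. Population behavior is dominated by a
small, fast, high-variability subpopulation. `saltmig` is for researchers
quantifying this behavior from 2-D tracking data (e.g. manual MTrackJ
centroids from slice-culture time-lapse imaging): it computes the per-cell
kinematics, detects and quantifies the bursts, characterizes population
heterogeneity, and tests whether a treatment selectively suppresses the
fast subpopulation.

## The quantities at the core

For a track sampled every Δt (default 11 min, 61 frames ≈ 11 h), with
step lengths dᵢ (μm):

- instantaneous speed: vᵢ = dᵢ / Δt (μm/hr)
- total path L = Σ dᵢ; net path (displacement) D = ‖x_N − x₁‖
- directionality = D / L ∈ [0, 1]; mean speed v̄ = L / (N−1)Δt;
  mean effective speed = v̄ × directionality
- sd of instantaneous speed: sample SD of {vᵢ}, the per-cell bursting
  surrogate
- movement peak: maximal run of ≥ 2 consecutive steps with vᵢ > 0;
  high-speed peak: a peak with max vᵢ > 20 μm/hr; distance per movement:
  area under the speed curve within the peak (= Σ dᵢ over the peak)
- population statistics: binned least-squares log-normal fit of mean
  speeds (with R²), Spearman correlations between per-cell parameters,
  Levene's test for variance equality between conditions, population
  centroids of the displacement-vs-variability scatter

A two-state semi-Markov simulator (`simulate_population()`, `preset()`)
generates populations with a fast subpopulation, amplification-dependent
enrichment, and a drug effect restricted to fast cells, providing ground
truth for every stage.

## Worked example

```r
library(saltmig)

# a simulated EGFR-amplified control population, 152 cells
sim <- simulate_population(preset("amp_control", seed = 7))
metrics <- cell_metrics(sim$tracks)
bursts  <- burst_metrics(sim$tracks)

fit <- fit_lognormal(metrics$mean_speed)
fit
#> <lognormal_fit> mu = 0.128, sigma = 0.437, R^2 = 0.972 (20 bins, 147 cells)

spearman_cor(metrics$sd_instantaneous_speed, metrics$mean_effective_speed)
#> <correlation_result> Spearman r = 0.934, p = 7.58e-69, n = 152

fast_subpopulation(cbind(metrics, bursts[-1]))$fast_fraction
#> [1] 0.05263158
```

The log-normal R² ≈ 0.97 says the per-cell mean speeds form the
heavy-tailed, log-normal-like distribution typical of migrating tumor
populations; the Spearman r ≈ 0.93 says cells with the most variable
instantaneous speed (the bursters) are also the ones that effectively
traverse tissue; and ~5% of cells sit above the 0.95 variability
quantile — the fast subpopulation.

Comparing a drug-treated amplified population against control:

```r
drug <- simulate_population(preset("amp_drug", seed = 8))
cmp <- compare_conditions(sim$tracks, drug$tracks)
cmp
#> <condition_comparison> n = 152 control vs 129 drug
#>   metrics changed at alpha: peaks_per_hr, high_speed_peaks_per_hr, sd_instantaneous_speed, mean_distance_per_movement_um, displacement_um
#>   variance changed (Levene): displacement_um, sd_instantaneous_speed
```

High-speed movements drop by about half and both the level and the
population spread of speed variability shrink — the signature of a
treatment acting selectively on the fast bursting subpopulation (for this
seed pair every metric moves; the overall movement rate is the one that
is typically *not* significantly changed across replicates).

The `analysis/` directory runs this workflow end to end
(`01_simulate.R` → `04_drug_comparison.R`), writing tables under
`results/`.

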