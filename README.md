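# tggpp

Robustness and uncertainty analysis of the temperature-and-greenness (TG)
model of terrestrial gross primary production (GPP), for ecosystem-flux and
remote-sensing researchers who want to know *when* a minimal satellite-driven
GPP model can be improved by parameter calibration — and when it cannot.

## The model

The TG model predicts monthly GPP at a flux site from two satellite
quantities only — the enhanced vegetation index (EVI) and land surface
temperature (LST, °C):

    GPP = m · EVI_scaled · LST_scaled

    EVI_scaled = max(EVI − 0.1, 0)

    LST_scaled = max( min[ (LST − x_n)/(x_o − x_n),
                           (x_m − LST)/(x_m − x_o) ], 0 )

`x_n`, `x_o`, `x_m` are the minimum, optimum and maximum LST for
photosynthesis (defaults 0, 30, 50 °C; strict ordering `x_n < x_o < x_m`
required) and `m` is a proportionality scalar (gC m⁻² day⁻¹), profiled out
by origin-constrained least squares rather than calibrated. The 0.1 offset
is the EVI at which GPP reaches zero.

Around that forward model the package provides the full robustness
pipeline:

- **Preprocessing** — snow/ice and cold-temperature (LST < −2 °C) QA
  screening of EVI, and singular-spectrum-analysis smoothing of EVI/LST
  (window 37 months, 6 leading components).
- **Morris screening** — one-at-a-time elementary effects of
  (x_n, x_o, x_m) on model RMSE; μ\* ranks influence, σ > 2μ\* flags
  interactions.
- **Bayesian calibration** — random-walk Metropolis–Hastings over uniform
  priors (x_n ∈ [−15, 10], x_o ∈ [10, 40], x_m ∈ [40, 65] °C) with a
  Gaussian error likelihood; convergence diagnostics include a
  prior-dominance check that reports parameters the data cannot inform.
- **Evaluation** — normalized Taylor-diagram statistics (R, STD, RMSD)
  of default versus calibrated predictions.
- **Attribution** — multiple linear regression of GPP on EVI, LST,
  precipitation and radiation with Johnson relative-weight decomposition of
  R².
- **Synthetic data** — a seeded generator of multi-year monthly series for
  all 12 plant functional types (PFTs) with known ground-truth parameters,
  standing in for flux-tower + satellite inputs.

## Worked example

Simulate ten years of a tropical evergreen broadleaf forest (true optimum
LST 15 °C — half the default), calibrate, and measure what calibration
buys:

```r
library(tggpp)
preset <- pft_presets()[["EBF"]]
site   <- simulate_site(preset, n_years = 10, seed = 1)
site
#> <site_series> SYN_EBF (EBF): 120 months, 2000-01-01 to 2009-12-01; 0 masked

chain <- calibrate_tg(site, n_iter = 5e4, seed = 2)
summarize_calibration(chain)
#>   parameter    mode median   mean ci_lower ci_upper rhat drift_frac   ks_d          status
#> 1       x_n -12.864 -2.861 -2.743  -14.524    9.391    1    0.01946 0.0322 prior-dominated
#> 2       x_o  18.424 16.112 15.905   10.296   20.994    1    0.00407 0.6164       converged
#> 3       x_m  47.754 48.162 48.458   43.356   55.297    1    0.00476 0.4042       converged
#> 4 log_sigma  -0.549 -0.544 -0.542   -0.666   -0.412    1    0.00414     NA       converged
```

The optimum converges near its true value (posterior median 16.1 °C against
a truth of 15 °C), while `x_n` is *prior-dominated*: the site's LST never
approaches the cold limit, so the data carry no information about it and
the posterior is indistinguishable from its uniform prior. On the Taylor
plane, calibration pulls the model from badly mis-scaled to usable:

```r
evaluate_tg(site, tg_params())                      # defaults (0, 30, 50)
#> <taylor_stats> r = 0.081, STD = 1.468, RMSD = 1.708, bias = -0.360 (n = 120)
su <- summarize_calibration(chain)
evaluate_tg(site, tg_params(su$median[1], su$median[2], su$median[3]))
#> <taylor_stats> r = 0.302, STD = 0.420, RMSD = 0.960, bias = -0.008 (n = 120)
```

Morris screening tells the same story from the sensitivity side — the
optimum dominates, the maximum temperature is last and could be dropped
from calibration:

```r
screen_tg(site, seed = 3)
#> <morris_result> r = 20 trajectories, p = 8 levels
#>   parameter    mu_star      sigma rank interaction_flag
#> 1       x_n 0.15281938 0.15569688    2            FALSE
#> 2       x_o 0.75924091 0.21830811    1            FALSE
#> 3       x_m 0.02321042 0.03501304    3            FALSE
```

`run_experiment(experiment_config(...))` chains all stages per PFT and
writes stage CSVs (`morris.csv`, `calibration.csv`, `convergence.csv`,
`taylor.csv`, `rwa.csv`) plus the simulated cohort and its ground-truth
manifest.

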