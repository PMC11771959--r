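# aeroforage

Central-place foraging of aerial insectivores analysed against
radar-measured insect traffic.

Colony-breeding swifts are central-place foragers: every feeding trip
starts and ends at the breeding colony, so trip distance, provisioning
rate and roost timing should track the abundance of airborne insect prey.
`aeroforage` implements the complete computation chain for studies that
pair a reverse-GPS biotelemetry system (ATLAS: 8-s fixes, ~10 m accuracy,
per-fix localization error *StdLoc* and base-station count *NBS*) with a
vertical-beam radar measuring the insect **movement traffic rate**

> MoTR(hour) = Σᵢ 1000 / w(aᵢ),  w(a) = 2·a·tan(θ/2),

the number of insects crossing a 1-km transect per hour, where each echo
at altitude `a` inside the 50–700 m band (class "insect", RCS ≥ 3 mm²) is
weighted by the beam width there; daily MoTR averages the 15 hourly values
of the 05:00–20:00 local window.

The package provides:

* **Track filtering** with attrition accounting: daylight restriction,
  >30 m/s speed rule, pooled 1.5×IQR StdLoc fence, NBS ≥ 4, 500-m jump
  (teleport-spike) rule, and the ≥4-active-tags day rule.
* **Daily foraging metrics**: mean/max colony distance, daily route under
  a 10-h coverage rule, colony visits detected as ≥60-s reception gaps
  bounded by near-colony fixes (the building blocks tag reception),
  foraging and net foraging duration (`day length − foraging duration`),
  roost arrival/departure as minutes after sunset/sunrise within ±60-min
  windows, and inter-individual distance in clock-aligned 5-min bins with
  a 4-bird minimum.
* **Inference**: Gamma(log)/Gaussian GLMs with Wald t tests, Spearman
  correlations, distribution choice by AIC (fitdistrplus), and all-subsets
  model selection with `AICc = −2logL + 2k + 2k(k+1)/(n−k−1)` (k includes
  the dispersion parameter), Akaike weights, and Δ<2 model averaging
  (full or conditional).
* **A seeded synthetic world** — multi-tag foraging tracks and radar echo
  streams with known ground truth (daily MoTR gamma-distributed with
  calibrated truncation to mean 1207.7 ± 566.7 on [164.4, 2518.9]
  insects km⁻¹ hr⁻¹; trip apogees, visit rates and arrival times coupled
  to MoTR; injected gross outliers) — so every stage is verified by
  parameter recovery.

## Worked example

The `analysis/` scripts run the whole chain on a simulated 31-day,
7-tag study (the first argument is the seed):

```sh
Rscript analysis/01_simulate.R 1   # fixes.csv, echoes.csv, truth.json
Rscript analysis/02_filter.R       # filtered.csv, attrition.json
Rscript analysis/03_metrics.R      # metrics.csv, visits.csv
Rscript analysis/04_motr.R         # motr.csv, motr_hourly.csv
Rscript analysis/05_fit.R          # table1.csv, table2.csv, report.json
```

Output of a run with seed 1 (all tables under `results/run/`):

```
Simulated 31 days x 7 tags: 1152862 fixes (114211 injected outliers), 447675 echoes
True daily MoTR: mean 1293.1, range [361.8, 2307.7] insects/km/hr

   stage removed frac_of_raw pct_of_raw
1  speed  114211  0.09906736        9.9
2 stdloc  114475  0.09929636        9.9
3    nbs   37030  0.03212006        3.2
4   jump       0  0.00000000        0.0
StdLoc fence: 21.4 m
Fix-level filters removed 23.0%; day rule removed 0.0%; total 23.0%

Mean colony distance: 3428 m; max: 9113 m; route (when defined): 169.3 km
Visits: 0.82 per tag per hour; arrival -17.2 min vs sunset; roost 11.47 +/- 0.30 h
Daily MoTR over 31 days: 1289.8 +/- 563.0 insects/km/hr (range 371.9-2299.7)
```

The speed filter removes exactly the 114,211 injected outliers (9.9% of
fixes); the StdLoc fence lands at 21.4 m and takes another 9.9%. The
fitted model suite then recovers the generator's response structure —
birds fly shorter trips, visit the colony more often, cluster closer
together and arrive earlier on insect-rich days, with no effect on route
length or flight speed:

```
 prediction                                 predictor   estimate      t        p   n  method
 Prediction 1: average distance from colony  motr      -4.73e-04  -8.73  1.3e-09  31  Gamma GLM
 Prediction 2: maximum distance from colony  motr      -3.15e+00  -4.01  3.9e-04  31  Gaussian GLM
 Prediction 5: frequency of colony visits    motr       3.56e-04   4.69  6.4e-05  31  Gamma GLM
 Prediction 7: evening arrival time          motr      -1.02e-02 -16.57  2.5e-16  31  Gaussian GLM
 Prediction 10: inter-individual distance    motr      -1.27e-04  -2.65  1.3e-02  31  Gamma GLM

Visit-frequency model set (AICc ranking):
            terms df logLik  AICc delta weight
             motr  3   24.4 -42.0  0.00  0.714
 mean_dist + motr  4   24.8 -40.1  1.83  0.286
        mean_dist  3   16.5 -26.1 15.88  0.000
 (intercept only)  2    4.1  -3.7 38.26  0.000
```

The same chain runs in one call on any fix/echo tables with the documented
CSV schemas:

```r
library(aeroforage)
res <- run_all(truth_config(seed = 1), "results/run")   # simulate + analyse
fixes <- read_fixes("my_fixes.csv")                     # or real data
filt  <- run_filter_chain(fixes, filter_config(), site_config())
daily <- compute_daily_metrics(filt$fixes)$daily
motr  <- motr_series(read_echoes("my_echoes.csv"))$daily
report <- run_paper_models(merge(daily, motr, by = "date"))
```

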