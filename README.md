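# transmig

Quantitative machinery for asking whether tumor–tissue matrix interfaces
**instruct** phenotype switching in migrating breast-cancer cells or act as
**permissive** filters on pre-existing subpopulations. The package is aimed
at quantitative cell biologists and biophysicists working with 3D
single-cell tracking and limiting-dilution proliferation assays; it bundles
three pieces of machinery plus the synthetic-data generators that make them
testable end to end:

1. **3D migration analytics** — time-averaged mean squared displacement
   (MSD) of single-cell tracks, snipping analysis to pick the maximal lag,
   diffusion-coefficient estimation via ⟨Δr²⟩ = 6D·Δt, speed and
   directionality (Euclidean / accumulated distance), and splitting of
   tracks at the interface plane.
2. **Absorbing-boundary egress model** — for cells diffusing in a dense
   compartment whose interface acts as an absorbing boundary (crossers
   switch to directed migration and do not return), the survival function
   is S(x,t) = erf(x / 2√(Dt)) and the expected egress depth is
   λ(t) = ∫(1−S)dx = 2√(Dt/π). With D = 0.75 µm² min⁻¹ and t = 24 h this
   gives 37.08 µm; over a 156 µm counting box and one cell doubling the
   predicted open/dense count ratio is 0.2377 × 2 = 0.4754. A
   bridge-corrected Monte-Carlo oracle and a through-origin count
   regression with 95% CI complete the model.
3. **Limiting-dilution heterogeneity simulator** — the 96-well assay
   (24-well blocks seeded 1111 → 1000 → 100 → 10 → 1 cells by serial
   random draws, 7-day exponential growth N(t) = Σ N\_{n,0}·R\_n^t),
   coefficient-of-variation profiles per block, systematic / stochastic /
   instructive / permissive subpopulation models, optional 3% pipetting
   error, and Kruskal–Wallis / Mann–Whitney trend tests.

## Worked example

```r
library(transmig)

# Egress model: how many cells should cross within 24 h?
predicted_count_ratio(D = 0.75, horizon = 1440, box_depth_L = 156,
                      proliferation_R = 2)
#> <egress_prediction: depth = 37.08 um, fraction = 0.2377,
#>                     proliferation-corrected ratio = 0.4754>

# Synthetic interface experiments reproduce that proportionality
reps <- simulate_interface_replicates(n_replicates = 20, seed = 301)
regress_counts(reps[, c("n_dense_0h", "n_open_final")])
#> <count_regression: m = 0.4451 [0.4091, 0.4812] (n = 20)>

# Diffusion recovery from 50 simulated 72-h tracks (10-min sampling)
set.seed(1234)
tracks <- lapply(1:50, function(i)
  brownian_track(track_sim_config(D = 0.75), track_id = i))
population_diffusion(tracks, max_lag = 720)[c("mean_D", "sd_D")]
#> $mean_D
#> [1] 0.7306747
#> $sd_D
#> [1] 0.2003647

# Heterogeneity assay: CV trends under the systematic model
sweep <- simulate_cv_sweep("systematic", n_subpop = 2:25,
                           replicates = 24, seed = 2024)
compare_trends(sweep, "seed_count")
#> <trend_test (Kruskal-Wallis rank sum test) on 'seed_count':
#>   statistic = 1195.518, p = 2.49e-260>
compare_trends(sweep, "n_subpop")
#> <trend_test (Kruskal-Wallis rank sum test) on 'n_subpop':
#>   statistic = 471.002, p = 3.74e-85>
```

The regression slope 0.445 [0.41, 0.48] brackets the analytic
instructive-interface prediction of 0.475 (crossings are detected on
10-min frames, which biases it slightly low — see the vignette); the mean
recovered D of 0.73 µm² min⁻¹ matches the generating 0.75; and the CV of
the simulated plate assay falls with seeded cell number while rising with
the number of subpopulations, both far below p = 0.001.

## Analysis workflow

The `analysis/` scripts run the full study pipeline on synthetic data and
write tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate_tracks.R` | generates random-migration and directed track ensembles |
| `analysis/02_msd_diffusion.R` | snipping profile, per-track diffusion fits, population D |
| `analysis/03_egress_prediction.R` | closed-form egress prediction, Monte-Carlo check, count regression |
| `analysis/04_heterogeneity_assay.R` | systematic/stochastic CV sweeps ± pipetting error, trend tests |
| `analysis/05_interface_scenarios.R` | instructive vs permissive CV contrast |

Run them in order with `Rscript analysis/01_simulate_tracks.R` etc.; each
prints what it found.

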