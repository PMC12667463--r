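---
title: "Models and methods: migration analytics and proliferation-heterogeneity simulation at matrix interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmig)
```

# The scientific question

When invasive breast-cancer cells (the motivating system is the
MDA-MB-231 line) migrate across a sharp interface between a dense,
tumor-like collagen matrix and an open, stroma-like one, they switch
phenotype: migration becomes directed and proliferation rises. Two
competing explanations exist. An *instructive* interface triggers the
switch in every cell that crosses; a *permissive* interface merely filters
a pre-existing subpopulation that already carries the phenotype. The two
hypotheses make different quantitative predictions, and this package
implements the machinery to test them:

1. **Transmigration statistics.** If the interface is instructive (no
   selection), the number of cells found in the open compartment after
   24 h should equal the number that random migration alone delivers to
   the interface. That number follows from the cells' diffusion
   coefficient via an absorbing-boundary model.
2. **Heterogeneity statistics.** If the interface filters
   fast-proliferating clones, the transmigrated population should be more
   homogeneous — visible as a lower coefficient of variation (CV) in a
   limiting-dilution proliferation assay. If it instructs all cells
   uniformly, CV profiles should be unchanged.

# Single-cell track analytics

## MSD estimator

For a track sampled at positions $\mathbf{r}(t_i)$, the time-averaged
mean squared displacement at lag $\Delta t$ is the average of
$\lVert\mathbf{r}(t_{i+k})-\mathbf{r}(t_i)\rVert^2$ over **all**
overlapping ordered pairs with $t_{i+k}-t_i = \Delta t$
(`compute_msd()`). Overlapping pairs use the 10-min sampled data fully;
the estimator's semantics are pinned by a brute-force double-loop oracle
in the test suite. Lags are restricted to multiples of the sampling
interval; irregularly sampled tracks are handled by binning pair
separations to the nearest multiple within a tolerance (default half an
interval). For 3D free diffusion
$\langle\Delta r^2\rangle = 6D\,\Delta t$, so `fit_diffusion()` performs
an ordinary least-squares fit of MSD against lag and reports
$D = \text{slope}/6$.

The regression includes an intercept by default: a constant offset
absorbs localisation noise, and published MSD regressions for this kind
of data are not forced through the origin. Whether the original analysis
included one is not documented, so both behaviours are supported
(`intercept = FALSE` forces the origin). A fitted slope $\le 0$ is
reported as-is and flagged rather than clamped.

Degenerate cases are defined explicitly: an identically zero MSD curve
(a stationary cell) has slope 0, $D = 0$, and is treated as a perfect
fit ($r^2 = 1$), since the residuals vanish while the total variance is
zero.

## Snipping analysis

Long lags are poorly averaged (few independent pairs) and bend the MSD
curve away from linearity; short maximal lags waste data.
`snipping_profile()` scans candidate maximal lags (the analysis scripts
use a 2–24 h grid), fits every track at each candidate, and selects the
candidate with the maximal mean $r^2$, ties going to the smallest lag.
The mean slope per candidate is reported as a plateau diagnostic but is
not an automatic selection criterion — no quantitative plateau rule is
established, so the profile is left to the analyst. Note that for ideal
simulated Brownian tracks (no localisation noise, no confinement) the
mean $r^2$ decreases monotonically with the maximal lag, so the smallest
candidate wins; the 12-h optimum reported for real tracks reflects noise
structure that the generator deliberately does not model.

## Speed and directionality

`migration_metrics()` reports the accumulated 3D path length, the net
(Euclidean) displacement, speed = accumulated distance / duration, and
the directionality ratio Euclidean/accumulated, which is 1 for perfectly
straight migration and tends to 0 for random or looping motion. A track
whose accumulated path length is zero is assigned directionality 0.

# The absorbing-boundary egress model

Cells in the dense compartment migrate randomly (diffusively) and, upon
reaching the interface, switch irreversibly to directed migration away
from it — so the interface acts as an *absorbing boundary* for the dense
population. For a half-space homogeneously populated at density 1, the
survival probability of a cell starting at depth $x$ is

$$S(x,t) = \mathrm{erf}\!\left(\frac{x}{2\sqrt{Dt}}\right),$$

and integrating the absorbed fraction over the half-space gives the
*egress depth*

$$\lambda(t) = \int_0^\infty \bigl(1-S(x,t)\bigr)\,dx = 2\sqrt{Dt/\pi},$$

the equivalent slab depth emptied across the interface per unit area.
With $D = 0.75\ \mu\mathrm{m^2\,min^{-1}}$ and $t = 24$ h,
$\lambda = 37.08\ \mu$m. Counting boxes extend 156 µm perpendicular to
the interface, so the egressed fraction is $37.08/156 = 0.2377$, and with
one population doubling over the 24 h window (proliferation constant
$R = 2$ per day) the expected open-side count is
$0.2377 \times 2 = 0.4754$ of the dense-side count at 0 h — the
instructive-interface prediction against which the measured
through-origin regression slope (`regress_counts()`) is compared. Two
digits of the fraction are often quoted truncated (0.23, giving 46%);
the package reports unrounded values.

`predicted_count_ratio()` applies the proliferation correction as a
single multiplicative factor $R^{t/24\mathrm{h}}$; growth during transit
is not timed more finely, consistent with assuming "roughly one
doubling". The count regression is forced through the origin by default
because the model predicts strict proportionality; an intercept option
exists.

## Monte-Carlo oracle and discrete boundary monitoring

`monte_carlo_egress()` simulates 1D walkers started uniformly in
$[0, \text{depth}]$ with Gaussian steps of variance $2D\,dt$ and an
absorbing boundary at 0. A subtlety matters quantitatively: scoring
absorption only when a *sampled* position crosses the boundary misses
excursions between samples and understates absorption by roughly
$0.58\sqrt{2D\,dt}$ of egress depth (about 6% at $dt = 10$ min for the
default parameters). The oracle therefore applies the standard
Brownian-bridge correction — a surviving step from $a$ to $b$ is
additionally absorbed with probability $\exp(-ab/D\,dt)$ — which makes
it converge to the continuous-time closed form (`bridge = TRUE`,
the default). The uncorrected variant (`bridge = FALSE`) is retained
deliberately: it shares the sampled-position crossing convention of the
track generator and of any frame-based tracking pipeline, and it is the
correct oracle for the synthetic interface experiment below. The same
effect explains why the synthetic count-regression slope sits a few
percent below the analytic 0.475.

# The limiting-dilution heterogeneity assay

## Assay model

A population is divided into $n$ subpopulations with per-day
proliferation constants $R_n$ and initial proportions $p_n$. A plate is
simulated (`simulate_plate()`) as:

* **Source block:** each of 24 wells receives 1111 cells by a
  multinomial draw from the proportions (an effectively infinite pool).
* **Dilution chain:** the well seeded with 1000 cells draws them without
  replacement (multivariate hypergeometric) from the *seeded composition*
  of its corresponding 1111-cell well; the 100-cell well draws from the
  1000-cell well, and so on down to 1 cell. Draws are non-depleting:
  each block's well grows from its own seeded composition.
* **Growth:** deterministic exponential,
  $N(t) = \sum_n N_{n,0} R_n^{t}$ with $t$ in days (`grow()`), 7 days by
  default; cell numbers are real-valued, matching a calculated (not
  branching-process) growth model. The end-point readout is taken as
  proportional to cell number, so CV is computed on the simulated counts
  directly.
* **CV profile:** per analyzed block (1000/100/10 by default; the 1-cell
  block is excluded because most wells are empty after incubation),
  CV = sample sd / mean of the final totals across the 24 wells
  (`cv_profile()`).

Optional pipetting error (`pipette_cv`, e.g. 0.03) perturbs every
transferred count multiplicatively by $\mathcal N(0, \text{cv})$ noise
before rounding, floored at 0 and capped (with a warning) at the parent
well's content.

## Subpopulation models

* **Systematic:** $R_i = \bar R + 0.05\,(i - (n+1)/2)$, equal
  proportions — evenly spaced constants around mean 2 whose range grows
  with $n$ (`systematic_constants()`).
* **Stochastic:** $R_n \sim \mathcal N(2, \sigma)$, truncated well above
  zero. The law's $\sigma$ is not documented for the original
  simulations; the package default is $\sigma = 0.1$, chosen once as a
  biologically plausible ~5% relative spread in daily growth factors, and
  every result that depends on it says so. In `simulate_cv_sweep()` each
  subpopulation count's constants are sampled **once** and shared by all
  replicate plates — the sampled population is part of the scenario, as
  in the original single-sampling design. Re-drawing constants for every
  replicate (`resample_per_replicate = TRUE`) adds realized-sample
  variance to the between-replicate noise and markedly weakens the
  subpopulation-count trend; both modes are available.
* **Instructive scenario:** the transmigrated set is the
  non-transmigrated set with every constant shifted by +0.2
  (`instructive_transform()`) — mean 2.0 → 2.2 with the spread exactly
  preserved.
* **Permissive scenario:** the transmigrated set is sampled from the
  normal law conditioned on $R \ge 2.15$ (`permissive_transform()`,
  rejection sampling with an acceptance-probability guard), a strictly
  less heterogeneous population.

## Statistics

`compare_trends()` applies a Kruskal–Wallis test across more than two
groups of CV values and a Mann–Whitney (Wilcoxon rank-sum) test for two
groups, without multiplicity correction, at the conventional 0.05
threshold. The headline contrasts are:

* CV vs seeded cell number and CV vs subpopulation count (systematic and
  stochastic sweeps, 24 replicate plates × subpopulation counts 2–25):
  both trends are significant far below $p = 0.001$ and survive 3%
  pipetting error.
* Instructive vs permissive: the instructive shift leaves the pooled CV
  profiles statistically indistinguishable, while permissive selection
  lowers CV at every analyzed block (one-sided tests). The instructive
  comparison is made on pooled profiles rather than per block: a uniform
  additive shift does lower the *relative* spread of growth factors by
  the ratio of the means (≈9% here), a real but small effect that
  per-block tests at 24 replicates can sometimes resolve; the profile
  comparison matches how the scenarios are read off CV-vs-cell-number
  curves.

# Synthetic data generator

The generator provides the study conditions end-to-end without any
external data:

* `brownian_track()`: per-axis Gaussian steps of variance $2D\,dt$
  ($D = 0.75\ \mu\mathrm{m^2\,min^{-1}}$, $dt = 10$ min, 72 h by
  default).
* `directed_track()`: constant step length $v\,dt$
  ($v = 0.3\ \mu\mathrm{m\,min^{-1}}$) with the heading tilted per step
  by a $\mathcal N(0, 0.3\ \mathrm{rad})$ angle about a random
  perpendicular axis. The angular-noise magnitude is a package choice
  (no generative model for post-crossing directionality is documented);
  0.3 rad keeps directionality in the 0.9–1 range over 72 h.
* `interface_experiment()`: cells seeded uniformly in a 400-µm dense
  slab diffuse until their first sampled position at or beyond the
  interface, then switch irreversibly to directed motion away from it
  (the instructive rule); the population doubles synchronously every
  24 h (duplication in place). `n_dense_0h` counts cells initially in
  the 156-µm dense box; `n_open_final` counts all transmigrated cells at
  the horizon. Two bookkeeping choices keep the counts commensurate with
  the closed-form model: transmigrated cells are tallied regardless of
  how deep they have run into the open compartment (directed motion at
  0.3 µm min⁻¹ would carry early crossers past a literal 156-µm box,
  which the egress model implicitly counts as "found open-side"), and
  lateral box faces are not applied (the generator seeds only inside the
  lateral extent, so edge flux would be unbalanced; in a statistically
  homogeneous lateral environment it cancels). Strict half-open 3D box
  counts remain available via `count_in_box()`.

What the generator does **not** model — and what passing tests therefore
do not show about real data: localisation noise, collagen-fiber
microstructure and steric hindrance, cell–cell interactions, stochastic
division timing, back-crossing of transmigrated cells, and the
luminescence transform of the plate readout. The generator validates the
analytics under their own assumptions; it is not a surrogate for the
biology.

# Numerical choices and problem sizes

* Error function via `2*pnorm(z*sqrt(2)) - 1`; quadrature oracles in the
  tests use `integrate()` at `rel.tol = 1e-9`.
* The Monte-Carlo oracle uses $10^5$ walkers (Monte-Carlo relative error
  ≈ 1%, well inside the 2% agreement it is asked to demonstrate).
* Dilution draws use the sequential-conditional hypergeometric method
  (`rhyper()` per subpopulation), exact and $O(n)$ per transfer.
* Sweeps use subpopulation counts 2–25 with 24 replicate plates
  (1728 CV values per trend test, a few seconds per sweep); diffusion
  recovery uses 50 tracks of 72 h at 10-min sampling with a 12-h maximal
  lag. These sizes reproduce the reported significances with comfortable
  margins while keeping the whole analysis re-runnable in minutes.
* All stochastic entry points accept explicit seeds and are bit-for-bit
  reproducible given one; sub-seeds for independent stages are drawn
  from the seeded stream.

# Known limitations

* The egress model is 1D and semi-infinite: lateral motion, finite slab
  depth corrections, and back-crossing are ignored (by design, matching
  the model being reproduced).
* Growth is deterministic; at the 10-cell and especially the excluded
  1-cell block, division-time stochasticity in real wells adds variance
  the simulation does not carry.
* The snipping selector automates only the max-$r^2$ rule; the slope
  plateau is a reported diagnostic.
* CV values from replicate plates are treated as independent
  observations in the trend tests, mirroring the original analysis
  design ("N = 24").
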