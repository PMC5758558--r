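# yeastlab

Two-level analysis and simulation of *Saccharomyces cerevisiae* batch
cultures: population growth kinetics on one side, single-cell morphometry
on the other, and a stochastic individual-based simulator whose output is
directly comparable to both.

The package is aimed at microbiologists and modellers who study how
oxygen availability (aerobic vs microaerophilic growth) shapes a yeast
culture — its growth rate and carrying capacity at the population level,
and the sizes and shapes of budded and unbudded cells at the individual
level — and who want measured and simulated observations on the same
schema so that one can calibrate the other.

## What it implements

**Population level.** The three-phase piecewise linear (Buchanan) primary
growth model on the log10 scale,

    P(t) = P0                              for t <= t_lag
    P(t) = P0 + mu (t - t_lag) / ln 10     for t_lag < t <= t_max
    P(t) = Pmax                            for t >  t_max

with `t_max = t_lag + (Pmax - P0) ln 10 / mu` derived by continuity.
`fit_buchanan()` estimates the parameters by profiling the breakpoints
over a grid with exact conditional least squares and a local polish;
`assign_phase()` labels any sampling time lag/log/stationary.

**Individual level.** A microscopy image pipeline (`segment_image()`,
`measure_objects()`, `classify_budding()`, `cell_records()`): background
flattening, automatic thresholding (IsoData-style "default", Intermodes,
Yen), watershed separation, chain-code perimeters with bias correction,
second-moment ellipse diameters, circularity `4*pi*A/P^2` and elongation
`D_MAX/D_MIN`, and a bud-vs-separate-cell rule based on lobe area ratio.
A ground-truthed synthetic scene generator (`generate_scene()`) stands in
for micrographs.

**Statistics.** Chi-square independence, Bonett-gated two-sample t tests
(Welch with floored df when variances differ), Welch ANOVA with
Games-Howell letters, quadratic discriminant allocation, and group
summaries (`summarize_groups()`).

**Simulator.** An individual-based model of a yeast batch culture on a
closed lattice: size-scaled uptake, respiration-first metabolism with
fermentation overflow, a two-phase budding cycle with stochastic mass
thresholds, replicative and chronological lifespan, per-cell lag times,
and an oxygen policy that is the *only* difference between the aerobic
and microaerophilic scenarios.  Carbon is conserved to machine precision,
and snapshots project each cell as tangent mother/bud circles onto the
same cell-record schema the image pipeline produces.

## Worked example

Fit-free use of the published kinetic estimates, phase labelling, and the
oxygen comparison:

```r
library(yeastlab)

kin <- load_fixture("kinetic_parameters")
aer <- kin[kin$condition == "aerobic", ]
fit <- buchanan_params(P0 = aer$log10_N0[1], Pmax = aer$log10_Nmax[1],
                       t_lag = aer$t_lag[1], mu = aer$mu[1])
fit
#> Buchanan three-phase fit
#>   P0    = 4.6200 log10 cfu/mL
#>   Pmax  = 8.9700 log10 cfu/mL
#>   t_lag = 6.3100 h
#>   mu    = 0.8000 h^-1 (ln scale)
#>   t_max = 18.8303 h (derived)

assign_phase(fit, c(4.5, 12, 21))
#> [1] lag        log        stationary

r <- compare_two_means(kin$mu[kin$condition == "aerobic"],
                       kin$mu[kin$condition == "microaerophilic"])
sprintf("test: %s  t = %.3f  df = %d  p = %.3f", r$test, r$t, r$df, r$p_value)
#> "test: welch  t = 4.938  df = 3  p = 0.016"
```

The culture leaves the lag phase at 6.31 h, reaches stationary at
18.83 h, and the aerobic maximum growth rate is significantly higher than
the microaerophilic one (p = 0.016, Welch t with floored df after
Bonett's variance test rejects equal variances).

Measuring a synthetic micrograph — a budded doublet (mother radius 30 px,
bud 15 px) and a lone circular cell:

```r
sc <- generate_scene(scene_spec(list(
  scene_object(150, 150, 30, 30, bud_r = 15),
  scene_object(350, 350, 35, 35)), 512, 512, noise_sd = 0.01, seed = 3))
cell_records(sc$image, condition = "aerobic", time_h = 12)[,
  c("id", "area_um2", "dmax_um", "circularity", "elongation", "budded")]
#>   id area_um2 dmax_um circularity elongation budded
#> 1  1    33.69   8.733      0.7159      1.623   TRUE
#> 2  2    36.63   6.830      1.0000      1.000  FALSE
```

The doublet is recognised as one budded cell (elongation 1.62, the
bud-bearing shape), the lone cell as an unbudded circle; the measured
areas sit within a fraction of a percent of the analytic ground truth in
`sc$truth`.

Simulating both oxygen conditions end to end:

```r
rep <- end_to_end(list(seed = 1, duration_h = 24,
                       conditions = list(aerobic = list(),
                                         microaerophilic = list())))
rep
#> end-to-end report: aerobic, microaerophilic
#>   aerobic: mu = 0.547, t_lag = 4.55 h, t_max = 13.45 h
#>   microaerophilic: mu = 0.239, t_lag = 3.04 h, t_max = 18.38 h
#>   faster growth: aerobic
```

A command-line front end over the same functions ships in
`inst/cli/yeastlab.R` (`synth-scene`, `segment`, `fit-growth`, `stats`,
`simulate`, `compare`, `run-all`).

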