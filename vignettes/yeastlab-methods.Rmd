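---
title: "Methods: two-level analysis and simulation of yeast batch cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level analysis and simulation of yeast batch cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastlab)
```

`yeastlab` studies *Saccharomyces cerevisiae* batch cultures at two levels
of observation that constrain each other: the population level (a growth
curve and its kinetic parameters) and the individual level (the sizes and
shapes of the cells that make up that population).  This vignette explains
the models behind each module, the tunable parameters that matter, the
design decisions taken where the methodology was genuinely open, and what
the synthetic-data generators do and do not emulate.

## The population model

Batch growth on the log10 scale is described by the three-phase piecewise
linear (Buchanan) primary model

$$
P(t) \;=\;
\begin{cases}
P_0 & t \le t_{lag}\\
P_0 + \mu\,(t - t_{lag})/\ln 10 & t_{lag} < t \le t_{max}\\
P_{max} & t > t_{max}
\end{cases}
$$

with $P_0$ and $P_{max}$ in log10 cfu/mL, $t_{lag}$ the lag duration (h)
and $\mu$ the maximum specific growth rate on the natural-log scale
(h$^{-1}$), the parameterization used by the standard
predictive-microbiology fitters.  Continuity pins the log-to-stationary
transition at $t_{max} = t_{lag} + (P_{max}-P_0)\ln 10/\mu$, which is how
`transition_time()` derives it; it is not a free parameter.

**Fitting.**  The objective is piecewise linear in $t$, so it is flat or
kinked in the breakpoints and defeats naive gradient starts.
`fit_buchanan()` therefore profiles the two breakpoints on a grid built
from the observed sampling times and their midpoints, solves the
conditionally *linear* subproblem $(P_0, \mu)$ exactly at each grid point
by least squares, and polishes the winning pair with a Nelder-Mead search
clamped to the observation window.  Curves with fewer than 6 points, or
with no identifiable growth phase (fitted $\mu \le 0$: flat or decreasing
data), are refused with an error rather than silently defaulted.  Raw
counts can be supplied with `scale = "linear"` and are log10-transformed
internally.

**Phase labels.**  `assign_phase()` maps a sampling time to lag, log or
stationary.  A time exactly at a breakpoint is assigned to the *earlier*
phase; the convention is arbitrary, documented here, and pinned by a test.

**Recovery study.**  `synth_growth_curve()` adds iid Gaussian noise on the
log10 scale to exact model values.  The default recovery experiment (100
curves, 20 points over 0–30 h, noise sd 0.05 log units — the magnitude of
plate-count scatter) recovers each parameter with a median relative error
well under 5%.  What this does *not* emulate: autocorrelated residuals,
heteroscedastic counting error at low densities, or model misspecification
(real curves are not exactly piecewise linear); recovery on real data is
accordingly somewhat worse than on these synthetic curves.

## Morphometry

The image pipeline mirrors the usual bright-cells-on-dark-background
protocol: subtract a heavily blurred copy (background flattening),
rescale to 8-bit, stretch contrast with a small saturated-pixel fraction,
auto-threshold, close, fill holes, separate touching objects with a
distance-map watershed, and drop small or border-touching objects.
Defaults: `blur_sigma = 20` px (large relative to a cell of ~60 px
diameter at the 0.0975 um/px calibration, small relative to a 512 px
field), `saturated_fraction = 0.0035`, `closing_radius = 2` px,
`min_object_area = 100` px².  Border-touching objects are excluded, the
standard practice when per-object measurements must be unbiased.

**Thresholds.**  "Default" is implemented as the IsoData-style iterative
intermeans algorithm, the conventional meaning of that method name;
Intermodes (smooth the histogram until bimodal, take the midpoint of the
two modes) and Yen (maximum correlation criterion) follow their published
algorithms, all computed on a 256-bin histogram.  One numerical subtlety:
with a sparse foreground the intermeans iteration has a degenerate fixed
point *inside* the background cluster, so the iteration is started midway
across the occupied intensity range rather than at the global mean.

**Measurements.**  Area is the calibrated pixel count.  The perimeter
estimator is the chain-code boundary length with the Vossepoel–Smeulders
bias correction (0.980 per axial step, 1.406 per diagonal step, −0.091
per corner); on digitized disks of the sizes measured here it is accurate
to well under 1%, which keeps the circularity $C = 4\pi A/P^2$ of a
rasterized circle at 1 after clipping numeric overshoot.  Major and minor
diameters come from the second-moment best-fit ellipse (with the 1/12
pixel-footprint term), matching the ellipse-fit definition of the aspect
ratio $AR = D_{MAX}/D_{MIN}$.  Labels under 4 px are excluded with a
warning.

**Budding.**  A connected component that the watershed splits into two
lobes is one *budded* cell when the smaller lobe is less than
`similarity_ratio` (default 0.8) times the larger lobe's area — the bud is
the smaller attached cell; lobes of similar size are treated as two
separate unbudded cells, and components with more than two lobes are kept
but flagged for review (`budded = NA`).  The 0.8 default quantifies
"similar size", which has no published numeric value; it is exposed in
the interface precisely because it is a judgment call.

**Synthetic scenes.**  `generate_scene()` renders bright ellipses (and
circular mother + tangent-circle bud doublets) with Gaussian pixel noise,
and returns analytic ground truth (ellipse area $\pi a b$, Ramanujan
perimeter, tangent-circle formulas for doublets).  Scenes emulate the
geometry and contrast of bright-field micrographs of yeast, not their
optics: no point-spread blur, no uneven illumination, no debris or
out-of-focus cells.  Passing the 3% recovery tests therefore validates
the measurement chain, not robustness to real-world imaging artifacts —
which is exactly what the ground-truthed fixture is for.  An optional
outlier filter (`filter_outliers()`, records beyond k = 3 IQR from the
per-sample median area) stands in for the manual debugging step of a real
analysis; the rule is a package choice, since no published rule exists.

## The statistical battery

* **Contingency analysis** uses the Pearson chi-square statistic with no
  continuity correction, validated against brute-force expected counts.
* **Two-sample comparisons** are gated by Bonett's (2006)
  kurtosis-adjusted variance-equality test at the 5% level: if equality
  is rejected, Welch's t is used, otherwise the pooled t.  The trimmed
  mean in the kurtosis estimate uses trim proportion $1/(2\sqrt{n-4})$,
  falling back to the untrimmed mean for $n \le 4$ where that proportion
  is undefined.  The Welch degrees of freedom are *truncated to the
  integer below*, reproducing the convention of common commercial
  statistics software so that published p values can be compared digit
  for digit (for the growth-rate data in the embedded fixtures this gives
  df = 3 and p = 0.016).
* **Multi-group comparisons** use Welch's heteroscedastic ANOVA followed
  by Games–Howell pairwise comparisons (studentized-range quantiles with
  Welch-type pairwise dfs).  The compact letter display is built by an
  insert-and-absorb pass over the pairwise significance matrix; no
  canonical algorithm is prescribed for letter displays, so the simplest
  correct one is used.
* **Classification** is quadratic discriminant allocation (group-specific
  Gaussian covariances) via `MASS::qda`, with priors proportional to
  group sizes — the natural choice when the reported quantity is the
  resubstitution allocation rate.  Predictor sets whose scaled design
  matrix has a condition number above `max_condition` (default 1e4) are
  refused: near-collinear predictor pairs (area with perimeter, or all
  four size measures together) otherwise produce unstable covariance
  inverses.

## The individual-based simulator

The simulator represents every cell explicitly on a closed cubic lattice
(default $30^3$ sites) of well-stirred micro-volumes holding glucose,
organic N, ammonium, dissolved O2, ethanol and CO2.  The system is sealed
to everything except molecular oxygen: under the **aerobic** policy each
site's O2 relaxes toward saturation every step (a stirred, surface-aerated
flask); under the **microaerophilic** policy only the initially dissolved
O2 is available.  That single policy switch is the only difference between
the two scenarios.

Each 1-min time step shuffles the acting order, and each living, adapted
cell then: moves to a random neighbouring site; takes up substrates by the
min rule (`min(site stock, rate x M^(2/3))`, surface-area scaling) with
saturating feedbacks that throttle glucose uptake when the internal carbon
pool is full and N uptake when the N reserve is full; metabolizes;
reproduces; and is checked for viability.  Within-site contention honours
the shuffled order — each cell sees only what its predecessors left — via
a grouped cumulative sum rather than a per-cell loop, which keeps the pure
R implementation fast without changing the sequential semantics.

**Metabolism.**  Energy demand (maintenance `k_maint * M` plus a
synthesis cost per unit of new mass) is met by respiration first
(1 glucose : 6 O2 → 6 CO2) while local oxygen lasts, then by fermentation
(1 glucose → 2 ethanol + 2 CO2), with energy yields in the textbook ~16:1
ratio per glucose.  New structural mass is built from glucose carbon and
NH4/organic N at a fixed C:N; growth is rate-capped at `r_growth * M` per
step.  Unmet maintenance draws down the carbohydrate reserve, then
catabolizes structural mass itself (cells shrink in deep starvation, down
to a floor of 0.2 `m_C`), and only then raises the mortality index D.
Cells die when D exceeds the chronological threshold or their bud-scar
count exceeds the replicative limit; a dead cell's carbon returns to its
site as organic carbon, a choice made so that the total-carbon audit is
exactly conservative.  The audit (`total_carbon()`) sums every
carbon-bearing pool and is invariant to floating-point accumulation
(~1e-15 relative over 2000 steps).

These pathway yields make the oxygen effect *emergent*: respiring cells
assimilate ~57% of glucose carbon, fermenting cells ~8%, so with one
shared uptake rate constant the aerobic culture grows roughly twice as
fast as the microaerophilic one and the fitted Buchanan $\mu$ ordering
reproduces the experimental ordering without being programmed in.

**Reproduction.**  The two-phase budding cycle follows the standard
start-mass formulation: an unbudded cell enters the budding phase once
its mass exceeds its Start mass ($M_{Start} \sim m_C(1 + N(0,
\sigma_{mC}))$, truncated positive) *and* it has grown at least
$\Delta m_{B1}$ since birth or the last release; the bud is released once
it has grown a per-cycle threshold $\Delta m_{B2}(1 + N(0,
\sigma_{mB2}))$ *and* a minimum time $\Delta t_2$ has elapsed.  The
daughter starts unbudded with the bud's mass and scar count 0; the mother
gains a scar.  Defaults ($m_C = 10$ CN-biomass-pmol, $\sigma_{mC} = 0.2$,
$\Delta m_{B1} = 1$, $\Delta m_{B2} = 5$, $\sigma_{mB2} = 0.25$) sit
inside the ranges conventionally swept for this organism; $\Delta t_2$
(default 30 min) has no published value and is exposed in the
configuration.

**Individual lag.**  Each inoculum cell draws an adaptation delay from a
truncated normal (default mean 5 h, sd 1.5 h — matching lag durations of
~6–8 h in the fitted curves once adaptation spread is accounted for).
During its lag a cell does not move, take up, grow, or reproduce, and its
size does not change; whether lagging cells should perform maintenance
uptake is not settled, and the dormant choice is the simplest one
consistent with unchanged lag-phase size distributions.  This is a known
limitation: real lag-phase cells do change size.

**Scenario scale.**  The default medium is a 10 g/L-glucose equivalent
scaled to a desk-size simulated volume (1e5 glucose-pmol, inoculum 100
cells, ~2.5 decades of growth to ~1.3e4 cells over 24 h).  Simulated
curves use log10 of the viable count with an arbitrary volume offset,
which the Buchanan fit absorbs into $P_0$/$P_{max}$; $\mu$, $t_{lag}$ and
$t_{max}$ are scale-free.  The mass-to-volume factor (8.7 um³ per biomass
unit) is a calibration knob chosen so a mother at the critical mass
projects to a 5–6 um diameter, the magnitude of measured minor diameters;
it is documented as a calibration, not a claim.

**Output.**  `sample_snapshot()` draws up to 500 cells without
replacement (the sample size used when mimicking microscopy counts),
converts mother and bud masses to sphere radii, and projects each cell as
two externally tangent circles: $A = \pi(R_m^2+R_b^2)$,
$P = 2\pi(R_m+R_b)$, $D_{MAX} = 2(R_m+R_b)$, $D_{MIN} = 2R_m$, so
$C = (R_m^2+R_b^2)/(R_m+R_b)^2$ and $AR = (R_m+R_b)/R_m$.  Unbudded cells
are exactly circular ($C = AR = 1$); budded cells run from a nascent bud
($AR \to 1$) to an equal-size pair ($C = 0.5$, $AR = 2$).  Snapshots use
the cell-record schema, so the morphometry summaries, statistics and
comparison tools consume simulated and measured cells identically.

## Comparison workflow

`compare_distributions()` contrasts simulated snapshots with reference
cell tables per budded/unbudded stratum: mean and sd differences plus the
two-sample Kolmogorov–Smirnov distance (chosen as the distance statistic
because the reference workflow compares distributions visually; KS makes
that comparison quantitative without distributional assumptions), with
optional overlay histograms.  `end_to_end()` chains simulate → fit →
phase-label → summarize → compare for one or both oxygen policies and
emits a manifest (config hash, seed, package version, outputs) from which
every artifact can be regenerated.

## Numerical choices and problem sizes

Simulations in the tests and in the acceptance script use the default
scenario (lattice $30^3$, 1-min steps, inoculum 100, 24 h horizon;
2000 steps for the conservation audit; ten seed pairs for the
aerobic-vs-microaerophilic ordering), sizes chosen so the whole suite
runs comfortably on a laptop while the emergent behaviour — three
identifiable growth phases and the oxygen-driven $\mu$ ordering — is
well inside its asymptotic regime.  Fitting tolerances: the breakpoint
polish runs Nelder-Mead to `reltol 1e-12`; noiseless recovery is exact to
~1e-8 relative.  Ties at phase boundaries go to the earlier phase;
watershed separation uses tolerance 1 on the distance map (a single
ellipse must not self-split, two overlapping cells must).

## Known limitations

* Simulated cells are spheres; real yeast are spheroids, so simulated
  unbudded cells have exactly $AR = 1$ while measured ones average ~1.15.
* The Crabtree effect is deliberately out of scope (low-glucose
  scenario); do not use the default parameterization at high glucose.
* Pathway stoichiometry/yield constants are textbook values exposed in
  the configuration, not organism-calibrated estimates.
* The synthetic micrograph generator does not model microscope optics;
  segmentation robustness to focus and illumination artifacts is
  untested by design.
* One embedded summary value is internally inconsistent in its source
  (the microaerophilic log-to-stationary transition-time mean); the
  fixtures report both the printed and the recomputed value and warn on
  load rather than silently preferring either.
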