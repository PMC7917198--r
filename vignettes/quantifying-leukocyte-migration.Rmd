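---
title: "Quantifying leukocyte migration toward wounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leukocyte migration toward wounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundtrack)
```

# The setting

In tail-wound recruitment assays, leukocytes (neutrophils and macrophages)
are followed in 2D time-lapse movies — typically 2 h at one frame per
minute, starting around 1 h post wounding, on maximum-projection images.
Each cell yields a track: a time-ordered sequence of positions in
micrometres. `woundtrack` computes the standard per-track and cohort
statistics for such tracks, compares groups (e.g. genotypes), simulates
realistic synthetic cohorts, and links raw per-frame detections into
tracks. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
establish.

All internal units are micrometres and minutes; unit conversion (e.g.
pixel size) happens once, at the I/O boundary (`read_tracks(scale = )`).
Frame indices are 0-based internally; dialects with 1-based slice numbers
are converted on read. Tracks are 2D: a z column in an input table is
ignored with a warning, because the assay tracks maximum projections.

# Per-track statistics

For a track with positions $p_1, \dots, p_N$:

* net displacement $d_{net} = d(p_1, p_N)$;
* total displacement $d_{tot} = \sum_{i=1}^{N-1} d(p_i, p_{i+1})$;
* meandering index $M.I. = d_{net} / d_{tot} \in [0, 1]$;
* mean speed $\bar v = d_{tot} / \text{elapsed time}$.

Two conventions deserve note. First, if a cell is undetected for some
intermediate frames, the step spans the gap — no positions are invented —
and the elapsed time in $\bar v$ counts the true number of frames. A
step-wise path length can therefore underestimate the distance actually
travelled; because all cohorts are recorded at the same frame rate the
measures remain comparable, which is the property the assay relies on.
Second, a perfectly stationary cell has $d_{tot} = 0$ and no defined
meandering index; `meandering_index()` returns `NA` with a message and
such cells are excluded from group statistics rather than coerced to 0
or 1.

# Wound geometry

The wound edge is a user-supplied polyline (`wound_frame()`), commonly a
single near-vertical segment at the cut; the distance from a point is the
minimum over segments of the orthogonal projection clamped to the
endpoints. Three thresholds parameterise the wound-relative measures, all
inclusive at the boundary:

| parameter | default | meaning |
|---|---|---|
| `classify_threshold` | 200 μm | cells starting within it are *local residents*, beyond it *distant*; uses the first frame only |
| `arrival_radius` | 20 μm | a cell has *arrived* once any frame is within it; it *stayed* if every later frame remains within it |
| `recruit_band` | 200 μm | positions within it count as recruited cells |

Classification deliberately uses only the starting location: the point of
the distant/local split is that cell behaviour changes near the wound, so
the category must be fixed before that change. For the same reason
`summarize_tracks(until_arrival = TRUE)` computes the motility metrics on
the pre-arrival segment of each track — an arrested cell contributes its
migration phase, not its arrest phase, to speed and meandering
comparisons.

# Cohort MSD and the persistent-random-walk fit

The cohort mean squared displacement at lag $t$ is anchored at each
track's start:

$$MSD(t) = \frac{1}{K} \sum_{i=1}^{K} d(p_{i,1}, p_{i,1+t})^2 .$$

This is *not* the time-averaged MSD common in single-particle tracking:
each of the $K$ cells contributes exactly one squared displacement per
lag. Cells lacking the frame at some lag are excluded from that lag
(`n_cells` records inclusion), and the SEM is the across-cell standard
deviation divided by $\sqrt{n}$, matching how such curves are shaded.
The conventional time-averaged estimator is available with
`compute_msd(anchored = FALSE)`; it averages over all start points within
each track first and has far lower variance per lag.

Distant cells are modelled as persistent random walkers, whose MSD
follows the Fürth form

$$MSD(t) = 2 v^2 \tau t - 2 (v\tau)^2 (1 - e^{-t/\tau}),$$

ballistic ($v^2 t^2$) for $t \ll \tau$ and diffusive with slope
$2 v^2 \tau$ for $t \gg \tau$. From $D = \frac{1}{2n}\,dMSD/dt$ with
dimension $n = 2$, the cell diffusivity is $D = v^2 \tau / 2$.

`fit_prw()` minimises unweighted squared residuals with
Levenberg–Marquardt (`minpack.lm::nlsLM`). The fit is deterministic:
starting values are $v_0 = \sqrt{MSD(t_1)}/t_1$ (the ballistic-limit
speed at the first populated lag; an explicit `v0` can be given, e.g. the
mean cohort speed) and $\tau_0 = 10$ min, with box bounds
$v \in (0, 100]$ μm/min and $\tau \in (0, 10^3]$ min — generous for
leukocytes. A fit with $\tau$ pinned at a bound is flagged
(`tau_at_bound`). At least five positive lags are required inside the fit
window. The default windows follow assay practice: 80 min for fast
(neutrophil-like) cohorts over a 2 h movie, the full span for slower
(macrophage-like) cohorts; both are arguments.

## Which estimator for parameter recovery, and why

The package validates the simulator-plus-fit machinery by a recovery
harness: simulate 50 unbiased walkers for 120 frames at 1 min (the movie
geometry of the assay), fit, and require $v$ within 10% and $\tau$ within
25% of truth on at least 9 of 10 seeds. Two choices here were genuinely
open:

* **Estimator.** The anchored estimator has exactly $K = 50$ independent
  samples per lag and its per-lag noise is strongly correlated across
  lags; in practice $\tau$ is unidentifiable from it at this cohort size
  (errors up to ~100% across seeds, whatever the window). The recovery
  harness therefore uses the time-averaged estimator, which is the
  variance-efficient choice when the walkers are genuinely homogeneous —
  exactly the situation the harness constructs. The anchored estimator
  remains the default for cohort analysis, where heterogeneity and
  directed motion make its interpretation (displacement since the movie
  start) the relevant one.
* **Window.** The two parameters are jointly identifiable only around the
  ballistic-to-diffusive crossover, so the harness fits lags up to
  $3\tau_{true}$ (30 min). Much longer windows let the (noisy,
  correlated) diffusive tail dominate the unweighted fit and degrade the
  $v$–$\tau$ split.

# Anteroposterior velocity

`v_ap()` rotates coordinates so the anteroposterior body axis is aligned
across larvae and projects each per-step velocity onto that axis; the
axis is oriented so positive means toward the wound. The cohort time
course `vap_over_time()` pools every cell-step within a frame (each step
weighted equally, not each cell) and averages over non-overlapping
windows of three consecutive frames, reporting mean, SEM and the pooled
count; a window with no observations is a gap, not a zero. A sliding
(overlapping) window is available but off by default, since
non-overlapping bins are the plain reading of "averaged over three
consecutive time frames". In a responding cohort the curve starts
positive and decays toward zero as cells arrive and arrest; in an
unbiased cohort it fluctuates around zero throughout.

# The synthetic cohort generator

`simulate_cohort()` produces discrete correlated random walks with, per
step of length $v\,dt$: heading carried over with wrapped-normal turning
noise of variance $\sigma^2_\theta = 2\,dt/\tau$, so the per-step
directional correlation is $e^{-\sigma^2_\theta/2} = e^{-dt/\tau}$
exactly. This walker's large-$K$ MSD matches the Fürth form with the
same $v$ and $\tau$ up to discretisation terms that are negligible at
$dt = 1$ min, $\tau = 10$ min (fitting the exact discrete-walk
expectation recovers $v$ and $\tau$ within 0.5%); the heading-persistence
construction was preferred over an Ornstein–Uhlenbeck velocity process
because it is simpler to seed deterministically and keeps per-step speed
exactly $v$.

Defaults embody the assay conditions: 120 min at 1 min frames; $v = 6$
μm/min and $\tau = 10$ min, typical of interstitial zebrafish
neutrophils; starting positions uniform between 50 and 350 μm from a
400-μm vertical wound edge, spanning the local-resident and distant
bands. Chemotactic `bias` $\in [0,1]$ mixes the persistent heading with
the wound-ward direction before the turning noise; with any bias, cells
reaching `arrest_radius` (20 μm) of the edge stop. Arrest is absorbing by
default; with `depart_prob > 0` an arrested cell resumes walking per
frame with that probability, and a departing cell is desensitised (it
walks on unbiased and does not re-arrest), emulating resident cells that
leave the wound again. Cohorts are bit-identical for a given seed.

What the simulator does *not* emulate: cell–cell interactions and
crowding at the wound, speed fluctuations (per-step speed is exactly
$v$), gradual gradient build-up (bias is constant in time and space),
cells entering or leaving the field, and segmentation noise in positions.
Passing the recovery and phenotype tests therefore shows the estimators
are correct for the model the analysis assumes — not that real wounds
satisfy that model.

`simulate_detection_movie()` converts a cohort into per-frame detection
sets with independent Bernoulli dropouts (miss rate up to 0.3) and keeps
the ground-truth correspondence for scoring a tracker.

# Global track linking

`link_detections()` reproduces the automatic-tracking stage: tracks are
created one at a time, each as the highest-scoring path through the
detection graph, with birth and death states. A candidate track scores
`appear_logp` + `disappear_logp` + one `det_logp` per claimed detection +
motion scores $-d^2 / (2\sigma^2 k) + (k-1)\,$`gap_logp` per link
spanning $k$ frames; links may skip up to `max_gap` missed frames.
Unclaimed detections are treated as cost-free clutter, so a track is
worth creating only while its total score is positive — this is the
stopping rule, and it subsumes the appearance-plus-disappearance floor.
The per-detection reward is required for the scoring to rank "create a
track" against "leave as clutter" at all; it plays the role of the
detection-versus-clutter likelihood ratio in probabilistic linking
frameworks.

While a new track is searched for, *swap* operations may modify links in
the pre-existing tracks. These are implemented in the canonical way: the
search runs on the residual graph of a unit-capacity score network, in
which every link already claimed by a track can be traversed in reverse
at negated score. Each accepted path is then the largest possible
improvement of the total score, and when the best candidate path is no
longer positive the linking is the *global* optimum of the scoring model
(successive-shortest-path optimality). A plain greedy variant without
swaps (`swap = FALSE`) is kept for comparison, and `swap_pass()` exposes
the repair operation separately as a local search over tail exchanges and
splits, monotone in the total score. Division and death are not
modelled: tracks neither split nor merge.

No scoring parameters are published for the assay's tracking runs, so the
defaults (`appear_logp = disappear_logp = -5`, `det_logp = 5`,
`gap_logp = log 0.1`) are calibrated on synthetic data only: they make
tracks of three or more well-matched detections worth creating, and they
reproduce ground truth exactly on well-separated noiseless movies.
`sigma` should be set near the expected frame-to-frame displacement
($\approx v\,dt$).

# Group comparison

`compare_groups()` is the classical unpaired, two-tailed two-sample
t-test with pooled variance — the convention in this assay's statistics —
with Welch's form behind a flag. Scalars are reported as mean ± SD;
curve shading is SEM. Stars follow 0.05 / 0.01 / 0.001 / 0.0001. No
multiple-testing correction is applied, and none is claimed: p-values are
raw, as the reports state. When both groups are numerically constant and
equal the statistic is degenerate and $t = 0, p = 1$ is returned by
convention (with a message); this case actually occurs, e.g. when
comparing mean speeds of two simulated cohorts whose per-step speed is
exactly $v$.

The t-test's empirical type-I error on simulated null cohorts is checked
to be within 0.05 ± 0.02 over 2000 replicates.

# Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale problems
chosen to exercise every code path while staying quick: 200 random
cohorts (≤10 tracks × ≤20 frames) for the brute-force MSD comparison,
10 seeds × 50 cells × 120 frames for parameter recovery, $10^4$ random
tracks for the metric invariants, a 100-case random suite (≤3 cells ×
≤4 frames) against the exhaustive-enumeration linking oracle, 10
five-cell movies for link accuracy, and 2000 null comparisons for t-test
calibration. Every stochastic step takes an explicit integer seed, and
all results are reproducible bit-for-bit from it.

# Known limitations

* Only 2D tracks; the assay analyses maximum projections, and 3D linking
  is out of scope.
* The anchored MSD assumes cells present from their own first frame;
  cells appearing mid-movie are anchored at their own entry, since no
  alignment rule to the wounding time is defined for late arrivals.
* The Fürth fit treats lags as independent observations (unweighted
  least squares); standard errors of $v$ and $\tau$ are not reported
  because the residuals are strongly correlated across lags.
* The linker's scoring has no mitosis/apoptosis events and no
  measurement-noise model beyond the Gaussian motion score.
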