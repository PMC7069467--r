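---
title: "Time-varying directed EEG networks in disorders of consciousness: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying directed EEG networks in disorders of consciousness: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docnet)
```

## The scientific problem

Patients with disorders of consciousness (DOC) — the unresponsive wakefulness
syndrome (UWS) and the minimally conscious state (MCS) — may retain covert
neural processing that behavioural scales such as the CRS-R cannot detect.
Event-related potentials (ERPs) to an emotional auditory oddball index
successive processing stages (N1: early sensory; P3a: involuntary attention;
LPP: sustained elaboration), and the *dynamics* of directed cortical
connectivity during those stages — in particular frontoparietal, top-down
flow — track the level of consciousness. `docnet` implements the complete
analysis chain: ERP preprocessing and mass-univariate condition contrasts;
per-trial time-varying multivariate autoregressive (MVAR) modelling with a
Kalman filter; adaptive directed transfer function (ADTF) networks averaged
trial by trial; between-group difference networks at snapshot latencies;
weighted graph properties; and their Pearson association with CRS-R totals.
Because no patient EEG is distributed, a synthetic-data module generates
every input with planted, recoverable effects.

## Models

### Time-varying MVAR with the Kalman filter

For one trial $y(t) \in \mathbb{R}^n$ (n channels) the model is

$$y(t) = \sum_{k=1}^{p} A_k(t)\, y(t-k) + e(t),$$

with the vectorized coefficients treated as a random-walk state,
$x(t) = x(t-1) + w(t)$, $w \sim \mathcal{N}(0,\, uc \cdot I)$, observed
through the lagged data. The update coefficient `uc` is the single tuning
knob: it sets the tracking bandwidth (larger `uc` follows faster coefficient
changes but yields noisier estimates) and also drives the recursive,
innovation-based estimate of the observation-noise variance. Defaults are
`p = 5`, `uc = 1e-3` (`kalman_config()`); both matter and both are exposed.

Two observation-noise models are available. The default (`"scalar"`) uses one
pooled innovation variance; with $Q = uc\,I$ and $R = r\,I$ the filter for
the full vectorized state decouples exactly into per-channel filters sharing
a single state covariance, which is what makes per-trial fitting of
27-channel data cheap. The `"diagonal"` mode keeps an independent variance
and covariance per sink channel.

Coefficients for $t \le p$ are back-filled with the first estimate so the
model's time axis matches the epoch. A fixed-interval (RTS) smoothing pass
(`smooth = TRUE`) is available; see "Snapshot latencies and filter lag".

### ADTF

With $\bar A(f,t) = I - \sum_k A_k(t) e^{-i 2 \pi f k / f_s}$ and
$H(f,t) = \bar A(f,t)^{-1}$, the normalized ADTF is

$$\gamma^2_{ij}(f,t) = \frac{|H_{ij}(f,t)|^2}{\sum_m |H_{im}(f,t)|^2},$$

a frequency-resolved, sink-normalized measure of directed flow $j \to i$
(a form of multivariate Granger causality). Band integration uses a ratio
of sums,
$\theta^2_{ij}(t) = \sum_{f} |H_{ij}|^2 \big/ \sum_f \sum_m |H_{im}|^2$,
chosen over the mean of per-frequency $\gamma^2$ because it preserves the
per-sink normalization (every row of the integrated matrix sums to 1; the
per-frequency average is available through `integrate_band()` on a
normalized object). Per-trial networks are averaged entrywise across trials
(`average_trials()`), which suppresses unstable single-trial patterns while
conserving the time course.

The default frequency grid is 1–30 Hz at 1 Hz. The acquisition band reaches
down to 0.1 Hz, but a 1.2 s epoch cannot resolve 0.1 Hz, so the grid starts
at 1 Hz. Self-flow (diagonal) entries are retained in ADTF matrices but the
diagonal is zeroed before graph metrics.

### Graph properties

`graph_properties()` computes, on the symmetrized matrix
$(w + w^\top)/2$ by default (a directed variant is a switch):

* **C** — Onnela weighted clustering: geometric-mean triangle intensity over
  $k_i(k_i - 1)$. Weights are used as-is when they are already in $[0,1]$
  (ADTF weights are, by construction) and rescaled by the maximum otherwise;
  not rescaling normalized weights keeps C monotone when coupling is dialed
  up.
* **L** — characteristic path length: mean Dijkstra distance on edge lengths
  $1/w$ over connected ordered pairs (disconnected pairs are excluded and
  counted; an edgeless graph reports `Inf`).
* **Ge** — global efficiency: mean of $1/d_{ij}$, disconnected pairs
  contributing 0.
* **Le** — local efficiency: mean over nodes of the global efficiency of the
  node's neighbourhood subgraph.

Higher C, Ge, Le and lower L indicate stronger connectivity; this ordering
is verified on synthetic networks with increasing planted coupling.

### Statistics

Mass-univariate condition contrasts run a two-tailed t-test at every channel
and time point in 0–1000 ms (paired across subjects within group; Welch
between groups), with Benjamini–Hochberg FDR control pooled over channels ×
time — the default in the mass-univariate ERP literature. Zero-variance
points report $p = 1$ rather than NaN. Edge-wise difference networks retain
directed edges with Welch $p < 0.05$, deliberately uncorrected — matching the
retention rule of edge-wise time-varying network comparisons — and the null
calibration test documents that the expected retained fraction equals the
nominal level; a BH-corrected mode is behind a flag. Associations use
Pearson's r with the two-tailed p from the t transform on $n-2$ degrees of
freedom.

## Snapshot latencies and filter lag

A causal filter estimates $A(t)$ from samples up to $t$; a coupling that
switches on at 300 ms is therefore invisible *at* the 300 ms snapshot no
matter how fast the filter tracks. For snapshot-based group comparisons the
pipeline therefore runs the Kalman filter forward and then applies RTS
smoothing, so the estimate at $t$ uses the whole trial symmetrically and the
network time course aligns with stimulus-locked latencies. Averaging a
forward and a time-reversed filter was rejected: time reversal flips the
direction of Granger-causal influence and would cancel exactly the
directionality of interest.

## The synthetic-data generator

`simulation_scenario()` defines the study conditions: 27-channel 10-20
montage at 500 Hz, epochs −200..1000 ms, 8 subjects per simulated group, 60
deviant and 60 standard trials per subject. Each trial is an
innovation-driven VAR(1) path: a stable diagonal background (coefficient
0.7) plus a weak random cross-coupling matrix (SD 0.03, drawn once per
scenario and rescaled to spectral radius ≤ 0.85) that gives every channel
pair a nonzero connectivity floor, standing in for the cortical background
and volume conduction of real EEG. The planted effect is a directed
F3 → P3 (frontal-to-parietal) coefficient of 0.35 switched on during
300–1000 ms of deviant trials in MCS-like subjects only.

ERP templates are Gaussian-windowed half-sine bumps with fixed scalp-weight
vectors: N1 (100–200 ms, frontal, −2 µV standards / −6 µV deviants, both
groups), P3a (250–350 ms, frontal, +6 µV, deviants of MCS-like subjects
only), no LPP in either patient group. Per-subject multiplicative amplitude
jitter (SD 0.15) provides between-subject variability; innovations have a
3 µV SD. These effect sizes are deliberately at the upper end of what real
patient ERPs show: the scaled-down design (60 trials, 8 subjects per group
versus ~96 deviants and 14–18 patients per group in a full study) must reach
comparable detection power for the planted effects to be recoverable by the
same statistics. With these choices the within-group paired contrast detects
the planted windows with wide FDR-significant runs, while the P3a window
stays clean in the UWS-like group.

The stimulus generator produces 110-stimulus oddball blocks (86 standards,
12 happy, 12 sad) by sampling distinct gaps between standards, which
enforces the "no two deviants in adjacent positions" reading of
"not presented in quick succession"; stricter gaps would be a parameter of
the same placement scheme.

`generate_cohort()` draws CRS-R totals around diagnosis-specific means
(MCS 9, UWS 5, SD 2.5, clipped to [1, 23]) and decomposes them greedily into
sub-scores respecting the per-subscale maxima (4, 5, 6, 3, 2, 3) — simple
and schema-valid, though real CRS-R profiles distribute points differently
(arousal is rarely 0, for instance). Each subject carries a latent network
strength built against the *realized* totals, with the noise component
residualized against them, so that the within-aetiology sample correlation
equals the configured value by construction (0.5 traumatic, 0 nontraumatic
by default) — the planted correlation is a group-level invariant, not merely
an expectation, and recovery checks then measure estimation error rather
than planting luck. In the association recovery study the
strength scales the planted coupling of a stationary analytic network for
*all* subjects, without the diagnosis gate: the gate models the
event-locked dynamic response, while the latent strength models a subject's
overall connectivity level; tying the gate into the association study would
let the diagnosis difference in CRS-R means masquerade as a score–network
correlation and would break the planted null in the nontraumatic group.

What the generator does **not** emulate: volume-conduction forward models,
ocular or muscle artifacts, electrode drift, non-stationary background
rhythms, or realistic CRS-R sub-score profiles. Passing recovery tests
therefore show that the pipeline recovers what it models — not that it is
robust to everything real EEG contains.

## Numerical choices

* FIR filtering: windowed-sinc (Hamming), order from the narrower transition
  band (0.1 Hz at the low edge, 7.5 Hz at the high edge by default), applied
  by FFT convolution with exact group-delay compensation.
* Trial rejection: per-trial max absolute voltage across channels versus
  across-trial mean + 3 SD, strict inequality; with zero SD the threshold
  equals the mean and ties are kept, so identical trials are never rejected.
  A peak-to-peak statistic is a config option.
* ADTF: singular spectral matrices are ridge-regularized (`1e-8` diagonal
  loading) with a count surfaced in warnings; all-zero sink rows become
  uniform rows. For order-1 models the per-frequency inverses are computed
  through one eigendecomposition per time point.
* Kalman: the state covariance is kept symmetric; the observation-noise
  estimate is initialized from the per-channel data variance unless
  configured.
* BH-FDR delegates to `stats::p.adjust`; shortest paths delegate to
  `igraph::distances` (Dijkstra). Both are cross-checked against brute-force
  enumerations in the test suite.

## Problem sizes in the validation studies

The end-to-end recovery study (`recovery_study()`) runs the full chain —
simulation, per-trial Kalman + ADTF, snapshot difference networks,
mass-univariate ERP contrasts, association — on the default scenario, 20
replicates by default. For these studies the network fits use order
`p = 1` (matched to the generator's VAR(1) background — an order selection
helper, `select_var_order()`, recovers this from the data), `uc = 1e-2` with
RTS smoothing, and the ADTF is evaluated on a 100 ms time grid over 2–30 Hz
at 2 Hz steps: the integrand is smooth for a low-order background and the
planted dynamics evolve over hundreds of milliseconds, so the coarser grids
change the snapshot statistics negligibly while keeping a full 20-replicate
study around ten minutes on one core. With 702 directed edges tested
uncorrected at $\alpha = 0.05$, a specific null edge is retained in ~5% of
replicates by design; recovery rates are therefore assessed against a 90%
threshold rather than 100%.

## Known limitations

* The per-sink (inflow) normalization makes ADTF rows compositional: strong
  inflow on one edge necessarily depresses the others in that row. The
  column-normalized variant is available but off by default.
* Difference networks are uncorrected by design; interpret single retained
  edges accordingly (the BH mode exists for conservative use).
* The Kalman estimator attenuates coefficients slightly at large `uc`
  (finite effective estimation window); for stationary signals use small
  `uc` or the OLS fit.
* `run_pipeline()` is a single-machine orchestration with file-based
  resumability, not a scheduler.
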