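---
title: "Modelling mouse-brain dynamics, frequency optimization, and simulated injury with kurnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mouse-brain dynamics, frequency optimization, and simulated injury with kurnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kurnet)
```

## The model

`kurnet` simulates resting-state functional connectivity (FC) as the
correlation structure of coupled phase oscillators placed on a structural
connectome (SC). Each brain region `a` carries a phase `theta_a` evolving
as

$$\frac{d\theta_a}{dt} \;=\; \omega_a \;+\; g \sum_{b=1}^{N} A_{ba}\,
\sin(\theta_b - \theta_a),$$

where `A` is the weighted SC with row = source and column = target (so
`A_ba` is the influence of oscillator `b` on `a`), `omega_a` is the node's
natural angular frequency, and `g` a global coupling constant. We use the
synchronizing sign convention `sin(theta_b - theta_a)`: with it, raising
`g` drives the network from incoherence through a transition into phase
locking, which is the behavior that every quantity downstream (synchrony
curves, metastability peaks, coupling-at-maximum-metastability) relies on.

Natural frequencies are drawn uniformly from the BOLD band, 0.01–0.1 Hz,
and multiplied by $2\pi$ (rad/s). Initial phases are uniform on
$[0, 2\pi)$. Neural activity is represented directly as
$\sin(\theta_a(t))$ and simulated FC is the pairwise Pearson correlation
of these signals over the post-transient samples. Global synchrony and
metastability are the time mean and time SD of the Kuramoto order
parameter $R(t) = |N^{-1}\sum_b e^{i\theta_b(t)}|$. No time delays, noise
terms, or hemodynamic convolution are included: at BOLD-band frequencies
and mouse-brain length scales, conduction delays are negligible relative
to oscillation periods, and sin(theta) stands in for the slow activity
fluctuation itself.

Directed and undirected architectures are compared throughout. The
undirected variant of a directed SC sums the two directions of every
edge; both variants are rescaled so the maximum edge weight is 1 and
self-connections are zero.

## Connectome construction and graph measures

Whole-brain networks are assembled from one hemisphere's ipsilateral and
contralateral blocks under bilateral symmetry
(`mirror_bilateral()`): node order is hemisphere A then hemisphere B, and
the block matrix is `[[ipsi, contra], [contra, ipsi]]`, so every weight
leaving an A-region equals its homologous counterpart leaving the paired
B-region. Hemisphere A is, by convention, the "first" hemisphere — the
one that receives simulated injury.

`reduce_to_regions()` extracts a subnetwork without re-normalizing, so a
reduced model and the full model share one edge scale (re-normalizing
would silently rescale the coupling term by an arbitrary factor that
depends on which regions survived quality control).

Randomized control architectures use directed Maslov–Sneppen edge swaps
(`randomize_directed()`): two directed edges exchange targets when no
self-loop or duplicate would result, each weight travelling with its
source. Every edge is swapped 20 times on average. This conserves the in-
and out-degree sequence of every node and the global multiset of edge
weights exactly, which the test suite asserts elementwise.

Weighted global efficiency is the mean over ordered node pairs of the
inverse shortest-path length, where each edge has length 1/weight
(`global_efficiency()`, via igraph's Dijkstra paths). Unreachable pairs
contribute zero — the standard convention, and the one that keeps the
measure finite when an injury fully disconnects a region.

## Numerical integration

The integrator is fixed-step classical RK4 (compiled, RcppArmadillo) with
`dt_s = 0.05` s and output sampling every `sample_dt_s = 0.5` s. BOLD-band
oscillations (≤ 0.1 Hz) are oversampled by two orders of magnitude at this
step; the suite verifies that halving `dt_s` changes synchrony and
metastability by less than $10^{-3}$ on a 20-node network, and a runtime
guard warns if `dt * max|dtheta/dt|` exceeds 0.5 rad. The default
simulation protocol is 600 s with the first 120 s discarded as transient;
optimization iterations use 200 s with the first 20% (40 s) discarded —
the protocol states no separate transient rule for iterations, so the
same fraction is applied.

Phases are integrated unwrapped; all downstream statistics pass through
`exp(i theta)` or `sin(theta)` and are unaffected. Because the coupling
term depends only on phase differences, adding a constant to all initial
phases leaves $R(t)$, synchrony, metastability, and simulated FC invariant
(tested to $10^{-9}$).

## Empirical-FC quality control

`region_filter()` applies three sequential filters to a region-level BOLD
recording: (1) keep regions whose labels exactly match the SC; (2) keep
regions with voxel count *strictly above* the median of the matched set —
ties at the median are excluded; (3) drop regions whose time-series
variance falls below $10^{-6}$ (in the stored units of the series).
Edge-strength comparison between two FC networks
(`fc_similarity()`) is the Pearson correlation of the strictly-upper-
triangle entries over the common regions, using raw signed correlations —
no thresholding or absolute values, since the model must account for
negative edges too. The same function applied to a (simulated, empirical)
pair is the model's *predictive power*.

## Frequency optimization

The optimizer (`optimize_frequencies()`) iterates: simulate → FC → score →
update. The update for node `a` is

$$\Delta\omega_a \;=\; c \,\cdot\, (\omega_{hi}-\omega_{lo}) \,\cdot\,
\hat E_a \,\cdot\, (s^{sim}_a - s^{emp}_a),$$

with `c = 0.005`, the band width $(\omega_{hi}-\omega_{lo}) = 0.09\,
\mathrm{Hz} \times 2\pi$, `s` the nodal FC strength (sum of positive
incident FC edges), and $\hat E_a$ the node's minimum control energy
normalized to unit maximum within the iteration. Nodes whose simulated
strength exceeds the target's are sped up, which pulls them away from the
synchronized cluster and lowers their FC strength; the opposite for nodes
that are too weak. Frequencies are floored at a small positive value
($2\pi \times 10^{-3}$ rad/s) and may exceed the band's upper edge —
high-frequency solutions are not excluded.

Control energies come from the stable linear surrogate
$dx/dt = A_{stab}\,x + u$ with identity input. Design choices the
procedure leaves open, and how they are fixed here:

* **Stabilization.** $A_{stab} = W/(1+\lambda_{max}) - I$, where
  $\lambda_{max}$ is the spectral radius of the (nonnegative) weight
  matrix. Every eigenvalue then has real part in $(-2, 0)$: the standard
  normalize-then-shift recipe in linear network control.
* **Horizon and quadrature.** Dimensionless horizon `T = 1`; the
  controllability Gramian $W_T = \int_0^T e^{At}e^{A't}\,dt$, the
  minimum-energy input
  $u^*(t) = e^{A'(T-t)} W_T^{-1}\,(x_T - e^{AT}x_0)$, and the nodal
  energies $E_a = \int_0^T u^*_a(t)^2 dt$ are all evaluated by composite
  Simpson quadrature on one shared 201-point grid. Sharing the grid makes
  the decomposition identity $\sum_a E_a = v' W_T^{-1} v$ hold to
  round-off, which the suite checks at $10^{-6}$ relative tolerance, and
  the whole route is validated against a discretized least-squares
  minimum-energy oracle within 1% on small systems. Matrix exponentials
  use scaling-and-squaring Padé (`Matrix::expm`); a near-singular Gramian
  is reported and ridge-regularized with a documented jitter.
* **Energy normalization.** $E$ is rescaled to unit maximum per iteration
  so that `c` controls step size regardless of network size or state
  scale; the raw energies have no intrinsic scale here.
* **Update sign.** The strength difference is read literally as
  (simulated − target); the `direction` argument exposes the opposite
  reading.
* **States.** $x_0$ = simulated nodal FC strengths, $x_T$ = target nodal
  FC strengths, both raw (not normalized), matching the choice of raw
  strength differences in the update.
* **Initial conditions.** Initial phases are drawn once per optimization
  run and reused across iterations, so between-iteration differences are
  attributable to the frequency updates alone; a self-consistent target
  (the model's own iteration-0 FC) is then an exact fixed point, which
  the suite asserts. Initial frequencies are shared across per-subject
  models through one seed.
* **Coupling during fitting.** The protocol fixes `g` at the approximate
  metastability maximum of the architecture being fitted — the regime
  where the dynamics are most flexible. For the full-scale mouse networks
  those values are 1.0 (undirected) and 3.5 (directed), exposed as
  `pipeline_config()` defaults; for the smaller, denser synthetic
  networks the peak sits at much weaker coupling (around 0.15 for the
  default generator), so the acceptance analysis first sweeps `g` and
  uses the computed argmax rather than the full-scale constants.

Divergence (any $|\omega|$ beyond ten times the initial band width)
aborts the run; the trace records per-iteration frequency vectors, MSE,
predictive power, and the best iteration (argmax predictive power).

## Simulated injury

`apply_injury()` multiplies all edges into and out of the targeted
hemisphere-A nodes by `(1 - fraction)` through a single mask, so an edge
between two targeted nodes is scaled once per application — the
composition of two injuries therefore equals a single injury at
$1-(1-f)(1-g)$ on every touched edge, asserted exactly in the suite. The
packaged default region set (`inst/extdata/injury_regions.csv`) lists 14
cortical and hippocampal acronyms where neurodegeneration is observed
after mild controlled cortical impact, with flags for regions that drop
out of reduced networks during quality control; targets absent from a
reduced model are skipped silently and counted, so typically only eight
or nine regions are actually lesioned.

`injury_sweep()` grades the lesion over twenty levels (5%–100% in 5%
steps), re-simulating with the optimized frequencies and the *same*
initial phases as the uninjured baseline, so that all FC change is
attributable to structure. Derived measures per level: edge-strength
correlation to the uninjured FC, mean regional FC distance (per-node
Euclidean distance between FC rows, excluding directly injured nodes; a
whole-matrix Frobenius variant is available via `fc_distance(method =
"frobenius")`), structural global efficiency, and nodal FC strengths.
`strength_change_analysis()` counts, per region and level, the fraction
of models whose strength strictly decreased (ties are not decreases),
restricted to regions common to all models and not directly injured.

## The synthetic study conditions

The generator (`synth_config()`) defines the desk-scale conditions under
which everything above is exercised:

* **Connectome** — 30 regions per hemisphere by default (60 nodes);
  log-normal edge weights (meanlog 0, sdlog 1) emulating heavy-tailed
  tract-tracing strengths; 35% directed edge density; direction bias 0.8
  (a connected pair is unidirectional with that probability), matching
  the strong directionality of tract-tracing connectomes; contralateral
  weights at half the ipsilateral scale with 90% homotopic connection
  probability; mirrored bilaterally and normalized. The first region
  labels reuse the packaged injury acronyms so the default lesion set
  resolves on synthetic networks.
* **Target FC** — *noisy* mode builds a valid correlation matrix from a
  two-factor construction (one common factor setting mean edge strength
  0.25, one balanced ±factor setting edge-strength SD 0.12, Gaussian
  jitter 0.02, nearest-correlation projection if needed), with per-subject
  region dropout leaving 65–82% of nodes — the proportions seen after
  empirical quality control. *Self-consistent* mode simulates FC from
  known ground-truth frequencies and returns both.
* **BOLD** — Gaussian series realizing a target FC, with injected
  near-constant regions (variance below the 10⁻⁶ floor) and voxel counts
  spanning the median threshold, so every quality-control filter removes
  exactly its constructed victims.

What passing under these conditions does and does not show: the noisy
targets reproduce the *marginal statistics* of empirical FC (edge mean
and spread, dropout), but by construction they carry no
structure–function coupling, so no frequency assignment can fit them —
predictive powers against them hover near zero and the paired
baseline/optimized comparisons are noise-level. Demonstrations that the
optimizer works therefore use self-consistent targets, where best
predictive power exceeds the starting value in at least 9 of 10 seeds
(25 iterations of 60 s on the 60-node network). Real empirical FC lies
between these extremes. Synthetic networks are also far smaller than a
whole-brain connectome, which compresses the interesting range of `g`
and weakens cross-model statistics (the hypoconnectivity-frequency trend
over 6 models is unstable where the full-scale analysis, with 58 models
and 103 regions, is strongly powered).

Problem sizes used by the acceptance analysis (`scripts/acceptance.R`):
60-node networks, 5-seed sweeps of 300 s, 6 synthetic subjects, 15-
iteration fits of 60 s, 10-seed recovery at 25 iterations, and 20-level
injury sweeps of 60 s per level — chosen so the whole analysis reruns
from scratch in minutes on one CPU while keeping every stage's statistics
interpretable.

## Known limitations

* The Kuramoto phase reduction has no amplitude dynamics, delays, or
  hemodynamics; simulated "BOLD" is sin(phase).
* The linear control surrogate's stabilization recipe, horizon, and
  energy normalization are conventions (exposed as arguments), not
  identified quantities.
* The degree-preserving randomization conserves the weight multiset
  globally, not each node's weight sequence; in- and out-*strength*
  distributions are preserved only statistically.
* Injury is purely structural (edge scaling); excitability changes and
  time-evolving degeneration are out of scope.
* The synthetic generator does not model anesthesia effects, scanner
  noise spectra, or biophysically realistic hemodynamics.
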