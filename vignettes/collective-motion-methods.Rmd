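---
title: "Equation-free analysis of collective motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equation-free analysis of collective motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(comodyn)
```

`comodyn` analyzes the latent dynamics of multi-agent collective motion
without fitting equations of motion. It couples a zonal schooling simulator
(for controlled, labeled regimes) with dynamic mode decomposition (DMD),
its reproducing-kernel extension, Koopman spectral kernels between fitted
systems, dynamic structure factors, and a small embedding/classification
layer. This vignette documents the models, the numerical choices, and the
limits of what the test suite demonstrates.

## The zonal schooling model

Each of `N` point agents carries a constant individual speed and a unit
heading. The plane around an agent is divided into three concentric zones:

* **repulsion** (`dist < r_r`): the desired heading is the normalized sum
  of unit vectors *away* from these neighbors. This zone has absolute
  priority — when occupied, the outer zones are ignored.
* **orientation** (`r_r <= dist < r_o`): the normalized sum of the
  neighbors' headings.
* **attraction** (`r_o <= dist < r_a`): the normalized sum of unit vectors
  *toward* the neighbors.

When both outer zones are occupied their unit contributions are averaged
with weight 1/2 each; with no neighbors in any zone the agent keeps its
heading. The heading change per step is capped at `beta` radians, turning
toward the desired direction. Positions advance by `speed * dt` along the
new heading.

The orientation radius `r_o` is the single control parameter: `r_o = 2`
yields a disordered swarm, `r_o = 10` a rotating torus (milling), and
`r_o = 13` parallel translation — quantified by the polarization
`P = ||sum d_i||/N` and the angular momentum `M = ||sum u_ic x d_i||/N`
about the group centroid, both in [0, 1].

### Parameter defaults and why

| parameter | default | rationale |
|---|---|---|
| `n_agents` | 64 | standard group size for this model family |
| `speed` | 4 m/s | nominal constant speed; per-agent multiplicative noise `sigma = 0.05` drawn once at initialization ("constant within a particle") |
| `dt` | 0.01 s | integration and sampling step |
| `r_r, r_o, r_a` | 2, 10, 20 m | zone radii; `r_o` is the regime dial |
| `beta` | 0.01 rad/step | per-step turn cap, i.e. ~1 rad/s at `dt = 0.01` |
| `boundary_radius` | 25 m | circular arena; `Inf` disables it |

The published description of this simulation leaves `r_r`, `r_a` and
`beta` unspecified, so they were fixed here, once, by requiring the model
to reproduce its own documented regime map (swarm/torus/parallel at
`r_o` = 2/10/13). Two observations drove the choice. First, `beta` is a
*per-step* cap: at `dt = 0.01` s a cap of 0.7 rad/step would allow 70
rad/s of turning, which lets the group align almost instantly and
produces parallel motion at every `r_o`; a cap of 0.01 rad/step (~1
rad/s, the order of the turning rates used in the classic zonal-model
literature, where a torus of radius ~10 m at 4 m/s needs only ~0.4 rad/s)
preserves the milling state while still letting alignment win when the
orientation zone is wide. Second, with `r_r = 1` a thin orientation shell
at `r_o = 2` still organizes milling; `r_r = 2` makes the `r_o = 2` case
an orientation-free, genuinely disordered swarm. All three values are
ordinary configuration fields, not constants.

Other numerical conventions: initial positions are uniform in angle at
radii uniform in [6, 16] m; initial headings are the counter-clockwise
tangent (perpendicular to the position vector, common handedness — the
initial condition is deliberately torus-friendly, and the other regimes
emerge from it); the update is synchronous. Boundary handling replaces
the desired direction with the unit vector toward the origin whenever the
provisional next position would leave the arena, and — because a
turn-limited agent can still be carried over the rim in rare corner cases
— clamps the position radially to the boundary as a last resort, keeping
the containment invariant exact. Exactly coincident agents repel along a
random direction drawn from the run's seeded stream, so runs remain
reproducible.

## Observables fed to the decompositions

For swarm analysis the package uses the *nearest-sorted distance matrix*:
for each agent, its `N - 1` distances to the others sorted ascending, rows
concatenated (p = `N(N-1)` = 4032 for `N = 64`). Sorting removes agent
identity, which both matches the metric interaction (agents do not
discriminate individuals) and makes the series vary more smoothly in time
than the fixed-order variant — a property the test suite asserts.
`fixed_distance` (upper triangle, fixed order) and `cartesian` (stacked
coordinates) variants exist for comparison.

For the 5-on-5 game-style segments, the per-frame 5x5 attacker–defender
matrix puts the ball handler's sorted defender distances in column 1 and
orders the remaining attackers by decreasing nearest-defender separation
(ties broken by attacker index, for reproducibility). Its top row yields
the four *critical distances* — ball-mark, ball-help, pass-mark,
pass-help — and the nine input variants (1–4 critical distances; 3x3,
4x4, 5x5 blocks; 25 unsorted distances; 20 Cartesian coordinates).

## Dynamic mode decomposition

With snapshots `Y = [y_1 .. y_{tau-1}]`, `Y' = [y_2 .. y_tau]` and the
reduced SVD `Y = U S V*`, the POD-projected propagator
`Fhat = U* Y' V S^{-1}` is eigendecomposed; modes are
`Phi = Y' V S^{-1} W Lambda^{-1}` and amplitudes `psi = Phi^+ y_1`. The
temporal frequency of an eigenvalue is `Im(log lambda) / (2 pi dt)` in Hz
(principal branch) and the growth rate `Re(log lambda) / dt`; the complex
logarithm cleanly separates oscillation from growth. Numerical choices:

* the default rank is the numerical rank of the singular spectrum at a
  relative threshold of 1e-10; a requested rank beyond it is truncated
  with a warning;
* an exactly zero eigenvalue leaves its mode column unscaled (the
  `Lambda^{-1}` factor is undefined there) and is reported as fully
  decayed (`growth = -Inf`);
* the spectral amplitude of a mode defaults to `|psi_j| * ||phi_j||`
  (`"psi"` alone is selectable); conjugate pairs are merged onto the
  non-negative frequency axis with their amplitudes summed;
* band-restricted spatial power maps average `|phi_j|^2` elementwise over
  the modes whose frequency lies in the band.

## DMD with reproducing kernels

For low-dimensional or transiently nonlinear series, the same projection
is performed in the RKHS of a kernel `k`: the centered Gram matrix
`H G_yy H` (`H = I - 1/n`, size `tau - 1`) is truncated to its leading
eigenpairs `B, S`, and the projected Koopman operator
`Fhat = S^{-1/2} B* H G_yy' H B S^{-1/2}` is eigendecomposed. The shifted
Gram `G_yy'[i, j] = k(y_i, y_{j+1})` is centered with the same `H` on
both sides. Kernels: Gaussian (bandwidth defaulting to the median
pairwise snapshot distance), linear, and polynomial. Components with Gram
eigenvalues below `1e-12 * max` are dropped — with exact arithmetic the
centered Gram is singular, so some threshold is unavoidable, and this one
sits well below any data scale used here. Each row `b_j` of `T^{-1}`
(the mode coordinates) is normalized to unit norm with a real-positive
leading entry, compensated on the columns of `T`, which fixes the
otherwise arbitrary per-mode complex scale without changing `T Lambda
T^{-1}`.

Two consistency anchors justify the construction: with the linear kernel
on full-rank linear data the eigenvalues equal plain DMD's exactly (the
kernel-PCA basis spans the same space), and on a weakly nonlinear fixture
(`x1 <- lambda x1; x2 <- mu x2 + c x1^2`) a degree-2 polynomial kernel
recovers the analytic Koopman triple `{lambda, mu, lambda^2}`. Data-space
reconstruction through a pre-image map is out of scope; in its place the
package offers the exact linear-kernel path and a one-step spectral
prediction error in the kernel-PCA coordinates
(`kdmd_one_step_error()`), which the tests use to show the Gaussian
kernel out-predicting plain DMD on the nonlinear fixture at equal rank.

## Koopman spectral kernels

Similarity between two fitted systems is the principal-angle
(Binet–Cauchy) kernel between their Koopman-mode subspaces, computed
entirely from Gram matrices. The cross block uses the upper-right part of
the centered Gram of the two snapshot series concatenated in time (one
centering matrix of size `n_i + n_j`); for Gaussian kernels the cross
bandwidth is re-resolved by the median heuristic on the concatenated
data. The generalized eigenproblem's spectrum comes in +/- pairs; the
absolute values are deduplicated, sorted descending, the top
`min(r_i, r_j)` kept and clipped to [0, 1]. The scalar kernel is their
**product** by default — the determinant (Binet–Cauchy) form for
principal angles — with the sum selectable; the induced squared distance
is `k(i,i) + k(j,j) - 2 k(i,j)`, clipped at zero (per-pair bandwidths can
produce slightly negative values; the triangle inequality is not
guaranteed and not asserted).

## Dynamic structure factors

The longitudinal and transverse current modes at wave vector `q` are
`j_L = sum_i (v_i . qhat) exp(i q . r_i)` and the perpendicular analogue.
`S_a(q, w)` is the squared temporal Fourier transform scaled by
`dt / (2 pi N T)`, averaged over `n_angles` equally spaced directions
(default 16) and over trials; negative-frequency bins are folded onto the
positive axis, making the one-sided spectrum satisfy Parseval against the
mean squared current exactly. No taper is applied by default — the
quantity of interest is peak location, which windowing does not move — a
Hann option exists. Mean group drift is not subtracted (no such step in
the source protocol); a flag could be added trivially. The dispersion
slope `c` is the least-squares fit of `w_peak(q) = c |q|` through the
origin; a ridge on the last frequency bin is flagged as possible
aliasing. For the ballistic oracle the spectrum is evaluated with the
wave vector parallel to the motion — with angle averaging, pairs of
off-axis directions would outweigh the aligned one and bias the apparent
ridge low.

## Embedding and prediction

Classical (Torgerson) MDS double-centers the squared distances and keeps
the top non-negative eigenpairs; on exact Euclidean input the embedded
distances reproduce the originals to round-off (asserted at 1e-8, and
cross-checked against `stats::cmdscale`). Prediction uses a Gaussian
naive Bayes with a variance floor of 1e-9 (degenerate likelihoods
otherwise arise from duplicated segments), class priors from the training
folds, stratified 5-fold cross-validation with a seeded assignment, and
the *median* fold error as the headline number. Feature vectors are the
kernel-matrix rows restricted to training columns (similarities to the
training set); a distance-row alternative is accepted. The naive Bayes
core is intentionally small and is verified against `e1071::naiveBayes`
in the test suite.

## Synthetic data: what it emulates, what it does not

* `linear_fixture` / `koopman_oscillator_fixture`: exact oracles for the
  decompositions; the oscillator replaces an unavailable demonstration
  system with a documented, analytically solvable stand-in.
* `ballistic_fixture`: a plane-wave oracle for the structure factors.
* `game_segment_generator`: 5 attackers + 5 defenders + ball at 25
  frames/s, segment lengths uniform in 3–8 s, balanced binary labels.
  The class signal lives in the *dynamics of the critical distances*:
  "score" segments carry a slow (~0.5 Hz) defender-gap oscillation whose
  amplitude grows through the segment on the ball-handler and one
  off-ball attacker; "no-score" segments have tight tracking with
  small fast (~4 Hz) jitter. Formation centers and orientations are
  randomized per segment so absolute Cartesian coordinates carry no
  class information — which is precisely what makes the
  distance-dynamics-beat-Cartesian ordering testable. A `class_effect`
  of 0 makes the classes generatively identical (chance-level control).

Passing tests on these generators demonstrate that the pipeline recovers
dynamics it is designed to see under controlled conditions. They do not
demonstrate performance on real tracking data: real possessions switch
ball handlers, change tempo mid-segment, and carry measurement noise and
identity errors none of which the generator emulates.

## Problem sizes used by the checks

The regime analyses use 5 seeds per `r_o` in 40 s runs (64 agents,
dt = 0.01 s), with 10 s analysis windows starting at 10 s (torus) or 30 s
(swarm, parallel) to skip the transient, and rank-100 DMD on the
4032-dimensional sorted-distance series. Structure factors use 8
wavenumbers in [0.3, 2] m^-1 and 8 directions; classification uses 40
segments. These sizes give stable qualitative statistics while keeping a
full run in minutes on one core.

## Known limitations

* The spatial-power maps of the simulated torus show their
  nearest-neighbor weakness most cleanly *relative to the other regimes*;
  the absolute level depends on the repulsion radius, which governs how
  actively nearest-neighbor distances fluctuate.
* Koopman spectral kernels with per-pair Gaussian bandwidths define a
  similarity, not a true kernel matrix; PSD-ness is not guaranteed.
* The schooling model is 2-D, metric-only (no topological/k-nearest
  interactions, no blind angle), with speed noise only.
* Plain DMD amplitudes are fitted from the first snapshot only; for
  strongly transient data the kernel variant is the intended tool.
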