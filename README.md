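# comodyn — equation-free analysis of collective motion dynamics

`comodyn` is an R toolkit for extracting, classifying and predicting the
latent dynamics of multi-agent collective motion directly from trajectory
data, with no equations of motion fitted. It targets researchers in
collective-behavior science, active matter and sports analytics who have
time-resolved positions of interacting agents (fish, birds, players) and
want to ask: *what coherent dynamical structures does this group express,
and do they predict what the group achieves?*

## What is inside

* **Zonal schooling simulator** — the classic metric
  repulsion/orientation/attraction model: `N` constant-speed agents whose
  headings respond to neighbors in three concentric zones, with a per-step
  turning cap `beta` and a circular arena. Sweeping the orientation radius
  `r_o` through 2, 10, 13 m produces the swarm, torus (milling) and
  parallel regimes, quantified by the polarization
  `P = ||Σ d_i||/N` and angular momentum `M = ||Σ u_ic × d_i||/N`.
* **Dynamic mode decomposition (DMD)** — with snapshots
  `Y = [y_1 … y_{τ−1}]`, `Y' = [y_2 … y_τ]` and reduced SVD `Y = U Σ V*`,
  the projected propagator `F̂ = U* Y' V Σ⁻¹` is eigendecomposed; modes
  `Φ = Y' V Σ⁻¹ W Λ⁻¹`, amplitudes `ψ = Φ⁺ y_1`, and each eigenvalue
  `λ_j` carries a temporal frequency `Im(ln λ_j)/(2π Δt)` and growth rate
  `Re(ln λ_j)/Δt`.
* **DMD with reproducing kernels** — the same projection performed in the
  RKHS of a Gaussian, linear or polynomial kernel via centered Gram
  matrices (`F̂ = S̄^{-1/2} B̄* H G_yy' H B̄ S̄^{-1/2}`), for
  low-dimensional and transiently nonlinear series.
* **Koopman spectral kernels** — principal-angle (Binet–Cauchy) similarity
  between two fitted systems' Koopman-mode subspaces, computed purely from
  Gram matrices, giving a kernel and distance matrix over a collection of
  labeled trajectory segments.
* **Dynamic structure factors** — longitudinal/transverse current spectra
  `S_α(q, ω)` and the Brillouin-style dispersion fit `ω_peak = c |q|`.
* **Embedding and prediction** — classical MDS of the spectral-kernel
  distances, and Gaussian naive-Bayes prediction with stratified 5-fold
  cross-validation (median fold error, confusion counts).
* **Synthetic-data generators** — seeded fixtures with analytically known
  ground truth for every stage, including a 5-on-5 game-segment generator
  whose class signal lives in the dynamics of the four critical
  attacker–defender distances (ball-mark, ball-help, pass-mark,
  pass-help).

## Worked example

Simulate the milling (torus) regime, decompose its nearest-sorted distance
series, and classify synthetic game segments:

```r
library(comodyn)

p  <- schooling_params(r_o = 10, duration = 20, analysis_start = 10, seed = 1)
tr <- simulate_school(p)
round(colMeans(order_parameter_series(tr)[, -1]), 3)
#>     polarization angular_momentum
#>            0.102            0.836

s   <- build_snapshot_sequence(tr, "sorted_distance", from = 10)
fit <- fit_dmd(s, rank = 100)
fit
#> DMD: rank 100, dt = 0.01 s; |lambda| in [0.993, 1]
sp <- temporal_spectrum(fit)
head(sp[order(-sp$amplitude), ], 3)
#>   frequency amplitude   growth
#> 1     0.000      1055 -0.00086
#> 2     0.000       342 -0.30490
#> 3     0.105       256 -0.08702

set <- game_segment_generator(m = 20, class_effect = 1, seed = 5)
km  <- kernel_and_distance_matrix(set, kernel_spec("gaussian"), rank = 8)
nb_predict_cv(km$K, km$labels, folds = 5, seed = 7)
#> Naive Bayes 5-fold CV: median error 0.000
#> confusion (positive = score): TP 10 TN 9 FP 1 FN 0
```

Reading the output: the low polarization (0.10) with high angular momentum
(0.84) identifies the torus; the DMD spectrum is dominated by slowly
decaying low-frequency modes (the 0.105 Hz line is the group's rotation
timescale); and the spectral-kernel classifier separates the two synthetic
segment classes essentially perfectly (median cross-validated error 0.000)
because their critical-distance dynamics differ by construction.

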