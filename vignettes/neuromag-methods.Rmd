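---
title: "neuromag: models, assumptions, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuromag: models, assumptions, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the forward
model and its assumptions, the parameters that matter, what the synthetic
generators emulate (and what they do not), the numerical choices, and the
design decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The forward model

A spiking neuron is represented as a tree of cylindrical compartments
(μm coordinates; the soma is a zero-length compartment whose radius is the
sphere radius). Two current systems are derived from a *prescribed*
intracellular potential and drive the two field modalities:

* **Longitudinal (axial) currents** `I_a` along each compartment source the
  extracellular magnetic field through the compartmental Biot–Savart sum.
  Only intracellular axial currents enter; extracellular return currents
  are neglected, which is adequate when the sensor standoff is small
  compared with the depolarization length.
* **Transmembrane currents** `I_m` at each compartment source the
  extracellular potential through the standard line-source closed form
  (zero-length soma falls back to a point source), with the reference
  electrode at infinity.

With the package's fixed unit system (μm, ms, mV, nA, S/m) the Biot–Savart
prefactor μ0/4π is exactly 100 pT·μm²/(nA·μm) and the potential prefactor
is 1000/(4πσ_e) μV·μm/nA; no other unit constants appear anywhere.

**Assumptions.** Quasi-magnetostatics (fields follow currents
instantaneously); purely resistive, homogeneous, isotropic extracellular
medium (no frequency-dependent tissue filtering); membrane currents
confined to the compartment line; no ephaptic coupling between cells
(fields superpose linearly — an invariant the tests check to 1e-12).

### The traveling-wave substitute for biophysics

Real simulations obtain currents from conductance-based models. Every
analysis in scope depends only on the *geometry* of the currents, not on
channel kinetics, so the package instead prescribes the intracellular
potential as a traveling wave of path distance `s` from the soma,
φ_i(s, t) = φ_m(s − s₀ − v·t). Axial current follows from the
core-conductor conductance g = σ_i π r²/L and transmembrane current from
Kirchhoff's law at each node, so ΣI_m = 0 holds *by construction* at every
time step. Defaults: conduction velocity v = 500 μm/ms, σ_i = σ_e =
0.3 S/m (conductivities are not dictated by the analyses; both are
configurable), and s₀ chosen so the wave peak sits at half the maximum
path length at the middle of the 7 ms window — the classic mid-axon
snapshot.

Two waveforms are provided. `gaussian_ap(sigma = 167)` is the canonical
symmetric Gaussian depolarization used for all scaling and sign-structure
analyses. `asymmetric_ap(sigma, skew = 3)` is a piecewise Gaussian with a
slow trailing edge; physiological action potentials depolarize much faster
than they repolarize, so the forward current lobe dominates the reverse
one. The polarity-based reconstruction fixtures use it, because with a
perfectly symmetric wave the sign of a sensor's largest sample is a coin
flip between the equal-magnitude forward and reverse lobes — a degeneracy
real cells do not have.

## 2. Multipole scaling and its null planes

For the infinite-cylinder model the two source densities are the first and
second derivative of φ_m(z). A unimodal φ_m therefore gives exactly one
sign reversal for the longitudinal current and two for the transmembrane
current; the fields they source decay as 1/R³ (dipole) and 1/R⁴
(quadrupole; 1/R³ for the potential at an infinite reference).

One geometric subtlety matters for reproducing the exponents numerically:
the perpendicular bisector through the wave centre is the exact *null
plane* of the dipolar azimuthal field (the opposing current lobes cancel
there), and likewise the quadrupole angular factor 3cos²θ−1 vanishes at
θ ≈ 54.7°. `cylinder_scaling_exponents()` therefore evaluates along a ray
45° from the axis, where both angular factors are bounded away from zero,
and fits log|field| against log R over 10σ–100σ. The recovered slopes
(≈ 3.00 for |B|, 2.96 for φ, 3.99 for |∇φ|; recomputed by the acceptance
report) are insensitive to the ray angle except near the null planes.

Degenerate inputs: grids must be uniform (non-uniform spacing errors out);
evaluation points within 0.1 μm of a source raise a singular-evaluation
error rather than clamping — all in-scope sensor geometries guarantee a
≥ 5 μm standoff, so silent clamping would only ever hide a configuration
bug.

## 3. Templates, similarity, and the effective radius

A spike template is the N_R × N_T matrix of one modality on one sensor
array over one spike (defaults: 224 steps of 31.25 μs). Rotating a
template resamples it at sensor coordinates rotated by −θ using the K = 5
nearest samples, inverse-distance weighted; the weights are a convex
combination (they sum to 1) and an exact coordinate match short-circuits
the division. The printed form of that interpolation rule divides the
already-normalised sum by K once more, which uniformly scales values by
1/K — irrelevant inside cosine similarities but not for absolute field
values. The default follows the normalised convex combination;
`divide_by_k = TRUE` reproduces the printed formula. Planar components mix
as vectors under rotation ((B_x, B_y) → rotated pair), which is why
rotating a planar template requires its orthogonal partner; B_z and φ
transform as scalars.

The sweep operator averages rotations over θ = 0, 15°, …, 345°; the
similarity between cells n and m at displacement Δr is the Frobenius
cosine between M_n and the translated spread template of m, with the
translation factored out of the rotation integral (valid in the
fine-pitch limit; translations snap to the sensor grid). The effective
radius at threshold γ is the radius of the disc with the same area as the
region where similarity exceeds γ — the operational pairwise resolution
limit.

**Desk scale.** The reference analyses used arrays of 1500×1500 sensors at
2 μm pitch; that object is ~40 GB per template and is memory-prohibitive
in CI. Tests and examples run on 40×40 to 60×60 grids at 10 μm with the
same displacement grids (±400 μm @ 50, ±200 μm @ 20). Consequently only
*orderings* (φ similarity above B_z; B_z effective radius below φ's) are
asserted, never the published absolute radii, which additionally depend on
morphologically detailed reference cells that this package deliberately
does not ship.

## 4. Population discrimination

Channel matrices stack flattened templates (full 224-sample windows; no
peak-aligned cropping) of randomly placed, randomly oriented cells as
columns, after per-modality power equalisation (section 6). The condition
number σ_max/σ_min measures how well simultaneous sources can be
separated; σ_min < 1e-12·σ_max returns an `Inf` sentinel. Populations
default to the stated cortical surface density of 340 cells/mm² scaled to
the array area.

The bootstrap capacity estimator is this package's own definition (the
reference procedure is underspecified): resample condition numbers within
each cell count, interpolate mean −log10(condition) linearly across cell
counts, take the largest count at or above threshold, and report the
median over replicates (default 1000, seeded). −log10 of the `Inf`
sentinel is capped at −16 so one degenerate draw cannot poison a
replicate mean.

## 5. Synthetic morphologies: what they emulate

`make_ball_stick()` is the canonical validation cell: 20 μm soma, 1 mm
axon of 2 μm diameter in 0.5 μm segments, along +x. Its defaults stay a
uniform cylinder.

`make_branched_cell()` is the stand-in for elongated layer-V pyramidal
geometry: one dominant tapered trunk along +x plus a few minor processes,
the first of which always opposes the trunk (180° ± 20°) — the
configuration whose opposing longitudinal currents invert nearby B_z
polarity and motivate the CNBE second pass. Two physiological features are
on by default and were frozen before the acceptance measurements:

* **distal taper** (proximal:distal diameter 3:1): axial current scales
  with r², concentrating signal power toward the soma;
* **hillock thickening** (radius ×2.5 decaying over 50 μm): the axon
  initial segment is the strongest magnetic source in real cells, and the
  hillock-localisation step of CNBE presumes exactly that. Without it the
  per-sensor power peak sits roughly one sensor pitch inside the process
  (a pure end effect of the lateral field kernel) and the CNBE cut line
  eats into the trunk.

What the generators do **not** emulate: dendritic arborisation beyond
straight processes, 3-D curvature (cells are planar before suspension at
15 μm), conduction failure and branch-point delays, biophysical channel
gradients, and cell-to-cell morphological variability beyond branch angles.
A green directional test on these fixtures therefore establishes that the
*mechanism* (multipole order, polarity structure) produces the claimed
ordering — not that the published effect sizes transfer to real cells.

## 6. Recordings and noise

Poisson trains draw per-cell rates from N(5, 1) Hz truncated at 0.1 Hz
(the normal law has mass below zero; the truncation point is the package's
choice) and delete spikes violating the 2 ms refractory period, keeping
the earlier spike. Templates are added at spike samples; spikes overrunning
the recording end are truncated and counted.

Because volts and teslas are numerically incommensurable, magnetic
modalities are rescaled so the highest-power magnetic component matches
the (never rescaled) potential's mean-square power, with a single common
factor preserving B_x:B_y:B_z ratios; the operation is idempotent and
exact to 1e-9 relative. Thermal noise uses the Johnson formula
√(4k_B T R B) at T = 300 K by default; the quoted 7.35 μVrms for 100 kΩ
over 32 kHz implies T ≈ 306 K, so the package's 300 K value reproduces
7.28 μVrms — the formula, not the printed rounding, is authoritative here.
Bandwidth rescaling is the white-noise √(B₂/B₁) rule (7.1 μVrms over
300 Hz–10 kHz → 12.9 μVrms at 32 kHz).

Spike-train agreement uses greedy one-to-one unit pairing maximising
matched-spike counts within 1 ms, accuracy TP/(TP+FP+FN), and
well-detected = accuracy > 0.8. The greedy matcher is this package's
definition; reference pipelines delegate to an external comparison
framework.

## 7. Polarity-boundary reconstruction

`sensor_polarity()` labels each sensor by the sign of its largest-|value|
sample (chosen over the time-mean sign for noise robustness; zero
waveforms are excluded). GNBE fits a soft-margin RBF-kernel SVM — solved
as the standard dual QP with quadprog — on positions vs. labels and
extracts the zero level-set of the decision function on a 4×-densified
grid; the longest contour is the boundary. Defaults the reference left
unrecorded: kernel scale 2× pitch, cost C = 1, and per-sensor slack
weights (power/max power)^0.25 so that sensors whose waveform is
noise-dominated cannot drag the boundary (set `power_weight = 0` for the
plain SVM). The bias is found by minimising the weighted hinge loss
directly, which stays stable when almost all dual variables sit on their
(tiny) box bounds. The boundary is invariant to positive rescaling of the
template, and label negation leaves it unchanged up to solver precision.

CNBE refines the first pass near the soma: hillock = power-weighted
centroid of the 4 strongest sensors; the next 96 sensors in 24 groups of 4
yield centroids snapped to the first-pass boundary; outliers (mean
distance to 4 nearest neighbours > 50 μm) are dropped; a weighted line fit
(hillock weight 50×, configurable — no reference value exists) sets the
process direction; sensors behind a perpendicular cut 10 μm behind the
hillock are excluded and the boundary re-estimated. Arrays under 100
sensors use proportional ranks. If every candidate point is discarded, or
the exclusion leaves a single polarity, CNBE falls back to the first pass
with a warning rather than fabricating a boundary.

Reconstruction error is the mean over dominant-process segment midpoints
(projected to the array plane) of the distance to the boundary polyline;
midpoints rather than densely resampled segments are the package's choice
(segments are ≤ 10 μm in the fixtures, so the difference is below any
tolerance used). The error-vs-path-distance profile supports the
near-soma analyses.

## 8. Numerical choices and tolerances

* Finite differences: second-order central (one-sided second-order at the
  boundaries); the convergence test asserts observed order ≥ 2.
* Sign counting skips samples below 1% of the peak magnitude (float dust).
* Current conservation: |ΣI_m| ≤ 1e-6 of the peak |I_m| (exact by
  construction for propagated waves; the discretised analytic profile has
  its monopole residue subtracted).
* Condition-number sentinel at 1e-12 relative; SVM dual jitter 1e-8·n.
* Translation deltas snap to the grid with a warning beyond 1e-9 pitch
  units.
* Experiment configs are schema-validated (missing fields reported by
  dotted path); every stochastic sub-operation receives a seed derived
  from the top-level seed, and reruns are byte-identical.

## 9. Known limitations

The package does not run a spike sorter (it generates recordings and
evaluates any sorter's output), does not model probe-shank geometry beyond
rejecting intersecting segments, does not reproduce absolute published
effect sizes that require morphologically detailed reference neurons, and
its boundary estimators presume a dominant elongated process — cells
without one (stellate, anaxonic) have no single boundary to estimate, and
the methods are expected to fail gracefully rather than meaningfully
there.
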