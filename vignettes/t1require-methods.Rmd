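---
title: "Internal-reference T1 mapping: models, calibration, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-reference T1 mapping: models, calibration, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1require)
```

## The estimation problem

A T1-weighted image encodes T1 contrast through a known signal equation, but
multiplied by an arbitrary scanner gain and, for spin echo, modulated by T2
decay and proton density. The idea of internal-reference calibration is that
healthy gray matter, white matter and CSF are always present in a brain
scan and have well-characterized relaxation values at 3&nbsp;T, so their mean
intensities pin down the unknown gain; once the gain is known, the signal
equation can be inverted voxel by voxel. The method is deliberately
retrospective: it consumes an existing weighted image plus its tissue
segmentation and produces an *estimate* of quantitative T1, trading the
accuracy of prospective relaxometry for applicability to archived and
multi-site data.

The key modelling assumptions are:

* the gain is spatially constant within the fitting unit (one axial slice
  for spin echo, the whole volume for MPRAGE), while T1 varies voxel to
  voxel;
* reference tissues in the scanned brain actually have the literature
  relaxation values (the method is calibrated *to* those values, so
  systematic deviation in a patient shifts the whole map);
* for spin echo, T2 and proton density can be replaced by per-tissue
  literature constants; the error this introduces is quantified below;
* for MPRAGE, transverse decay at the echo time, readout imperfections and
  B1 inhomogeneity are neglected, and the receive factor `sin α` is absorbed
  into the fitted scale.

## Signal models

**Spin echo.** `S = k ρ (1 − e^(−TR/T1)) e^(−TE/T2)`. The T2/ρ correction
multiplies each brain voxel by `e^(TE/T2_ref)/ρ_ref` of its tissue class,
yielding `S_T1 = k (1 − e^(−TR/T1))`, which inverts analytically. CSF's T2
is so long (1447&nbsp;ms against TE = 10&nbsp;ms) that its echo-decay factor
is effectively 1; using the literature value directly implements this.

**MPRAGE.** The sequence cycle is inversion → wait `TI` → `N` spoiled
gradient-echo readouts with flip `α` spaced `TR` → recovery `Trec`. Writing
`E1 = e^(−TR/T1)` and `q = cos α · E1`, one readout block maps longitudinal
magnetization as `M → M0(1 − E1) + qM`, so the train is a geometric sum and
the periodic steady state is the fixed point of an affine map, solved in
closed form. The image contrast is taken at the center of k-space, readout
index `⌊N/2⌋ − 1` (configurable). We validate this closed form against an
independent oracle that simulates the recursion step by step until
convergence; the suite asserts agreement to better than 0.1% (the two are
in fact indistinguishable at double precision) over T1 from 400 to
4000&nbsp;ms for all built-in presets, and the
center-of-k-space signal is strictly decreasing in T1 over 1–5000&nbsp;ms
for every preset, which guarantees a unique table inversion.

**Look-Locker reference.** The apparent recovery sampled at multiple
inversion times follows `S(TI) = A − B e^(−TI/T1*)` (the decaying-exponential
convention; a growing exponential diverges and cannot describe recovery),
and the repeated readouts make `T1*` underestimate T1; the standard
correction is `T1 = T1*(B/A − 1)`, with `B/A ≤ 1` flagged unphysical.

**Error propagation.** Differentiating the spin-echo model in T1 and in T2
and equating the relative signal perturbations gives
`δT1/T1 = TE · δT2 · T1 (e^(TR/T1) − 1) / (TR · T2²)`. At TR = 525&nbsp;ms,
TE = 10&nbsp;ms this evaluates to ≈5.6% for average gray matter and ≈8.8%
for white matter under a 50% T2 error — the quantitative justification for
fixing T2 at literature values. `scripts/acceptance.R` recomputes both, and
a test confirms the closed form against a finite-difference perturbation of
the full model.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `TR`, `TE` (spin echo) | 525, 10 | ms | the validated acquisition protocol |
| MPRAGE `TR, TE, α, TI, Trec, N` | 8, 2.89, 9°, 358, 400, 176 | ms/deg | single-site MPRAGE protocol; six multi-scanner presets via `scanner_presets()` |
| reference T1 (GM/WM/CSF) | 1331 / 832 / 2500 | ms | 3 T literature means; CSF pinned at 2500 ms (literature spans 2000–4000+) to preserve GM–CSF contrast |
| reference T2, ρ | 110, 79.6, 1447 ms; 0.807, 0.679, 1 | ms, — | 3 T literature means |
| `sigma` (correction smoothing) | 2 | voxels | in-plane Gaussian on the T2/ρ factor field; see resolution caveat below |
| `min_voxels` | 50 | voxels | minimum per-tissue count for a slice to be calibratable; small enough to keep most slices, large enough for stable means |
| `clamp_max` | 5000 | ms | voxels inverting beyond it are *invalidated*, never silently clamped |
| LUT range / step | 1–5000 / 1 | ms | step bounds the inversion error at 0.5 ms, negligible against noise |

## The digital phantom

`make_phantom()` builds nested ellipsoids — CSF shell, cortical GM ribbon,
WM core, two ventricle-like CSF bodies — filling ~90% of the grid, so that
≥80% of labeled axial slices carry at least 50 voxels of each reference
tissue (asserted in the suite at 32³ and 64³), which is what the slicewise
spin-echo rule needs. Per-voxel T1/T2/ρ are drawn from truncated normals (±3σ, keeping
values physical) at the literature means with `heterogeneity` scaling the
literature standard deviations; `heterogeneity = 1` is the study condition,
`0` gives the exact-recovery fixtures. CSF T1 and ρ have no literature σ in
the reference table and stay fixed, so a fully heterogeneous phantom still
has an atom-valued CSF distribution — relevant when interpreting
distributional statistics (a Kolmogorov distance between two maps jumps to
the CSF mass for arbitrarily small shifts of that atom).

Simulators evaluate the forward models voxelwise and add seeded Gaussian
noise scaled to the mean in-head signal (Rician optionally; Gaussian keeps
the fits unbiased, which is what estimator tests need). The MPRAGE
simulator applies a *global* `M0`, matching the calibration's model: real
proton-density variation across tissues is deliberately not simulated for
that sequence, since the whole-volume fit could not absorb it and the
phantom is meant to test the algorithm under its own assumptions. What
passing phantom tests therefore show is internal consistency, calibration
correctness, gain invariance and noise behaviour — not robustness to
segmentation error, partial-volume mixing, B0/B1 fields, or patients whose
reference tissues deviate from literature values; none of those are
modelled.

Problem sizes used throughout the suite are the package's validation
choices: 64³ phantoms for round-trip and multi-scanner experiments, 32–48³
for unit-level checks, 1000 replicates for estimator-bias Monte Carlo, 500
voxels for the Look-Locker noise study.

## Numerical choices

* **Gain fits are closed-form.** Both `k` (spin echo) and `M0` (MPRAGE)
  enter their models linearly, so the least-squares solutions are exact
  projections (`k = Σ s_i f_i / Σ f_i²`); tests confirm an iterative
  optimizer lands on the same values. This removes convergence failures
  from the per-slice loop entirely.
* **Look-Locker fitting uses variable projection.** For fixed `T1*` the
  model is linear in `(A, B)`; the 1-D profile over `T1*` is minimized by a
  geometric coarse grid (64 points, 30–10000 ms) plus golden-section
  refinement (60 iterations, bracket ~1e−12). This is the same least-squares
  minimum a Levenberg–Marquardt fit finds (cross-checked against
  `minpack.lm` in the tests) but vectorizes over ~1e5 voxels. Magnitude
  data lose polarity; it is restored by brute force over the sign-flip
  index, keeping the candidate with minimal residual (ties go to the fewest
  flips). Degenerate voxels (constant signal, `B/A ≤ 1`, non-finite
  results) are flagged invalid rather than reported.
* **Lookup-table inversion** interpolates the inverse linearly; signals
  outside the tabulated range are invalid. If a parameter set ever made the
  signal non-monotone, the builder would restrict to the largest monotone
  subrange — and errors out if that subrange fails to cover 400–4000 ms;
  for the built-in presets monotonicity holds over the full 1–5000 ms
  table, so the fallback never triggers.
* **Morphology** (mask closing, hole filling) uses 6-connected binary
  operations written directly on arrays; closing guarantees the brain mask
  contains the tissue union.
* **Invalid voxels are first-class.** Every pipeline returns a validity
  mask; out-of-model signals (`S_T1 ≥ k`, signals beyond the LUT, fits with
  `B/A ≤ 1`, T1 beyond `clamp_max`) are excluded from every downstream
  statistic rather than clamped.

## Open design choices and their resolution

* **Per-slice versus global gain (spin echo).** The gain is fitted per
  axial slice, which absorbs slow B0-related intensity variation along the
  slice axis at the cost of requiring all three tissues per slice. MPRAGE
  uses one whole-volume fit and has no such requirement — an intentional
  asymmetry reflecting how each sequence is used.
* **Regression direction.** `compare_maps(A, B)` regresses B on A with A
  the reference method; the convention is documented and configurable by
  swapping arguments. Lin's concordance uses population (1/n) moments per
  its standard definition; a sample-moment variant is available.
* **Smoothing scale is resolution-dependent.** The correction field is
  smoothed in-plane to soften hard segmentation boundaries. The kernel must
  stay narrower than the thinnest structure: on phantom-scale grids, where
  the CSF shell is only a few voxels thick, a 2-voxel σ mixes GM and CSF
  factors across the shell and visibly biases the CSF median, so
  phantom-scale analyses use `sigma = 1` while the default stays 2 voxels
  for ~1 mm clinical grids. This is a known limitation of hard-boundary
  correction fields generally.
* **Effective range.** The ±10% band condition on a regression line is
  solved exactly from the two band-edge intersections and intersected with
  (0, 3000] ms, the analysis ceiling; a brute-force scan over a 1 ms grid
  verifies the algebra in tests.
* **Readout index.** Image contrast is attributed to the center of k-space,
  `⌊N/2⌋ − 1`; presets with an odd number of phase-encoding steps floor the
  index. The index is exposed for sequences reordered differently.

## Known limitations

Beyond the simulator gaps listed above: the method inherits any bias in the
segmentation (probabilistic maps are hardened by argmax with a 0.5 floor);
calibration to fixed reference values means global pathology shifts the
map's scale rather than being detected; the spin-echo slicewise rule leaves
apex and skull-base slices unconverted; and the MPRAGE signal model ignores
T2* decay, which is a deliberate modelling choice, adequate at short echo
times.
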