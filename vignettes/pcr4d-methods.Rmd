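---
title: "Simulating scanned carbon-ion delivery to moving lung tumors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating scanned carbon-ion delivery to moving lung tumors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package simulates

Scanned carbon-ion therapy delivers dose as thousands of narrow pencil
beams ("spots"), magnetically scanned across iso-energy layers.  When
the target moves with respiration, the moving anatomy and the moving
beam spot interfere — the *interplay effect* — producing hot and cold
spots inside the target that neither a static calculation nor a simple
margin can predict.  Two countermeasures are simulated here:

* **Phase-controlled rescanning (PCR):** each iso-energy layer is
  scanned *n* times at a dose rate tuned so the n passes exactly span
  one respiratory window, averaging each spot's dose over the breathing
  cycle.
* **Respiratory gating:** the beam is only on during the quiescent
  peri-exhalation phases (T40–T60 of a ten-phase cycle), shrinking both
  the residual motion and the treated volume.

The package generates synthetic ten-phase breathing lung phantoms with
known ground-truth deformations, plans fields on WEPL-envelope target
volumes, simulates the timed delivery event by event, accumulates dose
at the reference exhale phase (T50), and reports the standard plan
metrics: CTV D95 / Dmax / Dmin, the homogeneity index
HI = 100 · SD(CTV voxel dose) / prescription, lung V20, OAR doses, and
total delivery time.

# The synthetic 4D phantom

Real inputs of such a study — patient 4DCTs with delineated structures —
cannot be redistributed, so the phantom module generates a stylized
thorax analytically: an elliptic-cylinder body (water-equivalent
density 1.0), two ellipsoidal lungs (0.3), a spherical tumor (1.0)
inside the left lung, a heart ellipsoid and a spinal-cord cylinder.
Patient axes are x = LR (+x patient left), y = AP (+y anterior),
z = SI; the default grid is 64 × 64 × 96 voxels at 2 mm (configurable —
the shipped analyses and tests use a coarser 3 mm desk-scale grid where
runtime matters).

**Motion.**  The tumor center displaces from its exhale rest position by
`w(phi) * A`, where `A` is the per-axis peak amplitude and
`w(phi) = cos^4(pi * phi)` with `phi` the phase fraction from peak
inhalation — a long quiescent exhale with a comparatively sharp inhale
excursion, the standard single-parameter respiratory waveform (a
sinusoid is selectable).  Default amplitudes are the clinical cohort
averages, 1.4 × 2.2 × 7.2 mm LR × AP × SI with a 3.8 s period; cohort
studies draw amplitudes and periods from the observed clinical ranges
(SI up to ~22 mm, periods 2.7–5.5 s).

**Deformation.**  The displacement field is a windowed translation
around the tumor: rigid within a core radius (GTV + 4 mm), tapering
smoothly (raised cosine) to exactly zero on an anisotropic ellipsoid
(default semi-axes 34 × 34 × 70 mm), which lies inside the chest wall.
Three properties motivated this choice over a generic Gaussian window:
the tumor translates rigidly, so the generated center-of-mass excursion
*equals* the requested amplitude; the displacement is exactly zero at
the deformation extent and the chest wall; and the forward map
`x = r + u(r)` remains a contraction at clinical SI amplitudes, so it
is invertible by fixed-point iteration (tolerance 10⁻³ mm).  A
configuration whose contraction bound reaches 0.95 is rejected rather
than silently folded.  Phase anatomies are pull-backs of the analytic
rest geometry — densities are advected, not resampled, so T50
reproduces the rest geometry bit for bit and total "mass" varies by
less than 2% across phases.

Each phase stores its ground-truth phase-to-reference displacement
field.  This deliberately replaces deformable image registration: with
known deformations, dose accumulation is exactly testable and any
observed target-dose degradation is attributable to delivery physics
alone, not to registration error.

The only randomness is a seeded jitter of the tumor position (± a few
mm), which differentiates phantom realizations in cohort studies;
phantoms are bit-identical for identical parameters and seed.

**Phase semantics.**  Anatomy is piecewise constant within each of the
ten phase bins (time binning assumed): the tumor is static within a
phase and jumps at bin boundaries, the same assumption 4DCT-based
simulation studies make.

# WEPL ray tracing and field-specific target volumes

Carbon beams stop at a water-equivalent depth, so target coverage must
be guaranteed in WEPL space per beam direction.  Rays are traced in
parallel-beam geometry (no source divergence — second-order at lung
depths) with exact voxel-boundary (Siddon-style) integration; the
per-ray cumulative WEPL is exact for piecewise-constant densities, and
the test suite checks it against fine-step quadrature.

For each beam port, CTV masks of the selected phases (gated: T40–T60;
ungated: T00–T90) are traced on a 1 mm lateral raster.  Per ray, the
proximal bound is the *minimum* over phases of the WEPL at CTV entry
and the distal bound the *maximum* at CTV exit; rays that never cross
the CTV are excluded.  This is the field-specific target volume (FTV):
by construction the gated FTV is contained in the ungated one, and
adding phases can only grow the envelope.  WEPL clipping is per ray
(whether curved distal edges should be regularized per region is left
open in the underlying method; per-ray is implemented).

# Beam model and spot-weight optimization

The dose engine is a deliberately simple pencil-beam superposition —
enough structure to exercise interplay mechanics without institutional
beam data:

* lateral kernel: Gaussian with σ = penumbra / (2 Φ⁻¹(0.8)) =
  5.0 / 1.6832 ≈ 2.97 mm, constant with depth (a single printed
  penumbra value, no depth dependence available);
* depth profile vs (WEPL − layer range): proximal plateau at 0.35 of
  the peak rising over ~3 mm, distal Gaussian falloff σ = 1.5 mm —
  an asymmetric carbon-like pristine peak; all parameters
  configurable;
* layers every 3.0 mm WEPL, spots on a 2.0 mm lateral raster covering
  every ray whose envelope contains the layer range plus one raster
  ring, serpentine scan path;
* RBE: doses are treated as already RBE-weighted (identity); nonlinear
  RBE modelling is out of scope.

Spot weights are optimized per field by nonnegative least squares
(cyclic coordinate descent on the sparse dose-influence matrix,
deterministic and monotone) against a flat prescription over the FTV
voxels, then rescaled so the minimum FTV dose equals 95% of the
prescription — the "FTV enclosed by the 95% isodose line" normalization.
Multi-field plans optimize each field independently to
prescription / n_fields on its own FTV and sum.

Two numerical points deserve note.  First, the residual has a nonzero
floor (a perfectly flat dose is unattainable with fixed layers and a
smooth kernel), so convergence is declared when the residual norm stops
improving (relative improvement < 10⁻⁴ over a 10-sweep window; cap
5000 sweeps; hitting the cap is an error, not a silent return).
Second, on coarse (3 mm) grids parts of the FTV's curved distal rim
fall between 3 mm layers where only the 1.5 mm distal falloff reaches
them; the least-squares solution then boosts distal spots, and the
min-dose rescale can inflate the absolute dose scale (markedly so for
large-amplitude ungated envelopes).  This is an honest consequence of
the fixed global layer grid at desk-scale resolution — the comparative
results (gated vs ungated, n-trends, convergence ratios) are
unaffected, but absolute D95/Dmax values at 3 mm should not be
over-interpreted.

# Timed delivery and phase-controlled rescanning

Machine constants are the published ones: 420 ms range-shifter and
150 ms energy-change control times, scan speeds 100 mm/ms (SI) and
50 mm/ms (LR), travel between spots at the slower of the two axes.
The respiratory phase clock is global and perfectly periodic (the
stated assumption of the simulated treatments): t = 0 is T00 for
ungated and T40 — a gate opening — for gated delivery.

Per layer, a time window W is fixed and the layer dose rate is set so
that the n rescan passes (each delivering weight/n per spot, the path
reversing between passes) exactly fill W; each pass spans W/n.  Gated:
W is the gate-open duration (3/10 of the cycle) and each layer occupies
one gate, the energy change happening between gates.  Ungated: layers
run back to back separated by the energy-change time.

**The ungated window (a decision the method leaves open).**  Published
descriptions tie the PCR dose rate to "the gating window time" but do
not state the ungated per-layer policy.  A gate-window-equivalent
ungated budget (0.3 cycle) was tried first and rejected: each spot can
then only ever sample ~3 consecutive phases, so the ungated treatment
dose cannot converge to a planning dose whose spots are spread over
*all ten* phases — the central rescanning benefit disappears, which
contradicts the method's own reported behaviour.  The implemented
default is therefore one full respiratory cycle per ungated layer (the
original PCR idea: the "gating window" of an ungated delivery is the
whole cycle), under which per-spot phase coverage approaches uniform
and the treatment dose converges to the planning dose as n grows.  The
budget remains configurable (`base_layer_time_s`).

Two consequences are documented rather than hidden.  (1) With the
full-cycle window, the ungated schedule is necessarily *longer* than
the gated one for the same spot map (the gated schedule wastes 0.7
cycle per layer waiting but its beam-on window is 0.3 cycle), so the
clinical observation "gated delivery takes longer" is not reproduced —
within this timing model the observation is incompatible with the
convergence behaviour, and convergence was prioritized.  (2) Because
pass time is exactly cycle/n and the scan path reverses each pass,
pairs of passes see mirror-symmetric phases of the time-symmetric
cos⁴ waveform — at n = 4 a spot effectively samples ~2 distinct
anatomies, slowing convergence relative to patient data, whose
breathing has no such exact symmetry or cycle lock.  Residual
inhomogeneity at n = 4 therefore stays above 1.5× the planning HI at
the large (8–20 mm SI) amplitudes the acceptance study stipulates;
the trend (HI falling monotonically toward planning, most of the
improvement by n = 4) is reproduced.

Every scheduled dwell interval is apportioned to respiratory phases by
exact time overlap, giving a per-spot, per-phase weight-fraction matrix
whose rows sum to one (conserved to 10⁻¹²).  Gated events lie wholly
inside gates, so their fractions are supported on T40–T60 only.

# Dose accumulation and metrics

Per-phase doses (per-spot weights × phase fractions, computed on that
phase's density) are pulled back to T50 voxel centers: the stored
phase-to-reference displacement is inverted pointwise by fixed-point
iteration and the phase dose is sampled trilinearly — a deterministic
gather, matching the "transform phase doses to the reference phase"
formulation.  Pull-back warping does not conserve integral dose
exactly; on default phantoms the drift is asserted < 2%.  On a static
phantom the whole chain is exact: treatment dose equals planning dose
to ~10⁻¹⁴ relative, for every rescan number, strategy, and field count.

Metrics follow the clinical definitions: D95 from the exact empirical
dose distribution (no binning; exported DVH curves use 0.1 Gy bins),
raw voxel Dmin/Dmax (no D1/D99 surrogates), HI normalized by the
*prescription* (as defined, not by the mean CTV dose), lung V20 as the
percentage of lung voxels at or above 20 Gy(RBE).  Paired strategy
comparisons use a Wilcoxon signed-rank test with an exact
sign-enumeration null for n ≤ 15 and a tie-corrected,
continuity-corrected normal approximation above; the exact branch is
verified against R's reference implementation and against the closed
2/64 two-sided p for six uniformly positive differences.

# What the synthetic world does and does not establish

The phantom reproduces the *structure* of the clinical problem — lung
densities, WEPL-relevant heterogeneity, clinically scaled periodic
motion, gateable quiescent exhale — but not CT texture and noise,
hysteresis (different inhale/exhale paths), cardiac motion, irregular
breathing, or inter-fraction change.  Green tests therefore establish
that the *pipeline* is correct (oracle equivalences, conservation
laws, exactness limits) and that the *comparative physics* behaves as
reported: interplay shrinks monotonically with rescan number toward
the planning dose; gating improves single-rescan homogeneity and
strictly shrinks the FTV and lung V20 on every seed; multiple fields
average single-field interplay.  Absolute HI or D95 values at a given
n are model-scale quantities and are not comparable to patient
averages — the synthetic amplitudes (8–20 mm SI in the acceptance
cohort) deliberately exceed the clinical cohort mean (7.2 mm), and a
single idealized waveform replaces fourteen measured traces.

# Numerical choices, in one place

* WEPL integration: exact per-voxel segment lengths; profiles exact at
  breakpoints, linear in between.
* Deformation inversion: fixed-point, tolerance 10⁻³ mm, contraction
  bound checked at generation (reject ≥ 0.95).
* Optimizer: NNLS coordinate descent, plateau tolerance 10⁻⁴ over 10
  sweeps, cap 5000, influence-matrix entries below 10⁻⁹ dropped,
  lateral kernel truncated at 5σ.
* Zero-weight layers deliver nothing but still occupy their window;
  zero-dwell events at a window's closing boundary belong to the
  closing phase.
* D95 from order statistics (largest dose with ≥ 95% of voxels at or
  above it); ties handled by counting, not interpolation.
* All schedules, phantoms and optimizations are deterministic given
  the configuration and seed; there is no hidden RNG use.

# Known limitations

* The timing model cannot simultaneously reproduce ungated-convergence
  and gated-prolongation; see the delivery section.
* Coarse grids inflate the absolute dose scale of small gated fields
  (distal-rim coverage); use ≤ 2.5 mm voxels for absolute numbers.
* Single-structure spherical tumors only; no pleural attachment or
  irregular GTV shapes.
* Parallel beams; no nuclear halo or range-shifter scatter beyond the
  WEPL bookkeeping.
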