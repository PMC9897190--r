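---
title: "Four-tract tractography targeting: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-tract tractography targeting: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourtract)
```

## The problem

MR-guided focused-ultrasound (MRgHIFU) thalamotomy for essential tremor
ablates the ventral intermediate nucleus (VIM) of the thalamus — a target
invisible on conventional MRI. Landmark-based ("indirect") targeting places
the lesion by arithmetic on the anterior and posterior commissures (AC, PC),
which ignores individual anatomy; sensory and motor adverse effects arise
when the ablation reaches the medial lemniscus (ML) or corticospinal tract
(CST). Four-tract targeting instead delineates, by deterministic
tractography, the two components of the dentato-rubro-thalamic tract — the
decussating dDRTT (via the contralateral dentate nucleus, passing the
anterior margin of the red nucleus) and the non-decussating ndDRTT
(ipsilateral dentate, posterior red-nucleus margin) — plus the CST and ML,
and places the sonication target at the posterior confluence of the two DRTT
components while enforcing a safety margin from CST and ML.

This package implements that pipeline end to end — tensor fitting,
tensor-deflection tracking with the published parameter sets and rescue
cascade, AC-PC frame arithmetic, confluence targeting with margins, burn-in
overlays, and the cohort offset statistics — and ships a synthetic diffusion
phantom with known ground truth so every stage is testable without patient
data.

## Diffusion model and tensor fit

Signal follows the single-tensor model \(S_i = S_0 \exp(-b_i\,
g_i^{\top} D\, g_i)\). `fit_tensor_loglinear()` solves, per voxel, the
ordinary least-squares system \(\ln S_i = \ln S_0 - b_i g_i^\top D g_i\) for
the six unique elements of \(D\) and \(\ln S_0\). Choices worth knowing:

* **Unweighted (OLS) fit.** The simplest published estimator; exact on
  noiseless data, and easy for an independent oracle to reproduce bit-wise.
  No weighting, no robust reweighting (RESTORE-type estimators are out of
  scope).
* **Non-positive signals** are clamped to \(10^{-3}\) of the voxel's mean
  b0 signal before the logarithm, and such voxels are flagged
  (`fit_ok = FALSE`) rather than repaired silently.
* **No eigenvalue clipping.** Strongly negative eigenvalues
  (\(\lambda_3 < -0.1\,\lambda_1\)) flag the voxel but the tensor is kept.
* **Numerical-noise tensors.** A fitted tensor whose largest element is
  below \(10^{-10}\) mm²/s (orders of magnitude below any physiological
  diffusivity) is set to exactly zero: fractional anisotropy is
  scale-invariant, so solver residue would otherwise masquerade as
  anisotropy in perfectly uniform voxels.

Fractional anisotropy is computed from tensor invariants,
\(\mathrm{FA} = \sqrt{3/2}\,\sqrt{1 - 3\bar\lambda^2 / \lVert D\rVert_F^2}\),
which is algebraically identical to the eigenvalue form but exact in the
tensor elements. Eigenvalues come from the trigonometric closed form for
symmetric 3×3 matrices and principal eigenvectors from the projector
\((D-\lambda_2 I)(D-\lambda_3 I)\), vectorized across the half-million
voxels of a volume; near-isotropic voxels get a deterministic placeholder
direction (their FA is below any tracking threshold anyway) and the rare
anisotropic-but-degenerate voxel falls back to `eigen()`.

## Tensor-deflection tracking

`tend_step()` implements the deflection update
\[
v_{\text{out}} \propto f\,\hat e_1 + (1-f)\,
\mathrm{normalize}\big((1-g)\,v_{\text{in}} + g\,\hat D v_{\text{in}}\big),
\]
with \(\hat e_1\) sign-aligned to the incoming direction and \(\hat D\) the
tensor scaled by its largest eigenvalue. Defaults are \(f = \mathrm{FA}\)
and \(g = 1\) — standard tensor-deflection weighting; the source method
names the approach but not the weights, so these are package choices.

Propagation (`propagate_streamline()`) is bidirectional fixed-step Euler at
1.0 mm with nearest-neighbour tensor lookup — no interpolation. That choice
trades smoothness for bit-stable reproducibility and a trivially matched
oracle; with `tend_f = 1` the tracker coincides pointwise with plain
principal-eigenvector streamlining, which the test suite asserts to
\(10^{-9}\) mm. A direction terminates when the next position leaves the
grid, when FA at the next position falls below `fa_min`, when the turn
between successive step directions exceeds `max_angle_deg` — interpreted
**per step**, not per mm, matching common deterministic-tracker semantics —
or when total length would exceed `max_length_mm` (default 250 mm, a
generous runaway guard; the published settings specify only minima).

The published parameter sets are the defaults of `tracking_params()`
(FA ≥ 0.2, length ≥ 80 mm, angle ≤ 20°/step) and `fallback_params()`
(FA ≥ 0.11, ≥ 40 mm, ≤ 50°).

Seeding places one seed per seed-ROI voxel centre plus, with
`seeds_per_voxel = 9` by default, eight reproducibly jittered seeds within
±0.35 voxel per axis. A streamline is retained iff it reaches the minimum
length and passes within half a voxel diagonal of every include-ROI
(waypoint) mask.

## The four recipes and the rescue cascade

`tract_recipes()` encodes: CST — precentral seed, ipsilateral
cerebral-peduncle waypoint; ML — postcentral seed, dorso-lateral midbrain
waypoint; ndDRTT — ipsilateral dentate seed, ipsilateral red nucleus and
precentral waypoints; dDRTT — contralateral dentate seed, same waypoints.
When the dDRTT comes back empty, `build_tract()` applies the rescue cascade
in the published order: (1) re-examine the red-nucleus ROI — operationalized
as a one-voxel (26-connected) dilation, since the original manual
re-inspection has no algorithmic definition; (2) retry with the fallback
parameters; (3) substitute the combined motor ROI (precentral +
supplementary motor + premotor) for the precentral waypoint. The cascade is
restricted to the dDRTT: the source text discusses only that tract as hard
to delineate. `cascade_step` records which rung succeeded.

## Targeting

`acpc_frame()` builds the stereotactic triad from AC, PC and a mid-sagittal
point: anterior axis from PC toward AC, superior axis the orthogonal
component of the midline direction, lateral axis their cross product with
the treated side positive. Coordinates follow the treatment-planning
conventions: L from the mid-sagittal plane, A anterior of PC, S above the
AC-PC plane.

The indirect target is L = 14 mm, A = 25 % of the AC-PC length, S = +2 mm
(starting above the plane keeps the ovoid lesion from extending
inferiorly). With an enlarged third ventricle the target moves to
10.5 mm — the midpoint of the published 10–11 mm range — lateral to the
ventricle wall, and only ever *more* lateral than 14 mm, matching the
direction of the published correction.

`confluence_target()` operationalizes "most posterior confluence": within a
1.5 mm-thick axial slab (two tracking steps) centred at the target level,
both DRTT footprints are rasterized at 0.5 mm, dilated one cell,
intersected; the 8-connected intersection component with the most posterior
centroid wins. An empty intersection with an inter-bundle gap ≤ 2 mm falls
back to the midpoint of the closest approach pair; a larger gap is an
error. `enforce_margins()` then measures the minimum Euclidean distance to
all CST and ML streamline *points* — not burned masks, which read about
0.5 mm larger because of the burn-in inflation — and, if violated, walks
the candidate away from the nearest violating point in 0.25 mm in-plane
steps, constrained to the DRTT footprint, giving up beyond 3 mm of travel.
Plans are produced at S = +2 and +4 mm with a configurable margin
(2 mm default; some sites use 4 mm).

`target_offset()` reports the indirect-to-tract-target Euclidean distance
with the indirect S taken as 2 mm — the convention of the published case
table. (Pass `indirect_s = NULL` for the plain metric.)

## Burn-in overlays

`voxelize_bundle()` marks every voxel whose centre is within 0.5 mm of a
streamline segment — the inflation is the voxelization threshold itself
rather than a post-hoc dilation, mirroring the voxel-wise console
behaviour — plus the voxel containing each vertex, so a bundle always
covers itself. `compose_overlay()` writes the merged CST + ML object as a
black fill (volume minimum) and the merged DRTT object as a white contour —
its 6-connected surface voxels, since the console display shows an outline,
not a fill — drawn on top. Output is NIfTI: the console's DICOM burn-in
exists to smuggle tracts into planning software, whereas this artifact's
contract is the voxel content, so a research format is used and DICOM
export is out of scope. Contour thickness and intensities have no published
values; grid-surface and volume min/max are package choices.

## The synthetic phantom

`phantom_four_tract()` generates the study conditions: a 96×96×60 lattice
at 2.5 mm (240×240×150 mm field of view) aligned with the AC-PC frame
(AC = (0, 13, 0), PC = (0, −13, 0), so the AC-PC length is 26 mm), with a
32-direction b = 800 s/mm² protocol, S0 = 1000, four b0 volumes and
optional Rician noise through two Gaussian channels with a mandatory seed.
Four curved bundles reproduce the relative anatomy: CST through the
cerebral peduncle and posterior limb, ML posterior to it, and the two DRTT
components flanking the red nucleus (anterior/posterior margins, 9 mm
apart) before converging to parallel courses — dDRTT anterior — through the
VIM region at S = 0–16 and on to motor cortex. Tubes have radius 4 mm,
FA 0.7 and mean diffusivity 0.8×10⁻³ mm²/s (background 0.7×10⁻³);
centerlines are natural cubic splines through control points,
chord-parameterized and resampled at uniform arc length, and in-bundle
tensors are axially symmetric with the eigenvalue pair that reproduces the
target FA and mean diffusivity exactly. Overlapping tubes resolve by
nearest centerline.

Several geometric choices are consequences of that overlap rule on a
2.5 mm lattice and are worth recording:

* a single-tensor voxel cannot represent a crossing, so the dDRTT/ndDRTT
  cores never approach closer than 2 mm, and the decussation region keeps
  them far apart;
* where the two DRTT tubes overlap, their tangents must differ by less
  than the 20° per-step stopping rule, or streamlines crossing a claim
  boundary die. The phantom therefore lets the components share their
  lateral motion while converging (the shared component keeps the mutual
  angle near 10°) and completes the convergence below the S = +2 slab;
* the ascent-to-lateral turn at the red nucleus is spread over more than
  10 mm of arc so that per-voxel tangent jumps stay under the angle rule;
* seed ROIs are small spheres at bundle endpoints: the tube radius minus
  half a voxel diagonal bounds the seed offset that can survive
  nearest-neighbour lookup over a 130 mm course, and keeping retained
  streamlines within ~2 mm of truth is what makes ROI waypoints and
  footprint geometry meaningful at this resolution.

ROI masks (dentate nuclei, red nuclei, cerebral peduncle, dorso-lateral
midbrain box, pre/postcentral, supplementary motor, premotor, combined
motor, third-ventricle walls, AC/PC landmark spheres) are analytic spheres
and boxes on the tracking grid, with all geometry recorded in
`phantom$roi_table` — the source ROIs are hand-drawn, so the phantom fixes
them explicitly. Two variants exercise the cascade: `low_fa_decussation`
drops the dDRTT decussation-segment FA to 0.15 (between the 0.2 default
and 0.11 fallback thresholds, so the tract vanishes at cascade steps 0–1
and reappears at step 2), and `ddrtt_premotor` reroutes the dDRTT cortical
ending into the premotor ROI (recoverable only by the combined motor ROI,
step 3).

What the phantom does *not* emulate: crossing-fibre voxels,
susceptibility/eddy distortion, partial-volume gradients at tissue
interfaces, anatomical T1/T2/FGATIR contrast, and realistic cortical
geometry. Passing tests therefore demonstrate the correctness of the
algorithms under the stated model, not clinical performance on patient
data.

## The bundled case table

`table1_cases()` ships the published 18-case comparison of indirect and
tractography-based targets. `cohort_report()` recomputes each case's
Euclidean offset under the table's stated convention (indirect S = 2 mm),
rounds as the table does (2 decimals per case, 1 decimal for cohort means,
sample SD with n − 1), and runs paired t tests on the anterior and lateral
coordinates. Three rows (16–18) carry provenance notes: their printed
distances are not reproducible from their printed coordinates under the
stated convention (two match an S = 0 computation truncated to 2 decimals;
one matches neither), so the report carries both the recomputed and the
printed values and flags the disagreements rather than silently correcting
either. The printed cohort mean (1.80 mm) also differs in the second
decimal from the mean of the printed column (1.77) — likely computed from
unrounded coordinates — which is reported, not reconciled. One case has no
second target, so second-target statistics use n = 17.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
native phantom size (552 960 voxels, 36 volumes, ~50 streamlines): the
vectorized fit and eigensystem make that a seconds-scale computation, so no
scaled-down surrogate is needed. Every stochastic step (noise synthesis,
seed jitter) takes an explicit integer seed, and the end-to-end pipeline is
byte-deterministic for a fixed configuration — `run_pipeline()` rerun with
the same seed reproduces `plan.json` exactly, and provenance (config hash,
parameters, cascade steps) is written next to every result.

## Known limitations

* Nearest-neighbour lookup makes streamlines drift outward on curves
  (Euler + piecewise-constant tangents); the phantom's retention criteria
  absorb this, but real-data use would typically want trilinear
  interpolation, which is deliberately not implemented here.
* The single-tensor model cannot represent the actual dDRTT/ndDRTT/CST
  crossings of real midbrain anatomy; the phantom's geometric work-arounds
  (above) are honest about this.
* The margin search moves the candidate only in-plane and gives up at
  3 mm; a clinically tight phantom can therefore legitimately fail with a
  margin-infeasible error, which callers should treat as a planning
  outcome, not a bug.
* Inputs are assumed co-registered; registration and distortion correction
  are upstream, out-of-scope steps.
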