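---
title: "Benchmarking metal artifact reduction for particle-therapy CT: models and methods"
author: "marbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking metal artifact reduction for particle-therapy CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`marbench` evaluates how much an iterated NMAR+FSMAR metal artifact
reduction improves carbon-ion treatment-planning quantities — CT numbers,
water-equivalent path length (WEPL), and dose — on a synthetic pelvic
phantom with hip implants, against the artifact-free ground truth that a
physical experiment obtains by scanning the phantom without implants. This
vignette explains each model in the chain, the tunable parameters with
their defaults and units, the numerical choices, and what the synthetic
setting can and cannot say about real data.

## The digital phantom

`defaultPhantom()` describes a pelvis-scale scene as analytic shapes
rasterized by centre-of-voxel inclusion: an elliptical body (fat rim + soft
tissue), a sacrum, two hip bones and two femoral heads (cortical shell with
trabecular core), a gel-filled bladder-like cavity, a gas-filled
rectum-like cavity, a central prostate-like PTV and a lateral sarcoma-like
PTV near the implant side. The implant replaces a femoral head's interior
with a 40 mm metal disc, leaving a cortical rim — so the benchmark retains
a periprosthetic-bone region, the place where MAR corrections are known to
struggle. `mirrorImplant()` reflects the implant across the midsagittal
plane to produce the bilateral configuration; voxel centres are symmetric
about the midline, so the mirrored rasterization is exact.

Slices are identical in shape and stacked (default 10 slices of 2 mm,
matching a typical pelvic protocol's slice thickness) so that volume-based
metrics such as D_1cc are meaningful; the default in-plane grid is
256 × 256 at 2 mm. The ground-truth HU image is the per-voxel material mean
plus seeded Gaussian noise with a per-material SD.

Material CT numbers (air −1000, fat −100, soft tissue 40, gel 20,
trabecular bone 300, cortical bone 1200, metal 8000 HU; noise SDs 5–50 HU)
are plausible stand-ins chosen to be consistent with the calibration
curve's anchor tissues — no physical phantom's values are asserted — and
everything is configurable through `materialTable()`. The one structural
requirement is that the metal mean sits far above the segmentation
threshold (3000 HU) and cortical bone far below it.

What the phantom does *not* emulate: realistic pelvic anatomy (organs are
ellipses), bone texture, partial-volume mixtures at interfaces (shapes are
rasterized binarily), patient-to-patient variation, and positioning
differences between the with- and without-implant "scans" (our scenarios
are perfectly co-registered by construction, where the physical experiment
needed image registration). Passing the benchmark therefore demonstrates
that the correction chain removes the modelled artifact physics on
pelvis-like geometry — not that it reaches clinical-grade performance on
real anatomy.

## CT acquisition and reconstruction

Acquisition is parallel-beam: equispaced view angles over 180°, line
integrals computed by midpoint quadrature with bilinear interpolation
(compiled code; step = half a detector bin). A fan-beam geometry would be
closer to a clinical scanner but adds nothing to the artifact mechanism —
streaks arise and are corrected in the same way — so the simpler geometry
was kept, with the geometry arguments isolated so the projector pair could
be swapped later.

Metal corruption applies, in order:

1. **beam hardening** as a quadratic penalty on the metal-only line
   integral, `p' = p − β · p_metal²` (β unitless, default 0.01). A single
   parameter stands in for polychromatic spectra; because the penalty is
   quadratic, rays crossing *both* implants (p_metal roughly doubled) are
   hit about four times harder than single-implant rays, which is what
   concentrates the characteristic dark band between bilateral implants;
2. **photon starvation**: Poisson counting noise on `n0 · exp(−p')`
   (default n0 = 10⁷ counts) with a detector floor of ε counts (default 5)
   before log conversion. The floor caps measurable line integrals at
   `log(n0/ε) ≈ 14.5`; rays through two implants exceed that, so their
   signal saturates and the reconstruction shows the deep dark band and
   noise streaks seen clinically with bilateral prostheses, while
   single-implant rays (a few hundred counts) stay only mildly corrupted.

These three numbers are the package's artifact dial. The defaults were
chosen once, by inspecting artifact morphology: a deep, starvation-
dominated inter-implant band for the bilateral case, mild streaking for
the unilateral case, and far-field soft tissue that remains usable —
mirroring the qualitative picture reported for hip prostheses. They do
not model any specific scanner's physics. With `β = 0` and `n0 = ∞` the
corruption is the bit-exact identity, which the null experiment exploits.

Reconstruction is standard FBP: band-limited discrete ramp kernel,
Hann-apodized by default (ramp selectable), pixel-driven back projection.
Hann was chosen because un-apodized ramp ringing at the implant edge would
confound the MAR evaluation. On the metal-free phantom at 360 views the
round trip is accurate to ~3 HU RMSE away from material boundaries; a
2-voxel rim at boundaries is excluded from such fidelity statements
because partial-volume blur there is a property of any reconstruction, not
an artifact.

## The MAR chain

`imar()` reproduces the published iterative structure: segment metal by
threshold, mark the sinogram's metal trace (forward projection of the
metal mask, thresholded just above zero path length), then iterate
NMAR → FSMAR with the FSMAR output seeding the next iteration's prior;
after the last pass the original metal voxels are reinserted so implants
stay visible.

* **Prior image** (`buildPrior()`): non-metal voxels are classified by HU
  into air / soft / bone (boundaries −500 and 300 HU); air and soft are
  replaced by class values (−1000, 40 HU), bone keeps its measured HU so
  bone gradients survive the normalization, and metal voxels become soft
  tissue. The first prior is built from a **linear-interpolation
  precorrected** reconstruction (`liPrecorrect()`), not the raw FBP image:
  severe dark streaks fall below the air threshold and would otherwise be
  classified as air, poisoning the prior — with the precorrected seed the
  iteration converges in 2–3 passes instead of stalling.
* **NMAR** (`nmar()`): the corrupted sinogram is divided by the forward
  projection of the prior plus a guard `δ = 10⁻³ · max(p_prior)`, the
  trace bins of the normalized sinogram are replaced by 1-D linear
  interpolation along the detector axis per view (cubic interpolation was
  rejected: overshoot re-creates bright bands), then denormalized and
  reconstructed.
* **FSMAR** (`fsmar()`): `out = lowpass(corrected) + w · highpass(original)
  + (1 − w) · highpass(corrected)` with an in-plane Gaussian split
  (σ = 4 mm) and a distance-transform weight `w` that is 0 within 3 mm of
  metal and ramps to 1 at 10 mm. Far from the implant the original's sharp
  high frequencies are restored; near it the in-painted image prevails so
  the original's streaky high frequencies are not reintroduced.

Iteration count (3), thresholds, σ and the weight band are free parameters
of `marParams()`; the commercial hip pre-set they would correspond to is
proprietary and unpublished, so these defaults were tuned once on the
synthetic phantom and are not claimed to match any vendor values.

## Calibration and WEPL

The HU→RLSP map is entered directly from its six control points
(`defaultCalibration()`); deriving the curve from a scanned standard
phantom is out of scope. Above the last point (3095 HU, RLSP 2.602) the
default policy clamps: whether a scanner reports extended HU above that is
scanner-dependent, and clamping bounds the WEPL contribution of saturated
metal voxels; linear extrapolation is selectable. Below the first point
the map clamps at 0 (stopping power cannot be negative). HU values are
treated as real numbers throughout; no integer quantization.

Overrides assign a fixed RLSP to named structures, applied after the
curve in list order with provenance recorded. The stock pipeline overrides
the whole gas-holding rectum structure to water (RLSP 1.0) — the
protocol-style answer to non-reproducible rectal filling. Covering the
structure rather than only the gas voxels also neutralises the
partial-volume rim that reconstruction smears around the sharp gas
boundary, which would otherwise register as a range deviation that no MAR
method could (or should) fix.

WEPL is accumulated along rays by midpoint sampling (default step 0.5 mm,
bilinear in-plane interpolation, outside-grid samples contribute zero);
halving the step changes totals by well under 0.1 mm. ΔWEPL is the
per-depth difference of two profiles on the identical ray, summarised by
its signed extremum. Bundle summaries (`rayBundle()` + the pipeline)
truncate each ray at the distal PTV edge plus the distal margin: range
deviations beyond the beam's stopping point cannot affect the plan, and
including the full exit path would mix recon partial-volume effects distal
to the target into a beam-relevant summary. Full-length profiles are still
exported for figure-style overlays.

## The surrogate dose engine

The engine exists to translate range errors into dose/DVH/gamma language,
not to emulate a clinical beam model. Depth dose is an analytic SOBP
template in WEPL: entrance plateau (30% of the SOBP level), logistic
buildup (20–80% over 4 mm) to a flat plateau spanning `[R − M, R]`, and a
logistic distal falloff (80–20% over 2 mm). Planning on an RLSP map spans
a ray bundle over the target's beam's-eye view, freezes `R` (deepest
distal edge + 3 mm), `M` (covering the shallowest proximal edge − 3 mm),
and a lateral aperture (extent + 5 mm margin, Gaussian penumbra σ = 2 mm);
the plan's normalisation (mean PTV dose = prescription on the planning
map) is frozen too, so recalculation on another map changes nothing but
the medium. Angles whose bundle crosses metal before the distal target
edge are rejected — with bilateral implants that leaves the
anterior-posterior vertical beam, reproducing the clinical constraint.
Doses are reported in % of prescription; RBE is a fixed scalar of 1 and
dose units are abstract. Absolute DVH values of a pencil-beam planning
system are explicitly out of reach; only directional and differential
statements are made.

The sharp distal edge is a deliberate stress amplifier: with a 2 mm
falloff, a 7 mm WEPL planning error removes the distal part of the target
from the plateau entirely, so the FBP-planned bilateral case shows a
collapse of recalculated D_V98% where the clinical study shows a few
percent. The direction and the ordering (FBP ≫ MAR-corrected error) are
the reproducible content; magnitudes are not comparable across dose
engines.

## Gamma, DVH, ROI

Gamma uses 1% local dose difference / 2 mm distance-to-agreement with a
10% low-dose cutoff taken from the reference distribution's maximum; the
reference role is fixed as the planning image's dose (which of the two
distributions "local difference" normalises by is genuinely ambiguous in
commercial tools; the choice is recorded here and switchable in code). The
spatial search visits voxel centres in order of increasing distance with
early termination, then minimises γ² analytically along every axis-aligned
lattice edge in the neighbourhood — the evaluated dose is linear along an
edge, so the minimum is an exact quadratic solution. A fixed sub-voxel
sampling lattice was tried first and rejected: across the 2 mm distal
falloff the dose changes several tolerance-widths per 0.2 mm step, so any
affordable lattice misses the matching point and inflates γ by factors.
Voxel-centre-only mode is retained (`gammaParams(subvoxel = FALSE)`)
because it is exactly enumerable by a brute-force oracle, which the test
suite exploits. 2-D per-slice rates restrict the search in-plane and the
worst slice is reported alongside the 3-D global rate.

DVH metrics are computed from the voxel values directly (curves are
binned only for export, 0.1% bins): D_mean, D_V98% (dose covering 98% of
the volume, interpolated between order statistics), V_D95%, D_1cc
(interpolated at the 1 cc order statistic; sub-1 cc structures fall back
to D_max with a warning), and a fixed-absolute-dose volume metric whose
threshold defaults to 50% of prescription — in surrogate dose units an
absolute Gy level is meaningless, so the threshold is expressed as a
prescription fraction and configurable.

ROI analysis follows the cursor-style protocol: a 12 mm disc on a streak
region and a same-tissue reference disc, over five consecutive central
slices, reporting per-slice and pooled mean CT number, difference, and
noise (SD).

The far-field stability check ("contralateral soft tissue changes by
< 10 HU on average") is evaluated on the unilateral scenario's
contralateral half, which is where such a claim is well defined. On a
bilateral phantom every soft-tissue voxel lies on rays through at least
one implant, so in-painting legitimately moves even distant tissue by
10–20 HU; that bilateral far-field value is computed and reported too
(with the inter-implant corridor excluded from the region), but it is a
different quantity, not the contralateral one.

## The experiment and its controls

`runExperiment()` wires the chain together for the scenario grid
{gt, unilateral, bilateral} × {fbp, imar}. The ground-truth reference
image is the FBP reconstruction of the implant-free phantom — a ground
truth of the same "scanner", as a physical experiment would use — and all
phantoms share one noise seed so non-implant voxels are identical across
scenarios. Per-stage random seeds derive deterministically from the single
config seed; a rerun is byte-identical (the report bundle carries MD5
checksums and every reported number traces to a stored intermediate;
`renderReport()` only redraws from those files).

Two controls bound the interpretation. The `gt` scenario compares its own
reconstruction against the voxel truth, quantifying the reconstruction
fidelity floor (about 0.9 mm WEPL at default resolution, dominated by
partial-volume at tangential surfaces). The null experiment disables
corruption entirely and compares an implant scenario's FBP against the
ground-truth reconstruction: WEPL deviations along the beam corridor drop
below 0.5 mm and optimised-vs-recalculated gamma passes at 100%,
demonstrating that the pipeline does not fabricate artifact signal.

Problem sizes used by the shipped analyses: the full experiment runs at
256 × 256 × 10 voxels (2 mm, 360 views) in about six minutes on one CPU;
the test suite exercises the same code mostly at 128 × 128 × 2 (4 mm, 180
views), which preserves every qualitative behaviour at a fraction of the
cost.

## Known limitations

* Parallel-beam, in-slice 2-D transport replicated per slice; no fan/cone
  beam, scatter, helical sampling, or couch kicks.
* One artifact physics (quadratic beam hardening + floored Poisson
  starvation); real polychromatic and scatter effects differ in detail.
* The FSMAR weighting restores the original's high frequencies *far* from
  metal and suppresses them near it; the published variant orients the
  weight the other way (original detail near metal). For this benchmark's
  geometry the difference is minor — the contracted behaviour (identity
  when inputs agree, edge restoration away from metal, no streak
  reintroduction at the implant) is what the tests pin down.
* Periprosthetic bone is not fully recovered by the correction — a known
  failure mode of this class of algorithms; the suite asserts only that
  the correction does not make it worse than FBP.
* Absolute dosimetry, RBE biology, robustness/CTV margins and clinical
  protocol compliance are out of scope.
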