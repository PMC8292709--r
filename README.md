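# marbench

Metal implants wreck CT images. In carbon-ion (and proton) therapy this is
not merely cosmetic: treatment planning converts each CT number (HU) to the
relative linear stopping power (RLSP) of the tissue, and the beam's range —
where the Bragg peak stops — is the integral of RLSP along the beam path,
the water-equivalent path length

```
WEPL = L_w = L_m × RLSP .
```

Dark and bright streaks from a hip prosthesis therefore translate directly
into range errors, shifted dose edges, and lost target coverage. Iterative
metal artifact reduction (iMAR-style) corrects the images by repeatedly
applying normalized sinogram in-painting (NMAR) and frequency-split
recombination (FSMAR), but it can also introduce new artifacts, so its
dosimetric benefit has to be quantified, not assumed.

`marbench` is a self-contained benchmark of that whole question. It
provides, as composable S4 building blocks:

* **`synthetic phantom`** — a digital pelvic phantom (soft tissue, fat,
  pelvis and femoral heads, bladder- and rectum-like cavities, two target
  volumes) with none, unilateral or bilateral high-density hip implants
  (`defaultPhantom()`, `buildPhantom()`, `mirrorImplant()`);
* **CT model** — parallel-beam forward projection, metal-induced corruption
  (beam hardening on the metal-only line integral + Poisson photon
  starvation with a detector floor), and filtered back projection
  (`forwardProject()`, `corruptSinogram()`, `fbp()`);
* **MAR** — metal segmentation, tissue-class prior, NMAR normalized
  in-painting, FSMAR frequency split, iterated as `imar()`;
* **calibration** — the six-point piecewise-linear HU→RLSP curve
  (control points (−1000, 0), (−200, 0.8), (−100, 0.95), (0, 1.0),
  (50, 1.05), (3095, 2.602)) with structure overrides such as
  rectal-gas-as-water (`defaultCalibration()`, `applyCalibration()`);
* **WEPL** — ray tracing, ΔWEPL between reconstructions, CT-number line
  profiles, beam's-eye-view ray bundles (`traceWEPL()`, `deltaWEPL()`,
  `rayBundle()`);
* **dose engine** — a surrogate spread-out-Bragg-peak model with a sharp,
  WEPL-indexed distal edge, plan-on-A / recalculate-on-B workflow
  (`planBeams()`, `computeDose()`, `recalculateDose()`);
* **metrics** — gamma analysis (1%/2 mm, local, 10% cutoff; 3-D and
  per-slice 2-D with worst slice), DVH statistics (D_mean, D_V98%, V_D95%,
  D_1cc, V at a fixed dose level), and ROI CT-number/noise comparison
  (`gammaIndex()`, `dvhMetrics()`, `roiStats()`);
* **pipeline** — `runExperiment()` orchestrates phantom → acquisition →
  {FBP, iMAR} → calibration → {WEPL, plan/recalculate} → {gamma, DVH, ROI}
  and writes a fully reproducible report bundle; `renderReport()` redraws
  the figures from the stored intermediates.

The dose engine is deliberately a surrogate: absolute DVH numbers depend on
the clinical pencil-beam system and are out of reach; what the benchmark
asserts is directional — how much of the artifact-induced range and dose
error a MAR correction removes.

## A worked example

```r
library(marbench)

cfg <- experimentConfig(outDir = "demo",
                        phantomDim = c(256, 256, 2),
                        scenarios = c("gt", "unilateral", "bilateral"),
                        seed = 1)
bundle <- runExperiment(cfg)
bundle$weplTable
```

```
           scenario recon max_abs_dwepl_mm extremum_mm
maxAbs           gt   fbp        0.8878383  -0.8878383
maxAbs2  unilateral   fbp        0.2154528   0.2154528
maxAbs1  unilateral  imar        0.5572528  -0.5572528
maxAbs3   bilateral   fbp        7.0350299  -7.0350299
maxAbs11  bilateral  imar        1.7380620  -1.7380620
```

Reading this: with bilateral implants the uncorrected (FBP) reconstruction
under-estimates the water-equivalent depth along the anterior-posterior
beam corridor by up to 7.0 mm (the dark inter-implant band depresses CT
numbers, hence RLSP); the iterated MAR correction brings that down to
1.7 mm — a 75% reduction. The `gt` row is the reconstruction-fidelity
floor (recon vs. the voxel truth), and the unilateral rows show that a
midline beam avoiding the single implant is barely affected in the first
place.

The dosimetric consequence, from the same bundle (prostate-like target,
single AP beam, plan on each reconstruction, recalculate on ground truth):

```r
res <- bundle$scenarios$bilateral$plans$prostate_bilateral
res$fbp$gamma   # 3-D pass 96.2%, worst 2-D slice 96.2%
res$imar$gamma  # 3-D pass 100.0%, worst 2-D slice 100.0%
res$fbp$dvh$ptv_prostate   # D_V98% optimized 96.8 vs recalculated 3.6
res$imar$dvh$ptv_prostate  # D_V98% optimized 96.5 vs recalculated 95.8
```

Planned on the artifact-laden FBP image, the beam's range is set ~7 mm WEPL
too short, so on the true anatomy the distal target edge falls out of the
plateau and D_V98% collapses; planned on the MAR-corrected image the
recalculated coverage is within half a percent of the optimised plan.

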