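---
title: "Methods: organoid screen quantification and cell-state fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organoid screen quantification and cell-state fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The measurement model

`tboscreen` quantifies drug effects on tumor-forebrain organoids (TBOs):
neural organoids carrying embedded, fluorescently tagged tumor cells, imaged
as cleared whole mounts in multi-channel 3D confocal stacks.  The
per-organoid readout is the **summed brightness** of each compartment,
totalled over all confocal planes:

* tumor readout: total tumor-marker intensity (e.g. GFP/647) within the
  segmented *tumor areas*;
* neuronal (TME) readout: total neuronal-marker intensity (e.g. MAP2C/488)
  over the *whole organoid*.

Compartment *areas* (tumor voxel count; organoid-minus-tumor voxel count)
are carried alongside, because a drug can shrink a compartment's footprint,
dim its marker, or both.  Sums are exact arithmetic over masked voxels —
`sum_brightness()` is required (and tested) to agree with a naive voxel
loop to floating-point accuracy, and per-plane values add up to the total
exactly.

# The organoid phantom

Every downstream stage is validated by parameter recovery on synthetic
phantoms with voxel-level ground truth (`phantom_spec()`,
`generate_organoid_stack()`).  The phantom is deliberately minimal: the
goal is to test the *measurement math*, not to imitate optics.

* **Geometry.** The organoid is an ellipsoid — a circle per plane whose
  radius varies with depth; the z semi-axis spans the stack.  Tumor foci are
  spheres, placed entirely inside the organoid and pairwise disjoint.
* **Intensities.** Tumor channel: `tumor_intensity * (1 - tumor_kill)`
  inside foci.  Neuronal channel: `neuronal_intensity * (1 - neuronal_kill)`
  in the organoid outside foci.  Both channels carry a constant
  `background_intensity` inside the organoid (tissue autofluorescence) and
  are zero outside, apart from noise.  `tumor_kill` / `neuronal_kill` in
  [0, 1] are the simulated drug effect.
* **Noise.** Additive Gaussian, SD `noise_sd`, clipped at zero — the
  simplest model whose effect on a masked sum has a closed-form variance,
  which is what sets the tolerances in the recovery tests.
* **Defaults as study conditions.** 29 planes, 64×64-pixel planes, organoid
  radius 24 px, three foci of fixed radius 6 px (≈8% tumor volume
  fraction), tumor 200 / neuronal 150 / background 20 AU, noise SD 10 (5%
  of the tumor signal), four organoids per treatment group.  The fixed
  focus radius with integer centres makes the tumor voxel count a
  translation-invariant constant across phantoms, so group-mean ratios
  estimate `1 - kill` without focus-geometry sampling noise — recovery
  tests then probe the segmentation and background correction, not the
  random geometry.
* **Seeding.** One master seed; per-well seeds are derived by a stable
  31-bit string hash of the well id (`derive_seed()`), so generation is
  order-independent and byte-reproducible.
* **Not emulated.** Point-spread function, depth attenuation, bleaching,
  clearing artifacts, multi-lineage TME composition, sub-voxel geometry.
  Passing recovery tests therefore demonstrates correctness of the
  quantification pipeline on idealized tissue, not robustness to optical
  artifacts of real stacks.

# Segmentation

`segment_organoid()` thresholds the channel sum per plane (Otsu), fills
holes and keeps the largest connected component per plane.  Two refinements
matter in practice:

* **Consistency band.** A plane's Otsu threshold is accepted only within
  0.5×–2× of the whole-stack Otsu threshold; otherwise the plane inherits
  the global value.  Two-class Otsu on a plane whose background class is
  small, or which contains a small very bright structure, happily separates
  *bright-vs-rest* instead of *tissue-vs-background* (in development we
  observed per-plane thresholds of ~165 where the correct split was ~50
  once the neuronal compartment was strongly dimmed, which collapsed the
  organoid mask onto the tumor foci).  The band keeps per-plane adaptivity
  for ordinary planes and falls back to the stack-level split for
  degenerate ones.  A pure 3D global threshold (`scope = "global"`) and
  fixed thresholds are available.
* **Contrast guard.** `segment_tumor_areas()` runs Otsu on the tumor
  channel restricted to organoid voxels and rejects thresholds that merely
  split noise: the threshold must exceed the median within-organoid
  intensity by at least 1.5 noise SDs (noise estimated from out-of-organoid
  voxels via the 97.5th percentile / 1.96, robust to zero-clipping).  With
  the default intensities this puts the tumor detection floor at a kill
  fraction of roughly 0.85 — beyond that, the residual tumor signal
  (≤ 1.5 SD above autofluorescence) is genuinely indistinguishable from
  background and the mask is (correctly) empty.

Whether per-plane or 3D thresholding, and whether brightness should be
background-corrected, are not universally settled for this assay; both are
exposed as options with the defaults above.

# Background correction

With background confined to the organoid (autofluorescence), the median of
*out-of-organoid* voxels estimates only the detector offset (~0 here), and
sums corrected that way retain a kill-dependent bias of
`kill * B / (signal + B)`.  The default estimator is therefore
**cross-compartment**: the tumor channel's background is the median
tumor-channel intensity over organoid voxels *outside* the tumor mask, and
the neuronal channel's background is the median neuronal-channel intensity
over tumor voxels.  This exploits the compartment specificity of the
markers (the tumor tag is absent from the TME; the neuronal marker is
absent from tumor foci), which is exactly why a two-marker design permits
compartment-resolved screening in the first place.  The estimate times the
measured voxel count is subtracted per plane (preserving additivity
exactly); the out-of-organoid estimator remains available
(`background = "outside"`), as does no correction (the default for plain
measurement; recovery analyses switch it on).

# Screen statistics

* **Normalization.** Treated group mean divided by control (DMSO) group
  mean, per compartment; the control normalizes to 1 by construction and
  effects are floored at 0.  The reported SEM is the treated SEM over the
  control mean — control noise shifts every drug identically and is not
  drug-specific dispersion, so it is not propagated.
* **Testing.** Two-sided Wilcoxon rank-sum against control: exact
  distribution when the combined sample size is ≤ 20 without ties,
  otherwise the normal approximation with tie and continuity correction.
  Note the granularity at screening group sizes: at n = 4 vs 4 the
  attainable two-sided p-values are multiples of 2/70, the smallest being
  0.0286, so the realized size at α = 0.05 is 1/35 — detection at n = 4
  requires complete separation of the two groups.
* **Multiple testing.** Benjamini–Hochberg across drugs, per compartment
  (raw p-values are also reported).  A **hit** is adjusted tumor p < α
  *and* normalized tumor effect < 1, i.e. a significant tumor reduction; α
  defaults to 0.05.  **Selectivity** is the TME effect minus the tumor
  effect (positive = spares the microenvironment more than the tumor).
* **Fields.** The screen defaults to compartment areas (`tumor_area`,
  `tme_area`); when the simulated (or biological) effect is an intensity
  kill rather than a footprint change, the summed-brightness fields are the
  right choice and are the default for dose-response curves.

# Dose-response and the therapeutic window

`build_curve()` normalizes each dose group to control and tests it per
compartment; dose 0 is the control row, pinned at 1.  The **first
significant dose** is the lowest dose with p < α *and* a normalized mean
below 1 (a significant *reduction* — the curves of interest are
decreasing).  The **therapeutic window** is `[lower, upper]` with `lower`
the first significant tumor dose and `upper` the largest tested dose
strictly below the first significant neuronal dose (or the top dose if the
neuronal compartment is never significantly reduced); it exists when
`lower <= upper`.  Stricter α can only move both ends later (or remove the
window) — it never extends the window to the left nor shrinks it from the
right; this is asserted as a property test.

Per-dose tests are not multiplicity-adjusted within a curve by default
(mirroring per-dose reporting conventions); BH within the curve is a
config option.  An optional Hill fit (`fit_hill()`) reports EC50 but never
gates the window.  One consequence of the exact test's granularity is worth
stating: with six doses, five of the per-curve (dose, compartment) cells
are true nulls in the window-recovery simulation, each carrying a
false-significant-reduction probability of about 0.025 at n = 8, which
bounds per-run window recovery near 88–90% — the observed recovery rate is
computed, not assumed, by the acceptance script.

# The single-cell arm

* **Generator.** `generate_expression_matrix()` draws negative-binomial
  counts (log-normal per-gene baselines; per-cell weights renormalized so
  the expected library size hits `library_size_mean`).  Each non-undiff
  state owns a disjoint signature list multiplied by
  `signature_fold_change` (default 4) in its cells; cycling cells multiply
  S or G2M lists by `cycling_fold_change`.  The cycling fold defaults to
  10: canonical cycle markers (cyclins, MKI67, TOP2A) are near-binary
  between cycling and non-cycling cells, a far stronger modulation than
  subtle state signatures — at 4× over an always-expressed baseline, G1
  cells overlap the cycling score distribution for *any* classifier.
  Weight renormalization means the realized fold is compressed slightly
  below nominal (compositional closure; ~4 → ~3.7 at default settings),
  which the generator tests acknowledge.  Default conditions: `primary` and
  `TBO` share a balanced state distribution; `spheres` are skewed to
  0.7 NProg-like and 0.6 cycling (vs 0.2) — the qualitative situation the
  fidelity analyses exist to detect.  A knockout table can silence chosen
  genes in one (state, condition), emulating a differentiation marker
  absent from one model's cells.
* **Module score.** Mean normalized expression (library-size 10,000,
  log1p) of the signature genes minus the mean over control genes sampled
  (seeded) from expression-matched bins: 25 equal-frequency bins over
  per-gene averages, 50 controls per signature gene, signature genes
  excluded from the control pool.  Scores are deterministic given the seed
  and invariant to cell order.
* **Classification.** Arg-max signature when the best score exceeds the
  threshold (default 0), else `undiff`; ties break by signature order.  The
  zero threshold works because signature genes' *averages* (which drive
  control matching) include their up-regulated state cells, so controls sit
  above the baseline of non-expressing cells and every score of a cell
  outside the signature's state is negatively biased.  Cell-cycle phase is
  the arg-max of S/G2M scores when either is positive, else G1.
* **Fidelity metrics.** Per-condition state proportions (sum to 1);
  cycling fractions; pseudobulk Pearson correlation between conditions
  (pseudobulk = mean *normalized* expression, which removes library-size
  confounding between conditions); and per-gene Wilcoxon differential
  expression with BH adjustment and log2 fold changes of de-logged group
  means (nonparametric testing mirrors the rest of the pipeline; count-model
  DE is out of scope).

# Numerical choices and degenerate inputs

* Constant stacks segment to an empty mask with a warning, not an error;
  empty planes are allowed.
* Identical values across both test groups give p = 1 ("degenerate"
  method tag).
* A singleton group reports SD 0 (and hence SEM 0) by documented policy.
* Zero-count cells are dropped with a warning during normalization; genes
  all-zero in both DE groups are excluded and counted.
* Background-corrected sums are not floored per plane (additivity is
  exact); normalized effects are floored at 0.
* All simulation seeds stay below 2^31; per-object seeds come from a
  stable polynomial string hash, not R's RNG state.

# Problem sizes used by the tests

Simulation-heavy checks (type-I calibration, window recovery) use a reduced
phantom (15 planes, 32×32, one 4-px focus): the statistical properties
under test do not depend on stack size.  Effect-size recovery, segmentation
recovery and power use the full default geometry.  The single-cell
acceptance checks use the default 1000 cells/condition and full gene panel;
unit tests use a reduced spec (150 cells/condition, 25-gene signatures,
500 background genes) whose smaller control-gene bins widen the scorer's
noise — their tolerances are set accordingly, and the spec-level tolerances
are asserted at full size.

# Known limitations

* The segmentation is organoid-level; single-cell segmentation, counting,
  deconvolution and cross-organoid registration are out of scope.
* The tumor detection floor (~1.5 noise SDs above autofluorescence) means
  kill fractions above ~0.85 at default intensities measure as complete
  kill.
* The generator's phantoms omit optical artifacts (above), and its count
  matrices omit batch effects, doublets and ambient RNA; fidelity results
  on synthetic data demonstrate the statistics, not performance on real
  accession data.
* Dataset integration, UMAP/clustering, CNV inference and expression-based
  drug-response prediction are deliberately not part of this package.
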