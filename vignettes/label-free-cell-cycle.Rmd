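---
title: "Label-free cell-cycle analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free cell-cycle analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocycle)
```

## The problem

Imaging flow cytometers record, for every cell passing the flow cell, a
brightfield image (transmitted light) and a darkfield image (light scattered
into a cone around 90 degrees). Neither channel requires a stain. The
question this package addresses is how much cell-cycle information those two
label-free channels carry: can we recover each cell's DNA content — a
continuous quantity rising from 2N in G1 through S to 4N in G2/M — and its
discrete mitotic phase (prophase, metaphase, anaphase, telophase) without
any nuclear dye?

The workflow is supervised. A training subset is annotated with ground
truth, typically the integrated intensity of a stoichiometric DNA stain
(e.g. propidium iodide) and phase labels derived from a mitosis marker. A
boosted regression ensemble then predicts DNA content, and a boosted
classifier predicts the mitotic phase, both from a fixed 213-feature
morphological profile. Predicted DNA-content distributions are converted to
G1/S/G2M fractions with the Watson pragmatic curve fit, so an entirely
unstained population can be scored once the models are trained — the core
"transfer" scenario reproduced by `demo_block_experiment()`.

## The synthetic study population

No instrument data ship with the package. Instead, `generate_population()`
draws cells with known phase and DNA content and renders their image pairs,
so every downstream stage can be validated against a known truth.

What the generator emulates, and the defaults that define the study
conditions:

* **Phase composition.** Priors G1 0.55, S 0.20, G2 0.20, prophase 0.02,
  metaphase/anaphase/telophase 0.01 each — an asynchronously cycling line
  with rare mitotic figures (about 5% combined), the class imbalance the
  classifier must survive.
* **DNA content.** `c = 2` in G1, linear `2..4` through S (uniform cycle
  position), `c = 4` in G2 and all mitotic phases.
* **Stoichiometric stain.** Integrated stain is `c * dna_g1 * (1 + eps)`
  with `eps ~ N(0, stain_cv)`; `stain_cv = 0.05` by default, matching a
  well-stained fixed sample where the G1 peak CV is a few percent.
* **Size coupling.** Projected radius scales as `(c/2)^0.5` around a base
  radius of 8 px with lognormal jitter (sdlog 0.08): cells roughly conserve
  area density as they double their volume over the cycle.
* **Morphology.** Interphase and prophase cells are ellipses with a
  heavy-tailed natural ellipticity (axis ratio `1 + |N(0, 0.25)|`, capped at
  1.9); metaphase plates are elongated (ratio at least 1.6); anaphase is two
  overlapping lobes (centres 1.2 lobe radii apart); telophase two disjoint
  lobes (2.4–3.2 lobe radii). All outlines carry low-order harmonic
  roughness (about 3%) because real boundaries are never conics. Prophase
  carries interior granular texture of *variable* amplitude (uniform on
  0–0.10), so weakly textured prophases genuinely shade into round G2 cells.
  These overlaps are deliberate: on real Jurkat data the reference workflow
  reports high accuracy for anaphase/telophase but only moderate accuracy
  for prophase and metaphase, and a generator whose classes are perfectly
  separable would misrepresent the difficulty of the task. The morphology
  rules themselves are invented stand-ins (the real study used actual cell
  images), and are documented as such in the feature manifest's provenance.
* **Darkfield.** A speckle field under a Gaussian envelope whose centre is
  randomly offset from the brightfield cell — the two channels are not
  registered, which is why the darkfield frame is never segmented — and
  whose integrated intensity scales with DNA content. The true instrument's
  darkfield appearance is not quantitatively described anywhere we could
  anchor to, so the speckle parameters are unconstrained choices.
* **Frames.** Each cell's square frame side is drawn uniformly from 30–60
  px, the size range of real instrument tiles. Images are floating gray in
  [0, 1] in memory and 16-bit on disk, avoiding quantisation artifacts in
  feature tests.
* **Mitotic block.** `block_shift = s` moves probability mass `s` out of
  G1/S (proportionally) into the G2 + mitotic pool (proportionally),
  emulating a Nocodazole-type microtubule poison. By construction the 4N
  fraction rises by exactly `s`.

What the generator does **not** emulate: optics (no point-spread function,
no true side-scatter physics), debris, doublets other than telophase,
illumination gradients, or focus variation. Tests passing on this generator
therefore demonstrate that the algorithms are implemented correctly and
behave as designed under the assumed statistical structure — not that the
numerical accuracies would transfer to instrument data.

Reproducibility: one RNG stream per population, split per cell by a
counter-derived seed, so equal `(config, seed)` give bit-identical
populations and any subset of cells regenerates identically.

## Preprocessing: reshape, montage, segmentation

Tiles are reshaped to 55x55: smaller frames are centred and padded with
values resampled from their own 2-px border frame (the safest label-free
proxy for background; there is no reference empty field in flow), larger
frames are centre-cropped. Content pixels are never interpolated. Cropping
that would remove object-like pixels (above background mean + 3 s.d.)
beyond a 2% tolerance raises a QC flag. For odd gaps the extra row/column
goes to the bottom/right — a deterministic layout rule. Montages tile up to
`grid^2` cells (15 x 15 = 225 by default) row-major with a JSON index map;
build/split is a bit-exact round trip.

Segmentation operates on brightfield only: Sobel gradient magnitude, a
global Otsu threshold floored at background mean + 2 background s.d. of the
enhanced image, morphological closing (disc, 5 px), hole filling, and
largest-component selection with a 50 px^2 minimum area. Because the
gradient magnitude straddles the true edge by about a pixel, a single
4-neighbourhood erosion recentres the mask; on noiseless synthetic disks
the test suite asserts the mask area within 10% of the analytic area. Telophase
cells legitimately present as doublets, so `multiple_objects` is recorded
but, by default, not discarded — only `no_object`, `too_small` and
`missing_values` are. The reference pipeline's exact threshold settings
live in software we do not have; the operator choices here are our own and
are configurable through `segmentation_params()`.

## The 213-feature profile

`feature_manifest()` fixes the order, names and provenance of all 213
features (version tag `v1`; any change to identities or order bumps the
version, and models refuse tables from a different version). The published
description of the reference workflow gives only the total (213) and the
five categories; the per-feature identities below are a principled
reconstruction consistent with that total:

| block | channel | count |
|---|---|---|
| shape scalars | brightfield object | 17 |
| Zernike magnitudes, degree <= 9 | brightfield object | 30 |
| intensity | brightfield object | 16 |
| radial distribution (4 rings x 3 stats) | brightfield object | 12 |
| Haralick texture (13 stats x scales 1, 2, 4) | brightfield object | 39 |
| granularity spectrum | brightfield object | 16 |
| intensity | darkfield full frame | 16 |
| radial distribution | darkfield full frame | 12 |
| Haralick texture | darkfield full frame | 39 |
| granularity spectrum | darkfield full frame | 16 |

Numerical conventions worth knowing:

* **Perimeter** uses intercept counts (Crofton-style, pi/4 times the
  fg/bg transition count along rows and columns) with a half-pixel end
  correction per direction; form factor `4*pi*A/P^2` is then ~1 for
  digitized disks.
* **Haralick**: region pixels are quantized to 8 gray levels by min–max
  binning (ties at bin edges to the lower bin), making all 13 statistics
  exactly invariant to affine intensity rescaling; co-occurrence matrices
  are symmetric, averaged over the four principal directions per offset
  scale; a constant region takes the conventions ASM = 1, contrast = 0,
  entropy = 0, correlation = 0.
* **Granularity**: percentage of background-subtracted regional image
  volume removed by grayscale openings with disc elements of radius 1..16;
  elements are non-negative and sum to at most 100 by construction.
* **Radial distribution**: four equal-width annuli from the region centroid
  (frame centre for darkfield) to the most distant region pixel, half-open
  ring boundaries, and a CV over 8 angular wedges per ring.
* **Zernike** moments are computed on the mask mapped to the unit disk
  around its centroid, normalised to unit mass, so magnitudes are
  scale-invariant.

The darkfield is always processed whole-frame. Cells whose profile contains
non-finite values are discarded, mirroring the reference workflow's
missing-value filter.

## Boosted learning

*Regression* (`fit_lsboost`) is stagewise least-squares gradient boosting:
depth-3 `rpart` trees fitted to residuals, shrinkage `nu = 0.1`, minimum
leaf 10. *Classification* (`fit_rusboost`) is multi-class AdaBoost (SAMME
weight update) in which each stage's weak learner trains on a
class-balanced random undersample of the weighted training set, while the
stage weight comes from the weighted error on the full training set. With
the undersample ratio at infinity the algorithm reduces exactly to plain
multi-class AdaBoost, a property the test suite checks against an
independent brute-force implementation. The reference workflow delegated
both learners to a black-box toolbox routine whose internal settings are
not published; the defaults here are conventional and fully configurable
via `boost_params()`.

The ensemble size can be fixed (`M`) or selected by fivefold internal
cross-validation (`internal_cv_stopping()`), which only ever sees the outer
training split and picks the stage minimising mean internal validation
loss, ties to the smallest ensemble. Outer evaluation
(`cross_validate()`) uses stratified folds — by class for classification,
by target decile for regression — with Pearson r per fold, or per-class
true positive rates with a pooled confusion matrix. Folds partition the
cells exactly once; degenerate folds (a class absent from a fold, or a
single-class training split at very small n) are excluded from means with
a warning rather than silently imputed.

For classification the canonical class scheme merges G1/S/G2 into one
interphase class (`merge_phase_labels()`): a single DNA-content axis cannot
separate them cell-by-cell, which is precisely why interphase substructure
is handled by the regression arm plus histogram deconvolution instead. The
blocked-experiment scheme additionally merges
metaphase/anaphase/telophase, as appropriate when a blocking agent leaves
almost no cells in the individual late-mitotic classes.

Leave-one-feature-out importance (`lofo_importance()`) re-runs the outer
cross-validation without each feature in turn. Because many morphological
features are strongly correlated, removing any single one usually changes
the metric very little — duplicated-feature tests document this caveat —
so category roll-ups accompany the per-feature values.

## Watson pragmatic histogram deconvolution

`fit_watson()` converts a DNA-content histogram (default 256 equal-width
bins over `[0, 1.02 * max]`) into G1/S/G2M fractions:

1. the G1 peak is the global mode after 3-bin moving-average smoothing,
   refined to sub-bin precision by a parabola through the mode and its
   neighbours;
2. the G2 peak is the highest local mode within `[1.7, 2.3] * muG1`
   (`fix_g2_ratio = TRUE` pins `muG2 = 2 * muG1` instead; the fallback when
   no mode is found is the same 2:1 ratio);
3. Gaussians are fitted to the *outer halves* of each peak — the region S
   phase cannot reach — extended 6 bins past the peak top to anchor
   amplitude and mean;
4. per-bin S counts between the peaks are the observed counts minus both
   fitted Gaussians, clipped at zero;
5. fractions are component totals over their sum, hence always summing
   to 1.

Two implementation choices deserve explanation. First, the half-peak fits
minimise Poisson deviance on raw counts rather than unweighted squared
error: most of a 256-bin histogram is near-empty tail, and under equal
weights those bins dominate the objective and destabilise the fitted width.
Second, the S plateau does not stop abruptly at the peaks: measurement
noise smears early-S cells below the G1 peak and late-S cells above the G2
peak, so the outer halves are not perfectly S-free and a plain half-peak
fit systematically over-credits G1. Pass one therefore estimates the
plateau level L from the middle third between the peaks; pass two refits
each half-peak with an explicit spillover term `L * Phi(+/-(x - mu)/sigma)`
and credits the smeared mass `L * (sigmaG1 + sigmaG2) / sqrt(2*pi)` back to
S. The test suite asserts the resulting accuracy on the reference mixture
(fG1 = 0.60, fS = 0.25, fG2M = 0.15, CV 5%, n = 10^4): each recovered
fraction within 0.03 of truth. All coordinates enter the fit relative to
the peak location, so fractions are exactly equivariant under intensity
rescaling — predicted DNA content in arbitrary model units needs no
calibration before fitting.

Degenerate inputs: histograms whose smoothed maximum is less than twice the
median positive bin are rejected as flat; a G1 CV outside (0.005, 0.4)
raises a diagnostic warning; a single-component population yields fG1 near
1 with the G2 component at zero amplitude.

Binning guidance: the 256-bin default suits 10^4 or more cells. For
smaller populations keep roughly 20 or more cells per occupied bin — the
package's own tests use 128 bins at n around 3000 and 64 bins for the
1200-cell arms of the block demo.

`compare_populations()` reports fraction deltas between two fits and, given
raw per-cell intensities, percentile bootstrap intervals over cells
(B = 200, seeded).

## Problem sizes and reproducibility

The bundled validation runs at sizes a laptop handles comfortably: the
default study population is 3000 cells (about 2–3 minutes to render and
profile), learning checks use 10-fold outer cross-validation with fixed
ensemble sizes (M = 60 regression, M = 40 classification) — internal early
stopping is exercised and tested at smaller n where its nested cost is
negligible — and the block-transfer demo trains on 1500 stained cells and
scores two unstained arms of 1200. Every stochastic step (population
generation, reshape padding, fold assignment, per-stage undersampling,
bootstrap) is driven by explicit seeds, and identical configurations
reproduce bit-identical artifacts and reports; `run_pipeline()` writes an
MD5 lineage manifest alongside its outputs.

## Known limitations

* Generator morphology is a stand-in; absolute accuracy figures obtained on
  it say nothing quantitative about instrument data.
* The per-feature identities of the 213-feature profile are a
  reconstruction constrained by the published total and category names;
  `v1` is therefore a manifest version, not a claim of exact equivalence.
* The Watson pragmatic scheme reports G2 and M as one fraction (identical
  DNA content) and intrinsically attributes peak-adjacent ambiguity to S;
  on S-free mixtures it agrees with a two-component Gaussian EM fit to
  within 0.02.
* No watershed splitting of touching cells, no fluorescence-driven
  segmentation, no probability calibration of the classifier, and no
  pseudotime ordering of DNA content.
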