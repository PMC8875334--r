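---
title: "Density-banded quantification of decidual IHC: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-banded quantification of decidual IHC: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophoquant)
```

## The problem

At the maternal–fetal interface, fetal extravillous trophoblasts invade the
maternal decidua and intermix with maternal stroma. Quantifying how a protein
(here NRF2, the master regulator of the oxidative-stress response, and KEAP1,
its negative regulator) is expressed *separately* in trophoblast-rich and
maternal-only tissue requires more than a whole-slide average: serial
sections are stained for CK7 (which marks trophoblasts), NRF2, and KEAP1, and
the CK7 section is used as a spatial reference to classify tissue before
reading intensities off the other two sections.

trophoquant implements this whole chain — tile flat-fielding and stitching,
tissue and region-of-disinterest masking, H-DAB stain separation, a fixed
50-px patch grid classified into trophoblast-density bands, serial-section
registration, band-wise gray-level quantification, trophoblast counting — and
the downstream statistics (robust outlier screening, rank and parametric
group tests, site-adjusted linear and linear mixed models) plus a
permutation-based gene-set enrichment statistic for NRF2 target sets.

Because clinical slides cannot ship with a package, every stage is validated
against *synthetic slide phantoms* with exact ground truth. The generator is
first-class, tested code, not a throwaway fixture.

## The color model

Bright-field IHC obeys Lambert–Beer absorption: with white illumination
$I_0 = 255$ and per-stain absorbance (optical density, OD) $A_h$ and $A_d$,
the observed channel intensity is

$$ I_c = 255 \cdot 10^{-(A_h \mathbf{h}_c + A_d \mathbf{d}_c)}, $$

where $\mathbf{h}$ and $\mathbf{d}$ are the unit reference absorbance
vectors of hematoxylin and DAB (the Ruifrok–Johnston H-DAB basis). The
renderer uses exactly this forward model; `separate_hdab()` inverts it by
least squares projection of the per-pixel OD onto the two-stain basis, with
negative concentrations clipped at zero and saturated pixels capped at
$\log_{10} 255 \approx 2.41$ OD. Because the renderer and the deconvolution
share the physics but not the code path, render–invert round trips are a
meaningful test, not a tautology.

Rendering noise is additive Gaussian *in absorbance space* (clipped to valid
RGB), so at zero noise the rendered gray level is strictly monotone in stain
strength — the property the monotonicity tests assert.

## The gray-level convention

Intensities are reported on the 0–255 gray scale after the standard Rec. 601
luma conversion (0.299 R + 0.587 G + 0.114 B): 0 is black (maximal
staining), 255 is white (no staining). Staining intensity is therefore
*inversely* proportional to expression, and the package never inverts this
internally — band means are reported as gray levels and lower means more
protein. The luma weights are recorded here because they are part of the
numeric provenance: changing them changes every reported mean.

## Synthetic slide phantoms

`generate_phantom()` builds a ground-truth section:

* **Trophoblasts** are non-overlapping disks (default radius 9 px, minimum
  gap 2 px), placed as clusters on a jittered hexagonal lattice (default 4
  clusters of 19 cells — two lattice rings, interior fill ≈ 0.73) plus
  isolated singles (default 20). The dense-but-untouching lattice matters
  twice: untouched disks make the count truth unambiguous, and an interior
  fill above one half guarantees that patches in cluster cores genuinely
  exceed the 50% fraction boundary, so the "high" band is populated.
  Cells are only placed on stroma, as invading trophoblasts are in tissue.
* **Maternal stroma** is a smooth random occupancy field thresholded to
  cover a target fraction of the canvas (default 0.85).
* **Exclusion structures** (vessels/glands/muscle) are random polygons,
  capped at 30% of the canvas.
* **Per-marker appearance** is a pair of DAB strengths (trophoblast,
  maternal) in [0, 1]; defaults give CK7 strong trophoblast-specific
  staining (0.80 vs 0.04), NRF2 0.60 vs 0.15 and KEAP1 0.50 vs 0.20, i.e.
  both markers expressed in both compartments but enriched in trophoblasts.
* **Serial sectioning** is emulated by a per-marker rigid integer
  translation bounded by ±50 px; CK7 is the reference at the origin.
* Everything is a pure function of the arguments including the seed.

The renderer cuts the canvas into scanner-style tiles (default 512 px,
configurable overlap) and applies a radial optical vignette whose corner
attenuation equals `vignette_strength`. The vignette is *shared* by all
tiles of a section, as lens shading is a property of the optics; a single
multiplicative gain raster of tile shape is then a well-posed estimand for
flat-field correction. Pixel size is an explicit calibration field
(µm/px) rather than an assumed constant, and all areas are reported in mm²
through it.

What the phantoms deliberately do **not** emulate: nuclear morphology,
multinucleated giant cells, scanner color profiles, stain batch variation,
tissue folds, or sectioning distortions beyond rigid translation. Passing
the phantom studies therefore demonstrates that the algorithmic chain is
correct and calibrated under its stated model, not that it is robust to
every artifact of real slides.

## Flat-field correction and stitching

The gain field is estimated from background pixels — bright
(min channel > 120) and achromatic (channel spread < 25), a classification
that separates blank glass from chromatic stained tissue even under strong
shading — as per-block medians across all tiles, bilinearly interpolated to
pixel resolution and normalized to mean 1 per channel. Tiles are divided by
the gain, rescaled to preserve global mean brightness, and clipped to 8 bit.
On a phantom with corner attenuation 0.3 this reduces the background
coefficient of variation by more than a factor of 4 (the shipped benchmark
computes it at run time).

Stitching places tiles at their declared grid positions (scanner stages
report positions; no correlation-based placement, which keeps mosaicking
deterministic) and blends overlaps by linear feathering. At zero overlap
stitching is the exact inverse of tile cutting, which the tests assert
pixel-for-pixel.

## Tissue, regions of disinterest, and area

A pixel is tissue iff its mean-filtered luma falls below `white_threshold`
(default 240 on corrected scans; on uncorrected vignetted material a lower
threshold such as 215 is appropriate and is what the recovery study uses).
Small speckles are removed and small holes filled (64 px defaults). Manually
annotated exclusion polygons (muscle, villous tissue, vessels, glands, poor
morphology) are rasterized by an even-odd scanline fill over pixel centers —
coordinates are 0-based, origin top-left, x = column. The area denominator
uses **tissue-only pixels** inside the included region, not the bounding
rectangle; the alternative would inflate areas with background glass.

## The patch grid and density bands

The CK7 scan is separated into H and DAB OD; CK7 positivity is DAB OD ≥ 0.15
(stain-separated thresholding is robust to counterstain variation, unlike
raw-color rules), with objects under 16 px discarded. The scan is tiled into
50 × 50 px patches (partial edge patches kept and flagged); each patch's
trophoblast fraction is CK7-positive pixels over *included tissue pixels* in
the patch — computing over tissue avoids diluting edge patches with
background. Bands follow the fixed rule: fraction 0 → maternal; greater
than 0 up to and including 0.5 → low; strictly above 0.5 → high. The
boundary case of exactly one half is "low" because the high band is defined
as *more than* 50%.

## Counting and density

Trophoblasts are counted as connected components of the CK7 mask after a
light morphological opening; components above `max_cell_px` are treated as
touching clusters and contribute `round(area / single-cell area)` cells,
with the single-cell area taken as the first mode of the observed
component-area distribution. Density is count over included tissue area in
cells/mm². For non-touching phantoms recovery is essentially exact (worst
relative error well under 1% in the shipped study).

## Serial-section registration

Sections cut microns apart and scanned on the same stage differ by
translation only, so the transform is restricted to integer translation
within a 100 px search radius — no rotation or scale, which keeps the
transform invertible and the failure modes interpretable. The translation
maximizes the zero-mean correlation of the two cleaned tissue masks,
computed as a circular FFT cross-correlation on 2× downsampled masks
followed by an exact full-resolution refinement in a ±2 px window around
the (parabolically interpolated) coarse peak. Using the *same* mask
pipeline on both sides matters: mixing a smoothed mask with a raw-threshold
mask introduces a reproducible 1 px bias. A correlation score below 0.2
returns the identity with a warning; empty or constant masks are errors.
Injected offsets up to ±50 px are recovered exactly in the shipped study.

## Band-wise intensity quantification

The marker scan's gray raster is aligned onto the CK7 frame (luma commutes
with translation, so only the gray raster is moved; out-of-frame pixels are
filled white = no staining) and each included patch receives the mean gray
over its included tissue pixels. Band means are unweighted means of patch
means (each patch counts once), the overall mean averages all included
patches, and a band with no patches is reported as missing — never as 0,
which would fake maximal staining. Results are independent of patch
bookkeeping order; patch means are looked up by grid coordinates.

## The statistical layer

* **Robust outlier screening** (`rout_outliers()`): median/MAD location and
  scale, two-sided normal p-values on the standardized residuals,
  Benjamini–Hochberg FDR at Q (default 0.01). This is a documented
  approximation of the robust-regression-plus-FDR outlier procedure popular
  in commercial software, not a bit-level clone; for the constant model the
  two coincide in spirit. Zero-spread samples flag nothing instead of
  dividing by zero.
* **Kruskal–Wallis + Dunn** (`kruskal_dunn()`): tie-corrected rank omnibus
  statistic; for total n ≤ 9 the omnibus p is the exhaustive permutation
  p-value over all distinct label assignments (the asymptotic chi-square is
  available and is the default at larger n). Dunn z-tests on mean ranks use
  the classical tie correction; the multiplicity adjustment defaults to
  Bonferroni — the classical Dunn adjustment — and is configurable; both raw
  and adjusted p-values are reported so either convention can be quoted.
* **One-way ANOVA + Tukey HSD** (`anova_tukey()`), used for trophoblast
  amount and density, delegates to `aov()`/`TukeyHSD()`.
* **Site-adjusted linear model** (`fit_site_adjusted_linear()`): OLS of a
  slide-level outcome on diagnostic group plus recruitment site, with
  estimated marginal means ± SEM via emmeans. A single-level site is
  dropped (leaving all other estimates unchanged); rank deficiency is an
  error naming the collinear terms.
* **Density-band linear mixed model** (`fit_density_band_mixed()`): REML
  (lme4) fit of band-level means on group, band and site with a
  subject-specific random intercept absorbing within-subject correlation
  across bands. Only the trophoblast-containing bands (low, high) enter. A
  group-by-band interaction is included by default so that within-band group
  contrasts are free to differ; Wald z inference via asymptotic emmeans
  keeps simulation studies fast. Duplicated subject-by-band rows are
  averaged (the subject-band mean is the observational unit); when no
  subject has two bands the random intercept is inestimable and the fit
  falls back to fixed effects with a warning rather than reporting a
  spurious variance. REML with Wald tests was chosen as the standard
  practice behind "estimated means ± SEM" outputs.
* The significance level is 0.05 throughout.

Calibration, recomputed by the tests and the acceptance script: omnibus
type-I error within [0.03, 0.07] at α = 0.05 over 1000 null simulations for
both pipelines; mixed-model group-effect recovery bias below 25% of an
8-gray-level effect at 25 subjects/group over 200 simulations; the outlier
screen flags a 50-MAD outlier always and well under 2% of null points.

## Gene-set enrichment

Genes are ranked by the signal-to-noise ratio between the two phenotype
classes (Welch t is available), with class SDs floored so constant genes
cannot dominate, and ties broken by gene identifier for determinism. The
enrichment score is the signed maximum deviation of a weighted
Kolmogorov–Smirnov running sum: hits increment in proportion to
|metric|^p (p = 1 by default, normalized to total 1) and every rank
decrements uniformly by 1/N. The sum therefore starts and ends at zero, ES
∈ [−1, 1], and with p = 0 the score reduces to the classical KS deviation
of the set's rank distribution from uniform (a single top-ranked gene
scores 1 − 1/N). Note that some other implementations decrement only at
misses, by 1/(N − N_hit); for sets that are small relative to the ranking
the two conventions nearly coincide, and the test suite cross-checks
against an independent implementation at that tolerance.

Significance uses **phenotype** permutation (100 permutations by default) —
preserving inter-gene correlation, unlike gene permutation — with one
shared permutation block per analysis so per-set results do not depend on
the order sets are supplied. NES is ES divided by the mean |permuted ES| of
matching sign; the p-value is the fraction of matching-sign permutations at
least as extreme, floored at 1/(n+1) so it is never exactly zero (a flag
records when the floor binds). The five NRF2 functional set names
(antioxidant proteins; phase I and II metabolizing enzymes; chaperone and
stress response proteins; phase III detoxifying proteins; ubiquitination
and proteasomal degradation) with transcript counts 18/48/43/4/5 — 118
pooled — ship as a *synthetic-membership* GMT fixture
(`inst/extdata/nrf2_gene_sets_synthetic.gmt`): real memberships are user
configuration, loaded with `read_gmt()`.

## Problem sizes and numerical choices

The shipped validation studies use: 100 phantoms of 1536 × 1536 px (3 × 3
tiles of 512 px) with three serial sections each, vignette 0.1 and
absorbance noise SD 0.02, flat-fielding exercised separately in its own
benchmark; 1000 null simulations for the omnibus tests; 200 simulations for
mixed-model recovery and outlier calibration; 200 null and 50 implanted
datasets (500 genes, 20 vs 20 samples, 100 permutations) for enrichment.
These sizes give stable rates while keeping a full run on a single CPU in
the minutes range; they are stated here so that reruns are exactly
reproducible.

Numerical conventions worth knowing: 8-bit images are held as numeric
arrays in 0–255 and rounded only at tile/scan boundaries; the OD ceiling is
log10(255); patch bookkeeping is 0-based half-open pixel intervals,
row-major; the registration score is normalized to [0, 1]; seeds derive
from a single master seed via `sample.int(2^30)` so every study is
reproducible from one integer.

## Known limitations

* Exclusion regions are taken from annotations; there is no automated
  vessel/gland detection.
* Registration is translation-only by design; sections with rotation or
  nonrigid distortion would need a different aligner upstream.
* Cluster splitting by area is approximate for heavily confluent staining;
  counts on such material carry the stated ±1-cell-per-cluster uncertainty.
* The patch fraction is an area fraction of CK7-positive signal, not a
  counted-cell fraction; with the defaults the two orderings agree on
  phantoms, but they are not the same quantity.
* No nuclear-vs-cytoplasmic compartment scoring and no multi-marker
  colocalization beyond the CK7-guided masking.
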