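# trophoquant

Automated, patch-based quantification of bright-field immunohistochemistry
(IHC) in decidual tissue, stratified by trophoblast density — together with
the study-level statistics and a permutation gene-set enrichment stage, all
validated on synthetic slide phantoms with exact ground truth.

## The scientific problem

In the decidua basalis, fetal extravillous trophoblasts (marked by CK7)
invade and intermix with maternal stroma. To compare the expression of NRF2
— the transcription factor governing the oxidative-stress response — and its
negative regulator KEAP1 between pregnancy groups *within* each cellular
compartment, serial sections stained for CK7, NRF2 and KEAP1 are processed
as follows:

1. scanner tiles are flat-field corrected and stitched into whole-section
   scans;
2. tissue is detected and manually annotated regions of disinterest
   (vessels, glands, muscle, villous tissue, poor morphology) are excluded;
3. the CK7 scan is separated into hematoxylin and DAB optical densities
   under the Lambert–Beer two-stain model, and CK7-positive trophoblast
   signal is thresholded at DAB OD ≥ 0.15;
4. a 50 × 50 px patch grid classifies tissue by trophoblast fraction into
   density bands — maternal (0%), low (>0–50%), high (>50%); a fraction of
   exactly 50% is "low";
5. the NRF2 and KEAP1 scans are registered onto the CK7 frame (integer
   translation, FFT cross-correlation of tissue masks) and each band's mean
   gray level (0 = black = maximal staining, 255 = white = none; intensity
   is inversely proportional to expression) is reported, along with the
   trophoblast count and density (cells/mm² of included tissue);
6. group comparisons use robust outlier screening (median/MAD + FDR),
   Kruskal–Wallis with Dunn post hoc, one-way ANOVA with Tukey, a
   site-adjusted linear model for slide-level means, and a linear mixed
   model with a subject random intercept for the repeated band-level means;
7. NRF2 target gene sets are scored with a weighted Kolmogorov–Smirnov
   enrichment statistic (ES), normalized against phenotype permutations
   (NES, permutation p).

Every stage runs on synthetic phantoms — serial-section renderings of a
known tissue layout with injected rigid offsets, vignetting and noise — so
the whole chain is testable end to end without clinical material.

## Worked example

```r
library(trophoquant)

ph <- generate_phantom(seed = 7)            # ground-truth section layout
ph
#> Synthetic decidual slide phantom
#>   canvas: 1536 x 1536 px (0.662 um/px)
#>   trophoblasts: 96 (76 clustered, 20 single)
#>   markers: CK7, NRF2, KEAP1
#>   exclusion regions: 2

tilesets <- lapply(setNames(nm = c("CK7", "NRF2", "KEAP1")), function(m)
  render_section(ph, m, vignette_strength = 0.1, noise_sd = 0.02))

res <- quantify_slide(tilesets, flatfield = FALSE, white_threshold = 215,
                      subject_id = "subj01")
res$summaries$NRF2
#> Band intensity summary [NRF2, subject subj01]
#>      band mean_gray n_patches
#>  maternal    101.97       785
#>       low     87.95        66
#>      high     68.54         4
#>   overall mean gray: 100.73 over 855 patches
#>   trophoblasts: 96 (108.9 cells/mm^2 over 0.881 mm^2)

res$transforms$NRF2
#> Rigid transform: dy = -44, dx = -23 (score 0.893)
unname(ph$section_offsets$NRF2)   # injected truth, recovered exactly
#> [1] -44 -23
```

Reading the output: gray decreases from maternal (102.0) through low (88.0)
to high (68.5) trophoblast density, i.e. NRF2 staining is strongest in
trophoblast-rich patches — exactly the ordering implied by the phantom's
stain strengths (trophoblast 0.60 vs maternal 0.15). The 96 trophoblasts
over 0.881 mm² of included tissue give 108.9 cells/mm², and the injected
serial-section offset (−44, −23) px is recovered exactly from the tissue
masks.

Downstream, `fit_density_band_mixed()` takes one row per subject × band
(e.g. from `as.data.frame()` on the summaries) and returns group × band
estimated means ± SEM with within-band contrasts; `run_table()` produces
the enrichment table (set, transcripts, ES, NES, p) for the five NRF2
functional gene sets plus their pooled union (`read_gmt()` loads set
memberships; a synthetic-membership placeholder ships in `inst/extdata/`).

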