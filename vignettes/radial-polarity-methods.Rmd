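---
title: "Quantifying apical-basal polarity in acinus images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apical-basal polarity in acinus images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialpolarity)
```

## The measurement problem

Mammary epithelial cells grown in 3D culture with reconstituted basement
membrane form acini: round, single-layered glandular units with apical-basal
polarity. Markers such as ZO-1 or cortical actin concentrate toward the
lumen (apical), while markers such as β4-integrin concentrate at the
basement membrane (basal). Loss of this radial organization is an early
event in carcinoma initiation, which makes a quantitative, observer-free
polarity readout valuable for prevention-oriented screens. Visual scoring
at the microscope is slow and subjective; this package replaces it with a
radial intensity profile computed per acinus from a two-channel widefield
image: a nuclear stain (used only to find and delimit acini) and the
polarity marker of interest.

## The pipeline

For each field of view:

1. **Segmentation.** The nuclear channel is smoothed with a 3×3 mean
   filter, binarized by global Otsu thresholding on a 256-bin histogram,
   and mask borders are smoothed by morphological opening and closing
   (disk radius 2 by default). Touching acini are separated by a watershed
   on the negated Euclidean distance map of the mask; shallow seeds within
   `seed_suppression_depth` (default 2 px) of a neighboring basin are
   suppressed so single round blobs are not fragmented. Pixels on divide
   lines revert to background. Finally the labels are dilated (default
   3 px at 20×) because the true membrane edge of an acinus lies outside
   the region found from the nuclear stain.
2. **Quality filtering.** Acini are excluded, in order, when they touch
   the image border, fall outside a configured area range, or score below
   a focus cutoff on the WAVR wavelet focus measure (below).
3. **Contour terracing.** Inside each retained ROI the Euclidean distance
   to the nearest background pixel is treated as a height map — the ROI is
   a "mountain" with its peak at the center — and sliced into `n` terraces
   of equal height range (`n = 8` by default, within the useful 5–10 range
   for acini sampled at 20–40 px diameter; the bin count should be adapted
   to magnification). Terrace 1 is the innermost; terrace `n` touches the
   boundary. Working with distance terraces rather than inscribed circles
   means irregular (non-circular) acini need not be discarded.
4. **Radial profile and RP index.** The mean polarity-marker intensity of
   each terrace is divided by the whole-ROI mean, giving normalized values
   RP_i that are independent of staining efficacy, on a normalized radius
   running from 0 (center) to 1 (periphery). The signed summary is

   RP = s · Σᵢ |1 − RP_i|,

   where the sign s is +1 for descending profiles (apical marker), −1 for
   ascending ones (basal), and 0 for flat profiles. The magnitude is a
   dispersion of the profile about uniformity: 0 for a radially uniform
   marker, larger the more concentrated the marker is at the center (or
   periphery).
5. **Group statistics.** Retained acini are summarized per condition
   (mean, SD, SEM of RP and the group-mean profile) and compared with a
   classical pooled-variance Student's t-test (two-sided; Welch available
   behind a flag).

### Choices the algorithm leaves open, and what this package does

* **Sign of a discrete profile.** The sign is taken from the ordinary
  least-squares slope of RP_i against the terrace's normalized radius
  (i − 0.5)/n. This is robust to single-terrace noise and reduces to the
  intuitive "descending curve ⇒ apical". Slopes within 1e-9 of zero give
  sign 0; such profiles have near-zero magnitude anyway.
* **Distance binning.** Terrace membership is `ceiling(n·d/d_max)` clamped
  to 1..n (then flipped so 1 = center); pixels at exactly the peak go to
  terrace 1. ROIs that are one pixel thin, or that leave any terrace
  empty, are excluded as `degenerate` rather than silently re-binned,
  because merging bins would break cross-acinus comparability of RP_i.
* **Normalizer region.** Profiles and the normalizing whole-acinus mean
  are both computed on the dilated ROI, so the normalization identity
  Σ (countᵢ/area)·RP_i = 1 holds exactly.
* **Dilation collisions.** When dilated labels would meet, contested
  pixels go to the nearest original ROI (ties to the lower label id);
  labels never merge.
* **Coordinates.** 0-based (row, col); bounding boxes half-open.

## The WAVR focus measure

Out-of-focus acini are detected from the nuclear channel with a
wavelet-based focus measure: a single-level 2-D Daubechies-6 transform of
the min-max-normalized bounding-box crop, summarized as the ratio of
detail to approximation energy,

WAVR = (Σ H² + Σ V² + Σ D²) / Σ A².

Defocus removes high-frequency detail, so lower values mean blurrier.
Implementation details that matter:

* The crop is mirrored in both directions before the periodized transform
  (symmetric extension). Without this, the wrap-around discontinuity
  contributes spurious detail energy that dominates at heavy blur and can
  break the monotone response to defocus.
* The transform is orthonormal, so subband coefficient energies equal the
  energies of the reconstructed subband images (Parseval); the ratio is
  computed on coefficients.
* The measure is computed on the un-masked rectangular crop (expanded to
  at least 16×16). Masking to the ROI would inject artificial sharp edges
  into the detail bands.
* WAVR is invariant to intensity scaling but its absolute scale depends on
  image texture, optics, magnification and implementation detail. A fixed
  default cutoff of 0.8 is provided for continuity with customary usage on
  20× widefield nuclear stains, but the portable route is data driven:
  histogram the WAVR values of a visually (or ground-truth) labeled blurry
  and sharp set, fit each class with a Levenberg–Marquardt normal fit
  (`fit_normal()`, Freedman–Diaconis binning with a floor of 10 bins), and
  take the between-means intersection of the two fitted curves
  (`choose_cutoff()`). On synthetic data, whose WAVR scale is far from
  0.8, all tests and examples use either a fitted cutoff or a cutoff of 0.

## What the simulator emulates — and what it does not

`simulate_field()` renders fields of round acini with known ground truth
so that every stage is testable without microscope data:

* **Nuclear channel.** A ring of `nuclei_per_acinus` sharp-edged nuclei at
  0.7·R around each center — deliberately under-covering the true acinus
  extent, which exercises the rationale for ROI dilation — modulated by
  fine-grained chromatin texture, plus a dimmer intra-acinar haze filling
  the interior. The haze stands in for the out-of-focus light that fills
  acinus interiors in real widefield images; without it an Otsu mask of a
  nuclei ring would be an annulus and the distance terraces would never
  see the acinus center.
* **Polarity channel.** A monotone radial law, I(ρ) = 1 + a(1 − ρ) for
  apical, 1 + aρ for basal, flat for nonpolar, with a soft membrane edge
  extending ~2.5 px beyond the nuclear-derived radius. The linear
  center-peaked apical law reflects small-lumen acini (e.g. HMT-3522 S1);
  an `annular` mode with the apical peak on a ring is available for
  large-lumen cysts but unused by default.
* **Degradations.** Per-acinus Gaussian defocus (σ = `defocus_sigma`,
  applied to both channels before noise, as optics act before the camera)
  and field-wide additive Gaussian noise (default sd 2% of the dynamic
  range, a typical noise floor for sCMOS acquisition of stained acini).
* **Determinism.** Everything derives from `seed`; identical configs give
  bit-identical fields.

Defaults (8 acini of radius 15–25 px in a 512² field, 10 nuclei per
acinus, equal phenotype mix, gradient strength a = 1) were chosen once to
resemble a 20× widefield field of view. The test suite mostly uses a
scaled-down variant (256², 4 acini of radius 12–16) to keep runtimes
short; the acceptance script uses the same scaled-down fields with 14–50
fields per experiment (50 acini per group for the polarity comparison, 100
for focus classification, ~200 for the null pool).

What the simulator does *not* model: realistic PSFs, 3-D structure,
multicellular texture beyond the nuclei ring, uneven illumination, or
multimodal marker distributions. Passing tests therefore demonstrate the
algorithm's internal correctness and its behavior under the modeled
degradations, not performance on any particular microscope's images —
on real data the WAVR cutoff and the size range must be established per
dataset, as the interface encourages.

## Numerical and statistical notes

* **Otsu.** The 256-bin histogram spans the observed min–max range; the
  mask is strictly above the selected cut. A constant image yields an
  empty mask with a warning. The implementation agrees exactly with
  exhaustive between-class-variance maximization (tested on random
  images).
* **t-test calibration.** The type-I error of the pooled t-test on RP
  indexes is checked by resampling: a pool of simulated nonpolar acini is
  run through the full imaging pipeline once, then 1,000 replicates draw
  two disjoint groups of 50 from the pool and test at α = 0.05. Under
  this exchangeable null the rejection rate stays within 0.05 ± 0.02.
  (Simulating 100,000 acini through the image pipeline would test the
  same property at far greater cost; the pool design is the package's
  calibration choice.)
* **Blind scoring.** Supervised visual scoring is supported without a
  GUI: `write_blind_manifest()` exports per-acinus crops under randomized
  names in a seeded random order, with condition labels only in a
  separate key file, so any external tool can be used for blind scoring.
* **Statistical units.** Acini are treated as independent units, as in
  the standard analysis of such experiments; `field_id` is recorded in
  every row so users can aggregate per field or fit hierarchical models
  instead.

## Known limitations

* The RP index is insensitive to small radial shifts and unsuited to
  multimodal marker distributions; the profile itself (RP_1..RP_n) is
  retained in all outputs for richer curve descriptors.
* Very large-lumen cysts (apical maximum far from the center) weaken the
  monotone-slope sign convention.
* Segmentation operates on whole acini; nucleus-level segmentation and
  3-D stacks are out of scope (maximum-intensity projections must be
  precomputed).
* WAVR absolute values are not transferable across implementations or
  optics; only orderings and data-driven cutoffs are.
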