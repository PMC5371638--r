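---
title: "Measuring chromosome territory positioning with ctRadial"
author: "ctRadial authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromosome territory positioning with ctRadial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctRadial)
```

## The measurement problem

Interphase chromosomes occupy discrete sub-volumes of the nucleus —
chromosome territories (CTs) — and their radial position correlates with
gene density: gene-rich chromosomes (such as human chromosome 19) sit
toward the nuclear interior, gene-poor ones (such as chromosome 18) toward
the periphery. Perturbations of nuclear lamins can change both chromosome
copy number and territory position, so a quantitative readout of *where* a
territory sits, robust to nuclear size and shape, is needed.

`ctRadial` implements that readout for 3D-FISH confocal stacks of
individually cropped nuclei: a DAPI channel delimits the nucleus, one or
two chromosome-paint channels mark territories, and optional channels carry
an immunostained lamina reference and a BAC-probed gene locus.

## The percent radial distance construction

For each territory the package builds three collinear points:

* **A** — the geometric centre of the segmented nucleus,
* **B** — the geometric centre of the territory,
* **C** — the point where the ray from A through B crosses the nuclear
  periphery.

With `X = |AB|` and `Y = |AC|`, the percent radial distance is

$$\mathrm{RD} = 100 \cdot \frac{X}{Y},$$

so 0% is the nuclear centre and 100% the periphery, independent of nuclear
size and (for a convex nucleus) insensitive to ellipticity, because the
normalization distance `Y` is measured along the same ray as `X`.

Two details are resolved explicitly because a binary mask has no continuous
boundary:

* **Periphery crossing.** The ray is marched in physical micrometres at a
  step of one quarter of the smallest voxel dimension; C is the midpoint of
  the last sample inside the mask and the first sample outside. At the
  default calibration this locates the boundary to roughly 0.13 um, without
  the cost of a marching-cubes isosurface.
* **Degeneracy.** If B coincides with A within 1e-9 um the measurement
  returns RD = 0 with C flagged undefined. If a noisy segmentation puts B
  marginally outside the mask, RD is capped at 100.

All geometry is computed in micrometres, never in voxel units: confocal
stacks are strongly anisotropic (default calibration 0.34 um z-step against
0.105 um pixels), and any voxel-space shortcut would bias distances along z
by a factor of three.

### Sub-shell binning

Radial distances are summarized in five concentric sub-shells of 20% RD
each, labelled I (innermost) to V (peripheral). Shell boundaries are
**upper-inclusive**: shell *k* covers RD in ((k−1)·20, k·20], with RD = 0
assigned to shell I. This convention is forced by the field's labelling of
RD ≈ 80% as shell IV and RD ≈ 60% as shell III; it is unit-tested at the
boundaries. No equal-volume erosion-shell variant is provided — the shells
are equal-width in RD, not equal-volume in nuclear content.

### Locus-to-lamina distances

Gene loci are scored by the closest distance between the locus **centre of
mass** (intensity-weighted — a diffraction-limited spot is better located
by its intensity profile than by its thresholded footprint) and the
**surface** of the lamina anchor. The surface is the set of anchor voxels
with at least one of six face-neighbours outside the mask; the distance is
the minimum Euclidean distance in um to those voxel centres. This matches
an exhaustive search by construction and is tested against one. Nuclei and
territories, in contrast, use the unweighted geometric centroid — solid
bodies rather than point sources.

## Segmentation choices

* Otsu's threshold is the default for every channel; a fixed threshold is
  available as a configuration knob and the method used is echoed in every
  report. The fixed threshold is inclusive (`intensity >= t`).
* Components are 26-connected in 3D. Objects under 50 voxels (configurable)
  are discarded as hybridization speckle; locus spots use a lower floor of
  10 voxels.
* The nucleus is the largest component after 3D cavity filling (background
  regions not connected to the image border become foreground). Filling
  matters: chromocenters and nucleoli produce dark interior volumes, and an
  unfilled nucleus would bias its geometric centre.
* Interphase copy number is the number of retained territory objects in a
  paint channel: fewer than 2 is a loss (0 additionally QC-flagged as a
  possible hybridization failure), 2 is diploid, more than 2 an aneuploid
  gain. Metaphase spreads are classified separately by total chromosome
  count: 45–46 pseudo-diploid, <45 loss, >46 gain.

## Statistics

Shell distributions of two conditions are compared twice — a chi-squared
test on the 2×5 contingency table (shells empty in both conditions dropped
with a warning) and per-shell 2×2 Fisher's exact tests — and both results
are reported; when the two routes disagree at the 0.05 level the report
flags the disagreement rather than resolving it. Raw (unbinned) distance
samples are compared with the two-sample Kolmogorov–Smirnov test; volume
comparisons across conditions or shells use the Kruskal–Wallis rank test
with midrank ties. Dispersion is reported as median and IQR (Q3 − Q1,
linear-interpolation quantiles). No multiple-testing correction is applied
by default, matching the reporting convention of the source analyses;
`p.adjust` can be applied downstream by the user.

On the expression side, a gene is deregulated when its absolute linear
fold change is **at least 2.0 (inclusive)** and its p-value is **strictly
below 0.05**; per-chromosome percent deregulation is
100 · (deregulated genes on the chromosome) / (coding genes on the
chromosome), and chromosomes are flagged significant **strictly above
0.7%**. These boundary conventions are read literally from the filter
definition and are unit-tested at the boundaries (FC = 1.99 fails,
p = 0.05 fails, 0.7% exactly is not significant). The deregulation–density
relationship is summarized by the r² of an ordinary least-squares fit of
percent deregulation on gene density (genes/Mbp).

## The synthetic-data generator

Because raw confocal stacks for this kind of study are rarely deposited,
every stage is validated against a generator with planted ground truth.

* **Nucleus**: a convex triaxial ellipsoid. Convexity keeps the A→B→C ray
  construction unambiguous; real Lamin-depleted nuclei show invaginations
  and blebs, which the generator deliberately does not reproduce (see
  *Limitations*). Default semi-axes (4.2, 3.8, 3.2) um give a nuclear
  volume of ~214 um³, a compact near-diploid epithelial nucleus.
* **Territories**: equal-volume balls of the `n` voxels nearest the planted
  centroid, `n = round(targetVolume / voxelVolume)` — the rendered volume
  matches the target to one voxel. The planted centroid sits at
  `fractionalRd` times the centre-to-surface distance along a chosen
  direction, so the planted RD is exact by construction. Default per-copy
  volume 2.8 um³, the scale of painted territories in colorectal
  adenocarcinoma lines. In cohorts, copies are rejection-sampled to be at
  least one ball diameter plus 0.4 um apart, so planted copies are distinct
  hybridization signals.
* **Acquisition**: voxel size 0.34 × 0.105 × 0.105 um (z, y, x), 8-bit
  depth; Gaussian PSF of sigma (0.30, 0.13, 0.13) um; Poisson shot noise at
  80 photons per unit signal and Gaussian read noise of 1 quantization
  unit. The detector of the reference acquisitions is uncharacterized, so
  the noise defaults were fixed once at a level where Otsu segmentation
  recovers ≥ 99% of planted voxels — the generator validates the geometry
  pipeline; it is not a camera model.
* **Expression tables**: per chromosome, exactly
  `round(fraction/100 × codingGenes)` genes pass the deregulation filter
  and every other gene fails at least one criterion (too-small fold change,
  p ≥ 0.05, or both, in 40/40/20 proportions), so the planted fraction is
  recovered exactly up to rounding. A forced-id mechanism plants a common
  deregulated set across two knockdown tables for overlap tests.
* **Reproducibility**: the acquisition seed makes stacks and tables
  bit-identical across runs; cohort cell `i` is seeded `seed + i`.

The shipped `chromosome_annotation_synthetic.tsv` is a synthetic stand-in
for a genome-browser gene census: lengths are approximate human chromosome
lengths, and densities for chromosomes 1, 11, 16, 17, 18 and 19 match the
published per-chromosome gene densities (15.83, 17.5, 17.05, 24.21, 8.21
and 37.08 genes/Mbp); other rows are plausible placeholders.

## Validation scale and observed performance

The test suite and the acceptance script size their simulations to run on
a single CPU in minutes; the sizes are the package's chosen validation
conditions, stated here so results are interpretable:

* RD recovery: 100 cells, one territory each, planted RD uniform on
  [5%, 95%], full default acquisition. Mean absolute recovery error is
  well under 3 RD points (typically ~0.6).
* Ploidy: 100 nuclei, 30% planted with a third copy. Copy counts are
  recovered exactly on every cell at these noise levels.
* Null calibration: 200 random 60/60 splits of one pooled RD sample keep
  the chi-squared rejection rate at or below 7% at nominal 5%; KS power
  against a planted lognormal median shift (0.72 → 1.40 um, sdlog 0.5,
  n = 60 per group) exceeds 90%.
* Oracles: connected-component labeling is checked against a brute-force
  flood fill, lamina distances against an exhaustive surface scan (exact
  agreement), Kruskal–Wallis against the closed-form midrank statistic
  (1e-9), and r² against the squared Pearson correlation (1e-12).

## Numerical and interface conventions

* Axis order is (Z, Y, X) everywhere; voxel indices are 1-based in R code;
  the physical coordinate of a voxel is its centre,
  `(index − 0.5) × voxelSize` um.
* TIFF stacks are written channel-major (C, Z, Y, X) with a JSON sidecar
  carrying voxel size, channel names and bit depth; on read the sidecar,
  then ImageJ-style tags, then a configured default (with a warning) supply
  the calibration. Proprietary LSM/CZI files are out of scope — convert to
  TIFF first.
* Component ordering is deterministic: decreasing size, ties broken by the
  smallest (z, y, x) minimum voxel index, so reports are byte-identical
  across reruns with the same seed.
* Chromosome labels are normalized to 1–22, X, Y; genes mapping to several
  chromosomes are counted once per chromosome.

## Design decisions that were genuinely open

* The periphery point C is taken on the binary mask edge, not a rendered
  isosurface; which of the two the original interactive tools used is not
  documentable, so the cheaper, testable construction was chosen and is
  stated in every report.
* Aneuploid cells contribute every territory copy as an independent
  measurement (pooled per-territory n), and diploid/aneuploid strata are
  kept separate with a pooled view also emitted.
* Fold changes are declared linear in the input schema; log2 inputs must
  be converted upstream.
* Both the chi-squared and per-shell Fisher routes are always computed —
  reporting both is a reporting decision, not an inference one.

## Limitations

* The generator's nuclei are smooth and convex; lobulated or invaginated
  nuclei can place the mask edge closer to the centre than the convex
  hull, and passing synthetic tests does not certify behaviour on such
  shapes. The RD construction itself remains well-defined whenever A lies
  inside the mask.
* No spectral bleed-through, no mitotic figures, and only a Gaussian PSF:
  optical aberrations and depth-dependent attenuation are not modelled.
* One nucleus per stack is assumed (cropped fields); touching nuclei are
  not split.
* Published image-derived numbers (median RD and volume tables from real
  knockdown experiments) require the original microscopy data and are
  emulated here only in table *shape*, not in value.
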