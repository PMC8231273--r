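---
title: "Spatial analysis of drug distribution in lung MSI data: models and methods"
author: "msiSpatial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial analysis of drug distribution in lung MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiSpatial)
```

# Scope

`msiSpatial` analyses MALDI mass spectrometry imaging (MSI) data from
drug-distribution experiments in lung tissue: centroid spectra acquired on a
regular 400 µm raster over transverse lobe sections, with a drug channel
(GirP-derivatized budesonide, m/z 564.308), a sprayed internal standard
(derivatized triamcinolone acetonide, m/z 568.283), a tissue marker (heme b,
m/z 616.176) and — on consecutive sections acquired in a high-mass window —
the surfactant marker SP-C (m/z 4188). This vignette explains the models
and procedures, the tunable parameters, and the design decisions taken
where the methodology was genuinely open.

# The analysis pipeline

## Ion images, normalization, masking

An ion image is built per pixel as the **sum** of centroid intensities
within ± `toleranceDa` of the target m/z (0.005 Da for the small molecules,
1 Da for SP-C). Summing is robust to centroid splitting; `aggregate = "max"`
is available where a single-centroid convention is preferred. Pixels not
acquired, dropped, or thresholded away are *missing* (`NA`), never zero, so
every downstream statistic runs over tissue pixels only.

The drug channel is divided pixel-wise by the internal-standard channel;
pixels with a non-positive reference are dropped and tallied. Because both
channels share each pixel's acquisition efficiency (spray density, matrix
crystallization, laser coupling), the ratio cancels common-mode variation —
this is the entire point of spraying a chemically similar internal standard.

The tissue mask is taken from the heme channel, which is present only where
there is tissue: a pixel is on-tissue when its heme intensity exceeds
`minFraction` (default 0.05) of the median positive heme intensity, and
only the largest connected component is kept. The default 0.05 is
deliberately permissive — heme is orders of magnitude above its background
on tissue — and the component filter removes stray off-tissue specks.

## Detection threshold from control sections

Sections from animals that never received the drug define what "no signal"
looks like in the drug window. The threshold is the 0.99 quantile
(linear-interpolation convention, `stats::quantile` type 7) of the pooled
on-tissue normalized control intensities; treated-section pixels above it
count as detected drug. The quantile is a tunable: control-based thresholding fixes no particular
rule, so 0.99 was fixed once as "1% false-positive pixels on the controls
by construction." Thresholding is applied to *normalized* intensities:
normalization is part of map creation, so the detection decision should be
made on the scale the maps are drawn on.

## Quartile binning and clumps

Each section is scaled and mean-centered (z-scored over on-tissue pixels,
on the normalized linear scale — no log transform is part of this step) and
binned into intensity quartiles by rank: rank $r$ of $n$ maps to label
$\lceil 4r/n \rceil$, with ties broken deterministically by row-major pixel
order. Binning therefore depends only on ranks: z-scoring first changes
nothing (it is monotone), which the test suite asserts. The four classes
always partition the tissue with sizes differing by at most one pixel.

**Clumps** are the connected components of 4th-quartile pixels. The default
adjacency is 8-neighbor ("queen"); "adjacent raster cells" admits either
convention, and 4-neighbor is available by argument. A clump set is summarized by its count
and median size in pixels. Components are found by iterative minimum-label
propagation, and the implementation is checked exhaustively against an
independent flood-fill oracle on all $2^{16}$ 4×4 grids and on random
50×50 grids.

## Tissue border and distance profiles

The tissue border is the **alpha shape** of the on-tissue pixel centers in
physical millimetres: an edge between two centers belongs to the border
when one of the two circles of radius $\alpha$ through them contains no
other tissue center. For $\alpha$ at least the diameter of the point set
this is exactly the convex hull (and the implementation takes that path);
for small $\alpha$ the border follows concavities. The default
$\alpha = 1.2$ mm (3 × pixel pitch) is the smallest value that reliably
keeps the generator's lobe masks single-ringed. Values below the pixel
pitch are rejected: a raster mask cannot support boundary detail below its
own step. Candidate border vertices are restricted to mask-boundary pixels,
which is exact for $\alpha \ge$ pitch (an interior grid point always has a
neighbor inside any such circle through it).

Each 4th-quartile pixel's Euclidean distance to the nearest border point is
binned into half-open 3 mm intervals [0,3), [3,6), [6,9), [9,12); fractions
divide by the total number of 4th-quartile pixels. Pixels that fall outside
all rings (possible only with a small $\alpha$) are assigned distance 0 and
tallied as a warning count in the profile and the pipeline manifest.

## Group comparisons

Per-section (per-animal) values — never pixels — are the experimental unit.
Two groups are compared with a Wilcoxon rank-sum test using mid-ranks for
ties; for combined $n \le 20$ the two-sided p-value is **exact**, by full
enumeration of all $\binom{n_A+n_B}{n_A}$ assignments of the observed
ranks, with the doubled-smaller-tail convention
$p = \min(1,\, 2\min(P(W \le w), P(W \ge w)))$. A deviation-based
enumeration ($P(|W - EW| \ge |w - EW|)$) is provided for sensitivity
analyses. Larger samples fall back to the tie-corrected normal
approximation. The exact path is verified against a bit-mask permutation
oracle on all sizes up to $n = 10$, with and without ties.

The per-bin distance comparisons use the per-animal bin *fractions*
(counts are available by argument) and report raw p-values, one per 3 mm
bin, without multiplicity adjustment — matching how such per-bin results
are conventionally reported.

Animal-level covariates available only as mean ± SD per group are compared
by reconstructing the one-way ANOVA from summaries:
$SSB = \sum_i n_i(\bar x_i - \bar x)^2$, $SSW = \sum_i (n_i - 1) s_i^2$,
$F = (SSB/(k-1)) / (SSW/(N-k))$, identical to `aov()` on any raw data with
those summaries (property-tested). A Tukey HSD from summaries is included
as the conventional post hoc companion; it is one of several defensible
post hoc procedures, and others would give other p-values.

# The synthetic cohort generator

No raw data are publicly deposited for studies of this design, so the
package ships a seeded generator whose defaults encode the study
conditions; it is first-class, tested code, and the ground truth it returns
(mask, drug field) is what several tests validate against.

## Geometry

The default grid is 50 × 125 pixels at 400 µm pitch — a ~20 × 50 mm
transverse lobe section. The mask is a randomly modulated ellipse
(low-order sinusoidal radius perturbations) with a disk-shaped "bite"
removed at a random boundary point, guaranteeing at least one concavity;
the largest connected component is kept. Across seeds the mask fills
roughly 55% of the grid, within the 30–80% band the downstream geometry
assumes. Consecutive-section pairs (drug and SP-C acquisitions) share the
same mask with independent noise, since 20 µm neighbouring sections are
near-identical in gross geometry.

## Intensity model

The drug field is a sum of isotropic Gaussian foci on the mask. Foci
centers are drawn with peripheral bias: with probability `peripheralBias` a
center is sampled with weight $e^{-d/\lambda}$ ($d$ = distance to border,
$\lambda = 2$ mm), otherwise with weight proportional to $d$. The four
patterns are:

| pattern   | foci | σ (mm) | bias | emulates                           |
|-----------|-----:|-------:|-----:|------------------------------------|
| clumpy    |    4 |    2.5 |  0   | saline vehicle: few dense patches   |
| dispersed |   40 |    0.8 |  0.7 | surfactant-assisted spreading       |
| cleared   |   40 |    0.8 |  0.7 | dispersed × (1 − 0.93) after 2 h    |
| control   |    0 |      — |  —   | no drug                             |

The 0.93 clearance default matches the ~93% loss of lung budesonide
observed two hours after intratracheal administration. A cleared section is defined as
its seed-matched dispersed section with the *entire* drug window (signal
plus in-window background) attenuated by the clearance fraction, so the
total-intensity ratio between matched sections is exactly
$1 - \text{clearanceFraction}$; control sections keep an unattenuated
background, which is why the above-threshold pixel count of a cleared
section collapses against the control-derived threshold.

Multiplicative noise has two parts, and the split matters. A per-pixel
acquisition-efficiency factor (log-normal, CV = `noiseCv`, default 0.3) is
**shared by all channels of a dataset** — spray and matrix heterogeneity
act on every ion of a pixel alike, which is precisely why internal-standard
normalization works. A smaller channel-specific residual (CV = `noiseCv`/6)
survives normalization. Modelling all noise as channel-independent would
make normalization *add* noise (a ratio of independent log-normals), and
its heavy tails fragment the top quartile of the large foci into spurious
singleton clumps — inverting the median-size ordering the patterns are
meant to produce. `noiseCv = 0` produces a fully noiseless section
(multiplicative noise, chemical background and noise peaks all off), used
by the ground-truth recovery tests.

Every registered channel also sits on an additive chemical background:
gamma-distributed with shape 16 (a sum of many small matrix-cluster
contributions, hence mildly dispersed; an exponential's heavy tail would
again seed spurious top-quartile singletons), with mean 6% of the base
intensity in the drug window, 3% for the internal standard and SP-C, and
0.3% for heme (heme's background must stay far below the mask threshold).
This background is what gives control sections a full log-intensity
distribution and makes the control-derived threshold meaningful. Sparse
chemical-noise centroids (Poisson rate 4 per pixel, ~0.1% of base
intensity, sampled outside the target windows) populate the rest of each
spectrum, so off-tissue pixels are non-empty and masking is genuinely
exercised.

The SP-C channel mixes the (normalized) drug field with an independent
smooth field in proportion `spcCoupling` (default 0.8) for
surfactant-treated patterns; at full coupling and zero noise its rank
correlation with the drug image is exactly 1. Sections of the saline-only
pattern carry no SP-C signal, and budesonide-free controls carry SP-C
uncorrelated with (absent) drug.

Pattern defaults were calibrated once so that the generator reproduces the
*ordering* of the clump statistics — the dispersed group shows more,
smaller clumps — not their absolute values, which no published numbers pin
down. With these defaults the separation is complete in both statistics
across seeds, so a 5-vs-5 exact Wilcoxon comparison attains its minimum
two-sided p-value of $2/\binom{10}{5} \approx 0.0079$.

## What the generator does not emulate

No derivatization chemistry, matrix crystallization texture, mass-accuracy
drift, isotope envelopes, or inter-animal anatomical variation beyond the
randomized lobe outline. Passing tests on synthetic cohorts demonstrate
that the pipeline recovers known spatial structure under this model — not
that the model captures every property of real acquisitions.

# File format

Datasets are written as processed-mode, centroid imzML/ibd pairs: 64-bit
m/z (a 0.005 Da window needs the precision), 32-bit intensities, pixel
coordinates 1-based in the file (imzML convention) and 0-based in memory,
with the conversion confined to the I/O boundary. Continuous-mode files are
rejected rather than silently converted, since the analysis assumes
centroided acquisitions. The ibd UUID is derived from the MD5 of the binary
payload, making exports byte-reproducible; the recorded ibd MD5 is verified
on read. Files written by the package are also readable by the standard
Python imzML parser, which the test suite checks.

# Numerical choices and degenerate inputs

* Quartile ties: broken by row-major pixel order — fully deterministic and
  documented, because any tie rule is arbitrary.
* Constant sections cannot be z-scored (error), constant channels have no
  rank correlation (error), all-zero heme means no detectable tissue
  (error). Empty clump sets are valid (count 0, median `NA`).
* Masks smaller than 4×4 pixels and alpha values below the pixel pitch are
  rejected with sizing errors.
* Exact-test tail comparisons use a 10⁻⁹ tolerance on rank sums (mid-ranks
  are multiples of ½, so this only absorbs float noise).
* The pipeline writes no timestamps into its summary or manifest, so a
  rerun with the same configuration is byte-identical.

# Problem sizes used by the test suite

The suite exercises full-size sections (50 × 125 px) throughout. The
pattern-recovery property runs 20 independent cohorts of 3 sections per
pattern; the group-separation check uses the 5-vs-5 group design; oracle
equivalence covers all 65,536 4×4 grids plus 1,000 random 50×50 grids;
I/O round-trips run on 25 randomized small datasets and a full 5-section
cohort. These sizes keep the default run of the suite within a few minutes
while leaving every scientific claim tested at the scale the pipeline
actually operates on.

# Limitations

* The alpha-shape ring assembly assumes the border edges of a fat,
  connected mask; pathological masks (one-pixel-wide spurs) can yield
  non-simple walks. Generator masks are smooth by construction.
* The colocalization score is computed on a shared grid; no image
  registration between consecutive sections is attempted.
* No spatial autocorrelation correction is applied to pixel-level
  summaries; inference is deliberately at the section level.
* The SP-C target (m/z 4188) is stored as an opaque registry entry: whether
  it is a monoisotopic or average mass of the palmitoylated peptide is not
  specified by the assay description, so no formula check is possible.
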