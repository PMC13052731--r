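---
title: "Methods: nuclear morphometry and migration quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear morphometry and migration quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nucmorph quantifies the microscopy readouts used to study transient
nuclear softening: treating cells with a histone deacetylase (HDAC)
inhibitor such as trichostatin A (TSA) decondenses chromatin, softens the
nucleus, and transiently raises interstitial 3D migration through dense
extracellular matrix. The package implements the measurement chain —
chromatin condensation parameter (CCP), strain-tracked nuclear aspect
ratio (NAR), 3D infiltration scoring, scratch closure, per-cell intensity,
nascent matrix per nucleus, and differential-expression (DE) summaries —
together with a seeded synthetic-data generator that provides ground truth
for every stage. This vignette records the models, the parameters that
matter, and the design decisions taken where the underlying methods
literature leaves the choice open.

## The chromatin condensation parameter

Condensed heterochromatin appears in DAPI images as bright punctate foci;
decondensed chromatin is smooth. The CCP measures this as Sobel edge
density inside a nucleus mask:

1. intensities are min–max normalized *within the mask*, so staining
   brightness and any affine intensity rescaling cancel exactly;
2. the 3×3 Sobel gradient magnitude is computed (reflected padding at the
   image border, with a warning when a mask touches the border);
3. pixels whose magnitude exceeds a threshold are counted as edge pixels,
   restricted to the mask interior eroded by 1 px so the nuclear rim —
   otherwise the dominant artifact — is never scored;
4. CCP = edge pixels / mask area, a unitless fraction in [0, 1].

**Threshold design.** The methods literature never states the edge
cutoff, and the choice is not innocuous. A cutoff relative to the
*observed* maximum gradient cannot behave correctly: smoothing an image
compresses its gradient histogram from the top, so the above-threshold
fraction *rises* under blur, the opposite of what an edge-density proxy
for condensation must do. nucmorph therefore fixes the threshold on the
normalized gradient scale: `frac` times the maximum magnitude a
unit-range image can produce (`4 * sqrt(2)` for the 3×3 Sobel pair). The
default `frac = 0.25` places the cutoff *between* two physically distinct
gradient scales: nucleus-wide shading (a smooth dome of radius $r$
contributes normalized gradients of order $2/r$, about 0.17 of the Sobel
scale for a 12 px nucleus, and must not count as edges) and punctate
heterochromatin foci (gradients of order $A/\sigma$, several times
higher). At substantially lower fractions the dome itself is scored as
edge and the condensed/decondensed contrast inverts; the resulting
default yields CCP values of ~0.1–0.2 for condensed nuclei, the range
typically reported for this statistic. Otsu-on-gradient is available as
an alternative policy, and the policy and threshold used are attached to
every result.

Per-nucleus CCP values are reported as a percent change against the mean
CCP of the vehicle-control population,
$100\,(\mathrm{CCP}_i - \overline{\mathrm{CCP}}_{ctrl}) / \overline{\mathrm{CCP}}_{ctrl}$,
so the control population is centred at 0% by construction.

## Nuclear aspect ratio under applied strain

NAR is the major/minor axis ratio of the ellipse with the same second
central moments as the nucleus mask (the *moment ellipse*; the bounding
or boundary-fitted ellipse would weight outliers and boundary noise far
more heavily). Moments are computed with the 1/12 per-pixel variance
correction — a pixel is a unit square, not a point — which keeps small
rasterized shapes close to their continuous counterparts. A numeric mask
is treated as per-pixel coverage weights, so anti-aliased rasterizations
can be measured at sub-pixel precision; binary masks of nuclei with
minor semi-axis below ~6 px carry an intrinsic discretization error of
1–4%, which is why the strain pipeline quotes a 3% tolerance against
affine ground truth while the anti-aliased validation reaches 1%. Masks
with a moment minor axis below 2 px are rejected as degenerate.

Tracking across strain levels uses greedy nearest-centroid matching after
compensating the global affine stretch between frames, estimated from the
per-axis ratio of centroid-cloud standard deviations (the applied strain
moves every nucleus; the compensation removes that common motion before
distances are compared). The default residual displacement gate is 15 px.
Tracks are anchored at 0% strain; a nucleus lost at any level censors the
rest of its track rather than being interpolated. The response summary
fits an ordinary least-squares NAR-vs-strain slope per track and reports
the Pearson correlation of pooled (strain, ΔNAR) pairs with
ΔNAR = NAR(ε) − NAR(0); a flat response (zero variance) reports r = 0
with a `constant` flag rather than NA.

## 3D infiltration scoring

The migration assay images two channels through a devitalized tissue
section: a cell channel and a tissue channel. Depth is signed along z,
positive into the tissue, so flipping a stack in z negates depths.

*Interface.* Each plane's tissue occupancy fraction (Otsu-binarized over
the whole channel) is computed; the interface is the first z, linearly
interpolated between planes, where occupancy crosses half its plateau
(maximum) value. The rule works for either stack orientation. Its worst
case is half a z-step when the true interface falls on a plane.

*Cells.* Cells are detected as 26-neighbourhood local maxima of the
Gaussian-smoothed cell channel (σ = blob radius / 2 per axis, in voxel
units) above 0.3× the smoothed maximum, with maxima closer than two blob
radii suppressed in descending-intensity order, and refined by an
intensity-weighted centroid over a blob-sized window. Depth is centroid z
minus interface z.

*Embedded.* "Entirely embedded within the tissue" is operationalized as
depth ≥ margin, with the margin defaulting to the blob radius: a sphere
whose centre is one radius below the interface is exactly fully inside.
Full 3D per-cell segmentation is deliberately out of scope; the margin
rule is the geometric equivalent for the rendered blobs.

Percent migrated is embedded / total × 100 over the field of view, and
the cumulative-frequency curve reports the percent of cells at or above
each depth bin, always ending at 100%.

## Scratch closure

The scratch void is detected by *texture*, not brightness, because a
cell monolayer and a void can share mean intensity: a local
intensity-variance map (7×7 box) is Otsu-thresholded, and the
low-variance mask is morphologically closed, then dilated by the window
half-width — a windowed variance erodes a true void by half a window at
each texture boundary, and the dilation compensates that bias exactly for
straight boundaries. Two guards make the detector honest: the
low-variance class must sit at least 5× below the texture class in mean
local variance (otherwise the frame is confluent and the Otsu split is
just texture noise — a real void sits ~500× below the texture class,
while in a confluent frame the two classes differ by barely 20%, so the
0.2 ratio gate separates the regimes by orders of magnitude), and the
component must span ≥90% of the frame height.
The closure rate is the OLS slope of area versus time over frames before
the first fully closed frame.

## Intensity and nascent-matrix readouts

Per-cell intensity is the mean of the fluorescence channel over each
nucleus mask (the per-cell ROI choice is configurable upstream by what is
segmented; nucleus masks are the default because they are what the
counterstain defines). Percent-positive uses a strict inequality, so
cells at exactly the threshold are negative; the threshold is a required
analysis parameter, with Otsu over the per-cell means as an optional
default. Nascent-matrix area is the Otsu foreground of the matrix
channel after removing speckles below the minimum object area, divided by
the nucleus count from the counterstain channel. A saturation QC flag is
raised when more than 20% of the matrix foreground sits at the channel
maximum, since densely overlapping staining cannot be quantified
reliably.

## DE summaries

A gene is differentially expressed when adjusted p < 0.05 **and** linear
|fold change| > 2, both strict; on the log2 scale the second cut is
|log2fc| > 1, matching DESeq2-output conventions. Rows with missing padj
are dropped with a logged count. Set overlaps are computed exactly
(sizes, pairwise intersections, unique counts, and full membership
patterns), and matched fold-change correlation reports Pearson's r with
an OLS fit over genes present in both tables — genes in one table only
are excluded, never imputed. Which genes enter the correlation (union or
intersection of the groups' DE sets, or any custom set) is the caller's
choice via `gene_filter`; the analysis scripts use the union.

## Statistics

Two groups are compared with an unpaired two-sided t-test (pooled
variance by default, matching the classic unpaired test; Welch via
`welch = TRUE`), three or more with one-way ANOVA plus Tukey's HSD
(via the studentized-range distribution underlying `TukeyHSD`), with
significance at α = 0.05. The ANOVA path's type-I error is verified by
simulation to sit within Monte-Carlo error of α.

## The synthetic generator: what it emulates, and what it does not

All validation runs on generated data with known truth, because the
original study's raw images and sequencing data are not available at
analysis time. The generator is a first-class, tested module and its
defaults are the study conditions used throughout:

- **Nucleus fields** — 25 non-overlapping elliptical nuclei per field
  (matching the per-condition nucleus counts of the motivating assay),
  mean radius 12 px, rendered as a uniform interior plus a faint radial
  dome plus sum-of-Gaussian heterochromatin foci (8 per nucleus, σ ≈
  radius/8). The condensation knob scales foci amplitude *and* sharpness:
  decondensed chromatin is dimmer and smoother, not merely dimmer — an
  amplitude-only change would be invisible to any normalization-invariant
  texture statistic, and texture smoothing is what decondensation looks
  like in DAPI. Within-nucleus intensity variance is strictly increasing
  in the knob. The dome matters: it anchors the per-nucleus intensity
  range so foci contrast is measured against a stable baseline, as in
  real nuclei.
- **Strain series** — the base frame resampled under the plane-strain
  affine map x → (1+ε)x with configurable transverse contraction
  (area-preserving 1/(1+ε) by default, since only grip-to-grip axial
  strain is controlled in the physical assay; "none" reproduces pure
  uniaxial stretch). True NAR per nucleus per frame follows from the
  transformed covariance analytically. Nucleus placement is confined so
  no nucleus leaves the field of view at maximum strain — the physical
  assay tracks the same nuclei at every strain level.
- **Migration stacks** — tissue occupying z ≥ interface with speckle
  texture; cells as 3D Gaussian blobs (radius 5 µm, z-step 2 µm). The
  default depth distribution is bimodal: surface-retained cells rest *on
  top of* the section, centroid about one blob radius above the
  interface, and infiltrated cells lie at least one radius below it.
  Partially embedded intermediates are transient states of the real assay
  and are not drawn by default; a normal depth distribution is available
  for distribution-shift experiments. Truth flags a cell embedded iff its
  whole blob support is inside the tissue (depth ≥ blob radius).
- **Scratch series** — high-variance speckle monolayer with a central
  low-intensity band narrowing linearly to zero; truth areas are exact
  rectangle areas.
- **DE tables** — true effects get |log2fc| in [1, 4] and padj < 0.05;
  background genes get small-noise fold changes and padj ≥ 0.05, so the
  significance filter recovers truth exactly by construction (filter
  *behaviour* near the cuts is tested separately with padj values
  straddling 0.05).

Not emulated: optical point-spread functions, shot noise statistics,
uneven illumination, chromatic registration error, segmentation-breaking
cell clumping, or any transcriptome-level count structure (DE tables are
consumed downstream of model fitting, never simulated at read level).
Passing tests therefore demonstrate correctness of the measurement chain
given clean, well-separated objects — they do not certify robustness to
acquisition pathologies of real microscopy.

## Numerical choices and degenerate inputs

- Determinism: every generator routes randomness through an
  integer-seeded RNG scope that restores global RNG state; identical
  spec + seed reproduce outputs bit for bit, and report bundles embed no
  timestamps so reruns are byte-identical.
- Segmentation: Otsu threshold (fixed override available), holes filled
  before measurement, optional distance-transform watershed with h = 2 px
  tolerance for touching nuclei, minimum object area 50 px². Constant
  images yield zero objects, not an error.
- Problem sizes in the tests and acceptance script — fields of 25 nuclei,
  10 tracked nuclei across 6 strain levels, stacks of 20–40 cells, 20
  seeded stacks for depth-recovery statistics, 1000-gene DE tables, 1000
  null simulations for ANOVA calibration — were chosen as the smallest
  sizes at which the verified properties are statistically meaningful,
  and mirror the per-condition scale of the motivating assay.
- Ties: percent-positive and the DE filter use strict inequalities
  throughout, so boundary values are never counted as positive.
- Degenerate masks: empty masks error; masks with moment minor axis
  below 2 px are rejected for NAR; empty cell sets error for
  percent-migrated and cumulative frequency rather than returning NaN.

## Known limitations

- The CCP edge threshold, while principled, remains a tunable with no
  published reference value; comparisons should always be within-study
  against a contemporaneous control population, which the percent-change
  normalization enforces.
- NAR from binary masks is discretization-limited below ~6 px minor
  semi-axis; strain-series conclusions should rest on nuclei imaged at
  ≥10 px radius.
- Interface detection assumes a monotone occupancy transition; tissue
  channels with internal voids large enough to dent the occupancy
  plateau would need the detection profile inspected (it is attached to
  the result).
- The blob-maxima cell detector assumes cells further apart than two
  blob radii; heavily clumped cells will be under-counted.
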