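---
title: "Methods: automated MLH1 screening of tissue microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated MLH1 screening of tissue microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Loss of nuclear MLH1 expression marks mismatch-repair-deficient (dMMR)
colorectal cancers, a clinically important subgroup for Lynch-syndrome
screening and immunotherapy eligibility. Screening a tissue microarray (TMA)
of immunostained cores by eye is slow and observer-dependent. `tmascreen`
implements a reproducible digital pipeline that, for each 0.6 mm core on a
brightfield H-DAB slide, calls the dominant histology (normal epithelium vs
tumour) and the MLH1 status (proficient vs deficient), and — crucially —
*flags* any core whose cell-level evidence is not decisive instead of
guessing, so that only ambiguous material goes back to a pathologist.

# Pipeline and model

The stage order is fixed: colour deconvolution, positive cell detection,
smoothed neighbourhood features, tissue classification, dearraying,
certification, evaluation.

## Stain physics

Brightfield absorbance follows Beer-Lambert per RGB channel:
`I = I0 * 10^(-OD)` with `OD = sum_s c_s * v_s`, where `v_s` are unit OD
vectors for haematoxylin, DAB and an orthogonal residual. The defaults are
the H-DAB vectors (0.67253, 0.56452, 0.47856), (0.25141, 0.41193, 0.87585)
with background (235, 232, 239). `deconvolve()` inverts the 3x3 system per
pixel, clamping negative concentrations at zero. Intensity is clamped at 1
before the log so black pixels stay finite, and OD is clamped at zero above
the white point.

The round trip compose-then-deconvolve is exact up to 8-bit quantisation:
below roughly 1 OD per channel the error stays under 0.02 OD, which covers
the nuclear staining range the simulator produces; at very high OD (dark
pixels, intensity < ~10) quantisation alone exceeds that bound, which is a
property of 8-bit imaging, not of the inversion.

`estimate_stain_vectors()` recovers the two dominant stain directions from
the OD point cloud: stained pixels (total OD >= 0.3) are projected onto
their top two principal directions, the 1st/99th percentile angles give
initial extremes, and each direction is then refined by an angular
mean-shift (window 4 degrees, 3 iterations) over the extreme cluster. The
refinement matters: a raw quantile direction sits in the noise tail and is
biased outward by ~3 degrees at our noise level, while the pure-stain pixel
clusters have symmetric noise so their local mean is unbiased. The OD floor
of 0.3 keeps background noise and faint cytoplasmic counterstain out of the
extremes.

## Positive cell detection

Detection runs on the haematoxylin OD channel (DAB is not subtracted), with
all lengths in microns converted through the pixel size: Gaussian smoothing
(sigma 1.5 um), background estimation by grayscale opening with an 8 um
disc (subtracted; pixels whose background exceeds 2 OD are excluded),
threshold 0.1 OD, hole filling, watershed splitting on the distance
transform with an h-maxima depth of 0.5 um, and an area gate of 10-400 um^2.
Two numerical choices deserve note:

* the watershed runs on the *raw* distance transform: blurring it first
  flattens the twin maxima of touching nuclei and measurably lowers recall;
* each object is shrunk to its half-maximum contour (never below the
  detection threshold) before measurement. Gaussian smoothing roughly
  doubles the thresholded support of a nucleus; for a blurred plateau the
  half-max contour recovers the true extent, which is what makes measured
  areas land within ~10% of truth.

Cells are grown from nuclei by iterative 8-connected label dilation up to
5 um, which partitions contested space at (pixelwise) equal distance from
the competing nucleus boundaries; the cytoplasm is the cell minus the
nucleus. Perimeters use the Vossepoel-Smeulders chain-code estimator
(0.980/1.406 per axial/diagonal step) and circularity `4*pi*A/P^2` is capped
at 1. A cell is `Positive` iff its nucleus DAB OD mean is `>= 0.2`
(inclusive: the printed threshold is a lower bound of the 1+ grade), with a
single threshold — no 1+/2+/3+ grading.

## Neighbourhood features and tissue classification

For every raw feature (areas, circularity, six compartment OD means) a
smoothed counterpart is added: a Gaussian-weighted average over neighbours
within 3 sigma (FWHM 25 um, sigma = FWHM/2.3548), restricted to cells of the
same Positive/Negative base class and never crossing core boundaries. The
restriction is read as the *base* classification (the plausible reading;
the alternative, pooling over all neighbours, is a flag in
`add_smoothed_features()` and is exercised in tests). Smoothing is a convex
combination, so smoothed values stay inside the local feature range.

A random forest (100 trees, `sqrt(p)` features per split, fixed seed, no
depth limit — the protocol names none, so these are package defaults chosen
for determinism and adequacy) is trained on *all* raw + smoothed features of
cells inside annotated training regions; 14 regions of 500 x 500 um are
montaged row-major (`floor(sqrt(n))` rows) with 50 um background gutters so
detections cannot straddle regions. At application time the forest assigns
one of four tissue classes — normal epithelium, tumour, immune infiltrate,
stroma — with ties broken by that fixed class order; the marker base class
is carried through untouched.

## Dearraying

A tissue mask (total OD >= 0.1, specks < 100 um^2 removed) is computed at a
coarse working resolution (~4 um/px — core localisation needs no sub-micron
detail). Blobs of at least 2% of a core's area vote, weighted by size, for
row/column positions; indices come from rounding against the nominal 0.9 mm
pitch and a weighted least-squares fit gives the regular grid, with empty
intersections filled in. Each core's tissue fraction is measured in a disc
of diameter 0.9 mm x 105% and the core is valid iff that fraction reaches
5% — "density threshold 5.0" is read as percent cover and "bounds scale
105.0" as percent disc scaling, since the source protocol does not state
units. Manual review is replaced by a scriptable override table
(`apply_overrides()`). The fit assumes an axis-aligned grid; rotations
beyond ~2 degrees are out of scope.

## Certification

Per valid core, cells are tallied by composite class. Histology certifies as
`Normal` or `Tumour` when the corresponding fraction of *all* classified
cells reaches 75% (inclusive). The denominator is a genuine ambiguity in the
source protocol; all-cells is the literal reading and the default, with
epithelial-only exposed as `histology_denominator = "epithelial_cells"`
because the choice changes flag rates. MLH1 certifies as
`Proficient`/`Deficient` when the positive (negative) fraction of
*epithelial* cells reaches 75% — stroma and immune cells are disregarded so
that MLH1-negative infiltrate cannot masquerade as deficient tumour. The two
axes are assessed independently; any uncertain axis flags the core with that
reason. Cores with fewer than 20 classified cells are `Invalid` (a numeric
floor replacing the study's manual invalidation of near-empty cores). Since
75% > 50%, at most one class per axis can certify, and raising the threshold
can only move cores from certified to flagged (monotonicity, tested). A
deficient-normal call is representable but biologically unexpected and
warns.

## Agreement statistics

Flagged and invalid cores are excluded, the rest are cross-tabulated against
reference review with MLH1-deficient tumour as the positive class.
Sensitivity and specificity carry exact Clopper-Pearson intervals
(beta-quantile form; at k = n the lower bound is `(alpha/2)^(1/n)`). Cohen's
kappa uses `po`, `pe` from the 2x2 margins and the asymptotic Wald interval
`kappa +/- z * sqrt(po(1-po)/(n(1-pe)^2))`, with the upper bound left
untruncated above 1 as is conventional for Wald intervals near-perfect
agreement. The bundled `reference_confusion()` (tp 17, fp 1, fn 0, tn 56)
is the unique integer table consistent with a 74-core validation reporting
100% sensitivity, 98.25% specificity and one false positive; on it the
package reproduces sensitivity 100% (80.49, 100), specificity 98.25%
(90.61, 99.96) and kappa 0.963 with lower bound 0.890.

# The synthetic TMA generator

Because no slide data ships with the package, `render_tma()` fabricates a
brightfield TMA with per-cell ground truth. Nuclei are placed by hard-core
dart throwing (minimum centre distance 1.5 x the scenario's mean radius,
attempt cap 10x the target count, Poisson-drawn counts at 2000 cells/mm^2 by
default) inside a 0.6 mm tissue disc on a 0.9 mm grid cell; tissue classes
occupy contiguous angular sectors sized by the composition so neighbourhood
features see locally pure tissue, as in real cores. Morphology is
class-coded — tumour nuclei large and eccentric (5.2 um, aspect 1.7), immune
small and round (2.2 um), stroma spindle (aspect 3), normal epithelium in
between — values that are calibration knobs of the simulator, not claims
about the study's histology. Marker-positive nuclei receive DAB at the
scenario OD; 30% of their pixels are dense chromogen deposits (5% residual
counterstain, 1.3x DAB), mirroring how precipitate locally obscures the
counterstain on real slides — these DAB-dominant pixels are what anchors
stain-vector estimation. Nuclei occlude the faint (0.1 OD) cytoplasmic
counterstain. Gaussian noise (sd 0.02 OD) is added per channel in OD space —
multiplicative in intensity, matching stain physics — before 8-bit
quantisation. Weak/patchy staining multiplies DAB by
`1 + a*sin(2*pi*x/300um)*sin(2*pi*y/300um)`; scant tissue confines cells to
a randomly placed sub-disc of the requested area fraction.

The default whole-slide layout mirrors the validation study's arithmetic:
74 unambiguous cores (30 proficient normal, 26 proficient tumour, 18
deficient tumour), 25 ambiguous cores in the five flag categories (scant
mixed tissue, atypical tumour morphology, heavy immune infiltrate,
normal-only mucosa with abundant stroma — 16 histology-ambiguous in all —
8 weak/patchy-stain cores and 1 ambiguous on both axes), 15 orientation
blanks, and 48 sub-threshold scant cores, so that exactly 99 cores survive
dearraying. Positions are permuted from the seed under the constraint that
every row and column keeps at least two full cores, which keeps the grid
fit well posed.

What the simulator does *not* emulate: optical blur and focus variation,
scanner illumination gradients and compression artefacts, chromatin texture
beyond the bimodal DAB model, nuclear pleomorphism within a class, tissue
folds, and real tumour architecture (glands, necrosis). Passing tests
therefore demonstrate that the pipeline's logic and numerics are sound under
controlled staining physics — not that the trained classifier would transfer
to real slides, which requires retraining on real annotations.

# Problem sizes and runtime choices

The simulator's native resolution is 0.5 um/px (the protocol's requested
pixel size). Whole-slide runs in the test suite and acceptance script render
and detect at 1 um/px — at desk scale this keeps a full 9 x 18 screen (render,
train on 14 synthetic regions, detect ~50k cells, classify, certify) around
five minutes on one CPU, and all detection parameters are specified in
microns so nothing but sampling density changes. Per-core unit tests use
0.5 um/px; dearraying tests render at 4 um/px. The `tma_image` container
keeps the slide as per-core tiles (a full 9 x 18 slide at 0.5 um/px is
32400 x 16200 pixels; tiles bound memory), with `tma_as_array()` /
`tma_thumbnail()` for assembly.

# Known limitations

* Detection reproduces the *parameter semantics* of the optimised protocol,
  not the bit-level behaviour of any particular viewer's implementation;
  the background model (grayscale opening) and boundary refinement are this
  package's documented choices.
* At realistic density (~2000 cells/mm^2) around 10% of nuclei genuinely
  overlap their neighbour; watershed recovers most but counts on dense cores
  sit ~5-10% below truth. Certification depends on class *fractions*, which
  the tests show are preserved.
* The dearrayer assumes an axis-aligned regular grid and anchors row/column
  1 at the first occupied line; a wholly empty leading row or column would
  shift labels.
* Cohen's kappa uses the simple asymptotic variance; statistical packages
  differ in the third decimal of the upper bound.
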