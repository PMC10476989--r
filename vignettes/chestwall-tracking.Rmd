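---
title: "Chest wall tracking in EPID cine images: methods and design"
author: "epidCWP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chest wall tracking in EPID cine images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidCWP)
```

# The measurement model

A tangential breast field seen by the EPID contains, from medial to
lateral: the bright blocked region under the jaw/MLC, a dark strip of
exposed lung, the rib (a local intensity maximum in the attenuation-up
convention), breast/mediastinal tissue, the skin–air "flash", and the
bright blocked region beyond the lateral jaw. Every analysis in this
package reduces to locating landmarks of one-dimensional row profiles
$I(x)$ inside a region of interest (ROI) and aggregating per-row distances.

**ROI.** The ROI is a band of rows centered halfway between the superior
and inferior image borders, spanning 15 mm above and below by default.
The row count is derived from physical span and row spacing,
`2 * round(halfSpanMm / rowSpacingMm) + 1`: 61 rows at ~0.5 mm EPID pixels
and 31 rows at ~1 mm DRR pixels. Deriving the count from the physical span
(rather than fixing 61) keeps EPID and DRR ROIs the same anatomical height.

**Field borders.** On centered first differences of the (optionally
smoothed) profile, the medial border is the steepest decline and the
lateral border the steepest incline to its right. Restricting the lateral
search to columns right of the medial candidate prevents pairing
inversions. If the resulting width falls below `minFieldWidthMm` (default
55 mm), the profile is assumed to exhibit the narrow-field failure mode —
an MLC corner with a rib close to the leaf weakens the medial gradient
until the skin–air drop wins — and the medial border is re-assigned to the
*second-steepest distinct decline*. We rank local minima of the derivative
rather than raw samples: a blurred edge spans several columns, so the
samples flanking the steepest decline would otherwise outrank every other
edge and the fallback would land on the shoulder of the wrong feature.
The 55 mm default is a configuration value, not a constant: clinically it
derives from the narrowest credible tangential field minus a safety
margin, and should be reviewed per center.

**The three detectors.** Per ROI row, after excluding a 2 mm penumbra
margin at both borders:

* *Peak*: the chest wall is `argmax I(x)` in the open field. Simple and
  robust, but the maximum can sit anywhere within the rib, so it reads
  systematically lateral of the lung–rib junction by up to the rib
  half-thickness; plateau ties resolve to the leftmost column and a
  plateau wider than 2 mm raises a "broad peak" flag.
* *Inflection*: the profile is cropped to the 5 mm window ending at the
  peak — 5 mm because rib thickness reaches about 5 mm, so the window is
  guaranteed to bracket the lung–rib transition — and the chest wall is
  the maximum of the first derivative in that window: the upward
  inflection at the junction. This is the anatomical landmark a human
  reviewer measures, which is why it is the default algorithm everywhere.
* *Canny*: a classical Canny chain (Gaussian smoothing, Sobel gradients,
  non-maximum suppression, hysteresis on the gradient magnitude normalized
  to its image maximum) reduces the frame to single-pixel edges; the chest
  wall is the first edge pixel from the medial border, excluding 2 mm
  around either border. Features are distinguished *only* by relative
  position, so noise edges inside the lung are misidentified as chest
  wall — the documented weakness of this detector. Defaults are sigma 2
  with thresholds 0.01/0.02 (clean phantom-like images); for noisy
  patient-like images sigma 4 with a single threshold parameter 0.006 is
  the recommended setting. A single threshold is interpreted as the high
  hysteresis threshold with low = high/2, mirroring the ratio of the
  phantom pair; both can also be set explicitly.

**Aggregation.** The frame's chest wall position is the median of the
per-row distances, with the sample standard deviation (n−1; defined as 0
for a single row) as uncertainty. Whether the spread should be a
population or sample SD is not fixed by convention in this field; we use
the sample SD since the ROI rows are a sample of the anatomy's extent.
Rows are processed independently — no cross-row smoothing — so the SD is
an honest per-row spread statistic. A frame is rejected when border
detection fails on more than half of the ROI rows, or when no row yields a
chest wall column.

# Motion, setup error and sign conventions

*Intrafraction motion* is the shift of each cine frame's median CWP
against the first analyzable frame of the beam; the signed shift of
greatest magnitude (ties toward the earlier frame) is reported against a
3 mm tolerance. *Setup error* is the difference between the first EPID
frame and the planning DRR measurement, against a 5 mm tolerance.

All signed outputs use one convention: **positive = deeper breath hold**,
i.e. the chest wall displaced posteriorly so that more lung enters the
field. With a medial reference edge the raw distance grows with a deeper
breath; with a lateral reference it shrinks, so lateral-referenced raw
differences are negated. This makes the two referencings interchangeable,
which matters because the lateral edge is the safer reference under MLC
shielding: superior–inferior motion changes where the MLC-defined medial
"edge" intersects the ROI, which would masquerade as anterior–posterior
motion. The package therefore defaults to the lateral edge for motion and
setup analyses (configurable), while algorithm-accuracy work uses the
medial edge, whose distance is directly the exposed-lung width.

Rejected frames are skipped with a warning, never interpolated: motion is
only claimed where it was measured.

The DRR is made comparable to portal images by re-weighting CT numbers
before projection: values in [−1000, 100] get weight 0.5 and values in
(100, 1000] get weight 2.0 (boundary 100 in the lower interval; inputs
outside [−1000, 1000] clamp to the nearest bound). The projected profile
then shares the in-breast peak and lung–rib inflection of an MV image, so
the identical inflection pipeline runs on a 31-row DRR ROI.

# Reporting plane and DICOM handling

Whether millimetre values live at the detector or the isocenter plane is
ambiguous in routine practice; since EPID (magnified) and DRR (isocenter)
measurements must subtract meaningfully, this package reports **at
isocenter**: when a file carries both the radiation machine SAD and the RT
image SID, the stored pixel spacing is rescaled by SAD/SID; otherwise the
spacing is used as-is and the frame is flagged `planeVerified = FALSE`.
The synthetic generator writes SAD = SID so its tests are
plane-independent.

DICOM RT Image I/O is implemented in the package (explicit VR little
endian, 16-bit pixels with a fixed rescale slope of 1e-4): only the tags
the tool needs are written, and unknown elements are skipped on read. The
writer is cross-checked in the test suite against an independent DICOM
implementation. Missing pixel data or missing pixel spacing are hard
errors — a measurement without geometry would be unitless. Images are
normalized on read to the attenuation-up convention (denser anatomy
brighter; an `invert` flag handles transmission-style input) and to
columns running medial to lateral (a `flipColumns` override).

# The synthetic phantom: what it emulates and what it does not

The generator is the oracle for every quantitative claim in the test
suite, so its construction is chosen to make ground truth *exact*:

* Region boundaries (jaws, lung–rib junction, rib end, skin) are
  continuous millimetre positions; each transition is rendered as a
  Gaussian CDF of scale `edgeSoftnessMm`. The rendered profile is thus
  analytically the blurred piecewise-constant anatomy, with its steepest
  gradients and its derivative maximum exactly at the exported truth
  positions, up to pixel sampling.
* `edgeSoftnessMm` defaults to 0.5 mm, the scale of detector/source blur
  at isocenter for a ~0.4 mm-pixel panel. Real jaw penumbra is broader;
  modelling all edges with one small softness keeps every landmark's truth
  position exact, which is the property the oracle needs.
* Default geometry: 128 × 224 pixels at 0.5 mm, jaws at 16.3 / 96.3 mm
  (80 mm field), 5 mm rib, 20 mm flash. The jaw positions deliberately do
  **not** coincide with pixel centers or boundaries: grid-aligned edges
  create symmetric derivative ties whose leftmost-tie resolution produces
  a systematic half-pixel bias that no real acquisition exhibits.
* Intensities (blocked 1.0, rib 0.75, breast 0.6, lung 0.35, flash 0.1 on
  a unitless 0–1 attenuation scale) reproduce the ordering of a real
  tangential frame; no spectrum or scatter modelling, since the detectors
  consume only profile shape.
* Noise is additive Gaussian with SD a fraction (default 2%) of the
  intensity range, reflecting dose-integrated cine frames; a Poisson
  option exists behind a flag. Noise is seeded and applied after blurring;
  geometry (and hence truth) never depends on the seed.
* Chest wall curvature is a quadratic bow across rows (default amplitude
  1 mm), so per-row distances genuinely vary and the reported SD is
  non-trivial, as in patient data.
* The MLC-corner scenario lowers the medial blocked level to
  `mlcIntensity` (default 0.55): the medial drop (0.55 → 0.35) then loses
  to the skin–air drop (0.6 → 0.1) while remaining clearly the
  second-steepest distinct decline. Values so low that the medial drop
  ties the rib–breast shoulder (≈0.15 deep) would make the fallback
  genuinely ambiguous, which is a different (and unrecoverable) condition
  from the one this scenario models.
* The CT phantom extrudes the same 2-D geometry into depth (air −1000,
  lung −750, soft tissue 40, rib 700; 20 mm chest wall, 10 mm rib slab,
  60 mm of breast tissue along the ray) and is projected by parallel-ray
  summation of `w(CT) * (CT + 1000)`. Columns are sampled at 0.5 mm and
  averaged down to the 1 mm DRR pixel after a 0.6 mm detector blur, so
  region boundaries are resolved at sub-pixel scale before the coarser
  sampling; the aperture is composited with a 0.6 mm softness (a computed
  aperture is sharp before detector blur) and an in-field scale of 0.85,
  which keeps the medial border the steepest decline as in portal images.

What the phantom does *not* emulate: realistic heart/diaphragm anatomy,
rib curvature and overlap (the DRR truth is a clean junction; real DRR
SDs are inflated by overlapping ribs), scatter, beam-energy effects,
bolus air gaps, and detector artifacts. Passing tests therefore
demonstrate that the algorithms recover a known geometry under controlled
blur and noise — pixel-level localization, correct sign conventions,
correct flagging — not that they are robust to every anatomical
confounder of clinical images.

# Numerical choices

* Gradients are centered first differences, optionally after a 3-point
  moving-average smoothing (default on); centered stencils avoid the
  half-pixel bias of one-sided differences.
* All reported locations are integer pixel columns converted to mm —
  matching pixel-resolution reporting conventions. An optional parabolic
  sub-pixel refinement exists as a flag but is off by default, so
  measured accuracies are honestly pixel-limited (~0.25 mm mean absolute
  at 0.5 mm pixels).
* Ties (steepest decline, argmax, plateau) always resolve to the leftmost
  column: deterministic output.
* The in-field crop is the half-open interval
  `(medial + margin, lateral − margin]`, whose length in columns equals
  the field width minus twice the margin.
* The inflection window is clipped only by the need for three samples, not
  by the penumbra margin: for very small exposed-lung distances the
  junction legitimately lies inside the margin, and the medial border's
  own (negative) derivative cannot win an argmax of positive rises.
* Simulation sizes used by the test suite and the acceptance script — 40
  noise-seeded EPID frames, 10 DRRs, 50 cine series of 8 frames, 20
  DRR/EPID pairs, 100 low-noise seeds, 1000 random profiles against
  brute-force oracles — were chosen to exercise every code path at
  sub-pixel statistical resolution while keeping a full run in the
  minutes range on one CPU.

# Known limitations

* Very small exposed lung (~1 mm) overlaps the medial penumbra: the
  junction estimate acquires a bias of order the edge softness (≈0.4 mm
  at defaults). This is a physical resolution limit, not a code path that
  can be fixed by tuning.
* The Canny detector inherits its documented failure mode: lung-region
  noise edges are misidentified as chest wall; no contour tracing or
  per-patient parameter optimization is attempted.
* IMRT segments, MPEG-format cine, bolus, and real-time operation are out
  of scope; the per-beam analysis assumes static open (or corner-blocked)
  fields.
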