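---
title: "Dynamic anterior corneal curvature topography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic anterior corneal curvature topography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corvistopo)
```

This vignette is the package's own account of its science: the models each
stage assumes, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the design decisions
that were genuinely open.

## The pipeline and its assumptions

An air-puff Scheimpflug acquisition is a stack of grayscale frames
(`CorvisSequence`) showing the cornea as a bright, near-horizontal band on
a dark background. Rows increase downward, columns rightward, and every
boundary is a real-valued function row(column). The pipeline assumes:

* the cornea is the largest bright structure, and impurities (eyelashes,
  tears) are each well under a third of its area;
* the anterior and posterior boundaries are single-valued in column —
  true for the central cornea imaged by these devices;
* the deformation keeps the band inside the frame;
* intensities are meaningful only up to smooth illumination changes —
  which is precisely why segmentation runs on local-phase features rather
  than gradients.

## Phase symmetry and asymmetry

Segmentation needs contrast invariance because illumination falls off
laterally and tissue reflectivity varies. Local phase delivers it: at a
ridge the bandpass quadrature responses are even-dominated, at an edge
odd-dominated, regardless of amplitude. The bank is log-Gabor (log-Gaussian
radial profile, no DC response, single-sided angular Gaussian), with
defaults of 4 scales from wavelength 4 px with ratio 2.1, 6 orientations,
`sigmaOnF = 0.55` (about two octaves per filter). These are conventional
phase-congruency settings; all are exposed in the `phase` config block.

Per orientation and scale the symmetry numerator is
`max(|e| - |o| - T, 0)`; asymmetry swaps the roles. The noise floor `T`
is estimated per orientation from the finest scale — median amplitude
divided by `sqrt(ln 4)`, the median-to-mean factor of a Rayleigh
distribution — times `noiseK = 2`, then decayed down the geometric
wavelength progression. The decay direction is not arbitrary: with
constant-octave filters the frequency-domain area a scale intercepts grows
with the square of its center frequency, so white noise excites fine
scales hardest (the test suite measures exactly this on seeded noise).
Orientations combine by summing numerators and denominators with uniform
weights. Both maps land in [0, 1] by construction.

Two practical caveats the tests encode explicitly. First, the clamped
(zero-floored) numerator is used; a signed variant would let strong even
responses mask nearby edges. Second, energy normalization makes the
measures flare up wherever total amplitude is tiny — in empty background
far from any structure — unless the noise term has something to bite on.
On noise-free synthetic imagery the global asymmetry maximum can therefore
sit on a far-field sidelobe; at realistic acquisition noise (σ ≈ 0.01) the
floor suppresses it and the edges win. The pipeline is additionally
shielded by the cornea mask and the candidate search window.

## Artifact removal

Binarization uses Otsu's histogram threshold (the band/background mixture
is strongly bimodal; the choice is config-exposed). Closing uses the
10 × 60 px rectangular element, long axis horizontal, implemented as
separable shift-based max/min filters with the erosion anchored on the
reflected element: this exact pairing keeps the closing extensive
(output ⊇ input) and idempotent even for even-sized elements, which
off-the-shelf implementations shift by a pixel. The component filter
labels 8-connected components (diagonal continuity survives noise) and
keeps everything at least 1/3 the area of the largest.

One subtlety feeds segmentation: the binary component necessarily stops at
the threshold crossing, a couple of pixels inside the band's diffuse
intensity tails. Multiplying the frame by that hard mask would create a
false step displaced from the true boundary and bias the asymmetry peak
(measured: about −1.3 px on the posterior boundary). The mask is therefore
dilated by `maskGrow = 8` px before the multiplication, restoring the
genuine edge profile while still excising detached artifacts.

## Boundary tracing

The midline is, per column, the median row of mask-interior symmetry
pixels above `tauSym = 0.1` (lower median for even counts, so the point
stays on a pixel row), fitted with a degree-5 polynomial, weighted by the
recorded symmetry intensities (uniform weights are one switch away; on
synthetic data the two differ negligibly). Columns in the outer sixth at
each end are excluded from every fit and flagged: phase responses fade
where illumination does, and only the central two-thirds is read
quantitatively. The fitted polynomial extrapolates across the flagged
ends.

Boundary candidates are asymmetry *peaks* (column-wise local maxima above
`tauAsym = 0.3`, refined to sub-pixel position by parabolic
interpolation) within ±0.75 band thicknesses of the midline; the peak
with the largest row below the midline is the anterior point, the
smallest row above it the posterior one. Three deliberate choices live
here:

* **Peaks, not pixels.** The supra-threshold blob around an edge is
  several pixels wide; taking the nearest supra-threshold *pixel* to the
  midline biases boundaries inward by 2–4 px. The peak of the asymmetry
  profile sits on the intensity inflection — the boundary itself. The
  literal any-pixel rule remains available (`candidateMode = "any"`).
* **The threshold is 0.3, not 0.1.** The 0.1 value belongs to the
  symmetry map; the band interior carries weak ringing responses near 0.2
  that must not qualify as edges.
* **The search window is 0.75 thicknesses.** At 0.5 the true edge sits
  exactly on the window boundary and sub-pixel refinement can push it
  out.

**Boundary model.** The midline keeps the degree-5 polynomial. For the
boundary curves a global quintic was the initial design too, but it
cannot represent the localized concavity the air puff imprints: on the
highest-concavity synthetic frame the best quintic is off by ~7.6 px
where it matters most. The default boundary model is therefore a cubic
smoothing spline with 15 equivalent degrees of freedom and one robust
refit after discarding residuals beyond 3 × the median absolute residual
(artifact-touched columns). `df = 15` balances tracking the deformation
dimple (model error < 0.1 px) against curvature noise from candidate
jitter (radius error ~0.1 mm at rest); both ends of that trade-off were
measured on generator output before freezing the default. `boundaryModel
= "poly5"` restores the quintic.

## Curvature estimation

The area-error circle fit minimizes
J = Σᵢ (πR² − π[(xᵢ−x_c)² + (yᵢ−y_c)²])². Substituting
B = R² − x_c² − y_c² makes the bracket affine in (B, x_c, y_c): the
minimizer solves one 3 × 3 normal system, with no iteration and no
starting value — the property that makes it practical for 576 columns ×
140 frames. Coordinates are centered on the window centroid first (exact
translation equivariance, better conditioning); collinearity is detected
from the point covariance spectrum and reported as a degenerate arc
(straight boundaries yield invalid columns, i.e. infinite radius).

The window is 27 px per side (55 samples) and slides over the *fitted*
boundary: raw candidates fluctuate by a few hundredths of a pixel, and on
a shallow 55-px arc (sagitta ≈ 0.8 px at R = 487.5 px) such fluctuations
are fatal to any direct fit — the suite demonstrates the bias of the fit
on raw noisy shallow arcs deliberately. Windows shorter than 55 samples
(ends, invalid neighbors) are flagged rather than fitted. The sign is
positive where the fitted center lies below the boundary (convex toward
the camera), negative in the concavity; the radius is reported in mm via
the 0.016 mm pixel pitch, the scale on which the normalization
breakpoints are meaningful. The area fit carries a known small-arc bias
relative to the orthogonal-distance fit; a comparison test keeps the two
within a fraction of a percent on the arcs this pipeline fits.

## Normalization and CIECAM02 fusion

The piecewise radius normalization is implemented exactly through its
published constants: 0 below −35 mm; 0.009 (R+35) to 7 mm; 0.1333 (R−7) +
0.3761 to 10 mm; 0.009 (R−10) + 0.7761 to 35 mm; 1 above. The printed
constants imply a 0.0019 dip entering the third branch and a 1.0011 value
clamped at the fourth's top; these are preserved verbatim (they are part
of the published constants), with `continuous = TRUE` offering
junction-matched slopes. Most of the palette deliberately covers the
physiological 7–10 mm range; concave radii compress toward blue.

The 256-entry blue-to-red palette ships as a CSV table (bit-exact,
linearly interpolated). Fusion works per pixel in CIECAM02: the gray
anatomy pixel (g,g,g) is forward-transformed for its lightness J; the
pseudo-color pixel contributes hue quadrature H and saturation s (chroma
C by config); the inverse model returns sRGB. Viewing conditions default
to D65, adapting luminance 60 cd/m², background 20, average surround —
unstated by convention, so config-exposed. The degree of adaptation is
fixed at D = 1 (discount the illuminant): display-referred neutrals then
stay exactly achromatic, which both keeps gray pixels gray and makes
"fusion preserves lightness" hold to better than 0.5 J units; D = NA
restores the CIE adaptation formula. The forward model reproduces the
published CIECAM02 worked example to its printed precision, and
forward∘inverse is identity to ~5e-14. Out-of-gamut inverse results are
channel-clipped with per-pixel flags and a per-strip clip fraction.

The rendered strip is 21 px wide, centered on the anterior boundary;
invalid or flagged columns stay gray; everything outside the strip is the
unmodified frame. One palette and normalization serve the whole sequence,
so equal radii are equal colors in every frame. Sequences render to
per-frame PNGs plus a shared colorbar; no video container is written (no
suitable encoder dependency), and the PNGs are the bit-exact record.

## The synthetic generator

The generator emulates what the segmentation has to survive, with exact
analytic ground truth. Geometry: the anterior boundary at rest is a
circular arc (default radius 7.8 mm — a typical human anterior cornea —
apex at row 45 so the lateral sag of the posterior arc stays inside 200
rows); the posterior boundary is the concentric arc 0.55 mm below (a
normal central thickness). Deformation adds a downward Gaussian
indentation (σ = 60 px ≈ 1 mm) whose amplitude follows a raised-cosine
pulse over frames, peaking at 1 mm in frame 70 of 140. These values were
fixed from the imaging literature the device family defines: the
resulting peak distance (~3.9 mm between flanking apexes) and concave
apex radius (~−1 mm) are in the clinically reported range. Per-column
signed radii come from the closed-form curvature of the analytic
boundary; flanking apex positions from root-finding on its derivative;
frames are labeled "during" deformation exactly while the analytic apex
curvature is negative (a displacement threshold of w²/R_px pixels).

Appearance: the band is two opposing sigmoid edges (σ = 2 px, measured
along columns) whose inflections sit exactly on the analytic boundaries,
times a 5 % midline bump that makes the noise-free per-column intensity
argmax land exactly on the midline — two properties the oracle tests use
directly. A multiplicative left-right illumination ramp (0.85 → 1),
additive Gaussian noise (σ = 0.01), and 2–4 px wide bright Bezier
eyelash strokes (detached by ≥ 18 px so the 10-row closing cannot bridge
them, or attached on request) complete the corruption model. Same config
and seed give bit-identical output; frame t draws from a seed derived
from (config seed, t), so sequences and standalone frames agree.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: speckle statistics of Scheimpflug scatter
(noise is Gaussian, not multiplicative), specular reflexes at the apex,
motion blur and eye movement between frames, tear-film bright lines
touching the band over many columns, true air-puff mechanics (the
raised-cosine pulse and Gaussian dimple are smooth stand-ins chosen for
unimodality, not physics), and the posterior boundary's optical
distortion through the cornea. Results on real acquisitions will be
noisier particularly at the band ends, which is why end columns are
flagged rather than scored.

## Numerical choices and degenerate inputs

* Polynomial fits run on columns scaled to [−1, 1]; degree is exactly 5
  and at least 6 distinct columns are required, else an error.
* Even-count medians take the lower median (stay on a pixel row).
* Circle fits require 3 non-collinear points; collinearity is a relative
  1e-10 test on the covariance spectrum; non-positive squared radius is
  reported as "no real radius".
* Blank or constant frames fail binarization with "empty frame"; the
  sequence driver logs per-frame failures and aborts only past 50 %.
* Peak distance demands two interior row-minima flanking a depression of
  at least 0.5 px prominence; convex frames report "PD undefined".
* Frames are normalized by the file bit depth on input — never per-frame
  min-max, which would break palette comparability across the video.
* Highest concavity ties break toward the earliest frame.

## Problem sizes in the test suite

The suite exercises full 200 × 576 frames throughout; sequence-level
checks sample representative frames across the deformation cycle (10
paired frames for the artifact-robustness bound, 7 for the
thickness/peak-distance agreement) and the 140-frame count contract runs
on a noise-free rest sequence. The phase-map loop oracle runs at 32 × 32
with 3 scales, where the naive per-pixel implementation is exact and
cheap. These sizes were chosen so the whole suite completes in about a
minute while every quantitative bound is still measured on the
full-resolution imaging geometry.

## Known limitations

* The boundary spline extrapolates linearly across the flagged end
  columns; end-column values are reported but should not be trusted.
* The area-error circle fit is biased low on shallow raw arcs; it is only
  ever applied to smoothed boundaries here.
* CIECAM02 fusion clips out-of-gamut results per channel; with very dark
  anatomy under a saturated palette the hue can shift where clipping
  occurs (the clip fraction is reported per frame).
* Attached eyelashes that merge with the band survive artifact removal by
  design; the candidate search window suppresses their influence on the
  boundary but cannot remove their intensity footprint.
* Stage labels ("before"/"during"/"after") use a displacement threshold;
  on real data the transition frames are genuinely ambiguous.
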