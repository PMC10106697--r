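---
title: "Identifying fish spermatogenic cell types from immunofluorescence sections"
author: "SpermatoTyper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying fish spermatogenic cell types from immunofluorescence sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpermatoTyper)
```

## The problem

Fish spermatogenesis proceeds inside clonal cysts: a single type A
spermatogonium (SPG-A) divides into cysts of 2, 4, 8 cells, differentiates
into type B spermatogonia (SPG-B, 16 up to 256 cells per cyst), enters
meiosis as primary spermatocytes (SPC-I, with leptotene, early/mid/late
zygotene and pachytene substages), and continues through secondary
spermatocytes (SPC-II), spermatids (SPD) and spermatozoa (SPZ). On a
multi-channel immunofluorescence section (DAPI plus antibodies against Ddx4,
Piwil1, Sycp3 and Pcna) these twelve types and subtypes are distinguishable
by a combination of nuclear morphometry, relative marker levels and
subnuclear marker localization. `SpermatoTyper` implements that integrated
criterion as a reproducible pipeline: segment nuclei, group them into cysts,
measure them, normalize intensities within the image, quantify Sycp3/Pcna
localization, and classify every nucleus with a deterministic rule cascade.
A synthetic-scene generator with machine-readable ground truth makes every
stage testable without microscopy data.

## Nuclear morphometry

**Diameter.** The nuclear "diameter" follows the histological convention:
the perimeter of the nucleus divided by the circular constant $\pi$. The
perimeter is measured on a sub-pixel contour — the binary region mask is
lightly blurred and the 0.5 iso-contour extracted by marching squares
(`grDevices::contourLines`). A raw marching-squares contour of a digitized
disc overestimates the true perimeter by about 5%; the blurred contour is
accurate to well under 1%, and the test suite holds the estimator to a 2%
bias bound on ideal discs and ellipses of 15 px and larger. Because the
estimator is perimeter-based, a square region of side $s$ reports diameter
$4s/\pi$, not the area-equivalent $2s/\sqrt{\pi}$ — a property the tests
check explicitly.

**Mask refinement.** Nuclei are detected on the DAPI channel by Gaussian
smoothing (default $\sigma$ = 0.3 µm), a global Otsu threshold computed on
log-intensities (so dim and bright nucleus populations fall on the same side
of the threshold), hole filling (nucleoli are DAPI-dark and must not
fragment their nucleus), and a distance-transform watershed to split
touching nuclei; regions below 2 µm² are discarded. A global threshold
necessarily sits far below the plateau of bright nuclei, which would inflate
their masks and dilute their mean intensities, so each nucleus mask is then
refined to its half-maximum boundary (pixels above background plus half the
background-subtracted in-mask median, connected to the original region).
This removes the class-dependent bias: measured mean diameters land within
about 1% of the generating values for every class from 2 µm spermatozoa to
6.5 µm spermatogonia.

**Nucleoli** are counted as connected DAPI-dark blobs inside the nucleus:
intensity below $(1-0.25)\times$ the in-mask median, area at least 0.3 µm²,
not touching the nuclear boundary.

## Relative intensities and normalization

Absolute fluorescence is meaningless across images, so intensities are
expressed relative to the `SPG-A(2,4,8-cell)` reference class measured *in
the same image*: each nucleus' background-subtracted mean is divided by the
mean over the reference nuclei. The reference class therefore averages
exactly 1 by construction, and every relative quantity is invariant to a
global intensity scaling — the pipeline's defense against illumination
differences (an exact invariance test, and a measured ~0.1% residual under a
20% linear illumination ramp, are in the suite). Background is estimated per
channel as the median over non-nucleus pixels; subtracting it is what makes
"marker absent" read as ≈ 0 rather than as the background-to-reference
ratio. With a zero background estimate the formula reduces to the plain
ratio of raw means. Sycp3 is essentially absent from the reference class, so
it has no usable own denominator; its levels are expressed in
reference-DAPI-equivalent units, which preserves zero and scale invariance.

When no ground truth identifies the reference nuclei, an auto-reference mode
flags candidates as members of 2–8-cell cysts whose diameter lies within one
profile standard deviation of the reference mean (5.74 ± 0.82 µm) and whose
raw Ddx4 signal is in the top quartile of the image; their mean anchors the
normalization. Explicit reference ids always override.

## Cyst grouping

Cysts are clones of contiguous same-stage cells. `groupCysts` implements
fixed-distance single linkage (two nuclei share a cyst iff a chain of
pairwise distances at most the link distance connects them). In images that
mix 2 µm spermatozoa with 6.5 µm spermatogonia no single global distance
works — it either splits the large-nucleus cysts or merges the small ones —
so the pipeline default (`assignCystsToRecords`) links two nuclei when their
distance is at most twice the mean of their two diameters. The fixed-link
interface remains available for explicit control.

## Subnuclear localization and SPC-I staging

Across meiotic prophase, Sycp3 spreads from one nuclear pole (leptotene)
over the nucleus as a stripe (zygotene) until it fills it (pachytene), while
Pcna moves from co-polar with Sycp3, to the complementary side, to sparse
puncta of decreasing level, to undetectable. Three mask-level metrics
quantify this on background-subtracted signal:

* `rho` — distance between the intensity-weighted centroid and the nuclear
  centroid, divided by the equivalent radius. A half-disc of signal has its
  centroid $4R/3\pi \approx 0.42R$ off-center, anchoring the polar regime.
* `coverage` — fraction of the nuclear area above threshold (default:
  background mean + 3 background sd).
* `punctateness` — number of distinct above-threshold blobs (≥ 2 px).

A first-match decision list maps metrics to a closed pattern vocabulary
(absent, dots, polar, stripe, whole, punctate, diffuse) with boundaries
rho ≥ 0.35 and coverage ≤ 0.5 for polar, coverage ≥ 0.9 for whole, 7+ blobs
for punctate, and a detectability floor of 0.05 relative units. Substages
then follow from the joint pattern: co-polar Sycp3/Pcna (angular separation
< 60°) is leptotene; complementary (> 120°) early zygotene; Sycp3 stripe
with punctate Pcna is mid or late zygotene split at 65% coverage, with the
decreasing Pcna level (threshold 0.375 relative units) breaking ties within
±0.05 of the boundary; whole-nucleus Sycp3 with no Pcna is pachytene. All
thresholds live in `defaultThresholds()` and were chosen to separate the
synthetic stage prototypes with maximal margin; on rendered scenes the
staging is error-free without noise and confuses at most adjacent stages at
the default noise level.

## The classification cascade

`classifyCell` applies a first-match cascade: (r1) any meiotic Sycp3 pattern
calls SPC-I with the substage above; (r2/r3) Ddx4 at reference level
(≥ 0.8) calls type A spermatogonia, singles versus 2–8-cell cysts, with
Pcna ≥ 0.5 distinguishing mitotic from quiescent singles; (r4) intermediate
Ddx4 (0.35–0.8) with high Pcna calls type B, split into the 16,32-cell
versus 64,128,256-cell classes by Sycp3 dots (late only), diameter
(≥ 4.6 µm, the midpoint of the published class means 5.01 and 4.14) or a
visible nucleolus; (r5) with Sycp3 and Pcna off and Ddx4 low, size and the
residual germline markers order the post-meiotic series — SPC-II above
3.5 µm, SPD with a Ddx4/Piwil1 trace, SPZ bare; (r6) anything else falls
back to the nearest class prototype in standardized (diameter, relative
DAPI) space, recorded in the rule trace. Piwil1 only corroborates — the
cascade runs on the Ddx4/Sycp3/Pcna triple stain and tolerates a missing
Piwil1 channel. Without Sycp3/Pcna channels no substage is claimed: the
fallback reports meiotic nuclei at type level ("SPC-I").

On mixed twelve-class scenes at default noise the pipeline reaches ≈ 98%
agreement with the generator truth, with every confusion between
developmentally adjacent classes (the SPG-B split, a 2-cell cyst read as
singles when segmentation drops a member, SPD↔SPC-II). "Adjacent" here means
consecutive stages in the developmental order, which includes
SPC-I(P)↔SPC-II and SPC-II↔SPD alongside the within-type splits.

## The clay-ball cyst model

The clonal generation of an SPG-B cyst is inferred from the number of cells
visible on its largest planar section. The model packs $n$ unit spheres into
the minimal cyst ball of radius $(n/\phi)^{1/3}(d/2)(1+s)$ (default packing
fraction $\phi$ = 0.60, slack $s$ = 0.02) by random insertion followed by
centripetal compression: centers start dilute, pairwise overlaps are relaxed
with a small decaying jitter, and the confining radius shrinks stepwise. Two
regimes deserve note. First, very small clusters cannot reach bulk
densities at all — a kissing pair alone fixes the enclosing ball at radius
$d$ — so $n = 1, 2$ are exact special cases and, in general, when the random
packing jams before the nominal density is reached the achieved jamming
radius is reported as the cyst ball (typically 5–10% above nominal for
16–64 cells). A section counts every cell whose sphere meets the cutting
plane ($|z_c - z| < d/2$); the maximum over planes is exact, obtained by
sweeping the finite set of critical plane positions.

Averaged over 200 packed cysts, the largest sections of 32-cell and
256-cell cysts contain about 14.4 and 55.0 cells — matching the published
anchors 14.3 ± 1.5 and 54.9 ± 10.7 that identify the two SPG-B classes.
`inferGeneration` inverts the model by picking the power of two whose
expected count is nearest an observation; it round-trips every simulated
mean and maps 14.3 to 32 and 54.9 to 256.

**The analytic oracle and its known bias.** `expectedSectionCount` is the
uniform-density slab expectation: $n$ times the volume fraction of the
nominal ball within $d/2$ of a central plane, clipped to $[1, n]$. It is an
independent closed form for checking the simulation, but it spreads density
over the entire ball, whereas a real packing confines centers to radius
$R - d/2$ and layers them against the wall. Central sections of packed
cysts therefore catch systematically more cells than the oracle predicts:
the simulated/analytic ratio is ≈ 1.20 at 16 cells, ≈ 1.15 at 32, and decays
to ≈ 1.09 by 256. The published anchors show the same excess (14.3 versus
12.7 analytic). A uniform close-agreement band across all cyst sizes is
therefore unattainable for a geometrically faithful simulation; the package
documents the decaying excess instead and the corresponding acceptance
check is expected to fail below 128 cells.

Group comparisons use the classical unpaired, two-tailed, pooled-variance
Student's *t*-test (`stats::t.test`, `var.equal = TRUE`), with Welch's
correction behind a flag; zero pooled variance returns p = 1 for equal
means and p = 0 otherwise, by documented convention.

## The scene generator

The generator is first-class, tested code: it renders what the analysis
assumes, and its defaults are the study conditions. Each planned cyst
becomes a clone of elliptical nuclei (axis ratio uniform in [1, 1.4]) on a
jittered golden-angle spiral, spaced 1.3× the mean member diameter, with
cyst hulls kept 12 µm apart; cysts are placed largest-first by rejection
sampling and a plan that cannot be placed raises an overcrowded-scene error.
Per nucleus, the equivalent diameter and DAPI level are drawn from the
label's profile (published means and sds for the four SPG classes; for
SPC-I through SPZ, 6.0/4.0/3.0/2.0 µm and 1.5/2.0/2.5/3.0 relative DAPI,
following the documented size decrease and condensation increase, with sds
chosen at roughly the published classes' coefficients of variation). Marker
levels are drawn at 8% CV (truncated at ±2 sd) around the profile means,
which encode the ordinal relations seen by immunofluorescence; the
magnitudes are editable calibration parameters, not published constants.

Two conventions make the generator measurable without bias. The drawn
"diameter" is the perimeter/π quantity, so ellipse axes are scaled to make
the rendered perimeter exactly $\pi d$. And every plateau is scaled so the
*mask mean* equals the drawn level times the base intensity (100 counts):
nucleoli (rendered at 0.4× plateau, one large 0.25-diameter nucleolus in
the reference class, one to three 0.16-diameter nucleoli in the 16,32-cell
class) are compensated in DAPI, and concentrated patterns (polar
half-planes offset 0.15 R, stripes at 57.5% ± 2% and 75% ± 2% coverage for
mid/late zygotene, 8–12 punctate foci of 0.45 µm, 2–4 dots of 0.55 µm) are
compensated in the markers. Background (10 counts), an optional
multiplicative linear illumination ramp applied identically to every
channel, and Gaussian noise (default sd 5, i.e. 5% of the reference DAPI
plateau) are added last. Scenes are bit-reproducible given the config seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real sections: optics (no point-spread function, single plane
rather than a confocal stack), chromatin texture beyond mean DAPI and
nucleoli, autofluorescence structure beyond a flat background, antibody
penetration artifacts, irregular (non-elliptical) nuclear shapes, and
partial-volume effects of physical section thickness. Thresholds proven on
synthetic prototypes will need recalibration on real data; they are all
exposed in `defaultThresholds()` and the profile YAML for that reason.

## Problem sizes and numerical choices

The acceptance computations use 200 cysts per clay-ball anchor, scenes of
120–160 nuclei per measured class with 160–240 co-rendered reference
nuclei (2048² px at 0.2 µm/px), and the mixed twelve-class scene with 310
nuclei (1280² px). Scene sizes were set so that Monte-Carlo sampling error
of the drawn distributions (whose spreads are the published class standard
deviations) stays well inside the stated tolerances. Degenerate inputs are handled explicitly: blank images return
empty label maps, an empty plan renders pure background, empty feature
tables classify to empty call sets, packing outside φ ∈ [0.45, 0.70] and
unplaceable scenes raise classed errors, and a missing reference set raises
`missingReferenceError` rather than silently normalizing.

## Session info

```{r}
sessionInfo()
```
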