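---
title: "Design-based stereology for segmental cord morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology for segmental cord morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordstereo)
```

## The measurement model

`cordstereo` implements the classical design-based workflow for
estimating cross-sectional areas and volumes of a segmented organ from
sectioned material, in the form used for equine cervical spinal cord
morphometry.

A segment is cut into slabs by parallel blades at a fixed interval
$T$ (default 3.8 mm) with a uniformly random first cut; slabs may be
systematically subsampled at 1/2 or 1/3. One histological section is
taken per sectioned slab. On each section image, a square point grid
with area-per-point $a/p$ and a uniformly random offset is
superimposed, and the points hitting each compartment (gross section
GS, white matter WM, grey matter GM, dorsal and ventral horn DH/VH,
central canal CC) are tallied, conventionally in triplicate with
re-randomized grids. With $\sum p$ the (possibly fractional) mean
tally per section, $S_n$ the number of sections and $t$ the distance
between consecutive sections,

$$A_\text{mean} = \frac{\sum_i \sum p_i \cdot a/p}{S_n}, \qquad
  \hat V = \sum_i \sum p_i \cdot a/p \cdot t .$$

Both estimators are unbiased under systematic uniform random (SUR)
sampling: the random grid offset makes $E[\text{count} \cdot a/p]$
equal the profile area, and the random first cut makes the section
positions a uniformly-phased lattice, so $E[\hat V]$ equals the true
volume. The package's phantom tests verify both properties against
closed forms (see below).

Diameters are measured as axis-aligned caliper extents on dorsal-up
sections: the transverse diameter TD is the horizontal extent of a
compartment mask and the vertical diameter VD the vertical extent,
each including one pixel of width so a single-pixel mask has nonzero
diameter. The compression ratio $\mathrm{VD}/\mathrm{TD} \times 100$
is a scale-free shape index. Shrinkage between processing states is
reported as $(\text{pre} - \text{post})/\text{pre} \times 100$.

## Sampling geometry: partial slabs and section placement

Two details of the sampling plan matter for unbiasedness and are easy
to get wrong:

* **The leading partial slab.** With a random first cut at
  $r \in [0, T)$ the piece $[0, r)$ is a genuine slab of tissue and is
  retained in the tiling, but it starts at the organ end rather than
  at a knife cut. Measurement sections live at the cut surfaces
  $r + kT$, which form the uniformly-phased lattice the Cavalieri
  estimator needs. Placing an extra section at $z \approx 0$ would add
  roughly $t \cdot A(0)$ to the expected volume — a bias of several
  percent on a cord-sized object — so the partial slab carries no
  section.
* **The microtome offset.** The section actually mounted is one of the
  first 30 sections (10 µm each) cut from a slab's cranial face, i.e.
  at a random offset within $[0, 0.3]$ mm. `section_positions()` draws
  this offset *once per segment* and applies it to every slab, keeping
  consecutive positions exactly $kT$ apart as the constant-$t$ volume
  estimator assumes (independent per-slab offsets would jitter the
  spacing by several percent of $t$). A lattice point that falls past
  the caudal face of a thin trailing partial slab has left the tissue
  and is dropped.

The effective post-processing spacing $t$ (default 3.4 mm times the
subsampling denominator) is a *measured input*, never derived from a
shrinkage model: the ratio 3.4/3.8 corresponds to a 10.53%
longitudinal reduction, while the longitudinal tissue shrinkage
reported from length measurements is 11.91%. The package treats this
as a documented inconsistency of the source protocol and does not
reconcile the two numbers.

## The coefficient of error

`ce_systematic()` predicts the relative standard error of a Cavalieri
estimate from the ordered section counts $P_i$ using the
Gundersen–Jensen decomposition: with truncated sums
$A = \sum_1^n P_i^2$, $B = \sum_1^{n-1} P_i P_{i+1}$,
$C = \sum_1^{n-2} P_i P_{i+2}$,

$$\nu = 0.0724 \, \frac{\bar b}{\sqrt{\bar a}} \sqrt{n \sum P_i},
\qquad
\mathrm{Var}_\mathrm{SRS} = \frac{3(A - \nu) - 4B + C}{240},
\qquad
\mathrm{CE} = \frac{\sqrt{\nu + \mathrm{Var}_\mathrm{SRS}}}{\sum P_i},$$

with negative $\mathrm{Var}_\mathrm{SRS}$ clipped to zero. Three
numerical choices deserve note:

* **Truncated sums.** $A$, $B$, $C$ run over $n$, $n-1$ and $n-2$
  terms, so for a perfectly constant count sequence
  $3A - 4B + C = 2c^2$ rather than 0; the residual CE is the exact
  closed form $\sqrt{2/240}/n$, which the tests assert.
* **The shape coefficient** $\bar b/\sqrt{\bar a}$ (mean profile
  boundary over the square root of mean profile area) defaults to 6,
  an oblong-profile value; for validation experiments it is computed
  from the phantom's own perimeter and area.
* **The smoothness constant.** The denominator 240 belongs to the
  smoothness class in which the area profile vanishes smoothly at both
  ends of the object. A *cut segment* has jump discontinuities at its
  faces; for that class the appropriate constant is 12. Both are
  exposed as arguments. The calibration experiments below use 240 for
  a spindle-shaped phantom and 12 for a cut segment; with the
  mismatched constant the prediction understates the realized
  variability by roughly a factor 2.5.

Because the raw per-section counts behind the published tables were
never deposited, printed CE values cannot be recomputed exactly; the
package instead validates that predicted CE calibrates the *realized*
sampling variability on phantoms (below).

## The phantom generator

`horse_csc_spec()` builds an eight-segment organ whose cross-sections
are nested analytic shapes: a linearly tapering gross-section ellipse;
a grey-matter butterfly of four horn ellipses joined by a rectangular
isthmus; and a micrometre-scale elliptical central canal inside the
isthmus. Everything has a closed-form area and volume
(`true_area()`, `true_volume()`), with white matter defined by
subtraction so that $A_{GS} = A_{WM} + A_{GM} + A_{CC}$ holds exactly.
A quadrature integrator (midpoint rule, $10^4$ steps per segment)
cross-checks the closed forms to $10^{-6}$ relative.

The default geometry is *schematic, not anatomically calibrated*: the
published per-segment summary only constrains areas and lengths, so
the defaults were chosen once to land in those ranges — segment
lengths 40–95 mm rising from C1 to C3 and falling to C8 (total
571 mm, matching a ~57–61 cm cervical cord), gross-section areas
120–175 mm², grey-matter areas 9–28 mm², canal areas 37–59 × 10⁻³ mm²
with a dorsoventrally flattened profile whose vertical diameter
declines caudally, and a vertical/transverse aspect ratio tapering
from 0.66 to 0.60. With the default 1/1, 1/2 and 1/3 slab fractions
per segment, every segment yields 8–13 kept slabs. What the phantom
deliberately does **not** emulate: histological texture and staining,
nerve roots, section deformation other than global anisotropic
shrinkage, segmentation error (inputs are perfect label masks), and
butterfly shapes more realistic than ellipses. Passing phantom tests
therefore demonstrate correctness of the *estimators* under ideal
labeling, not robustness to real-image segmentation noise.

`apply_shrinkage()` scales transverse, vertical and longitudinal
dimensions by separate factors. Applying the reported linear factors
(14.18%, 16.66%, 11.91%) yields a volumetric shrinkage of
$1 - (1-0.1418)(1-0.1666)(1-0.1191) = 37.0\%$ — visibly more than the
29.3% measured volumetrically. The phantom makes this tension
explorable instead of hiding it: anisotropic linear shrinkage measured
on diameters need not reproduce a volumetric figure measured by
displacement and point counting.

In the simulation pipeline, per-animal variation is emulated by a
log-normal scale jitter (8% CV on cross-sectional dimensions, 4% on
lengths), which reproduces the order of the between-animal SEs in the
published per-segment table.

## Statistics layer

Group summaries are mean ± SE (sample SD over $\sqrt n$). Duncan's
multiple range test uses the pooled one-way mean square error, ordered
means, and for a stretch of $p$ consecutive ordered means the critical
range $q\!\left(1-\alpha_p,\, p,\, df\right)\sqrt{MSE/n}$ with the
protection level $\alpha_p = 1-(1-\alpha)^{p-1}$ on the
studentized-range distribution (quantiles from `qtukey`, no hard-coded
tables, so any $df$ works). The step-down rule — once a stretch tests
homogeneous nothing inside it is tested — makes the non-significance
relation a union of intervals; letters are built with the
insert-and-absorb algorithm and assigned in descending-mean order, so
they reconstruct the pairwise significance matrix exactly (a property
the tests check by reconstruction, and against an independent
brute-force implementation). With zero residual variance the exact
tie rule applies: groups differ iff their means differ. Under a
global null with eight groups of five, the protected procedure's
first test runs at level $1-(1-0.05)^7 \approx 0.30$, so roughly 30%
of null datasets show at least two letter groups; the test suite
monitors this with a 2000-simulation band of 0.20–0.40.

Pearson correlations use the exact $t$ transform with star levels
0.05/0.01/0.001. The observation unit for correlation tables is
configurable (the source is ambiguous between per-animal-per-segment
observations and per-segment means); the pipeline default pools
subject-by-segment rows.

For table reproduction, rounding is half-up to the printed decimals
and applied only at report time. Percentages recomputed from printed
*means* can differ from figures the source computed per animal; those
checks carry a 0.2-percentage-point allowance. The printed volume
share of the cord in the CNS (32.6%) computes to 32.66% from the
printed means — apparently truncated rather than rounded in print —
so that check allows one unit in the last printed digit.

## Validation experiment sizes

The validation experiments are sized to give Monte-Carlo standard
errors comfortably below the asserted tolerances: 500 random grid
offsets (area unbiasedness, MC SE ≈ 0.1% against a 1% band), 500
random systematic designs (volume unbiasedness, same band), 500
replicate Cavalieri runs for CE calibration (CV/CE ratio asserted
within a factor 2; measured ≈ 1.0 on the spindle and ≈ 1.2 on the cut
segment), 50 random eight-group layouts for Duncan oracle equivalence,
and 2000 null simulations for the type-I monitor. Rasterization uses
10 µm pixels where sub-0.1% area accuracy is needed and 40–50 µm
pixels elsewhere; CE experiments use single counts per section
(`repeats = 1`) because the noise term of the CE formula models one
systematic count — triplicate averaging would silently divide the
realized grid noise by three without the predictor knowing.

## Known limitations

* WM both ways: the package reports white matter both directly
  counted and by subtraction (`wm_consistency()`); which pathway the
  original protocol used is not recorded, and the two differ by the
  counting noise of the grids involved.
* Printed CE values, per-animal raw counts and the published
  correlation table cannot be reproduced exactly without the raw data;
  the package validates the *methods* on phantoms instead.
* Diameters are axis-aligned extents, not Feret diameters; tilted
  input masks should use `reorient = TRUE` or be pre-oriented.
* The Cavalieri spacing check rejects nonuniform spacing beyond 1% of
  $t$; irregularly spaced sections need a different estimator
  entirely and are out of scope.
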