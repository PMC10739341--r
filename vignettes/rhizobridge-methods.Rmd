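---
title: "Methods: from root images to stochastic architecture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from root images to stochastic architecture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizobridge)
library(dplyr)
```

rhizobridge connects three things that are usually studied apart: the
*phenology* of adventitious rooting in vegetatively propagated cuttings
(when roots first appear, as a function of thermal time), *image-based
phenotyping* of root system architecture (RSA) on high-contrast germination
paper, and a *stochastic functional–structural root model* whose parameters
are derived automatically from the extracted traits rather than measured by
hand. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the problem was genuinely
open.

## Thermal time and rooting phenology

Daily weather records (mean, max, min temperature in °C) are reduced to
three unitless daily indices, accumulated from a chosen start date:

* **Chilling units (CU)** — a piecewise-linear measure of cold exposure:
  0 outside (−3.4, 10.4] °C, `0.159·T + 0.506` on (−3.4, 3.5] and
  `−0.159·T + 1.621` on (3.5, 10.4]. The printed coefficients make the
  function slightly negative just above −3.4 °C (−0.0346 in the limit).
  We keep those values as printed rather than clamping at zero: the branch
  constants are part of the published calibration, and silently editing
  them would make cumulative sums irreproducible against it.
* **Forcing units (FU)** — a logistic measure of warm exposure,
  `FU = 1/(1 + e^(−0.47·T + 6.49))`, bounded in (0, 1) with midpoint
  ≈ 13.81 °C. Among the typographically plausible readings of the source
  formula this is the only one that is bounded, monotone, and consistent
  with the logistic forcing functions of the forestry literature it draws
  on, so it is the form implemented.
* **Growing degree days (GDD)** — `max((Tmax + Tmin)/2, 0)`, base 0 °C.

Accumulation refuses to interpolate: a missing calendar day in the window
is a hard error, because a silent gap corrupts every cumulative value after
it.

**T50** is the estimated number of days until half of a cohort of cuttings
shows its first stem-borne root longer than 3 mm. Rooting is tracked daily,
so the data are interval-censored counts: a cutting recorded on day *d*
rooted somewhere in (*d*−1, *d*], and cuttings that never rooted are
right-censored at the end of the observation window. We fit the
two-parameter log-logistic time-to-event curve
`F(t) = 1/(1 + (t/t50)^(−b))` by maximum likelihood on those interval
contributions and report the fitted median `t50` with a delta-method
standard error from the observed information. A least-squares fit to the
cumulative rooted fraction recovers the same point estimate but its
standard errors are badly miscalibrated (the cumulative fractions are
serially correlated); in our calibration runs the likelihood-based 95%
intervals cover the simulated truth ~95% of the time, which is the property
the rest of the analysis depends on. A cohort in which fewer than half the
cuttings ever root has no identifiable median and is rejected with an
explicit error. T50 estimates are then regressed on cumulative thermal time
by ordinary least squares (`regress_t50()`), reporting slope, R², mean
squared residual and the two-sided slope *p*-value.

## Trait extraction from binary masks

The package starts from a segmented (binary) root image with a known
mm-per-pixel scale; segmentation of raw photographs is upstream of this
package. Extraction proceeds:

1. **Component filtering.** 8-connected foreground components smaller than
   `min_px` (default 2, i.e. single-pixel specks) are removed — the same
   pre-filter applied to segmented germination-paper images before feature
   extraction. The filter is idempotent.
2. **Skeletonization.** Zhang–Suen thinning produces a one-pixel-wide
   topological skeleton. The local root radius at each skeleton pixel is
   the Euclidean distance transform minus half a pixel (distances are
   measured centre-to-centre; the stroke edge lies half a pixel closer).
3. **Skeleton graph.** Adjacent skeleton pixels form a step graph; a
   diagonal step whose endpoints share an orthogonal corner pixel is
   redundant and is pruned, otherwise lengths double-count and every
   staircase corner masquerades as a branch point. Node degree in the
   pruned graph classifies tips (degree ≤ 1) and branch points (≥ 3).
4. **Path metrics.** The graph is decomposed into maximal paths between
   tips/junctions. Each path is measured as a polyline subsampled every 4
   pixels, which suppresses chain-code staircase noise (raw 1/√2 step sums
   overestimate length by up to 8% at unlucky angles; subsampled chords are
   accurate to ~1–2% on straight strokes). Total root length adds a tip
   correction of one local radius per tip, because thinning retracts the
   skeleton about one radius short of each stroke cap. Orientation is the
   length-weighted mean absolute angle of path chords from the downward
   vertical, in [0°, 90°]; average diameter is length-weighted along the
   same paths; surface area treats each chord as a cylinder slice of its
   local diameter.
5. **Region metrics.** Network area is the foreground pixel count times the
   pixel area. The convex hull is taken over pixel *corners* (centres
   ± half a pixel): a hull over centres would be strictly smaller than the
   pixel union and a solid convex blob would get solidity > 1, violating
   the definition `solidity = network_area / convex_area ∈ (0, 1]`. Holes
   are 4-connected background components not touching the border
   (8-connected foreground with 4-connected background is the standard
   duality that avoids paradoxical hole counts).

Digitization tolerances, verified continuously by the test suite against
masks built with analytic ground truth: total length within 5%, diameters
within 1 pixel, orientation within 2°. These tolerances presuppose a
*legible* image — strokes that occlude themselves in projection merge their
ink, and the merged geometry is genuinely absent from the image (see
Limitations).

"Number of roots" is operationalized as the tip count, the whole-root-image
convention of the extraction tool the trait names mirror; the counting rule
is otherwise undefined for adventitious root crowns.

## From trait summaries to growth-model parameters

`summarize_traits()` reduces a trait table (one row per plant/image) to
per-trait {min, median, max} plus the elapsed observation time *t* in days.
`derive_root_type_parameters()` maps that summary to the 12 parameters of
one root order through a declarative equation table — each parameter is one
R function of the operand accessor, so a corrected transcription is a
one-line edit. Trait operands arrive in mm and are converted to cm at the
accessor boundary; every derived length is cm and rates are cm/day.

The fixed rows are unambiguous: axial resolution `Δx` = 0.5 cm for
primaries and 0.1 cm for higher orders; tropism trial count `N` = root
order; insertion angle `θ` = the median per-image mean orientation;
`σ` = the sample standard deviation (n−1) of per-image mean orientation;
radial growth rate `a_r = (a_max − a_i)/t`, converted to mm/h (radii
cm → mm, days → hours).

The remaining rows combine order statistics of length, depth, diameter,
surface area and tip counts with powers of the root order. The plain-text
source for these equations does not preserve fraction bars, exponents or
decimal points (its own piecewise chilling formula prints −0.159 as
"−0159"), so the operand grouping implemented here is the one that is
dimensionally consistent and biologically plausible at the magnitudes of
real cutting root systems:

| parameter | implemented form (operands in cm / cm²) |
|---|---|
| `l_b` | RootLength_min / NumberRoot_min · (1/order) |
| `l_a` | (RootLength_max − RootLength_median) / NumberRoot_max · (1/order) |
| `l_n` | SurfaceArea_median / NumberRoot_median · 5/order² |
| `l_max` | Depth_max · 1.2 / order³ |
| `r` | (RootLength_max − RootLength_min)/t · 1.5/order |
| `a_i` | Diameter_min / NumberRoot_min · 1/order² |
| `a_max` | Diameter_max / (5·order²) |

Two sanity anchors fix the ambiguous constants: `l_max` must *bind* (a
maximal length twelve times the observed depth would never constrain a
simulation, whereas the model is explicitly described as limited by its
maximal root lengths), and `l_n` must produce branch spacings on the order
of millimetres to centimetres (the denominator reading gives 14 µm, an
impossible lateral density). `t` is taken as the elapsed days of the
observation window supplied by the user. Root orders beyond 3 are rejected;
the parameterization defines primary, secondary and tertiary axes only.
`validate_parameters()` reports (never repairs) inconsistent sets: an empty
branching zone (`l_b + l_a > l_max`), non-positive `r`, `a_i > a_max`, or
an insertion angle outside [0°, 180°].

A note on the zone symbols: `l_b` is implemented as the unbranched zone
*before* the first lateral (measured from the base) and `l_a` as the
unbranched *apical* tail, the convention of the simulation lineage these
symbols come from; the source's printed labels for the two are reversed
relative to that convention, so the implementation names the zones
explicitly rather than trusting either label.

## The stochastic root simulator

Each axis grows toward a realized maximal length along the saturating
exponential `l(age) = l_max·(1 − e^(−r·age/l_max))` — initial slope `r`,
asymptote `l_max`. The functional form is adopted from the root-model
lineage the parameterization targets; growth *saturates* at `l_max` rather
than halting (an unobservable distinction in the data, resolved in favour
of the smooth form). The step increment is laid down in sub-segments of at
most `Δx` (cm), each steered by the axis's tropism.

**Stochasticity.** Every realized parameter of every axis is one draw from
a truncated normal centred on the derived value. The source prescribes the
distribution but not its spread, so the default policy is sd = 10% of the
mean, truncated at [max(0, mean − 2sd), mean + 2sd]; `sd_frac` is
configurable globally or per parameter, and `sd_frac = 0` gives a
deterministic run. Reproducibility is strict: one seed fixes the entire
run, each axis owns its RNG stream, and child streams derive from stable
(parent, site) indices, so the draw sequence of one axis never perturbs
another's. Identical configs and seeds give bit-identical segment tables.

**Tropism.** Per sub-segment, `N` candidate headings are drawn — the
current heading rotated by a polar angle ~ N(0, σΔx) about a uniform random
azimuth — and the candidate that best satisfies the mode wins:
gravitropism minimises the angle to the downward vertical, plagiotropism
the angle to the horizontal plane, exotropism the angle to the axis's birth
heading. The angular scale is `σΔx = Δx·σ`: σ is stored in the parameter
table in degrees per cm of axis, so the product is converted degrees →
radians at the point of use. With `N` = root order (the parameterization's
own rule) primaries get `N = 1`, i.e. an unsteered random walk; that is
implemented as specified, and tests that need directional contrast raise
`N` explicitly. Defaults: gravitropism for primaries, exotropism for
laterals.

**Branching.** Lateral sites occupy the zone between the basal unbranched
zone (`l_b`) and the distal unbranched zone (`l_a`), spaced `l_n` apart
inclusive of both ends — a branch zone of 6 cm with 1 cm spacing carries
exactly 7 sites. A lateral initiates in the step after the parent tip
overtakes its site (no extra delay parameter; none is defined). Its polar
insertion angle is a truncated-normal draw around `θ`, its radial azimuth
uniform in [0°, 360°). Requesting a deeper order than the parameter table
provides is an error at initialisation.

**Radial growth.** Node radii start at `a_i` and grow toward `a_max` at
`a_r` (mm/h, applied per day of node age), so basal tissue is older and
thicker and no node ever shrinks.

**Confinement.** Two containers mirror the study systems: a thin slab
(germination-paper pouch, default 279.4 × 381 × 3.175 mm) and a cylinder
(Deepot, default 63.5 mm diameter × 254 mm deep). Planar boundaries confine
by exact mirror folding — correct for any thickness, which matters because
the pouch (3.175 mm) is thinner than a primary sub-segment (5 mm); the
cylinder wall reflects radially. The heading component normal to the
violated boundary is negated. A configuration whose in-plane slab or
cylinder dimensions are smaller than twice the axial resolution is rejected
(reflection geometry degenerates); the slab's thinness is exactly the
quasi-2D regime the pouch exists to create and is exempt from that check.

**Rendering.** `render_projection()` projects the system orthographically
onto the x–z or y–z plane and strokes each segment at its local diameter
(stroke widths are odd pixel counts; the centre-line pixel already
contributes one pixel, so a radius of r px dilates by round(r − 0.5)).
An optional trim radius removes geometry farther than that distance from
the stem base, mirroring the practice of trimming excised root crowns to a
10 cm radius before imaging. The result is a `root_image` with provenance
`"simulated"`, ready for the same trait extraction as observed masks —
closing the parameterize → simulate → re-extract loop. Systems are also
exportable as RSML 1.0 and as flat segment CSVs.

## Evaluation

Observed and simulated trait tables are compared per shared numeric trait
with a two-sided Welch *t*-test (pooled-variance variant available;
the source specifies only "*t* tests", and Welch is the safer default under
unequal variances), Bonferroni-adjusted over the family of shared traits in
one comparison. A trait whose adjusted *p* falls below α = 0.05 is a
*misclassification*; the **sensitivity rate** is the percentage of traits
with no detectable difference, `100·(n_traits − n_misclassified)/n_traits`,
read off the implied confusion matrix.

`cross_validate()` runs the full workflow: one random 5-fold split of the
observed samples (whole plants, never individual roots — pseudo-replication
would inflate every test), then all C(5,3) = 10 train/test fold
permutations. Per permutation, training-fold records are summarized and
converted to parameters, one system is simulated/rendered/re-extracted per
test-fold sample, and the trait families are compared. The "10 iterations"
of the evaluation are these 10 fold permutations of a single split — the
reading the workflow's fold arithmetic supports. A permutation whose
pipeline fails is flagged in the report with its error message, never
silently dropped. The Bonferroni family is the shared trait set of one
comparison, not the union across permutations.

## What the synthetic data does and does not emulate

The fixture generator produces every input the pipeline consumes, each with
machine-readable ground truth: sinusoid-plus-noise weather series;
interval-censored rooting cohorts drawn from a log-logistic with known
median (recorded at the first daily check at or after the event, so the
recorded fraction by day *d* equals F(*d*) exactly); stroked polyline masks
with exact constructed length, width and orientation; and full
simulate–render–extract round trips packaged with the simulator's own
analytic totals. "Observed" image cohorts are simulator draws with
between-plant stochasticity — they mimic segmented mask *geometry*, not
photographs: no segmentation errors, no illumination artifacts, no pest
damage, no root–paper adhesion effects. Passing tests therefore certify the
computational chain (geometry in → traits → parameters → simulation →
evaluation), not the upstream imaging and segmentation of real plants.

Problem sizes in the test suite and acceptance script are the package's
chosen desk-scale conditions: cohorts of 12 synthetic images, 8–12
simulated days, 2 primary roots, renders at 0.25–0.5 mm/px, T50 cohorts of
200 cuttings, and 500–1000 Monte-Carlo replicates for the family-wise error
checks.

## Known limitations

* **Projection occlusion.** Crowded or strongly wiggling systems overlap
  themselves in a 2D render; merged ink shortens every skeleton-based
  measure (6–12% length undercount for unsteered random-walk axes, more for
  dense laterals near their parent). This is information loss in the image,
  not extractor error; the recovery tolerances are stated for legible
  renders, and the 2D→3D accuracy drop it causes is a finding of the study
  this package operationalizes, not a defect to be patched.
* **Equation transcription.** The ambiguous operand groupings above are
  implemented as a declarative table precisely so a reading against the
  typeset source is a one-line correction.
* **Weak primary steering.** `N = RootOrder` gives primaries a single
  tropism trial; their paths are random walks unless the user raises `N`.
* **No physiology.** Water, nutrients, soil strength and shoot coupling are
  out of scope; the simulator is geometry and timing only.
* **T50 near-degenerate cohorts.** When all cuttings root within a single
  daily check, the slope is unidentifiable; the estimator returns the
  observed step day with zero standard error and flags convergence.
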