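---
title: "Visual statistics for root growth ensembles: methods and design"
author: "rootbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual statistics for root growth ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootbox)
```

## The problem

Early-stage seedling roots (the canonical system is *Arabidopsis thaliana*
grown on agar plates and scanned daily) are segmented from images as sets
of pixels, one set per root individual, grouped into ensembles sharing a
genotype or growth condition. Trait averages hide the structure of such an
ensemble: how variable the shapes are, what a "typical" root looks like,
how fast the group grows and how trustworthy a representative estimate is
for a given sample size. rootbox turns pixel sets into time-parameterized
planar curves and computes curve-ensemble statistics on them: a curve box
plot, a geometric-median representative, per-day time-lines with
confidence zones, and a bootstrap validity indicator.

## From pixels to curves

Each root arrives as a `PixelTrace`: segmented pixels, the pixel nearest
the seed (the start), the acquisition day `d`, and the scan resolution in
dpi. World coordinates are image pixels (`x` = column, `y` = row, y
growing downward); metric lengths follow from `mm = px * 25.4 / dpi`.

Pixels are ordered by running Dijkstra on the 8-connected pixel graph
from the start, with edge weights 1 (axis steps) and sqrt(2) (diagonal
steps). The resulting shortest-path distances, normalized to [0, 1], are
the sample parameters. Pixels unreachable from the start are segmentation
debris and are dropped with a warning rather than failing the root; ties
in distance are broken by (row, col) order so the output is reproducible.

The number of spline control points balances smoothing against
over-fitting. A spectral argument gives the lower bound
`#CP >= #samples / (4 pi)` on a unit domain; the package uses
`ceiling(1.2 * #samples / (4 pi))`, floored at the spline order 4, which
stays above the bound for every sample count while remaining close to it.
Knots are placed by de Boor-style averaging of sample-parameter quantiles
so that the curve segments hold roughly equal numbers of samples; this
also keeps the Schoenberg-Whitney condition, hence a full-rank
least-squares system. Control points are then the per-coordinate linear
least-squares solution, and the knot vector is affinely mapped from
[0, 1] to [0, d]. The time parameterization is therefore day-linear — a
deliberate approximation that is accurate at daily resolution only. When
one individual was imaged on several days, the final day's trace is
fitted and the domain scaled; sub-daily timing is not modeled.

## A common basis and Euclidean coefficient vectors

Curves fitted per root live on different knot vectors. For ensemble
statistics every curve is refit onto one shared clamped basis: `n` is the
maximal member control-point count, and interior knots are selected from
the pool of all member knots (merged, rounded to 12 decimals,
deduplicated, restricted to the common day domain). If the pool offers
exactly the needed number of interior knots it is used as-is, so an
ensemble already sharing a basis keeps it; otherwise quantiles of the
pool are used, falling back to uniform spacing for degenerate pools.
Members are evaluated at `max(128, 4n)` uniform probe parameters and
refit by least squares; each curve becomes the vector
`x = (cx_1..cx_n, cy_1..cy_n)` in R^(2n). On smooth root-like curves this
refit moves the geometry by well under half a pixel (a tested invariant).
Ensembles with differing day spans are refit over the intersection of the
domains, with a warning.

## L1 depth, the geometric median and zoning

For a point set `x_1..x_n`, let `r(z)` be the norm of the sum of unit
vectors from `z` toward the samples distinct from `z`, and `w(z)` the
indicator that `z` coincides with a sample. The L1 data depth is

    L1D(z) = 1 - max(r(z) - w(z), 0) / n,

a value in (0, 1] that is 1 at the geometric median and decays outward.
Only direction vectors enter, so the depth ordering is invariant under
translation, rotation and uniform scaling — a property the test suite
checks explicitly. Member depths are the depths of their coefficient
vectors; the deepest member generalizes "the most central curve".

The geometric median (Fermat-Weber point) is computed by the damped
Weiszfeld iteration started at the mean. Two numerical details matter.
First, the damping uses the *multiplicity* of a coincident sample, not
just a 0/1 flag: with duplicated rows (bootstrap resamples produce them
constantly) the optimality condition at a sample point is
`r <= multiplicity`. Second, when the minimizer is a data point the
iteration approaches it asymptotically without landing on it; the solver
therefore checks the nearest sample for the optimality condition after
iterating and snaps to it when it is the exact minimizer (and at least as
good in objective). Convergence uses a step tolerance of `1e-10` times
the data range, an iteration cap of 1000 with a reported flag, and an
additional machine-precision objective-decrease stop, valid because the
iteration is monotone. The median curve is the median vector read back on
the shared basis: a virtual representative that need not be a member. One
known behavior inherited from the coefficient-space construction is a
mild smoothing of the representative relative to individual members, so
tortuosity-like traits are conservatively represented.

Zones follow the curve box-plot convention: curves with depth at or above
the median depth form the interquartile set; the outlier threshold
extends Tukey's whisker rule on the depth scale, flagging curves whose
depth falls more than `3 * (max depth - median depth)` *below* the median
depth. The subtraction direction is this package's reading of the rule
(the alternative — subtracting from the maximum — would shrink the inlier
range as the deepest curve improves, which inverts the whisker
semantics); it is a documented choice, not a claim about other
implementations. The factor 3 is the conventional far-out multiplier and
is a parameter everywhere it appears.

A modified band depth baseline is included for comparison: a curve's
depth is its mean fractional time inside the convex hull spanned, at each
of 128 probe parameters, by J-subsets of the other curves (J = 2 by
default, the minimal band; a summed multi-J variant is available).
Boundary membership counts as inside, with a 1e-9 relative orientation
tolerance.

## Time-lines

Evaluating every curve at the day stamps gives (position, day) samples; a
thin-plate spline `F(x) = b0 + b.x + sum_j a_j |x - c_j|^2 log|x - c_j|`
is fitted to them by least squares. The design matrix has columns
`[1, x, y, phi_1..phi_N]`; the normal equations are solved with
Jacobi-preconditioned conjugate gradients capped at `10 (N + 3)`
iterations, because the non-compact kernels make the system badly
conditioned and an iterative solver degrades gracefully there (it also
handles the consistent-but-singular interpolation regime where centers
equal samples). Kernel centers default to the curves' control points:
resolution-free, close to the data, and independent of the probe count;
using the samples themselves gives very similar fields at higher cost.
TPS reproduces affine fields exactly, which the suite verifies to 1e-8.

Time-lines are the isocurves `F = day`, extracted by marching squares on
a 256 x 256 grid over the 5 %-padded ensemble bounding box (the grid is
sampled once and reused across levels). Because F is a single-valued
field, level sets of distinct days cannot cross — the minimal-bending
property of the TPS makes them smooth as well. Each time-line carries a
variance: the population variance (divide-by-k, about the mean) of
`F(C_k(day)) - day` over the curves covering that day. The confidence
zone is drawn between the isocurves of `day - sigma` and `day + sigma`
— a one-standard-deviation convention, rendered as three nested sub-bands
so the fill alpha decays linearly toward the border. Time-lines use a
blue colormap with earlier days brighter.

## Bootstrap validity indicator

The median curve is deterministic, so its sampling stability is assessed
by bootstrap: B with-replacement resamples of the ensemble rows (indices
may repeat and need not cover all members), one geometric median per
resample, all driven by a single seeded generator advancing sequentially.
The replicate medians form an ensemble themselves; their L1-depth
interquartile subset, rendered as the union of curve strokes (rasterized
at 256 probes, dilated by the stroke radius, morphologically closed,
hole-filled, outer contour extracted), is the validity indicator — a
spatial confidence region for the representative. Raster union rather
than a convex hull keeps wiggly replicate sets from over-covering.
B defaults to 300: across reruns the indicator area's coefficient of
variation at B = 300 is a fraction of its value at B = 25 (tested), and
the area grows as the ensemble shrinks (tested as a paired sign test of
m = 20 versus m = 100 over 20 replicate generator runs). Replicate
medians use a 1e-6 relative tolerance — far below the raster cell size —
to avoid the slow convergence tail.

## Synthetic ensembles

The generator emulates the phenotypes the statistics are meant to
summarize: near-vertical growth with per-individual speed and tilt
variation and smooth lateral wiggle. Individual k grows from a plate
origin (default (400, 50) px, keeping image coordinates positive) with a
constant speed drawn from Normal(120, 25) px/day truncated at 10 % of the
base (about 2.5 mm/day at 1200 dpi), a tilt from Normal(0, 0.08 rad),
and a three-harmonic sinusoidal wiggle of ~4 px amplitude vanishing at
the seed; samples are jittered with 1 px isotropic noise and fitted with
the same control-point rule as real traces over 5 days. These defaults
are the package's standing study conditions; all tests and the
acceptance script use them unless a scenario explicitly varies one knob.
The "low noise" regime used by the recovery harnesses is defined once as
speedSd 0.5 px/day, angleSd 0.001 rad, wiggleAmp 0.25 px, noiseSd 0.1 px
(about 0.4 % relative variation). What the generator does *not* emulate:
lateral branching, gravitropic curvature trends, segmentation dropouts
and merged neighboring roots. Green tests therefore certify the
statistical machinery on clean near-vertical ensembles, not robustness to
segmentation pathology.

The inverse path — rasterizing a curve to an 8-connected pixel chain and
reconstructing it — closes the loop for end-to-end tests; the round trip
stays within one pixel.

## Numerical choices and degenerate inputs

- Spline evaluation clamps parameters to the domain ends to absorb
  floating-point drift; clamped knots make the curve interpolate its
  terminal control points exactly.
- Rank deficiency in any least-squares fit (empty knot spans) is an
  error, not a silent pseudo-inverse.
- The store serializes numbers at 17 significant digits, which
  round-trips IEEE doubles exactly (a tested invariant).
- A single curve is a valid ensemble: its depth is 1, it is its own
  median, and its bootstrap replicates all equal it.
- All-equal depths put every curve in the interquartile zone.
- Isocurve extraction returns an empty set when the level is outside the
  field range on the box; the variance of a day no curve covers is NA
  with a warning.
- Degenerate (zero-area) validity indicators fall back to the replicate
  stroke polyline.

## Problem sizes

Default analyses in the documentation and tests use ensembles of 5-100
curves, 60-sample generator trajectories, 256-probe refits, a 256 x 256
contour grid, 400-cell indicator rasters and 300 bootstrap iterations;
the bootstrap property harness runs 20 paired generator replicates.
These sizes were chosen so every documented property is demonstrated on
the scale of a typical genotype group (10-20 roots, with 100 as the
large-ensemble contrast).

## Known limitations

- Day-linear time is only accurate at daily resolution; time-lines for
  fractional days interpolate the TPS field, not real growth dynamics.
- The geometric-median representative smooths tortuosity relative to
  true members.
- The outlier rule's subtraction direction is a documented convention.
- The confidence-zone width (one sigma) is a convention; the variance
  itself is reported so other widths can be drawn.
- Band depth with J = 2 treats the degenerate two-point hull (a segment)
  as the band, which is strict for exactly-collinear ensembles.
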