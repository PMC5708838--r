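---
title: "Quantifying flow-induced subcellular polarity: methods and design notes"
author: "flowpol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flow-induced subcellular polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

An endothelial cell under directed laminar shear can polarize the
activity of signalling molecules — visualized with a translocating
fluorescent biosensor — toward its downstream edge, while disturbed flow
with no net direction leaves the signal uniform. The raw observable is a
time-lapse of one isolated cell: 30 frames at 30 or 60 s intervals after
flow onset, 16-bit grayscale, one cell per field. The quantity of
interest is *where and how strongly* fluorescence accumulates along the
flow axis over time, summarized so that treatment groups of a dozen cells
can be compared statistically.

`flowpol` implements that measurement as a fixed chain, with each stage
an exported function so every step can be validated in isolation.

## The quantification chain

**Background.** Each frame's background level is estimated as the mean
over the four `corner_size × corner_size` (default 20 px) corner patches,
which the acquisition protocol keeps cell-free, and subtracted with
clipping at zero. Clipping keeps intensities physical; its only side
effect is a sub-noise positive bias in empty regions, which the
segmentation threshold sits far above.

**Segmentation.** The cell outline is re-identified in every frame
(the cell migrates): threshold, removal of connected components below
`min_speckle_area` (default 64 px), morphological closing with a disc of
radius `closing_radius` (default 3 px), hole filling, largest component.
The threshold method is Otsu, but it is *calibrated on the first (basal)
frame and applied to all frames* of a stack. This is a deliberate choice:
the basal frame's histogram is cleanly bimodal (background vs. cell), so
Otsu is well posed there. On a strongly polarized late frame the cell
class itself becomes bimodal — a bright downstream pole versus a dimmer
body — and a per-frame Otsu can land *inside* the cell, amputating the
upstream half and corrupting the bounding box that anchors the spatial
grid. Per-frame recalibration remains available as
`threshold = "otsu-frame"`, and any numeric threshold can be supplied.

**Orientation.** All analysis assumes the downstream edge is to the left,
so part index 1 is the downstream-most position. Stacks recorded with
rightward flow are mirrored once; mirroring preserves intensities and
areas exactly.

**Gridding and projection.** The mask's tight bounding box is divided
into 50 equal-width column intervals along the flow axis and 50
equal-height row intervals (half-open intervals, last closed, 0-based
coordinates — each pixel belongs to exactly one part). Part values are
*fractions of whole-cell fluorescence*, so the spatial profile is
independent of expression level and cell size; pixels inside the box but
outside the mask contribute nothing. The grid is re-derived from each
frame's own bounding box, which keeps part indices comparable across
frames as relative positions within the (migrating, deforming) cell.

**Difference accumulation.** Static structure — the bright nucleus,
unbound reporter — dominates raw intensity but carries no information
about flow-induced redistribution. Differencing each frame's fraction
grid against frame 1 removes it: `D_t = I_t − I_1`. The sum of successive
pairwise differences telescopes to exactly `I_T − I_1`, and the
implementation stores the per-frame differences so the map's rows are the
cumulative change since flow onset. Row 1 is identically zero by
construction. Whether the differencing should act on raw images or on
fraction grids is a genuine ambiguity; it acts on fraction grids here, so
that the cancellation is of static *relative* structure and the result
stays expression-invariant. (At the level of fitted statistics the two
choices differ only through total-intensity drift, which the fraction
representation deliberately discards.)

**Normalization.** Each row is divided by the mean of the basal
(frame 1) profile, mapping the basal mean to 1.0. Since a percentage
profile over 50 parts always has mean 2, this is a fixed rescaling that
makes rows of different cells directly comparable and the map dimensionless.

**Logistic fit and polarity statistics.** The minute-30 row (the
distribution has become steady by then) is fitted with

$$y(x) = \frac{A_1 - A_2}{1 + e^{(x - X_0)/D}} + A_2,$$

by Levenberg–Marquardt least squares over parts \(x = 1..50\). Three
statistics summarize polarity:

* the **range** \(|A_1 - A_2|\) — the intensity of polarization;
* the **onset** \(X'\) — scanning upward from the downstream end, the
  first integer part whose analytic slope magnitude (or that at
  \(x + 1\)) is below 0.005 while the magnitude at \(x - 1\) is not;
  undefined (NA) when no part qualifies, as for a flat fit;
* the **inflection slope** \(y'(X_0) = (A_2 - A_1)/(4D)\), negative for
  downstream-high profiles.

Because the map rows are differences, they sum to zero across parts; a
fitted row is therefore the underlying logistic *minus its spatial mean*.
The range, onset and slope are all invariant to that constant offset —
only the individual plateau values \(A_1, A_2\) are mean-centred.

**Group statistics.** Metrics are computed per cell and then aggregated
(mean ± SD per group), mirroring how per-cell spreads are reported;
groups are compared to the control by a two-tailed, equal-variance
Student t-test (the classic spreadsheet default; Welch available via
`var_equal = FALSE`). No multiple-testing correction is applied, and the
output notes it. Cells with undefined onset are omitted from onset
statistics; a group with fewer than two defined values gets an NA
p-value rather than an error.

## Numerical choices in the fit

Initialization is deterministic: \(A_1 = y_1\), \(A_2 = y_{50}\),
\(X_0\) at the largest absolute finite-difference gradient, \(D = 2\).
If that start fails, three further deterministic starts cover gentle
slopes (large \(|D|\), both orientations) — important for near-flat
profiles, where the gradient start is numerically singular — followed by
at most five jittered restarts from an internally seeded RNG (the global
RNG state is saved and restored, so fitting never perturbs user
randomness and is bit-reproducible). A profile with standard deviation
below `1e-9` is returned directly as the degenerate fit
\(A_1 = A_2 = \bar y\). If nothing converges, an error of class
`flowpol_fit_failure` carries the best attempt. \(D\) is unconstrained
except \(D \neq 0\); its sign freedom lets the same code fit
downstream-high and upstream-high profiles, and no box constraints are
imposed on \(X_0\) — a consequence is that a noise-only profile can be
"fitted" by a far-extrapolated curve whose in-domain variation is tiny;
its range is then small but not zero, which is exactly how unpolarized
cells behave in group comparisons. When the onset condition holds at
several parts, the first (most downstream) match is returned.

## The synthetic generator

The generator exists so that every downstream stage has ground truth. A
cell is a superellipse body (semi-axes 45 × 75 px in a 192 × 192 px
field) containing a static nuclear disc at 1.8× cytoplasmic brightness,
over a constant background offset of 100 counts, with cytoplasm at 3000
counts and additive Gaussian pixel noise (sd 25 counts, ~1% of the
cytoplasmic signal) — magnitudes typical of a cooled-CCD 16-bit
acquisition. Thirty frames at 60 s intervals; polarity grows linearly
from zero at frame 1 to full amplitude at frame 30.

Polarity is injected *in fraction space*: the flow-axis column fractions
of frame \(t\) equal those of frame 1 plus
\(\mathrm{ramp}(t) \cdot (L - \bar L)/50\), where \(L\) is the target
logistic evaluated at parts 1..50. Subtracting \(\bar L\) makes the shift
zero-sum, i.e. the total fluorescent pool is conserved and the
downstream gain is fed by diffuse upstream depletion — translocation, not
synthesis. This is also the only injection that the difference-based map
can represent exactly: map rows sum to zero, so the recoverable signal is
the logistic up to a constant. The injected \((|A_1-A_2|, X_0, D)\) are
recovered exactly (up to grid discretization) by the full pipeline, which
is what the round-trip tests assert.

Two geometric constraints follow from conservation. First, each column
must absorb its share of depletion without any pixel going negative; the
generator validates this and rejects specifications whose dimmest
cytoplasm would fall below 5% of basal. Second, a smoothly tapered
outline (an ellipse) leaves the extreme upstream columns only a few
pixels tall, so their share of depletion would extinguish them; the
default superellipse exponent of 20 gives the blunt outline of a
well-spread cell whose end columns stay comfortably bright. Both
geometry and exponent are configurable.

Default polarity parameters model a strongly polarized laminar condition:
range 1.15, inflection at part 12, \(D = 1\) (inflection slope −0.29).
The unpolarized twin (\(A_1 = A_2\)) models disturbed flow. Cohorts
draw per-cell jitter — lognormal on range (CV 0.3), expression (CV 0.3),
semi-axes (CV 0.08) and \(D\) (CV 0.25, multiplicative because it is a
positive scale parameter), Gaussian on \(X_0\) (sd 2 parts) — spreads of
the order seen in single-cell polarity measurements. Per-cell seeds
derive deterministically from one master seed.

What the generator does **not** emulate: photobleaching, cell migration
and shape change over the stack (the mask is static), focus drift,
uneven illumination, camera shot noise's intensity dependence, and
multi-cell fields. Passing tests therefore demonstrate the correctness
of the quantification chain on an idealized cell, not robustness to
every artifact of real acquisitions; the per-frame segmentation and
per-frame grids are exercised but not stressed by migration.

## Problem sizes and reproducibility

The test-suite and acceptance runs use 200 replicate profiles for
recovery studies, 1000 random parameter draws for the onset and
inflection-slope oracles, 50 random frames for the exhaustive grid
oracles, and image-level cohorts of 12 polarized versus 5 unpolarized
cells at the full 30-frame, 192 × 192 px study conditions. All
stochastic steps take explicit seeds; identical seeds give bit-identical
stacks, maps, CSVs and rendered heatmaps.

## Known limitations

* The spatial grid is anchored to the segmented bounding box; systematic
  segmentation bias (e.g. a threshold that clips the dim upstream rim)
  shifts part indices and hence \(X_0\) and \(X'\).
* The onset rule is threshold-based (0.005 in normalized units per
  part); its value is a convention, and onset comparisons are only
  meaningful at a fixed threshold.
* Only the flow-axis projection is analyzed; row-resolved (cross-flow)
  structure is averaged away by design.
* The minute-30 row is a single time slice; no time-resolved fitting is
  attempted since the distribution is steady by then.
* Fraction-space differencing discards total-intensity dynamics
  (photobleaching, expression drift) — intentional, but it means the
  method cannot distinguish redistribution from asymmetric gain.
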