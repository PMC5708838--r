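# flowpol

Quantifies **flow-induced subcellular polarity** from time-lapse
fluorescence microscopy of single biosensor-expressing cells. When an
adherent cell is exposed to directed fluid shear, activity reporters (such
as GTPase biosensors) can redistribute toward the downstream edge; under
disturbed, directionless flow they stay uniform. `flowpol` turns a raw
image stack into a time-by-position activity map along the flow axis and
condenses each cell's polarity into three statistics that can be compared
across treatment groups.

## What it computes

For each cell, frames `I_1..I_T` (chronological, one frame every 30 or
60 s after flow onset) are processed as:

1. **Background subtraction** — the mean of the four corner patches of
   each frame (cell-free by experimental design) is subtracted, clipping
   at zero.
2. **Segmentation** — threshold (Otsu, calibrated on the basal frame),
   speckle removal, morphological closing, hole filling, largest
   component; re-done per frame because the cell migrates.
3. **Orientation** — frames are mirrored if needed so the downstream edge
   is on the left; position 1 of every profile is the downstream-most part.
4. **Gridding** — the cell bounding box is split into 50 × 50 equal parts
   and each part's fraction of whole-cell fluorescence is computed.
5. **Difference accumulation** — `D_t = I_t − I_1` on the fraction grids;
   the summed successive differences telescope to `I_T − I_1`, cancelling
   everything static since frame 1 (nucleus, unbound reporter).
6. **Projection and normalization** — each difference grid is compressed
   into a 50-part percentage profile along the flow axis and divided by
   the basal profile mean, giving a `T × 50` spatiotemporal map.
7. **Polarity statistics** — the minute-30 row is fitted with the logistic

   `y = (A1 − A2) / (1 + exp((x − X0)/D)) + A2`

   yielding the polarity range `|A1 − A2|`, the onset `X'` (first part
   where the slope magnitude falls below 0.005), and the inflection slope
   `y'(X0) = (A2 − A1)/(4D)`.
8. **Group statistics** — per-group mean ± SD of each metric and
   two-sample Student t-tests against the control group.

A synthetic-image generator (`synthetic_cell_spec()`,
`generate_cell_stack()`, `generate_cohort()`) renders cells with known
ground-truth polarity so the whole chain is testable without external
data.

## Worked example

```r
library(flowpol)

g <- generate_cell_stack(synthetic_cell_spec(), seed = 1)
g$stack
#> frame_stack: 30 frames of 192x192 px, every 60s, flow left [synthetic]

q <- quantify_stack(g$stack)
m <- cell_metrics(q$map, minute = 30)
m$fit
#> logistic_fit: A1 = 0.8856, A2 = -0.2646, X0 = 12, D = 1.001 (SSE 1.79e-05)
sprintf("range |A1-A2| = %.3f, onset X' = %d, inflection slope = %.3f",
        m$range, m$onset, m$slope)
#> "range |A1-A2| = 1.150, onset X' = 17, inflection slope = -0.287"
```

The generated cell carries an injected polarity range of 1.15 centred at
part 12; the fit recovers the range to three decimals, the inflection
position exactly, and a slope of `-(1.150)/(4 × 1.001) = -0.287`. The map
rows are cumulative changes since frame 1, so the fitted plateaus are
mean-centred; their difference, not their absolute level, carries the
polarity.

The scripts under `analysis/` run the full study: `01_simulate.R` writes
a 12-cell laminar and a 5-cell disturbed cohort as 16-bit TIFF series,
`02_quantify.R` drives `run_pipeline()` over them (maps, heatmaps,
metrics and group summary under `results/pipeline/`), and
`03_recovery.R` measures parameter recovery versus profile noise.

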