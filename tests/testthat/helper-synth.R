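# Shared fixtures: everything is generated in code at test time.

# A short laminar-like stack: default geometry/intensity but few frames,
# linear ramp to full polarity at the last frame.
test_spec <- function(n_frames = 6L, noise_sigma = 0, ...) {
  synthetic_cell_spec(n_frames = n_frames, noise_sigma = noise_sigma, ...)
}

# Unpolarized (disturbed-flow-like) twin of a spec: equal plateaus.
unpolarized <- function(spec) {
  mid <- mean(spec$polarity_params[c("A1", "A2")])
  spec$polarity_params[c("A1", "A2")] <- c(mid, mid)
  spec
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Exhaustive per-pixel oracle for the 50x50 fraction grid: a plain double
# loop over every pixel, independent of the vectorized implementation.
fraction_grid_oracle <- function(frame, mask, n_bins = 50L) {
  b <- mask$bbox
  g <- matrix(0, n_bins, n_bins)
  H <- b[["row_max"]] - b[["row_min"]]
  W <- b[["col_max"]] - b[["col_min"]]
  for (i in seq_len(nrow(frame))) {
    for (j in seq_len(ncol(frame))) {
      if (!mask$mask[i, j]) next
      r <- min(n_bins, (n_bins * ((i - 1) - b[["row_min"]])) %/% H + 1)
      c <- min(n_bins, (n_bins * ((j - 1) - b[["col_min"]])) %/% W + 1)
      g[r, c] <- g[r, c] + frame[i, j]
    }
  }
  g / sum(frame[mask$mask])
}

# Dense-scan oracle for the onset rule, written as a direct transcription
# of the rule over all candidate positions.
onset_oracle <- function(A1, A2, X0, D, threshold = 0.005, n_bins = 50L) {
  slope_at <- function(x) {
    u <- exp((x - X0) / D)
    s <- -(A1 - A2) * u / (D * (1 + u)^2)
    if (!is.finite(u)) 0 else s
  }
  for (x in 2:(n_bins - 1)) {
    ok <- (abs(slope_at(x)) < threshold || abs(slope_at(x + 1)) < threshold) &&
      abs(slope_at(x - 1)) >= threshold
    if (ok) return(as.integer(x))
  }
  NA_integer_
}

# Random blob mask for grid oracle tests: union of a few discs, largest
# connected component kept so it is a valid single-component cell mask.
random_cell_mask <- function(shape = c(64L, 64L)) {
  m <- matrix(FALSE, shape[1], shape[2])
  ctr <- shape / 2
  for (k in 1:3) {
    cen <- ctr + stats::runif(2, -8, 8)
    rad <- stats::runif(1, 8, 14)
    r <- matrix(seq_len(shape[1]), shape[1], shape[2])
    c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    m <- m | ((r - cen[1])^2 + (c - cen[2])^2 <= rad^2)
  }
  lab <- EBImage::bwlabel(m)
  keep <- which.max(tabulate(lab[lab > 0]))
  mm <- matrix(lab == keep, shape[1], shape[2])
  structure(list(mask = mm, bbox = flowpol:::mask_bbox(mm), area = sum(mm)),
            class = "cell_mask")
}

quiet_quantify <- function(stack, ...) suppressWarnings(quantify_stack(stack, ...))

# Numeric derivative of the logistic at X0: 5-point stencil with a step
# proportional to the curve's own slope scale D, accurate for any fitted
# parameter scale.
logistic_num_deriv <- function(f) {
  h <- 1e-3 * abs(f$D)
  ev <- function(d) logistic_curve(f$X0 + d, f$A1, f$A2, f$X0, f$D)
  (-ev(2 * h) + 8 * ev(h) - 8 * ev(-h) + ev(-2 * h)) / (12 * h)
}
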