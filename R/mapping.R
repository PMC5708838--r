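#' Partition a cell bounding box into an n x n grid
#'
#' Divides the mask's tight bounding box into `n_bins` equal-width column
#' intervals along the flow axis and `n_bins` equal-height row intervals.
#' Intervals are half-open (the last closed), so every pixel belongs to
#' exactly one part. Parts may be empty when the bounding box is thinner
#' than `n_bins` pixels (a warning is emitted).
#'
#' @param mask a `cell_mask` from [segment_cell()].
#' @param n_bins number of parts per axis (default 50).
#' @return an object of class `cell_grid`: list with `bbox`, `n_bins`.
#' @export
partition_cell <- function(mask, n_bins = 50L) {
  stopifnot(inherits(mask, "cell_mask"))
  if (mask$area == 0L) stop("empty mask", call. = FALSE)
  b <- mask$bbox
  n_bins <- as.integer(n_bins)
  if ((b[["row_max"]] - b[["row_min"]]) < n_bins ||
      (b[["col_max"]] - b[["col_min"]]) < n_bins)
    warning("bounding box thinner than n_bins pixels; some parts will be empty")
  structure(list(bbox = b, n_bins = n_bins), class = "cell_grid")
}

## part index (1-based) of 0-based pixel coordinate p in half-open [lo, hi)
## split into n equal-width intervals; exact in integer arithmetic
part_index <- function(p, lo, hi, n) {
  pmin.int(n, (n * (p - lo)) %/% (hi - lo) + 1L)
}

#' Fluorescence fraction per grid part
#'
#' Entry `(r, c)` is the summed masked intensity of part `(r, c)` divided by
#' the whole-cell masked total, so all entries are non-negative and sum
#' to 1. Pixels inside the bounding box but outside the mask contribute
#' nothing. Column part 1 is the left-most (downstream after orientation)
#' interval.
#'
#' @param frame 2-D numeric matrix (background-subtracted).
#' @param mask the `cell_mask` segmented from this frame.
#' @param grid a [partition_cell()] geometry.
#' @return `n_bins x n_bins` numeric matrix of fractions.
#' @export
fraction_grid <- function(frame, mask, grid) {
  stopifnot(is.matrix(frame), inherits(mask, "cell_mask"),
            inherits(grid, "cell_grid"))
  nb <- grid$n_bins
  b <- grid$bbox
  idx <- which(mask$mask, arr.ind = TRUE)
  v <- frame[mask$mask]
  tot <- sum(v)
  if (tot <= 0) stop("degenerate frame: zero total masked intensity",
                     call. = FALSE)
  rbin <- part_index(idx[, 1] - 1L, b[["row_min"]], b[["row_max"]], nb)
  cbin <- part_index(idx[, 2] - 1L, b[["col_min"]], b[["col_max"]], nb)
  g <- matrix(0, nb, nb)
  acc <- rowsum(v, group = (cbin - 1L) * nb + rbin)
  g[as.integer(rownames(acc))] <- acc
  g / tot
}

#' Frame-difference accumulation
#'
#' Subtracts the first grid from every later one: `D_t = I_t - I_1` for
#' `t = 2..T`. Because the sum of successive differences telescopes, the
#' cumulative difference equals `I_T - I_1` exactly; any component static
#' since frame 1 — the nucleus, unbound biosensor — cancels from every
#' `D_t`.
#'
#' @param grids chronological list of [fraction_grid()] matrices (>= 2).
#' @return an object of class `difference_stack`: list with `deltas` (list
#'   of `D_t`, `t = 2..T`) and `cumulative` (`I_T - I_1`).
#' @export
difference_accumulate <- function(grids) {
  if (length(grids) < 2L)
    stop("insufficient data: need at least 2 grids", call. = FALSE)
  deltas <- lapply(grids[-1], function(g) g - grids[[1]])
  structure(list(deltas = deltas, cumulative = deltas[[length(deltas)]]),
            class = "difference_stack")
}

#' Project a grid onto the flow axis
#'
#' Compresses a 50x50 matrix into a 50-vector by column sums expressed as a
#' percentage of the grand total: entry `c` is
#' `100 * sum(column c) / grand_total`. Column part 1 is the
#' downstream-most. For difference matrices pass the full frame's grand
#' total (1 for fraction grids) so signs are preserved.
#'
#' @param grid `n x n` numeric matrix (a fraction grid or a difference).
#' @param grand_total denominator; defaults to `sum(grid)`.
#' @return numeric `n`-vector of percentages.
#' @export
project_profile <- function(grid, grand_total = sum(grid)) {
  stopifnot(is.matrix(grid))
  if (grand_total <= 0)
    stop("degenerate frame: non-positive grand total", call. = FALSE)
  100 * colSums(grid) / grand_total
}

#' Assemble a normalized spatiotemporal map
#'
#' Stacks chronological flow-axis profiles into a `T x n` matrix and
#' divides every entry by the mean of the basal (pre-stimulation) profile,
#' mapping the basal mean to 1.0 so cells with different expression levels
#' are comparable.
#'
#' @param profiles chronological list of profiles (rows of the map).
#' @param basal the basal profile of the same cell.
#' @param times numeric vector of acquisition times, seconds from flow
#'   onset, one per profile.
#' @param n_cells number of cells contributing (1 for a single cell).
#' @return an object of class `st_map`: list with `matrix` (`T x n`),
#'   `times`, `n_cells`.
#' @export
normalize_profiles <- function(profiles, basal,
                               times = seq_along(profiles), n_cells = 1L) {
  b <- mean(basal)
  if (!is.finite(b) || b <= 0)
    stop("degenerate basal: non-positive basal mean", call. = FALSE)
  stopifnot(length(times) == length(profiles))
  m <- do.call(rbind, profiles) / b
  dimnames(m) <- NULL
  structure(list(matrix = m, times = as.numeric(times),
                 n_cells = as.integer(n_cells)), class = "st_map")
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf("st_map: %d time points x %d parts (n_cells = %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_cells))
  invisible(x)
}

#' Average spatiotemporal maps across cells
#'
#' Entry-wise arithmetic mean of same-shaped maps, as used for the
#' group-level map of a treatment cohort.
#'
#' @param maps list of [normalize_profiles()] maps of identical shape.
#' @return an `st_map` with `n_cells = length(maps)`.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "st_map")))
  d <- dim(maps[[1]]$matrix)
  for (m in maps)
    if (!identical(dim(m$matrix), d))
      stop("incompatible maps: shapes differ", call. = FALSE)
  avg <- Reduce(`+`, lapply(maps, `[[`, "matrix")) / length(maps)
  structure(list(matrix = avg, times = maps[[1]]$times,
                 n_cells = length(maps)), class = "st_map")
}

#' Quantify one stack into a spatiotemporal map
#'
#' Runs the full single-cell chain: corner background subtraction,
#' per-frame segmentation, orientation so downstream is left, 50x50 grid
#' fractions per frame (grid re-derived from each frame's bounding box,
#' since the cell migrates), frame-difference accumulation against frame 1,
#' flow-axis projection, and basal normalization. Row `t` of the map is the
#' cumulative change of the flow-axis percentage profile since frame 1
#' (row 1 is identically zero), divided by the basal profile mean.
#'
#' @param stack a raw [frame_stack()].
#' @param corner_size background corner patch side, px.
#' @param threshold,min_speckle_area,closing_radius see [segment_cell()].
#' @param n_bins parts per axis (default 50).
#' @return list with `map` (an `st_map`), `masks`, `grids`, `profiles`
#'   (raw per-frame percentage profiles) and `basal` (frame 1's profile).
#' @export
quantify_stack <- function(stack, corner_size = 20L, threshold = "otsu",
                           min_speckle_area = 64L, closing_radius = 3L,
                           n_bins = 50L) {
  stopifnot(inherits(stack, "frame_stack"))
  bg <- subtract_background(stack, corner_size)
  masks <- segment_stack(bg, threshold = threshold,
                         min_speckle_area = min_speckle_area,
                         closing_radius = closing_radius)
  o <- orient_to_flow(bg, masks)
  bg <- o$stack; masks <- o$masks
  grids <- mapply(function(f, m) fraction_grid(f, m, partition_cell(m, n_bins)),
                  bg$frames, masks, SIMPLIFY = FALSE)
  profiles <- lapply(grids, project_profile)
  ds <- difference_accumulate(grids)
  rows <- c(list(rep(0, n_bins)),
            lapply(ds$deltas, project_profile, grand_total = 1))
  times <- stack$interval_s * seq_along(stack$frames)
  map <- normalize_profiles(rows, basal = profiles[[1]], times = times)
  list(map = map, masks = masks, grids = grids, profiles = profiles,
       basal = profiles[[1]])
}

#' Render a spatiotemporal map as a pseudocolor heatmap
#'
#' Writes a PNG with part index 1..n on the x axis (downstream left) and
#' time increasing downward, colors running blue (low) through cyan,
#' yellow, red (high). Rendering is deterministic for a fixed input.
#'
#' @param map an `st_map`.
#' @param out PNG file path.
#' @param upscale integer pixel replication factor per matrix cell.
#' @return invisibly, `out`.
#' @export
render_map <- function(map, out, upscale = 8L) {
  stopifnot(inherits(map, "st_map"))
  pal <- grDevices::colorRampPalette(c("#00008F", "blue", "cyan", "yellow",
                                       "red", "#8F0000"))(256)
  m <- map$matrix
  rng <- range(m)
  idx <- if (diff(rng) == 0) matrix(128L, nrow(m), ncol(m))
         else matrix(1L + as.integer(round(255 * (m - rng[1]) / diff(rng))),
                     nrow(m), ncol(m))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  arr <- array(0, c(nrow(m), ncol(m), 3))
  arr[, , 1] <- rgb[1, ]; arr[, , 2] <- rgb[2, ]; arr[, , 3] <- rgb[3, ]
  up <- function(a) a[rep(seq_len(nrow(a)), each = upscale),
                      rep(seq_len(ncol(a)), each = upscale)]
  big <- array(0, c(nrow(m) * upscale, ncol(m) * upscale, 3))
  for (k in 1:3) big[, , k] <- up(arr[, , k])
  ok <- tryCatch({ png::writePNG(big, out); TRUE },
                 error = function(e) stop("I/O error writing ", out, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(out)
}

#' Write a spatiotemporal map as CSV
#'
#' One row per time point (`time_s` column) and columns `part_01..part_n`,
#' printed at full double precision so repeated runs are byte-identical.
#'
#' @param map an `st_map`.
#' @param path CSV file path.
#' @return invisibly, `path`.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "st_map"))
  nb <- ncol(map$matrix)
  header <- paste(c("time_s", sprintf("part_%02d", seq_len(nb))),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(map$matrix)), function(i) {
    paste(c(fmt_num(map$times[i]), fmt_num(map$matrix[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)
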