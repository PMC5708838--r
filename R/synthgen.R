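#' Specification of a synthetic biosensor-expressing cell
#'
#' Describes one simulated cell for [generate_cell_stack()]: a superellipse
#' cell body containing a brighter static nuclear disc, imaged over
#' `n_frames` frames at `frame_interval_s` seconds. From frame 2 onward a
#' polarized signal component grows along the flow axis following
#' `polarity_ramp`, so that the final frame's flow-axis fraction profile
#' differs from the first frame's by the (mean-centred) logistic curve
#' given by `polarity_params`. Total cell fluorescence is conserved: the
#' downstream gain is balanced by diffuse upstream depletion, emulating
#' translocation of a fixed biosensor pool rather than net synthesis.
#'
#' @param image_shape integer (rows, cols) of each frame.
#' @param cell_center (row, col) centre of the cell body; default image centre.
#' @param cell_axes (row, col) semi-axes of the cell body, pixels.
#' @param superellipse_n exponent of the superellipse outline
#'   `|dr/a|^n + |dc/b|^n <= 1`; `2` is an ellipse, larger values give the
#'   blunter outline of a well-spread cell. The default `20` keeps the
#'   upstream and downstream end columns thick enough to carry their share
#'   of the conserved-pool redistribution without going dark.
#' @param nucleus_center (row, col) centre of the nuclear disc.
#' @param nucleus_radius radius of the nuclear disc, pixels.
#' @param nucleus_gain multiplicative brightness of the nucleus relative to
#'   cytoplasm (> 1); the nucleus is static so frame differencing cancels it.
#' @param base_intensity cytoplasmic intensity in frame 1, camera counts.
#' @param background_offset constant offset added everywhere, camera counts.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_s acquisition interval, seconds (30 or 60).
#' @param polarity_params named vector `c(A1, A2, X0, D)` of the target
#'   spatial logistic in 50-part flow-axis coordinates (part 1 = downstream).
#' @param polarity_ramp per-frame amplitude schedule in `[0, 1]`; must be 0
#'   at frame 1 and reach 1 at the final frame. Default: linear.
#' @param flow_dir `"left"` or `"right"`: side of the image the flow exits
#'   (the downstream edge of the cell).
#' @param n_bins number of flow-axis parts (default 50).
#' @param corner_size side of the corner background patches that must stay
#'   cell-free, pixels.
#' @return an object of class `cell_spec`.
#' @seealso [generate_cell_stack()], [generate_cohort()]
#' @export
synthetic_cell_spec <- function(image_shape = c(192L, 192L),
                                cell_center = round(image_shape / 2),
                                cell_axes = c(45, 75),
                                superellipse_n = 20,
                                nucleus_center = cell_center + c(-8, 10),
                                nucleus_radius = 12,
                                nucleus_gain = 1.8,
                                base_intensity = 3000,
                                background_offset = 100,
                                noise_sigma = 25,
                                n_frames = 30L,
                                frame_interval_s = 60,
                                polarity_params = c(A1 = 1.9, A2 = 0.75,
                                                    X0 = 12, D = 1),
                                polarity_ramp = NULL,
                                flow_dir = c("left", "right"),
                                n_bins = 50L,
                                corner_size = 20L) {
  flow_dir <- match.arg(flow_dir)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L)
    stop("invalid spec: n_frames must be >= 2", call. = FALSE)
  if (is.null(polarity_ramp))
    polarity_ramp <- seq(0, 1, length.out = n_frames)
  if (length(polarity_ramp) != n_frames ||
      any(polarity_ramp < 0 | polarity_ramp > 1) ||
      polarity_ramp[1] != 0 ||
      abs(polarity_ramp[n_frames] - 1) > 1e-12)
    stop("invalid spec: polarity_ramp must be in [0,1], start at 0 and reach 1",
         call. = FALSE)
  pp <- polarity_params
  if (length(pp) != 4) stop("invalid spec: polarity_params needs (A1, A2, X0, D)",
                            call. = FALSE)
  names(pp) <- c("A1", "A2", "X0", "D")
  if (pp[["D"]] == 0) stop("invalid spec: D must be non-zero", call. = FALSE)
  stopifnot(nucleus_gain > 1, background_offset >= 0, noise_sigma >= 0,
            base_intensity > 0, all(cell_axes > 0), nucleus_radius > 0)
  spec <- list(image_shape = as.integer(image_shape),
               cell_center = as.numeric(cell_center),
               cell_axes = as.numeric(cell_axes),
               superellipse_n = superellipse_n,
               nucleus_center = as.numeric(nucleus_center),
               nucleus_radius = nucleus_radius,
               nucleus_gain = nucleus_gain,
               base_intensity = base_intensity,
               background_offset = background_offset,
               noise_sigma = noise_sigma,
               n_frames = n_frames,
               frame_interval_s = frame_interval_s,
               polarity_params = pp,
               polarity_ramp = polarity_ramp,
               flow_dir = flow_dir,
               n_bins = as.integer(n_bins),
               corner_size = as.integer(corner_size))
  class(spec) <- "cell_spec"
  spec
}

## superellipse membership for all pixels; centres at pixel centres (1-based)
superellipse_mask <- function(shape, center, axes, n) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (abs((r - center[1]) / axes[1])^n + abs((c - center[2]) / axes[2])^n) <= 1
}

disc_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1])^2 + (c - center[2])^2) <= radius^2
}

validate_cell_geometry <- function(spec, cell, nuc) {
  sh <- spec$image_shape
  if (!any(cell)) stop("invalid spec: empty cell mask", call. = FALSE)
  if (any(cell[1, ]) || any(cell[sh[1], ]) || any(cell[, 1]) || any(cell[, sh[2]]))
    stop("invalid spec: cell touches the image border", call. = FALSE)
  if (any(nuc & !cell))
    stop("invalid spec: nucleus outside cell", call. = FALSE)
  cs <- spec$corner_size
  corners <- rbind(c(1, cs, 1, cs), c(1, cs, sh[2] - cs + 1, sh[2]),
                   c(sh[1] - cs + 1, sh[1], 1, cs),
                   c(sh[1] - cs + 1, sh[1], sh[2] - cs + 1, sh[2]))
  for (k in seq_len(4))
    if (any(cell[corners[k, 1]:corners[k, 2], corners[k, 3]:corners[k, 4]]))
      stop("invalid spec: cell pixels inside a corner background patch",
           call. = FALSE)
  invisible(TRUE)
}

#' Generate one synthetic time-lapse stack with ground truth
#'
#' Renders the cell described by `spec` into `n_frames` frames. Frame 1 is
#' the basal state: uniform cytoplasm at `base_intensity` plus the nuclear
#' disc at `nucleus_gain` times that, plus `background_offset` everywhere.
#' Later frames redistribute cytoplasmic signal between flow-axis columns so
#' that the cell's column fraction profile shifts by
#' `polarity_ramp[t] * (L - mean(L)) / n_bins`, where `L` is the target
#' logistic evaluated at parts `1..n_bins`. Gaussian noise of sd
#' `noise_sigma` is added independently to every pixel. The same `spec` and
#' `seed` always produce bit-identical output.
#'
#' @param spec a [synthetic_cell_spec()].
#' @param seed integer seed for the pixel noise.
#' @return a list with elements `stack` (a [frame_stack()]) and `truth`, a
#'   `ground_truth` list carrying the cell `mask`, the `basal_profile`
#'   (percent per part in frame 1), the `final_profile` (the logistic at
#'   parts `1..n_bins`), `delta_profile` (`final_profile` minus its mean:
#'   the expected final row of the difference-based map), and `params`.
#' @export
generate_cell_stack <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cell_spec"))
  sh <- spec$image_shape
  nb <- spec$n_bins
  cell <- superellipse_mask(sh, spec$cell_center, spec$cell_axes,
                            spec$superellipse_n)
  nuc <- disc_mask(sh, spec$nucleus_center, spec$nucleus_radius)
  validate_cell_geometry(spec, cell, nuc)
  cyto <- cell & !nuc

  ## flow-axis column bins over the true bounding box (same half-open
  ## equal-width convention as partition_cell)
  cols_any <- which(apply(cell, 2, any))
  col_min <- min(cols_any) - 1L          # 0-based half-open bbox
  col_max <- max(cols_any)
  W <- col_max - col_min
  colbin_of <- function(j1) pmin(nb, (nb * ((j1 - 1L) - col_min)) %/% W + 1L)
  ## part 1 must be the downstream-most column: for flow to the right the
  ## downstream edge is the right image edge, so reverse the part order
  orient_bin <- function(b) if (spec$flow_dir == "right") nb + 1L - b else b

  colix <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
  bin_cyto <- orient_bin(colbin_of(colix[cyto]))
  bin_nuc <- orient_bin(colbin_of(colix[nuc]))

  base <- spec$base_intensity
  S_cyto <- tabulate(bin_cyto, nbins = nb)               # cytoplasm px / part
  colint1 <- base * S_cyto +
    base * spec$nucleus_gain * tabulate(bin_nuc, nbins = nb)
  T1 <- sum(colint1)

  pp <- spec$polarity_params
  L <- logistic_curve(seq_len(nb), pp[["A1"]], pp[["A2"]], pp[["X0"]], pp[["D"]])
  delta <- (L - mean(L)) / nb            # zero-sum target fraction shift
  per_px <- ifelse(S_cyto > 0, T1 * delta / S_cyto, 0)
  if (any(S_cyto == 0 & abs(delta) > 0))
    stop("invalid spec: a flow-axis part holds no cytoplasm pixels",
         call. = FALSE)
  wmin <- 1 + min(per_px) / base
  if (wmin < 0.05)
    stop("invalid spec: polarity amplitude too large for the cell geometry ",
         sprintf("(dimmest cytoplasm would fall to %.2f of basal)", wmin),
         call. = FALSE)

  basemap <- matrix(0, sh[1], sh[2])
  basemap[cyto] <- base
  basemap[nuc] <- base * spec$nucleus_gain
  addmap <- matrix(0, sh[1], sh[2])
  addmap[cyto] <- per_px[bin_cyto]

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    f <- basemap + spec$polarity_ramp[t] * addmap + spec$background_offset
    if (spec$noise_sigma > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, spec$noise_sigma),
                      sh[1], sh[2])
    frames[[t]] <- pmax(f, 0)
  }

  stack <- frame_stack(frames, interval_s = spec$frame_interval_s,
                       flow_dir = spec$flow_dir, label = "synthetic")
  truth <- structure(list(mask = cell,
                          basal_profile = 100 * colint1 / T1,
                          final_profile = L,
                          delta_profile = L - mean(L),
                          params = pp,
                          spec = spec),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Per-cell jitter for synthetic cohorts
#'
#' Multiplicative/additive perturbations applied independently to each cell
#' of [generate_cohort()]. Defaults emulate the cell-to-cell spread seen in
#' single-cell polarity experiments: ~30% coefficient of variation on the
#' polarity amplitude and on expression level, a couple of parts of onset
#' position jitter, and mild geometric variability.
#'
#' @param range_cv lognormal CV of the plateau difference `A1 - A2`.
#' @param x0_sd Gaussian sd of the inflection position `X0`, parts.
#' @param d_cv lognormal CV of the slope scale `D` (a positive scale
#'   parameter, so it is jittered multiplicatively).
#' @param axes_cv lognormal CV of the cell semi-axes.
#' @param intensity_cv lognormal CV of the basal expression level.
#' @return a list of class `cohort_jitter`.
#' @export
cohort_jitter <- function(range_cv = 0.3, x0_sd = 2, d_cv = 0.25,
                          axes_cv = 0.08, intensity_cv = 0.3) {
  structure(list(range_cv = range_cv, x0_sd = x0_sd, d_cv = d_cv,
                 axes_cv = axes_cv, intensity_cv = intensity_cv),
            class = "cohort_jitter")
}

lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

#' Generate a cohort of jittered synthetic cells
#'
#' Draws `n_cells` independent stacks from `base_spec`, perturbing per cell
#' the polarity amplitude, inflection position, slope scale, cell size and
#' expression level according to `jitter`. Per-cell seeds are derived
#' deterministically from `seed`, so the whole cohort is reproducible.
#'
#' @param base_spec a [synthetic_cell_spec()] giving the cohort's central
#'   conditions.
#' @param n_cells number of cells (>= 1).
#' @param jitter a [cohort_jitter()]; use `cohort_jitter(0, 0, 0, 0, 0)` for
#'   identical replicates.
#' @param seed master integer seed.
#' @return list of length `n_cells`, each element as returned by
#'   [generate_cell_stack()].
#' @export
generate_cohort <- function(base_spec, n_cells, jitter = cohort_jitter(),
                            seed = 1L) {
  stopifnot(inherits(base_spec, "cell_spec"), inherits(jitter, "cohort_jitter"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L)
    stop("invalid argument: n_cells must be >= 1", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  cell_seeds <- sample.int(.Machine$integer.max, n_cells)
  rf <- lognorm_factor(n_cells, jitter$range_cv)
  x0j <- stats::rnorm(n_cells, 0, jitter$x0_sd)
  df <- lognorm_factor(n_cells, jitter$d_cv)
  axf <- lognorm_factor(n_cells, jitter$axes_cv)
  inf <- lognorm_factor(n_cells, jitter$intensity_cv)

  lapply(seq_len(n_cells), function(i) {
    sp <- base_spec
    pp <- sp$polarity_params
    mid <- (pp[["A1"]] + pp[["A2"]]) / 2
    half <- (pp[["A1"]] - pp[["A2"]]) / 2 * rf[i]
    pp[["A1"]] <- mid + half
    pp[["A2"]] <- mid - half
    pp[["X0"]] <- min(max(pp[["X0"]] + x0j[i], 3), sp$n_bins - 3)
    pp[["D"]] <- pp[["D"]] * df[i]
    sp$polarity_params <- pp
    sp$cell_axes <- sp$cell_axes * axf[i]
    sp$base_intensity <- sp$base_intensity * inf[i]
    generate_cell_stack(sp, seed = cell_seeds[i])
  })
}

#' Simulate normalized minute-30 profiles directly
#'
#' Profile-level counterpart of the image generator, for fast parameter
#' recovery studies: each replicate is the mean-centred logistic at parts
#' `1..n_bins` plus i.i.d. Gaussian noise of sd `sigma`, i.e. the ideal
#' final row of a difference-based spatiotemporal map.
#'
#' @param n number of replicate profiles.
#' @param params named `c(A1, A2, X0, D)`.
#' @param sigma profile noise sd (normalized fluorescence units).
#' @param seed integer seed.
#' @param n_bins number of parts (default 50).
#' @param center logical; subtract the curve mean (the difference-map
#'   convention). Set `FALSE` for raw logistic samples.
#' @return numeric matrix `n x n_bins`, one profile per row.
#' @export
simulate_profiles <- function(n, params, sigma = 0.05, seed = 1L,
                              n_bins = 50L, center = TRUE) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  L <- logistic_curve(seq_len(n_bins), params[["A1"]], params[["A2"]],
                      params[["X0"]], params[["D"]])
  if (center) L <- L - mean(L)
  t(replicate(n, L + stats::rnorm(n_bins, 0, sigma)))
}

#' Write a frame stack as a numbered 16-bit TIFF series
#'
#' Files are named `001.tif`, `002.tif`, ... in chronological order.
#' Intensities are rounded to integer camera counts and stored as 16-bit
#' grayscale; values above 65535 are clipped with a warning.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%03d.tif", seq_along(stack$frames)))
  for (i in seq_along(stack$frames)) {
    v <- round(stack$frames[[i]])
    if (any(v > 65535)) {
      warning("clipping intensities above the 16-bit range")
      v <- pmin(v, 65535)
    }
    tiff::writeTIFF(v / 65535, paths[i], bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(paths)
}

#' Write ground truth sidecar files
#'
#' Stores the basal/final/delta profiles as CSV and the logistic parameters
#' plus acquisition metadata as JSON next to a written stack.
#'
#' @param truth the `truth` element returned by [generate_cell_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "ground_truth_profiles.csv")
  df <- data.frame(part = seq_along(truth$final_profile),
                   basal_profile = truth$basal_profile,
                   final_profile = truth$final_profile,
                   delta_profile = truth$delta_profile)
  utils::write.csv(df, csv, row.names = FALSE)
  js <- file.path(dir, "ground_truth_params.json")
  pp <- truth$params
  writeLines(sprintf(paste0(
    '{"A1": %.17g, "A2": %.17g, "X0": %.17g, "D": %.17g, ',
    '"frame_interval_s": %.17g, "flow_dir": "%s"}'),
    pp[["A1"]], pp[["A2"]], pp[["X0"]], pp[["D"]],
    truth$spec$frame_interval_s, truth$spec$flow_dir), js)
  invisible(c(csv, js))
}
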