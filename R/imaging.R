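#' Construct a frame stack
#'
#' An ordered time-lapse of one single-cell field. All frames must share a
#' shape and there must be at least two of them.
#'
#' @param frames list of 2-D numeric intensity matrices, chronological.
#' @param interval_s acquisition interval, seconds.
#' @param flow_dir `"left"` or `"right"`: image side of the downstream edge.
#' @param label free-text treatment-group label.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, interval_s, flow_dir = c("left", "right"),
                        label = "") {
  flow_dir <- match.arg(flow_dir)
  if (length(frames) < 2L)
    stop("insufficient data: a stack needs at least 2 frames", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: frames have mixed shapes", call. = FALSE)
  structure(list(frames = frames, interval_s = interval_s,
                 flow_dir = flow_dir, label = label),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack: %d frames of %dx%d px, every %gs, flow %s%s\n",
              length(x$frames), d[1], d[2], x$interval_s, x$flow_dir,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Load a TIFF time-lapse as a frame stack
#'
#' Accepts either a directory holding a numbered series (`001.tif`,
#' `002.tif`, ...; any zero padding, sorted by the numeric part of the file
#' name regardless of listing order) or a single multi-page TIFF. Pixel
#' values are returned in camera counts assuming 16-bit storage.
#'
#' @param path directory of a TIFF series, or one multi-page TIFF file.
#' @param flow_dir `"left"` or `"right"`.
#' @param interval_s acquisition interval, seconds.
#' @param label treatment-group label.
#' @return a [frame_stack()].
#' @export
load_stack <- function(path, flow_dir = c("left", "right"), interval_s = 60,
                       label = "") {
  flow_dir <- match.arg(flow_dir)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) < 2L)
      stop("insufficient data: fewer than 2 TIFF frames in ", path,
           call. = FALSE)
    num <- suppressWarnings(
      as.integer(sub("\\D*(\\d+)\\D*$", "\\1",
                     tools::file_path_sans_ext(basename(files)))))
    if (anyNA(num))
      stop("format error: frame file names must contain a frame number",
           call. = FALSE)
    files <- files[order(num)]
    frames <- lapply(files, function(f) tiff::readTIFF(f) * 65535)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("insufficient data: fewer than 2 pages in ", path, call. = FALSE)
    frames <- lapply(pages, function(p) p * 65535)
  } else {
    stop("format error: no such file or directory: ", path, call. = FALSE)
  }
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]   # collapse grayscale channels
    f
  })
  frame_stack(frames, interval_s = interval_s, flow_dir = flow_dir,
              label = label)
}

#' Subtract corner-estimated background
#'
#' The background level of each frame is the mean intensity over its four
#' `corner_size` x `corner_size` corner patches, which by experimental
#' design contain no cell. That level is subtracted from every pixel and
#' the result is clipped at zero to keep intensities physical.
#'
#' @param stack a [frame_stack()].
#' @param corner_size side of the square corner patches, pixels; patches
#'   must not overlap and may span at most a quarter of the frame.
#' @return a background-subtracted [frame_stack()].
#' @export
subtract_background <- function(stack, corner_size = 20L) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames[[1]])
  cs <- as.integer(corner_size)
  if (cs < 1L || cs > min(d) %/% 4L)
    stop("invalid argument: corner_size must be in [1, min(shape)/4]",
         call. = FALSE)
  if (2L * cs > d[1] || 2L * cs > d[2])
    stop("invalid argument: corner patches overlap", call. = FALSE)
  stack$frames <- lapply(stack$frames, function(f) {
    bg <- mean(c(f[1:cs, 1:cs], f[1:cs, (d[2] - cs + 1):d[2]],
                 f[(d[1] - cs + 1):d[1], 1:cs],
                 f[(d[1] - cs + 1):d[1], (d[2] - cs + 1):d[2]]))
    pmax(f - bg, 0)
  })
  stack
}

mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  ## 0-based, half-open [min, max)
  c(row_min = min(rows) - 1L, row_max = max(rows),
    col_min = min(cols) - 1L, col_max = max(cols))
}

#' Segment the cell body of one frame
#'
#' Thresholds a background-subtracted frame (Otsu by default), removes
#' speckle objects smaller than `min_speckle_area`, applies morphological
#' closing with a disc of radius `closing_radius`, fills holes, and keeps
#' the largest connected component.
#'
#' @param frame 2-D numeric matrix, background-subtracted.
#' @param threshold `"otsu"` or a numeric absolute threshold in intensity
#'   units.
#' @param min_speckle_area smallest object area kept before closing, px.
#' @param closing_radius radius of the closing structuring element, px.
#' @return an object of class `cell_mask`: list with logical `mask`,
#'   0-based half-open `bbox` `(row_min, row_max, col_min, col_max)` and
#'   pixel `area`.
#' @export
segment_cell <- function(frame, threshold = "otsu", min_speckle_area = 64L,
                         closing_radius = 3L) {
  stopifnot(is.matrix(frame))
  if (identical(threshold, "otsu")) {
    mx <- max(frame)
    if (mx <= 0)
      stop("segmentation failure: frame has no signal", call. = FALSE)
    thr <- EBImage::otsu(frame / mx, range = c(0, 1)) * mx
  } else {
    thr <- as.numeric(threshold)
  }
  bw <- frame > thr
  if (!any(bw))
    stop("segmentation failure: empty mask after thresholding", call. = FALSE)
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_speckle_area)
  if (length(keep) == 0L)
    stop("segmentation failure: empty mask after speckle filtering",
         call. = FALSE)
  bw <- matrix(lab %in% keep, nrow(frame), ncol(frame))
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    bw <- EBImage::closing(bw, brush) > 0
  }
  bw <- EBImage::fillHull(EBImage::bwlabel(bw)) > 0
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  bw <- matrix(lab == which.max(areas), nrow(frame), ncol(frame))
  structure(list(mask = bw, bbox = mask_bbox(bw), area = sum(bw)),
            class = "cell_mask")
}

#' Segment every frame of a stack
#'
#' The cell migrates under flow, so the outline is re-identified in each
#' frame independently. With the default `threshold = "otsu"` the Otsu
#' level is calibrated once on the first (basal) frame — whose histogram is
#' cleanly background-versus-cell bimodal — and applied to every frame;
#' recalibrating on a strongly polarized frame can otherwise split the cell
#' class itself and amputate the dim upstream region. Use
#' `threshold = "otsu-frame"` to recalibrate per frame, or pass a numeric
#' absolute threshold.
#'
#' @param stack a background-subtracted [frame_stack()].
#' @inheritParams segment_cell
#' @return list of [segment_cell()] masks, one per frame.
#' @export
segment_stack <- function(stack, threshold = "otsu", min_speckle_area = 64L,
                          closing_radius = 3L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (identical(threshold, "otsu")) {
    f1 <- stack$frames[[1]]
    mx <- max(f1)
    if (mx <= 0)
      stop("segmentation failure: basal frame has no signal", call. = FALSE)
    threshold <- EBImage::otsu(f1 / mx, range = c(0, 1)) * mx
  } else if (identical(threshold, "otsu-frame")) {
    threshold <- "otsu"
  }
  lapply(stack$frames, segment_cell, threshold = threshold,
         min_speckle_area = min_speckle_area,
         closing_radius = closing_radius)
}

mirror_matrix <- function(m) m[, ncol(m):1, drop = FALSE]

#' Mirror a stack (and masks) horizontally
#'
#' Pure left-right reflection of every frame; an involution. Metadata are
#' untouched.
#'
#' @param stack a [frame_stack()].
#' @param masks optional list of `cell_mask` objects to mirror alongside.
#' @return the mirrored stack, or `list(stack, masks)` when masks are given.
#' @export
flip_horizontal <- function(stack, masks = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  stack$frames <- lapply(stack$frames, mirror_matrix)
  if (is.null(masks)) return(stack)
  nc <- ncol(stack$frames[[1]])
  masks <- lapply(masks, function(m) {
    m$mask <- mirror_matrix(m$mask)
    b <- m$bbox
    m$bbox <- c(row_min = b[["row_min"]], row_max = b[["row_max"]],
                col_min = nc - b[["col_max"]], col_max = nc - b[["col_min"]])
    m
  })
  list(stack = stack, masks = masks)
}

#' Orient a stack so the downstream edge is on the left
#'
#' If `flow_dir` is `"right"` the frames (and masks, if given) are mirrored
#' horizontally and `flow_dir` is set to `"left"`; otherwise this is the
#' identity. After orientation, part index 1 of every profile is the
#' downstream-most column.
#'
#' @param stack a [frame_stack()].
#' @param masks optional list of `cell_mask` objects.
#' @return oriented stack, or `list(stack, masks)` when masks are given.
#' @export
orient_to_flow <- function(stack, masks = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$flow_dir == "left")
    return(if (is.null(masks)) stack else list(stack = stack, masks = masks))
  out <- flip_horizontal(stack, masks)
  if (is.null(masks)) {
    out$flow_dir <- "left"
    out
  } else {
    out$stack$flow_dir <- "left"
    out
  }
}
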