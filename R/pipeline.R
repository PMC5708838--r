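#' Default analysis parameters
#'
#' The tunable knobs of the quantification chain with their defaults:
#' `corner_size` (20 px background patches), `threshold` (`"otsu"`),
#' `min_speckle_area` (64 px), `closing_radius` (3 px), `n_bins` (50),
#' `onset_threshold` (0.005 slope units), `minute` (30), `var_equal`
#' (`TRUE`, Student rather than Welch).
#'
#' @param ... overrides of the defaults above.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(corner_size = 20L, threshold = "otsu", min_speckle_area = 64L,
            closing_radius = 3L, n_bins = 50L, onset_threshold = 0.005,
            minute = 30, var_equal = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(over)] <- over
  p
}

#' Run the full analysis pipeline over a cohort configuration
#'
#' Executes imaging, mapping, polarity fitting and group statistics for
#' every cell listed in `config`, and writes the complete output tree:
#' per-cell map CSVs and heatmaps, per-group average maps and heatmaps, a
#' per-cell metrics CSV and a group summary CSV, plus a log of every
#' parameter used. A failing cell is logged and skipped; an entirely empty
#' cohort is a fatal error.
#'
#' @param config path to a YAML file, or an equivalent list, of the form
#'   ```
#'   control_group: control
#'   params: {corner_size: 20, min_speckle_area: 64, closing_radius: 3,
#'            n_bins: 50, onset_threshold: 0.005, minute: 30}
#'   groups:
#'     - label: control
#'       flow_dir: left
#'       interval_s: 60
#'       cells: [path/to/cell1, path/to/cell2]
#'   ```
#'   where each cell path is a numbered TIFF series directory (or
#'   multi-page TIFF) readable by [load_stack()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with `metrics` (per-cell data frame),
#'   `summary` (the [group_summary()] data frame), `maps` (per-group
#'   average `st_map`s) and `failures` (character vector of skipped cells).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$groups))
  params <- do.call(pipeline_params, as.list(config$params))
  control_group <- if (is.null(config$control_group)) "control"
                   else config$control_group

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "heatmaps"), showWarnings = FALSE)
  logfile <- file.path(out_dir, "pipeline.log")
  logline <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", sep = "", file = logfile, append = TRUE)
    message(msg)
  }
  cat("", file = logfile)
  logline("parameters: ",
          paste(names(params), vapply(params, format, ""), sep = "=",
                collapse = ", "))

  metrics <- list()
  group_maps <- list()
  failures <- character()
  for (grp in config$groups) {
    label <- grp$label
    stopifnot(!is.null(label), !is.null(grp$cells))
    flow_dir <- if (is.null(grp$flow_dir)) "left" else grp$flow_dir
    interval_s <- if (is.null(grp$interval_s)) 60 else grp$interval_s
    cell_maps <- list()
    for (cell in grp$cells) {
      cell_id <- basename(cell)
      res <- tryCatch({
        if (!dir.exists(cell) && !file.exists(cell))
          stop("cell input not found: ", cell, call. = FALSE)
        stack <- load_stack(cell, flow_dir = flow_dir,
                            interval_s = interval_s, label = label)
        q <- quantify_stack(stack, corner_size = params$corner_size,
                            threshold = params$threshold,
                            min_speckle_area = params$min_speckle_area,
                            closing_radius = params$closing_radius,
                            n_bins = params$n_bins)
        met <- cell_metrics(q$map, minute = params$minute,
                            threshold = params$onset_threshold)
        list(q = q, met = met)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        if (grepl("cell input not found", conditionMessage(res)))
          stop(conditionMessage(res), call. = FALSE)
        logline("SKIPPED ", label, "/", cell_id, ": ",
                conditionMessage(res))
        failures <- c(failures, paste0(label, "/", cell_id))
        next
      }
      logline(label, "/", cell_id, ": mask areas ",
              paste(vapply(res$q$masks, `[[`, 0L, "area"), collapse = " "))
      write_map_csv(res$q$map,
                    file.path(out_dir, "maps",
                              paste0(label, "_", cell_id, ".csv")))
      render_map(res$q$map,
                 file.path(out_dir, "heatmaps",
                           paste0(label, "_", cell_id, ".png")))
      fit <- res$met$fit
      metrics[[length(metrics) + 1L]] <- data.frame(
        cell_id = cell_id, group = label,
        A1 = fit$A1, A2 = fit$A2, X0 = fit$X0, D = fit$D,
        range = res$met$range,
        onset = if (is.na(res$met$onset)) NA_integer_ else res$met$onset,
        slope = res$met$slope, sse = fit$residual_sse,
        converged = fit$converged)
      cell_maps[[length(cell_maps) + 1L]] <- res$q$map
    }
    if (length(cell_maps)) {
      avg <- average_maps(cell_maps)
      group_maps[[label]] <- avg
      write_map_csv(avg, file.path(out_dir, "maps",
                                   paste0(label, "_average.csv")))
      render_map(avg, file.path(out_dir, "heatmaps",
                                paste0(label, "_average.png")))
    }
  }
  if (length(metrics) == 0L)
    stop("fatal: no cell could be processed", call. = FALSE)
  metrics <- do.call(rbind, metrics)
  metrics <- metrics[order(metrics$group, metrics$cell_id), ]
  rownames(metrics) <- NULL
  write_df_csv(metrics, file.path(out_dir, "metrics.csv"))

  summary <- NULL
  if (control_group %in% metrics$group &&
      length(unique(metrics$group)) > 1L) {
    summary <- group_summary(metrics, control_group = control_group,
                             var_equal = params$var_equal)
    write_df_csv(summary, file.path(out_dir, "group_summary.csv"))
    logline("group summary written (t-tests vs '", control_group,
            "', no multiple-testing correction)")
  }
  logline(sprintf("done: %d cells quantified, %d skipped",
                  nrow(metrics), length(failures)))
  invisible(list(metrics = metrics, summary = summary, maps = group_maps,
                 failures = failures))
}

## full-precision, locale-independent CSV so re-runs are byte-comparable
write_df_csv <- function(df, path) {
  cols <- lapply(df, function(x) {
    if (is.double(x)) ifelse(is.na(x), "NA", sprintf("%.17g", x))
    else as.character(x)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}
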