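#' Two-sample t-test of a metric against the control group
#'
#' Two-tailed Student's t-test, equal-variance by default (the classic
#' spreadsheet default); set `var_equal = FALSE` for the Welch variant.
#' Degenerate input with zero variance in both groups returns `p = 1` when
#' the means agree (no evidence of a difference) rather than erroring.
#'
#' @param group numeric metric values of the treatment group (length >= 2).
#' @param control numeric metric values of the control group (length >= 2).
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return the p-value.
#' @export
compare_to_control <- function(group, control, var_equal = TRUE) {
  group <- group[is.finite(group)]
  control <- control[is.finite(control)]
  if (length(group) < 2L || length(control) < 2L)
    stop("both groups need at least 2 finite values", call. = FALSE)
  if (stats::sd(group) == 0 && stats::sd(control) == 0) {
    return(if (mean(group) == mean(control)) 1 else .Machine$double.xmin)
  }
  stats::t.test(group, control, var.equal = var_equal)$p.value
}

#' Group-level summary of polarity metrics
#'
#' Per group: n, mean and SD of each metric (`range`, `onset`, `slope`),
#' and the two-sample t-test p-value against the control group for each
#' metric. Cells whose onset is undefined are omitted from the onset
#' statistics. No multiple-testing correction is applied.
#'
#' @param metrics data frame with columns `cell_id`, `group`, `range`,
#'   `onset`, `slope` (one row per cell), e.g. from [run_pipeline()].
#' @param control_group label of the reference group.
#' @param var_equal passed to [compare_to_control()].
#' @return data frame, one row per group, with columns `group`, `n`,
#'   `mean_*`, `sd_*`, `p_*` for each metric (`p_*` is `NA` for the control
#'   row), ordered with the control first.
#' @export
group_summary <- function(metrics, control_group = "control",
                          var_equal = TRUE) {
  stopifnot(all(c("group", "range", "onset", "slope") %in% names(metrics)))
  if (!control_group %in% metrics$group)
    stop("control group '", control_group, "' not present", call. = FALSE)
  groups <- unique(metrics$group)
  groups <- c(control_group, setdiff(groups, control_group))
  ctrl <- metrics[metrics$group == control_group, ]
  one <- function(g) {
    m <- metrics[metrics$group == g, ]
    row <- data.frame(group = g, n = nrow(m))
    for (v in c("range", "onset", "slope")) {
      x <- m[[v]][is.finite(m[[v]])]
      row[[paste0("mean_", v)]] <- mean(x)
      row[[paste0("sd_", v)]] <- stats::sd(x)
      cx <- ctrl[[v]][is.finite(ctrl[[v]])]
      row[[paste0("p_", v)]] <-
        if (g == control_group || length(x) < 2L || length(cx) < 2L)
          NA_real_
        else compare_to_control(x, cx, var_equal = var_equal)
    }
    row
  }
  do.call(rbind, lapply(groups, one))
}
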