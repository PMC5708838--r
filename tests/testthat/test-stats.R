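test_that("t-test behaves at the extremes and is symmetric", {
  x <- c(1.1, 0.9, 1.0, 1.2, 0.8)
  expect_equal(compare_to_control(x, x), 1)
  expect_lt(compare_to_control(x + 100 * stats::sd(x), x), 0.001)
  y <- x * 2 + 0.3
  expect_equal(compare_to_control(x, y), compare_to_control(y, x))
  expect_error(compare_to_control(1, x), "at least 2")
  # zero variance in both groups, equal means
  expect_equal(compare_to_control(rep(2, 3), rep(2, 4)), 1)
})

test_that("equal-variance p-values agree with a permutation oracle", {
  withr::local_seed(42)
  x <- stats::rnorm(10, 0.6)
  y <- stats::rnorm(10, 0)
  p_t <- compare_to_control(x, y)
  # 10,000-draw permutation test on the absolute mean difference
  pool <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(10000, {
    idx <- sample.int(20, 10)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("group summary aggregates metrics and tests against control", {
  withr::local_seed(3)
  metrics <- data.frame(
    cell_id = 1:14,
    group = rep(c("control", "treated"), each = 7),
    range = c(stats::rnorm(7, 1.15, 0.2), stats::rnorm(7, 0.4, 0.1)),
    onset = c(12:18, rep(NA_integer_, 7)),
    slope = c(stats::rnorm(7, -0.29, 0.05), stats::rnorm(7, -0.07, 0.02)))
  gs <- group_summary(metrics, control_group = "control")
  expect_equal(gs$group, c("control", "treated"))
  expect_equal(gs$n, c(7L, 7L))
  expect_true(is.na(gs$p_range[1]))
  expect_lt(gs$p_range[2], 0.05)
  expect_true(is.na(gs$p_onset[2]))  # no defined onsets in the treated group
  expect_equal(gs$mean_onset[1], 15)
  expect_error(group_summary(metrics, control_group = "nope"), "not present")
})

test_that("the pipeline runs a cohort end to end, deterministically", {
  root <- withr::local_tempdir()
  spec <- test_spec(n_frames = 5, noise_sigma = 15)
  lam <- generate_cohort(spec, 3, seed = 11)
  dis <- generate_cohort(unpolarized(spec), 2, seed = 22)
  for (i in 1:3)
    write_stack(lam[[i]]$stack, file.path(root, "control", paste0("cell", i)))
  for (i in 1:2)
    write_stack(dis[[i]]$stack, file.path(root, "disturbed", paste0("cell", i)))
  cfg <- list(
    control_group = "control",
    params = list(minute = 5),
    groups = list(
      list(label = "control", flow_dir = "left", interval_s = 60,
           cells = as.list(file.path(root, "control", paste0("cell", 1:3)))),
      list(label = "disturbed", flow_dir = "left", interval_s = 60,
           cells = as.list(file.path(root, "disturbed", paste0("cell", 1:2))))))

  out1 <- file.path(root, "out1")
  res <- suppressMessages(suppressWarnings(run_pipeline(cfg, out1)))
  expect_equal(nrow(res$metrics), 5)
  expect_equal(sort(unique(res$metrics$group)), c("control", "disturbed"))
  expect_gt(mean(res$metrics$range[res$metrics$group == "control"]),
            mean(res$metrics$range[res$metrics$group == "disturbed"]))
  expect_true(file.exists(file.path(out1, "metrics.csv")))
  expect_true(file.exists(file.path(out1, "group_summary.csv")))
  expect_true(file.exists(file.path(out1, "maps", "control_average.csv")))
  expect_true(file.exists(file.path(out1, "heatmaps", "control_average.png")))
  # per-frame mask areas are logged
  expect_true(any(grepl("mask areas", readLines(file.path(out1, "pipeline.log")))))

  out2 <- file.path(root, "out2")
  suppressMessages(suppressWarnings(run_pipeline(cfg, out2)))
  for (f in c("metrics.csv", "group_summary.csv", "maps/control_average.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("a YAML config file drives the pipeline", {
  root <- withr::local_tempdir()
  g <- generate_cell_stack(test_spec(n_frames = 5), seed = 1)
  write_stack(g$stack, file.path(root, "grp", "c1"))
  write_stack(generate_cell_stack(test_spec(n_frames = 5), seed = 2)$stack,
              file.path(root, "grp", "c2"))
  cfg_file <- file.path(root, "cfg.yaml")
  writeLines(c(
    "control_group: grp",
    "params:",
    "  minute: 5",
    "groups:",
    "  - label: grp",
    "    flow_dir: left",
    "    interval_s: 60",
    "    cells:",
    paste0("      - ", file.path(root, "grp", c("c1", "c2")))), cfg_file)
  res <- suppressMessages(suppressWarnings(
    run_pipeline(cfg_file, file.path(root, "out"))))
  expect_equal(nrow(res$metrics), 2)
})

test_that("missing inputs are fatal but broken cells are skipped", {
  root <- withr::local_tempdir()
  g <- generate_cell_stack(test_spec(n_frames = 5), seed = 1)
  write_stack(g$stack, file.path(root, "grp", "c1"))
  cfg <- list(control_group = "grp", params = list(minute = 5),
              groups = list(list(label = "grp", flow_dir = "left",
                                 cells = list(file.path(root, "grp", "c1"),
                                              file.path(root, "grp", "nope")))))
  expect_error(suppressMessages(run_pipeline(cfg, file.path(root, "o1"))),
               "not found")

  # a readable but unusable cell (blank frames) is skipped, not fatal
  blank <- file.path(root, "grp", "blank")
  dir.create(blank, recursive = TRUE)
  for (k in 1:5)
    tiff::writeTIFF(matrix(0, 64, 64), file.path(blank, sprintf("%03d.tif", k)))
  cfg$groups[[1]]$cells[[2]] <- blank
  res <- suppressMessages(suppressWarnings(run_pipeline(cfg, file.path(root, "o2"))))
  expect_equal(nrow(res$metrics), 1)
  expect_equal(res$failures, "grp/blank")
})
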