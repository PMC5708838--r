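test_that("grid partition assigns every pixel to exactly one part", {
  # bounding box exactly 100 px wide: every column part is 2 px
  m <- matrix(FALSE, 120, 120)
  m[11:110, 11:110] <- TRUE
  cm <- structure(list(mask = m, bbox = flowpol:::mask_bbox(m),
                       area = sum(m)), class = "cell_mask")
  grid <- partition_cell(cm)
  f <- matrix(1, 120, 120)
  g <- fraction_grid(f, cm, grid)
  # uniform intensity + equal-area parts: every fraction is 1/2500
  expect_equal(max(abs(g - 1 / 2500)), 0, tolerance = 1e-12)
  expect_equal(sum(g), 1, tolerance = 1e-9)
})

test_that("fraction grid matches the exhaustive per-pixel oracle", {
  withr::local_seed(99)
  for (k in 1:10) {
    cm <- random_cell_mask()
    f <- matrix(stats::runif(64 * 64, 0, 100), 64, 64)
    grid <- suppressWarnings(partition_cell(cm))
    g <- fraction_grid(f, cm, grid)
    expect_lt(max(abs(g - fraction_grid_oracle(f, cm))), 1e-12)
    expect_equal(sum(g), 1, tolerance = 1e-9)
  }
})

test_that("degenerate frames are rejected", {
  cm <- random_cell_mask()
  grid <- suppressWarnings(partition_cell(cm))
  expect_error(fraction_grid(matrix(0, 64, 64), cm, grid), "degenerate")
  expect_error(project_profile(matrix(0, 50, 50)), "degenerate")
})

test_that("difference accumulation telescopes bit-exactly", {
  withr::local_seed(1)
  grids <- replicate(30, matrix(stats::rnorm(2500), 50, 50), simplify = FALSE)
  ds <- difference_accumulate(grids)
  expect_length(ds$deltas, 29)
  expect_identical(ds$cumulative, grids[[30]] - grids[[1]])
  # explicit pairwise telescoping sum agrees to float accumulation error
  tele <- Reduce(`+`, lapply(2:30, function(t) grids[[t]] - grids[[t - 1]]))
  expect_lt(max(abs(tele - ds$cumulative)), 1e-12)

  const <- replicate(3, grids[[1]], simplify = FALSE)
  dc <- difference_accumulate(const)
  expect_true(all(dc$cumulative == 0))
  expect_error(difference_accumulate(grids[1]), "insufficient")
})

test_that("static nuclear signal cancels from the difference map", {
  # the cumulative difference must be blind to the nucleus: doubling its
  # static brightness changes frame 1 and frame T alike, so the difference
  # grids and the map are unchanged
  spec <- test_spec(n_frames = 4, noise_sigma = 0)
  dim_nuc <- generate_cell_stack(spec, seed = 1)
  spec2 <- spec
  spec2$nucleus_gain <- 3.5
  bright_nuc <- generate_cell_stack(spec2, seed = 1)
  q1 <- quiet_quantify(dim_nuc$stack)
  q2 <- quiet_quantify(bright_nuc$stack)
  cum1 <- difference_accumulate(q1$grids)$cumulative
  cum2 <- difference_accumulate(q2$grids)$cumulative
  expect_lt(max(abs(cum1 - cum2)), 1e-9)
  expect_equal(q1$map$matrix, q2$map$matrix, tolerance = 1e-9)
})

test_that("projection behaves like column sums in percent", {
  u <- matrix(1 / 2500, 50, 50)
  expect_equal(project_profile(u), rep(2, 50), tolerance = 1e-12)
  withr::local_seed(2)
  g <- matrix(stats::runif(2500), 50, 50)
  p <- project_profile(g)
  expect_equal(sum(p), 100, tolerance = 1e-6)
  expect_equal(project_profile(g[, 50:1]), rev(p), tolerance = 1e-12)
  # brute-force double loop oracle
  brute <- numeric(50)
  for (c in 1:50) for (r in 1:50) brute[c] <- brute[c] + g[r, c]
  expect_equal(p, 100 * brute / sum(g), tolerance = 1e-12)
})

test_that("basal normalization maps the basal mean to one and is scale-free", {
  basal <- rep(2, 50)
  m <- normalize_profiles(list(basal), basal, times = 60)
  expect_equal(m$matrix[1, ], rep(1, 50))
  expect_error(normalize_profiles(list(basal), rep(0, 50), times = 60),
               "degenerate basal")

  g <- generate_cell_stack(test_spec(n_frames = 4, noise_sigma = 0), seed = 2)
  q1 <- quiet_quantify(g$stack)
  scaled <- g$stack
  scaled$frames <- lapply(scaled$frames, function(f) f * 7)
  q2 <- quiet_quantify(scaled)
  expect_equal(q1$map$matrix, q2$map$matrix, tolerance = 1e-9)
})

test_that("cells differing only in expression level give the same map", {
  spec <- test_spec(n_frames = 4, noise_sigma = 0)
  bright <- spec
  bright$base_intensity <- spec$base_intensity * 2
  q1 <- quiet_quantify(generate_cell_stack(spec, seed = 3)$stack)
  q2 <- quiet_quantify(generate_cell_stack(bright, seed = 3)$stack)
  expect_equal(q1$map$matrix, q2$map$matrix, tolerance = 1e-6)
})

test_that("map averaging is the entry-wise mean", {
  g <- generate_cell_stack(test_spec(n_frames = 3, noise_sigma = 0), seed = 4)
  map <- quiet_quantify(g$stack)$map
  one <- average_maps(list(map))
  expect_equal(one$matrix, map$matrix)
  neg <- map
  neg$matrix <- -map$matrix
  zero <- average_maps(list(map, neg))
  expect_true(all(zero$matrix == 0))
  expect_equal(zero$n_cells, 2L)
  short <- map
  short$matrix <- map$matrix[1:2, , drop = FALSE]
  expect_error(average_maps(list(map, short)), "incompatible")
})

test_that("averaging reduces noise toward the ground-truth profile", {
  spec <- test_spec(n_frames = 4, noise_sigma = 40)
  maps <- lapply(1:8, function(i)
    quiet_quantify(generate_cell_stack(spec, seed = 100 + i)$stack)$map)
  avg <- average_maps(maps)
  truth <- generate_cell_stack(test_spec(n_frames = 4, noise_sigma = 0),
                               seed = 1)$truth$delta_profile
  rmse <- function(m) sqrt(mean((m$matrix[4, ] - truth)^2))
  expect_lt(rmse(avg), mean(vapply(maps, rmse, 0)))
})

test_that("maps render deterministically and flag the polarized pole", {
  g <- generate_cell_stack(synthetic_cell_spec(n_frames = 8, noise_sigma = 0),
                           seed = 1)
  map <- quiet_quantify(g$stack)$map
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.png"); p2 <- file.path(d, "b.png")
  render_map(map, p1); render_map(map, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # downstream columns dominate the final rows
  expect_lt(which.max(map$matrix[8, ]), 15)

  const <- map
  const$matrix[] <- 1
  pc <- file.path(d, "c.png")
  render_map(const, pc)
  px <- png::readPNG(pc)
  expect_lte(length(unique(as.vector(px))), 3)  # a single RGB colour
})

test_that("map CSVs are written at full precision", {
  g <- generate_cell_stack(test_spec(n_frames = 3, noise_sigma = 0), seed = 5)
  map <- quiet_quantify(g$stack)$map
  d <- withr::local_tempdir()
  f <- file.path(d, "map.csv")
  write_map_csv(map, f)
  back <- utils::read.csv(f)
  expect_equal(back$time_s, map$times)
  expect_equal(unname(as.matrix(back[, -1])), map$matrix, tolerance = 1e-15,
               ignore_attr = TRUE)
})
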