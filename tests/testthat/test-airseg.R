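grid_from <- function(vals, spacing = 10) voxel_grid(vals, spacing)

test_that("region growing floods a uniform grid completely", {
  g <- grid_from(array(5000, c(6, 6, 6)))
  m <- region_grow(g, segmentation_config(seed = c(3, 3, 3)))
  expect_true(all(m$values))
})

test_that("a tissue wall outside the band stops the growth", {
  vals <- array(5000, c(8, 8, 8))
  vals[, , 4] <- 30000                     # wall splits x into two chambers
  g <- grid_from(vals)
  m <- region_grow(g, segmentation_config(seed = c(4, 4, 2)))
  expect_true(all(m$values[, , 1:3]))
  expect_false(any(m$values[, , 4:8]))
})

test_that("region growing is voxel-identical to the frontier-expansion
           oracle on random instances", {
  set.seed(31)
  for (i in 1:50) {
    dims <- c(20L, 20L, 20L)
    vals <- array(sample.int(60000, prod(dims), TRUE), dims)
    seed <- sapply(dims, function(d) sample.int(d, 1))
    tol <- sample(c(5000, 15000, 30000), 1)
    conn <- sample(c(6L, 26L), 1)
    centre <- vals[seed[1], seed[2], seed[3]]
    cfg <- segmentation_config(seed = seed, tolerance = tol,
                               connectivity = conn, seed_gray = centre)
    got <- region_grow(grid_from(vals), cfg)
    want <- oracle_flood_fill(vals, seed, centre - tol, centre + tol, conn)
    expect_identical(got$values, want)
  }
})

test_that("region growing matches the oracle exhaustively on 6^3 grids
           over every seed", {
  set.seed(77)
  for (rep_i in 1:2) {
    dims <- c(6L, 6L, 6L)
    vals <- array(sample.int(40000, prod(dims), TRUE), dims)
    for (z in 1:6) for (y in 1:6) for (x in 1:6) {
      seed <- c(z, y, x)
      centre <- vals[z, y, x]
      cfg <- segmentation_config(seed = seed, tolerance = 10000,
                                 seed_gray = centre)
      got <- region_grow(grid_from(vals), cfg)
      want <- oracle_flood_fill(vals, seed, centre - 10000, centre + 10000)
      if (!identical(got$values, want))
        fail(sprintf("mismatch at seed (%d,%d,%d)", z, y, x))
    }
    succeed()
  }
})

test_that("enlarging the tolerance never shrinks the mask", {
  set.seed(5)
  vals <- array(sample.int(60000, 12^3, TRUE), c(12, 12, 12))
  g <- grid_from(vals)
  seed <- c(6, 6, 6)
  prev <- NULL
  for (tol in c(2000, 8000, 20000, 40000)) {
    m <- region_grow(g, segmentation_config(seed = seed, tolerance = tol,
                                            seed_gray = vals[6, 6, 6]))
    if (!is.null(prev)) expect_true(all(m$values[prev]))
    prev <- m$values
  }
})

test_that("growth past the guard limit raises a distinct leak error", {
  g <- grid_from(array(5000, c(10, 10, 10)))
  cfg <- segmentation_config(seed = c(5, 5, 5), max_voxels = 50)
  expect_error(region_grow(g, cfg), class = "lungmorph_leak_error")
})

test_that("extend_roi is a fixed point on a complete component and grows a
           partial base to the full lumen", {
  vals <- array(5000, c(8, 8, 8))
  vals[, , 4] <- 30000
  g <- grid_from(vals)
  cfg <- segmentation_config(seed = c(4, 4, 2))
  full <- region_grow(g, cfg)
  expect_identical(extend_roi(g, full, cfg)$values, full$values)

  base <- voxel_mask(array(FALSE, dim(vals)), g$spacing)
  base$values[4, 4, 1] <- TRUE
  expect_identical(extend_roi(g, base, cfg)$values, full$values)

  empty <- voxel_mask(array(FALSE, dim(vals)), g$spacing)
  expect_error(extend_roi(g, empty, cfg), "empty")
})

test_that("exclude_external_air keeps exactly the seed's component", {
  arr <- array(FALSE, c(9, 9, 9))
  arr[2:4, 2:4, 2:4] <- TRUE               # component 1 (seed)
  arr[7:8, 7:8, 7:8] <- TRUE               # component 2
  arr[1, 9, 9] <- TRUE                     # component 3
  m <- voxel_mask(arr, 10)
  kept <- exclude_external_air(m, c(3, 3, 3))
  expect_true(all(kept$values[2:4, 2:4, 2:4]))
  expect_equal(sum(kept$values), 27L)
  # a single-component mask is unchanged
  single <- voxel_mask(array(c(TRUE, FALSE), c(4, 4, 4)) & TRUE, 10)
  single$values[] <- FALSE; single$values[1:2, 1:2, 1:2] <- TRUE
  expect_identical(exclude_external_air(single, c(1, 1, 1))$values,
                   single$values)
  expect_error(exclude_external_air(m, c(5, 5, 5)), "not inside")
})

test_that("fill_noise_voxels removes interior speckle but keeps 2-voxel
           septa", {
  arr <- array(TRUE, c(9, 9, 9))
  arr[5, 5, 5] <- FALSE                    # isolated noise hole
  arr[, 4:5, 9] <- FALSE                   # 2-voxel-thick wall slab edge
  m <- fill_noise_voxels(voxel_mask(arr, 10))
  expect_true(m$values[5, 5, 5])
  expect_false(any(m$values[, 4:5, 9]))
})

test_that("split by a supplied tree mask partitions the lumen exactly", {
  ph <- cached_phantom("neonate")
  entire <- voxel_mask(ph$tree_mask$values | ph$terminal_mask$values,
                       ph$tree_mask$spacing)
  parts <- split_tree_terminal(entire, ph$tree_mask)
  expect_identical(parts$terminal_mask$values, ph$terminal_mask$values)
  expect_false(any(parts$tree_mask$values & parts$terminal_mask$values))
})

test_that("split by boundary voxels keeps the tracheal side as tree and
           reports a non-disconnecting boundary", {
  # dumbbell: two chambers joined by a 1-voxel-wide neck
  arr <- array(FALSE, c(5, 5, 11))
  arr[2:4, 2:4, 1:4] <- TRUE
  arr[3, 3, 5:7] <- TRUE
  arr[2:4, 2:4, 8:11] <- TRUE
  entire <- voxel_mask(arr, 10)
  bnd <- matrix(c(3, 3, 6), 1)
  parts <- split_tree_terminal(entire, bnd, seed = c(3, 3, 2))
  expect_true(all(parts$tree_mask$values[2:4, 2:4, 1:4]))
  expect_true(all(parts$terminal_mask$values[2:4, 2:4, 8:11]))
  expect_true(parts$tree_mask$values[3, 3, 6])   # boundary joins the tree

  expect_error(split_tree_terminal(entire, matrix(c(2, 2, 2), 1),
                                   seed = c(3, 3, 2)),
               "does not disconnect")
  expect_error(split_tree_terminal(entire, matrix(numeric(0), 0, 3),
                                   seed = c(3, 3, 2)), "empty boundary")
})

test_that("terminal side of a rounds-0 neonate phantom falls into six
           lobar sacs", {
  ph <- cached_phantom("neonate")
  comp <- lungmorph:::cpp_label_components(
    as.vector(ph$terminal_mask$values), dim(ph$terminal_mask$values), 6L)
  # sacs share apertures only through the tree, so with the tree removed
  # the terminal mask separates into the six lobar sacs
  expect_equal(attr(comp, "n_components"), 6L)
})

test_that("the lung outline recovers the truth lung volume", {
  ph <- cached_phantom("neonate")
  rep <- cached_pipeline("neonate")
  expect_lt(rep$metrics$VL_error_frac, 0.05)
  expect_error(segment_lung_outline(ph$gray, c(7000, 65535),
                                    seed_in_lung = c(1, 1, 1)),
               "not inside")
})

test_that("closing radius 0 on a solid body returns exactly the tissue
           component", {
  vals <- array(2000, c(8, 8, 8))
  vals[3:6, 3:6, 3:6] <- 8000
  g <- grid_from(vals)
  m <- segment_lung_outline(g, c(7000, 65535), seed_in_lung = c(4, 4, 4),
                            closing_radius = 0L)
  expect_equal(sum(m$values), 64L)
  expect_true(all(m$values[3:6, 3:6, 3:6]))
})
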