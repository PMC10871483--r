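test_that("calibration shapes carry their closed-form volume and surface", {
  cal <- generate_calibration("sphere", radius = 200, spacing = 5)
  expect_equal(cal$analytic_volume, 4 / 3 * pi * 0.2^3, tolerance = 1e-12)
  expect_equal(cal$analytic_surface, 4 * pi * 0.2^2, tolerance = 1e-12)

  cyl <- generate_calibration("cylinder", radius = 100, length = 1000,
                              spacing = 5)
  expect_equal(cyl$analytic_surface,
               2 * pi * 0.1 * 1.0 + 2 * pi * 0.1^2, tolerance = 1e-12)
  expect_equal(cyl$analytic_volume, pi * 0.1^2 * 1.0, tolerance = 1e-12)

  # voxelization agrees with the closed forms
  tws <- generate_calibration("tube_with_sac", radius = 150, length = 400,
                              tube_radius = 50, spacing = 4)
  expect_equal(mask_volume(tws$mask), tws$analytic_volume, tolerance = 0.02)

  expect_error(generate_calibration("sphere", radius = 1, spacing = 5),
               "unresolvable")
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_stage_phantom(tiny_spec(rng_seed = 3))
  b <- generate_stage_phantom(tiny_spec(rng_seed = 3))
  expect_identical(a$gray$values, b$gray$values)
  expect_identical(a$terminal_mask$values, b$terminal_mask$values)
  expect_equal(a$true_VA, b$true_VA)
})

test_that("distinct seeds give distinct phantoms (septum orientations)", {
  a <- generate_stage_phantom(tiny_spec(rng_seed = 3, rounds = 1L))
  b <- generate_stage_phantom(tiny_spec(rng_seed = 4, rounds = 1L))
  expect_false(identical(a$sac_labels$values, b$sac_labels$values))
})

test_that("the unsubdivided neonate phantom has one sac per lobe and the
           target intercept diameter", {
  ph <- cached_phantom("neonate")
  labs <- setdiff(unique(as.vector(ph$sac_labels$values)), 0L)
  expect_length(labs, 6L)
  # truth mean line-intercept diameter tracks the neonate group mean
  expect_lt(abs(ph$true_mean_diameter - 349) / 349, 0.10)
  # mask-level invariants
  expect_false(any(ph$tree_mask$values & ph$terminal_mask$values))
  expect_true(all(ph$lung_mask$values[ph$tree_mask$values |
                                        ph$terminal_mask$values]))
  expect_true(ph$true_VL >= ph$true_VA)
  expect_gt(ph$true_VA, 0)
})

test_that("phantom air is one connected lumen reaching essentially all
           terminal air from the trachea", {
  for (stage in c("neonate", "14dpn")) {
    ph <- cached_phantom(stage)
    air <- voxel_mask(ph$tree_mask$values | ph$terminal_mask$values,
                      ph$tree_mask$spacing)
    comp <- exclude_external_air(air, ph$trachea_seed)
    reach <- sum(comp$values & ph$terminal_mask$values) /
      sum(ph$terminal_mask$values)
    expect_gt(reach, 0.99)
    # and the gray-band segmentation from the same seed still captures the
    # great bulk of it despite noise and partial volume
    grown <- fill_noise_voxels(
      region_grow(ph$gray, segmentation_config(seed = ph$trachea_seed)))
    expect_gt(sum(grown$values & ph$terminal_mask$values) /
                sum(ph$terminal_mask$values), 0.95)
  }
})

test_that("subdividing zero rounds is the identity", {
  lm <- label_map(array(rep(c(0L, 1L), each = 32), c(4, 4, 4)), 10)
  expect_identical(subdivide_sacs(lm, 0L, 30), lm)
})

test_that("one septation round splits a spherical sac into two connected
           chambers and removes about one septum slab of air", {
  sp <- 8; R <- 150
  dims <- rep(ceiling((2 * R + 80) / sp) + 1, 3)
  ctr <- rep((dims[1] - 1) * sp / 2, 3)
  arr <- array(0L, dims)
  arr[lungmorph:::paint_sphere(array(FALSE, dims), ctr, R, rep(sp, 3))] <- 1L
  lm <- label_map(arr, sp)
  parent_vox <- sum(arr > 0L)
  set.seed(9)
  out <- subdivide_sacs(lm, 1L, septum_thickness = 24)
  labs <- setdiff(unique(as.vector(out$values)), 0L)
  expect_length(labs, 2L)
  removed <- parent_vox - sum(out$values > 0L)
  slab_vox <- pi * R^2 * 24 / sp^3          # full central slab, no aperture
  expect_gt(removed, 0.4 * slab_vox)
  expect_lt(removed, 1.1 * slab_vox)
  # the aperture keeps the two chambers one connected air space
  comp <- lungmorph:::cpp_label_components(as.vector(out$values > 0L),
                                           dim(out$values), 6L)
  expect_equal(attr(comp, "n_components"), 1L)
})

test_that("repeated septation of the same sacs multiplies labels and
           shrinks the mean sac diameter", {
  base <- cached_phantom("neonate")$sac_labels
  set.seed(14)
  split3 <- subdivide_sacs(base, 3L, septum_thickness = 41)
  eq_diam <- function(lm) {
    voxvol <- prod(lm$spacing)
    counts <- table(lm$values[lm$values > 0L])
    mean((6 * as.numeric(counts) * voxvol / pi)^(1 / 3))
  }
  n0 <- length(setdiff(unique(as.vector(base$values)), 0L))
  n3 <- length(setdiff(unique(as.vector(split3$values)), 0L))
  expect_equal(n0, 6L)
  expect_gte(n3, n0)
  expect_gt(n3, 6L)
  expect_lt(eq_diam(split3), eq_diam(base))
})

test_that("rendering honours contrast polarity, blur and noise settings", {
  ph <- generate_stage_phantom(tiny_spec(rng_seed = 2))
  lung <- ph$lung_mask
  air <- voxel_mask(ph$tree_mask$values | ph$terminal_mask$values,
                    lung$spacing)
  clean <- render_gray(lung, air, blur_sigma = 0, noise_sd = 0)
  inside <- clean$values[lung$values]
  expect_setequal(unique(inside), c(5000, 8000))
  expect_lt(mean(clean$values[air$values]),
            mean(clean$values[lung$values & !air$values]))
  # zero-mean noise leaves mask-restricted means nearly unchanged; with
  # ~10^6 air voxels the noise SE is well below one gray unit
  big <- cached_phantom("neonate")
  big_air <- voxel_mask(big$tree_mask$values | big$terminal_mask$values,
                        big$tree_mask$spacing)
  noisy <- render_gray(big$lung_mask, big_air, blur_sigma = 0,
                       noise_sd = 400, rng_seed = 11)
  expect_lt(abs(mean(noisy$values[big_air$values]) - 5000), 1)
  expect_lt(abs(mean(noisy$values[big$lung_mask$values &
                                    !big_air$values]) - 8000), 1)
})

test_that("unresolvable specs are refused rather than blurred away", {
  expect_error(generate_stage_phantom(
    phantom_spec("neonate", septum_thickness_target = 15, spacing = 10,
                 sac_diameter_target = 349)),
    "unresolvable")
  expect_error(phantom_spec("neonate", sac_diameter_target = 20,
                            septum_thickness_target = 41), "target")
  expect_error(phantom_spec("nope"), "unknown stage")
})
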