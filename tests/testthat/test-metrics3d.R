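test_that("voxel-count volume is exact arithmetic", {
  arr <- array(FALSE, c(10, 10, 10))
  arr[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  expect_equal(mask_volume(voxel_mask(arr, 10)), 0.001)
  expect_equal(mask_volume(voxel_mask(array(FALSE, c(3, 3, 3)), 10)), 0)
  # anisotropic spacing
  one <- array(FALSE, c(2, 2, 2)); one[1, 1, 1] <- TRUE
  expect_equal(mask_volume(voxel_mask(one, c(5, 10, 20))), 1000 / 1e9)
})

test_that("volume is additive over disjoint masks", {
  set.seed(3)
  a <- array(runif(8^3) < 0.3, c(8, 8, 8))
  b <- array(runif(8^3) < 0.3, c(8, 8, 8)) & !a
  expect_equal(mask_volume(voxel_mask(a | b, 7)),
               mask_volume(voxel_mask(a, 7)) + mask_volume(voxel_mask(b, 7)))
})

test_that("a single voxel exposes six faces", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(mask_surface_area(voxel_mask(one, 10), "voxel_face"),
               6 * 100 / 1e6)
})

test_that("calibration sphere: volume within 2%, isosurface area within 5%,
           and the raw face count shows the staircase bias", {
  cal <- generate_calibration("sphere", radius = 200, spacing = 5)
  v <- mask_volume(cal$mask)
  s_iso <- mask_surface_area(cal$mask, "isosurface")
  s_face <- mask_surface_area(cal$mask, "voxel_face")
  expect_lt(abs(v - cal$analytic_volume) / cal$analytic_volume, 0.02)
  expect_lt(abs(s_iso - cal$analytic_surface) / cal$analytic_surface, 0.05)
  expect_gt(s_face, s_iso)
  # face counting overestimates curved surfaces by about 3/2
  expect_equal(s_face / cal$analytic_surface, 1.5, tolerance = 0.05)
})

test_that("isosurface error shrinks as the voxel spacing shrinks", {
  errs <- sapply(c(10, 5), function(sp) {
    cal <- generate_calibration("sphere", radius = 200, spacing = sp)
    abs(mask_surface_area(cal$mask) - cal$analytic_surface) /
      cal$analytic_surface
  })
  expect_lt(errs[2], errs[1])
})

test_that("the subtraction rule is literal arithmetic with a guarded
           precondition", {
  entire <- structure(list(volume = 2.0, surface_area = 50,
                           voxel_count = 200L, method = "isosurface"),
                      class = "roi_metrics")
  tree <- structure(list(volume = 0.3, surface_area = 7,
                         voxel_count = 30L, method = "isosurface"),
                    class = "roi_metrics")
  got <- terminal_airspace_metrics(entire, tree)
  expect_equal(got$volume, 1.7)
  expect_equal(got$surface_area, 43)
  same <- terminal_airspace_metrics(entire, entire)
  expect_equal(same$volume, 0)
  expect_equal(same$surface_area, 0)
  expect_error(terminal_airspace_metrics(tree, entire), "inconsistent")
})

test_that("subtraction is consistent on the phantom: V_A + V(tree) equals
           V(entire) exactly", {
  ph <- cached_phantom("neonate")
  entire <- voxel_mask(ph$tree_mask$values | ph$terminal_mask$values,
                       ph$tree_mask$spacing)
  m_e <- roi_metrics(entire)
  m_t <- roi_metrics(ph$tree_mask)
  m_a <- terminal_airspace_metrics(m_e, m_t)
  expect_equal(m_a$volume + m_t$volume, m_e$volume, tolerance = 1e-12)
  expect_equal(m_a$volume, mask_volume(ph$terminal_mask), tolerance = 1e-12)
})

test_that("specimen metrics satisfy the physical invariants and the
           degenerate lung-equals-air case", {
  rep <- cached_pipeline("neonate")
  expect_gt(rep$metrics$VL_mm3, 0)
  expect_gte(rep$metrics$VL_mm3, rep$metrics$VA_mm3)
  expect_gt(rep$metrics$SA_mm2, 0)

  ph <- cached_phantom("neonate")
  entire <- voxel_mask(ph$tree_mask$values | ph$terminal_mask$values,
                       ph$tree_mask$spacing)
  degenerate <- specimen_metrics(list(entire_mask = entire,
                                      tree_mask = ph$tree_mask,
                                      lung_mask = entire))
  expect_equal(degenerate$VL, mask_volume(entire))
})

test_that("empty masks are rejected by the surface estimator", {
  expect_error(mask_surface_area(voxel_mask(array(FALSE, c(3, 3, 3)), 5)),
               "empty")
})
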