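test_that("systematic section selection follows the fractionator rule", {
  cfg <- stereology_config()
  # 80 slices, interval 10, 0-based start 3 -> slices 4, 14, ..., 74
  expect_equal(select_sections(80, cfg, start = 3),
               seq(4, 74, by = 10))
  # as many slices as sections: every slice, start forced to 0
  expect_equal(select_sections(8, cfg, start = 0), 1:8)
  expect_error(select_sections(5, cfg), "fewer slices")
  expect_error(select_sections(80, cfg, start = 10), "start")
})

test_that("every slice is selected uniformly over many seeded draws", {
  cfg <- stereology_config()
  n_slices <- 40L; k <- 5L; draws <- 4000L
  counts <- integer(n_slices)
  set.seed(123)
  for (i in seq_len(draws)) {
    idx <- select_sections(n_slices, cfg)
    counts[idx] <- counts[idx] + 1L
  }
  p <- 1 / k
  se <- sqrt(p * (1 - p) / draws)
  expect_true(all(abs(counts / draws - p) < 3 * se + 0.01))
})

test_that("line casting is reproducible, isotropic in angle, and
           degenerates to horizontal on single-row sections", {
  set.seed(5)
  a <- cast_line(c(50L, 60L), c(10, 10))
  set.seed(5)
  b <- cast_line(c(50L, 60L), c(10, 10))
  expect_identical(a, b)

  set.seed(6)
  angles <- replicate(1000, cast_line(c(50L, 60L), c(10, 10))$angle)
  ks <- suppressWarnings(stats::ks.test(angles, "punif", 0, pi))
  expect_gt(ks$p.value, 0.01)

  expect_equal(cast_line(c(1L, 30L), c(10, 10))$angle, 0)
})

test_that("intercepts on a stripe pattern are exact, and scale by sqrt(2)
           on the diagonal", {
  st <- stripe_section(60, 100, air_px = 20, tissue_px = 5)
  sp <- c(10, 10)
  horiz <- list(point = c(300, 500), angle = 0)
  ch <- line_intercepts(st$air, st$lung, horiz, sp)
  air <- ch$length_um[ch$kind == "air"]
  sep <- ch$length_um[ch$kind == "septum"]
  expect_true(all(abs(air - 200) <= sp[1] / 4 + 1e-9))
  expect_true(all(abs(sep - 50) <= sp[1] / 4 + 1e-9))

  diag45 <- list(point = c(300, 500), angle = pi / 4)
  ch45 <- line_intercepts(st$air, st$lung, diag45, sp)
  air45 <- ch45$length_um[ch45$kind == "air"]
  expect_true(all(abs(air45 - 200 * sqrt(2)) <= 4 * sp[1] / 4))
})

test_that("a line with no lung content yields no chords", {
  empty <- matrix(FALSE, 30, 30)
  ln <- list(point = c(150, 150), angle = 0.3)
  expect_equal(nrow(line_intercepts(empty, empty, ln, c(10, 10))), 0L)
})

test_that("septum chords require air on both sides: pleural tissue is
           never measured", {
  # air | tissue | background: the outer tissue band borders background
  air <- matrix(FALSE, 20, 40); air[, 5:20] <- TRUE
  lung <- matrix(FALSE, 20, 40); lung[, 3:30] <- TRUE
  ln <- list(point = c(100, 200), angle = 0)
  ch <- line_intercepts(air, lung, ln, c(10, 10))
  expect_false(any(ch$kind == "septum"))
})

test_that("the default protocol measures 40 intercepts per quantity with
           the documented summary statistics", {
  rep <- cached_pipeline("neonate")
  expect_equal(rep$morphometry$n_chords, 80L)
  ph <- cached_phantom("neonate")
  seg_air <- ph$terminal_mask
  m <- measure_lung(seg_air, ph$lung_mask, stereology_config(rng_seed = 21),
                    other_air_mask = ph$tree_mask)
  expect_equal(m$summary$n_air, 40L)
  expect_equal(m$summary$n_septum, 40L)
  air <- m$chords$length_um[m$chords$kind == "air"]
  expect_equal(m$summary$diameter_mean, mean(air))
  expect_equal(m$summary$diameter_sd, stats::sd(air))
  expect_equal(sort(unique(table(m$chords$section[m$chords$kind == "air"]))),
               5L)
})

test_that("measurement fails loudly when the lung cannot supply the
           requested chords", {
  tiny_air <- voxel_mask(array(FALSE, c(10, 10, 10)), 10)
  tiny_air$values[5, 5, 5] <- TRUE
  lung <- voxel_mask(array(TRUE, c(10, 10, 10)), 10)
  cfg <- stereology_config(n_sections = 1L, max_line_retries = 5L)
  expect_error(measure_lung(tiny_air, lung, cfg), "retries exhausted")
})

test_that("the protocol recovers truth intercepts on phantoms and
           preserves the developmental ordering", {
  neo <- cached_pipeline("neonate")
  late <- cached_pipeline("57dpn")
  expect_lt(abs(neo$morphometry$diameter_mean_um - neo$truth$diameter_um) /
              neo$truth$diameter_um, 0.15)
  expect_lt(late$morphometry$diameter_mean_um,
            neo$morphometry$diameter_mean_um)
})
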