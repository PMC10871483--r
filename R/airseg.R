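# Seeded region growing of the air lumen within a gray-tolerance band.
#
# The tolerance is a fixed band centred on the gray value of the seed
# region (trachea centre): a voxel joins the mask if it is connected to the
# seed through voxels whose gray value lies within [centre - tol,
# centre + tol]. Growth is fully 3D and deterministic. A guard limit turns
# tolerance misconfiguration (flooding into the background) into a
# distinct leak error instead of a silently wrong mask.

#' Segmentation configuration
#'
#' @param seed voxel subscript `(z, y, x)` (1-based) on the trachea
#'   centreline.
#' @param tolerance half-width of the gray band (default 1100, the centre
#'   of the study's 1000--1200 range).
#' @param connectivity 6, 18 or 26 (default 6; face connectivity prevents
#'   diagonal leakage through one-voxel septa).
#' @param max_voxels guard limit; growth beyond it raises a leak error
#'   (`NULL`: unlimited).
#' @param seed_gray explicit band centre; by default the median gray of
#'   the 3x3x3 neighbourhood of the seed, which is the reproducible
#'   analogue of a human picking a representative air value rather than
#'   one noisy voxel.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(seed, tolerance = 1100, connectivity = 6L,
                                max_voxels = NULL, seed_gray = NULL) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  seed <- as.integer(seed)
  if (length(seed) != 3L) stop("seed must be a (z, y, x) voxel subscript")
  structure(list(seed = seed, tolerance = tolerance,
                 connectivity = as.integer(connectivity),
                 max_voxels = max_voxels, seed_gray = seed_gray),
            class = "segmentation_config")
}

seed_band <- function(grid, cfg) {
  dims <- dim(grid$values)
  if (any(cfg$seed < 1L) || any(cfg$seed > dims))
    stop("seed lies outside the volume")
  centre <- cfg$seed_gray
  if (is.null(centre)) {
    lo <- pmax(cfg$seed - 1L, 1L)
    hi <- pmin(cfg$seed + 1L, dims)
    centre <- stats::median(grid$values[lo[1]:hi[1], lo[2]:hi[2],
                                        lo[3]:hi[3]])
  }
  c(centre - cfg$tolerance, centre + cfg$tolerance)
}

leak_error <- function(count) {
  stop(structure(class = c("lungmorph_leak_error", "error", "condition"),
                 list(message = paste0(
                        "region growth exceeded the guard limit (",
                        format(count, big.mark = ","),
                        " voxels): tolerance band leaks out of the air ",
                        "spaces"),
                      call = sys.call(-1))))
}

#' Seeded region growing
#'
#' Grows from the seed through all connected voxels whose gray value lies
#' within the tolerance band around the seed gray value.
#'
#' @param grid a [voxel_grid()].
#' @param cfg a [segmentation_config()].
#' @return a [voxel_mask()] with attributes `band` (the gray band used),
#'   `seed_gray` and `voxel_count`. Raises a `lungmorph_leak_error` if the
#'   guard limit is exceeded.
#' @export
region_grow <- function(grid, cfg) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(cfg, "segmentation_config"))
  band <- seed_band(grid, cfg)
  dims <- dim(grid$values)
  res <- cpp_flood_fill(as.numeric(grid$values), dims,
                        as.integer(linear_index(cfg$seed, dims)),
                        band[1], band[2], cfg$connectivity,
                        if (is.null(cfg$max_voxels)) -1 else cfg$max_voxels)
  if (res$leaked) leak_error(res$count)
  out <- voxel_mask(array(res$mask, dims), grid$spacing)
  attr(out, "band") <- band
  attr(out, "seed_gray") <- mean(band)
  attr(out, "voxel_count") <- res$count
  out
}

#' Extend a region of interest by renewed region growing
#'
#' Re-seeds region growing from every frontier voxel of an existing ROI
#' with the same gray band, emulating the manual workflow of propagating
#' the ROI slice by slice from the airway walls into the terminal
#' air-space walls. The result always contains the base ROI.
#'
#' @param grid a [voxel_grid()].
#' @param base a nonempty [voxel_mask()] to extend.
#' @param cfg a [segmentation_config()] (band taken from its seed/seed_gray).
#' @return a [voxel_mask()] containing `base`.
#' @export
extend_roi <- function(grid, base, cfg) {
  stopifnot(inherits(base, "voxel_mask"))
  check_aligned(grid, base)
  if (!any(base$values)) stop("base ROI is empty")
  band <- seed_band(grid, cfg)
  dims <- dim(grid$values)
  seeds <- which(base$values) - 1L
  res <- cpp_flood_fill(as.numeric(grid$values), dims, as.integer(seeds),
                        band[1], band[2], cfg$connectivity,
                        if (is.null(cfg$max_voxels)) -1 else cfg$max_voxels)
  if (res$leaked) leak_error(res$count)
  voxel_mask(array(res$mask, dims) | base$values, grid$spacing)
}

#' Keep only the air connected to the seed
#'
#' Non-pulmonary air (gas in the gut, air between lung segments, vessel
#' lumina falling into the band) is removed by keeping only the connected
#' component of the mask that contains the seed -- the automated analogue
#' of the study's visual exclusion.
#'
#' @param mask a [voxel_mask()].
#' @param seed voxel subscript `(z, y, x)` inside the mask.
#' @param connectivity 6, 18 or 26.
#' @return the single-component [voxel_mask()] containing the seed.
#' @export
exclude_external_air <- function(mask, seed, connectivity = 6L) {
  stopifnot(inherits(mask, "voxel_mask"))
  dims <- dim(mask$values)
  seed <- as.integer(seed)
  if (any(seed < 1L) || any(seed > dims) || !mask$values[seed[1], seed[2], seed[3]])
    stop("seed is not inside the mask")
  res <- cpp_flood_fill(as.numeric(mask$values), dims,
                        as.integer(linear_index(seed, dims)),
                        0.5, 1.5, as.integer(connectivity), -1)
  voxel_mask(array(res$mask, dims), mask$spacing)
}

#' Split the air lumen into bronchial tree and terminal air spaces
#'
#' The boundary between conducting airways and terminal air spaces is an
#' anatomical judgement, so it must be supplied: either as a tree mask
#' (e.g. phantom ground truth) or as a set of boundary voxels at the
#' bronchiole outlets that disconnect the lumen; the component containing
#' the trachea seed then becomes the tree.
#'
#' @param entire [voxel_mask()] of the entire air spaces.
#' @param tree_definition either a [voxel_mask()] (must be a subset of
#'   `entire`) or an n x 3 matrix of boundary voxel subscripts.
#' @param seed trachea seed subscript, required for the boundary form.
#' @param connectivity 6, 18 or 26.
#' @return list with `tree_mask` and `terminal_mask` (disjoint; their
#'   union is `entire`).
#' @export
split_tree_terminal <- function(entire, tree_definition, seed = NULL,
                                connectivity = 6L) {
  stopifnot(inherits(entire, "voxel_mask"))
  dims <- dim(entire$values)
  if (inherits(tree_definition, "voxel_mask")) {
    check_aligned(entire, tree_definition)
    if (any(tree_definition$values & !entire$values))
      stop("tree definition is not a subset of the entire air spaces")
    tree <- tree_definition$values
  } else {
    bnd <- as.matrix(tree_definition)
    if (nrow(bnd) == 0L) stop("empty boundary voxel set")
    if (is.null(seed)) stop("boundary form requires the trachea seed")
    inside <- entire$values[bnd]
    if (!all(inside)) stop("boundary voxels must lie inside the air mask")
    cut <- entire$values
    cut[bnd] <- FALSE
    seed <- as.integer(seed)
    if (!cut[seed[1], seed[2], seed[3]])
      stop("seed was removed by the boundary; place it in the trachea")
    res <- cpp_flood_fill(as.numeric(cut), dims,
                          as.integer(linear_index(seed, dims)),
                          0.5, 1.5, as.integer(connectivity), -1)
    tree <- array(res$mask, dims)
    tree[bnd] <- TRUE                   # boundary voxels belong to the tree
    if (all(tree == entire$values))
      stop("boundary does not disconnect the air spaces")
  }
  list(tree_mask = voxel_mask(tree, entire$spacing),
       terminal_mask = voxel_mask(entire$values & !tree, entire$spacing))
}

#' Fill interior noise voxels of an air mask
#'
#' Additive noise pushes isolated voxels inside the air lumen out of the
#' tolerance band; they survive as one-voxel "walls" that fragment the
#' mask, split line intercepts and inflate the apparent surface area. A
#' non-air voxel with at least `min_air_neighbors` of its 6 face
#' neighbours in air is such a hole, not a wall: real septa are at least
#' two voxels thick, so their voxels never exceed 4 air neighbours.
#'
#' @param mask a [voxel_mask()] of air.
#' @param min_air_neighbors threshold (default 5).
#' @param iterations passes (default 2, for 2-voxel noise clusters).
#' @return the filled [voxel_mask()].
#' @export
fill_noise_voxels <- function(mask, min_air_neighbors = 5L,
                              iterations = 2L) {
  stopifnot(inherits(mask, "voxel_mask"))
  arr <- mask$values
  d <- dim(arr)
  for (i in seq_len(iterations)) {
    cnt <- array(0L, d)
    cnt[-1, , ] <- cnt[-1, , ] + arr[-d[1], , ]
    cnt[-d[1], , ] <- cnt[-d[1], , ] + arr[-1, , ]
    cnt[, -1, ] <- cnt[, -1, ] + arr[, -d[2], ]
    cnt[, -d[2], ] <- cnt[, -d[2], ] + arr[, -1, ]
    cnt[, , -1] <- cnt[, , -1] + arr[, , -d[3]]
    cnt[, , -d[3]] <- cnt[, , -d[3]] + arr[, , -1]
    fill <- !arr & cnt >= min_air_neighbors
    if (!any(fill)) break
    arr <- arr | fill
  }
  voxel_mask(arr, mask$spacing)
}

# r iterations of face-adjacent dilation / erosion; kept internal.
dilate6 <- function(arr, r) {
  for (i in seq_len(r)) {
    shifted <- arr
    d <- dim(arr)
    shifted[-1, , ] <- shifted[-1, , ] | arr[-d[1], , ]
    shifted[-d[1], , ] <- shifted[-d[1], , ] | arr[-1, , ]
    shifted[, -1, ] <- shifted[, -1, ] | arr[, -d[2], ]
    shifted[, -d[2], ] <- shifted[, -d[2], ] | arr[, -1, ]
    shifted[, , -1] <- shifted[, , -1] | arr[, , -d[3]]
    shifted[, , -d[3]] <- shifted[, , -d[3]] | arr[, , -1]
    arr <- shifted
  }
  arr
}

erode6 <- function(arr, r) !dilate6(!arr, r)

#' Segment the lung outline
#'
#' The lung outline (for total lung volume) is the connected component of
#' tissue-plus-internal-air containing the seed, morphologically closed to
#' fill residual gaps.
#'
#' @param grid a [voxel_grid()].
#' @param tissue_band numeric `(lo, hi)` gray range covering lung tissue.
#' @param seed_in_lung voxel subscript inside the lung.
#' @param air_mask optional [voxel_mask()] of the internal air spaces to
#'   union in before taking the component.
#' @param closing_radius closing radius in voxels (face-adjacent
#'   dilation/erosion iterations).
#' @param connectivity 6, 18 or 26.
#' @return a [voxel_mask()] of the lung outline.
#' @export
segment_lung_outline <- function(grid, tissue_band, seed_in_lung,
                                 air_mask = NULL, closing_radius = 2L,
                                 connectivity = 6L) {
  stopifnot(inherits(grid, "voxel_grid"), length(tissue_band) == 2L)
  dims <- dim(grid$values)
  cand <- grid$values >= tissue_band[1] & grid$values <= tissue_band[2]
  if (!is.null(air_mask)) {
    check_aligned(grid, air_mask)
    cand <- cand | air_mask$values
  }
  seed <- as.integer(seed_in_lung)
  if (any(seed < 1L) || any(seed > dims) || !cand[seed[1], seed[2], seed[3]])
    stop("seed is not inside the tissue/air candidate region")
  res <- cpp_flood_fill(as.numeric(cand), dims,
                        as.integer(linear_index(seed, dims)),
                        0.5, 1.5, as.integer(connectivity), -1)
  comp <- array(res$mask, dims)
  if (!any(comp)) stop("empty lung outline")
  if (closing_radius > 0L)
    comp <- erode6(dilate6(comp, closing_radius), closing_radius)
  voxel_mask(comp, grid$spacing)
}

#' Full air-space segmentation of a volume
#'
#' Convenience wrapper running the study's segmentation sequence: region
#' growing from the trachea seed, restriction to seed-connected air,
#' tree/terminal split, and lung-outline segmentation.
#'
#' @param grid a [voxel_grid()].
#' @param cfg a [segmentation_config()].
#' @param tree_definition passed to [split_tree_terminal()].
#' @param tissue_band gray range for [segment_lung_outline()]; by default
#'   from just above the air band to the 16-bit maximum.
#' @param closing_radius closing radius for the lung outline.
#' @return list of class `airspace_segmentation` with `entire_mask`,
#'   `tree_mask`, `terminal_mask`, `lung_mask` and a `log` of the band and
#'   voxel counts.
#' @export
segment_airspaces <- function(grid, cfg, tree_definition,
                              tissue_band = NULL, closing_radius = 2L) {
  grown <- region_grow(grid, cfg)
  band <- attr(grown, "band")
  entire <- exclude_external_air(grown, cfg$seed, cfg$connectivity)
  entire <- fill_noise_voxels(entire)
  if (is.null(tissue_band)) tissue_band <- c(band[2], 65535)
  if (inherits(tree_definition, "voxel_mask")) {
    # a truth/an external tree mask may overhang the segmented lumen by a
    # partial-volume shell, and conversely the segmented lumen carries a
    # one-voxel partial-volume halo along the airway walls that belongs to
    # the tree, not to the terminal air spaces: clip the dilated tree to
    # the segmented lumen
    check_aligned(entire, tree_definition)
    tree_definition <- voxel_mask(dilate6(tree_definition$values, 1L) &
                                    entire$values,
                                  entire$spacing)
  }
  parts <- split_tree_terminal(entire, tree_definition, seed = cfg$seed,
                               connectivity = cfg$connectivity)
  lung <- segment_lung_outline(grid, tissue_band,
                               seed_in_lung = cfg$seed, air_mask = entire,
                               closing_radius = closing_radius,
                               connectivity = cfg$connectivity)
  structure(list(entire_mask = entire,
                 tree_mask = parts$tree_mask,
                 terminal_mask = parts$terminal_mask,
                 lung_mask = lung,
                 log = list(band = band,
                            seed = cfg$seed,
                            tolerance = cfg$tolerance,
                            connectivity = cfg$connectivity,
                            entire_voxels = sum(entire$values),
                            tree_voxels = sum(parts$tree_mask$values),
                            terminal_voxels = sum(parts$terminal_mask$values),
                            lung_voxels = sum(lung$values))),
            class = "airspace_segmentation")
}
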