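# Synthetic developing-lung phantoms with voxel-level ground truth.
#
# The phantom abstracts the developing marsupial lung to the features the
# measurement pipeline sees: a trachea and per-lobe bronchial tubes, each
# opening into a lobar air sac; rounds of septation that subdivide sacs by
# finite-thickness planar septa (each pierced by an aperture, so the whole
# air lumen stays one connected space, as in the real organ); PTA-like
# contrast (bright tissue, dark air) with partial-volume blur and additive
# noise. Stage parameters track the per-stage morphometry of the packaged
# specimen table.

# Per-stage defaults: line-intercept diameter target and septum thickness
# (micrometres) are the stage group means of the packaged specimen table;
# subdivision rounds increase as compartmentalization progresses; spacing
# is chosen so the septa stay resolvable (>= 2 voxels). The 13dpc entry has
# no printed morphometry (deflated fetal lung); its diameter is scaled from
# the neonate by the cube root of the lung-volume ratio.
stage_table <- data.frame(
  stage = c("13dpc", "neonate", "4dpn", "7dpn", "11dpn", "14dpn",
            "21dpn", "28dpn", "35dpn", "49dpn", "57dpn", "adult"),
  diameter = c(220, 349, 258, 192, 141, 126, 108, 89, 70, 52, 51, 79),
  septum = c(41, 41, 34, 24, 25, 26, 18, 20, 16, 12, 10, 10),
  rounds = c(0L, 0L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L, 3L),
  spacing = c(10, 10, 10, 10, 10, 10, 8, 8, 7, 6, 5, 5),
  stringsAsFactors = FALSE)

#' Stage parameter table for the phantom generator
#'
#' @return data.frame with one row per developmental stage: target
#'   line-intercept air-space diameter and septum thickness (micrometres),
#'   default septation rounds and default voxel spacing.
#' @export
phantom_stages <- function() stage_table

#' Specify a developing-lung phantom
#'
#' Defaults emulate PTA-stained micro-CT: dark air lumina
#' (`gray_air = 5000`), bright tissue (`gray_tissue = 8000`), mounting
#' background below air (`gray_background = 2000`), sub-voxel
#' partial-volume blur and additive Gaussian noise. The air/tissue contrast
#' is set so that the segmentation tolerance band (1000--1200 gray values
#' around an air seed) reaches the half-way point of the blurred air-tissue
#' edge while tissue itself stays several noise SDs outside the band.
#'
#' @param stage_label one of the stages in [phantom_stages()].
#' @param n_lobes number of lung lobes (default 6: four right, two left).
#' @param sac_diameter_target target mean line-intercept air-space diameter
#'   (micrometres); default: stage group mean.
#' @param septum_thickness_target septum thickness (micrometres); default:
#'   stage group mean.
#' @param subdivision_rounds septation rounds applied to the lobar sacs.
#' @param airway_generations tube levels from trachea to sac (>= 1).
#' @param gray_air,gray_tissue,gray_background 16-bit gray levels; tissue
#'   must be brighter than air.
#' @param noise_sd additive Gaussian noise SD in gray units.
#' @param blur_sigma partial-volume blur SD in micrometres (default: half a
#'   voxel).
#' @param spacing isotropic voxel spacing in micrometres.
#' @param rng_seed integer seed; identical seeds give identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(stage_label = "neonate",
                         n_lobes = 6L,
                         sac_diameter_target = NULL,
                         septum_thickness_target = NULL,
                         subdivision_rounds = NULL,
                         airway_generations = 2L,
                         gray_air = 5000,
                         gray_tissue = 8000,
                         gray_background = 2000,
                         noise_sd = 400,
                         blur_sigma = NULL,
                         spacing = NULL,
                         rng_seed = 1L) {
  row <- stage_table[stage_table$stage == stage_label, ]
  if (nrow(row) != 1L)
    stop("unknown stage label: ", stage_label, " (see phantom_stages())")
  if (is.null(sac_diameter_target)) sac_diameter_target <- row$diameter
  if (is.null(septum_thickness_target)) septum_thickness_target <- row$septum
  if (is.null(subdivision_rounds)) subdivision_rounds <- row$rounds
  if (is.null(spacing)) spacing <- row$spacing
  if (is.null(blur_sigma)) blur_sigma <- 0.5 * spacing
  if (gray_tissue <= gray_air)
    stop("gray_tissue must exceed gray_air (stained tissue is bright)")
  if (!(sac_diameter_target > septum_thickness_target) ||
      septum_thickness_target <= 0)
    stop("need sac_diameter_target > septum_thickness_target > 0")
  if (subdivision_rounds < 0L) stop("subdivision_rounds must be >= 0")
  if (airway_generations < 1L) stop("airway_generations must be >= 1")
  structure(list(stage_label = stage_label,
                 n_lobes = as.integer(n_lobes),
                 sac_diameter_target = sac_diameter_target,
                 septum_thickness_target = septum_thickness_target,
                 subdivision_rounds = as.integer(subdivision_rounds),
                 airway_generations = as.integer(airway_generations),
                 gray_air = gray_air, gray_tissue = gray_tissue,
                 gray_background = gray_background,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 spacing = spacing, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Analytic calibration shapes
#'
#' Voxelizes an ideal shape and returns it with its closed-form volume and
#' surface area, used to validate the voxel-count and isosurface
#' estimators.
#'
#' @param shape `"sphere"`, `"cylinder"` or `"tube_with_sac"`.
#' @param radius sphere/cylinder radius in micrometres.
#' @param length cylinder (or tube) length in micrometres.
#' @param tube_radius tube radius for `"tube_with_sac"`.
#' @param spacing isotropic voxel spacing in micrometres.
#' @param gray_air,gray_tissue gray levels used for the rendered grid.
#' @return list with `grid` (a [voxel_grid()]; shape dark as an air cast),
#'   `mask` (a [voxel_mask()] of the ideal shape), `analytic_volume` (mm^3)
#'   and `analytic_surface` (mm^2).
#' @export
generate_calibration <- function(shape = c("sphere", "cylinder",
                                           "tube_with_sac"),
                                 radius = 200, length = 1000,
                                 tube_radius = radius / 3, spacing = 5,
                                 gray_air = 5000, gray_tissue = 8000) {
  shape <- match.arg(shape)
  if (radius < 2 * spacing)
    stop("unresolvable shape: radius below 2 voxels")
  pad <- 4 * spacing
  if (shape == "sphere") {
    ext <- 2 * radius + 2 * pad
    dims <- rep(ceiling(ext / spacing) + 1L, 3L)
    ctr <- rep((dims[1] - 1) * spacing / 2, 3L)
    arr <- paint_sphere(empty_mask_array(dims), ctr, radius, rep(spacing, 3))
    V <- 4 / 3 * pi * radius^3
    S <- 4 * pi * radius^2
  } else if (shape == "cylinder") {
    extz <- length + 2 * pad
    extxy <- 2 * radius + 2 * pad
    dims <- c(ceiling(extz / spacing) + 1L, rep(ceiling(extxy / spacing) + 1L, 2L))
    cyx <- (dims[2:3] - 1) * spacing / 2
    arr <- paint_cylinder_z(empty_mask_array(dims), cyx, pad, length, radius,
                            rep(spacing, 3))
    V <- pi * radius^2 * length
    S <- 2 * pi * radius * length + 2 * pi * radius^2
  } else {
    if (tube_radius >= radius) stop("tube_radius must be below sphere radius")
    if (tube_radius < 2 * spacing)
      stop("unresolvable shape: tube radius below 2 voxels")
    # sphere centred low, tube extending in +z from where the sphere's
    # cross-section equals the tube radius
    q <- sqrt(radius^2 - tube_radius^2)
    extz <- 2 * radius + length + 2 * pad
    extxy <- 2 * radius + 2 * pad
    dims <- c(ceiling(extz / spacing) + 1L, rep(ceiling(extxy / spacing) + 1L, 2L))
    cyx <- (dims[2:3] - 1) * spacing / 2
    zc <- pad + radius
    arr <- paint_sphere(empty_mask_array(dims), c(zc, cyx), radius,
                        rep(spacing, 3))
    arr <- paint_cylinder_z(arr, cyx, zc + q, length + (radius - q),
                            tube_radius, rep(spacing, 3))
    h <- radius - q
    capV <- pi * h^2 * (radius - h / 3)
    V <- 4 / 3 * pi * radius^3 + pi * tube_radius^2 * (length + h) - capV
    S <- 4 * pi * radius^2 - 2 * pi * radius * h +
      2 * pi * tube_radius * (length + h) + pi * tube_radius^2
  }
  mask <- voxel_mask(arr, spacing)
  gray <- array(gray_tissue, dim(arr))
  gray[arr] <- gray_air
  list(grid = voxel_grid(gray, spacing, name = shape),
       mask = mask,
       analytic_volume = V / 1e9,
       analytic_surface = S / 1e6)
}

#' Subdivide air sacs by planar septation
#'
#' Each round splits every sufficiently large sac by a planar septum of the
#' given thickness through its centroid, with a random orientation drawn
#' from the current RNG. The septum is pierced by an aperture (a cylindrical
#' opening near the centroid), so the two daughter sacs stay connected --
#' septation subdivides the air space without sealing it off. Septum voxels
#' outside the aperture become tissue (label 0).
#'
#' @param sacs a [label_map()] of air sacs.
#' @param rounds number of septation rounds (>= 0).
#' @param septum_thickness septum thickness in micrometres; must be at
#'   least one voxel.
#' @param min_diameter smallest equivalent-sphere diameter still split
#'   (default four septum thicknesses).
#' @param aperture_frac aperture diameter as a fraction of the sac's
#'   equivalent diameter.
#' @param max_retries orientation re-draws per sac before it is skipped.
#' @return a new [label_map()]; the label count never decreases.
#' @export
subdivide_sacs <- function(sacs, rounds, septum_thickness,
                           min_diameter = 4 * septum_thickness,
                           aperture_frac = 0.35, max_retries = 8L) {
  stopifnot(inherits(sacs, "label_map"))
  if (rounds < 0) stop("rounds must be >= 0")
  if (rounds == 0) return(sacs)
  spacing <- sacs$spacing
  if (septum_thickness < max(spacing))
    stop("unresolvable septum: thinner than one voxel")
  arr <- sacs$values
  dims <- dim(arr)
  voxvol <- prod(spacing)
  for (round_i in seq_len(rounds)) {
    labs <- setdiff(sort(unique(as.vector(arr))), 0L)
    next_label <- max(labs) + 1L
    for (lab in labs) {
      lin <- which(arr == lab)
      if (length(lin) == 0L) next
      eq_d <- (6 * length(lin) * voxvol / pi)^(1 / 3)
      if (eq_d < min_diameter) next
      sub <- arrayInd(lin, dims)
      coords <- cbind((sub[, 1] - 1) * spacing[1],
                      (sub[, 2] - 1) * spacing[2],
                      (sub[, 3] - 1) * spacing[3])
      ctr <- colMeans(coords)
      done <- FALSE
      for (try_i in seq_len(max_retries)) {
        nrm <- random_unit_vector()
        d <- as.vector((coords - matrix(ctr, nrow(coords), 3,
                                        byrow = TRUE)) %*% nrm)
        half <- septum_thickness / 2
        sideA <- d > half
        sideB <- d < -half
        slab <- !sideA & !sideB
        if (!any(sideA) || !any(sideB)) next
        # aperture: cylindrical opening through the slab near the centroid
        u <- random_unit_vector()
        u <- u - sum(u * nrm) * nrm
        un <- sqrt(sum(u^2))
        if (un < 1e-9) next
        u <- u / un
        offset <- runif(1, 0, 0.15 * eq_d) * u
        ap_r <- max(aperture_frac * eq_d / 2, 1.6 * max(spacing))
        rel <- coords - matrix(ctr + offset, nrow(coords), 3, byrow = TRUE)
        inplane2 <- rowSums(rel^2) - (as.vector(rel %*% nrm))^2
        aperture <- slab & inplane2 <= ap_r^2
        if (!any(aperture)) next
        arr[lin[slab & !aperture]] <- 0L
        arr[lin[aperture]] <- lab
        arr[lin[sideB]] <- next_label
        next_label <- next_label + 1L
        done <- TRUE
        break
      }
      if (!done) next
    }
  }
  labs <- setdiff(sort(unique(as.vector(arr))), 0L)
  label_map(arr, spacing,
            label_names = stats::setNames(paste0("sac_", seq_along(labs)),
                                          as.character(labs)))
}

#' Render a gray-value volume from phantom masks
#'
#' Air voxels take `gray_air`, tissue (lung minus air) `gray_tissue`, and
#' everything else `gray_background` (below air, emulating the mounting
#' medium). The ideal image is smoothed with a Gaussian of SD `blur_sigma`
#' (partial-volume effect), then zero-mean Gaussian noise is added and the
#' result clipped to the 16-bit range.
#'
#' @param lung_mask,air_mask aligned [voxel_mask()]s; air must lie inside
#'   the lung.
#' @param gray_air,gray_tissue,gray_background gray levels.
#' @param blur_sigma blur SD in micrometres.
#' @param noise_sd noise SD in gray units.
#' @param rng_seed optional seed for the noise; `NULL` uses the current
#'   RNG state.
#' @return a [voxel_grid()].
#' @export
render_gray <- function(lung_mask, air_mask, gray_air = 5000,
                        gray_tissue = 8000, gray_background = 2000,
                        blur_sigma = 0, noise_sd = 0, rng_seed = NULL) {
  check_aligned(lung_mask, air_mask)
  spacing <- lung_mask$spacing
  ideal <- array(gray_background, dim(lung_mask$values))
  ideal[lung_mask$values] <- gray_tissue
  ideal[air_mask$values] <- gray_air
  out <- if (blur_sigma > 0)
    blur3d(ideal, rep(blur_sigma, 3), spacing) else ideal
  add_noise <- function() {
    if (noise_sd > 0)
      out <<- out + array(rnorm(length(out), 0, noise_sd), dim(out))
  }
  if (is.null(rng_seed)) add_noise() else with_seed(rng_seed, add_noise())
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  voxel_grid(out, spacing, name = "phantom")
}

#' Generate a stage phantom with ground truth
#'
#' Builds a trachea plus per-lobe bronchial tubes, each opening into a
#' lobar air sac; applies the stage's septation rounds
#' (see [subdivide_sacs()]); renders the gray volume; and records truth
#' metrics computed from the masks at generation resolution. The truth
#' air-space "diameter" and septum thickness are defined exactly as the
#' stereology module measures them -- as mean line-intercept lengths --
#' measured here with a dense deterministic-seed line protocol; the lobar
#' sac radius is sized so that the expected sphere intercept (two thirds of
#' the sphere diameter, i.e. 4V/S) matches the stage target.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth`: fields `gray`, `lung_mask`,
#'   `tree_mask`, `terminal_mask`, `sac_labels`, `lobe_labels`, `true_VL`,
#'   `true_VA` (mm^3), `true_SA` (mm^2), `true_mean_diameter`,
#'   `true_mean_septum` (micrometres), `trachea_seed` (voxel subscript)
#'   and `spec`.
#' @export
generate_stage_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  spacing <- rep(sp, 3)
  t_sep <- spec$septum_thickness_target
  if (t_sep < 2 * sp)
    stop("unresolvable spec: septum thickness below 2 voxels at this spacing")
  with_seed(spec$rng_seed, {
    # geometry (micrometres). The mean line intercept of a convex body is
    # 4V/S = (2/3) d for a sphere of diameter d, so lobar sacs are sized
    # 1.5x the target intercept. Each septation round shrinks the mean
    # intercept: exactly 2/3 for the first centroid split of a sphere
    # (volume kept, two cut faces added), and ~0.77 per later round
    # (irregular chambers, septum apertures, resolvability floor) --
    # constants calibrated once on the generator itself. A voxelized
    # sphere measures 0.935x its analytic intercept under the chord
    # protocol, which the sizing also compensates.
    r_sub <- spec$subdivision_rounds
    shrink <- if (r_sub == 0) 1 else (2 / 3) * 0.77^(r_sub - 1)
    d0 <- (1.5 / 0.935) * spec$sac_diameter_target / shrink
    r_sac <- d0 / 2
    r_airway <- max(0.15 * d0, 3 * sp)
    r_trachea <- 1.3 * r_airway
    wall <- max(2 * t_sep, 4 * sp)
    margin <- wall + 6 * sp
    n_up <- ceiling(spec$n_lobes / 2)
    n_lo <- spec$n_lobes - n_up
    ring_need <- function(k) if (k <= 1) 0.61 * (d0 + t_sep) else
      1.05 * (d0 + t_sep) / (2 * sin(pi / k))
    ring_r <- max(ring_need(n_up), ring_need(max(n_lo, 1)))
    L_tr <- max(0.8 * d0, 20 * sp)
    z_car <- margin + L_tr
    z_up <- z_car + 0.6 * d0
    # rings overlap in z (no sac-free slices between them); the angular
    # stagger keeps the 3D distance between inter-ring sac centres at
    # d0 + septum
    stagger <- if (n_lo > 0) 2 * ring_r * sin(pi / (2 * max(n_lo, n_up))) else 0
    dz_rings <- 1.02 * sqrt(max((d0 + t_sep)^2 - stagger^2, 0))
    dz_rings <- max(dz_rings, 0.35 * d0)
    z_lo <- z_up + dz_rings
    half_xy <- ring_r + r_sac + margin
    ext_z <- (if (n_lo > 0) z_lo else z_up) + r_sac + margin
    dims <- c(ceiling(ext_z / sp) + 1L, rep(ceiling(2 * half_xy / sp) + 1L, 2L))
    cyx <- c(half_xy, half_xy)

    ang_up <- (seq_len(n_up) - 1) * 2 * pi / n_up + pi / 2
    ang_lo <- if (n_lo > 0)
      (seq_len(n_lo) - 1) * 2 * pi / n_lo + pi / 2 + pi / max(n_lo, 1) else
      numeric(0)
    centers <- rbind(
      if (n_up > 0) cbind(z_up, cyx[1] + ring_r * sin(ang_up),
                          cyx[2] + ring_r * cos(ang_up)),
      if (n_lo > 0) cbind(z_lo, cyx[1] + ring_r * sin(ang_lo),
                          cyx[2] + ring_r * cos(ang_lo)))

    carina <- c(z_car, cyx)
    airways <- empty_mask_array(dims)
    airways <- paint_capsule(airways, c(margin, cyx), carina, r_trachea,
                             spacing)
    lung <- empty_mask_array(dims)
    lung <- paint_capsule(lung, c(margin, cyx), carina, r_trachea + wall,
                          spacing)
    sac_arr <- array(0L, dims)
    lobe_arr <- array(0L, dims)
    for (i in seq_len(spec$n_lobes)) {
      target <- centers[i, ]
      # tube path carina -> sac centre, optionally via jittered waypoints
      pts <- list(carina)
      gens <- spec$airway_generations
      if (gens > 1) {
        for (g in seq_len(gens - 1)) {
          frac <- g / gens
          base <- carina + frac * (target - carina)
          jit <- random_unit_vector() * 0.08 * d0
          pts[[length(pts) + 1L]] <- base + jit
        }
      }
      pts[[length(pts) + 1L]] <- target
      rr <- r_airway
      for (k in seq_len(length(pts) - 1L)) {
        airways <- paint_capsule(airways, pts[[k]], pts[[k + 1L]], rr, spacing)
        lung <- paint_capsule(lung, pts[[k]], pts[[k + 1L]], rr + wall,
                              spacing)
        rr <- max(rr * 0.85, 2 * sp)
      }
      sph <- paint_sphere(empty_mask_array(dims), target, r_sac, spacing)
      sac_arr[sph] <- i
      lobe_arr[sph] <- i
    }
    # the parenchyma is a contiguous tissue mass: fill each lobe ring with
    # an ellipsoid so air spaces are embedded in tissue, not thin shells
    if (n_up > 0)
      lung <- paint_ellipsoid(lung, c(z_up, cyx),
                              c(r_sac + wall,
                                rep(ring_r + r_sac + wall, 2)), spacing)
    if (n_lo > 0)
      lung <- paint_ellipsoid(lung, c(z_lo, cyx),
                              c(r_sac + wall,
                                rep(ring_r + r_sac + wall, 2)), spacing)

    sac_labels <- label_map(sac_arr, spacing)
    if (spec$subdivision_rounds > 0)
      sac_labels <- subdivide_sacs(sac_labels, spec$subdivision_rounds, t_sep)
    terminal <- labels_to_mask(sac_labels)
    # septation turned some sac voxels into tissue; airway lumina stay air
    tree_arr <- airways & !terminal$values
    lung <- lung | airways | (sac_arr > 0L)

    tree_mask <- voxel_mask(tree_arr, spacing)
    lung_mask <- voxel_mask(lung, spacing)
    entire <- voxel_mask(tree_arr | terminal$values, spacing)

    seed_vox <- c(round((margin + 0.3 * L_tr) / sp) + 1L,
                  round(cyx[1] / sp) + 1L, round(cyx[2] / sp) + 1L)

    gray <- render_gray(lung_mask, entire,
                        gray_air = spec$gray_air,
                        gray_tissue = spec$gray_tissue,
                        gray_background = spec$gray_background,
                        blur_sigma = spec$blur_sigma,
                        noise_sd = spec$noise_sd)
    gray$name <- paste0("phantom_", spec$stage_label)

    chord <- dense_chord_stats(terminal, lung_mask, other_mask = tree_mask,
                               n_sections = 8L, lines_per_section = 60L)

    structure(list(
      gray = gray,
      lung_mask = lung_mask,
      tree_mask = tree_mask,
      terminal_mask = terminal,
      sac_labels = sac_labels,
      lobe_labels = label_map(lobe_arr, spacing),
      true_VL = mask_volume(lung_mask),
      true_VA = mask_volume(terminal),
      true_SA = mask_surface_area(entire) - mask_surface_area(tree_mask),
      true_mean_diameter = chord$diameter_mean,
      true_mean_septum = chord$septum_mean,
      trachea_seed = seed_vox,
      spec = spec), class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(paste0("<phantom_truth> stage %s  dim %s  spacing %g um\n",
                     "  V_L %.4g mm^3  V_A %.4g mm^3  S_A %.4g mm^2\n",
                     "  intercept diameter %.3g um  septum %.3g um  sacs %d\n"),
              x$spec$stage_label, paste(dim(x$gray$values), collapse = "x"),
              x$spec$spacing, x$true_VL, x$true_VA, x$true_SA,
              x$true_mean_diameter, x$true_mean_septum,
              length(setdiff(unique(as.vector(x$sac_labels$values)), 0L))))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the gray volume and truth masks as NRRD plus a `truth.json` of
#' the scalar truth metrics.
#'
#' @param phantom a `phantom_truth`.
#' @param dir output directory (created if needed).
#' @return `invisible(dir)`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(phantom$gray, file.path(dir, "gray.nrrd"))
  write_mask(phantom$lung_mask, file.path(dir, "lung_mask.nrrd"))
  write_mask(phantom$tree_mask, file.path(dir, "tree_mask.nrrd"))
  write_mask(phantom$terminal_mask, file.path(dir, "terminal_mask.nrrd"))
  truth <- list(stage = phantom$spec$stage_label,
                true_VL_mm3 = phantom$true_VL,
                true_VA_mm3 = phantom$true_VA,
                true_SA_mm2 = phantom$true_SA,
                true_mean_diameter_um = phantom$true_mean_diameter,
                true_mean_septum_um = phantom$true_mean_septum,
                trachea_seed = phantom$trachea_seed,
                spacing_um = phantom$spec$spacing,
                rng_seed = phantom$spec$rng_seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
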