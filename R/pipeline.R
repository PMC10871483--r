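# End-to-end orchestration: phantom -> segmentation -> 3D metrics ->
# stereology, with a manifest so a run is fully specified by its
# configuration, plus the regression harness against the packaged
# specimen table.

#' Run the full morphometry pipeline on a phantom
#'
#' Generates (or accepts) a stage phantom, segments its air spaces by
#' seeded region growing from the trachea, splits tree and terminal air
#' spaces using the phantom truth tree, derives V_L, V_A and S_A, and runs
#' the line-intercept stereology on the segmented terminal air spaces.
#' A run is fully specified by its configuration; the same configuration
#' reproduces the same report bit for bit.
#'
#' @param config list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{stage}{stage label for the phantom (default `"neonate"`).}
#'     \item{seed}{global RNG seed; per-stage seeds are derived from it by
#'       fixed offsets (phantom +1, stereology +2).}
#'     \item{tolerance}{region-growing tolerance (default 1100).}
#'     \item{connectivity}{6, 18 or 26 (default 6).}
#'     \item{phantom}{optional named list of [phantom_spec()] overrides.}
#'     \item{stereology}{optional named list of [stereology_config()]
#'       overrides.}
#'     \item{out_dir}{optional output directory for masks and JSON
#'       reports.}
#'   }
#' @param phantom optionally a pre-built `phantom_truth` to analyse
#'   (overrides the phantom part of `config`).
#' @return list of class `pipeline_report` with `metrics` (V_L/V_A/S_A and
#'   recovery vs truth), `morphometry`, `truth`, `segmentation` log and
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), phantom = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- config$stage %||% "neonate"
  seed <- as.integer(config$seed %||% 1L)
  tolerance <- config$tolerance %||% 1100
  connectivity <- as.integer(config$connectivity %||% 6L)

  if (is.null(phantom)) {
    ph_args <- c(list(stage_label = stage, rng_seed = seed + 1L),
                 config$phantom)
    phantom <- do.call(phantom_spec, ph_args)
    phantom <- generate_stage_phantom(phantom)
  }

  cfg <- segmentation_config(seed = phantom$trachea_seed,
                             tolerance = tolerance,
                             connectivity = connectivity,
                             max_voxels = 0.9 * length(phantom$gray$values))
  seg <- segment_airspaces(phantom$gray, cfg,
                           tree_definition = phantom$tree_mask)

  metrics <- specimen_metrics(seg)

  st_args <- c(list(rng_seed = seed + 2L), config$stereology)
  st_cfg <- do.call(stereology_config, st_args)
  air <- if (st_cfg$use_entire_air) seg$entire_mask else seg$terminal_mask
  other <- if (st_cfg$use_entire_air) NULL else seg$tree_mask
  morpho <- measure_lung(air, seg$lung_mask, st_cfg, other_air_mask = other)

  truth_air <- voxel_mask(phantom$tree_mask$values |
                            phantom$terminal_mask$values,
                          phantom$tree_mask$spacing)
  inter <- sum(seg$entire_mask$values & truth_air$values)
  dice <- 2 * inter / (sum(seg$entire_mask$values) + sum(truth_air$values))

  report <- list(
    metrics = list(VL_mm3 = metrics$VL, VA_mm3 = metrics$VA,
                   SA_mm2 = metrics$SA,
                   SA_over_VA = metrics$SA / metrics$VA,
                   dice_vs_truth_air = dice,
                   VA_error_frac = abs(metrics$VA - phantom$true_VA) /
                     phantom$true_VA,
                   VL_error_frac = abs(metrics$VL - phantom$true_VL) /
                     phantom$true_VL),
    morphometry = list(
      diameter_mean_um = morpho$summary$diameter_mean,
      diameter_sd_um = morpho$summary$diameter_sd,
      septum_mean_um = morpho$summary$septum_mean,
      septum_sd_um = morpho$summary$septum_sd,
      n_chords = morpho$summary$n),
    truth = list(VL_mm3 = phantom$true_VL, VA_mm3 = phantom$true_VA,
                 SA_mm2 = phantom$true_SA,
                 diameter_um = phantom$true_mean_diameter,
                 septum_um = phantom$true_mean_septum),
    segmentation = seg$log,
    manifest = list(stage = stage, seed = seed, tolerance = tolerance,
                    connectivity = connectivity,
                    phantom_seed = seed + 1L, stereology_seed = seed + 2L,
                    spacing_um = phantom$spec$spacing,
                    package_version = as.character(
                      utils::packageVersion("lungmorph"))))
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phantom(phantom, file.path(config$out_dir, "phantom"))
    jsonlite::write_json(report[c("metrics", "truth", "segmentation",
                                  "manifest")],
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report$morphometry,
                         file.path(config$out_dir, "morpho.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(morpho$chords, file.path(config$out_dir, "chords.csv"),
              row.names = FALSE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_report> stage %s  seed %d\n",
                     "  V_L %.4g mm^3  V_A %.4g mm^3  S_A %.4g mm^2\n",
                     "  Dice vs truth air %.3f  V_A error %.1f%%\n",
                     "  diameter %.0f um  septum %.0f um  (%d chords)\n"),
              x$manifest$stage, x$manifest$seed,
              x$metrics$VL_mm3, x$metrics$VA_mm3, x$metrics$SA_mm2,
              x$metrics$dice_vs_truth_air, 100 * x$metrics$VA_error_frac,
              x$morphometry$diameter_mean_um, x$morphometry$septum_mean_um,
              x$morphometry$n_chords))
  invisible(x)
}

#' Recompute and check every summary statistic of the specimen table
#'
#' Recomputes every per-stage mean and SD from the packaged individual
#' records (round-half-up at the printed precision), the three body-mass
#' correlations in both conventions (raw and log10), the surface-area fold
#' change from birth to 14 dpn and the neonate surface area in cm^2, and
#' compares them against the published summary values.
#'
#' @param records optional specimen table (default: [load_table1()]).
#' @return list of class `table1_validation`: `cells` (data.frame of every
#'   group-summary cell with recomputed value, published value and match
#'   flag), `correlations` (data.frame with both conventions per metric),
#'   `derived` (fold changes etc.) and `all_means_match` /
#'   `all_cells_match` summaries.
#' @export
validate_against_table1 <- function(records = load_table1()) {
  printed <- read.csv(system.file("extdata", "table1_group_means.csv",
                                  package = "lungmorph", mustWork = TRUE),
                      stringsAsFactors = FALSE)
  fields <- names(table1_fields)
  cells <- list()
  for (i in seq_len(nrow(printed))) {
    g <- printed$age_label[i]
    for (f in fields) {
      key <- c(bw = "bw", diameter = "diam", septum = "septum",
               VL = "vl", VA = "va", SA = "sa")[[f]]
      pm <- printed[[paste0(key, "_mean")]][i]
      ps <- printed[[paste0(key, "_sd")]][i]
      if (is.na(pm)) next
      gs <- group_summary(records, f, g, rounded = TRUE)
      cells[[length(cells) + 1L]] <- data.frame(
        age_label = g, field = f,
        mean_calc = gs[["mean"]], mean_printed = pm,
        mean_match = isTRUE(gs[["mean"]] == pm),
        sd_calc = gs[["sd"]], sd_printed = ps,
        sd_match = isTRUE(gs[["sd"]] == ps),
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)

  printed_r <- c(VL = 0.987, VA = 0.915, SA = 0.971)
  corr <- do.call(rbind, lapply(names(printed_r), function(f) {
    raw <- correlation(records, f, "none")
    lg <- correlation(records, f, "log10")
    data.frame(field = f, r_printed = printed_r[[f]],
               r_raw = raw$r, r_log10 = lg$r,
               raw_matches = round_half_up(raw$r, 3) == printed_r[[f]],
               log10_matches = round_half_up(lg$r, 3) == printed_r[[f]],
               n = raw$n, stringsAsFactors = FALSE)
  }))

  derived <- list(
    neonate_SA_cm2 = round_half_up(
      group_summary(records, "SA", "neonate")[["mean"]] / 100, 3),
    d14_SA_cm2 = round_half_up(
      group_summary(records, "SA", "14dpn")[["mean"]] / 100, 3),
    SA_fold_neonate_to_14dpn = fold_change(records, "SA", "neonate", "14dpn"),
    BW_fold_neonate_to_adult = fold_change(records, "bw", "neonate", "adult"),
    VL_fold_neonate_to_adult = fold_change(records, "VL", "neonate", "adult"))

  structure(list(cells = cells,
                 correlations = corr,
                 derived = derived,
                 all_means_match = all(cells$mean_match),
                 all_cells_match = all(cells$mean_match & cells$sd_match),
                 pass = all(cells$mean_match) && all(corr$raw_matches)),
            class = "table1_validation")
}

#' @export
print.table1_validation <- function(x, ...) {
  bad <- x$cells[!(x$cells$mean_match & x$cells$sd_match), ]
  cat(sprintf("<table1_validation> %d cells checked, %d mismatching\n",
              nrow(x$cells), nrow(bad)))
  if (nrow(bad) > 0) print(bad, row.names = FALSE)
  cat("correlations:\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
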