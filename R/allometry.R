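# The packaged specimen table and the allometric analysis: group summary
# statistics, fold changes, body-mass correlations and double-logarithmic
# regressions of lung volume (V_L), terminal air-space volume (V_A) and
# air-space surface area (S_A).

table1_fields <- c(bw = "bw_g", diameter = "diam_um", septum = "septum_um",
                   VL = "vl_mm3", VA = "va_mm3", SA = "sa_mm2")

# digits each field is reported with in the per-stage summary
table1_digits <- c(bw = 2L, diameter = 0L, septum = 0L, VL = 2L, VA = 2L,
                   SA = 2L)

stage_order <- c("13dpc", "neonate", "4dpn", "7dpn", "11dpn", "14dpn",
                 "21dpn", "28dpn", "35dpn", "49dpn", "57dpn", "adult")

# md5 of the packaged CSV, guarding against silent corruption
table1_md5 <- "ab9dba753cf99f7536f42eaafe06f310"

#' Load the packaged per-specimen morphometry table
#'
#' One row per specimen: age group, body weight (g), line-intercept
#' air-space diameter and septum thickness (mean and SD, micrometres) and
#' the volumetric results V_L, V_A (mm^3) and S_A (mm^2). The four late
#' fetal specimens have no body weight, V_A or S_A. Group summary rows are
#' never stored; they are recomputed by [group_summary()].
#'
#' @param path optional CSV path (defaults to the packaged file).
#' @param verify_checksum verify the packaged file's md5 (default `TRUE`
#'   for the packaged file).
#' @return data.frame of 35 specimen records, age ordered.
#' @export
load_table1 <- function(path = NULL, verify_checksum = is.null(path)) {
  if (is.null(path))
    path <- system.file("extdata", "table1_individuals.csv",
                        package = "lungmorph", mustWork = TRUE)
  if (verify_checksum) {
    digest <- unname(tools::md5sum(path))
    if (!identical(digest, table1_md5))
      stop("packaged specimen table is corrupted (md5 mismatch: ",
           digest, ")")
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$age_label <- factor(d$age_label, levels = stage_order)
  if (anyNA(d$age_label)) stop("unknown age label in specimen table")
  d[order(d$age_label), , drop = FALSE]
}

resolve_field <- function(field) {
  if (field %in% names(table1_fields)) return(table1_fields[[field]])
  if (field %in% table1_fields) return(field)
  stop("unknown field: ", field, " (use one of ",
       paste(names(table1_fields), collapse = ", "), ")")
}

#' Group mean and SD for one age stage
#'
#' @param records specimen table from [load_table1()].
#' @param field one of `"bw"`, `"diameter"`, `"septum"`, `"VL"`, `"VA"`,
#'   `"SA"` (or a raw column name).
#' @param age_label the age stage.
#' @param rounded round (half-up) to the precision the field is reported
#'   with.
#' @return named numeric `c(mean =, sd =, n =)`; SD is the n-1 sample SD.
#' @export
group_summary <- function(records, field, age_label, rounded = FALSE) {
  col <- resolve_field(field)
  v <- records[[col]][records$age_label == age_label]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no values for ", field, " at ", age_label)
  m <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else NA_real_
  if (rounded) {
    d <- table1_digits[[if (field %in% names(table1_digits)) field else
      names(table1_fields)[table1_fields == col]]]
    m <- round_half_up(m, d)
    s <- round_half_up(s, d)
  }
  c(mean = m, sd = s, n = length(v))
}

#' Body-mass correlation of a lung metric
#'
#' Pearson correlation of body weight against the metric over the
#' individual postnatal specimens (the fetal records carry no body
#' weight), on raw values or after log10 transform of both variables. The
#' slope and intercept of the corresponding least-squares line are
#' returned with it.
#'
#' @param records specimen table.
#' @param field metric, as in [group_summary()].
#' @param transform `"none"` or `"log10"`.
#' @return object of class `regression_result`: `slope`, `intercept`, `r`,
#'   `n`, `transform`.
#' @export
correlation <- function(records, field, transform = c("none", "log10")) {
  transform <- match.arg(transform)
  col <- resolve_field(field)
  x <- records$bw_g
  y <- records[[col]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fewer than 3 paired values")
  if (transform == "log10") {
    if (any(x <= 0) || any(y <= 0)) stop("log10 needs positive values")
    x <- log10(x); y <- log10(y)
  }
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = stats::cor(x, y),
                 n = length(x),
                 transform = transform,
                 field = field),
            class = "regression_result")
}

#' Double-logarithmic (allometric) fit of a lung metric on body mass
#'
#' Least-squares line on `(log10 BW, log10 field)`; the slope is the
#' allometric exponent.
#'
#' @inheritParams correlation
#' @return a `regression_result` with `transform = "log10"`.
#' @export
loglog_fit <- function(records, field) correlation(records, field, "log10")

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> %s ~ BW (%s): slope %.4f  intercept %.4f  r %.4f  n %d\n",
    x$field, x$transform, x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Fold change of a group mean between two stages
#'
#' @param records specimen table.
#' @param field metric, as in [group_summary()].
#' @param age_from,age_to age stages; the result is
#'   `mean(age_to) / mean(age_from)`.
#' @return the ratio of group means.
#' @export
fold_change <- function(records, field, age_from, age_to) {
  from <- group_summary(records, field, age_from)[["mean"]]
  to <- group_summary(records, field, age_to)[["mean"]]
  if (from == 0) stop("zero denominator group mean")
  to / from
}

#' Log-log allometry plot with regression line
#'
#' @param records specimen table.
#' @param field metric, as in [group_summary()].
#' @param path output file (`.svg`, `.pdf` or `.png`).
#' @return `invisible(path)`.
#' @export
plot_allometry <- function(records, field, path) {
  col <- resolve_field(field)
  ok <- stats::complete.cases(records$bw_g, records[[col]])
  x <- records$bw_g[ok]; y <- records[[col]][ok]
  fit <- loglog_fit(records, field)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = 5, height = 5),
         pdf = grDevices::pdf(path, width = 5, height = 5),
         png = grDevices::png(path, width = 1000, height = 1000, res = 200),
         stop("unsupported figure format: ", ext))
  on.exit(grDevices::dev.off())
  graphics::plot(x, y, log = "xy", pch = 19, cex = 0.8,
                 xlab = "body mass (g)",
                 ylab = sprintf("%s", field),
                 main = sprintf("%s vs body mass (slope %.2f, r %.3f)",
                                field, fit$slope, fit$r))
  xs <- range(x)
  lines_x <- 10^seq(log10(xs[1]), log10(xs[2]), length.out = 50)
  graphics::lines(lines_x, 10^(fit$intercept + fit$slope * log10(lines_x)),
                  col = "firebrick", lwd = 2)
  invisible(path)
}
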