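#' @useDynLib lungmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd rnorm runif median aggregate lm coef complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

# Axis convention: arrays are indexed [z, y, x]; axis 1 (z) is the slice
# axis of the acquisition stack. Spacing is always carried in micrometres;
# volumes and surfaces are converted to mm^3 / mm^2 only in the metrics
# layer.

#' Construct a voxel grid
#'
#' A `voxel_grid` is the unit every imaging stage operates on: a 3D array of
#' gray values (16-bit semantics, 0--65535) together with the per-axis voxel
#' spacing in micrometres, in `(z, y, x)` axis order with `z` the slice axis.
#'
#' @param values 3D numeric array of gray values in `[0, 65535]`.
#' @param spacing numeric length-1 or length-3 voxel spacing in micrometres
#'   `(z, y, x)`; all components must be positive.
#' @param name optional free-text label.
#' @return An object of class `voxel_grid` with fields `values`, `spacing`
#'   and `name`.
#' @export
voxel_grid <- function(values, spacing, name = "") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (any(dim(values) < 1L))
    stop("all grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (micrometres)")
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 65535)
    stop("gray values must lie in [0, 65535]")
  structure(list(values = values, spacing = spacing, name = as.character(name)),
            class = "voxel_grid")
}

#' Construct a boolean mask aligned to a voxel grid
#'
#' @param values 3D logical array.
#' @param spacing voxel spacing in micrometres, as in [voxel_grid()].
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(values, spacing) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("'values' must be a 3D array")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask may not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (micrometres)")
  structure(list(values = values, spacing = spacing), class = "voxel_mask")
}

#' Construct a label map
#'
#' Label 0 is background; positive labels identify disjoint regions (e.g.
#' individual terminal air sacs or lung lobes).
#'
#' @param values 3D integer array of non-negative labels.
#' @param spacing voxel spacing in micrometres.
#' @param label_names optional named character vector mapping
#'   `"<label>" -> name`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(values, spacing, label_names = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("'values' must be a 3D array")
  storage.mode(values) <- "integer"
  if (anyNA(values) || min(values) < 0L)
    stop("labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(values = values, spacing = spacing,
                 label_names = label_names),
            class = "label_map")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s  dim %s  spacing %s um  gray [%g, %g]\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> dim %s  spacing %s um  foreground %d voxels\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> dim %s  spacing %s um  %d labels\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              length(setdiff(unique(as.vector(x$values)), 0L))))
  invisible(x)
}

#' Convert a label map to a mask of all labelled voxels
#' @param labels a [label_map()].
#' @return a [voxel_mask()] that is `TRUE` wherever the label is positive.
#' @export
labels_to_mask <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  voxel_mask(labels$values > 0L, labels$spacing)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grids/masks are not aligned: shapes differ")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("grids/masks are not aligned: spacings differ")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# File formats. TIFF (multi-page or slice-stack directory) carries no
# spacing, so it must be supplied explicitly -- all downstream quantities
# are spacing-dependent and a silent default would corrupt them. NRRD and
# MetaImage store spacing in their headers; MetaImage ElementSpacing is
# interpreted as millimetres (the usual MetaIO convention), NRRD spacings
# as micrometres unless the header declares other space units.

format_from_path <- function(path) {
  if (dir.exists(path)) return("tiff_stack")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "tif" = , "tiff" = "tiff",
         "nrrd" = "nrrd",
         "mhd" = "mha",
         stop("unrecognised volume format: ", path))
}

#' Read an image volume
#'
#' Supported formats: single multi-page TIFF, a directory of TIFF slices
#' (sorted by file name; slice index becomes axis 1), NRRD (raw encoding)
#' and MetaImage (`.mhd` + `.raw`). NRRD/MetaImage spacing metadata is
#' converted to micrometres. Plain TIFF carries no spacing, so `spacing`
#' must be given; supplying none is an error, never a silent default.
#'
#' @param path file (or slice directory) to read.
#' @param format_hint optional format override: `"tiff"`, `"tiff_stack"`,
#'   `"nrrd"` or `"mha"`.
#' @param spacing voxel spacing in micrometres, required for TIFF input.
#' @param name label for the returned grid (defaults to the file name).
#' @return a [voxel_grid()].
#' @export
read_volume <- function(path, format_hint = NULL, spacing = NULL,
                        name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (is.null(format_hint)) format_from_path(path) else format_hint
  out <- switch(fmt,
    tiff = read_tiff_volume(path),
    tiff_stack = read_tiff_stack(path),
    nrrd = read_nrrd(path),
    mha = read_mha(path),
    stop("unknown format: ", fmt))
  if (is.null(out$spacing)) {
    if (is.null(spacing))
      stop("format stores no voxel spacing; pass `spacing` (micrometres) explicitly")
    out$spacing <- spacing
  }
  voxel_grid(out$values, out$spacing, name = name)
}

#' Read a mask
#'
#' Reads a volume (any supported format) and thresholds at half the maximum
#' foreground encoding, so 0/255 TIFF masks and 0/1 NRRD masks both round
#' trip.
#'
#' @inheritParams read_volume
#' @return a [voxel_mask()].
#' @export
read_mask <- function(path, format_hint = NULL, spacing = NULL) {
  g <- read_volume(path, format_hint = format_hint, spacing = spacing)
  voxel_mask(g$values >= 127.5 | (g$values > 0 & max(g$values) <= 1),
             g$spacing)
}

#' Write an image volume
#'
#' TIFF output is 16-bit; NRRD and MetaImage store `uint16` raw data plus
#' the spacing metadata (micrometre / millimetre conventions as in
#' [read_volume()]).
#'
#' @param grid a [voxel_grid()].
#' @param path output file; for `format = "tiff_stack"` a directory.
#' @param format one of `"tiff"`, `"tiff_stack"`, `"nrrd"`, `"mha"`
#'   (default: from the file extension).
#' @return `invisible(path)`.
#' @export
write_volume <- function(grid, path, format = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  fmt <- if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) "tiff" else if (ext == "nrrd") "nrrd"
    else if (ext == "mhd") "mha" else stop("cannot infer format for ", path)
  } else format
  vals <- round(grid$values)
  switch(fmt,
    tiff = write_tiff_volume(vals, path, bits = 16L),
    tiff_stack = write_tiff_stack(vals, path, bits = 16L),
    nrrd = write_nrrd(vals, grid$spacing, path, type = "uint16"),
    mha = write_mha(vals, grid$spacing, path, type = "MET_USHORT"),
    stop("unknown format: ", fmt))
  invisible(path)
}

#' Write a mask
#'
#' Foreground is encoded as 255 and background as 0 for TIFF output
#' (8-bit); NRRD/MetaImage masks are written as `uint8` 0/1 with spacing
#' metadata, so the round trip preserves every voxel and the spacing.
#'
#' @param mask a [voxel_mask()].
#' @param path output file (or directory for `"tiff_stack"`).
#' @param format as in [write_volume()].
#' @return `invisible(path)`.
#' @export
write_mask <- function(mask, path, format = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  fmt <- if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) "tiff" else if (ext == "nrrd") "nrrd"
    else if (ext == "mhd") "mha" else stop("cannot infer format for ", path)
  } else format
  vals <- array(ifelse(mask$values, 255L, 0L), dim(mask$values))
  switch(fmt,
    tiff = write_tiff_volume(vals, path, bits = 8L),
    tiff_stack = write_tiff_stack(vals, path, bits = 8L),
    nrrd = write_nrrd(array(as.integer(mask$values), dim(mask$values)),
                      mask$spacing, path, type = "uint8"),
    mha = write_mha(array(as.integer(mask$values), dim(mask$values)),
                    mask$spacing, path, type = "MET_UCHAR"),
    stop("unknown format: ", fmt))
  invisible(path)
}

# -- TIFF -------------------------------------------------------------------

# tiff::readTIFF returns matrices indexed [row, col]; we map slice -> z,
# row -> y, col -> x.
read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice shapes in TIFF stack")
  nz <- length(pages); ny <- shapes[1, 1]; nx <- shapes[2, 1]
  vals <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) vals[i, , ] <- pages[[i]]
  list(values = vals, spacing = NULL)
}

read_tiff_stack <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no TIFF slices in ", path)
  pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice shapes in TIFF slice stack")
  nz <- length(pages); ny <- shapes[1, 1]; nx <- shapes[2, 1]
  vals <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) vals[i, , ] <- pages[[i]]
  list(values = vals, spacing = NULL)
}

write_tiff_volume <- function(vals, path, bits) {
  maxv <- if (bits == 16L) 65535 else 255
  pages <- lapply(seq_len(dim(vals)[1]),
                  function(i) matrix(vals[i, , ] / maxv,
                                     nrow = dim(vals)[2], ncol = dim(vals)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
}

write_tiff_stack <- function(vals, path, bits) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  maxv <- if (bits == 16L) 65535 else 255
  nz <- dim(vals)[1]
  for (i in seq_len(nz)) {
    f <- file.path(path, sprintf("slice_%05d.tif", i))
    tiff::writeTIFF(matrix(vals[i, , ] / maxv,
                           nrow = dim(vals)[2], ncol = dim(vals)[3]),
                    f, bits.per.sample = bits, compression = "none")
  }
}

# -- NRRD (raw encoding, little endian) -------------------------------------

nrrd_dtypes <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "double",  size = 4L, signed = TRUE),
  double = list(what = "double",  size = 8L, signed = TRUE))

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*", fixed = FALSE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  type <- sub("^unsigned char$", "uint8",
          sub("^unsigned short$", "uint16", tolower(fields[["type"]])))
  dt <- nrrd_dtypes[[type]]
  if (is.null(dt)) stop("unsupported NRRD type: ", fields[["type"]])
  enc <- tolower(fields[["encoding"]])
  if (enc != "raw") stop("only raw NRRD encoding is supported")
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  spacing <- NULL
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
  unit_scale <- 1
  if (!is.null(fields[["space units"]])) {
    u <- gsub('"', "", strsplit(trimws(fields[["space units"]]), "\\s+")[[1]][1])
    unit_scale <- switch(tolower(u),
                         "mm" = 1000, "millimeter" = 1000,
                         "um" = 1, "micron" = 1, "micrometer" = 1,
                         "cm" = 10000,
                         stop("unsupported NRRD space unit: ", u))
  }
  n <- prod(sizes)
  raw <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                 endian = "little")
  if (length(raw) != n) stop("truncated NRRD data")
  # NRRD lists sizes fastest axis first; our fastest axis is z.
  vals <- array(as.numeric(raw), dim = sizes)
  sp <- if (is.null(spacing)) NULL else spacing * unit_scale
  if (any(!is.null(sp)) && any(sp <= 0)) stop("non-positive NRRD spacing")
  list(values = vals, spacing = sp)
}

write_nrrd <- function(vals, spacing_um, path, type = "uint16") {
  dt <- nrrd_dtypes[[type]]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(vals), collapse = " ")),
           paste0("spacings: ", paste(format(spacing_um, scientific = FALSE),
                                      collapse = " ")),
           'space units: "um" "um" "um"',
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
}

# -- MetaImage (.mhd header + .raw data) ------------------------------------

read_mha <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (line in lines) {
    parts <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  sizes <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1]])
  type <- kv[["ElementType"]]
  dt <- switch(type,
               MET_UCHAR = nrrd_dtypes$uint8,
               MET_USHORT = nrrd_dtypes$uint16,
               MET_SHORT = nrrd_dtypes$int16,
               MET_FLOAT = nrrd_dtypes$float,
               MET_DOUBLE = nrrd_dtypes$double,
               stop("unsupported MetaImage ElementType: ", type))
  spacing <- if (!is.null(kv[["ElementSpacing"]]))
    as.numeric(strsplit(kv[["ElementSpacing"]], "\\s+")[[1]]) * 1000 else NULL
  datafile <- kv[["ElementDataFile"]]
  if (is.null(datafile) || identical(datafile, "LOCAL"))
    stop("only separate-raw MetaImage files are supported")
  rawpath <- file.path(dirname(path), datafile)
  con <- file(rawpath, "rb")
  on.exit(close(con))
  n <- prod(sizes)
  raw <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                 endian = "little")
  if (length(raw) != n) stop("truncated MetaImage data")
  list(values = array(as.numeric(raw), dim = sizes), spacing = spacing)
}

write_mha <- function(vals, spacing_um, path, type = "MET_USHORT") {
  rawname <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste0("DimSize = ", paste(dim(vals), collapse = " ")),
           paste0("ElementSpacing = ",
                  paste(format(spacing_um / 1000, scientific = FALSE),
                        collapse = " ")),
           paste0("ElementType = ", type),
           paste0("ElementDataFile = ", rawname))
  writeLines(hdr, path)
  size <- if (type == "MET_UCHAR") 1L else 2L
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(as.integer(round(vals)), con, size = size, endian = "little")
}
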