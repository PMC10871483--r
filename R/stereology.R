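# Fractionator sampling and line-intercept morphometry.
#
# The protocol mirrors manual on-screen morphometry: the lung's slice range
# is divided into a fixed number of systematic uniform random sections
# (interval = floor(length / n), random start), a line is cast at a uniform
# random position and angle over each sampled section, and the first few
# air-space and septum intercepts along the line are measured. A chord is a
# maximal run along the line: an air chord is a run of air bounded by
# tissue on both sides; a septum chord is a run of tissue bounded by air on
# both sides (so pleural or hilar tissue is never counted as a septum).

#' Stereology configuration
#'
#' Defaults reproduce the study protocol: 8 systematic sections with 5 air
#' and 5 septum intercepts each, i.e. 40 measurements per lung.
#'
#' @param n_sections number of systematically sampled sections.
#' @param air_chords_per_section air intercepts measured per section.
#' @param septum_chords_per_section septum intercepts measured per section.
#' @param rng_seed seed for section start, line positions and angles.
#' @param max_line_retries lines cast per section before giving up.
#' @param use_entire_air measure on the entire air lumen instead of the
#'   terminal air spaces only (default `FALSE`).
#' @return an object of class `stereology_config`.
#' @export
stereology_config <- function(n_sections = 8L,
                              air_chords_per_section = 5L,
                              septum_chords_per_section = 5L,
                              rng_seed = 1L,
                              max_line_retries = 100L,
                              use_entire_air = FALSE) {
  stopifnot(n_sections >= 1L, air_chords_per_section >= 0L,
            septum_chords_per_section >= 0L, max_line_retries >= 1L)
  structure(list(n_sections = as.integer(n_sections),
                 air_chords_per_section = as.integer(air_chords_per_section),
                 septum_chords_per_section = as.integer(septum_chords_per_section),
                 rng_seed = as.integer(rng_seed),
                 max_line_retries = as.integer(max_line_retries),
                 use_entire_air = isTRUE(use_entire_air)),
            class = "stereology_config")
}

#' Systematic uniform random section selection
#'
#' The sampling interval is `k = floor(n_slices / n_sections)`; a random
#' start is drawn uniformly from the first interval and every k-th slice is
#' taken until `n_sections` sections are selected. Slice indices are
#' 1-based.
#'
#' @param n_slices number of slices available (the length of the lung in
#'   slices).
#' @param cfg a [stereology_config()].
#' @param start optional fixed 0-based start within `[0, k)`; drawn from
#'   the current RNG when `NULL`.
#' @return integer vector of `n_sections` slice indices (1-based).
#' @export
select_sections <- function(n_slices, cfg = stereology_config(),
                            start = NULL) {
  n <- cfg$n_sections
  if (n_slices < n)
    stop("fewer slices (", n_slices, ") than sections (", n, ")")
  k <- floor(n_slices / n)
  if (is.null(start)) start <- sample.int(k, 1L) - 1L
  if (start < 0 || start >= k) stop("start must lie in [0, k)")
  idx <- start + k * (seq_len(n) - 1L) + 1L
  idx[idx <= n_slices]
}

#' Cast a random test line over a section
#'
#' Draws a uniform angle in `[0, pi)` and a uniform perpendicular offset
#' across the section, i.e. an isotropic uniform random (IUR) test line.
#' Offset-uniform casting makes line-intercept sampling length-unbiased:
#' throwing a line through a uniform random point instead concentrates
#' lines near the section centre and systematically shortens the sampled
#' intercepts.
#'
#' @param section_dim dimensions `(ny, nx)` of the section in voxels.
#' @param spacing_yx voxel spacing `(y, x)` in micrometres.
#' @return list with `point` (micrometre coordinates `(y, x)` of a point
#'   on the line) and `angle` (uniform in `[0, pi)`); degenerate
#'   single-row sections give a horizontal line.
#' @export
cast_line <- function(section_dim, spacing_yx = c(1, 1)) {
  ext <- (section_dim - 1) * spacing_yx
  angle <- if (section_dim[1] <= 1L) 0 else runif(1, 0, pi)
  nrm <- c(cos(angle), -sin(angle))
  half_w <- (abs(nrm[1]) * ext[1] + abs(nrm[2]) * ext[2]) / 2
  offset <- runif(1, -half_w, half_w)
  point <- ext / 2 + offset * nrm
  list(point = point, angle = angle)
}

# Sample class codes along a line through a section.
# Classes: 0 background, 1 measured air, 2 tissue, 3 other air (e.g. the
# conducting tree when measuring terminal air spaces only).
sample_line_classes <- function(air_sl, lung_sl, other_sl, spacing_yx,
                                point, angle, step) {
  dims <- dim(air_sl)
  ext <- (dims - 1) * spacing_yx
  dirv <- c(sin(angle), cos(angle))
  diag_len <- sqrt(sum(ext^2)) + 2 * step
  ts <- seq(-diag_len, diag_len, by = step)
  py <- point[1] + ts * dirv[1]
  px <- point[2] + ts * dirv[2]
  iy <- round(py / spacing_yx[1]) + 1L
  ix <- round(px / spacing_yx[2]) + 1L
  ok <- iy >= 1L & iy <= dims[1] & ix >= 1L & ix <= dims[2]
  cls <- integer(length(ts))            # background outside the section
  if (any(ok)) {
    lin <- cbind(iy[ok], ix[ok])
    a <- air_sl[lin]
    l <- lung_sl[lin]
    o <- if (is.null(other_sl)) rep(FALSE, nrow(lin)) else other_sl[lin]
    cls[ok] <- ifelse(a, 1L, ifelse(o, 3L, ifelse(l, 2L, 0L)))
  }
  cls
}

#' Measure intercepts along one line
#'
#' Samples the masks along the line at a sub-voxel step
#' (`min(spacing) / 4`) and extracts maximal runs: air chords are runs of
#' the measured air mask bounded by tissue on both sides; septum chords are
#' tissue runs bounded by measured air on both sides. Runs touching the
#' section border, background, or non-measured air are discarded as
#' clipped.
#'
#' @param air_section 2D logical matrix of the measured air mask.
#' @param lung_section 2D logical matrix of the lung outline.
#' @param line a line as returned by [cast_line()].
#' @param spacing_yx voxel spacing `(y, x)` in micrometres.
#' @param other_section optional 2D logical matrix of air that must not be
#'   measured (e.g. the conducting tree).
#' @param min_chord_um smallest intercept recorded (default two voxels,
#'   the resolvability floor): grazing lines otherwise flicker across a
#'   profile rim and shed sub-voxel fragments no observer would record.
#' @return data.frame with columns `length_um` and `kind`
#'   (`"air"`/`"septum"`) in the order encountered along the line.
#' @export
line_intercepts <- function(air_section, lung_section, line,
                            spacing_yx = c(1, 1), other_section = NULL,
                            min_chord_um = 2 * max(spacing_yx)) {
  step <- min(spacing_yx) / 4
  cls <- sample_line_classes(air_section, lung_section, other_section,
                             spacing_yx, line$point, line$angle, step)
  r <- rle(cls)
  n <- length(r$values)
  out_len <- numeric(0)
  out_kind <- character(0)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      v <- r$values[i]
      left <- r$values[i - 1]; right <- r$values[i + 1]
      len <- r$lengths[i] * step
      if (len < min_chord_um) next
      if (v == 1L && left == 2L && right == 2L) {
        out_len <- c(out_len, len)
        out_kind <- c(out_kind, "air")
      } else if (v == 2L && left == 1L && right == 1L) {
        out_len <- c(out_len, len)
        out_kind <- c(out_kind, "septum")
      }
    }
  }
  data.frame(length_um = out_len, kind = out_kind,
             stringsAsFactors = FALSE)
}

collect_section_chords <- function(air_sl, lung_sl, other_sl, spacing_yx,
                                   n_air, n_septum, max_lines,
                                   take_all = FALSE) {
  got_air <- numeric(0); got_sep <- numeric(0)
  lines_cast <- 0L
  air_line <- integer(0); sep_line <- integer(0)
  while (lines_cast < max_lines &&
         (take_all || length(got_air) < n_air ||
          length(got_sep) < n_septum)) {
    lines_cast <- lines_cast + 1L
    ln <- cast_line(dim(air_sl), spacing_yx)
    ch <- line_intercepts(air_sl, lung_sl, ln, spacing_yx, other_sl)
    if (nrow(ch) == 0L) next
    if (take_all) {
      got_air <- c(got_air, ch$length_um[ch$kind == "air"])
      got_sep <- c(got_sep, ch$length_um[ch$kind == "septum"])
      air_line <- c(air_line, rep(lines_cast, sum(ch$kind == "air")))
      sep_line <- c(sep_line, rep(lines_cast, sum(ch$kind == "septum")))
    } else {
      a <- ch$length_um[ch$kind == "air"]
      s <- ch$length_um[ch$kind == "septum"]
      need_a <- n_air - length(got_air)
      need_s <- n_septum - length(got_sep)
      take_a <- utils::head(a, max(need_a, 0))
      take_s <- utils::head(s, max(need_s, 0))
      got_air <- c(got_air, take_a)
      got_sep <- c(got_sep, take_s)
      air_line <- c(air_line, rep(lines_cast, length(take_a)))
      sep_line <- c(sep_line, rep(lines_cast, length(take_s)))
    }
    if (take_all && lines_cast >= max_lines) break
  }
  list(air = got_air, septum = got_sep,
       air_line = air_line, septum_line = sep_line,
       complete = take_all ||
         (length(got_air) >= n_air && length(got_sep) >= n_septum))
}

#' Fractionator line-intercept morphometry of a lung
#'
#' Runs [select_sections()] over the slice range occupied by the lung (the
#' "length of the lung"), casts random lines over each sampled section and
#' collects the configured number of air-space and septum intercepts
#' (first valid chords along each line). With the default configuration
#' this yields exactly 8 x (5 + 5) = 40 measurements.
#'
#' @param air_mask [voxel_mask()] of the air spaces to measure (terminal
#'   air spaces by default; see `use_entire_air` in
#'   [stereology_config()]).
#' @param lung_mask [voxel_mask()] of the lung outline.
#' @param cfg a [stereology_config()].
#' @param other_air_mask optional mask of air excluded from measurement
#'   (the conducting tree when measuring terminal air spaces).
#' @return list with `chords` (data.frame: `length_um`, `kind`, `section`,
#'   `line`) and `summary` (class `morphometry_summary`: mean and n-1
#'   sample SD per kind plus counts).
#' @export
measure_lung <- function(air_mask, lung_mask, cfg = stereology_config(),
                         other_air_mask = NULL) {
  check_aligned(air_mask, lung_mask)
  spacing <- lung_mask$spacing
  # the sampled span is the slice range containing measurable air spaces;
  # for a real lung this is the length of the lung, and it keeps sections
  # off any purely conducting (e.g. tracheal) span of the stack
  occupied <- which(apply(air_mask$values, 1, any))
  if (length(occupied) == 0L) stop("air mask is empty")
  zr <- occupied[1]:occupied[length(occupied)]
  with_seed(cfg$rng_seed, {
    secs <- select_sections(length(zr), cfg)
    slices <- zr[secs]
    chords <- list()
    k <- max(floor(length(zr) / cfg$n_sections), 1L)
    for (si in seq_along(slices)) {
      # a section with too little measurable lung (e.g. grazing the organ
      # pole) is refocused to the nearest workable slice, as an observer
      # would; the systematic position is preserved up to a few slices
      offsets <- c(0L, as.vector(rbind(seq_len(k), -seq_len(k))))
      res <- NULL
      z <- slices[si]
      for (o in offsets) {
        zo <- slices[si] + o
        if (zo < zr[1] || zo > zr[length(zr)]) next
        air_sl <- air_mask$values[zo, , ]
        if (!any(air_sl)) next
        lung_sl <- lung_mask$values[zo, , ]
        other_sl <- if (is.null(other_air_mask)) NULL else
          other_air_mask$values[zo, , ]
        cand <- collect_section_chords(air_sl, lung_sl, other_sl,
                                       spacing[2:3],
                                       cfg$air_chords_per_section,
                                       cfg$septum_chords_per_section,
                                       cfg$max_line_retries)
        if (cand$complete) { res <- cand; z <- zo; break }
      }
      if (is.null(res))
        stop("line retries exhausted on section ", slices[si],
             ": lung too small or empty for the requested chord counts")
      chords[[si]] <- data.frame(
        length_um = c(res$air, res$septum),
        kind = c(rep("air", length(res$air)),
                 rep("septum", length(res$septum))),
        section = z,
        line = c(res$air_line, res$septum_line),
        stringsAsFactors = FALSE)
    }
    chords <- do.call(rbind, chords)
    air_len <- chords$length_um[chords$kind == "air"]
    sep_len <- chords$length_um[chords$kind == "septum"]
    summary <- structure(list(
      diameter_mean = mean(air_len),
      diameter_sd = stats::sd(air_len),
      septum_mean = if (length(sep_len)) mean(sep_len) else NA_real_,
      septum_sd = if (length(sep_len) > 1) stats::sd(sep_len) else NA_real_,
      n = nrow(chords),
      n_air = length(air_len),
      n_septum = length(sep_len)), class = "morphometry_summary")
    list(chords = chords, summary = summary)
  })
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf(paste0("<morphometry_summary> n = %d\n",
                     "  air-space diameter %.1f (+/- %.1f) um  [n = %d]\n",
                     "  septum thickness   %.1f (+/- %.1f) um  [n = %d]\n"),
              x$n, x$diameter_mean, x$diameter_sd, x$n_air,
              x$septum_mean, x$septum_sd, x$n_septum))
  invisible(x)
}

# Dense deterministic-RNG chord statistics used for phantom ground truth:
# the large-sample limit of the measurement protocol (many lines per
# section, every valid chord kept, sections weighted equally as in the
# 5-per-section protocol).
dense_chord_stats <- function(air_mask, lung_mask, other_mask = NULL,
                              n_sections = 24L, lines_per_section = 60L) {
  spacing <- lung_mask$spacing
  occupied <- which(apply(air_mask$values, 1, any))
  zr <- occupied[1]:occupied[length(occupied)]
  secs <- select_sections(length(zr),
                          stereology_config(n_sections = n_sections))
  slices <- zr[secs]
  air_means <- numeric(0); sep_means <- numeric(0)
  n_air <- 0L; n_sep <- 0L
  for (z in slices) {
    res <- collect_section_chords(air_mask$values[z, , ],
                                  lung_mask$values[z, , ],
                                  if (is.null(other_mask)) NULL else
                                    other_mask$values[z, , ],
                                  spacing[2:3], 0L, 0L,
                                  lines_per_section, take_all = TRUE)
    if (length(res$air)) {
      air_means <- c(air_means, mean(res$air))
      n_air <- n_air + length(res$air)
    }
    if (length(res$septum)) {
      sep_means <- c(sep_means, mean(res$septum))
      n_sep <- n_sep + length(res$septum)
    }
  }
  list(diameter_mean = mean(air_means), septum_mean = mean(sep_means),
       n_air = n_air, n_septum = n_sep)
}
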