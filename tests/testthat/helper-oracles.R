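# Independent oracles and shared fixtures.

# Reference flood fill, deliberately implemented differently from the
# package (synchronous frontier expansion by array shifts, not a BFS
# queue), for equivalence testing of the region grower.
oracle_flood_fill <- function(vals, seed, lo, hi, connectivity = 6L) {
  d <- dim(vals)
  in_band <- vals >= lo & vals <= hi
  mask <- array(FALSE, d)
  if (!in_band[seed[1], seed[2], seed[3]]) return(mask)
  mask[seed[1], seed[2], seed[3]] <- TRUE
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  keep <- if (connectivity == 6L) m == 1 else if (connectivity == 18L)
    m >= 1 & m <= 2 else m >= 1
  offs <- offs[keep, ]
  shift_arr <- function(a, o) {
    out <- array(FALSE, d)
    zs <- seq_len(d[1]) - o[1]; ys <- seq_len(d[2]) - o[2]
    xs <- seq_len(d[3]) - o[3]
    okz <- zs >= 1 & zs <= d[1]; oky <- ys >= 1 & ys <= d[2]
    okx <- xs >= 1 & xs <= d[3]
    out[okz, oky, okx] <- a[zs[okz], ys[oky], xs[okx]]
    out
  }
  repeat {
    grown <- mask
    for (i in seq_len(nrow(offs)))
      grown <- grown | shift_arr(mask, as.integer(offs[i, ]))
    grown <- grown & in_band
    if (identical(grown, mask)) break
    mask <- grown
  }
  mask
}

# Vertical stripe section: air columns of width `air_px`, tissue walls of
# width `tissue_px`, everything inside the lung.
stripe_section <- function(ny, nx, air_px, tissue_px) {
  period <- air_px + tissue_px
  xcol <- ((seq_len(nx) - 1) %% period) < air_px
  air <- matrix(rep(xcol, each = ny), ny, nx)
  lung <- matrix(TRUE, ny, nx)
  list(air = air, lung = lung)
}

# Stage phantoms and pipeline runs are expensive; build each once per test
# session and share across files.
.fixture_env <- new.env(parent = emptyenv())

cached_phantom <- function(stage, seed = 5L) {
  key <- paste0("phantom_", stage, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_stage_phantom(
      phantom_spec(stage, rng_seed = seed + 1L))
  .fixture_env[[key]]
}

cached_pipeline <- function(stage, seed = 5L) {
  key <- paste0("pipeline_", stage, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_pipeline(list(stage = stage, seed = seed),
                                        phantom = cached_phantom(stage, seed))
  .fixture_env[[key]]
}

# small, fast phantom for structural/determinism tests
tiny_spec <- function(rng_seed = 1L, rounds = 0L) {
  phantom_spec("neonate", sac_diameter_target = 150,
               septum_thickness_target = 30, subdivision_rounds = rounds,
               spacing = 12, rng_seed = rng_seed)
}
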