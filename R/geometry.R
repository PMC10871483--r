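# Internal geometry / numeric helpers. All coordinates in micrometres;
# voxel centres sit at (index - 1) * spacing along each axis.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

axis_coords <- function(dims, spacing) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
}

empty_mask_array <- function(dims) array(FALSE, dims)

# subscript ranges of the bounding box of a ball/segment, clipped to grid
bbox_range <- function(lo_um, hi_um, dims, spacing) {
  lo <- pmax(1L, floor(lo_um / spacing) + 1L)
  hi <- pmin(dims, ceiling(hi_um / spacing) + 1L)
  if (any(lo > hi)) NULL else list(lo = lo, hi = hi)
}

# Paint a solid sphere into a logical array (in place semantics via return).
paint_sphere <- function(arr, center, radius, spacing) {
  dims <- dim(arr)
  bb <- bbox_range(center - radius, center + radius, dims, spacing)
  if (is.null(bb)) return(arr)
  iz <- bb$lo[1]:bb$hi[1]; iy <- bb$lo[2]:bb$hi[2]; ix <- bb$lo[3]:bb$hi[3]
  dz2 <- ((iz - 1) * spacing[1] - center[1])^2
  dy2 <- ((iy - 1) * spacing[2] - center[2])^2
  dx2 <- ((ix - 1) * spacing[3] - center[3])^2
  sub <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= radius^2
  arr[iz, iy, ix] <- arr[iz, iy, ix] | sub
  arr
}

# Solid capsule (cylinder with hemispherical caps) from p1 to p2.
paint_capsule <- function(arr, p1, p2, radius, spacing) {
  dims <- dim(arr)
  lo <- pmin(p1, p2) - radius
  hi <- pmax(p1, p2) + radius
  bb <- bbox_range(lo, hi, dims, spacing)
  if (is.null(bb)) return(arr)
  iz <- bb$lo[1]:bb$hi[1]; iy <- bb$lo[2]:bb$hi[2]; ix <- bb$lo[3]:bb$hi[3]
  cz <- (iz - 1) * spacing[1]; cy <- (iy - 1) * spacing[2]
  cx <- (ix - 1) * spacing[3]
  nz <- length(cz); ny <- length(cy); nx <- length(cx)
  Z <- array(cz, c(nz, ny, nx))
  Y <- array(rep(cy, each = nz), c(nz, ny, nx))
  X <- array(rep(cx, each = nz * ny), c(nz, ny, nx))
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) return(paint_sphere(arr, p1, radius, spacing))
  t <- ((Z - p1[1]) * d[1] + (Y - p1[2]) * d[2] + (X - p1[3]) * d[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  qz <- p1[1] + t * d[1]; qy <- p1[2] + t * d[2]; qx <- p1[3] + t * d[3]
  sub <- (Z - qz)^2 + (Y - qy)^2 + (X - qx)^2 <= radius^2
  arr[iz, iy, ix] <- arr[iz, iy, ix] | sub
  arr
}

# Finite cylinder (flat caps) along +z from z0 to z0+len, for calibration.
paint_cylinder_z <- function(arr, center_yx, z0, len, radius, spacing) {
  dims <- dim(arr)
  bb <- bbox_range(c(z0, center_yx - radius),
                   c(z0 + len, center_yx + radius), dims, spacing)
  if (is.null(bb)) return(arr)
  iz <- bb$lo[1]:bb$hi[1]; iy <- bb$lo[2]:bb$hi[2]; ix <- bb$lo[3]:bb$hi[3]
  cz <- (iz - 1) * spacing[1]
  dy2 <- ((iy - 1) * spacing[2] - center_yx[1])^2
  dx2 <- ((ix - 1) * spacing[3] - center_yx[2])^2
  inz <- cz >= z0 & cz <= z0 + len
  sub <- outer(outer(inz, dy2, function(a, b) ifelse(a, b, Inf)), dx2, `+`) <=
    radius^2
  arr[iz, iy, ix] <- arr[iz, iy, ix] | sub
  arr
}

# Gaussian blur of a numeric array, sigma in micrometres per axis.
blur3d <- function(arr, sigma_um, spacing) {
  if (all(sigma_um <= 0)) return(arr)
  sig_vox <- sigma_um / spacing
  out <- cpp_blur3d(as.numeric(arr), dim(arr), as.numeric(sig_vox))
  array(out, dim(arr))
}

linear_index <- function(idx, dims) {
  # 1-based (z,y,x) subscript -> 0-based linear index
  (idx[1] - 1L) + dims[1] * ((idx[2] - 1L) + dims[2] * (idx[3] - 1L))
}

# uniform random unit vector (z,y,x)
random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Solid axis-aligned ellipsoid.
paint_ellipsoid <- function(arr, center, semi, spacing) {
  dims <- dim(arr)
  bb <- bbox_range(center - semi, center + semi, dims, spacing)
  if (is.null(bb)) return(arr)
  iz <- bb$lo[1]:bb$hi[1]; iy <- bb$lo[2]:bb$hi[2]; ix <- bb$lo[3]:bb$hi[3]
  dz2 <- (((iz - 1) * spacing[1] - center[1]) / semi[1])^2
  dy2 <- (((iy - 1) * spacing[2] - center[2]) / semi[2])^2
  dx2 <- (((ix - 1) * spacing[3] - center[3]) / semi[3])^2
  sub <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
  arr[iz, iy, ix] <- arr[iz, iy, ix] | sub
  arr
}
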