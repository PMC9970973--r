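#' Re-order a plane-major frame sequence into a hyperstack
#'
#' The camera records `N = Z x T` frames, plane-major within each volume:
#' volume `t` consists of frames `(t-1)*Z + 1 ... t*Z`. No pixel values are
#' altered.
#'
#' @param frames `[row, col, N]` array (or list of matrices).
#' @param z_planes Number of planes `Z` per volume.
#' @param geometry Optional [acquisition_geometry()] stored on the result.
#' @return Object of class `hyperstack` with `data` indexed
#'   `[row, col, z, t]`, `n_planes` and `n_volumes`.
#' @export
deinterleave <- function(frames, z_planes, geometry = NULL) {
  fr <- as_frames(frames)
  n <- dim(fr)[3]
  if (n %% z_planes != 0)
    stop("frame count N = ", n, " is not a multiple of Z = ", z_planes)
  nt <- n %/% z_planes
  structure(list(data = array(fr, dim = c(dim(fr)[1:2], z_planes, nt)),
                 geometry = geometry, n_planes = as.integer(z_planes),
                 n_volumes = as.integer(nt)),
            class = "hyperstack")
}

#' @export
print.hyperstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hyperstack: %d x %d pixels, Z=%d planes, T=%d volumes\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Crop a hyperstack to the slit field of view
#'
#' The same rectangular crop (1-based inclusive row/col ranges) is applied
#' to every plane and timepoint, removing the dark border outside the field
#' slit.
#'
#' @param hs A `hyperstack`.
#' @param bounds `list(row = c(first, last), col = c(first, last))`, e.g.
#'   from [slit_bounds()] or [auto_slit_bounds()].
#' @return Cropped `hyperstack`.
#' @export
crop_to_slit <- function(hs, bounds) {
  d <- dim(hs$data)
  r <- bounds$row; cc <- bounds$col
  if (r[1] < 1 || r[2] > d[1] || cc[1] < 1 || cc[2] > d[2] ||
      r[1] > r[2] || cc[1] > cc[2])
    stop("crop bounds outside frame or empty")
  hs$data <- hs$data[r[1]:r[2], cc[1]:cc[2], , , drop = FALSE]
  hs
}

#' Estimate the slit bounds from the temporal-mean image
#'
#' Thresholds the mean image (over planes and time) halfway between its
#' minimum and maximum and returns the bounding box of the bright region.
#' Intended to be run on the CMO channel, whose static signal fills the
#' slit.
#'
#' @param x A `hyperstack` or `[row, col, frame]` array.
#' @return `list(row = , col = )` 1-based inclusive bounds.
#' @export
auto_slit_bounds <- function(x) {
  img <- if (inherits(x, "hyperstack")) rowMeans(x$data, dims = 2)
  else rowMeans(as_frames(x), dims = 2)
  thr <- (max(img) + min(img)) / 2
  on <- img > thr
  rows <- which(rowSums(on) > 0); cols <- which(colSums(on) > 0)
  if (!length(rows)) stop("no bright region found")
  list(row = c(min(rows), max(rows)), col = c(min(cols), max(cols)))
}

# output lab grid of the transformed stack: 0-based integer voxel positions
# spanning the axis-aligned bounding box of the rotated, rescaled input grid
lab_grid <- function(d, geometry) {
  s <- geometry$dz_prime / geometry$px_sample
  corners <- as.matrix(expand.grid(x = c(0, d[2] - 1), y = c(0, d[1] - 1),
                                   k = c(0, d[3] - 1)))
  lab <- stack_to_lab(corners, geometry) / geometry$px_sample
  lo <- floor(apply(lab, 2, min)); hi <- ceiling(apply(lab, 2, max))
  list(origin = lo, nx = hi[1] - lo[1] + 1, ny = hi[2] - lo[2] + 1,
       nz = hi[3] - lo[3] + 1, scale = s)
}

#' Transform one volume of a hyperstack into lab coordinates
#'
#' Maps the sheared acquisition grid (plane `k` at depth `k * dz'` along the
#' detection axis, tilted `theta_ls` from vertical) onto an isotropic
#' lab-frame grid at the lateral pixel size: axial rescale by
#' `dz' / px_sample` followed by rotation by `theta_ls` about the y axis,
#' with z increasing upwards from the coverslip. The default `"composite"`
#' method performs both steps in a single trilinear resampling (one
#' interpolation pass); `"two-step"` materialises the axially rescaled
#' volume first and then rotates it (two interpolation passes) and exists as
#' the independently-coded reference implementation.
#'
#' @param hs A `hyperstack` (or `[row, col, z]` array).
#' @param geometry An [acquisition_geometry()]; defaults to the one stored
#'   on the hyperstack.
#' @param t Volume (timepoint) index.
#' @param method `"composite"` or `"two-step"`.
#' @return Object of class `lab_volume`: `data` indexed `[z, y, x]`
#'   (isotropic voxels of edge `px_sample`), `voxel_um`, `origin`
#'   (0-based lab voxel coordinates of `data[1,1,1]`), and `support`
#'   (`[z, x]` logical matrix marking output voxels whose interpolation
#'   stencil lies fully inside the acquired stack; voxels outside fade to 0
#'   over one interpolation cell and should be excluded from quantitative
#'   comparisons).
#' @export
to_lab_frame <- function(hs, geometry = NULL, t = 1,
                         method = c("composite", "two-step")) {
  method <- match.arg(method)
  if (inherits(hs, "hyperstack")) {
    if (is.null(geometry)) geometry <- hs$geometry
    vol <- hs$data[, , , t]
  } else vol <- hs
  if (is.null(geometry)) stop("an acquisition_geometry is required")
  d <- dim(vol)   # (rows y, cols x', planes k)
  g <- lab_grid(d, geometry)
  out <- if (method == "composite") {
    resample_composite(vol, geometry, g)
  } else {
    resample_two_step(vol, geometry, g)
  }
  structure(list(data = out$data, voxel_um = geometry$px_sample,
                 origin = g$origin, support = out$support,
                 geometry = geometry),
            class = "lab_volume")
}

# single-pass resampling: for each output lab voxel, pull back through the
# inverse rotation + axial rescale and interpolate the raw stack trilinearly.
# y passes through the rotation untouched, so the (x, z) -> (x', k) mapping
# is computed once and reused for every y row.
resample_composite <- function(vol, geometry, g) {
  R <- rotation_y(geometry$theta_ls)
  xs <- g$origin[1] + 0:(g$nx - 1)
  zs <- g$origin[3] + 0:(g$nz - 1)
  gx <- matrix(xs, g$nz, g$nx, byrow = TRUE)   # [z, x]
  gz <- matrix(zs, g$nz, g$nx)
  # inverse rotation (transpose): stack coords in pixel units
  cx <- t(R)[1, 1] * gx + t(R)[1, 3] * gz
  ck <- (t(R)[3, 1] * gx + t(R)[3, 3] * gz) / g$scale
  d <- dim(vol)
  support <- cx >= 0 & cx <= d[2] - 1 & ck >= 0 & ck <= d[3] - 1
  list(data = interp_xz_stack(vol, cx, ck, g), support = support)
}

# gather-based bilinear interpolation in the (x', k) plane applied to all y
# rows at once; vol is [y, x', k], cx/ck are [z, x] matrices of stack coords
interp_xz_stack <- function(vol, cx, ck, g) {
  d <- dim(vol)
  ny <- d[1]
  x0 <- floor(cx); k0 <- floor(ck)
  fx <- cx - x0; fk <- ck - k0
  out <- array(0, dim = c(g$nz, ny, g$nx))
  corner <- function(xi, ki, wt) {
    ok <- xi >= 0 & xi <= d[2] - 1 & ki >= 0 & ki <= d[3] - 1 & wt > 0
    if (!any(ok)) return(NULL)
    idx <- which(ok)
    # linear index into vol for y = 1, then offsets for each y row
    base <- (ki[idx]) * ny * d[2] + (xi[idx]) * ny + 1
    list(idx = idx, base = base, wt = wt[idx])
  }
  pieces <- list(corner(x0, k0, (1 - fx) * (1 - fk)),
                 corner(x0 + 1, k0, fx * (1 - fk)),
                 corner(x0, k0 + 1, (1 - fx) * fk),
                 corner(x0 + 1, k0 + 1, fx * fk))
  vflat <- as.vector(vol)
  nzx <- g$nz * g$nx
  for (p in pieces) {
    if (is.null(p)) next
    for (y in seq_len(ny)) {
      vals <- vflat[p$base + (y - 1)] * p$wt
      # out is [z, y, x]: linear index = z + (y-1)*nz + (x-1)*nz*ny
      zi <- (p$idx - 1) %% g$nz + 1
      xi <- (p$idx - 1) %/% g$nz + 1
      oidx <- zi + (y - 1) * g$nz + (xi - 1) * g$nz * ny
      out[oidx] <- out[oidx] + vals
    }
  }
  out
}

# reference implementation: explicit axial rescale to isotropic voxels
# (linear interpolation along k), then explicit rotation about y (bilinear
# in the x'-z' plane), on the same output grid as the composite method
resample_two_step <- function(vol, geometry, g) {
  d <- dim(vol)
  s <- g$scale
  nz2 <- floor((d[3] - 1) * s) + 1
  # step 1: rescale k -> z' at unit (pixel) spacing
  kf <- (0:(nz2 - 1)) / s
  k0 <- pmin(floor(kf), d[3] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  w <- kf - k0
  iso <- array(0, dim = c(d[1], d[2], nz2))
  for (j in seq_len(nz2))
    iso[, , j] <- vol[, , k0[j] + 1] * (1 - w[j]) + vol[, , k1[j] + 1] * w[j]
  # step 2: rotate about y on the shared output grid
  R <- rotation_y(geometry$theta_ls)
  xs <- g$origin[1] + 0:(g$nx - 1)
  zs <- g$origin[3] + 0:(g$nz - 1)
  gx <- matrix(xs, g$nz, g$nx, byrow = TRUE)
  gz <- matrix(zs, g$nz, g$nx)
  cx <- t(R)[1, 1] * gx + t(R)[1, 3] * gz
  cz <- t(R)[3, 1] * gx + t(R)[3, 3] * gz   # z' in pixel units
  g2 <- g; g2$scale <- 1
  support <- cx >= 0 & cx <= d[2] - 1 & cz >= 0 & cz <= nz2 - 1
  list(data = interp_xz_stack(iso, cx, cz, g2), support = support)
}

#' Rotate an isotropic volume about the y axis
#'
#' Bilinear pull-back resampling in the x-z plane (y rows pass through
#' unchanged), onto the axis-aligned bounding box of the rotated grid.
#' Used for view manipulation of already-isotropic volumes; [to_lab_frame()]
#' performs the rescale and rotation of raw stacks in a single pass.
#'
#' @param vol `[y, x, z]` numeric array (isotropic voxels).
#' @param theta_deg Rotation angle about y, degrees.
#' @param origin 0-based `(x, y, z)` coordinates of `vol[1, 1, 1]`.
#' @return `list(data = [y, x, z] array, origin = )` with the new origin.
#' @export
rotate_volume_y <- function(vol, theta_deg, origin = c(0, 0, 0)) {
  d <- dim(vol)
  stopifnot(length(d) == 3)
  R <- rotation_y(theta_deg)
  xr <- origin[1] + c(0, d[2] - 1)
  zr <- origin[3] + c(0, d[3] - 1)
  corners <- as.matrix(expand.grid(x = xr, z = zr))
  labx <- R[1, 1] * corners[, 1] + R[1, 3] * corners[, 2]
  labz <- R[3, 1] * corners[, 1] + R[3, 3] * corners[, 2]
  lo <- c(floor(min(labx)), origin[2], floor(min(labz)))
  nx <- ceiling(max(labx)) - lo[1] + 1
  nz <- ceiling(max(labz)) - lo[3] + 1
  gx <- matrix(lo[1] + 0:(nx - 1), nz, nx, byrow = TRUE)
  gz <- matrix(lo[3] + 0:(nz - 1), nz, nx)
  cx <- t(R)[1, 1] * gx + t(R)[1, 3] * gz - origin[1]
  cz <- t(R)[3, 1] * gx + t(R)[3, 3] * gz - origin[3]
  g <- list(nx = nx, nz = nz)
  out <- interp_xz_stack(vol, cx, cz, g)   # [z, y, x]
  list(data = aperm(out, c(2, 3, 1)), origin = lo)
}

#' Orthogonal sections through a lab-frame volume
#'
#' @param labvol A `lab_volume`.
#' @param x,y,z 1-based indices of the intersecting planes.
#' @return `list(xy = , xz = , yz = )` of section matrices; `xy` is
#'   `data[z, , ]`, `xz` is `data[, y, ]`, `yz` is `data[, , x]`.
#' @export
orthogonal_views <- function(labvol, x, y, z) {
  d <- dim(labvol$data)
  if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3])
    stop("section index out of range")
  list(xy = labvol$data[z, , ], xz = labvol$data[, y, ],
       yz = labvol$data[, , x])
}

#' Maximum intensity projection of a lab-frame volume
#'
#' @param labvol A `lab_volume` (or `[z, y, x]` array).
#' @param axis `"z"` (default), `"y"` or `"x"`.
#' @return Projection matrix (per-pixel maximum along the axis).
#' @export
mip <- function(labvol, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  a <- if (inherits(labvol, "lab_volume")) labvol$data else labvol
  m <- switch(axis, z = 1L, y = 2L, x = 3L)
  apply(a, setdiff(1:3, m), max)
}

#' Default depth-coding colormap
#'
#' A cold-to-light perceptual ramp (deep blue through cyan to white) whose
#' red channel increases strictly monotonically with depth, so depth order
#' is recoverable from any rendered pixel.
#'
#' @param n Number of colours.
#' @return n x 3 matrix of RGB values in `[0, 1]`.
#' @export
depth_colormap <- function(n) {
  ramp <- grDevices::colorRamp(c("#000540", "#2060C0", "#40E0E0", "#FFFFFF"))
  rgb <- ramp(seq(0, 1, length.out = n)) / 255
  rgb[, 1] <- seq(0.02, 1, length.out = n)   # enforce strict monotonicity
  rgb
}

#' Depth-coded maximum intensity projection along z
#'
#' Each pixel is coloured by the depth (z index) of its maximum along the
#' projection axis and weighted by the maximum intensity (normalised to the
#' volume maximum). A zero volume renders black.
#'
#' @param labvol A `lab_volume` (or `[z, y, x]` array).
#' @param colormap Function `n -> n x 3` RGB matrix; must be monotone in at
#'   least one channel. Defaults to [depth_colormap()].
#' @return `[y, x, 3]` RGB array in `[0, 1]`.
#' @export
depth_coded_mip <- function(labvol, colormap = depth_colormap) {
  a <- if (inherits(labvol, "lab_volume")) labvol$data else labvol
  d <- dim(a)
  cmap <- colormap(max(d[1], 2))[seq_len(d[1]), , drop = FALSE]
  strict_mono <- function(v) length(v) < 2 || all(diff(v) > 0) ||
    all(diff(v) < 0)
  if (!any(apply(cmap, 2, strict_mono)))
    stop("colormap must be strictly monotone in at least one channel")
  vmax <- apply(a, c(2, 3), max)
  zarg <- apply(a, c(2, 3), which.max)
  peak <- max(vmax)
  inten <- if (peak > 0) vmax / peak else vmax
  out <- array(0, dim = c(d[2], d[3], 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(cmap[zarg, ch], d[2], d[3]) * inten
  out
}
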