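#' Acquisition geometry of an oblique light-sheet stack
#'
#' Describes how a volume is sampled by the microscope: the light-sheet angle
#' relative to the horizontal sample surface, the plane spacing along the
#' detection axis, the number of retained planes per volume, and the lateral
#' sample-space pixel size implied by the camera pixel pitch and magnification.
#'
#' @param theta_ls Light-sheet angle with respect to the horizontal, degrees.
#'   Must lie strictly between 0 and 90.
#' @param dz_prime Plane spacing along the detection axis, micrometres.
#' @param n_planes Number of planes retained per volume.
#' @param px_sample Lateral sample-space pixel size, micrometres. Defaults to
#'   `camera_px / magnification`; if given explicitly it must agree with that
#'   ratio to four decimal places.
#' @param camera_px Detector pixel pitch, micrometres.
#' @param magnification Sample-to-image magnification.
#' @param vps Volumes per second.
#' @param frames_per_sweep Camera frames per piezo sweep; only `n_planes` of
#'   them are retained (the remainder covers the nonlinear turnaround of the
#'   scan).
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(theta_ls = 37, dz_prime = 1.3, n_planes = 38,
                                 px_sample = NULL, camera_px = 6.5,
                                 magnification = 44, vps = 8,
                                 frames_per_sweep = 48) {
  # theta_ls = 0 (untilted stack) is degenerate for a real oblique
  # acquisition but valid for reconstruction, where it reduces to a pure
  # axial rescale
  stopifnot(theta_ls >= 0, theta_ls < 90, dz_prime > 0, camera_px > 0,
            magnification > 0, n_planes >= 1, vps > 0,
            n_planes <= frames_per_sweep)
  implied <- camera_px / magnification
  if (is.null(px_sample)) {
    px_sample <- implied
  } else if (abs(px_sample - implied) > 5e-5) {
    stop("px_sample (", px_sample, ") disagrees with camera_px/magnification (",
         signif(implied, 6), ") beyond 4 decimal places")
  }
  stopifnot(px_sample > 0)
  structure(list(theta_ls = theta_ls, dz_prime = dz_prime,
                 n_planes = as.integer(n_planes), px_sample = px_sample,
                 camera_px = camera_px, magnification = magnification,
                 vps = vps, frames_per_sweep = as.integer(frames_per_sweep)),
            class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "acquisition_geometry: theta_ls=%g deg, dz'=%g um, %d planes, px=%.4f um, %g vps\n",
    x$theta_ls, x$dz_prime, x$n_planes, x$px_sample, x$vps))
  invisible(x)
}

#' Sample-space pixel size from camera pitch and magnification
#'
#' @param camera_px Detector pixel pitch, micrometres.
#' @param magnification Sample-to-image magnification.
#' @return Lateral pixel size in sample space, micrometres.
#' @export
sample_pixel_size <- function(camera_px, magnification) {
  stopifnot(camera_px > 0, magnification > 0)
  camera_px / magnification
}

#' Field-of-view extent of a pixel range
#'
#' @param n_px Number of pixels.
#' @param px_sample Sample-space pixel size, micrometres.
#' @return FOV extent in micrometres.
#' @export
fov_um <- function(n_px, px_sample) {
  stopifnot(n_px >= 1, px_sample > 0)
  n_px * px_sample
}

#' Number of volumes in an acquisition
#'
#' @param duration_s Acquisition duration, seconds.
#' @param vps Volumes per second.
#' @return Integer volume count (`duration_s * vps`, rounded to nearest).
#' @export
n_volumes <- function(duration_s, vps) {
  stopifnot(duration_s > 0, vps > 0)
  as.integer(round(duration_s * vps))
}

# 3x3 rotation about the lab y axis mapping stack coordinates
# (x' in-sheet lateral, y sheet propagation, z' detection axis, all in pixel
# units after axial rescale) to lab coordinates (x, y, z with z up from the
# coverslip).  Positive theta tips the detection axis toward lab +z so plane
# index increases with height.
rotation_y <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), 0, -sin(th),
           0, 1, 0,
           sin(th), 0, cos(th)), nrow = 3)  # columns are images of the axes
}

#' Map lab-frame positions to acquisition-stack coordinates
#'
#' Inverse of [stack_to_lab()]: positions in micrometres (x, y, z with z up
#' from the coverslip) are expressed as detector-frame column/row (0-based
#' pixel units) and fractional plane index k.
#'
#' @param p_um N x 3 matrix of lab positions, micrometres.
#' @param geometry An [acquisition_geometry()].
#' @return N x 3 matrix with columns `col`, `row`, `k`.
#' @export
lab_to_stack <- function(p_um, geometry) {
  R <- rotation_y(geometry$theta_ls)
  u <- t(R) %*% (rbind(p_um[, 1], p_um[, 2], p_um[, 3]) / geometry$px_sample)
  s <- geometry$dz_prime / geometry$px_sample
  cbind(col = u[1, ], row = u[2, ], k = u[3, ] / s)
}

#' Map acquisition-stack coordinates to lab-frame positions
#'
#' A point at detector column/row (0-based pixel units) on plane `k` lies at
#' depth `k * dz_prime` along the detection axis, which is tilted `theta_ls`
#' from vertical; this returns its lab-frame position in micrometres.
#'
#' @param stack N x 3 matrix with columns `col`, `row`, `k` (0-based).
#' @param geometry An [acquisition_geometry()].
#' @return N x 3 matrix of lab positions `(x, y, z)`, micrometres.
#' @export
stack_to_lab <- function(stack, geometry) {
  s <- geometry$dz_prime / geometry$px_sample
  R <- rotation_y(geometry$theta_ls)
  v <- R %*% rbind(stack[, 1], stack[, 2], stack[, 3] * s)
  t(v) * geometry$px_sample
}
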