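# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# quiet optics for geometric tests: no noise, identity-free small frames
noiseless_optics <- function(geometry, frame_shape = c(28, 28),
                             chromatic = affine_params(), ...) {
  full <- c(2 * frame_shape[1], frame_shape[2])
  optics_config(geometry, frame_shape = frame_shape,
                read_noise_sd = 0, shot_noise = FALSE, bg_rate = 0,
                fpn_map = matrix(0, full[1], full[2]),
                chromatic = chromatic, ...)
}

# geometry with an exactly integer axial scale (px = 0.25 um, dz' = 0.75 um,
# s = 3), convenient for resampling-equivalence tests
integer_scale_geometry <- function(theta_ls = 37, n_planes = 16) {
  acquisition_geometry(theta_ls = theta_ls, dz_prime = 0.75,
                       n_planes = n_planes, camera_px = 6.5,
                       magnification = 26)
}

# separable Gaussian blur of a 3D array (structures smooth at the plane
# spacing scale, as the resampling equivalence assumes)
gauss_blur3 <- function(a, sigma) {
  k <- stats::dnorm(seq(-3 * sigma, 3 * sigma), 0, sigma)
  k <- k / sum(k)
  cv <- function(v) {
    n <- length(k)
    padded <- c(rep(v[1], n), v, rep(v[length(v)], n))
    as.numeric(stats::filter(padded, k, sides = 2))[(n + 1):(n + length(v))]
  }
  for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2]))
    a[i, j, ] <- cv(a[i, j, ])
  for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[3]))
    a[i, , j] <- cv(a[i, , j])
  for (i in seq_len(dim(a)[2])) for (j in seq_len(dim(a)[3]))
    a[, i, j] <- cv(a[, i, j])
  a
}

# render a single point-like emitter at given stack coordinates and return
# the reconstructed green-channel lab volume plus the true lab position
render_and_reconstruct_emitter <- function(stack_pos, geometry, optics,
                                           baseline_f = 500) {
  lab <- stack_to_lab(rbind(stack_pos), geometry)
  cells <- list(cell_spec("e", "hipsc", centroid_um = as.numeric(lab),
                          size_um = 0.05, baseline_f = baseline_f))
  tr <- simulate_traces(cells, duration_s = 0.5, rate_hz = 2, seed = 1)
  acq <- render_acquisition(cells, tr, optics, seed = 1)
  ch <- split_channels(acq$frames[, , seq_len(geometry$n_planes)])
  hs <- deinterleave(ch$green, geometry$n_planes, geometry)
  list(labvol = to_lab_frame(hs, geometry), lab_um = as.numeric(lab))
}

# voxel position (0-based lab voxel coords) of the intensity argmax
argmax_voxel <- function(labvol) {
  am <- which(labvol$data == max(labvol$data), arr.ind = TRUE)[1, ]
  c(am[3] - 1 + labvol$origin[1], am[2] - 1 + labvol$origin[2],
    am[1] - 1 + labvol$origin[3])
}

# interior (eroded full-support) comparison of two lab volumes
interior_rel_rms <- function(v1, v2) {
  supp <- v1$support & v2$support
  er <- supp & FALSE
  nr <- nrow(supp); nc <- ncol(supp)
  er[2:(nr - 1), 2:(nc - 1)] <- supp[1:(nr - 2), 1:(nc - 2)] &
    supp[3:nr, 3:nc] & supp[2:(nr - 1), 2:(nc - 1)]
  idx <- which(er, arr.ind = TRUE)
  a <- b <- numeric(0)
  for (y in seq_len(dim(v1$data)[2])) {
    a <- c(a, v1$data[cbind(idx[, 1], y, idx[, 2])])
    b <- c(b, v2$data[cbind(idx[, 1], y, idx[, 2])])
  }
  sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
}

# brute-force Pearson chi-square via expected counts, independent of the
# implementation under test
chi2_brute <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# cached noiseless / noisy table-1 cohorts (built once per test run)
.cohort_cache <- new.env(parent = emptyenv())
table1_cohort <- function(noise_sd) {
  key <- paste0("n", noise_sd)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(table1_design(), seed = 11,
                                            noise_sd = noise_sd)
  .cohort_cache[[key]]
}
classified_records <- function(noise_sd) {
  key <- paste0("r", noise_sd)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- classify_cohort(table1_cohort(noise_sd))
  .cohort_cache[[key]]
}
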