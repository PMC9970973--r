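test_that("deinterleave reorders plane-major frames and conserves voxels", {
  set.seed(1)
  fr <- array(runif(6 * 5 * 4560), dim = c(6, 5, 4560))
  hs <- deinterleave(fr, 38)
  expect_equal(hs$n_volumes, 120L)
  expect_equal(dim(hs$data), c(6L, 5L, 38L, 120L))
  # volume t is frames (t-1)*Z+1 .. t*Z, pixel values untouched
  expect_identical(hs$data[, , 3, 2], fr[, , 38 + 3])
  expect_equal(sum(hs$data), sum(fr))
  # Z = 1 leaves the sequence unchanged
  hs1 <- deinterleave(fr[, , 1:10], 1)
  expect_identical(hs1$data[, , 1, ], fr[, , 1:10])
  expect_error(deinterleave(fr[, , 1:10], 4), "N = 10.*Z = 4")
})

test_that("crop_to_slit crops identically across planes/timepoints and validates bounds", {
  set.seed(2)
  fr <- array(runif(12 * 14 * 8), dim = c(12, 14, 8))
  hs <- deinterleave(fr, 4)
  full <- crop_to_slit(hs, list(row = c(1, 12), col = c(1, 14)))
  expect_identical(full$data, hs$data)
  crp <- crop_to_slit(hs, list(row = c(3, 9), col = c(2, 12)))
  expect_identical(crp$data[, , 2, 1], fr[3:9, 2:12, 2])
  expect_error(crop_to_slit(hs, list(row = c(0, 9), col = c(2, 12))))
  expect_error(crop_to_slit(hs, list(row = c(9, 3), col = c(2, 12))))
})

test_that("auto slit bounds recover the rendered slit within 2 px and raise the mean", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 6,
                              camera_px = 6.5, magnification = 13)
  opt <- optics_config(geo, frame_shape = c(32, 40), read_noise_sd = 0,
                       shot_noise = FALSE, bg_rate = 30,
                       chromatic = affine_params(),
                       fpn_map = matrix(0, 64, 40), slit_inset_px = 4)
  cells <- list(cell_spec("c", "hipsc", c(8, 8, 3), 3, baseline_f = 200))
  tr <- simulate_traces(cells, duration_s = 1, rate_hz = 2, seed = 1)
  acq <- render_acquisition(cells, tr, opt, seed = 1)
  red <- split_channels(acq$frames)$red
  est <- auto_slit_bounds(red)
  truth <- slit_bounds(opt)
  expect_lte(max(abs(est$row - truth$row)), 2)
  expect_lte(max(abs(est$col - truth$col)), 2)
  hs <- deinterleave(red, geo$n_planes)
  cropped <- crop_to_slit(hs, est)
  expect_gt(mean(cropped$data), mean(hs$data))
})

test_that("an untilted stack with dz' = px reconstructs to the identity", {
  geo <- acquisition_geometry(theta_ls = 0, dz_prime = 0.25, n_planes = 8,
                              camera_px = 6.5, magnification = 26)
  set.seed(3)
  vol <- array(sample(0:100, 10 * 12 * 8, replace = TRUE),
               dim = c(10, 12, 8))
  lv <- to_lab_frame(deinterleave(vol, 8, geo), geo)
  # data[z, y, x] must equal vol[y, x, k] exactly on the integer grid
  expect_equal(dim(lv$data), c(8, 10, 12))
  expect_equal(max(abs(aperm(lv$data, c(2, 3, 1)) - vol)), 0)
})

test_that("point emitters across a 3x3x3 grid reconstruct within one voxel at 37 deg", {
  geo <- acquisition_geometry()
  # thin sheet: localization probes the geometry, not the axial profile
  opt <- noiseless_optics(geo, frame_shape = c(28, 28), sheet_waist_um = 1.5)
  errs <- c()
  for (cc in c(9.3, 14.0, 18.7)) for (rr in c(9.5, 14, 18.5))
    for (kk in c(12, 18, 26)) {
      res <- render_and_reconstruct_emitter(c(cc, rr, kk), geo, opt)
      err <- max(abs(argmax_voxel(res$labvol) - res$lab_um / geo$px_sample))
      errs <- c(errs, err)
    }
  expect_lte(max(errs), 1)
})

test_that("emitter round trips hold at several sheet angles", {
  for (th in c(0, 20, 37, 53)) {
    geo <- acquisition_geometry(theta_ls = th, dz_prime = 0.75,
                                n_planes = 12, camera_px = 6.5,
                                magnification = 26)
    opt <- noiseless_optics(geo, frame_shape = c(24, 24),
                            sheet_waist_um = 1.5)
    res <- render_and_reconstruct_emitter(c(11.4, 12.6, 6), geo, opt)
    err <- max(abs(argmax_voxel(res$labvol) - res$lab_um / geo$px_sample))
    expect_lte(err, 1)
  }
})

test_that("composite resampling matches the explicit two-step oracle", {
  set.seed(5)
  geo <- integer_scale_geometry()
  vol <- gauss_blur3(array(rnorm(24 * 24 * 16), dim = c(24, 24, 16)), 2)
  hs <- deinterleave(vol, 16, geo)
  v1 <- to_lab_frame(hs, geo, method = "composite")
  v2 <- to_lab_frame(hs, geo, method = "two-step")
  expect_lt(interior_rel_rms(v1, v2), 1e-4)
})

test_that("the reconstructed z extent matches the closed-form rotated bounding box", {
  geo <- acquisition_geometry()
  opt <- noiseless_optics(geo, frame_shape = c(28, 28))
  res <- render_and_reconstruct_emitter(c(14, 14, 18), geo, opt)
  d <- dim(res$labvol$data)
  s <- geo$dz_prime / geo$px_sample
  th <- geo$theta_ls * pi / 180
  # analytic bounding box of the rotated, rescaled grid (in voxels):
  # z ranges from -x_max sin(theta) to k_max s cos(theta)
  expect_equal(d[1],
               ceiling(37 * s * cos(th)) - floor(-27 * sin(th)) + 1)
  expect_lt(abs(d[1] - (27 * sin(th) + 37 * s * cos(th))), 3)
})

test_that("rotation by theta then -theta returns smooth volumes within tolerance", {
  set.seed(6)
  vol <- gauss_blur3(array(rnorm(20 * 30 * 30), dim = c(20, 30, 30)), 4)
  fwd <- rotate_volume_y(vol, 25)
  back <- rotate_volume_y(fwd$data, -25, origin = fwd$origin)
  # back$origin is <= 0; map the original voxel block into the back-rotated
  # array and compare the central region, where the support is full
  off <- -back$origin + 1   # (x, y, z) array offsets of original (0,0,0)
  sub <- back$data[, off[1]:(off[1] + 29), off[3]:(off[3] + 29)]
  ctr <- function(a) a[, 9:22, 9:22]
  a <- ctr(vol); b <- ctr(sub)
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 0.02)
})

test_that("orthogonal views slice the volume by definition", {
  set.seed(7)
  lv <- structure(list(data = array(runif(6 * 7 * 8), dim = c(6, 7, 8)),
                       voxel_um = 1, origin = c(0, 0, 0)),
                  class = "lab_volume")
  v <- orthogonal_views(lv, x = 3, y = 4, z = 5)
  expect_identical(v$xy, lv$data[5, , ])
  expect_identical(v$xz, lv$data[, 4, ])
  expect_identical(v$yz, lv$data[, , 3])
  cv <- lv; cv$data[] <- 3
  vc <- orthogonal_views(cv, 1, 1, 1)
  expect_true(all(vc$xy == 3) && all(vc$xz == 3) && all(vc$yz == 3))
  expect_error(orthogonal_views(lv, x = 9, y = 1, z = 1), "out of range")
})

test_that("sections through a rendered emitter contain its peak", {
  geo <- acquisition_geometry()
  opt <- noiseless_optics(geo, frame_shape = c(28, 28))
  res <- render_and_reconstruct_emitter(c(14, 14, 18), geo, opt)
  vx <- argmax_voxel(res$labvol) - res$labvol$origin + 1
  v <- orthogonal_views(res$labvol, x = vx[1], y = vx[2], z = vx[3])
  peak <- max(res$labvol$data)
  expect_equal(max(v$xy), peak)
  expect_equal(max(v$xz), peak)
  expect_equal(max(v$yz), peak)
})

test_that("maximum intensity projections obey their definition", {
  a <- array(0, dim = c(4, 5, 6))
  a[2, 3, 4] <- 7
  expect_equal(sum(mip(a, "z") > 0), 1)
  expect_equal(mip(a, "z")[3, 4], 7)
  set.seed(8)
  b <- array(runif(4 * 5 * 6), dim = c(4, 5, 6))
  pz <- mip(b, "z")
  for (k in 1:4) expect_true(all(pz >= b[k, , ]))
  # two laterally separated emitters both appear
  c2 <- array(0, dim = c(5, 6, 9))
  c2[2, 3, 2] <- 5; c2[4, 5, 8] <- 6
  expect_equal(sum(mip(c2, "z") > 0), 2)
})

test_that("depth-coded projections colour by depth with monotone hue order", {
  vol <- array(0, dim = c(10, 6, 8))
  vol[3, , ] <- 2
  img <- depth_coded_mip(vol)
  # single active plane: one uniform hue wherever there is intensity
  cols <- matrix(img, ncol = 3)
  on <- rowSums(cols) > 0
  expect_equal(nrow(unique(round(cols[on, , drop = FALSE], 12))), 1)
  # two depths: deeper emitter gets the larger red-channel value
  v2 <- array(0, dim = c(10, 6, 8))
  v2[2, 3, 2] <- 2; v2[8, 3, 6] <- 2
  img2 <- depth_coded_mip(v2)
  expect_gt(img2[3, 6, 1], img2[3, 2, 1])
  # zero volume renders black
  expect_true(all(depth_coded_mip(array(0, dim = c(4, 4, 4))) == 0))
})
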