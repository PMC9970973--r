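test_that("estimate_fpn is the exact per-pixel mean and is permutation invariant", {
  zero <- array(0, dim = c(8, 10, 50))
  expect_equal(estimate_fpn(zero)$offset, matrix(0, 8, 10))
  const <- array(100, dim = c(8, 10, 25))
  expect_equal(estimate_fpn(const)$offset, matrix(100, 8, 10))
  set.seed(1)
  fr <- array(rnorm(8 * 10 * 30, 100, 5), dim = c(8, 10, 30))
  perm <- fr[, , sample(30)]
  expect_equal(estimate_fpn(fr)$offset, estimate_fpn(perm)$offset)
  expect_equal(estimate_fpn(fr)$n_dark_frames, 30)
})

test_that("estimate_fpn error obeys the sigma/sqrt(n) sampling bound", {
  truth <- 100 + sin(seq_len(128)) %o% cos(seq_len(96) / 3)
  sigma <- 3; n <- 200
  set.seed(42)
  dark <- array(rep(truth, n) + rnorm(128 * 96 * n, 0, sigma),
                dim = c(128, 96, n))
  est <- estimate_fpn(dark)$offset
  frac_within <- mean(abs(est - truth) <= 4 * sigma / sqrt(n))
  expect_gte(frac_within, 0.999)
})

test_that("subtract_fpn subtracts and clamps at zero", {
  fpn <- matrix(10, 4, 4)
  frame <- matrix(10, 4, 4)
  expect_equal(subtract_fpn(frame, fpn), matrix(0, 4, 4))
  frame2 <- matrix(c(5, 15, 9, 30), 2, 2)
  expect_equal(subtract_fpn(frame2, matrix(10, 2, 2)),
               matrix(c(0, 5, 0, 20), 2, 2))
  expect_error(subtract_fpn(matrix(0, 3, 3), fpn), "mismatch")
})

test_that("FPN-corrected rendered frames recover the clean signal mean", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 6,
                              camera_px = 6.5, magnification = 13)
  opt_clean <- noiseless_optics(geo, frame_shape = c(24, 24))
  cells <- list(cell_spec("c", "hipsc", c(5, 5, 3), 3, baseline_f = 400))
  tr <- simulate_traces(cells, duration_s = 1, rate_hz = 1, seed = 1)
  clean <- render_acquisition(cells, tr, opt_clean, seed = 1)$frames
  opt_noisy <- optics_config(geo, frame_shape = c(24, 24), read_noise_sd = 0,
                             shot_noise = TRUE, bg_rate = 0,
                             chromatic = affine_params())
  noisy <- render_acquisition(cells, tr, opt_noisy, seed = 2)$frames
  corr <- subtract_fpn(noisy, opt_noisy$fpn_map)
  # shot-noise bound on the mean of ~24x24x6 pixels
  npix <- length(clean)
  bound <- 5 * sqrt(max(mean(clean), 1) / npix)
  expect_lt(abs(mean(corr) - mean(clean)), bound)
})

test_that("split_channels produces equal tiles per layout", {
  fr <- matrix(seq_len(512 * 6), 512, 6)
  halves <- split_channels(fr, "top-bottom")
  expect_equal(dim(halves$green), c(256L, 6L))
  expect_equal(dim(halves$red), c(256L, 6L))
  expect_equal(halves$green, fr[1:256, ])
  checker <- matrix(c(1, 2, 3, 4), 2, 2)
  lr <- split_channels(checker, "left-right")
  expect_equal(lr$green, checker[, 1, drop = FALSE])
  expect_equal(lr$red, checker[, 2, drop = FALSE])
  expect_error(split_channels(matrix(0, 5, 4), "top-bottom"), "odd")
})

test_that("each detector half contains exactly its channel's emitters", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 4,
                              camera_px = 6.5, magnification = 13)
  opt <- noiseless_optics(geo, frame_shape = c(48, 48))
  bs <- render_bead_stack(opt, n_beads = 5, seed = 2)
  ch <- split_channels(bs$frames[, , 1])
  expect_gt(max(ch$green), 0)
  expect_gt(max(ch$red), 0)
  cg <- detect_bead_centroids(ch$green, threshold = max(ch$green) / 3)
  cr <- detect_bead_centroids(ch$red, threshold = max(ch$red) / 3)
  expect_equal(nrow(cg), 5)
  expect_equal(nrow(cr), 5)
})

test_that("bead-calibrated registration recovers the chromatic scale and aligns beads", {
  geo <- acquisition_geometry()
  opt <- noiseless_optics(
    geo, frame_shape = c(96, 128),
    chromatic = affine_params(0.3, 0.9, 0.9, 1.2, -0.8))
  bs <- render_bead_stack(opt, n_beads = 10, seed = 4)
  # demagnified Fluo-4 path: bead distances in the green half are 0.9x red
  ratio <- as.numeric(dist(bs$beads_green) / dist(bs$beads_red))
  expect_equal(ratio, rep(0.9, length(ratio)), tolerance = 1e-9)
  fit <- calibrate_registration(bs$frames)
  expect_lt(abs(fit$scale_x - 0.9), 1e-3)
  expect_lt(abs(fit$scale_y - 0.9), 1e-3)
  ch <- split_channels(bs$frames[, , 1])
  reg <- apply_affine(ch$green, fit)
  cr <- detect_bead_centroids(ch$red)
  m_before <- match_centroids(detect_bead_centroids(ch$green), cr, 10)
  m_after <- match_centroids(detect_bead_centroids(reg), cr, 3)
  mis <- function(m) mean(sqrt(rowSums((m$moving - m$fixed)^2)))
  expect_equal(nrow(m_after$moving), 10)
  expect_lt(max(sqrt(rowSums((m_after$moving - m_after$fixed)^2))), 0.5)
  # registration reduces the mean bead mismatch at least tenfold
  expect_gt(mis(m_before) / mis(m_after), 10)
})

test_that("collinear bead layouts are rejected as degenerate calibration fixtures", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 4,
                              camera_px = 6.5, magnification = 13)
  opt <- noiseless_optics(geo, frame_shape = c(48, 48))
  line <- cbind(10 + 3 * (0:4), 10 + 1.5 * (0:4))
  expect_error(render_bead_stack(opt, positions = line), "collinear")
  # three non-collinear beads are a valid boundary fixture
  tri <- rbind(c(10, 10), c(30, 12), c(20, 30))
  expect_silent(bs <- render_bead_stack(opt, positions = tri))
  expect_equal(nrow(bs$beads_red), 3)
})
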