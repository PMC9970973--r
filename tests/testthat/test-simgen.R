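test_that("a field with no adult cells is a pure hiPSC layer", {
  fld <- build_cell_field(field_um = c(60, 30), n_adult = 0, seed = 1)
  kinds <- vapply(fld$cells, `[[`, character(1), "kind")
  expect_true(all(kinds == "hipsc"))
  expect_gt(length(fld$cells), 0)
})

test_that("cell placement is deterministic for a fixed seed", {
  a <- build_cell_field(field_um = c(120, 40), n_adult = 3, seed = 9)
  b <- build_cell_field(field_um = c(120, 40), n_adult = 3, seed = 9)
  expect_identical(a, b)
  c <- build_cell_field(field_um = c(120, 40), n_adult = 3, seed = 10)
  expect_false(identical(a, c))
})

test_that("adult rectangles are placed without overlap (brute-force check)", {
  fld <- build_cell_field(field_um = c(300, 40), n_adult = 5, seed = 3)
  adults <- Filter(function(cl) cl$kind == "adult", fld$cells)
  expect_equal(length(adults), 5)
  # brute force: sample points inside each rectangle, check none falls
  # inside any other rectangle
  inside <- function(cl, pts) {
    th <- cl$orientation_deg * pi / 180
    d <- sweep(pts, 2, cl$centroid_um[1:2])
    u <- d[, 1] * cos(th) + d[, 2] * sin(th)
    v <- -d[, 1] * sin(th) + d[, 2] * cos(th)
    abs(u) <= cl$size_um[1] / 2 & abs(v) <= cl$size_um[2] / 2
  }
  sample_rect <- function(cl, n = 400) {
    th <- cl$orientation_deg * pi / 180
    u <- runif(n, -cl$size_um[1] / 2, cl$size_um[1] / 2)
    v <- runif(n, -cl$size_um[2] / 2, cl$size_um[2] / 2)
    cbind(cl$centroid_um[1] + u * cos(th) - v * sin(th),
          cl$centroid_um[2] + u * sin(th) + v * cos(th))
  }
  set.seed(1)
  for (i in seq_along(adults)) for (j in seq_along(adults)) {
    if (i == j) next
    expect_false(any(inside(adults[[j]], sample_rect(adults[[i]]))))
  }
})

test_that("unsatisfiable adult density fails explicitly", {
  expect_error(
    build_cell_field(field_um = c(70, 40), n_adult = 12, seed = 1,
                     max_tries = 50),
    "without overlap")
})

test_that("adult cells sit above the hiPSC layer", {
  fld <- build_cell_field(field_um = c(120, 40), n_adult = 3, seed = 2)
  z <- vapply(fld$cells, function(cl) cl$centroid_um[3], numeric(1))
  kinds <- vapply(fld$cells, `[[`, character(1), "kind")
  expect_gt(min(z[kinds == "adult"]), max(z[kinds == "hipsc"]))
})

test_that("a quiescent uncoupled cell stays at baseline fluorescence", {
  cl <- cell_spec("q", "adult", c(10, 10, 9), c(30, 10), baseline_f = 120,
                  paced_responsive = FALSE)
  tr <- simulate_traces(list(cl), duration_s = 10, rate_hz = 4, seed = 1)
  expect_equal(tr$traces[, 1], rep(120, 40))
  expect_length(tr$ground_truth$event_times[[1]], 0)
})

test_that("a 5 s spontaneous rhythm over 15 s yields 3 evenly spaced events", {
  cl <- cell_spec("s", "hipsc", c(10, 10, 2), 6, spontaneous_period_s = 5)
  tr <- simulate_traces(list(cl), duration_s = 15, rate_hz = 4, seed = 1)
  ev <- tr$ground_truth$event_times[[1]]
  expect_equal(ev, c(2.5, 7.5, 12.5))
})

test_that("negative force-frequency relation lowers paced amplitudes", {
  kin <- default_kinetics("hipsc")
  expect_lt(transient_amplitude(kin, 0.5), transient_amplitude(kin, 0.16))
  # non-increasing in frequency whenever the slope is <= 0 (property)
  freqs <- seq(0.1, 1.2, by = 0.1)
  for (slope in c(0, -0.3, -0.8)) {
    k <- calcium_kinetics(ffr_slope = slope)
    amps <- transient_amplitude(k, freqs)
    expect_true(all(diff(amps) <= 1e-12))
    expect_true(all(amps > 0))
  }
})

test_that("paced amplitude reduction appears in rendered traces", {
  fld <- build_cell_field(field_um = c(60, 30), n_adult = 0, seed = 1)
  cells <- lapply(fld$cells, function(cl) {
    cl$spontaneous_period_s <- 6.25; cl$phase_s <- 1.2; cl
  })
  unpaced <- simulate_traces(cells, pacing_protocol(enabled = FALSE),
                             duration_s = 15, rate_hz = 4, seed = 1)
  paced <- simulate_traces(cells, pacing_protocol(enabled = TRUE),
                           duration_s = 15, rate_hz = 4, seed = 1)
  peak <- function(tr) max(tr$traces[, 1]) - min(tr$traces[, 1])
  expect_lt(peak(paced), peak(unpaced))
})

test_that("coupled cells share the layer rhythm and the waveform peaks at 1", {
  hip <- cell_spec("h", "hipsc", c(10, 10, 2), 6, spontaneous_period_s = 5)
  ad <- cell_spec("a", "adult", c(12, 10, 9), c(30, 10), is_coupled = TRUE)
  tr <- simulate_traces(list(hip, ad), duration_s = 15, rate_hz = 4, seed = 1)
  expect_equal(tr$ground_truth$event_times[["a"]],
               tr$ground_truth$event_times[["h"]])
  tt <- seq(0, 5, by = 0.001)
  expect_equal(max(transient_waveform(tt, default_kinetics("adult"))), 1,
               tolerance = 1e-5)
})

test_that("pacing faster than the refractory limit warns and thins events", {
  cl <- cell_spec("a", "adult", c(10, 10, 9), c(30, 10))
  fast <- pacing_protocol(enabled = TRUE, freq_hz = 5)
  expect_warning(
    tr <- simulate_traces(list(cl), fast, duration_s = 5, rate_hz = 20,
                          seed = 1),
    "refractory")
  ev <- tr$ground_truth$event_times[[1]]
  expect_true(all(diff(ev) >= 0.3 - 1e-12))
})

test_that("rendered frames with zero photons equal the fixed-pattern map exactly", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 4,
                              camera_px = 6.5, magnification = 13)
  opt <- optics_config(geo, frame_shape = c(16, 16), read_noise_sd = 0,
                       photon_scale = 0, chromatic = affine_params())
  cells <- list(cell_spec("c", "hipsc", c(5, 5, 2), 3, baseline_f = 100))
  tr <- simulate_traces(cells, duration_s = 1, rate_hz = 2, seed = 1)
  acq <- render_acquisition(cells, tr, opt, seed = 1)
  for (i in seq_len(dim(acq$frames)[3]))
    expect_equal(acq$frames[, , i], opt$fpn_map)
})

test_that("a 15 s acquisition at 8 vps with 38 planes yields 120 x 38 frames", {
  geo <- acquisition_geometry(vps = 8)
  opt <- noiseless_optics(geo, frame_shape = c(10, 12))
  cells <- list(cell_spec("c", "hipsc", c(0.8, 0.7, 2), 1,
                          spontaneous_period_s = 5))
  tr <- simulate_traces(cells, duration_s = 15, rate_hz = 8, seed = 1)
  acq <- render_acquisition(cells, tr, opt, seed = 1)
  expect_equal(dim(acq$frames)[3], 120 * 38)
  expect_equal(acq$n_volumes, 120)
})

test_that("noiseless rendering is additive over cells (photon conservation)", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 6,
                              camera_px = 6.5, magnification = 13)
  opt <- noiseless_optics(geo, frame_shape = c(24, 24))
  c1 <- cell_spec("c1", "hipsc", c(4, 4, 2), 2, baseline_f = 200)
  c2 <- cell_spec("c2", "hipsc", c(8, 7, 4), 2, baseline_f = 150)
  tr_both <- simulate_traces(list(c1, c2), duration_s = 1, rate_hz = 1,
                             seed = 1)
  tr1 <- simulate_traces(list(c1), duration_s = 1, rate_hz = 1, seed = 1)
  tr2 <- simulate_traces(list(c2), duration_s = 1, rate_hz = 1, seed = 1)
  both <- render_acquisition(list(c1, c2), tr_both, opt, seed = 1)$frames
  solo <- render_acquisition(list(c1), tr1, opt, seed = 1)$frames +
    render_acquisition(list(c2), tr2, opt, seed = 1)$frames
  expect_equal(both, solo, tolerance = 1e-9)
})

test_that("rendering is bit-identical for identical seeds", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 4,
                              camera_px = 6.5, magnification = 13)
  opt <- optics_config(geo, frame_shape = c(16, 16),
                       chromatic = affine_params())
  cells <- list(cell_spec("c", "hipsc", c(5, 5, 2), 3, baseline_f = 200))
  tr <- simulate_traces(cells, duration_s = 1, rate_hz = 2, seed = 1)
  a <- render_acquisition(cells, tr, opt, seed = 7)
  b <- render_acquisition(cells, tr, opt, seed = 7)
  expect_identical(a$frames, b$frames)
})

test_that("identity chromatic yields identical bead halves; out-of-volume cells vanish", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 4,
                              camera_px = 6.5, magnification = 13)
  opt <- noiseless_optics(geo, frame_shape = c(48, 48))
  bs <- render_bead_stack(opt, n_beads = 6, seed = 2)
  ch <- split_channels(bs$frames[, , 1])
  expect_equal(ch$green, ch$red, tolerance = 1e-12)
  # a cell far outside the imaged volume contributes nothing
  far <- cell_spec("far", "hipsc", c(500, 500, 400), 3, baseline_f = 1e4)
  tr <- simulate_traces(list(far), duration_s = 1, rate_hz = 1, seed = 1)
  acq <- render_acquisition(list(far), tr, opt, seed = 1)
  expect_equal(max(abs(acq$frames)), 0)
})
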