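test_that("roi_trace averages the ROI per timepoint", {
  vol4 <- array(3, dim = c(5, 20, 20, 7))
  tr <- roi_trace(vol4, roi3d(c(2, 11), c(3, 12), 2), dt_s = 0.5)
  expect_equal(tr$values, rep(3, 7))
  expect_equal(tr$dt_s, 0.5)
  expect_error(roi_trace(vol4, roi3d(c(15, 25), c(1, 5), 1)), "outside")
})

test_that("ROI traces follow the generating cell and separate disjoint cells", {
  geo <- acquisition_geometry(theta_ls = 37, dz_prime = 1.0, n_planes = 8,
                              camera_px = 6.5, magnification = 13)
  opt <- noiseless_optics(geo, frame_shape = c(24, 48))
  # place cells on known stack coordinates so ROIs are easy to state
  p1 <- stack_to_lab(rbind(c(12, 12, 3)), geo)
  p2 <- stack_to_lab(rbind(c(36, 12, 5)), geo)
  c1 <- cell_spec("c1", "hipsc", as.numeric(p1), 2,
                  spontaneous_period_s = 3, phase_s = 1, baseline_f = 200)
  # quiescent adult far from c1 (the confluent hiPSC layer beats as a
  # syncytium, so an independent silent ROI needs a non-layer cell)
  c2 <- cell_spec("c2", "adult", as.numeric(p2), c(8, 3), baseline_f = 200,
                  paced_responsive = FALSE)
  tr <- simulate_traces(list(c1, c2), duration_s = 10, rate_hz = 4, seed = 1)
  acq <- render_acquisition(list(c1, c2), tr, opt, seed = 1)
  hs <- deinterleave(split_channels(acq$frames)$green, geo$n_planes, geo)
  roi_of <- function(col, row, k) roi3d(col + 1 + c(-3, 3),
                                        row + 1 + c(-3, 3), k + 1)
  t1 <- roi_trace(hs, roi_of(12, 12, 3), dt_s = 0.25)
  t2 <- roi_trace(hs, roi_of(36, 12, 5), dt_s = 0.25)
  expect_gt(stats::cor(t1$values, tr$traces[, 1]), 0.99)
  # the quiescent neighbour's ROI stays flat
  expect_lt(stats::sd(t2$values) / mean(t2$values), 1e-6)
})

test_that("F0 estimation recovers baselines", {
  expect_equal(estimate_f0(rep(7, 10)), 7)
  sq <- rep(c(10, 10, 10, 10, 30), 10)   # square wave, 20% duty
  expect_equal(estimate_f0(sq, q = 0.1), 10)
  cl <- cell_spec("c", "hipsc", c(0, 0, 2), 6, spontaneous_period_s = 5,
                  baseline_f = 150)
  tr <- simulate_traces(list(cl), duration_s = 15, rate_hz = 4, seed = 1)
  expect_lt(abs(estimate_f0(tr$traces[, 1]) - 150) / 150, 0.02)
  expect_error(estimate_f0(c(-5, -5, 1)), "positive")
  # window method
  expect_equal(estimate_f0(sq, method = "window", window = c(0, 0.3),
                           dt_s = 0.1), 10)
})

test_that("dF/F0 obeys its algebraic identities", {
  expect_equal(dff(rep(5, 8), f0 = 5)$values, rep(0, 8))
  expect_equal(dff(c(5, 10), f0 = 5)$values, c(0, 1))
  expect_error(dff(1:3, f0 = 0))
  set.seed(2)
  v <- 100 + 40 * pmax(sin(seq(0, 8 * pi, length.out = 120)), 0) +
    rnorm(120, 0, 2)
  d1 <- dff(v, dt_s = 0.1)
  d2 <- dff(3.7 * v, dt_s = 0.1)
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
  expect_equal(d2$f0, 3.7 * d1$f0, tolerance = 1e-12)
})

test_that("event detection recovers generated event times at SNR >= 5", {
  expect_equal(nrow(detect_events(rep(0, 50), dt_s = 0.25)), 0)
  cl <- cell_spec("c", "hipsc", c(0, 0, 2), 6, spontaneous_period_s = 5,
                  phase_s = 2.5, baseline_f = 100)
  tr <- simulate_traces(list(cl), duration_s = 15, rate_hz = 4, seed = 3,
                        noise_sd = 10)
  ev <- detect_events(dff(tr$traces[, 1], dt_s = 0.25))
  expect_equal(nrow(ev), 3)
  truth <- c(2.5, 7.5, 12.5) + transient_peak_delay(cl$kinetics)
  expect_true(all(abs(ev$peak_time_s - truth) <= 0.25))
})

test_that("event count and peak timing hold across 100 seeded noisy traces", {
  kin <- default_kinetics("hipsc")
  delay <- transient_peak_delay(kin)
  n_ok <- 0
  for (s in 1:100) {
    cl <- cell_spec("c", "hipsc", c(0, 0, 2), 6, spontaneous_period_s = 5,
                    phase_s = 2.5)
    tr <- simulate_traces(list(cl), duration_s = 15, rate_hz = 4, seed = s,
                          noise_sd = 10)
    ev <- detect_events(dff(tr$traces[, 1], dt_s = 0.25))
    if (nrow(ev) == 3 &&
        all(abs(ev$peak_time_s - (c(2.5, 7.5, 12.5) + delay)) <= 0.25))
      n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 99)
})

test_that("adult kinetics give a steeper (more negative) decay slope than hiPSC", {
  mk <- function(kind) {
    cl <- cell_spec("c", kind, c(0, 0, 2),
                    if (kind == "adult") c(30, 10) else 6,
                    spontaneous_period_s = 5, phase_s = 2.5,
                    paced_responsive = FALSE)
    tr <- simulate_traces(list(cl), duration_s = 15, rate_hz = 8, seed = 1)
    detect_events(dff(tr$traces[, 1], dt_s = 0.125))
  }
  ad <- mk("adult"); hp <- mk("hipsc")
  expect_lt(mean(ad$decay_slope), mean(hp$decay_slope))
  expect_lt(mean(ad$decay_slope), 0)
})

test_that("period measurement averages inter-event intervals", {
  ev <- data.frame(peak_time_s = c(0, 5, 10))
  p <- measure_period(ev)
  expect_equal(p$period_s, 5)
  expect_equal(p$sd_s, 0)
  expect_null(measure_period(data.frame(peak_time_s = 3)))
  # generator parameter recovery at the 6.25 s spontaneous rhythm
  cl <- cell_spec("c", "hipsc", c(0, 0, 2), 6, spontaneous_period_s = 6.25,
                  phase_s = 1.2)
  tr <- simulate_traces(list(cl), duration_s = 30, rate_hz = 4, seed = 2,
                        noise_sd = 10)
  ev2 <- detect_events(dff(tr$traces[, 1], dt_s = 0.25))
  expect_lt(abs(measure_period(ev2)$period_s - 6.25), 0.25)
})

test_that("pacing capture counts events inside the post-stimulus window", {
  stim <- c(1, 3, 5, 7)
  ev <- data.frame(peak_time_s = stim + 0.2)
  expect_equal(pacing_capture(ev, stim, 0.5)$fraction, 1.0)
  expect_equal(pacing_capture(data.frame(peak_time_s = numeric(0)),
                              stim, 0.5)$fraction, 0.0)
  expect_error(pacing_capture(ev, stim, 2.5), "overlap")
  # full pipeline: paced generator run at 0.5 Hz is fully captured
  cl <- cell_spec("c", "hipsc", c(0, 0, 2), 6, spontaneous_period_s = 6.25)
  tr <- simulate_traces(list(cl), pacing_protocol(enabled = TRUE),
                        duration_s = 15, rate_hz = 4, seed = 1,
                        noise_sd = 5)
  ev2 <- detect_events(dff(tr$traces[, 1], dt_s = 0.25))
  cap <- pacing_capture(ev2, tr$ground_truth$stimuli, 0.5)
  expect_equal(cap$fraction, 1.0)
})
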