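#' Configuration of the low-magnification widefield renderer
#'
#' @param shape `c(rows, cols)` of the camera frame in pixels.
#' @param px_um Sample-space pixel size, um.
#' @param fps Frame rate.
#' @param bg_level Transillumination background intensity, counts.
#' @param cell_absorbance Fractional darkening of the transillumination
#'   image inside an adult cell body.
#' @param shortening_frac Fractional shortening of the adult long axis at
#'   full activation.
#' @param fluo_scale Counts per unit fluorescence in the epi-fluorescence
#'   channel.
#' @param noise_sd Gaussian camera noise SD, counts.
#' @return Object of class `widefield_config`.
#' @export
widefield_config <- function(shape = c(56, 80), px_um = 1, fps = 4,
                             bg_level = 1000, cell_absorbance = 0.4,
                             shortening_frac = 0.1, fluo_scale = 1,
                             noise_sd = 3) {
  stopifnot(length(shape) == 2, all(shape >= 8), px_um > 0, fps > 0,
            bg_level > 0, cell_absorbance > 0, cell_absorbance < 1,
            shortening_frac > 0, shortening_frac < 1, noise_sd >= 0)
  structure(list(shape = as.integer(shape), px_um = px_um, fps = fps,
                 bg_level = bg_level, cell_absorbance = cell_absorbance,
                 shortening_frac = shortening_frac, fluo_scale = fluo_scale,
                 noise_sd = noise_sd),
            class = "widefield_config")
}

# soft oriented-rectangle footprint of an adult cell in widefield pixels,
# with the long axis shortened by factor (1 - shorten)
rect_footprint <- function(cl, config, shorten = 0) {
  px <- config$px_um
  nr <- config$shape[1]; nc <- config$shape[2]
  x0 <- cl$centroid_um[1] / px; y0 <- cl$centroid_um[2] / px
  L <- cl$size_um[1] * (1 - shorten) / px / 2
  W <- cl$size_um[2] / px / 2
  th <- cl$orientation_deg * pi / 180
  X <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) - x0
  Y <- matrix(0:(nr - 1), nr, nc) - y0
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  edge <- 0.7
  stats::plogis((L - abs(U)) / edge) * stats::plogis((W - abs(V)) / edge)
}

# isotropic blob footprint of a hiPSC cell in widefield pixels
blob_footprint <- function(cl, config) {
  px <- config$px_um
  nr <- config$shape[1]; nc <- config$shape[2]
  sig <- max(cl$size_um[1] / px / 2, 0.8)
  X <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) - cl$centroid_um[1] / px
  Y <- matrix(0:(nr - 1), nr, nc) - cl$centroid_um[2] / px
  exp(-(X^2 + Y^2) / (2 * sig^2))
}

#' Render a 2D widefield acquisition (transillumination + fluorescence)
#'
#' Transillumination: adult cells appear as dark rectangles on a bright
#' background; a contracting cell's rectangle shortens along its long axis
#' following the normalised displacement trace, so the temporal standard
#' deviation of the image is elevated at the two cell ends. The confluent
#' hiPSC monolayer is essentially transparent in transillumination and
#' contributes no contrast. Fluorescence: projected Fluo-4 intensity with no
#' optical sectioning -- the hiPSC layer and adult cells are summed.
#'
#' @param cells List of [cell_spec()]s.
#' @param traces A [simulate_traces()] result; its sampling rate should
#'   equal `config$fps`.
#' @param config A [widefield_config()].
#' @param seed Integer seed for the camera noise.
#' @return List with `transillumination` and `fluorescence`
#'   (`[row, col, frame]` arrays), `dt_s` and `config`.
#' @export
render_widefield <- function(cells, traces, config = widefield_config(),
                             seed = 1) {
  stopifnot(inherits(traces, "simulated_traces"),
            inherits(config, "widefield_config"))
  nT <- length(traces$times)
  nr <- config$shape[1]; nc <- config$shape[2]
  trans <- array(0, dim = c(nr, nc, nT))
  fluo <- array(0, dim = c(nr, nc, nT))
  adult_idx <- which(vapply(cells, function(cl) cl$kind == "adult",
                            logical(1)))
  hipsc_idx <- setdiff(seq_along(cells), adult_idx)
  # static hiPSC fluorescence footprints (shape does not move)
  hipsc_fp <- lapply(cells[hipsc_idx], blob_footprint, config = config)
  for (t in seq_len(nT)) {
    tr <- matrix(config$bg_level, nr, nc)
    fl <- matrix(0, nr, nc)
    for (j in seq_along(hipsc_idx))
      fl <- fl + hipsc_fp[[j]] * traces$traces[t, hipsc_idx[j]]
    for (i in adult_idx) {
      sh <- config$shortening_frac * traces$displacement[t, i]
      fp <- rect_footprint(cells[[i]], config, shorten = sh)
      tr <- tr - config$bg_level * config$cell_absorbance * fp
      fl <- fl + fp * traces$traces[t, i]
    }
    trans[, , t] <- tr
    fluo[, , t] <- config$fluo_scale * fl
  }
  if (config$noise_sd > 0) {
    withr::with_seed(seed, {
      trans <- trans + array(stats::rnorm(length(trans), 0, config$noise_sd),
                             dim = dim(trans))
      fluo <- fluo + array(stats::rnorm(length(fluo), 0, config$noise_sd),
                           dim = dim(fluo))
    })
  }
  list(transillumination = pmax(trans, 0), fluorescence = pmax(fluo, 0),
       dt_s = 1 / config$fps, config = config)
}
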