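#' Optical and detector configuration for rendering synthetic acquisitions
#'
#' @param geometry An [acquisition_geometry()].
#' @param frame_shape `c(rows, cols)` of ONE spectral half of the detector
#'   frame; the full dual-channel frame stacks the two halves per
#'   `channel_layout`.
#' @param sheet_waist_um Gaussian light-sheet thickness (1/e^2 full waist),
#'   um; emitters are weighted `exp(-2 d^2 / waist^2)` with `d` the distance
#'   from the sheet along the detection axis.
#' @param fpn_map Fixed-pattern-noise offset image of the full dual-channel
#'   frame; `NULL` builds a deterministic default pattern (column stripes on
#'   a gentle gradient).
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param shot_noise Apply Poisson shot noise to the photon signal.
#' @param photon_scale Counts per unit fluorophore concentration; 0 renders
#'   no photons at all (frames are then FPN + read noise only).
#' @param bg_rate Uniform background fluorophore level inside the slit (in
#'   the same units as cell fluorescence, i.e. multiplied by
#'   `photon_scale`).
#' @param channel_layout `"top-bottom"` or `"left-right"`.
#' @param green_first Whether the green (Fluo-4) half is the first tile.
#' @param chromatic [affine_params()] describing the residual chromatic
#'   transform of the Fluo-4 path, acting about the half-frame centre:
#'   green-channel features sit at `chromatic(p)` when the corresponding red
#'   features sit at `p` (the default ~0.9x scale mimics the extra
#'   magnification of the Fluo-4 arm). Its scale must lie in (0.5, 1.5).
#' @param slit_inset_px Dark border (pixels) of the rectangular field slit
#'   on each side of each half-frame; photons fall only inside the slit.
#' @param psf_sigma_px Lateral Gaussian blur SD applied to point-like
#'   sources, pixels.
#' @param cmo_level Static red-channel (CMO) fluorophore level relative to
#'   each cell's `baseline_f`.
#' @return Object of class `optics_config`.
#' @export
optics_config <- function(geometry = acquisition_geometry(),
                          frame_shape = c(64, 96), sheet_waist_um = 3,
                          fpn_map = NULL, read_noise_sd = 2,
                          shot_noise = TRUE, photon_scale = 1, bg_rate = 2,
                          channel_layout = c("top-bottom", "left-right"),
                          green_first = TRUE,
                          chromatic = affine_params(rotation_deg = 0.3,
                                                    scale_x = 0.9,
                                                    scale_y = 0.9,
                                                    tx_px = 1.2,
                                                    ty_px = -0.8),
                          slit_inset_px = 3, psf_sigma_px = 1.2,
                          cmo_level = 0.6) {
  channel_layout <- match.arg(channel_layout)
  stopifnot(inherits(geometry, "acquisition_geometry"),
            length(frame_shape) == 2, all(frame_shape >= 8),
            sheet_waist_um > 0, read_noise_sd >= 0, photon_scale >= 0,
            bg_rate >= 0, psf_sigma_px > 0)
  if (chromatic$scale_x <= 0.5 || chromatic$scale_x >= 1.5 ||
      chromatic$scale_y <= 0.5 || chromatic$scale_y >= 1.5)
    stop("chromatic scale must lie in (0.5, 1.5)")
  full_shape <- if (channel_layout == "top-bottom")
    c(2 * frame_shape[1], frame_shape[2])
  else c(frame_shape[1], 2 * frame_shape[2])
  if (is.null(fpn_map)) fpn_map <- default_fpn_map(full_shape)
  if (!identical(dim(fpn_map), as.integer(full_shape)))
    stop("fpn_map shape must match the full dual-channel frame")
  structure(list(geometry = geometry, frame_shape = as.integer(frame_shape),
                 full_shape = as.integer(full_shape),
                 sheet_waist_um = sheet_waist_um, fpn_map = fpn_map,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 photon_scale = photon_scale, bg_rate = bg_rate,
                 channel_layout = channel_layout, green_first = green_first,
                 chromatic = chromatic, slit_inset_px = slit_inset_px,
                 psf_sigma_px = psf_sigma_px, cmo_level = cmo_level),
            class = "optics_config")
}

# deterministic sCMOS-like offset pattern: column stripes + mild gradient
default_fpn_map <- function(shape) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  100 + 4 * sin(2 * pi * cc / 7) + 2 * r / shape[1]
}

# slit support mask (logical matrix) of one half-frame
slit_mask <- function(optics) {
  m <- matrix(FALSE, optics$frame_shape[1], optics$frame_shape[2])
  ins <- optics$slit_inset_px
  m[(ins + 1):(optics$frame_shape[1] - ins),
    (ins + 1):(optics$frame_shape[2] - ins)] <- TRUE
  m
}

#' Slit bounds of the rendered field as 1-based inclusive index ranges
#'
#' @param optics An [optics_config()].
#' @return `list(row = c(first, last), col = c(first, last))` within one
#'   half-frame.
#' @export
slit_bounds <- function(optics) {
  ins <- optics$slit_inset_px
  list(row = c(ins + 1L, optics$frame_shape[1] - ins),
       col = c(ins + 1L, optics$frame_shape[2] - ins))
}

# chromatic transform re-centred on the half-frame centre
chromatic_centred <- function(optics) {
  ctr <- c((optics$frame_shape[2] - 1) / 2, (optics$frame_shape[1] - 1) / 2)
  shift <- function(t) {
    a <- affine_params(); a$offset <- t; a$tx_px <- t[1]; a$ty_px <- t[2]; a
  }
  compose_affine(shift(ctr), compose_affine(optics$chromatic, shift(-ctr)))
}

# additively draw a cell footprint (in fluorophore units, weight w) into a
# half-frame image; positions are 0-based pixel centres (x = col, y = row)
draw_cell <- function(img, cl, x0, y0, w, optics) {
  if (w <= 0) return(img)
  px <- optics$geometry$px_sample
  nr <- nrow(img); nc <- ncol(img)
  if (cl$kind == "hipsc") {
    sig <- max(cl$size_um[1] / px / 2, optics$psf_sigma_px)
    ext <- ceiling(3 * sig)
  } else {
    L <- cl$size_um[1] / px / 2; W <- cl$size_um[2] / px / 2
    ext <- ceiling(sqrt(L^2 + W^2) + 3)
  }
  rr <- max(0, floor(y0 - ext)):min(nr - 1, ceiling(y0 + ext))
  cc <- max(0, floor(x0 - ext)):min(nc - 1, ceiling(x0 + ext))
  if (length(rr) == 0 || length(cc) == 0) return(img)
  X <- matrix(cc, length(rr), length(cc), byrow = TRUE) - x0
  Y <- matrix(rr, length(rr), length(cc)) - y0
  if (cl$kind == "hipsc") {
    f <- exp(-(X^2 + Y^2) / (2 * sig^2))
  } else {
    th <- cl$orientation_deg * pi / 180
    U <- X * cos(th) + Y * sin(th)
    V <- -X * sin(th) + Y * cos(th)
    edge <- max(optics$psf_sigma_px * 0.7, 0.7)
    f <- stats::plogis((L - abs(U)) / edge) * stats::plogis((W - abs(V)) / edge)
  }
  img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + w * f
  img
}

# assemble a full dual-channel detector frame from ideal half images
assemble_frame <- function(green_half, red_half, optics) {
  if (optics$channel_layout == "top-bottom") {
    if (optics$green_first) rbind(green_half, red_half)
    else rbind(red_half, green_half)
  } else {
    if (optics$green_first) cbind(green_half, red_half)
    else cbind(red_half, green_half)
  }
}

# detector noise model: Poisson shot noise on the photon signal, fixed
# pattern offset, then Gaussian read noise; counts clamped at 0
add_detector_noise <- function(photons, optics) {
  counts <- if (optics$shot_noise && any(photons > 0)) {
    p <- stats::rpois(length(photons), as.vector(photons))
    matrix(p, nrow(photons))
  } else photons
  counts <- counts + optics$fpn_map
  if (optics$read_noise_sd > 0)
    counts <- counts + matrix(
      stats::rnorm(length(counts), 0, optics$read_noise_sd), nrow(counts))
  pmax(counts, 0)
}

#' Render a 3D oblique light-sheet acquisition as raw detector frames
#'
#' Produces the camera-frame sequence of a plane-scanned acquisition: for
#' each of `T` volumes, `n_planes` frames are emitted plane-major
#' (`N = Z x T`). Plane `k` samples the tilted sheet at depth `k * dz'`
#' along the detection axis; each cell contributes a lateral footprint at
#' its in-sheet position weighted by the Gaussian sheet profile. Each frame
#' holds both spectral half-images; the Fluo-4 half is pre-distorted by the
#' chromatic affine, and the dark slit border, fixed-pattern noise, shot
#' noise and read noise are applied.
#'
#' @param cells List of [cell_spec()]s.
#' @param traces A [simulate_traces()] result; its sampling rate should be
#'   the volume rate.
#' @param optics An [optics_config()].
#' @param seed Integer seed for the noise draws.
#' @return Object of class `raw_frame_sequence`: list with `frames`
#'   (`[row, col, N]` array), `dt_s` (inter-frame interval), `optics` and
#'   `ground_truth`.
#' @export
render_acquisition <- function(cells, traces, optics = optics_config(),
                               seed = 1) {
  stopifnot(inherits(traces, "simulated_traces"),
            inherits(optics, "optics_config"))
  geo <- optics$geometry
  nT <- length(traces$times)
  Z <- geo$n_planes
  nr <- optics$frame_shape[1]; nc <- optics$frame_shape[2]
  mask <- slit_mask(optics)
  chrom_inv <- invert_affine(chromatic_centred(optics))

  # per-cell stack-frame coordinates
  pos <- t(vapply(cells, `[[`, numeric(3), "centroid_um"))
  stk <- if (length(cells)) lab_to_stack(pos, geo) else
    matrix(numeric(0), ncol = 3)
  frames <- array(0, dim = c(optics$full_shape, Z * nT))

  withr::with_seed(seed, {
    for (t in seq_len(nT)) {
      for (k in seq_len(Z)) {
        g <- matrix(0, nr, nc); r <- matrix(0, nr, nc)
        for (i in seq_along(cells)) {
          dz_um <- (k - 1 - stk[i, "k"]) * geo$dz_prime
          w <- exp(-2 * dz_um^2 / optics$sheet_waist_um^2)
          if (w < 1e-4) next
          g <- draw_cell(g, cells[[i]], stk[i, "col"], stk[i, "row"],
                         w * traces$traces[t, i], optics)
          r <- draw_cell(r, cells[[i]], stk[i, "col"], stk[i, "row"],
                         w * optics$cmo_level * cells[[i]]$baseline_f,
                         optics)
        }
        g <- g + optics$bg_rate; r <- r + optics$bg_rate
        g <- apply_affine(g, chrom_inv)
        g[!mask] <- 0; r[!mask] <- 0
        photons <- optics$photon_scale * assemble_frame(g, r, optics)
        frames[, , (t - 1) * Z + k] <- add_detector_noise(photons, optics)
      }
    }
  })

  structure(list(frames = frames, dt_s = 1 / (traces$rate_hz * Z),
                 optics = optics, geometry = geo,
                 ground_truth = traces$ground_truth,
                 n_planes = Z, n_volumes = nT),
            class = "raw_frame_sequence")
}

#' Render a dual-channel bead-calibration frame
#'
#' The same bead field is imaged in both spectral halves; the green (Fluo-4)
#' positions are the red positions mapped through the chromatic affine
#' (about the half-frame centre). True correspondences are returned for
#' testing the registration fit.
#'
#' @param optics An [optics_config()].
#' @param n_beads Number of beads (>= 3; the affine fit needs three
#'   non-collinear points).
#' @param seed Integer seed for bead placement and noise.
#' @param positions Optional N x 2 `(x, y)` 0-based bead positions in the
#'   red half-frame (overrides random placement); a collinear layout is
#'   rejected.
#' @param bead_brightness Peak fluorophore level per bead.
#' @param min_sep_px Minimum pairwise bead distance for random placement
#'   (bead calibration slides are prepared sparse so that spots stay
#'   resolvable); placement fails after bounded retries if the frame cannot
#'   hold `n_beads` at this spacing.
#' @return List with `frames` (`[row, col, 1]` array), `beads_red`,
#'   `beads_green` (true positions, row-aligned) and `optics`.
#' @export
render_bead_stack <- function(optics = optics_config(), n_beads = 9, seed = 1,
                              positions = NULL, bead_brightness = 500,
                              min_sep_px = 6) {
  stopifnot(inherits(optics, "optics_config"))
  nr <- optics$frame_shape[1]; nc <- optics$frame_shape[2]
  chrom <- chromatic_centred(optics)
  margin <- optics$slit_inset_px + 5
  red <- withr::with_seed(seed, {
    if (is.null(positions)) {
      if (n_beads < 3) stop("need at least 3 beads for an affine fit")
      # jittered grid: sparse, non-clumping placement for any seed
      gx <- seq(margin, nc - 1 - margin, by = min_sep_px)
      gy <- seq(margin, nr - 1 - margin, by = min_sep_px)
      grid <- as.matrix(expand.grid(x = gx, y = gy))
      if (nrow(grid) < n_beads)
        stop("frame too small for ", n_beads, " beads at spacing >= ",
             min_sep_px, " px")
      pick <- grid[sample.int(nrow(grid), n_beads), , drop = FALSE]
      jit <- matrix(stats::runif(2 * n_beads, -min_sep_px / 4,
                                 min_sep_px / 4), ncol = 2)
      pick + jit
    } else as.matrix(positions)
  })
  if (nrow(red) < 3) stop("need at least 3 beads for an affine fit")
  cf <- sweep(red, 2, colMeans(red))
  sv <- svd(cf)$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("bead layout is collinear; affine calibration would be degenerate")
  green <- transform_points(chrom, red)

  draw_beads <- function(pts) {
    img <- matrix(0, nr, nc)
    s <- optics$psf_sigma_px
    for (i in seq_len(nrow(pts))) {
      x0 <- pts[i, 1]; y0 <- pts[i, 2]
      rr <- max(0, floor(y0 - 4 * s)):min(nr - 1, ceiling(y0 + 4 * s))
      cc <- max(0, floor(x0 - 4 * s)):min(nc - 1, ceiling(x0 + 4 * s))
      if (!length(rr) || !length(cc)) next
      X <- matrix(cc, length(rr), length(cc), byrow = TRUE) - x0
      Y <- matrix(rr, length(rr), length(cc)) - y0
      img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] +
        bead_brightness * exp(-(X^2 + Y^2) / (2 * s^2))
    }
    img
  }
  mask <- slit_mask(optics)
  g <- draw_beads(green); r <- draw_beads(red)
  g[!mask] <- 0; r[!mask] <- 0
  photons <- optics$photon_scale * assemble_frame(g, r, optics)
  frame <- withr::with_seed(seed + 1L, add_detector_noise(photons, optics))
  list(frames = array(frame, dim = c(dim(frame), 1)),
       beads_red = red, beads_green = green, optics = optics)
}
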