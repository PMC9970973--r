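#' @title Detector-frame conditioning
#' @description Fixed-pattern-noise estimation/subtraction, spectral channel
#'   splitting, and channel co-registration. Frame sequences are 3D numeric
#'   arrays `[row, col, frame]` of non-negative counts.
#' @name preprocess
NULL

# coerce a list of matrices to [row, col, frame] array
as_frames <- function(frames) {
  if (is.list(frames)) {
    shp <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
      stop("frames differ in shape")
    frames <- array(unlist(frames), dim = c(shp, length(frames)))
  }
  if (length(dim(frames)) == 2) frames <- array(frames, dim = c(dim(frames), 1))
  stopifnot(length(dim(frames)) == 3)
  frames
}

#' Estimate the fixed-pattern-noise map from dark frames
#'
#' The map is the exact per-pixel arithmetic mean of shutter-closed detector
#' frames (and hence invariant to frame order).
#'
#' @param dark_frames 3D array `[row, col, frame]` or list of matrices.
#' @return Object of class `fixed_pattern_map` with elements `offset`
#'   (matrix, float counts) and `n_dark_frames`.
#' @export
estimate_fpn <- function(dark_frames) {
  dk <- as_frames(dark_frames)
  n <- dim(dk)[3]
  if (n < 1) stop("need at least one dark frame")
  offset <- rowMeans(dk, dims = 2)
  structure(list(offset = offset, n_dark_frames = n),
            class = "fixed_pattern_map")
}

#' Subtract a fixed-pattern-noise map from frames
#'
#' Corrected counts are clamped at zero: the FPN is an additive detector
#' offset, so a corrected pixel cannot be negative.
#'
#' @param frames Matrix or 3D frame array.
#' @param fpn A `fixed_pattern_map` (or plain offset matrix).
#' @return Corrected frames with the input shape.
#' @export
subtract_fpn <- function(frames, fpn) {
  offset <- if (inherits(fpn, "fixed_pattern_map")) fpn$offset else fpn
  d <- dim(frames)
  if (length(d) == 2) {
    if (!identical(d, dim(offset))) stop("frame/FPN shape mismatch")
    return(pmax(frames - offset, 0))
  }
  stopifnot(length(d) == 3)
  if (!identical(d[1:2], dim(offset))) stop("frame/FPN shape mismatch")
  out <- pmax(frames - as.vector(offset), 0)  # offset recycles over frames
  array(out, dim = d)
}

#' Split a dual-channel detector frame into its two spectral halves
#'
#' The image of each spectral channel falls on one half of the camera sensor;
#' the frame is cut into two equal tiles. By default the layout is
#' top/bottom with the green (Fluo-4) channel in the top half.
#'
#' @param frame Matrix, or 3D frame array (split applied per frame).
#' @param layout `"top-bottom"` (split rows) or `"left-right"` (split
#'   columns).
#' @param green_first If `TRUE` (default) the first tile (top or left) is the
#'   green channel.
#' @return `list(green = , red = )` of matrices (or 3D arrays).
#' @export
split_channels <- function(frame, layout = c("top-bottom", "left-right"),
                           green_first = TRUE) {
  layout <- match.arg(layout)
  d <- dim(frame)
  nd <- length(d)
  stopifnot(nd %in% c(2, 3))
  n <- if (layout == "top-bottom") d[1] else d[2]
  if (n %% 2 != 0)
    stop("cannot split ", layout, ": dimension ", n, " is odd")
  h <- n / 2
  take <- function(idx) {
    if (layout == "top-bottom") {
      if (nd == 2) frame[idx, , drop = FALSE] else frame[idx, , , drop = FALSE]
    } else {
      if (nd == 2) frame[, idx, drop = FALSE] else frame[, idx, , drop = FALSE]
    }
  }
  first <- take(seq_len(h)); second <- take(h + seq_len(h))
  if (green_first) list(green = first, red = second)
  else list(green = second, red = first)
}

#' Co-register the green channel onto the red channel's grid
#'
#' Applies the resampling transform (see [fit_affine()]) to every green
#' frame.
#'
#' @param green_frames Matrix or 3D frame array (Fluo-4, moving).
#' @param params `affine_params` resampling transform.
#' @param interpolation Passed to [apply_affine()].
#' @return Registered frames with the input shape.
#' @export
register_channels <- function(green_frames, params,
                              interpolation = "bilinear") {
  d <- dim(green_frames)
  if (length(d) == 2) return(apply_affine(green_frames, params, interpolation))
  out <- array(0, dim = d)
  for (i in seq_len(d[3]))
    out[, , i] <- apply_affine(green_frames[, , i], params, interpolation)
  out
}

#' Detect bead centroids in a single-channel image
#'
#' Finds isolated local maxima above a threshold and refines each to an
#' intensity-weighted centroid over a square window. Intended for sparse
#' sub-resolution bead fields where connected-component segmentation is
#' unnecessary.
#'
#' @param img Numeric matrix.
#' @param threshold Absolute intensity threshold; defaults to half the image
#'   maximum.
#' @param window Half-width of the centroid window in pixels.
#' @return N x 2 matrix of `(x, y)` 0-based centroid coordinates, ordered by
#'   decreasing peak intensity.
#' @export
detect_bead_centroids <- function(img, threshold = NULL, window = 3) {
  stopifnot(is.matrix(img))
  if (is.null(threshold)) threshold <- max(img) / 2
  nr <- nrow(img); nc <- ncol(img)
  cand <- which(img > threshold, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr & cand[, 2] > 1 & cand[, 2] < nc,
               , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
    keep[i] <- img[r, c] == max(nb) &&
      sum(nb == max(nb)) == 1   # strict local maximum
  }
  peaks <- cand[keep, , drop = FALSE]
  if (nrow(peaks) == 0) return(matrix(numeric(0), ncol = 2,
                                      dimnames = list(NULL, c("x", "y"))))
  o <- order(img[peaks], decreasing = TRUE)
  peaks <- peaks[o, , drop = FALSE]
  out <- matrix(NA_real_, nrow(peaks), 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(nrow(peaks))) {
    r <- peaks[i, 1]; c <- peaks[i, 2]
    rr <- max(1, r - window):min(nr, r + window)
    cc <- max(1, c - window):min(nc, c + window)
    w <- img[rr, cc]
    w <- pmax(w - threshold / 2, 0)       # suppress background in the window
    tot <- sum(w)
    out[i, ] <- c(sum(rep(cc - 1, each = length(rr)) * w) / tot,
                  sum(rep(rr - 1, times = length(cc)) * w) / tot)
  }
  out
}

#' Match two centroid sets by mutual nearest neighbours
#'
#' @param moving,fixed N x 2 `(x, y)` coordinate matrices.
#' @param max_dist Maximum pairing distance in pixels.
#' @return `list(moving = , fixed = )` of row-aligned matched coordinates.
#' @export
match_centroids <- function(moving, fixed, max_dist = 10) {
  if (nrow(moving) == 0 || nrow(fixed) == 0)
    return(list(moving = moving[0, , drop = FALSE],
                fixed = fixed[0, , drop = FALSE]))
  d2 <- outer(moving[, 1], fixed[, 1], "-")^2 +
    outer(moving[, 2], fixed[, 2], "-")^2
  im <- apply(d2, 1, which.min)
  jf <- apply(d2, 2, which.min)
  ok <- which(jf[im] == seq_len(nrow(moving)) &
                d2[cbind(seq_len(nrow(moving)), im)] <= max_dist^2)
  list(moving = moving[ok, , drop = FALSE],
       fixed = fixed[im[ok], , drop = FALSE])
}

#' Fit the channel co-registration transform from a bead acquisition
#'
#' Convenience pipeline: split a dual-channel bead frame, detect bead
#' centroids in each half, pair them by mutual nearest neighbour and fit the
#' affine resampling transform of the green channel.
#'
#' @param bead_frame Dual-channel detector frame (matrix) or frame array
#'   (temporal mean is used).
#' @param layout,green_first Passed to [split_channels()].
#' @param max_dist Centroid pairing distance, pixels.
#' @return `affine_params` with attribute `residual_rms`.
#' @export
calibrate_registration <- function(bead_frame, layout = "top-bottom",
                                   green_first = TRUE, max_dist = 10) {
  fr <- as_frames(bead_frame)
  img <- rowMeans(fr, dims = 2)
  ch <- split_channels(img, layout, green_first)
  cg <- detect_bead_centroids(ch$green)
  cr <- detect_bead_centroids(ch$red)
  m <- match_centroids(cg, cr, max_dist)
  if (nrow(m$moving) < 3)
    stop("fewer than 3 bead correspondences found")
  fit_affine(m$moving, m$fixed)
}
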