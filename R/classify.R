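#' Temporal activity map of a frame sequence
#'
#' Per-pixel temporal standard deviation divided by the temporal mean.
#' The population (1/n) standard deviation is used, so for a pixel
#' alternating between 90 and 110 the map value is exactly
#' 10/100 = 0.1. Pixels with zero temporal mean are flagged `NA` (the ratio
#' is undefined there) rather than propagated as infinities.
#'
#' @param frames `[row, col, frame]` array (>= 2 frames) or list of
#'   matrices.
#' @param source `"transillumination"` or `"fluorescence"` (metadata).
#' @return Object of class `activity_map` with elements `map` and
#'   `source`.
#' @export
activity_map <- function(frames,
                         source = c("transillumination", "fluorescence")) {
  source <- match.arg(source)
  fr <- as_frames(frames)
  n <- dim(fr)[3]
  if (n < 2) stop("activity map needs at least 2 frames")
  mu <- rowMeans(fr, dims = 2)
  ss <- rowMeans(fr^2, dims = 2) - mu^2
  sd_pop <- sqrt(pmax(ss, 0))
  map <- sd_pop / mu
  map[mu == 0] <- NA_real_
  structure(list(map = map, source = source, n_frames = n),
            class = "activity_map")
}

# analytic end-band and background-ring masks of a rod-shaped cell in the
# map's pixel grid; band_frac is the fraction of the long axis per end
cell_region_masks <- function(cl, shape, px_um, band_frac = 0.15,
                              ring_width_px = 4) {
  nr <- shape[1]; nc <- shape[2]
  x0 <- cl$centroid_um[1] / px_um; y0 <- cl$centroid_um[2] / px_um
  L <- cl$size_um[1] / px_um / 2; W <- cl$size_um[2] / px_um / 2
  th <- cl$orientation_deg * pi / 180
  X <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) - x0
  Y <- matrix(0:(nr - 1), nr, nc) - y0
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  pad <- 1.5   # allow for edge softness and motion excursion
  inside <- abs(U) <= L + pad & abs(V) <= W + pad
  ends <- inside & abs(U) >= L * (1 - 2 * band_frac) - pad
  ring <- !inside & abs(U) <= L + pad + ring_width_px &
    abs(V) <= W + pad + ring_width_px
  list(ends = ends, ring = ring, body = inside)
}

#' Classify a rod-shaped cell as contracting from a transillumination
#' activity map
#'
#' A contracting cell's ends sweep back and forth, lighting up the activity
#' map as bright outlines at the two ends of the long axis. The cell is
#' called contracting when the mean map value over the two end bands exceeds
#' `threshold` times the mean over a background ring around the cell.
#'
#' @param map An [activity_map()] (transillumination source).
#' @param cell The adult [cell_spec()] (provides the rectangle geometry).
#' @param px_um Pixel size of the map, um.
#' @param threshold End-band / background ratio threshold.
#' @param band_frac Fraction of the long axis in each end band.
#' @param ring_width_px Background ring width, pixels.
#' @return Logical.
#' @export
is_contracting <- function(map, cell, px_um, threshold = 3,
                           band_frac = 0.15, ring_width_px = 4) {
  m <- if (inherits(map, "activity_map")) map$map else map
  masks <- cell_region_masks(cell, dim(m), px_um, band_frac, ring_width_px)
  if (!any(masks$ends) || !any(masks$ring))
    stop("cell mask is empty or falls outside the map")
  ends_mean <- mean(m[masks$ends], na.rm = TRUE)
  ring_mean <- mean(m[masks$ring], na.rm = TRUE)
  isTRUE(ends_mean > threshold * max(ring_mean, .Machine$double.eps))
}

#' Does a cell show calcium transients?
#'
#' 3D path: at least one detected transient event in the cell's ROI trace.
#' Widefield path: the fluorescence activity map averaged over the cell
#' body exceeds a threshold.
#'
#' @param events A `transient_events` data frame (3D path), or `NULL`.
#' @param map An [activity_map()] of the fluorescence channel (widefield
#'   path), or `NULL`.
#' @param cell,px_um Cell geometry for the widefield path.
#' @param map_threshold Mean body std/mean threshold for the widefield
#'   path.
#' @return Logical.
#' @export
has_transients <- function(events = NULL, map = NULL, cell = NULL,
                           px_um = NULL, map_threshold = 0.1) {
  if (!is.null(events)) return(nrow(events) >= 1)
  if (is.null(map) || is.null(cell) || is.null(px_um))
    stop("widefield path needs map, cell and px_um")
  m <- if (inherits(map, "activity_map")) map$map else map
  masks <- cell_region_masks(cell, dim(m), px_um)
  mean(m[masks$body], na.rm = TRUE) > map_threshold
}

#' Match two event trains by peak-time proximity
#'
#' Greedy one-to-one matching over candidate pairs within `tol_s`, taken in
#' order of increasing time difference (then time). The procedure is
#' symmetric in the two trains and the number of matches is non-decreasing
#' in `tol_s`.
#'
#' @param peaks_a,peaks_b Event peak times, seconds.
#' @param tol_s Matching tolerance.
#' @return Matrix with columns `a`, `b` of matched times (0 rows if none).
#' @export
match_peaks <- function(peaks_a, peaks_b, tol_s = 0.5) {
  stopifnot(tol_s > 0)
  if (!length(peaks_a) || !length(peaks_b))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  pairs <- expand.grid(i = seq_along(peaks_a), j = seq_along(peaks_b))
  pairs$d <- abs(peaks_a[pairs$i] - peaks_b[pairs$j])
  pairs <- pairs[pairs$d <= tol_s, , drop = FALSE]
  pairs <- pairs[order(pairs$d, peaks_a[pairs$i], peaks_b[pairs$j]), ,
                 drop = FALSE]
  used_a <- logical(length(peaks_a)); used_b <- logical(length(peaks_b))
  keep <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      keep <- c(keep, r)
    }
  }
  cbind(a = peaks_a[pairs$i[keep]], b = peaks_b[pairs$j[keep]])
}

#' Are two event trains synchronized?
#'
#' True when both trains are non-empty and the matched fraction of the
#' shorter train (see [match_peaks()]) is at least `min_match_frac`.
#'
#' @param peaks_a,peaks_b Event peak times, seconds.
#' @param tol_s Matching tolerance.
#' @param min_match_frac Required matched fraction of the shorter train.
#' @return Logical.
#' @export
is_synchronized <- function(peaks_a, peaks_b, tol_s = 0.5,
                            min_match_frac = 0.8) {
  if (!length(peaks_a) || !length(peaks_b)) return(FALSE)
  m <- match_peaks(peaks_a, peaks_b, tol_s)
  nrow(m) / min(length(peaks_a), length(peaks_b)) >= min_match_frac
}

#' Classify an adult cell as electrically coupled to the hiPSC layer
#'
#' Coupled when the adult and hiPSC event trains are synchronized in the
#' unpaced acquisition, OR synchronized in the paced acquisition with at
#' least one matched pair not attributable to the stimulation (the adult
#' peak of the pair lies outside every stimulus capture window). Synchrony
#' observed only at the pacing frequency is explicitly NOT coupling: the
#' cells may simply both be responding to the field.
#'
#' @param adult_unpaced,hipsc_unpaced Peak times in the unpaced
#'   acquisition; pass `NULL` for `adult_unpaced` (with a warning recorded
#'   via the `restricted` attribute) when no unpaced acquisition exists.
#' @param adult_paced,hipsc_paced Peak times in the paced acquisition.
#' @param stimuli Stimulus times of the paced acquisition.
#' @param tol_s,min_match_frac Synchrony parameters (see
#'   [is_synchronized()]).
#' @param capture_window_s Post-stimulus window attributing an event to the
#'   stimulation.
#' @return Logical; attribute `restricted` is `TRUE` when only the paced
#'   rule could be applied.
#' @export
classify_coupled <- function(adult_unpaced, hipsc_unpaced, adult_paced,
                             hipsc_paced, stimuli, tol_s = 0.5,
                             min_match_frac = 0.8, capture_window_s = 0.5) {
  restricted <- is.null(adult_unpaced)
  if (!restricted &&
      is_synchronized(adult_unpaced, hipsc_unpaced, tol_s, min_match_frac)) {
    out <- TRUE
  } else if (is_synchronized(adult_paced, hipsc_paced, tol_s,
                             min_match_frac)) {
    m <- match_peaks(adult_paced, hipsc_paced, tol_s)
    in_window <- vapply(m[, "a"], function(t)
      any(t >= stimuli & t <= stimuli + capture_window_s), logical(1))
    out <- any(!in_window)
  } else {
    out <- FALSE
  }
  attr(out, "restricted") <- restricted
  out
}

# event detection on one cell's fluorescence trace
trace_events <- function(values, dt_s, ...) {
  tr <- dff(values, dt_s = dt_s)
  detect_events(tr, ...)
}

#' Classify every FOV of a simulated cohort
#'
#' Runs the full screening pipeline per FOV: dF/F0 event detection on the
#' adult cell and its nearest hiPSC neighbour in both acquisitions,
#' synchrony-based coupling classification with the pacing-frequency
#' exclusion, and (optionally) contraction detection on a rendered
#' transillumination activity map via the end-band rule.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param tol_s,min_match_frac,capture_window_s Coupling parameters.
#' @param min_separation_s Event-detection separation.
#' @param contraction `"render"` (render widefield transillumination per
#'   FOV and apply [is_contracting()]) or `"skip"` (`NA` labels).
#' @param wf_config [widefield_config()] for the contraction path.
#' @param contraction_threshold End-band ratio threshold.
#' @return Data frame with one row per FOV: condition columns, classified
#'   `contracting`, adult/hiPSC transient flags per acquisition, and
#'   `coupled`.
#' @export
classify_cohort <- function(cohort, tol_s = 0.5, min_match_frac = 0.8,
                            capture_window_s = 0.5, min_separation_s = 0.5,
                            contraction = c("render", "skip"),
                            wf_config = NULL, contraction_threshold = 3) {
  contraction <- match.arg(contraction)
  if (is.null(wf_config) && contraction == "render") {
    f <- cohort$fovs[[1]]
    wf_config <- widefield_config(
      shape = c(ceiling(f$field_um[2]), ceiling(f$field_um[1])),
      px_um = 1, fps = cohort$rate_hz)
  }
  rows <- lapply(cohort$fovs, function(f) {
    kinds <- vapply(f$cells, `[[`, character(1), "kind")
    adult <- which(kinds == "adult")[1]
    hipsc_idx <- which(kinds == "hipsc")
    # nearest hiPSC ROI to the adult cell
    ad_pos <- f$cells[[adult]]$centroid_um[1:2]
    dists <- vapply(hipsc_idx, function(i)
      sum((f$cells[[i]]$centroid_um[1:2] - ad_pos)^2), numeric(1))
    href <- hipsc_idx[which.min(dists)]
    dt <- 1 / cohort$rate_hz
    ev <- function(acq, i) trace_events(acq$traces[, i], dt,
                                        min_separation_s = min_separation_s)
    a_un <- ev(f$unpaced, adult); h_un <- ev(f$unpaced, href)
    a_pa <- ev(f$paced, adult);  h_pa <- ev(f$paced, href)
    coupled <- classify_coupled(a_un$peak_time_s, h_un$peak_time_s,
                                a_pa$peak_time_s, h_pa$peak_time_s,
                                f$stimuli, tol_s, min_match_frac,
                                capture_window_s)
    contracting <- NA
    if (contraction == "render") {
      contracting <- FALSE
      for (acq in list(f$unpaced, f$paced)) {
        wf <- render_widefield(f$cells, acq, wf_config, seed = f$seed + 3L)
        am <- activity_map(wf$transillumination, "transillumination")
        if (is_contracting(am, f$cells[[adult]], wf_config$px_um,
                           threshold = contraction_threshold)) {
          contracting <- TRUE
          break
        }
      }
    }
    data.frame(fov_id = f$fov_id, coculture = f$condition$coculture,
               day = f$condition$day, nbleb = f$condition$nbleb,
               contracting = contracting,
               transients_unpaced = nrow(a_un) >= 1,
               transients_paced = nrow(a_pa) >= 1,
               hipsc_transients_unpaced = nrow(h_un) >= 1,
               hipsc_transients_paced = nrow(h_pa) >= 1,
               coupled = as.logical(coupled),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
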