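#' Rectangular single-plane 3D ROI
#'
#' A `100 x 100 x 1`-voxel region by default, matching the ROI size used for
#' dF/F0 trace extraction from reconstructed volumes. Ranges are 1-based
#' inclusive.
#'
#' @param x,y `c(first, last)` voxel ranges along x and y.
#' @param z Single z plane index.
#' @param channel Channel label (`"green"`/`"red"`).
#' @param label `"hipsc"` or `"adult"`.
#' @return Object of class `roi3d`.
#' @export
roi3d <- function(x, y, z, channel = "green",
                  label = c("hipsc", "adult")) {
  label <- match.arg(label)
  stopifnot(length(x) == 2, length(y) == 2, length(z) == 1,
            x[1] <= x[2], y[1] <= y[2], z >= 1)
  structure(list(x = as.integer(x), y = as.integer(y), z = as.integer(z),
                 channel = channel, label = label),
            class = "roi3d")
}

#' Mean-intensity trace of an ROI over a volume timelapse
#'
#' @param volumes A `[z, y, x, t]` array, a list of `lab_volume`s, or a
#'   `hyperstack` (whose `[row, col, z, t]` data is addressed with `y = row`,
#'   `x = col`).
#' @param roi An [roi3d()].
#' @param dt_s Sampling interval of the timelapse, seconds.
#' @return Object of class `trace`: `values` (mean ROI intensity per
#'   timepoint) and `dt_s`.
#' @export
roi_trace <- function(volumes, roi, dt_s = 1) {
  vals <- if (is.list(volumes) && inherits(volumes[[1]], "lab_volume")) {
    vapply(volumes, function(v) {
      d <- dim(v$data)
      check_roi(roi, d)
      mean(v$data[roi$z, roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]])
    }, numeric(1))
  } else if (inherits(volumes, "hyperstack")) {
    d <- dim(volumes$data)
    check_roi(roi, c(d[3], d[1], d[2]))
    apply(volumes$data[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2], roi$z, ,
                       drop = FALSE], 4, mean)
  } else {
    d <- dim(volumes)
    stopifnot(length(d) == 4)
    check_roi(roi, d[1:3])
    apply(volumes[roi$z, roi$y[1]:roi$y[2], roi$x[1]:roi$x[2], ,
                  drop = FALSE], 4, mean)
  }
  structure(list(values = as.numeric(vals), dt_s = dt_s), class = "trace")
}

check_roi <- function(roi, d_zyx) {
  if (roi$z > d_zyx[1] || roi$y[2] > d_zyx[2] || roi$x[2] > d_zyx[3])
    stop("ROI extends outside the volume")
  invisible(TRUE)
}

#' Estimate the baseline fluorescence F0 of a trace
#'
#' Default method: mean of the samples at or below the 10th percentile of
#' the trace (robust to the fraction of time spent in transients).
#' Alternative: mean over an explicit (pre-stimulus) time window.
#'
#' @param trace A `trace` object or numeric vector.
#' @param method `"percentile"` or `"window"`.
#' @param q Percentile (0-1) for the percentile method.
#' @param window `c(start_s, end_s)` for the window method.
#' @param dt_s Sampling interval when `trace` is a bare vector.
#' @return Baseline `f0` (> 0; offset-uncorrected traces that yield a
#'   non-positive baseline raise an error).
#' @export
estimate_f0 <- function(trace, method = c("percentile", "window"), q = 0.1,
                        window = NULL, dt_s = NULL) {
  method <- match.arg(method)
  v <- if (inherits(trace, "trace")) trace$values else as.numeric(trace)
  if (inherits(trace, "trace")) dt_s <- trace$dt_s
  if (!length(v)) stop("empty trace")
  f0 <- if (method == "percentile") {
    mean(v[v <= stats::quantile(v, q)])
  } else {
    stopifnot(!is.null(window), !is.null(dt_s))
    idx <- which(seq_along(v) * dt_s - dt_s >= window[1] &
                   seq_along(v) * dt_s - dt_s <= window[2])
    if (!length(idx)) stop("baseline window contains no samples")
    mean(v[idx])
  }
  if (f0 <= 0)
    stop("estimated F0 is not positive; offset-correct the trace first")
  f0
}

#' Compute the dF/F0 trace
#'
#' `(F - F0) / F0` elementwise; exactly invariant to multiplicative gain of
#' `F` when `F0` is estimated from the same trace.
#'
#' @param trace A `trace` object or numeric vector.
#' @param f0 Baseline; defaults to [estimate_f0()] of the trace.
#' @param dt_s Sampling interval when `trace` is a bare vector.
#' @return Object of class `dff_trace`: `values`, `f0`, `f0_method`,
#'   `dt_s`.
#' @export
dff <- function(trace, f0 = NULL, dt_s = NULL) {
  v <- if (inherits(trace, "trace")) trace$values else as.numeric(trace)
  if (inherits(trace, "trace")) dt_s <- trace$dt_s
  method <- "given"
  if (is.null(f0)) {
    f0 <- estimate_f0(v)
    method <- "percentile"
  }
  if (f0 <= 0) stop("f0 must be positive")
  structure(list(values = (v - f0) / f0, f0 = f0, f0_method = method,
                 dt_s = dt_s),
            class = "dff_trace")
}

# robust noise SD of a trace from first differences (transients are sparse
# so the difference distribution is noise-dominated)
robust_noise_sd <- function(v) {
  stats::mad(diff(v)) / sqrt(2)
}

# prominence of a local maximum: height above the higher of the two minima
# separating it from the nearest higher samples (or the record ends)
peak_prominence <- function(v, i) {
  higher_left <- which(v[seq_len(i - 1)] > v[i])
  lo <- if (length(higher_left)) max(higher_left) + 1 else 1
  higher_right <- which(v[(i + 1):length(v)] > v[i])
  hi <- if (length(higher_right)) i + min(higher_right) - 1 else length(v)
  left_min <- min(v[lo:i]); right_min <- min(v[i:hi])
  v[i] - max(left_min, right_min)
}

#' Detect calcium-transient events in a dF/F0 trace
#'
#' Local maxima with prominence above a threshold and a minimum mutual
#' separation. The default prominence threshold is five times the robust
#' noise SD of the trace (median absolute deviation of first differences,
#' scaled), floored at 0.05 dF/F0. The initial decay slope after each peak
#' is a least-squares linear fit over the first 30% of the fall (samples
#' until the trace has dropped by `decay_frac` of the prominence).
#'
#' @param x A `dff_trace` (or numeric vector with `dt_s`).
#' @param min_prominence Prominence threshold; `NULL` for the robust
#'   default.
#' @param min_separation_s Minimum separation between retained peaks.
#' @param decay_frac Fraction of the fall used for the decay-slope fit.
#' @param dt_s Sampling interval when `x` is a bare vector.
#' @return Data frame of class `transient_events`: `peak_time_s`,
#'   `peak_dff`, `prominence`, `decay_slope` (dF/F0 per second),
#'   `width_s` (half-prominence width). Zero rows if no event is found.
#' @export
detect_events <- function(x, min_prominence = NULL, min_separation_s = 0.5,
                          decay_frac = 0.3, dt_s = NULL) {
  v <- if (inherits(x, "dff_trace")) x$values else as.numeric(x)
  if (inherits(x, "dff_trace")) dt_s <- x$dt_s
  stopifnot(!is.null(dt_s), dt_s > 0)
  n <- length(v)
  empty <- data.frame(peak_time_s = numeric(0), peak_dff = numeric(0),
                      prominence = numeric(0), decay_slope = numeric(0),
                      width_s = numeric(0))
  class(empty) <- c("transient_events", "data.frame")
  if (n < 3) return(empty)
  if (is.null(min_prominence))
    min_prominence <- max(5 * robust_noise_sd(v), 0.05)
  # strict interior local maxima (plateaus: first sample of the plateau)
  cand <- which(diff(sign(diff(v))) < 0) + 1
  cand <- cand[vapply(cand, function(i) v[i] > v[i - 1] && v[i] >= v[i + 1],
                      logical(1))]
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # enforce separation, keeping the more prominent peak
  o <- order(prom, decreasing = TRUE)
  sel <- logical(0); sel_idx <- integer(0)
  for (j in o) {
    if (all(abs(cand[j] - sel_idx) * dt_s >= min_separation_s)) {
      sel_idx <- c(sel_idx, cand[j])
    }
  }
  sel_idx <- sort(sel_idx)
  prom <- prom[match(sel_idx, cand)]
  slope <- width <- numeric(length(sel_idx))
  for (j in seq_along(sel_idx)) {
    i <- sel_idx[j]
    stop_at <- if (j < length(sel_idx)) sel_idx[j + 1] - 1 else n
    target <- v[i] - decay_frac * prom[j]
    k <- i
    while (k < stop_at && v[k + 1] <= v[k] && v[k] > target) k <- k + 1
    k <- max(k, i + 1)
    if (k > n) k <- n
    seg <- i:min(k, n)
    slope[j] <- if (length(seg) >= 2)
      stats::coef(stats::lm(v[seg] ~ seg))[2] / dt_s else NA_real_
    # half-prominence width
    half <- v[i] - prom[j] / 2
    l <- i; while (l > 1 && v[l - 1] >= half) l <- l - 1
    r <- i; while (r < n && v[r + 1] >= half) r <- r + 1
    width[j] <- (r - l) * dt_s
  }
  out <- data.frame(peak_time_s = (sel_idx - 1) * dt_s, peak_dff = v[sel_idx],
                    prominence = prom, decay_slope = slope, width_s = width)
  class(out) <- c("transient_events", "data.frame")
  out
}

#' Mean and SD of the inter-event interval
#'
#' @param events A `transient_events` data frame (or vector of peak times).
#' @return `list(period_s, sd_s, n_intervals)`, or `NULL` when fewer than
#'   two events are available (the period is then undefined).
#' @export
measure_period <- function(events) {
  tt <- if (is.data.frame(events)) events$peak_time_s else as.numeric(events)
  if (length(tt) < 2) return(NULL)
  d <- diff(sort(tt))
  list(period_s = mean(d), sd_s = stats::sd(d), n_intervals = length(d))
}

#' Per-stimulus capture of transient events
#'
#' A stimulus is captured when an event peak falls inside
#' `[stimulus, stimulus + window_s]`.
#'
#' @param events A `transient_events` data frame (or vector of peak times).
#' @param stimuli Strictly increasing stimulus times, seconds.
#' @param window_s Capture window after each stimulus; must be smaller than
#'   the shortest inter-stimulus interval (overlapping windows are
#'   ambiguous).
#' @return `list(captured = logical per stimulus, fraction = )`.
#' @export
pacing_capture <- function(events, stimuli, window_s = 0.5) {
  tt <- if (is.data.frame(events)) events$peak_time_s else as.numeric(events)
  stopifnot(length(stimuli) >= 1, all(diff(stimuli) > 0))
  if (length(stimuli) > 1 && window_s >= min(diff(stimuli)))
    stop("capture windows overlap: window_s must be below the stimulus period")
  captured <- vapply(stimuli, function(s)
    any(tt >= s & tt <= s + window_s), logical(1))
  list(captured = captured, fraction = mean(captured))
}

#' Time from a transient onset to its fluorescence peak
#'
#' Closed-form peak delay of the difference-of-exponentials waveform; useful
#' for relating generator event times to detected peak times.
#'
#' @param kinetics A [calcium_kinetics()] object.
#' @return Delay in seconds.
#' @export
transient_peak_delay <- function(kinetics) {
  rt <- kinetics$rise_tau_s; dt <- kinetics$decay_tau_s
  rt * dt / (dt - rt) * log(dt / rt)
}
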