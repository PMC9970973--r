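#' Simulate per-cell fluorescence traces and ground-truth event times
#'
#' The confluent hiPSC-CM layer beats as a syncytium: all hiPSC cells share
#' one layer rhythm. Unpaced, the layer rhythm is the spontaneous train of
#' the first hiPSC cell with a defined `spontaneous_period_s` (events at
#' `phase_s + k * period`, default phase half a period). Under pacing,
#' responsive hiPSC cells are captured at each stimulus (with a small
#' excitation-to-transient latency) and the layer may additionally produce
#' spontaneous non-stimulus events (`extra_event_times`), which is what makes
#' coupling observable under pacing.
#'
#' Adult cells: coupled cells reproduce the layer train (plus
#' `coupling_lag_s`); uncoupled cells follow their own spontaneous rhythm if
#' they have one, are captured directly by field stimulation when
#' `paced_responsive` in a paced run, or remain quiescent at `baseline_f`.
#'
#' Transient amplitude follows each cell's negative force-frequency
#' relation evaluated at the realised beat frequency, so paced transients at
#' 0.5 Hz are smaller than spontaneous ones at ~0.16 Hz.
#'
#' @param cells List of [cell_spec()] objects (e.g. from
#'   [build_cell_field()]).
#' @param protocol A [pacing_protocol()]; use `enabled = FALSE` for the
#'   unpaced acquisition.
#' @param duration_s Acquisition duration, seconds.
#' @param rate_hz Sampling rate of the traces (volumes per second for 3D
#'   acquisitions).
#' @param seed Integer seed (noise only; event times are deterministic).
#' @param noise_sd Additive Gaussian measurement noise on the fluorescence
#'   traces (counts-equivalent units); 0 for noiseless traces.
#' @param coupling_lag_s Delay of coupled adult events after the layer
#'   event.
#' @param capture_latency_s Stimulus-to-transient latency.
#' @param guard_s No event is generated within `guard_s` of the end of the
#'   acquisition (transients truncated by the end of the record are not
#'   simulated, mirroring how boundary-truncated transients cannot be scored).
#' @param refractory_s Minimum inter-event interval; pacing faster than this
#'   drops events with a warning.
#' @param extra_event_times Optional non-stimulus hiPSC-layer event times
#'   for paced runs (ignored when `protocol$enabled` is `FALSE`).
#' @return Object of class `simulated_traces`: list with `times` (sample
#'   times), `traces` (time x cell fluorescence matrix, columns named by cell
#'   id), `displacement` (time x cell normalised shortening traces in
#'   `[0, 1]`), and `ground_truth` (per-cell event times and labels, plus the
#'   stimulus train).
#' @export
simulate_traces <- function(cells, protocol = pacing_protocol(enabled = FALSE),
                            duration_s = 15, rate_hz = 4, seed = 1,
                            noise_sd = 0, coupling_lag_s = 0,
                            capture_latency_s = 0.05, guard_s = 1.5,
                            refractory_s = 0.3, extra_event_times = NULL) {
  stopifnot(duration_s > 0, rate_hz > 0, noise_sd >= 0)
  times <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  stimuli <- stimulus_times(protocol, duration_s, guard_s)
  if (protocol$enabled && 1 / protocol$freq_hz < refractory_s) {
    warning("pacing period ", 1 / protocol$freq_hz,
            " s is below the refractory limit ", refractory_s,
            " s; dropping unresolvable stimuli")
    stimuli <- thin_events(stimuli, refractory_s)
  }

  # layer rhythm
  layer_cell <- NULL
  for (cl in cells)
    if (cl$kind == "hipsc" && !is.na(cl$spontaneous_period_s)) {
      layer_cell <- cl; break
    }
  spont_layer <- if (!is.null(layer_cell)) {
    spontaneous_train(layer_cell, duration_s, guard_s)
  } else numeric(0)
  hipsc_responsive <- any(vapply(
    cells, function(cl) cl$kind == "hipsc" && cl$paced_responsive,
    logical(1)))
  layer_events <- if (protocol$enabled) {
    ev <- if (hipsc_responsive) stimuli + capture_latency_s else numeric(0)
    if (!is.null(extra_event_times))
      ev <- sort(c(ev, extra_event_times[extra_event_times <=
                                           duration_s - guard_s]))
    ev
  } else spont_layer
  layer_freq <- if (protocol$enabled) protocol$freq_hz
  else if (!is.null(layer_cell)) 1 / layer_cell$spontaneous_period_s
  else NA_real_

  n <- length(cells)
  ids <- vapply(cells, `[[`, character(1), "id")
  traces <- matrix(0, length(times), n, dimnames = list(NULL, ids))
  disp <- matrix(0, length(times), n, dimnames = list(NULL, ids))
  events <- vector("list", n); names(events) <- ids
  freqs <- numeric(n)

  for (i in seq_len(n)) {
    cl <- cells[[i]]
    if (cl$kind == "hipsc") {
      ev <- if (cl$paced_responsive || !protocol$enabled) layer_events
      else numeric(0)
      fq <- layer_freq
    } else if (cl$is_coupled) {
      if (!protocol$enabled && cl$coupling_mode == "paced_only") {
        ev <- numeric(0); fq <- NA_real_
      } else {
        ev <- layer_events + coupling_lag_s
        fq <- layer_freq
      }
    } else if (protocol$enabled) {
      if (cl$paced_responsive) {
        ev <- stimuli + capture_latency_s; fq <- protocol$freq_hz
      } else {
        ev <- spontaneous_train(cl, duration_s, guard_s)
        fq <- if (is.na(cl$spontaneous_period_s)) NA_real_
        else 1 / cl$spontaneous_period_s
      }
    } else {
      ev <- spontaneous_train(cl, duration_s, guard_s)
      fq <- if (is.na(cl$spontaneous_period_s)) NA_real_
      else 1 / cl$spontaneous_period_s
    }
    ev <- ev[ev >= 0 & ev <= duration_s - guard_s]
    events[[i]] <- ev
    freqs[i] <- fq
    g <- event_sum(times, ev, cl$kinetics)
    amp <- if (length(ev) && !is.na(fq)) transient_amplitude(cl$kinetics, fq)
    else 0
    traces[, i] <- cl$baseline_f * (1 + amp * g)
    if (cl$is_contractile) disp[, i] <- pmin(g, 1)
  }

  if (noise_sd > 0) {
    traces <- withr::with_seed(seed, {
      traces + matrix(stats::rnorm(length(traces), 0, noise_sd),
                      nrow(traces))
    })
  }

  labels <- data.frame(
    id = ids,
    kind = vapply(cells, `[[`, character(1), "kind"),
    is_coupled = vapply(cells, `[[`, logical(1), "is_coupled"),
    is_contractile = vapply(cells, `[[`, logical(1), "is_contractile"),
    n_events = vapply(events, length, integer(1)),
    stringsAsFactors = FALSE)

  structure(list(times = times, traces = traces, displacement = disp,
                 ground_truth = list(event_times = events, stimuli = stimuli,
                                     layer_events = layer_events,
                                     labels = labels),
                 protocol = protocol, rate_hz = rate_hz,
                 duration_s = duration_s),
            class = "simulated_traces")
}

# autonomous event train of one cell
spontaneous_train <- function(cl, duration_s, guard_s) {
  if (is.na(cl$spontaneous_period_s)) return(numeric(0))
  phase <- if (is.na(cl$phase_s)) cl$spontaneous_period_s / 2 else cl$phase_s
  ev <- seq(phase, duration_s, by = cl$spontaneous_period_s)
  ev[ev <= duration_s - guard_s]
}

# enforce a minimum spacing by dropping events greedily
thin_events <- function(ev, min_dt) {
  if (length(ev) < 2) return(ev)
  keep <- ev[1]
  for (t in ev[-1]) if (t - keep[length(keep)] >= min_dt) keep <- c(keep, t)
  keep
}

# superposition of normalised transient waveforms at the event times
event_sum <- function(times, ev, kinetics) {
  g <- numeric(length(times))
  for (t0 in ev) g <- g + transient_waveform(times - t0, kinetics)
  g
}
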