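#' Calcium-transient kinetics of a simulated cell
#'
#' Transients are modelled as a peak-normalised difference of exponentials
#' `A (exp(-t/decay_tau_s) - exp(-t/rise_tau_s))`. The amplitude follows a
#' linear negative force-frequency relation around a reference beat
#' frequency: `amp(f) = amp0 + ffr_slope * (f - f_ref_hz)`, floored at 5% of
#' `amp0` so a transient never vanishes entirely.
#'
#' Adult ventricular cardiomyocytes have faster calcium reuptake than
#' stem-cell-derived ones, hence the smaller default decay time constant.
#'
#' @param rise_tau_s,decay_tau_s Rise and decay time constants, seconds;
#'   must be positive and distinct.
#' @param amp0 Peak dF/F0 amplitude at the reference frequency.
#' @param ffr_slope Amplitude change per Hz of beat frequency; must be <= 0.
#' @param spark_rate Rate (events/s) of small localised calcium events in
#'   otherwise quiescent cells; 0 disables.
#' @param f_ref_hz Reference beat frequency for `amp0`.
#' @return Object of class `calcium_kinetics`.
#' @export
calcium_kinetics <- function(rise_tau_s = 0.15, decay_tau_s = 0.8,
                             amp0 = 1.0, ffr_slope = -0.8, spark_rate = 0,
                             f_ref_hz = 0.16) {
  stopifnot(rise_tau_s > 0, decay_tau_s > 0, rise_tau_s != decay_tau_s,
            amp0 > 0, ffr_slope <= 0, spark_rate >= 0, f_ref_hz > 0)
  structure(list(rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 amp0 = amp0, ffr_slope = ffr_slope, spark_rate = spark_rate,
                 f_ref_hz = f_ref_hz),
            class = "calcium_kinetics")
}

#' Default kinetics presets per cell kind
#'
#' @param kind `"hipsc"` or `"adult"`.
#' @return A [calcium_kinetics()] object.
#' @export
default_kinetics <- function(kind = c("hipsc", "adult")) {
  kind <- match.arg(kind)
  if (kind == "hipsc") calcium_kinetics(0.15, 0.8, 1.0, -0.8)
  else calcium_kinetics(0.05, 0.35, 1.5, -1.0)
}

#' Transient amplitude at a given beat frequency
#'
#' @param kinetics A [calcium_kinetics()] object.
#' @param freq_hz Beat frequency, Hz.
#' @return Positive dF/F0 peak amplitude.
#' @export
transient_amplitude <- function(kinetics, freq_hz) {
  stopifnot(freq_hz > 0)
  pmax(kinetics$amp0 + kinetics$ffr_slope * (freq_hz - kinetics$f_ref_hz),
       0.05 * kinetics$amp0)
}

#' Peak-normalised transient waveform
#'
#' @param t Time since the event, seconds (values < 0 give 0).
#' @param kinetics A [calcium_kinetics()] object.
#' @return Waveform values with peak exactly 1.
#' @export
transient_waveform <- function(t, kinetics) {
  rt <- kinetics$rise_tau_s; dt <- kinetics$decay_tau_s
  tpk <- rt * dt / (dt - rt) * log(dt / rt)
  pk <- exp(-tpk / dt) - exp(-tpk / rt)
  w <- ifelse(t >= 0, (exp(-t / dt) - exp(-t / rt)) / pk, 0)
  pmax(w, 0)
}

#' Specification of a single simulated cell
#'
#' Adult cardiomyocytes are rod-shaped (rectangle with a long and short
#' axis) and sit on top of the confluent stem-cell layer; hiPSC-CM are
#' round blobs tiling the bottom layer.
#'
#' @param id Character id.
#' @param kind `"hipsc"` or `"adult"`.
#' @param centroid_um Length-3 lab-frame position `(x, y, z)` in um, z
#'   increasing upwards from the coverslip.
#' @param size_um For adult: `c(long_axis, short_axis)`; for hipsc: blob
#'   radius (scalar).
#' @param orientation_deg In-plane angle of the long axis (adult only).
#' @param spontaneous_period_s Autonomous inter-transient interval, or `NA`
#'   for a quiescent cell.
#' @param phase_s Time of the first autonomous transient.
#' @param kinetics A [calcium_kinetics()] object; defaults per `kind`.
#' @param is_coupled Ground-truth electrical coupling to the hiPSC layer
#'   rhythm (adult only).
#' @param coupling_mode `"both"`: follows the layer in unpaced and paced
#'   acquisitions; `"paced_only"`: quiescent unpaced, follows the layer only
#'   under pacing (the layer must then produce non-stimulus events for the
#'   coupling to be observable).
#' @param is_contractile Whether mechanical shortening occurs (FALSE under
#'   para-nitroblebbistatin).
#' @param paced_responsive Whether the cell is captured by field stimulation
#'   in paced acquisitions.
#' @param baseline_f Resting fluorescence (counts-equivalent units).
#' @return Object of class `cell_spec`.
#' @export
cell_spec <- function(id, kind = c("hipsc", "adult"), centroid_um,
                      size_um, orientation_deg = 0,
                      spontaneous_period_s = NA_real_, phase_s = NA_real_,
                      kinetics = NULL, is_coupled = FALSE,
                      coupling_mode = c("both", "paced_only"),
                      is_contractile = FALSE, paced_responsive = TRUE,
                      baseline_f = 100) {
  kind <- match.arg(kind)
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(length(centroid_um) == 3, baseline_f > 0)
  if (!is.na(spontaneous_period_s)) stopifnot(spontaneous_period_s > 0)
  if (is.null(kinetics)) kinetics <- default_kinetics(kind)
  structure(list(id = as.character(id), kind = kind,
                 centroid_um = as.numeric(centroid_um),
                 size_um = as.numeric(size_um),
                 orientation_deg = orientation_deg,
                 spontaneous_period_s = spontaneous_period_s,
                 phase_s = phase_s, kinetics = kinetics,
                 is_coupled = is_coupled, coupling_mode = coupling_mode,
                 is_contractile = is_contractile,
                 paced_responsive = paced_responsive,
                 baseline_f = baseline_f),
            class = "cell_spec")
}

#' Build a synthetic co-culture cell field
#'
#' A confluent layer of round hiPSC-CM blobs tiles the bottom of the field
#' (jittered hexagonal-ish grid); `n_adult` rod-shaped adult cardiomyocytes
#' are scattered on top, placed by rejection sampling so that no two
#' rectangles overlap (a conservative circumscribed-circle criterion is
#' used, which guarantees true non-overlap).
#'
#' @param field_um `c(x_extent, y_extent)` of the field, um.
#' @param n_adult Number of adult cells to place (0 allowed).
#' @param adult_long_um,adult_short_um Adult rectangle axes, um.
#' @param adult_orientation_sd_deg SD of the orientation jitter about the x
#'   axis.
#' @param hipsc_radius_um hiPSC blob radius, um.
#' @param hipsc_layer_z_um Height of the hiPSC layer centre above the
#'   coverslip; adult cells are placed above it.
#' @param adult_z_um Height of adult cell centres.
#' @param baseline_f Resting fluorescence per cell.
#' @param seed Integer seed (placement is deterministic given the seed).
#' @param max_tries Rejection-sampling budget per adult cell; exhausting it
#'   raises an error (unsatisfiable density).
#' @return List with elements `cells` (list of [cell_spec()]) and
#'   `field_um`.
#' @export
build_cell_field <- function(field_um = c(120, 40), n_adult = 3,
                             adult_long_um = 30, adult_short_um = 10,
                             adult_orientation_sd_deg = 8,
                             hipsc_radius_um = 6, hipsc_layer_z_um = 2,
                             adult_z_um = 9, baseline_f = 100,
                             seed = 1, max_tries = 1000) {
  stopifnot(all(field_um > 0), n_adult >= 0, adult_long_um > 0,
            adult_short_um > 0, hipsc_radius_um > 0,
            adult_z_um > hipsc_layer_z_um)
  withr::with_seed(seed, {
    cells <- list()
    # hiPSC layer: jittered grid of blobs covering the field
    pitch <- 1.7 * hipsc_radius_um
    gx <- seq(pitch / 2, field_um[1] - pitch / 4, by = pitch)
    gy <- seq(pitch / 2, field_um[2] - pitch / 4, by = pitch)
    idx <- 0
    for (yy in gy) for (xx in gx) {
      idx <- idx + 1
      jit <- stats::runif(2, -0.2, 0.2) * pitch
      cells[[length(cells) + 1]] <- cell_spec(
        id = sprintf("hipsc_%03d", idx), kind = "hipsc",
        centroid_um = c(xx + jit[1], yy + jit[2],
                        hipsc_layer_z_um + stats::runif(1, -0.5, 0.5)),
        size_um = hipsc_radius_um, baseline_f = baseline_f)
    }
    # adult cells on top, non-overlapping
    diag_half <- sqrt(adult_long_um^2 + adult_short_um^2) / 2
    placed <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n_adult)) {
      ok <- FALSE
      for (tr in seq_len(max_tries)) {
        p <- c(stats::runif(1, diag_half, field_um[1] - diag_half),
               stats::runif(1, min(diag_half, field_um[2] / 2),
                            max(field_um[2] - diag_half, field_um[2] / 2)))
        if (nrow(placed) == 0 ||
            all(sqrt(colSums((t(placed) - p)^2)) >= 2 * diag_half)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place adult cell ", i, " without overlap after ",
             max_tries, " tries; reduce density")
      placed <- rbind(placed, p)
      cells[[length(cells) + 1]] <- cell_spec(
        id = sprintf("adult_%02d", i), kind = "adult",
        centroid_um = c(p, adult_z_um),
        size_um = c(adult_long_um, adult_short_um),
        orientation_deg = stats::rnorm(1, 0, adult_orientation_sd_deg),
        baseline_f = baseline_f)
    }
    list(cells = cells, field_um = field_um)
  })
}

#' Electrical field-stimulation protocol
#'
#' @param enabled Whether pacing is applied.
#' @param freq_hz Stimulation frequency.
#' @param pulse_ms Pulse duration (metadata).
#' @param amplitude_v Field amplitude (metadata).
#' @param prepace_s Pre-pacing duration before the acquisition (metadata).
#' @param start_s Time of the first stimulus within the acquisition.
#' @return Object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(enabled = TRUE, freq_hz = 0.5, pulse_ms = 2,
                            amplitude_v = 20, prepace_s = 60, start_s = 1) {
  if (enabled) stopifnot(freq_hz > 0)
  structure(list(enabled = enabled, freq_hz = freq_hz, pulse_ms = pulse_ms,
                 amplitude_v = amplitude_v, prepace_s = prepace_s,
                 start_s = start_s),
            class = "pacing_protocol")
}

#' Stimulus times of a pacing protocol over an acquisition
#'
#' @param protocol A [pacing_protocol()].
#' @param duration_s Acquisition duration, seconds.
#' @param guard_s No stimuli are emitted within `guard_s` of the end of the
#'   acquisition (a transient started there would be truncated).
#' @return Strictly increasing vector of stimulus times (possibly empty).
#' @export
stimulus_times <- function(protocol, duration_s, guard_s = 1.5) {
  if (!protocol$enabled) return(numeric(0))
  seq(protocol$start_s, duration_s - guard_s, by = 1 / protocol$freq_hz)
}
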