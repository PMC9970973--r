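#' Write a frame sequence as a 16-bit multi-page TIFF
#'
#' Counts are stored as 16-bit unsigned integers; values above `max_count`
#' are clipped.
#'
#' @param frames `[row, col, frame]` array or list of matrices.
#' @param path Output path.
#' @param max_count Full-scale count value (default 65535).
#' @export
write_frames_tiff <- function(frames, path, max_count = 65535) {
  fr <- as_frames(frames)
  pages <- lapply(seq_len(dim(fr)[3]), function(i)
    pmin(pmax(fr[, , i], 0), max_count) / max_count)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a frame sequence
#'
#' Inverse of [write_frames_tiff()]: 16-bit pages are rescaled back to
#' integer counts.
#'
#' @param path TIFF file path.
#' @param max_count Full-scale count value used when writing.
#' @return `[row, col, frame]` array of counts.
#' @export
read_frames_tiff <- function(path, max_count = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  round(arr * max_count)
}

#' Serialize generator / acquisition parameters to YAML
#'
#' Captures the acquisition geometry, pacing protocol and seed of a run so
#' a synthetic dataset can be regenerated exactly.
#'
#' @param geometry An [acquisition_geometry()].
#' @param protocol A [pacing_protocol()] or `NULL`.
#' @param seed Integer seed.
#' @param extra Named list of additional scalar parameters.
#' @param path Output path.
#' @export
write_config_yaml <- function(geometry, protocol = NULL, seed = NULL,
                              extra = list(), path) {
  cfg <- list(geometry = unclass(geometry))
  if (!is.null(protocol)) cfg$protocol <- unclass(protocol)
  if (!is.null(seed)) cfg$seed <- seed
  if (length(extra)) cfg <- c(cfg, extra)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a configuration written by [write_config_yaml()]
#'
#' @param path YAML path.
#' @return List with `geometry` restored as an `acquisition_geometry` (and
#'   `protocol` as a `pacing_protocol` when present).
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  cfg$geometry <- acquisition_geometry(
    theta_ls = g$theta_ls, dz_prime = g$dz_prime, n_planes = g$n_planes,
    px_sample = g$px_sample, camera_px = g$camera_px,
    magnification = g$magnification, vps = g$vps,
    frames_per_sweep = g$frames_per_sweep)
  if (!is.null(cfg$protocol)) {
    p <- cfg$protocol
    cfg$protocol <- pacing_protocol(p$enabled, p$freq_hz, p$pulse_ms,
                                    p$amplitude_v, p$prepace_s, p$start_s)
  }
  cfg
}

#' Write per-FOV cell records to CSV
#'
#' @param records Data frame from [classify_cohort()] or
#'   [cohort_truth_records()].
#' @param path Output path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read per-FOV cell records from CSV
#'
#' @param path CSV path written by [write_records_csv()].
#' @return Data frame with logical label columns restored.
#' @export
read_records_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("nbleb", "contracting", "transients_unpaced",
               "transients_paced", "hipsc_transients_unpaced",
               "hipsc_transients_paced", "coupled"))
    if (cl %in% names(rec)) rec[[cl]] <- as.logical(rec[[cl]])
  rec
}

#' Write ground-truth event times to CSV
#'
#' Long format: one row per (cell, event).
#'
#' @param ground_truth The `ground_truth` element of a
#'   [simulate_traces()] result.
#' @param path Output path.
#' @export
write_ground_truth_csv <- function(ground_truth, path) {
  ev <- ground_truth$event_times
  rows <- lapply(names(ev), function(id) {
    if (!length(ev[[id]])) return(NULL)
    data.frame(id = id, event_time_s = ev[[id]])
  })
  rows <- c(rows, list(
    if (length(ground_truth$stimuli))
      data.frame(id = "stimulus", event_time_s = ground_truth$stimuli)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(id = character(0),
                                      event_time_s = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
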