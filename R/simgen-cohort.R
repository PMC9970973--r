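#' Design of a synthetic co-culture imaging cohort
#'
#' A cohort is a set of fields of view (FOVs), each holding one adult
#' cardiomyocyte on a hiPSC-CM layer and imaged twice (unpaced then paced at
#' 0.5 Hz). Two allocation modes are supported: `"fixed"` draws exact
#' per-condition counts (hypergeometric-style: which FOVs carry each label is
#' randomised but the totals are exact, so a published summary table can be
#' reproduced to the count), `"bernoulli"` draws each label independently
#' with the given probabilities.
#'
#' @param conditions Data frame with one row per experimental condition and
#'   columns `coculture`, `day` (0/1), `nbleb` (logical), `n_fov`, plus
#'   either exact counts (`fixed`): `n_contr`, `n_hipsc_unpaced`,
#'   `n_adult_unpaced`, `n_hipsc_paced`, `n_adult_paced`, `n_coupled`; or
#'   probabilities (`bernoulli`): `p_coupled`, `p_contractile`.
#' @param allocation `"fixed"` or `"bernoulli"`.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(conditions, allocation = c("fixed", "bernoulli")) {
  allocation <- match.arg(allocation)
  need <- c("coculture", "day", "nbleb", "n_fov")
  need <- c(need, if (allocation == "fixed")
    c("n_contr", "n_hipsc_unpaced", "n_adult_unpaced", "n_hipsc_paced",
      "n_adult_paced", "n_coupled")
    else c("p_coupled", "p_contractile"))
  missing <- setdiff(need, names(conditions))
  if (length(missing))
    stop("conditions is missing columns: ", paste(missing, collapse = ", "))
  stopifnot(all(conditions$n_fov >= 1))
  if (allocation == "bernoulli")
    stopifnot(all(conditions$p_coupled >= 0 & conditions$p_coupled <= 1),
              all(conditions$p_contractile >= 0 &
                    conditions$p_contractile <= 1))
  structure(list(conditions = conditions, allocation = allocation),
            class = "cohort_design")
}

#' Cohort design reproducing the published co-culture summary counts
#'
#' Encodes, per co-culture sample (two co-cultures, imaged on the starting
#' day and the following day, with and without the myosin inhibitor
#' para-nitroblebbistatin), the exact number of FOVs and the exact counts of
#' contracting cells, hiPSC/adult transients in unpaced and paced
#' acquisitions, and coupled adult cells: 45 FOVs overall, 16 coupled
#' (4/21 on day 0, 12/24 on day 1; 8/22 control, 8/23 NBleb), 14 with
#' contraction (13/22 control, 1/23 NBleb).
#'
#' @return A `cohort_design` with fixed-count allocation.
#' @export
table1_design <- function() {
  conditions <- data.frame(
    coculture = rep(c("C", "D"), each = 4),
    day = rep(c(0L, 0L, 1L, 1L), 2),
    nbleb = rep(c(FALSE, TRUE), 4),
    n_fov = c(5L, 5L, 5L, 6L, 6L, 5L, 6L, 7L),
    n_contr = c(5L, 0L, 2L, 0L, 4L, 0L, 2L, 1L),
    n_hipsc_unpaced = c(5L, 4L, 4L, 5L, 1L, 0L, 4L, 7L),
    n_adult_unpaced = c(2L, 1L, 3L, 4L, 1L, 0L, 4L, 1L),
    n_hipsc_paced = c(4L, 4L, 3L, 4L, 6L, 4L, 4L, 6L),
    n_adult_paced = c(5L, 4L, 4L, 5L, 6L, 5L, 5L, 7L),
    n_coupled = c(1L, 1L, 3L, 4L, 1L, 1L, 3L, 2L))
  cohort_design(conditions, "fixed")
}

# Assign per-FOV roles for one condition row under fixed-count allocation.
# Returns a data.frame of n_fov rows with logical flags and an adult "role".
allocate_condition <- function(row, seed) {
  n <- row$n_fov
  cu <- row$n_coupled - max(0, row$n_coupled - row$n_adult_unpaced)
  po <- row$n_coupled - cu        # coupled observable only under pacing
  auton <- row$n_adult_unpaced - cu
  resp <- row$n_adult_paced - row$n_coupled - auton
  if (row$n_coupled > row$n_hipsc_paced)
    stop("infeasible counts: more coupled cells than paced-active hiPSC FOVs")
  if (cu > row$n_hipsc_unpaced)
    stop("infeasible counts: unpaced-coupled cells exceed unpaced-active hiPSC FOVs")
  if (resp < 0)
    stop("infeasible counts: adult paced transients fewer than coupled + autonomous cells")
  if (row$n_contr > row$n_adult_paced + auton)
    stop("infeasible counts: contracting cells must have transients in some acquisition")
  # roles by position, then shuffled
  role <- c(rep("coupled_unpaced", cu), rep("coupled_paced_only", po),
            rep("autonomous", auton), rep("responder", resp),
            rep("silent", n - cu - po - auton - resp))
  # hiPSC activity flags: paced-active FOVs cover all coupled cells;
  # unpaced-active FOVs cover the unpaced-coupled cells first
  ph <- logical(n); ph[seq_len(row$n_coupled)] <- TRUE
  extra_ph <- row$n_hipsc_paced - row$n_coupled
  free <- which(!ph)
  ph[free[seq_len(extra_ph)]] <- TRUE
  uh <- logical(n); uh[seq_len(cu)] <- TRUE
  extra_uh <- row$n_hipsc_unpaced - cu
  free <- setdiff(seq_len(n), which(uh))
  uh[free[seq_len(extra_uh)]] <- TRUE
  # contraction among cells with events (all non-silent roles have events)
  active <- which(role != "silent")
  contr <- logical(n); contr[active[seq_len(row$n_contr)]] <- TRUE
  perm <- withr::with_seed(seed, sample.int(n))
  data.frame(role = role[perm], hipsc_unpaced = uh[perm],
             hipsc_paced = ph[perm], contracting = contr[perm],
             stringsAsFactors = FALSE)
}

#' Simulate a full imaging cohort with ground truth
#'
#' Every FOV gets its own cell field (one adult cell on a hiPSC layer) and
#' two simulated acquisitions sharing that field: unpaced, then paced at the
#' protocol frequency. Ground-truth labels are drawn per the design.
#'
#' @param design A [cohort_design()].
#' @param duration_s,rate_hz Acquisition duration and trace sampling rate.
#' @param seed Master seed; per-FOV seeds are derived from it.
#' @param noise_sd Trace measurement noise (0 for noiseless ground-truth
#'   runs).
#' @param field_um Field extent per FOV.
#' @param protocol Pacing protocol of the paced acquisition.
#' @param hipsc_period_s Spontaneous period of the hiPSC layer.
#' @param hipsc_phase_s Phase of the first layer event.
#' @param autonomous_period_s,autonomous_phase_s Rhythm of uncoupled adult
#'   cells that beat on their own.
#' @return Object of class `cohort`: list of FOV records, each with
#'   `fov_id`, `condition` (coculture/day/nbleb), `cells`, `unpaced` and
#'   `paced` ([simulate_traces()] results), `stimuli` and `truth` (logical
#'   ground-truth labels).
#' @export
simulate_cohort <- function(design, duration_s = 15, rate_hz = 4, seed = 1,
                            noise_sd = 8, field_um = c(80, 56),
                            protocol = pacing_protocol(enabled = TRUE),
                            hipsc_period_s = 6.25, hipsc_phase_s = 1.2,
                            autonomous_period_s = 4.3,
                            autonomous_phase_s = 2.6) {
  stopifnot(inherits(design, "cohort_design"))
  conditions <- design$conditions
  fovs <- list()
  fov_id <- 0
  for (ci in seq_len(nrow(conditions))) {
    row <- conditions[ci, ]
    alloc <- if (design$allocation == "fixed") {
      allocate_condition(row, seed = seed + 1000L * ci)
    } else {
      withr::with_seed(seed + 1000L * ci, {
        coupled <- stats::rbinom(row$n_fov, 1, row$p_coupled) == 1
        contr <- stats::rbinom(row$n_fov, 1, row$p_contractile) == 1
        data.frame(role = ifelse(coupled, "coupled_unpaced", "responder"),
                   hipsc_unpaced = TRUE, hipsc_paced = TRUE,
                   contracting = contr, stringsAsFactors = FALSE)
      })
    }
    for (fi in seq_len(row$n_fov)) {
      fov_id <- fov_id + 1
      a <- alloc[fi, ]
      fov_seed <- seed + 7L * fov_id
      field <- build_cell_field(field_um = field_um, n_adult = 1,
                                seed = fov_seed)
      cells <- lapply(field$cells, function(cl) {
        if (cl$kind == "hipsc") {
          cl$spontaneous_period_s <- if (a$hipsc_unpaced) hipsc_period_s
          else NA_real_
          cl$phase_s <- hipsc_phase_s
          cl$paced_responsive <- a$hipsc_paced
        } else {
          cl$is_coupled <- a$role %in% c("coupled_unpaced",
                                         "coupled_paced_only")
          cl$coupling_mode <- if (a$role == "coupled_paced_only")
            "paced_only" else "both"
          cl$is_contractile <- a$contracting
          if (a$role == "autonomous") {
            cl$spontaneous_period_s <- autonomous_period_s
            cl$phase_s <- autonomous_phase_s
          }
          cl$paced_responsive <- a$role %in% c("autonomous", "responder")
        }
        cl
      })
      stim <- stimulus_times(protocol, duration_s)
      extras <- if (a$role == "coupled_paced_only" && length(stim) >= 2) {
        stim[unique(pmin(c(2, 5), length(stim)))] + 1.0
      } else NULL
      unpaced <- simulate_traces(cells, pacing_protocol(enabled = FALSE),
                                 duration_s, rate_hz, seed = fov_seed + 1L,
                                 noise_sd = noise_sd)
      paced <- simulate_traces(cells, protocol, duration_s, rate_hz,
                               seed = fov_seed + 2L, noise_sd = noise_sd,
                               extra_event_times = extras)
      adult <- which(vapply(cells, `[[`, character(1), "kind") == "adult")
      truth <- list(
        coupled = a$role %in% c("coupled_unpaced", "coupled_paced_only"),
        contracting = a$contracting,
        adult_unpaced = length(unpaced$ground_truth$event_times[[adult]]) > 0,
        adult_paced = length(paced$ground_truth$event_times[[adult]]) > 0,
        hipsc_unpaced = a$hipsc_unpaced, hipsc_paced = a$hipsc_paced,
        role = a$role)
      fovs[[fov_id]] <- list(
        fov_id = fov_id,
        condition = list(coculture = row$coculture, day = row$day,
                         nbleb = row$nbleb),
        cells = cells, field_um = field_um,
        unpaced = unpaced, paced = paced,
        stimuli = paced$ground_truth$stimuli,
        truth = truth, seed = fov_seed)
    }
  }
  structure(list(fovs = fovs, design = design, duration_s = duration_s,
                 rate_hz = rate_hz, seed = seed, noise_sd = noise_sd),
            class = "cohort")
}

#' Ground-truth cell records of a simulated cohort
#'
#' One row per FOV with the generator's labels, in the same shape as
#' [classify_cohort()] output, for direct comparison.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Data frame of per-FOV ground-truth labels.
#' @export
cohort_truth_records <- function(cohort) {
  do.call(rbind, lapply(cohort$fovs, function(f) {
    data.frame(fov_id = f$fov_id, coculture = f$condition$coculture,
               day = f$condition$day, nbleb = f$condition$nbleb,
               contracting = f$truth$contracting,
               transients_unpaced = f$truth$adult_unpaced,
               transients_paced = f$truth$adult_paced,
               hipsc_transients_unpaced = f$truth$hipsc_unpaced,
               hipsc_transients_paced = f$truth$hipsc_paced,
               coupled = f$truth$coupled,
               stringsAsFactors = FALSE)
  }))
}
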