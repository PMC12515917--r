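#' Simulate a mixed-event validation record
#'
#' A randomized record for detector validation: normal baseline (120--155
#' bpm), moderate variability, about 3 contractions per 10 min, and 2--4
#' injected events (accelerations and typed decelerations) placed at least
#' one minute from the record edges on distinct contractions.
#'
#' @param seed Integer seed.
#' @param duration_s Record duration (default 1500 s).
#' @return A `ctg_record`; the injected events are its annotations.
#' @export
simulate_event_fixture <- function(seed, duration_s = 1500) {
  with_seed(seed, {
    base <- stats::runif(1, 120, 155)
    amp <- stats::runif(1, 8, 12)
    rec <- simulate_record(sim_params(
      baseline_bpm = base, variability_amp = amp, contraction_rate = 3,
      duration_s = duration_s, seed = sample.int(1e8, 1)
    ))
    ctr <- rec$events[rec$events$kind == "contraction", ]
    usable <- which(ctr$onset_s > 120 & ctr$end_s < duration_s - 120)
    n_ev <- min(length(usable), sample(2:4, 1))
    picks <- sort(usable[sample.int(length(usable), n_ev)])
    kinds <- sample(c("acceleration", "early_decel", "late_decel",
                      "variable_decel"), n_ev, replace = TRUE)
    for (j in seq_len(n_ev)) {
      k <- kinds[j]; ci <- picks[j]
      rec <- tryCatch(switch(k,
        acceleration = inject_acceleration(
          rec, onset_s = ctr$end_s[ci] + 20,
          height = stats::runif(1, 18, 25), duration_s = 40),
        early_decel = inject_deceleration(
          rec, "early_decel", ci, depth = stats::runif(1, 30, 50),
          duration_s = 90),
        late_decel = inject_deceleration(
          rec, "late_decel", ci, depth = stats::runif(1, 30, 50),
          duration_s = 90, lag_s = stats::runif(1, 25, 40)),
        variable_decel = inject_deceleration(
          rec, "variable_decel", ci, depth = stats::runif(1, 25, 45),
          duration_s = 50, onset_to_nadir_s = stats::runif(1, 6, 15))
      ), error = function(e) rec)   # skip events that would overlap
    }
    rec
  })
}

#' Event-recovery rate of the rule engine on annotated records
#'
#' Runs acceleration and deceleration detection on each record and matches
#' the injected annotations (events at least `edge_s` from the record
#' edges) against detections by kind and timing overlap.
#'
#' @param records A list of annotated `ctg_record`s.
#' @param edge_s Edge margin; injected events closer than this to either
#'   record edge are not scored.
#' @return A list: `rate` (matched / scored), `n_events`, `n_matched`,
#'   and a per-event tibble `details`.
#' @export
event_recovery <- function(records, edge_s = 60) {
  fhr_kinds <- c("acceleration", "prolonged_acceleration", "early_decel",
                 "late_decel", "variable_decel")
  rows <- list()
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    dur <- record_duration(rec)
    truth <- rec$events[rec$events$kind %in% fhr_kinds &
                        rec$events$onset_s >= edge_s &
                        rec$events$end_s <= dur - edge_s, ]
    if (nrow(truth) == 0) next
    det <- dplyr::bind_rows(
      detect_accelerations(rec),
      suppressWarnings(detect_decelerations(rec))
    )
    for (j in seq_len(nrow(truth))) {
      hit <- FALSE
      if (nrow(det)) {
        overlap <- det$onset_s < truth$end_s[j] &
          det$end_s > truth$onset_s[j]
        hit <- any(overlap & !is.na(det$kind) &
                     det$kind == truth$kind[j])
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        record = ri, kind = truth$kind[j],
        onset_s = truth$onset_s[j], matched = hit)
    }
  }
  details <- dplyr::bind_rows(rows)
  list(rate = mean(details$matched), n_events = nrow(details),
       n_matched = sum(details$matched), details = details)
}
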