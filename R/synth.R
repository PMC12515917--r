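#' Simulation parameters for a synthetic CTG record
#'
#' Controls for the paired FHR/UC generator. Defaults follow the clinical
#' population the toolkit targets: a mean FHR baseline of 142 bpm, moderate
#' short-term variability (10 bpm per-minute peak-to-trough), and about
#' 3 contractions per 10 minutes.
#'
#' @param baseline_bpm FHR baseline in bpm.
#' @param variability_amp Per-minute peak-to-trough FHR fluctuation in bpm.
#'   The generated band-limited noise is rescaled so the median per-minute
#'   peak-to-trough amplitude equals this value exactly.
#' @param contraction_rate Contractions per 10 minutes (0 disables UC bumps).
#' @param event_requests List of event requests; each element is a list with
#'   a `kind` field (`"acceleration"`, `"early_decel"`, `"late_decel"`,
#'   `"variable_decel"`, `"sinusoidal"`) plus the arguments of the matching
#'   `inject_*()` function.
#' @param duration_s Record duration in seconds.
#' @param seed Integer seed; identical seeds give bit-identical records.
#' @param gap_spec List of `list(channel, start_s, end_s)` signal-loss gaps.
#' @param gestational_age Weeks (default 34).
#' @param resting_tone Baseline UC pressure in mmHg.
#' @param contraction_amp,contraction_duration Length-2 ranges (mmHg, s)
#'   sampled per contraction.
#' @return A `sim_params` list.
#' @export
sim_params <- function(baseline_bpm = 142, variability_amp = 10,
                       contraction_rate = 3, event_requests = list(),
                       duration_s = 1200, seed = 1, gap_spec = list(),
                       gestational_age = 34, resting_tone = 10,
                       contraction_amp = c(40, 70),
                       contraction_duration = c(60, 90)) {
  stopifnot(duration_s > 0, contraction_rate >= 0, variability_amp >= 0,
            baseline_bpm >= 60, baseline_bpm <= 210)
  structure(as.list(environment()), class = "sim_params")
}

# band-limited FHR variability: beat-scale jitter (0.5-1.5 Hz) plus slow
# wander (0.01-0.1 Hz), rescaled so the median per-minute peak-to-trough
# amplitude equals `amp` exactly (peak-to-trough is scale-homogeneous).
variability_noise <- function(n, fs, amp) {
  if (amp <= 0 || n < 2) return(numeric(n))
  t <- seq(0, by = 1 / fs, length.out = n)
  f_slow <- stats::runif(6, 0.01, 0.1)
  f_fast <- stats::runif(10, 0.5, 1.5)
  ph <- stats::runif(16, 0, 2 * pi)
  w <- c(stats::runif(6, 0.5, 1), stats::runif(10, 0.3, 1))
  x <- numeric(n)
  fr <- c(f_slow, f_fast)
  for (j in seq_along(fr)) x <- x + w[j] * sin(2 * pi * fr[j] * t + ph[j])
  m <- measured_p2p(x, fs)
  if (m <= 0) return(numeric(n))
  x * (amp / m)
}

# median per-minute peak-to-trough amplitude over non-overlapping 60 s windows
measured_p2p <- function(x, fs, mask = NULL) {
  wl <- as.integer(60 * fs)
  nw <- length(x) %/% wl
  if (nw == 0) return(diff(range(x)))
  p2p <- vapply(seq_len(nw), function(k) {
    seg <- x[((k - 1) * wl + 1):(k * wl)]
    if (!is.null(mask)) seg <- seg[mask[((k - 1) * wl + 1):(k * wl)]]
    if (length(seg) < 2) return(NA_real_)
    diff(range(seg))
  }, numeric(1))
  stats::median(p2p, na.rm = TRUE)
}

raised_cosine <- function(t, onset, duration) {
  u <- (t - onset) / duration
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Simulate a paired FHR/UC record
#'
#' Builds a 4 Hz CTG record: FHR = baseline + band-limited variability,
#' UC = resting tone + smooth raised-cosine contraction bumps (annotated),
#' then applies every requested event via the `inject_*()` functions and
#' finally punches the requested signal-loss gaps. Fully deterministic under
#' `params$seed`.
#'
#' @param params A [sim_params()].
#' @return A [ctg_record()] carrying annotations for contractions and all
#'   injected events, with the generator parameters stored in `$sim_params`.
#' @examples
#' rec <- simulate_record(sim_params(duration_s = 600, seed = 7))
#' mean(rec$signals$fhr)   # close to 142
#' @export
simulate_record <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    fs <- 4
    n <- as.integer(round(params$duration_s * fs))
    t <- seq(0, by = 1 / fs, length.out = n)
    fhr <- params$baseline_bpm +
      variability_noise(n, fs, params$variability_amp)

    # contractions: smooth unimodal raised-cosine bumps
    uc <- rep(params$resting_tone, n) +
      if (params$variability_amp > 0) {
        vn <- variability_noise(n, fs, 2)
        vn
      } else numeric(n)
    events <- ctg_events()
    if (params$contraction_rate > 0) {
      mean_gap <- 600 / params$contraction_rate
      pos <- stats::runif(1, 0.3, 0.9) * mean_gap
      while (TRUE) {
        dur <- stats::runif(1, params$contraction_duration[1],
                            params$contraction_duration[2])
        amp <- stats::runif(1, params$contraction_amp[1],
                            params$contraction_amp[2])
        if (pos + dur > params$duration_s - 5) break
        uc <- uc + amp * raised_cosine(t, pos, dur)
        events <- dplyr::bind_rows(events, ctg_events(
          "contraction", pos, pos + dur / 2, pos + dur, amp))
        pos <- pos + dur / 2 + mean_gap * stats::runif(1, 0.75, 1.25)
      }
    }

    rec <- ctg_record(
      fhr = pmin(pmax(fhr, 60), 210), uc = pmin(pmax(uc, 0), 100),
      fs = fs, gestational_age = params$gestational_age, events = events
    )
    rec$sim_params <- params

    for (req in params$event_requests) {
      kind <- req$kind
      req$kind <- NULL
      rec <- switch(kind,
        acceleration = do.call(inject_acceleration, c(list(rec), req)),
        early_decel = ,
        late_decel = ,
        variable_decel = do.call(inject_deceleration,
                                 c(list(rec, kind = kind), req)),
        sinusoidal = do.call(inject_sinusoidal, c(list(rec), req)),
        stop("unknown event request kind: ", kind, call. = FALSE)
      )
    }

    for (g in params$gap_spec) {
      idx <- which(t >= g$start_s & t < g$end_s)
      ch <- match.arg(g$channel, c("fhr", "uc", "both"))
      if (ch %in% c("fhr", "both")) rec$signals$fhr_valid[idx] <- FALSE
      if (ch %in% c("uc", "both")) rec$signals$uc_valid[idx] <- FALSE
    }
    rec
  })
}

# reject FHR events whose spans overlap an already-injected FHR event
check_fhr_overlap <- function(record, onset_s, end_s) {
  fhr_kinds <- c("acceleration", "prolonged_acceleration", "early_decel",
                 "late_decel", "variable_decel", "sinusoidal")
  ev <- record$events[record$events$kind %in% fhr_kinds, ]
  if (nrow(ev) && any(onset_s < ev$end_s & end_s > ev$onset_s)) {
    stop("requested event [", round(onset_s), ", ", round(end_s),
         "] s overlaps an existing FHR event; incompatible overlapping ",
         "events are rejected", call. = FALSE)
  }
}

record_baseline_level <- function(record) {
  if (!is.null(record$sim_params)) record$sim_params$baseline_bpm
  else stats::median(record$signals$fhr[record$signals$fhr_valid])
}

#' Inject a deceleration coupled to a contraction
#'
#' Subtracts a smooth dip from the FHR trace, timed against an annotated
#' contraction. Early decelerations (ED) are gradual (onset-to-nadir at
#' least 30 s) with the nadir coincident with the contraction peak; late
#' decelerations (LD) are the same shape with the nadir delayed past the
#' peak by `lag_s`; variable decelerations (VD) are abrupt (onset-to-nadir
#' under 30 s), at least 15 bpm deep, lasting 15 s to under 2 min.
#'
#' @param record A `ctg_record` with annotated contractions.
#' @param kind `"early_decel"`, `"late_decel"`, or `"variable_decel"`.
#' @param contraction_index Which annotated contraction to couple to.
#' @param depth Deceleration depth in bpm (VD requires `depth >= 15`).
#' @param duration_s Total event duration; ED/LD default 80 s (gradual),
#'   VD default 50 s.
#' @param lag_s LD only: nadir delay after the contraction peak (default 30).
#' @param onset_to_nadir_s VD only: drop time, must be < 30 s (default 10).
#' @return The modified record with the event annotated.
#' @export
inject_deceleration <- function(record, kind, contraction_index, depth,
                                duration_s = NULL, lag_s = 30,
                                onset_to_nadir_s = 10) {
  kind <- match.arg(kind, c("early_decel", "late_decel", "variable_decel"))
  ctr <- record$events[record$events$kind == "contraction", ]
  if (contraction_index < 1 || contraction_index > nrow(ctr)) {
    stop("contraction ", contraction_index, " does not exist (record has ",
         nrow(ctr), ")", call. = FALSE)
  }
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  peak <- ctr$nadir_or_peak_s[contraction_index]
  t <- record$signals$time_s

  if (kind == "variable_decel") {
    duration_s <- duration_s %||% 50
    if (depth < 15) {
      stop("variable decelerations require a decline of >= 15 bpm",
           call. = FALSE)
    }
    if (onset_to_nadir_s >= 30) {
      stop("variable decelerations require onset-to-nadir < 30 s",
           call. = FALSE)
    }
    if (duration_s < 15 || duration_s >= 120) {
      stop("variable deceleration duration must lie in [15 s, 120 s)",
           call. = FALSE)
    }
    onset <- peak + 2          # onset typically delayed past the peak
    nadir <- onset + onset_to_nadir_s
    end <- onset + duration_s
    dip <- numeric(length(t))
    down <- t >= onset & t <= nadir
    up <- t > nadir & t <= end
    dip[down] <- depth * 0.5 * (1 - cos(pi * (t[down] - onset) / onset_to_nadir_s))
    dip[up] <- depth * 0.5 * (1 + cos(pi * (t[up] - nadir) / (end - nadir)))
  } else {
    duration_s <- duration_s %||% 80
    if (duration_s < 60) {
      stop("gradual decelerations need onset-to-nadir >= 30 s, so a total ",
           "duration >= 60 s", call. = FALSE)
    }
    nadir <- if (kind == "early_decel") peak else peak + lag_s
    if (kind == "late_decel" && lag_s <= 0) {
      stop("late decelerations need the nadir strictly after the ",
           "contraction peak (lag_s > 0)", call. = FALSE)
    }
    onset <- nadir - duration_s / 2
    end <- nadir + duration_s / 2
    dip <- depth * raised_cosine(t, onset, duration_s)
  }
  if (onset < 0 || end > record_duration(record)) {
    stop("deceleration does not fit inside the record", call. = FALSE)
  }
  check_fhr_overlap(record, onset, end)
  record$signals$fhr <- pmin(pmax(record$signals$fhr - dip, 60), 210)
  record$events <- dplyr::bind_rows(
    record$events, ctg_events(kind, onset, nadir, end, depth))
  record
}

#' Inject a contraction
#'
#' Adds a raised-cosine pressure bump to the UC channel, centered at
#' `peak_s`, and annotates it. Useful for constructing records whose
#' contraction timing is controlled directly.
#'
#' @param record A `ctg_record`.
#' @param peak_s Peak time in seconds.
#' @param amplitude Bump amplitude in mmHg.
#' @param duration_s Total bump duration (default 70 s).
#' @return The modified record.
#' @export
inject_contraction <- function(record, peak_s, amplitude, duration_s = 70) {
  stopifnot(amplitude > 0, duration_s > 0)
  onset <- peak_s - duration_s / 2
  end <- peak_s + duration_s / 2
  if (onset < 0 || end > record_duration(record)) {
    stop("contraction does not fit inside the record", call. = FALSE)
  }
  t <- record$signals$time_s
  record$signals$uc <- pmin(pmax(
    record$signals$uc + amplitude * raised_cosine(t, onset, duration_s),
    0), 100)
  record$events <- dplyr::bind_rows(
    record$events,
    ctg_events("contraction", onset, peak_s, end, amplitude))
  # keep contractions in time order so positional indexing stays sane
  ctr <- record$events$kind == "contraction"
  record$events <- dplyr::bind_rows(
    record$events[ctr, ][order(record$events$onset_s[ctr]), ],
    record$events[!ctr, ])
  record
}

#' Inject an acceleration
#'
#' Adds a transient FHR rise with an abrupt onset (onset-to-peak under
#' 30 s). Durations of 2--10 min are annotated `prolonged_acceleration`.
#'
#' @param record A `ctg_record`.
#' @param onset_s Onset time in seconds.
#' @param height Rise above baseline in bpm.
#' @param duration_s Total duration (onset to return), default 30 s.
#' @return The modified record with the event annotated.
#' @export
inject_acceleration <- function(record, onset_s, height, duration_s = 30) {
  stopifnot(height > 0, duration_s >= 10)
  if (duration_s >= 600) {
    stop("rises lasting >= 10 min are baseline changes, not accelerations",
         call. = FALSE)
  }
  t <- record$signals$time_s
  rise_s <- min(15, duration_s / 2)   # onset-to-peak < 30 s always
  peak <- onset_s + rise_s
  end <- onset_s + duration_s
  if (onset_s < 0 || end > record_duration(record)) {
    stop("acceleration does not fit inside the record", call. = FALSE)
  }
  check_fhr_overlap(record, onset_s, end)
  bump <- numeric(length(t))
  up <- t >= onset_s & t <= peak
  down <- t > peak & t <= end
  bump[up] <- height * 0.5 * (1 - cos(pi * (t[up] - onset_s) / rise_s))
  bump[down] <- height * 0.5 * (1 + cos(pi * (t[down] - peak) / (end - peak)))
  record$signals$fhr <- pmin(pmax(record$signals$fhr + bump, 60), 210)
  kind <- if (duration_s >= 120) "prolonged_acceleration" else "acceleration"
  record$events <- dplyr::bind_rows(
    record$events, ctg_events(kind, onset_s, peak, end, height))
  record
}

#' Inject a sinusoidal pattern
#'
#' Replaces the FHR trace over a window with a smooth sinusoid around the
#' baseline, suppressing variability and accelerations there. The pattern
#' must oscillate at 3--5 cycles/min and last at least 20 minutes.
#'
#' @param record A `ctg_record`.
#' @param cycles_per_min Oscillation rate, in \[3, 5\].
#' @param duration_s Window length, >= 1200 s.
#' @param onset_s Window start (default 0).
#' @param amplitude Peak-to-trough amplitude in bpm (default 10).
#' @return The modified record with the event annotated.
#' @export
inject_sinusoidal <- function(record, cycles_per_min, duration_s,
                              onset_s = 0, amplitude = 10) {
  if (cycles_per_min < 3 || cycles_per_min > 5) {
    stop("sinusoidal patterns oscillate at 3-5 cycles/min", call. = FALSE)
  }
  if (duration_s < 1200) {
    stop("sinusoidal patterns last >= 20 min (1200 s)", call. = FALSE)
  }
  end <- onset_s + duration_s
  if (onset_s < 0 || end > record_duration(record)) {
    stop("sinusoidal window does not fit inside the record", call. = FALSE)
  }
  check_fhr_overlap(record, onset_s, end)
  t <- record$signals$time_s
  base <- record_baseline_level(record)
  idx <- t >= onset_s & t <= end
  f <- cycles_per_min / 60
  record$signals$fhr[idx] <-
    base + amplitude / 2 * sin(2 * pi * f * (t[idx] - onset_s))
  record$events <- dplyr::bind_rows(
    record$events,
    ctg_events("sinusoidal", onset_s, onset_s + duration_s / 2, end,
               amplitude))
  record
}
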