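## Deterministic FIGO-style rule engine over ctg_records:
## baseline, variability, accelerations, decelerations (typed against
## contractions), sinusoidal pattern, contraction statistics, and the
## three-tier Class I/II/III interpretation.

odd_k <- function(k, n) {
  k <- min(as.integer(k), n)
  if (k %% 2L == 0L) k <- k - 1L
  max(k, 1L)
}

# centered moving average; invalid samples carry no weight
smooth_ma <- function(x, valid, k) {
  k <- odd_k(k, length(x))
  xz <- ifelse(valid, x, 0)
  w <- as.numeric(valid)
  kern <- rep(1, k)
  num <- stats::filter(xz, kern, sides = 2)
  den <- stats::filter(w, kern, sides = 2)
  out <- as.numeric(num) / pmax(as.numeric(den), 1e-12)
  # filter() leaves NA at the edges; fall back to the nearest interior value
  bad <- is.na(out) | as.numeric(den) < 1
  if (any(!bad)) {
    idx <- which(!bad)
    out[bad] <- out[idx[pmax(1, findInterval(which(bad), idx))]]
  }
  out
}

# shared per-record analysis: smoothed trace, rolling-median baseline curve,
# and the excursion mask (candidate accel/decel samples, grown by hysteresis)
fhr_context <- function(record) {
  s <- record$signals
  fs <- record$fs
  n <- nrow(s)
  valid <- s$fhr_valid & !is.na(s$fhr)
  if (!any(valid)) {
    return(list(valid = valid, n = n, fs = fs, indeterminate = TRUE))
  }
  med <- stats::median(s$fhr[valid])
  xf <- ifelse(valid, s$fhr, med)
  m <- stats::runmed(xf, odd_k(600 * fs + 1, n), endrule = "median")
  sm <- smooth_ma(s$fhr, valid, 5 * fs)
  dev <- sm - m
  core <- abs(dev) > 7
  excl <- grow_runs(core, abs(dev) > 2.5)
  list(x = s$fhr, valid = valid, n = n, fs = fs, t = s$time_s,
       m = as.numeric(m), sm = sm, dev = dev, excl = excl,
       indeterminate = FALSE)
}

# expand TRUE cores outward while `cond` holds
grow_runs <- function(core, cond) {
  out <- core
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    if (any(core[starts[j]:ends[j]])) out[starts[j]:ends[j]] <- TRUE
  }
  out
}

runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Estimate the FHR baseline
#'
#' The baseline is the mean FHR over stable segments — valid signal outside
#' candidate acceleration/deceleration excursions — following an iterative
#' scheme: a 10-min rolling median gives a provisional baseline curve,
#' excursions beyond 7 bpm from it (grown by hysteresis to 2.5 bpm) are
#' excluded, and the mean is taken over the remaining stable segments of at
#' least 2 min. If no 2-min segment survives (e.g. very frequent
#' decelerations), progressively shorter segments are used and the result
#' is flagged. Tachycardia / bradycardia are flagged when the rolling
#' baseline stays above 160 / below 110 bpm for at least 10 min.
#'
#' @param record A `ctg_record` (at least 10 min of valid FHR for a
#'   determinate estimate).
#' @return A `ctg_baseline` list: `value` (bpm), `stable_segments` tibble
#'   (`start_s`, `end_s`), `tachycardia`, `bradycardia`, `indeterminate`,
#'   `fallback`.
#' @export
estimate_baseline <- function(record) {
  ctx <- fhr_context(record)
  fs <- record$fs
  out <- list(value = NA_real_,
              stable_segments = tibble::tibble(start_s = numeric(),
                                               end_s = numeric()),
              tachycardia = FALSE, bradycardia = FALSE,
              indeterminate = TRUE, fallback = FALSE)
  class(out) <- "ctg_baseline"
  if (ctx$indeterminate) return(out)

  stable <- ctx$valid & !ctx$excl
  segs <- if (any(stable)) runs_of(stable) else
    matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
  seg_len <- if (nrow(segs)) (segs[, 2] - segs[, 1] + 1) / fs else numeric()

  pick <- NULL
  for (min_len in c(120, 60, 30)) {
    keep <- seg_len >= min_len
    if (any(keep)) { pick <- segs[keep, , drop = FALSE]; break }
  }
  out$fallback <- !is.null(pick) && !any(seg_len >= 120)
  if (is.null(pick) || sum(ctx$valid) < 600 * fs) {
    out$value <- stats::median(ctx$x[ctx$valid])
    out$indeterminate <- TRUE
  } else {
    idx <- unlist(lapply(seq_len(nrow(pick)),
                         function(j) pick[j, 1]:pick[j, 2]))
    out$value <- mean(ctx$x[idx])
    out$indeterminate <- FALSE
    keep120 <- seg_len >= 120
    if (any(keep120)) {
      s120 <- segs[keep120, , drop = FALSE]
      out$stable_segments <- tibble::tibble(
        start_s = ctx$t[s120[, 1]], end_s = ctx$t[s120[, 2]])
    }
  }

  sustained <- function(mask) {
    if (!any(mask)) return(FALSE)
    r <- runs_of(mask & ctx$valid)
    nrow(r) > 0 && any((r[, 2] - r[, 1] + 1) / fs >= 600)
  }
  out$tachycardia <- sustained(ctx$m > 160)
  out$bradycardia <- sustained(ctx$m < 110)
  out
}

#' @export
print.ctg_baseline <- function(x, ...) {
  cat(sprintf("<ctg_baseline> %.1f bpm | tachy %s | brady %s | %s\n",
              x$value, x$tachycardia, x$bradycardia,
              if (x$indeterminate) "indeterminate" else "determinate"))
  invisible(x)
}

#' Classify baseline variability
#'
#' Variability is the per-minute peak-to-trough FHR amplitude, measured on
#' valid signal outside accel/decel excursions, summarized as the median
#' over 1-min windows: absent (< 2 bpm), minimal (<= 5), moderate (> 5 and
#' <= 25), marked (> 25).
#'
#' @param record A `ctg_record`.
#' @return A list with `level` (factor) and `amplitude` (bpm), class
#'   `ctg_variability`; level `NA` if every window is excluded.
#' @export
classify_variability <- function(record) {
  ctx <- fhr_context(record)
  fs <- record$fs
  out <- structure(list(level = NA_character_, amplitude = NA_real_),
                   class = "ctg_variability")
  if (ctx$indeterminate) return(out)
  usable <- ctx$valid & !ctx$excl
  wl <- as.integer(60 * fs)
  nw <- ctx$n %/% wl
  if (nw == 0) return(out)
  p2p <- vapply(seq_len(nw), function(k) {
    i <- ((k - 1) * wl + 1):(k * wl)
    xs <- ctx$x[i][usable[i]]
    if (length(xs) < 30 * fs) return(NA_real_)
    diff(range(xs))
  }, numeric(1))
  if (all(is.na(p2p))) return(out)
  amp <- stats::median(p2p, na.rm = TRUE)
  out$amplitude <- amp
  out$level <- if (amp < 2) "absent" else if (amp <= 5) "minimal"
               else if (amp <= 25) "moderate" else "marked"
  out
}

# generic excursion scan shared by acceleration / deceleration detection.
# sign +1 looks for rises (dev > 0), -1 for dips.
scan_excursions <- function(ctx, sign, core_thr, merge_s = 5, cap_s = 60) {
  fs <- ctx$fs
  dev <- sign * ctx$dev
  core <- dev > core_thr & ctx$valid
  if (!any(core)) return(NULL)
  runs <- runs_of(core)
  # merge runs separated by less than merge_s
  if (nrow(runs) > 1) {
    merged <- list()
    cur <- runs[1, ]
    for (j in 2:nrow(runs)) {
      if ((runs[j, 1] - cur[2]) / fs < merge_s) cur[2] <- runs[j, 2]
      else { merged[[length(merged) + 1]] <- cur; cur <- runs[j, ] }
    }
    merged[[length(merged) + 1]] <- cur
    runs <- do.call(rbind, merged)
  }
  cap <- as.integer(cap_s * fs)
  raw_dev <- sign * (ctx$x - ctx$m)
  lapply(seq_len(nrow(runs)), function(j) {
    a <- runs[j, 1]; b <- runs[j, 2]
    # extend outward to the 1-bpm crossing (capped)
    lo <- a
    while (lo > 1 && a - lo < cap && dev[lo - 1] > 1) lo <- lo - 1
    hi <- b
    while (hi < ctx$n && hi - b < cap && dev[hi + 1] > 1) hi <- hi + 1
    seg <- lo:hi
    pk <- seg[which.max(dev[seg])]
    list(onset = ctx$t[lo], peak_t = ctx$t[pk], end = ctx$t[hi],
         magnitude = max(raw_dev[seg][ctx$valid[seg]], dev[pk]),
         duration = (hi - lo) / fs,
         onset_to_peak = (pk - lo) / fs)
  })
}

#' Detect accelerations
#'
#' Transient FHR rises above the rolling baseline meeting the
#' gestational-age rule: at or after 32 weeks, a peak of at least 15 bpm
#' lasting at least 15 s (before 32 weeks: 10 bpm / 10 s), shorter than
#' 2 min; rises of 2--10 min are annotated `prolonged_acceleration`;
#' rises of 10 min or more are left to baseline re-estimation.
#'
#' @param record A `ctg_record`; `record$gestational_age` selects the rule.
#' @return An event tibble (see [ctg_events()]).
#' @export
detect_accelerations <- function(record) {
  ctx <- fhr_context(record)
  if (ctx$indeterminate) return(ctg_events())
  ga <- record$gestational_age %||% 34
  thr <- if (!is.na(ga) && ga < 32) 10 else 15
  min_dur <- if (!is.na(ga) && ga < 32) 10 else 15
  cands <- scan_excursions(ctx, +1, core_thr = 0.6 * thr, cap_s = 45)
  out <- ctg_events()
  for (cd in cands %||% list()) {
    if (cd$magnitude < thr) next
    if (cd$duration < min_dur || cd$duration >= 600) next
    if (cd$onset_to_peak >= 30 && cd$duration < 120) next  # gradual rise
    kind <- if (cd$duration < 120) "acceleration" else "prolonged_acceleration"
    out <- dplyr::bind_rows(out, ctg_events(kind, cd$onset, cd$peak_t,
                                            cd$end, cd$magnitude))
  }
  out
}

#' Detect contractions from the UC channel
#'
#' Prominence-gated bump detection: the resting tone is a 5-min rolling
#' median, and excursions at least 15 mmHg above it lasting at least 20 s
#' are annotated as contractions with their peak time and amplitude.
#'
#' @param record A `ctg_record`.
#' @return An event tibble of `"contraction"` rows.
#' @export
detect_contractions <- function(record) {
  s <- record$signals
  fs <- record$fs
  valid <- s$uc_valid & !is.na(s$uc)
  if (!any(valid)) return(ctg_events())
  med <- stats::median(s$uc[valid])
  u <- ifelse(valid, s$uc, med)
  tone <- as.numeric(stats::runmed(u, odd_k(300 * fs + 1, length(u)),
                                   endrule = "median"))
  sm <- smooth_ma(s$uc, valid, 10 * fs)
  dev <- sm - tone
  core <- dev > 10 & valid
  if (!any(core)) return(ctg_events())
  runs <- runs_of(core)
  out <- ctg_events()
  for (j in seq_len(nrow(runs))) {
    a <- runs[j, 1]; b <- runs[j, 2]
    lo <- a; hi <- b
    cap <- as.integer(60 * fs)
    while (lo > 1 && a - lo < cap && dev[lo - 1] > 2) lo <- lo - 1
    while (hi < length(u) && hi - b < cap && dev[hi + 1] > 2) hi <- hi + 1
    if ((hi - lo) / fs < 20) next
    seg <- lo:hi
    pk <- seg[which.max(dev[seg])]
    mag <- max(u[seg] - tone[seg])
    if (mag < 15) next
    out <- dplyr::bind_rows(out, ctg_events(
      "contraction", s$time_s[lo], s$time_s[pk], s$time_s[hi], mag))
  }
  out
}

#' Detect and type decelerations against contractions
#'
#' Dips below the rolling baseline are first screened (depth at least
#' 15 bpm, duration at least 15 s), then typed by shape and timing:
#' variable decelerations (VD) are abrupt — onset-to-nadir under 30 s with
#' total duration under 2 min; gradual dips (onset-to-nadir at least 30 s)
#' are early decelerations (ED) when the nadir falls within 10 s of a
#' contraction peak and late decelerations (LD) when the nadir lags the
#' peak by more than 10 s. Gradual dips with no usable contraction are
#' returned untyped (`NA` kind) with a warning — timing cannot be resolved
#' from the FHR channel alone.
#'
#' @param record A `ctg_record`.
#' @param contractions Optional pre-computed contraction events
#'   ([detect_contractions()] is run otherwise).
#' @return A tibble like [ctg_events()] plus a `kind` possibly `NA` for
#'   untyped gradual dips.
#' @export
detect_decelerations <- function(record, contractions = NULL) {
  ctx <- fhr_context(record)
  if (ctx$indeterminate) return(ctg_events())
  if (is.null(contractions)) contractions <- detect_contractions(record)
  peaks <- contractions$nadir_or_peak_s
  cands <- scan_excursions(ctx, -1, core_thr = 8, cap_s = 60)
  out <- ctg_events()
  untyped <- 0L
  for (cd in cands %||% list()) {
    if (cd$magnitude < 15 || cd$duration < 15) next
    if (cd$onset_to_peak < 30 && cd$duration < 120) {
      out <- dplyr::bind_rows(out, ctg_events(
        "variable_decel", cd$onset, cd$peak_t, cd$end, cd$magnitude))
      next
    }
    if (cd$onset_to_peak < 30) next  # slow shallow drift, not a typed decel
    # gradual: needs a concurrent contraction
    if (length(peaks)) {
      delta <- cd$peak_t - peaks
      near <- which(abs(delta) <= 120)
    } else near <- integer()
    if (!length(near)) {
      untyped <- untyped + 1L
      out <- dplyr::bind_rows(out, tibble::tibble(
        kind = NA_character_, onset_s = cd$onset,
        nadir_or_peak_s = cd$peak_t, end_s = cd$end,
        magnitude = cd$magnitude))
      next
    }
    j <- near[which.min(abs(cd$peak_t - peaks[near]))]
    lag <- cd$peak_t - peaks[j]
    kind <- if (abs(lag) <= 10) "early_decel"
            else if (lag > 10) "late_decel"
            else NA_character_
    if (is.na(kind)) untyped <- untyped + 1L
    out <- dplyr::bind_rows(out, tibble::tibble(
      kind = kind, onset_s = cd$onset, nadir_or_peak_s = cd$peak_t,
      end_s = cd$end, magnitude = cd$magnitude))
  }
  if (untyped > 0) {
    warning(untyped, " gradual deceleration(s) left untyped: no usable ",
            "concurrent contraction (unimodal failure mode)", call. = FALSE)
  }
  out
}

#' Detect a sinusoidal pattern
#'
#' Scans 1-min windows for spectral concentration in the 3--5 cycles/min
#' band (at least 60% of non-DC power, peak-to-trough 3--35 bpm); the
#' pattern is present when at least 20 consecutive windows qualify and no
#' acceleration is detected inside the run.
#'
#' @param record A `ctg_record` with at least 20 min of signal.
#' @return A list: `detected`, `onset_s`, `end_s`, `cycles_per_min`.
#' @export
detect_sinusoidal <- function(record) {
  s <- record$signals
  fs <- record$fs
  out <- list(detected = FALSE, onset_s = NA_real_, end_s = NA_real_,
              cycles_per_min = NA_real_)
  wl <- as.integer(60 * fs)
  nw <- nrow(s) %/% wl
  if (nw < 20) return(out)
  ok <- logical(nw)
  domf <- numeric(nw)
  for (k in seq_len(nw)) {
    i <- ((k - 1) * wl + 1):(k * wl)
    if (!all(s$fhr_valid[i])) next
    x <- s$fhr[i] - mean(s$fhr[i])
    if (diff(range(x)) < 3 || diff(range(x)) > 35) next
    p <- Mod(stats::fft(x))[2:(wl %/% 2)]^2   # bins 1..(wl/2-1) cycles/min
    conc <- sum(p[3:5]) / sum(p)
    if (conc >= 0.6) {
      ok[k] <- TRUE
      domf[k] <- which.max(p[3:5]) + 2
    }
  }
  if (!any(ok)) return(out)
  runs <- runs_of(ok)
  lens <- runs[, 2] - runs[, 1] + 1
  acc <- detect_accelerations(record)
  for (j in order(lens, decreasing = TRUE)) {
    if (lens[j] < 20) break
    on_s <- (runs[j, 1] - 1) * 60
    end_s <- runs[j, 2] * 60
    has_acc <- nrow(acc) > 0 &&
      any(acc$onset_s < end_s & acc$end_s > on_s)
    if (!has_acc) {
      out$detected <- TRUE
      out$onset_s <- on_s
      out$end_s <- end_s
      out$cycles_per_min <- stats::median(domf[runs[j, 1]:runs[j, 2]])
      return(out)
    }
  }
  out
}

#' Contraction rate and tachysystole flag
#'
#' Counts detected contractions over an up-to-30-min observation window and
#' averages to a per-10-min rate; more than 5 per 10 min is tachysystole.
#' Windows shorter than 30 min extrapolate the rate and set
#' `low_confidence`.
#'
#' @param record A `ctg_record`.
#' @param contractions Optional pre-computed contraction events.
#' @return A list: `rate_per_10min`, `tachysystole`, `n_contractions`,
#'   `low_confidence`, `indeterminate`.
#' @export
contraction_stats <- function(record, contractions = NULL) {
  s <- record$signals
  fs <- record$fs
  if (!any(s$uc_valid)) {
    return(list(rate_per_10min = NA_real_, tachysystole = NA,
                n_contractions = NA_integer_, low_confidence = TRUE,
                indeterminate = TRUE))
  }
  if (is.null(contractions)) contractions <- detect_contractions(record)
  valid_dur <- sum(s$uc_valid) / fs
  win <- min(valid_dur, 1800)
  t_end <- max(s$time_s)
  n_in <- sum(contractions$nadir_or_peak_s >= t_end - win)
  rate <- if (win > 0) n_in / (win / 600) else NA_real_
  list(rate_per_10min = rate, tachysystole = isTRUE(rate > 5),
       n_contractions = nrow(contractions),
       low_confidence = valid_dur < 1800, indeterminate = FALSE)
}

#' Three-tier CTG interpretation
#'
#' Applies the intrapartum classification: Class I requires a 110--160 bpm
#' determinate baseline, moderate variability, and no late or variable
#' decelerations (early decelerations and accelerations are allowed);
#' Class III is absent variability with recurrent late decelerations,
#' recurrent variable decelerations or bradycardia — or a sinusoidal
#' pattern; everything else, including records with indeterminate
#' components, is Class II. "Recurrent" means at least half of the
#' detected contractions carry the deceleration type (with at least two
#' such decelerations).
#'
#' @param record A `ctg_record`.
#' @return A `ctg_class` object: `class` (`"I"`, `"II"`, `"III"`),
#'   `reasons` (character vector of fired rules), and `features` (the
#'   component analyses).
#' @export
classify_ctg <- function(record) {
  base <- estimate_baseline(record)
  ctr <- detect_contractions(record)
  vari <- classify_variability(record)
  dec <- suppressWarnings(detect_decelerations(record, ctr))
  sinus <- detect_sinusoidal(record)
  cstats <- contraction_stats(record, ctr)

  n_ld <- sum(dec$kind == "late_decel", na.rm = TRUE)
  n_vd <- sum(dec$kind == "variable_decel", na.rm = TRUE)
  n_untyped <- sum(is.na(dec$kind))
  n_ctr <- nrow(ctr)
  recurrent_ld <- n_ctr >= 2 && n_ld >= 2 && n_ld / n_ctr >= 0.5
  recurrent_vd <- n_ctr >= 2 && n_vd >= 2 && n_vd / n_ctr >= 0.5

  features <- list(baseline = base, variability = vari,
                   decelerations = dec, contractions = ctr,
                   contraction_stats = cstats, sinusoidal = sinus)
  reasons <- character()

  absent_var <- identical(vari$level, "absent")
  if (sinus$detected) reasons <- c(reasons, "sinusoidal-pattern")
  if (absent_var && recurrent_ld)
    reasons <- c(reasons, "absent-variability+recurrent-late-decel")
  if (absent_var && recurrent_vd)
    reasons <- c(reasons, "absent-variability+recurrent-variable-decel")
  if (absent_var && base$bradycardia)
    reasons <- c(reasons, "absent-variability+bradycardia")
  if (length(reasons)) {
    return(new_ctg_class("III", reasons, features))
  }

  indet <- base$indeterminate || is.na(vari$level)
  if (indet) {
    return(new_ctg_class("II", "indeterminate-component", features))
  }

  cls1 <- c(
    "baseline-110-160" = base$value >= 110 && base$value <= 160 &&
      !base$tachycardia && !base$bradycardia,
    "moderate-variability" = identical(vari$level, "moderate"),
    "no-late-decel" = n_ld == 0,
    "no-variable-decel" = n_vd == 0,
    "no-untyped-decel" = n_untyped == 0
  )
  if (all(cls1)) {
    return(new_ctg_class("I", names(cls1), features))
  }
  new_ctg_class("II", paste0("not-I:", names(cls1)[!cls1]), features)
}

new_ctg_class <- function(class, reasons, features) {
  structure(list(class = class, reasons = reasons, features = features),
            class = "ctg_class")
}

#' @export
print.ctg_class <- function(x, ...) {
  cat(sprintf("<ctg_class> Class %s | %s\n", x$class,
              paste(x$reasons, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.ctg_class <- function(x, ...) {
  tibble::tibble(class = x$class, reason = x$reasons)
}

#' @export
glance.ctg_class <- function(x, ...) {
  tibble::tibble(
    class = x$class,
    baseline_bpm = x$features$baseline$value,
    variability = x$features$variability$level,
    variability_bpm = x$features$variability$amplitude,
    n_contractions = nrow(x$features$contractions),
    n_decels = nrow(x$features$decelerations),
    sinusoidal = x$features$sinusoidal$detected
  )
}

#' Map a three-tier class to a binary label
#'
#' @param ctg_class A `ctg_class` object or a `"I"`/`"II"`/`"III"` string.
#' @param policy `"strict"` (default): only Class I is normal;
#'   `"ii_normal"`: Classes I and II are normal.
#' @return `"normal"` or `"abnormal"`.
#' @export
to_binary <- function(ctg_class, policy = c("strict", "ii_normal")) {
  policy <- match.arg(policy)
  cls <- if (inherits(ctg_class, "ctg_class")) ctg_class$class else ctg_class
  stopifnot(cls %in% c("I", "II", "III"))
  normal <- if (policy == "strict") "I" else c("I", "II")
  if (cls %in% normal) "normal" else "abnormal"
}
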