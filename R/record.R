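#' Paired FHR/UC cardiotocography record
#'
#' The central data container: a fetal heart rate (bpm) and uterine
#' contraction pressure (mmHg) series sampled on a common 4 Hz grid, with
#' per-channel validity masks (signal-loss gaps are marked invalid, never
#' interpolated) and a table of annotated events.
#'
#' @param fhr,uc Numeric vectors of equal length: FHR in bpm, UC in mmHg.
#' @param fhr_valid,uc_valid Logical masks, same length; `FALSE` marks gaps.
#' @param fs Sampling frequency in Hz (default 4).
#' @param gestational_age Weeks; affects acceleration criteria.
#' @param events Tibble of event annotations (see [ctg_events()]).
#' @param figo_class Optional `"I"`, `"II"`, or `"III"`.
#' @param binary_label Optional `"normal"` or `"abnormal"`.
#'
#' @return An object of class `ctg_record`: a list with a `signals` tibble
#'   (`time_s`, `fhr`, `uc`, `fhr_valid`, `uc_valid`), an `events` tibble,
#'   and metadata fields.
#' @export
ctg_record <- function(fhr, uc, fhr_valid = NULL, uc_valid = NULL, fs = 4,
                       gestational_age = 34, events = ctg_events(),
                       figo_class = NA_character_,
                       binary_label = NA_character_) {
  n <- length(fhr)
  if (length(uc) != n) stop("fhr and uc must have equal length", call. = FALSE)
  if (is.null(fhr_valid)) fhr_valid <- !is.na(fhr)
  if (is.null(uc_valid)) uc_valid <- !is.na(uc)
  stopifnot(length(fhr_valid) == n, length(uc_valid) == n)
  if (any(fhr[fhr_valid] < 60 | fhr[fhr_valid] > 210, na.rm = TRUE)) {
    stop("valid FHR samples must lie in [60, 210] bpm", call. = FALSE)
  }
  if (any(uc[uc_valid] < 0 | uc[uc_valid] > 100, na.rm = TRUE)) {
    stop("valid UC samples must lie in [0, 100] mmHg", call. = FALSE)
  }
  structure(
    list(
      signals = tibble::tibble(
        time_s = seq(0, by = 1 / fs, length.out = n),
        fhr = as.numeric(fhr), uc = as.numeric(uc),
        fhr_valid = as.logical(fhr_valid), uc_valid = as.logical(uc_valid)
      ),
      events = events,
      fs = fs,
      gestational_age = gestational_age,
      figo_class = figo_class,
      binary_label = binary_label
    ),
    class = "ctg_record"
  )
}

#' Event annotation table
#'
#' Builds the annotation tibble attached to a [ctg_record()]. Each row is
#' one event with its onset, nadir-or-peak, and end times in seconds, and a
#' magnitude (decel depth / accel height in bpm, contraction amplitude in
#' mmHg).
#'
#' @param kind Character vector: one of `"acceleration"`,
#'   `"prolonged_acceleration"`, `"early_decel"`, `"late_decel"`,
#'   `"variable_decel"`, `"sinusoidal"`, `"contraction"`,
#'   `"tachycardia_segment"`, `"bradycardia_segment"`.
#' @param onset_s,nadir_or_peak_s,end_s Event timing in seconds,
#'   `onset_s <= nadir_or_peak_s <= end_s`.
#' @param magnitude Positive magnitude (bpm or mmHg).
#' @return A tibble with those four columns plus `kind`.
#' @export
ctg_events <- function(kind = character(), onset_s = numeric(),
                       nadir_or_peak_s = numeric(), end_s = numeric(),
                       magnitude = numeric()) {
  valid_kinds <- c(
    "acceleration", "prolonged_acceleration", "early_decel", "late_decel",
    "variable_decel", "sinusoidal", "contraction", "tachycardia_segment",
    "bradycardia_segment"
  )
  if (!all(kind %in% valid_kinds)) {
    stop("unknown event kind(s): ",
         paste(setdiff(kind, valid_kinds), collapse = ", "), call. = FALSE)
  }
  if (any(onset_s > nadir_or_peak_s) || any(nadir_or_peak_s > end_s)) {
    stop("event timing must satisfy onset <= nadir/peak <= end", call. = FALSE)
  }
  if (any(magnitude <= 0)) stop("event magnitudes must be positive", call. = FALSE)
  tibble::tibble(
    kind = as.character(kind), onset_s = as.numeric(onset_s),
    nadir_or_peak_s = as.numeric(nadir_or_peak_s), end_s = as.numeric(end_s),
    magnitude = as.numeric(magnitude)
  )
}

#' @export
print.ctg_record <- function(x, ...) {
  dur <- nrow(x$signals) / x$fs
  cat(sprintf(
    "<ctg_record> %.1f min at %g Hz | %d events | FHR gaps %.0f%% | class %s\n",
    dur / 60, x$fs, nrow(x$events),
    100 * mean(!x$signals$fhr_valid), x$figo_class
  ))
  invisible(x)
}

#' @export
format.ctg_record <- function(x, ...) {
  sprintf("<ctg_record %.1f min, %d events>",
          nrow(x$signals) / x$fs / 60, nrow(x$events))
}

record_duration <- function(record) nrow(record$signals) / record$fs

#' Tidy a CTG record into a long tibble
#'
#' @param x A `ctg_record`.
#' @param ... Unused.
#' @return A tibble with `time_s`, `channel` (`"fhr"`/`"uc"`), `value`, and
#'   `valid` columns, one row per sample per channel.
#' @export
tidy.ctg_record <- function(x, ...) {
  s <- x$signals
  dplyr::bind_rows(
    tibble::tibble(time_s = s$time_s, channel = "fhr",
                   value = s$fhr, valid = s$fhr_valid),
    tibble::tibble(time_s = s$time_s, channel = "uc",
                   value = s$uc, valid = s$uc_valid)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ctg_record <- function(object, ...) {
  d <- tidy.ctg_record(object)
  d$value[!d$valid] <- NA_real_
  d$channel <- factor(d$channel, c("fhr", "uc"),
                      c("FHR (bpm)", "UC (mmHg)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s / 60, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write / read a CTG record as CSV (+ JSON annotation sidecar)
#'
#' The CSV holds `time_s, fhr_bpm, uc_mmhg, fhr_valid, uc_valid`; events and
#' metadata go to `<path>.events.json` when `jsonlite` is available.
#'
#' @param record A `ctg_record`.
#' @param path CSV file path.
#' @export
write_record_csv <- function(record, path) {
  s <- record$signals
  utils::write.csv(
    data.frame(time_s = s$time_s, fhr_bpm = s$fhr, uc_mmhg = s$uc,
               fhr_valid = as.integer(s$fhr_valid),
               uc_valid = as.integer(s$uc_valid)),
    path, row.names = FALSE
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(
      gestational_age = record$gestational_age,
      figo_class = record$figo_class, binary_label = record$binary_label,
      fs = record$fs, events = record$events
    )
    jsonlite::write_json(side, paste0(path, ".events.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  d <- utils::read.csv(path)
  fs <- if (nrow(d) > 1) 1 / diff(d$time_s[1:2]) else 4
  ctg_record(d$fhr_bpm, d$uc_mmhg, as.logical(d$fhr_valid),
             as.logical(d$uc_valid), fs = round(fs, 6))
}
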