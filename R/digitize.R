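#' Convert an RGB chart image to grayscale
#'
#' The gray level is the unweighted mean of the three channel values,
#' G(x, y) = (R + G + B) / 3. Single-channel input passes through unchanged.
#'
#' @param image Either an `H x W x 3` numeric array or an `H x W` matrix.
#' @return An `H x W` numeric matrix.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) == 2) return(image)
  if (length(d) == 3 && d[3] == 3) {
    return((image[, , 1] + image[, , 2] + image[, , 3]) / 3)
  }
  stop("expected a gray matrix or a 3-channel array, got dims ",
       paste(d, collapse = "x"), call. = FALSE)
}

#' Binarize a grayscale chart
#'
#' Thresholds the gray image at `layout$threshold` (tau, default 50). Under
#' the default `dark_trace` polarity the foreground mask is B = 1 where
#' G < tau, selecting the dark trace pixels and discarding the lighter
#' background grid; under `light_trace` the complementary form B = 1 where
#' G > tau is applied. The inequality is strict under both polarities, so G = tau is
#' always background.
#'
#' @param gray An `H x W` gray matrix (or RGB array, grayscaled first).
#' @param layout A [chart_layout()] supplying `threshold` and `polarity`.
#' @return An integer 0/1 matrix of the same dimensions, class `ctg_mask`.
#' @export
binarize <- function(gray, layout = chart_layout()) {
  g <- to_grayscale(gray)
  b <- if (layout$polarity == "dark_trace") g < layout$threshold
       else g > layout$threshold
  structure(matrix(as.integer(b), nrow(g), ncol(g)),
            class = c("ctg_mask", "matrix", "array"))
}

#' Extract one column's signal value from a binary mask
#'
#' Averages the band template over the foreground rows of column `col`
#' (the valid pixel set for that time point). An empty column yields `NA`
#' (a gap) by default, or the epsilon-guarded value 0 in paper-faithful
#' mode.
#'
#' @param mask A binary mask from [binarize()].
#' @param col Column index, 0-based.
#' @param channel `"fhr"` or `"uc"`.
#' @param layout A [chart_layout()].
#' @param paper_faithful If `TRUE`, empty columns return
#'   `sum / (0 + 1e-6) = 0` instead of `NA`.
#' @return A single value in the channel's clinical units, or `NA`.
#' @export
extract_column <- function(mask, col, channel = c("fhr", "uc"),
                           layout = chart_layout(), paper_faithful = FALSE) {
  channel <- match.arg(channel)
  if (col < 0 || col >= ncol(mask)) stop("column outside image", call. = FALSE)
  band <- if (channel == "fhr") layout$fhr_band else layout$uc_band
  tmpl <- if (channel == "fhr") fhr_template else uc_template
  rows0 <- band[1]:band[2]
  fg <- rows0[mask[rows0 + 1L, col + 1L] == 1L]
  if (length(fg) == 0) {
    return(if (paper_faithful) 0 else NA_real_)
  }
  if (paper_faithful) sum(tmpl(fg, layout)) / (length(fg) + 1e-6)
  else mean(tmpl(fg, layout))
}

#' Extract standardized FHR and UC series from a chart image
#'
#' The full digitization pipeline: grayscale, threshold at tau, then for
#' every pixel column average each band's affine template over the
#' foreground rows. Columns with no foreground pixel become gaps (`NA` with
#' `valid = FALSE`); gaps are never interpolated.
#'
#' @param image Gray matrix, RGB array, or `ctg_chart`.
#' @param layout A [chart_layout()]; dimensions must match the image.
#' @param paper_faithful Use the epsilon-guarded 0 for empty columns
#'   instead of gap markers.
#' @return A tibble of class `ctg_signals` with columns `col` (0-based),
#'   `time_s`, `fhr`, `fhr_valid`, `uc`, `uc_valid`.
#' @examples
#' rec <- simulate_record(sim_params(duration_s = 480, seed = 1))
#' lay <- compact_layout(96, 64, 480)
#' sig <- extract_signals(render_chart(rec, lay), lay)
#' @export
extract_signals <- function(image, layout = chart_layout(),
                            paper_faithful = FALSE) {
  g <- to_grayscale(unclass(image))
  if (nrow(g) != layout$height_px || ncol(g) != layout$width_px) {
    stop("image dimensions ", nrow(g), "x", ncol(g),
         " do not match layout ", layout$height_px, "x", layout$width_px,
         call. = FALSE)
  }
  b <- binarize(g, layout)

  band_series <- function(band, tmpl) {
    sub <- b[(band[1] + 1L):(band[2] + 1L), , drop = FALSE]
    tv <- tmpl(band[1]:band[2], layout)
    counts <- colSums(sub)
    sums <- colSums(sub * tv)
    if (paper_faithful) {
      list(value = sums / (counts + 1e-6), valid = counts > 0)
    } else {
      v <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
      list(value = v, valid = counts > 0)
    }
  }
  f_ser <- band_series(layout$fhr_band, fhr_template)
  u_ser <- band_series(layout$uc_band, uc_template)
  n <- layout$width_px
  structure(
    tibble::tibble(
      col = seq_len(n) - 1L,
      time_s = (seq_len(n) - 1L) * layout$seconds_per_col,
      fhr = f_ser$value, fhr_valid = f_ser$valid,
      uc = u_ser$value, uc_valid = u_ser$valid
    ),
    class = c("ctg_signals", class(tibble::tibble())),
    layout = layout
  )
}

#' Stack extracted signal pairs into the two-channel time-series matrix
#'
#' Builds the `2N x n` matrix whose rows interleave the FHR and UC series of
#' each of the N digitized images: rows (2k-1, 2k) hold (FHR_k, UC_k).
#'
#' @param extractions A list of `ctg_signals` tibbles (from
#'   [extract_signals()]), all with the same number of columns.
#' @return A `ctg_signal_matrix`: a numeric `2N x n` matrix `X` with
#'   attributes `channel_of_row` (alternating `"fhr"`/`"uc"`) and `gap_mask`
#'   (logical `2N x n`, `TRUE` where the value is a gap).
#' @export
assemble_matrix <- function(extractions) {
  if (length(extractions) == 0) {
    return(structure(matrix(numeric(), 0, 0),
                     channel_of_row = character(),
                     gap_mask = matrix(logical(), 0, 0),
                     class = c("ctg_signal_matrix", "matrix", "array")))
  }
  ns <- vapply(extractions, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop("all extracted series must have the same length; got lengths ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  }
  n <- ns[1]
  N <- length(extractions)
  X <- matrix(NA_real_, 2 * N, n)
  gap <- matrix(TRUE, 2 * N, n)
  for (k in seq_len(N)) {
    e <- extractions[[k]]
    X[2 * k - 1, ] <- e$fhr
    X[2 * k, ] <- e$uc
    gap[2 * k - 1, ] <- !e$fhr_valid
    gap[2 * k, ] <- !e$uc_valid
  }
  structure(X,
            channel_of_row = rep(c("fhr", "uc"), N),
            gap_mask = gap,
            class = c("ctg_signal_matrix", "matrix", "array"))
}

#' Round-trip a record through rendering and digitization
#'
#' Convenience for validation: renders `record` with `layout`, re-extracts
#' the signals, and reports per-channel maximum absolute error over valid,
#' non-edge columns together with gap bookkeeping.
#'
#' @param record A `ctg_record`.
#' @param layout A [chart_layout()].
#' @return A list with `max_err_fhr`, `max_err_uc` (bpm / mmHg),
#'   `gap_match` (logical: extracted gaps exactly at blank input columns),
#'   and the extraction tibble.
#' @export
round_trip_error <- function(record, layout = chart_layout()) {
  chart <- render_chart(record, layout)
  ex <- extract_signals(chart, layout)
  s <- record$signals
  col0 <- pmin(floor(s$time_s / layout$seconds_per_col),
               layout$width_px - 1L)

  chan_err <- function(values, valid, ex_val, ex_valid, range) {
    truth <- tapply(ifelse(valid, pmin(pmax(values, range[1]), range[2]),
                           NA_real_),
                    col0, mean, na.rm = TRUE)
    cols <- as.integer(names(truth)) + 1L
    keep <- !is.na(truth)
    cols <- cols[keep]; truth <- truth[keep]
    if (length(cols) > 2) {      # drop edge columns
      interior <- cols > min(cols) & cols < max(cols)
      cols <- cols[interior]; truth <- truth[interior]
    }
    stopifnot(all(ex_valid[cols]))
    max(abs(ex_val[cols] - truth))
  }
  rep <- attr(chart, "render_report")
  gap_match <-
    identical(which(!ex$fhr_valid) - 1L, as.integer(rep$blank_fhr_cols)) &&
    identical(which(!ex$uc_valid) - 1L, as.integer(rep$blank_uc_cols))
  list(
    max_err_fhr = chan_err(s$fhr, s$fhr_valid, ex$fhr, ex$fhr_valid,
                           layout$fhr_range),
    max_err_uc = chan_err(s$uc, s$uc_valid, ex$uc, ex$uc_valid,
                          layout$uc_range),
    gap_match = gap_match,
    extraction = ex
  )
}
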