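#' Render a CTG record as a two-band paper-style chart image
#'
#' Draws the FHR and UC traces into their layout bands through the exact
#' inverse of the digitizer's affine templates, over a background grid drawn
#' at a sub-threshold intensity so that binarization removes it. Invalid
#' (gap) samples leave their columns blank: a gap column contains grid only.
#'
#' @param record A [ctg_record()]. Its duration must fit the layout width
#'   (`duration <= width_px * seconds_per_col`).
#' @param layout A [chart_layout()].
#' @param grid Draw the background grid (default `TRUE`).
#' @return A `ctg_chart`: a `height_px x width_px` numeric matrix of gray
#'   levels in \[0, 255\] with attributes `layout` and `render_report` (a
#'   list with clipped-sample counts and per-channel blank columns).
#' @export
render_chart <- function(record, layout = chart_layout(), grid = TRUE) {
  dur <- record_duration(record)
  n_cols <- layout$width_px
  if (dur > n_cols * layout$seconds_per_col + 1e-9) {
    stop("record duration (", round(dur), " s) exceeds chart capacity (",
         n_cols * layout$seconds_per_col, " s)", call. = FALSE)
  }
  dark <- layout$polarity == "dark_trace"
  bg <- if (dark) 255 else 0
  fg <- if (dark) 0 else 255
  gr <- if (dark) layout$grid_intensity else 255 - layout$grid_intensity
  img <- matrix(bg, layout$height_px, n_cols)

  if (grid) {
    vcols <- seq(1L, n_cols, by = 20L)
    img[, vcols] <- gr
    for (band in list(layout$fhr_band, layout$uc_band)) {
      hrows <- seq(band[1] + 1L, band[2] + 1L, by = 10L)
      img[hrows, ] <- gr
    }
  }

  s <- record$signals
  col0 <- pmin(floor(s$time_s / layout$seconds_per_col), n_cols - 1L)
  report <- list(clipped_fhr = 0L, clipped_uc = 0L,
                 blank_fhr_cols = integer(), blank_uc_cols = integer())

  draw <- function(img, values, valid, band, range) {
    clipped <- sum(valid & (values < range[1] | values > range[2]))
    v <- pmin(pmax(values, range[1]), range[2])
    rows0 <- round(band_row_of(v, band, range))
    ok <- valid
    img[cbind(rows0[ok] + 1L, col0[ok] + 1L)] <- fg
    blank <- setdiff(seq_len(n_cols) - 1L, col0[ok])
    list(img = img, clipped = clipped, blank = blank)
  }
  d1 <- draw(img, s$fhr, s$fhr_valid, layout$fhr_band, layout$fhr_range)
  d2 <- draw(d1$img, s$uc, s$uc_valid, layout$uc_band, layout$uc_range)
  report$clipped_fhr <- d1$clipped
  report$clipped_uc <- d2$clipped
  report$blank_fhr_cols <- d1$blank
  report$blank_uc_cols <- d2$blank

  structure(d2$img, class = c("ctg_chart", "matrix", "array"),
            layout = layout, render_report = report)
}

#' @export
print.ctg_chart <- function(x, ...) {
  rep <- attr(x, "render_report")
  cat(sprintf("<ctg_chart> %d x %d px | %d clipped samples | %d/%d blank FHR/UC cols\n",
              nrow(x), ncol(x), rep$clipped_fhr + rep$clipped_uc,
              length(rep$blank_fhr_cols), length(rep$blank_uc_cols)))
  invisible(x)
}

#' Write a chart image to PNG
#'
#' @param chart A `ctg_chart` (or numeric gray matrix in \[0,255\]).
#' @param path Output file path.
#' @export
write_chart_png <- function(chart, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG requires the 'png' package", call. = FALSE)
  }
  png::writePNG(unclass(chart) / 255, path)
  invisible(path)
}

#' Read a chart image (PNG)
#'
#' @param path PNG file; RGB images are accepted and grayscaled on read.
#' @return A numeric matrix (or H x W x 3 array) of gray levels in \[0,255\].
#' @export
read_chart_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG requires the 'png' package", call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img * 255
}
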