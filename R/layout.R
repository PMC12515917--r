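#' Chart layout geometry for two-band CTG strips
#'
#' Describes the geometry of a paper-style cardiotocography chart: overall
#' raster size, the row bands holding the fetal-heart-rate (FHR) and uterine
#' contraction (UC) traces, the clinical value range each band spans, the
#' binarization threshold, and the chart speed (seconds of signal per pixel
#' column). The defaults reproduce a 1,653 x 2,339 px hospital strip whose
#' FHR band occupies rows 281--569 (60--210 bpm) and whose UC band occupies
#' rows 628--770 (0--100 mmHg), digitized with a fixed gray threshold of 50.
#'
#' Row indices are 0-based inclusive band bounds, so the default FHR band is
#' 289 rows tall and one row corresponds to 150/288 (about 0.52) bpm.
#'
#' @param height_px,width_px Raster dimensions in pixels (rows, columns).
#' @param fhr_band,uc_band Integer length-2 vectors: first and last row
#'   (0-based, inclusive) of each trace band. Bands must be disjoint.
#' @param fhr_range,uc_range Clinical value ranges `(min, max)` mapped onto
#'   each band; band top row maps to the range maximum.
#' @param threshold Gray level tau in (0, 255) separating trace from
#'   background during binarization.
#' @param polarity `"dark_trace"` (trace pixels darker than tau, the
#'   default) or `"light_trace"` (trace pixels lighter than tau).
#' @param seconds_per_col Chart speed: seconds of signal represented by one
#'   pixel column. The default 0.25 s matches one 4 Hz sample per column.
#' @param grid_intensity Gray level used for the background grid when
#'   rendering; must sit on the background side of `threshold`.
#'
#' @return An object of class `ctg_layout` (a named list).
#' @examples
#' lay <- chart_layout()
#' fhr_template(281, lay)  # 210 bpm at the band top
#' uc_template(770, lay)   # 0 mmHg at the band bottom
#' @export
chart_layout <- function(height_px = 1653L, width_px = 2339L,
                         fhr_band = c(281L, 569L), uc_band = c(628L, 770L),
                         fhr_range = c(60, 210), uc_range = c(0, 100),
                         threshold = 50, polarity = c("dark_trace", "light_trace"),
                         seconds_per_col = 0.25, grid_intensity = 200) {
  polarity <- match.arg(polarity)
  stopifnot(
    height_px > 0, width_px > 0,
    length(fhr_band) == 2L, length(uc_band) == 2L,
    fhr_band[1] < fhr_band[2], uc_band[1] < uc_band[2],
    fhr_range[1] < fhr_range[2], uc_range[1] < uc_range[2],
    threshold > 0, threshold < 255,
    seconds_per_col > 0
  )
  if (max(fhr_band) >= height_px || max(uc_band) >= height_px ||
      min(fhr_band) < 0 || min(uc_band) < 0) {
    stop("trace bands must lie within the image (0-based rows)", call. = FALSE)
  }
  if (fhr_band[2] >= uc_band[1] && uc_band[2] >= fhr_band[1]) {
    stop("FHR and UC bands must be disjoint", call. = FALSE)
  }
  structure(
    list(
      height_px = as.integer(height_px), width_px = as.integer(width_px),
      fhr_band = as.integer(fhr_band), uc_band = as.integer(uc_band),
      fhr_range = as.numeric(fhr_range), uc_range = as.numeric(uc_range),
      threshold = threshold, polarity = polarity,
      seconds_per_col = seconds_per_col, grid_intensity = grid_intensity
    ),
    class = "ctg_layout"
  )
}

#' @export
print.ctg_layout <- function(x, ...) {
  cat(sprintf(
    "<ctg_layout> %d x %d px | FHR rows %d-%d -> %g-%g bpm | UC rows %d-%d -> %g-%g mmHg | tau=%g (%s) | %.3g s/col\n",
    x$height_px, x$width_px, x$fhr_band[1], x$fhr_band[2],
    x$fhr_range[1], x$fhr_range[2], x$uc_band[1], x$uc_band[2],
    x$uc_range[1], x$uc_range[2], x$threshold, x$polarity, x$seconds_per_col
  ))
  invisible(x)
}

# two-point affine band template: band top row -> value max, bottom -> min.
# Strictly monotone decreasing in the row index (the image y axis points down).
band_template <- function(row, band, range) {
  if (any(row < band[1] | row > band[2])) {
    stop("row index outside the trace band [", band[1], ", ", band[2], "]",
         call. = FALSE)
  }
  range[2] - (range[2] - range[1]) * (row - band[1]) / (band[2] - band[1])
}

# inverse: clinical value -> fractional row (clipping handled by caller)
band_row_of <- function(value, band, range) {
  band[1] + (range[2] - value) / (range[2] - range[1]) * (band[2] - band[1])
}

#' Affine row-to-value templates for the FHR and UC bands
#'
#' Maps a pixel row index inside a trace band to the clinical value drawn at
#' that row. The map is affine and strictly decreasing: the band's top row
#' carries the range maximum (210 bpm / 100 mmHg by default) and the bottom
#' row the minimum (60 bpm / 0 mmHg).
#'
#' @param row Integer (or numeric) row index, 0-based; vectorized.
#' @param layout A [chart_layout()].
#' @return Numeric vector of bpm (`fhr_template`) or mmHg (`uc_template`).
#' @export
fhr_template <- function(row, layout = chart_layout()) {
  band_template(row, layout$fhr_band, layout$fhr_range)
}

#' @rdname fhr_template
#' @export
uc_template <- function(row, layout = chart_layout()) {
  band_template(row, layout$uc_band, layout$uc_range)
}

# quantization step (value change per row) for round-trip error bounds
layout_step <- function(layout) {
  c(fhr = diff(layout$fhr_range) / diff(layout$fhr_band),
    uc  = diff(layout$uc_range) / diff(layout$uc_band))
}

#' Compact layout for desk-scale experiments
#'
#' A small chart geometry used for fast rendering of many records (model
#' smoke training, examples). Same band structure as [chart_layout()], with
#' the two bands brought close together so convolutional receptive fields
#' can span both channels at low resolution.
#'
#' @param width_px,height_px Raster size in pixels.
#' @param duration_s Signal duration one strip should hold; fixes the chart
#'   speed as `duration_s / width_px`.
#' @return A `ctg_layout`.
#' @export
compact_layout <- function(width_px = 96L, height_px = 64L, duration_s = 480) {
  chart_layout(
    height_px = height_px, width_px = width_px,
    fhr_band = c(2L, as.integer(round(height_px * 0.55))),
    uc_band = c(as.integer(round(height_px * 0.60)), height_px - 2L),
    seconds_per_col = duration_s / width_px
  )
}
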