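test_that("grayscale conversion is the unweighted channel mean", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(30, 60, 90)
  g <- to_grayscale(img)
  expect_equal(g[1, 1], 60)
  expect_equal(g[2, 2], 0)
  gray <- matrix(c(10, 20, 30, 40), 2)
  expect_identical(to_grayscale(gray), gray)   # idempotent on gray input
  expect_error(to_grayscale(array(0, c(2, 2, 4))), "3-channel")
})

test_that("binarization is strict at the threshold under both polarities", {
  lay <- chart_layout()
  g <- matrix(c(40, 200, 50, 0), 2)
  b <- binarize(g, lay)
  expect_equal(b[1, 1], 1L)   # 40 < 50: trace
  expect_equal(b[2, 1], 0L)   # 200: background
  expect_equal(b[1, 2], 0L)   # exactly tau: background
  lay_light <- chart_layout(polarity = "light_trace")
  bl <- binarize(g, lay_light)
  expect_equal(bl[1, 1], 0L)
  expect_equal(bl[2, 1], 1L)
  expect_equal(bl[1, 2], 0L)  # strict under the light-trace form too
})

test_that("band templates hit the clinical range endpoints", {
  lay <- chart_layout()
  expect_equal(fhr_template(281, lay), 210)
  expect_equal(fhr_template(569, lay), 60)
  expect_equal(fhr_template(425, lay), 135)   # band midpoint
  expect_equal(uc_template(628, lay), 100)
  expect_equal(uc_template(770, lay), 0)
  expect_equal(uc_template(699, lay), 50)
  expect_error(fhr_template(100, lay), "outside")
  expect_error(uc_template(575, lay), "outside")
  # strictly monotone decreasing in the row index
  rows <- 281:569
  expect_true(all(diff(fhr_template(rows, lay)) < 0))
  expect_true(all(diff(uc_template(628:770, lay)) < 0))
})

test_that("column extraction averages the template over foreground rows", {
  lay <- chart_layout()
  m <- matrix(0L, lay$height_px, lay$width_px)
  m[281 + 1, 5 + 1] <- 1L
  m[569 + 1, 8 + 1] <- 1L
  m[281 + 1, 8 + 1] <- 1L
  mask <- structure(m, class = c("ctg_mask", "matrix", "array"))
  expect_equal(extract_column(mask, 5, "fhr", lay), 210)
  expect_equal(extract_column(mask, 8, "fhr", lay), 135)  # mean(210, 60)
  expect_true(is.na(extract_column(mask, 9, "fhr", lay)))
  expect_equal(extract_column(mask, 9, "fhr", lay, paper_faithful = TRUE), 0)
})

test_that("render/digitize round trip stays within one quantization step", {
  lay <- chart_layout()
  step <- c(150 / 288, 100 / 142)
  rec <- simulate_record(sim_params(
    duration_s = 584, seed = 21,
    gap_spec = list(list(channel = "fhr", start_s = 200, end_s = 230),
                    list(channel = "uc", start_s = 400, end_s = 410))))
  rt <- round_trip_error(rec, lay)
  expect_lt(rt$max_err_fhr, step[1])
  expect_lt(rt$max_err_uc, step[2])
  expect_true(rt$gap_match)
})

test_that("the background grid never reaches the digitizer", {
  lay <- chart_layout()
  rec <- simulate_record(sim_params(duration_s = 584, seed = 22))
  with_grid <- extract_signals(render_chart(rec, lay, grid = TRUE), lay)
  without <- extract_signals(render_chart(rec, lay, grid = FALSE), lay)
  expect_identical(with_grid$fhr, without$fhr)
  expect_identical(with_grid$uc, without$uc)
})

test_that("gaps propagate and are never interpolated", {
  lay <- compact_layout(96, 64, 480)
  rec <- simulate_record(sim_params(
    duration_s = 480, seed = 3,
    gap_spec = list(list(channel = "both", start_s = 100, end_s = 130))))
  ex <- extract_signals(render_chart(rec, lay), lay)
  gap_cols <- unique(floor(rec$signals$time_s[!rec$signals$fhr_valid] /
                             lay$seconds_per_col))
  expect_setequal(ex$col[!ex$fhr_valid], gap_cols)
  expect_true(all(is.na(ex$fhr[!ex$fhr_valid])))
  # an all-background image digitizes to all gaps
  blank <- matrix(255, lay$height_px, lay$width_px)
  exb <- extract_signals(blank, lay)
  expect_true(all(!exb$fhr_valid) && all(!exb$uc_valid))
})

test_that("clipped samples are flagged in the render report", {
  lay <- compact_layout(96, 64, 480)
  rec <- simulate_record(quiet_params(baseline = 210, duration_s = 480))
  ch <- render_chart(rec, lay)
  # constant 210 bpm occupies the topmost FHR band row in every column
  ex <- extract_signals(ch, lay)
  expect_true(all(ex$fhr[ex$fhr_valid] == 210))
  rec2 <- simulate_record(quiet_params(duration_s = 480))
  rec2$signals$uc <- rep(0, nrow(rec2$signals))
  ex2 <- extract_signals(render_chart(rec2, lay), lay)
  expect_true(all(ex2$uc[ex2$uc_valid] == 0))
})

test_that("assemble_matrix interleaves FHR and UC rows", {
  lay <- compact_layout(48, 64, 240)
  exs <- lapply(1:3, function(s) {
    rec <- simulate_record(sim_params(duration_s = 240, seed = s))
    extract_signals(render_chart(rec, lay), lay)
  })
  X <- assemble_matrix(exs)
  expect_equal(dim(X), c(6, 48))
  expect_equal(attr(X, "channel_of_row"),
               rep(c("fhr", "uc"), 3))
  X1 <- assemble_matrix(exs[1])
  expect_equal(unname(X1[1, ]), exs[[1]]$fhr)
  expect_equal(unname(X1[2, ]), exs[[1]]$uc)
  X0 <- assemble_matrix(list())
  expect_equal(nrow(X0), 0)
  short <- exs[[1]][1:10, ]
  expect_error(assemble_matrix(list(exs[[1]], short)), "same length")
})

test_that("extraction rejects images that do not match the layout", {
  lay <- chart_layout()
  expect_error(extract_signals(matrix(255, 100, 100), lay),
               "do not match")
})
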