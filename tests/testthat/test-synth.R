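test_that("simulated records carry the requested baseline and variability", {
  rec <- simulate_record(sim_params(baseline_bpm = 142, variability_amp = 10,
                                    contraction_rate = 0,
                                    duration_s = 1200, seed = 7))
  expect_equal(mean(rec$signals$fhr), 142, tolerance = 0.01)
  # per-minute peak-to-trough is rescaled to the target exactly (median)
  p2p <- sapply(seq_len(20), function(k) {
    idx <- ((k - 1) * 240 + 1):(k * 240)
    diff(range(rec$signals$fhr[idx]))
  })
  expect_equal(median(p2p), 10, tolerance = 1e-6)
})

test_that("zero variability gives a constant trace equal to baseline", {
  rec <- simulate_record(quiet_params(baseline = 142, seed = 3))
  expect_true(all(rec$signals$fhr == 142))
  expect_true(all(rec$signals$uc == 10))
})

test_that("identical seeds give bit-identical records", {
  p <- sim_params(duration_s = 900, seed = 42)
  expect_identical(simulate_record(p), simulate_record(p))
})

test_that("record invariants hold across seeds and event mixes", {
  for (seed in 1:5) {
    rec <- simulate_event_fixture(seed, duration_s = 900)
    s <- rec$signals
    expect_true(all(s$fhr[s$fhr_valid] >= 60 & s$fhr[s$fhr_valid] <= 210))
    expect_true(all(s$uc[s$uc_valid] >= 0 & s$uc[s$uc_valid] <= 100))
    ev <- rec$events
    expect_true(all(ev$onset_s <= ev$nadir_or_peak_s))
    expect_true(all(ev$nadir_or_peak_s <= ev$end_s))
    expect_true(all(ev$magnitude > 0))
  }
})

test_that("early decelerations align their nadir with the contraction peak", {
  rec <- contraction_record()
  ctr <- rec$events[rec$events$kind == "contraction", ]
  out <- inject_deceleration(rec, "early_decel", 2, depth = 30)
  ann <- out$events[out$events$kind == "early_decel", ]
  expect_equal(ann$nadir_or_peak_s, ctr$nadir_or_peak_s[2])
})

test_that("late decelerations echo the constructed lag", {
  rec <- contraction_record()
  ctr <- rec$events[rec$events$kind == "contraction", ]
  out <- inject_deceleration(rec, "late_decel", 1, depth = 30, lag_s = 30)
  ann <- out$events[out$events$kind == "late_decel", ]
  expect_equal(ann$nadir_or_peak_s - ctr$nadir_or_peak_s[1], 30)
})

test_that("variable decelerations respect the abrupt-onset rule", {
  rec <- contraction_record()
  out <- inject_deceleration(rec, "variable_decel", 1, depth = 20,
                             onset_to_nadir_s = 10)
  ann <- out$events[out$events$kind == "variable_decel", ]
  expect_equal(nrow(ann), 1)
  expect_equal(ann$nadir_or_peak_s - ann$onset_s, 10)
  # a decline under 15 bpm is not a variable deceleration
  expect_error(inject_deceleration(rec, "variable_decel", 1, depth = 10),
               ">= 15 bpm")
  expect_error(inject_deceleration(rec, "variable_decel", 1, depth = 20,
                                   onset_to_nadir_s = 35), "< 30 s")
  expect_error(inject_deceleration(rec, "variable_decel", 1, depth = 20,
                                   duration_s = 130), "120")
})

test_that("decelerations need an existing target contraction", {
  rec <- simulate_record(quiet_params())
  expect_error(inject_deceleration(rec, "early_decel", 1, depth = 30),
               "does not exist")
})

test_that("overlapping incompatible events are rejected", {
  rec <- contraction_record()
  out <- inject_deceleration(rec, "early_decel", 2, depth = 30)
  expect_error(inject_deceleration(out, "late_decel", 2, depth = 30),
               "overlap")
})

test_that("sinusoidal injection enforces rate and duration limits", {
  rec <- simulate_record(quiet_params(duration_s = 1800))
  out <- inject_sinusoidal(rec, cycles_per_min = 4, duration_s = 1500)
  # dominant frequency of the injected window is 4 cycles/min
  x <- out$signals$fhr[1:(1500 * 4)]
  p <- Mod(fft(x - mean(x)))^2
  freqs <- (seq_along(p) - 1) / 1500   # Hz
  expect_equal(freqs[which.max(p[2:3000]) + 1], 4 / 60, tolerance = 1e-6)
  expect_error(inject_sinusoidal(rec, 2, 1500), "3-5 cycles")
  expect_error(inject_sinusoidal(rec, 4, 600), "1200")
})

test_that("gap specs invalidate exactly the requested samples", {
  rec <- simulate_record(sim_params(
    duration_s = 600, seed = 2,
    gap_spec = list(list(channel = "fhr", start_s = 100, end_s = 130))))
  t <- rec$signals$time_s
  expect_true(all(!rec$signals$fhr_valid[t >= 100 & t < 130]))
  expect_true(all(rec$signals$fhr_valid[t < 100 | t >= 130]))
  expect_true(all(rec$signals$uc_valid))
})

test_that("make_dataset reproduces the cohort mix and is deterministic", {
  ds <- make_dataset(326, seed = 5, render = FALSE)
  expect_equal(sum(ds$binary_label == "normal"), 224)
  expect_equal(sum(ds$binary_label == "abnormal"), 102)
  ds2 <- make_dataset(326, seed = 5, render = FALSE)
  expect_identical(ds$figo_class, ds2$figo_class)
  expect_identical(ds$binary_label, ds2$binary_label)

  d1 <- make_dataset(10, c(1, 0, 0), seed = 1, render = FALSE)
  expect_true(all(d1$figo_class == "I"))
  expect_error(make_dataset(0), "positive")
  expect_error(make_dataset(10, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("the timing dataset carries no class signal in the FHR channel", {
  ds <- make_timing_dataset(30, seed = 4)
  cnt <- sapply(ds$record, function(r) {
    sum(r$events$kind %in% c("early_decel", "late_decel"))
  })
  # identical deceleration counts in both classes, by construction
  expect_true(all(cnt == cnt[1]))
  # normal records carry EDs (nadir at contraction peak), abnormal LDs
  for (i in c(1, 2)) {
    ev <- ds$record[[i]]$events
    dec <- ev[ev$kind %in% c("early_decel", "late_decel"), ]
    ctr <- ev[ev$kind == "contraction", ]
    lag <- dec$nadir_or_peak_s - ctr$nadir_or_peak_s
    if (ds$binary_label[i] == "normal") {
      expect_true(all(abs(lag) < 1e-9))
      expect_true(all(dec$kind == "early_decel"))
    } else {
      expect_true(all(lag >= 35 & lag <= 60))
      expect_true(all(dec$kind == "late_decel"))
    }
  }
  expect_identical(make_timing_dataset(30, seed = 4)$binary_label,
                   ds$binary_label)
})

test_that("record CSV round trip preserves signals and masks", {
  rec <- simulate_record(sim_params(
    duration_s = 300, seed = 9,
    gap_spec = list(list(channel = "uc", start_s = 50, end_s = 70))))
  path <- tempfile(fileext = ".csv")
  write_record_csv(rec, path)
  back <- read_record_csv(path)
  expect_equal(back$signals$fhr, rec$signals$fhr)
  expect_equal(back$signals$uc_valid, rec$signals$uc_valid)
  unlink(path)
})
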