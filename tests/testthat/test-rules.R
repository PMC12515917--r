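test_that("baseline estimation recovers constant traces and flags extremes", {
  b <- estimate_baseline(simulate_record(quiet_params(baseline = 140)))
  expect_equal(b$value, 140)
  expect_false(b$tachycardia || b$bradycardia || b$indeterminate)

  b165 <- estimate_baseline(simulate_record(quiet_params(baseline = 165,
                                                         duration_s = 720)))
  expect_true(b165$tachycardia)
  b105 <- estimate_baseline(simulate_record(quiet_params(baseline = 105,
                                                         duration_s = 720)))
  expect_true(b105$bradycardia)
})

test_that("baseline is recovered within 2 bpm across the normal range", {
  for (b in c(110, 125, 142, 160)) {
    for (seed in 1:3) {
      rec <- simulate_record(sim_params(
        baseline_bpm = b, variability_amp = 15, contraction_rate = 0,
        duration_s = 1200, seed = seed))
      est <- estimate_baseline(rec)
      expect_lt(abs(est$value - b), 2)
    }
  }
})

test_that("short records give an indeterminate baseline", {
  rec <- simulate_record(quiet_params(duration_s = 300))
  expect_true(estimate_baseline(rec)$indeterminate)
})

test_that("variability classes follow the amplitude thresholds", {
  lv <- function(amp, seed = 2) {
    classify_variability(simulate_record(sim_params(
      baseline_bpm = 140, variability_amp = amp, contraction_rate = 0,
      duration_s = 1200, seed = seed)))
  }
  expect_equal(lv(0)$level, "absent")
  expect_equal(lv(4)$level, "minimal")
  expect_equal(lv(10)$level, "moderate")
  expect_equal(lv(30)$level, "marked")
  # a pure 4-bpm sinusoid is minimal variability
  rec <- simulate_record(quiet_params(duration_s = 1800))
  rec <- inject_sinusoidal(rec, 4, 1500, amplitude = 4)
  expect_equal(classify_variability(rec)$level, "minimal")
})

test_that("acceleration detection applies the gestational-age rule", {
  mk <- function(height, ga, dur = 20) {
    rec <- simulate_record(quiet_params(seed = 1, gestational_age = ga))
    rec <- inject_acceleration(rec, 600, height, dur)
    detect_accelerations(rec)
  }
  expect_equal(nrow(mk(15, 34)), 1)   # >= 15 bpm for 20 s at 34 wk
  expect_equal(nrow(mk(12, 34)), 0)   # below the post-32-week rule
  expect_equal(nrow(mk(12, 30)), 1)   # >= 10 bpm rule before 32 wk
  long <- mk(20, 34, dur = 180)
  expect_equal(long$kind, "prolonged_acceleration")
})

test_that("decelerations are typed by shape and contraction timing", {
  rec <- contraction_record()
  rec <- inject_deceleration(rec, "early_decel", 1, depth = 30)
  rec <- inject_deceleration(rec, "late_decel", 2, depth = 30, lag_s = 25)
  rec <- inject_deceleration(rec, "variable_decel", 3, depth = 25,
                             duration_s = 45, onset_to_nadir_s = 8)
  det <- detect_decelerations(rec)
  expect_setequal(det$kind, c("early_decel", "late_decel",
                              "variable_decel"))
  truth <- rec$events[rec$events$kind %in% det$kind, ]
  for (k in det$kind) {
    expect_lt(abs(det$nadir_or_peak_s[det$kind == k] -
                    truth$nadir_or_peak_s[truth$kind == k]), 10)
  }
})

test_that("removing the UC channel makes gradual decelerations untypable", {
  rec <- simulate_record(sim_params(140, 8, 3, duration_s = 1800,
                                    seed = 14))
  rec <- inject_deceleration(rec, "early_decel", 2, depth = 30)
  typed <- detect_decelerations(rec)
  expect_equal(typed$kind, "early_decel")
  rec$signals$uc_valid[] <- FALSE
  expect_warning(untyped <- detect_decelerations(rec), "untyped")
  expect_true(is.na(untyped$kind))
})

test_that("sinusoidal patterns need 3-5 cycles/min for at least 20 min", {
  base <- sim_params(140, 10, 0, duration_s = 1800, seed = 3)
  rec <- simulate_record(sim_params(140, 10, 0, duration_s = 1800, seed = 3,
    event_requests = list(list(kind = "sinusoidal", cycles_per_min = 4,
                               duration_s = 1500, onset_s = 100))))
  hit <- detect_sinusoidal(rec)
  expect_true(hit$detected)
  expect_equal(hit$cycles_per_min, 4)
  expect_false(detect_sinusoidal(simulate_record(base))$detected)
  # a 19-min sinusoid (constructed directly) falls short of the rule
  r19 <- simulate_record(base)
  t <- r19$signals$time_s
  r19$signals$fhr[t < 1140] <- 140 + 5 * sin(2 * pi * (4 / 60) * t[t < 1140])
  expect_false(detect_sinusoidal(r19)$detected)
})

test_that("contraction statistics average to a per-10-min rate", {
  r18 <- simulate_record(sim_params(140, 5, 6, duration_s = 1800, seed = 8))
  n18 <- sum(r18$events$kind == "contraction")
  s18 <- contraction_stats(r18)
  expect_equal(s18$n_contractions, n18)
  expect_equal(s18$rate_per_10min, n18 / 3)
  if (n18 > 15) expect_true(s18$tachysystole)

  r12 <- simulate_record(sim_params(140, 5, 4, duration_s = 1800, seed = 9))
  s12 <- contraction_stats(r12)
  expect_false(s12$tachysystole)

  flat <- simulate_record(quiet_params(duration_s = 1800))
  sf <- contraction_stats(flat)
  expect_equal(sf$rate_per_10min, 0)
  expect_false(sf$tachysystole)

  nouc <- flat
  nouc$signals$uc_valid[] <- FALSE
  expect_true(contraction_stats(nouc)$indeterminate)
})

test_that("three-tier classification matches the rule definitions", {
  cI <- classify_ctg(simulate_record(sim_params(142, 10, 3,
    duration_s = 1800, seed = 11,
    event_requests = list(list(kind = "acceleration", onset_s = 400,
                               height = 20, duration_s = 30)))))
  expect_equal(cI$class, "I")
  expect_true(length(cI$reasons) > 0)

  cII <- classify_ctg(simulate_record(sim_params(142, 4, 3,
                                                 duration_s = 1800,
                                                 seed = 12)))
  expect_equal(cII$class, "II")

  r3 <- simulate_record(sim_params(140, 0.5, 2.5, duration_s = 1800,
                                   seed = 13))
  for (i in seq_len(sum(r3$events$kind == "contraction"))) {
    r3 <- inject_deceleration(r3, "late_decel", i, depth = 30, lag_s = 30)
  }
  cIII <- classify_ctg(r3)
  expect_equal(cIII$class, "III")
  expect_true(any(grepl("late-decel", cIII$reasons)))

  sin3 <- classify_ctg(simulate_record(sim_params(140, 10, 0,
    duration_s = 1800, seed = 15,
    event_requests = list(list(kind = "sinusoidal", cycles_per_min = 3.5,
                               duration_s = 1500, onset_s = 60)))))
  expect_equal(sin3$class, "III")
  expect_true("sinusoidal-pattern" %in% sin3$reasons)
})

test_that("classification is invariant under appended all-gap padding", {
  rec <- simulate_record(sim_params(142, 10, 3, duration_s = 1800,
                                    seed = 16))
  cls <- classify_ctg(rec)$class
  n_pad <- 240
  padded <- ctg_record(
    fhr = c(rec$signals$fhr, rep(140, n_pad)),
    uc = c(rec$signals$uc, rep(10, n_pad)),
    fhr_valid = c(rec$signals$fhr_valid, rep(FALSE, n_pad)),
    uc_valid = c(rec$signals$uc_valid, rep(FALSE, n_pad)),
    events = rec$events
  )
  padded$sim_params <- rec$sim_params
  expect_equal(classify_ctg(padded)$class, cls)
})

test_that("binary mapping follows the configured policy", {
  expect_equal(to_binary("I"), "normal")
  expect_equal(to_binary("II"), "abnormal")
  expect_equal(to_binary("III"), "abnormal")
  expect_equal(to_binary("II", policy = "ii_normal"), "normal")
})

test_that("injected events are recovered on seeded mixed fixtures", {
  recs <- lapply(1:20, simulate_event_fixture)
  rv <- event_recovery(recs)
  expect_gte(rv$rate, 0.95)
})
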