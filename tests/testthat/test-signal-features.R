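test_that("blink interpolation fills short gaps and leaves long gaps invalid", {
  # single invalid sample between equal neighbours
  r <- flat_recording(c(5, 5, 0, 5))
  out <- interpolate_invalid(r)
  expect_equal(out$value, c(5, 5, 5, 5))
  expect_true(all(out$valid))
  expect_equal(out$n_interpolated, 1L)

  # a 300 ms run at 150 Hz (45 samples) exceeds the 150 ms limit
  v <- rep(5, 200)
  v[100:144] <- 0
  out <- interpolate_invalid(flat_recording(v))
  expect_equal(out$n_interpolated, 0L)
  expect_equal(out$n_still_invalid, 45L)
  expect_false(any(out$valid[100:144]))
  # a 150 ms run (22 samples) is interpolated
  v2 <- rep(5, 200)
  v2[100:121] <- 0
  out2 <- interpolate_invalid(flat_recording(v2))
  expect_equal(out2$n_interpolated, 22L)
  expect_true(all(out2$valid))

  # identity on a fully valid series; valid samples never altered
  r3 <- flat_recording(5 + sin(seq(0, 4, length.out = 300)))
  out3 <- interpolate_invalid(r3)
  expect_identical(out3$value, r3$value)
  expect_equal(length(out$value), length(v))

  expect_error(interpolate_invalid(flat_recording(rep(0, 10))), "empty signal")
})

test_that("interpolation preserves valid samples under random blink patterns", {
  p <- generator_params(n_participants = 2, n_stimuli = 4, seed = 5)
  tab <- generate_trial_table(params = p)
  sigs <- generate_raw_signals(tab, blink_rate = 0.2, seed = 9)
  for (rec in sigs$pupil) {
    out <- interpolate_invalid(rec)
    expect_equal(length(out$value), length(rec$value))
    ok <- rec$valid & rec$value >= 2 & rec$value <= 10
    expect_identical(out$value[ok], rec$value[ok])
  }
  # blink rate 0 leaves no invalid samples
  sigs0 <- generate_raw_signals(tab, blink_rate = 0, seed = 9)
  expect_true(all(vapply(sigs0$pupil, function(r) all(r$valid), logical(1))))
})

test_that("baseline correction is subtractive and translation-invariant", {
  # constant series: corrected series identically zero
  r <- flat_recording(rep(5, 1200))
  bc <- baseline_correct_pupil(r, onset = 0)
  expect_equal(bc$feature, 0)
  expect_true(all(bc$corrected$value == 0))

  # baseline mean 4.2, stimulus-window mean 4.5 -> feature 0.3
  tt <- -1.5 + (0:1199) / 150
  v <- ifelse(tt <= 0, 4.2, ifelse(tt <= 1, 4.35, 4.5))
  # baseline window (-1, 1): mean of 4.2 (first half) and 4.35 (second half)
  r2 <- flat_recording(v)
  bc2 <- baseline_correct_pupil(r2, onset = 0)
  manual_base <- mean(v[tt >= -1 - 1/300 & tt <= 1 + 1/300])
  manual_stim <- mean(v[tt >= -1/300 & tt <= 6 + 1/300])
  expect_equal(bc2$feature, manual_stim - manual_base, tolerance = 1e-12)

  # translation invariance
  r3 <- flat_recording(r2$value + 2.34)
  bc3 <- baseline_correct_pupil(r3, onset = 0)
  expect_equal(bc3$feature, bc2$feature, tolerance = 1e-12)
  expect_equal(bc3$corrected$value, bc2$corrected$value, tolerance = 1e-12)

  # no valid baseline -> missing, never zero-filled
  r4 <- flat_recording(rep(5, 1200),
                       valid = c(rep(FALSE, 400), rep(TRUE, 800)))
  bc4 <- baseline_correct_pupil(r4, onset = 0)
  expect_true(is.na(bc4$feature))
  expect_equal(bc4$flag, "no_baseline")
})

test_that("trough-to-peak scoring matches a brute-force pair oracle", {
  fs <- 10
  tt <- seq(-2, 7.5, by = 1 / fs)

  # monotone decreasing series scores zero
  r <- flat_recording(5 - 0.1 * seq_along(tt), fs = fs, t0 = -2, modality = "scr")
  expect_equal(score_scr_trough_to_peak(r, onset = 0), 0)

  # two overlapping waves: the larger rise wins
  wave <- function(t, on, amp) {
    w <- ifelse(t > on, exp(-(t - on) / 2) - exp(-(t - on) / 0.75), 0)
    amp * w / max(w)
  }
  v <- 2 + wave(tt, 1.2, 0.2) + wave(tt, 3.2, 0.6)
  r2 <- flat_recording(v, fs = fs, t0 = -2, modality = "scr")
  amp <- score_scr_trough_to_peak(r2, onset = 0)
  # independent oracle: max over all trough/peak index pairs in the window
  win <- which(tt >= 1 - 0.05 & tt <= 6 + 0.05)
  brute <- 0
  for (i in win) for (j in win) if (j > i) brute <- max(brute, v[j] - v[i])
  expect_equal(amp, brute, tolerance = 1e-12)
  expect_gte(amp, 0.6 - 0.05)

  # tonic-shift invariance and gain linearity
  r3 <- flat_recording(v + 3, fs = fs, t0 = -2, modality = "scr")
  expect_equal(score_scr_trough_to_peak(r3, onset = 0), amp, tolerance = 1e-12)
  r4 <- flat_recording(2 + 2 * (v - 2), fs = fs, t0 = -2, modality = "scr")
  expect_equal(score_scr_trough_to_peak(r4, onset = 0), 2 * amp,
               tolerance = 1e-12)

  # sub-threshold rise scores zero; out-of-window onset is a missing flag
  r5 <- flat_recording(2 + wave(tt, 1.2, 0.005), fs = fs, t0 = -2,
                       modality = "scr")
  expect_equal(score_scr_trough_to_peak(r5, onset = 0), 0)
  expect_true(is.na(score_scr_trough_to_peak(r2, onset = 100)))
})

test_that("heart-rate change score is post minus pre", {
  expect_equal(hr_difference_score(70, 68), -2)
  expect_equal(hr_difference_score(70, 70), 0)
  pre <- c(60, 70, 80)
  post <- c(66, 63, 80)
  expect_equal(hr_difference_score(pre, post), post - pre)
})

test_that("zero-noise raw-signal round trip recovers the planted features", {
  p <- generator_params(n_participants = 3, n_stimuli = 6, seed = 11)
  tab <- generate_trial_table(params = p)
  sigs <- generate_raw_signals(tab, seed = 12)
  feats <- extract_trial_features(sigs)
  m <- merge(tab, feats, by = c("participant_id", "stimulus_id"),
             suffixes = c("", "_hat"))
  expect_equal(nrow(m), nrow(tab))
  big <- abs(m$pupil) > 0.01
  expect_lt(max(abs(m$pupil_hat - m$pupil)[big] / abs(m$pupil)[big]), 0.05)
  expect_lt(max(abs(m$scr_hat - m$scr) / pmax(m$scr, 1e-6)), 0.05)
  expect_lt(max(abs(m$hr_hat - m$hr)), 1e-8)

  # a trial with zero SCR amplitude produces a flat phasic score
  tab0 <- tab
  tab0$scr[1] <- 0
  s0 <- generate_raw_signals(tab0, seed = 12)
  f0 <- extract_trial_features(s0)
  expect_equal(f0$scr[f0$trial_id == "P01_S01"], 0)
})

test_that("per-cell missingness and manifest mismatches are explicit", {
  p <- generator_params(n_participants = 2, n_stimuli = 4, seed = 21)
  tab <- generate_trial_table(params = p)
  sigs <- generate_raw_signals(tab, seed = 22)
  # knock out the baseline window of one pupil trial
  rec <- sigs$pupil[["P01"]]
  onset <- rec$events$onset_s[2]
  kill <- rec$time_s >= onset - 1.2 & rec$time_s <= onset + 1.2
  rec$value[kill] <- 0
  sigs$pupil[["P01"]] <- rec
  feats <- extract_trial_features(sigs)
  bad <- feats$trial_id == rec$events$trial_id[2]
  expect_true(is.na(feats$pupil[bad]))
  expect_equal(feats$pupil_flag[bad], "no_baseline")
  expect_true(all(!is.na(feats$pupil[!bad])))
  expect_true(all(!is.na(feats$scr)))
  expect_equal(attr(feats, "quality")$n_missing[["pupil"]], 1L)

  sigs$hr <- sigs$hr[-1, ]
  expect_error(extract_trial_features(sigs), "unmatched trial id")
})

test_that("invalid recording construction is rejected", {
  expect_error(signal_recording("pupil", 0, 1:3, 1:3), "sampling_rate")
  expect_error(signal_recording("pupil", 10, c(1, 1, 2), 1:3),
               "strictly increasing")
  expect_error(generate_raw_signals(data.frame(participant_id = "P1"),
                                    sampling_rates = c(pupil = -1, scr = 10)),
               "invalid parameter")
})
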