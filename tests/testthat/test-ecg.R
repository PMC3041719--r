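test_that("cycle length and anchored intervals are reproduced", {
  expect_equal(ecg_timing(70)$rr, 60 / 70)
  # default coefficients are anchored at a 1-second cycle
  t60 <- ecg_timing(60)
  expect_equal(t60$qt, 0.40, tolerance = 1e-12)
  expect_equal(t60$pr, 0.16, tolerance = 1e-12)
  expect_equal(t60$qrs, 0.09, tolerance = 1e-12)
  expect_equal(t60$p_dur, 0.09, tolerance = 1e-12)
  expect_equal(t60$dhf, 1 - (0.02 + 0.40) / 1.0, tolerance = 1e-12)
})

test_that("interval invariants hold at every supported heart rate", {
  for (hr in 40:160) {
    tm <- ecg_timing(hr)
    expect_true(tm$p_dur > 0 && tm$p_dur < tm$pr)
    expect_true(tm$pr < tm$rr)
    expect_true(tm$qrs > 0 && tm$qrs < tm$qt && tm$qt < tm$rr)
    expect_true(tm$dhf > 0 && tm$dhf < 1)
    expect_true(tm$pr + tm$qt < tm$rr)
  }
})

test_that("diastolic fraction shrinks strictly with heart rate", {
  dhf <- vapply(40:160, function(hr) ecg_timing(hr)$dhf, 0)
  expect_true(all(diff(dhf) < 0))
  expect_gt(ecg_timing(40)$dhf, ecg_timing(160)$dhf)
})

test_that("out-of-range rate and degenerate coefficient tables are rejected", {
  expect_error(ecg_timing(161), class = "cardiolab_validation_error")
  expect_error(ecg_timing(39), class = "cardiolab_validation_error")
  bad <- default_ecg_coefficients()
  bad$qt <- c(0.9, 0, 0)  # longer than the cycle at high rates
  expect_error(validate_ecg_coefficients(bad), class = "cardiolab_config_error")
})

test_that("waveform fragments sit on their intervals over exact zero baseline", {
  tm <- ecg_timing(70)
  cyc <- synthesize_ecg_cycle(tm, resolution = 0.001)
  expect_true(all(is.finite(cyc$ecg_au)))
  # TP segment (after T end, before next P) is exactly zero
  tp <- cyc$ecg_au[cyc$time_s > tm$pr + tm$qt & cyc$time_s < tm$rr]
  expect_true(all(tp == 0))
  # PR segment between P end and QRS onset is exactly zero
  prseg <- cyc$ecg_au[cyc$time_s > tm$p_dur & cyc$time_s < tm$pr]
  expect_true(all(prseg == 0))
  # P and QRS energy inside their supports
  expect_gt(max(cyc$ecg_au[cyc$time_s < tm$p_dur]), 0)
  qrs <- cyc$ecg_au[cyc$time_s >= tm$pr & cyc$time_s < tm$pr + tm$qrs]
  expect_gt(max(qrs), 0.9)   # dominant R peak
  expect_lt(min(qrs), 0)     # triphasic: negative lobes present
  expect_error(synthesize_ecg_cycle(tm, resolution = 0.002),
               class = "cardiolab_validation_error")
})

test_that("QRS integral scales with its duration under rate change", {
  res <- 1e-4
  int_per_width <- vapply(c(60, 150), function(hr) {
    tm <- ecg_timing(hr)
    cyc <- synthesize_ecg_cycle(tm, resolution = res)
    sel <- cyc$time_s >= tm$pr & cyc$time_s < tm$pr + tm$qrs
    sum(cyc$ecg_au[sel]) * res / tm$qrs
  }, 0)
  expect_equal(int_per_width[1], int_per_width[2], tolerance = 1e-2)
})

test_that("concatenated cycles are periodic", {
  tm <- ecg_timing(60)  # 1000 samples per cycle exactly
  one <- synthesize_ecg_cycle(tm, resolution = 0.001)
  two <- c(one$ecg_au, one$ecg_au)
  n <- nrow(one)
  expect_identical(two[seq_len(n)], two[n + seq_len(n)])
})

test_that("trigger schedule mirrors electrical timing", {
  tm <- ecg_timing(60)
  sch <- trigger_schedule(tm, delay = 0)
  expect_equal(sch$ventricular_onset, 0.16, tolerance = 1e-12)
  expect_equal(sch$atrial_onset, 0)
  sch <- trigger_schedule(tm, delay = 0.02)
  expect_lt(sch$atrial_onset, sch$ventricular_onset)
  expect_equal(sch$ventricular_onset - sch$atrial_onset, tm$pr)
  # systolic duration shortens with rate
  s60 <- trigger_schedule(ecg_timing(60))$systolic_duration_ventricular
  s160 <- trigger_schedule(ecg_timing(160))$systolic_duration_ventricular
  expect_lt(s160, s60)
  # systole spilling past the cycle end is caught
  expect_error(trigger_schedule(ecg_timing(160), delay = 0.2),
               class = "cardiolab_timing_error")
  expect_error(trigger_schedule(tm, delay = -0.1),
               class = "cardiolab_validation_error")
})
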