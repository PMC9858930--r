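# Beat segmentation, APD, Ca-transient statistics, alternans / EAD
# detection, spark statistics and Welch's t-test, validated against
# constructed fixtures with known ground truth.

test_that("segment_beats windows every stimulus and flags missing upstrokes", {
  tr <- generate_synthetic_trace(n_beats = 10, cycle_length = 1000)
  b <- segment_beats(tr)
  expect_equal(nrow(b), 10)
  expect_equal(b$t_end[-10] - b$t_start[-10], rep(1, 9))
  expect_true(all(b$captured))
  tr2 <- generate_synthetic_trace(n_beats = 6, skipped_beats = 4)
  b2 <- segment_beats(tr2)
  expect_identical(which(!b2$captured), 4L)
})

test_that("APD90 of a trapezoidal action potential matches the closed form", {
  # instant rise to +40 at t = 1 ms, plateau 200 ms, linear fall to -85
  # over 100 ms: APD90 = 200 + (40 - (-72.5)) / 125 * 100 = 290 ms
  tt <- 0:400
  v <- rep(-85, length(tt))
  v[tt >= 1 & tt <= 201] <- 40
  fall <- tt > 201 & tt <= 301
  v[fall] <- 40 - 1.25 * (tt[fall] - 201)
  expect_equal(apd(v, tt, time_unit = "ms"), 290, tolerance = 1e-9)
  # half-repolarisation level: 200 + (40 - (-22.5))/125*100 = 250
  expect_equal(apd(v, tt, level = 0.5, time_unit = "ms"), 250,
               tolerance = 1e-9)
  # degenerate constant-voltage "beat" -> undefined-metric marker
  expect_true(is.na(apd(rep(-85, 100), 1:100, time_unit = "ms")))
})

test_that("APD is invariant to time shifts and common voltage offsets", {
  tr <- generate_synthetic_trace(n_beats = 1, apd = 163)
  sel <- tr$data$time < 1
  v <- tr$data$v[sel]
  tt <- tr$data$time[sel]
  a0 <- apd(v, tt)
  expect_equal(apd(v, tt + 17.3), a0, tolerance = 1e-9)
  expect_equal(apd(v + 12, tt, v_diastolic = v[1] + 12), a0,
               tolerance = 1e-9)
  expect_equal(a0, 163, tolerance = 1.5)  # generator places APD90 by design
})

test_that("transient statistics recover constructed maxima and diastole", {
  expect_equal(transient_stats(rep(0.2, 50)),
               list(ca_max = 0.2, ca_diastolic = 0.2))
  # raised cosine of known peak
  tt <- seq(0, 500, by = 1)
  ca <- 0.1 + 0.55 * 0.5 * (1 - cos(2 * pi * pmin(tt, 400) / 400))
  st <- transient_stats(ca, tt, stim_time = 0)
  expect_equal(st$ca_max, 0.65, tolerance = 1e-6)
  # diastolic value is the sample immediately preceding the stimulus
  st2 <- transient_stats(ca, tt, stim_time = 10.5)
  expect_equal(st2$ca_diastolic, ca[11])
})

test_that("EAD detector: monotone repolarisation clean, one bump one event", {
  tr0 <- generate_synthetic_trace(n_beats = 3)
  sel <- tr0$data$time < 1
  expect_equal(nrow(detect_eads(tr0$data$v[sel], tr0$data$time[sel])), 0)
  tr1 <- generate_synthetic_trace(n_beats = 3, ead_beats = 2, ead_rise = 5)
  sel2 <- tr1$data$time >= 1 & tr1$data$time < 2
  e <- detect_eads(tr1$data$v[sel2], tr1$data$time[sel2])
  expect_equal(nrow(e), 1)
  expect_gte(e$rise, 2)
  expect_gte(e$duration, 5)
})

test_that("alternans detector follows the printed alternating-beat series", {
  expect_false(detect_alternans(rep(150, 8))$detected)
  expect_false(detect_alternans(seq(100, 170, by = 10))$detected)  # ramp
  # alternating AP durations of the rapid-pacing analysis: mean |delta|
  # over the five consecutive alternating differences is 23.2 ms
  dur <- c(157, 131, 156, 132, 156, 139)
  rep_alt <- detect_alternans(dur, metric = "apd90")
  expect_true(rep_alt$detected)
  expect_equal(rep_alt$magnitude, mean(abs(diff(dur))))
  expect_equal(rep_alt$magnitude, 23.2, tolerance = 1e-9)
  expect_identical(rep_alt$window, c(1, 6))
})

test_that("spark statistics rescale linearly to the full-scale CRU count", {
  empty <- data.frame(cru = integer(), t_start = numeric(),
                      t_end = numeric(), peak_open = numeric())
  s0 <- spark_statistics(empty, NULL, n_cru = 2000, span = 10)
  expect_equal(s0$n_events, 0)
  expect_equal(s0$rate_full_scale, 0)
  # 100 events in 10 s simulated with 2000 of 20000 CRUs -> 100 per s
  ev <- data.frame(cru = rep(1:10, 10), t_start = seq(0.05, 9.95, length.out = 100),
                   t_end = seq(0.06, 9.96, length.out = 100),
                   peak_open = 5)
  beats <- data.frame(beat = 1:10, t_start = 0:9, t_end = 1:10,
                      stim_time = 0:9)
  s1 <- spark_statistics(ev, beats, n_cru = 2000, full_scale_n = 20000)
  expect_equal(s1$rate_per_s, 10)
  expect_equal(s1$rate_full_scale, 100)
  expect_equal(sum(s1$per_beat), 100)
})

test_that("Welch t-test matches the hand formula and the reference implementation", {
  r0 <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  r <- welch_ttest(a, b)
  expect_equal(r$t, -1 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(r$df, 6, tolerance = 1e-12)
  ref <- stats::t.test(a, b)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # random-sample agreement with the reference to 1e-10 relative
  set.seed(4)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    mine <- welch_ttest(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(welch_ttest(c(1, 1), c(2, 2)), "unequal means")
})

test_that("synthetic generator ground truth drives every detector correctly", {
  # no anomalies: all detectors silent
  tr <- generate_synthetic_trace(n_beats = 8)
  an <- analyze_trace(tr, skip_first = 0)
  expect_false(an$alternans_apd$detected)
  expect_length(an$ead_beats, 0)
  expect_length(an$skipped_beats, 0)
  # implanted APD alternans of 20 ms on a 150 ms APD
  tr_a <- generate_synthetic_trace(n_beats = 10, apd = 150,
                                   alternans_delta = 20)
  bm <- beat_metrics(tr_a)
  alt <- detect_alternans(bm$apd90, metric = "apd90")
  expect_true(alt$detected)
  expect_equal(alt$magnitude, 20, tolerance = 1)
  # implanted skipped beats are exactly the uncaptured ones
  tr_s <- generate_synthetic_trace(n_beats = 8, skipped_beats = c(3, 5))
  expect_identical(analyze_trace(tr_s)$skipped_beats, c(3L, 5L))
  # EAD in a skipped beat is contradictory
  expect_error(generate_synthetic_trace(n_beats = 5, ead_beats = 3,
                                        skipped_beats = 3),
               "cannot carry an EAD")
})
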