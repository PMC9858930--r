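# Pacing protocols, the stochastic engine front end, spark-event
# extraction and trace input/output.

test_that("protocols assemble segments and stimulus trains correctly", {
  srs <- build_protocol("srs", 1, 5, durations = c(10, 10, 10))
  expect_equal(nrow(srs$segments), 3)
  expect_equal(sum(srs$segments$duration), 30)
  expect_equal(srs$segments$frequency, c(1, 5, 1))
  expect_length(stimulus_times(srs), 10 + 50 + 10)
  const6 <- build_protocol("constant", f_slow = 6, durations = 30)
  expect_equal(nrow(const6$segments), 1)
  expect_length(stimulus_times(const6), 180)
  expect_error(build_protocol("constant", 1, durations = 0), "positive")
  expect_error(build_protocol("constant", 8,
                              stimulus = list(amplitude = -60, width = 200)),
               "cycle length")
})

test_that("stimulus bookkeeping: floor(duration x frequency) per segment", {
  set.seed(10)
  for (i in 1:20) {
    f1 <- runif(1, 0.5, 7)
    f2 <- runif(1, 0.5, 7)
    d <- runif(3, 0.7, 12)
    proto <- build_protocol("srs", f1, f2, durations = d)
    expect_length(stimulus_times(proto),
                  floor(d[1] * f1) + floor(d[2] * f2) + floor(d[3] * f1))
    st <- stimulus_times(proto)
    expect_true(all(diff(st) > 0))
    expect_true(all(st < sum(d)))
  }
})

test_that("identical seed and configuration reproduce the identical trace", {
  p <- default_parameters(50)
  proto <- build_protocol("constant", 2, durations = 1)
  cfg <- simulation_config(seed = 17, protocol = proto, n_cru = 50)
  t1 <- run_protocol(p, cfg)
  t2 <- run_protocol(p, cfg)
  expect_identical(t1$data, t2$data)
  expect_identical(t1$sparks, t2$sparks)
  t3 <- run_protocol(p, simulation_config(seed = 18, protocol = proto,
                                          n_cru = 50))
  expect_false(identical(t3$data$ca_myo, t1$data$ca_myo))
})

test_that("scenario plumbing applies once and refuses stacking", {
  p <- default_parameters(20)
  proto <- build_protocol("constant", 1, durations = 0.2)
  cfg <- simulation_config(seed = 1, protocol = proto, n_cru = 20,
                          scenario = "mutant_control")
  tr <- run_protocol(p, cfg)
  expect_identical(tr$scenario, "mutant_control")
  pre <- apply_scenario(p, "wt_bar")
  expect_error(run_protocol(pre, cfg), "refusing to stack")
  expect_error(run_protocol(p, simulation_config(scenario = "bogus",
                                                 protocol = proto,
                                                 n_cru = 20)),
               "unknown scenario")
})

test_that("spark event extraction: thresholds, merging, engine agreement", {
  # constructed counts: two supra-threshold episodes separated by > gap
  time <- seq(0, 100, by = 1)
  x <- integer(length(time))
  x[11:15] <- 4L
  x[41:44] <- 3L
  ev <- detect_spark_events(x, time, threshold = 2, gap = 5)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$peak_open, c(4, 3))
  # episodes separated by < gap merge into one
  y <- integer(length(time))
  y[11:14] <- 5L
  y[17:20] <- 3L
  ev2 <- detect_spark_events(y, time, threshold = 2, gap = 5)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$peak_open, 5)
  # all-zero counts -> no events
  expect_equal(nrow(detect_spark_events(integer(101), time)), 0)
  # sub-threshold counts are ignored
  expect_equal(nrow(detect_spark_events(rep(1L, 101), time, threshold = 2)), 0)

  # the engine's online detector agrees with the reference implementation
  # when the trace is recorded at the CRU substep resolution
  p <- default_parameters(40)
  cfg <- simulation_config(seed = 5, protocol = build_protocol("constant", 2,
                                                               durations = 1),
                           n_cru = 40, record_every = 0.06, record_cru = TRUE)
  tr <- run_protocol(p, cfg, spark_threshold = 2, spark_gap = 5)
  ref <- detect_spark_events(tr$cru_open, tr$data$time * 1e3,
                             threshold = 2, gap = 5)
  expect_equal(nrow(ref), nrow(tr$sparks))
  if (nrow(ref) > 0) {
    o1 <- ref[order(ref$cru, ref$t_start), ]
    o2 <- tr$sparks[order(tr$sparks$cru, tr$sparks$t_start), ]
    expect_equal(o1$cru, o2$cru)
    expect_equal(o1$t_start, o2$t_start * 1e3, tolerance = 1e-6)
    expect_equal(o1$peak_open, o2$peak_open)
  }
})

test_that("stimulus calibration brackets the capture threshold", {
  p <- default_parameters(100)
  amp <- calibrate_stimulus(p, n_cru = 100, lo = 5, hi = 150, tol = 10)
  thr <- attr(amp, "threshold")
  amp <- as.numeric(amp)
  expect_lt(amp, 0)
  expect_lt(thr, 0)
  expect_equal(amp, 1.5 * thr)
  # the recommended amplitude captures; a small fraction of it does not
  proto_ok <- build_protocol("constant", 2, durations = 0.5,
                             stimulus = list(amplitude = amp, width = 1))
  tr_ok <- run_protocol(p, simulation_config(seed = 2, protocol = proto_ok,
                                             n_cru = 100))
  expect_true(any(tr_ok$data$v > 0))
  proto_no <- build_protocol("constant", 2, durations = 0.5,
                             stimulus = list(amplitude = 0.2 * thr, width = 1))
  tr_no <- run_protocol(p, simulation_config(seed = 2, protocol = proto_no,
                                             n_cru = 100))
  expect_false(any(tr_no$data$v > 0))
})

test_that("trace CSV round trip preserves samples, sparks and metadata", {
  p <- default_parameters(30)
  cfg <- simulation_config(seed = 9, protocol = build_protocol("constant", 2,
                                                               durations = 1),
                          n_cru = 30)
  tr <- run_protocol(p, cfg)
  path <- file.path(withr::local_tempdir(), "trace.csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$data$v, tr$data$v, tolerance = 1e-9)
  expect_equal(back$data$ca_myo, tr$data$ca_myo, tolerance = 1e-9)
  expect_equal(nrow(back$sparks), nrow(tr$sparks))
  expect_equal(back$stim_times, tr$stim_times)
  expect_identical(back$scenario, "wt_control")
  expect_equal(back$n_cru, 30)
  # analysis runs identically on the round-tripped trace
  expect_equal(beat_metrics(back)$apd90, beat_metrics(tr)$apd90,
               tolerance = 1e-6)
})

test_that("halving dt leaves beat-averaged Ca maxima within 1%", {
  p <- default_parameters()
  proto <- build_protocol("constant", 1, durations = 3)
  peak_mean <- function(dt) {
    vals <- c()
    for (seed in 1:3) {
      cfg <- simulation_config(dt = dt, seed = seed, protocol = proto,
                               n_cru = 800)
      bm <- beat_metrics(run_protocol(p, cfg, spark_threshold = 3))
      vals <- c(vals, bm$ca_max[2:3])
    }
    mean(vals)
  }
  a <- peak_mean(0.02)
  b <- peak_mean(0.01)
  expect_lt(abs(a - b) / b, 0.01)
})

test_that("spark production scales with the number of release units", {
  p <- default_parameters()
  proto <- build_protocol("constant", 1, durations = 3)
  n_small <- 150
  n_big <- 600
  r_small <- run_protocol(p, simulation_config(seed = 21, protocol = proto,
                                               n_cru = n_small),
                          spark_threshold = 3)
  r_big <- run_protocol(p, simulation_config(seed = 22, protocol = proto,
                                             n_cru = n_big),
                        spark_threshold = 3)
  per_small <- nrow(r_small$sparks) / n_small
  per_big <- nrow(r_big$sparks) / n_big
  # equal per-CRU intensity within sampling error (sqrt-N band, ~3 sigma)
  expect_lt(abs(per_small - per_big) / per_big,
            3 * sqrt(1 / nrow(r_small$sparks) + 1 / nrow(r_big$sparks)) + 0.05)
})
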