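# Beat segmentation and arrhythmia analytics: APD, Ca-transient
# statistics, spark statistics, alternans / EAD / skipped-beat detection,
# Welch's t-test, and the synthetic-trace generator used to validate every
# detector against known ground truth.

#' Segment a trace into beats
#'
#' One window per stimulus, `[stim, next stim)`; the last window extends
#' to the end of the trace.  A beat counts as captured when the membrane
#' potential crosses 0 mV within `capture_window` ms of its stimulus
#' (upstroke detection); a delivered stimulus without an upstroke is a
#' skipped beat.
#'
#' @param trace a `simulation_trace` (needs `data$time`, `data$v`,
#'   `stim_times`).
#' @param capture_window ms after the stimulus within which the upstroke
#'   must occur.
#' @return data.frame with `beat`, `stim_time` (s), `t_start`, `t_end`
#'   (s) and `captured`.
#' @export
segment_beats <- function(trace, capture_window = 50) {
  st <- trace$stim_times
  if (!length(st)) stop("segment_beats: trace has no stimulus times")
  tt <- trace$data$time
  vv <- trace$data$v
  if (!length(tt)) stop("segment_beats: empty trace")
  t_end <- c(st[-1], max(tt) + 1e-9)
  captured <- vapply(seq_along(st), function(i) {
    sel <- tt >= st[i] & tt <= min(st[i] + capture_window / 1e3, t_end[i])
    any(vv[sel] > 0)
  }, logical(1))
  data.frame(beat = seq_along(st), stim_time = st, t_start = st,
             t_end = t_end, captured = captured)
}

#' Action potential duration
#'
#' Time from the maximum upstroke velocity (max dV/dt) to the voltage
#' crossing `V_peak - level * (V_peak - V_diastolic)`, linearly
#' interpolated between samples.  The default `level = 0.9` is APD90.
#'
#' @param v voltage samples of one beat window (mV).
#' @param time sample times (s or ms; the result is in the same unit
#'   scaled to ms if `time` is in seconds and `time_unit = "s"`).
#' @param level repolarisation fraction (0.9 = APD90).
#' @param v_diastolic diastolic reference voltage; default, the first
#'   sample of the window.
#' @param time_unit `"s"` (trace convention) or `"ms"`.
#' @return APD in ms, or `NA_real_` if the beat is degenerate (no
#'   upstroke, or repolarisation never reaches the threshold).
#' @export
apd <- function(v, time, level = 0.9, v_diastolic = NULL,
                time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  stopifnot(length(v) == length(time), length(v) >= 3)
  if (time_unit == "s") time <- time * 1e3
  if (is.null(v_diastolic)) v_diastolic <- v[1]
  v_peak <- max(v)
  if (v_peak - v_diastolic < 1) return(NA_real_)  # no depolarisation
  dv <- diff(v) / diff(time)
  i_up <- which.max(dv)
  t_up <- time[i_up + 1]
  i_peak <- which.max(v)
  v_thr <- v_peak - level * (v_peak - v_diastolic)
  below <- which(v <= v_thr & seq_along(v) > i_peak)
  if (!length(below)) return(NA_real_)
  i2 <- below[1]
  i1 <- i2 - 1
  t_cross <- if (v[i1] == v[i2]) time[i2] else
    time[i1] + (v[i1] - v_thr) / (v[i1] - v[i2]) * (time[i2] - time[i1])
  t_cross - t_up
}

#' Calcium transient statistics of one beat
#'
#' `ca_max` is the window maximum; `ca_diastolic` is the value at the
#' sample immediately preceding the stimulus (measured just prior to the
#' beat), falling back to the first window sample when no stimulus time is
#' supplied.
#'
#' @param ca myoplasmic Ca2+ samples (uM).
#' @param time sample times (only needed with `stim_time`).
#' @param stim_time stimulus time of this beat (same unit as `time`).
#' @return list with `ca_max` and `ca_diastolic` (uM).
#' @export
transient_stats <- function(ca, time = NULL, stim_time = NULL) {
  stopifnot(length(ca) >= 1)
  dia <- if (!is.null(stim_time) && !is.null(time)) {
    before <- which(time < stim_time)
    if (length(before)) ca[max(before)] else ca[1]
  } else ca[1]
  list(ca_max = max(ca), ca_diastolic = dia)
}

#' Detect early afterdepolarisations in one beat
#'
#' An EAD is a net depolarisation during repolarisation: after the
#' plateau apex and before the voltage first returns within 10 mV of its
#' diastolic value, any maximal interval with sustained `dV/dt > 0`
#' lasting at least `min_duration` ms and rising at least `min_rise` mV is
#' reported.  The apex is the maximum of a heavily smoothed (~25 ms) copy
#' of the trace, so that neither the narrow Na+ spike nor the normal
#' spike-notch-dome rebound of a guinea-pig action potential counts as an
#' event.  Voltage is also lightly smoothed
#' (3-sample running mean) so that single-sample channel noise does not
#' split an event.
#'
#' @param v voltage samples of one captured beat (mV).
#' @param time sample times (s).
#' @param min_rise minimal net depolarisation (mV).
#' @param min_duration minimal duration of the rising interval (ms).
#' @param v_diastolic diastolic reference; default the first sample.
#' @param apex_blank ms after the upstroke excluded from the search, so
#'   that the phase-1 notch-to-dome rebound is never counted.
#' @return data.frame with `onset` (s), `rise` (mV), `duration` (ms); zero
#'   rows when the beat repolarises monotonically.
#' @export
detect_eads <- function(v, time, min_rise = 2, min_duration = 5,
                        v_diastolic = NULL, apex_blank = 60) {
  stopifnot(length(v) == length(time))
  empty <- data.frame(onset = numeric(), rise = numeric(),
                      duration = numeric())
  if (length(v) < 5) return(empty)
  if (is.null(v_diastolic)) v_diastolic <- v[1]
  vs <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  vs[1] <- v[1]
  vs[length(v)] <- v[length(v)]
  vs <- as.numeric(vs)
  # plateau apex: first prominent local max of a ~25 ms smoothed trace
  dt_med <- stats::median(diff(time))
  w <- max(3L, as.integer(round(0.025 / dt_med)))
  if (w %% 2 == 0) w <- w + 1L
  vh <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  vh[is.na(vh)] <- -Inf  # edges cannot host the apex
  i_up <- which.max(diff(v))
  i_blank <- i_up + as.integer(ceiling(apex_blank / 1e3 / dt_med))
  i_peak <- max(which.max(vh), min(i_blank, length(v) - 3L))
  back <- which(vs <= v_diastolic + 10 & seq_along(vs) > i_peak)
  i_end <- if (length(back)) back[1] else length(vs)
  if (i_end - i_peak < 3) return(empty)
  seg <- vs[i_peak:i_end]
  tseg <- time[i_peak:i_end]
  up <- diff(seg) > 0
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- empty
  for (k in which(r$values)) {
    i1 <- starts[k]
    i2 <- ends[k] + 1
    dur_ms <- (tseg[i2] - tseg[i1]) * 1e3
    rise <- seg[i2] - seg[i1]
    if (dur_ms >= min_duration && rise >= min_rise) {
      out <- rbind(out, data.frame(onset = tseg[i1], rise = rise,
                                   duration = dur_ms))
    }
  }
  out
}

#' Detect alternans in a beat-metric sequence
#'
#' Alternans is flagged when consecutive beat-to-beat differences
#' alternate in sign over a window of at least `min_beats` beats and the
#' mean absolute difference exceeds `rel_threshold` of the window mean.
#' The reported magnitude is the mean absolute difference over the longest
#' alternating window.
#'
#' @param x numeric metric per beat (e.g. APD, Ca-transient amplitude).
#' @param rel_threshold minimal relative alternation magnitude.
#' @param min_beats minimal number of beats in the alternating window.
#' @param metric name recorded in the report.
#' @return list (`alternans_report`): `detected`, `magnitude`,
#'   `relative`, `window` (beat index range), `metric`.
#' @export
detect_alternans <- function(x, rel_threshold = 0.05, min_beats = 4,
                             metric = "metric") {
  if (length(x) < min_beats) {
    stop("detect_alternans: need at least min_beats = ", min_beats,
         " values")
  }
  d <- diff(x)
  alt <- sign(d[-1]) * sign(d[-length(d)]) < 0 & d[-1] != 0
  # longest run of TRUE in alt -> window of consecutive alternating diffs
  best_len <- 0
  best_end <- 0
  if (length(alt)) {
    r <- rle(alt)
    ends <- cumsum(r$lengths)
    for (k in which(r$values)) {
      if (r$lengths[k] > best_len) {
        best_len <- r$lengths[k]
        best_end <- ends[k]
      }
    }
  }
  # alt[i] refers to diffs i and i+1, i.e. beats i..i+2
  n_diffs <- if (best_len > 0) best_len + 1 else
    as.numeric(length(d) >= 1 && all(d[1] != 0))
  window <- if (best_len > 0) c(best_end - best_len + 1, best_end + 2) else
    c(NA_integer_, NA_integer_)
  if (best_len > 0) {
    idx <- window[1]:(window[2] - 1)      # diff indices in the window
    magnitude <- mean(abs(d[idx]))
    relative <- magnitude / mean(x[window[1]:window[2]])
  } else {
    magnitude <- 0
    relative <- 0
  }
  detected <- best_len > 0 && (window[2] - window[1] + 1) >= min_beats &&
    relative > rel_threshold
  structure(list(detected = detected, magnitude = magnitude,
                 relative = relative, window = window, metric = metric),
            class = "alternans_report")
}

#' Spark statistics
#'
#' Aggregates spark events per beat and per second, and rescales the rate
#' to the full-scale CRU count: desk-scale runs simulate `n_cru` of the
#' `full_scale_n` release units, and spark counts scale linearly with the
#' number of units, so the full-scale-equivalent rate is
#' `rate * full_scale_n / n_cru`.
#'
#' @param events spark data.frame (`t_start` in s, optionally
#'   `peak_ca_ds`), e.g. `trace$sparks`.
#' @param beats beat windows from [segment_beats()] (`NULL` = only
#'   per-second statistics over `span`).
#' @param n_cru number of simulated CRUs.
#' @param full_scale_n full-scale CRU count.
#' @param span time span (s) for the per-second rate; default the beat
#'   windows' span, or the event span.
#' @return list with `n_events`, `per_beat` (counts aligned to beats),
#'   `rate_per_s`, `rate_full_scale`, `per_beat_full_scale` (mean),
#'   `amplitude_mean` (uM, `NA` without amplitudes).
#' @export
spark_statistics <- function(events, beats = NULL, n_cru,
                             full_scale_n = 20000, span = NULL) {
  n_ev <- nrow(events)
  if (is.null(span)) {
    span <- if (!is.null(beats)) max(beats$t_end) - min(beats$t_start)
    else if (n_ev > 0) max(events$t_end) - min(events$t_start)
    else NA_real_
  }
  per_beat <- NULL
  if (!is.null(beats)) {
    per_beat <- vapply(seq_len(nrow(beats)), function(i) {
      sum(events$t_start >= beats$t_start[i] &
            events$t_start < beats$t_end[i])
    }, numeric(1))
  }
  rate <- if (is.finite(span) && span > 0) n_ev / span else NA_real_
  list(
    n_events = n_ev,
    per_beat = per_beat,
    rate_per_s = rate,
    rate_full_scale = rate * full_scale_n / n_cru,
    per_beat_full_scale = if (!is.null(per_beat))
      mean(per_beat) * full_scale_n / n_cru else NA_real_,
    amplitude_mean = if (n_ev > 0 && "peak_ca_ds" %in% names(events))
      mean(events$peak_ca_ds) else NA_real_
  )
}

#' Welch's two-sided t-test
#'
#' Two-sample t statistic under unequal variances with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p value.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list (`comparison_result`): `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b`, `t`, `df`, `p`.
#' @examples
#' welch_ttest(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a)
  nb <- length(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(mean_a = mean(a), mean_b = mean(b), sd_a = 0,
                            sd_b = 0, n_a = na, n_b = nb, t = 0,
                            df = na + nb - 2, p = 1),
                       class = "comparison_result"))
    }
    stop("welch_ttest: zero variance in both samples with unequal means")
  }
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = na, n_b = nb, t = tstat, df = df, p = p),
            class = "comparison_result")
}

#' Per-beat metrics of a trace
#'
#' Segments the trace into beats and computes, per beat: capture flag,
#' APD at the configured repolarisation level, peak voltage (overshoot),
#' amplitude (peak minus diastolic), diastolic interval (APD-end of the
#' previous beat to this upstroke), Ca-transient maximum and diastolic
#' value, spark count and EAD count.
#'
#' @param trace a `simulation_trace`.
#' @param level repolarisation level for [apd()].
#' @param capture_window ms, see [segment_beats()].
#' @param ead_min_rise,ead_min_duration EAD detector settings.
#' @return data.frame, one row per delivered stimulus.
#' @export
beat_metrics <- function(trace, level = 0.9, capture_window = 50,
                         ead_min_rise = 2, ead_min_duration = 5) {
  beats <- segment_beats(trace, capture_window)
  tt <- trace$data$time
  vv <- trace$data$v
  ca <- trace$data$ca_myo
  n <- nrow(beats)
  res <- beats
  res$apd90 <- NA_real_
  res$peak_v <- NA_real_
  res$amplitude <- NA_real_
  res$diastolic_interval <- NA_real_
  res$ca_max <- NA_real_
  res$ca_diastolic <- NA_real_
  res$spark_count <- 0
  res$ead_count <- 0
  apd_end_prev <- NA_real_
  for (i in seq_len(n)) {
    sel <- tt >= beats$t_start[i] & tt < beats$t_end[i]
    if (!any(sel)) next
    vb <- vv[sel]
    tb <- tt[sel]
    cb <- ca[sel]
    pre <- which(tt < beats$stim_time[i])
    v_dia <- if (length(pre)) vv[max(pre)] else vb[1]
    ts <- transient_stats(ca, tt, beats$stim_time[i])
    res$ca_max[i] <- max(cb)
    res$ca_diastolic[i] <- ts$ca_diastolic
    res$spark_count[i] <- sum(trace$sparks$t_start >= beats$t_start[i] &
                                trace$sparks$t_start < beats$t_end[i])
    if (beats$captured[i]) {
      a <- apd(vb, tb, level = level, v_diastolic = v_dia)
      res$apd90[i] <- a
      res$peak_v[i] <- max(vb)
      res$amplitude[i] <- max(vb) - v_dia
      eads <- detect_eads(vb, tb, min_rise = ead_min_rise,
                          min_duration = ead_min_duration,
                          v_diastolic = v_dia)
      res$ead_count[i] <- nrow(eads)
      if (!is.na(a)) {
        dv <- diff(vb) / diff(tb)
        t_up <- tb[which.max(dv) + 1]
        if (!is.na(apd_end_prev)) {
          res$diastolic_interval[i] <- (t_up - apd_end_prev) * 1e3
        }
        apd_end_prev <- t_up + a / 1e3
      }
    }
  }
  res
}

#' Summary analysis of a trace
#'
#' Convenience wrapper producing the per-beat table, alternans reports on
#' APD and Ca-transient amplitude, the EAD and skipped-beat summaries and
#' spark statistics.
#'
#' @param trace a `simulation_trace`.
#' @param skip_first beats discarded as warm-up before the alternans test.
#' @param ... passed to [beat_metrics()].
#' @return list with `beats`, `alternans_apd`, `alternans_ca`,
#'   `ead_beats`, `skipped_beats`, `sparks`.
#' @export
analyze_trace <- function(trace, skip_first = 2, ...) {
  bm <- beat_metrics(trace, ...)
  beats <- segment_beats(trace)
  ok <- bm$captured & !is.na(bm$apd90)
  idx <- which(ok)
  idx <- idx[idx > skip_first]
  alt_apd <- if (length(idx) >= 4) {
    detect_alternans(bm$apd90[idx], metric = "apd90")
  } else NULL
  alt_ca <- if (length(idx) >= 4) {
    detect_alternans(bm$ca_max[idx] - bm$ca_diastolic[idx],
                     metric = "ca_amplitude")
  } else NULL
  list(beats = bm,
       alternans_apd = alt_apd,
       alternans_ca = alt_ca,
       ead_beats = bm$beat[bm$ead_count > 0],
       skipped_beats = bm$beat[!bm$captured],
       sparks = spark_statistics(trace$sparks, beats, trace$n_cru,
                                 trace$n_cru_full))
}

#' Generate a synthetic trace with known ground truth
#'
#' Deterministic parametric action-potential and Ca-transient waveforms
#' with optional injected APD alternans, EAD bumps and skipped beats, used
#' to validate the detectors: the generator returns the trace together
#' with the exact labels it implanted.
#'
#' The AP is piecewise linear: a 1 ms upstroke to `peak_v`, a plateau
#' declining to 30% repolarisation, and a linear final repolarisation of
#' 35 ms, arranged so that APD90 equals the requested `apd` exactly.  EAD
#' bumps are an 8 ms linear rise of `ead_rise` mV followed by a 12 ms
#' return to the baseline, inserted at 60% repolarisation.
#'
#' @param n_beats number of stimuli.
#' @param cycle_length ms between stimuli.
#' @param apd target APD90 (ms).
#' @param peak_v peak (overshoot) voltage, mV.
#' @param v_rest resting voltage, mV.
#' @param alternans_delta beat-to-beat APD alternation (ms; even beats get
#'   `apd + delta/2`, odd beats `apd - delta/2`).
#' @param ead_beats integer beat indices that receive one EAD bump each.
#' @param ead_rise bump height (mV).
#' @param skipped_beats integer beat indices with no upstroke.
#' @param ca_diastolic,ca_amplitude Ca-transient baseline and amplitude
#'   (uM); the transient is a raised cosine of duration 60% of `apd`+100.
#' @param dt sample interval (ms).
#' @param noise_sd optional Gaussian voltage noise (mV).
#' @param seed RNG seed for the noise.
#' @return A `simulation_trace` whose `truth` element lists the implanted
#'   `apd` per beat, `ead_beats`, `skipped_beats` and `alternans_delta`.
#' @export
generate_synthetic_trace <- function(n_beats = 10, cycle_length = 1000,
                                     apd = 180, peak_v = 38, v_rest = -85,
                                     alternans_delta = 0,
                                     ead_beats = integer(0), ead_rise = 5,
                                     skipped_beats = integer(0),
                                     ca_diastolic = 0.1,
                                     ca_amplitude = 0.5,
                                     dt = 1, noise_sd = 0, seed = 1L) {
  if (length(intersect(ead_beats, skipped_beats))) {
    stop("generate_synthetic_trace: a skipped beat cannot carry an EAD")
  }
  stopifnot(n_beats >= 1, cycle_length > 0, apd > 40,
            apd < cycle_length - 50)
  fall <- 35
  t_total <- n_beats * cycle_length
  time <- seq(0, t_total, by = dt)
  v <- rep(v_rest, length(time))
  ca <- rep(ca_diastolic, length(time))
  stim <- (seq_len(n_beats) - 1) * cycle_length
  rng_range <- peak_v - v_rest
  truth_apd <- numeric(n_beats)
  for (b in seq_len(n_beats)) {
    apd_b <- apd + ifelse(b %% 2 == 0, 1, -1) * alternans_delta / 2
    truth_apd[b] <- apd_b
    if (b %in% skipped_beats) {
      truth_apd[b] <- NA_real_
      next
    }
    t0 <- stim[b]
    t_p <- apd_b - 6 / 7 * fall        # plateau end (relative to upstroke)
    knots_t <- c(0, 1, 1 + t_p, 1 + t_p + fall)
    knots_v <- c(v_rest, peak_v, peak_v - 0.3 * rng_range, v_rest)
    rel <- time - t0
    seg <- rel >= 0 & rel <= cycle_length - dt / 2
    v[seg] <- stats::approx(knots_t, knots_v, xout = pmin(rel[seg],
                                                          max(knots_t)),
                            rule = 2)$y
    if (b %in% ead_beats) {
      # V-shaped bump at 60% repolarisation on the final fall: an explicit
      # 6 ms rise of ead_rise mV, then a 10 ms return to the baseline
      v60 <- peak_v - 0.6 * rng_range
      t60 <- 1 + t_p + (knots_v[3] - v60) / (knots_v[3] - v_rest) * fall
      base_end <- stats::approx(knots_t, knots_v, xout = min(t60 + 20,
                                                             max(knots_t)),
                                rule = 2)$y
      bsel <- rel >= t60 & rel <= t60 + 20
      v[bsel] <- stats::approx(c(t60, t60 + 8, t60 + 20),
                               c(v60, v60 + ead_rise, base_end),
                               xout = rel[bsel], rule = 2)$y
    }
    # Ca transient: raised cosine
    dur <- 0.6 * apd_b + 100
    csel <- rel >= 5 & rel <= 5 + dur
    ca[csel] <- ca_diastolic + ca_amplitude *
      0.5 * (1 - cos(2 * pi * (rel[csel] - 5) / dur))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  dat <- data.frame(time = time / 1e3, v = v, ca_myo = ca)
  out <- list(data = dat,
              sparks = data.frame(cru = integer(), t_start = numeric(),
                                  t_end = numeric(), peak_open = numeric(),
                                  peak_ca_ds = numeric()),
              stim_times = stim / 1e3, n_cru = 1L, n_cru_full = 20000L,
              scenario = "synthetic", config = list(dt = dt),
              spark_threshold = 2, spark_gap = 5,
              truth = list(apd = truth_apd, ead_beats = ead_beats,
                           skipped_beats = skipped_beats,
                           alternans_delta = alternans_delta))
  class(out) <- "simulation_trace"
  out
}
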