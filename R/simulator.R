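# Time-stepping front end: pacing protocols, scenario execution, seeded
# reproducibility, trace recording and spark-event extraction.
#
# Times inside the engine are ms; recorded traces and spark events report
# seconds.

#' Build a pacing protocol
#'
#' Either a constant-frequency train or the slow-rapid-slow (S-R-S)
#' protocol: `f_slow` for `durations[1]`, `f_fast` for `durations[2]`,
#' then `f_slow` again for `durations[3]` (default 10 s each, the 1-5-1 Hz
#' protocol used to elicit afterdepolarisations).
#'
#' @param kind `"constant"` or `"srs"`.
#' @param f_slow slow (or constant) pacing frequency (Hz).
#' @param f_fast rapid frequency (Hz, S-R-S only).
#' @param durations segment durations (s): one value for `"constant"`,
#'   three (or one, recycled) for `"srs"`.
#' @param stimulus list with `amplitude` (uA/uF, negative = depolarising;
#'   `NULL` = use the parameter set's calibrated default) and `width` (ms).
#' @return A `pacing_protocol`: list with `segments` (data.frame
#'   `frequency`, `duration`) and `stimulus`.
#' @examples
#' build_protocol("srs", 1, 5)            # 1-5-1 Hz, 10 s each
#' build_protocol("constant", f_slow = 6, durations = 30)
#' @export
build_protocol <- function(kind = c("constant", "srs"), f_slow = 1,
                           f_fast = 5, durations = NULL,
                           stimulus = list(amplitude = NULL, width = 1)) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (is.null(durations)) durations <- 10
    stopifnot(length(durations) == 1)
    if (f_slow <= 0 || durations <= 0) {
      stop("build_protocol: frequency and duration must be positive")
    }
    segments <- data.frame(frequency = f_slow, duration = durations)
  } else {
    if (is.null(durations)) durations <- c(10, 10, 10)
    if (length(durations) == 1) durations <- rep(durations, 3)
    stopifnot(length(durations) == 3)
    if (f_slow <= 0 || f_fast <= 0 || any(durations <= 0)) {
      stop("build_protocol: frequencies and durations must be positive")
    }
    segments <- data.frame(frequency = c(f_slow, f_fast, f_slow),
                           duration = durations)
  }
  if (stimulus$width >= 1e3 / max(segments$frequency)) {
    stop("build_protocol: stimulus width must be shorter than the cycle length")
  }
  structure(list(segments = segments, stimulus = stimulus),
            class = "pacing_protocol")
}

#' Stimulus times of a protocol
#'
#' Each segment contributes `floor(duration * frequency)` stimuli at its
#' cycle length, starting at the segment onset.
#'
#' @param protocol a `pacing_protocol`.
#' @return Stimulus onset times (s), strictly increasing.
#' @export
stimulus_times <- function(protocol) {
  t0 <- 0
  out <- numeric(0)
  for (i in seq_len(nrow(protocol$segments))) {
    f <- protocol$segments$frequency[i]
    d <- protocol$segments$duration[i]
    k <- floor(d * f)
    if (k >= 1) out <- c(out, t0 + (seq_len(k) - 1) / f)
    t0 <- t0 + d
  }
  out
}

#' Simulation configuration
#'
#' @param dt integration/gating time step (ms).
#' @param record_every sampling interval of the recorded trace (ms).
#' @param seed integer RNG seed (one master seed spawns independent
#'   per-CRU streams).
#' @param n_cru number of Ca2+ release units (`NULL` = take from the
#'   parameter set).
#' @param scenario scenario name applied to the baseline parameters
#'   (`NULL` = use the parameters as given).
#' @param protocol a `pacing_protocol`.
#' @param record_cru if `TRUE`, also record per-CRU open-RyR2 counts at
#'   every sample (memory-heavy; meant for short validation runs).
#' @param sealed closed-membrane mode: all sarcolemmal currents off
#'   (conservation testing).
#' @param cru_every operator-splitting ratio: the stochastic gating and
#'   local (dyad/junctional-SR) Ca2+ updates run every `cru_every` global
#'   steps, i.e. at `dt * cru_every` ms, while membrane potential, gates
#'   and bulk Ca2+ advance at `dt`.  The whole-cell L-type current and
#'   transfer fluxes are re-evaluated against the fresh voltage and bulk
#'   concentrations every global step.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dt = 0.02, record_every = 1, seed = 1L,
                              n_cru = NULL, scenario = NULL,
                              protocol = build_protocol("constant", 1,
                                                        durations = 10),
                              record_cru = FALSE, sealed = FALSE,
                              cru_every = 3L) {
  stopifnot(dt > 0, record_every >= dt, cru_every >= 1)
  structure(list(dt = dt, record_every = record_every,
                 seed = as.integer(seed), n_cru = n_cru,
                 scenario = scenario, protocol = protocol,
                 record_cru = record_cru, sealed = sealed,
                 cru_every = as.integer(cru_every)),
            class = "simulation_config")
}

#' Run a pacing protocol
#'
#' Integrates the whole-cell model with explicit Euler at `dt`, stepping
#' the stochastic RyR2/L-type clusters each step with the frozen-rate
#' scheme, injecting rectangular stimulus pulses at the protocol-defined
#' times and recording every `record_every` ms.  Identical seed and
#' configuration give identical traces.
#'
#' @param params a `model_parameters` object (baseline; if
#'   `config$scenario` is set it is applied here).
#' @param config a `simulation_config`.
#' @param spark_threshold minimal open-RyR2 count that defines a spark.
#' @param spark_gap episodes separated by less than this (ms) merge into
#'   one spark.
#' @return A `simulation_trace`: list with `data` (data.frame, time in s:
#'   `time`, `v`, `ca_myo`, `ca_nsr`, `ca_jsr_mean`, `ca_ds_mean`, the
#'   currents, `open_ryr`, `open_lcc`, `h_gate`), `sparks` (data.frame
#'   `cru`, `t_start`, `t_end`, `peak_open`, `peak_ca_ds`, s), `stim_times`
#'   (s), `n_cru`, `scenario`, `config`, and optionally `cru_open`.
#' @export
run_protocol <- function(params, config, spark_threshold = 2, spark_gap = 5) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(config, "simulation_config"))
  if (!is.null(config$scenario)) {
    if (params$scenario != "wt_control" &&
        params$scenario != config$scenario) {
      stop("params already carry scenario '", params$scenario,
           "'; refusing to stack scenario '", config$scenario, "'")
    }
    if (params$scenario == "wt_control") {
      params <- apply_scenario(params, config$scenario)
    }
  }
  if (!is.null(config$n_cru)) {
    params$geometry$n_cru <- as.integer(config$n_cru)
  }
  validate_parameters(params)

  proto <- config$protocol
  stim_s <- stimulus_times(proto)
  t_end_ms <- sum(proto$segments$duration) * 1e3
  amp <- proto$stimulus$amplitude
  if (is.null(amp)) amp <- params$stimulus$amplitude
  width <- proto$stimulus$width
  if (is.null(width)) width <- params$stimulus$width

  init <- c(params$initial, params$ions[c("na_i", "k_i")])
  raw <- .engine_run(unclass(params), stim_s * 1e3, amp, width, t_end_ms,
                     config$dt, config$record_every, config$seed,
                     isTRUE(config$sealed), isTRUE(params$ions$clamp_na_k),
                     isTRUE(config$record_cru), as.integer(spark_threshold),
                     spark_gap, init, config$cru_every %||% 3L)

  cols <- c("v", "ca_myo", "ca_nsr", "ca_jsr_mean", "ca_ds_mean", "i_na",
            "i_ca_l", "i_k", "i_k1", "i_kp", "i_ncx", "i_nak", "i_bg",
            "i_stim", "open_ryr", "open_lcc", "na_i", "k_i", "h_gate",
            "total_ca")
  dat <- data.frame(time = raw$time / 1e3)
  for (cn in cols) dat[[cn]] <- raw[[cn]]
  sp <- raw$sparks
  sparks <- data.frame(cru = sp$cru, t_start = sp$t_start / 1e3,
                       t_end = sp$t_end / 1e3, peak_open = sp$peak_open,
                       peak_ca_ds = sp$peak_ca_ds)
  out <- list(data = dat, sparks = sparks, stim_times = stim_s,
              n_cru = params$geometry$n_cru,
              n_cru_full = params$geometry$n_cru_full,
              scenario = params$scenario, config = config,
              spark_threshold = spark_threshold, spark_gap = spark_gap)
  if (isTRUE(config$record_cru)) out$cru_open <- raw$cru_open
  class(out) <- "simulation_trace"
  out
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace>", x$scenario, "-", nrow(x$data), "samples,",
      length(x$stim_times), "stimuli,", nrow(x$sparks), "sparks,",
      x$n_cru, "CRUs\n")
  invisible(x)
}

#' Detect spark events from per-CRU open-RyR2 counts
#'
#' A spark is a maximal episode during which a CRU's open-RyR2 count is at
#' least `threshold`; episodes of the same CRU separated by less than
#' `gap` ms are merged.  This is the reference implementation of the spark
#' definition the engine applies online at full time resolution.
#'
#' @param counts integer matrix of open-RyR2 counts, rows = time samples,
#'   columns = CRUs (a plain vector is treated as one CRU).
#' @param time sample times (ms), same length as `nrow(counts)`.
#' @param threshold minimal open count in a spark (>= 1).
#' @param gap merge gap (ms).
#' @return data.frame with `cru`, `t_start`, `t_end` (ms), `peak_open`.
#' @export
detect_spark_events <- function(counts, time, threshold = 2, gap = 5) {
  stopifnot(threshold >= 1)
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  stopifnot(nrow(counts) == length(time))
  out <- list()
  for (ic in seq_len(ncol(counts))) {
    above <- counts[, ic] >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    idx <- which(r$values)
    ep <- data.frame(t_start = time[starts[idx]], t_end = time[ends[idx]],
                     i_start = starts[idx], i_end = ends[idx])
    # merge episodes separated by < gap
    keep <- list(ep[1, ])
    if (nrow(ep) > 1) {
      for (k in 2:nrow(ep)) {
        last <- keep[[length(keep)]]
        if (ep$t_start[k] - last$t_end < gap) {
          last$t_end <- ep$t_end[k]
          last$i_end <- ep$i_end[k]
          keep[[length(keep)]] <- last
        } else {
          keep[[length(keep) + 1]] <- ep[k, ]
        }
      }
    }
    ep <- do.call(rbind, keep)
    ep$peak_open <- vapply(seq_len(nrow(ep)), function(k) {
      max(counts[ep$i_start[k]:ep$i_end[k], ic])
    }, numeric(1))
    ep$cru <- ic
    out[[length(out) + 1]] <- ep[, c("cru", "t_start", "t_end", "peak_open")]
  }
  if (!length(out)) {
    return(data.frame(cru = integer(), t_start = numeric(),
                      t_end = numeric(), peak_open = numeric()))
  }
  do.call(rbind, out)
}

#' Calibrate the stimulus amplitude
#'
#' Finds the diastolic threshold amplitude (smallest magnitude of a
#' rectangular pulse that elicits an action potential from rest) by
#' bisection and returns `safety` times that magnitude (a negative
#' current, uA/uF).  The pacing default in [default_parameters()] was set
#' with this routine.
#'
#' @param params a `model_parameters` object.
#' @param width pulse width (ms).
#' @param safety safety factor applied to the measured threshold.
#' @param n_cru release units used in the probe runs (small is fine:
#'   capture is driven by the Na+ current).
#' @param lo,hi bracket for the threshold magnitude (uA/uF).
#' @param tol bisection tolerance (uA/uF).
#' @param seed RNG seed for the probe runs.
#' @return Recommended stimulus amplitude (negative, uA/uF), with the
#'   measured threshold in attribute `"threshold"`.
#' @export
calibrate_stimulus <- function(params, width = 1, safety = 1.5,
                               n_cru = 200, lo = 2, hi = 200, tol = 2,
                               seed = 1L) {
  captures <- function(amp_mag) {
    proto <- build_protocol("constant", f_slow = 2, durations = 0.5,
                            stimulus = list(amplitude = -amp_mag,
                                            width = width))
    cfg <- simulation_config(seed = seed, n_cru = n_cru, protocol = proto)
    tr <- run_protocol(params, cfg)
    any(tr$data$v[tr$data$time <= 0.05] > 0)
  }
  if (!captures(hi)) stop("calibrate_stimulus: no capture at the upper bracket")
  if (captures(lo)) {
    warning("calibrate_stimulus: capture already at the lower bracket")
    return(structure(-safety * lo, threshold = -lo))
  }
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  structure(-safety * hi, threshold = -hi)
}

#' Write / read a simulation trace
#'
#' The trace samples go to `path` as plain CSV; spark events and a JSON
#' metadata sidecar (scenario, seed, configuration) are written next to it
#' as `<path>_sparks.csv` and `<path>_meta.json`.
#'
#' @param trace a `simulation_trace`.
#' @param path CSV file path for the samples.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `simulation_trace` (without per-CRU data).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "simulation_trace"))
  utils::write.csv(trace$data, path, row.names = FALSE)
  base <- sub("\\.csv$", "", path)
  utils::write.csv(trace$sparks, paste0(base, "_sparks.csv"),
                   row.names = FALSE)
  meta <- list(scenario = trace$scenario, n_cru = trace$n_cru,
               n_cru_full = trace$n_cru_full,
               stim_times = trace$stim_times,
               spark_threshold = trace$spark_threshold,
               spark_gap = trace$spark_gap,
               seed = trace$config$seed, dt = trace$config$dt,
               record_every = trace$config$record_every,
               package_version = as.character(utils::packageVersion("crusim")))
  jsonlite::write_json(meta, paste0(base, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  dat <- utils::read.csv(path)
  base <- sub("\\.csv$", "", path)
  sparks_path <- paste0(base, "_sparks.csv")
  meta_path <- paste0(base, "_meta.json")
  sparks <- if (file.exists(sparks_path)) utils::read.csv(sparks_path) else
    data.frame(cru = integer(), t_start = numeric(), t_end = numeric(),
               peak_open = numeric(), peak_ca_ds = numeric())
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
    else list()
  out <- list(data = dat, sparks = sparks,
              stim_times = meta$stim_times %||% numeric(0),
              n_cru = meta$n_cru %||% NA_integer_,
              n_cru_full = meta$n_cru_full %||% 20000L,
              scenario = meta$scenario %||% NA_character_,
              config = meta, spark_threshold = meta$spark_threshold %||% 2,
              spark_gap = meta$spark_gap %||% 5)
  class(out) <- "simulation_trace"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
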