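# Deterministic membrane currents (Luo-Rudy-style), SERCA and NCX fluxes,
# the GHK unitary L-type flux, Hodgkin-Huxley gate kinetics and the full
# derivative assembly with inter-compartment mass balance.
#
# Sign conventions: membrane currents are positive outward (uA/uF), so
# dV/dt = -(sum of currents).  Fluxes are uM/ms referred to the volume of
# the compartment whose derivative they enter.

#' SERCA pump flux
#'
#' Whole-cell SR Ca2+ uptake `J = 2 * vcycle * Ap`, where `vcycle` is the
#' per-molecule cycling rate (Hill function of myoplasmic Ca2+,
#' `vcycle_max * ca^h / (ca^h + km_fwd^h)`, times a luminal
#' back-inhibition factor `1 / (1 + (ca_nsr / k_nsr)^hill_nsr)` that is
#' negligible at physiological loads and stalls the pump against an
#' extreme luminal gradient) and `Ap` the SERCA concentration per litre
#' cytosol.  The factor 2 is the Ca2+ stoichiometry per cycle.  The flux
#' scales exactly linearly with `Ap`, which is what the beta-adrenergic
#' scenario multiplies.
#'
#' @param ca_myo myoplasmic free Ca2+ (uM).
#' @param ca_nsr network SR free Ca2+ (uM).
#' @param pumps the `pumps` component of a parameter set.
#' @return Uptake flux (uM/ms, myoplasm-referred, myoplasm -> NSR).
#' @examples
#' p <- default_parameters()
#' serca_flux(0.3, 800, p$pumps)
#' @export
serca_flux <- function(ca_myo, ca_nsr, pumps) {
  stopifnot(all(ca_myo >= 0), all(ca_nsr >= 0))
  s <- pumps$serca
  vcycle <- s$vcycle_max * ca_myo^s$hill / (ca_myo^s$hill + s$km_fwd^s$hill)
  if (!is.null(s$k_nsr)) {
    vcycle <- vcycle / (1 + (ca_nsr / s$k_nsr)^s$hill_nsr)
  }
  2 * vcycle * s$ap
}

#' Sodium-calcium exchanger current
#'
#' Electrogenic 3Na+:1Ca2+ exchange in the standard saturating form.
#' Positive current is outward (reverse mode, Ca2+ entry); the forward
#' extrusion mode carries inward (negative) current, which is the
#' depolarising contribution during a Ca2+ transient.
#'
#' @param v membrane potential (mV).
#' @param na_i intracellular Na+ (mM).
#' @param ca_myo myoplasmic free Ca2+ (uM).
#' @param params full parameter set (uses `pumps$ncx`, `extracellular`,
#'   `physical`).
#' @return Current (uA/uF).
#' @export
ncx_current <- function(v, na_i, ca_myo, params) {
  stopifnot(all(na_i > 0), all(ca_myo >= 0))
  n <- params$pumps$ncx
  ex <- params$extracellular
  ph <- params$physical
  vf <- v * 1e-3 * ph$faraday / (ph$r_gas * ph$temperature)
  ca_mM <- ca_myo * 1e-3
  num <- exp(n$eta * vf) * na_i^3 * ex$ca_o -
    exp((n$eta - 1) * vf) * ex$na_o^3 * ca_mM
  den <- (n$km_na^3 + ex$na_o^3) * (n$km_ca * 1e-3 + ex$ca_o) *
    (1 + n$ksat * exp((n$eta - 1) * vf))
  n$k_ncx * num / den
}

#' Unitary L-type channel Ca2+ flux (GHK constant-field form)
#'
#' Single open-channel Ca2+ flux into the dyadic subspace, using the
#' Goldman-Hodgkin-Katz current equation for a divalent ion with
#' permeability `p_dhpr` and activity coefficients `gamma_i`, `gamma_o`.
#' The removable singularity at `v = 0` is handled by a series expansion.
#'
#' @param v membrane potential (mV).
#' @param ca_ds dyadic subspace Ca2+ (uM).
#' @param ca_o extracellular Ca2+ (mM).
#' @param p_dhpr single-channel permeability (cm^3/s).
#' @param v_ds subspace volume (L).
#' @param temperature temperature (K).
#' @param gamma_i,gamma_o internal/external activity coefficients.
#' @return List with `current` (pA, positive outward) and `flux` (uM/ms
#'   into the subspace, positive inward).
#' @export
lcc_unitary_flux <- function(v, ca_ds, ca_o, p_dhpr,
                             v_ds = 1e-18, temperature = 310,
                             gamma_i = 1, gamma_o = 0.341) {
  stopifnot(all(is.finite(v)), all(ca_ds >= 0), ca_o >= 0)
  faraday <- 96485
  r_gas <- 8.314
  z <- 2
  u <- z * (v * 1e-3) * faraday / (r_gas * temperature)
  ci <- ca_ds * 1e-9   # uM -> mol/cm^3
  co <- ca_o * 1e-6    # mM -> mol/cm^3
  # i = P zF * u/(e^u - 1) * (gi ci e^u - go co);  u/(e^u-1) -> 1 as u -> 0
  small <- abs(u) < 1e-4
  uf <- ifelse(small, 1 - u / 2 + u^2 / 12, u / expm1(u))
  i_amp <- p_dhpr * z * faraday * uf * (gamma_i * ci * exp(u) - gamma_o * co)
  flux <- -i_amp * 1e3 / (z * faraday * v_ds)
  list(current = i_amp * 1e12, flux = flux)
}

#' Luo-Rudy-style gate rate constants
#'
#' Alpha/beta opening and closing rates (1/ms) of the fast Na+ gates
#' (m, h, j) and the time-dependent K+ activation gate (x) at a membrane
#' potential, in the classic guinea-pig ventricular formulation.
#' `x_rate_scale` uniformly scales the x-gate kinetics (a calibration knob
#' for action potential duration and its rate dependence).
#'
#' @param v membrane potential (mV).
#' @param x_rate_scale multiplier on alpha_x and beta_x.
#' @param x_beta_scale additional multiplier on beta_x only; values > 1
#'   speed x-gate deactivation at rest and flatten the APD restitution.
#' @return Named list of lists: `m`, `h`, `j`, `x`, each with `alpha` and
#'   `beta` (1/ms).
#' @export
lr_gate_rates <- function(v, x_rate_scale = 1, x_beta_scale = 1) {
  am <- if (abs(v + 47.13) < 1e-6) 3.2 else
    0.32 * (v + 47.13) / (1 - exp(-0.1 * (v + 47.13)))
  bm <- 0.08 * exp(-v / 11)
  if (v >= -40) {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp((v + 10.66) / -11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * v) / (1 + exp(-0.1 * (v + 32)))
  } else {
    ah <- 0.135 * exp((80 + v) / -6.8)
    bh <- 3.56 * exp(0.079 * v) + 3.1e5 * exp(0.35 * v)
    aj <- (-1.2714e5 * exp(0.2444 * v) - 3.474e-5 * exp(-0.04391 * v)) *
      (v + 37.78) / (1 + exp(0.311 * (v + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * v) / (1 + exp(-0.1378 * (v + 40.14)))
  }
  ax <- x_rate_scale * 0.0005 * exp(0.083 * (v + 50)) / (1 + exp(0.057 * (v + 50)))
  bx <- x_beta_scale * x_rate_scale * 0.0013 * exp(-0.06 * (v + 20)) /
    (1 + exp(-0.04 * (v + 20)))
  list(m = list(alpha = am, beta = bm),
       h = list(alpha = ah, beta = bh),
       j = list(alpha = aj, beta = bj),
       x = list(alpha = ax, beta = bx))
}

#' Hodgkin-Huxley gate derivatives
#'
#' Relaxation `dg/dt = alpha(v) * (1 - g) - beta(v) * g` for the gates
#' `m`, `h`, `j`, `x`; the fixed point of each gate is
#' `g_inf = alpha / (alpha + beta)`.
#'
#' @param gates named list or vector with elements `m`, `h`, `j`, `x`,
#'   each in `[0, 1]`.
#' @param v membrane potential (mV).
#' @param x_rate_scale multiplier on the x-gate kinetics.
#' @return Named list of derivatives (1/ms).
#' @export
lr_gate_derivatives <- function(gates, v, x_rate_scale = 1, x_beta_scale = 1) {
  g <- as.list(gates)
  stopifnot(all(unlist(g[c("m", "h", "j", "x")]) >= 0),
            all(unlist(g[c("m", "h", "j", "x")]) <= 1))
  r <- lr_gate_rates(v, x_rate_scale, x_beta_scale)
  lapply(stats::setNames(c("m", "h", "j", "x"), c("m", "h", "j", "x")),
         function(nm) r[[nm]]$alpha * (1 - g[[nm]]) - r[[nm]]$beta * g[[nm]])
}

#' Gate steady states
#'
#' `g_inf(v) = alpha / (alpha + beta)` for each Hodgkin-Huxley gate.
#'
#' @inheritParams lr_gate_rates
#' @return Named numeric vector (`m`, `h`, `j`, `x`).
#' @export
lr_gate_steady_state <- function(v, x_rate_scale = 1, x_beta_scale = 1) {
  r <- lr_gate_rates(v, x_rate_scale, x_beta_scale)
  vapply(r, function(g) g$alpha / (g$alpha + g$beta), numeric(1))
}

# Deterministic membrane currents at one instant (uA/uF, positive
# outward).  Internal; used by assemble_derivatives() and mirrored by the
# compiled engine.
membrane_currents <- function(v, gates, ca_myo, na_i, k_i, params,
                              sealed = FALSE, i_stim = 0) {
  ex <- params$extracellular
  mb <- params$membrane
  ph <- params$physical
  rtf <- ph$r_gas * ph$temperature / ph$faraday * 1e3  # mV
  if (sealed) {
    return(list(i_na = 0, i_k = 0, i_k1 = 0, i_kp = 0, i_ncx = 0,
                i_nak = 0, i_bg = 0, i_stim = 0))
  }
  e_na <- rtf * log(ex$na_o / na_i)
  e_k <- rtf * log((ex$k_o + mb$pr_nak * ex$na_o) / (k_i + mb$pr_nak * na_i))
  e_k1 <- rtf * log(ex$k_o / k_i)
  e_ca <- rtf / 2 * log(ex$ca_o * 1e3 / ca_myo)
  i_na <- mb$g_na * gates$m^3 * gates$h * gates$j * (v - e_na)
  xi <- if (v > -100) {
    2.837 * (exp(0.04 * (v + 77)) - 1) / ((v + 77) * exp(0.04 * (v + 35)))
  } else 1
  gk <- mb$g_k * sqrt(ex$k_o / 5.4)
  i_k <- gk * gates$x * xi * (v - e_k)
  ak1 <- 1.02 / (1 + exp(0.2385 * (v - e_k1 - 59.215)))
  bk1 <- (0.49124 * exp(0.08032 * (v - e_k1 + 5.476)) +
            exp(0.06175 * (v - e_k1 - 594.31))) /
    (1 + exp(-0.5143 * (v - e_k1 + 4.753)))
  i_k1 <- mb$g_k1 * sqrt(ex$k_o / 5.4) * ak1 / (ak1 + bk1) * (v - e_k1)
  i_kp <- mb$g_kp * (v - e_k1) / (1 + exp((7.488 - v) / 5.98))
  i_ncx <- ncx_current(v, na_i, ca_myo, params)
  sigma <- (exp(ex$na_o / 67.3) - 1) / 7
  f_nak <- 1 / (1 + 0.1245 * exp(-0.1 * v / rtf) + 0.0365 * sigma * exp(-v / rtf))
  nk <- params$pumps$nak
  i_nak <- nk$i_max * f_nak / (1 + (nk$km_nai / na_i)^1.5) *
    ex$k_o / (ex$k_o + nk$km_ko)
  bg <- params$pumps$background
  i_bg <- bg$g_cab * (v - e_ca) + bg$g_nab * (v - e_na)
  list(i_na = i_na, i_k = i_k, i_k1 = i_k1, i_kp = i_kp, i_ncx = i_ncx,
       i_nak = i_nak, i_bg = i_bg, i_stim = i_stim)
}

#' Assemble the time derivatives of every continuous variable
#'
#' Reference (R-level) implementation of the full balance equations the
#' compiled engine integrates: `dV/dt = -(sum of currents)`, each
#' compartment's free-Ca derivative as the rapid-buffering factor times
#' the net flux, with volume-ratio conversion between compartments, and
#' Na+/K+ balances from their currents (zero when clamped).  Intended for
#' small-state validation (conservation, sign checks); the production path
#' is [run_protocol()].
#'
#' @param state list with `v`, `ca_myo`, `ca_nsr`, `na_i`, `k_i`, `gates`
#'   (list `m`, `h`, `j`, `x`) and `cru`, a list with numeric vectors
#'   `ca_jsr`, `ca_ds` and integer vectors `n_open_ryr`, `n_open_lcc` (one
#'   entry per CRU).
#' @param params a `model_parameters` object.
#' @param sealed if `TRUE`, all sarcolemmal currents and the L-type flux
#'   are switched off (closed-membrane configuration: total cell Ca2+ is
#'   conserved).
#' @param i_stim applied stimulus current (uA/uF, negative = depolarising).
#' @return List of derivatives: `dv`, `dca_myo`, `dca_nsr`, `dna_i`,
#'   `dk_i`, `dgates`, per-CRU `dca_jsr`, `dca_ds`, plus the evaluated
#'   `currents` and whole-cell `fluxes`.
#' @export
assemble_derivatives <- function(state, params, sealed = FALSE, i_stim = 0) {
  g <- params$geometry
  tr <- params$transport
  scale <- g$n_cru / g$n_cru_full
  v_myo_eff <- g$v_myo * scale
  v_nsr_eff <- g$v_nsr * scale
  c_tot <- params$membrane$acap * params$membrane$cm
  kappa_ca <- c_tot * 1e-3 / (2 * params$physical$faraday * g$v_myo)  # z = 2
  kappa_q <- c_tot * 1e-3 / (params$physical$faraday * g$v_myo)       # per charge

  cur <- membrane_currents(state$v, state$gates, state$ca_myo, state$na_i,
                           state$k_i, params, sealed = sealed, i_stim = i_stim)

  cru <- state$cru
  n <- length(cru$ca_jsr)
  stopifnot(length(cru$ca_ds) == n, length(cru$n_open_ryr) == n,
            length(cru$n_open_lcc) == n)

  j_rel <- tr$g_rel * cru$n_open_ryr * (cru$ca_jsr - cru$ca_ds)
  j_lcc <- if (sealed) rep(0, n) else {
    u <- lcc_unitary_flux(state$v, cru$ca_ds, params$extracellular$ca_o,
                          params$channels$p_dhpr, v_ds = g$v_ds_unit,
                          temperature = params$physical$temperature)
    u$flux * cru$n_open_lcc
  }
  j_xfer <- tr$g_xfer * (cru$ca_ds - state$ca_myo)
  j_tr <- tr$g_tr * (state$ca_nsr - cru$ca_jsr)

  beta_ds <- rapid_buffer_factor(cru$ca_ds, list(params$buffers$subspace))
  beta_jsr <- rapid_buffer_factor(cru$ca_jsr, list(params$buffers$casq))
  beta_myo <- rapid_buffer_factor(state$ca_myo,
                                  list(params$buffers$troponin,
                                       params$buffers$calmodulin))

  dca_ds <- beta_ds * (j_rel + j_lcc - j_xfer)
  dca_jsr <- beta_jsr * (j_tr - j_rel * g$v_ds_unit / g$v_jsr_unit)

  i_ca_l <- if (sealed) 0 else {
    u <- lcc_unitary_flux(state$v, cru$ca_ds, params$extracellular$ca_o,
                          params$channels$p_dhpr, v_ds = g$v_ds_unit,
                          temperature = params$physical$temperature)
    sum(u$current * cru$n_open_lcc) * 1e-6 / (c_tot * scale)  # pA -> uA/uF
  }

  j_serca <- serca_flux(state$ca_myo, state$ca_nsr, params$pumps)
  j_leak <- params$pumps$g_leak * (state$ca_nsr - state$ca_myo)
  j_xfer_myo <- sum(j_xfer * g$v_ds_unit) / v_myo_eff
  j_tr_nsr <- sum(j_tr * g$v_jsr_unit) / v_nsr_eff
  j_sarc <- if (sealed) 0 else {
    bg_ca <- params$pumps$background$g_cab *
      (state$v - params$physical$r_gas * params$physical$temperature /
         params$physical$faraday * 1e3 / 2 *
         log(params$extracellular$ca_o * 1e3 / state$ca_myo))
    -bg_ca * kappa_ca + cur$i_ncx * kappa_q
  }

  dca_myo <- beta_myo * (j_xfer_myo - j_serca + j_leak + j_sarc)
  dca_nsr <- (j_serca - j_leak) * g$v_myo / g$v_nsr - j_tr_nsr

  i_sum <- cur$i_na + i_ca_l + cur$i_k + cur$i_k1 + cur$i_kp + cur$i_ncx +
    cur$i_nak + cur$i_bg + cur$i_stim
  dv <- -i_sum
  dgates <- lr_gate_derivatives(state$gates, state$v,
                                params$membrane$x_rate_scale,
                                params$membrane$x_beta_scale %||% 1)
  if (isTRUE(params$ions$clamp_na_k) || sealed) {
    dna_i <- 0
    dk_i <- 0
  } else {
    dna_i <- -(cur$i_na + 3 * cur$i_nak + 3 * cur$i_ncx +
                 params$pumps$background$g_nab * 0) * kappa_q * 1e-3
    dk_i <- -(cur$i_k + cur$i_k1 + cur$i_kp - 2 * cur$i_nak) * kappa_q * 1e-3
  }

  out <- list(dv = dv, dca_myo = dca_myo, dca_nsr = dca_nsr,
              dna_i = dna_i, dk_i = dk_i, dgates = dgates,
              dca_jsr = dca_jsr, dca_ds = dca_ds,
              currents = c(cur, list(i_ca_l = i_ca_l)),
              fluxes = list(j_serca = j_serca, j_leak = j_leak,
                            j_xfer_myo = j_xfer_myo, j_tr_nsr = j_tr_nsr,
                            j_rel_unit = j_rel))
  bad <- !is.finite(c(out$dv, out$dca_myo, out$dca_nsr, out$dca_jsr, out$dca_ds))
  if (any(bad)) {
    stop("assemble_derivatives: non-finite derivative encountered (v = ",
         state$v, ", ca_myo = ", state$ca_myo, ")")
  }
  out
}

#' Total cell Ca2+ content
#'
#' Sums free plus buffer-bound Ca2+ over all compartments, weighted by
#' their volumes (mol).  The sealed-membrane configuration must conserve
#' this quantity.
#'
#' @param state state list as in [assemble_derivatives()] (uses `ca_myo`,
#'   `ca_nsr` and `cru$ca_jsr`, `cru$ca_ds`).
#' @param params a `model_parameters` object.
#' @return Total Ca2+ amount (mol).
#' @export
total_calcium <- function(state, params) {
  g <- params$geometry
  scale <- g$n_cru / g$n_cru_full
  bound <- function(ca, buffers) {
    s <- 0
    for (b in buffers) s <- s + b$btot * ca / (b$kd + ca)
    s
  }
  myo <- (state$ca_myo + bound(state$ca_myo,
                               list(params$buffers$troponin,
                                    params$buffers$calmodulin))) *
    g$v_myo * scale
  nsr <- state$ca_nsr * g$v_nsr * scale
  jsr <- sum((state$cru$ca_jsr + bound(state$cru$ca_jsr,
                                       list(params$buffers$casq))) *
               g$v_jsr_unit)
  ds <- sum((state$cru$ca_ds + bound(state$cru$ca_ds,
                                     list(params$buffers$subspace))) *
              g$v_ds_unit)
  (myo + nsr + jsr + ds) * 1e-6  # uM * L -> mol
}
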