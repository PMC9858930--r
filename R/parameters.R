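# Parameter set, compartment geometry, buffers and the scenario system.
#
# All concentrations are in uM (Na+/K+ in mM), time in ms, voltage in mV,
# currents in uA/uF, volumes in litres.  The structural composition of the
# cell is fixed by the biology (49 RyR2 and 14 L-type channels per release
# unit, 20,000 units at full scale); every kinetic constant is an ordinary
# list entry that can be overridden or serialised, and the four named
# scenarios are plain multiplier sets applied on top of the wild-type
# baseline.

#' Default (wild-type, calibrated) model parameters
#'
#' Returns the full parameter set of the stochastic local-control myocyte
#' model: compartment geometry, Ca2+ buffers, RyR2 and L-type channel rate
#' constants, pump/exchanger parameters, membrane conductances,
#' extracellular milieu and initial conditions.  The numeric values are the
#' bundled wild-type calibration: pacing this parameter set at 1 Hz
#' reproduces the reference envelopes for the Ca2+ transient, APD90 and
#' spark rate (see the package vignette for the calibration rationale).
#'
#' Geometry notes: `n_cru` defaults to the desk-scale 2,000 release units;
#' `n_cru_full = 20000` is the full-scale reference count used to rescale
#' whole-cell fluxes, so bulk concentrations are `n_cru`-invariant in
#' expectation.  Per-CRU volumes (`v_jsr_unit`, `v_ds_unit`) are physical
#' single-unit volumes; total junctional-SR volume is
#' `n_cru_full * v_jsr_unit`.
#'
#' @param n_cru number of stochastic Ca2+ release units to simulate
#'   (desk-scale default 2000; the full-scale model uses 20000).
#' @return An object of class `model_parameters`: a named nested list with
#'   components `geometry`, `buffers`, `channels`, `pumps`, `membrane`,
#'   `transport`, `extracellular`, `ions`, `physical`, `initial` and
#'   `scenario` (the name of the applied scenario, `"wt_control"` here).
#' @examples
#' p <- default_parameters()
#' p$geometry$n_ryr_per_cru  # 49
#' p$geometry$n_lcc_per_cru  # 14
#' @export
default_parameters <- function(n_cru = 2000L) {
  p <- list(
    schema_version = 1L,
    scenario = "wt_control",
    geometry = list(
      v_myo      = 25.84e-12,  # L, bulk myoplasm
      v_nsr      = 2.1e-12,    # L, network SR
      v_jsr_unit = 8.0e-18,    # L per CRU, junctional SR
      v_ds_unit  = 1.0e-18,    # L per CRU, dyadic subspace
      n_cru      = as.integer(n_cru),
      n_cru_full = 20000L,
      n_ryr_per_cru = 49L,
      n_lcc_per_cru = 14L
    ),
    buffers = list(
      casq      = list(btot = 26000, kd = 800),  # uM, JSR-referred (calsequestrin)
      troponin  = list(btot = 58,    kd = 0.5),  # uM, myoplasm
      calmodulin= list(btot = 24,    kd = 2.38), # uM, myoplasm
      subspace  = list(btot = 200,   kd = 10)    # uM, anionic dyad buffer
    ),
    channels = list(
      # L-type single-channel permeability, cm^3/s (GHK constant-field form)
      p_dhpr = 1.8e-13,
      # luminal regulation Phi = phi_m * [Ca]jsr + phi_b (multiplies RyR2 opening)
      phi_m = 1.2e-3,   # 1/uM
      phi_b = 0.02,     # dimensionless
      ryr2 = list(
        k_open_max = 0.5,    # 1/ms, maximal opening rate at saturating dyad Ca
        hill_ca_ds = 3,      # Hill coefficient of dyad-Ca activation
        k_ca       = 18,     # uM, half-activation dyad Ca
        k_close    = 0.5,    # 1/ms, O2 -> C1
        k_adapt    = 0.25,   # 1/ms, O2 -> C3 (adaptation, terminates sparks)
        k_recover  = 0.0012  # 1/ms, C3 -> C1 (recovery, spark refractoriness)
      ),
      lcc = list(
        act_max    = 0.6,  v_act = -5,  k_act = 6,    # C1 -> O2 (Boltzmann)
        deact_max  = 2.0,  v_deact = -30, k_deact = 6,# O2 -> C1
        f_oo       = 0.25,                            # O2 -> O3
        g_oo       = 0.25,                            # O3 -> O2
        ca_inact_slope   = 3.3e-3,                    # 1/(uM ms), O2 -> C4
        ca_inact_max     = 2.5,                       # 1/ms, saturation of O2 -> C4
        ca_inact_recover = 0.03,                      # 1/ms, C4 -> C1
        v_inact_max = 0.08, v_inact_vhalf = -20, v_inact_k = 6,  # O2 -> C5
        v_inact_recover = 0.03,                       # 1/ms, C5 -> C1 (at rest)
        c6_entry_max = 0.01, c6_vhalf = -30, c6_k = 5,# C1 -> C6 (deep closed)
        c6_recover = 0.01                             # 1/ms, C6 -> C1 (at rest)
      )
    ),
    pumps = list(
      serca = list(
        ap         = 75,      # uM SERCA per L cytosol
        vcycle_max = 3.0e-3,  # 1/ms per molecule
        km_fwd     = 0.6,     # uM
        hill       = 2,
        k_nsr      = 3000,    # uM, luminal back-inhibition midpoint
        hill_nsr   = 4        # steepness of the back-inhibition
      ),
      ncx = list(
        k_ncx = 1700,  # uA/uF scaling
        km_na = 87.5,  # mM
        km_ca = 1380,  # uM
        eta   = 0.35,
        ksat  = 0.1
      ),
      nak = list(i_max = 1.0, km_nai = 10, km_ko = 1.5),
      background = list(g_cab = 2.0e-4, g_nab = 1.4e-3),  # mS/uF
      g_leak = 3.0e-5  # 1/ms, NSR -> myo leak
    ),
    membrane = list(
      cm   = 1.0,        # uF/cm^2
      acap = 1.534e-4,   # cm^2, capacitive area
      g_na = 10,         # mS/uF
      g_k  = 0.75,       # mS/uF (scaled with sqrt(k_o/5.4))
      g_k1 = 0.6047,     # mS/uF (scaled with sqrt(k_o/5.4))
      g_kp = 0.0183,     # mS/uF
      x_rate_scale = 1.0,  # multiplies alpha_x/beta_x (K+ activation kinetics)
      x_beta_scale = 4.0,  # extra factor on beta_x: fast deactivation at rest
                           # flattens APD rate-dependence (restitution)
      pr_nak = 0.01833   # Na+ permeability ratio in E_K
    ),
    transport = list(
      g_rel  = 0.62,   # 1/ms per open RyR2, JSR -> dyad
      g_xfer = 20,     # 1/ms, dyad -> myo
      g_tr   = 0.05    # 1/ms, NSR -> JSR refill
    ),
    extracellular = list(ca_o = 1.8, na_o = 140, k_o = 5.4),  # mM
    ions = list(na_i = 10, k_i = 145, clamp_na_k = TRUE),     # mM
    physical = list(
      faraday = 96485,     # C/mol
      r_gas   = 8.314,     # J/(mol K)
      temperature = 310    # K
    ),
    initial = list(
      v = -85, ca_myo = 0.12, ca_nsr = 890, ca_jsr = 890, ca_ds = 0.12,
      m = 0.0012, h = 0.985, j = 0.99, x = 0.005
    ),
    stimulus = list(amplitude = -60, width = 1)  # uA/uF, ms
  )
  class(p) <- "model_parameters"
  validate_parameters(p)
  p
}

#' Validate a model parameter set
#'
#' Checks the structural invariants of the parameter object: positive
#' volumes, non-negative buffer capacities with positive dissociation
#' constants, non-negative rate constants and multiplier-safe fields.
#' Called by [default_parameters()] and [apply_scenario()].
#'
#' @param p a `model_parameters` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(p) {
  g <- p$geometry
  stopifnot(
    g$v_myo > 0, g$v_nsr > 0, g$v_jsr_unit > 0, g$v_ds_unit > 0,
    g$n_cru >= 1, g$n_ryr_per_cru >= 1, g$n_lcc_per_cru >= 1
  )
  for (b in p$buffers) stopifnot(b$btot >= 0, b$kd > 0)
  ch <- p$channels
  stopifnot(ch$p_dhpr >= 0, ch$phi_m >= 0, ch$phi_b >= 0)
  stopifnot(all(unlist(ch$ryr2) >= 0))
  stopifnot(ch$lcc$act_max >= 0, ch$lcc$deact_max >= 0,
            ch$lcc$ca_inact_slope >= 0, ch$lcc$v_inact_max >= 0)
  s <- p$pumps$serca
  stopifnot(s$ap >= 0, s$vcycle_max >= 0, s$km_fwd > 0)
  stopifnot(p$pumps$ncx$km_na > 0, p$pumps$ncx$km_ca > 0)
  stopifnot(all(unlist(p$transport) >= 0))
  invisible(p)
}

# Registry of the four built-in scenarios.  Multipliers are applied by
# apply_scenario(); wt_control is the identity.  The morphological changes
# (SR volumes +50%, calsequestrin buffer -95%, luminal regulation slope
# +90%) model the calsequestrin-null mutant; the L-type (+40%) and SERCA
# (+50%) changes model beta-adrenergic stimulation; the stimulated mutant
# composes both sets.
.scenario_registry <- list(
  wt_control = list(
    name = "wt_control",
    phi_m_scale = 1, serca_ap_scale = 1, jsr_volume_scale = 1,
    nsr_volume_scale = 1, casq_btot_scale = 1, p_dhpr_scale = 1
  ),
  mutant_control = list(
    name = "mutant_control",
    phi_m_scale = 1.9, serca_ap_scale = 1, jsr_volume_scale = 1.5,
    nsr_volume_scale = 1.5, casq_btot_scale = 0.05, p_dhpr_scale = 1
  ),
  wt_bar = list(
    name = "wt_bar",
    phi_m_scale = 1, serca_ap_scale = 1.5, jsr_volume_scale = 1,
    nsr_volume_scale = 1, casq_btot_scale = 1, p_dhpr_scale = 1.4
  ),
  mutant_bar = list(
    name = "mutant_bar",
    phi_m_scale = 1.9, serca_ap_scale = 1.5, jsr_volume_scale = 1.5,
    nsr_volume_scale = 1.5, casq_btot_scale = 0.05, p_dhpr_scale = 1.4
  )
)

#' Built-in scenario modifier sets
#'
#' The four simulated conditions map onto parameter multipliers applied to
#' the wild-type baseline:
#' \describe{
#'   \item{`wt_control`}{identity (all multipliers 1).}
#'   \item{`mutant_control`}{calsequestrin-null morphology: junctional and
#'     network SR volumes x1.5, calsequestrin capacity x0.05 (-95%),
#'     luminal regulation slope `phi_m` x1.9 (+90%).}
#'   \item{`wt_bar`}{beta-adrenergic stimulation: L-type single-channel
#'     permeability x1.4 (+40%), SERCA concentration x1.5 (+50%).}
#'   \item{`mutant_bar`}{composition of the mutant and beta-adrenergic
#'     multipliers.}
#' }
#'
#' @param name one of `"wt_control"`, `"mutant_control"`, `"wt_bar"`,
#'   `"mutant_bar"`; if missing, the list of all four is returned.
#' @return A scenario modifier list (fields `name`, `phi_m_scale`,
#'   `serca_ap_scale`, `jsr_volume_scale`, `nsr_volume_scale`,
#'   `casq_btot_scale`, `p_dhpr_scale`), or the named list of all four.
#' @examples
#' scenario_modifiers("mutant_control")$casq_btot_scale  # 0.05
#' names(scenario_modifiers())
#' @export
scenario_modifiers <- function(name) {
  if (missing(name)) return(.scenario_registry)
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(.scenario_registry)) {
    stop("unknown scenario name: ", paste(name, collapse = ", "),
         " (expected one of ",
         paste(names(.scenario_registry), collapse = ", "), ")")
  }
  .scenario_registry[[name]]
}

#' Apply a scenario to a parameter set
#'
#' Returns a new parameter set with the scenario multipliers applied:
#' `phi_m`, SERCA `ap`, `v_jsr_unit`, `v_nsr`, calsequestrin `btot` and
#' `p_dhpr` are each multiplied by the corresponding scale; the input is
#' untouched.  Multipliers act on independent fields, so application is
#' compositional and order-independent.
#'
#' @param params a `model_parameters` object (usually the wild-type
#'   baseline from [default_parameters()]).
#' @param scenario a scenario name (see [scenario_modifiers()]) or a
#'   modifier list with the same fields.
#' @return A new, validated `model_parameters` object.
#' @examples
#' p <- default_parameters()
#' m <- apply_scenario(p, "mutant_control")
#' m$buffers$casq$btot / p$buffers$casq$btot  # 0.05
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(params, "model_parameters"))
  if (is.character(scenario)) scenario <- scenario_modifiers(scenario)
  needed <- c("name", "phi_m_scale", "serca_ap_scale", "jsr_volume_scale",
              "nsr_volume_scale", "casq_btot_scale", "p_dhpr_scale")
  if (!all(needed %in% names(scenario))) {
    stop("scenario modifiers must contain fields: ",
         paste(setdiff(needed, names(scenario)), collapse = ", "))
  }
  sc <- scenario
  stopifnot(all(unlist(sc[needed[-1]]) > 0))
  q <- params
  q$channels$phi_m      <- q$channels$phi_m      * sc$phi_m_scale
  q$pumps$serca$ap      <- q$pumps$serca$ap      * sc$serca_ap_scale
  q$geometry$v_jsr_unit <- q$geometry$v_jsr_unit * sc$jsr_volume_scale
  q$geometry$v_nsr      <- q$geometry$v_nsr      * sc$nsr_volume_scale
  q$buffers$casq$btot   <- q$buffers$casq$btot   * sc$casq_btot_scale
  q$channels$p_dhpr     <- q$channels$p_dhpr     * sc$p_dhpr_scale
  q$scenario <- sc$name
  validate_parameters(q)
  q
}

#' Rapid-buffering factor
#'
#' Instantaneous-equilibrium treatment of Ca2+ buffering: the free-Ca
#' derivative in a buffered compartment is multiplied by
#' `beta = 1 / (1 + sum(btot * kd / (kd + ca)^2))`.
#' `beta` lies in (0, 1], tends to 1 as all capacities tend to 0, and is
#' decreasing in each `btot`.
#'
#' @param ca free Ca2+ concentration (uM, scalar or vector, >= 0).
#' @param buffers list of buffers, each a list with `btot` (uM) and `kd`
#'   (uM); an empty list means no buffering.
#' @return The buffering factor(s), same length as `ca`.
#' @examples
#' rapid_buffer_factor(0, list(list(btot = 100, kd = 1)))  # 1/101
#' rapid_buffer_factor(1, list())                          # 1
#' @export
rapid_buffer_factor <- function(ca, buffers) {
  if (any(!is.finite(ca)) || any(ca < 0)) {
    stop("ca must be finite and non-negative")
  }
  denom <- rep(1, length(ca))
  for (b in buffers) {
    denom <- denom + b$btot * b$kd / (b$kd + ca)^2
  }
  1 / denom
}

#' Write / read a parameter set as JSON
#'
#' Parameter files are plain JSON with a `schema_version` field; reading
#' re-validates all invariants.
#'
#' @param params a `model_parameters` object.
#' @param path file path.
#' @return `read_parameters` returns a validated `model_parameters`
#'   object; `write_parameters` returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version)) stop("not a parameter file: missing schema_version")
  p$geometry$n_cru <- as.integer(p$geometry$n_cru)
  p$geometry$n_cru_full <- as.integer(p$geometry$n_cru_full)
  p$geometry$n_ryr_per_cru <- as.integer(p$geometry$n_ryr_per_cru)
  p$geometry$n_lcc_per_cru <- as.integer(p$geometry$n_lcc_per_cru)
  class(p) <- "model_parameters"
  validate_parameters(p)
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  g <- x$geometry
  cat("<model_parameters> scenario:", x$scenario, "\n")
  cat(sprintf("  %d CRUs (%d full scale), %d RyR2 + %d L-type channels each\n",
              g$n_cru, g$n_cru_full, g$n_ryr_per_cru, g$n_lcc_per_cru))
  cat(sprintf("  phi_m = %.4g /uM, phi_b = %.3g, P_dhpr = %.3g cm^3/s\n",
              x$channels$phi_m, x$channels$phi_b, x$channels$p_dhpr))
  cat(sprintf("  SERCA Ap = %.3g uM, vcycle_max = %.3g /ms; CASQ btot = %.4g uM\n",
              x$pumps$serca$ap, x$pumps$serca$vcycle_max, x$buffers$casq$btot))
  invisible(x)
}
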