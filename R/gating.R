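# Stochastic Markov gating: the three-state RyR2 cluster, the six-state
# L-type channel, a fixed-step stochastic stepper and an exact
# Gillespie/SSA oracle used to validate it.
#
# State conventions:
#   RyR2 cluster  -- integer counts c(c1, o2, c3), c1 + o2 + c3 = 49.
#   L-type channel -- per-channel integer codes 1..6 for states
#                     C1, O2, O3, C4, C5, C6 (open set = {2, 3}), or the
#                     equivalent count vector (channels in the same state
#                     are exchangeable).
# Rate sets are square matrices (1/ms) whose [i, j] entry is the
# per-channel transition rate from state i to state j; only edges present
# in the channel diagrams are nonzero.

.RYR2_STATES <- c("C1", "O2", "C3")
.LCC_STATES  <- c("C1", "O2", "O3", "C4", "C5", "C6")

#' Luminal regulation function of the RyR2
#'
#' The opening rate of the RyR2 is multiplied by an affine function of
#' SR luminal free Ca2+: `Phi = phi_m * ca_sr + phi_b`.  The slope
#' `phi_m` is the luminal Ca2+ regulation coefficient that the
#' calsequestrin-null scenario increases by 90%.
#'
#' @param phi_m slope (1/uM), >= 0.
#' @param phi_b offset (dimensionless), >= 0.
#' @param ca_sr SR luminal free Ca2+ (uM, scalar or vector, >= 0).
#' @return `Phi` (dimensionless multiplier), same length as `ca_sr`.
#' @examples
#' luminal_phi(1.2e-3, 0.05, 800)
#' @export
luminal_phi <- function(phi_m, phi_b, ca_sr) {
  if (phi_m < 0 || phi_b < 0 || any(ca_sr < 0)) {
    stop("luminal_phi: phi_m, phi_b and ca_sr must be non-negative")
  }
  phi_m * ca_sr + phi_b
}

#' RyR2 cluster transition rates
#'
#' Per-channel rates of the three-state RyR2 chain at a frozen context.
#' Opening (C1 -> O2) is Hill-activated by dyadic subspace Ca2+ and
#' multiplied by the luminal regulation function of the junctional SR;
#' closing (O2 -> C1), adaptation (O2 -> C3) and recovery (C3 -> C1) are
#' constants from the parameter set.
#'
#' @param state integer cluster counts `c(c1, o2, c3)`.
#' @param ca_ds dyadic subspace Ca2+ (uM).
#' @param ca_jsr junctional SR free Ca2+ (uM).
#' @param channels the `channels` component of a parameter set.
#' @return A list with `per_channel` (3x3 rate matrix, 1/ms), `cluster`
#'   (matrix scaled by state occupancy) and `context`.
#' @export
ryr2_rates <- function(state, ca_ds, ca_jsr, channels) {
  stopifnot(length(state) == 3, all(state >= 0), ca_ds >= 0, ca_jsr >= 0)
  r <- channels$ryr2
  phi <- luminal_phi(channels$phi_m, channels$phi_b, ca_jsr)
  hill <- if (ca_ds > 0) {
    ca_ds^r$hill_ca_ds / (ca_ds^r$hill_ca_ds + r$k_ca^r$hill_ca_ds)
  } else 0
  q <- matrix(0, 3, 3, dimnames = list(.RYR2_STATES, .RYR2_STATES))
  q["C1", "O2"] <- phi * r$k_open_max * hill
  q["O2", "C1"] <- r$k_close
  q["O2", "C3"] <- r$k_adapt
  q["C3", "C1"] <- r$k_recover
  list(per_channel = q, cluster = q * as.numeric(state),
       context = list(ca_ds = ca_ds, ca_jsr = ca_jsr))
}

#' L-type channel transition rates
#'
#' Per-channel rates of the six-state L-type Ca2+ channel chain at a
#' frozen membrane potential and subspace Ca2+.  Activation (C1 -> O2) and
#' deactivation are Boltzmann functions of voltage; the two open states
#' interconvert (O2 <-> O3); inactivation is either voltage dependent
#' (O2 -> C5) or Ca2+ dependent (O2 -> C4, rate linear in subspace Ca2+);
#' C6 is a deep closed state entered from C1 at strong depolarisation with
#' slow recovery at rest.
#'
#' @param state per-channel state codes (integer vector, values 1..6) or a
#'   length-6 count vector; only used for validation.
#' @param v membrane potential (mV).
#' @param ca_ds dyadic subspace Ca2+ (uM).
#' @param channels the `channels` component of a parameter set.
#' @return A list with `per_channel` (6x6 rate matrix, 1/ms) and `context`.
#' @export
lcc_rates <- function(state, v, ca_ds, channels) {
  stopifnot(is.finite(v), ca_ds >= 0)
  l <- channels$lcc
  q <- matrix(0, 6, 6, dimnames = list(.LCC_STATES, .LCC_STATES))
  rest <- 1 / (1 + exp((v + 40) / 6))  # ~1 polarised, ~0 depolarised
  q["C1", "O2"] <- l$act_max / (1 + exp(-(v - l$v_act) / l$k_act))
  q["O2", "C1"] <- l$deact_max / (1 + exp((v - l$v_deact) / l$k_deact))
  q["O2", "O3"] <- l$f_oo
  q["O3", "O2"] <- l$g_oo
  q["O2", "C4"] <- min(l$ca_inact_slope * ca_ds,
                       l$ca_inact_max %||% Inf)
  q["C4", "C1"] <- l$ca_inact_recover
  q["O2", "C5"] <- l$v_inact_max / (1 + exp(-(v - l$v_inact_vhalf) / l$v_inact_k))
  q["C5", "C1"] <- l$v_inact_recover * rest
  q["C1", "C6"] <- l$c6_entry_max / (1 + exp(-(v - l$c6_vhalf) / l$c6_k))
  q["C6", "C1"] <- l$c6_recover * rest
  list(per_channel = q, context = list(v = v, ca_ds = ca_ds))
}

#' Fixed-step stochastic update of a channel ensemble
#'
#' Advances an ensemble of identical Markov channels by one time step with
#' the frozen-rate scheme used by the simulation engine: each channel
#' leaves its state with probability `1 - exp(-k_exit * dt)` and the
#' destination is drawn proportionally to the outgoing rates.  Channels in
#' the same state are exchangeable, so the update samples aggregated
#' binomial/multinomial counts.  Channel number is conserved.  Determinism
#' follows R's RNG: the same `set.seed()` state, arguments included,
#' reproduces the same output.
#'
#' @param state either an integer count vector over states (length =
#'   number of states) or a per-channel state-code vector (values in
#'   `1..nrow(rates)`), selected by `per_channel`.
#' @param rates square rate matrix (1/ms), `rates[i, j]` the per-channel
#'   rate from state i to state j.
#' @param dt time step (ms); per-channel total exit rate times `dt` must
#'   not exceed 0.1 (otherwise an error asks for substepping).
#' @param per_channel if `TRUE`, `state` is a per-channel code vector and
#'   a per-channel vector is returned; otherwise counts in, counts out.
#' @return Updated state in the same representation.
#' @export
step_channels <- function(state, rates, dt, per_channel = FALSE) {
  stopifnot(is.matrix(rates), nrow(rates) == ncol(rates), dt > 0,
            all(rates >= 0))
  k <- nrow(rates)
  diag(rates) <- 0
  exit <- rowSums(rates)
  if (max(exit) * dt > 0.1) {
    stop(sprintf(paste0("step_channels: dt = %g ms is too large for the ",
                        "largest exit rate %g /ms (exit*dt must be <= 0.1); ",
                        "substep the interval"), dt, max(exit)))
  }
  counts <- if (per_channel) {
    stopifnot(all(state %in% seq_len(k)))
    tabulate(state, nbins = k)
  } else {
    stopifnot(length(state) == k, all(state >= 0))
    as.integer(state)
  }
  new_counts <- counts
  moves <- vector("list", k)
  for (i in seq_len(k)) {
    if (counts[i] == 0 || exit[i] == 0) next
    p_leave <- 1 - exp(-exit[i] * dt)
    n_leave <- stats::rbinom(1, counts[i], p_leave)
    if (n_leave == 0) next
    dest <- stats::rmultinom(1, n_leave, rates[i, ] / exit[i])[, 1]
    new_counts[i] <- new_counts[i] - n_leave
    new_counts <- new_counts + dest
    moves[[i]] <- dest
  }
  if (!per_channel) return(new_counts)
  # re-materialise a per-channel vector consistent with the sampled moves
  out <- state
  for (i in seq_len(k)) {
    dest <- moves[[i]]
    if (is.null(dest)) next
    idx <- which(state == i)
    movers <- if (length(idx) > 1) sample(idx, sum(dest)) else idx[seq_len(sum(dest))]
    out[movers] <- rep(seq_len(k), dest)
  }
  out
}

#' Exact stochastic simulation (Gillespie) of a channel ensemble
#'
#' Statistically exact jump trajectory of the same Markov chain the
#' fixed-step engine integrates, used as the validation oracle.  Rates may
#' be a constant matrix or a function `function(counts, t)` returning one
#' (rates must be piecewise constant between jumps).
#'
#' @param state initial integer count vector over states.
#' @param rates square rate matrix (1/ms) or a function of `(counts, t)`.
#' @param t_end end time (ms).
#' @return A data.frame with columns `time` and one count column per
#'   state; the first row is the initial state at time 0, subsequent rows
#'   are the post-jump states.  A chain with zero total propensity stays
#'   constant (single jump-free trajectory).
#' @export
gillespie_exact <- function(state, rates, t_end) {
  stopifnot(all(state >= 0), t_end > 0)
  counts <- as.integer(state)
  k <- length(counts)
  get_q <- if (is.function(rates)) rates else function(counts, t) rates
  times <- 0
  traj <- list(counts)
  t <- 0
  repeat {
    q <- get_q(counts, t)
    diag(q) <- 0
    a <- q * counts          # propensity of each (from, to) move
    a_tot <- sum(a)
    if (a_tot == 0) break
    t <- t + stats::rexp(1, a_tot)
    if (t >= t_end) break
    mv <- sample.int(k * k, 1, prob = as.vector(a))
    from <- (mv - 1) %% k + 1
    to <- (mv - 1) %/% k + 1
    counts[from] <- counts[from] - 1L
    counts[to] <- counts[to] + 1L
    times <- c(times, t)
    traj[[length(traj) + 1]] <- counts
  }
  out <- as.data.frame(do.call(rbind, traj))
  names(out) <- if (!is.null(names(state))) names(state) else paste0("s", seq_len(k))
  cbind(time = times, out)
}

#' Stationary distribution of a single-channel Markov chain
#'
#' Solves the stationary linear system `pi Q = 0`, `sum(pi) = 1` for the
#' chain defined by a rate matrix.  Used as the analytic oracle for the
#' long-run occupancy of the stochastic steppers.
#'
#' @param rates square rate matrix (1/ms).
#' @return Named stationary probability vector.
#' @examples
#' q <- matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE)
#' stationary_distribution(q)  # 2/3, 1/3
#' @export
stationary_distribution <- function(rates) {
  k <- nrow(rates)
  q <- rates
  diag(q) <- 0
  gen <- t(q)
  diag(gen) <- -rowSums(q)
  a <- rbind(gen, rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(a, b)
  names(pi) <- rownames(rates)
  pi
}

#' Stationary RyR2 open probability at a frozen context
#'
#' Convenience oracle: stationary probability of the open state of the
#' three-state RyR2 chain at fixed dyadic-subspace and junctional-SR Ca2+.
#'
#' @inheritParams ryr2_rates
#' @return Stationary open probability (scalar).
#' @export
ryr2_open_probability <- function(ca_ds, ca_jsr, channels) {
  q <- ryr2_rates(c(1L, 0L, 0L), ca_ds, ca_jsr, channels)$per_channel
  unname(stationary_distribution(q)["O2"])
}
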