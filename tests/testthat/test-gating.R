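# Markov gating: luminal regulation, rate construction, the fixed-step
# stepper and its exact-SSA oracle.

test_that("luminal regulation function is affine with the advertised slope", {
  expect_equal(luminal_phi(0, 0.7, c(0, 100, 5000)), rep(0.7, 3))
  phi_m <- 1.2e-3
  ca <- c(50, 400, 800, 1600)
  expect_equal(luminal_phi(phi_m, 0.02, 2 * ca) - luminal_phi(phi_m, 0.02, ca),
               phi_m * ca)
  # the mutant multiplies phi_m by 1.9, so the shift is 0.9 * phi_m * ca
  expect_equal(luminal_phi(1.9 * phi_m, 0.02, ca) - luminal_phi(phi_m, 0.02, ca),
               0.9 * phi_m * ca)
  expect_error(luminal_phi(-1, 0, 1), "non-negative")
  expect_error(luminal_phi(1, 1, -5), "non-negative")
})

test_that("RyR2 rates: closed channels stay closed without dyad Ca", {
  ch <- default_parameters()$channels
  r0 <- ryr2_rates(c(49L, 0L, 0L), ca_ds = 0, ca_jsr = 800, channels = ch)
  expect_equal(r0$per_channel["C1", "O2"], 0)
  # only the diagram edges are nonzero
  r1 <- ryr2_rates(c(40L, 5L, 4L), ca_ds = 20, ca_jsr = 800, channels = ch)
  q <- r1$per_channel
  nz <- which(q > 0, arr.ind = TRUE)
  edges <- paste(rownames(q)[nz[, 1]], colnames(q)[nz[, 2]])
  expect_setequal(edges, c("C1 O2", "O2 C1", "O2 C3", "C3 C1"))
  # cluster rates scale with occupancy
  expect_equal(r1$cluster["C1", "O2"], 40 * q["C1", "O2"])
  # opening rate increases with luminal Ca at fixed dyad Ca
  r2 <- ryr2_rates(c(49L, 0L, 0L), 20, 1600, ch)
  expect_gt(r2$per_channel["C1", "O2"], q["C1", "O2"])
})

test_that("stationary RyR2 open probability scales near-linearly with luminal Ca", {
  ch <- default_parameters()$channels
  # operating point chosen in the linear (unsaturated) response regime:
  # at low dyad Ca the adaptation sink has not saturated the chain, so
  # Po tracks the luminal factor nearly proportionally
  po1 <- ryr2_open_probability(ca_ds = 2, ca_jsr = 700, ch)
  po2 <- ryr2_open_probability(ca_ds = 2, ca_jsr = 1400, ch)
  ratio <- po2 / po1
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.05)
  # monotone in ca_jsr across a grid (luminal regulation monotonicity)
  pos <- vapply(seq(100, 2000, by = 100), function(cj)
    ryr2_open_probability(2, cj, ch), numeric(1))
  expect_true(all(diff(pos) > 0))
})

test_that("stationary distribution solver matches the 2-state closed form", {
  q <- matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("C", "O"), c("C", "O")))
  expect_equal(unname(stationary_distribution(q)), c(2 / 3, 1 / 3))
})

test_that("long-run stepper occupancy matches the analytic stationary law", {
  ch <- default_parameters()$channels
  q <- ryr2_rates(c(1L, 0L, 0L), ca_ds = 12, ca_jsr = 800, ch)$per_channel
  pi_exact <- stationary_distribution(q)
  set.seed(42)
  dt <- 0.1
  n_ch <- 49L
  burn <- 2000L
  n_keep <- 20000L
  state <- c(n_ch, 0L, 0L)
  occ <- numeric(3)
  for (i in seq_len(burn + n_keep)) {
    state <- step_channels(state, q, dt)
    if (i > burn) occ <- occ + state
  }
  occ <- occ / (n_keep * n_ch)
  # generous band: autocorrelated time average over 2000 ms x 49 channels
  expect_equal(unname(occ), unname(pi_exact), tolerance = 0.15)
  expect_lt(max(abs(occ - pi_exact)), 0.02)
})

test_that("L-type rates: Ca-dependent inactivation and resting closure", {
  ch <- default_parameters()$channels
  q0 <- lcc_rates(rep(1L, 14), v = 0, ca_ds = 0, ch)$per_channel
  expect_equal(q0["O2", "C4"], 0)
  # strictly increasing in ca_ds up to the saturation cap
  cas <- c(1, 10, 50, 200)
  r_inact <- vapply(cas, function(ca)
    lcc_rates(rep(1L, 14), 0, ca, ch)$per_channel["O2", "C4"], numeric(1))
  expect_true(all(diff(r_inact) > 0))
  expect_lte(max(r_inact), ch$lcc$ca_inact_max)
  # resting potential: stationary open probability < 1e-3
  qrest <- lcc_rates(rep(1L, 14), -85, 0.1, ch)$per_channel
  pi <- stationary_distribution(qrest)
  expect_lt(pi["O2"] + pi["O3"], 1e-3)
})

test_that("step_channels conserves channels, is deterministic, and caps dt", {
  ch <- default_parameters()$channels
  q <- ryr2_rates(c(1L, 0L, 0L), 12, 800, ch)$per_channel
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:49, 3, replace = TRUE)
    s2 <- step_channels(n, q, 0.1)
    expect_identical(sum(s2), sum(n))
    expect_true(all(s2 >= 0))
  }
  # zero rates: state unchanged
  expect_identical(step_channels(c(10L, 5L, 34L), matrix(0, 3, 3), 1),
                   c(10L, 5L, 34L))
  # determinism under the same seed
  set.seed(123)
  a <- replicate(20, step_channels(c(30L, 10L, 9L), q, 0.1))
  set.seed(123)
  b <- replicate(20, step_channels(c(30L, 10L, 9L), q, 0.1))
  expect_identical(a, b)
  # per-channel representation conserves the ensemble too
  set.seed(11)
  pc <- step_channels(rep(1L, 14), lcc_rates(rep(1L, 14), 0, 5, ch)$per_channel,
                      0.05, per_channel = TRUE)
  expect_length(pc, 14)
  expect_true(all(pc %in% 1:6))
  expect_error(step_channels(c(49L, 0L, 0L), q * 100, 1), "substep")
})

test_that("fixed-step occupancy matches exact SSA on a 2-state toy", {
  # k12 = 1/ms, k21 = 2/ms: stationary open fraction 1/3
  q <- matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE)
  set.seed(17)
  dt <- 0.03
  state <- c(1L, 0L)
  thin <- 150          # 4.5 ms between kept samples >> mixing time (1/3 ms)
  kept <- integer(0)
  for (i in 1:300000) {
    state <- step_channels(state, q, dt)
    if (i %% thin == 0) kept <- c(kept, state[2])
  }
  n_open <- sum(kept)
  n_tot <- length(kept)
  # exact occupancy from the SSA-equivalent stationary law
  chi <- stats::chisq.test(c(n_open, n_tot - n_open), p = c(1 / 3, 2 / 3))
  expect_gt(chi$p.value, 0.01)
})

test_that("gillespie_exact: absorption, dwell-time mean, refinement limit", {
  # single absorbing state: no jumps after absorption
  q_abs <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  set.seed(1)
  traj <- gillespie_exact(c(1L, 0L), q_abs, t_end = 50)
  expect_equal(nrow(traj), 2)             # initial state + one jump
  expect_equal(unlist(traj[2, -1], use.names = FALSE), c(0, 1))

  # exponential dwell time with k = 1/ms has mean 1 ms
  set.seed(2)
  dwell <- replicate(4000, {
    tr <- gillespie_exact(c(1L, 0L), q_abs, t_end = 100)
    tr$time[2]
  })
  se <- stats::sd(dwell) / sqrt(length(dwell))
  expect_lt(abs(mean(dwell) - 1), 3 * se)

  # first-opening time of the 3-state RyR2: fixed-step engine at small dt
  # agrees in distribution with the SSA (KS test)
  ch <- default_parameters()$channels
  q <- ryr2_rates(c(1L, 0L, 0L), 15, 800, ch)$per_channel
  first_open_ssa <- function() {
    tr <- gillespie_exact(c(C1 = 1L, O2 = 0L, C3 = 0L), q, t_end = 500)
    i <- which(tr$O2 == 1)[1]
    if (is.na(i)) NA_real_ else tr$time[i]
  }
  first_open_step <- function(dt) {
    s <- c(1L, 0L, 0L)
    for (i in 1:200000) {
      s <- step_channels(s, q, dt)
      if (s[2] == 1L) return(i * dt)
    }
    NA_real_
  }
  set.seed(3)
  ssa <- replicate(300, first_open_ssa())
  stp <- replicate(300, first_open_step(0.05))
  ks <- suppressWarnings(stats::ks.test(ssa, stp))
  expect_gt(ks$p.value, 0.01)
})
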