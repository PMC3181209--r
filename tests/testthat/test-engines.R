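test_that("with all reactions silent the volume grows exponentially", {
  # zero every rate constant; keep growth
  zero <- as.list(setNames(rep(0, 17), c(
    "k_sMR", "k_sR", "k_2R", "k_m2R", "k_r", "k_mr", "k_dr1", "k_mdr1",
    "k_dr2", "k_mdr2", "k_s1MY", "k_s0MY", "k_sY", "k_p", "k_mp", "k_ft",
    "h_t")))
  p <- do.call(lac_params, zero)
  init <- cell_state(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0), V = 0.3,
                     mode = "stochastic")
  set.seed(21)
  ch <- simulate_cell_stochastic(init, 20, p, sample_times = seq(0, 20, 2))
  expect_equal(ch$samples$V_fL, 0.3 * exp(p$g * ch$samples$time_min),
               tolerance = 1e-12)
  expect_true(all(ch$samples[, species_names()] ==
                  rep(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0),
                      each = nrow(ch$samples))))
})

test_that("frozen-volume SSA reproduces birth-death first moments", {
  # pure birth-death of lacI mRNA: 0 -> MR at k_sMR*Omega, MR -> 0 at lambda
  zero <- as.list(setNames(rep(0, 16), c(
    "k_sR", "k_2R", "k_m2R", "k_r", "k_mr", "k_dr1", "k_mdr1",
    "k_dr2", "k_mdr2", "k_s1MY", "k_s0MY", "k_sY", "k_p", "k_mp", "k_ft",
    "h_t")))
  p <- do.call(lac_params, c(zero, list(k_sMR = 40, lambda_MR = 0.8,
                                        g = 1e-12)))
  V <- 2
  mean_expected <- 40 * molecules_per_nM(V) / 0.8   # ~60 copies
  init <- cell_state(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0), V = V,
                     mode = "stochastic")
  set.seed(22)
  ch <- simulate_cell_stochastic(init, 800, p,
                                 sample_times = seq(50, 800, 1))
  m <- mean(ch$samples$MR)
  # Poisson stationary distribution: SD/sqrt(n_eff) with tau ~ 1/lambda
  se <- sqrt(mean_expected) / sqrt(750 * 0.8 / 2)
  expect_lt(abs(m - mean_expected), 4 * se)
})

test_that("refresh-interval halving leaves summary statistics unchanged", {
  p <- nominal_params(I_ex = 10e3)
  init <- attractor_state("off", 10e3, p, mode = "stochastic")
  run_mean <- function(refresh_dt, seed) {
    set.seed(seed)
    ch <- simulate_cell_stochastic(init, 120, p,
                                   sample_times = seq(20, 120, 2),
                                   refresh_dt = refresh_dt)
    mean(ch$samples$I)
  }
  coarse <- vapply(1:4, function(s) run_mean(0.5, s), numeric(1))
  fine <- vapply(5:8, function(s) run_mean(0.125, s), numeric(1))
  se <- sqrt(stats::var(coarse) / 4 + stats::var(fine) / 4)
  expect_lt(abs(mean(coarse) - mean(fine)), 4 * se + 0.01 * mean(coarse))
})

test_that("SSA converges to the hybrid ODE solution in the large-volume limit", {
  # every copy number, the operator pool included, is scaled 100x with the
  # volume; concentrations must then follow the deterministic rate
  # equations up to O(1/sqrt(Omega)) fluctuations. The comparison is run
  # in the monostable uninduced regime, where the limit theorem applies
  # cleanly (inside the bistable window metastable excursions make
  # single-trajectory convergence slow); observables are time-averaged
  # and replicate-averaged, with tolerances a few times the remaining
  # Monte Carlo error.
  p0 <- nominal_params(I_ex = 0)
  ps <- lac_params_update(p0, V_s_crit = 1e5, V_d_crit = 2e5)
  off <- attractor_state("off", 0, p0, mode = "deterministic")
  V0 <- 0.75 * 100
  Om <- molecules_per_nM(V0)
  x0 <- pmax(round(off$x * Om), 0)
  conc0 <- x0 / Om
  st <- seq(5, 100, 1)
  pv <- lacpop:::.param_vector(ps)
  set.seed(31)
  ssa <- replicate(4, {
    r <- lacpop:::.ssa_cell(x0, V0, TRUE, 0, 100, pv, st, 0.5)
    m <- r$samples[seq_len(r$n_samples), ]
    om_t <- molecules_per_nM(m[, 2])
    c(MR = mean(m[, 3] / om_t), R2 = mean(m[, 5] / om_t),
      YT = mean((m[, 11] + m[, 12]) / om_t))
  })
  ode <- lacpop:::.cell_hybrid(conc0, V0, TRUE, 0, 100, ps, st)
  sm <- ode$samples
  ref <- c(MR = mean(sm[, 3]), R2 = mean(sm[, 5]),
           YT = mean(sm[, 11] + sm[, 12]))
  got <- rowMeans(ssa)
  expect_lt(abs(got["MR"] - ref["MR"]) / ref["MR"], 0.08)
  expect_lt(abs(got["R2"] - ref["R2"]) / ref["R2"], 0.06)
  expect_lt(abs(got["YT"] - ref["YT"]) / ref["YT"], 0.12)
})

test_that("hybrid engine: promoter sawtooth, continuity and conservation", {
  p <- nominal_params(I_ex = 24e3)
  off <- attractor_24("off", "deterministic")
  set.seed(41)
  ch <- simulate_cell_deterministic(off, 120, p,
                                    sample_times = seq(0, 120, 0.5))
  s <- ch$samples
  ot <- s$O + s$R2O
  # between events total operator amount (conc * V) is exactly 1 or 2 copies
  amt <- ot * molecules_per_nM(s$V_fL)
  expect_true(all(abs(amt - round(amt)) < 1e-4))
  expect_true(all(round(amt) %in% c(1, 2)))
  # concentration decays as 1/V between events: amount is constant there
  t_dup <- ch$duplication_times[1]
  pre <- s$time_min < t_dup
  expect_equal(stats::sd(amt[pre]) / mean(amt[pre]), 0, tolerance = 1e-6)
  # duplication doubles the operator concentration (pre-existing unit free
  # or bound, the amount jumps from 1 to 2 copies)
  expect_equal(round(amt[which(!pre)[1]]), 2)
})

test_that("hybrid division with symmetric split leaves concentrations continuous", {
  p <- nominal_params(I_ex = 24e3)
  off <- attractor_24("off", "deterministic")
  set.seed(42)
  ch <- simulate_cell_deterministic(
    off, 80, p, sample_times = seq(0, 80, 0.25), policy = "first",
    interventions = list(
      intervention_asymmetric_division(1, 0.5, follow = "d1")))
  t_div <- ch$division_times[1]
  s <- ch$samples
  before <- max(which(s$time_min < t_div))
  after <- min(which(s$time_min >= t_div))
  # 0.25-min sampling: concentrations move by < ~1% across the division
  expect_equal(s$Y_total_nM[after], s$Y_total_nM[before], tolerance = 0.02)
  expect_equal(s$O[after] + s$R2O[after], s$O[before] + s$R2O[before],
               tolerance = 0.02)
  # volume halves exactly at the forced symmetric division
  expect_equal(ch$division_volumes[1] / 2, s$V_fL[after],
               tolerance = 0.01)
})

test_that("interventions override exactly one division", {
  p <- nominal_params(I_ex = 24e3)
  off <- attractor_24("off", "deterministic")
  set.seed(43)
  ch <- simulate_cell_deterministic(
    off, 100, p, sample_times = seq(0, 100, 1),
    interventions = list(
      intervention_asymmetric_division(1, 0.15, follow = "smaller")))
  # followed daughter has 15% of the mother volume
  s <- ch$samples
  t_div <- ch$division_times[1]
  after <- min(which(s$time_min > t_div))
  expect_equal(s$V_fL[after],
               0.15 * ch$division_volumes[1] * exp(p$g * (s$time_min[after] - t_div)),
               tolerance = 1e-6)
  # delayed division: division occurs exactly `delay` after duplication
  set.seed(44)
  ch2 <- simulate_cell_deterministic(
    attractor_24("on", "deterministic"), 200, p,
    sample_times = seq(0, 200, 5),
    interventions = list(intervention_delayed_division(1, 50)))
  expect_equal(ch2$division_times[1] - ch2$duplication_times[1], 50,
               tolerance = 1e-9)
  expect_error(intervention_asymmetric_division(1, 1.2), "ratio")
  expect_error(intervention_delayed_division(1, -5), "delay")
})

test_that("compiled and R rate equations agree (dual-route check)", {
  p <- nominal_params(I_ex = 24e3)
  AoV <- estimate_A_over_V(p); OT <- estimate_O_T(p)
  init <- lacpop:::.continuum_init(OT, high = FALSE)
  times <- seq(0, 150, 5)
  compiled <- continuum_trajectory(times, p, AoV, OT, init = init)
  rfun <- function(t, y, parms) {
    list(ode_rhs(y, p, A_over_V = AoV, dilution_rate = p$g,
                 operator_dilution = FALSE))
  }
  rref <- deSolve::lsoda(init, times, rfun, parms = NULL,
                         rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(compiled[, 2:11]), unname(rref[, 2:11]),
               tolerance = 1e-6)
})
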