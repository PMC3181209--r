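test_that("cycle-average estimators: closed form equals quadrature", {
  p <- nominal_params()
  expect_equal(estimate_A_over_V(p), estimate_A_over_V(p, "quadrature"),
               tolerance = 1e-10)
  expect_equal(estimate_O_T(p), estimate_O_T(p, "quadrature"),
               tolerance = 1e-10)
})

test_that("estimator limits and invariances", {
  p <- nominal_params()
  # sphere-free limit: very large division volume leaves only the
  # cylinder-wall contribution 2/R0
  p_big <- lac_params(V_d_crit = 1e9, V_s_crit = 0.9e9)
  expect_equal(estimate_A_over_V(p_big), 2 / p$R0, tolerance = 1e-6)
  # operator estimate is independent of V_d_crit at fixed V_s_crit
  e1 <- estimate_O_T(lac_params(V_d_crit = 1.5))
  e2 <- estimate_O_T(lac_params(V_d_crit = 1.9))
  expect_equal(e1, e2, tolerance = 1e-12)
  # duplication at birth: whole cycle at 2 copies; closed form continues to
  # hold right down to the boundary V_s_crit -> V_d_crit/2
  p_edge <- lac_params(V_s_crit = 0.750001, V_d_crit = 1.5)
  expect_equal(estimate_O_T(p_edge), estimate_O_T(p_edge, "quadrature"),
               tolerance = 1e-6)
  expect_error(estimate_O_T(lac_params(V_s_crit = 0.7, V_d_crit = 1.5)))
})

test_that("continuum RHS: constitutive source and state guard", {
  p <- nominal_params()
  OT <- estimate_O_T(p)
  x0 <- rep(0, 10); x0[4] <- OT
  d <- continuum_rhs(x0, p, 5.7, OT)
  expect_equal(unname(d[1]), 0.23)
  bad <- x0; bad[5] <- OT * 1.5; bad[4] <- 0
  expect_error(continuum_rhs(bad, p, 5.7, OT), "state error")
})

test_that("switch is bistable at 24 uM and monostable at 0 and 60 uM", {
  p <- nominal_params()
  ss24 <- continuum_steady_states(24e3, p)
  expect_equal(nrow(ss24), 3)
  expect_equal(sum(ss24$stable), 2)
  expect_false(ss24$stable[2])                 # middle state is the saddle
  expect_true(all(diff(ss24$Y_total_nM) > 0))
  ss0 <- continuum_steady_states(0, p)
  expect_equal(nrow(ss0), 1)
  expect_true(ss0$stable)
  expect_lt(ss0$Y_total_nM, 20)                # repressed branch
  ss60 <- continuum_steady_states(60e3, p)
  expect_equal(nrow(ss60), 1)
  expect_true(ss60$stable)
  expect_gt(ss60$Y_total_nM, 200)              # induced branch
})

test_that("bifurcation scan forms an S with a bistable window", {
  p <- nominal_params()
  scan <- fixture("bif_scan", function()
    bifurcation_scan(seq(14e3, 40e3, by = 2e3), p))
  win <- attr(scan, "bistable_window")
  expect_false(is.null(win))
  expect_true(win[1] <= 24e3 && 24e3 <= win[2])
  # on the bistable grid points: 2 stable branches bracketing the saddle
  at24 <- scan[scan$I_ex_nM == 24e3, ]
  expect_equal(nrow(at24), 3)
  expect_equal(sum(at24$stable), 2)
})

test_that("repressor association rescaling preserves the bifurcation diagram", {
  # slower repressor-operator kinetics with the equilibrium constant held
  # fixed leave all steady states unchanged
  p <- nominal_params()
  p_slow <- lac_params(k_r = 0.6, k_mr = 2.4 * 0.6 / 960)
  for (iex in c(18e3, 24e3, 30e3)) {
    a <- continuum_steady_states(iex, p)
    b <- continuum_steady_states(iex, p_slow)
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$Y_total_nM, b$Y_total_nM, tolerance = 1e-4)
    expect_equal(a$stable, b$stable)
  }
})

test_that("attractor states are steady under the continuum flow", {
  p <- nominal_params(24e3)
  off <- attractor_24("off", "deterministic")
  on <- attractor_24("on", "deterministic")
  expect_lt(off$x[9] + off$x[10], 20)
  expect_gt(on$x[9] + on$x[10], 150)
  # stochastic conversion: integer copies, one operator unit
  s_off <- attractor_24("off", "stochastic")
  expect_true(all(s_off$x == round(s_off$x)))
  expect_equal(s_off$x[4] + s_off$x[5], 1)
})
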