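test_that("the reaction scheme has 25 reactions over 10 species", {
  rt <- reaction_table()
  expect_equal(nrow(rt), 25)
  expect_equal(length(species_names()), 10)
  S <- stoichiometry_matrix()
  expect_equal(dim(S), c(10, 25))
})

test_that("stoichiometry columns and chromosomal-unit conservation", {
  S <- stoichiometry_matrix()
  expect_equal(unname(S[, 3]), c(0, -2, 1, 0, 0, 0, 0, 0, 0, 0))
  # operator units are never created or destroyed by reactions
  expect_equal(unname(colSums(S[c("O", "R2O"), ])), rep(0, 25))
  # YIex -> Y + I returns both carrier and inducer
  x <- c(0, 0, 0, 1, 0, 0, 0, 0, 0, 1)
  expect_equal(unname(x + S[, 16]), c(0, 0, 0, 1, 0, 1, 0, 0, 1, 0))
  # closed repression/derepression cycle has zero net stoichiometry
  expect_equal(unname(S[, 5] + S[, 7] + S[, 8] + S[, 6]), rep(0, 10))
})

test_that("propensity functions match hand-computed values", {
  p <- nominal_params()
  a <- propensities(rep(0, 10), 1, p)
  expect_equal(a[1], 0.23 * molecules_per_nM(1))
  expect_equal(a[1], 0.1385, tolerance = 1e-3)
  expect_equal(sum(a[-1] > 0), 0)   # I_ex = 0: only constitutive source
  # identical-pair combinatorics for dimerisation
  x <- c(0, 2, 0, 1, 0, 0, 0, 0, 0, 0)
  a <- propensities(x, 1, p)
  expect_equal(a[3], 50 * 2 * 1 / molecules_per_nM(1))
  expect_equal(a[3], 166.05, tolerance = 1e-4)
  # a single inducer molecule cannot fire the bimolecular-inducer steps
  x <- c(0, 0, 5, 0, 1, 1, 0, 0, 0, 0)
  a <- propensities(x, 1, p)
  expect_equal(a[7], 0)
  expect_equal(a[9], 0)
  expect_error(propensities(c(-1, rep(0, 9)), 1, p), "state corruption")
})

test_that("deterministic rates are the large-volume limit of the propensities", {
  p <- nominal_params(I_ex = 24e3)
  conc <- c(0.5, 2, 8, 1.2, 1.2, 3e4, 12, 0.3, 40, 2)
  # independent mass-action rate table (nM/min), one entry per reaction
  det_rates <- with(p, c(
    k_sMR, k_sR * conc[1], k_2R * conc[2]^2, k_m2R * conc[3],
    k_r * conc[3] * conc[4], k_mr * conc[5],
    k_dr1 * conc[6]^2 * conc[5], k_mdr2 * conc[7] * conc[4],
    k_dr2 * conc[6]^2 * conc[3], k_mdr1 * conc[7],
    k_s1MY * conc[4], k_s0MY * conc[5], k_sY * conc[8],
    k_p * I_ex * conc[9], k_mp * conc[10], k_ft * conc[10],
    ht_um * (area_from_volume(1e5, R0) / 1e5) * I_ex,
    ht_um * (area_from_volume(1e5, R0) / 1e5) * conc[6],
    lambda_MR * conc[1], lambda_MY * conc[8], lambda_R * conc[2],
    lambda_R2 * conc[3], lambda_Y * conc[9], lambda_YIex * conc[10],
    lambda_I2R2 * conc[7]))
  V <- 1e5                       # large volume: ~6e4 molecules per nM
  Om <- molecules_per_nM(V)
  x <- round(conc * Om)
  a <- propensities(x, V, p)
  expect_equal(a / Om, det_rates, tolerance = 2e-4)
})

test_that("rate equations: constitutive source, lacI mRNA balance, dilution", {
  p <- nominal_params()
  d <- ode_rhs(rep(0, 10), p, A_over_V = 5.7, dilution_rate = p$g)
  expect_equal(unname(d[1]), 0.23)
  expect_equal(unname(d[-1]), rep(0, 9))
  # decoupled lacI mRNA steady state k_sMR / (lambda_MR + g)
  mr_ss <- 0.23 / (0.462 + 0.0231)
  expect_equal(mr_ss, 0.4741, tolerance = 1e-4)
  cc <- c(mr_ss, rep(0, 9))
  expect_equal(unname(ode_rhs(cc, p, 5.7, p$g)[1]), 0, tolerance = 1e-12)
})

test_that("repression/derepression cycle closes thermodynamically", {
  p <- nominal_params()
  # (k_r/k_-r) (k_dr1/k_-dr2) = (k_dr2/k_-dr1) exactly at the defaults
  lhs <- (p$k_r / p$k_mr) * (p$k_dr1 / p$k_mdr2)
  rhs <- p$k_dr2 / p$k_mdr1
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_equal(lhs, 2.5e-8, tolerance = 1e-12)
})

test_that("O + R2O is preserved by the deterministic rates", {
  p <- nominal_params(I_ex = 24e3)
  set.seed(7)
  for (i in 1:5) {
    cc <- stats::runif(10, 0, 10); cc[6] <- stats::runif(1, 0, 1e5)
    d <- ode_rhs(cc, p, 5.7, dilution_rate = 0)
    expect_equal(unname(d[4] + d[5]), 0, tolerance = 1e-9)
  }
})
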