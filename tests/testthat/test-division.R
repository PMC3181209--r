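test_that("duplication and division hazards follow the power law", {
  p <- nominal_params()
  expect_equal(duplication_hazard(p$V_s_crit, p), p$g * p$n_s)
  expect_equal(p$g * p$n_s, 0.5775, tolerance = 1e-10)
  expect_equal(duplication_hazard(0.5 * p$V_s_crit, p),
               0.5775 * 0.5^25, tolerance = 1e-6)
  V <- seq(0.4, 2, length.out = 50)
  expect_true(all(diff(duplication_hazard(V, p)) > 0))
  expect_equal(division_hazard(p$V_d_crit, p, duplicated = TRUE),
               p$g * p$n_d)
  expect_equal(division_hazard(5, p, duplicated = FALSE), 0)
})

test_that("closed-form event-time sampler inverts the cumulative hazard", {
  p <- nominal_params()
  # u -> 1 gives an immediate event
  expect_lt(sample_event_time(0.9, "duplication", p, u = 1 - 1e-12), 1e-9)
  # analytic inversion: Lambda(t) = -log(u)
  V0 <- 0.8; u <- 0.37
  t <- sample_event_time(V0, "duplication", p, u = u)
  Lambda <- (V0 / p$V_s_crit)^p$n_s * (exp(p$n_s * p$g * t) - 1)
  expect_equal(Lambda, -log(u), tolerance = 1e-10)
})

test_that("sampled event times match a brute-force survival simulation", {
  p <- nominal_params()
  V0 <- 0.75
  set.seed(101)
  ts_closed <- vapply(stats::runif(3000), function(u)
    sample_event_time(V0, "duplication", p, u = u), numeric(1))
  # independent oracle: fine time-stepping Bernoulli thinning of the hazard
  dt <- 0.02
  tmax <- 60
  grid <- seq(dt / 2, tmax, by = dt)
  haz <- duplication_hazard(V0 * exp(p$g * grid), p)
  pfire <- 1 - exp(-haz * dt)
  ts_brute <- replicate(1500, {
    k <- which(stats::runif(length(grid)) < pfire)[1]
    if (is.na(k)) tmax else grid[k]
  })
  ks <- suppressWarnings(stats::ks.test(ts_closed, ts_brute))
  expect_gt(ks$p.value, 1e-3)
  # event volumes concentrate near the critical volume (sharp hazard)
  Vev <- V0 * exp(p$g * ts_closed)
  expect_lt(stats::sd(Vev) / mean(Vev), 0.06)
  expect_equal(mean(Vev), p$V_s_crit, tolerance = 0.05)
})

test_that("stochastic partitioning conserves volume and every species", {
  p <- nominal_params()
  set.seed(11)
  for (i in 1:30) {
    x <- c(rpois(3, 20), 1, 1, rpois(5, 2000))
    m <- cell_state(x, V = runif(1, 1, 2), duplicated = TRUE,
                    mode = "stochastic")
    pt <- partition_cell(m, p)
    expect_identical(pt$d1$x + pt$d2$x, as.numeric(x))
    expect_equal(pt$d1$V + pt$d2$V, m$V)
    expect_equal(pt$d1$x[4] + pt$d1$x[5], 1)  # one operator unit each
    expect_equal(pt$d2$x[4] + pt$d2$x[5], 1)
    expect_false(pt$d1$duplicated || pt$d2$duplicated)
  }
})

test_that("binomial partitioning success probability is the volume fraction", {
  p <- nominal_params()
  x <- c(0, 0, 0, 1, 1, 0, 0, 0, 1000, 0)
  m <- cell_state(x, 1.5, TRUE, mode = "stochastic")
  set.seed(12)
  got <- replicate(2000, partition_cell(m, p, f = 0.3)$d1$x[9])
  # E[X1] = f X; SE of the mean over 2000 draws ~ 0.32
  expect_equal(mean(got), 300, tolerance = 0.01)
  expect_equal(stats::sd(got), sqrt(1000 * 0.3 * 0.7), tolerance = 0.1)
})

test_that("the two operator units partition hypergeometrically", {
  p <- nominal_params()
  x <- c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0)   # one free, one repressed unit
  m <- cell_state(x, 1.5, TRUE, mode = "stochastic")
  set.seed(13)
  d1_free <- replicate(1500, partition_cell(m, p)$d1$x[4])
  expect_true(all(d1_free %in% c(0, 1)))
  expect_equal(mean(d1_free), 0.5, tolerance = 0.07)
})

test_that("deterministic partitioning is a Dirac delta in concentrations", {
  p <- nominal_params()
  V <- 1.5
  conc <- c(0.47, 0.27, 0.2, 0.06, 2 / molecules_per_nM(V) - 0.06,
            5e4, 15, 0.08, 10, 0.5)
  m <- cell_state(conc, V, TRUE, mode = "deterministic")
  pt <- partition_cell(m, p, f = 0.5)
  # all non-operator concentrations identical to the mother, bit-exact
  expect_identical(pt$d1$x[-(4:5)], conc[-(4:5)])
  expect_identical(pt$d2$x[-(4:5)], conc[-(4:5)])
  # symmetric split of a 2-copy mother keeps operator concentrations too
  expect_equal(pt$d1$x[4] + pt$d1$x[5], conc[4] + conc[5], tolerance = 1e-12)
  expect_equal(pt$d1$x[5] / (pt$d1$x[4] + pt$d1$x[5]),
               conc[5] / (conc[4] + conc[5]), tolerance = 1e-12)
})

test_that("division is gated on DNA duplication", {
  p <- nominal_params()
  m <- cell_state(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0), 1.4, FALSE,
                  mode = "stochastic")
  expect_error(partition_cell(m, p), "gating violation")
})
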