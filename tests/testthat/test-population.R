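test_that("census bookkeeping balances births and removals exactly", {
  p <- nominal_params()
  off <- cell_state(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0), 0.75,
                    mode = "stochastic")
  set.seed(51)
  pop <- simulate_population(rep(list(off), 4), t_end = 250, N_cellsmax = 30,
                             mode = "stochastic", sample_times = c(100, 250),
                             params = lac_params())
  expect_equal(pop$final_census, 4 + pop$n_divisions - pop$n_removals)
  expect_equal(pop$final_census, 30)   # cap reached and held
  # every snapshot census is at most the cap
  expect_true(all(pop$mean_timecourse$census <= 30))
})

test_that("before the cap every lineage is complete (two daughters each)", {
  p <- nominal_params()
  off <- cell_state(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0), 0.75,
                    mode = "stochastic")
  set.seed(52)
  pop <- simulate_population(off, t_end = 150, N_cellsmax = 1e6,
                             mode = "stochastic", sample_times = 150,
                             params = p)
  expect_equal(pop$n_removals, 0)
  expect_equal(pop$n_cells_total, 1 + 2 * pop$n_divisions)
  expect_equal(pop$final_census, 1 + pop$n_divisions)
  # census grows at rate ~ g: N(t) ~ exp(g t) within Monte Carlo error
  expect_equal(log(pop$final_census) / 150, p$g, tolerance = 0.2)
})

test_that("a census cap of one cell reduces the population to a chain", {
  off <- cell_state(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0), 0.75,
                    mode = "stochastic")
  set.seed(53)
  pop <- simulate_population(off, t_end = 300, N_cellsmax = 1,
                             mode = "stochastic", sample_times = seq(50, 300, 50),
                             params = lac_params())
  expect_equal(pop$final_census, 1)
  expect_true(all(pop$mean_timecourse$census == 1))
  expect_equal(pop$n_removals, pop$n_divisions)
})

test_that("pooled statistics are order-invariant and census-weighted", {
  p <- nominal_params()
  off <- cell_state(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0), 0.75,
                    mode = "stochastic")
  set.seed(54)
  rb <- run_batches(3, init = off, t_end = 200, N_cellsmax = 20,
                    mode = "stochastic", sample_times = 200, params = p)
  snap <- rb$snapshots
  expect_equal(nrow(snap), 3 * 20)
  pooled_mean <- mean(snap$V_fL)
  bm <- tapply(snap$V_fL, snap$batch_id, mean)
  bn <- tapply(snap$V_fL, snap$batch_id, length)
  expect_equal(pooled_mean, sum(bm * bn) / sum(bn))
  set.seed(99)
  perm <- sample(nrow(snap))
  expect_equal(mean(snap$V_fL[perm]), pooled_mean)
  expect_equal(distribution_distance(snap$V_fL, snap$V_fL[perm]), 0)
})

test_that("sharp-hazard limit reproduces the closed-form cycle averages", {
  # with very sharp hazards and partitioning, duplication happens exactly
  # at V_s_crit and division at V_d_crit with exact halving, and the
  # population stays synchronized (no noise to desynchronize it). The
  # per-snapshot population means, averaged over snapshots spanning one
  # full division cycle, then sweep the cycle uniformly in time and must
  # equal the closed-form cycle-average estimators.
  p <- lac_params(n_s = 400, n_d = 400, q = 2e4)
  set.seed(55)
  td <- log(2) / p$g
  st <- 400 - td + seq_len(60) * td / 60
  g <- geometry_only_population(p, t_end = 400, N_cellsmax = 300,
                                n_batches = 2, n_init = 30,
                                sample_times = st)
  snap_mean <- function(col_fun) {
    per <- tapply(seq_len(nrow(g$cells)),
                  interaction(g$cells$batch, g$cells$time_min),
                  function(i) mean(col_fun(g$cells[i, ])))
    mean(per)
  }
  aov <- snap_mean(function(d) area_from_volume(d$V_fL, p$R0) / d$V_fL)
  ot <- snap_mean(function(d)
    d$n_chromosomes / molecules_per_nM(d$V_fL))
  expect_equal(aov, estimate_A_over_V(p), tolerance = 0.01)
  expect_equal(ot, estimate_O_T(p), tolerance = 0.02)
})

test_that("geometry-only snapshot carries valid chromosome counts", {
  set.seed(56)
  g <- geometry_only_population(lac_params(), t_end = 200, N_cellsmax = 100,
                                n_batches = 2, n_init = 20)
  expect_true(all(g$cells$n_chromosomes %in% c(1L, 2L)))
  expect_true(all(g$cells$V_fL > 0.2 & g$cells$V_fL < 2.5))
  expect_equal(nrow(g$cells), 200)
})
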