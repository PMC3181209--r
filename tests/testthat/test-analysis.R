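test_that("number density functions normalize to unit area", {
  set.seed(71)
  s <- stats::rgamma(500, 2, 0.1)
  h <- ndf(s, bins = 40)
  expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1,
               tolerance = 1e-12)
  expect_equal(sum(h$count), 500)
  h1 <- ndf(5)
  expect_equal(sum(h1$count > 0), 1)     # single sample occupies one bin
  expect_error(ndf(numeric(0)), "empty")
})

test_that("mode splitting recovers a synthetic two-component mixture", {
  set.seed(72)
  s <- c(stats::rnorm(600, 0, 1), stats::rnorm(400, 8, 1))
  m <- split_modes(s)
  expect_equal(nrow(m), 2)
  expect_equal(m$mean[1], 0, tolerance = 2 * 1 / sqrt(600) * 2)
  expect_equal(m$mean[2], 8, tolerance = 2 * 2 / sqrt(400))
  expect_equal(m$weight, c(0.6, 0.4), tolerance = 0.05)
  expect_equal(sum(m$weight), 1)
  # unimodal sample: valley rejected
  m1 <- split_modes(stats::rnorm(800, 3, 1))
  expect_equal(nrow(m1), 1)
})

test_that("tail and shape statistics match known distributions", {
  set.seed(73)
  ex <- stats::rexp(2e4)
  st <- tail_and_shape_stats(ex)
  expect_equal(st$skewness, 2, tolerance = 0.1)
  expect_gt(st$tail_mass_3sd, 0.005)
  sym <- tail_and_shape_stats(stats::rnorm(2e4))
  expect_lt(abs(sym$skewness), 0.1)
  dg <- tail_and_shape_stats(rep(3, 50))
  expect_true(dg$degenerate)
  expect_error(tail_and_shape_stats(1:5), "at least 10")
})

test_that("division-time statistics sharpen with the hazard exponent", {
  p <- nominal_params()
  h <- division_time_histogram(c(28, 30, 32, 29, 31))
  expect_equal(h$mean, 30)
  expect_equal(h$n, 5)
  # CV of division volumes decreases monotonically with sharpness
  set.seed(74)
  cvs <- vapply(c(10, 25, 100), function(nd) {
    pp <- lac_params(n_d = nd)
    tt <- vapply(stats::runif(2000), function(u)
      sample_event_time(0.75, "division", pp, u = u), numeric(1))
    V <- 0.75 * exp(pp$g * tt)
    stats::sd(V) / mean(V)
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
})

test_that("Kolmogorov-Smirnov distance handles ties and edge cases", {
  expect_equal(distribution_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(distribution_distance(c(0, 0, 1), c(5, 6, 7)), 1)
  # heavy ties at zero, handled on the pooled support
  expect_equal(distribution_distance(c(0, 0, 0, 1), c(0, 0, 1, 1)), 0.25)
  expect_error(distribution_distance(numeric(0), 1:3), "empty")
})
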