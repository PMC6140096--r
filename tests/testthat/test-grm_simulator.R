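test_that("the cumulative response function is a logistic in the predictor", {
  expect_equal(grm_cumulative(0, 1, 0), .5)
  expect_equal(grm_cumulative(0, 1, -1.5), exp(1.5) / (1 + exp(1.5)))
  # zero loading on the second dimension: theta2 is irrelevant
  p1 <- grm_cumulative(c(.7, -2), c(1, 0), .3)
  p2 <- grm_cumulative(c(.7, 5), c(1, 0), .3)
  expect_equal(p1, p2)
  # matrix input vectorizes over persons
  th <- matrix(rnorm(10), 10, 1)
  expect_equal(grm_cumulative(th, 1, .2), plogis(th[, 1] - .2))
})

test_that("condition presets and validation behave", {
  std <- grm_condition("standard")
  long <- grm_condition("long_test")
  expect_equal(long$delta, matrix(rep(std$delta, 3), 18, 1))
  expect_equal(grm_condition("small_n")$N, 200L)
  expect_equal(grm_condition("two_dim")$theta_cor[1, 2], .5)
  expect_equal(grm_condition("polytomous")$m, 4L)
  expect_error(grm_condition("standard", delta = matrix(c(1, 0), 1, 2),
                             J = 1, m = 2, Q = 1, N = 10, alpha = matrix(1)),
               "strictly increasing")
  expect_error(grm_condition("two_dim",
                             theta_cor = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("simulation is reproducible and matches null-discrimination margins", {
  cond <- grm_condition("standard")
  a <- simulate_grm(cond, seed = 12)
  b <- simulate_grm(cond, seed = 12)
  expect_identical(unclass(a)[, ], unclass(b)[, ])

  # alpha = 0: scores independent of theta, P(X >= x) = logistic(-0) = .5
  null_cond <- grm_condition("custom", J = 2, m = 2, Q = 1, N = 20000,
                             alpha = matrix(0, 2, 1),
                             delta = rbind(c(-1, 1), c(-1, 1)))
  X <- simulate_grm(null_cond, seed = 5)
  for (x in 1:2) {
    expect_equal(mean(X[, 1] >= x), .5, tolerance = .02)
  }

  # two-dimensional preset: generated thetas correlate about .5
  td <- simulate_grm(grm_condition("two_dim"), seed = 3, N = 20000)
  expect_equal(cor(attr(td, "theta"))[1, 2], .5, tolerance = .03)
})

test_that("simulated margins match the quadrature oracle", {
  cond <- grm_condition("standard")
  X <- simulate_grm(cond, seed = 31, N = 1e6)
  for (i in c(1L, 4L)) {
    oracle <- stats::integrate(function(t)
      plogis(t - cond$delta[i, 1]) * dnorm(t), -Inf, Inf)$value
    expect_equal(mean(X[, i] >= 1), oracle, tolerance = .002)
  }
})

test_that("population reliability obeys its limits and is seed-stable", {
  null_cond <- grm_condition("custom", J = 2, m = 1, Q = 1, N = 100,
                             alpha = matrix(0, 2, 1),
                             delta = matrix(0, 2, 1))
  expect_equal(unname(population_item_reliability(null_cond, 1e4, seed = 1)),
               c(0, 0))
  cond <- grm_condition("standard")
  r1 <- population_item_reliability(cond, 2e5, seed = 10)
  r2 <- population_item_reliability(cond, 2e5, seed = 20)
  expect_true(all(r1 >= 0 & r1 <= 1))
  expect_true(all(abs(r1 - r2) < .01))
  expect_error(population_item_reliability(cond, 100), "10\\^4")
})

test_that("conditions round-trip through JSON configuration", {
  cond <- grm_condition("unequal_alpha")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "custom", J = cond$J, m = cond$m,
                            Q = cond$Q, N = cond$N, alpha = cond$alpha,
                            delta = cond$delta,
                            theta_cor = cond$theta_cor),
                       path, digits = NA)
  back <- read_grm_condition(path)
  expect_equal(back$alpha, cond$alpha)
  expect_equal(back$delta, cond$delta)
})
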