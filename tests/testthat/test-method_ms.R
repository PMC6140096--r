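test_that("candidate generation at the worked example's boundary cell", {
  ex <- fix_artificial_example()
  pp <- build_pplus(as_cumulative_tables(ex$marginal, ex$joint))
  # row 8 = pi1(1), column 2 = pi2(1): no neighbor below, three available
  k <- ms_candidates(pp$marginals, pp$cells, 8, 2)
  expect_equal(sort(k$sources), c(.32, .51, .70))
  expect_equal(length(k$estimates), 6L)  # two transforms per neighbor
  expect_equal(k$value, mean(k$estimates))
  # an interior unobservable cell sees all four neighbors (8 candidates)
  k2 <- ms_candidates(pp$marginals, pp$cells, 4, 6)
  expect_equal(length(k2$estimates), 8L)
})

test_that("constant P(++) with equal marginals is approximated exactly", {
  p <- .5; cval <- .4; J <- 3
  marg <- matrix(p, J, 1)
  joint <- array(NA_real_, c(1, 1, J, J))
  for (i in 1:J) for (j in 1:J) if (i != j) joint[1, 1, i, j] <- cval
  pp <- build_pplus(as_cumulative_tables(marg, joint))
  ap <- ms_approximate(pp)
  expect_true(all(abs(ap$filled - cval) < 1e-12))
})

test_that("MS reliability is deterministic and permutation-equivariant", {
  X <- item_scores(fix_scores(200, 5, 2, 909), m = 2)
  r1 <- ms_reliability(X)
  expect_identical(r1$estimates, ms_reliability(X)$estimates)
  # permuting persons changes nothing
  Xp <- item_scores(unclass(X)[sample(nrow(X)), ], m = 2)
  expect_equal(unname(ms_reliability(Xp)$estimates), unname(r1$estimates))
  # permuting items permutes the estimates
  perm <- c(3, 1, 5, 2, 4)
  Xi <- item_scores(unclass(X)[, perm], m = 2,
                    item_labels = colnames(X)[perm])
  expect_equal(unname(ms_reliability(Xi)$estimates),
               unname(r1$estimates[perm]))
})

test_that("MS agrees cellwise with the reference implementation (frozen)", {
  # test-score MS on two fixtures, values frozen from mokken 3.1.2
  Xa <- item_scores(fix_scores(150, 5, 1, 101))
  expect_equal(ms_test_reliability(Xa), 0.374598546243, tolerance = 1e-9)
  Xb <- item_scores(fix_scores(120, 4, 3, 202), m = 3)
  expect_equal(suppressWarnings(ms_test_reliability(Xb)),
               0.501822038555, tolerance = 1e-9)
})

test_that("MS hits the comonotone and independence limits", {
  # identical items: all observable P(++) entries .5, marginals .5
  base <- rep(c(0L, 1L), each = 100)
  X <- item_scores(cbind(base, base, base))
  est <- ms_reliability(X)$estimates
  # sample (N-1) variance slightly exceeds the population value
  expect_true(all(abs(est - 199 / 200) < 1e-12))

  set.seed(88)
  ind <- item_scores(matrix(rbinom(4000 * 4, 1, .6), 4000, 4))
  expect_true(all(abs(ms_reliability(ind)$estimates) < .06))
})

test_that("MS recovers the population reliability for exchangeable items", {
  cond <- grm_condition("standard", delta = matrix(0.3, 6, 1))
  rho <- population_item_reliability(cond, n_simulees = 2e5, seed = 42)
  X <- simulate_grm(cond, seed = 43, N = 1e4)
  est <- ms_reliability(X)$estimates
  expect_lt(abs(stats::median(est) - stats::median(rho)), .02)
})

test_that("MS errors on degenerate inputs", {
  expect_error(ms_reliability(item_scores(matrix(c(0, 1, 1, 0), 4, 1))),
               "at least 2 items")
  flat <- item_scores(cbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L)), m = 1)
  expect_error(ms_reliability(flat), "zero variance")
})
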