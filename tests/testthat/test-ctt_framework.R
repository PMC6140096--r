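test_that("cumulative tables hold sample proportions with pi0 = 1", {
  d <- item_scores(matrix(c(0, 1, 2, 2), 4, 1), m = 2)
  tab <- estimate_cumulative_tables(d)
  expect_equal(unname(tab$marginal[1, ]), c(1, .75, .50))

  two <- item_scores(cbind(c(0, 1, 1, 1), c(0, 1, 1, 1)))
  t2 <- estimate_cumulative_tables(two)
  expect_equal(t2$joint[1, 1, 1, 2], .75)   # comonotone bound attained

  set.seed(2)
  r <- item_scores(matrix(sample(0:2, 60, TRUE), 20, 3), m = 2)
  expect_true(all(estimate_cumulative_tables(r)$marginal[, 1] == 1))
})

test_that("estimated joint proportions respect the Frechet bounds and symmetry", {
  set.seed(11)
  for (rep in 1:5) {
    X <- fix_scores(60, 4, 3, 300 + rep)
    tab <- estimate_cumulative_tables(item_scores(X, m = 3))
    for (i in 1:3) for (j in (i + 1):4) for (x in 1:3) for (y in 1:3) {
      pxy <- tab$joint[x, y, i, j]
      px <- tab$marginal[i, x + 1]; py <- tab$marginal[j, y + 1]
      expect_gte(pxy, max(0, px + py - 1) - 1e-12)
      expect_lte(pxy, min(px, py) + 1e-12)
      expect_equal(pxy, tab$joint[y, x, j, i])
    }
  }
})

test_that("item steps are ordered ascending with a deterministic tie rule", {
  ex <- fix_artificial_example()
  tab <- as_cumulative_tables(ex$marginal, ex$joint)
  ord <- order_item_steps(tab)
  expect_equal(ord$label,
               c("pi2(2)", "pi2(1)", "pi2(4)", "pi2(3)",
                 "pi1(4)", "pi1(3)", "pi1(2)", "pi1(1)"))

  # comparison-sort oracle on distinct random marginals
  set.seed(4)
  p1 <- matrix(sort(runif(20), decreasing = TRUE), 10, 2, byrow = FALSE)
  p1 <- t(apply(matrix(runif(20), 10, 2), 1, sort, decreasing = TRUE))
  tab2 <- as_cumulative_tables(p1, array(NA_real_, c(2, 2, 10, 10)))
  ord2 <- order_item_steps(tab2)
  expect_equal(ord2$pi, sort(p1))

  # ties: both rules are deterministic and are permutations of each other
  pt <- rbind(c(.8, .4), c(.8, .4))
  tabt <- as_cumulative_tables(pt, array(NA_real_, c(2, 2, 2, 2)))
  o1 <- order_item_steps(tabt, "item_desc_score")
  o2 <- order_item_steps(tabt, "item_asc_score")
  expect_equal(o1$item, c(1L, 2L, 1L, 2L))
  expect_equal(sort(o1$label), sort(o2$label))

  single <- as_cumulative_tables(matrix(.5, 1, 1),
                                 array(NA_real_, c(1, 1, 1, 1)))
  expect_equal(nrow(order_item_steps(single)), 1L)
})

test_that("the ordered P(++) matrix reproduces the artificial example", {
  ex <- fix_artificial_example()
  pp <- build_pplus(as_cumulative_tables(ex$marginal, ex$joint))
  expect_equal(pp$cells[4, 7], .81)
  expect_true(is.na(pp$cells[5, 3]))
  # exactly m = 2 unobservable cells per row, in the same-item pattern
  expect_equal(unname(rowSums(is.na(pp$cells))), rep(2, 8))
  for (r in 1:8) for (cc in 1:8)
    expect_equal(is.na(pp$cells[r, cc]),
                 pp$order$item[r] == pp$order$item[cc])
  # reading back any observable cell returns the original joint value
  for (r in 1:8) for (cc in 1:8) {
    if (!is.na(pp$cells[r, cc])) {
      o <- pp$order
      expect_equal(pp$cells[r, cc],
                   ex$joint[o$x[r], o$x[cc], o$item[r], o$item[cc]])
    }
  }
  # complement identity
  obs <- !is.na(pp$cells)
  expect_equal(pp$complement[obs],
               (1 - outer(pp$marginals, rep(1, 8)) -
                  outer(rep(1, 8), pp$marginals) + pp$cells)[obs])

  one <- item_scores(matrix(c(0, 1, 0, 1), 4, 1))
  pp1 <- build_pplus(estimate_cumulative_tables(one))
  expect_true(all(is.na(pp1$cells)))
})

test_that("reliability assembly matches closed forms and a brute-force sum", {
  # dichotomous reduction (Eq. 17 form)
  expect_equal(reliability_from_approximation(matrix(.484), .68, .68 * .32),
               (.484 - .68^2) / (.68 * .32))
  # independence gives zero
  marg <- c(.9, .4)
  expect_equal(reliability_from_approximation(outer(marg, marg), marg, .3), 0)
  # m = 2 brute-force double-sum oracle
  approx <- rbind(c(.85, .40), c(.40, .35))
  v <- sum((0:2)^2 * c(.1, .5, .4)) - sum((0:2) * c(.1, .5, .4))^2
  brute <- 0
  for (x in 1:2) for (y in 1:2)
    brute <- brute + approx[x, y] - marg[x] * marg[y]
  expect_equal(reliability_from_approximation(approx, marg, v), brute / v)
  expect_error(reliability_from_approximation(matrix(.4), .5, 0),
               "degenerate")
})

test_that("pplus diagnostics and CSV dump work", {
  X <- item_scores(fix_scores(80, 4, 2, 55), m = 2)
  pp <- build_pplus(estimate_cumulative_tables(X))
  expect_true(pp$n_monotonicity_violations >= 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pplus(pp, path)
  dumped <- utils::read.csv(path, check.names = FALSE)
  expect_equal(dumped$step, pp$order$label)
  expect_equal(sum(is.na(dumped[, -(1:2)])), sum(is.na(pp$cells)))
})
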