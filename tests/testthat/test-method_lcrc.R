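test_that("K = 1 is the closed-form MLE and yields zero reliability", {
  X <- item_scores(fix_scores(80, 4, 2, 606), m = 2)
  fit <- fit_lcm(X, K = 1)
  expect_equal(fit$weights, 1)
  for (j in 1:4)
    expect_equal(fit$response[j, , 1],
                 tabulate(X[, j] + 1L, nbins = 3) / 80)
  # single class implies independence: product of marginals, rho = 0
  tab <- lcrc_joint_approx(fit, 2)
  marg <- lcm_marginal(fit, 2)
  expect_equal(tab, outer(marg, marg))
  est <- lcrc_reliability(X, K = 1)$estimates
  expect_equal(unname(est), rep(0, 4))
})

test_that("the two worked latent class models give .484/.099 and .508/.210", {
  m2 <- fix_two_class_model(1)
  m3 <- fix_three_class_model(1)
  # identical fitted marginals...
  expect_equal(lcm_marginal(m2, 1), .68)
  expect_equal(lcm_marginal(m3, 1), .68)
  # ...but diverging joint approximations and reliabilities
  expect_equal(lcrc_joint_approx(m2, 1)[1, 1], .4 * .5^2 + .6 * .8^2)
  expect_equal(lcrc_joint_approx(m3, 1)[1, 1],
               .4 * .5^2 + .3 * .6^2 + .3 * 1.0^2)
  expect_equal(round(lcrc_model_reliability(m2, 1), 3), .099)
  expect_equal(round(lcrc_model_reliability(m3, 1), 3), .210)
})

test_that("EM recovers a known two-class model and its reliability", {
  # class weights are weakly identified at N = 5000 (sampling SD of the
  # small-class weight is about .015), so recovery is asserted on medians
  # over three replicate samples rather than on one draw
  gen <- fix_two_class_model(6)
  rho_true <- lcrc_model_reliability(gen, 1)
  wdev <- respdev <- lcrcdev <- numeric(3)
  for (s in 1:3) {
    X <- simulate_lcm(gen, 5000, seed = s)
    fit <- fit_lcm(X, K = 2, n_starts = 10, seed = 100 + s)
    wdev[s] <- abs(min(fit$weights) - .4)
    p <- sort(fit$response[, 2, ])
    respdev[s] <- stats::median(abs(p - rep(c(.5, .8), each = 6)))
    est <- lcrc_reliability(X, K = 2, n_starts = 10, seed = 100 + s)$estimates
    lcrcdev[s] <- abs(mean(est) - rho_true)
  }
  expect_lt(stats::median(wdev), .03)
  expect_lt(stats::median(respdev), .03)
  expect_lt(stats::median(lcrcdev), .02)
})

test_that("EM log-likelihood is monotone and the best start wins", {
  X <- item_scores(fix_scores(150, 5, 1, 505))
  fit <- fit_lcm(X, K = 3, n_starts = 6, seed = 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10 * abs(fit$loglik)))
  expect_true(all(fit$loglik >= fit$start_logliks - 1e-9))
})

test_that("the fitted log-likelihood matches the reference fit (frozen)", {
  # poLCA 1.6.0.2, nclass = 2, nrep = 15 on the same data: llik -1495.014046
  X <- simulate_lcm(fix_two_class_model(6), 400, seed = 31)
  fit <- fit_lcm(X, K = 2, n_starts = 15, seed = 5)
  expect_equal(fit$loglik, -1495.014046, tolerance = 1e-5)
})

test_that("lcrc_joint_approx tables are symmetric, bounded and monotone", {
  X <- item_scores(fix_scores(200, 4, 3, 808), m = 3)
  fit <- suppressWarnings(fit_lcm(X, K = 2, n_starts = 5, seed = 3))
  for (i in 1:4) {
    tab <- lcrc_joint_approx(fit, i)
    expect_equal(tab, t(tab))
    expect_true(all(tab >= 0 & tab <= 1))
    expect_true(all(apply(tab, 1, diff) <= 1e-12))  # nonincreasing in y
    expect_true(all(apply(tab, 2, diff) <= 1e-12))  # nonincreasing in x
  }
})

test_that("identifiability and settings bookkeeping", {
  pat <- rbind(c(0, 1), c(1, 0), c(0, 1), c(1, 1), c(0, 0))
  tiny <- item_scores(pat[rep(1:5, 2), ])   # N = 10, 5 distinct patterns
  w <- capture_warnings(fit_lcm(tiny, K = 6, n_starts = 2, seed = 1))
  expect_true(any(grepl("identifiable", w)))
  X <- item_scores(fix_scores(120, 4, 1, 12))
  rep <- lcrc_reliability(X, K = 2, n_starts = 3, seed = 99)
  expect_equal(rep$settings$seed, 99)
  expect_equal(rep$settings$K, 2L)
  expect_s3_class(attr(rep, "model"), "latent_class_model")
})
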