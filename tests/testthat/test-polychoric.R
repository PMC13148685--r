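test_that("thresholds are normal quantiles of cumulative proportions", {
  expect_equal(estimate_thresholds(rep(1:2, each = 50)), 0)
  th <- estimate_thresholds(rep(1:4, each = 25))
  expect_equal(th, qnorm(c(.25, .5, .75)))
  # proportions (0.1587, 0.8413) put the single threshold near -1
  x <- c(rep(1, 1587), rep(2, 8413))
  expect_equal(estimate_thresholds(x), qnorm(0.1587), tolerance = 1e-6)
  expect_error(estimate_thresholds(rep(1, 30)), "degenerate")
})

test_that("perfect concordance and independence are recovered", {
  set.seed(11)
  x <- sample(1:4, 4000, replace = TRUE)
  fit <- estimate_polychoric_rho(x, x)
  expect_gte(fit$rho, 0.99)
  y <- sample(1:4, 4000, replace = TRUE) # independent draw
  expect_lt(abs(estimate_polychoric_rho(x, y)$rho), 0.05)
})

test_that("two-step estimate matches the brute-force grid oracle", {
  set.seed(21)
  for (rho in c(-0.7, -0.3, 0, 0.4, 0.8)) {
    p <- draw_ordinal_pair(300, rho)
    est <- estimate_polychoric_rho(p$x, p$y)$rho
    expect_lt(abs(est - oracle_polychoric_rho(p$x, p$y)), 0.01)
  }
})

test_that("latent rho 0.6 at n = 5000 is estimated within 0.05 and agrees with the oracle", {
  set.seed(31)
  p <- draw_ordinal_pair(5000, 0.6)
  est <- estimate_polychoric_rho(p$x, p$y)$rho
  expect_gte(est, 0.55)
  expect_lte(est, 0.65)
  expect_lt(abs(est - oracle_polychoric_rho(p$x, p$y)), 0.01)
})

test_that("estimation is symmetric in its arguments", {
  set.seed(41)
  for (rho in c(-0.5, 0.5)) {
    p <- draw_ordinal_pair(200, rho, c(-1, 0), c(-0.3, 0.8))
    expect_equal(estimate_polychoric_rho(p$x, p$y)$rho,
                 estimate_polychoric_rho(p$y, p$x)$rho, tolerance = 1e-4)
  }
})

test_that("estimator is nearly unbiased over replicates", {
  # mean bias below 0.03 per true rho at n = 500
  set.seed(51)
  for (rho in c(-0.5, 0, 0.5)) {
    est <- replicate(200, {
      p <- draw_ordinal_pair(500, rho)
      estimate_polychoric_rho(p$x, p$y)$rho
    })
    expect_lt(abs(mean(est) - rho), 0.03)
  }
})

test_that("polychoric_matrix assembles a unit-diagonal symmetric matrix", {
  lev <- afro47_levels()
  res <- polychoric_matrix(lev)
  expect_s3_class(res, "polychoric_result")
  expect_equal(diag(res$corr), rep(1, 4), ignore_attr = TRUE)
  expect_equal(res$corr, t(res$corr))
  expect_true(all(abs(res$corr) <= 1))
  expect_true(all(res$converged))
  expect_equal(res$n_obs, 47)
  expect_length(res$thresholds$che, 3)
  expect_length(res$thresholds$bsp, 2)
})

test_that("independent factors give near-zero off-diagonals, duplicates near one", {
  set.seed(61)
  lev <- cbind(a = sample(1:4, 1000, TRUE), b = sample(1:5, 1000, TRUE))
  res <- polychoric_matrix(lev)
  expect_lt(abs(res$corr[1, 2]), 0.06)
  expect_false(res$smoothed)
  x <- sample(1:4, 200, TRUE)
  dup <- polychoric_matrix(cbind(x = x, y = x))
  expect_gte(dup$corr[1, 2], 0.99)
})

test_that("degenerate variables are excluded with a warning", {
  set.seed(71)
  lev <- cbind(a = sample(1:4, 50, TRUE), b = sample(1:3, 50, TRUE),
               c = rep(2L, 50))
  expect_warning(res <- polychoric_matrix(lev), "degenerate.*c")
  expect_equal(colnames(res$corr), c("a", "b"))
  expect_equal(res$excluded, "c")
})

test_that("non-PSD matrices are smoothed to unit-diagonal PSD", {
  R <- rbind(c(1, 0.9, -0.9), c(0.9, 1, 0.9), c(-0.9, 0.9, 1))
  expect_lt(min(eigen(R)$values), 0)
  sm <- hfvuln:::smooth_psd(R)
  expect_true(sm$smoothed)
  expect_gte(min(eigen(sm$corr)$values), 0)
  expect_equal(diag(sm$corr), rep(1, 3))
  psd <- hfvuln:::smooth_psd(diag(3))
  expect_false(psd$smoothed)
})
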