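test_that("latent draws are deterministic under a seed and match the target correlation", {
  cfg_id <- synthetic_config(n_countries = 10000, latent_corr = diag(4),
                             thresholds = reference_generating_structure()$thresholds,
                             seed = 5)
  Z <- generate_latent(cfg_id)
  expect_identical(Z, generate_latent(cfg_id))
  offdiag <- cor(Z)[upper.tri(diag(4))]
  expect_true(all(abs(offdiag) < 0.05))

  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.8
  cfg <- synthetic_config(n_countries = 10000, latent_corr = R,
                          thresholds = reference_generating_structure()$thresholds,
                          seed = 6)
  r12 <- cor(generate_latent(cfg))[1, 2]
  expect_gte(r12, 0.77)
  expect_lte(r12, 0.83)
})

test_that("configs with invalid correlation matrices are rejected", {
  th <- reference_generating_structure()$thresholds
  bad <- matrix(0.9, 4, 4)
  bad[1, 2] <- bad[2, 1] <- -0.9  # indefinite
  diag(bad) <- 1
  expect_error(synthetic_config(latent_corr = bad, thresholds = th),
               "positive semi-definite")
  asym <- diag(4)
  asym[1, 2] <- 0.5
  expect_error(synthetic_config(latent_corr = asym, thresholds = th),
               "symmetric")
  expect_error(synthetic_config(outcome_r2 = 1), "outcome_r2")
})

test_that("discretization respects band masses and the tie rule", {
  spec1 <- data.frame(name = "f1", max_level = 2L, denominator = 2L)
  set.seed(8)
  z <- matrix(rnorm(20000), ncol = 1)
  d <- discretize(z, list(0), spec1)
  expect_equal(mean(d$levels == 2), 0.5, tolerance = 0.02)
  # a value exactly at a threshold takes the higher level
  d2 <- discretize(matrix(c(-0.1, 0, 0.1), ncol = 1), list(0), spec1)
  expect_equal(unname(d2$levels[, 1]), c(1L, 2L, 2L))
  spec5 <- data.frame(name = "f1", max_level = 5L, denominator = 5L)
  d5 <- discretize(z, list(qnorm(c(.2, .4, .6, .8))), spec5)
  props <- as.numeric(table(d5$levels) / nrow(z))
  expect_equal(props, rep(0.2, 5), tolerance = 0.02)
  expect_error(discretize(z, list(c(-1, 0, 0.5, 1, 1.5)), spec5),
               "too many thresholds")
})

test_that("generated raw indicators band back to the generated levels", {
  cfg <- synthetic_config(n_countries = 200, seed = 9)
  tab <- generate_country_table(cfg)
  p <- build_profiles(tab$records)
  ds <- profiles_to_dataset(p)
  expect_identical(unname(ds$levels), unname(tab$data$levels))
})

test_that("outcome R-squared is recovered in expectation, including the null", {
  cfg0 <- synthetic_config(n_countries = 200, outcome_r2 = 0, seed = 10)
  r2 <- replicate(60, {
    cfg0$seed <- cfg0$seed + 1L
    tab <- generate_country_table(cfg0)
    correlate(rowMeans(tab$latent), tab$outcome$outcome)$r_squared
  })
  expect_lt(mean(r2), 0.03)
})

test_that("polychoric estimation recovers the generating latent correlation", {
  R <- matrix(0.5, 4, 4)
  diag(R) <- 1
  cfg <- synthetic_config(n_countries = 2000, latent_corr = R, seed = 12)
  est <- polychoric_matrix(discretize(generate_latent(cfg),
                                      cfg$thresholds))$corr
  expect_true(all(abs(est[upper.tri(est)] - 0.5) < 0.05))
})

test_that("the synthetic pipeline closes end to end", {
  cfg <- synthetic_config(n_countries = 60, seed = 13)
  tab <- generate_country_table(cfg)
  path <- write_indicator_csv(tab$records)
  out_dir <- file.path(tempdir(), "synth_run")
  res <- run_pipeline(list(indicators_csv = path, output_dir = out_dir,
                           weights_method = "polychoric_pca"), quiet = TRUE)
  expect_equal(nrow(res$scores), 60)
  expect_equal(sum(res$weights$weights), 100, tolerance = 1e-6)
  expect_true(file.exists(file.path(out_dir, "results.csv")))
})
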