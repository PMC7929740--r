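test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_subjects = 0), "invalid config")
  expect_error(suppressWarnings(toy_config(eigenvalues = c(-1, 2, 1))),
               "invalid config")
  bad <- diag(9)[1:2, ]
  bad[2, 1] <- 0.5  # not orthonormal
  expect_error(simulation_config(true_components = bad,
                                 eigenvalues = c(1, 1)),
               "orthonormal")
  expect_error(toy_config(noise_sd = -1), "invalid config")
})

test_that("the generator is fully deterministic given the seed", {
  a <- simulate_actigraphy(simulation_config(n_subjects = 4, seed = 33))
  b <- simulate_actigraphy(simulation_config(n_subjects = 4, seed = 33))
  expect_identical(a$minute_records, b$minute_records)
  expect_identical(a$subject_covariates, b$subject_covariates)
  expect_identical(a$day_covariates, b$day_covariates)
  expect_identical(a$truth$scores, b$truth$scores)
})

test_that("covariate marginals hit their nominal rates at large n", {
  cfg <- simulation_config(n_subjects = 2000, seed = 5)
  cov <- simulate_covariates(cfg)
  expect_lt(abs(mean(cov$days$workday) - 0.4), 0.03)
  expect_lt(abs(mean(cov$subjects$age) - 50), 1.5)
  expect_true(all(table(cov$subjects$group) > 0))
})

test_that("score decomposition yields the closed-form within-person day correlation", {
  cfg <- toy_config(n_subjects = 500, days = 14, eigenvalues = 2,
                    icc = 0.5, seed = 9)
  cov <- simulate_covariates(cfg)
  xi <- simulate_scores(cfg, cov)[, 1]
  # empirical mean cross-day product within subject / total variance
  sid <- cov$days$subject_id
  S <- tapply(xi, sid, sum)
  Q <- tapply(xi^2, sid, sum)
  n_i <- tapply(xi, sid, length)
  icc_hat <- (sum(S^2 - Q) / sum(n_i * (n_i - 1))) / stats::var(xi)
  expect_gte(icc_hat, 0.45)
  expect_lte(icc_hat, 0.55)
})

test_that("noise-free covariate effect shifts scores by exactly the effect size", {
  G <- matrix(0, 1, 16,
              dimnames = list(NULL, actfda:::sim_design_columns()))
  G[1, "workday"] <- 0.5
  cfg <- simulation_config(n_subjects = 40, days_per_subject = 6,
                           mean_curve = c(10 * sqrt(1440), rep(0, 8)),
                           true_components = diag(9)[2, , drop = FALSE],
                           eigenvalues = 1, effect_matrix = G,
                           subject_sd = 0, day_sd = 0, noise_sd = 0,
                           gap_rate = 0, seed = 2)
  cov <- simulate_covariates(cfg)
  xi <- simulate_scores(cfg, cov)[, 1]
  expect_equal(unique(xi[cov$days$workday == 1]), 0.5)
  expect_equal(unique(xi[cov$days$workday == 0]), 0)
})

test_that("degenerate noiseless curves equal the mean curve; activity is nonnegative", {
  cfg <- toy_config(n_subjects = 3, days = 2, eigenvalues = c(0, 0, 0),
                    noise_sd = 0, seed = 4)
  cov <- simulate_covariates(cfg)
  xi <- simulate_scores(cfg, cov)
  expect_true(all(xi == 0))
  mr <- simulate_curves(cfg, cov, xi)
  expect_true(all(abs(mr$activity - 10) < 1e-9))

  ds <- simulate_actigraphy(simulation_config(n_subjects = 3, seed = 8))
  expect_true(all(ds$minute_records$activity[ds$minute_records$observed] >= 0))
})

test_that("opposite unit scores mirror the curves around the mean (no flooring)", {
  cfg <- toy_config(n_subjects = 2, days = 1, eigenvalues = 1,
                    noise_sd = 0, mean_level = 50, seed = 3)
  cov <- simulate_covariates(cfg)
  xi <- matrix(c(1, -1), ncol = 1)
  mr <- simulate_curves(cfg, cov, xi)
  y <- matrix(mr$activity, nrow = 2, byrow = TRUE)
  expect_equal(colMeans(y), rep(50, 1440), tolerance = 1e-9)
})

test_that("stored truth reproduces every curve exactly when noise and gaps are off", {
  cfg <- toy_config(n_subjects = 4, days = 3, noise_sd = 0, gap_rate = 0,
                    seed = 12)
  ds <- simulate_actigraphy(cfg)
  tr <- ds$truth
  coefs <- sweep(tr$scores %*% tr$config$true_components, 2,
                 tr$config$mean_curve, "+")
  recon <- pmax(eval_basis(coefs, fourier_basis()), 0)
  expect_equal(ds$minute_records$activity, as.vector(t(recon)),
               tolerance = 1e-12)
})

test_that("gap injection is a no-op at rate 0 and matches its expected missingness", {
  cfg <- toy_config(n_subjects = 4, days = 2, seed = 21)
  ds <- simulate_actigraphy(cfg)
  expect_identical(inject_gaps(ds$minute_records, 0, 30, seed = 1),
                   ds$minute_records)

  cfg2 <- toy_config(n_subjects = 72, days = 14, seed = 22)
  mr <- simulate_actigraphy(cfg2)$minute_records
  gapped <- inject_gaps(mr, gap_rate = 2, gap_length = 30, seed = 77)
  n_days <- nrow(unique(gapped[, c("subject_id", "date")]))
  miss_per_day <- sum(!gapped$observed) / n_days
  expect_gt(miss_per_day, 54)   # within 10% of 2 * 30 = 60
  expect_lt(miss_per_day, 66)
  # observed values unchanged
  expect_identical(gapped$activity[gapped$observed],
                   mr$activity[gapped$observed])
  # reproducible
  expect_identical(inject_gaps(mr, 2, 30, seed = 77), gapped)
})
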