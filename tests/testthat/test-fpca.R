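test_that("degenerate inputs: identical curves give zero eigenvalues; n<2 errors", {
  fb <- fourier_basis()
  C <- matrix(rep(c(5, 1, 0, 2, 0, 0, 0, 0, 0), each = 20), nrow = 20)
  fp <- fit_fpca(C, basis = fb)
  expect_lt(max(fp$eigenvalues), 1e-20)
  expect_equal(fp$n_retained, 0L)
  expect_error(fit_fpca(C[1, , drop = FALSE]), "degenerate")
})

test_that("a rank-1 spread along one basis function is recovered exactly", {
  fb <- fourier_basis()
  mu <- c(10, 0, 3, 0, 0, 0, 0, 0, 0)
  C <- rbind(matrix(rep(mu + c(0, 1, 0, 0, 0, 0, 0, 0, 0), 10),
                    nrow = 10, byrow = TRUE),
             matrix(rep(mu - c(0, 1, 0, 0, 0, 0, 0, 0, 0), 10),
                    nrow = 10, byrow = TRUE))
  fp <- fit_fpca(C, basis = fb)
  expect_equal(sum(fp$eigenvalues > 1e-12), 1L)
  expect_lt(principal_angle(fp$eigen_coefficients[1, ],
                            c(0, 1, rep(0, 7))), 1e-6)
  # sign orientation: largest coefficient positive
  expect_gt(fp$eigen_coefficients[1, 2], 0)
})

test_that("coefficient-space fPCA equals brute-force PCA of discretized curves", {
  fb <- fourier_basis()
  set.seed(101)
  C <- matrix(rnorm(50 * 9, sd = rep(c(3, 2, 1.5, 1, rep(0.3, 5)),
                                     each = 50)), nrow = 50)
  C <- sweep(C, 2, c(20, rep(0, 8)), "+")
  curves <- eval_basis(C, fb)
  fp <- fit_fpca(C, basis = fb)
  oracle <- discretized_pca(curves)
  nz <- fp$eigenvalues > 1e-8
  expect_lt(max(abs(fp$eigenvalues[nz] - oracle$values[which(nz)]) /
                  fp$eigenvalues[nz]), 1e-8)
  for (k in which(nz)) {
    phi_fit <- drop(fp$eigen_coefficients[k, ] %*% t(fb$eval))
    expect_lt(principal_angle(phi_fit, oracle$vectors[, k]), 1e-6)
  }
})

test_that("noiseless simulated eigenstructure is recovered", {
  # independent day-curves (one per subject) so eigenvector sampling error
  # is governed by the curve count alone
  cfg <- toy_config(n_subjects = 13000, days = 1, eigenvalues = c(4, 2, 1),
                    noise_sd = 0, icc = 0, seed = 19)
  cov <- simulate_covariates(cfg)
  xi <- simulate_scores(cfg, cov)
  # render the noiseless curves on the minute grid and project back
  curves <- eval_basis(sweep(xi %*% cfg$true_components, 2,
                             cfg$mean_curve, "+"))
  fp <- fit_fpca(project_to_basis(curves))
  expect_lt(max(abs(fp$variance_proportions[1:3] - c(4, 2, 1) / 7)), 0.02)
  for (k in 1:3)
    expect_lt(principal_angle(fp$eigen_coefficients[k, ],
                              cfg$true_components[k, ]), 2)
})

test_that("the cumulative-variance rule picks the smallest sufficient K", {
  # the four printed per-component variance shares of the motivating analysis
  props <- c(0.343, 0.165, 0.148, 0.118)
  K <- select_num_components(props, 0.75)
  expect_equal(K, 4L)
  expect_equal(round(100 * sum(props[1:K]), 1), 77.4)

  expect_equal(select_num_components(c(0.80, 0.10, 0.05)), 1L)
  expect_equal(select_num_components(c(0.30, 0.30, 0.30, 0.10), 0.75), 3L)
  expect_error(select_num_components(props, 1.01), "invalid config")
  expect_error(select_num_components(props, 0), "invalid config")
  expect_error(select_num_components(c(0.8, 0.4)), "at most 1")
})

test_that("scores are centered projections, standardized to pooled SD one", {
  fb <- fourier_basis()
  set.seed(55)
  C <- matrix(rnorm(200 * 9), 200, 9) %*% diag(c(3, 2, 1, rep(0.5, 6)))
  fp <- fit_fpca(C, basis = fb)
  # the mean curve scores 0 on every component
  sc0 <- compute_scores(fp, matrix(fp$mean_coefficients, 1),
                        components = 1:4)
  expect_lt(max(abs(sc0$score)), 1e-10)
  # mean + 2*phi1 scores 2 raw, 2/sd1 standardized, 0 elsewhere
  c1 <- fp$mean_coefficients + 2 * fp$eigen_coefficients[1, ]
  sc1 <- compute_scores(fp, matrix(c1, 1), components = 1:4)
  expect_equal(sc1$score[1], 2, tolerance = 1e-10)
  expect_equal(sc1$score_std[1], 2 / fp$score_sd[1], tolerance = 1e-10)
  expect_lt(max(abs(sc1$score[-1])), 1e-10)
  # brute-force projection oracle + pooled-SD-1 invariant
  sc <- compute_scores(fp, C, components = 1:9)
  for (k in c(1, 3, 7)) {
    oracle <- drop(sweep(C, 2, colMeans(C)) %*% fp$eigen_coefficients[k, ])
    expect_equal(sc$score[sc$component == k], oracle, tolerance = 1e-10)
    expect_equal(sd(sc$score_std[sc$component == k]), 1, tolerance = 1e-10)
  }
  # reconstruction with all components reproduces the centered coefficients
  w <- scores_wide(sc, value = "score")
  xi <- as.matrix(w[, paste0("comp", 1:9)])
  recon <- xi %*% fp$eigen_coefficients
  expect_equal(recon, sweep(C, 2, colMeans(C)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("component effect curves are symmetric around the mean", {
  set.seed(66)
  C <- matrix(rnorm(100 * 9), 100, 9)
  fp <- fit_fpca(C)
  cur <- component_effect_curves(fp, 2)
  expect_equal((cur$plus + cur$minus) / 2, cur$mean, tolerance = 1e-12)
  expect_error(component_effect_curves(fp, 10), "out of range")
  # zero-eigenvalue component: all three curves identical
  Cc <- cbind(matrix(rnorm(100 * 2), 100, 2),
              matrix(rep(c(1, 0, 0, 0, 0, 0, 0), each = 100), 100))
  fp0 <- fit_fpca(Cc)
  cur0 <- component_effect_curves(fp0, 9)
  expect_equal(cur0$plus, cur0$mean)
})

test_that("duplicating every curve leaves eigenfunctions and proportions unchanged", {
  set.seed(77)
  C <- matrix(rnorm(40 * 9), 40, 9)
  a <- fit_fpca(C)
  b <- fit_fpca(rbind(C, C))
  expect_equal(a$variance_proportions, b$variance_proportions,
               tolerance = 1e-9)
  expect_equal(a$eigen_coefficients, b$eigen_coefficients,
               tolerance = 1e-7)
})
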