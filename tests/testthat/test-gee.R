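# clustered Gaussian data with exchangeable correlation, known effects
make_clustered <- function(n_clusters, n_per, beta = c(1, 0.5),
                           tau_b = 1, tau_e = 1, seed = 1) {
  set.seed(seed)
  id <- rep(seq_len(n_clusters), each = n_per)
  x <- rnorm(n_clusters * n_per)
  b <- rnorm(n_clusters, sd = tau_b)
  y <- beta[1] + beta[2] * x + b[id] + rnorm(length(id), sd = tau_e)
  data.frame(id = id, x = x, y = y)
}

test_that("with one observation per cluster the GEE reduces to OLS", {
  d <- make_clustered(80, 1, seed = 3)
  g <- fit_gee(y ~ x, d, id = "id")
  ols <- coef(lm(y ~ x, d))
  expect_equal(unname(g$coefficients), unname(ols), tolerance = 1e-10)
  expect_equal(g$alpha, 0)
})

test_that("the exchangeable correlation estimate recovers the true ICC", {
  d <- make_clustered(500, 10, tau_b = 1, tau_e = 1, seed = 5)
  g <- fit_gee(y ~ x, d, id = "id")
  expect_gte(g$alpha, 0.45)
  expect_lte(g$alpha, 0.55)
})

test_that("robust and model-based SEs agree when the working model is right", {
  d <- make_clustered(1000, 5, tau_b = 1, tau_e = 1, seed = 7)
  g <- fit_gee(y ~ x, d, id = "id")
  ratio <- sqrt(diag(g$vcov_robust)) / sqrt(diag(g$vcov_model))
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("independence working correlation matches OLS point estimates and a cluster sandwich", {
  d <- make_clustered(60, 6, seed = 9)
  g <- fit_gee(y ~ x, d, id = "id", corstr = "independence")
  fit <- lm(y ~ x, d)
  expect_equal(unname(g$coefficients), unname(coef(fit)), tolerance = 1e-10)
  vc <- sandwich::vcovCL(fit, cluster = d$id, type = "HC0", cadjust = FALSE)
  expect_equal(unname(g$vcov_robust), unname(vc), tolerance = 1e-6)
})

test_that("degenerate designs raise informative errors", {
  d <- make_clustered(30, 4, seed = 11)
  d$x2 <- d$x
  expect_error(fit_gee(y ~ x + x2, d, id = "id"), "x2")
  d1 <- d[d$id == 1, ]
  expect_error(fit_gee(y ~ x, d1, id = "id"), "2 clusters")
})

test_that("BH q-values and rejections match the step-up definition", {
  out <- bh_fdr(rep(1, 6))
  expect_true(all(out$q == 1) && !any(out$reject))

  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  out <- bh_fdr(p, alpha = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- c(runif(m), rbeta(sample(0:10, 1), 0.2, 5))
    o5 <- bh_oracle(p, 0.05)
    r5 <- bh_fdr(p, 0.05)
    expect_equal(r5$q, o5$q, tolerance = 1e-12)
    expect_identical(r5$reject, o5$reject)
    # monotonicity of the rejection set in alpha
    r1 <- bh_fdr(p, 0.01)
    expect_true(all(!r1$reject | r5$reject))
  }
})

test_that("the results table has one row per covariate level plus references", {
  cfg <- simulation_config(n_subjects = 40, days_per_subject = 7, seed = 41)
  ds <- simulate_actigraphy(cfg)
  pp <- preprocess_actigraphy(ds$minute_records, ds$day_covariates)
  valid <- which(pp$day_curves$meta$valid)
  coefs <- project_to_basis(pp$day_curves$values[valid, ])
  fp <- fit_fpca(coefs)
  sc <- compute_scores(fp, coefs,
                       meta = pp$day_curves$meta[valid,
                                                 c("subject_id", "date")])
  fr <- build_analysis_frame(sc, ds$subject_covariates, ds$day_covariates)
  a <- fit_associations(fr, components = 1:2, clinical = c("none", "group"))
  tab <- a$table
  # base model: one estimated row per design column (minus intercept),
  # plus one reference row per factor covariate, per component
  base <- tab[tab$model == "none" & tab$component == 1, ]
  X <- stats::model.matrix(
    ~ age + sex + education + partner + bmi + chronic + cigarettes +
      drinks + workday + season, fr)
  n_factors <- sum(vapply(fr[c("sex", "partner", "workday", "season")],
                          nlevels, 0L) > 1L)
  expect_equal(sum(!base$ref), ncol(X) - 1L)
  expect_equal(sum(base$ref), n_factors)
  # season: three non-reference rows, winter marked as reference
  sea <- base[base$variable == "season", ]
  expect_setequal(sea$level[!sea$ref], c("autumn", "spring", "summer"))
  expect_equal(sea$level[sea$ref], "winter")
  # group model adds remitted/current plus the "none" reference row
  grp <- tab[tab$model == "group" & tab$component == 2 &
               tab$variable == "group", ]
  expect_setequal(grp$level[!grp$ref], c("remitted", "current"))
  expect_equal(grp$level[grp$ref], "none")
  # q-values never undercut their p-values
  expect_true(all(tab$q >= tab$p - 1e-12, na.rm = TRUE))
  # empty input gives an empty table
  expect_equal(nrow(build_results_table(list())), 0L)
})
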