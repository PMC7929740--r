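# Independent oracles used across test files. These deliberately use naive
# loop-based or dense-matrix computations, not the package's own code paths.

# Brute-force Benjamini-Hochberg: q_i = min over j >= i of m * p_(j) / j,
# rejections = all p <= largest p_(i) with p_(i) <= i * alpha / m.
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  ok <- which(ps <= seq_len(m) * alpha / m)
  thresh <- if (length(ok)) ps[max(ok)] else -Inf
  list(q = q, reject = p <= thresh)
}

# Brute-force PCA of discretized 1440-point curves (dense covariance).
discretized_pca <- function(curves) {
  S <- stats::cov(curves)
  ee <- eigen(S, symmetric = TRUE)
  list(values = ee$values, vectors = ee$vectors)
}

# Angle in degrees between a fitted direction and a true direction (either
# may be sign-flipped).
principal_angle <- function(u, v) {
  ip <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, ip)) * 180 / pi
}

# Small simulation config for fast tests: 3 pure-harmonic components, flat
# mean curve well above zero, no covariate effects.
toy_config <- function(n_subjects = 20, days = 14, eigenvalues = c(4, 2, 1),
                       noise_sd = 0, gap_rate = 0, seed = 1,
                       icc = 0.5, mean_level = 10) {
  K <- length(eigenvalues)
  comps <- diag(9)[c(2, 4, 6, 8, 3, 5, 7, 9, 1)[seq_len(K)], , drop = FALSE]
  G <- matrix(0, K, 16, dimnames = list(NULL, actfda:::sim_design_columns()))
  simulation_config(
    n_subjects = n_subjects, days_per_subject = days,
    mean_curve = c(mean_level * sqrt(1440), rep(0, 8)),
    true_components = comps, eigenvalues = eigenvalues,
    effect_matrix = G,
    subject_sd = sqrt(icc * eigenvalues),
    day_sd = sqrt((1 - icc) * eigenvalues),
    noise_sd = noise_sd, gap_rate = gap_rate, seed = seed)
}

# Minute records for one subject-day with a given number of observed
# minutes, at a constant activity level.
one_day_records <- function(subject_id, date, n_observed, level = 100) {
  obs <- seq_len(1440) <= n_observed
  data.frame(subject_id = subject_id, date = as.Date(date),
             minute_of_day = 0:1439,
             activity = ifelse(obs, level, NA_real_),
             observed = obs)
}
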