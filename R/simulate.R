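#' Configuration for the synthetic actigraphy generator
#'
#' The generator draws subject- and day-level covariates, per-day component
#' scores with a subject random effect (so repeated days of one person are
#' correlated), and minute-level activity curves
#' \deqn{X_{ij}(t) = \max\{0,\; \mu(t) + \sum_k \xi_{ijk}\,\phi_k(t) +
#'   \varepsilon_{ij}(t)\},}
#' where the mean curve \eqn{\mu} and the orthonormal component functions
#' \eqn{\phi_k} live in the nine-function Fourier basis, the scores decompose
#' as \eqn{\xi_{ijk} = \Gamma_k' z_{ij} + b_{ik} + e_{ijk}} with
#' \eqn{b_{ik} \sim N(0,\tau_{b,k}^2)} per subject and
#' \eqn{e_{ijk} \sim N(0,\tau_{e,k}^2)} per day, and
#' \eqn{\varepsilon_{ij}(t) \sim N(0,\sigma^2)} is white minute noise.
#' Non-wear is injected afterwards as contiguous unobserved minute runs
#' (Poisson number of gaps per day, geometric lengths).
#'
#' Defaults emulate the sampling design of a two-week wrist-actigraphy study
#' in an adult psychiatric cohort: 359 subjects wearing the device for 14
#' consecutive days, nine modes of daily variation whose variance shares put
#' 77.4% of curve variability in the top four (overall level, early-vs-late
#' morning activity, biphasic-vs-monophasic shape, early-vs-late biphasic
#' timing), covariate effects on the per-SD scale of an epidemiological
#' association table, and a within-person day-to-day score correlation of
#' 0.5.
#'
#' @param n_subjects Number of subjects (default 359).
#' @param days_per_subject Consecutive recording days per subject (default 14).
#' @param n_basis Fourier basis size (default 9).
#' @param mean_curve Length-`n_basis` coefficient vector of \eqn{\mu};
#'   default is a diurnal profile (night floor, morning rise, daytime plateau
#'   with a shallow midday dip, evening decline) projected onto the basis.
#' @param true_components K x `n_basis` matrix of orthonormal component
#'   coefficient vectors (rows); default the nine built-in modes.
#' @param eigenvalues Length-K score variances (activity-units squared),
#'   nonincreasing; default `0.343, 0.165, 0.148, 0.118` and five equal minor
#'   shares of the remaining 22.6%, scaled by a total of 6.5e6.
#' @param effect_matrix K x covariate matrix \eqn{\Gamma} of raw score
#'   effects; columns must be named after the simulated design columns (see
#'   Details). Default: per-SD effects of the association-table magnitudes on
#'   the four leading components, zero on the minor ones.
#' @param subject_sd,day_sd Length-K between-subject and within-subject score
#'   SDs \eqn{\tau_b, \tau_e}; by default each eigenvalue is treated as the
#'   TOTAL score variance — the part explained by the covariate effects
#'   (under nominal design variances) is subtracted and the remainder split
#'   half-and-half between subject and day level (day-to-day intraclass
#'   correlation 0.5).
#' @param noise_sd Minute-level residual SD \eqn{\sigma} (default 25).
#' @param gap_rate Expected non-wear gaps per day (default 2).
#' @param gap_length Mean gap length in minutes (default 30).
#' @param start_date_range Two dates bounding the simulated first recording
#'   day of each subject.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(n_subjects = 359L,
                              days_per_subject = 14L,
                              n_basis = 9L,
                              mean_curve = NULL,
                              true_components = NULL,
                              eigenvalues = NULL,
                              effect_matrix = NULL,
                              subject_sd = NULL,
                              day_sd = NULL,
                              noise_sd = 25,
                              gap_rate = 2,
                              gap_length = 30,
                              start_date_range = as.Date(c("2015-01-01",
                                                           "2016-12-31")),
                              seed = 1L) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 1L)
    stop("invalid config: n_subjects must be a positive integer")
  if (days_per_subject < 1L)
    stop("invalid config: days_per_subject must be a positive integer")
  basis <- fourier_basis(n_basis)
  if (is.null(mean_curve)) mean_curve <- default_mean_coefficients(basis)
  if (length(mean_curve) != n_basis)
    stop("invalid config: mean_curve must have n_basis coefficients")
  if (is.null(true_components)) true_components <- default_components(basis)
  true_components <- as.matrix(true_components)
  if (ncol(true_components) != n_basis)
    stop("invalid config: true_components must have n_basis columns")
  K <- nrow(true_components)
  G <- tcrossprod(true_components)
  if (max(abs(G - diag(K))) > 1e-8)
    stop("invalid config: true_components must be pairwise orthonormal ",
         "in coefficient space (tolerance 1e-8)")
  if (is.null(eigenvalues)) {
    shares <- c(0.343, 0.165, 0.148, 0.118, rep(0.226 / 5, 5))[seq_len(K)]
    eigenvalues <- shares * 6.5e6
  }
  if (length(eigenvalues) != K || any(eigenvalues < 0))
    stop("invalid config: eigenvalues must be K nonnegative variances")
  if (is.null(effect_matrix))
    effect_matrix <- default_effect_matrix(K, sqrt(eigenvalues))
  effect_matrix <- as.matrix(effect_matrix)
  if (nrow(effect_matrix) != K)
    stop("invalid config: effect_matrix must have one row per component")
  if (is.null(colnames(effect_matrix)) ||
      !all(colnames(effect_matrix) %in% sim_design_columns()))
    stop("invalid config: effect_matrix columns must be named after ",
         "simulated design columns: ",
         paste(sim_design_columns(), collapse = ", "))
  if (is.null(subject_sd) && is.null(day_sd)) {
    # eigenvalues are TOTAL score variances: the random part absorbs the
    # variance the covariate effects explain (nominal design variances),
    # split half between subject and day level (day-to-day ICC 0.5)
    ev <- drop(effect_matrix^2 %*%
                 sim_design_variances()[colnames(effect_matrix)])
    resid_var <- pmax(eigenvalues - ev, 0)
    if (any(ev > eigenvalues))
      warning("covariate effects explain more than an eigenvalue; ",
              "residual score variance clamped at 0")
    subject_sd <- sqrt(resid_var / 2)
    day_sd <- sqrt(resid_var / 2)
  }
  if (is.null(subject_sd)) subject_sd <- sqrt(eigenvalues / 2)
  if (is.null(day_sd)) day_sd <- sqrt(eigenvalues / 2)
  if (length(subject_sd) != K || length(day_sd) != K ||
      any(subject_sd < 0) || any(day_sd < 0))
    stop("invalid config: subject_sd and day_sd must be K nonnegative SDs")
  if (length(noise_sd) != 1L || noise_sd < 0)
    stop("invalid config: noise_sd must be a single nonnegative value")
  if (gap_rate < 0 || gap_length <= 0)
    stop("invalid config: gap_rate must be >= 0 and gap_length > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 days_per_subject = as.integer(days_per_subject),
                 period = basis$period,
                 n_basis = as.integer(n_basis),
                 mean_curve = as.numeric(mean_curve),
                 true_components = true_components,
                 eigenvalues = as.numeric(eigenvalues),
                 effect_matrix = effect_matrix,
                 subject_sd = as.numeric(subject_sd),
                 day_sd = as.numeric(day_sd),
                 noise_sd = noise_sd,
                 gap_rate = gap_rate,
                 gap_length = gap_length,
                 start_date_range = as.Date(start_date_range),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic actigraphy config: %d subjects x %d days, ",
                     "%d components, noise SD %.3g, seed %d\n"),
              x$n_subjects, x$days_per_subject, nrow(x$true_components),
              x$noise_sd, x$seed))
  invisible(x)
}

# Diurnal mean profile projected onto the Fourier basis: night floor ~60,
# morning rise around 07:00, daytime plateau near 380 with a shallow midday
# dip, evening decline around 22:00.
default_mean_coefficients <- function(basis = fourier_basis()) {
  t <- basis$grid
  shape <- 60 + 340 * (stats::plogis((t - 420) / 55) -
                         stats::plogis((t - 1320) / 65)) -
    35 * exp(-((t - 790) / 95)^2)
  project_to_basis(shape, basis)
}

# Nine orthonormal modes of daily variation in Fourier-coefficient space.
# Rows 1-4 are interpretable: overall daytime level; early-vs-late morning
# (time-of-day preference); biphasic-vs-monophasic (12-h harmonic with a
# midday trough for positive scores); early-vs-late biphasic timing. Rows
# 5-9 complete an orthonormal set and carry the residual smooth day-to-day
# shape variability real curves exhibit beyond the leading modes.
default_components <- function(basis = fourier_basis()) {
  stopifnot(basis$n_basis == 9L)
  v <- rbind(
    c(0.75,  0.25, -0.55, 0.00, -0.15, 0.0, 0.0, 0.00, 0),
    c(0.00,  0.80,  0.15, 0.30,  0.00, 0.2, 0.0, 0.00, 0),
    c(0.00,  0.00, -0.10, 0.20, -0.80, 0.0, -0.2, 0.00, 0),
    c(0.00,  0.10,  0.00, 0.85,  0.20, 0.0, 0.0, 0.15, 0))
  Q <- qr.Q(qr(t(rbind(v, diag(9)[c(1, 3, 6, 8, 9), ]))))[, 1:9]
  comps <- t(Q)
  # orient each mode so its largest-magnitude coefficient is positive
  for (k in seq_len(nrow(comps))) {
    j <- which.max(abs(comps[k, ]))
    if (comps[k, j] < 0) comps[k, ] <- -comps[k, ]
  }
  colnames(comps) <- colnames(basis$eval)
  comps
}

# Columns of the simulated score design, in order. Continuous covariates are
# standardized with the generator's nominal moments; binaries enter as 0/1.
sim_design_columns <- function() {
  c("age_z", "male", "education_z", "partner", "bmi_z", "chronic_z",
    "cigarettes_z", "drinks_z", "workday", "season_autumn", "season_spring",
    "season_summer", "group_remitted", "group_current", "ids_z", "antidep")
}

# Nominal variances of the design columns (z-scored continuous -> 1,
# Bernoulli -> p(1-p), category dummies -> p(1-p)); used to apportion the
# eigenvalues between covariate-explained and random score variance.
sim_design_variances <- function() {
  c(age_z = 1, male = 0.365 * 0.635, education_z = 1, partner = 0.52 * 0.48,
    bmi_z = 1, chronic_z = 1, cigarettes_z = 1, drinks_z = 1,
    workday = 0.4 * 0.6, season_autumn = 0.25 * 0.75,
    season_spring = 0.25 * 0.75, season_summer = 0.25 * 0.75,
    group_remitted = 0.49 * 0.51, group_current = 0.26 * 0.74,
    ids_z = 1, antidep = 0.17 * 0.83)
}

# Nominal moments used to standardize continuous covariates in the design.
sim_nominal_moments <- function() {
  list(age = c(50, 12), education = c(13, 3), bmi = c(26.5, 5),
       chronic = c(0.9, 1), cigarettes = c(2.5, 5.5), drinks = c(0.7, 1),
       ids = c(19, 13))
}

# Default score-effect matrix: per-SD effect sizes typical of a multivariable
# actigraphy association table, converted to raw score units by the component
# score SDs. Minor components get no covariate effects.
default_effect_matrix <- function(K, score_sd) {
  per_sd <- rbind(
    c(-0.15, -0.05, -0.13, -0.17, -0.12, -0.11, -0.14,  0.08, 0.17,
       0.10,  0.15,  0.29, -0.06, -0.24, -0.14, -0.17),
    c( 0.08, -0.02, -0.01,  0.18,  0.05, -0.01,  0.03, -0.05, 0.28,
       0.19,  0.33,  0.18, -0.04,  0.02, -0.05, -0.12),
    c(-0.10, -0.03,  0.04, -0.02, -0.01, -0.03, -0.05, -0.04, 0.73,
       0.02,  0.14,  0.33, -0.05,  0.00, -0.02, -0.08),
    c( 0.10, -0.07, -0.03,  0.05,  0.01, -0.05,  0.02, -0.01, 0.19,
       0.14,  0.26,  0.24,  0.08, -0.01, -0.04, -0.11))
  G <- matrix(0, nrow = K, ncol = ncol(per_sd))
  for (k in seq_len(min(K, 4L))) G[k, ] <- per_sd[k, ] * score_sd[k]
  colnames(G) <- sim_design_columns()
  G
}

#' Draw subject- and day-level covariates
#'
#' Subject covariates follow the marginal distributions of an adult
#' psychiatric cohort: age N(50, 12), BMI N(26.5, 5), education years
#' N(13, 3), 63% female, 52% partnered, chronic-disease counts Poisson(0.9),
#' zero-inflated cigarettes/day, gamma drinks/day, diagnostic group
#' (none/remitted/current) multinomial (0.25, 0.49, 0.26), a depressive
#' symptom score whose mean and spread depend on group, and antidepressant
#' and benzodiazepine use more frequent in the current group. Each subject
#' records on consecutive calendar days from a start date drawn uniformly in
#' `start_date_range`; work/school-day flags are Bernoulli(0.4) and season
#' follows the calendar date.
#'
#' @param config A [simulation_config()].
#' @return List with data.frames `subjects` (one row per subject) and `days`
#'   (one row per subject-day: `subject_id`, `date`, `workday`, `season`).
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 101L)
  n <- config$n_subjects
  group <- sample(c("none", "remitted", "current"), n, replace = TRUE,
                  prob = c(0.25, 0.49, 0.26))
  ids_mu <- c(none = 6, remitted = 20.9, current = 28.6)[group]
  ids_sd <- c(none = 4.9, remitted = 12.5, current = 11.4)[group]
  antidep_p <- c(none = 0.022, remitted = 0.193, current = 0.372)[group]
  benzo_p <- c(none = 0.005, remitted = 0.045, current = 0.053)[group]
  smoker <- stats::rbinom(n, 1L, 0.25)
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = round(stats::rnorm(n, 50, 12), 1),
    male = stats::rbinom(n, 1L, 0.365),
    education = pmax(6, round(stats::rnorm(n, 13, 3))),
    partner = stats::rbinom(n, 1L, 0.52),
    bmi = round(pmax(15, stats::rnorm(n, 26.5, 5)), 1),
    chronic = stats::rpois(n, 0.9),
    cigarettes = smoker * round(stats::rexp(n, rate = 1 / 10)),
    drinks = round(stats::rgamma(n, shape = 0.5, scale = 1.4), 1),
    group = factor(group, levels = c("none", "remitted", "current")),
    ids = round(pmax(0, stats::rnorm(n, ids_mu, ids_sd))),
    antidep = stats::rbinom(n, 1L, antidep_p),
    benzo = stats::rbinom(n, 1L, benzo_p),
    stringsAsFactors = FALSE)
  span <- as.integer(diff(config$start_date_range))
  start <- config$start_date_range[1] + sample.int(span + 1L, n, TRUE) - 1L
  days <- data.frame(
    subject_id = rep(subjects$subject_id, each = config$days_per_subject),
    date = as.Date(as.vector(vapply(start, function(s)
      as.integer(s + seq_len(config$days_per_subject) - 1L),
      integer(config$days_per_subject))), origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  days$workday <- stats::rbinom(nrow(days), 1L, 0.4)
  days$season <- season_of(days$date)
  list(subjects = subjects, days = days)
}

# Day-level design matrix matching sim_design_columns(), built from the
# simulated covariates with the generator's nominal standardization.
sim_design_matrix <- function(covariates) {
  s <- covariates$subjects[match(covariates$days$subject_id,
                                 covariates$subjects$subject_id), ]
  d <- covariates$days
  m <- sim_nominal_moments()
  z <- function(x, key) (x - m[[key]][1]) / m[[key]][2]
  Z <- cbind(age_z = z(s$age, "age"),
             male = s$male,
             education_z = z(s$education, "education"),
             partner = s$partner,
             bmi_z = z(s$bmi, "bmi"),
             chronic_z = z(s$chronic, "chronic"),
             cigarettes_z = z(s$cigarettes, "cigarettes"),
             drinks_z = z(s$drinks, "drinks"),
             workday = d$workday,
             season_autumn = as.integer(d$season == "autumn"),
             season_spring = as.integer(d$season == "spring"),
             season_summer = as.integer(d$season == "summer"),
             group_remitted = as.integer(s$group == "remitted"),
             group_current = as.integer(s$group == "current"),
             ids_z = z(s$ids, "ids"),
             antidep = s$antidep)
  Z
}

#' Draw realized component scores
#'
#' Scores decompose as \eqn{\xi_{ijk} = \Gamma_k' z_{ij} + b_{ik} + e_{ijk}};
#' the subject effect \eqn{b_{ik}} induces a within-person day-to-day score
#' correlation of \eqn{\tau_b^2 / (\tau_b^2 + \tau_e^2)}.
#'
#' @param config A [simulation_config()].
#' @param covariates Output of [simulate_covariates()].
#' @return Matrix of realized scores, one row per row of `covariates$days`,
#'   one column per component.
#' @export
simulate_scores <- function(config, covariates) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 202L)
  K <- nrow(config$true_components)
  Z <- sim_design_matrix(covariates)
  G <- config$effect_matrix
  if (!all(colnames(G) %in% colnames(Z)))
    stop("shape error: effect_matrix columns do not match the simulated design")
  fixed <- Z[, colnames(G), drop = FALSE] %*% t(G)
  sid <- match(covariates$days$subject_id, covariates$subjects$subject_id)
  b <- matrix(stats::rnorm(config$n_subjects * K), ncol = K) %*%
    diag(config$subject_sd, K)
  e <- matrix(stats::rnorm(nrow(Z) * K), ncol = K) %*%
    diag(config$day_sd, K)
  xi <- fixed + b[sid, , drop = FALSE] + e
  colnames(xi) <- paste0("comp", seq_len(K))
  xi
}

#' Render minute-level activity curves from scores
#'
#' Evaluates \eqn{\max\{0, \mu(t) + \sum_k \xi_{ijk}\phi_k(t) +
#' \varepsilon_{ij}(t)\}} at the 1440 minute midpoints of each subject-day.
#'
#' @param config A [simulation_config()].
#' @param covariates Output of [simulate_covariates()].
#' @param scores Matrix from [simulate_scores()] (rows matching
#'   `covariates$days`).
#' @return A minute-record `data.table`: `subject_id`, `date`,
#'   `minute_of_day` (0-1439), `activity`, `observed` (all `TRUE` here).
#' @export
simulate_curves <- function(config, covariates, scores) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 303L)
  basis <- fourier_basis(config$n_basis, config$period)
  coefs <- sweep(scores %*% config$true_components, 2, config$mean_curve, "+")
  curves <- eval_basis(coefs, basis)
  if (config$noise_sd > 0)
    curves <- curves + stats::rnorm(length(curves), sd = config$noise_sd)
  curves <- pmax(curves, 0)
  n_days <- nrow(covariates$days)
  data.table::data.table(
    subject_id = rep(covariates$days$subject_id, each = config$period),
    date = rep(covariates$days$date, each = config$period),
    minute_of_day = rep.int(seq_len(config$period) - 1L, n_days),
    activity = as.vector(t(curves)),
    observed = TRUE)
}

#' Inject non-wear gaps into minute records
#'
#' Marks contiguous minute runs unobserved: the number of gaps per
#' subject-day is Poisson(`gap_rate`), gap lengths are geometric with mean
#' `gap_length` minutes, and start positions are uniform over the day (gaps
#' are truncated at midnight). Observed values are never altered; unobserved
#' minutes get `observed = FALSE` and `NA` activity.
#'
#' @param minute_records Minute-record table as from [simulate_curves()].
#' @param gap_rate Expected gaps per day (`0` leaves the input unchanged).
#' @param gap_length Mean gap length in minutes.
#' @param seed Integer seed for gap placement.
#' @return The minute-record table with gaps applied.
#' @export
inject_gaps <- function(minute_records, gap_rate, gap_length, seed = 1L) {
  if (gap_rate < 0) stop("gap_rate must be >= 0")
  mr <- data.table::as.data.table(minute_records)
  if (gap_rate == 0) return(mr)
  set.seed(seed)
  data.table::setorder(mr, subject_id, date, minute_of_day)
  day_id <- paste(mr$subject_id, mr$date)
  day_start <- which(!duplicated(day_id))
  day_len <- diff(c(day_start, nrow(mr) + 1L))
  n_gaps <- stats::rpois(length(day_start), gap_rate)
  drop_idx <- vector("list", length(day_start))
  for (i in which(n_gaps > 0L)) {
    len <- stats::rgeom(n_gaps[i], prob = 1 / gap_length) + 1L
    from <- sample.int(day_len[i], n_gaps[i], replace = TRUE)
    idx <- unlist(lapply(seq_along(from), function(g)
      seq.int(from[g], min(from[g] + len[g] - 1L, day_len[i]))))
    drop_idx[[i]] <- day_start[i] + unique(idx) - 1L
  }
  idx <- unlist(drop_idx)
  if (length(idx)) {
    mr$observed[idx] <- FALSE
    mr$activity[idx] <- NA_real_
  }
  mr[]
}

#' Simulate a complete actigraphy dataset with stored truth
#'
#' Runs covariate, score, curve and gap simulation in sequence. The returned
#' object keeps the full configuration and the realized scores so downstream
#' recovery can be checked against ground truth; with `noise_sd = 0` and
#' `gap_rate = 0` the stored truth reproduces every curve exactly.
#'
#' @param config A [simulation_config()].
#' @return A `sim_dataset`: list with `minute_records`, `subject_covariates`,
#'   `day_covariates`, and `truth` (the config plus realized `scores`).
#' @export
simulate_actigraphy <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  covariates <- simulate_covariates(config)
  scores <- simulate_scores(config, covariates)
  minute_records <- simulate_curves(config, covariates, scores)
  minute_records <- inject_gaps(minute_records, config$gap_rate,
                                config$gap_length, seed = config$seed + 404L)
  structure(list(minute_records = minute_records,
                 subject_covariates = covariates$subjects,
                 day_covariates = covariates$days,
                 truth = list(config = config, scores = scores)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("Synthetic actigraphy dataset: %d subjects, %d ",
                     "subject-days, %d minute records (%.1f%% observed)\n"),
              nrow(x$subject_covariates), nrow(x$day_covariates),
              nrow(x$minute_records), 100 * mean(x$minute_records$observed)))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `minute_records.csv` (long format:
#' `subject_id,date,minute_of_day,activity,observed`),
#' `subject_covariates.csv`, `day_covariates.csv`, and `truth.json` (config
#' and realized scores) into `dir`.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("minute_records.csv", "subject_covariates.csv",
                            "day_covariates.csv", "truth.json"))
  data.table::fwrite(dataset$minute_records, paths[1])
  data.table::fwrite(dataset$subject_covariates, paths[2])
  data.table::fwrite(dataset$day_covariates, paths[3])
  truth <- dataset$truth
  truth$config <- unclass(truth$config)
  truth$config$start_date_range <- as.character(truth$config$start_date_range)
  jsonlite::write_json(truth, paths[4], digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(paths)
}
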