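#' Average each subject's valid days into a 10-minute diurnal curve
#'
#' Aggregates minute-level day curves over 10-minute bins (bin value = mean
#' of its constituent minutes) and averages the binned curves over each
#' subject's valid days, yielding one 144-point diurnal profile per subject.
#' Day-varying covariates are collapsed to the subject level: the
#' work/school-day flag becomes the proportion of valid days that are
#' workdays, and season becomes the modal season of the valid days (ties
#' broken by the fixed level order winter, autumn, spring, summer).
#'
#' @param day_curves An imputed `day_curves` object (valid days complete).
#' @param bin_width Bin width in minutes (default 10).
#' @return A `subject_curves` object: matrix `values` (subjects by 144),
#'   `grid` of bin midpoints in minutes, and data.frame `subjects`
#'   (`subject_id`, `n_valid_days`, `prop_workdays`, `modal_season`).
#'   Subjects with zero valid days are dropped and listed in the `dropped`
#'   attribute.
#' @export
build_subject_curves <- function(day_curves, bin_width = 10L) {
  stopifnot(inherits(day_curves, "day_curves"))
  m <- day_curves$meta
  if (anyNA(m$valid)) stop("run flag_valid_days() before build_subject_curves")
  period <- ncol(day_curves$values)
  if (period %% bin_width != 0L)
    stop("bin_width must divide the day length")
  nbin <- period %/% bin_width
  ids <- unique(m$subject_id)
  keep_rows <- which(m$valid)
  if (length(keep_rows) && anyNA(day_curves$values[keep_rows, ]))
    stop("valid days contain missing values; run impute_missing() first")
  bin_of <- rep(seq_len(nbin), each = bin_width)
  subj <- list(); curves <- list(); dropped <- character(0)
  for (sid in ids) {
    rows <- which(m$subject_id == sid & m$valid)
    if (length(rows) == 0L) { dropped <- c(dropped, sid); next }
    day_mean <- colMeans(day_curves$values[rows, , drop = FALSE])
    binned <- as.vector(rowsum(day_mean, bin_of)) / bin_width
    curves[[sid]] <- binned
    season_counts <- table(factor(as.character(m$season[rows]),
                                  levels = levels(m$season)))
    subj[[sid]] <- data.frame(
      subject_id = sid, n_valid_days = length(rows),
      prop_workdays = mean(as.integer(m$workday[rows]) == 1L),
      modal_season = names(season_counts)[which.max(season_counts)],
      stringsAsFactors = FALSE)
  }
  if (length(dropped))
    message("dropped ", length(dropped), " subject(s) with no valid days")
  values <- do.call(rbind, curves)
  subjects <- do.call(rbind, subj)
  rownames(values) <- rownames(subjects) <- NULL
  structure(list(values = values,
                 grid = (seq_len(nbin) - 0.5) * bin_width,
                 subjects = subjects),
            class = "subject_curves", dropped = dropped)
}

#' Join subject covariates onto subject curves for FoSR
#'
#' Merges the subject-level covariate table with the per-subject curve
#' summaries, z-scores the continuous determinants (so coefficient functions
#' are per covariate SD, matching the score regressions) and recodes
#' categorical determinants with the conventional reference levels.
#'
#' @param subject_curves A `subject_curves` object.
#' @param subject_covariates Subject-level covariate table.
#' @return data.frame with one row per curve row, model-ready.
#' @export
prepare_fosr_frame <- function(subject_curves, subject_covariates) {
  stopifnot(inherits(subject_curves, "subject_curves"))
  s <- as.data.frame(subject_covariates)
  out <- subject_curves$subjects
  j <- match(out$subject_id, s$subject_id)
  if (anyNA(j)) stop("subject covariates missing for some curve subjects")
  for (v in setdiff(names(s), names(out))) out[[v]] <- s[[v]][j]
  zsc <- function(x) as.numeric(scale(x))
  for (v in intersect(c("age", "education", "bmi", "chronic", "cigarettes",
                        "drinks", "ids"), names(out)))
    out[[v]] <- zsc(out[[v]])
  if ("male" %in% names(out)) {
    out$sex <- factor(ifelse(out$male == 1, "male", "female"),
                      levels = c("female", "male"))
    out$male <- NULL
  }
  if ("partner" %in% names(out))
    out$partner <- factor(ifelse(out$partner == 1, "yes", "no"),
                          levels = c("no", "yes"))
  out$modal_season <- factor(out$modal_season,
                             levels = c("winter", "autumn", "spring",
                                        "summer"))
  if ("group" %in% names(out))
    out$group <- factor(as.character(out$group),
                        levels = c("none", "remitted", "current"))
  for (v in intersect(c("antidep", "benzo"), names(out)))
    out[[v]] <- factor(ifelse(out[[v]] == 1, "yes", "no"),
                       levels = c("no", "yes"))
  droplevels(out)
}

#' Function-on-scalar regression of diurnal curves
#'
#' Regresses subject-level diurnal curves on scalar covariates,
#' \eqn{Y_i(t) = \sum_j x_{ij} \beta_j(t) + E_i(t)}. Each coefficient
#' function is expanded in a cubic B-spline basis on the daily grid
#' (`n_basis` functions, default 10) and the stacked model is fitted by
#' least squares across subjects and grid points, which factorizes into
#' \eqn{\hat B = (X'X)^{-1} X' Y \Theta (\Theta'\Theta)^{-1}}. With
#' `n_basis` equal to the number of grid points the basis is the identity
#' and the fit reduces to independent pointwise ordinary least squares.
#'
#' Pointwise standard errors use a cluster (subject-level) sandwich over the
#' curve residuals. The global per-covariate test is a Wald test on the
#' covariate's full block of basis coefficients against a Hotelling
#' \eqn{T^2} F reference (exact under Gaussian errors with an unstructured
#' residual covariance across the grid): with \eqn{q} basis functions,
#' \eqn{n} subjects and \eqn{p} design columns,
#' \eqn{F = T^2 (n-p-q+1) / ((n-p)q) \sim F_{q,\,n-p-q+1}} under the null.
#'
#' An optional second-difference roughness penalty on the basis coefficients
#' is available (`penalty = "gcv"`), with the penalty weight chosen by
#' generalized cross-validation.
#'
#' @param curves A `subject_curves` object (or a plain matrix, in which case
#'   `grid` must be supplied).
#' @param formula RHS-only or two-sided formula naming covariate columns of
#'   `data` (the LHS is ignored; the outcome is the curve matrix).
#' @param data Covariate data.frame, one row per curve row (e.g. from
#'   [prepare_fosr_frame()]).
#' @param n_basis Number of B-spline functions per coefficient function
#'   (default 10); use the number of grid points for a saturated fit.
#' @param penalty `"none"` (default) or `"gcv"`.
#' @param gcv_grid Candidate penalty weights for `penalty = "gcv"`.
#' @param grid Grid midpoints when `curves` is a plain matrix.
#' @return A `fosr_fit`: `grid`, `terms`, coefficient-function matrix `beta`
#'   (terms by grid), sandwich `se` (same shape), basis matrix `theta`,
#'   basis-coefficient matrix `B`, per-term covariances, `global`
#'   (data.frame of Wald statistics, df and p-values), and fit metadata.
#' @export
fit_fosr <- function(curves, formula, data, n_basis = 10L,
                     penalty = c("none", "gcv"),
                     gcv_grid = 10^seq(-2, 6, length.out = 25),
                     grid = NULL) {
  penalty <- match.arg(penalty)
  Y <- if (inherits(curves, "subject_curves")) curves$values else
    as.matrix(curves)
  if (is.null(grid))
    grid <- if (inherits(curves, "subject_curves")) curves$grid else
      stop("supply grid when curves is a plain matrix")
  n <- nrow(Y); Tn <- ncol(Y)
  X <- stats::model.matrix(stats::delete.response(stats::terms(formula)),
                           as.data.frame(data))
  if (nrow(X) != n) stop("covariate rows do not match curve rows")
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, p)]]
    stop("collinearity error: design is rank deficient in column(s) ",
         paste(bad, collapse = ", "))
  }
  if (n_basis > Tn) stop("n_basis cannot exceed the number of grid points")
  theta <- if (n_basis == Tn) diag(Tn) else
    unclass(splines::bs(grid, df = n_basis, degree = 3L, intercept = TRUE,
                        Boundary.knots = c(0, max(grid) + grid[1])))
  q <- ncol(theta)
  XtXi <- solve(crossprod(X))
  G <- XtXi %*% t(X)                      # p x n projector
  TtT <- crossprod(theta)
  if (penalty == "gcv") {
    D <- diff(diag(q), differences = 2L)
    P <- crossprod(D)
    best <- NULL
    for (lam in gcv_grid) {
      M <- solve(TtT + lam * P)
      B <- G %*% Y %*% theta %*% M
      fitted <- X %*% B %*% t(theta)
      rss <- sum((Y - fitted)^2)
      edf <- p * sum(diag(theta %*% M %*% t(theta)))
      gcv <- (rss / (n * Tn)) / (1 - edf / (n * Tn))^2
      if (is.null(best) || gcv < best$gcv)
        best <- list(gcv = gcv, lambda = lam, M = M, B = B)
    }
    M <- best$M; B <- best$B; lambda <- best$lambda
  } else {
    M <- solve(TtT)
    B <- G %*% Y %*% theta %*% M
    lambda <- 0
  }
  beta_fun <- B %*% t(theta)              # p x Tn coefficient functions
  fitted <- X %*% beta_fun
  resid <- Y - fitted
  # basis-coefficient residuals per subject, for covariances
  Rc <- resid %*% theta %*% M             # n x q
  S_model <- crossprod(Rc) / max(n - p, 1L)
  dfc <- n / max(n - p, 1L)               # small-sample sandwich correction
  cov_sand <- vector("list", p)
  cov_model <- vector("list", p)
  se <- matrix(0, p, Tn, dimnames = list(colnames(X), NULL))
  for (j in seq_len(p)) {
    w <- G[j, ]^2
    cov_sand[[j]] <- crossprod(Rc * sqrt(w)) * dfc
    cov_model[[j]] <- XtXi[j, j] * S_model
    se[j, ] <- sqrt(pmax(rowSums((theta %*% cov_sand[[j]]) * theta), 0))
  }
  names(cov_sand) <- names(cov_model) <- colnames(X)
  df2 <- n - p - q + 1L
  global <- data.frame(term = colnames(X), wald = NA_real_, df1 = q,
                       df2 = df2, statistic = NA_real_, p = NA_real_,
                       stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    T2 <- tryCatch(drop(B[j, ] %*% solve(cov_model[[j]], B[j, ])),
                   error = function(e) NA_real_)
    global$wald[j] <- T2
    if (!is.na(T2) && df2 >= 1L && penalty == "none") {
      Fstat <- T2 * df2 / ((n - p) * q)
      global$statistic[j] <- Fstat
      global$p[j] <- stats::pf(Fstat, q, df2, lower.tail = FALSE)
    } else if (!is.na(T2)) {
      global$statistic[j] <- T2
      global$p[j] <- stats::pchisq(T2, df = q, lower.tail = FALSE)
    }
  }
  rownames(beta_fun) <- colnames(X)
  structure(list(grid = grid, terms = colnames(X), beta = beta_fun, se = se,
                 theta = theta, B = B, cov_coef = cov_sand,
                 cov_coef_model = cov_model, global = global,
                 fitted = fitted, residuals = resid, n = n, p = p,
                 n_basis = q, penalty = penalty, lambda = lambda,
                 formula = formula),
            class = "fosr_fit")
}

#' @export
print.fosr_fit <- function(x, ...) {
  cat(sprintf(paste0("Function-on-scalar regression: %d subjects, %d grid ",
                     "points, %d-function coefficient basis (%s)\n"),
              x$n, length(x$grid), x$n_basis,
              if (x$penalty == "none") "unpenalized"
              else sprintf("GCV penalty, lambda = %.3g", x$lambda)))
  g <- x$global[x$global$term != "(Intercept)", ]
  if (nrow(g)) {
    cat("Global covariate tests:\n")
    print(data.frame(term = g$term, statistic = round(g$statistic, 3),
                     p = signif(g$p, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Pointwise confidence bands for FoSR coefficient functions
#'
#' Normal-theory pointwise bands
#' \eqn{\hat\beta_j(t) \pm z_{1-(1-\mathrm{level})/2}\,\widehat{SE}_j(t)}.
#'
#' @param fit A `fosr_fit`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Long data.frame: `term`, `t` (grid minutes), `beta`, `se`, `lo`,
#'   `hi`.
#' @export
pointwise_bands <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fosr_fit"))
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
    stop("invalid config: level must lie strictly between 0 and 1")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- do.call(rbind, lapply(seq_along(fit$terms), function(j) {
    data.frame(term = fit$terms[j], t = fit$grid, beta = fit$beta[j, ],
               se = fit$se[j, ],
               lo = fit$beta[j, ] - zq * fit$se[j, ],
               hi = fit$beta[j, ] + zq * fit$se[j, ],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Subject-resampling bootstrap for FoSR global tests
#'
#' Robust alternative to the Hotelling-F global test: resamples subjects
#' with replacement, refits, and compares the observed Wald statistic of
#' each covariate block to its bootstrap null distribution obtained by
#' centering the bootstrap coefficient blocks at the estimate.
#'
#' @param curves,formula,data,n_basis As in [fit_fosr()].
#' @param n_boot Number of bootstrap draws (default 500).
#' @param seed Integer seed.
#' @return data.frame: `term`, `statistic` (observed Wald), `p_boot`.
#' @export
fosr_bootstrap_global <- function(curves, formula, data, n_basis = 10L,
                                  n_boot = 500L, seed = 1L) {
  fit <- fit_fosr(curves, formula, data, n_basis = n_basis)
  Y <- if (inherits(curves, "subject_curves")) curves$values else
    as.matrix(curves)
  set.seed(seed)
  p <- fit$p
  stat_obs <- fit$global$wald
  exceed <- numeric(p)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(Y), replace = TRUE)
    fb <- fit_fosr(Y[idx, , drop = FALSE], formula,
                   as.data.frame(data)[idx, , drop = FALSE],
                   n_basis = n_basis, grid = fit$grid)
    for (j in seq_len(p)) {
      d <- fb$B[j, ] - fit$B[j, ]
      stat_b <- tryCatch(drop(d %*% solve(fb$cov_coef_model[[j]], d)),
                         error = function(e) NA_real_)
      if (!is.na(stat_b) && stat_b >= stat_obs[j])
        exceed[j] <- exceed[j] + 1
    }
  }
  data.frame(term = fit$terms, statistic = stat_obs,
             p_boot = (exceed + 1) / (n_boot + 1))
}
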