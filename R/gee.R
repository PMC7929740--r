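#' Gaussian GEE with exchangeable working correlation
#'
#' Fits identity-link Gaussian generalized estimating equations for repeated
#' days clustered within subjects. The working correlation is exchangeable
#' (a common correlation \eqn{\alpha} between any two days of one subject;
#' moment estimator from cross-day residual products) or independence.
#' Inference uses the robust sandwich covariance
#' \eqn{A^{-1} \left(\sum_i U_i U_i'\right) A^{-1}} over clusters; the
#' model-based covariance is also returned. Wald z statistics and normal
#' p-values are reported per coefficient.
#'
#' The exchangeable working covariance has the closed-form inverse
#' \eqn{V_i^{-1} = \frac{1}{\sigma^2(1-\alpha)}\left[I -
#' \frac{\alpha}{1+(n_i-1)\alpha} J\right]}, so the fit is a few
#' cluster-aggregated matrix products and scales to thousands of clusters.
#'
#' @param formula Model formula (Gaussian outcome).
#' @param data data.frame with the model variables and the cluster id.
#' @param id Cluster identifier: a column name in `data` or a vector.
#' @param corstr Working correlation: `"exchangeable"` or `"independence"`.
#' @param maxit,tol Iteration control for the coefficient/correlation
#'   updates.
#' @return A `gee_fit`: coefficients, robust and model-based covariance,
#'   per-coefficient robust SE / z / p, working correlation `alpha`,
#'   residual variance `sigma2`, cluster and observation counts, and the
#'   number of rows dropped as incomplete cases.
#' @export
fit_gee <- function(formula, data, id, corstr = c("exchangeable",
                                                  "independence"),
                    maxit = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  data <- as.data.frame(data)
  cl_raw <- if (is.character(id) && length(id) == 1L) data[[id]] else id
  if (length(cl_raw) != nrow(data))
    stop("cluster id must match the number of rows in data")
  vars <- all.vars(formula)
  keep <- stats::complete.cases(data[, vars, drop = FALSE]) & !is.na(cl_raw)
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  cl <- factor(cl_raw[keep])
  if (nlevels(cl) < 2L)
    stop("GEE requires at least 2 clusters")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("collinearity error: design is rank deficient in column(s) ",
         paste(bad, collapse = ", "))
  }
  N <- nrow(X); p <- ncol(X)
  nvec <- as.vector(table(cl))
  npairs <- sum(nvec * (nvec - 1)) / 2
  alpha_lo <- -1 / (max(nvec) - 1 + 1e-12)
  beta <- qr.coef(qx, y)
  alpha <- 0
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    sigma2 <- sum(r^2) / (N - p)
    if (corstr == "exchangeable" && npairs > p) {
      S <- rowsum(r, cl)
      Q <- rowsum(r^2, cl)
      alpha <- sum((S^2 - Q) / 2) / ((npairs - p) * sigma2)
      alpha <- min(max(alpha, alpha_lo + 1e-6), 1 - 1e-6)
    } else alpha <- 0
    cc <- alpha / (1 + (nvec - 1) * alpha)
    Xs <- rowsum(X, cl)
    ys <- rowsum(y, cl)
    A <- crossprod(X) - crossprod(Xs, Xs * cc)
    b <- crossprod(X, y) - crossprod(Xs, cc * ys)
    beta_new <- drop(solve(A, b))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol * (1 + max(abs(beta)))) break
  }
  r <- y - drop(X %*% beta)
  sigma2 <- sum(r^2) / (N - p)
  scale_inv <- 1 / (sigma2 * (1 - alpha))
  A_full <- A * scale_inv
  rs <- rowsum(r, cl)
  U <- (rowsum(X * r, cl) - Xs * drop(cc * rs)) * scale_inv
  meat <- crossprod(U)
  bread <- solve(A_full)
  vcov_robust <- bread %*% meat %*% bread
  vcov_model <- bread
  se <- sqrt(diag(vcov_robust))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, se = se, z = z, p = pval,
                 vcov_robust = vcov_robust, vcov_model = vcov_model,
                 alpha = alpha, sigma2 = sigma2, corstr = corstr,
                 n_clusters = nlevels(cl), n_obs = N,
                 n_dropped = n_dropped, formula = formula),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(paste0("Gaussian GEE (%s working correlation): %d obs in %d ",
                     "clusters; alpha = %.3f, sigma^2 = %.4g\n"),
              x$corstr, x$n_obs, x$n_clusters, x$alpha, x$sigma2))
  tab <- data.frame(beta = x$coefficients, robust_se = x$se, z = x$z,
                    p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment: \eqn{q_i = \min_{j \ge i} m\,p_{(j)}/j} (capped at
#' 1), with the rejection set at level `alpha` equal to all p-values at most
#' the largest \eqn{p_{(i)} \le i\alpha/m}. Rejections are exactly
#' `q <= alpha`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return data.frame with `p`, `q` and logical `reject`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, reject = q <= alpha)
}

# Covariates of the base (always-adjusted) block, and the optional clinical
# covariates; separate models per clinical covariate avoid the collinearity
# of highly correlated psychiatric measures.
assoc_base_terms <- function() {
  c("age", "sex", "education", "partner", "bmi", "chronic", "cigarettes",
    "drinks", "workday", "season")
}

#' Prepare a day-level analysis frame for the association models
#'
#' Joins standardized component scores (wide, one column per component) with
#' subject- and day-level covariates, recodes categorical determinants as
#' factors with the conventional reference levels (female sex, no partner,
#' non-workday, winter, no-diagnosis group, no antidepressant), and z-scores
#' the continuous determinants so coefficients are per covariate SD.
#'
#' @param score_table Long score table from [compute_scores()] carrying
#'   `subject_id` and `date`.
#' @param subject_covariates Subject-level covariate table (as produced by
#'   [simulate_covariates()] or read from CSV).
#' @param day_covariates Day-level covariate table (`subject_id`, `date`,
#'   `workday`, optionally `season`).
#' @return data.frame with `subject_id`, `date`, `comp<k>` standardized
#'   scores, and model-ready covariate columns.
#' @export
build_analysis_frame <- function(score_table, subject_covariates,
                                 day_covariates) {
  w <- scores_wide(score_table, value = "score_std")
  s <- as.data.frame(subject_covariates)
  d <- as.data.frame(day_covariates)
  d$date <- as.Date(d$date)
  w$date <- as.Date(w$date)
  out <- merge(w, s, by = "subject_id", sort = FALSE)
  dn <- setdiff(names(d), names(out))
  j <- match(paste(out$subject_id, out$date), paste(d$subject_id, d$date))
  for (v in dn) out[[v]] <- d[[v]][j]
  if (!"season" %in% names(out)) out$season <- season_of(out$date)
  zsc <- function(x) as.numeric(scale(x))
  for (v in intersect(c("age", "education", "bmi", "chronic", "cigarettes",
                        "drinks", "ids"), names(out)))
    out[[v]] <- zsc(out[[v]])
  out$sex <- factor(ifelse(out$male == 1, "male", "female"),
                    levels = c("female", "male"))
  out$partner <- factor(ifelse(out$partner == 1, "yes", "no"),
                        levels = c("no", "yes"))
  out$workday <- factor(ifelse(as.integer(out$workday) == 1, "yes", "no"),
                        levels = c("no", "yes"))
  out$season <- factor(as.character(out$season),
                       levels = c("winter", "autumn", "spring", "summer"))
  if ("group" %in% names(out))
    out$group <- factor(as.character(out$group),
                        levels = c("none", "remitted", "current"))
  if ("antidep" %in% names(out))
    out$antidep <- factor(ifelse(out$antidep == 1, "yes", "no"),
                          levels = c("no", "yes"))
  if ("benzo" %in% names(out))
    out$benzo <- factor(ifelse(out$benzo == 1, "yes", "no"),
                        levels = c("no", "yes"))
  out$male <- NULL
  droplevels(out)
}

#' Fit the per-component association models
#'
#' For every retained component and every requested clinical covariate
#' (plus the covariate-free base model), fits a GEE of the standardized
#' day-level score on the base sociodemographic, health/lifestyle and
#' sampling block — age, sex, education, partner status, BMI, chronic
#' diseases, cigarettes/day, drinks/day, work/school day, season — plus at
#' most one clinical covariate. Clinical covariates never co-occur in one
#' model.
#'
#' @param frame Analysis frame from [build_analysis_frame()].
#' @param components Integer vector of component indices (columns
#'   `comp<k>` must exist).
#' @param clinical Character vector out of `"none"`, `"group"`, `"ids"`,
#'   `"antidep"`, `"benzo"`.
#' @param corstr Working correlation passed to [fit_gee()].
#' @param fdr_alpha FDR level for the q-values.
#' @return An `assoc_results` list: `fits` (named list of `gee_fit`s) and
#'   `table` (the long results table from [build_results_table()]).
#' @export
fit_associations <- function(frame, components,
                             clinical = c("none", "group", "ids", "antidep"),
                             corstr = "exchangeable", fdr_alpha = 0.05) {
  clinical <- match.arg(clinical, c("none", "group", "ids", "antidep",
                                    "benzo"), several.ok = TRUE)
  fits <- list()
  for (k in components) {
    for (cv in clinical) {
      rhs <- paste(assoc_base_terms(), collapse = " + ")
      if (cv != "none") rhs <- paste(rhs, "+", cv)
      f <- stats::as.formula(paste0("comp", k, " ~ ", rhs))
      fits[[paste0("comp", k, ".", cv)]] <-
        list(component = k, clinical = cv,
             fit = fit_gee(f, frame, id = "subject_id", corstr = corstr))
    }
  }
  structure(list(fits = fits,
                 table = build_results_table(fits, fdr_alpha = fdr_alpha)),
            class = "assoc_results")
}

# Map a model.matrix term name to (variable, level) using the factor levels
# of the fitted frame; continuous terms get level "".
term_variable_level <- function(term) {
  known <- list(sex = c("female", "male"), partner = c("no", "yes"),
                workday = c("no", "yes"),
                season = c("winter", "autumn", "spring", "summer"),
                group = c("none", "remitted", "current"),
                antidep = c("no", "yes"), benzo = c("no", "yes"))
  for (v in names(known)) {
    for (lev in known[[v]]) {
      if (term == paste0(v, lev)) return(c(v, lev))
    }
  }
  c(term, "")
}

#' Assemble the long association results table
#'
#' One row per (component, model, covariate level): coefficient, robust SE,
#' Wald p, and an FDR q-value computed within each (component, model) family
#' of non-reference tests. Reference levels of categorical covariates are
#' emitted as rows flagged `ref = TRUE` with empty estimates, mirroring the
#' conventional epidemiological results layout.
#'
#' @param fits List of `list(component, clinical, fit)` entries as built by
#'   [fit_associations()].
#' @param fdr_alpha FDR level.
#' @return data.frame with columns `component`, `model`, `variable`,
#'   `level`, `beta`, `se`, `z`, `p`, `q`, `ref`, `n_subjects`, `n_days`.
#' @export
build_results_table <- function(fits, fdr_alpha = 0.05) {
  if (length(fits) == 0L)
    return(data.frame(component = integer(0), model = character(0),
                      variable = character(0), level = character(0),
                      beta = numeric(0), se = numeric(0), z = numeric(0),
                      p = numeric(0), q = numeric(0), ref = logical(0),
                      n_subjects = integer(0), n_days = integer(0)))
  n_obs_by_comp <- tapply(vapply(fits, function(f) f$fit$n_obs, 0),
                          vapply(fits, function(f) f$clinical, ""),
                          function(x) length(unique(x)))
  if (any(n_obs_by_comp > 1L))
    stop("integrity error: component models were fitted on different samples")
  ref_levels <- list(sex = "female", partner = "no", workday = "no",
                     season = "winter", group = "none", antidep = "no",
                     benzo = "no")
  rows <- list()
  for (f in fits) {
    fit <- f$fit
    terms <- setdiff(names(fit$coefficients), "(Intercept)")
    vl <- t(vapply(terms, term_variable_level, character(2)))
    q <- bh_fdr(fit$p[terms], alpha = fdr_alpha)$q
    block <- data.frame(component = f$component, model = f$clinical,
                        variable = vl[, 1], level = vl[, 2],
                        beta = unname(fit$coefficients[terms]),
                        se = unname(fit$se[terms]), z = unname(fit$z[terms]),
                        p = unname(fit$p[terms]), q = q, ref = FALSE,
                        n_subjects = fit$n_clusters, n_days = fit$n_obs,
                        stringsAsFactors = FALSE)
    for (v in unique(vl[vl[, 2] != "", 1])) {
      present <- vl[vl[, 1] == v, 2]
      ref <- setdiff(ref_levels[[v]], present)
      if (length(ref) == 0L) ref <- ref_levels[[v]][1]
      block <- rbind(block,
                     data.frame(component = f$component, model = f$clinical,
                                variable = v, level = ref[1],
                                beta = NA_real_, se = NA_real_, z = NA_real_,
                                p = NA_real_, q = NA_real_, ref = TRUE,
                                n_subjects = fit$n_clusters,
                                n_days = fit$n_obs))
    }
    rows[[length(rows) + 1L]] <- block
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$component, out$model, out$variable, out$ref,
                   out$level), ]
  rownames(out) <- NULL
  out
}

#' @export
print.assoc_results <- function(x, ...) {
  cat(sprintf("GEE association results: %d model fits, %d table rows\n",
              length(x$fits), nrow(x$table)))
  invisible(x)
}
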