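#' Functional PCA of daily activity curves in Fourier-coefficient space
#'
#' Fits the mean function and the principal directions of day-to-day
#' variation from the basis coefficients of all valid subject-days pooled
#' across participants. Because the Fourier basis is orthonormal on the
#' minute grid, PCA of the 9-dimensional coefficient vectors is exactly
#' functional PCA of the discretized 1440-point curves; the discretized-curve
#' route is kept as a test oracle.
#'
#' Each eigenfunction is sign-oriented so that its largest-magnitude Fourier
#' coefficient is positive (the sign of a principal direction is otherwise
#' arbitrary).
#'
#' @param coefs Matrix of basis coefficients, one row per valid subject-day.
#' @param threshold Cumulative variance proportion required of the retained
#'   leading components (default 0.75).
#' @param basis The [fourier_basis()] the coefficients live in.
#' @return An `fpca_model`: `mean_coefficients`, `eigen_coefficients` (one
#'   eigenfunction per row, coefficient space), `eigenvalues` (descending),
#'   `variance_proportions`, `n_retained`, `score_sd`, `n_curves`, `basis`.
#' @export
fit_fpca <- function(coefs, threshold = 0.75, basis = fourier_basis()) {
  C <- as.matrix(coefs)
  if (nrow(C) < 2L)
    stop("degenerate input: functional PCA needs at least 2 day-curves")
  if (ncol(C) != basis$n_basis)
    stop("coefficient matrix does not match the basis dimension")
  mu <- colMeans(C)
  S <- stats::cov(C)
  ee <- eigen(S, symmetric = TRUE)
  lambda <- pmax(ee$values, 0)
  E <- t(ee$vectors)
  for (k in seq_len(nrow(E))) {
    j <- which.max(abs(E[k, ]))
    if (E[k, j] < 0) E[k, ] <- -E[k, ]
  }
  colnames(E) <- colnames(basis$eval)
  total <- sum(lambda)
  props <- if (total > 0) lambda / total else rep(0, length(lambda))
  n_ret <- if (total > 0) select_num_components(props, threshold) else 0L
  structure(list(mean_coefficients = mu, eigen_coefficients = E,
                 eigenvalues = lambda, variance_proportions = props,
                 n_retained = n_ret, score_sd = sqrt(lambda),
                 n_curves = nrow(C), basis = basis),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("Functional PCA of %d day-curves (%d-function Fourier basis)\n",
              x$n_curves, x$basis$n_basis))
  k <- seq_len(max(x$n_retained, min(4L, length(x$eigenvalues))))
  cat(sprintf("  retained %d components, cumulative variance %.1f%%\n",
              x$n_retained,
              100 * sum(x$variance_proportions[seq_len(x$n_retained)])))
  for (i in k)
    cat(sprintf("  component %d: eigenvalue %.4g (%.1f%% of variance)\n",
                i, x$eigenvalues[i], 100 * x$variance_proportions[i]))
  invisible(x)
}

#' Number of components needed to reach a cumulative variance threshold
#'
#' Returns the smallest K whose leading variance proportions sum to at least
#' `threshold` (default 0.75, the retain-at-least-75%-of-variability rule).
#'
#' @param variance_proportions Nonincreasing proportions summing to at most 1.
#' @param threshold Required cumulative proportion, in (0, 1].
#' @return Integer K.
#' @export
select_num_components <- function(variance_proportions, threshold = 0.75) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("invalid config: threshold must lie in (0, 1]")
  p <- as.numeric(variance_proportions)
  if (any(p < -1e-12) || sum(p) > 1 + 1e-9)
    stop("variance proportions must be nonnegative and sum to at most 1")
  if (is.unsorted(rev(p), strictly = FALSE) && any(diff(p) > 1e-12))
    stop("variance proportions must be sorted in decreasing order")
  cum <- cumsum(p)
  k <- which(cum >= threshold - 1e-12)
  if (length(k) == 0L) {
    warning("cumulative variance never reaches the threshold; ",
            "retaining all components")
    return(length(p))
  }
  as.integer(k[1])
}

#' Per-day component scores
#'
#' Projects centered coefficient vectors onto the eigenfunctions:
#' \eqn{\xi_{dk} = (c_d - \bar c)' e_k}. Standardized scores divide by the
#' pooled score SD of each component (\eqn{\sqrt{\lambda_k}}), so a
#' regression coefficient on the standardized scale is an effect in SD units
#' of that component.
#'
#' @param model An `fpca_model`.
#' @param coefs Coefficient matrix (rows = subject-days).
#' @param meta Optional data.frame with one row per coefficient row
#'   (e.g. `subject_id`, `date`, covariates) carried into the output.
#' @param components Which components to score (default all retained).
#' @return Long-format data.frame (`ScoreTable`): the `meta` columns plus
#'   `component`, `score` (raw) and `score_std`.
#' @export
compute_scores <- function(model, coefs, meta = NULL,
                           components = seq_len(model$n_retained)) {
  stopifnot(inherits(model, "fpca_model"))
  C <- as.matrix(coefs)
  if (length(components) == 0L) components <- seq_along(model$eigenvalues)
  centered <- sweep(C, 2, model$mean_coefficients)
  xi <- centered %*% t(model$eigen_coefficients[components, , drop = FALSE])
  sds <- model$score_sd[components]
  std <- sweep(xi, 2, ifelse(sds > 0, sds, 1), "/")
  n <- nrow(C)
  base <- if (is.null(meta)) data.frame(row = seq_len(n)) else
    as.data.frame(meta)
  out <- do.call(rbind, lapply(seq_along(components), function(i) {
    cbind(base, data.frame(component = components[i], score = xi[, i],
                           score_std = std[, i]))
  }))
  rownames(out) <- NULL
  out
}

#' Pivot a long score table to one column per component
#'
#' @param score_table Output of [compute_scores()].
#' @param value Which score column to spread (`"score_std"` or `"score"`).
#' @return data.frame with the meta columns and `comp<k>` columns.
#' @export
scores_wide <- function(score_table, value = "score_std") {
  st <- data.table::as.data.table(score_table)
  idcols <- setdiff(names(st), c("component", "score", "score_std"))
  f <- stats::as.formula(paste(paste(idcols, collapse = " + "),
                               "~ component"))
  w <- data.table::dcast(st, f, value.var = value)
  comp_cols <- setdiff(names(w), idcols)
  data.table::setnames(w, comp_cols, paste0("comp", comp_cols))
  as.data.frame(w)
}

#' Mean-plus/minus-one-SD effect curves of a component
#'
#' Evaluates the mean daily activity curve and the mean plus/minus one score
#' SD of component `k` on the minute grid — the standard way to visualize
#' what a component does to the daily profile.
#'
#' @param model An `fpca_model`.
#' @param k Component index.
#' @return List of three 1440-vectors: `mean`, `plus`, `minus`.
#' @export
component_effect_curves <- function(model, k) {
  stopifnot(inherits(model, "fpca_model"))
  if (length(k) != 1L || k < 1L || k > nrow(model$eigen_coefficients))
    stop("component index out of range")
  mu <- eval_basis(model$mean_coefficients, model$basis)
  phi <- eval_basis(model$eigen_coefficients[k, ], model$basis)
  s <- model$score_sd[k]
  list(mean = mu, plus = mu + s * phi, minus = mu - s * phi)
}

#' Write an fPCA model to JSON
#'
#' Dumps the basis specification, mean coefficients, eigenfunctions,
#' eigenvalues and variance proportions as structured text.
#'
#' @param model An `fpca_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fpca_model <- function(model, path) {
  stopifnot(inherits(model, "fpca_model"))
  obj <- list(basis = list(type = "fourier", n_basis = model$basis$n_basis,
                           period = model$basis$period),
              mean_coefficients = model$mean_coefficients,
              eigen_coefficients = model$eigen_coefficients,
              eigenvalues = model$eigenvalues,
              variance_proportions = model$variance_proportions,
              n_retained = model$n_retained,
              score_sd = model$score_sd,
              n_curves = model$n_curves)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
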