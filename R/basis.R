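#' Orthonormal Fourier basis on the 24-hour minute grid
#'
#' Constructs the basis used to pre-smooth daily activity curves: the constant
#' function plus sine/cosine pairs at harmonics of the 24-hour period,
#' \eqn{\phi_0(t) = 1/\sqrt{T}} and, for harmonic \eqn{k},
#' \eqn{\sqrt{2/T}\,\sin(2\pi k t/T)} and \eqn{\sqrt{2/T}\,\cos(2\pi k t/T)}.
#' With the default `n_basis = 9` the harmonics run to \eqn{k = 4}. The basis
#' is evaluated at minute midpoints and is exactly orthonormal with respect to
#' the discrete inner product \eqn{\sum_m f(t_m) g(t_m) \Delta} with
#' \eqn{\Delta = 1} minute.
#'
#' @param n_basis Odd number of basis functions (constant + sine/cosine pairs).
#' @param period Length of the day in minutes; fixed at 1440 for daily curves.
#' @return An object of class `fourier_basis`: a list with the evaluation
#'   matrix `eval` (`period` rows, `n_basis` columns, one row per minute
#'   midpoint), the midpoint `grid`, `n_basis` and `period`. Column order is
#'   constant, then sin/cos per harmonic.
#' @examples
#' fb <- fourier_basis()
#' max(abs(crossprod(fb$eval) - diag(9)))  # orthonormal on the grid
#' @export
fourier_basis <- function(n_basis = 9L, period = 1440L) {
  n_basis <- as.integer(n_basis)
  if (n_basis < 1L || n_basis %% 2L != 1L)
    stop("n_basis must be a positive odd integer (constant + sin/cos pairs)")
  grid <- seq_len(period) - 0.5
  B <- matrix(0, nrow = period, ncol = n_basis)
  B[, 1L] <- 1 / sqrt(period)
  amp <- sqrt(2 / period)
  nm <- "const"
  for (k in seq_len((n_basis - 1L) / 2L)) {
    w <- 2 * pi * k * grid / period
    B[, 2L * k]      <- amp * sin(w)
    B[, 2L * k + 1L] <- amp * cos(w)
    nm <- c(nm, paste0("sin", k), paste0("cos", k))
  }
  colnames(B) <- nm
  structure(list(eval = B, grid = grid, n_basis = n_basis, period = period),
            class = "fourier_basis")
}

#' @export
print.fourier_basis <- function(x, ...) {
  cat(sprintf("Fourier basis: %d functions, period %d minutes\n",
              x$n_basis, x$period))
  invisible(x)
}

#' Project day curves onto the Fourier basis
#'
#' Least-squares projection of fully observed 1440-minute curves onto the
#' basis. Because the basis is orthonormal on the grid this equals the inner
#' product of each curve with each basis function (grid spacing 1 minute),
#' but the projection is computed through the normal equations so it remains
#' a least-squares fit for any basis.
#'
#' @param values Numeric vector of length `basis$period`, or a matrix with
#'   one curve per row.
#' @param basis A [fourier_basis()].
#' @return A coefficient vector of length `n_basis`, or a matrix with one
#'   coefficient row per curve.
#' @export
project_to_basis <- function(values, basis = fourier_basis()) {
  one <- is.null(dim(values))
  X <- if (one) matrix(values, nrow = 1L) else as.matrix(values)
  if (ncol(X) != basis$period)
    stop(sprintf("curves must have %d values per day", basis$period))
  if (anyNA(X))
    stop("curves contain missing values; impute before basis projection")
  # normal equations; Gram is the identity for this basis
  cf <- t(solve(crossprod(basis$eval), crossprod(basis$eval, t(X))))
  colnames(cf) <- colnames(basis$eval)
  if (one) drop(cf) else cf
}

#' Evaluate basis-coefficient vectors on the minute grid
#'
#' @param coefs Coefficient vector (length `n_basis`) or matrix (one row per
#'   curve).
#' @param basis A [fourier_basis()].
#' @return Curve values at the minute midpoints (vector or matrix).
#' @export
eval_basis <- function(coefs, basis = fourier_basis()) {
  one <- is.null(dim(coefs))
  C <- if (one) matrix(coefs, nrow = 1L) else as.matrix(coefs)
  if (ncol(C) != basis$n_basis)
    stop(sprintf("expected %d coefficients per curve", basis$n_basis))
  Y <- C %*% t(basis$eval)
  if (one) drop(Y) else Y
}
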