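# Building systems from model parameters or from observed time series.

#' Stationary joint covariance of a two-node AR(1) process
#'
#' For the vector autoregression `X[t+1] = A X[t] + e`, `e ~ N(0, Sigma)`,
#' solves the discrete Lyapunov equation `S = A S A' + Sigma` for the
#' stationary covariance `S` (by direct vectorised solve) and returns the
#' joint covariance of `(X[t], X[t+1])`,
#' `[[S, S A'], [A S, S]]`, as a Gaussian two-part system.
#'
#' @param coupling 2x2 coupling matrix `A`; its spectral radius must be
#'   strictly below 1 for a stationary solution to exist.
#' @param noise_cov 2x2 symmetric positive-definite innovation covariance.
#' @return A [gaussian_system()].
#' @examples
#' stationary_lagged_cov(matrix(0.4, 2, 2), diag(2))
#' @export
stationary_lagged_cov <- function(coupling, noise_cov) {
  A <- as.matrix(coupling); Sig <- as.matrix(noise_cov)
  if (any(dim(A) != c(2, 2)) || any(dim(Sig) != c(2, 2))) {
    stop("`coupling` and `noise_cov` must be 2x2 matrices.", call. = FALSE)
  }
  if (max(abs(Sig - t(Sig))) > 1e-10) {
    stop("`noise_cov` must be symmetric.", call. = FALSE)
  }
  if (min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("`noise_cov` must be positive definite.", call. = FALSE)
  }
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1) {
    stop("Nonstationary system: spectral radius of `coupling` is ",
         signif(rho, 4), " >= 1.", call. = FALSE)
  }
  # vec(S) = (I - A (x) A)^{-1} vec(Sigma)
  vecS <- solve(diag(4) - kronecker(A, A), as.vector(Sig))
  S <- matrix(vecS, 2, 2)
  S <- (S + t(S)) / 2
  joint <- rbind(cbind(S, S %*% t(A)),
                 cbind(A %*% S, S))
  gaussian_system(joint)
}

check_series <- function(series, lag, min_pairs = 10) {
  m <- as.matrix(series)
  if (!is.numeric(m) || ncol(m) != 2) {
    stop("`series` must be a numeric matrix or data frame with 2 columns.",
         call. = FALSE)
  }
  if (any(is.na(m))) stop("`series` must not contain missing values.", call. = FALSE)
  if (!is.numeric(lag) || length(lag) != 1 || lag < 1 || lag != round(lag)) {
    stop("`lag` must be a positive integer.", call. = FALSE)
  }
  if (nrow(m) - lag < min_pairs) {
    stop("Need at least ", min_pairs, " (past, future) pairs: T - lag = ",
         nrow(m) - lag, ".", call. = FALSE)
  }
  m
}

#' Estimate a Gaussian system from a bivariate time series
#'
#' Stacks the lagged pairs `(x[t], x[t + lag])` and takes their sample
#' covariance (denominator `n - 1`) as the joint covariance of past and
#' future, giving the maximum-entropy Gaussian model consistent with the
#' second moments of the data.
#'
#' @param series Numeric matrix or data frame, rows = time points, two
#'   columns = the two parts.
#' @param lag Time delay between past and future (default 1, the Markovian
#'   one-step decomposition).
#' @return A [gaussian_system()].
#' @export
estimate_gaussian <- function(series, lag = 1) {
  m <- check_series(series, lag)
  if (any(apply(m, 2, stats::var) == 0)) {
    stop("Numerical degeneracy: constant column in `series`.", call. = FALSE)
  }
  t_idx <- seq_len(nrow(m) - lag)
  stacked <- cbind(m[t_idx, , drop = FALSE], m[t_idx + lag, , drop = FALSE])
  gaussian_system(stats::cov(stacked))
}

#' Estimate a discrete system from an integer-valued time series
#'
#' Plug-in (maximum-likelihood) empirical pmf of the lagged pairs
#' `(x[t], x[t + lag])`; the alphabet is inferred from the observed values.
#'
#' For series produced by [sample_transition_pairs()], which emits
#' independent (past, future) pairs as consecutive rows, only the
#' within-pair transitions are counted (odd `t`); the pairing is carried by
#' the `"paired"` attribute of the series and can be forced with `paired`.
#'
#' @inheritParams estimate_gaussian
#' @param paired If `TRUE`, rows are independent (past, future) pairs and
#'   only transitions within a pair are counted. Defaults to the `"paired"`
#'   attribute of `series` (set by [sample_transition_pairs()]), else `FALSE`.
#' @return A [discrete_system()].
#' @export
estimate_discrete <- function(series, lag = 1,
                              paired = isTRUE(attr(series, "paired"))) {
  m <- check_series(series, lag, min_pairs = 1)
  if (any(m != round(m)) || any(m < 0)) {
    stop("`series` must contain nonnegative integers for discrete estimation.",
         call. = FALSE)
  }
  t_idx <- seq_len(nrow(m) - lag)
  if (paired) {
    if (lag != 1) {
      stop("Paired series are one-step transition pairs; use lag = 1.",
           call. = FALSE)
    }
    t_idx <- t_idx[t_idx %% 2 == 1]
  }
  tab <- data.frame(x1 = m[t_idx, 1], x2 = m[t_idx, 2],
                    y1 = m[t_idx + lag, 1], y2 = m[t_idx + lag, 2])
  tab$p <- 1 / nrow(tab)
  discrete_system(tab)
}
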