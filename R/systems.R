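# Two-part dynamical systems at two time points. Discrete systems are joint
# pmfs over the four slots (x1, x2, y1, y2) = (part 1 past, part 2 past,
# part 1 future, part 2 future); Gaussian systems are 4x4 covariance matrices
# of the stacked vector in the same slot order.

SLOTS <- c("x1", "x2", "y1", "y2")

#' Discrete two-part dynamical system
#'
#' Wraps a joint probability mass function over the past and future states of
#' a bipartite process. States are nonnegative integers; the table need not
#' enumerate zero-probability states.
#'
#' @param pmf Data frame with integer columns `x1`, `x2`, `y1`, `y2` (part 1
#'   past, part 2 past, part 1 future, part 2 future) and a probability
#'   column `p`. Masses must be nonnegative and sum to one; duplicate states
#'   are aggregated.
#' @return An object of class `phiid_discrete`, a tibble of states with
#'   attribute `alphabet` (number of symbols per slot).
#' @examples
#' # a fair bit copied from part 1's past to part 2's future
#' make_copy_system()
#' @export
discrete_system <- function(pmf) {
  pmf <- as.data.frame(pmf)
  need <- c(SLOTS, "p")
  if (!all(need %in% names(pmf))) {
    stop("`pmf` must have columns x1, x2, y1, y2, p.", call. = FALSE)
  }
  pmf <- pmf[, need]
  for (s in SLOTS) {
    v <- pmf[[s]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      stop("State columns must be nonnegative integers.", call. = FALSE)
    }
    pmf[[s]] <- as.integer(v)
  }
  if (any(is.na(pmf$p)) || any(pmf$p < -1e-12)) {
    stop("Probability masses must be nonnegative.", call. = FALSE)
  }
  pmf$p <- pmax(pmf$p, 0)
  if (abs(sum(pmf$p) - 1) > 1e-9) {
    stop("Probability masses must sum to 1.", call. = FALSE)
  }
  key <- do.call(paste, pmf[SLOTS])
  if (anyDuplicated(key)) {
    agg <- rowsum(pmf$p, key)
    first <- !duplicated(key)
    pmf <- pmf[first, ]
    pmf$p <- agg[match(do.call(paste, pmf[SLOTS]), rownames(agg)), 1]
  }
  pmf <- pmf[order(pmf$x1, pmf$x2, pmf$y1, pmf$y2), ]
  alphabet <- vapply(pmf[SLOTS], function(v) max(v) + 1L, 1L)
  structure(tibble::as_tibble(pmf), alphabet = alphabet,
            class = c("phiid_discrete", class(tibble::tibble())))
}

#' Gaussian two-part dynamical system
#'
#' Wraps the covariance matrix of the stacked vector
#' `(x1, x2, y1, y2)` of a stationary Gaussian process. Mutual informations of
#' jointly Gaussian variables depend on the covariance only, so the mean is
#' not stored.
#'
#' @param cov 4x4 symmetric positive-semidefinite matrix with positive
#'   diagonal, rows/columns in slot order `x1, x2, y1, y2`.
#' @return An object of class `phiid_gaussian`.
#' @export
gaussian_system <- function(cov) {
  cov <- as.matrix(cov)
  if (!is.numeric(cov) || any(dim(cov) != c(4, 4))) {
    stop("`cov` must be a 4x4 numeric matrix.", call. = FALSE)
  }
  if (max(abs(cov - t(cov))) > 1e-8) {
    stop("`cov` must be symmetric.", call. = FALSE)
  }
  cov <- (cov + t(cov)) / 2
  if (any(diag(cov) <= 0)) {
    stop("`cov` must have a positive diagonal.", call. = FALSE)
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("`cov` must be positive semidefinite.", call. = FALSE)
  }
  dimnames(cov) <- list(SLOTS, SLOTS)
  structure(list(cov = cov), class = "phiid_gaussian")
}

#' @export
print.phiid_gaussian <- function(x, ...) {
  cat("<Gaussian two-part system>\n")
  print(round(x$cov, 6))
  invisible(x)
}

is_phiid_system <- function(x) {
  inherits(x, "phiid_discrete") || inherits(x, "phiid_gaussian")
}

# Validate and normalise a variable group: a character subset of the slots,
# e.g. c("x1") or c("y1", "y2").
check_group <- function(g, arg = "group") {
  g <- unique(as.character(g))
  if (length(g) == 0 || !all(g %in% SLOTS)) {
    stop("`", arg, "` must be a nonempty subset of ",
         paste(SLOTS, collapse = ", "), ".", call. = FALSE)
  }
  SLOTS[SLOTS %in% g]
}

# --- discrete internals ------------------------------------------------------

# Shannon entropy (bits) of the marginal over `cols`.
discrete_entropy <- function(pmf, cols) {
  p <- rowsum(pmf$p, do.call(paste, pmf[cols]))[, 1]
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Per-row marginal probability over `cols`, aligned to pmf rows.
local_prob <- function(pmf, cols) {
  key <- do.call(paste, pmf[cols])
  m <- rowsum(pmf$p, key)
  m[match(key, rownames(m)), 1]
}

# --- Gaussian internals ------------------------------------------------------

gauss_logdet <- function(S) {
  d <- determinant(S, logarithm = TRUE)
  if (d$sign <= 0) return(NA_real_)
  as.numeric(d$modulus)
}

# log-determinant with diagonal jitter fallback for near-singular blocks
gauss_logdet_safe <- function(S) {
  ld <- gauss_logdet(S)
  if (is.na(ld)) {
    ld <- gauss_logdet(S + diag(1e-10, nrow(S)))
    if (is.na(ld)) {
      stop("Covariance submatrix numerically singular.", call. = FALSE)
    }
  }
  ld
}

#' Mutual information between two groups of variables
#'
#' Computes `I(a; b)` in bits. For discrete systems this is the plug-in
#' Shannon mutual information of the marginalised pmf; for Gaussian systems
#' it is `0.5 * log2(det(S_a) * det(S_b) / det(S_ab))`. Tiny negative values
#' from floating-point round-off are clipped to zero.
#'
#' @param system A [discrete_system()] or [gaussian_system()].
#' @param a,b Disjoint variable groups: character subsets of
#'   `c("x1", "x2", "y1", "y2")`, where `x` is the past and `y` the future.
#' @return Mutual information in bits (nonnegative scalar).
#' @examples
#' mutual_info(make_copy_system(), "x1", "y2")  # 1 bit
#' @export
mutual_info <- function(system, a, b) {
  a <- check_group(a, "a"); b <- check_group(b, "b")
  if (length(intersect(a, b)) > 0) {
    stop("Variable groups `a` and `b` must be disjoint.", call. = FALSE)
  }
  mi <- if (inherits(system, "phiid_discrete")) {
    discrete_entropy(system, a) + discrete_entropy(system, b) -
      discrete_entropy(system, union(a, b))
  } else if (inherits(system, "phiid_gaussian")) {
    S <- system$cov
    ab <- SLOTS[SLOTS %in% union(a, b)]
    0.5 / log(2) * (gauss_logdet_safe(S[a, a, drop = FALSE]) +
                      gauss_logdet_safe(S[b, b, drop = FALSE]) -
                      gauss_logdet_safe(S[ab, ab, drop = FALSE]))
  } else {
    stop("`system` must be a discrete or Gaussian two-part system.",
         call. = FALSE)
  }
  max(mi, 0)
}

#' Conditional mutual information between variable groups
#'
#' Computes `I(a; b | c)` in bits via the chain rule,
#' `I(a; b, c) - I(a; c)`. With `a = "x1"`, `b = "y2"`, `c = "x2"` this is
#' the transfer entropy from part 1 to part 2.
#'
#' @inheritParams mutual_info
#' @param c Conditioning variable group, disjoint from `a` and `b`.
#' @return Conditional mutual information in bits.
#' @export
cond_mutual_info <- function(system, a, b, c) {
  a <- check_group(a, "a"); b <- check_group(b, "b"); c <- check_group(c, "c")
  if (length(intersect(a, b)) > 0 || length(intersect(a, c)) > 0 ||
      length(intersect(b, c)) > 0) {
    stop("Variable groups must be pairwise disjoint.", call. = FALSE)
  }
  mutual_info(system, a, union(b, c)) - mutual_info(system, a, c)
}
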