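# Generators for the worked binary systems, pure-atom constructions, the
# two-node AR family, and samplers for estimation studies.

uniform_pmf <- function(states) {
  discrete_system(data.frame(x1 = states[, 1], x2 = states[, 2],
                             y1 = states[, 3], y2 = states[, 4],
                             p = 1 / nrow(states)))
}

bits2 <- as.matrix(expand.grid(0:1, 0:1))

#' The copy-transfer system
#'
#' `x1`, `x2` and `y1` are i.i.d. fair bits and `y2 = x1`: the information in
#' part 1's past is copied into part 2's future. Eight equiprobable states;
#' its decomposition is a single one-bit transfer atom `un1->un2`.
#'
#' @return A [discrete_system()].
#' @export
make_copy_system <- function() {
  g <- as.matrix(expand.grid(x1 = 0:1, x2 = 0:1, y1 = 0:1))
  uniform_pmf(cbind(g, g[, "x1"]))
}

#' The downward-XOR system
#'
#' `x1`, `x2` and `y2` are i.i.d. fair bits and `y1 = x1 XOR x2`: synergistic
#' information in the joint past becomes unique to part 1's future. Its
#' decomposition is a single one-bit downward-causation atom `syn->un1`.
#'
#' @return A [discrete_system()].
#' @export
make_downward_xor <- function() {
  g <- as.matrix(expand.grid(x1 = 0:1, x2 = 0:1, y2 = 0:1))
  uniform_pmf(cbind(g[, c("x1", "x2")], (g[, "x1"] + g[, "x2"]) %% 2,
                    g[, "y2"]))
}

#' The parity-preserving random (PPR) system
#'
#' The past `(x1, x2)` is uniform on its four states and the future is
#' uniform over the two states with the same parity: one bit is carried
#' purely as persistent synergy (`syn->syn`), invisible to transfer entropy
#' and active information storage.
#'
#' @return A [discrete_system()].
#' @export
make_ppr <- function() {
  states <- NULL
  for (i in seq_len(nrow(bits2))) {
    par <- sum(bits2[i, ]) %% 2
    fut <- bits2[(bits2[, 1] + bits2[, 2]) %% 2 == par, , drop = FALSE]
    states <- rbind(states, cbind(bits2[i, 1], bits2[i, 2], fut))
  }
  uniform_pmf(states)
}

# part-swap of a discrete system (x1<->x2, y1<->y2)
swap_parts <- function(system) {
  discrete_system(data.frame(x1 = system$x2, x2 = system$x1,
                             y1 = system$y2, y2 = system$y1, p = system$p))
}

mirror_label <- function(label) chartr("12", "21", label)

pure_atom_base <- function(label) {
  switch(label,
    # one fair bit shared by all four variables
    "red->red" = uniform_pmf(cbind(0:1, 0:1, 0:1, 0:1)),
    # part 1 copies itself; part 2 past and future are fresh coins
    "un1->un1" = {
      g <- as.matrix(expand.grid(x1 = 0:1, x2 = 0:1, y2 = 0:1))
      uniform_pmf(cbind(g[, c("x1", "x2")], g[, "x1"], g[, "y2"]))
    },
    "un1->un2" = make_copy_system(),
    # duplication: part 1's bit is broadcast to both futures
    "un1->red" = uniform_pmf(cbind(bits2, bits2[, 1], bits2[, 1])),
    # shared past bit retained only by part 1
    "red->un1" = {
      g <- as.matrix(expand.grid(b = 0:1, y2 = 0:1))
      uniform_pmf(cbind(g[, "b"], g[, "b"], g[, "b"], g[, "y2"]))
    },
    # XOR broadcast to both futures
    "syn->red" = uniform_pmf(cbind(bits2, (bits2[, 1] + bits2[, 2]) %% 2,
                                   (bits2[, 1] + bits2[, 2]) %% 2)),
    "syn->un1" = make_downward_xor(),
    "syn->syn" = make_ppr(),
    # shared past bit, parity-encoded in the joint future
    "red->syn" = {
      states <- NULL
      for (b in 0:1) {
        fut <- bits2[(bits2[, 1] + bits2[, 2]) %% 2 == b, , drop = FALSE]
        states <- rbind(states, cbind(b, b, fut))
      }
      uniform_pmf(states)
    },
    # part 1's bit parity-encoded in the joint future; part 2 past independent
    "un1->syn" = {
      states <- NULL
      for (i in seq_len(nrow(bits2))) {
        fut <- bits2[(bits2[, 1] + bits2[, 2]) %% 2 == bits2[i, 1], ,
                     drop = FALSE]
        states <- rbind(states, cbind(bits2[i, 1], bits2[i, 2], fut))
      }
      uniform_pmf(states)
    },
    NULL)
}

#' Construct a binary system whose decomposition is a single atom
#'
#' Builds a small binary system whose MMI decomposition has exactly one atom
#' of one bit, with every other atom below `1e-10` in magnitude. The
#' construction is verified against the full decomposition at build time and
#' an internal-consistency error is raised if the check fails. Labels with
#' parts 1 and 2 exchanged are produced by part-swapping the base
#' construction.
#'
#' @param atom_label One of the 16 canonical atom labels, e.g. `"un1->red"`.
#' @return A [discrete_system()].
#' @examples
#' make_pure_atom_system("syn->red")  # broadcast XOR
#' @export
make_pure_atom_system <- function(atom_label) {
  if (!is.character(atom_label) || length(atom_label) != 1 ||
      !atom_label %in% phiid_atom_labels()) {
    stop("`atom_label` must be one of the 16 canonical atom labels.",
         call. = FALSE)
  }
  sys <- pure_atom_base(atom_label)
  if (is.null(sys)) {
    base <- pure_atom_base(mirror_label(atom_label))
    if (is.null(base)) {
      stop("No pure-atom construction available for '", atom_label, "'.",
           call. = FALSE)
    }
    sys <- swap_parts(base)
  }
  atoms <- phiid_decompose(sys, "mmi")$atoms
  others <- atoms[setdiff(names(atoms), atom_label)]
  if (abs(atoms[atom_label] - 1) > 1e-10 || any(abs(others) > 1e-10)) {
    stop("Internal consistency failure: construction for '", atom_label,
         "' is not a pure-atom system.", call. = FALSE)
  }
  sys
}

#' Two-node AR system with shared coupling and correlated noise
#'
#' The stationary Gaussian system of `X[t+1] = A X[t] + e` with `A` the 2x2
#' matrix with all entries `a` and innovation covariance with unit diagonal
#' and off-diagonal `noise_corr`. As the noise correlation grows the system
#' becomes redundancy-dominated and whole-minus-sum integrated information
#' turns negative while its revised counterpart stays nonnegative.
#'
#' @param a Coupling strength; the all-`a` matrix has spectral radius `|2a|`,
#'   which must be below 1.
#' @param noise_corr Innovation correlation, in (-1, 1).
#' @return A [gaussian_system()].
#' @export
make_ar_system <- function(a, noise_corr) {
  if (abs(2 * a) >= 1) {
    stop("Stationarity requires |2a| < 1 for the all-`a` coupling matrix.",
         call. = FALSE)
  }
  if (abs(noise_corr) >= 1) {
    stop("`noise_corr` must lie in (-1, 1).", call. = FALSE)
  }
  stationary_lagged_cov(matrix(a, 2, 2),
                        matrix(c(1, noise_corr, noise_corr, 1), 2, 2))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Sample independent transition pairs from a discrete system
#'
#' Draws `n` i.i.d. (past, future) pairs from the joint pmf and emits them as
#' consecutive rows of a `2n x 2` integer matrix (odd rows = past states,
#' even rows = future states). Pairs are sampled independently rather than
#' rolled out as a Markov chain: a single trajectory of a
#' parity-conserving system would stay in one parity class and misrepresent
#' the stationary joint distribution. The returned matrix carries a
#' `"paired"` attribute honoured by [estimate_discrete()].
#'
#' @param system A [discrete_system()].
#' @param n Number of pairs to draw.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Integer matrix with `2 n` rows, 2 columns and attribute
#'   `paired = TRUE`.
#' @export
sample_transition_pairs <- function(system, n, seed = NULL) {
  stopifnot(inherits(system, "phiid_discrete"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count.", call. = FALSE)
  }
  idx <- with_seed(seed,
                   sample.int(nrow(system), size = n, replace = TRUE,
                              prob = system$p))
  out <- matrix(0L, 2 * n, 2)
  out[seq(1, 2 * n, by = 2), ] <- cbind(system$x1, system$x2)[idx, ]
  out[seq(2, 2 * n, by = 2), ] <- cbind(system$y1, system$y2)[idx, ]
  attr(out, "paired") <- TRUE
  out
}

#' Simulate a two-node Gaussian AR(1) process
#'
#' Rolls out `X[t+1] = A X[t] + e`, `e ~ N(0, Sigma)`, for `n_steps` steps,
#' initialising at the stationary distribution so finite-sample moment
#' estimates are free of transient bias.
#'
#' @param coupling 2x2 coupling matrix with spectral radius below 1.
#' @param noise_cov 2x2 positive-definite innovation covariance.
#' @param n_steps Number of time points to return.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Numeric matrix with `n_steps` rows and 2 columns.
#' @export
simulate_ar <- function(coupling, noise_cov, n_steps, seed = NULL) {
  A <- as.matrix(coupling)
  joint <- stationary_lagged_cov(coupling, noise_cov)  # validates inputs
  S <- joint$cov[1:2, 1:2]
  L_s <- t(chol(S))
  L_e <- t(chol(as.matrix(noise_cov)))
  with_seed(seed, {
    x <- matrix(0, n_steps, 2)
    x[1, ] <- L_s %*% stats::rnorm(2)
    if (n_steps > 1) {
      eps <- L_e %*% matrix(stats::rnorm(2 * (n_steps - 1)), 2)
      for (t in 2:n_steps) {
        x[t, ] <- A %*% x[t - 1, ] + eps[, t - 1]
      }
    }
    x
  })
}
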