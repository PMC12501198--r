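# Shared fixtures and independent oracles, built in code.

# random discrete system on binary (optionally larger) alphabets
random_discrete <- function(alphabet = c(2, 2, 2, 2)) {
  g <- expand.grid(x1 = seq_len(alphabet[1]) - 1, x2 = seq_len(alphabet[2]) - 1,
                   y1 = seq_len(alphabet[3]) - 1, y2 = seq_len(alphabet[4]) - 1)
  w <- stats::runif(nrow(g))
  g$p <- w / sum(w)
  discrete_system(g)
}

# random 4x4 SPD covariance (a valid joint past/future covariance)
random_gaussian <- function() {
  m <- matrix(stats::rnorm(16), 4)
  gaussian_system(crossprod(m) + diag(0.5, 4))
}

# independent plug-in entropy/MI oracle working on a plain data frame,
# bypassing the package's marginalisation code path
oracle_entropy <- function(df, cols) {
  p <- tapply(df$p, interaction(df[cols], drop = TRUE), sum)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mi <- function(df, a, b) {
  oracle_entropy(df, a) + oracle_entropy(df, b) - oracle_entropy(df, union(a, b))
}

# conditional MI by explicit conditioning: sum_c p(c) I(a;b | C = c)
oracle_cmi_discrete <- function(df, a, b, cond) {
  key <- interaction(df[cond], drop = TRUE)
  total <- 0
  for (lv in levels(key)) {
    sub <- df[key == lv, , drop = FALSE]
    pc <- sum(sub$p)
    if (pc == 0) next
    sub$p <- sub$p / pc
    total <- total + pc * oracle_mi(sub, a, b)
  }
  total
}

# Gaussian conditional MI through the partial covariance (Schur complement),
# an independent route from the package's difference-of-MIs
oracle_cmi_gaussian <- function(S, a, b, cond) {
  part <- S[c(a, b), c(a, b)] -
    S[c(a, b), cond, drop = FALSE] %*%
    solve(S[cond, cond, drop = FALSE], S[cond, c(a, b), drop = FALSE])
  ia <- seq_along(a); ib <- length(a) + seq_along(b)
  0.5 * log2(det(part[ia, ia, drop = FALSE]) * det(part[ib, ib, drop = FALSE]) /
               det(part))
}

# pointwise CCS single-target redundancy, written as a naive per-state loop
oracle_ccs_single <- function(df, s1, s2, tgt) {
  marg <- function(cols, row) {
    sel <- rep(TRUE, nrow(df))
    for (cc in cols) sel <- sel & df[[cc]] == row[[cc]]
    sum(df$p[sel])
  }
  total <- 0
  for (r in seq_len(nrow(df))) {
    if (df$p[r] == 0) next
    row <- df[r, ]
    li <- function(src) {
      log2(marg(c(src, tgt), row) / (marg(src, row) * marg(tgt, row)))
    }
    i1 <- li(s1); i2 <- li(s2); i12 <- li(c(s1, s2))
    co <- i1 + i2 - i12
    s <- function(x) (x > 1e-10) - (x < -1e-10)
    if (s(i1) == s(i2) && s(i2) == s(i12) && s(i12) == s(co)) {
      total <- total + df$p[r] * co
    }
  }
  total
}

# duplication system with flip noise: both futures copy part 1's past bit
# through independent binary symmetric channels with error `eps`
noisy_duplication <- function(eps) {
  g <- expand.grid(x1 = 0:1, x2 = 0:1, e1 = 0:1, e2 = 0:1)
  pe <- function(e) ifelse(e == 1, eps, 1 - eps)
  discrete_system(data.frame(
    x1 = g$x1, x2 = g$x2,
    y1 = (g$x1 + g$e1) %% 2, y2 = (g$x1 + g$e2) %% 2,
    p = 0.25 * pe(g$e1) * pe(g$e2)))
}

# duplication pair embedded among three independent noise bits, emulating a
# small multivariate recording in which only one mechanism is duplicative
embedded_duplication <- function(eps, n, seed) {
  s <- sample_transition_pairs(noisy_duplication(eps), n, seed = seed)
  set.seed(seed + 5000)
  extra <- matrix(stats::rbinom(3 * nrow(s), 1, 0.5), ncol = 3)
  out <- cbind(s, extra)
  attr(out, "paired") <- TRUE
  out
}

expect_all_near <- function(x, y, tol) {
  expect_true(max(abs(x - y)) < tol,
              label = paste0("max|diff| = ", signif(max(abs(x - y)), 3),
                             " < ", tol))
}
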