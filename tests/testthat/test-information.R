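test_that("discrete mutual information matches hand values", {
  copy <- make_copy_system()
  expect_equal(mutual_info(copy, "x1", "x2"), 0)      # independent fair bits
  expect_equal(mutual_info(copy, "x1", "y2"), 1)      # a bit and its copy
  expect_equal(mutual_info(copy, c("x1", "x2"), c("y1", "y2")), 1)
  expect_error(mutual_info(copy, "x1", "x1"), "disjoint")
  expect_error(mutual_info(copy, "x1", "z9"), "subset")
})

test_that("Gaussian mutual information matches the correlation closed form", {
  S <- diag(4)
  S[1, 3] <- S[3, 1] <- 0.6
  g <- gaussian_system(S)
  expect_equal(mutual_info(g, "x1", "y1"), -0.5 * log2(1 - 0.36),
               tolerance = 1e-12)
  expect_equal(mutual_info(g, "x1", "y2"), 0)
})

test_that("Gaussian MI agrees with a Monte-Carlo density-ratio estimate", {
  rho <- 0.45
  S <- diag(4); S[1, 3] <- S[3, 1] <- rho
  g <- gaussian_system(S)
  set.seed(2024)
  n <- 2e5
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  log_joint <- -0.5 * (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2) -
    log(2 * pi) - 0.5 * log(1 - rho^2)
  log_marg <- stats::dnorm(z1, log = TRUE) + stats::dnorm(z2, log = TRUE)
  mc <- mean((log_joint - log_marg) / log(2))
  expect_equal(mutual_info(g, "x1", "y1"), mc, tolerance = 0.02)
})

test_that("MI is symmetric for both system kinds", {
  set.seed(5)
  d <- random_discrete()
  g <- random_gaussian()
  groups <- list("x1", "x2", c("x1", "x2"), "y1", c("y1", "y2"))
  for (a in groups) for (b in groups) {
    if (length(intersect(a, b)) > 0) next
    expect_equal(mutual_info(d, a, b), mutual_info(d, b, a))
    expect_equal(mutual_info(g, a, b), mutual_info(g, b, a),
                 tolerance = 1e-12)
  }
})

test_that("conditional MI agrees with independent oracles", {
  copy <- make_copy_system()
  # exhaustive enumeration of the 8-state pmf gives exactly one bit
  expect_equal(cond_mutual_info(copy, "x1", "y2", "x2"), 1)
  ppr <- make_ppr()
  expect_equal(cond_mutual_info(ppr, "x1", "y2", "x2"), 0)

  set.seed(31)
  for (rep in 1:5) {
    d <- random_discrete()
    expect_equal(cond_mutual_info(d, "x1", "y2", "x2"),
                 oracle_cmi_discrete(as.data.frame(d), "x1", "y2", "x2"),
                 tolerance = 1e-10)
    g <- random_gaussian()
    expect_equal(cond_mutual_info(g, "x1", "y2", "x2"),
                 oracle_cmi_gaussian(g$cov, "x1", "y2", "x2"),
                 tolerance = 1e-9)
  }
})

test_that("independent variables carry zero conditional information", {
  # y1 independent of everything else
  g <- expand.grid(x1 = 0:1, x2 = 0:1, y1 = 0:1)
  g$y2 <- g$x2
  g$p <- 1 / 8
  d <- discrete_system(g)
  expect_equal(cond_mutual_info(d, "x1", "y1", "x2"), 0)
})

test_that("copy dynamics preserve a full bit (data processing check)", {
  copy <- make_copy_system()
  # the copied bit carries all of x1's entropy into part 2's future
  expect_equal(mutual_info(copy, "x1", "y2"),
               oracle_entropy(as.data.frame(copy), "x1"))
  expect_equal(mutual_info(copy, "x1", "y1"), 0)
})

test_that("the stationary Lyapunov solve matches closed forms", {
  # decoupled: joint covariance is block diagonal
  s0 <- stationary_lagged_cov(matrix(0, 2, 2), diag(2))
  expect_equal(unname(s0$cov), rbind(cbind(diag(2), matrix(0, 2, 2)),
                                     cbind(matrix(0, 2, 2), diag(2))))
  # all-0.4 coupling, unit noise: variance 17/9, covariance 8/9
  s1 <- stationary_lagged_cov(matrix(0.4, 2, 2), diag(2))
  expect_equal(s1$cov[1, 1], 17 / 9, tolerance = 1e-12)
  expect_equal(s1$cov[1, 2], 8 / 9, tolerance = 1e-12)
  # and the fixed-point property S = A S A' + Sigma
  S <- s1$cov[1:2, 1:2]
  A <- matrix(0.4, 2, 2)
  expect_all_near(S, A %*% S %*% t(A) + diag(2), 1e-12)
  # lagged block is S A'
  expect_all_near(s1$cov[1:2, 3:4], S %*% t(A), 1e-12)

  expect_error(stationary_lagged_cov(matrix(0.5, 2, 2), diag(2)),
               "Nonstationary")
  expect_error(stationary_lagged_cov(diag(0.5, 2), matrix(0, 2, 2)),
               "positive definite")
})

test_that("Gaussian estimation recovers the analytic AR covariance", {
  A <- matrix(0.4, 2, 2)
  Sig <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  x <- simulate_ar(A, Sig, 1e5, seed = 1234)
  est <- estimate_gaussian(x)
  expect_all_near(est$cov, stationary_lagged_cov(A, Sig)$cov, 0.05)

  expect_error(estimate_gaussian(x[1:5, ]), "pairs")
  expect_error(estimate_gaussian(cbind(rep(1, 100), rnorm(100))),
               "degeneracy")
  expect_error(estimate_gaussian(x, lag = 1e5), "pairs")
})

test_that("pure-noise series show vanishing lagged cross-covariance", {
  x <- simulate_ar(matrix(0, 2, 2), diag(2), 5e4, seed = 9)
  est <- estimate_gaussian(x)
  expect_lt(max(abs(est$cov[1:2, 3:4])), 0.03)
})

test_that("discrete estimation recovers a sampled pmf", {
  copy <- make_copy_system()
  ser <- sample_transition_pairs(copy, 2e4, seed = 77)
  est <- estimate_discrete(ser)
  merged <- merge(as.data.frame(copy), as.data.frame(est),
                  by = c("x1", "x2", "y1", "y2"), all = TRUE)
  merged[is.na(merged)] <- 0
  expect_all_near(merged$p.x, merged$p.y, 0.02)
})

test_that("discrete estimation handles tiny and structured inputs", {
  # a single transition pair
  one <- estimate_discrete(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(nrow(one), 1)
  expect_equal(one$p, 1)
  # alternating column at lag 1: only the two observed transitions
  alt <- estimate_discrete(cbind(rep(0:1, 10), rep(0:1, 10)))
  expect_equal(nrow(alt), 2)
  expect_equal(sort(alt$p), c(9 / 19, 10 / 19))
  expect_error(estimate_discrete(matrix(rnorm(40), 20, 2)),
               "nonnegative integers")
})
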