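# count function, position-range algebra, truncated Poisson gap law, and
# exact likelihood evaluation

test_that("count_vector counts letters over the alphabet", {
  expect_equal(count_vector("AAC", dna), c(2L, 1L, 0L, 0L))
  expect_equal(count_vector("", dna), c(0L, 0L, 0L, 0L))
  expect_equal(count_vector("GATTACA", dna), c(3L, 1L, 1L, 2L))
  expect_equal(sum(count_vector("GATTACA", dna)), 7L)
  expect_error(count_vector("AXC", dna), "'X' at offset 2")
})

test_that("valid_position_range returns the admissible interval", {
  expect_equal(valid_position_range(2, L = 10, J = 5, prev = 3), 4:7)
  expect_equal(valid_position_range(1, L = 8, J = 8), 1L)
  expect_equal(valid_position_range(1, L = 10, J = 5), 1:6)
  expect_error(valid_position_range(2, L = 10, J = 5, prev = 7), "infeasible")
  expect_error(valid_position_range(1, L = 3, J = 5), "cannot hold")
})

test_that("truncated Poisson pmf renormalizes Poisson weights over the support", {
  expect_equal(trunc_poisson_pmf(1:3, rate = 1, support = 1:3),
               c(0.6, 0.3, 0.1), tolerance = 1e-12)
  expect_equal(trunc_poisson_pmf(5, rate = 17.3, support = 5L), 1)
  expect_equal(sum(trunc_poisson_pmf(1:6, rate = 2.3, support = 1:6)), 1,
               tolerance = 1e-12)
  expect_error(trunc_poisson_pmf(4, rate = 1, support = 1:3), "outside")
  expect_error(trunc_poisson_pmf(1, rate = 1, support = integer(0)), "empty")
})

test_that("truncated Poisson pmf sums to one for randomized rates and supports", {
  set.seed(42)
  for (r in 1:25) {
    rate <- runif(1, 0.05, 8)
    dmax <- sample(1:12, 1)
    expect_equal(sum(trunc_poisson_pmf(seq_len(dmax), rate, seq_len(dmax))), 1,
                 tolerance = 1e-12)
  }
})

test_that("sequence likelihood matches hand evaluation in both scenarios", {
  st_unif <- motif_state(rep(0.25, 4),
                         list(matrix(0.25, 4, 2)), list(1))
  x <- encode_sequence("AC", dna)
  expect_equal(sequence_log_likelihood(x, w = 2, state = st_unif),
               2 * log(0.25), tolerance = 1e-12)

  # generic parameters, L = 4, J = 2, a = (1, 3): background factor over
  # positions {2, 4} plus the two motif emission terms, summed by hand
  st <- toy_state(p = 4, J = 2, seed = 7)
  x <- encode_sequence("GATC", dna)
  a <- c(1L, 3L)
  hand <- log(st$theta0[x[2]]) + log(st$theta0[x[4]]) +
          log(st$thetas[[1]][x[1], 1]) + log(st$thetas[[1]][x[3], 2])
  expect_equal(sequence_log_likelihood(x, w = 1, a = a, state = st), hand,
               tolerance = 1e-12)

  # a (nearly) degenerate column contributes ~log(1) = 0 at the observed letter
  Th <- matrix(1e-12, 4, 1); Th[2, 1] <- 1 - 3e-12
  stdeg <- motif_state(rep(0.25, 4), list(Th), list(numeric(0)))
  x <- encode_sequence("C", dna)
  expect_equal(sequence_log_likelihood(x, 1, a = 1L, state = stdeg),
               0, tolerance = 1e-9)  # bg term cancels: log(theta0) - log(theta0) + log(~1)
  expect_error(sequence_log_likelihood(x, 1, a = c(1L, 2L), state = stdeg),
               "length")
})

test_that("total likelihood is additive and order-invariant", {
  st <- toy_state(p = 4, J = 2, seed = 3)
  d <- toy_data(c("GATC", "CCGA", "TTAC"))
  w <- c(1L, 2L, 1L)
  A <- list(matrix(c(1L, NA, 2L, 3L, NA, 4L), 3, 2))
  tot <- total_log_likelihood(d, w, A, st)
  by_hand <- sequence_log_likelihood(d$codes[[1]], 1, c(1, 3), st) +
             sequence_log_likelihood(d$codes[[2]], 2, state = st) +
             sequence_log_likelihood(d$codes[[3]], 1, c(2, 4), st)
  expect_equal(tot, by_hand, tolerance = 1e-12)

  perm <- c(3, 1, 2)
  d2 <- toy_data(c("TTAC", "GATC", "CCGA"))
  A2 <- list(A[[1]][perm, , drop = FALSE])
  expect_equal(total_log_likelihood(d2, w[perm], A2, st), tot, tolerance = 1e-12)

  expect_error(total_log_likelihood(d, c(1L, NA, 1L), A, st), "complete")
})

test_that("a motif identical to the background is indistinguishable", {
  theta0 <- c(0.4, 0.3, 0.2, 0.1)
  st <- motif_state(theta0, list(cbind(theta0, theta0)), list(1.3))
  x <- encode_sequence("ACGTAG", dna)
  bg <- sequence_log_likelihood(x, w = 2, state = st)
  for (a1 in 1:4) for (a2 in (a1 + 1):6) {
    if (a2 > 6) next
    expect_equal(sequence_log_likelihood(x, 1, c(a1, a2), st), bg,
                 tolerance = 1e-12)
  }
})

test_that("log joint equals the term-by-term hand computation", {
  st <- toy_state(p = 4, J = 2, lambda = 1.7, seed = 11)
  d <- toy_data(c("GATC", "ACGT"))
  w <- c(1L, 2L)
  A <- list(matrix(c(2L, NA, 4L, NA), 2, 2))
  hy <- hyperparameters(alpha0 = 1, alpha = 1, beta = 1, nu = 1)
  lj <- log_joint(d, w, A, st, hy)
  lam <- st$lambdas[[1]][1]
  hand <- total_log_likelihood(d, w, A, st) +
    lgamma(4) +                       # flat Dirichlet density on theta0
    2 * lgamma(4) +                   # two flat motif columns
    dgamma(lam, 1, 1, log = TRUE) +
    2 * log(1 / 2) +                  # uniform label prior, two sequences
    log(1 / 3) +                      # first position uniform on {1..3}
    log((lam^2 / 2) / (lam + lam^2 / 2))  # gap d = 2 truncated to {1, 2}
  expect_equal(lj, hand, tolerance = 1e-12)

  # a single-column motif contributes no gap term and no rate prior
  st1 <- motif_state(st$theta0, list(st$thetas[[1]][, 1, drop = FALSE]),
                     list(numeric(0)))
  A1 <- list(matrix(c(2L, NA), 2, 1))
  lj1 <- log_joint(d, w, A1, st1, hy)
  hand1 <- total_log_likelihood(d, w, A1, st1) + lgamma(4) + lgamma(4) +
    2 * log(1 / 2) + log(1 / 4)
  expect_equal(lj1, hand1, tolerance = 1e-12)
})

test_that("position rows violating the invariants are rejected", {
  expect_error(validate_position_row(c(3L, 2L), 6, 2), "increasing")
  expect_error(validate_position_row(c(0L, 2L), 6, 2), ">= 1")
  expect_error(validate_position_row(c(2L, 7L), 6, 2), "upper bound")
  expect_equal(validate_position_row(c(4L, 6L), 6, 2), c(4L, 6L))
  expect_equal(validate_position_row(c(5L, 6L), 6, 2), c(5L, 6L))
})
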