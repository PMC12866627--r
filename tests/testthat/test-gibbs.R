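# conjugate updates, the sequential position sampler, the exact DP
# marginalizer and the masked-label update, each checked against closed
# forms or brute-force enumeration

test_that("background update pools non-motif counts into the Dirichlet posterior", {
  # one background sequence AAC: counts (2,1,0,0), flat prior -> mean (3,2,1,1)/7
  d <- toy_data("AAC")
  post <- update_theta0(d, 2L, list(matrix(NA_integer_, 1, 1)), sample = FALSE)
  expect_equal(post, c(3, 2, 1, 1) / 7, tolerance = 1e-12)

  # motif-labeled sequence: its binding position is excluded from the pool
  d2 <- toy_data(c("AAC", "GG"))
  A2 <- list(matrix(c(NA_integer_, 1L), 2, 1))
  post2 <- update_theta0(d2, c(2L, 1L), A2, sample = FALSE)
  expect_equal(post2, (1 + c(2, 1, 1, 0)) / 8, tolerance = 1e-12)

  # motif spanning every sequence leaves no background letters: prior mean
  d3 <- toy_data(c("A", "C"))
  A3 <- list(matrix(c(1L, 1L), 2, 1))
  expect_equal(update_theta0(d3, c(1L, 1L), A3, sample = FALSE),
               rep(0.25, 4), tolerance = 1e-12)

  # sampling mean converges to the analytic mean
  set.seed(1)
  draws <- replicate(4000, update_theta0(d, 2L, list(matrix(NA_integer_, 1, 1))))
  expect_lt(max(abs(rowMeans(draws) - c(3, 2, 1, 1) / 7)), 0.015)
})

test_that("motif column update is the Dirichlet posterior of position counts", {
  # letters A, A, C at the single motif position, flat prior
  d <- toy_data(c("AG", "AT", "CC"))
  A <- list(matrix(c(1L, 1L, 1L), 3, 1))
  post <- update_theta_k(d, c(1L, 1L, 1L), A, 1, sample = FALSE)
  expect_equal(post[, 1], c(3, 2, 1, 1) / 7, tolerance = 1e-12)

  # no assigned sequences: prior fallback, columns sum to 1
  post0 <- update_theta_k(d, c(2L, 2L, 2L), A, 1, sample = FALSE)
  expect_equal(post0[, 1], rep(0.25, 4), tolerance = 1e-12)
  set.seed(2)
  draw <- update_theta_k(d, c(1L, 1L, 1L), A, 1)
  expect_equal(colSums(draw), 1, tolerance = 1e-12)
})

test_that("conjugate gap-rate update draws from Gamma(beta + sum d, nu + m)", {
  # gaps (1, 2, 1) across three assigned sequences -> Gamma(5, 4), mean 1.25
  d <- toy_data(c("ACGTA", "ACGTA", "ACGTA"))
  A <- list(matrix(c(1L, 1L, 2L, 2L, 3L, 3L), 3, 2))
  w <- c(1L, 1L, 1L)
  set.seed(5)
  x1 <- update_lambda_k(d, w, A, 1)
  set.seed(5)
  x2 <- rgamma(1, shape = 5, rate = 4)
  expect_equal(x1, x2, tolerance = 1e-12)

  # no assigned sequences: prior draw Gamma(1, 1)
  set.seed(6)
  y1 <- update_lambda_k(d, c(2L, 2L, 2L), A, 1)
  set.seed(6)
  y2 <- rgamma(1, 1, 1)
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("exact MH gap-rate update matches the quadrature posterior", {
  # fixed truncated gaps; equilibrium mean of the MH chain vs numerical
  # integration of Gamma(1,1) x truncated-Poisson likelihood
  d <- toy_data(c("ACGTAC", "ACGTAC", "ACGTAC", "ACGTAC"))
  A <- list(matrix(c(1L, 1L, 2L, 1L, 2L, 3L, 3L, 4L), 4, 2))
  w <- rep(1L, 4)
  gaps <- A[[1]][, 2] - A[[1]][, 1]
  dmax <- (6 - 2 + 2) - A[[1]][, 1]
  lgrid <- seq(0.002, 20, by = 0.002)
  lik <- sapply(lgrid, function(lam) {
    lz <- sapply(dmax, function(dm) log(sum(lam^(1:dm) / factorial(1:dm))))
    exp(-lam + sum(gaps * log(lam)) - sum(lz))
  })
  truth_mean <- sum(lgrid * lik) / sum(lik)
  set.seed(9)
  cur <- 1
  draws <- numeric(20000)
  for (t in seq_along(draws)) {
    cur <- update_lambda_k(d, w, A, 1, method = "mh", current = cur)
    draws[t] <- cur
  }
  expect_lt(abs(mean(draws[-(1:500)]) - truth_mean) / truth_mean, 0.05)
})

test_that("forced configurations and cancelling emissions behave as required", {
  # J = L: the only valid vector is returned with probability one
  st <- toy_state(p = 4, J = 4, lambda = rep(1, 3), seed = 4)
  x <- encode_sequence("ACGT", dna)
  expect_equal(sample_positions_row(x, 1, st, a = 1:4), 1:4)

  # emissions equal to the background cancel: conditional weights reduce to
  # the gap prior, checked against direct enumeration of the gap law
  theta0 <- c(0.4, 0.3, 0.2, 0.1)
  stu <- motif_state(theta0, list(cbind(theta0, theta0)), list(0.8))
  x6 <- encode_sequence("ACGTAC", dna)
  set.seed(11)
  a <- c(1L, 2L)
  hits <- matrix(0, 0, 2)
  for (t in 1:6000) {
    a <- sample_positions_row(x6, 1, stu, a)
    hits <- rbind(hits, a)
  }
  vecs <- enumerate_position_vectors(6, 2)
  lw <- vapply(vecs, position_vector_log_weight, 0, x = x6, state = stu)
  pr <- exp(lw - max(lw)); pr <- pr / sum(pr)
  keys <- vapply(vecs, paste, "", collapse = "-")
  emp <- table(factor(paste(hits[, 1], hits[, 2], sep = "-"), levels = keys))
  expect_lt(tv_dist(as.numeric(emp) / nrow(hits), pr), 0.05)
})

test_that("sequential sampler's long-run law matches exhaustive enumeration", {
  st <- toy_state(p = 4, J = 2, lambda = 1.2, seed = 8)
  x <- encode_sequence("GATACC", dna)
  vecs <- enumerate_position_vectors(6, 2)
  lw <- vapply(vecs, position_vector_log_weight, 0, x = x, state = st)
  pr <- exp(lw - max(lw)); pr <- pr / sum(pr)
  keys <- vapply(vecs, paste, "", collapse = "-")
  set.seed(21)
  a <- c(1L, 2L)
  counts <- setNames(numeric(length(keys)), keys)
  for (t in 1:20000) {
    a <- sample_positions_row(x, 1, st, a)
    k <- paste(a, collapse = "-")
    counts[k] <- counts[k] + 1
  }
  expect_lt(tv_dist(counts / sum(counts), pr), 0.05)
})

test_that("DP marginal equals the explicit sum over all position vectors", {
  # single path when J = L
  st4 <- toy_state(p = 4, J = 4, lambda = rep(0.9, 3), seed = 14)
  x4 <- encode_sequence("GTAC", dna)
  lat4 <- dp_position_marginal(x4, 1, st4)
  expect_equal(lat4$log_marginal,
               sequence_log_likelihood(x4, 1, 1:4, st4), tolerance = 1e-10)

  # L = 6, J = 2: all valid pairs
  st <- toy_state(p = 4, J = 2, lambda = 1.4, seed = 15)
  x <- encode_sequence("ACGGTA", dna)
  vecs <- enumerate_position_vectors(6, 2)
  lw <- vapply(vecs, position_vector_log_weight, 0, x = x, state = st)
  bg <- sum(log(st$theta0)[x])
  enum <- bg + max(lw) + log(sum(exp(lw - max(lw))))
  lat <- dp_position_marginal(x, 1, st)
  expect_equal(lat$log_marginal, enum, tolerance = 1e-10)

  # J = 3 cross-check on a longer sequence
  st3 <- toy_state(p = 4, J = 3, lambda = c(1, 2), seed = 16)
  x8 <- encode_sequence("ACGGTACT", dna)
  vecs3 <- enumerate_position_vectors(8, 3)
  lw3 <- vapply(vecs3, position_vector_log_weight, 0, x = x8, state = st3)
  enum3 <- sum(log(st3$theta0)[x8]) + max(lw3) + log(sum(exp(lw3 - max(lw3))))
  expect_equal(dp_position_marginal(x8, 1, st3)$log_marginal, enum3,
               tolerance = 1e-10)
})

test_that("DP backward samples follow the enumerated posterior", {
  st <- toy_state(p = 4, J = 2, lambda = 1.1, seed = 17)
  x <- encode_sequence("TTGACA", dna)
  vecs <- enumerate_position_vectors(6, 2)
  lw <- vapply(vecs, position_vector_log_weight, 0, x = x, state = st)
  pr <- exp(lw - max(lw)); pr <- pr / sum(pr)
  keys <- vapply(vecs, paste, "", collapse = "-")
  lat <- dp_position_marginal(x, 1, st)
  set.seed(31)
  draws <- replicate(10000, paste(dp_position_sample(lat), collapse = "-"))
  emp <- table(factor(draws, levels = keys)) / 10000
  expect_lt(tv_dist(as.numeric(emp), pr), 0.05)
})

test_that("masked-label update matches the enumerated label posterior", {
  st <- toy_state(p = 4, J = 2, lambda = 1.3, seed = 19)
  d <- toy_data("ACGTT")
  labels <- label_state(NA, K = 1)
  # exact P(w = 1): uniform prior x position-marginalized emission-ratio mass
  vecs <- enumerate_position_vectors(5, 2)
  lw <- vapply(vecs, position_vector_log_weight, 0, x = d$codes[[1]], state = st)
  mass1 <- sum(exp(lw))
  p1 <- mass1 / (mass1 + 1)
  set.seed(41)
  labs <- replicate(4000, update_label(1, d, labels, st)$label)
  se <- sqrt(p1 * (1 - p1) / 4000)
  expect_lt(abs(mean(labs == 1) - p1), 4 * se + 0.005)

  # an infeasible motif (J > L) is never selected
  st_long <- toy_state(p = 4, J = 7, lambda = rep(1, 6), seed = 20)
  labs2 <- replicate(200, update_label(1, d, labels, st_long)$label)
  expect_true(all(labs2 == 2))

  # motif identical to background: label frequencies follow the prior
  theta0 <- c(0.3, 0.3, 0.2, 0.2)
  stbg <- motif_state(theta0, list(cbind(theta0, theta0)), list(1))
  set.seed(43)
  labs3 <- replicate(4000, update_label(1, d, labels, stbg)$label)
  expect_lt(abs(mean(labs3 == 1) - 0.5), 4 * sqrt(0.25 / 4000))

  # known labels are protected
  known <- label_state(1L, K = 1)
  expect_error(update_label(1, d, known, st), "known")
})
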