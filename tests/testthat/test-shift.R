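# the coordinated block shift move: proposal bookkeeping, boundary
# handling, acceptance contract and mode escape

# small instance with a planted contiguous-ish motif used across these tests
shift_fixture <- function(seed = 2, n = 6, conc = 0.9) {
  set.seed(seed)
  p <- 4; J <- 3; L <- 10
  Th <- matrix((1 - conc) / 3, p, J)
  Th[1, 1] <- conc; Th[2, 2] <- conc; Th[3, 3] <- conc
  A <- matrix(0L, n, J)
  seqs <- character(n)
  for (i in seq_len(n)) {
    x <- sample.int(p, L, replace = TRUE)
    a <- c(sample.int(3, 1), 0L, 0L)
    a[2] <- a[1] + sample(1:2, 1); a[3] <- a[2] + sample(1:2, 1)
    A[i, ] <- a
    for (j in 1:J) x[a[j]] <- sample.int(p, 1, prob = Th[, j])
    seqs[i] <- paste(c("A", "C", "G", "T")[x], collapse = "")
  }
  list(data = toy_data(seqs), A = A, w = rep(1L, n),
       state = motif_state(rep(0.25, 4), list(Th), list(c(1, 1.2))))
}

test_that("shift proposals preserve the position invariants or auto-reject", {
  fx <- shift_fixture()
  set.seed(7)
  n_feasible <- 0
  for (r in 1:60) {
    prop <- propose_shift(1, fx$state, list(fx$A), fx$w, fx$data)
    if (!prop$feasible) next
    n_feasible <- n_feasible + 1
    for (i in prop$rows) {
      expect_silent(validate_position_row(prop$positions[i, ],
                                          fx$data$lengths[i], 3))
    }
    expect_equal(colSums(prop$theta), rep(1, 3), tolerance = 1e-12)
    expect_true(all(prop$lambda > 0))
    expect_true(is.finite(prop$lq_forward) && is.finite(prop$lq_reverse))
  }
  expect_gt(n_feasible, 10)
})

test_that("a shift against the sequence boundary is infeasible and auto-rejects", {
  # motif occupying the final positions: a backward (delta = -1) whole-block
  # shift must refill past the sequence end -> infeasible
  d <- toy_data("ACGTAC")
  A <- list(matrix(c(5L, 6L), 1, 2))
  st <- motif_state(rep(0.25, 4),
                    list(cbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1))),
                    list(1))
  set.seed(1)
  prop <- propose_shift(1, st, A, 1L, d,
                        tuning = shift_tuning(force = list(delta = -1, l = 2, s = 1)))
  expect_false(prop$feasible)
  res <- accept_shift(prop, st, A, 1L, d)
  expect_false(res$accepted)
  expect_identical(res$state, st)
  expect_identical(res$positions, A)
  expect_identical(res$log_alpha, -Inf)
})

test_that("the acceptance ratio uses the exact log-joint difference", {
  fx <- shift_fixture(seed = 5)
  hy <- hyperparameters()
  set.seed(11)
  checked <- 0
  for (r in 1:40) {
    prop <- propose_shift(1, fx$state, list(fx$A), fx$w, fx$data, hy)
    if (!prop$feasible) next
    res <- accept_shift(prop, fx$state, list(fx$A), fx$w, fx$data, hy)
    new_state <- fx$state
    new_state$thetas[[1]] <- prop$theta
    new_state$lambdas[[1]] <- prop$lambda
    dlj <- log_joint(fx$data, fx$w, list(prop$positions), new_state, hy) -
           log_joint(fx$data, fx$w, list(fx$A), fx$state, hy)
    expect_equal(res$log_alpha, dlj + prop$lq_reverse - prop$lq_forward,
                 tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("forward and reverse proposal densities are computed independently", {
  # one-sequence toy with forced direction and block: recompute both
  # densities from first principles (urn-weighted gap conditional for the
  # refilled column, Dirichlet posterior density for the redrawn motif
  # column, lognormal densities for the re-proposed rates)
  d <- toy_data("ACGTACG")   # L = 7
  A <- matrix(c(2L, 4L, 6L), 1, 3)
  st <- toy_state(p = 4, J = 3, lambda = c(0.8, 1.4), seed = 3)
  hy <- hyperparameters()
  set.seed(19)
  prop <- propose_shift(1, st, list(A), 1L, d, hy,
                        tuning = shift_tuning(force = list(delta = -1, l = 2, s = 2)))
  expect_true(prop$feasible)
  # delta = -1, block [2, 3]: column 2 value is dropped, column 3's value
  # slides to column 2, column 3 is refilled beyond the old a3 = 6
  expect_identical(prop$positions[1, 2], A[1, 3])
  expect_identical(prop$col_new, 3L)
  x <- d$codes[[1]]
  lam_new <- prop$lambda
  # forward refill density: candidates are {7} only (a*2 = 6, L = 7)
  expect_identical(prop$positions[1, 3], 7L)
  # with a single candidate the positional factor is log(1) = 0, so the
  # forward density decomposes into the rate and Dirichlet parts
  cnt_new <- tabulate(x[7], 4)
  lq_theta_f <- gapmotif:::.ldirichlet(prop$theta[, 3], hy$alpha + cnt_new)
  rw_f <- prop$lambda_rw_slots
  lq_lam_f <- sum(dlnorm(lam_new[rw_f], log(st$lambdas[[1]][rw_f]), 0.3,
                         log = TRUE))
  expect_equal(prop$lq_forward, lq_theta_f + lq_lam_f, tolerance = 1e-10)
  # reverse: the mirror move must re-propose old column 2 (value 4) in the
  # range (2, 6) under the old rates, plus the old Dirichlet column density
  cand <- 3:5
  lw <- log(1 + hy$alpha * 0) + log(hy$alpha) - log(hy$alpha * 4) -
        log(st$theta0[x[cand]])           # empty-urn predictive, relative to bg
  lw <- lw + (cand - 2) * log(st$lambdas[[1]][1]) - lfactorial(cand - 2)
  dn <- 6 - cand
  dmax <- (7 - 3 + 3) - cand
  lz <- sapply(dmax, function(dm) log(sum(st$lambdas[[1]][2]^(1:dm) / factorial(1:dm))))
  lw <- lw + dn * log(st$lambdas[[1]][2]) - lfactorial(dn) - lz
  lq_pos_r <- lw[2] - log(sum(exp(lw)))   # old value 4 is the 2nd candidate
  cnt_old <- tabulate(x[4], 4)
  lq_theta_r <- gapmotif:::.ldirichlet(st$thetas[[1]][, 2], hy$alpha + cnt_old)
  rw_r <- intersect(c(1, 2, 3), 1:2)      # mirror RW set for delta=-1, s=2, e=3
  lq_lam_r <- sum(dlnorm(st$lambdas[[1]][rw_r], log(lam_new[rw_r]), 0.3,
                         log = TRUE))
  expect_equal(prop$lq_reverse, lq_pos_r + lq_theta_r + lq_lam_r,
               tolerance = 1e-10)
})

test_that("rejected proposals leave the chain state bit-identical", {
  fx <- shift_fixture(seed = 9)
  hy <- hyperparameters()
  set.seed(23)
  rejected <- 0
  for (r in 1:60) {
    prop <- propose_shift(1, fx$state, list(fx$A), fx$w, fx$data, hy)
    res <- accept_shift(prop, fx$state, list(fx$A), fx$w, fx$data, hy)
    if (!res$accepted) {
      rejected <- rejected + 1
      expect_identical(res$state, fx$state)
      expect_identical(res$positions, list(fx$A))
    }
  }
  expect_gt(rejected, 5)
})

test_that("shift moves rescue chains initialized at an offset local mode", {
  # strong planted motif, sampler started with every binding column shifted
  # by one column index; plain per-position resampling cannot coordinate
  # the realignment, the block shift can
  escaped <- function(shift_prob, s) {
    inst <- escape_instance(s)
    tr <- run_mcmc(inst$data, inst$labels, 3L, init = inst$init,
                   config = mcmc_config(n_iter = 500, burn_in = 350,
                                        seed = 700 + s,
                                        shift_move_prob = shift_prob))
    mean(map_estimates(tr)$positions[[1]] == inst$truth_A) > 0.8
  }
  with_shift <- vapply(1:20, function(s) escaped(1, s), TRUE)
  without <- vapply(1:20, function(s) escaped(0, s), TRUE)
  expect_gte(mean(with_shift), 0.8)
  expect_lt(mean(without), mean(with_shift))
})
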