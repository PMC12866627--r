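# conjugate Gibbs updates, sequential position sampling, exact DP
# marginalization over binding positions, and masked-label updates

# letter counts at current binding positions, per motif column and pooled
.motif_counts <- function(codes, w, positions, K, p) {
  cols <- vector("list", K)
  total <- numeric(p)
  for (k in seq_len(K)) {
    A <- positions[[k]]
    J <- ncol(A)
    rows <- which(!is.na(w) & w == k)
    cm <- matrix(0, p, J)
    if (length(rows)) {
      for (j in seq_len(J)) {
        letters <- vapply(rows, function(i) codes[[i]][A[i, j]], 0L)
        cm[, j] <- tabulate(letters, p)
      }
    }
    cols[[k]] <- cm
    total <- total + rowSums(cm)
  }
  list(cols = cols, total = total)
}

#' Gibbs update of the background distribution
#'
#' The background counts pool every letter of background-labeled sequences
#' and every non-motif position of motif-labeled sequences; by
#' Dirichlet-categorical conjugacy the full conditional is
#' `Dirichlet(alpha0 + counts)`.
#'
#' @param data A [sequence_dataset()].
#' @param labels A [label_state()] or complete integer label vector.
#' @param positions List of `K` position matrices.
#' @param hyper A [hyperparameters()].
#' @param sample Draw from the full conditional (default); `FALSE` returns
#'   the analytic posterior mean instead.
#' @return Probability vector of length `p`.
#' @export
update_theta0 <- function(data, labels, positions, hyper = hyperparameters(),
                          sample = TRUE) {
  w <- .label_vector(labels)
  K <- length(positions)
  p <- data$alphabet$p
  tot <- tabulate(unlist(data$codes), p)
  mc <- .motif_counts(data$codes, w, positions, K, p)
  alpha_post <- hyper$alpha0 + tot - mc$total
  if (sample) .rdirichlet1(alpha_post) else alpha_post / sum(alpha_post)
}

#' Gibbs update of one motif composition matrix
#'
#' Column `j` of motif `k` has full conditional
#' `Dirichlet(alpha + counts of letters observed at binding position j)`
#' across the sequences currently carrying motif `k`; with no assigned
#' sequences the draw falls back to the prior.
#'
#' @inheritParams update_theta0
#' @param k Motif index.
#' @return A `p x J_k` column-stochastic matrix.
#' @export
update_theta_k <- function(data, labels, positions, k, hyper = hyperparameters(),
                           sample = TRUE) {
  w <- .label_vector(labels)
  p <- data$alphabet$p
  A <- positions[[k]]
  J <- ncol(A)
  rows <- which(!is.na(w) & w == k)
  Th <- matrix(0, p, J)
  for (j in seq_len(J)) {
    cnt <- if (length(rows)) {
      tabulate(vapply(rows, function(i) data$codes[[i]][A[i, j]], 0L), p)
    } else rep(0L, p)
    alpha_post <- hyper$alpha + cnt
    Th[, j] <- if (sample) .rdirichlet1(alpha_post) else alpha_post / sum(alpha_post)
  }
  Th
}

# unnormalized log full conditional of one gap rate under the exact
# truncated-Poisson likelihood (constants in lambda dropped)
.lambda_loglik <- function(lam, d, dmax, beta, nu) {
  lz <- .tp_lz(lam, max(dmax))
  (beta - 1) * log(lam) - nu * lam + sum(d) * log(lam) - sum(lz[dmax])
}

.lambda_mh_step <- function(lam_j, d, dmax, beta, nu, sigma) {
  prop <- lam_j * exp(sigma * stats::rnorm(1))
  la <- .lambda_loglik(prop, d, dmax, beta, nu) -
        .lambda_loglik(lam_j, d, dmax, beta, nu) + log(prop) - log(lam_j)
  if (is.finite(la) && log(stats::runif(1)) < la) prop else lam_j
}

#' Update the gap rates of one motif
#'
#' Default `"conjugate"` mode draws `lambda_kj ~ Gamma(beta + sum of gaps,
#' nu + number of assigned sequences)`, the conjugate update obtained by
#' ignoring the truncation of the gap distribution (a documented
#' approximation; the truncated mass is small at the rates of interest).
#' `"mh"` mode instead performs one Metropolis-Hastings step with a log-space
#' Gaussian random walk targeting the exact truncated-Poisson full
#' conditional, and is what makes the chain exact on small instances.
#'
#' @inheritParams update_theta_k
#' @param method `"conjugate"` or `"mh"`.
#' @param current Current rate vector (required for `"mh"`).
#' @param sigma Random-walk scale in log space for `"mh"`.
#' @return Positive rate vector of length `J_k - 1`.
#' @export
update_lambda_k <- function(data, labels, positions, k, hyper = hyperparameters(),
                            method = c("conjugate", "mh"), current = NULL,
                            sigma = 0.5) {
  method <- match.arg(method)
  w <- .label_vector(labels)
  A <- positions[[k]]
  J <- ncol(A)
  if (J == 1L) return(numeric(0))
  rows <- which(!is.na(w) & w == k)
  m <- length(rows)
  out <- numeric(J - 1L)
  for (j in seq_len(J - 1L)) {
    d <- if (m) A[rows, j + 1L] - A[rows, j] else integer(0)
    if (method == "conjugate" || m == 0L) {
      out[j] <- stats::rgamma(1, shape = hyper$beta + sum(d),
                              rate = hyper$nu + m)
    } else {
      if (is.null(current)) stop("current rates are required for method = 'mh'",
                                 call. = FALSE)
      dmax <- (data$lengths[rows] - J + j + 1L) - A[rows, j]
      out[j] <- .lambda_mh_step(current[j], d, dmax, hyper$beta, hyper$nu, sigma)
    }
  }
  out
}

# ---- position sampling ------------------------------------------------------

# log emission ratios log theta[x, j] - log theta0[x], an L x J matrix
.emission_lr <- function(x, lth_k, lt0) {
  lth_k[x, , drop = FALSE] - lt0[x]
}

# one systematic-scan sweep of the per-position full conditionals for one row
.row_sweep <- function(a, ler, llam, lzs, L, J) {
  for (j in seq_len(J)) {
    lo <- if (j == 1L) 1L else a[j - 1L] + 1L
    hi <- if (j == J) L else a[j + 1L] - 1L
    hi <- min(hi, L - J + j)
    if (lo >= hi) { a[j] <- lo; next }
    cand <- lo:hi
    lw <- ler[cand, j]
    if (j > 1L) {
      d <- cand - a[j - 1L]
      lw <- lw + d * llam[j - 1L] - lfactorial(d)
    }
    if (j < J) {
      dn <- a[j + 1L] - cand
      dmax <- (L - J + j + 1L) - cand
      lw <- lw + dn * llam[j] - lfactorial(dn) - lzs[[j]][dmax]
    }
    w <- exp(lw - max(lw))
    a[j] <- cand[sample.int(length(cand), 1L, prob = w)]
  }
  a
}

# evaluation context: logs of the current parameters plus per-slot truncated
# Poisson normalizer tables up to the longest sequence
.make_ctx <- function(state, Lmax) {
  K <- state$K
  ctx <- list(lt0 = log(state$theta0), lth = vector("list", K),
              llam = vector("list", K), lzs = vector("list", K))
  for (k in seq_len(K)) {
    ctx$lth[[k]] <- log(state$thetas[[k]])
    lam <- state$lambdas[[k]]
    ctx$llam[[k]] <- log(lam)
    ctx$lzs[[k]] <- lapply(lam, .tp_lz, M = Lmax)
  }
  ctx
}

# draw a position vector from the gap prior (uniform first position, then
# truncated-Poisson gaps over the feasible ranges)
.prior_positions_draw <- function(L, J, lam) {
  a <- integer(J)
  a[1L] <- sample.int(L - J + 1L, 1L)
  if (J > 1L) for (j in 2:J) {
    dmax <- (L - J + j) - a[j - 1L]
    a[j] <- a[j - 1L] + .trunc_poisson_draw(lam[j - 1L], dmax)
  }
  a
}

#' Resample the binding positions of one sequence
#'
#' Sequentially resamples each binding position from its full conditional
#' given its neighbours: the candidate weight combines the emission ratio
#' against the background with the truncated-Poisson gap terms to the left
#' and right neighbours, over the admissible range.  One call performs one
#' full sweep over the `J_k` positions.
#'
#' @param x Integer code vector of the sequence (or character string plus
#'   `alphabet`).
#' @param k Motif index.
#' @param state A [motif_state()].
#' @param a Current position vector; `NULL` draws an initial vector from the
#'   gap prior before sweeping.
#' @param alphabet Required when `x` is a character string.
#' @return An integer position vector satisfying the position invariants.
#' @export
sample_positions_row <- function(x, k, state, a = NULL, alphabet = NULL) {
  if (is.character(x)) {
    if (is.null(alphabet)) stop("alphabet is required for character input", call. = FALSE)
    x <- encode_sequence(x, alphabet)
  }
  x <- as.integer(x)
  L <- length(x)
  J <- state$motif_lengths[k]
  if (L < J) stop(sprintf("sequence of length %d cannot hold a motif of length %d", L, J),
                  call. = FALSE)
  lam <- state$lambdas[[k]]
  if (is.null(a)) a <- .prior_positions_draw(L, J, lam)
  a <- validate_position_row(a, L, J)
  lt0 <- log(state$theta0)
  ler <- .emission_lr(x, log(state$thetas[[k]]), lt0)
  lzs <- lapply(lam, .tp_lz, M = L)
  .row_sweep(a, ler, log(lam), lzs, L, J)
}

# ---- exact dynamic-programming marginalization ------------------------------

# log transition matrix between consecutive motif columns: entry [prev, targ]
# is the truncated-Poisson log-probability of moving from position prev at
# column j to position targ at column j + 1
.dp_gap_matrix <- function(llam_j, lz_j, L, J, j) {
  M <- matrix(-Inf, L, L)
  hi_prev <- L - J + j
  hi_targ <- L - J + j + 1L
  for (a0 in seq.int(j, hi_prev)) {
    targ <- seq.int(a0 + 1L, hi_targ)
    d <- targ - a0
    M[a0, targ] <- d * llam_j - lfactorial(d) - lz_j[hi_targ - a0]
  }
  M
}

.dp_forward <- function(ler, Ms, L, J) {
  FF <- matrix(-Inf, J, L)
  first <- seq_len(L - J + 1L)
  FF[1L, first] <- -log(L - J + 1L) + ler[first, 1L]
  if (J > 1L) for (j in 2:J) {
    A <- FF[j - 1L, ] + Ms[[j - 1L]]      # rows: prev position, cols: target
    m <- apply(A, 2L, max)
    m2 <- ifelse(is.finite(m), m, 0)
    lse <- m2 + log(colSums(exp(sweep(A, 2L, m2, "-"))))
    FF[j, ] <- ler[, j] + lse
  }
  FF
}

.sample_log <- function(lw) {
  w <- exp(lw - max(lw))
  sample.int(length(lw), 1L, prob = w)
}

.dp_backsample <- function(FF, Ms, L, J) {
  a <- integer(J)
  a[J] <- .sample_log(FF[J, ])
  if (J > 1L) for (j in (J - 1L):1L) {
    a[j] <- .sample_log(FF[j, ] + Ms[[j]][, a[j + 1L]])
  }
  a
}

#' Exact marginal likelihood over binding positions
#'
#' Forward dynamic programming over (motif column, position) exactly sums
#' the posterior weight `uniform first-position prior x truncated-Poisson
#' gap terms x emission ratios` over every valid position vector, in
#' `O(J L^2)` time.  The returned lattice supports exact backward sampling
#' of a position vector via [dp_position_sample()], and the marginal is the
#' exact per-sequence log-likelihood under label `k` (background log-likelihood
#' plus the log marginalized motif factor).  Used both as an optional exact
#' position sampler and as the oracle against which the sequential sampler
#' is tested.
#'
#' @inheritParams sample_positions_row
#' @return An object of class `dp_lattice` with fields `log_marginal`
#'   (scalar), `forward` (`J x L` log matrix), `transitions`, `L`, `J`,
#'   `log_background`.
#' @export
dp_position_marginal <- function(x, k, state, alphabet = NULL) {
  if (is.character(x)) {
    if (is.null(alphabet)) stop("alphabet is required for character input", call. = FALSE)
    x <- encode_sequence(x, alphabet)
  }
  x <- as.integer(x)
  L <- length(x)
  J <- state$motif_lengths[k]
  if (L < J) {
    return(structure(list(log_marginal = -Inf, forward = NULL,
                          transitions = NULL, L = L, J = J,
                          log_background = sum(log(state$theta0)[x])),
                     class = "dp_lattice"))
  }
  lt0 <- log(state$theta0)
  bg <- sum(lt0[x])
  lam <- state$lambdas[[k]]
  llam <- log(lam)
  lzs <- lapply(lam, .tp_lz, M = L)
  Ms <- if (J > 1L) {
    lapply(seq_len(J - 1L), function(j) .dp_gap_matrix(llam[j], lzs[[j]], L, J, j))
  } else list()
  ler <- .emission_lr(x, log(state$thetas[[k]]), lt0)
  FF <- .dp_forward(ler, Ms, L, J)
  structure(list(log_marginal = bg + .logsumexp(FF[J, ]), forward = FF,
                 transitions = Ms, L = L, J = J, log_background = bg),
            class = "dp_lattice")
}

#' @rdname dp_position_marginal
#' @param lattice A `dp_lattice` from [dp_position_marginal()].
#' @export
dp_position_sample <- function(lattice) {
  if (!is.finite(lattice$log_marginal)) {
    stop("cannot sample positions from an infeasible lattice", call. = FALSE)
  }
  .dp_backsample(lattice$forward, lattice$transitions, lattice$L, lattice$J)
}

# ---- masked-label update ----------------------------------------------------

# log masses of the K + 1 label candidates relative to the background
# log-likelihood (which cancels); lattices kept for backward sampling
.label_masses <- function(x, L, state, lpl, ctx) {
  K <- state$K
  lmass <- c(rep(-Inf, K), lpl[K + 1L])
  lats <- vector("list", K)
  for (k in seq_len(K)) {
    J <- state$motif_lengths[k]
    if (L < J) next
    Ms <- if (J > 1L) {
      lapply(seq_len(J - 1L), function(j)
        .dp_gap_matrix(ctx$llam[[k]][j], ctx$lzs[[k]][[j]], L, J, j))
    } else list()
    ler <- .emission_lr(x, ctx$lth[[k]], ctx$lt0)
    FF <- .dp_forward(ler, Ms, L, J)
    lmass[k] <- lpl[k] + .logsumexp(FF[J, ])
    lats[[k]] <- list(FF = FF, Ms = Ms, J = J)
  }
  list(lmass = lmass, lats = lats)
}

#' Gibbs update of one masked label
#'
#' Draws the label of a masked sequence from its exact full conditional:
#' the probability of motif `k` is proportional to the label prior times the
#' exact position-marginalized likelihood from [dp_position_marginal()], and
#' the background mass to the prior times the background likelihood.  When a
#' motif label is drawn, a fresh position vector is sampled exactly from the
#' DP lattice.  Motifs longer than the sequence receive zero mass.
#'
#' @param i Sequence index (must be masked, i.e. `labels$known[i]` is FALSE).
#' @param data A [sequence_dataset()].
#' @param labels A [label_state()].
#' @param state A [motif_state()].
#' @param hyper A [hyperparameters()].
#' @return List with elements `label` (integer in `1..K+1`) and `a`
#'   (position vector, or `NULL` for background).
#' @export
update_label <- function(i, data, labels, state, hyper = hyperparameters()) {
  if (inherits(labels, "label_state") && labels$known[i]) {
    stop(sprintf("label of sequence '%s' is known and fixed", data$ids[i]),
         call. = FALSE)
  }
  K <- state$K
  lpl <- log(.label_prior_vec(hyper, K))
  ctx <- .make_ctx(state, data$lengths[i])
  x <- data$codes[[i]]
  lm <- .label_masses(x, data$lengths[i], state, lpl, ctx)
  if (all(!is.finite(lm$lmass))) {
    stop(sprintf("sequence '%s': every label candidate has zero mass", data$ids[i]),
         call. = FALSE)
  }
  lab <- .sample_log(lm$lmass)
  a <- if (lab <= K) {
    lat <- lm$lats[[lab]]
    .dp_backsample(lat$FF, lat$Ms, data$lengths[i], lat$J)
  } else NULL
  list(label = lab, a = a)
}
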