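# the iteration loop, trace container and MAP extraction

#' MCMC configuration
#'
#' @param n_iter Total iterations (default 1000).
#' @param burn_in Iterations discarded before summarizing (default 500).
#' @param seed Optional RNG seed; the whole run is reproducible from it.
#' @param shift_move_prob Per-iteration, per-motif probability of attempting
#'   a block shift move (default 1; motifs of length 1 never attempt one).
#' @param position_sampler `"sequential"` (one full-conditional sweep per
#'   row, O(n L) per iteration) or `"exact_dp"` (exact redraw from the DP
#'   lattice, O(J L^2) per row).
#' @param lambda_update `"conjugate"` (Gamma update ignoring truncation) or
#'   `"mh"` (exact truncated-Poisson target via one MH step).
#' @param lambda_mh_sigma Random-walk scale for `lambda_update = "mh"`.
#' @param shift A [shift_tuning()].
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 1000L, burn_in = 500L, seed = NULL,
                        shift_move_prob = 1,
                        position_sampler = c("sequential", "exact_dp"),
                        lambda_update = c("conjugate", "mh"),
                        lambda_mh_sigma = 0.5, shift = shift_tuning()) {
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  if (!(burn_in >= 0L && burn_in < n_iter)) {
    stop("burn_in must satisfy 0 <= burn_in < n_iter", call. = FALSE)
  }
  if (shift_move_prob < 0 || shift_move_prob > 1) {
    stop("shift_move_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_iter = n_iter, burn_in = burn_in, seed = seed,
                 shift_move_prob = shift_move_prob,
                 position_sampler = match.arg(position_sampler),
                 lambda_update = match.arg(lambda_update),
                 lambda_mh_sigma = lambda_mh_sigma, shift = shift),
            class = "mcmc_config")
}

# prior draw of every latent quantity (parameters, masked labels, positions)
.init_chain <- function(data, labels, motif_lengths, hyper, init) {
  n <- data$n
  p <- data$alphabet$p
  K <- labels$K
  w <- labels$labels
  if (!is.null(init)) {
    state <- init$state
    w <- .label_vector(init$labels)
    A <- init$positions
    return(list(state = state, w = w, A = A))
  }
  theta0 <- .rdirichlet1(rep(hyper$alpha0, p))
  thetas <- lapply(motif_lengths, function(J) {
    vapply(seq_len(J), function(j) .rdirichlet1(rep(hyper$alpha, p)),
           numeric(p))
  })
  lambdas <- lapply(motif_lengths, function(J) {
    stats::rgamma(max(J - 1L, 0L), shape = hyper$beta, rate = hyper$nu)
  })
  state <- motif_state(theta0, thetas, lambdas)
  prior <- .label_prior_vec(hyper, K)
  for (i in which(is.na(w))) {
    feas <- c(data$lengths[i] >= motif_lengths, TRUE)
    pr <- prior * feas
    w[i] <- sample.int(K + 1L, 1L, prob = pr)
  }
  A <- empty_positions(n, motif_lengths)
  for (k in seq_len(K)) {
    for (i in which(w == k)) {
      A[[k]][i, ] <- .prior_positions_draw(data$lengths[i], motif_lengths[k],
                                           lambdas[[k]])
    }
  }
  list(state = state, w = w, A = A)
}

#' Run the gapped-motif MCMC sampler
#'
#' Each iteration performs, in fixed order: the conjugate update of the
#' background `theta0`; the conjugate update of every motif matrix; the
#' gap-rate updates; one position-resampling pass over every motif-labeled
#' sequence; the exact full-conditional update of every masked label (with
#' fresh positions drawn from the DP lattice); and, with probability
#' `shift_move_prob` per motif, one block shift move.  Initial values are
#' drawn from the priors unless `init` is supplied.
#'
#' @param data A [sequence_dataset()].
#' @param labels A [label_state()]; known labels are held fixed, masked ones
#'   are imputed.
#' @param motif_lengths Integer vector of `K` motif lengths `J_k`.
#' @param hyper A [hyperparameters()].
#' @param config An [mcmc_config()].
#' @param init Optional list with `state`, `labels`, `positions` to start
#'   from instead of prior draws (used e.g. to study mode escape).
#' @return An object of class `mcmc_trace` holding per-iteration snapshots
#'   of all parameters and latent variables, the total log-likelihood, and
#'   per-motif shift-move attempt/acceptance flags.
#' @export
run_mcmc <- function(data, labels, motif_lengths, hyper = hyperparameters(),
                     config = mcmc_config(), init = NULL) {
  stopifnot(inherits(data, "sequence_dataset"), inherits(labels, "label_state"))
  K <- labels$K
  motif_lengths <- as.integer(motif_lengths)
  if (length(motif_lengths) != K) {
    stop(sprintf("motif_lengths must have length K = %d", K), call. = FALSE)
  }
  n <- data$n
  p <- data$alphabet$p
  Ls <- data$lengths
  Lmax <- max(Ls)
  known_motif <- which(labels$known & labels$labels <= K)
  bad <- known_motif[Ls[known_motif] < motif_lengths[labels$labels[known_motif]]]
  if (length(bad)) {
    stop(sprintf("sequence '%s' (length %d) cannot hold its known motif (length %d)",
                 data$ids[bad[1L]], Ls[bad[1L]],
                 motif_lengths[labels$labels[bad[1L]]]), call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  lpl <- log(.label_prior_vec(hyper, K))
  masked <- which(!labels$known)

  ini <- .init_chain(data, labels, motif_lengths, hyper, init)
  state <- ini$state; w <- ini$w; A <- ini$A

  n_iter <- config$n_iter
  trace <- list(
    n_iter = n_iter, burn_in = config$burn_in, K = K, p = p, n = n,
    motif_lengths = motif_lengths, ids = data$ids, known = labels$known,
    alphabet = data$alphabet, config = config, hyper = hyper,
    loglik = numeric(n_iter),
    theta0 = matrix(NA_real_, p, n_iter),
    thetas = lapply(motif_lengths, function(J) array(NA_real_, c(p, J, n_iter))),
    lambdas = lapply(motif_lengths, function(J)
      matrix(NA_real_, max(J - 1L, 0L), n_iter)),
    labels = matrix(NA_integer_, n, n_iter),
    positions = lapply(motif_lengths, function(J)
      array(NA_integer_, c(n, J, n_iter))),
    shift_attempt = matrix(FALSE, K, n_iter),
    shift_accept = matrix(FALSE, K, n_iter)
  )

  for (it in seq_len(n_iter)) {
    ## conjugate parameter updates given current (w, A)
    state$theta0 <- update_theta0(data, w, A, hyper)
    for (k in seq_len(K)) {
      state$thetas[[k]] <- update_theta_k(data, w, A, k, hyper)
      state$lambdas[[k]] <- update_lambda_k(
        data, w, A, k, hyper, method = config$lambda_update,
        current = state$lambdas[[k]], sigma = config$lambda_mh_sigma)
    }

    ## position sweep over every motif-labeled sequence
    ctx <- .make_ctx(state, Lmax)
    for (k in seq_len(K)) {
      J <- motif_lengths[k]
      rows <- which(w == k)
      if (!length(rows)) next
      if (config$position_sampler == "sequential") {
        llam <- ctx$llam[[k]]; lzs <- ctx$lzs[[k]]
        for (i in rows) {
          ler <- .emission_lr(data$codes[[i]], ctx$lth[[k]], ctx$lt0)
          A[[k]][i, ] <- .row_sweep(A[[k]][i, ], ler, llam, lzs, Ls[i], J)
        }
      } else {
        dpc <- new.env(parent = emptyenv())   # per-length transition cache
        for (i in rows) {
          L <- Ls[i]
          key <- as.character(L)
          if (is.null(dpc[[key]])) {
            dpc[[key]] <- if (J > 1L) {
              lapply(seq_len(J - 1L), function(j)
                .dp_gap_matrix(ctx$llam[[k]][j], ctx$lzs[[k]][[j]], L, J, j))
            } else list()
          }
          ler <- .emission_lr(data$codes[[i]], ctx$lth[[k]], ctx$lt0)
          FF <- .dp_forward(ler, dpc[[key]], L, J)
          A[[k]][i, ] <- .dp_backsample(FF, dpc[[key]], L, J)
        }
      }
    }

    ## masked-label updates from the exact DP conditional
    if (length(masked)) {
      dpm <- new.env(parent = emptyenv())  # transition cache keyed by (k, L)
      for (i in masked) {
        L <- Ls[i]
        lmass <- c(rep(-Inf, K), lpl[K + 1L])
        lats <- vector("list", K)
        for (k in seq_len(K)) {
          J <- motif_lengths[k]
          if (L < J) next
          key <- paste0(k, ":", L)
          if (is.null(dpm[[key]])) {
            dpm[[key]] <- if (J > 1L) {
              lapply(seq_len(J - 1L), function(j)
                .dp_gap_matrix(ctx$llam[[k]][j], ctx$lzs[[k]][[j]], L, J, j))
            } else list()
          }
          ler <- .emission_lr(data$codes[[i]], ctx$lth[[k]], ctx$lt0)
          FF <- .dp_forward(ler, dpm[[key]], L, J)
          lmass[k] <- lpl[k] + .logsumexp(FF[J, ])
          lats[[k]] <- list(FF = FF, Ms = dpm[[key]], J = J)
        }
        old <- w[i]
        if (all(!is.finite(lmass))) {
          stop(sprintf("sequence '%s': every label candidate has zero mass",
                       data$ids[i]), call. = FALSE)
        }
        w[i] <- .sample_log(lmass)
        if (!is.na(old) && old <= K) A[[old]][i, ] <- NA_integer_
        if (w[i] <= K) {
          lat <- lats[[w[i]]]
          A[[w[i]]][i, ] <- .dp_backsample(lat$FF, lat$Ms, L, lat$J)
        }
      }
    }

    ## block shift moves
    for (k in seq_len(K)) {
      if (motif_lengths[k] < 2L || !any(w == k)) next
      if (stats::runif(1) >= config$shift_move_prob) next
      trace$shift_attempt[k, it] <- TRUE
      prop <- propose_shift(k, state, A, w, data, hyper, config$shift)
      res <- accept_shift(prop, state, A, w, data, hyper)
      if (res$accepted) {
        trace$shift_accept[k, it] <- TRUE
        state <- res$state
        A <- res$positions
      }
    }

    ## record
    lt0 <- log(state$theta0)
    bg <- vapply(data$codes, function(x) sum(lt0[x]), 0)
    ll <- sum(bg)
    for (k in seq_len(K)) {
      lth <- log(state$thetas[[k]])
      J <- motif_lengths[k]
      for (i in which(w == k)) {
        a <- A[[k]][i, ]
        x <- data$codes[[i]]
        ll <- ll + sum(lth[cbind(x[a], seq_len(J))]) - sum(lt0[x[a]])
      }
    }
    trace$loglik[it] <- ll
    trace$theta0[, it] <- state$theta0
    trace$labels[, it] <- w
    for (k in seq_len(K)) {
      trace$thetas[[k]][, , it] <- state$thetas[[k]]
      if (motif_lengths[k] > 1L) trace$lambdas[[k]][, it] <- state$lambdas[[k]]
      trace$positions[[k]][, , it] <- A[[k]]
    }
  }
  structure(trace, class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  acc <- if (any(x$shift_attempt)) {
    sprintf("%.2f", sum(x$shift_accept) / sum(x$shift_attempt))
  } else "NA"
  cat(sprintf("<mcmc_trace> %d iterations (%d burn-in), K = %d, n = %d; final loglik %.2f; shift acceptance %s\n",
              x$n_iter, x$burn_in, x$K, x$n, x$loglik[x$n_iter], acc))
  invisible(x)
}

# marginal posterior mode with ties broken by the smallest value
.mode_int <- function(v) {
  v <- v[!is.na(v)]
  ux <- sort(unique(v))
  ux[which.max(tabulate(match(v, ux)))]
}

.mode_chr <- function(v) {
  ux <- sort(unique(v))
  ux[which.max(tabulate(match(v, ux)))]
}

#' Greedy motif matching against a reference
#'
#' For evaluation with `K > 1` the motif indices of an estimate are aligned
#' to a reference state by greedily assigning, for each reference motif in
#' turn, the unused estimated motif of equal length with the smallest
#' column-summed KL divergence.
#'
#' @param est,ref [motif_state()] objects with the same `K`.
#' @return Integer permutation `perm` such that estimated motif `perm[k]`
#'   corresponds to reference motif `k`.
#' @export
match_motifs <- function(est, ref) {
  K <- ref$K
  stopifnot(est$K == K)
  perm <- integer(K)
  used <- logical(K)
  for (k in seq_len(K)) {
    best <- NA_integer_; best_kl <- Inf
    for (m in which(!used)) {
      if (est$motif_lengths[m] != ref$motif_lengths[k]) next
      kl <- motif_kl(ref$thetas[[k]], est$thetas[[m]])
      if (kl < best_kl) { best <- m; best_kl <- kl }
    }
    if (is.na(best)) best <- which(!used)[1L]
    perm[k] <- best
    used[best] <- TRUE
  }
  perm
}

#' Posterior point estimates from a trace
#'
#' Discrete latent variables (labels and binding positions) are summarized
#' by their marginal posterior mode over the post-burn-in iterations, ties
#' broken by the smallest value; positions are taken over the iterations in
#' which the sequence carried its modal motif.  Continuous parameters are
#' posterior means, with motif columns renormalized to sum to one.
#'
#' @param trace An [run_mcmc()] trace.
#' @param burn_in Override of the burn-in stored in the trace.
#' @param reference Optional [motif_state()] ground truth; with `K > 1` the
#'   estimated motifs are relabeled by [match_motifs()] before summarizing.
#' @return List of class `gapmotif_map` with `state` (a [motif_state()]),
#'   `labels` (integer vector) and `positions` (list of `K` matrices).
#' @export
map_estimates <- function(trace, burn_in = NULL, reference = NULL) {
  if (is.null(burn_in)) burn_in <- trace$burn_in
  if (burn_in >= trace$n_iter) stop("empty post-burn-in window", call. = FALSE)
  post <- (burn_in + 1L):trace$n_iter
  K <- trace$K
  n <- trace$n
  theta0 <- rowMeans(trace$theta0[, post, drop = FALSE])
  theta0 <- theta0 / sum(theta0)
  thetas <- vector("list", K)
  lambdas <- vector("list", K)
  for (k in seq_len(K)) {
    Th <- apply(trace$thetas[[k]][, , post, drop = FALSE], c(1, 2), mean)
    thetas[[k]] <- sweep(Th, 2L, colSums(Th), "/")
    lambdas[[k]] <- if (trace$motif_lengths[k] > 1L) {
      rowMeans(trace$lambdas[[k]][, post, drop = FALSE])
    } else numeric(0)
  }
  state <- motif_state(theta0, thetas, lambdas)

  labels <- vapply(seq_len(n), function(i) .mode_int(trace$labels[i, post]), 0L)
  positions <- empty_positions(n, trace$motif_lengths)
  for (i in seq_len(n)) {
    k <- labels[i]
    if (k > K) next
    sel <- post[trace$labels[i, post] == k]
    J <- trace$motif_lengths[k]
    a <- vapply(seq_len(J), function(j)
      .mode_int(trace$positions[[k]][i, j, sel]), 0L)
    # slot-wise marginal modes can be jointly inconsistent (non-increasing)
    # when the alignment wobbles; fall back to the most frequent complete
    # row, which is always a valid sampled configuration
    if (J > 1L && any(diff(a) < 1L)) {
      rows <- t(trace$positions[[k]][i, , sel, drop = FALSE][1, , ])
      key <- apply(rows, 1L, paste, collapse = ",")
      a <- rows[match(.mode_chr(key), key), ]
    }
    positions[[k]][i, ] <- a
  }

  if (!is.null(reference) && K > 1L) {
    perm <- match_motifs(state, reference)
    state <- motif_state(state$theta0, state$thetas[perm], state$lambdas[perm])
    positions <- positions[perm]
    relab <- labels
    for (k in seq_len(K)) relab[labels == perm[k]] <- k
    labels <- relab
  }
  structure(list(state = state, labels = labels, positions = positions,
                 burn_in = burn_in), class = "gapmotif_map")
}
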