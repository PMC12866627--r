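# exact likelihood and log-joint evaluation

# log Dirichlet density at x with parameter vector alpha
.ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) - (sum(lgamma(alpha)) - lgamma(sum(alpha)))
}

# dirichlet draw; floor keeps every entry strictly positive so logs are finite
.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g <- pmax(g, 1e-300)
  g / sum(g)
}

#' Log-likelihood of a single sequence
#'
#' Under the background label (`w = K + 1`) every letter comes from
#' `theta0`.  Under a motif label `w = k` the letters at the binding
#' positions `a` come from the corresponding columns of the motif matrix and
#' all other letters from `theta0`.
#'
#' @param x Integer code vector of the sequence (see [encode_sequence()]),
#'   or a character string together with `alphabet`.
#' @param w Label in `1..K+1`.
#' @param a Binding-position vector of length `J_w` (motif labels only).
#' @param state A [motif_state()].
#' @param alphabet Required when `x` is a character string.
#' @return The log-likelihood (natural log), a finite scalar.
#' @export
sequence_log_likelihood <- function(x, w, a = NULL, state, alphabet = NULL) {
  if (is.character(x)) {
    if (is.null(alphabet)) stop("alphabet is required for character input", call. = FALSE)
    x <- encode_sequence(x, alphabet)
  }
  x <- as.integer(x)
  w <- as.integer(w)
  K <- state$K
  if (w < 1L || w > K + 1L) stop("label out of range", call. = FALSE)
  lt0 <- log(state$theta0)
  bg <- sum(lt0[x])
  if (w == K + 1L) {
    if (!is.null(a)) stop("background-labeled sequences carry no positions", call. = FALSE)
    return(bg)
  }
  J <- state$motif_lengths[w]
  a <- validate_position_row(a, length(x), J)
  Th <- state$thetas[[w]]
  bg + sum(log(Th[cbind(x[a], seq_len(J))])) - sum(lt0[x[a]])
}

#' Total log-likelihood of a dataset
#'
#' Sum of [sequence_log_likelihood()] over all sequences.  Labels must be
#' complete (no `NA`): during sampling masked labels are always imputed, so
#' callers holding masked data should pass the current imputed labels.
#'
#' @param data A [sequence_dataset()].
#' @param labels A [label_state()] or integer label vector (no `NA`).
#' @param positions List of `K` position matrices (`n x J_k`), rows `NA`
#'   unless the sequence carries that motif.
#' @param state A [motif_state()].
#' @return Scalar log-likelihood.
#' @export
total_log_likelihood <- function(data, labels, positions, state) {
  w <- .label_vector(labels)
  if (anyNA(w)) {
    stop("labels must be complete; impute or drop masked sequences first",
         call. = FALSE)
  }
  K <- state$K
  tot <- 0
  for (i in seq_len(data$n)) {
    a <- if (w[i] <= K) positions[[w[i]]][i, ] else NULL
    tot <- tot + tryCatch(
      sequence_log_likelihood(data$codes[[i]], w[i], a, state),
      error = function(e) stop(sprintf("sequence '%s': %s", data$ids[i],
                                       conditionMessage(e)), call. = FALSE))
  }
  tot
}

#' Log joint density of data, latent variables and parameters
#'
#' [total_log_likelihood()] plus the log prior densities: Dirichlet on
#' `theta0` and on each motif column, Gamma on each gap rate, a uniform
#' prior on the first binding position of each motif-labeled sequence,
#' truncated-Poisson terms on the consecutive-position gaps, and the label
#' prior.  This is the invariant density targeted by the sampler (up to the
#' constant from conditioning on known labels).
#'
#' @inheritParams total_log_likelihood
#' @param hyper A [hyperparameters()] object.
#' @return Scalar log joint density.
#' @export
log_joint <- function(data, labels, positions, state, hyper = hyperparameters()) {
  w <- .label_vector(labels)
  K <- state$K
  p <- state$p
  lj <- total_log_likelihood(data, labels, positions, state)
  lj <- lj + .ldirichlet(state$theta0, rep(hyper$alpha0, p))
  lpl <- log(.label_prior_vec(hyper, K))
  lj <- lj + sum(lpl[w])
  for (k in seq_len(K)) {
    Th <- state$thetas[[k]]
    J <- state$motif_lengths[k]
    for (j in seq_len(J)) {
      lj <- lj + .ldirichlet(Th[, j], rep(hyper$alpha, p))
    }
    lam <- state$lambdas[[k]]
    if (length(lam)) {
      lj <- lj + sum(stats::dgamma(lam, shape = hyper$beta, rate = hyper$nu,
                                   log = TRUE))
    }
    rows <- which(!is.na(w) & w == k)
    for (i in rows) {
      L <- data$lengths[i]
      a <- validate_position_row(positions[[k]][i, ], L, J)
      lj <- lj - log(L - J + 1)
      if (J > 1L) {
        for (j in 2:J) {
          dmax <- (L - J + j) - a[j - 1L]
          lj <- lj + log(trunc_poisson_pmf(a[j] - a[j - 1L], lam[j - 1L],
                                           seq_len(dmax)))
        }
      }
    }
  }
  lj
}
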