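# small deterministic builders shared across test files

dna <- motif_alphabet("dna")

# generic strictly positive state with K = 1, reproducible from seed
toy_state <- function(p = 4, J = 2, lambda = rep(1, max(J - 1, 0)), seed = 1) {
  set.seed(seed)
  theta0 <- as.numeric(prop.table(runif(p) + 0.2))
  Th <- vapply(seq_len(J), function(j) as.numeric(prop.table(runif(p) + 0.1)),
               numeric(p))
  motif_state(theta0, list(Th), list(lambda))
}

# dataset of explicit sequences over the DNA alphabet
toy_data <- function(seqs, alphabet = dna) {
  sequence_dataset(seqs, alphabet = alphabet)
}

# all valid position vectors for a motif of length J in a sequence of length L
enumerate_position_vectors <- function(L, J) {
  out <- list()
  rec <- function(prefix, j) {
    if (j > J) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    lo <- if (j == 1L) 1L else prefix[j - 1L] + 1L
    hi <- L - J + j
    if (lo > hi) return(invisible())
    for (a in lo:hi) rec(c(prefix, a), j + 1L)
  }
  rec(integer(0), 1L)
  out
}

# unnormalized log posterior weight of one position vector given fixed
# parameters: uniform first-position prior x truncated-Poisson gaps x
# emission ratios (independent arithmetic, no package DP code)
position_vector_log_weight <- function(a, x, state, k = 1) {
  Th <- state$thetas[[k]]
  lam <- state$lambdas[[k]]
  J <- ncol(Th)
  L <- length(x)
  lw <- -log(L - J + 1)
  for (j in seq_len(J)) {
    lw <- lw + log(Th[x[a[j]], j]) - log(state$theta0[x[a[j]]])
    if (j >= 2) {
      dmax <- (L - J + j) - a[j - 1]
      d <- a[j] - a[j - 1]
      wts <- sapply(seq_len(dmax), function(dd) lam[j - 1]^dd / factorial(dd))
      lw <- lw + log((lam[j - 1]^d / factorial(d)) / sum(wts))
    }
  }
  lw
}

# total-variation distance between an empirical table and exact probabilities
tv_dist <- function(emp, exact) 0.5 * sum(abs(emp - exact))
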