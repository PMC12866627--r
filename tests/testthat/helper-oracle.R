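# independent enumeration oracle for the collapsed posterior over
# (labels, positions): Dirichlet-categorical conjugacy in closed form,
# gap-rate (Gamma-prior, truncated-Poisson likelihood) integrals by
# trapezoid quadrature.  No package inference code is reused here.

oracle_lmbeta <- function(a) sum(lgamma(a)) - lgamma(sum(a))

# collapsed posterior for K = 1 over the joint configuration of all
# sequences; labels[i] = 1 (known motif), 2 (known background) or NA
# (masked: both options enumerated).  Returns per-config probabilities and
# the per-sequence option lists used for keying.
oracle_collapsed_posterior <- function(data, labels, J,
                                       lgrid = seq(0.01, 30, by = 0.01)) {
  p <- data$alphabet$p
  n <- data$n
  L <- data$lengths   # may vary per sequence
  glog <- log(lgrid)
  step <- lgrid[2] - lgrid[1]
  lz_cache <- list()
  lz_of <- function(dmax) {
    key <- as.character(dmax)
    if (is.null(lz_cache[[key]])) {
      lz_cache[[key]] <<- sapply(lgrid, function(lam)
        log(sum(lam^(seq_len(dmax)) / factorial(seq_len(dmax)))))
    }
    lz_cache[[key]]
  }
  # per-sequence options
  opts <- lapply(seq_len(n), function(i) {
    vecs <- enumerate_position_vectors(L[i], J)
    if (is.na(labels[i])) c(vecs, list(NULL))
    else if (labels[i] == 1L) vecs
    else list(NULL)
  })
  grid <- do.call(expand.grid, lapply(opts, seq_along))
  lp <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    c0 <- numeric(p)
    ccols <- matrix(0, p, J)
    v <- 0
    slot_acc <- matrix(0, length(lgrid), J - 1)
    for (i in seq_len(n)) {
      a <- opts[[i]][[grid[r, i]]]
      x <- data$codes[[i]]
      if (is.null(a)) { c0 <- c0 + tabulate(x, p); next }
      v <- v - log(L[i] - J + 1)
      c0 <- c0 + tabulate(x[-a], p)
      for (j in seq_len(J)) ccols[x[a[j]], j] <- ccols[x[a[j]], j] + 1
      if (J > 1) for (slot in seq_len(J - 1)) {
        d <- a[slot + 1] - a[slot]
        dmax <- (L[i] - J + slot + 1) - a[slot]
        slot_acc[, slot] <- slot_acc[, slot] +
          d * glog - lfactorial(d) - lz_of(dmax)
      }
    }
    v <- v + oracle_lmbeta(1 + c0) - oracle_lmbeta(rep(1, p))
    for (j in seq_len(J)) {
      v <- v + oracle_lmbeta(1 + ccols[, j]) - oracle_lmbeta(rep(1, p))
    }
    if (J > 1) for (slot in seq_len(J - 1)) {
      v <- v + log(sum(exp(slot_acc[, slot]) * exp(-lgrid)) * step)
    }
    lp[r] <- v
  }
  pr <- exp(lp - max(lp))
  list(prob = pr / sum(pr), grid = grid, opts = opts)
}

# index of a trace snapshot in the oracle's configuration grid; relies on
# expand.grid varying the first factor fastest
oracle_config_index <- function(oracle, trace, it) {
  n <- length(oracle$opts)
  lens <- lengths(oracle$opts)
  row <- 1L
  stride <- 1L
  for (i in seq_len(n)) {
    opt <- oracle$opts[[i]]
    if (trace$labels[i, it] == 2L) {
      idx <- which(vapply(opt, is.null, TRUE))
    } else {
      a <- trace$positions[[1]][i, , it]
      idx <- which(vapply(opt, function(v) !is.null(v) && all(v == a), TRUE))
    }
    row <- row + (idx - 1L) * stride
    stride <- stride * lens[i]
  }
  row
}
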