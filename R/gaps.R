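# position-range algebra and the truncated Poisson gap distribution

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Admissible range for a binding position
#'
#' For motif column `j` of a motif of length `J` in a sequence of length `L`,
#' the admissible positions are `{prev + 1, ..., L - J + j}` given the
#' previous binding position `prev`; for the first column (`j = 1`, `prev`
#' absent) they are `{1, ..., L - J + 1}`.  The upper bound guarantees that
#' the remaining `J - j` positions still fit inside the sequence.
#'
#' @param j Column index in `1..J`.
#' @param L Sequence length.
#' @param J Motif length (`L >= J`).
#' @param prev Previous binding position (required for `j >= 2`).
#' @return Integer vector of admissible positions.
#' @examples
#' valid_position_range(2, L = 10, J = 5, prev = 3)  # 4:7
#' @export
valid_position_range <- function(j, L, J, prev = NULL) {
  j <- as.integer(j); L <- as.integer(L); J <- as.integer(J)
  stopifnot(J >= 1L, j >= 1L, j <= J)
  if (L < J) stop(sprintf("sequence of length %d cannot hold a motif of length %d", L, J),
                  call. = FALSE)
  if (j == 1L) return(seq.int(1L, L - J + 1L))
  if (is.null(prev)) stop("prev is required for j >= 2", call. = FALSE)
  prev <- as.integer(prev)
  hi <- L - J + j
  if (prev >= hi) {
    stop(sprintf("infeasible: no admissible position for column %d after prev = %d (upper bound %d)",
                 j, prev, hi), call. = FALSE)
  }
  seq.int(prev + 1L, hi)
}

#' Truncated Poisson gap probability
#'
#' The gap `d` between consecutive binding positions is modelled by Poisson
#' weights `rate^d / d!` renormalized over the feasible gap support (gaps are
#' at least 1; adjacent positions have gap 1).  The support is the set of gap
#' values permitted by [valid_position_range()] for the next position.
#'
#' @param d Integer gap value(s) at which to evaluate the pmf.
#' @param rate Positive Poisson rate.
#' @param support Nonempty integer vector of feasible gap values.
#' @return Numeric probabilities; the pmf sums to 1 over `support`.
#' @examples
#' trunc_poisson_pmf(1:3, rate = 1, support = 1:3)  # 0.6 0.3 0.1
#' @export
trunc_poisson_pmf <- function(d, rate, support) {
  support <- as.integer(support)
  if (!length(support)) stop("empty gap support is infeasible", call. = FALSE)
  if (!(rate > 0)) stop("rate must be positive", call. = FALSE)
  d <- as.integer(d)
  if (!all(d %in% support)) {
    stop("gap value outside the truncation support", call. = FALSE)
  }
  lw <- support * log(rate) - lfactorial(support)
  exp(d * log(rate) - lfactorial(d) - .logsumexp(lw))
}

# one draw from the truncated Poisson over support 1..dmax
.trunc_poisson_draw <- function(rate, dmax) {
  if (dmax < 1L) stop("empty gap support is infeasible", call. = FALSE)
  if (dmax == 1L) return(1L)
  s <- seq_len(dmax)
  lw <- s * log(rate) - lfactorial(s)
  s[sample.int(dmax, 1L, prob = exp(lw - max(lw)))]
}

# log normalizers of the truncated Poisson over supports {1..d}, d = 1..M
.tp_lz <- function(rate, M) {
  lw <- seq_len(M) * log(rate) - lfactorial(seq_len(M))
  lz <- numeric(M)
  run <- -Inf
  for (d in seq_len(M)) {
    m <- max(run, lw[d])
    run <- m + log(exp(run - m) + exp(lw[d] - m))
    lz[d] <- run
  }
  lz
}
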