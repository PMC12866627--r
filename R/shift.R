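# Metropolis-Hastings block shift move: jointly re-proposes binding
# positions, motif columns and gap rates so the chain can escape modes in
# which the whole alignment sits at a one-column offset

#' Shift-move tuning parameters
#'
#' @param sigma Log-space Gaussian random-walk scale for the gap-rate
#'   proposals.
#' @param force Optional list with any of `delta`, `l`, `s` to pin the
#'   shift direction, block length and block start (diagnostics/testing
#'   only; `NULL` entries are drawn uniformly as usual).
#' @return A list of class `shift_tuning`.
#' @export
shift_tuning <- function(sigma = 0.3, force = NULL) {
  stopifnot(sigma > 0)
  structure(list(sigma = sigma, force = force), class = "shift_tuning")
}

# candidate range and log-weights for refilling column `col`, given the
# other entries of `arow` (its own entry is ignored).  Returns NULL when the
# range is empty.  The weight is the gap-prior conditional (truncated-Poisson
# terms to both neighbours under `lam`) times a predictive emission term: the
# Polya-urn predictive probability of the candidate's letter given the
# letters `cnt` already placed in this column by earlier rows, relative to
# the background.  Refilling rows sequentially with this urn approximates
# the collapsed full conditional of the refilled column, which is what makes
# realigning shifts acceptably probable.
.shift_fill_col <- function(arow, col, llam_l, llam_r, lz_r, L, J, x, cnt,
                            alpha, ltheta0, draw = TRUE, value = NULL) {
  lo <- if (col == 1L) 1L else arow[col - 1L] + 1L
  hi <- min(L - J + col, if (col < J) arow[col + 1L] - 1L else L)
  if (lo > hi) return(NULL)
  cand <- lo:hi
  lets <- x[cand]
  lw <- log(cnt[lets] + alpha) - log(sum(cnt) + alpha * length(cnt)) -
        ltheta0[lets]
  if (col > 1L) {
    d <- cand - arow[col - 1L]
    lw <- lw + d * llam_l - lfactorial(d)
  }
  if (col < J) {
    dn <- arow[col + 1L] - cand
    dmax <- (L - J + col + 1L) - cand
    lw <- lw + dn * llam_r - lfactorial(dn) - lz_r[dmax]
  }
  lse <- .logsumexp(lw)
  if (draw) {
    idx <- if (length(cand) == 1L) 1L else .sample_log(lw)
  } else {
    idx <- match(as.integer(value), cand)
    if (is.na(idx)) return(NULL)
  }
  list(a = cand[idx], letter = lets[idx], lq = lw[idx] - lse)
}

#' Propose a coordinated block shift
#'
#' Draws a direction `delta` (+1/-1), a block length `l` and a block start
#' uniformly, then builds the joint proposal: inside the block the
#' binding-position columns slide one column index in the direction of the
#' shift (their values are preserved; one end column is vacated), the vacated
#' position column is refilled per row from the gap-prior conditional over
#' its feasible range, the motif matrix columns slide in lockstep with the
#' vacated column redrawn from its posterior Dirichlet given the refilled
#' sites, and the gap rates adjacent to or inside the block are re-proposed
#' by a log-space Gaussian random walk.  Forward and reverse proposal
#' log-densities are accumulated with one shared routine so the Hastings
#' ratio is correct by construction.  If any row admits no feasible refill
#' the proposal is marked infeasible (auto-reject).
#'
#' @param k Motif index (`J_k >= 2`).
#' @param state A [motif_state()].
#' @param positions List of `K` position matrices.
#' @param labels A [label_state()] or complete integer label vector.
#' @param data A [sequence_dataset()].
#' @param hyper A [hyperparameters()].
#' @param tuning A [shift_tuning()].
#' @return An object of class `shift_proposal`; inspect `$feasible`,
#'   `$lq_forward`, `$lq_reverse` and the proposed `$positions`, `$theta`,
#'   `$lambda`.
#' @export
propose_shift <- function(k, state, positions, labels, data,
                          hyper = hyperparameters(), tuning = shift_tuning()) {
  w <- .label_vector(labels)
  J <- state$motif_lengths[k]
  if (J < 2L) stop("the shift move needs a motif with at least two columns", call. = FALSE)
  rows <- which(!is.na(w) & w == k)
  if (!length(rows)) stop("no sequences are currently assigned to this motif", call. = FALSE)
  p <- state$p
  force <- tuning$force
  delta <- if (!is.null(force$delta)) as.integer(force$delta) else sample(c(-1L, 1L), 1L)
  l <- if (!is.null(force$l)) as.integer(force$l) else sample.int(J, 1L)
  s <- if (!is.null(force$s)) as.integer(force$s) else {
    nb <- J - l + 1L
    if (nb == 1L) 1L else sample.int(nb, 1L)
  }
  e <- s + l - 1L
  stopifnot(delta %in% c(-1L, 1L), s >= 1L, e <= J)
  cdel <- if (delta == -1L) s else e   # column whose values are dropped
  cnew <- if (delta == -1L) e else s   # column refilled with fresh positions

  infeasible <- function() {
    structure(list(k = k, delta = delta, block = c(s, e), feasible = FALSE),
              class = "shift_proposal")
  }

  A <- positions[[k]]
  Ls <- data$lengths
  Anew <- A
  if (l >= 2L) {
    if (delta == -1L) {
      for (j in s:(e - 1L)) {
        Anew[rows, j] <- A[rows, j + 1L]
        if (any(Anew[rows, j] > Ls[rows] - J + j)) return(infeasible())
      }
    } else {
      for (j in (s + 1L):e) Anew[rows, j] <- A[rows, j - 1L]
    }
  }

  # gap rates: interior slots slide with the block (the new slot-j gap set
  # is exactly the old slot-(j-1) or slot-(j+1) set, so its rate moves with
  # it); only the slots whose gap sets are genuinely new - those adjacent to
  # the refilled column and the block edge - are re-proposed by a log-space
  # Gaussian random walk.  The forward and reverse random-walk slot sets
  # mirror each other, so the proposal densities pair up exactly.
  lam <- state$lambdas[[k]]
  sigma <- tuning$sigma
  all_slots <- seq_len(J - 1L)
  if (delta == 1L) {
    copy_to <- if (e - 1L >= s + 1L) (s + 1L):(e - 1L) else integer(0)
    rw_f <- intersect(c(s - 1L, s, e), all_slots)
    rw_r <- intersect(c(s - 1L, e - 1L, e), all_slots)
  } else {
    copy_to <- if (e - 2L >= s) s:(e - 2L) else integer(0)
    rw_f <- intersect(c(s - 1L, e - 1L, e), all_slots)
    rw_r <- intersect(c(s - 1L, s, e), all_slots)
  }
  lam_new <- lam
  for (j in copy_to) lam_new[j] <- if (delta == 1L) lam[j - 1L] else lam[j + 1L]
  lam_new[rw_f] <- lam[rw_f] * exp(sigma * stats::rnorm(length(rw_f)))
  lq_lambda_f <- sum(stats::dlnorm(lam_new[rw_f], log(lam[rw_f]), sigma, log = TRUE))
  lq_lambda_r <- sum(stats::dlnorm(lam[rw_r], log(lam_new[rw_r]), sigma, log = TRUE))

  # refill the vacated position column row by row under the proposed rates;
  # the urn counts accumulate the refilled letters so later rows are pulled
  # toward the emerging consensus
  ltheta0 <- log(state$theta0)
  # rows are refilled in order of increasing candidate-range width, so
  # narrow (informative) rows seed the urn before ambiguous ones choose;
  # the ordering is deterministic, hence reconstructable when this same
  # proposal is evaluated as the reverse of its mirror move
  width <- function(Am, col) {
    lo <- if (col == 1L) rep(1L, length(rows)) else Am[rows, col - 1L] + 1L
    hi <- pmin(Ls[rows] - J + col,
               if (col < J) Am[rows, col + 1L] - 1L else Ls[rows])
    hi - lo
  }
  ord_f <- rows[order(width(Anew, cnew), rows)]
  Lmax <- max(Ls[rows])
  llam_fl <- if (cnew > 1L) log(lam_new[cnew - 1L]) else NA_real_
  llam_fr <- if (cnew < J) log(lam_new[cnew]) else NA_real_
  lz_fr <- if (cnew < J) .tp_lz(lam_new[cnew], Lmax) else NULL
  lq_pos_f <- 0
  cnt <- numeric(p)
  for (i in ord_f) {
    res <- .shift_fill_col(Anew[i, ], cnew, llam_fl, llam_fr, lz_fr, Ls[i], J,
                           data$codes[[i]], cnt, hyper$alpha, ltheta0,
                           draw = TRUE)
    if (is.null(res)) return(infeasible())
    Anew[i, cnew] <- res$a
    cnt[res$letter] <- cnt[res$letter] + 1
    lq_pos_f <- lq_pos_f + res$lq
  }

  # motif columns slide with the block; the vacated column is redrawn from
  # its posterior Dirichlet given the refilled sites
  Th <- state$thetas[[k]]
  Thnew <- Th
  if (l >= 2L) {
    if (delta == -1L) Thnew[, s:(e - 1L)] <- Th[, (s + 1L):e]
    else              Thnew[, (s + 1L):e] <- Th[, s:(e - 1L)]
  }
  letters_new <- vapply(rows, function(i) data$codes[[i]][Anew[i, cnew]], 0L)
  cn <- tabulate(letters_new, p)
  newcol <- .rdirichlet1(hyper$alpha + cn)
  Thnew[, cnew] <- newcol
  lq_theta_f <- .ldirichlet(newcol, hyper$alpha + cn)

  # reverse move: same block, opposite direction, proposed from the new
  # state; it must refill column `cdel` with the old values under the old
  # rates, and redraw the old motif column there
  ord_r <- rows[order(width(A, cdel), rows)]
  llam_rl <- if (cdel > 1L) log(lam[cdel - 1L]) else NA_real_
  llam_rr <- if (cdel < J) log(lam[cdel]) else NA_real_
  lz_rr <- if (cdel < J) .tp_lz(lam[cdel], Lmax) else NULL
  lq_pos_r <- 0
  cnt_r <- numeric(p)
  for (i in ord_r) {
    res <- .shift_fill_col(A[i, ], cdel, llam_rl, llam_rr, lz_rr, Ls[i], J,
                           data$codes[[i]], cnt_r, hyper$alpha, ltheta0,
                           draw = FALSE, value = A[i, cdel])
    if (is.null(res)) return(infeasible())   # cannot happen for a valid A
    cnt_r[res$letter] <- cnt_r[res$letter] + 1
    lq_pos_r <- lq_pos_r + res$lq
  }
  letters_old <- vapply(rows, function(i) data$codes[[i]][A[i, cdel]], 0L)
  co <- tabulate(letters_old, p)
  lq_theta_r <- .ldirichlet(Th[, cdel], hyper$alpha + co)

  structure(list(
    k = k, delta = delta, block = c(s, e), block_len = l,
    col_deleted = cdel, col_new = cnew, rows = rows, feasible = TRUE,
    positions = Anew, theta = Thnew, lambda = lam_new,
    lambda_rw_slots = rw_f,
    lq_forward = lq_lambda_f + lq_pos_f + lq_theta_f,
    lq_reverse = lq_lambda_r + lq_pos_r + lq_theta_r,
    lq_parts = c(lambda_f = lq_lambda_f, pos_f = lq_pos_f, theta_f = lq_theta_f,
                 lambda_r = lq_lambda_r, pos_r = lq_pos_r, theta_r = lq_theta_r)
  ), class = "shift_proposal")
}

# contribution of motif k to the log joint: emission adjustments, gap-prior
# terms, and the priors on its columns and rates (terms constant across a
# shift proposal, e.g. the background likelihood, are omitted)
.motif_log_joint_terms <- function(k, Th, lam, A, rows, data, lt0, hyper) {
  J <- ncol(Th)
  lth <- log(Th)
  out <- 0
  for (j in seq_len(J)) out <- out + .ldirichlet(Th[, j], rep(hyper$alpha, nrow(Th)))
  if (length(lam)) {
    out <- out + sum(stats::dgamma(lam, shape = hyper$beta, rate = hyper$nu, log = TRUE))
    lzs <- lapply(lam, .tp_lz, M = max(data$lengths[rows]))
  }
  for (i in rows) {
    x <- data$codes[[i]]
    a <- A[i, ]
    out <- out + sum(lth[cbind(x[a], seq_len(J))]) - sum(lt0[x[a]])
    if (J > 1L) {
      L <- data$lengths[i]
      for (j in 2:J) {
        d <- a[j] - a[j - 1L]
        dmax <- (L - J + j) - a[j - 1L]
        out <- out + d * log(lam[j - 1L]) - lfactorial(d) - lzs[[j - 1L]][dmax]
      }
    }
  }
  out
}

#' Accept or reject a shift proposal
#'
#' Computes the Metropolis-Hastings acceptance probability
#' `min(1, exp(delta log-joint + log reverse density - log forward density))`
#' and applies the proposal on acceptance.  Rejection (including infeasible
#' proposals) leaves the state untouched.
#'
#' @param proposal A `shift_proposal` from [propose_shift()].
#' @inheritParams propose_shift
#' @return List with `accepted` (logical), `state`, `positions` and
#'   `log_alpha` (the log acceptance ratio, `-Inf` when infeasible).
#' @export
accept_shift <- function(proposal, state, positions, labels, data,
                         hyper = hyperparameters()) {
  if (!proposal$feasible) {
    return(list(accepted = FALSE, state = state, positions = positions,
                log_alpha = -Inf))
  }
  k <- proposal$k
  rows <- proposal$rows
  lt0 <- log(state$theta0)
  lj_old <- .motif_log_joint_terms(k, state$thetas[[k]], state$lambdas[[k]],
                                   positions[[k]], rows, data, lt0, hyper)
  lj_new <- .motif_log_joint_terms(k, proposal$theta, proposal$lambda,
                                   proposal$positions, rows, data, lt0, hyper)
  log_alpha <- (lj_new - lj_old) + (proposal$lq_reverse - proposal$lq_forward)
  if (!is.finite(log_alpha)) {
    warning("non-finite shift acceptance ratio; proposal rejected")
    return(list(accepted = FALSE, state = state, positions = positions,
                log_alpha = log_alpha))
  }
  accepted <- log(stats::runif(1)) < log_alpha
  if (accepted) {
    state$thetas[[k]] <- proposal$theta
    state$lambdas[[k]] <- proposal$lambda
    positions[[k]] <- proposal$positions
  }
  list(accepted = accepted, state = state, positions = positions,
       log_alpha = log_alpha)
}
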