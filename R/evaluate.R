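# recovery metrics: normalized L1 error, label and position accuracy,
# KL divergence between motif matrices

#' Normalized L1 error
#'
#' Mean absolute difference between two probability arrays of identical
#' shape (the total absolute error divided by the number of elements).
#'
#' @param est,truth Numeric arrays of the same shape.
#' @return Scalar in `[0, 2]`.
#' @export
normalized_l1 <- function(est, truth) {
  if (!identical(dim(est), dim(truth)) || length(est) != length(truth)) {
    stop("estimate and truth must have the same shape", call. = FALSE)
  }
  mean(abs(est - truth))
}

#' Label prediction accuracy
#'
#' Fraction of exact label matches, either over all sequences or restricted
#' to the masked ones (the quantity of interest when known labels are held
#' fixed).
#'
#' @param pred,truth Integer label vectors of equal length.
#' @param scope `"masked_only"` or `"all"`.
#' @param known Logical known-mask (required for `"masked_only"`).
#' @return Proportion in `[0, 1]`.
#' @export
label_accuracy <- function(pred, truth, scope = c("masked_only", "all"),
                           known = NULL) {
  scope <- match.arg(scope)
  pred <- .label_vector(pred); truth <- .label_vector(truth)
  stopifnot(length(pred) == length(truth))
  idx <- seq_along(pred)
  if (scope == "masked_only") {
    if (is.null(known)) stop("known mask required for scope = 'masked_only'",
                             call. = FALSE)
    idx <- which(!known)
  }
  if (!length(idx)) stop("empty scope: no sequences to score", call. = FALSE)
  mean(pred[idx] == truth[idx])
}

#' Binding-position accuracy
#'
#' Fraction of (sequence, motif column) slots at which the predicted
#' binding position equals the true one, over the sequences whose true
#' label is a motif.  A sequence predicted as background (or as a different
#' motif) contributes all its `J_k` slots as misses.
#'
#' @param pred_positions,true_positions Lists of `K` position matrices.
#' @param pred_labels,true_labels Integer label vectors.
#' @return Proportion in `[0, 1]`.
#' @export
position_accuracy <- function(pred_positions, pred_labels,
                              true_positions, true_labels) {
  pred_labels <- .label_vector(pred_labels)
  true_labels <- .label_vector(true_labels)
  K <- length(true_positions)
  hits <- 0L; slots <- 0L
  for (k in seq_len(K)) {
    J <- ncol(true_positions[[k]])
    for (i in which(true_labels == k)) {
      slots <- slots + J
      if (!is.na(pred_labels[i]) && pred_labels[i] == k) {
        hits <- hits + sum(pred_positions[[k]][i, ] == true_positions[[k]][i, ])
      }
    }
  }
  if (slots == 0L) stop("no motif-labeled sequences in the truth", call. = FALSE)
  hits / slots
}

# KL divergence between two categorical distributions, natural log
.kl_cat <- function(p, q) sum(p * (log(p) - log(q)))

#' KL divergence between motif matrices
#'
#' Column-wise Kullback-Leibler divergence `KL(true_j || est_j)` in nats,
#' combined across columns by sum (default) or mean.  With
#' `alignment = "best_offset"` the estimate may be slid against the truth
#' and the divergence is taken over the overlapping columns at the best
#' offset (an evaluation aid for diagnosing offset modes; the default
#' compares columns at a fixed, identical indexing).
#'
#' @param true,est `p x J` column-stochastic matrices.
#' @param mode `"sum"` or `"mean"` over columns.
#' @param alignment `"fixed"` or `"best_offset"`.
#' @param max_offset Largest |offset| tried under `"best_offset"`.
#' @return Nonnegative divergence in nats.
#' @export
motif_kl <- function(true, est, mode = c("sum", "mean"),
                     alignment = c("fixed", "best_offset"), max_offset = 2L) {
  mode <- match.arg(mode)
  alignment <- match.arg(alignment)
  true <- as.matrix(true); est <- as.matrix(est)
  if (nrow(true) != nrow(est)) stop("matrices differ in alphabet size", call. = FALSE)
  comb <- function(v) if (mode == "sum") sum(v) else mean(v)
  if (alignment == "fixed") {
    if (ncol(true) != ncol(est)) stop("matrices differ in motif length", call. = FALSE)
    return(comb(vapply(seq_len(ncol(true)),
                       function(j) .kl_cat(true[, j], est[, j]), 0)))
  }
  J <- min(ncol(true), ncol(est))
  best <- Inf
  for (off in -max_offset:max_offset) {
    jt <- seq_len(ncol(true)); je <- jt + off
    keep <- je >= 1L & je <= ncol(est)
    if (!any(keep)) next
    v <- vapply(which(keep), function(j) .kl_cat(true[, j], est[, j + off]), 0)
    best <- min(best, comb(v))
  }
  best
}

#' Full metric report for a fitted model against ground truth
#'
#' @param map A [map_estimates()] result.
#' @param truth The `truth` element of a [simulate_dataset()] result.
#' @param known Logical known-mask of the labels used for fitting.
#' @param kl_mode Passed to [motif_kl()].
#' @return List of class `metric_report` with per-motif L1 errors and KL
#'   divergences, background L1 error, and label/position accuracies.
#' @export
metric_report <- function(map, truth, known, kl_mode = "sum") {
  K <- truth$state$K
  l1_theta <- vapply(seq_len(K), function(k)
    normalized_l1(map$state$thetas[[k]], truth$state$thetas[[k]]), 0)
  kl <- vapply(seq_len(K), function(k)
    motif_kl(truth$state$thetas[[k]], map$state$thetas[[k]], mode = kl_mode), 0)
  structure(list(
    l1_theta0 = normalized_l1(map$state$theta0, truth$state$theta0),
    l1_theta = l1_theta,
    kl = kl,
    acc_labels_masked = label_accuracy(map$labels, truth$labels,
                                       "masked_only", known = known),
    acc_labels_all = label_accuracy(map$labels, truth$labels, "all"),
    acc_positions = position_accuracy(map$positions, map$labels,
                                      truth$positions, truth$labels)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> KL: %s | L1(theta0) %.4f | L1(theta): %s | acc W (masked) %.3f | acc A %.3f\n",
              paste(sprintf("%.3f", x$kl), collapse = ", "),
              x$l1_theta0,
              paste(sprintf("%.4f", x$l1_theta), collapse = ", "),
              x$acc_labels_masked, x$acc_positions))
  invisible(x)
}
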