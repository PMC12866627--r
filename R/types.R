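#' Sequence dataset
#'
#' Bundle a collection of sequences over a common alphabet.  Sequences are
#' stored both as (uppercased) strings and as integer code vectors; lengths
#' may differ between sequences.
#'
#' @param sequences Character vector of sequences.
#' @param ids Optional identifiers; defaults to the names of `sequences` or
#'   `seq001`, `seq002`, ...
#' @param alphabet A [motif_alphabet()].
#' @return An object of class `sequence_dataset` with fields `ids`,
#'   `sequences`, `codes` (list of integer vectors), `lengths`, `alphabet`
#'   and `n`.
#' @export
sequence_dataset <- function(sequences, ids = NULL,
                             alphabet = motif_alphabet("protein")) {
  sequences <- as.character(sequences)
  n <- length(sequences)
  if (n < 1L) stop("a dataset needs at least one sequence", call. = FALSE)
  if (is.null(ids)) {
    ids <- if (!is.null(names(sequences))) names(sequences)
           else sprintf("seq%03d", seq_len(n))
  }
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids and sequences differ in length", call. = FALSE)
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  codes <- vector("list", n)
  for (i in seq_len(n)) {
    codes[[i]] <- tryCatch(
      encode_sequence(sequences[i], alphabet),
      error = function(e) stop(sprintf("sequence '%s': %s", ids[i],
                                       conditionMessage(e)), call. = FALSE))
  }
  structure(list(ids = ids, sequences = toupper(sequences), codes = codes,
                 lengths = lengths(codes), alphabet = alphabet, n = n),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("<sequence_dataset> n = %d sequences over %s alphabet (p = %d), lengths %d..%d\n",
              x$n, x$alphabet$type, x$alphabet$p, min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Per-sequence motif labels with a known/masked partition
#'
#' Label `k` in `1..K` means sequence `i` carries an instance of motif `k`;
#' label `K + 1` means pure background.  `NA` marks a masked label: its true
#' value is unobserved and the sampler imputes it.  Labels flagged as known
#' are never altered by inference.
#'
#' @param labels Integer vector in `1..K+1`, `NA` for masked entries.
#' @param K Number of motifs (>= 1).
#' @param known Logical vector; defaults to `!is.na(labels)`.
#' @return An object of class `label_state` with fields `labels`, `K`, `known`.
#' @export
label_state <- function(labels, K, known = !is.na(labels)) {
  labels <- as.integer(labels)
  K <- as.integer(K)
  known <- as.logical(known)
  if (K < 1L) stop("K must be at least 1", call. = FALSE)
  if (length(known) != length(labels)) {
    stop("known mask and labels differ in length", call. = FALSE)
  }
  if (any(known & is.na(labels))) {
    stop("a known label cannot be missing", call. = FALSE)
  }
  obs <- labels[!is.na(labels)]
  if (length(obs) && (any(obs < 1L) || any(obs > K + 1L))) {
    stop(sprintf("labels must lie in 1..%d (background = %d)", K + 1L, K + 1L),
         call. = FALSE)
  }
  structure(list(labels = labels, K = K, known = known), class = "label_state")
}

.label_vector <- function(labels) {
  if (inherits(labels, "label_state")) labels$labels else as.integer(labels)
}

#' Motif model parameters
#'
#' The continuous parameters of the generative model: a shared background
#' distribution `theta0` over the alphabet, one column-stochastic composition
#' matrix per motif (`p` rows, `J_k` columns; column `j` is the categorical
#' emission distribution of the `j`-th binding position) and one positive gap
#' rate per internal gap slot (`J_k - 1` rates per motif; the expected spacing
#' between consecutive binding positions before truncation).
#'
#' @param theta0 Probability vector of length `p`.
#' @param thetas List of `K` matrices, each `p x J_k` with columns summing to 1.
#' @param lambdas List of `K` positive-rate vectors of length `J_k - 1`
#'   (`numeric(0)` when `J_k = 1`).
#' @return An object of class `motif_state`.
#' @export
motif_state <- function(theta0, thetas, lambdas) {
  theta0 <- as.numeric(theta0)
  thetas <- lapply(thetas, as.matrix)
  lambdas <- lapply(lambdas, as.numeric)
  K <- length(thetas)
  if (length(lambdas) != K) stop("thetas and lambdas differ in length", call. = FALSE)
  p <- length(theta0)
  if (any(theta0 <= 0) || abs(sum(theta0) - 1) > 1e-8) {
    stop("theta0 must be strictly positive and sum to 1", call. = FALSE)
  }
  motif_lengths <- integer(K)
  for (k in seq_len(K)) {
    Th <- thetas[[k]]
    if (nrow(Th) != p) stop("all motif matrices must have p rows", call. = FALSE)
    if (any(Th <= 0) || any(abs(colSums(Th) - 1) > 1e-8)) {
      stop(sprintf("columns of motif %d must be strictly positive and sum to 1", k),
           call. = FALSE)
    }
    motif_lengths[k] <- ncol(Th)
    if (length(lambdas[[k]]) != motif_lengths[k] - 1L) {
      stop(sprintf("motif %d needs %d gap rates", k, motif_lengths[k] - 1L),
           call. = FALSE)
    }
    if (length(lambdas[[k]]) && any(lambdas[[k]] <= 0)) {
      stop("gap rates must be strictly positive", call. = FALSE)
    }
  }
  structure(list(theta0 = theta0, thetas = thetas, lambdas = lambdas,
                 K = K, p = p, motif_lengths = motif_lengths),
            class = "motif_state")
}

#' @export
print.motif_state <- function(x, ...) {
  cat(sprintf("<motif_state> K = %d motif(s) over p = %d letters; lengths: %s\n",
              x$K, x$p, paste(x$motif_lengths, collapse = ", ")))
  invisible(x)
}

#' Prior hyperparameters
#'
#' Defaults are the noninformative choices used throughout: flat Dirichlet(1)
#' on the background and on every motif column, Gamma(shape = 1, rate = 1)
#' (i.e. Exponential(1)) on each gap rate, and a uniform prior over the
#' `K + 1` labels.
#'
#' @param alpha0 Dirichlet concentration for the background `theta0`.
#' @param alpha Dirichlet concentration for motif columns.
#' @param beta,nu Gamma shape and rate for each gap rate lambda.
#' @param label_prior Optional probability vector over the `K + 1` labels;
#'   `NULL` means uniform.
#' @return An object of class `gapmotif_hyper`.
#' @export
hyperparameters <- function(alpha0 = 1, alpha = 1, beta = 1, nu = 1,
                            label_prior = NULL) {
  stopifnot(alpha0 > 0, alpha > 0, beta > 0, nu > 0)
  if (!is.null(label_prior)) {
    label_prior <- as.numeric(label_prior)
    if (any(label_prior < 0) || abs(sum(label_prior) - 1) > 1e-8) {
      stop("label_prior must be a probability vector", call. = FALSE)
    }
  }
  structure(list(alpha0 = alpha0, alpha = alpha, beta = beta, nu = nu,
                 label_prior = label_prior),
            class = "gapmotif_hyper")
}

.label_prior_vec <- function(hyper, K) {
  if (is.null(hyper$label_prior)) return(rep(1 / (K + 1), K + 1))
  if (length(hyper$label_prior) != K + 1) {
    stop(sprintf("label_prior must have length K + 1 = %d", K + 1), call. = FALSE)
  }
  hyper$label_prior
}

#' Validate a binding-position vector
#'
#' A valid row for a motif of length `J` in a sequence of length `L` is a
#' strictly increasing integer vector `a` with `a[1] >= 1` and
#' `a[j] <= L - J + j` for every `j` (so the remaining motif positions always
#' fit to the right).
#'
#' @param a Integer vector of length `J`.
#' @param L Sequence length.
#' @param J Motif length.
#' @return `a` (as integer), invisibly checked.
#' @export
validate_position_row <- function(a, L, J) {
  a <- as.integer(a)
  if (length(a) != J) {
    stop(sprintf("position vector has length %d, expected %d", length(a), J),
         call. = FALSE)
  }
  if (anyNA(a)) stop("position vector contains NA", call. = FALSE)
  if (a[1L] < 1L) stop("first binding position must be >= 1", call. = FALSE)
  if (J > 1L && any(diff(a) < 1L)) {
    stop("binding positions must be strictly increasing", call. = FALSE)
  }
  if (any(a > L - J + seq_len(J))) {
    stop(sprintf("position vector violates the upper bound L - J + j (L = %d, J = %d)",
                 L, J), call. = FALSE)
  }
  a
}

# empty position container: one n x J_k integer matrix per motif, rows NA
# unless the sequence currently carries that motif
empty_positions <- function(n, motif_lengths) {
  lapply(motif_lengths, function(J) {
    matrix(NA_integer_, nrow = n, ncol = J)
  })
}
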