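# seeded synthetic-data generator: sequences with (optionally) embedded
# gapped motifs and partially masked labels, with full ground truth retained

#' Simulation configuration
#'
#' Defaults reproduce the single-motif benchmark conditions used throughout
#' the package: 200 protein sequences of length 10, one motif of length 5
#' whose columns are drawn from a sharply peaked Dirichlet (`eta = 0.1`),
#' labels from `Cat(0.8, 0.2)` (motif vs background), per-slot Poisson gap
#' rates drawn uniformly from `S = {0.5, 1, 1.5}`, and 20% of labels masked.
#'
#' @param n Number of sequences.
#' @param L Sequence length (constant across sequences).
#' @param alphabet A [motif_alphabet()].
#' @param motif_lengths Integer vector of `K` motif lengths.
#' @param eta Dirichlet concentration for motif columns; smaller values give
#'   sharper (more conserved) motifs.
#' @param rates Finite set `S` of candidate Poisson gap rates; each gap slot
#'   draws its rate uniformly from `S`.
#' @param label_probs Probability vector over the `K + 1` labels
#'   (motifs 1..K, then background).
#' @param mask_fraction Fraction of labels masked (set to `NA`) after
#'   generation.
#' @param seed Optional RNG seed.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n = 200L, L = 10L,
                              alphabet = motif_alphabet("protein"),
                              motif_lengths = 5L, eta = 0.1,
                              rates = c(0.5, 1, 1.5),
                              label_probs = NULL, mask_fraction = 0.2,
                              seed = NULL) {
  motif_lengths <- as.integer(motif_lengths)
  K <- length(motif_lengths)
  if (is.null(label_probs)) {
    label_probs <- if (K == 1L) c(0.8, 0.2) else rep(1 / (K + 1), K + 1)
  }
  stopifnot(n >= 1L, all(motif_lengths >= 1L), L >= max(motif_lengths),
            eta > 0, length(rates) >= 1L, all(rates > 0),
            length(label_probs) == K + 1L, abs(sum(label_probs) - 1) < 1e-8,
            mask_fraction >= 0, mask_fraction <= 1)
  structure(list(n = as.integer(n), L = as.integer(L), alphabet = alphabet,
                 motif_lengths = motif_lengths, K = K, eta = eta,
                 rates = as.numeric(rates), label_probs = as.numeric(label_probs),
                 mask_fraction = mask_fraction, seed = seed),
            class = "sim_config")
}

#' Benchmark simulation presets
#'
#' Four standard single-motif settings varying motif length, motif
#' conservation and gap-rate magnitude:
#' `1` = (J = 5, eta = 0.1, S = \{0.5, 1, 1.5\}),
#' `2` = (J = 5, eta = 0.2, S = \{0.5, 1, 1.5\}),
#' `3` = (J = 4, eta = 0.1, S = \{0.5, 1, 1.5\}),
#' `4` = (J = 5, eta = 0.1, S = \{1.5, 2, 2.5\}).
#'
#' @param id Preset number, 1 to 4.
#' @param seed Optional RNG seed stored in the config.
#' @return A [simulation_config()].
#' @export
simulation_preset <- function(id, seed = NULL) {
  id <- as.integer(id)
  stopifnot(id %in% 1:4)
  J <- c(5L, 5L, 4L, 5L)[id]
  eta <- c(0.1, 0.2, 0.1, 0.1)[id]
  rates <- if (id == 4L) c(1.5, 2, 2.5) else c(0.5, 1, 1.5)
  simulation_config(motif_lengths = J, eta = eta, rates = rates, seed = seed)
}

#' Generate a synthetic dataset with known ground truth
#'
#' The generative protocol: the background `theta0` is drawn from a flat
#' Dirichlet(1); each motif column from Dirichlet(`eta`); each gap rate
#' uniformly from the candidate set; each label from `label_probs`.  For a
#' motif-labeled sequence the first binding position is uniform over its
#' admissible range and each subsequent position adds a truncated-Poisson
#' gap over the feasible range (a gap that would overflow is drawn from the
#' renormalized feasible support, never resampled or clipped).  Letters at
#' binding positions come from the motif columns, all others from the
#' background.  Finally [mask_labels()] hides the requested fraction.
#'
#' @param config A [simulation_config()].
#' @return List of class `gapmotif_sim` with `data` (a [sequence_dataset()]),
#'   `labels` (a [label_state()] with masked entries), and `truth` (list with
#'   the true `state`, `labels` and `positions`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$alphabet$p
  K <- config$K
  n <- config$n
  L <- config$L
  theta0 <- .rdirichlet1(rep(1, p))
  thetas <- lapply(config$motif_lengths, function(J) {
    vapply(seq_len(J), function(j) .rdirichlet1(rep(config$eta, p)), numeric(p))
  })
  lambdas <- lapply(config$motif_lengths, function(J) {
    if (J > 1L) sample(config$rates, J - 1L, replace = TRUE) else numeric(0)
  })
  state <- motif_state(theta0, thetas, lambdas)

  w <- sample.int(K + 1L, n, replace = TRUE, prob = config$label_probs)
  A <- empty_positions(n, config$motif_lengths)
  seqs <- character(n)
  for (i in seq_len(n)) {
    x <- sample.int(p, L, replace = TRUE, prob = theta0)
    if (w[i] <= K) {
      k <- w[i]
      J <- config$motif_lengths[k]
      a <- .prior_positions_draw(L, J, lambdas[[k]])
      A[[k]][i, ] <- a
      for (j in seq_len(J)) {
        x[a[j]] <- sample.int(p, 1L, prob = thetas[[k]][, j])
      }
    }
    seqs[i] <- decode_sequence(x, config$alphabet)
  }
  data <- sequence_dataset(seqs, sprintf("sim%04d", seq_len(n)), config$alphabet)
  labels <- mask_labels(w, config$mask_fraction, K)
  structure(list(data = data, labels = labels,
                 truth = list(state = state, labels = w, positions = A),
                 config = config),
            class = "gapmotif_sim")
}

#' Mask a fraction of labels
#'
#' Exactly `round(fraction * n)` labels, chosen uniformly without
#' replacement, are set to `NA` with `known = FALSE`; the rest stay known.
#'
#' @param labels Complete integer label vector in `1..K+1`.
#' @param fraction Fraction to mask, in `[0, 1]`.
#' @param K Number of motifs.
#' @return A [label_state()].
#' @export
mask_labels <- function(labels, fraction, K) {
  labels <- as.integer(labels)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- length(labels)
  n_mask <- round(fraction * n)
  masked <- if (n_mask > 0) sample.int(n, n_mask) else integer(0)
  out <- labels
  out[masked] <- NA_integer_
  label_state(out, K)
}

#' Write a simulated dataset to disk
#'
#' Writes the sequences as FASTA, the (masked) labels and the ground-truth
#' labels/positions as TSV, and the ground-truth parameters as JSON.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "gapmotif_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    labels = file.path(dir, "labels.tsv"),
    true_labels = file.path(dir, "truth_labels.tsv"),
    true_positions = file.path(dir, "truth_positions.tsv"),
    truth = file.path(dir, "truth_params.json"))
  write_fasta(sim$data, paths["fasta"])
  write_labels_tsv(sim$labels, sim$data$ids, paths["labels"])
  write_labels_tsv(label_state(sim$truth$labels, sim$labels$K),
                   sim$data$ids, paths["true_labels"])
  write_positions_tsv(sim$truth$positions, sim$data$ids, paths["true_positions"])
  truth <- list(
    theta0 = sim$truth$state$theta0,
    thetas = lapply(sim$truth$state$thetas, function(m) unclass(m)),
    lambdas = sim$truth$state$lambdas,
    motif_lengths = sim$config$motif_lengths,
    alphabet = sim$data$alphabet$letters)
  jsonlite::write_json(truth, paths["truth"], digits = NA, pretty = TRUE)
  invisible(paths)
}
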