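# readers and writers for the on-disk formats: FASTA sequences, TSV labels
# and positions, CSV trace summaries

#' Read sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased and validated against the alphabet (an illegal
#' symbol is an error naming the record).
#'
#' @param path FASTA file.
#' @param alphabet A [motif_alphabet()].
#' @return A [sequence_dataset()].
#' @export
read_fasta <- function(path, alphabet = motif_alphabet("protein")) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  sequence_dataset(as.character(set), ids, alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param data A [sequence_dataset()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", data$ids, "\n", data$sequences), con)
  invisible(path)
}

#' Read per-sequence labels from TSV
#'
#' The file must have columns `id` and `label`; labels are integers in
#' `1..K+1` or the literal `NA` for masked entries.  Rows are aligned to
#' `ids`; unknown, missing or duplicated ids and out-of-range labels are
#' errors naming the offender.
#'
#' @param path TSV file with columns `id`, `label`.
#' @param ids Sequence ids of the dataset the labels belong to.
#' @param K Number of motifs.
#' @return A [label_state()].
#' @export
read_labels_tsv <- function(path, ids, K) {
  df <- utils::read.delim(path, colClasses = c("character", "integer"))
  if (!all(c("id", "label") %in% names(df))) {
    stop("label file must have columns 'id' and 'label'", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop(sprintf("duplicate id '%s' in label file", df$id[duplicated(df$id)][1L]),
         call. = FALSE)
  }
  unknown <- setdiff(df$id, ids)
  if (length(unknown)) {
    stop(sprintf("label file row for unknown id '%s'", unknown[1L]), call. = FALSE)
  }
  m <- match(ids, df$id)
  if (anyNA(m)) {
    stop(sprintf("no label row for id '%s'", ids[which(is.na(m))[1L]]),
         call. = FALSE)
  }
  lab <- df$label[m]
  bad <- which(!is.na(lab) & (lab < 1L | lab > K + 1L))
  if (length(bad)) {
    stop(sprintf("label %d for id '%s' outside 1..%d", lab[bad[1L]],
                 ids[bad[1L]], K + 1L), call. = FALSE)
  }
  label_state(lab, K)
}

#' Write per-sequence labels to TSV
#'
#' @param labels A [label_state()] (masked entries are written as `NA`).
#' @param ids Sequence ids.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_labels_tsv <- function(labels, ids, path) {
  df <- data.frame(id = ids, label = .label_vector(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write binding positions as TSV
#'
#' Long format with columns `id`, `motif`, `j`, `position` (1-based,
#' inclusive); one row per fitted (sequence, motif column) slot.
#'
#' @param positions List of `K` position matrices (`n x J_k`).
#' @param ids Sequence ids.
#' @param path File path.
#' @return `write_positions_tsv` returns `path` invisibly.
#' @export
write_positions_tsv <- function(positions, ids, path) {
  rows <- list()
  for (k in seq_along(positions)) {
    A <- positions[[k]]
    for (i in seq_len(nrow(A))) {
      if (anyNA(A[i, ])) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[i], motif = k, j = seq_len(ncol(A)), position = A[i, ])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = character(), motif = integer(), j = integer(),
               position = integer())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions_tsv
#' @param motif_lengths Integer vector of motif lengths `J_k`.
#' @return `read_positions_tsv` returns a list of `K` position matrices.
#' @export
read_positions_tsv <- function(path, ids, motif_lengths) {
  df <- utils::read.delim(path)
  A <- empty_positions(length(ids), motif_lengths)
  if (nrow(df)) {
    i <- match(df$id, ids)
    if (anyNA(i)) {
      stop(sprintf("positions file row for unknown id '%s'",
                   df$id[which(is.na(i))[1L]]), call. = FALSE)
    }
    for (r in seq_len(nrow(df))) {
      A[[df$motif[r]]][i[r], df$j[r]] <- df$position[r]
    }
  }
  A
}

#' Write a trace summary to CSV
#'
#' Columns, in order: `iteration`, `loglik`, then per motif `k` the pair
#' `shift_attempt_k`, `shift_accept_k` (0/1 flags).  Optionally writes
#' thinned parameter snapshots to `<path base>_snapshots.tsv` in long
#' format (`iteration`, `parameter`, `motif`, `row`, `col`, `value`).
#'
#' @param trace An [run_mcmc()] trace.
#' @param path Output CSV file.
#' @param snapshots Thinning interval for parameter snapshots (0 = none).
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path, snapshots = 0L) {
  df <- data.frame(iteration = seq_len(trace$n_iter), loglik = trace$loglik)
  for (k in seq_len(trace$K)) {
    df[[sprintf("shift_attempt_%d", k)]] <- as.integer(trace$shift_attempt[k, ])
    df[[sprintf("shift_accept_%d", k)]] <- as.integer(trace$shift_accept[k, ])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (snapshots > 0L) {
    its <- seq.int(snapshots, trace$n_iter, by = snapshots)
    rows <- list()
    for (it in its) {
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = it, parameter = "theta0", motif = 0L,
        row = seq_len(trace$p), col = 1L, value = trace$theta0[, it])
      for (k in seq_len(trace$K)) {
        Th <- trace$thetas[[k]][, , it]
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = it, parameter = "theta", motif = k,
          row = rep(seq_len(nrow(Th)), ncol(Th)),
          col = rep(seq_len(ncol(Th)), each = nrow(Th)), value = as.vector(Th))
        if (trace$motif_lengths[k] > 1L) {
          lam <- trace$lambdas[[k]][, it]
          rows[[length(rows) + 1L]] <- data.frame(
            iteration = it, parameter = "lambda", motif = k,
            row = seq_along(lam), col = 1L, value = lam)
        }
      }
    }
    snap_path <- paste0(sub("\\.csv$", "", path), "_snapshots.tsv")
    utils::write.table(do.call(rbind, rows), snap_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
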