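#' Sequence alphabets
#'
#' A `motif_alphabet` is the ordered set of `p` distinct single-character
#' symbols over which all sequences, motif columns and the background
#' distribution are defined.  Two standard alphabets are built in: `"dna"`
#' (A, C, G, T; p = 4) and `"protein"` (the 20 standard amino acids in
#' alphabetical one-letter order, p = 20).
#'
#' @param type `"protein"` or `"dna"`; ignored when `letters` is given.
#' @param letters Optional character vector of distinct single-character
#'   symbols defining a custom alphabet.
#' @return An object of class `motif_alphabet` with fields `letters`, `p`
#'   and `type`.
#' @examples
#' motif_alphabet("dna")
#' motif_alphabet(letters = c("H", "P"))  # hydrophobic/polar toy alphabet
#' @export
motif_alphabet <- function(type = c("protein", "dna"), letters = NULL) {
  if (is.null(letters)) {
    type <- match.arg(type)
    letters <- switch(type,
      dna     = c("A", "C", "G", "T"),
      protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    )
  } else {
    type <- "custom"
    letters <- as.character(letters)
  }
  if (any(nchar(letters) != 1L)) {
    stop("alphabet letters must be single characters", call. = FALSE)
  }
  if (anyDuplicated(letters)) {
    stop("alphabet letters must be unique", call. = FALSE)
  }
  if (length(letters) < 2L) {
    stop("an alphabet needs at least two letters", call. = FALSE)
  }
  structure(list(letters = letters, p = length(letters), type = type),
            class = "motif_alphabet")
}

#' @export
print.motif_alphabet <- function(x, ...) {
  cat(sprintf("<motif_alphabet> %s (p = %d): %s\n",
              x$type, x$p, paste(x$letters, collapse = "")))
  invisible(x)
}

#' Encode a sequence string as integer letter indices
#'
#' Letters are uppercased and mapped to their 1-based index in the alphabet.
#' An unknown symbol is an error naming the symbol and its offset.
#'
#' @param x A single character string.
#' @param alphabet A [motif_alphabet()].
#' @return Integer vector of codes in `1..p`.
#' @export
encode_sequence <- function(x, alphabet) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet$letters)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unknown symbol '%s' at offset %d", chars[bad], bad),
         call. = FALSE)
  }
  idx
}

#' @rdname encode_sequence
#' @param codes Integer vector of letter codes.
#' @export
decode_sequence <- function(codes, alphabet) {
  paste(alphabet$letters[codes], collapse = "")
}

#' Letter count vector of a sequence segment
#'
#' Maps a sequence (or subsequence) to its count vector over the alphabet:
#' entry `l` is the number of occurrences of the `l`-th letter.  This is the
#' sufficient statistic for both the background distribution and each motif
#' column.
#'
#' @param segment A character string or an integer vector of letter codes.
#' @param alphabet A [motif_alphabet()].
#' @return Integer vector of length `p`; entries sum to the segment length.
#' @examples
#' count_vector("GATTACA", motif_alphabet("dna"))
#' @export
count_vector <- function(segment, alphabet) {
  if (is.character(segment)) segment <- encode_sequence(segment, alphabet)
  segment <- as.integer(segment)
  if (length(segment) && (any(segment < 1L) || any(segment > alphabet$p))) {
    stop("letter codes out of range for this alphabet", call. = FALSE)
  }
  tabulate(segment, nbins = alphabet$p)
}
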