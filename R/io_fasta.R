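#' Read an aligned FASTA file
#'
#' Reads a FASTA file that is expected to hold a sequence alignment: all
#' records must have equal length (this function does not align). Sequences
#' are uppercased and `U` is normalised to `T`.
#'
#' @param path FASTA file path.
#' @return a `sequence_alignment`: list with `seqs` (named character vector)
#'   and `length` (alignment length in sites, 1-based columns in reports).
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  sequence_alignment(seqs)
}

#' Construct a sequence alignment from named character sequences
#'
#' @param seqs named character vector over the alphabet `{A,C,G,T,N,-}`
#'   (others are tolerated and treated as ambiguous).
#' @return a `sequence_alignment` object.
#' @export
sequence_alignment <- function(seqs) {
  nm <- names(seqs)
  seqs <- toupper(as.character(seqs)) # toupper drops names; restore below
  names(seqs) <- nm
  if (length(seqs)) {
    L <- unique(nchar(seqs))
    if (length(L) != 1) {
      stop(sprintf("alignment error: unequal sequence lengths (%s)",
                   paste(sort(L), collapse = ", ")))
    }
  } else L <- 0L
  if (is.null(names(seqs)) && length(seqs)) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  structure(list(seqs = seqs, length = as.integer(L)),
            class = "sequence_alignment")
}

#' @export
print.sequence_alignment <- function(x, ...) {
  cat(sprintf("sequence_alignment: %d sequences x %d sites\n",
              length(x$seqs), x$length))
  invisible(x)
}

#' Write an alignment to FASTA
#' @param aln a `sequence_alignment`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "sequence_alignment"))
  ss <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# alignment as a character matrix (rows = sequences, cols = sites)
alignment_matrix <- function(aln) {
  if (!length(aln$seqs)) return(matrix(character(), 0, 0))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- names(aln$seqs)
  m
}
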