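#' Read sequences or an alignment from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a named
#' character vector (one string per record), the representation used
#' throughout this package.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector; gaps written as `-`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# validate an alignment: named, equal lengths, >= 1 sequence
check_alignment <- function(aln) {
  if (!is.character(aln) || is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment must be a named character vector with unique names")
  if (length(unique(nchar(aln))) > 1L)
    stop("aligned sequences must all have the same length")
  aln
}

# resample alignment columns with replacement (bootstrap pseudo-replicate)
resample_columns <- function(aln, idx) {
  m <- seq_chars(check_alignment(aln))
  chars_to_seq(m[, idx, drop = FALSE])
}
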