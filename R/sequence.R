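#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases the input and rewrites T to U so that genome (DNA) and miRNA
#' (RNA) inputs share one alphabet. `N` is preserved; any other character is
#' an error.
#'
#' @param seq Character vector of nucleotide strings over
#'   `{A,C,G,T,U,N}` in either case.
#' @return Character vector of the same length over `{A,C,G,U,N}`.
#' @examples
#' normalize_to_rna("acgt")  # "ACGU"
#' @export
normalize_to_rna <- function(seq) {
  stopifnot(is.character(seq))
  out <- chartr("acgtun", "ACGUUN", seq)
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGUN]", "", out[bad]), "")))
    stop("invalid nucleotide character(s): ", paste(chars, collapse = ", "))
  }
  out
}

#' Reverse complement of an RNA string
#'
#' @param seq Character vector over `{A,C,G,U,N}`.
#' @return Reverse-complemented strings (A<->U, C<->G, N->N).
#' @export
rna_revcomp <- function(seq) {
  comp <- chartr("ACGUN", "UGCAN", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' Read a FASTA file as normalized RNA strings
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning a named
#' character vector in the package's RNA alphabet. Gzip input is accepted.
#'
#' @param path FASTA file path.
#' @return Named character vector of RNA sequences.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(names(seqs)))) stop("FASTA record without identifier in ", path)
  normalize_to_rna(seqs)
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
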