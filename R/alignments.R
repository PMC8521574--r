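# FASTA input/output and alignment-matrix helpers. Sequence IO goes through
# Biostrings; alignments are plain character matrices (rows = taxa).

#' Read and write aligned protein FASTA
#'
#' `read_protein_alignment()` reads an aligned FASTA file into a character
#' matrix (rows named by sequence, all rows equal length); `write_fasta()`
#' writes named sequences (protein or DNA strings) to FASTA.
#'
#' @param path File path.
#' @return For `read_protein_alignment()`, a character matrix.
#' @export
read_protein_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(ss))) != 1L) {
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  }
  m <- as.matrix(ss)
  rownames(m) <- names(ss)
  m
}

#' @rdname read_protein_alignment
#' @param sequences Named character vector of sequences.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(sequences, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  ss <- switch(type,
               AA = Biostrings::AAStringSet(sequences),
               DNA = Biostrings::DNAStringSet(sequences))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read unaligned sequences from FASTA
#'
#' @param path File path.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  ss <- switch(type,
               AA = Biostrings::readAAStringSet(path),
               DNA = Biostrings::readDNAStringSet(path))
  setNames(as.character(ss), names(ss))
}

# collapse an alignment matrix back to sequence strings
alignment_to_strings <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}
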