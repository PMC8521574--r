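# Genetic-code tables for the 61 sense codons of the standard code.
# Codons are ordered lexicographically over T, C, A, G (the conventional
# codon-table ordering); stops (TAA, TAG, TGA) are dropped, leaving 61
# states indexed 1..61 throughout the package.

.NUC <- c("T", "C", "A", "G")

#' Sense codons of the standard genetic code
#'
#' The 61 sense codons in T/C/A/G lexicographic order. This ordering defines
#' the state space of every codon matrix in the package: codon alignments are
#' integer matrices whose entries index into this vector (`NA` = gap/missing).
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' head(sense_codons())
sense_codons <- function() {
  .codon_tables()$codons
}

#' Amino acid encoded by each sense codon
#'
#' @return Named character vector of length 61 (names are codons, values
#'   one-letter amino acid codes), parallel to [sense_codons()].
#' @export
sense_codon_aa <- function() {
  .codon_tables()$aa
}

.codon_tables <- function() {
  if (is.null(.evosig_cache$codon_tables)) {
    all64 <- as.vector(t(outer(
      as.vector(t(outer(.NUC, .NUC, paste0))), .NUC, paste0
    )))
    gc <- Biostrings::GENETIC_CODE
    aa64 <- gc[all64]
    keep <- aa64 != "*"
    codons <- all64[keep]
    aa <- aa64[keep]
    names(aa) <- codons
    .evosig_cache$codon_tables <- list(codons = codons, aa = aa)
  }
  .evosig_cache$codon_tables
}

# Single-nucleotide-difference template over the 61 sense codons: index pairs
# (i, j), whether the change is a transition, and whether it is nonsynonymous.
# Computed once and cached; this is the sparsity structure of every GY94 rate
# matrix and of the simulator's event sampler.
.codon_template <- function() {
  if (is.null(.evosig_cache$codon_template)) {
    tab <- .codon_tables()
    codons <- tab$codons
    aa <- tab$aa
    n <- length(codons)
    split3 <- do.call(rbind, strsplit(codons, ""))
    ii <- integer(0); jj <- integer(0); ts <- logical(0); ns <- logical(0)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        diff <- split3[i, ] != split3[j, ]
        if (sum(diff) != 1L) next
        pos <- which(diff)
        pair <- sort(c(split3[i, pos], split3[j, pos]))
        ii <- c(ii, i); jj <- c(jj, j)
        ts <- c(ts, identical(pair, c("A", "G")) || identical(pair, c("C", "T")))
        ns <- c(ns, aa[i] != aa[j])
      }
    }
    .evosig_cache$codon_template <- list(ii = ii, jj = jj, ts = ts, ns = ns)
  }
  .evosig_cache$codon_template
}

#' Codon equilibrium frequency vectors
#'
#' `codon_freq_uniform()` returns the uniform distribution over the 61 sense
#' codons. `codon_freq_f3x4()` builds F3x4 frequencies from a 3 x 4 matrix of
#' position-specific nucleotide frequencies (rows = codon positions, columns
#' = T, C, A, G): the product frequency per codon, with stop codons removed
#' and the vector renormalised.
#'
#' @param nuc_freq Numeric 3 x 4 matrix; rows must each sum to 1.
#' @return Numeric vector of length 61 summing to 1, named by codon.
#' @export
codon_freq_uniform <- function() {
  codons <- sense_codons()
  setNames(rep(1 / length(codons), length(codons)), codons)
}

#' @rdname codon_freq_uniform
#' @export
codon_freq_f3x4 <- function(nuc_freq) {
  stopifnot(is.matrix(nuc_freq), nrow(nuc_freq) == 3L, ncol(nuc_freq) == 4L)
  if (any(abs(rowSums(nuc_freq) - 1) > 1e-8)) {
    stop("each row of 'nuc_freq' must sum to 1")
  }
  colnames(nuc_freq) <- .NUC
  codons <- sense_codons()
  split3 <- do.call(rbind, strsplit(codons, ""))
  p <- nuc_freq[1, split3[, 1]] * nuc_freq[2, split3[, 2]] * nuc_freq[3, split3[, 3]]
  setNames(p / sum(p), codons)
}

# Empirical F3x4 frequencies from a codon alignment (integer matrix over
# 1..61, NA = gap). A half-count pseudo-observation per nucleotide per
# position keeps all 61 frequencies strictly positive.
empirical_f3x4 <- function(codon_alignment) {
  codons <- sense_codons()
  obs <- codons[codon_alignment[!is.na(codon_alignment)]]
  if (length(obs) == 0L) return(codon_freq_uniform())
  split3 <- do.call(rbind, strsplit(obs, ""))
  nf <- matrix(0.5, 3, 4, dimnames = list(NULL, .NUC))
  for (pos in 1:3) {
    tb <- table(factor(split3[, pos], levels = .NUC))
    nf[pos, ] <- nf[pos, ] + as.numeric(tb)
  }
  nf <- nf / rowSums(nf)
  codon_freq_f3x4(nf)
}

# Translate a codon alignment (integer matrix, NA = gap) to a protein
# alignment (character matrix with '-' gaps), preserving dimnames.
translate_codon_alignment <- function(codon_alignment) {
  aa <- sense_codon_aa()
  out <- matrix("-", nrow(codon_alignment), ncol(codon_alignment),
                dimnames = dimnames(codon_alignment))
  idx <- !is.na(codon_alignment)
  out[idx] <- unname(aa[codon_alignment[idx]])
  out
}
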