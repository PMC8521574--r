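# Focal-species unique amino acid substitutions: gap-aware column masking,
# the uniqueness call, and an alignment-derived functional-impact score
# (a SIFT-style normalised probability; externally supplied SIFT calls can
# override it in downstream tables).

#' Gap-aware column mask
#'
#' A column is masked (excluded from analysis) when it contains a gap in any
#' taxon, or lies within `flank` columns of such a column. Columns carrying
#' an unknown residue `X` are treated like gap columns, since an unknown
#' residue cannot certify background identity.
#'
#' @param alignment Character protein alignment matrix.
#' @param flank Number of columns masked on each side of a gap column
#'   (default 10).
#' @return Logical vector, `TRUE` = masked.
#' @export
#' @examples
#' aln <- matrix("A", 3, 30, dimnames = list(c("a", "b", "c"), NULL))
#' aln[2, 15] <- "-"
#' which(compute_gap_mask(aln))  # columns 5..25
compute_gap_mask <- function(alignment, flank = 10) {
  stopifnot(flank >= 0)
  nc <- ncol(alignment)
  bad <- which(colSums(alignment == "-" | alignment == "X") > 0)
  mask <- rep(FALSE, nc)
  for (b in bad) {
    mask[max(1L, b - flank):min(nc, b + flank)] <- TRUE
  }
  mask
}

#' Find focal-unique amino acid substitutions
#'
#' Calls every unmasked column in which all non-focal taxa share one residue
#' and the focal taxon carries a different one. Each call is scored with
#' [impact_score()]; a call is flagged as having functional impact when its
#' score falls below `cutoff`.
#'
#' @param alignment Character protein alignment (>= 3 taxa).
#' @param focal Focal taxon name.
#' @param mask Logical column mask; computed with [compute_gap_mask()] and
#'   `flank` when `NULL`.
#' @param flank Flank width passed to [compute_gap_mask()].
#' @param pseudocount Pseudocount for [impact_score()].
#' @param cutoff Impact threshold on the score (default 0.05, the canonical
#'   deleterious cutoff).
#' @param external_scores Optional data frame with columns `column` and
#'   `score` carrying externally computed impact scores (e.g. database-backed
#'   SIFT predictions); where a call's column appears there, the external
#'   score overrides the alignment-derived one and the call's `method` is
#'   `"external"`.
#' @return Data frame with `column` (1-based), `focal_aa`, `background_aa`,
#'   `score`, `impact`, `method` (`"sift_like"` or `"external"`).
#' @export
find_unique_substitutions <- function(alignment, focal, mask = NULL,
                                      flank = 10, pseudocount = 1,
                                      cutoff = 0.05, external_scores = NULL) {
  if (!(focal %in% rownames(alignment))) {
    stop("focal taxon '", focal, "' absent from alignment")
  }
  if (nrow(alignment) < 3) stop("need at least 2 non-focal taxa")
  if (is.null(mask)) mask <- compute_gap_mask(alignment, flank)
  bg <- alignment[setdiff(rownames(alignment), focal), , drop = FALSE]
  foc <- alignment[focal, ]
  cols <- which(!mask)
  hit <- cols[vapply(cols, function(j) {
    u <- unique(bg[, j])
    length(u) == 1L && foc[j] != u
  }, TRUE)]
  score <- vapply(hit, function(j) {
    impact_score(alignment, j, focal, pseudocount = pseudocount)
  }, 0)
  method <- rep("sift_like", length(hit))
  if (!is.null(external_scores)) {
    stopifnot(all(c("column", "score") %in% colnames(external_scores)))
    idx <- match(hit, external_scores$column)
    use <- !is.na(idx)
    score[use] <- external_scores$score[idx[use]]
    method[use] <- "external"
  }
  data.frame(column = hit,
             focal_aa = unname(foc[hit]),
             background_aa = if (length(hit)) unname(bg[1, hit]) else character(0),
             score = score,
             impact = score < cutoff,
             method = method)
}

#' Alignment-derived functional-impact score
#'
#' A SIFT-style normalised probability computed from the non-focal rows of
#' the column: with residue counts `c(a)` over the `N` non-focal taxa and
#' pseudocount `pc`, `p(a) = (c(a) + pc/20) / (N + pc)` and the score is
#' `p(focal residue) / max_a p(a)`, in (0, 1]. Scores below 0.05 are
#' conventionally interpreted as substitutions with functional impact.
#'
#' @param alignment Character protein alignment matrix.
#' @param column Unmasked column index (1-based).
#' @param focal Focal taxon name.
#' @param focal_residue Residue scored at the column (default: the focal
#'   taxon's residue).
#' @param pseudocount Positive pseudocount (default 1).
#' @return Score in (0, 1].
#' @export
impact_score <- function(alignment, column, focal,
                         focal_residue = alignment[focal, column],
                         pseudocount = 1) {
  stopifnot(pseudocount > 0)
  col <- alignment[setdiff(rownames(alignment), focal), column]
  if (any(col %in% c("-", "X")) || focal_residue %in% c("-", "X")) {
    stop("impact_score called on a masked (gapped/unknown) column")
  }
  aa20 <- sort(unique(unname(sense_codon_aa())))
  counts <- table(factor(col, levels = aa20))
  n <- length(col)
  p <- (as.numeric(counts) + pseudocount / 20) / (n + pseudocount)
  names(p) <- aa20
  unname(p[focal_residue] / max(p))
}

#' Unique-substitution signature
#'
#' A gene carries the signature when at least one of its unique-substitution
#' calls is flagged as having functional impact.
#'
#' @param calls Data frame from [find_unique_substitutions()].
#' @return Logical scalar.
#' @export
unique_substitution_signature <- function(calls) {
  nrow(calls) > 0 && any(calls$impact)
}
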