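# MSA calling: intersection of the three adaptive-evolution signatures.
# "MSA" here abbreviates "multiple signs of adaptive evolution" (unrelated
# to multiple sequence alignment).

#' Call genes with multiple signs of adaptive evolution
#'
#' A gene is an MSA gene when at least two of the three signatures —
#' unique substitution with functional impact, elevated root-to-tip
#' divergence, positive selection — are true. Missing signature values
#' (`NA`) count as `FALSE` (a gene absent from a signature table does not
#' carry that signature).
#'
#' @param records Data frame with columns `orthogroup`, `gene`,
#'   `unique_sub_impact`, `divergent`, `positively_selected` (logical;
#'   `NA` allowed).
#' @return The input with signature `NA`s replaced by `FALSE` and a logical
#'   `msa` column appended.
#' @export
#' @examples
#' call_msa(data.frame(orthogroup = "OG1", gene = "g1",
#'                     unique_sub_impact = TRUE, divergent = FALSE,
#'                     positively_selected = TRUE))$msa  # TRUE
call_msa <- function(records) {
  need <- c("orthogroup", "gene", "unique_sub_impact", "divergent",
            "positively_selected")
  miss <- setdiff(need, colnames(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records[c("orthogroup", "gene")])) {
    stop("duplicate (orthogroup, gene) rows in records")
  }
  sig <- c("unique_sub_impact", "divergent", "positively_selected")
  for (s in sig) {
    records[[s]] <- ifelse(is.na(records[[s]]), FALSE, as.logical(records[[s]]))
  }
  records$msa <- rowSums(as.matrix(records[sig])) >= 2
  records
}

#' Summarise signature counts
#'
#' Counts per signature, the seven Venn cells of the three signatures, and
#' the MSA count.
#'
#' @param records Data frame as returned by [call_msa()].
#' @return Named list of counts: `n_genes`, `n_unique_sub_impact`,
#'   `n_divergent`, `n_positively_selected`, `n_msa`, and the Venn cells
#'   `venn_U`, `venn_D`, `venn_S`, `venn_UD`, `venn_US`, `venn_DS`,
#'   `venn_UDS` (exclusive cells; U = unique substitution, D = divergent,
#'   S = positively selected).
#' @export
summarize_signatures <- function(records) {
  if (!("msa" %in% colnames(records))) records <- call_msa(records)
  u <- records$unique_sub_impact
  d <- records$divergent
  s <- records$positively_selected
  list(n_genes = nrow(records),
       n_unique_sub_impact = sum(u),
       n_divergent = sum(d),
       n_positively_selected = sum(s),
       n_msa = sum(records$msa),
       venn_U = sum(u & !d & !s),
       venn_D = sum(!u & d & !s),
       venn_S = sum(!u & !d & s),
       venn_UD = sum(u & d & !s),
       venn_US = sum(u & !d & s),
       venn_DS = sum(!u & d & s),
       venn_UDS = sum(u & d & s))
}
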