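# Orthogroup table parsing and the orthogroup-level filters: all-species
# completeness, fuzzy one-to-one selection, longest-gene representatives,
# trimmed supermatrix concatenation, and a neighbor-joining fallback tree
# from Poisson-corrected protein distances.

#' Species panel
#'
#' The ordered set of species under analysis, with designated focal species
#' and outgroup.
#'
#' @param species Character vector of unique species names.
#' @param focal Focal species (the lineage tested for adaptive evolution).
#' @param outgroup Outgroup species used to root trees.
#' @return Object of class `species_panel`.
#' @export
species_panel <- function(species, focal, outgroup) {
  if (anyDuplicated(species)) stop("species names must be unique")
  if (!(focal %in% species)) stop("focal species not in panel")
  if (!(outgroup %in% species)) stop("outgroup species not in panel")
  if (identical(focal, outgroup)) stop("focal and outgroup must differ")
  structure(list(species = species, focal = focal, outgroup = outgroup),
            class = "species_panel")
}

#' Parse an orthogroup membership table
#'
#' Reads an OrthoFinder-style TSV: first column the orthogroup ID, one
#' column per species, cells empty or comma-separated gene IDs. Gene IDs
#' must be unique across the whole table.
#'
#' @param path TSV file path.
#' @param panel A [species_panel()]; every species column in the header must
#'   belong to the panel and every panel species must have a column.
#' @return List of orthogroup objects: `list(id, members)` with `members` a
#'   named list of gene-ID character vectors per species.
#' @export
parse_orthogroup_table <- function(path, panel) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("orthogroup table needs an ID column and species columns")
  species_cols <- colnames(tab)[-1]
  extra <- setdiff(species_cols, panel$species)
  if (length(extra)) {
    stop("species in header not in panel: ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(panel$species, species_cols)
  if (length(missing)) {
    stop("missing species column: ", paste(missing, collapse = ", "))
  }
  ogs <- lapply(seq_len(nrow(tab)), function(i) {
    members <- lapply(panel$species, function(sp) {
      cell <- tab[i, sp]
      if (is.na(cell) || cell == "") character(0)
      else trimws(strsplit(cell, ",")[[1]])
    })
    names(members) <- panel$species
    structure(list(id = tab[i, 1], members = members), class = "orthogroup")
  })
  all_genes <- unlist(lapply(ogs, function(og) unlist(og$members)))
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup)) {
    stop("duplicate gene ID across orthogroups: ", dup[1])
  }
  ogs
}

#' Keep orthogroups containing all panel species
#'
#' @param orthogroups List from [parse_orthogroup_table()].
#' @param panel A [species_panel()].
#' @return Filtered list (input order preserved).
#' @export
filter_all_species <- function(orthogroups, panel) {
  keep <- vapply(orthogroups, function(og) {
    all(vapply(og$members[panel$species], length, 0L) >= 1L)
  }, TRUE)
  orthogroups[keep]
}

#' Select fuzzy one-to-one orthogroups
#'
#' Keeps orthogroups in which at least a fraction `fuzziness` of the panel
#' species contribute exactly one gene and no species contributes more than
#' `max_copies` genes (every species must contribute at least one; apply
#' [filter_all_species()] first).
#'
#' @inheritParams filter_all_species
#' @param fuzziness Minimum fraction of strictly single-copy species, in
#'   `[0, 1]` (default 0.75).
#' @param max_copies Maximum gene count per species (default 3).
#' @return Filtered list (input order preserved).
#' @export
select_fuzzy_one_to_one <- function(orthogroups, panel, fuzziness = 0.75,
                                    max_copies = 3) {
  if (fuzziness < 0 || fuzziness > 1) stop("fuzziness must lie in [0, 1]")
  keep <- vapply(orthogroups, function(og) {
    n <- vapply(og$members[panel$species], length, 0L)
    all(n >= 1L) && all(n <= max_copies) && mean(n == 1L) >= fuzziness
  }, TRUE)
  orthogroups[keep]
}

#' Pick one representative gene per species
#'
#' For each species, the gene with the longest protein sequence (ungapped
#' length); ties broken by the lexicographically smallest gene ID.
#'
#' @param orthogroup An orthogroup with at least one gene per panel species.
#' @param panel A [species_panel()].
#' @param sequences Named character vector of protein sequences covering
#'   every member gene.
#' @return Named character vector: species -> gene ID.
#' @export
pick_representatives <- function(orthogroup, panel, sequences) {
  vapply(panel$species, function(sp) {
    genes <- orthogroup$members[[sp]]
    if (length(genes) == 0L) {
      stop("species ", sp, " has no gene in orthogroup ", orthogroup$id)
    }
    miss <- setdiff(genes, names(sequences))
    if (length(miss)) stop("no sequence for gene ", miss[1])
    len <- nchar(gsub("-", "", sequences[genes]))
    cand <- sort(genes[len == max(len)])
    cand[1]
  }, "")
}

#' Concatenate trimmed alignments into a supermatrix
#'
#' Removes, within each alignment, the columns that are gaps in every taxon
#' (empty sites), then concatenates the alignments in input order. Partition
#' boundaries (1-based, inclusive) are recorded in the `"partitions"`
#' attribute.
#'
#' @param alignments Named list of character alignment matrices, each with
#'   exactly one row per panel species.
#' @param panel A [species_panel()].
#' @return Character matrix (rows ordered as `panel$species`).
#' @export
build_supermatrix <- function(alignments, panel) {
  trimmed <- lapply(alignments, function(a) {
    if (!setequal(rownames(a), panel$species)) {
      stop("alignment rows do not match the species panel")
    }
    a <- a[panel$species, , drop = FALSE]
    keep <- colSums(a != "-") > 0
    a[, keep, drop = FALSE]
  })
  widths <- vapply(trimmed, ncol, 0L)
  out <- do.call(cbind, trimmed)
  ends <- cumsum(widths)
  attr(out, "partitions") <- data.frame(
    name = if (is.null(names(alignments))) as.character(seq_along(alignments))
           else names(alignments),
    start = c(1L, utils::head(ends, -1) + 1L)[seq_along(ends)],
    end = ends)
  out
}

# Poisson-corrected pairwise protein distances over mutually ungapped sites
.poisson_distances <- function(alignment) {
  taxa <- rownames(alignment)
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- alignment[i, ]; b <- alignment[j, ]
      ok <- a != "-" & b != "-" & a != "X" & b != "X"
      if (!any(ok)) stop("no mutually ungapped sites for pair ",
                         taxa[i], "/", taxa[j])
      p <- mean(a[ok] != b[ok])
      if (p >= 1) {
        stop("saturated pair ", taxa[i], "/", taxa[j],
             " (p = 1): Poisson distance undefined; consider a distance cap")
      }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Neighbor-joining tree from a protein alignment
#'
#' Builds a tree from Poisson-corrected pairwise distances
#' `d = -ln(1 - p)`, with `p` the mismatch fraction over mutually ungapped
#' (and non-`X`) sites, by neighbor joining; negative NJ branch lengths are
#' clamped to zero and the tree is rooted on the panel outgroup, with the
#' root placed at the midpoint of the outgroup's pendant edge (rooting at
#' the attachment node would credit the outgroup its entire branch as
#' root-to-tip distance and bias divergence comparisons). Used as the
#' fallback when no tree is supplied.
#'
#' @param alignment Character protein alignment (>= 3 rows, rownames =
#'   species).
#' @param panel A [species_panel()]; the outgroup must be an alignment row.
#' @return Rooted `phylo` tree.
#' @export
nj_tree <- function(alignment, panel) {
  if (nrow(alignment) < 3) stop("need at least 3 sequences")
  if (!(panel$outgroup %in% rownames(alignment))) {
    stop("outgroup ", panel$outgroup, " absent from alignment")
  }
  D <- .poisson_distances(alignment)
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- ape::root(tr, outgroup = panel$outgroup, resolve.root = TRUE)
  # split the outgroup's pendant edge at its midpoint across the root
  root <- length(tr$tip.label) + 1L
  kids <- which(tr$edge[, 1] == root)
  og_edge <- kids[tr$edge[kids, 2] == match(panel$outgroup, tr$tip.label)]
  if (length(og_edge) == 1L && length(kids) == 2L) {
    half <- tr$edge.length[og_edge] / 2
    tr$edge.length[og_edge] <- half
    sib <- setdiff(kids, og_edge)
    tr$edge.length[sib] <- tr$edge.length[sib] + half
  }
  tr
}
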