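# Root-to-tip divergence: per-orthogroup gene trees, root-to-tip branch
# length distances, and the elevated-divergence flag for the focal species.

#' Root-to-tip distances
#'
#' Sum of branch lengths on the unique root-to-leaf path, for every leaf. An
#' unrooted tree is rooted on `outgroup` first; an unrooted tree without an
#' outgroup is an error.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Optional outgroup leaf used to root an unrooted tree.
#' @return Named numeric vector of distances, one per leaf.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,C:4);")
#' root_to_tip_distances(tr)  # A=2, B=3, C=4
root_to_tip_distances <- function(tree, outgroup = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) stop("unrooted tree and no outgroup given")
    if (!(outgroup %in% tree$tip.label)) {
      stop("outgroup ", outgroup, " absent from tree")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  setNames(d, tree$tip.label)
}

#' Flag a focal gene as divergent
#'
#' Compares the focal root-to-tip distance with the non-focal distances. In
#' mode `"max"` (default, the strictest parameter-free reading of
#' "comparatively higher") the gene is flagged when the focal distance
#' exceeds `ratio` times the maximum non-focal distance. In mode `"zscore"`
#' it is flagged when the focal z-score against the non-focal mean/sd
#' exceeds `z`; with zero non-focal spread the statistic is `Inf` (or
#' `-Inf`) and the gene is flagged when the focal distance exceeds the mean.
#'
#' @param distances Named numeric vector from [root_to_tip_distances()].
#' @param focal Focal species name (>= 3 other species required).
#' @param mode `"max"` or `"zscore"`.
#' @param ratio Multiplier on the non-focal maximum (mode `"max"`).
#' @param z Z-score threshold (mode `"zscore"`).
#' @return List with `statistic` and `flag`.
#' @export
flag_divergent <- function(distances, focal, mode = c("max", "zscore"),
                           ratio = 1, z = 2) {
  mode <- match.arg(mode)
  if (!(focal %in% names(distances))) stop("focal species not in distances")
  others <- distances[setdiff(names(distances), focal)]
  if (length(others) < 3) stop("need at least 3 non-focal species")
  foc <- distances[[focal]]
  if (mode == "max") {
    stat <- if (max(others) > 0) foc / max(others) else Inf
    list(statistic = unname(stat), flag = foc > ratio * max(others))
  } else {
    s <- sd(others)
    if (s == 0) {
      list(statistic = if (foc > mean(others)) Inf else -Inf,
           flag = foc > mean(others))
    } else {
      stat <- (foc - mean(others)) / s
      list(statistic = unname(stat), flag = stat > z)
    }
  }
}

#' Per-orthogroup gene tree
#'
#' Returns the supplied per-orthogroup tree rooted on the panel outgroup
#' when one is given; otherwise falls back to the neighbor-joining tree of
#' [nj_tree()] computed from the orthogroup alignment.
#'
#' @param alignment Character protein alignment.
#' @param panel A [species_panel()].
#' @param tree Optional `phylo` tree supplied by the user.
#' @return Rooted `phylo` tree.
#' @export
gene_tree <- function(alignment, panel, tree = NULL) {
  if (!is.null(tree)) {
    if (!(panel$outgroup %in% tree$tip.label)) {
      stop("outgroup ", panel$outgroup, " absent from supplied tree")
    }
    if (!ape::is.rooted(tree)) {
      tree <- ape::root(tree, outgroup = panel$outgroup, resolve.root = TRUE)
    }
    return(tree)
  }
  nj_tree(alignment, panel)
}

#' Divergence signature for one orthogroup
#'
#' Convenience wrapper: gene tree, root-to-tip distances and the divergence
#' flag for the panel's focal species.
#'
#' @inheritParams gene_tree
#' @inheritParams flag_divergent
#' @return List with `distances`, `statistic`, `flag`.
#' @export
divergence_signature <- function(alignment, panel, tree = NULL,
                                 mode = c("max", "zscore"), ratio = 1, z = 2) {
  tr <- gene_tree(alignment, panel, tree)
  d <- root_to_tip_distances(tr, outgroup = panel$outgroup)
  fl <- flag_divergent(d, panel$focal, mode = mode, ratio = ratio, z = z)
  list(distances = d, statistic = fl$statistic, flag = fl$flag)
}
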