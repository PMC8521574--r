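# Independent brute-force oracles and shared fixtures. Each oracle is a
# deliberately naive implementation, kept free of the package's code paths
# so that agreement is informative.

# fixed 8-taxon study tree: focal terminal branch F of length 0.3,
# outgroup O attached at the root
fixed_tree_8 <- function() {
  ape::read.tree(text = paste0(
    "((((F:0.3,S1:0.2):0.1,(S2:0.15,S3:0.15):0.1):0.1,",
    "(S4:0.2,(S5:0.15,S6:0.15):0.1):0.1):0.2,O:0.5);"))
}

# per-column scan: a column is masked iff any column within +/- flank
# (including itself) has a gap or X in any taxon
oracle_gap_mask <- function(aln, flank) {
  nc <- ncol(aln)
  vapply(seq_len(nc), function(j) {
    win <- max(1, j - flank):min(nc, j + flank)
    any(aln[, win] %in% c("-", "X"))
  }, TRUE)
}

# textbook step-up: q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(vapply(i:m, function(j) p[o[j]] * m / j, 0)))
  }
  q
}

# path sum by parent-pointer walk from each tip to the root
oracle_root_to_tip <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(ntip + tree$Nnode)
  len_to_parent <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[e, 2]] <- tree$edge[e, 1]
    len_to_parent[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  d <- vapply(seq_len(ntip), function(tip) {
    tot <- 0
    node <- tip
    while (node != root) {
      tot <- tot + len_to_parent[node]
      node <- parent_of[node]
    }
    tot
  }, 0)
  setNames(d, tree$tip.label)
}

# Exhaustive enumeration of the site likelihood over all assignments of
# internal-node states (61^Nnode terms); feasible for <= 3 internal nodes.
# pattern: codon states in tip order, NA = gap (an edge into a gap tip
# contributes a factor of 1, since its transition row sums to 1).
oracle_enum_site_loglik <- function(pattern, tree, P_list, pi) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  stopifnot(nn <= 3)
  grid <- as.matrix(expand.grid(rep(list(1:61), nn)))
  lik <- pi[grid[, 1]]  # node ntip+1 is the root in ape numbering
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    P <- P_list[[e]]
    spa <- grid[, pa - ntip]
    if (ch <= ntip) {
      st <- pattern[ch]
      if (is.na(st)) next
      lik <- lik * P[cbind(spa, st)]
    } else {
      lik <- lik * P[cbind(spa, grid[, ch - ntip])]
    }
  }
  log(sum(lik))
}

# transition matrices for a single-omega process on every edge of a tree
single_omega_p_list <- function(tree, kappa, omega, pi) {
  Q <- codon_rate_matrix(kappa, omega, pi)
  lapply(tree$edge.length, function(t) transition_matrix(Q, t, pi))
}

# random gapped protein alignment
random_protein_alignment <- function(ntaxa, ncol, gap_prob = 0.05) {
  aa <- sort(unique(unname(sense_codon_aa())))
  m <- matrix(sample(aa, ntaxa * ncol, replace = TRUE), ntaxa, ncol)
  m[runif(ntaxa * ncol) < gap_prob] <- "-"
  rownames(m) <- paste0("t", seq_len(ntaxa))
  m
}

# balanced ultrametric fixture tree: 8 ingroup species at equal root-to-tip
# depth (terminal branches a quarter of the ingroup depth), outgroup at the
# root — every species has the same baseline root-to-tip distance, so a
# planted focal rate acceleration is the only divergence signal
balanced_tree_9 <- function(mean_depth = 0.3) {
  bal <- function(labs, step) {
    if (length(labs) == 1) return(labs)
    h <- length(labs) %/% 2
    paste0("(", bal(labs[1:h], step), ":", step, ",",
           bal(labs[(h + 1):length(labs)], step), ":", step, ")")
  }
  step <- 0.75 * mean_depth / 3
  ape::read.tree(text = paste0(
    "(", bal(sprintf("sp%02d", 1:8), step), ":", 0.25 * mean_depth,
    ",outgrp:", mean_depth, ");"))
}
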