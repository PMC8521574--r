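# Seeded codon-evolution simulator. Sites are assigned to the four Model A
# classes; codons then evolve along the tree by Gillespie event sampling
# under GY94 matrices scaled to mean rate 1, so that branch lengths are
# expected substitutions per codon site and the simulator keeps an exact
# per-branch, per-site event-count record that tests can use as an oracle.

#' Simulation configuration for a synthetic orthogroup
#'
#' Collects and validates the generative parameters of one synthetic
#' orthogroup: tree geometry, Model A site-class structure (proportions
#' `p0`/`p1`, purifying `omega0`, foreground `omega2`), `kappa`, codon
#' frequencies, planted focal-unique substitutions, focal-branch rate
#' acceleration, and the gap-injection process.
#'
#' @param n_species Number of leaves when a tree is simulated (>= 3).
#' @param n_codons Alignment length in codons.
#' @param tree_source Newick string for a fixed tree, or `NULL` to simulate
#'   one with [simulate_tree()].
#' @param focal,outgroup Leaf names of the focal species and the outgroup.
#' @param mean_depth Root-to-tip depth of a simulated tree (expected
#'   substitutions per codon site).
#' @param p0,p1 Site-class proportions (class 0 and class 1); the remainder
#'   is split into classes 2a/2b in proportion `p0 : p1`.
#' @param omega0 Purifying dN/dS in (0, 1].
#' @param omega2 Foreground dN/dS on the focal branch for 2a/2b sites (> 0;
#'   1 simulates the null).
#' @param kappa Transition/transversion ratio.
#' @param codon_frequencies `"uniform"`, or a length-61 frequency vector.
#' @param n_planted_unique_sites Focal-unique substitutions to plant.
#' @param focal_rate_multiplier Multiplier (>= 1) applied to the focal
#'   terminal branch length during simulation (rate acceleration).
#' @param gap_rate Per-cell gap probability in `[0, 1)` for [inject_gaps()].
#' @param gap_flank_clearance Columns around planted sites protected from
#'   gap injection so that planted signals survive gap masking.
#' @param seed Integer seed; every draw the generator makes is derived from
#'   it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species = 17, n_codons = 300, tree_source = NULL,
                       focal = "sp01", outgroup = "outgrp",
                       mean_depth = 0.5,
                       p0 = 0.45, p1 = 0.30, omega0 = 0.2, omega2 = 1,
                       kappa = 2, codon_frequencies = "uniform",
                       n_planted_unique_sites = 0,
                       focal_rate_multiplier = 1,
                       gap_rate = 0, gap_flank_clearance = 10, seed = 1) {
  stopifnot(n_species >= 3, n_codons >= 1,
            p0 >= 0, p1 >= 0, p0 + p1 <= 1, p0 + p1 > 0,
            omega0 > 0, omega0 <= 1, omega2 > 0, kappa > 0,
            n_planted_unique_sites >= 0, focal_rate_multiplier >= 1,
            gap_rate >= 0, gap_rate < 1, gap_flank_clearance >= 0)
  if (identical(codon_frequencies, "uniform")) {
    pi <- codon_freq_uniform()
  } else {
    pi <- codon_frequencies
    .check_pi(pi)
    if (abs(sum(pi) - 1) > 1e-12) pi <- pi / sum(pi)
  }
  if (identical(focal, outgroup)) stop("focal and outgroup must differ")
  out <- list(n_species = n_species, n_codons = n_codons,
              tree_source = tree_source, focal = focal, outgroup = outgroup,
              mean_depth = mean_depth, p0 = p0, p1 = p1,
              omega0 = omega0, omega2 = omega2, kappa = kappa,
              pi = pi, n_planted_unique_sites = n_planted_unique_sites,
              focal_rate_multiplier = focal_rate_multiplier,
              gap_rate = gap_rate, gap_flank_clearance = gap_flank_clearance,
              seed = seed)
  class(out) <- "sim_config"
  out
}

#' Simulate a rooted ultrametric species tree
#'
#' Draws a coalescent topology for the ingroup, rescales it so every
#' root-to-tip path equals `mean_depth`, and attaches the outgroup (leaf
#' `"outgrp"`) at the root. Ingroup leaves are named `sp01`, `sp02`, ...
#'
#' @param n_species Total number of leaves including the outgroup (>= 3).
#' @param seed Integer seed (deterministic output).
#' @param mean_depth Root-to-tip depth in expected substitutions per codon
#'   site.
#' @return Rooted binary `phylo` tree with `2 * n_species - 2` branches, all
#'   strictly positive.
#' @export
simulate_tree <- function(n_species, seed, mean_depth = 0.5) {
  if (n_species < 3) stop("too few taxa: need at least 3 species")
  stopifnot(mean_depth > 0)
  set.seed(seed)
  n_in <- n_species - 1L
  labs <- sprintf("sp%02d", seq_len(n_in))
  if (n_in == 2L) {
    ing <- ape::read.tree(text = sprintf("(%s:1,%s:1);", labs[1], labs[2]))
  } else {
    ing <- ape::rcoal(n_in, tip.label = labs)
  }
  depth <- max(ape::node.depth.edgelength(ing))
  ing$edge.length <- ing$edge.length / depth * (0.75 * mean_depth)
  nwk <- sub(";\\s*$", "", ape::write.tree(ing))
  full <- sprintf("(%s:%.10f,outgrp:%.10f);", nwk, 0.25 * mean_depth, mean_depth)
  ape::read.tree(text = full)
}

# per-state event sampler structure for one rate matrix
.rate_struct <- function(Q) {
  n <- nrow(Q)
  lapply(seq_len(n), function(i) {
    js <- which(Q[i, ] > 0 & seq_len(n) != i)
    rates <- Q[i, js]
    tot <- sum(rates)
    list(js = js, cum = cumsum(rates) / tot, total = tot)
  })
}

# Gillespie walk of one site along one branch; returns end state and the
# number of synonymous / nonsynonymous events
.evolve_site <- function(state, len, rs, is_ns_step) {
  nsyn <- 0L; nnon <- 0L
  t <- 0
  repeat {
    s <- rs[[state]]
    t <- t + rexp(1L, s$total)
    if (t > len) break
    k <- findInterval(runif(1L), s$cum) + 1L
    new <- s$js[k]
    if (is_ns_step[state, new]) nnon <- nnon + 1L else nsyn <- nsyn + 1L
    state <- new
  }
  c(state, nsyn, nnon)
}

#' Simulate a codon alignment under branch-site Model A
#'
#' Evolves `n_codons` sites along `tree` from a stationary root draw. Each
#' site belongs to one Model A class: class 0 evolves under `omega0` on all
#' branches, class 1 under omega = 1, classes 2a/2b under their background
#' omega (`omega0` / 1) on all branches except the focal terminal branch,
#' where they take `omega2`. Branch lengths are expected substitutions per
#' codon site (matrices scaled to mean rate 1); the focal terminal branch is
#' additionally stretched by `focal_rate_multiplier`. All substitution
#' events are recorded per site and branch.
#'
#' @param config A [sim_config()].
#' @param tree Rooted `phylo` tree containing the focal and outgroup leaves;
#'   if `NULL`, taken from `config$tree_source` or simulated.
#' @return List with `codon` (integer codon alignment), `protein` (its
#'   translation) and `truth` (site class labels, planted columns, event
#'   counts, parameters, tree, seed).
#' @export
simulate_orthogroup <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) {
    tree <- if (is.null(config$tree_source)) {
      simulate_tree(config$n_species, config$seed, config$mean_depth)
    } else {
      ape::read.tree(text = config$tree_source)
    }
  }
  miss <- setdiff(c(config$focal, config$outgroup), tree$tip.label)
  if (length(miss)) stop("tree lacks leaves: ", paste(miss, collapse = ", "))
  set.seed(config$seed)

  nsite <- config$n_codons
  p2 <- 1 - config$p0 - config$p1
  probs <- c(config$p0, config$p1,
             p2 * config$p0 / (config$p0 + config$p1),
             p2 * config$p1 / (config$p0 + config$p1))
  classes <- sample(c("0", "1", "2a", "2b"), nsite, replace = TRUE, prob = probs)

  pi <- config$pi
  # shared mixture scale (same convention as the likelihood engine): branch
  # lengths are substitutions per codon averaged over the background classes,
  # so foreground-selected sites with omega2 > 1 evolve proportionally faster
  rs_mix <- .mixture_rate_scale(config$kappa, config$omega0,
                                config$p0, config$p1, pi)
  Q <- list(codon_rate_matrix(config$kappa, config$omega0, pi, scale = FALSE) / rs_mix,
            codon_rate_matrix(config$kappa, 1, pi, scale = FALSE) / rs_mix,
            codon_rate_matrix(config$kappa, config$omega2, pi, scale = FALSE) / rs_mix)
  rs <- lapply(Q, .rate_struct)
  tmpl <- .codon_template()
  is_ns <- matrix(FALSE, 61, 61)
  is_ns[cbind(tmpl$ii, tmpl$jj)] <- tmpl$ns

  # omega (matrix index) per site for background and foreground branches
  bg_q <- ifelse(classes %in% c("0", "2a"), 1L, 2L)
  fg_q <- ifelse(classes == "0", 1L, ifelse(classes == "1", 2L, 3L))

  po <- ape::reorder.phylo(tree, "postorder")
  pre <- nrow(po$edge):1
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  fg_edge <- which(po$edge[, 2] == match(config$focal, tree$tip.label))

  states <- matrix(NA_integer_, nnode, nsite)
  root <- ntip + 1L
  states[root, ] <- sample.int(61L, nsite, replace = TRUE, prob = pi)
  nedge <- nrow(po$edge)
  ev_syn <- matrix(0L, nedge, nsite)
  ev_non <- matrix(0L, nedge, nsite)

  for (e in pre) {
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    len <- po$edge.length[e]
    qidx <- if (e == fg_edge) fg_q else bg_q
    if (e == fg_edge) len <- len * config$focal_rate_multiplier
    for (s in seq_len(nsite)) {
      r <- .evolve_site(states[pa, s], len, rs[[qidx[s]]], is_ns)
      states[ch, s] <- r[1]
      ev_syn[e, s] <- r[2]
      ev_non[e, s] <- r[3]
    }
  }

  codon <- states[seq_len(ntip), , drop = FALSE]
  rownames(codon) <- tree$tip.label
  truth <- list(classes = classes, planted_columns = integer(0),
                focal_accelerated = config$focal_rate_multiplier > 1,
                params = config[c("p0", "p1", "omega0", "omega2", "kappa",
                                  "focal_rate_multiplier")],
                pi = pi, seed = config$seed,
                events_syn = ev_syn, events_nonsyn = ev_non,
                edges = po$edge, edge_lengths = po$edge.length,
                fg_edge = fg_edge, tree = tree)
  list(codon = codon, protein = translate_codon_alignment(codon),
       truth = truth)
}

#' Plant focal-unique amino acid substitutions
#'
#' Picks `n_sites` alignment columns that are gap-free and invariant across
#' the non-focal taxa, and replaces the focal residue with a residue
#' different from the shared background residue. When a congruent codon
#' alignment is supplied, the focal codon at each planted column is replaced
#' by a codon of the new residue so translation consistency is preserved.
#'
#' @param protein Character protein alignment matrix (rows = taxa).
#' @param focal Focal taxon name.
#' @param n_sites Number of columns to plant.
#' @param seed Integer seed.
#' @param codon Optional congruent integer codon alignment to update.
#' @return List with `protein`, `codon` (or `NULL`) and `planted`, a data
#'   frame of planted columns with old/new focal residues.
#' @export
plant_unique_substitutions <- function(protein, focal, n_sites, seed,
                                       codon = NULL) {
  if (!(focal %in% rownames(protein))) stop("focal taxon not in alignment")
  if (nrow(protein) < 3) stop("alignment needs at least 3 taxa")
  if (n_sites == 0) {
    return(list(protein = protein, codon = codon,
                planted = data.frame(column = integer(0),
                                     old = character(0), new = character(0),
                                     background = character(0))))
  }
  bg <- protein[setdiff(rownames(protein), focal), , drop = FALSE]
  gap_free <- colSums(protein == "-" | protein == "X") == 0
  invariant <- apply(bg, 2, function(col) length(unique(col)) == 1L)
  eligible <- which(gap_free & invariant)
  if (length(eligible) < n_sites) {
    stop("insufficient eligible columns: need ", n_sites, ", have ",
         length(eligible))
  }
  set.seed(seed)
  cols <- sort(eligible[sample.int(length(eligible), n_sites)])
  aa20 <- sort(unique(unname(sense_codon_aa())))
  aa_tab <- sense_codon_aa()
  old <- protein[focal, cols]
  bg_res <- bg[1, cols]
  new <- vapply(bg_res, function(b) {
    cand <- setdiff(aa20, b)
    cand[sample.int(length(cand), 1L)]
  }, "")
  protein[focal, cols] <- new
  if (!is.null(codon)) {
    for (k in seq_along(cols)) {
      cand <- which(unname(aa_tab) == new[k])
      codon[focal, cols[k]] <- cand[sample.int(length(cand), 1L)]
    }
  }
  list(protein = protein, codon = codon,
       planted = data.frame(column = cols, old = unname(old),
                            new = unname(new), background = unname(bg_res)))
}

#' Inject gaps into an alignment
#'
#' Each (taxon, column) cell outside the protected columns independently
#' becomes a gap with probability `gap_rate`. A congruent codon alignment,
#' if supplied, is gapped at the same cells.
#'
#' @param protein Character protein alignment matrix.
#' @param gap_rate Per-cell gap probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param protect_columns Column indices never gapped (e.g. planted columns
#'   and their flanks).
#' @param codon Optional congruent integer codon alignment.
#' @return List with `protein` and `codon` (or `NULL`).
#' @export
inject_gaps <- function(protein, gap_rate, seed, protect_columns = integer(0),
                        codon = NULL) {
  stopifnot(gap_rate >= 0, gap_rate < 1)
  if (gap_rate == 0) return(list(protein = protein, codon = codon))
  set.seed(seed)
  mask <- matrix(runif(length(protein)) < gap_rate,
                 nrow(protein), ncol(protein))
  if (length(protect_columns)) mask[, protect_columns] <- FALSE
  protein[mask] <- "-"
  if (!is.null(codon)) codon[mask] <- NA_integer_
  list(protein = protein, codon = codon)
}
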