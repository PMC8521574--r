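# Branch-site positive-selection test (Model A vs fixed-omega null):
# codon threading, mixture likelihood over the four site classes, ML fitting
# by seeded multi-start Nelder-Mead, LRT, BH-FDR and NEB site posteriors.
# The foreground is the terminal branch leading to the focal species.

#' Thread a coding sequence onto a protein alignment
#'
#' Converts per-gene CDS into a codon alignment congruent with a protein
#' multiple alignment: each protein column maps to one codon column and
#' protein gaps propagate to codon gaps. Every CDS must translate exactly to
#' its ungapped protein row (a terminal stop codon is allowed and stripped).
#'
#' @param protein_alignment Character matrix (taxa x columns, gap `-`).
#' @param cds_by_taxon Named character vector of CDS (DNA) strings, one per
#'   alignment row.
#' @return Integer codon alignment (states index [sense_codons()], `NA` =
#'   gap) with the same dimnames as the protein alignment.
#' @export
thread_codons <- function(protein_alignment, cds_by_taxon) {
  taxa <- rownames(protein_alignment)
  if (is.null(taxa)) stop("protein alignment must have taxon rownames")
  miss <- setdiff(taxa, names(cds_by_taxon))
  if (length(miss)) stop("no CDS supplied for taxa: ", paste(miss, collapse = ", "))
  codons <- sense_codons()
  aa_tab <- sense_codon_aa()
  out <- matrix(NA_integer_, nrow(protein_alignment), ncol(protein_alignment),
                dimnames = dimnames(protein_alignment))
  for (tx in taxa) {
    cds <- toupper(gsub("U", "T", cds_by_taxon[[tx]]))
    if (nchar(cds) %% 3 != 0) stop("CDS length not a multiple of 3 for taxon ", tx)
    cd <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    if (length(cd) && cd[length(cd)] %in% c("TAA", "TAG", "TGA")) {
      cd <- cd[-length(cd)]
    }
    if (any(cd %in% c("TAA", "TAG", "TGA"))) {
      stop("internal stop codon in CDS of taxon ", tx, " at codon ",
           which(cd %in% c("TAA", "TAG", "TGA"))[1])
    }
    idx <- match(cd, codons)
    if (anyNA(idx)) {
      stop("unrecognised codon '", cd[which(is.na(idx))[1]], "' in CDS of taxon ", tx)
    }
    row <- protein_alignment[tx, ]
    ungapped <- which(row != "-")
    if (length(ungapped) != length(cd)) {
      stop("CDS of taxon ", tx, " codes for ", length(cd),
           " residues but its alignment row has ", length(ungapped))
    }
    mism <- which(unname(aa_tab[idx]) != row[ungapped])
    if (length(mism)) {
      stop("translation mismatch for taxon ", tx, " at alignment column ",
           ungapped[mism[1]])
    }
    out[tx, ungapped] <- idx
  }
  out
}

#' Branch-site model parameters
#'
#' Container for Model A parameters: site-class proportions `p0` (class 0,
#' omega0 on all branches) and `p1` (class 1, omega 1 everywhere), with the
#' remaining mass split proportionally into classes 2a/2b which take
#' `omega2` on the foreground branch only; `kappa`; and codon frequencies
#' `pi`. Under the null model `omega2` is fixed at 1.
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega0 Purifying-class dN/dS in (0, 1].
#' @param omega2 Foreground dN/dS (>= 1; 1 under the null).
#' @param p0,p1 Class proportions, non-negative, `p0 + p1 <= 1`, `p0 + p1 > 0`.
#' @param pi Codon frequency vector (length 61, sums to 1).
#' @return Object of class `branch_site_params` with derived proportions
#'   `p2a`, `p2b`.
#' @export
branch_site_params <- function(kappa, omega0, omega2 = 1, p0, p1, pi) {
  stopifnot(kappa > 0, omega0 > 0, omega0 <= 1, omega2 > 0,
            p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12, p0 + p1 > 0)
  .check_pi(pi)
  p2 <- max(0, 1 - p0 - p1)
  out <- list(kappa = kappa, omega0 = omega0, omega2 = omega2,
              p0 = p0, p1 = p1,
              p2a = p2 * p0 / (p0 + p1), p2b = p2 * p1 / (p0 + p1),
              pi = pi)
  stopifnot(abs(out$p0 + out$p1 + out$p2a + out$p2b - 1) < 1e-10)
  class(out) <- "branch_site_params"
  out
}

# encode alignment + tree for the C++ engine; compression collapses
# identical codon columns into weighted site patterns
.bs_encode <- function(codon_alignment, tree, focal, compress = TRUE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  taxa <- rownames(codon_alignment)
  miss <- setdiff(tree$tip.label, taxa)
  if (length(miss)) stop("alignment missing taxa: ", paste(miss, collapse = ", "))
  if (!(focal %in% tree$tip.label)) stop("focal species '", focal, "' not in tree")
  ntip <- length(tree$tip.label)
  m <- codon_alignment[tree$tip.label, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = ",")
  if (compress) {
    upat <- !duplicated(key)
    w <- as.numeric(table(factor(key, levels = key[upat])))
    patt <- m[, upat, drop = FALSE]
    site_to_pattern <- match(key, key[upat])
  } else {
    w <- rep(1, ncol(m))
    patt <- m
    site_to_pattern <- seq_len(ncol(m))
  }
  patt_int <- patt - 1L
  patt_int[is.na(patt_int)] <- -1L
  po <- ape::reorder.phylo(tree, "postorder")
  fg <- which(po$edge[, 2] == match(focal, tree$tip.label))
  list(patt = patt_int, w = w, site_to_pattern = site_to_pattern,
       edge_parent = po$edge[, 1] - 1L, edge_child = po$edge[, 2] - 1L,
       edge_len = po$edge.length, fg_edge = fg - 1L,
       root = ntip, ntips = ntip, nnodes = ntip + tree$Nnode)
}

.class_site_loglik <- function(enc, kappa, omega0, omega2, p0, p1, pi,
                               branch_scale = 1) {
  tmpl <- .codon_template()
  rate_scale <- .mixture_rate_scale(kappa, omega0, p0, p1, pi)
  cpp_class_site_loglik(enc$patt, enc$edge_parent, enc$edge_child,
                        enc$edge_len * branch_scale,
                        enc$fg_edge, enc$root, enc$ntips, enc$nnodes,
                        unname(pi), kappa, omega0, omega2, rate_scale,
                        tmpl$ii - 1L, tmpl$jj - 1L,
                        as.integer(tmpl$ts), as.integer(tmpl$ns))
}

.class_weights <- function(params) {
  c(params$p0, params$p1, params$p2a, params$p2b)
}

.mix_loglik <- function(clsll, weights, w) {
  mx <- apply(clsll, 2, max)
  sum(w * (mx + log(colSums(weights * exp(sweep(clsll, 2, mx))))))
}

#' Branch-site model log-likelihood
#'
#' Log-likelihood of a codon alignment under branch-site Model A (`model =
#' "alt"`) or the fixed-omega null (`model = "null"`, `omega2` forced to 1):
#' per site, the likelihoods of the four site classes (0, 1, 2a, 2b) are
#' mixed with the class proportions; branch lengths are taken from the tree
#' and the foreground is the terminal branch of `focal`.
#'
#' @param codon_alignment Integer codon alignment (see [thread_codons()]).
#' @param tree Rooted `phylo` tree whose tips are alignment rows.
#' @param params A [branch_site_params()] object.
#' @param model `"alt"` or `"null"`.
#' @param focal Focal species (foreground terminal branch).
#' @param compress Collapse identical columns into weighted patterns
#'   (identical result, faster).
#' @param branch_scale Scalar multiplier applied to all branch lengths.
#' @return Log-likelihood (scalar).
#' @export
model_log_likelihood <- function(codon_alignment, tree, params,
                                 model = c("alt", "null"), focal,
                                 compress = TRUE, branch_scale = 1) {
  model <- match.arg(model)
  enc <- .bs_encode(codon_alignment, tree, focal, compress = compress)
  omega2 <- if (model == "null") 1 else params$omega2
  clsll <- .class_site_loglik(enc, params$kappa, params$omega0, omega2,
                              params$p0, params$p1, params$pi, branch_scale)
  .mix_loglik(clsll, .class_weights(params), enc$w)
}

# parameter transforms: unconstrained theta <-> Model A box
.bs_untransform <- function(theta, model, scale_branches) {
  kappa <- exp(theta[1])
  omega0 <- stats::plogis(theta[2])
  ex <- exp(c(theta[3], theta[4], 0))
  pr <- ex / sum(ex)
  k <- 5L
  omega2 <- 1
  if (model == "alt") {
    omega2 <- 1 + 49 * stats::plogis(theta[5])
    k <- 6L
  }
  s <- if (scale_branches) exp(theta[k]) else 1
  list(kappa = kappa, omega0 = omega0, omega2 = omega2,
       p0 = pr[1], p1 = pr[2], scale = s)
}

.bs_transform <- function(kappa, omega0, omega2, p0, p1, model,
                          scale_branches, scale = 1) {
  p2 <- max(1e-6, 1 - p0 - p1)
  th <- c(log(kappa), stats::qlogis(min(omega0, 1 - 1e-8)),
          log(p0 / p2), log(p1 / p2))
  if (model == "alt") {
    th <- c(th, stats::qlogis(min(max((omega2 - 1) / 49, 1e-8), 1 - 1e-8)))
  }
  if (scale_branches) th <- c(th, log(scale))
  th
}

#' Fit the branch-site model by maximum likelihood
#'
#' Box-constrained maximisation of the Model A (or fixed-omega null)
#' log-likelihood with free parameters `kappa`, `omega0`, `p0`, `p1` and
#' (alternative only) `omega2` in `[1, 50]`; proportions are kept on the
#' simplex by a softmax transform and optimisation uses seeded multi-start
#' Nelder-Mead, keeping the best of `n_starts` runs. Branch lengths are held
#' fixed at the input tree's values unless `scale_branches = TRUE`, which
#' adds one global branch-length multiplier as a free parameter.
#'
#' @inheritParams model_log_likelihood
#' @param pi Codon frequencies; default: empirical F3x4 from the alignment.
#' @param n_starts Number of optimiser starts (default 3).
#' @param seed Integer seed controlling start jitter.
#' @param init Optional `branch_site_params` used as the first start (e.g.
#'   warm-starting the alternative fit from the null fit).
#' @param maxit,reltol Nelder-Mead control.
#' @param scale_branches Add a global branch-length scale parameter.
#' @return List with `params` ([branch_site_params()]), `lnL`, `convergence`
#'   (0 = converged), `branch_scale` and `model`.
#' @export
fit_branch_site <- function(codon_alignment, tree, focal,
                            model = c("alt", "null"), pi = NULL,
                            n_starts = 3, seed = 1, init = NULL,
                            maxit = 500, reltol = 1e-7,
                            scale_branches = FALSE) {
  model <- match.arg(model)
  if (is.null(pi)) pi <- empirical_f3x4(codon_alignment)
  .check_pi(pi)
  enc <- .bs_encode(codon_alignment, tree, focal)

  negll <- function(theta) {
    pp <- .bs_untransform(theta, model, scale_branches)
    clsll <- .class_site_loglik(enc, pp$kappa, pp$omega0, pp$omega2,
                                pp$p0, pp$p1, pi, pp$scale)
    p2 <- max(0, 1 - pp$p0 - pp$p1)
    wts <- c(pp$p0, pp$p1,
             p2 * pp$p0 / (pp$p0 + pp$p1), p2 * pp$p1 / (pp$p0 + pp$p1))
    -.mix_loglik(clsll, wts, enc$w)
  }

  # start set: package defaults, then (clamped) warm start, then a jittered
  # default. Warm-start proportions are pulled off the simplex corners so a
  # degenerate null fit cannot strand the simplex in extreme logit space.
  default <- list(kappa = 2, omega0 = 0.3, omega2 = 8, p0 = 0.6, p1 = 0.3)
  warm <- default
  if (!is.null(init)) {
    s0 <- max(init$p0, 0.05); s1 <- max(init$p1, 0.05)
    tot <- max(s0 + s1, 1e-6)
    if (tot > 0.95) { s0 <- 0.95 * s0 / tot; s1 <- 0.95 * s1 / tot }
    warm <- list(kappa = init$kappa, omega0 = min(max(init$omega0, 0.01), 0.99),
                 omega2 = max(init$omega2, 2.5), p0 = s0, p1 = s1)
  }
  starts <- list(default, warm,
                 list(kappa = 2, omega0 = 0.3, omega2 = 1.5, p0 = 0.6, p1 = 0.3))
  # staged multi-start: the first start runs the full simplex; later starts
  # are short exploratory runs, polished to full length only when they reach
  # the incumbent optimum
  best <- NULL
  for (s in seq_len(n_starts)) {
    b <- starts[[1 + (s - 1) %% length(starts)]]
    set.seed(seed + 7919L * (s - 1L))
    th0 <- .bs_transform(b$kappa, b$omega0,
                         if (model == "alt") b$omega2 else 1,
                         b$p0, b$p1, model, scale_branches)
    if (s > 2) th0 <- th0 + stats::rnorm(length(th0), 0, 0.4)
    it <- if (s == 1) maxit else max(100, ceiling(maxit / 5))
    fit <- stats::optim(th0, negll, method = "Nelder-Mead",
                        control = list(maxit = it, reltol = reltol))
    if (s > 1 && fit$value < best$value) {
      fit <- stats::optim(fit$par, negll, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pp <- .bs_untransform(best$par, model, scale_branches)
  params <- branch_site_params(pp$kappa, pp$omega0,
                               omega2 = if (model == "alt") pp$omega2 else 1,
                               p0 = pp$p0, p1 = pp$p1, pi = pi)
  list(params = params, lnL = -best$value, convergence = best$convergence,
       branch_scale = pp$scale, model = model)
}

#' Likelihood-ratio test for positive selection
#'
#' Computes the statistic `2 * (lnL_alt - lnL_null)` (clamped at 0) and its
#' upper-tail p-value from the chi-square distribution with one degree of
#' freedom. Setting `mixture = TRUE` uses the boundary-corrected 50:50
#' mixture of a point mass at 0 and chi-square(1) instead.
#'
#' @param lnL_alt,lnL_null Maximised log-likelihoods of the alternative and
#'   null models (`lnL_alt >= lnL_null - 1e-6`).
#' @param mixture Use the 50:50 mixture reference distribution.
#' @return List with `statistic` and `p`.
#' @export
#' @examples
#' lrt_pvalue(-1000, -1001.92)  # statistic 3.84, p ~ 0.05
lrt_pvalue <- function(lnL_alt, lnL_null, mixture = FALSE) {
  if (lnL_alt < lnL_null - 1e-6) {
    stop("lnL_alt < lnL_null: alternative fit did not reach the null optimum")
  }
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (stat == 0) 1 else 0.5 * p
  list(statistic = stat, p = min(1, p))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values, in the input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Numeric vector of q-values in `[0, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Naive empirical Bayes posteriors for foreground selection
#'
#' Per-site posterior probability of the positively selected classes (2a +
#' 2b) at the fitted parameter values: `P(class | site)` proportional to the
#' class proportion times the class site likelihood. Sites whose posterior
#' exceeds `cutoff` are the positively selected sites.
#'
#' @inheritParams model_log_likelihood
#' @param params Fitted alternative-model [branch_site_params()].
#' @param cutoff Posterior threshold for calling a selected site.
#' @return List with `posterior` (numeric per alignment column) and
#'   `selected_sites` (1-based column indices with posterior > cutoff).
#' @export
site_posteriors <- function(codon_alignment, tree, params, focal,
                            cutoff = 0.95) {
  enc <- .bs_encode(codon_alignment, tree, focal)
  clsll <- .class_site_loglik(enc, params$kappa, params$omega0,
                              params$omega2, params$p0, params$p1,
                              params$pi)
  wts <- .class_weights(params)
  mx <- apply(clsll, 2, max)
  num <- wts * exp(sweep(clsll, 2, mx))
  post <- sweep(num, 2, colSums(num), "/")
  fg <- colSums(post[3:4, , drop = FALSE])[enc$site_to_pattern]
  list(posterior = unname(fg), selected_sites = which(fg > cutoff))
}

#' Full branch-site test for one orthogroup
#'
#' Fits the fixed-omega null and the Model A alternative (warm-started from
#' the null), performs the LRT and computes NEB site posteriors.
#'
#' @inheritParams fit_branch_site
#' @param posterior_cutoff Posterior threshold for selected sites.
#' @param mixture Boundary-corrected LRT reference (see [lrt_pvalue()]).
#' @return List with `lnL_alt`, `lnL_null`, `statistic`, `p`, `params_alt`,
#'   `params_null`, `posterior`, `selected_sites`, `converged`.
#' @export
branch_site_test <- function(codon_alignment, tree, focal, pi = NULL,
                             n_starts = 3, seed = 1, maxit = 500,
                             posterior_cutoff = 0.95, mixture = FALSE,
                             scale_branches = FALSE) {
  if (is.null(pi)) pi <- empirical_f3x4(codon_alignment)
  fit0 <- fit_branch_site(codon_alignment, tree, focal, model = "null",
                          pi = pi, n_starts = n_starts, seed = seed,
                          maxit = maxit, scale_branches = scale_branches)
  fit1 <- fit_branch_site(codon_alignment, tree, focal, model = "alt",
                          pi = pi, n_starts = n_starts, seed = seed,
                          init = fit0$params, maxit = maxit,
                          scale_branches = scale_branches)
  # the null is nested in the alternative (omega2 = 1); numerical slack only
  lnL_alt <- max(fit1$lnL, fit0$lnL)
  lrt <- lrt_pvalue(lnL_alt, fit0$lnL, mixture = mixture)
  post <- site_posteriors(codon_alignment, tree, fit1$params, focal,
                          cutoff = posterior_cutoff)
  list(lnL_alt = fit1$lnL, lnL_null = fit0$lnL,
       statistic = lrt$statistic, p = lrt$p,
       params_alt = fit1$params, params_null = fit0$params,
       posterior = post$posterior, selected_sites = post$selected_sites,
       converged = fit1$convergence == 0 && fit0$convergence == 0)
}

#' Positive-selection signature
#'
#' A gene carries the positive-selection signature when its FDR-corrected
#' p-value is below `fdr` and at least one codon site has foreground
#' posterior above the cutoff.
#'
#' @param qvalues Numeric vector of BH q-values.
#' @param n_selected_sites Integer vector, number of sites with posterior
#'   above the cutoff, parallel to `qvalues`.
#' @param fdr FDR threshold (default 0.05).
#' @return Logical vector.
#' @export
selection_signature <- function(qvalues, n_selected_sites, fdr = 0.05) {
  stopifnot(length(qvalues) == length(n_selected_sites))
  qvalues < fdr & n_selected_sites >= 1
}
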