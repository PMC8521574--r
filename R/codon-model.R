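# GY94-style codon substitution model: rate matrix, transition probabilities
# and a reference Felsenstein pruning implementation over the 61 sense codons.

#' GY94 codon rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix of the Goldman-Yang codon
#' model: `q_ij = 0` for codon pairs differing at more than one nucleotide;
#' otherwise `q_ij = pi_j`, multiplied by `kappa` if the nucleotide change is
#' a transition and by `omega` if the amino acid changes (both factors can
#' apply). Diagonal entries make rows sum to zero and the matrix is rescaled
#' so that the expected substitution rate at stationarity,
#' `-sum(pi_i q_ii)`, equals 1 — branch lengths are then expected
#' substitutions per codon site.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (> 0).
#' @param pi Equilibrium codon frequencies: numeric vector of length 61
#'   summing to 1 (see [codon_freq_uniform()]).
#' In a multi-class (branch-site) mixture the scaling must be shared across
#' site classes so that high-omega classes evolve proportionally faster;
#' `scale = FALSE` returns the unscaled generator and [gy94_mean_rate()]
#' gives the stationary rate used to build such a shared factor.
#'
#' @param scale Rescale to mean rate 1 (default) or return the raw
#'   generator.
#' @return 61 x 61 numeric matrix with codon dimnames.
#' @export
#' @examples
#' Q <- codon_rate_matrix(kappa = 2, omega = 0.5, pi = codon_freq_uniform())
#' max(abs(rowSums(Q)))  # generator rows sum to 0
codon_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  stopifnot(kappa > 0, omega > 0)
  .check_pi(pi)
  tmpl <- .codon_template()
  n <- length(pi)
  Q <- matrix(0, n, n, dimnames = list(sense_codons(), sense_codons()))
  r <- pi[tmpl$jj]
  r[tmpl$ts] <- r[tmpl$ts] * kappa
  r[tmpl$ns] <- r[tmpl$ns] * omega
  Q[cbind(tmpl$ii, tmpl$jj)] <- r
  diag(Q) <- -rowSums(Q)
  if (scale) Q / sum(pi * -diag(Q)) else Q
}

#' Stationary substitution rate of the unscaled GY94 generator
#'
#' `sum_i pi_i * -q_ii` of the unscaled matrix — the factor by which
#' [codon_rate_matrix()] divides. The branch-site machinery divides all
#' class matrices by the single mixture rate
#' `(p0 + p2a) * gy94_mean_rate(kappa, omega0, pi) + (p1 + p2b) *
#' gy94_mean_rate(kappa, 1, pi)` (the background site-class mixture), so
#' branch lengths are expected substitutions per codon site averaged over
#' site classes and foreground-selected classes evolve faster.
#'
#' @inheritParams codon_rate_matrix
#' @return Positive scalar.
#' @export
gy94_mean_rate <- function(kappa, omega, pi) {
  tmpl <- .codon_template()
  r <- pi[tmpl$ii] * pi[tmpl$jj]
  r[tmpl$ts] <- r[tmpl$ts] * kappa
  r[tmpl$ns] <- r[tmpl$ns] * omega
  sum(r)
}

# shared scale of the Model A mixture: background-class-weighted mean rate
.mixture_rate_scale <- function(kappa, omega0, p0, p1, pi) {
  p2 <- max(0, 1 - p0 - p1)
  w0 <- p0 + p2 * p0 / (p0 + p1)  # classes with background omega0 (0, 2a)
  w1 <- p1 + p2 * p1 / (p0 + p1)  # classes with background omega 1 (1, 2b)
  w0 * gy94_mean_rate(kappa, omega0, pi) + w1 * gy94_mean_rate(kappa, 1, pi)
}

.check_pi <- function(pi) {
  if (length(pi) != 61L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("'pi' must be a positive vector over the 61 sense codons summing to 1")
  }
  invisible(TRUE)
}

#' Transition probability matrix of a reversible rate matrix
#'
#' Computes `P(t) = expm(Q t)` through the spectral decomposition of the
#' pi-symmetrised generator, which is exact for any time-reversible `Q` such
#' as the GY94 matrix.
#'
#' @param Q Rate matrix from [codon_rate_matrix()] (or any reversible
#'   generator with stationary distribution `pi`).
#' @param t Branch length (>= 0).
#' @param pi Stationary distribution of `Q`.
#' @return Stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix <- function(Q, t, pi) {
  stopifnot(t >= 0)
  d <- sqrt(pi)
  S <- Q * d * rep(1 / d, each = length(d))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  P <- (es$vectors / d) %*% (t(es$vectors) * exp(es$values * t) * rep(d, each = length(d)))
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Log-likelihood of one codon alignment column by pruning
#'
#' Reference (pure R) Felsenstein pruning for a single site: given one
#' transition matrix per branch, computes the log of the site likelihood
#' summed over root states weighted by `pi`. Gaps (`NA` states) are treated
#' as missing data (conditional vector of ones), so an all-gap column has
#' log-likelihood 0.
#'
#' @param pattern Integer vector of codon states (1..61, `NA` = gap) named
#'   by taxon, one entry per tip of `tree`.
#' @param tree A rooted `phylo` tree.
#' @param P_list List of transition matrices, one per row of `tree$edge`
#'   (same order).
#' @param pi Root state frequencies (length 61, sums to 1).
#' @return Log site likelihood (scalar).
#' @export
site_log_likelihood <- function(pattern, tree, P_list, pi) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  ntip <- length(tree$tip.label)
  if (is.null(names(pattern))) {
    if (length(pattern) != ntip) stop("unnamed 'pattern' must have one state per tip")
    states <- pattern
  } else {
    miss <- setdiff(tree$tip.label, names(pattern))
    if (length(miss)) stop("pattern missing taxa: ", paste(miss, collapse = ", "))
    states <- pattern[tree$tip.label]
  }
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(po$edge[, 1], po$edge[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  n <- length(pi)
  partial <- matrix(NA_real_, n, nnode)
  seen <- rep(FALSE, nnode)
  logscale <- 0
  for (k in seq_len(nrow(po$edge))) {
    pa <- po$edge[k, 1]; ch <- po$edge[k, 2]
    P <- P_list[[ord[k]]]
    if (ch <= ntip) {
      st <- states[ch]
      contrib <- if (is.na(st)) rep(1, n) else P[, st]
    } else {
      contrib <- P %*% partial[, ch]
    }
    mx <- max(contrib)
    if (mx > 0 && mx < 1e-6) {
      contrib <- contrib / mx
      logscale <- logscale + log(mx)
    }
    if (!seen[pa]) {
      partial[, pa] <- contrib
      seen[pa] <- TRUE
    } else {
      partial[, pa] <- partial[, pa] * contrib
    }
  }
  root <- ntip + 1L
  lik <- sum(pi * partial[, root])
  if (!is.finite(lik)) stop("non-finite site likelihood at root")
  log(lik) + logscale
}
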