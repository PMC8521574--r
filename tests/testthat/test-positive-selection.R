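# Codon threading, the Model A mixture likelihood, ML fitting, LRT, BH-FDR
# and NEB site posteriors.

test_that("codon threading maps CDS onto protein columns", {
  aln <- matrix(c("M", "A"), 1, 2, dimnames = list("t1", NULL))
  ca <- thread_codons(aln, c(t1 = "ATGGCT"))
  expect_equal(sense_codons()[ca[1, ]], c("ATG", "GCT"))

  gapped <- matrix(c("M", "-", "A"), 1, 3, dimnames = list("t1", NULL))
  ca2 <- thread_codons(gapped, c(t1 = "ATGGCTTAA"))  # terminal stop stripped
  expect_equal(sense_codons()[ca2[1, c(1, 3)]], c("ATG", "GCT"))
  expect_true(is.na(ca2[1, 2]))

  expect_error(thread_codons(aln, c(t1 = "ATGTAAGCT")), "internal stop")
  expect_error(thread_codons(aln, c(t1 = "ATGGTT")), "translation mismatch")
  expect_error(thread_codons(aln, c(t1 = "ATGGC")), "multiple of 3")
  expect_error(thread_codons(aln, c(other = "ATGGCT")), "no CDS")
})

sim_fixture <- function(seed, omega2 = 8, n_codons = 120) {
  tr <- fixed_tree_8()
  cfg <- sim_config(n_species = 8, n_codons = n_codons,
                    tree_source = ape::write.tree(tr), focal = "F",
                    outgroup = "O", omega2 = omega2, seed = seed)
  list(tree = tr, sim = simulate_orthogroup(cfg, tr))
}

test_that("the mixture likelihood is internally consistent", {
  fx <- sim_fixture(51, n_codons = 60)
  pi <- codon_freq_uniform()
  par1 <- branch_site_params(2, 0.2, omega2 = 1, p0 = 0.5, p1 = 0.3, pi = pi)

  # omega2 = 1 makes the alternative identical to the null
  expect_equal(model_log_likelihood(fx$sim$codon, fx$tree, par1, "alt", focal = "F"),
               model_log_likelihood(fx$sim$codon, fx$tree, par1, "null", focal = "F"),
               tolerance = 1e-12)

  # pattern compression is a pure optimisation
  par2 <- branch_site_params(2.3, 0.15, omega2 = 5, p0 = 0.4, p1 = 0.35, pi = pi)
  expect_equal(model_log_likelihood(fx$sim$codon, fx$tree, par2, "alt",
                                    focal = "F", compress = TRUE),
               model_log_likelihood(fx$sim$codon, fx$tree, par2, "alt",
                                    focal = "F", compress = FALSE),
               tolerance = 1e-10)
})

test_that("the engine matches a per-site pruning reference", {
  fx <- sim_fixture(52, n_codons = 50)
  tr <- fx$tree
  pi <- evosig:::empirical_f3x4(fx$sim$codon)
  par <- branch_site_params(1.8, 0.25, omega2 = 6, p0 = 0.5, p1 = 0.25, pi = pi)
  got <- model_log_likelihood(fx$sim$codon, tr, par, "alt", focal = "F")

  rs <- evosig:::.mixture_rate_scale(par$kappa, par$omega0, par$p0, par$p1, pi)
  Qs <- lapply(c(par$omega0, 1, par$omega2), function(w) {
    codon_rate_matrix(par$kappa, w, pi, scale = FALSE) / rs
  })
  fg_tip <- match("F", tr$tip.label)
  plist <- function(qb, qf) {
    lapply(seq_len(nrow(tr$edge)), function(e) {
      q <- if (tr$edge[e, 2] == fg_tip) Qs[[qf]] else Qs[[qb]]
      transition_matrix(q, tr$edge.length[e], pi)
    })
  }
  Ps <- list(plist(1, 1), plist(2, 2), plist(1, 3), plist(2, 3))
  w <- c(par$p0, par$p1, par$p2a, par$p2b)
  ref <- sum(vapply(seq_len(ncol(fx$sim$codon)), function(s) {
    pat <- fx$sim$codon[tr$tip.label, s]
    l <- vapply(Ps, function(P) site_log_likelihood(pat, tr, P, pi), 0)
    m <- max(l)
    m + log(sum(w * exp(l - m)))
  }, 0))
  expect_lt(abs(got - ref), 1e-6)
})

test_that("the likelihood is invariant to rerooting along a background branch", {
  fx <- sim_fixture(53, n_codons = 40)
  pi <- codon_freq_uniform()
  par <- branch_site_params(2, 0.2, omega2 = 4, p0 = 0.5, p1 = 0.3, pi = pi)
  l1 <- model_log_likelihood(fx$sim$codon, fx$tree, par, "alt", focal = "F")
  rerooted <- ape::root(ape::unroot(fx$tree), outgroup = "S4",
                        resolve.root = TRUE)
  l2 <- model_log_likelihood(fx$sim$codon, rerooted, par, "alt", focal = "F")
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("fits respect nesting and are deterministic", {
  fx <- sim_fixture(54, omega2 = 8, n_codons = 120)
  f0 <- fit_branch_site(fx$sim$codon, fx$tree, "F", model = "null", seed = 3)
  f1 <- fit_branch_site(fx$sim$codon, fx$tree, "F", model = "alt", seed = 3,
                        init = f0$params)
  expect_gte(f1$lnL, f0$lnL - 1e-6)
  f1b <- fit_branch_site(fx$sim$codon, fx$tree, "F", model = "alt", seed = 3,
                         init = f0$params)
  expect_identical(f1$lnL, f1b$lnL)
  expect_identical(f1$params$omega2, f1b$params$omega2)
})

test_that("under null data the foreground omega fits at its lower bound", {
  # 10 null simulations; omega2 should sit at (or near) the boundary in at
  # least half, the classic boundary behaviour of the branch-site LRT
  at_bound <- 0
  for (s in 1:10) {
    fx <- sim_fixture(60 + s, omega2 = 1, n_codons = 150)
    res <- branch_site_test(fx$sim$codon, fx$tree, "F", seed = 1)
    if (res$params_alt$omega2 < 1.2 || res$statistic < 1e-3) {
      at_bound <- at_bound + 1
    }
  }
  expect_gte(at_bound, 5)
})

test_that("LRT statistics map to chi-square(1) tails", {
  expect_equal(lrt_pvalue(-100, -100)$p, 1)
  expect_equal(lrt_pvalue(-100, -100)$statistic, 0)
  expect_equal(lrt_pvalue(-100, -100 - 3.841 / 2)$p, 0.05, tolerance = 1e-3)
  expect_equal(lrt_pvalue(-100, -100 - 6.635 / 2)$p, 0.01, tolerance = 1e-3)
  expect_error(lrt_pvalue(-105, -100), "did not reach")
  # boundary-corrected reference halves the tail
  expect_equal(lrt_pvalue(-100, -102, mixture = TRUE)$p,
               lrt_pvalue(-100, -102)$p / 2)
  expect_equal(lrt_pvalue(-100, -100, mixture = TRUE)$p, 1)
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("NEB posteriors vanish without selected classes and find planted sites", {
  fx <- sim_fixture(55, omega2 = 8, n_codons = 120)
  pi <- codon_freq_uniform()
  none <- branch_site_params(2, 0.2, omega2 = 8, p0 = 0.6, p1 = 0.4, pi = pi)
  post <- site_posteriors(fx$sim$codon, fx$tree, none, "F")
  expect_true(all(post$posterior == 0))
  expect_length(post$selected_sites, 0)

  # averaged over a few strong-selection fixtures, flagged sites are
  # predominantly truly selected
  hits <- 0; true_hits <- 0
  for (s in 1:6) {
    fx <- sim_fixture(70 + s, omega2 = 8, n_codons = 200)
    res <- branch_site_test(fx$sim$codon, fx$tree, "F", seed = 1)
    expect_true(all(res$posterior >= 0 & res$posterior <= 1))
    hits <- hits + length(res$selected_sites)
    true_hits <- true_hits +
      sum(fx$sim$truth$classes[res$selected_sites] %in% c("2a", "2b"))
  }
  expect_gt(hits, 0)
  expect_gte(true_hits / hits, 0.8)
})

test_that("the selection signature needs both the FDR and a selected site", {
  expect_identical(selection_signature(c(0.01, 0.01, 0.2), c(1, 0, 3)),
                   c(TRUE, FALSE, FALSE))
})
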