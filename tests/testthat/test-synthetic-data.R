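# Seeded codon-evolution generator: tree shape, event-count calibration,
# planted signals, gap injection and fixture serialisation.

test_that("simulated trees are rooted, binary, named and deterministic", {
  tr <- simulate_tree(3, seed = 1, mean_depth = 0.5)
  expect_true(ape::is.rooted(tr))
  expect_equal(length(tr$tip.label), 3)
  expect_equal(nrow(tr$edge), 4)
  expect_true(all(tr$edge.length > 0))

  expect_identical(ape::write.tree(simulate_tree(9, seed = 7)),
                   ape::write.tree(simulate_tree(9, seed = 7)))

  tr17 <- simulate_tree(17, seed = 3, mean_depth = 0.5)
  expect_equal(length(tr17$tip.label), 17)
  expect_equal(nrow(tr17$edge), 32)
  expect_true("outgrp" %in% tr17$tip.label)

  expect_error(simulate_tree(2, seed = 1), "too few taxa")
})

test_that("zero evolutionary time yields identical sequences", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  cfg <- sim_config(n_species = 4, n_codons = 40, focal = "A",
                    outgroup = "D", seed = 2)
  sim <- simulate_orthogroup(cfg, tr)
  expect_true(all(sim$codon == rep(sim$codon[1, ], each = 4)))
  expect_true(all(sim$protein == rep(sim$protein[1, ], each = 4)))
  expect_equal(sum(sim$truth$events_syn) + sum(sim$truth$events_nonsyn), 0)
})

test_that("event counts on a neutral branch match its length", {
  # single neutral class, kappa 1, uniform frequencies: the generator is
  # scaled to mean rate 1, so a branch of length 0.5 accumulates on average
  # 0.5 substitutions per codon site
  tr <- ape::read.tree(text = "((A:0.5,B:0):0,C:0);")
  cfg <- sim_config(n_species = 3, n_codons = 10000, focal = "A",
                    outgroup = "C", p0 = 0, p1 = 1, kappa = 1, seed = 11)
  sim <- simulate_orthogroup(cfg, tr)
  e <- which(sim$truth$edge_lengths > 0)
  expect_length(e, 1)
  rate <- sum(sim$truth$events_syn[e, ] + sim$truth$events_nonsyn[e, ]) / 10000
  expect_lt(abs(rate - 0.5) / 0.5, 0.05)
})

test_that("selected sites accumulate relatively more foreground nonsynonymous events", {
  tr <- fixed_tree_8()
  cfg <- sim_config(n_species = 8, n_codons = 400, focal = "F",
                    outgroup = "O", omega2 = 8,
                    tree_source = ape::write.tree(tr), seed = 4)
  sim <- simulate_orthogroup(cfg, tr)
  fg <- sim$truth$fg_edge
  sel <- sim$truth$classes %in% c("2a", "2b")
  frac_sel <- sum(sim$truth$events_nonsyn[fg, sel]) /
    max(1, sum(sim$truth$events_nonsyn[fg, sel] + sim$truth$events_syn[fg, sel]))
  cls0 <- sim$truth$classes == "0"
  frac0 <- sum(sim$truth$events_nonsyn[fg, cls0]) /
    max(1, sum(sim$truth$events_nonsyn[fg, cls0] + sim$truth$events_syn[fg, cls0]))
  expect_gt(frac_sel, frac0)
})

test_that("protein alignment is the codon translation at every stage", {
  for (seed in 1:3) {
    cfg <- sim_config(n_species = 8, n_codons = 60, focal = "sp01",
                      outgroup = "outgrp", n_planted_unique_sites = 3,
                      gap_rate = 0.05, seed = seed)
    sim <- simulate_orthogroup(cfg)
    expect_identical(evosig:::translate_codon_alignment(sim$codon), sim$protein)
    pl <- plant_unique_substitutions(sim$protein, "sp01", 3,
                                     seed = seed + 1, codon = sim$codon)
    expect_identical(evosig:::translate_codon_alignment(pl$codon), pl$protein)
    gp <- inject_gaps(pl$protein, 0.05, seed = seed + 2, codon = pl$codon)
    expect_identical(evosig:::translate_codon_alignment(gp$codon), gp$protein)
  }
})

test_that("planting respects its contract", {
  cfg <- sim_config(n_species = 8, n_codons = 80, focal = "sp01",
                    outgroup = "outgrp", mean_depth = 0.05, seed = 9)
  sim <- simulate_orthogroup(cfg)

  none <- plant_unique_substitutions(sim$protein, "sp01", 0, seed = 1)
  expect_identical(none$protein, sim$protein)
  expect_equal(nrow(none$planted), 0)

  pl <- plant_unique_substitutions(sim$protein, "sp01", 5, seed = 1)
  expect_equal(nrow(pl$planted), 5)
  for (cc in pl$planted$column) {
    bg <- pl$protein[setdiff(rownames(pl$protein), "sp01"), cc]
    expect_length(unique(bg), 1)
    expect_false(pl$protein["sp01", cc] == bg[1])
  }
  expect_error(plant_unique_substitutions(sim$protein, "sp01", 10000, seed = 1),
               "insufficient eligible columns")
})

test_that("gap injection is seeded, protected and binomial", {
  aln <- random_protein_alignment(10, 1000, gap_prob = 0)
  expect_identical(inject_gaps(aln, 0, seed = 1)$protein, aln)
  full <- inject_gaps(aln, 0.5, seed = 1,
                      protect_columns = seq_len(ncol(aln)))$protein
  expect_identical(full, aln)

  g <- inject_gaps(aln, 0.1, seed = 3)$protein
  n_gaps <- sum(g == "-")
  # binomial n = 10000, p = 0.1: 3 sd band
  expect_lt(abs(n_gaps - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_identical(inject_gaps(aln, 0.1, seed = 3)$protein, g)
})

test_that("fixture sets round-trip and are byte-identical across reruns", {
  cfgs <- lapply(1:3, function(i) {
    sim_config(n_species = 6, n_codons = 40, focal = "sp01",
               outgroup = "outgrp", n_planted_unique_sites = 2,
               gap_rate = 0.03, seed = 20 + i)
  })
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  man <- write_fixture_set(cfgs, d1)
  expect_length(man$orthogroups, 3)
  expect_length(man$orthogroups[[1]]$files, 4)

  fx <- read_fixture_orthogroup(d1, "OG0002")
  sim <- simulate_orthogroup(cfgs[[2]],
                             simulate_tree(6, cfgs[[1]]$seed, cfgs[[1]]$mean_depth))
  pl <- plant_unique_substitutions(sim$protein, "sp01", 2,
                                   seed = cfgs[[2]]$seed + 1, codon = sim$codon)
  expect_setequal(fx$truth$planted_columns, pl$planted$column)

  write_fixture_set(cfgs, d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})
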