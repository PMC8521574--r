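# Gap-aware masking, focal-unique calls and the alignment-derived impact
# score.

test_that("the mask covers gaps, unknowns and their flanks", {
  aln <- matrix("A", 3, 30, dimnames = list(c("a", "b", "f"), NULL))
  aln[2, 15] <- "-"
  m <- compute_gap_mask(aln, flank = 10)
  expect_equal(which(m), 5:25)

  clean <- matrix("L", 4, 12, dimnames = list(letters[1:4], NULL))
  expect_false(any(compute_gap_mask(clean)))

  xaln <- clean
  xaln[1, 6] <- "X"
  expect_equal(which(compute_gap_mask(xaln, flank = 2)), 4:8)

  # flank 0 masks exactly the gap/X columns
  g <- random_protein_alignment(5, 40, gap_prob = 0.1)
  expect_equal(compute_gap_mask(g, flank = 0),
               unname(colSums(g == "-" | g == "X") > 0))
})

test_that("masking is monotone in added gaps", {
  set.seed(1)
  for (r in 1:20) {
    aln <- random_protein_alignment(5, 50, gap_prob = 0.05)
    m1 <- compute_gap_mask(aln, flank = 10)
    aln[sample(5, 1), sample(50, 1)] <- "-"
    m2 <- compute_gap_mask(aln, flank = 10)
    expect_true(all(m2[m1]))
  }
})

test_that("unique-substitution calls require unanimous background", {
  aln <- matrix("A", 5, 9, dimnames = list(c("b1", "b2", "b3", "b4", "f"), NULL))
  aln["f", 3] <- "S"          # unanimous background, focal differs -> call
  aln["b1", 5] <- "T"          # background split -> no call
  aln["f", 5] <- "S"
  calls <- find_unique_substitutions(aln, "f")
  expect_equal(calls$column, 3)
  expect_equal(calls$focal_aa, "S")
  expect_equal(calls$background_aa, "A")
  expect_equal(calls$method, "sift_like")

  expect_error(find_unique_substitutions(aln, "nope"), "absent")

  # externally supplied scores override the alignment-derived one
  ext <- find_unique_substitutions(aln, "f",
                                   external_scores = data.frame(column = 3,
                                                                score = 0.5))
  expect_equal(ext$method, "external")
  expect_equal(ext$score, 0.5)
  expect_false(ext$impact)
})

test_that("impact score follows the normalised-probability formula", {
  aln <- matrix("L", 17, 3, dimnames = list(c(paste0("b", 1:16), "f"), NULL))
  expect_equal(impact_score(aln, 1, "f"), 1.0)

  aln["f", 2] <- "P"
  s <- impact_score(aln, 2, "f")
  expect_equal(s, (1 / 20) / 17 / ((16 + 1 / 20) / 17), tolerance = 1e-12)
  expect_equal(s, 0.05 / 16.05, tolerance = 1e-12)
  expect_lt(s, 0.05)

  split <- matrix(c(rep("L", 8), rep("I", 8), "I"), 17, 1,
                  dimnames = list(c(paste0("b", 1:16), "f"), NULL))
  expect_equal(impact_score(split, 1, "f"), 1.0)

  gapped <- aln
  gapped["b1", 3] <- "-"
  expect_error(impact_score(gapped, 3, "f"), "masked")
})

test_that("impact score is insensitive to duplicating the background", {
  aln <- matrix(c(rep("L", 12), rep("M", 4), "P"), 17, 1,
                dimnames = list(c(paste0("b", 1:16), "f"), NULL))
  s1 <- impact_score(aln, 1, "f")
  dup <- rbind(aln[1:16, , drop = FALSE], aln)
  rownames(dup) <- c(paste0("c", 1:16), paste0("b", 1:16), "f")
  s2 <- impact_score(dup, 1, "f")
  expect_lt(abs(s1 - s2), 0.01)
})

test_that("the gene-level signature needs one impactful call", {
  empty <- find_unique_substitutions(
    matrix("A", 4, 5, dimnames = list(letters[1:4], NULL)), "a")
  expect_false(unique_substitution_signature(empty))
  expect_true(unique_substitution_signature(
    data.frame(impact = c(FALSE, TRUE))))
  expect_false(unique_substitution_signature(
    data.frame(impact = c(FALSE, FALSE))))
})
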