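# Orthogroup table parsing, completeness and fuzzy one-to-one filters,
# longest-gene representatives, supermatrix trimming and the NJ fallback.

panel4 <- species_panel(c("A", "B", "C", "D"), focal = "A", outgroup = "D")

write_og_table <- function(rows, species = c("A", "B", "C", "D")) {
  path <- tempfile(fileext = ".tsv")
  header <- paste(c("Orthogroup", species), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

make_og <- function(id, counts) {
  members <- lapply(names(counts), function(sp) {
    if (counts[[sp]] == 0) character(0)
    else paste0(sp, "_", id, "_g", seq_len(counts[[sp]]))
  })
  names(members) <- names(counts)
  structure(list(id = id, members = members), class = "orthogroup")
}

test_that("orthogroup tables parse with empty cells and strict gene uniqueness", {
  p <- write_og_table(c("OG1\ta1\tb1,b2\tc1\td1", "OG2\ta2\t\tc2\td2"))
  ogs <- parse_orthogroup_table(p, panel4)
  expect_length(ogs, 2)
  expect_equal(ogs[[1]]$members$B, c("b1", "b2"))
  expect_equal(ogs[[2]]$members$B, character(0))

  bad <- write_og_table(c("OG1\ta1\tb1\tc1\td1"), species = c("A", "B", "C"))
  expect_error(parse_orthogroup_table(bad, panel4), "missing species column: D")

  extra <- write_og_table(c("OG1\ta1\tb1\tc1\td1\te1"),
                          species = c("A", "B", "C", "D", "E"))
  expect_error(parse_orthogroup_table(extra, panel4), "not in panel: E")

  dup <- write_og_table(c("OG1\ta1\tb1\tc1\td1", "OG2\ta1\tb2\tc2\td2"))
  expect_error(parse_orthogroup_table(dup, panel4), "duplicate gene ID")
})

test_that("all-species filter matches explicit membership checking", {
  ogs <- list(make_og("OG1", c(A = 1, B = 1, C = 1, D = 1)),
              make_og("OG2", c(A = 1, B = 0, C = 1, D = 1)),
              make_og("OG3", c(A = 2, B = 1, C = 3, D = 1)))
  kept <- filter_all_species(ogs, panel4)
  expect_equal(vapply(kept, function(o) o$id, ""), c("OG1", "OG3"))
  expect_identical(filter_all_species(kept, panel4), kept)

  set.seed(42)
  for (r in 1:100) {
    ogs <- lapply(1:6, function(i) {
      make_og(paste0("R", r, "OG", i),
              setNames(sample(0:3, 4, replace = TRUE), c("A", "B", "C", "D")))
    })
    kept <- filter_all_species(ogs, panel4)
    manual <- Filter(function(og) {
      ok <- TRUE
      for (sp in c("A", "B", "C", "D")) {
        if (length(og$members[[sp]]) == 0) ok <- FALSE
      }
      ok
    }, ogs)
    expect_identical(kept, manual)
  }
})

test_that("fuzzy one-to-one rule follows the stated thresholds", {
  keep1 <- make_og("K1", c(A = 1, B = 1, C = 1, D = 1))
  keep2 <- make_og("K2", c(A = 1, B = 1, C = 1, D = 2))  # 3/4 = 0.75
  rej1 <- make_og("R1", c(A = 2, B = 2, C = 1, D = 1))   # 0.5 < 0.75
  rej2 <- make_og("R2", c(A = 1, B = 1, C = 1, D = 4))   # copy cap
  out <- select_fuzzy_one_to_one(list(keep1, keep2, rej1, rej2), panel4)
  expect_equal(vapply(out, function(o) o$id, ""), c("K1", "K2"))
  expect_identical(select_fuzzy_one_to_one(out, panel4), out)
  expect_error(select_fuzzy_one_to_one(list(keep1), panel4, fuzziness = 1.2),
               "fuzziness")
})

test_that("representatives are the longest gene with lexicographic ties", {
  og <- make_og("OG9", c(A = 2, B = 1, C = 2, D = 1))
  seqs <- c(A_OG9_g1 = strrep("M", 100), A_OG9_g2 = strrep("M", 150),
            B_OG9_g1 = "MKL",
            C_OG9_g2 = strrep("A", 80), C_OG9_g1 = strrep("C", 80),
            D_OG9_g1 = "MW")
  rep <- pick_representatives(og, panel4, seqs)
  expect_equal(unname(rep["A"]), "A_OG9_g2")   # longest
  expect_equal(unname(rep["B"]), "B_OG9_g1")   # single gene
  expect_equal(unname(rep["C"]), "C_OG9_g1")   # tie -> smallest ID
  og_empty <- structure(list(id = "OG9",
    members = list(A = "A_OG9_g1", B = character(0),
                   C = "C_OG9_g1", D = "D_OG9_g1")), class = "orthogroup")
  expect_error(pick_representatives(og_empty, panel4, seqs), "no gene")
})

test_that("supermatrix trims empty sites and concatenates in order", {
  a1 <- matrix(sample(c("A", "C", "D"), 40, TRUE), 4, 10,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  a2 <- matrix(sample(c("E", "F", "G"), 80, TRUE), 4, 20,
               dimnames = list(c("D", "C", "B", "A"), NULL))
  sm <- build_supermatrix(list(x = a1, y = a2), panel4)
  expect_equal(ncol(sm), 30)
  expect_equal(attr(sm, "partitions")$end, c(10, 30))

  a1[, 3] <- "-"; a1[, 7] <- "-"
  sm2 <- build_supermatrix(list(x = a1, y = a2), panel4)
  expect_equal(ncol(sm2), 28)
  expect_false(any(colSums(sm2 != "-") == 0))

  sm_rev <- build_supermatrix(list(y = a2, x = a1), panel4)
  expect_equal(ncol(sm_rev), ncol(sm2))
  expect_equal(attr(sm_rev, "partitions")$name, c("y", "x"))

  rownames(a2)[1] <- "Z"
  expect_error(build_supermatrix(list(a1, a2), panel4), "do not match")
})

test_that("NJ fallback handles identical sequences and recovers clear topologies", {
  ident <- matrix("A", 3, 50, dimnames = list(c("A", "B", "D"), NULL))
  tr <- nj_tree(ident, panel4)
  expect_true(all(tr$edge.length == 0))

  # two clearly separated pairs: (A,B) vs (C,D)
  base <- sample(c("A", "C", "D", "E"), 200, TRUE)
  m <- rbind(A = base, B = base, C = base, D = base)
  m["A", 1:5] <- "F"
  m["B", 6:10] <- "G"
  m[c("C", "D"), 11:60] <- "H"
  m["C", 61:65] <- "I"
  m["D", 66:70] <- "K"
  tr <- nj_tree(m, panel4)
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.monophyletic(tr, c("A", "B")))

  sat <- rbind(A = rep("A", 10), B = rep("C", 10), C = rep("A", 10),
               D = rep("A", 10))
  expect_error(nj_tree(sat, panel4), "distance cap")
  expect_error(nj_tree(ident[1:3, ],
                       species_panel(c("A", "B", "D", "Q"), "A", "Q")),
               "outgroup")
})
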