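# Fixture sets: simulated orthogroups written to disk in the formats the
# analysis consumes (aligned protein FASTA, unaligned CDS FASTA, newick
# trees, an OrthoFinder-style TSV) plus ground-truth JSON per orthogroup.

#' Write a set of synthetic orthogroup fixtures
#'
#' For each configuration, simulates a codon alignment along the shared
#' species tree, plants focal-unique substitutions, injects gaps (planted
#' columns and their clearance flanks are protected), and writes per
#' orthogroup: the aligned protein FASTA, the unaligned CDS FASTA, the true
#' gene tree (newick) and the truth labels (JSON). A single orthogroup
#' membership TSV, the species tree and a JSON manifest are written at the
#' top level. Gene IDs are `<orthogroup>_<species>`.
#'
#' @param configs List of [sim_config()] objects (one per orthogroup); all
#'   must share the focal/outgroup naming of the species tree.
#' @param out_dir Output directory (created if needed).
#' @param tree Shared species tree; simulated from the first config when
#'   `NULL`.
#' @return The manifest (invisibly written to `manifest.json`): orthogroup
#'   IDs, per-orthogroup file lists, species table, seeds.
#' @export
write_fixture_set <- function(configs, out_dir, tree = NULL) {
  stopifnot(length(configs) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  if (is.null(tree)) {
    cfg1 <- configs[[1]]
    tree <- if (is.null(cfg1$tree_source)) {
      simulate_tree(cfg1$n_species, cfg1$seed, cfg1$mean_depth)
    } else {
      ape::read.tree(text = cfg1$tree_source)
    }
  }
  species <- tree$tip.label
  ape::write.tree(tree, file.path(out_dir, "species_tree.nwk"))

  og_ids <- sprintf("OG%04d", seq_along(configs))
  rows <- list()
  entries <- list()
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    og <- og_ids[k]
    sim <- simulate_orthogroup(cfg, tree)
    pl <- plant_unique_substitutions(sim$protein, cfg$focal,
                                     cfg$n_planted_unique_sites,
                                     seed = cfg$seed + 1L, codon = sim$codon)
    protect <- integer(0)
    if (nrow(pl$planted)) {
      protect <- unique(unlist(lapply(pl$planted$column, function(cc) {
        max(1L, cc - cfg$gap_flank_clearance):
          min(ncol(pl$protein), cc + cfg$gap_flank_clearance)
      })))
    }
    gp <- inject_gaps(pl$protein, cfg$gap_rate, seed = cfg$seed + 2L,
                      protect_columns = protect, codon = pl$codon)

    genes <- setNames(paste0(og, "_", species), species)
    prot_seq <- setNames(apply(gp$protein, 1, paste, collapse = "")[species],
                         genes[species])
    codons61 <- sense_codons()
    cds_seq <- setNames(vapply(species, function(sp) {
      idx <- gp$codon[sp, ]
      paste(codons61[idx[!is.na(idx)]], collapse = "")
    }, ""), genes[species])

    files <- list(protein = paste0(og, "_protein.faa"),
                  cds = paste0(og, "_cds.fna"),
                  tree = paste0(og, "_tree.nwk"),
                  truth = paste0(og, "_truth.json"))
    write_fasta(prot_seq, file.path(out_dir, files$protein), type = "AA")
    write_fasta(cds_seq, file.path(out_dir, files$cds), type = "DNA")
    ape::write.tree(tree, file.path(out_dir, files$tree))
    truth <- list(orthogroup = og,
                  classes = sim$truth$classes,
                  planted_columns = pl$planted$column,
                  planted = pl$planted,
                  focal_accelerated = sim$truth$focal_accelerated,
                  focal_rate_multiplier = cfg$focal_rate_multiplier,
                  omega2 = cfg$omega2,
                  params = sim$truth$params,
                  seed = cfg$seed)
    jsonlite::write_json(truth, file.path(out_dir, files$truth),
                         auto_unbox = TRUE, digits = NA)
    rows[[k]] <- c(Orthogroup = og, genes[species])
    entries[[k]] <- list(orthogroup = og, files = files)
  }
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  write.table(tab, file.path(out_dir, "orthogroups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(species = species,
                   focal = configs[[1]]$focal,
                   outgroup = configs[[1]]$outgroup,
                   species_tree = "species_tree.nwk",
                   orthogroup_table = "orthogroups.tsv",
                   orthogroups = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read one fixture orthogroup back
#'
#' @param dir Fixture directory written by [write_fixture_set()].
#' @param orthogroup Orthogroup ID (e.g. `"OG0001"`).
#' @return List with `protein` (alignment matrix, rows renamed to species),
#'   `cds` (named by species), `tree` and `truth`.
#' @export
read_fixture_orthogroup <- function(dir, orthogroup) {
  prot <- read_protein_alignment(file.path(dir, paste0(orthogroup, "_protein.faa")))
  rownames(prot) <- sub(paste0("^", orthogroup, "_"), "", rownames(prot))
  cds <- read_fasta(file.path(dir, paste0(orthogroup, "_cds.fna")), type = "DNA")
  names(cds) <- sub(paste0("^", orthogroup, "_"), "", names(cds))
  tree <- ape::read.tree(file.path(dir, paste0(orthogroup, "_tree.nwk")))
  truth <- jsonlite::read_json(file.path(dir, paste0(orthogroup, "_truth.json")),
                               simplifyVector = TRUE)
  list(protein = prot, cds = cds, tree = tree, truth = truth)
}
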