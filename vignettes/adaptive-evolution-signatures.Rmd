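---
title: "Detecting signatures of adaptive evolution in orthogroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting signatures of adaptive evolution in orthogroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evosig)
```

# The analysis

`evosig` screens a panel of species for genes in which one focal lineage
shows evidence of adaptive protein evolution. Starting from orthogroups
(gene families descending from a single ancestral gene), per-orthogroup
protein alignments, coding sequences and a rooted species tree, it computes
three independent signatures for the focal species and intersects them:

1. **Unique amino acid substitutions with functional impact** — alignment
   columns where every non-focal species carries one identical residue and
   the focal species a different one, scored for predicted impact.
2. **Elevated root-to-tip divergence** — the focal gene's root-to-tip
   branch-length distance on the orthogroup gene tree exceeds that of every
   other species.
3. **Positive selection** — a branch-site codon-model likelihood-ratio test
   on the focal terminal branch, with FDR correction across orthogroups and
   empirical-Bayes identification of the selected codon sites.

Genes carrying at least two of the three signatures are reported as showing
*multiple signs of adaptive evolution* (MSA genes — the acronym is the
field's term for this intersection, unrelated to multiple sequence
alignment). The package also contains a full generative counterpart: a
seeded codon-evolution simulator that produces orthogroup fixtures with
planted signals and ground-truth labels, which is how the analysis is
validated end to end.

# Orthogroup filtering

The analysis unit is the orthogroup set restricted in two steps:

* **all-species completeness** — at least one gene from every panel species;
* **fuzzy one-to-one selection** — at least a fraction `fuzziness` (default
  0.75) of species contribute exactly one gene and no species contributes
  more than `max_copies` (default 3).

Where a species contributes several genes, the longest protein is taken as
its representative; length ties break to the lexicographically smallest
gene ID so the choice is reproducible. "Fuzzy one-to-one" has no single
canonical definition; the defaults here mirror the commonly used
KinFin-style fuzziness threshold and both knobs are exposed.

For species-tree work the filtered alignments can be concatenated with
`build_supermatrix()`, which first removes columns that are gaps in every
taxon (empty sites) and records partition boundaries. Maximum-likelihood
tree inference is deliberately out of scope: the pipeline accepts a user
tree (preferred) and otherwise falls back to neighbor joining on
Poisson-corrected protein distances `d = -ln(1 - p)`, with `p` the mismatch
fraction over mutually ungapped sites — a deterministic, desk-scale
stand-in whose negative branch-length artifacts are clamped to zero. The
NJ tree is rooted on the panel outgroup with the root placed at the
midpoint of the outgroup's pendant edge: rooting at the attachment node
would credit the outgroup its entire (typically long) branch as
root-to-tip distance and systematically dominate divergence comparisons.

# Unique substitutions and the impact score

Columns are first masked by `compute_gap_mask()`: a column is excluded when
any taxon has a gap there or within `flank = 10` columns on either side.
The per-column (any-taxon) reading of the flank rule is the stricter of the
two possible interpretations, and unknown residues (`X`) are treated as
gap-equivalent because an unknown cannot certify background identity.
Columns where the focal residue is itself a gap are masked by the same
rule.

The impact score is a SIFT-style normalised probability computed from the
orthogroup alignment itself: with residue counts `c(a)` over the `N`
non-focal taxa and pseudocount `pc = 1`,

`p(a) = (c(a) + pc/20) / (N + pc)`, `score = p(focal) / max_a p(a)`.

Scores below 0.05 — the canonical deleterious cutoff — set the impact flag.
Output tables label the method `sift_like`; externally computed SIFT calls
can be substituted in downstream tables when a reference database is
available. A gene carries the signature when at least one call is
impactful.

# Root-to-tip divergence

`root_to_tip_distances()` sums branch lengths from the root to each leaf of
the orthogroup gene tree (supplied, or the NJ fallback, rooted on the
panel outgroup). The flag compares the focal distance with the others in
one of two modes:

* `max` (default): focal distance strictly exceeds `ratio` (default 1)
  times the largest non-focal distance — the most conservative
  parameter-free reading of "comparatively higher";
* `zscore`: focal z-score against the non-focal mean/sd exceeds `z`
  (default 2); with zero non-focal spread the statistic is reported as an
  infinity sentinel and the flag falls back to the mean comparison.

Both the statistic and the flag are reported so the sensitivity of the
choice can be audited. Distances are computed on whatever alignment type is
supplied; the package makes no attempt to convert between nucleotide and
protein branch-length scales.

# The branch-site test

The positive-selection test is the branch-site "Model A" likelihood-ratio
test. Sites fall into four classes: class 0 evolves with dN/dS `omega0 <= 1`
on all branches, class 1 with `omega = 1`, and classes 2a/2b take their
background omega (`omega0` or 1) everywhere except the foreground branch —
the focal species' terminal branch — where they take `omega2 >= 1`. The
null model fixes `omega2 = 1`; the alternative frees it. Twice the
log-likelihood difference is referred to a chi-square distribution with one
degree of freedom (the 50:50 boundary mixture is available via
`mixture = TRUE`), p-values are FDR-corrected across orthogroups by
Benjamini–Hochberg, and a gene is called positively selected when its
q-value is below 0.05 **and** at least one site has posterior probability
above 0.95 of belonging to the selected classes.

Implementation choices that matter:

* **Rate matrix.** GY94: single-nucleotide codon moves at rate
  `pi_j * kappa^[transition] * omega^[nonsynonymous]` over the 61 sense
  codons. Within the mixture all class matrices share one scale factor —
  the background-class-weighted mean rate — so branch lengths are expected
  substitutions per codon site averaged over site classes and selected
  classes evolve proportionally faster on the foreground branch. Codon
  frequencies default to F3x4 estimated from the data (with a half-count
  nucleotide pseudo-observation to keep frequencies positive); uniform
  frequencies are available for controlled experiments.
* **Likelihood.** Felsenstein pruning over the 61 codon states, implemented
  in compiled code with per-node rescaling against underflow; gaps are
  missing data (conditional vector of ones). Site patterns are compressed
  and weighted. Because classes 2a/2b differ from 0/1 only on the
  foreground edge, their likelihoods re-propagate only the foreground-to-
  root path of the stored background pass.
* **Optimisation.** Free parameters `kappa`, `omega0`, `p0`, `p1` (and
  `omega2` in `[1, 50]` for the alternative) are fitted by Nelder-Mead on
  transformed coordinates (log, logit, softmax). Multi-start with 3 seeded
  starts: the first runs the full simplex (`maxit = 500`,
  relative tolerance 1e-7) and later starts run short exploratory simplexes
  that are polished to full length when they beat the incumbent; the
  alternative fit is warm-started from the null fit with its proportions
  pulled off simplex corners. Refits with the same seed are bit-identical.
* **Branch lengths** are held fixed at the input tree's values. This keeps
  the per-orthogroup fit identifiable and fast on short alignments;
  `scale_branches = TRUE` adds a single global branch-length multiplier as
  a middle ground. Full per-branch re-estimation is out of scope.
* **Site posteriors** use naive empirical Bayes at the MLE (posterior of a
  class proportional to its proportion times its site likelihood; reported
  posterior = P(2a) + P(2b)). The Bayes empirical Bayes prior-integration
  grid is not implemented; output columns are named accordingly.

# The synthetic-data generator

`simulate_orthogroup()` is the exact generative counterpart of the fitted
model: sites are assigned to the four classes, a root codon is drawn from
the equilibrium frequencies, and each site evolves along each branch by
Gillespie event sampling under the same shared-scale GY94 matrices used by
the likelihood. Event sampling (rather than sampling from matrix
exponentials) means the simulator keeps an exact per-site, per-branch count
of synonymous and nonsynonymous events, which the test suite uses as an
oracle — e.g. a neutral branch of length 0.5 must accumulate 0.5
substitutions per site on average.

Planted signals:

* **unique substitutions** — in columns that are gap-free and invariant
  across the non-focal taxa, the focal residue (and codon) is replaced by a
  different residue;
* **rate acceleration** — the focal terminal branch length is multiplied by
  `focal_rate_multiplier` during simulation;
* **foreground selection** — classes 2a/2b simulated with `omega2 > 1`.

Gaps are injected per (taxon, column) cell independently with probability
`gap_rate`; planted columns and a `gap_flank_clearance` (default 10, the
mask flank) neighbourhood around them are protected so planted signals
remain recoverable after masking. Simulated species trees are coalescent
ultrametric with a configurable root-to-tip depth (in expected
substitutions per codon site), the outgroup attached at the root.

What the generator does *not* emulate: realistic indel evolution (gaps are
independent cells, not indel tracts), alignment error, sequencing error,
among-site synonymous-rate variation, and gene-tree/species-tree
discordance. Passing tests therefore demonstrate correctness of the
inference machinery under the model's own assumptions, not robustness to
real-data violations of them.

Default generator settings (17 species, 200–300 codons, root-to-tip depth
0.4–0.5, `kappa = 2`, `omega0 = 0.2`, `p0 = 0.45`, `p1 = 0.30`) were chosen
once as plausible for a plant ortholog panel: moderately conserved proteins
with about a quarter of sites in the potentially selected classes, and
branch lengths deep enough to be informative without saturating.

# Validation design and problem sizes

The test suite validates each layer against an independent oracle:
exhaustive enumeration over internal-node states for the pruning engine
(3–4-taxon trees, where 61^3 assignments are tractable); brute-force column
scans for the gap mask; parent-pointer path sums for root-to-tip distances;
textbook step-up for BH; explicit set algebra for the MSA intersection. The
operating characteristics of the LRT are measured by simulation at a fixed
8-taxon geometry with a foreground branch of 0.3 and 300 codons: 100 null
replicates (rejection rate must stay within two binomial standard errors of
the 5% level — the boundary makes chi-square(1) conservative, so observed
rates are typically 1–3%) and 100 replicates at `omega2 = 8` (rejection
rate at least 60%; observed power is substantially higher). End-to-end
determinism is checked by running the full pipeline twice on 20 synthetic
orthogroups and comparing file checksums.

Divergence-flag recall is measured on a balanced ultrametric fixture tree
(8 ingroup species plus the outgroup, depth 0.3, terminal branches a
quarter of the ingroup depth, 250 codons): on a balanced clock-like tree
every species has the same baseline root-to-tip distance, so the planted
focal rate acceleration is the only signal and recall measures the
detector rather than the luck of a randomly drawn (possibly near-zero)
focal terminal branch. Planted-unique-substitution recovery likewise uses
shallow-divergence fixtures with a zero-length focal branch, under which
the planted columns are provably the only focal-unique columns. These
sizes keep the suite informative at desk scale while exercising every code
path.

# Known limitations

* NEB (not BEB) site posteriors; with few sites and weak signal NEB is
  known to be anti-conservative.
* Branch lengths fixed to the input tree (optionally globally rescaled),
  not re-estimated per orthogroup.
* The NJ fallback tree is a convenience, not a substitute for ML gene
  trees; saturated distance pairs (`p = 1`) are an error rather than being
  capped.
* One focal gene per orthogroup is tested (the species representative);
  paralog-specific tests within fuzzy orthogroups are not attempted.
* The impact score is computed from the orthogroup alignment alone; it
  approximates, but is not, a database-backed SIFT prediction.
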