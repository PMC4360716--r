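---
title: "Methods: models, parameters and design choices in viroclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in viroclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`viroclade` packages the computational workflow for characterising an
uncultivated phage group from virome-assembled contigs: marker-gene
screening, distance phylogenetics with clade delineation, gene-content
comparison with a tree-concordance test, read recruitment,
composition-based host prediction, CRISPR-spacer matching, and counting
dN/dS. This vignette is the package's own account of the underlying
models, the parameters that matter, the numerical conventions, and the
limits of what its synthetic benchmark can show.

## Alignment and score statistics

Pairwise similarity everywhere in the package is exact affine-gap
Smith–Waterman local alignment (Biostrings' dynamic programming), not a
heuristic seed-and-extend search. Raw scores are converted with the
Karlin–Altschul formulas

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'},$$

with the standard gapped BLOSUM62 constants $\lambda = 0.267$,
$K = 0.041$ for proteins (gap open 11, extend 1) and $\lambda = 0.625$,
$K = 0.41$ for nucleotides (match +2, mismatch −3, gap open 5, extend
2). Three conventions to be aware of:

* The search space is **per pair** ($m \times n$), not database-wide.
  The workflow applies fixed thresholds (bit > 50, E < 10⁻³) rather
  than calibrated database statistics, so the per-pair convention is
  the simplest faithful choice; the constants are fields of
  `scoring_scheme()` and can be changed.
* A pair whose optimal local score is negative is reported as score 0
  with an empty alignment.
* Because both the raw optimal score and $mn$ are symmetric in the two
  sequences, hit qualification is symmetric; the all-vs-all gene
  comparison exploits this and computes only one triangle, using
  score-only alignments (no traceback) as a prefilter and full
  alignments only for qualifying pairs.

Progressive multiple alignment (`progressive_msa()`) is delegated to
the `mafft` executable — itself a guide-tree progressive aligner — for
three or more sequences; two sequences are aligned by exact global
Needleman–Wunsch so the two-row case coincides with the optimal
pairwise alignment; placement of candidates into a fixed reference
column space (`align_to_reference()`, used by the domain check) uses
`mafft --add --keeplength`, which discards candidate-specific
insertions. Manual curation of alignments is out of scope; trimming
coordinates are explicit arguments.

## Marker screening and the domain rule

A gene receives at most one marker label: the reference set giving its
best qualifying bit score; ties go to the alphabetically first
reference id. Screening applies two published selection rules: contigs
must be at least `min_contig_len` (default 10,000 bp), and a candidate
major capsid protein must *display both domain regions* of the
reference alignment. "Displaying" a domain is operationalised as at
least `min_domain_cov` (default 0.8) of the columns in the region being
non-gap in the candidate row, with the region boundaries given as
reference-MSA columns (defaults 122–162 and 735–766, the published
coordinates). The 80% coverage default is a design choice — the source
analysis gives coordinates but no coverage rule — chosen to be robust
to ragged alignment edges; it is configurable and the check is monotone
in coverage.

## Trees, supports, clades

Tree inference is neighbor joining on p-distances (mismatches over
shared non-gap columns; disjoint-coverage pairs get distance 1 and are
flagged). NJ replaces maximum-likelihood inference deliberately: the
downstream logic — support-based collapsing, clade delineation, RF
comparisons — is inference-agnostic, and `read_newick()` accepts
externally computed trees wherever a tree is consumed. Negative NJ
branch lengths are clamped to zero. Bootstrap supports are percentages
of column-resampled replicates containing each bipartition,
deterministic under a seed.

`collapse_low_support()` contracts internal edges with support strictly
below the threshold (support exactly 50 is kept, matching the strict
"lower than" reading). Implementation note: collapsing works by zeroing
the low-support edge lengths and merging zero-length dichotomies, so
retained edges shorter than 10⁻⁸ are first raised to 10⁻⁸.

`delineate_clades()` reports the maximal rooted subtrees with support ≥
`min_support` (default 80) whose leaves are all queries and which have
at least two leaves, in preorder. In the pipeline the marker tree
contains three kinds of leaves: screened query proteins, *designated
reference* leaves (the known members of the group of interest), and
*distant references* (relatives outside the group). Queries and
designated references are both eligible for clade membership; the
distant references bound the clades from above. This realises
phylogenetic placement ("near the known members on the tree") as clade
co-membership with designated references. With only queries in the
tree the rule would necessarily merge sister clades — the subtree
joining them is all-query and well supported — which is why the
reference tiers exist.

Rooting in the pipeline is midpoint rooting (with supports transferred
as edge properties); `root_with_outgroup()` is available when an
outgroup is known and places the root at the midpoint of the edge
separating a monophyletic outgroup.

## The concordance test

Whether gene content recapitulates the marker phylogeny is tested with
a Robinson–Foulds leaf-permutation test. The observed statistic is the
RF distance (symmetric difference of non-trivial bipartitions, on the
common leaf set) between the marker tree and the gene-content
dendrogram, heights ignored — RF is topology-only, so the dendrogram is
converted to a tree by dropping heights. The null distribution is the
RF distance to the dendrogram with leaf labels uniformly permuted.
Three p-values are reported:

* `p_empirical` $= (1 + \#\{\text{null} \le \text{obs}\})/(B+1)$ —
  valid but conservative, floor $1/(B+1)$;
* `p_normal` — lower tail of the normal approximation from the null
  mean and SD, which can go far below the empirical floor (this is how
  an astronomically small p-value can honestly be reported from 1000
  permutations);
* `p_randomized` — the tie-randomized empirical p. RF on permuted
  trees is discrete with a large atom at the maximum $2(n-3)$, so
  `p_empirical` is super-uniform rather than uniform under the null;
  the tie-randomized version is exactly uniform and is the quantity
  used for calibration checks (verified by a Kolmogorov–Smirnov test
  over 200 independent null pairs).

## Gene content

The proportion of genes shared by two contigs is the number of genes of
the smaller gene complement with a qualifying hit in the other contig,
divided by that smaller gene count. The "shortest contig" denominator
is read as a gene count, not base pairs — a gene count divided by a bp
length would not be a proportion. Clustering of $1-P$ uses complete
linkage, the default of the heatmap tool the original analysis cites.
Gene novelty has precedence reference-affiliated > group-only > unique,
with self-contig hits never counting toward group-only. Synteny blocks
tile one contig into 500-bp windows, locally align each window to the
other contig, and chain collinear adjacent window hits — Biostrings
reports a single optimal local alignment, so multiple blocks come from
the tiling, and block identity is the alignment-length-weighted mean of
its windows.

## Read recruitment

Translated recruitment emulates a six-frame-by-six-frame translated
search: each read/contig pair is scored by the best local protein
alignment among the 36 frame combinations (a score-only sweep finds the
best combination; full alignments are computed only for reads passing
the bit/E thresholds). Stop codons translate to `*` and score like any
other residue. Presence requires at least `presence_min_reads` (default
100) distinct recruited reads, counted before the plot-time identity
filter (≥ 60% amino-acid identity), matching the order of the
published methods. Coverage profiles tile $[0, L)$ into exactly
`n_windows` = 30 non-overlapping windows $[\lfloor iL/30\rfloor,
\lfloor (i+1)L/30 \rfloor)$ — the published worked example, 30 kb → 30
windows of 1 kb, is consistent with a tiling — and assign each read to
the window containing its alignment start. Raw counts are stored;
$\log_{10}(\text{count}+1)$ is applied only at plot time so zero-count
windows are displayable. Environment comparisons are Welch two-sample
t-tests, with fixed conventions for degenerate inputs (both groups
constant: p = 1 if means equal, else p = 0 with a `degenerate` flag).

## Host prediction

Tetranucleotide profiles count overlapping 4-mers on the given strand
only (the cited counter's default; a canonical-strand mode is a
possible extension, and the strand convention is an acknowledged open
question of the source). Windows containing N are excluded;
frequencies always sum to 1 over counted windows. The host call is the
argmin Euclidean distance over candidate host genomes, with
alphabetical tie-break, and carries a confidence tier taken from a
published calibration on known virus–host pairs: distance < 4·10⁻⁴ →
stated accuracy 95%; 4·10⁻⁴ ≤ d < 1·10⁻³ → 84%; otherwise no
prediction. Boundaries follow the strict "below" reading ("4·10⁻⁴
exactly" falls in the moderate tier). The calibration itself is not
re-derived: the two accuracies are constants of the published record.

CRISPR-spacer matches are significant at coverage > 0.8 of the spacer
and identity > 0.9 (strict inequalities), with an `exact` flag for
full-length perfect matches — on 25–50 bp sequences only those can be
fully trusted.

## Counting dN/dS

`ng86_pair()` is the Nei–Gojobori (1986) estimator: synonymous site
fractions per codon (mutations to stop codons are not counted as
synonymous opportunities, and each position contributes denominator 3,
so $S + N = 3 \times$ codons), observed differences with equal-weight
averaging over substitution orderings (pathways through stop codons
excluded; if all are blocked the unrestricted pathways are used),
Jukes–Cantor correction $d = -\tfrac34 \ln(1 - \tfrac43 p)$, and
$\omega = dN/dS$. Conventions: identical sequences give undefined ω
(0/0); if no nonsynonymous difference is observed, ω = 0 even when the
synonymous side is saturated; dS = 0 with dN > 0 and saturation cases
are flagged rather than forced. The group summary is the mean pairwise
ω within the designated group and within the rest, excluding and
counting undefined pairs — a descriptive analogue of a branch-model
contrast, deliberately not a likelihood method: ML codon models
(site/branch classes, likelihood-ratio tests) are out of scope, and
the estimator is labelled as what it is.

## The synthetic benchmark

The generator (`sim_config()`, `make_hosts()`, `make_phage_clades()`,
`make_reads()`, `make_spacers()`, `simulate_virome()`) emulates the
statistical structure the analysis assumes, with full determinism: one
global seed, child seeds derived per sub-generator by a labelled
integer hash (all below 2³¹).

* **Hosts** are sampled from distinct order-3 Markov chains with
  Dirichlet(1) transition rows, 200 kb by default — long enough for
  stable tetranucleotide signatures.
* **Phage genomes** are ordered gene modules: core genes (the four
  labelled markers g23/g20/g17/phoH at 300/250/250/200 codons plus
  generic 150-codon core genes), a clade-specific half of a flexible
  gene pool (120 codons each), and one private 100-codon gene per
  genome, separated by intergenic gaps that pad to `genome_len`
  (30 kb default). Bases are drawn with probability `amelioration_w`
  (default 0.7) from the assigned host's chain and otherwise uniformly,
  implemented at generation rather than post-hoc editing so the
  composition signal is analytically transparent.
* **Divergence** (`between_clade_div` = 0.5 root→clade ancestor,
  `within_clade_div` = 0.05 ancestor→leaf, both per-site substitution
  probabilities with a uniform kernel) is substitution-only inside
  genes: start codons are restored and mutation-created stops repaired
  at the third position, so gene coordinates are exact and marker
  alignments trivially validated. Each clade's leaves descend through
  two intermediate ancestors (half the within-clade divergence per
  level), and the two subgroups differ by one flexible-gene swap, so
  sequence divergence and gene content carry the *same* within-clade
  signal — this is what makes marker tree and gene-content dendrogram
  exactly concordant when both are estimated well. At
  `within_clade_div = 0` leaves are exact copies of the clade ancestor
  (identical-genome clades cannot carry genome-unique genes, so
  private genes and the subgroup swap are disabled in that case).
* **References** come in two tiers: per-clade ancestral marker proteins
  (the screening reference sets and the designated in-group reference
  leaves) and per-host root proteins (distant relatives bounding the
  clades in the tree). A single distant-only tier proved unusable: at
  0.5 between-clade divergence its proteins sit near 25% identity and
  bit scores straddle the 50-bit threshold, so screening loses genes.
* **Reads** are uniform substrings at abundance×length-proportional
  genome choice, random strand, independent per-base substitution
  errors; ids encode genome, start and strand. **Spacers** are excised
  windows mutated at `spacer_mut`, ids encoding source and realised
  mutation count. Quality ramps, indel error profiles, recombination
  and assembly artefacts are *not* modelled — passing tests show the
  analysis logic is correct under the stated generative model, not that
  it is robust to real 454/Illumina artefacts.

Two quantitative mismatches with real data are worth stating. First,
synthetic tetranucleotide distances (≈ 4·10⁻²) are two orders of
magnitude above the calibrated tier boundaries, so synthetic host calls
are correct as argmin choices but carry tier "none"; the tier logic is
exercised against the published printed distances instead. Second,
because simulated genes evolve without selective constraint, synthetic
ω scatters around 1 rather than the strong purifying values typical of
real capsid proteins.

## Problem sizes of the validation suite

The oracle and recovery checks run at sizes chosen to finish in minutes
on one core: Smith–Waterman vs a quadratic Gotoh oracle on 200 random
protein pairs (length ≤ 30); NJ on 200 random additive trees (n ≤ 12)
recovered to RF 0 and path distances within 10⁻⁹; RF vs brute-force
bipartition enumeration exhaustively over all unrooted topologies for
4–6 leaves, 3000 sampled topology pairs at 7 leaves, and 500 random
pairs up to 12 leaves; permutation calibration on 200 independent
10-leaf null pairs at 199 permutations; clade recovery over 20
generator seeds (3 clades × 4 genomes, 12 kb genomes, divergence
0.05/0.5) with the concordance test (1000 permutations) on three of
those seeds; host recovery at the full 5 × 200 kb host configuration.
Occasionally (about one seed in twenty) both distant references fail to
attach between two clades and the delineation merges them — a
stochastic tree error under these divergences, which the ≥ 95%-of-seeds
recovery target absorbs.

## Known limitations

* BLAST is not reimplemented: results are *exact* local alignments with
  fixed Karlin–Altschul constants, so scores near the thresholds can
  differ from a heuristic search with composition-based statistics.
* The E-value search-space convention (per-pair) matters for long
  subjects; database-wide E-values would be smaller by the database
  factor.
* Clade delineation depends on reference placement; with no or poorly
  placed distant references, well-supported sister-clade joins are
  reported as one clade.
* The tier accuracies (95%/84%) are constants from a published
  calibration on known virus–host pairs; nothing in this package
  re-validates them.
* `group_dnds()` averages pairwise ω, which is not a substitute for a
  branch-model likelihood contrast; saturated pairs are excluded, which
  biases group means at high divergence.
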