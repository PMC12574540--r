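---
title: "Pan-gene-family analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-gene-family analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangenefam)
```

# The problem

Large plant gene families — glycosyltransferases being a canonical example —
evolve by repeated duplication and loss, so a single reference genome badly
under-represents the family's diversity within a species. A pan-genome view
asks, over dozens of related genomes plus a distant outgroup:

* which family members does each genome carry (presence/absence variation,
  PAV), and which orthologous gene groups (OGGs) are core to the species
  versus private to single accessions;
* which members arose by tandem duplication (TD) versus retention of
  collinear copies from an ancient whole-genome triplication (WGT);
* how strong is purifying selection on the retained copies, stratified by
  copy number; and
* how expression diverges among multi-copy genes.

`pangenefam` implements this analysis chain as composable R functions, each
testable in isolation, together with a synthetic pangenome generator that
carries full ground truth for every stage.

# Family identification: the profile model

Members are found with a position-specific scoring profile rather than a
full profile HMM. From a seed alignment of the family domain,
`build_profile()` drops columns with more than 50% gaps (a trimming step in
the spirit of gap-based alignment trimming) and scores residue $a$ in
column $j$ as

$$s_j(a) = \log_2 \frac{(c_{j,a} + \kappa\, b_a)/(n_j + \kappa)}{b_a},$$

with $c_{j,a}$ the residue count, $n_j$ the non-gap count, $b$ the
background frequencies (uniform 1/20 by default, overridable) and
$\kappa$ a pseudocount (default 1). `score_sequence()` reports the best
*gapless* placement of the profile along a protein, allowing partial
overlap at the ends (unmatched columns score 0). `iterative_scan()`
mirrors the field's iterative build-and-rescan practice: confident hits
(default ≥ 25 bits) are anchored at their best window and rebuilt into a
species-specific profile, and the final round reports everything at or
above the inclusion threshold (default 15 bits).

Deliberate simplifications, documented as limitations: there are no
insert/delete states, so the realignment between rounds is gapless
anchoring; and there is no E-value calibration — thresholds are bit scores
chosen by the user. Externally computed HMMER searches can be substituted
via `read_domtblout()`, and an external keep-list (e.g. from a domain
annotation service) can filter the final set. The two defaults were chosen
from the score separation on simulated data, where true members score in
the hundreds of bits and background proteins near or below zero; they are
not calibrated significance levels.

Subfamily labels come from `assign_subfamily()`: best global-alignment
identity against a labeled reference panel (BLOSUM62,
Needleman–Wunsch via `Biostrings::pairwiseAlignment`), defaulting to
`"species-specific"` below 40% identity — the mechanism by which
lineage-specific members are recognized.

# Orthogroups, PAV categories and trends

`cluster_orthogroups()` treats similarity hits passing both an E-value
cutoff (default $10^{-20}$) and a bit-score floor as edges of an
undirected graph and takes connected components as OGGs — a deliberately
transparent stand-in for graph-clustering orthology tools, with ids
(`OG0000000`, ...) assigned by decreasing size then smallest member id.

With $N$ genomes, `classify_oggs()` partitions OGGs by presence count
$k$: core ($k = N$), softcore ($k = N-1$), dispensable
($2 \le k \le N-2$), private ($k = 1$). The boundary between softcore and
dispensable overlaps in informal range descriptions ("conserved in
$N{-}1$" versus "2 to $N{-}1$"); the package resolves it by giving exact
$N-1$ to softcore so the partition is exclusive. Presence means at least
one member gene — copy number is tracked separately (`gene_counts`).

`group_frequencies()` reports per-group presence percentages rounded
half-up to integers (the convention that yields trajectories like
62%, 91%, 92%, 100%), while gene-share percentages use two decimals
(72.53%-style). `detect_monotone_trends()` calls an OGG rising (falling)
when its trajectory along the ordered groups is monotone, not constant,
and spans at least `min_delta` percentage points — `min_delta` defaults to
10 because no published criterion exists; it is an explicit parameter.

# Tandem arrays

`detect_tandem_arrays()` follows the GFF-sort / BLASTP / positional
clustering recipe: isoforms are collapsed first (`filter_isoforms()`
keeps the longest CDS per locus, ties to the smallest id), similar pairs
(E ≤ $10^{-20}$) on one chromosome are clustered by single linkage on
gene-rank distance with a hard cutoff (`max_rank_gap`, default 5). Single
linkage with a cutoff equals the transitive closure of near pairs, which
matches the intuitive notion of a tandem array as a contiguous run.
"Gene distance" is not standardized in such recipes; rank distance is the
default because it makes arrays contiguous gene runs regardless of
intergenic span, and a base-pair mode (`distance = "bp"`) is available.
Strand is ignored for membership.

# Synteny blocks and WGT copy retention

`chain_collinear_blocks()` chains anchor pairs per chromosome pair and
orientation in *anchor-index* coordinates (each chromosome's family genes
numbered consecutively by rank). Consecutive chain members may skip at
most $u$ intervening family genes on either genome; maximal chains are
extracted greedily (longest first, deterministic tie-breaks), and chains
shorter than $s$ anchors are discarded. The defaults $e = 10^{-20}$,
$u = 1$, $s = 5$ follow standard collinearity-scan practice. E-values are
taken from the input hit table, never recomputed.

`classify_copy_retention()` counts, per outgroup gene, the distinct
target-genome block regions containing it as an anchor (overlapping
blocks on one chromosome are merged first so fragmented chains cannot
double-count), capped at 3 — the triplicated-then-fractionated classes.
For the outgroup comparison the pipeline default is a larger gap
allowance (`synteny_u = 20`): after a triplication, losses are
interspersed along each subgenome, so anchors in a surviving region are
separated by variable runs of lost genes and a strict $u = 1$ fragments
real regions. This is an analysis-parameter choice fixed a priori from
the structure of fractionation, not a tuning knob.

`attribute_duplication_origin()` combines the two signals: TD if in any
array, WGT if anchored in a block whose outgroup partner retains ≥ 2
copies, `both`/`none` otherwise.

# Selection: Nei–Gojobori Ka/Ks

`ng86_pair()` implements NG86 counting on a pairwise codon alignment
(typically produced by `back_translate()` from a protein alignment plus
the two CDS):

* **Sites.** For each codon, each position contributes the fraction of
  its single-nucleotide changes that are synonymous, with changes into
  stop codons removed from numerator *and* denominator; $S + N = 3$ per
  codon always. Site totals are averaged over the two sequences, so the
  statistic is symmetric in its arguments.
* **Differences.** Between diverged codons, all orderings of the
  substitutions are enumerated; orderings passing through a stop codon
  are excluded and the synonymous/nonsynonymous step counts averaged over
  the remainder. In the degenerate case where every ordering hits a stop,
  the non-stop steps are reweighted to the observed difference count and
  a warning is emitted.
* **Correction.** $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$
  (Jukes–Cantor) for both $p_S$ and $p_N$; a ratio is `undefined` when
  $K_s = 0$ or a proportion reaches the $3/4$ bound — undefined ratios
  are reported as such, never coerced into the positive class.

Columns with a gap or ambiguous nucleotide in either row are excluded
entirely; terminal stop codons are trimmed before validation.
`classify_selection()` applies the conventional reading — ratio > 1
positive, < 1 purifying, ≈ 1 neutral — with a strict tolerance
(`tol = 1e-9`) by default. This counting estimator is a stand-in for
maximum-likelihood codon models; numeric parity with ML software is not
claimed, and `summarize_strata()` only reports distributional summaries
(mean, median, n, undefined counts) per group × copy-class cell.

# Distance trees

`p_distance_matrix()` (mismatch fraction over mutually ungapped columns)
feeds `neighbor_joining()`, a canonical Saitou–Nei implementation with
Studier–Keppler updates, deterministic lexicographic tie-breaking and
non-negative branch lengths (a negative estimate is clamped to zero with
the deficit moved to its sister, preserving path lengths). This is the
desk-scale stand-in for ML tree inference; externally computed Newick
trees can be read with `ape::read.tree()` and annotated directly.
`annotate_clades()` reports, per subfamily, the size of the smallest
clade containing all members and the resulting monophyly fraction.

# Expression

`cluster_genes()` reproduces the standard heatmap pipeline: optional
replicate averaging per (tissue, stage), $\log_2(1+x)$ transform
(Spearman distances are invariant to it; the default applies it for the
exported matrix), distance $1 - \rho$ with mid-ranked ties, complete
linkage, deterministic leaf order. A constant gene vector has undefined
rank correlation; its distances are set to 1 with a warning rather than
silently dropped. `tissue_tau()` provides the $\tau$ specificity
statistic (threshold 0.85) since specificity is otherwise described only
qualitatively, and `dosage_summary()` adds member and summed per-tissue
profiles for multi-copy sets, flagging the tissue of maximal dosage.

# The synthetic pangenome

`simulate_pangenome()` generates the study design the toolkit targets,
with truth tables for every stage. Defaults mirror the observed structure
of a 61-accession tomato panel: four ordered domestication groups of
sizes 13/11/12/25; 118 OGGs mixed 58/31/10/19 over
core/softcore/dispensable/private; purifying Ka/Ks targets below 1
(0.3/0.2/0.1 for single/double/triple-copy strata); and a 60/30/10-style
retention mix (`loss_probs` = 0.5/0.3/0.2 for 1/2/3 copies). Family genes
share a 60-codon domain (10% diverged per OGG) between OGG-specific
flanks; every gene is further diverged at 20 substitutions/kb. Tandem
specs (size, rank spacing) are implanted per genome on distinct core
OGGs; one isoform pair is emitted every 20 loci to exercise the isoform
filter; intergenic spacing is geometric. The outgroup carries 300-codon
genes; a configurable fraction is triplicated into three dedicated
chromosomes of the target genome with per-gene retention drawn from
`loss_probs`, copies diverged at the per-stratum Ka/Ks targets.

What the simulator deliberately does **not** emulate: realistic
chromosome sizes, GC content or intron structure; sequence-level
similarity search (the similarity graph is emitted from truth with strong
intra-OGG and weak inter-OGG edges, so orthogroup recovery tests the
clustering rule, not an aligner); and biological noise in tandem-array
boundaries. Passing truth-recovery tests therefore demonstrates the
correctness of the algorithms under clean, known conditions — not
robustness to noisy real annotations.

`simulate_expression()` assigns archetypes — ubiquitous (a fixed,
non-monotone housekeeping-like profile), tissue-specific, stage-ramp,
silent — with multiplicative log-normal noise (sd 0.2 on the log2 scale).
Recovery tests treat (archetype, assigned tissue) as the truth label,
since two tissue-specific genes with different target tissues genuinely
differ, and exclude silent genes, whose correlation is undefined by the
constant-vector policy above.

# Reproducibility and problem sizes

All stochastic components take explicit integer seeds and restore the
caller's RNG state; identical configurations produce byte-identical
output files. The test suite and the acceptance script run the simulator
at 10 genomes × 50 OGGs with a 60-gene outgroup — sizes chosen so every
truth-recovery property is exercised (all four categories populated,
dispensable range non-empty, ≥ 5-anchor regions under fractionation)
while a full end-to-end run stays in the tens of seconds. The full
61-genome default configuration runs in well under a minute and is used
for interactive exploration rather than testing.

# Known limitations

* The profile scanner has no gap states and no E-value model; highly
  diverged members with large insertions in the domain may be missed.
* Connected-component orthology cannot split chimeric clusters the way
  tree-aware orthology tools do.
* NG86 ignores transition/transversion bias and codon frequencies; use
  the adapter route (externally computed pairwise results) when ML
  estimates are required.
* Copy-retention counting trusts the block chains; regions thinner than
  the minimum block size `s` are invisible to it.
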