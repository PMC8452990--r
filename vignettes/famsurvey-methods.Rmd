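---
title: "Methods and design of the famsurvey gene-family survey pipeline"
author: "famsurvey authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the famsurvey gene-family survey pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`famsurvey` implements the standard analysis arc of a genome-wide plant
gene-family survey, of the kind routinely published for families such as the
subtilisin-like serine proteases (SBTs): identify family members in a
proteome by a conserved-domain criterion, characterize the proteins, build a
neighbor-joining (NJ) phylogeny with bootstrap supports and assign members
to subfamilies, detect duplicate gene pairs and classify them as tandem or
segmental, estimate selection pressure with Ka/Ks, census promoter
cis-regulatory elements, and classify tissue-specific expression. Because
the real inputs of such surveys (a full genome, curated domain models,
public expression data) are large and external, the package ships a seeded
synthetic-genome generator whose outputs carry a complete ground-truth
record; every stage is tested against that truth at desk scale.

# Identification by profile scoring

Family membership is decided by scoring every gapless window of each
protein against a log-odds profile built from a seed alignment of the
family-defining domain. For column $c$ and residue $a$,

$$\mathrm{score}(c,a) = \log_2
  \frac{(n_{c,a} + \pi\, b_a)/(n_c + \pi)}{b_a},$$

with $n_{c,a}$ the residue count, $n_c$ the non-gap count, $\pi$ the
pseudocount (default 1) and $b_a$ the background frequency (default
uniform $1/20$). Columns with more than 50% gaps are dropped. A protein is
a member iff its best window reaches a configurable fraction (default 0.5)
of the profile's maximum attainable score; the same rule, with each
profile's own maximum, annotates accessory domains (PA, Inhibitor_I9).
This gapless profile scan deliberately replaces full profile-HMM
Viterbi/forward scoring: at desk scale it captures the same identification
semantics while remaining checkable against an exhaustive window oracle.
The ambiguity letter `X` scores 0 in any column; window-score ties are
resolved toward the smallest offset, with a $10^{-9}$ tolerance so that
floating-point summation order cannot flip the reported offset.

Molecular weight is the sum of average residue masses plus one water; the
isoelectric point is the zero crossing of the Henderson–Hasselbalch net
charge (positive groups $+1/(1+10^{\mathrm{pH}-pK_a})$, negative groups
$-1/(1+10^{pK_a-\mathrm{pH}})$), found by bisection on $[0,14]$ to
$10^{-3}$. Since net charge is strictly decreasing in pH the root is
unique. The pKa set and masses are EMBOSS-style constants packaged as a
user-replaceable TSV (`inst/extdata/aa_properties.tsv`): the constants are
pinned for reproducibility, not hard-coded.

# Alignment, distances, and the NJ tree

Pairwise alignment is Needleman–Wunsch with affine gaps (BLOSUM62, gap
open 11, extend 1; a gap run of length $L$ costs $\mathrm{open} + L\cdot
\mathrm{extend}$), with deterministic tie-breaking (match/mismatch over
gap-in-a over gap-in-b). The multiple alignment is progressive: a guide
tree from 3-mer count cosine distances via NJ, then profile–profile
Needleman–Wunsch merges in which a column pair scores the mean pairwise
substitution value and pairs involving gaps score a flat penalty. The
inner dynamic programs run in C++.

Distances are $p$ (mismatch proportion over shared non-gap columns) or
Poisson-corrected $d = -\ln(1-p)$ (the default, matching the common
protein default of distance-based phylogeny software). Saturated pairs
($p \ge 0.99$) are clamped with a warning rather than returned infinite,
keeping NJ defined.

NJ follows Saitou–Nei agglomeration with the Q-criterion and
Studier–Keppler updates; minimal-Q ties are broken by the lexically lowest
pair of cluster labels (a cluster is labeled by its smallest leaf id), and
negative branch lengths are clamped to zero. On any additive matrix the
implementation recovers the generating topology and branch lengths
exactly, which the tests verify on random additive cases and a worked
four-taxon example. Bootstrap resamples alignment columns with
replacement; the support of an internal edge is the fraction of replicate
trees containing its bipartition. The conventional 1,000 replicates is the
user-facing default for the pipeline's headline runs; the packaged tests
use 100 (and 20 in the smallest fixtures) because support recovery on the
planted two-clade fixtures is already exact there — the reduced replicate
counts are a choice about the test problem sizes, not about the method.

Subfamily assignment replaces the manual reading of a published tree
figure with a deterministic rule: each member takes the group of its
nearest labeled reference by patristic distance (ties: majority group
among equidistant references, then lexical order). A composition reporter
partitions each group by a clade-of-origin tag (e.g. monocot/dicot) and
rounds percentages to integers, reproducing the published Group-I
arithmetic (87 of 126 monocot = 69%, 39 dicot = 31%).

# Duplications and Ka/Ks

Similarity anchors come from Smith–Waterman local scores (BLOSUM62,
affine gaps) over all protein pairs; hits below a raw score of 50 are
dropped and the best 5 per query are kept. The raw-score threshold stands
in for a BLAST E-value cutoff: Karlin–Altschul statistics are out of
scope at desk scale, and the threshold is exposed in the configuration.
Collinear blocks are chained MCScanX-style: within a chromosome pair, the
longest anchor chains strictly monotone in gene rank on both sides (same
or inverted orientation) with per-step rank gaps of at most 25 are
extracted greedily; chains with fewer than 5 anchors are discarded. Gene
"position" here is always the rank along the chromosome, not base pairs,
because the tandem/segmental distinction is a gene-order concept.

Candidate duplicate pairs are reciprocal best hits among family members.
A pair is *tandem* iff on one chromosome with rank gap ≤ 1 (adjacent,
the common operational definition), else *segmental* iff it occurs as an
anchor inside a collinear block, else *dispersed* — a category added for
pairs matching neither rule. Tandem takes precedence over segmental.

Ka/Ks uses the Nei–Gojobori (1986) counting method. Per codon, the
synonymous site count at each position is the fraction of its single-
nucleotide changes that are synonymous, with changes to stop codons
excluded from both numerator and denominator; $N_c = 3 - S_c$, so
$S_c + N_c = 3$ holds exactly. Differences between codon pairs are
averaged with equal weights over all minimal mutational pathways,
excluding pathways through stop codons; in the degenerate case where every
pathway is blocked, the codon pair falls back to averaging over all
pathways with stop steps counted nonsynonymous. Proportions are corrected
with Jukes–Cantor, $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, flagged
undefined when $p \ge 3/4$. The ratio is defined only when $K_s > 0$;
selection is called purifying below 1, neutral at 1 (tolerance $10^{-9}$),
positive above 1. NG86 with equal pathway weights is the canonical,
oracle-checkable definition; published tables computed with other
estimators (e.g. DnaSP's) can differ by small method-dependent amounts,
which is why the tests validate against an independent brute-force
pathway enumeration rather than against external numbers.

# Promoters and cis-elements

The promoter of a gene is the up-to-2,000-bp region immediately upstream
of its start (strand-aware; minus-strand promoters are
reverse-complemented so the sequence reads 5'→3' toward the gene),
clipped at the chromosome boundary and — following the practice of
deleting overlapped regions — at the span of the nearest upstream gene of
any strand. Genes whose promoter clips to zero length are excluded with a
logged reason.

Elements are defined by IUPAC consensus strings in a packaged,
user-editable TSV with the three conventional categories
(growth/development, stress, phytohormone). The packaged consensi are
commonly published approximations; since scanning services do not publish
their matrix libraries, the table is configuration data, not a claim
about any external database, and published element proportions are not
reproduction targets. One curation rule: the table keeps only one of any
reverse-complement consensus pair (e.g. the CGTCA-motif but not the
TGACG-motif), because with both-strand scanning each member of such a
pair implies the other at every hit, which would double-count planted
ground truth. Scanning reports every matching offset on both strands,
overlapping matches included, and is tested against a naive
IUPAC-expansion oracle. The census reports per-category totals and
percentages, within-category element percentages, and a gene × element
count matrix.

# Expression

FPKM values are transformed as $\log_2(x+1)$. Tissue specificity uses the
tau index on the transformed profile,
$\tau = \sum_i (1 - x_i/x_{\max})/(n-1)$: 0 for uniform, 1 for one-hot
expression; the log transform damps dynamic range so tau reflects breadth
rather than magnitude. Calls use explicit thresholds because published
surveys classify heatmaps by inspection: *low* when no tissue reaches
1 FPKM; *specific* when $\tau \ge 0.85$ and the top tissue is expressed;
*ubiquitous* when every tissue reaches 1 FPKM with $\tau < 0.85$;
*intermediate* otherwise. Both thresholds are exposed in the
configuration.

# The synthetic generator

`synthetic_config()` defaults define the benchmark: 5 chromosomes, 200
background genes, 30 family genes in 6 subfamily groups (sizes
10/6/5/4/3/2, echoing the skew of real subfamily censuses), one planted
tandem pair and four segmental pairs (the published counts for the
pineapple SBT family: five pairs, one of them tandem), 6-anchor collinear
blocks, 8 tissues with 10 tissue-specific and 6 ubiquitous family genes
(six ubiquitous genes matching the reported count), and a purifying
divergence regime for planted pairs: synonymous substitution probability
0.3 at 4-fold-degenerate third positions versus 0.05 at nondegenerate
positions.

Construction details that matter for the guarantees:

* **Group backbones vs domains.** Each group has a random protein
  backbone carrying the domain consensus at a fixed offset. A member is
  the backbone mutated at `backbone_divergence` (default 0.3) with fresh
  domain copies re-embedded at `per_site_sub_rate` (default 0.05). The
  separation of the two rates keeps identification difficulty controlled
  by the domain rate alone, keeps subfamily assignment trivial at the
  distance level (within-group distances far below between-group), and —
  critically — keeps planted duplicate partners (≈ 97% identical) far
  closer to each other than to any other group member (≈ 50%), so
  reciprocal-best-hit pairing provably recovers them. Nonsynonymous
  divergence planting skips the domain codons, so the diagnostic domain
  stays at its nominal mutation rate even in pair partners.
* **Layout.** Tandem pairs occupy adjacent ranks; segmental pairs sit at
  the middle of 6-anchor blocks whose remaining anchors are background
  genes and their mutated copies on a second chromosome; all other family
  genes are buffered by background genes so no two family genes are ever
  accidentally adjacent. Genes are spaced by more than twice the promoter
  length, so promoter windows never truncate or collide.
* **Promoter truth.** Family-gene promoter windows are built as random
  background rejection-sampled until they contain no match of any table
  element, then planted with concrete IUPAC expansions of the configured
  element set at spaced offsets. All hits implied by the planted
  instances — including the mirror hit of a palindromic consensus and any
  nested match of another table entry — are recorded as truth, so
  re-scanning the emitted genome reproduces the truth record exactly.
* **Expression.** Specific genes draw 50–100 FPKM in one tissue and
  0–0.5 elsewhere; the 0.5 ceiling (within the "< 1 FPKM" background
  regime) follows from the tau formula: it bounds the off-tissue
  log-signal so far below the target tissue's that the $\tau \ge 0.85$
  call holds with overwhelming margin for any draw, rather than
  probabilistically. Ubiquitous genes draw 5–50 FPKM everywhere; all
  other genes stay below 1 FPKM.
* **Determinism.** One master seed drives labeled sub-streams (one per
  component, fixed label order), so outputs are byte-identical across
  runs and insensitive to evaluation order.

What the generator does *not* emulate: realistic intron length or GC
composition, indels (all divergence is substitutional), pseudogenes,
expression noise correlated across tissues, and domain architectures
beyond the three planted domains. Passing the planted-truth tests
therefore demonstrates correctness of the machinery under the stated
statistical structure, not performance on real genomes, where alignment
quality, E-value calibration and block chaining parameters all matter
more.

# Pipeline behavior and numerical choices

`run_survey()` executes the stages in order and writes one TSV per
product plus `report.json`; identical config and seed give byte-identical
reports. Any stage failure aborts with the stage name and leaves a
`failed` marker in the output directory. Stages are deliberately not
cached or resumable: at the problem sizes the package targets a full
re-run costs seconds, so a cache would add state without benefit.
Reciprocal-best-hit pairing can legitimately surface extra duplicate
pairs among unpaired same-group members (they are genuinely homologous);
such pairs are reported honestly — typically as *dispersed*, with
saturated (undefined) Ks — and the planted-truth tests assert the planted
pairs' types rather than forbidding additional discoveries.

Isoform policy: when an annotation carries several mRNAs per gene, the
isoform with the longest summed exon length represents the gene — a
choice the package documents rather than inherits from any source, since
surveys rarely state it.

Problem sizes used by the shipped tests: the full benchmark configuration
(230 genes, bootstrap 100) for ten seeds in the end-to-end suite; reduced
fixtures (about 52 genes, 2 chromosomes, bootstrap 20) for the per-module
tests; 500 random codon alignments of up to 30 codons for the Ka/Ks
oracle comparison; 50 random additive matrices of up to 12 taxa for NJ;
200 random promoters for the scanner oracle. These sizes were chosen so
the whole suite exercises every guarantee in a few minutes on one CPU.

# Known limitations

* The membership threshold (fraction of maximum profile score) is a
  surrogate for HMMER E-values; its default of 0.5 is comfortable for the
  planted regime but should be recalibrated for real proteomes.
* The progressive aligner is a straightforward guide-tree implementation
  without iterative refinement; deep or gappy families will align worse
  than with mature MSA tools.
* NG86 with Jukes–Cantor is the simplest consistent Ka/Ks estimator; it
  ignores transition/transversion bias and codon frequencies, and
  saturates (undefined) beyond $p = 3/4$.
* The element table's consensi are approximations; absolute element
  counts on real promoters depend entirely on the table supplied.
* Synteny chaining on very gene-dense toy chromosomes can chain genuine
  family homologies into blocks; on real genomes the default gap
  parameters behave as in standard collinearity tools.
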