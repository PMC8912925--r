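---
title: "Methods: phyloregulatory dissection of an LTR family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phyloregulatory dissection of an LTR family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Endogenous retrovirus (ERV) families amplify in bursts: a progenitor element
is copied many times in a short evolutionary window, then decays by
mutation. The long terminal repeat (LTR) carries the promoter, so the
regulatory behaviour of a family is largely the regulatory behaviour of its
LTR variants. When a family such as HERVH's LTR7 is treated as a single
unit, subfamily-specific regulation is averaged away. `phyloreg` implements
the analysis style this package calls *phyloregulatory*: resolve the family
into subfamilies on a phylogeny of individual LTR copies, then layer binary
regulatory calls (peak overlaps, expression flags) on those subfamilies and
test for enrichment; finally, dissect the consensus sequences themselves
for the mutational events — recombination, tandem duplication, motif gain —
that created the regulatory differences.

## Subfamily model and partitioning rule

The generative picture is a backbone tree whose tips are subfamily founders
(divergence on the order of 0.05 substitutions/site between founders), each
founder emitting a star-burst of copies with short terminal branches
(mean ~0.01 substitutions/site). On a bootstrapped tree of all copies a
subfamily appears as a clade that (i) is supported (bootstrap ≥ 0.95),
(ii) has strictly more than 10 members, and (iii) sits behind an internal
edge longer than 0.015 substitutions/site.

Deep backbone edges also satisfy (i)–(iii), but they subtend *groups* of
subfamilies. What distinguishes one amplification burst from such a group
is that the burst's own supported internal branches stay short. We
therefore accept the **minimal** qualifying clades — a subfamily contains
no smaller qualifying clade — and report coarser qualifying clades in a
diagnostics table (`$nested`). The rule is edge-based (bipartitions), so
results do not depend on rooting or leaf order. Thresholds are exposed
(`support_min`, `size_min`, `branch_min`); the member count is strict
(`> size_min`), as is the branch rule, while support uses `>=` after
normalizing percentages to proportions.

## Consensus, assignment, network

Majority-rule consensus uses a 51% threshold per column over
`A,C,G,T,-`: a winning gap deletes the column (consensuses may be shorter
than the alignment, preserving subfamily-specific indel structure), a
column without a 51% winner becomes `N` (a 50/50 split is *not* a
majority). Sequences can be re-assigned to subfamilies by nearest-consensus
p-distance after global pairwise alignment, with ties broken by consensus
name order.

The median-joining network over consensus sequences uses only gap- and
`N`-free polymorphic columns. The construction iterates: minimum spanning
network under Hamming distance (an edge is kept when its weight does not
exceed the minimax path weight between its endpoints plus `epsilon`,
default 0); per-site majority vectors of connected triples added when
novel; convergence; then pruning of median vectors that lie on no shortest
path between observed haplotypes. Determinism comes from sorted label
order and a documented tie rule (a three-way site tie takes the first
node's state). On small inputs the network's spanning length equals the
exhaustive Steiner minimum (tested).

## Dating

Two independent clocks are implemented. Orthologous presence: an element
present at the syntenic position of a species implies the insertion
predates that divergence; per subfamily we report the shared fraction per
species, ordered by divergence time. Terminal branch lengths: the pendant
edge of each copy is a proxy for post-insertion divergence; groups
(amplification waves) are compared with two-sided Wilcoxon rank-sum tests
under Bonferroni correction, the correction factor being the number of
pairwise tests performed.

## Regulatory overlay

Feature calls are binary per element: any-overlap (≥ 1 bp) or
fraction-of-element (default 70%) intersection with peak intervals
(computed with interval trees, verified against an all-pairs oracle);
top-septile calls for continuous nascent-transcription signal (positives
are the values reaching the `floor(n/7)`-th largest, boundary ties
included); strict `FPKM > 2` for expression. Subfamily proportions count
elements with no call row as negative. Enrichment uses 2×2 chi-square
without continuity correction (Fisher's exact test is substituted and
flagged when an expected cell falls below 1), Bonferroni-corrected by the
number of tests in the invocation.

## Recombination and duplication

Consensus alignments are cut into user-defined blocks (the bundled
simulator defaults to seven equal blocks of a ~450-bp ancestor). Each
block gets a bootstrapped tree; taxa entirely gapped in a block are
excluded from it. An incongruence event is a block-tree bipartition with
support ≥ 0.95 that is incompatible with the *supported* structure of the
reference topology restricted to shared taxa. Two numerical choices
matter on short (~64 bp) blocks:

* **BIONJ within blocks.** Plain neighbor-joining fails to join even
  identical sequence pairs in a noticeable fraction of bootstrap
  replicates when close relatives are present, because the Q-criterion is
  sensitive to noisy rate terms; the variance-weighted BIONJ join is
  stable. The family-level tree uses plain NJ; block trees use BIONJ.
* **Character-evidence gate.** Distance bootstrap can confidently support
  a clade that has no parsimony backing at all. An event therefore also
  requires the block topology to explain the block data strictly better
  than the reference (≥ 1 Fitch step). A genuine block exchange always
  leaves such sites; chance distance noise does not.

A bipartition and its complement count once; overlapping conflicting
clades within a block merge into one event, so the count is a minimum.
Direction is annotated from subfamily ages when supplied, otherwise `"?"`.
Note that a block swap between backbone *sisters* produces no
incongruence and is undetectable by design.

Tandem duplication is tested by globally aligning two blocks (match +1,
mismatch −1, gap open 2, extend 1) and computing identity over aligned
columns excluding terminal gaps; a call requires identity ≥ 0.70 and
adjacency. Copies that diverged ~0.1 substitutions/site each after
duplicating land near 81–82% identity under the Jukes–Cantor saturation
curve, comfortably inside the calling band.

The sliding-window breakpoint scan is advisory: it reports positions where
supported clades of consecutive *informative* windows (windows with at
least one supported split) are incompatible. Windows should be roughly
block-sized; the scan cannot replace explicit block definitions.

## Motifs

The scanner scores log2((p + 0.001)/background) per position, both
strands, skipping windows containing `N`; the default hit threshold is 80%
of the maximal achievable score. JASPAR count matrices (pseudocount 0.5)
and HOMER probability matrices are both parsed. Enrichment is ZOOPS (a
sequence either contains a hit or not) with a one-sided hypergeometric
test of target hits against the pooled background, per motif and block,
for every ordered subfamily pair when requested. The significance cutoff
is `p <= 1e-5`. Lineage-specific insertions are maximal alignment-column
runs where the target consensus has bases and every other consensus has
gaps, reported in target coordinates.

## What the simulator emulates — and what it does not

`simulate_family()` generates: a random backbone topology with fixed
per-edge founder divergence; Poisson substitution events per branch (so
realized divergence follows the Jukes–Cantor saturation curve
p = 3/4·(1−e^{−4d/3})); exponential terminal branch lengths, optionally
different per subfamily to create waves; geometric indels (mean 3 bp) on
terminal branches only; founder-level planted events (block recombination
before the burst, one tandem block duplication, one short motif gain) with
the exact founder MSA (`founder_aln`) and the block table in both frames
recorded as ground truth; per-subfamily Bernoulli regulatory marks;
uniform insertion ages within per-subfamily activity windows, which
deterministically induce the orthologous-presence matrix over a fixed
species ladder (chimpanzee 6, gorilla 9, orangutan 16, gibbon 20, macaque
25 Mya); default activity windows follow three waves (40–25, 20–9,
10–4 Mya).

Deliberately not modelled: selection, nested insertions, rate
heterogeneity among sites, realistic template-switching mechanics,
correlated marks, alignment error in the founder MSA. Passing tests
therefore demonstrate correctness of the algorithms under a clean
burst-amplification model, not robustness to every pathology of real
repeat annotations; with real data, alignment quality and annotation
fragmentation will dominate error long before these algorithms do.

Founders evolve by substitutions only; indels are confined to terminal
branches. This keeps founder block coordinates in the ancestor frame so
planted events are exactly defined — a bookkeeping choice, not a claim
about biology.

## Alignment

External MSAs (mafft, PRANK, MUSCLE) and external trees (newick with
support labels, normalized to [0, 1]) are accepted at every stage
boundary. The built-in aligner is reference-guided: each sequence is
globally aligned to a reference (by default the longest input) and the
pairwise alignments are merged, insertions opening shared gap columns.
This mirrors the common repeat-biology practice of aligning copies
against a consensus; it is not a progressive MSA, and independent
pairwise gap placement can wobble by a few columns around indels — one
reason consensus-level analyses in the tests use the simulator's exact
founder MSA.

## Problem sizes used by the test-suite and acceptance script

Chosen to exercise the published thresholds at desk scale: 20 simulated
families of 8 subfamilies × 20–40 copies for partition/consensus recovery
(bootstrap 100 replicates); 20 runs of three waves × four subfamilies × 50
copies for the dating check (wave means 0.005/0.012/0.025; waves are
pooled for the between-wave tests, while within-wave pairs come from the
subfamily-level invocation — with exponential terminal branches and
~450-bp sequences, narrower designs simply lack the rank-test power the
thresholds demand); 50 planted-swap plus 50 clean founder-level runs for
recombination (planted swaps are placed between the most divergent
founder pair, since sister-pair swaps are undetectable in principle); 30
runs for duplication identity; 1000 replicates of the null mark model
(8 subfamilies × 20 elements × 10 marks) for enrichment calibration; 20
planted-motif families, with block boundaries drawn around — never
through — the planted insertion, as an analyst defines blocks around
sequence features. Bootstrap replicate counts are configurable; 100 is
the package default.

## Known limitations

* The partitioning rule assumes burst-like amplification; families with
  gradual, ladder-like expansion will not show the long-edge/short-edge
  contrast the rule relies on.
* Incongruence detection is blind to recombination between sister
  lineages and to exchanges smaller than a block.
* The hypergeometric ZOOPS enrichment treats sequences as exchangeable;
  phylogenetic autocorrelation within a subfamily inflates effective
  significance, which is why the planted-motif cutoff is conservative
  (1e-5).
* The reference-guided aligner is adequate for intra-family divergences
  (~0.1 substitutions/site); deeper divergence warrants an external MSA.
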