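---
title: "Chromatin-state-modified regulatory network motifs: models and methods"
author: "chromotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state-modified regulatory network motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromotif)
```

## The problem

Transcription factors (TFs) wire genes into directed regulatory networks, and
recurring three-node wiring patterns — network motifs such as the feedforward
loop (FFL), in which a top TF regulates an intermediate TF and both regulate a
common target — are the building blocks of those networks. Promoter chromatin,
summarised as a small number of broad states, modulates what those wiring
patterns do: the same FFL wiring with an active target behaves differently
from one whose target promoter is bivalent ("poised"). `chromotif` implements
an analysis that treats structure and chromatin state jointly: it colors each
network node with a broad promoter state and asks which *colored* three-node
patterns are over-represented, how exclusive state compositions are to
particular structures, how FFLs change state and wiring between two cell
conditions, and which genes those changes single out.

## Building the network

Inputs are deliberately downstream of read processing: per-TF peak files
(BED or narrowPeak), DNase I hypersensitive site (DHS) intervals, and a gene
annotation with one TSS per gene. A TF binding site is the 40-bp window
centered on a peak summit (narrowPeak column 10 when present, the peak
midpoint otherwise); binding sites are kept only when they fall into a DHS;
and an edge TF → gene is created when a retained binding site overlaps the
gene promoter, defined as 0.5 kb upstream plus 0.5 kb downstream of the TSS.
All coordinates are BED-native 0-based half-open.

Two interpretation choices are genuinely open in this construction and are
exposed as options rather than hard-coded: whether "falling into" a DHS and
"located within" a promoter mean ≥ 1 bp overlap or full containment. The
default is 1-bp overlap — with 40-bp sites against 1-kb promoters the
difference is minor, and overlap is the standard reading — and
`containment = TRUE` switches both tests. Self-edges (a TF bound at its own
promoter) stay in the network but never enter triad enumeration.

## Broad chromatin states and promoter annotation

Fifteen-state genome segmentations are collapsed to four broad classes:
active promoter and strong enhancer labels become **StrongActivity**; weak
promoter/enhancer labels **WeakActivity**; the bivalent promoter label
**Poised**; and everything else — transcription-associated, insulator,
Polycomb-repressed, heterochromatin/low-signal, repetitive — **Repressed**.
The placement of transcription-associated labels is the one genuinely
ambiguous case; the map is a plain named vector (`default_state_map()`) so
users can re-route labels without touching code, and segmentations that
already carry broad labels pass through unchanged.

A gene's state is the broad state with maximal promoter fold enrichment
$(a_s/b)\,/\,(c_s/d)$, where $a_s$ is the number of promoter bases in state
$s$, $b$ the promoter length, $c_s$ the genome-wide bases in $s$ and $d$ the
total state-marked bases. Dividing by genome-wide abundance matters: a rare
state covering 40% of a promoter can out-enrich a ubiquitous state covering
60% (see the worked example in `?gene_states`). Numerical conventions: a
state absent genome-wide is skipped (its enrichment is undefined); a
promoter overlapping no segment is called Repressed, mirroring the
low-signal grouping, with a warning; exact ties break by the fixed priority
StrongActivity > Poised > WeakActivity > Repressed, chosen so the most
information-rich labels win deterministically.

## Colored triad census

All weakly connected induced three-node subgraphs are enumerated — there are
exactly 13 directed structures, a fact the test suite re-derives by brute
force over the 64 edge configurations — and each occurrence is keyed by a
canonical *colored* class: the minimum, over the six node permutations, of a
packed (adjacency bits, state triple) integer. Because the adjacency bits
dominate the encoding, the minimisation collapses colorings exactly up to
the automorphisms of the structure: swapping the two symmetric partners of a
mutual dyad with a common regulator does not create a new class, while the
FFL, which has no nontrivial automorphism, keeps all $4^3$ colorings
distinct. The census (compiled code, visiting each connected triple once
from its lexicographically smallest adjacent pair) is cross-checked in the
tests against an exhaustive $O(n^3)$ oracle and against an orbit count via
Burnside's lemma.

## The randomization null and motif significance

Significance is assessed against randomized networks that preserve, exactly:
every node's in- and out-degree; for every TF, the number of its targets in
each broad state (the state-modified degree distribution); and the count of
every two-node subgraph. The implementation is constrained double edge
swapping — $(u \to v, x \to y) \Rightarrow (u \to y, x \to v)$ accepted only
when the two targets share a state and no self-loop, duplicate edge, or new
mutual pair would be created — with mutual dyads swapped as units against
other mutual dyads so the mutual-edge count cannot drift. Every preservation
property is asserted exactly, on every replicate, in the test suite. The
swap budget is 10 × |E| attempted swaps per replicate (a standard mixing
heuristic; the source does not pin this down) and each replicate restarts
from the observed network.

A colored class observed $N_{real}$ times is significant when its empirical
$P$ — the fraction of 500 randomized networks containing it at least
$N_{real}$ times, with no pseudo-count, so the resolution floor is 1/500 —
is below 0.05 **and** $N_{real} - \bar N_{rand} > 0.05\,\bar N_{rand}$.
Only classes observed in the real network are tested.

## Exclusivity, expression contrasts and helper statistics

Mutual exclusivity of state compositions across motif structures (or cell
types) uses a binary matrix $M$ whose score $S_M$ is the fraction of rows
carrying exactly one 1. The null shuffles entries independently within each
column (column sums are preserved; the within-column variant follows the
column-permutation approach the analysis is modeled on), and $p$ is the
fraction of 10,000 permutations with $S_M$ at least the observed score. Rows
that become all-zero under permutation contribute 0 — the score only credits
compositions coupled to exactly one structure. Compositions are identified
by their state multiset so that colorings of structures with different
canonical position orders align on one row.

Expression contrasts between compositions of one FFL type (types I–IV by
the repressor/activator roles of the top and intermediate TFs, supplied as
an input table since the underlying curation is manual) use two-sided
Wilcoxon rank-sum tests on target expression, after removing targets shared
between compositions; groups under 3 targets are skipped. Gene-set
enrichment is the upper-tail hypergeometric $P(X \ge k)$ with
Benjamini–Hochberg correction across sets, on user-supplied flat gene sets
(no ontology-graph handling). The cell-type specificity score divides a
gene's expression by its total across cell lines, with 0.85 as the
specificity cutoff.

## Comparing conditions and ranking genes

Between a source and an end condition, every source FFL instance is
classified by its surviving edges (3 → no change, fewer → edge loss) and
end-condition instances not fully wired in the source are edge gains.
States are promoter properties, not network properties, so a gene absent
from one condition's network still takes its state from that condition's
gene-state table. The transition test counts, per change group and FFL
position, every (from → to) state pair — including within-state pairs,
which are informative — and compares each frequency with 1,000 artificial
instance sets assembled by uniformly sampling tops and intermediates from
the TF pool and bottoms from the target pool, size-matched to the real
group, three distinct genes per triple. The $p$-value is the fraction of
artificial sets with frequency ≥ the real one; ties count against
significance, and reported values never extrapolate below the 1/1,000
resolution floor. Artificial triples are not themselves re-classified into
change groups — only the group's size is matched; the alternative is
underdetermined by the source description.

Prioritization scores each deduplicated FFL instance (unordered gene
triple) as the sum over its three positions of a symmetric state-change
matrix — activation ↔ repression changes score 10, Poised ↔ Repressed 5,
StrongActivity ↔ WeakActivity 3, identity 0 — plus a flat 5 when the
instance changed structurally (once per instance, not per edge). A gene's
summary score sums over every instance containing it at any position; ranks
are descending with min-rank ties and deterministic gene-id ordering.
Scores are linear in the matrix, so uniform rescaling provably never
reorders genes — the package's reading of the observation that results are
robust to the matrix choice — and the matrix is an argument, not a
constant. Enrichment of a gene set in the top 1% uses the hypergeometric
test against the candidate universe.

## What the synthetic data emulates — and what it does not

`sim_spec()` defines study conditions under which every stage is testable
offline: a scale-free directed background (power-law out-degrees, TF-only
sources), promoters on a disjoint 2-kb tiling so annotation recovery is
exact, one peak per planted edge with its 40-bp summit window inside the
target promoter and its DHS, a segmentation covering each promoter with the
gene's planted state (gaps cycle the four states so all genome-wide totals
are positive), log-normal expression stratified by state, and planted
colored FFLs on dedicated nodes so recovery bounds are exact. The defaults
plant 50 (StrongActivity, StrongActivity, Poised) FFLs — the recovery
target — and 100 (Poised, StrongActivity, StrongActivity) FFLs that feed
the between-condition scenario: 30% of Poised tops flip to StrongActivity,
2% of background genes flip randomly, 20% of planted FFLs lose one edge.
The background (150 TFs, 700 genes) is sized so planted nodes remain a
minority of the regulatory gene pool; the transition test samples its
artificial instances from that pool, and a background dominated by planted
nodes would contaminate its own null — real networks are several orders of
magnitude larger than their FFL complement, and the generator follows that
proportion at desk scale.

What passing these tests does **not** show: real peaks have width and
summit-position noise spanning promoter boundaries; real segmentations
disagree with promoter boundaries and mix states within one promoter; real
networks have assortativity, autoregulation and shared targets between
motifs; and real state calls are themselves model outputs with error. The
synthetic bundles establish correctness of the machinery, not robustness to
those properties.

## Problem sizes and reproducibility

Default analysis sizes follow the published procedure (500 randomized
networks, 10,000 exclusivity permutations, 1,000 transition permutations);
the test suite exercises the same code paths at reduced replicate counts
(25–100 randomized networks, 99–200 permutations) chosen as the smallest
sizes at which the assertions are statistically meaningful. All randomness
flows from one root seed; each stochastic stage derives an independent
child stream (`child_seed()`), so reruns are byte-identical and stages are
reproducible in isolation. The pipeline driver (`run_pipeline()`) logs the
seed, the parameter values and per-stage record counts alongside its
tab-delimited outputs.

## Known limitations

Distal (enhancer-mediated) regulation is out of scope: edges require
promoter binding. One TSS per gene is assumed; per-transcript promoters
must be pre-expanded in the annotation. The exclusivity permutation is
independent per column; gene-set enrichment takes flat sets only; and the
empirical motif $P$ cannot resolve below 1/`n_random`, so strongly planted
classes saturate at the floor rather than producing graded significance.
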