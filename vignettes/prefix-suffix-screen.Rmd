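---
title: "Alignment-free screening for deletion-born fusion genes"
author: "PrefixSuffixScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free screening for deletion-born fusion genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PrefixSuffixScreen)
```

## The problem

Large genomic deletions in bacteria can join the 5' fragment of one
gene to the 3' fragment of another, creating a chimeric open reading
frame at the deletion junction — a *deletion-born fusion*. Because the
deletion itself is often beneficial, the fusion can hitchhike to high
frequency before it has any function of its own. Finding such genes in
genome collections of hundreds of thousands to millions of assemblies
is infeasible with alignment-based methods; this package implements an
alignment-free screen based only on the genomic distance between two
exact k-mer anchors, plus the downstream analyses needed to separate
deletion-born fusions from the main confounder, insertion-disrupted
genes.

## The prefix-suffix distance model

For a query gene of length $L$ we take two anchors: the *prefix* k-mer
at positions $[g, g+k)$ and the *suffix* k-mer at $[L-g-k, L-g)$
(0-based, half-open). Defaults are $k = 27$ and $g = 4$:

* $k = 27$ makes a spurious joint match of both anchors (54 exactly
  matching bases on one contig) vanishingly unlikely;
* the gap $g = 4$ skips the start/stop codons, and because 4 is not a
  multiple of 3 it shifts both windows out of frame relative to the
  CDS, suppressing matches to synonymous codon runs in homologs.

In every genome we locate all exact occurrences of both anchors on
both strands (`findExactMatches()`; ambiguous bases never match). A
locus is measured only when a prefix and a suffix match co-occur on
one contig with one orientation; the span runs from the prefix-window
start to the suffix-window end, so an intact allele gives a span of
$L - 2g$ and a *difference* $\Delta = \text{span} - (L - 2g)$ of 0. A
genome whose anchors sit on different contigs is *missing*;
opposite-orientation pairs are *discordant* (inversions are outside
the distance model). When an anchor matches several times, the pair
minimising $|\Delta|$ is chosen (ties to the smallest prefix
coordinate) — a conservative rule that biases toward the intact
interpretation rather than inflating structural-variant calls.

## Multimodality and the filtering cascade

Per gene, the $\Delta$ values of all non-missing genomes are clustered
with a one-dimensional DBSCAN (sort-and-scan implementation;
`clusterDifferences()`), with neighbourhood radius $\varepsilon = 800$
bp and core threshold `min_samples` = 25 genomes. Each genome is one
point; noise points are excluded from summaries. Cluster ids are
ordered by ascending $|\text{mean }\Delta|$, so cluster 0 is always
the intact-most cluster. Border points between two clusters are
assigned to the lower-valued cluster, making the result deterministic
and order-independent.

The cascade (`screenGene()`) then requires:

1. **multimodality** — at least two non-noise clusters;
2. **peak shape** — one cluster centred near 0 (the intact allele) and
   at least one cluster with mean $\Delta$ > 800 bp (a substantial
   intervening segment, the putative pre-deletion state). The
   tolerance for "centred near 0" is $\varepsilon$ itself, the only
   length scale already present in the clustering model.
3. **ancestral state** — see below.

Genes with only small positive shifts (internal-deletion scale) stop
at stage 1.

## Ancestral state by Fitch parsimony

A positive cluster can mean either a deletion-born fusion (split state
ancestral) or an insertion into an intact gene (intact state
ancestral). To distinguish them we sample up to 300 genomes per gene,
split evenly across clusters (`sampleByCluster()`; undersized clusters
contribute everything and the shortfall is redistributed
proportionally), extract the anchored locus from each genome and mask
it in the genome (`extractAndMask()`), so the tree built next reflects
genome-wide relatedness rather than the structural event itself.

Trees come from bottom-$s$ min-hash sketches ($s = 1000$, sketch k-mer
21) of the masked genomes: the Jaccard index $j$ estimated on the
bottom of the merged hash order is converted to a distance
$d = -\ln(2j/(1+j))/k$, and neighbour joining (with negative branches
clamped to 0) gives the topology. Two candidate outgroups are added;
the tree is rooted on whichever has the larger mean distance to the
other leaves.

Cluster labels are then discrete character states for bottom-up
multi-state Fitch parsimony over the clade spanned by the ingroup
(`fitchMRCA()`). The call at the ingroup MRCA is:

* `split_ancestor` — the MRCA set is exactly one positive cluster and
  at least one leaf carries the zero cluster (a deletion later created
  the fused gene);
* `intact_ancestor` — the MRCA set is exactly the zero cluster (the
  positive peak reflects disruption, typically insertion);
* `ambiguous` — any MRCA set with more than one state; these are
  excluded from fusion calls rather than resolved by an arbitrary
  tie-break.

Note a structural fact about this filter: if the derived clade is
sister to *all* other sampled genomes, Fitch at the MRCA is
irreducibly ambiguous; the call is informative exactly when the
ancestral-state genomes are paraphyletic around the derived clade.
The synthetic-data generator therefore nests event clades inside the
remainder diversity, which is also the realistic configuration.

## Mobile-element annotation and the group test

For each sampled genome of a positive cluster we extract the
*intervening sequence* (between the anchors, anchors excluded) and
compute the fraction of it covered by merged local-alignment hits
against an MGE/prophage database (`mgeCoverage()`; Smith-Waterman,
match 2, mismatch -3, gap open 5, extend 2; 12-column tabular hits can
be imported instead). Coverage fractions of split-ancestral loci are
compared against intact-ancestral loci with a two-sided Mann-Whitney U
test: exact enumeration over group assignments when $n_1 + n_2 \le
20$ (exact under ties), tie-corrected normal approximation otherwise.
Insertion-disrupted loci should be largely explained by mobile
elements; pre-deletion split loci should not.

## Selection on fusion alleles

Two dN/dS-style axes are computed for a candidate fusion
(`estimateSelection()`): against the observed intact alleles, and
against *surrogate pre-deletion genes*. Unique allele sequences are
collapsed with genome counts (`dedupSequences()`), codon-aligned to
the canonical CDS (translate-align-backmap when both sequences are
codon-sized, ends-free nucleotide alignment otherwise), and differing
codons are counted with NG86-style path averaging: multi-site codons
average the per-step synonymous/nonsynonymous classification over all
orderings of single-site paths, excluding orderings that pass through
a stop codon; codons that become stops are tracked separately as stop
gains. Codons overlapping gaps, insertions or ambiguous bases (for
example the NNN joints of surrogates) only increment a skipped-codon
counter. The estimate is the ratio of genome-weighted nonsynonymous to
synonymous counts — raw counts, not per-site-corrected; a per-site
correction would add little at the within-cluster divergences involved
and the raw ratio is the coarser, more honest summary. The ratio is
undefined when the weighted synonymous count is zero.

Surrogates (`buildSurrogate()`) tile the query against a split-state
locus with iterated local alignment, greedily by score with at most
20% query overlap between accepted segments, project each segment into
flanking genome context, take the maximal-overlap predicted ORF (both
strands, starts ATG/GTG/TTG, at least 90 bp, exhaustive enumeration),
and stitch the ORF sequences in query order with NNN joints to
preserve codon-phase ambiguity at the junctions.

## The Wright-Fisher hitchhiking simulator

`runWFReplicate()` implements a minimal forward-time haploid model of
a novel gene: $N$ individuals (default $10^6$) in state 0 (no gene,
fitness 1) or state 1 (non-functional gene, fitness $1-c$). Each
generation applies fitness-proportionate binomial resampling
(selection + drift), then splits the state-1 class by one trinomial
draw: functionalize with probability $p_\mathrm{func}$ (the rate often
written $\mu$) or lose the gene with probability $p_\mathrm{purge}$,
as mutually exclusive outcomes (their interaction is not otherwise
specified by the model; at realistic rates the collision probability
is negligible). A replicate ends at the first functionalized
individual, at extinction of state 1, or at $t_\mathrm{max} = 10^5$
generations. The initial state-1 count is $\mathrm{round}(N
p_\mathrm{init})$ with a minimum of one carrier whenever
$p_\mathrm{init} > 0$ — the lone-carrier case $p_\mathrm{init} =
10^{-6}$, $N = 10^6$ is the anchor for genes born by mechanisms other
than hitchhiking. State-2 fitness never matters because the run halts
at its first appearance.

`sweepFunctionalization()` evaluates a grid (default 20 log-spaced
points of $p_\mathrm{func} \in [10^{-16}, 10^{-2}]$ by 20 of
$p_\mathrm{purge} \in [10^{-8}, 10^{-2}]$, 100 replicates per cell,
seed 42) and records the fraction of replicates that functionalized.
Every (cell, replicate) derives its own RNG substream from the
top-level seed, so execution order cannot change results. The
qualitative outcome — a rare costly gene essentially never
functionalizes, while a gene hitchhiked to high frequency reliably
does once $\mu$ is non-negligible — is what the acceptance checks
assert, on a reduced grid ($5 \times 5$, $N = 10^5$, 50 replicates)
chosen to keep a full run in minutes while preserving the contrast.

## The synthetic-data generator

`generateCollection()` builds the study conditions end to end: a
random ancestor (GC 0.5), a known tree (random coalescent subtrees on
a backbone; event clades monophyletic and nested, as discussed above),
Jukes-Cantor point substitutions along branches, and planted events —
`deletion_fusion` (ancestor carries the two gene fragments separated
by a spacer of the event size; the clade carries the deletion that
fuses them) and `cargo_insertion` (ancestor carries the intact gene;
the clade carries a cargo sequence from a fixed bundled MGE fixture
inserted between the anchors). Two more-divergent outgroup genomes
retain the ancestral configuration. Default scales: 120 genomes of
200 kb, gene length 800 bp, substitution rate 0.01 per site per unit
branch — within-species scales for bacteria that keep a full run on a
single CPU in well under five minutes.

Design choices worth knowing:

* substitutions only — indels enter exclusively through planted
  events, so the truth table of expected differences is exact;
* the engineered loci sit in *protected zones* that mutations never
  touch, making anchor survival certain by construction (the
  detection-sensitivity question of anchors mutating away is real but
  orthogonal to what these fixtures test);
* fragment boundaries are flanked by in-frame stop codons and the
  downstream fragment starts with its own ATG, so ORF prediction on a
  split locus recovers the two fragments cleanly — this makes
  surrogate reconstruction exactly checkable;
* what the generator does **not** emulate: real bacterial composition
  (GC skew, operons, repeats), recombination, assembly fragmentation,
  and anchor-destroying terminal mutations. Passing tests therefore
  demonstrate correctness of the machinery under the stated model,
  not screen sensitivity on real collections.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally and in all outputs;
  the 1-based inclusive convention of tabular alignment files is
  converted on import.
* DBSCAN border ties go to the left (lower-valued) cluster; cluster
  means use assigned points only.
* An empty difference distribution is an error; a genome without a
  same-contig anchor pair is the value `missing`, not an error.
* Identical sketches across all genomes abort tree building (a star
  tree carries no ancestry signal).
* Mash distances are capped at 1; zero shared hashes give distance 1.
* Mann-Whitney exact enumeration is used through $n_1+n_2 = 20$
  (at most 184,756 assignments).
* All stochastic components (sampling, simulator, generator) take
  explicit seeds and restore the caller's RNG state.

## Scales used by the checks

The acceptance script and test suite regenerate everything from
scratch: one 120-genome/200 kb collection with a 5 kb deletion in a
40-genome clade; one 60-genome/60 kb collection with eight deletion
and eight insertion loci (3 kb cargo); oracle batteries of 50 contigs,
100 clustering instances and 200 random trees; 2000 neutral-drift and
500 waiting-time replicates; and two 5x5 sweeps at $N = 10^5$. These
sizes are the package's own trade-off between statistical resolution
and a desk-scale single-CPU run.

## Worked example

```{r example, eval = FALSE}
sc <- generateCollection(
    nGenomes = 120, genomeLen = 200000,
    events = plantedEvent("deletion_fusion", cladeSize = 40,
        size = 5000), seed = 11)
scr <- screenCollection(sc@queryGenes, sc@genomes)
res <- classifyGeneAncestry(scr$queries[[1]], scr$measurements,
    sc@genomes, sc@outgroups, seed = 9)
clusters(res$clusterSet)
res$ancestralCall
```

On this collection the screen finds two clusters at mean differences
0 (40 genomes, the fused clade) and +5000 (80 genomes, the ancestral
split state), and Fitch parsimony at the ingroup MRCA returns the
split cluster — a stage-3 putative deletion-born fusion.

## Known limitations

* Exact anchors make the screen conservative: one substitution in
  either window hides a genome from the gene entirely.
* The hash-table matching backend targets desk scale; an FM-index
  backend satisfying the same contract is the route to millions of
  genomes.
* Fitch parsimony reports ambiguity rather than resolving root-edge
  ties; candidate loci whose derived clade is basal among the samples
  are systematically excluded.
* Uncorrected dN/dS is coarse and terminal variation inside the
  anchor windows is invisible to it.
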