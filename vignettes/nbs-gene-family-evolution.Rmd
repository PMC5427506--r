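---
title: "Methods: comparative evolution of NBS-encoding resistance genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative evolution of NBS-encoding resistance genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsevol)
```

## The problem

Plant disease-resistance genes of the NBS (NB-ARC, Pfam PF00931) family are
among the most dynamic gene families in plant genomes: they expand by
tandem, ectopic and segmental duplication, contract by gene loss, and their
copy numbers differ several-fold even between close relatives such as
tomato, potato and pepper. `nbsevol` implements the comparative toolkit for
studying this turnover across a small set of related genomes:

1. **Classification** of each gene into a subclass (TNL, CNL, RNL) and an
   architecture category (intact, TN/CN/RN, NL, N).
2. **Chromosomal organization**: tandem-cluster assignment under a distance
   rule and summary statistics.
3. **Duplication–loss reconciliation** of gene trees against the species
   tree, with per-branch gain/loss ledgers and ancestral copy numbers.
4. **Duplication typing** (tandem / ectopic / segmental / unanchored) from
   cluster membership and simplified collinearity blocks, plus cross-genome
   locus-conservation classes.
5. A **birth–death simulator** that generates all of the above inputs with
   complete ground truth, used as the test harness for every other module.

The package never runs BLAST, HMMER or tree inference itself: gene
coordinates, domain calls, motif strings, trees and anchor pairs are
inputs, produced by standard upstream tools or by the simulator.

## Classification

A gene qualifies as NBS-encoding only if its domain-call list contains the
NBS domain. The architecture category is read off the N-to-C domain order:
an N-terminal domain (TIR, CC or RPW8) counts only when it occurs *before*
the NBS, the LRR module only when it occurs *after* it. A misplaced domain
(an upstream LRR, say) is ignored with a warning, since the categories
presuppose the canonical N-terminal–NBS–LRR layout. Both flanks present
gives `intact`, only the N-terminal flank `TN`, only the LRR `NL`, neither
`N`.

The subclass is decided by evidence in a fixed priority order:

1. an explicit N-terminal domain (TIR → TNL, CC → CNL, RPW8 → RNL);
   contradictory N-terminal domains leave the gene unclassified;
2. diagnostic residues in the six conserved NBS motifs (P-loop, Kinase-2,
   Kinase-3, RNBS-C, GLPL, RNBS-D): a proline at Kinase-2 position 1
   together with a cysteine at RNBS-C position 10 → RNL; an aspartate at
   the final Kinase-2 position → TNL; a tryptophan at RNBS-C position 7
   together with an aspartate at GLPL position 13 → CNL. The RNL
   conjunction is tested first because it is the rarest signature and
   would otherwise be shadowed by the TNL terminal-D rule whenever an RNL
   Kinase-2 happens to end in D;
3. the nearest classified neighbour on a supplied gene tree (breadth-first
   topological distance, deterministic tie-break by leaf order). These
   assignments are flagged `neighbor` in the output, because they are an
   inference, not an observation. This is also the mechanism by which
   NBS-only (`N`) genes, which carry no N-terminal evidence, receive a
   subclass.

Before tree-based analyses, `phylogeny_length_filter()` drops genes whose
NBS domain is at most `floor(2/3 × 290) = 193` aa. The 290-aa reference
length and the two-thirds fraction are both exposed in `filter_config()`;
the threshold is made integral (keep iff `nbs_len ≥ 194`) so the rule is
exact and reproducible. Genes with no measurable NBS length are dropped as
`unalignable` — the package does not realign sequences, so alignment-based
"too divergent" removal is represented by this explicit proxy.

## Chromosomal clusters

Two genes on the same chromosome belong to one cluster when their
start-to-start distance is at most 250 kb (`cluster_config()`; the metric
can be switched to end-to-start). Chaining is transitive, i.e. single
linkage: A–B and B–C within the threshold place A and C in one cluster
even when A–C exceeds it. Clusters need at least two members; the rest of
the anchored genes are singletons, and genes without a chromosome are
reported separately as unanchored. Ties at identical start coordinates are
broken by gene id, which makes the partition independent of input order.
All coordinates throughout the package are 1-based inclusive (GFF3
convention): a gene of length 1 has `start == end`.

Only NBS genes are considered when measuring gaps; intervening non-NBS
gene content is ignored, matching how published locus lists for this
family are constructed.

## Reconciliation and the gain/loss ledger

`lca_reconcile()` is standard duplication–loss parsimony with unit costs.
Every gene-tree node is mapped to the last common ancestor of its leaves'
species; a node is a duplication when it maps to the same species-tree
node as one of its children. Along each gene-tree edge, every species-tree
node crossed between the parent's and the child's mapping implies one loss
on the branch to that node's off-path child (with the parent's own node
included when the parent is a duplication). For a fixed rooting this
mapping minimises duplications + losses; the test suite checks this
against an exhaustive scenario minimiser on hundreds of random gene trees.

Unrooted trees are handled by `root_search()`, which scores every branch
as a root position and keeps the rooting with the fewest events, breaking
ties by fewer duplications and then by the lexicographically smallest leaf
label in the smaller daughter clade, so results are canonical. Polytomies
are rejected by default; `polytomies = "resolve"` applies a greedy
resolution that joins children with the deepest common species mapping
first (same-species children pair up first, minimising spurious
duplications) and flags the result. A basal multifurcation in Newick is
indistinguishable from an unrooted tree, so both are routed through the
same policy.

`tally_branches()` aggregates a forest of per-family reconciliations into
per-branch gains and losses plus the ancestral lineage count A: each
family contributes one root lineage, plus one more for every duplication
mapped to the species-tree root. A family whose root maps *below* the
species root is counted as present from the root, with one loss on the
off-path branch at every species-tree node crossed down to its mapping.
This origin-at-root convention keeps the additive ledger exact on every
branch — `ledger_check()` verifies `c(child) = c(parent) + gains − losses`
and reproduces observed tip counts by construction — and matches the
framing in which all extant genes descend from a fixed set of ancestral
genes. The alternative (counting late-originating families as gains on
the branch where they first appear) would leave the upper branches of the
ledger silent about those families.

When subclass labels are available, families can be reconciled as separate
per-subclass forests and tallied independently; the ledger then reports
per-subclass ancestral counts and branch totals.

## Collinearity blocks and duplication typing

`find_collinear_blocks()` is a deliberately simplified collinearity
finder: anchors (putative homologous gene pairs) are chained when their
gene-order indices are strictly monotone on both sides — same or inverted
orientation — with successive index gaps of at most `max_gap_genes` on
both sides; chains need `min_anchors` anchors, and blocks are extracted
greedily longest-first so each anchor is used at most once. The defaults
`min_anchors = 5`, `max_gap_genes = 25` are the ones conventionally used
by collinearity tools in this field. The quadratic longest-chain dynamic
program is exact (checked against exhaustive subset search in tests).

Only duplications mapped to *terminal* species-tree branches are typed:
their two copies both live in one extant genome, so their positions are
observable. The precedence is: `unanchored` (either copy lacks a
chromosome) over `tandem` (both copies share a cluster) over `segmental`
(the pair is an anchor inside a within-genome block, or both copies lie
within `max_gap_genes` gene-order positions of one block's two sides)
over `ectopic` (everything else). Tandem outranks segmental because the
cluster criterion is positionally more specific; the block-flanking window
exists because NBS genes themselves are often not anchors of the blocks
that carried them. Both choices are explicit parameters, since no
operational standard exists for separating segmental from ectopic beyond
synteny membership.

Locus conservation links loci (clusters and singletons) across genomes
when a member gene of one locus is anchored, inside a *cross-genome*
block, to a member gene of another. Connected groups of loci are classed
by the set of genomes they span (all-three, one pair, species-specific),
and the class counts count each group once, so per-genome locus totals
decompose exactly into 3×(all-three) + 2×(pairs) + singles.

## The simulator

`simulate_forest()` evolves each ancestral gene independently along the
species tree under a continuous-time birth–death process: exponential
waiting times between events (so event order within a branch is well
defined, which a per-branch Poisson count would not give), duplications
copying a lineage with a mechanism drawn from the tandem/ectopic/segmental
mix, losses deleting one. Surviving lineages at the tips become gene
records; the full event log, pruned true gene trees, homology pairs and
labels are returned as ground truth, and replaying the log reproduces the
tip counts exactly (asserted in tests).

Defaults are chosen to emulate a three-species Solanaceae-like comparison:
species tree `((tomato,potato),pepper)` with unit-length internal
branches; 176 ancestral families (150 CNL, 22 TNL, 4 RNL); duplication
rate 0.3 and loss rate 0.2 per lineage per unit branch length, giving
forests of several hundred tip genes with visible turnover on every
branch; a mechanism mix of 59 % tandem, 39 % ectopic, 2 % segmental,
mirroring the relative contributions reported for this family; and
architecture-erosion probabilities (`p_lose_nterm = 0.55`,
`p_lose_lrr = 0.40`) that reproduce realistic intact/TN/NL/N proportions.

`place_genes()` makes the mechanisms positionally real. Every family owns
a base locus laid out in the same order along every species' chromosomes
(12 chromosomes of 60 Mb, base loci 400 kb apart — farther than the
250-kb cluster rule, so distinct families do not merge into clusters).
Original lineages sit at the base locus; tandem copies land 5–100 kb from
their parent copy; ectopic copies at uniform random genome positions;
segmental copies in a fresh region together with five filler genes whose
anchor pairs make the copied block detectable by the block finder. Anchor
pairs between surviving original copies of each family provide the
cross-genome collinearity used by the locus-conservation analysis.

`emit_motifs()` writes the six motif strings from per-class consensus
sequences; each residue matches the consensus with probability
`motif_fidelity` and is otherwise uniform over the 20 amino acids. The
non-diagnostic background comes from the consensus rather than from noise:
a fully random background would create a spurious diagnostic signature
roughly once per twenty genes and make perfect recovery impossible even
at fidelity 1. At fidelity 1 the motif classifier recovers every label; at
fidelity 0 it falls to the level supported by surviving N-terminal
domains.

What the simulator does *not* emulate: nucleotide-level sequence
evolution and alignment noise, selection, pseudogenisation, gene
conversion between paralogs, assembly artefacts, and real gene-density
variation along chromosomes. Passing recovery tests therefore show that
the analysis modules are correct on data that obey their assumptions —
not that those assumptions hold for any particular real genome.

## Numerical conventions and degenerate inputs

* Report rounding is fixed: ratios to 2 decimals, percentages to 1
  decimal, so written tables are string-stable across runs.
* A species with clustered genes but no singletons reports an infinite
  clustered/singleton ratio rather than an error; empty inputs yield
  empty (header-only) tables.
* Single-gene families are valid gene trees (`(g1_tomato);`) and
  reconcile to zero events plus the origin-at-root losses.
* Duplicate start coordinates, cluster ties and block ties are all broken
  deterministically (gene id, leaf order, extraction order), so every
  pipeline output is byte-identical for identical inputs and seed.
* Multi-transcript inputs: when isoform-tagged ids (`gene.1`, `gene.2`)
  are detected, the reader keeps the longest model per gene and logs the
  collapse.

## Problem sizes used by the test suite

The bundled suites run at desk scale, chosen to finish in seconds while
still exercising every code path: the reconciliation oracle compares 500
random gene trees of up to 6 leaves against exhaustive minimisation; the
cluster oracle 200 random instances of up to 50 genes; recovery suites use
forests of 100 families (loss-free exact recovery) and the 176-family
default configuration (subclass recovery and mechanism typing). Genome
-scale gene counts for real species require the corresponding assemblies
and annotations, which the package treats strictly as user inputs; the
bundled published count tables under `inst/extdata/` let the summary
arithmetic (proportions, ratios, the branch ledger) be reproduced without
them.

## Known limitations

* Reconciliation is parsimony with unit costs; with substantial loss the
  inferred event counts are a lower bound on the true ones (asserted, not
  corrected). No likelihood model, transfers, or divergence-time use.
* The collinearity finder is a monotone-chain heuristic, not a full
  collinearity package: no e-value model, no weighting by similarity
  scores, greedy block extraction.
* Duplication typing covers terminal-branch events only; internal-branch
  duplications cannot be positionally typed from extant genomes.
* The motif classifier reads fixed diagnostic positions; it does not
  align or discover motifs.
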