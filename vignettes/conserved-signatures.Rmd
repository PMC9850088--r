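---
title: "Methods: conserved cross-species signatures of intestinal inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved cross-species signatures of intestinal inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucsig)
```

## Scientific question

How much of the transcriptional response in DSS-induced mouse colitis is
conserved in human ulcerative colitis? `ucsig` answers this by calling
significant differential expression independently in each species,
combining heterogeneous human cohorts into one robust signature,
projecting the mouse signature onto it through orthology, and then
prioritizing the conserved genes by network centrality, genomic context
and enrichment, with qPCR-style validation arithmetic at the end.

## Significance filtering

A gene is significantly differentially expressed (SDE) when its
BH-adjusted p-value is **at most 0.05** (the boundary is significant)
*and* it clears an effect-size floor:

* total-RNA assays: **|log2FC| > 1** (strict; a two-fold change exactly
  does not qualify),
* small-RNA assays: **fold change > 1.5**, i.e. |log2FC| > log2(1.5),
  reflecting the compressed dynamic range of miRNA quantification.

Missing adjusted p-values are treated as not significant — the common
cause is independent-filtering NA from the upstream DE tool, and
imputing significance there would be anti-conservative. Genes with
log2FC exactly 0 carry no direction and are excluded. Direction is the
sign of log2FC. `tally_by_biotype` summarizes an SDE set as up/down
counts per biotype over the closed vocabulary `pcg`, `lncrna`, `mirna`,
`other` (unknown labels are coerced to `other` with a warning).

## Combining human cohorts

Human UC data come from multiple cohorts with different platforms and
power. `combine_datasets` requires a gene to be significant (adjusted
p ≤ 0.05) in at least `min_support` cohorts (default 2) and to have
**agreeing fold-change signs across its significant cohorts** —
non-significant cohorts do not vote on direction. Genes meeting the
support threshold with conflicting signs among significant cohorts are
placed in an explicit *inconsistent* partition: they are real signal of
cohort heterogeneity and are reported, but never enter the signature.
Setting `min_support` above the number of supplied cohorts is allowed
and yields an empty signature — degenerate configurations exit cleanly
rather than erroring.

miRNAs follow a dedicated two-cohort rule (`combine_mirna`): with
exactly two small-RNA cohorts, one significant cohort suffices
(provided any second observation does not significantly contradict it),
and the output records whether both cohorts supported the call. The
relaxed path used for cross-species miRNA comparison
(`relaxed_mirna_overlap`) loosens the cutoff to adjusted **p < 0.1
(strict)** with no fold-change floor, acknowledging the low power of
small-RNA profiling; the stringent call is by construction a subset of
the relaxed one.

## Cross-species overlap

Orthology is given as mouse→human pairs labeled `one2one` or
`one2many`; a `one2one` gene may appear in exactly one pair, while
`one2many` fan-outs are first-class. `overlap_species` enumerates every
(mouse SDE, human SDE) orthologous pair and classifies it by the
direction pair: up/up → `concordant_up`, down/down → `concordant_down`,
anything else → `contra`. Gene-level tallies count **distinct mouse
genes**, and a mouse gene with several human orthologs is concordant if
*any* of its pairs is — the biological claim is "this mouse gene has a
conserved response", which one concordant ortholog establishes.

The tissue **core set** (`core_set`) keeps mouse genes concordant in
*both* colon and blood. Whether the direction also agrees *between*
tissues is kept as an annotation (`cross_tissue_agreement`), not used as
a filter: a gene up in inflamed colon and down in circulating blood is
still a conserved, interpretable responder.

`tally_concordance` also accepts raw class counts directly
(`tally_concordance(n_up_up, n_down_down, n_contra)`), so published
summary tables can be pushed through the same arithmetic as computed
overlaps.

## Genomic context

Intervals are **1-based and fully inclusive**. The distance between two
non-overlapping intervals is the gap between them,
`later.start − earlier.end` (overlapping or touching intervals have
distance 0), and a neighbor qualifies when that distance is **≤ the
window (100 kb by default), inclusive at the boundary**. This is
deliberately *not* the `GenomicRanges::distance` convention (which
counts the positions strictly between the intervals); the gap convention
here keeps the worked arithmetic in reports simple, and BED input is
converted to 1-based coordinates at the reading boundary
(`read_bed_loci`). lncRNA neighbor assignment (`lncrna_neighbors`)
anchors on the **gene body** by default — regulatory reach of a lncRNA
locus is not confined to its TSS — with `anchor = "tss"` available;
by default only expressed protein-coding genes are eligible neighbors.
`risk_locus_proximity` applies the same window logic to disease-risk
loci.

## Enrichment

`enrich` is the classical one-sided hypergeometric over-representation
test: with a universe of size N, a term of size K, a query of size n and
k hits, the p-value is `phyper(k − 1, K, N − K, n, lower.tail = FALSE)`.
Query genes outside the universe are trimmed with a warning; terms
smaller than `min_term_size` (default 3) are skipped. Multiple testing
uses Benjamini–Hochberg via `stats::p.adjust`; `gene_ratio = k / K`.
Results are ordered by (FDR, p, term id) so output is stable.

## Network prioritization

Candidate genes are ranked on a confidence-scored interaction network
(STRING-style; scores on 0–1000 are divided by 1000 at import, and the
default inclusion cutoff is **0.4, STRING's "medium confidence"**
threshold — a deliberate balance between coverage and noise for a
prioritization, as opposed to a validation, task). Three complementary
measures are computed with `igraph`:

* **degree** — direct interaction count (confidence-weighted strength
  when edge weights are enabled);
* **harmonic closeness** — mean inverse shortest-path distance,
  well-defined on disconnected networks (unreachable nodes contribute
  0);
* **betweenness** — shortest-path betweenness normalized by the number
  of node pairs.

Each measure is min-max scaled over the node set (a constant measure
scales to 0.5 for every node, i.e. it is uninformative and neutral) and
the three are combined as an **unweighted mean** by default: absent
evidence that one topological aspect matters more than another,
equal weights are the assumption that is easiest to interrogate, and
`combined_rank(weights = …)` exposes the knob. Ranks are dense (ties
share a rank) and tied rows are ordered by node id, so results are
bit-stable. With confidence weighting on, path computations use edge
length `1 − confidence + 1e−6`; the epsilon keeps perfect-confidence
edges at a positive length.

## qPCR validation

`ddct_fold_change` implements Livak's 2^(−ΔΔCt): technical replicates
are averaged arithmetically on the Ct scale (Ct is already logarithmic,
so the arithmetic mean of Ct is the geometric mean of abundance — the
appropriate pooling); the per-sample reference is the **arithmetic mean
Ct of the reference panel** (GUSB, B2M, ACTB, TBP by default), which
equally weights the panel genes on the log scale; ΔΔCt is the
difference of group-mean ΔCt between case and control, computed per
tissue.

## Synthetic study generator

The generator's defaults *are* the modeled study design: one mouse
dataset and four human cohorts per tissue, colon and blood, with 50
concordant-up, 30 concordant-down, 20 contra-regulated, 15
direction-inconsistent, 25 species-specific and 500 null genes
(biotypes 70% pcg / 15% lncrna / 15% other). Planted effects have
|log2FC| ~ around μ = 3 with noise σ = 0.5; adjusted p-values for
"fired" genes are drawn from U[0, 0.05] and for silent genes from
U(0.05, 1], so the significance boundary is exercised from both sides.
Two design decisions matter for interpretation:

* **Sign reflection**: planted fold-change *signs* are exact at any
  noise level (noise perturbs magnitude only), so direction-based truth
  (concordance classes) is recoverable exactly even at σ > 0, while
  magnitude-based statistics remain noisy. The generator validates
  direction logic, not effect-size estimation.
* **Scope**: the generator plants marginal per-gene signals with
  independent noise. It does not model inter-gene correlation,
  library-size effects, batch structure or p-value miscalibration; it is
  a correctness instrument for the pipeline logic, not a benchmark of
  upstream DE inference.

Companion generators produce matched orthology (with controllable
one-to-many and unmapped fractions; only null genes are remapped so
planted truth is untouched), gene loci with a brute-force neighbor
truth, hub-planted networks, Ct tables realizing chosen fold changes
exactly at zero noise, target maps and gene-set collections with one
planted enriched term. Problem sizes throughout (e.g. 640 genes, 1000
loci, ≤ 60 noise nodes) are the package's own choices, sized so the
full test suite — including brute-force oracles — runs in well under a
minute.

## Determinism and reproducibility

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state (`with_seed`). `run_pipeline` writes no timestamps,
so two runs with the same configuration produce byte-identical
artifacts; the test suite asserts this. `scripts/acceptance.R --seed
<int> --out <path>` recomputes the headline quantities against the
installed package and writes them as JSON.
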