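---
title: "Methods: regulatory barcodes and venom-gland heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory barcodes and venom-gland heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxreghet)
```

## The scientific question

Elapid snake venom glands do not express their toxin arsenal uniformly:
different secretory cells specialize in different toxin paralogs, and
functionally distinct paralogs (e.g. cytotoxin-like vs neurotoxin-like
three-finger toxins) occupy different regions along the gland's
anterior-posterior axis. `toxreghet` implements an integrative analysis that
asks *why*: it characterizes each toxin gene by its **regulatory barcode** —
the set of transcription factors (TFs) with predicted binding sites in its
promoter — and then tests whether barcode similarity, rather than physical
genomic proximity, tracks the co-expression and spatial co-occurrence of
toxins across the gland.

The pipeline chains six analysis stages:

1. **expression** — single-cell QC (cells with >= 1000 counts and >= 100
   detected genes are kept, both thresholds inclusive), Louvain clustering,
   toxin-cell classification via epithelial markers (LAMA3/EPCAM-style),
   pseudo-bulk construction, TMM normalization against a bulk library, and a
   clr-based expression-divergence test.
2. **coexpr** — weighted co-expression modules on toxin cells: soft
   threshold for scale-free topology, adjacency, topological overlap (TOM),
   fixed-height tree cut with a minimum module size of 30, eigengene-based
   merging at dissimilarity 0.2, and module-trait correlation.
3. **regnet** — 500 bp TSS-anchored promoter extraction, PWM scanning of
   JASPAR-style motif records, candidate-TF calling ("at least one binding
   site" for a toxin-module TF), and randomized regression-tree TF -> toxin
   importance weights.
4. **evodist** — p/JC69 distances from aligned promoters and peptides,
   neighbor-joining trees, patristic distance matrices.
5. **spatial** — Pearson co-occurrence of per-toxin ion images over the
   gland mask, intensity-weighted axis centroids, one-way ANOVA of centroid
   by functional group.
6. **integrate** — barcode Jaccard similarity, midpoint genomic distance
   (same-scaffold pairs only), the pairwise-matrix Pearson correlation
   engine with an optional Mantel permutation p, GRN assembly with
   protein-link edges, and degree / betweenness centralities.

## Key statistics and their definitions

**Expression divergence.** CPM profiles are compositional, so both the
pseudo-bulk and bulk profiles are centered-log-ratio transformed,
`clr(x)_g = ln x_g - mean(ln x)`, after replacing zeros by half the smallest
nonzero CPM (configurable). Because neither axis is an error-free reference,
the null line through the non-toxin cloud is fitted by total least squares
(first principal axis), and each gene's divergence is its *signed orthogonal
distance* from that line. The null band is the central 99% of non-toxin
residuals — two-sided (0.5th to 99.5th percentile), matching the two dashed
bounds such comparisons draw; a toxin is flagged iff its residual leaves the
band. By construction ~1% of null genes fall outside, which the test suite
verifies on 5000 simulated genes.

**Topological overlap.** Adjacency is `|cor|^beta` (unsigned by default; the
signed variant `((1+cor)/2)^beta` is a flag), and
`TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`. The
scale-free fit index bins log10 connectivity into 10 equal-occupancy bins
and regresses log10 p(k) on log10 k; the index is the squared correlation,
set to 0 when the slope is positive. The chosen power is the smallest one
reaching fit 0.8, else the argmax with a warning. Module detection cuts the
average-linkage tree of `1 - TOM` at a fixed height (default 0.99) and
discards clusters below 30 genes instead of using dynamic tree cutting: the
fixed cut is deterministic and adequate for block-structured data, and the
height is exposed for real datasets.

**Merging.** "Correlation threshold of 0.2" is interpreted as an eigengene
*dissimilarity* cut: module pairs with `1 - cor(E_a, E_b) < 0.2` (i.e.
correlation > 0.8) are merged iteratively, recomputing eigengenes, to a
fixed point. The eigengene is the first principal component of the module's
standardized expression, oriented to correlate positively with the module
mean and scaled to unit variance.

**PWM scanning.** Position frequency matrices become log2-odds PWMs with a
pseudocount of 1 distributed by the background (uniform by default):
`PWM_bi = log2((n_bi + bg_b) / (N_i + 1) / bg_b)`. Every window on both
strands scoring at least `score_fraction` (default 0.85, a "deficit" of
0.15 — the cited scanner's documented default; the paper does not state its
threshold) of the motif's maximum attainable score is reported; `N` bases
contribute 0. Overlapping hits all count, so a promoter can carry several
sites for one TF.

**Importance weights.** Per target, an ensemble of randomized regression
trees (bootstrap per tree, sqrt-mtry feature sampling, best SSE split) is
fitted with TF expression as predictors; a TF's importance is its total
variance reduction, normalized to sum one per target. This is authored in
compiled code inside the package with a self-contained deterministic RNG —
no random-forest package of the appropriate kind is assumed — and the suite
checks that the true simulated regulator ranks first.

**Trees and patristic distances.** The likelihood tree search of the
original workflow is deliberately replaced by neighbor joining over p/JC69
distances: it is deterministic, exactly recovers additive matrices, and the
analysis-critical quantity is the *patristic distance correlation*, not the
tree itself. Ties in the Q criterion break lexicographically so the output
is a pure function of the input; an externally inferred Newick tree can be
supplied directly to `patristic()`. Gap handling is pairwise deletion (the
original's gap policy is unstated).

**Matrix correlations.** All integrative claims are Pearson correlations
over upper-triangle pairs complete in both matrices (cross-scaffold genomic
distances are missing by design). Because pairwise entries are not
independent, `matrix_correlation()` optionally adds a Mantel permutation p
(label permutation of one matrix); the default is off to mirror the plain
tests the source analysis reports, and the suite verifies the permutation
test holds its 5% size under independence.

## The synthetic world

The generator exists so that every stage is verifiable without the deposited
genome, scRNA-seq and imaging data. It states one world; its defaults are
not tuned per test.

* **Gene family.** A pure-birth tree; promoters (500 bp) and coding
  sequences evolve along the same topology under uniform Jukes-Cantor
  substitution (no indels, so outputs are already aligned). Functional
  groups are clades. Motifs evolve as per-branch gain/loss processes:
  shared TFs are present at the root, group TFs can only be gained inside
  their clade; at the tips each present motif overwrites the TF consensus at
  a TF-specific, non-overlapping offset (losses leave evolved background).
  Genes are laid out in tandem in tree order over two scaffolds, so genomic
  distance tracks phylogenetic distance, as in real toxin arrays.
* **Cells.** Counts are negative binomial with log-normal depths
  (mean 5000). A toxin's mean is
  `depth x weight x (leak + sum of planted TF activities)`; TF transcripts
  co-vary with their activities, so regulation is recoverable from
  expression. Populations: one secretory population per group (60% of cells
  in total, marker-positive) plus a marker-negative rest.
* **Sections.** Each toxin's ion image is a masked Gaussian profile along
  the anterior-posterior axis centered at its group's position (defaults
  spread over 0.2-0.8) plus truncated pixel noise; intensity outside the
  gland mask is exactly 0.

**Calibrated effect sizes.** The source study does not report how strongly
TF programs drive toxin expression, so the following were chosen once, on
biological grounds, and frozen: 2 shared + 4 group-specific TFs per group
(a small shared competence program, a larger specific one); cross-group
activity 0.02 (strong but not absolute partitioning); NB dispersion 0.1
(typical UMI overdispersion for moderately expressed genes); TF-activity
noise is *mean-preserving log-normal* (sd 0.15) — multiplicative noise keeps
silent populations exactly silent, where additive noise would leak toxin
expression into non-secretory cells; and three groups by default, matching
the three toxin co-expression modules and the several co-regulated toxin
families of the real gland. The three-group default also matters
statistically: with exactly two mutually exclusive programs, the *other*
group's TFs are precisely as informative to a regression tree as the true
regulators (the split is the same, inverted), and no importance measure can
separate them; with three or more programs the true regulators dominate.

**What a green test does not establish.** The generator omits doublets,
ambient RNA, isoform structure, indels and alignment error, chromatin
state, realistic mass spectra, and batch effects. Recovery at defaults
demonstrates that the implementations are correct and that the integrative
logic behaves as designed on data with the assumed structure — not that the
pipeline is robust to every artifact of real single-cell or imaging data.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed through a named-stream splitter
  (`substream_seed()`), so adding a component never perturbs another's
  draws; the compiled tree ensemble carries its own xorshift RNG.
* Constant genes/images yield missing correlations with warnings rather
  than errors; all-zero libraries and empty masks are errors naming the
  offender.
* clr requires positivity; zeros receive half the smallest nonzero value.
* Negative NJ branch lengths clamp to zero with a warning; JC69 is
  undefined at p >= 3/4 (missing, with a warning).
* Promoters are clamped at scaffold edges with a warning; a TSS outside its
  scaffold is an error.
* Cluster labels, module labels and NJ joins all have deterministic
  ordering/tie-break rules so repeated runs are bit-identical.

## Known limitations

Module counts on real data are resolution- and cut-height-dependent and are
not expected to match any particular published count. The fixed-height tree
cut requires within-module correlations to be strong after soft
thresholding; weak, nested module structure calls for dynamic cutting,
which is out of scope. The Pearson co-occurrence of ion images stands in
for an unpublished proprietary statistic; its sign structure, not its
magnitude, is the reproducible quantity, and a cosine alternative is
provided behind a flag.
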