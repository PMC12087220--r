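# toxreghet

Regulatory barcodes and the cellular/spatial heterogeneity of toxin
production in a snake venom gland.

Venom glands partition toxin production: individual secretory cells
specialize in subsets of toxin paralogs, and functionally distinct paralogs
(cytotoxin-like vs neurotoxin-like three-finger toxins) occupy different
regions along the gland's anterior–posterior axis. `toxreghet` asks what
organizes this heterogeneity. It characterizes each toxin gene by its
**regulatory barcode** — the set of transcription factors (TFs) with
predicted binding sites in its 500 bp promoter, `B_g` — and tests whether
barcode similarity `J(g,h) = |B_g ∩ B_h| / |B_g ∪ B_h|`, rather than
physical genomic distance `|mid_g − mid_h|`, tracks toxin co-expression
(Spearman ρ across single cells), spatial co-occurrence (Pearson r of ion
images across the gland section), and promoter/peptide co-evolution
(correlation of patristic distance matrices from neighbor-joining trees).

The package implements the full chain as reusable, tested functions:

| stage      | functions |
|------------|-----------|
| expression | `filter_cells()`, `cluster_cells()`, `classify_toxin_cells()`, `pseudobulk_and_normalize()` (TMM via edgeR), `clr_divergence()`, `spearman_coexpression()` |
| coexpr     | `pick_soft_threshold()`, `adjacency_matrix()`, `tom_similarity()`, `detect_modules()`, `eigengenes_and_membership()`, `merge_modules()`, `module_trait_correlation()` |
| regnet     | `extract_promoters()`, `read_pfms()`, `pwm_scan()`, `call_candidate_tfs()`, `importance_network()` (Rcpp tree ensemble) |
| evodist    | `pairwise_distance()`, `neighbor_joining()`, `patristic()` |
| spatial    | `spatial_correlation()`, `axis_localization()`, `group_location_test()` |
| integrate  | `jaccard_matrix()`, `genomic_distance()`, `matrix_correlation()` (optional Mantel p), `build_grn()`, `centralities()` |
| syndata    | `simulate_family()`, `simulate_cells()`, `simulate_sections()`, `write_fixture()`, `simulate_venom_fixture()` |

plus `run_pipeline()`, which orchestrates everything over a fixture
directory and writes TSV outputs and a JSON report.

A synthetic-data module generates a complete, self-contained venom-gland
world — a tandem toxin family co-evolving on one tree, planted TF motif
barcodes, population-structured negative-binomial single-cell counts, and
gland sections with an anterior–posterior group gradient — so every stage is
verifiable without the original sequencing, imaging or genome data. See the
methods vignette (`vignettes/toxreghet-methods.Rmd`) for the models,
parameter defaults, and their rationale.

## Worked example

```r
library(toxreghet)

dir <- tempfile()
simulate_venom_fixture(dir, seed = 1, n_genes = 20, n_cells = 400)
report <- run_pipeline(dir, file.path(dir, "out"), seed = 1, n_trees = 200)
report$correlations
```

```
                     comparison          r            p n_pairs mantel_p
1 promoter_vs_peptide_patristic  0.9402990 6.203570e-90     190       NA
2       jaccard_vs_coexpression  0.9194266 3.985714e-78     190       NA
3   jaccard_vs_genomic_distance -0.4009765 8.984428e-05      90       NA
4            jaccard_vs_spatial  0.9296715 1.825506e-83     190       NA
5   genomic_distance_vs_spatial -0.4291185 2.441422e-05      90       NA
6       coexpression_vs_spatial  0.9182705 1.438936e-77     190       NA
```

Reading the rows: promoter and peptide patristic distances are strongly
positively correlated (the family co-evolves); toxins sharing more of their
TF barcode are more co-expressed across cells and more co-localized across
the gland section; and genomic distance correlates *negatively* with spatial
co-occurrence — near neighbours co-occur — but much more weakly than the
barcode does. `n_pairs` drops to 90 for genomic comparisons because pairs on
different scaffolds are undefined by construction. On this fixture the
pipeline kept 399/400 cells through QC, called 237 toxin cells, and
assembled 14 candidate regulator TFs into the TF→toxin network
(`report$n_candidate_tfs`; per-node degrees and betweenness are in
`out/centralities.tsv`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full analysis from scratch at the given seed: it simulates a
fixture, runs `run_pipeline()` end to end (QC → modules → promoter scanning
→ barcodes → importance network → trees → spatial tests → integrative
correlations), logs the summary to stderr, and writes the JSON report to
`--out`.
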