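# immunatlas

Analysis of multi-organ single-cell immune atlases: do immune cells
transcriptionally adapt to the organ they reside in? Given a raw
cell-by-gene UMI count matrix with organ and cell-type annotations,
immunatlas gates the CD45+ (PTPRC ≥ 1 read) compartment, applies standard
quality control, and then asks which genes are *organ-specific* within each
immune cell type — significantly up-regulated in exactly one organ and
uniquely elevated in that organ's pseudobulk profile — and which of those
are shared across immune compartments. It also quantifies composition
(hypergeometric cluster×organ enrichment), organ–organ expression
similarity (pseudobulk Pearson correlation), per-cell gene-module activity
(the rank-based UCell statistic, score = 1 − U′/(n·maxRank)), ssGSEA for
bulk validation profiles, and preranked GSEA with a permutation null.

It is aimed at computational immunologists working with integrated atlases
(e.g. HCA-derived collections) and at anyone needing a tested, scriptable
re-implementation of this analysis chain. Because the headline statistics
of published atlases hinge on gates and boundary conventions (exclusion at
`< 1000` UMI, `< 200` genes, `> 15%` mito, testing only genes expressed in
`> 50%` of a ≥ 40-cell group), every such rule here is explicit,
configurable and covered by boundary tests. A negative-binomial simulator
with planted organ-specific genes, cell-type markers and active gene
modules makes every stage verifiable by parameter recovery — no downloads
required.

## Worked example

```r
library(immunatlas)

design <- demo_design(seed = 1)   # 5 organs x 4 cell types, 2,000 genes:
                                  # 3 kidney + 3 thymus pan-cell-type plants (fold 6),
                                  # one gene planted in TWO organs (a negative control),
                                  # a 30-gene module active only in thymic B cells (fold 4)
sim <- simulate_atlas(design)
b   <- qc_pipeline(sim$bundle)    # CD45 gate -> cell QC -> gene filter
sigs <- detect_organ_signatures(b)
head(signature_sharing(sigs))
```

```
     gene  organ n_cell_types_detected n_cell_types_analyzed sharing_fraction shared_flag
 gene0101 kidney                     4                     4             1.00        TRUE
 gene0102 kidney                     4                     4             1.00        TRUE
 gene0103 kidney                     4                     4             1.00        TRUE
 gene0201 thymus                     4                     4             1.00        TRUE
 gene0202 thymus                     4                     4             1.00        TRUE
 gene0203 thymus                     4                     4             1.00        TRUE
```

All six pan-cell-type plants are recovered in the signatures of all four
cell types (sharing fraction 1.0, flagged as shared since 1.0 > 0.5); the
module genes surface only in the thymus/B signature (fraction 0.25, not
shared); the gene planted in two organs appears in no signature — the
uniqueness screen removes it. QC retained 4,460 of 5,000 simulated cells
(the rest are deliberately injected violators and CD45-negative cells).

Scoring the planted module per cell and comparing strata:

```r
scores <- ucell_score(b, gene_set("module", design$module_genes))
b$cell_meta$stratum <- paste(b$cell_meta$organ, b$cell_meta$cell_type, sep = "|")
compare_group_scores(scores, b$cell_meta, "stratum")$summary
```

the planted-active stratum leads by a wide margin (median UCell score 0.65
in thymus|B vs ≤ 0.34 everywhere else; all pairwise BH-adjusted Wilcoxon
p < 0.01), and preranked GSEA flags the module only there (ES 0.81,
q ≈ 0.002).

The same chain runs end-to-end with artifact and provenance files via

```r
run_pipeline(default_config(seed = 1, outdir = "out"))
```

writing TSV tables (QC report, enrichment map, pseudobulk, correlations,
DE, signatures + Newick dendrograms, UCell scores, GSEA) plus a JSON
provenance block per stage; reruns with the same config are bit-identical.

## Acceptance script

`scripts/acceptance.R` re-runs the full demo pipeline from scratch against
the installed package under a given seed and writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — atlas IO (MTX/TSV/GMT), simulator, gating/QC, composition,
  differential expression, signature detection, module scoring, GSEA,
  pipeline driver.
- `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are generated in code.
- `vignettes/organ-signatures.Rmd` — the model, its assumptions, parameter
  meanings and the package's design choices.
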