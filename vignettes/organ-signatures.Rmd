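---
title: "Detecting organ-specific immune gene signatures with immunatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting organ-specific immune gene signatures with immunatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunatlas)
```

## The analysis and its assumptions

Immune cells circulate through every organ, and a long-standing question is
whether they merely pass through or transcriptionally adapt to their host
tissue. immunatlas implements a complete analysis chain for multi-organ
single-cell immune atlases built from raw UMI count matrices:

1. **Gating and QC.** An "immune cell" is defined operationally as a cell
   with at least one read of *PTPRC* (CD45). Cells with fewer than 1,000
   UMI, fewer than 200 detected genes or more than 15% mitochondrial UMI
   are removed, then genes detected in at most 4 cells are dropped. All
   exclusion thresholds are strict inequalities, so a cell sitting exactly
   on a boundary is retained; this matters for reproducing cell counts and
   is fixed by `qc_thresholds()`.
2. **Composition.** Cluster-by-organ association is tested with the
   upper-tail hypergeometric probability P(X >= k) of the observed overlap
   (over-representation; the population is exactly the table supplied).
   Raw p < 0.05 flags significance, matching common practice for these
   enrichment heatmaps; a BH-adjusted matrix is emitted alongside for
   transparency.
3. **Pseudobulk and correlation.** Per-group (organ, or organ x cell type)
   arithmetic means of log-normalized expression, compared across organs
   with Pearson correlation after dropping zero-variance genes.
4. **Differential expression.** One-vs-rest two-sided Wilcoxon rank-sum
   tests on log-normalized expression (`ln(1 + 1e4 * count / cell_total)`),
   within each immune cell type. A comparison runs only when both the group
   and the rest contain at least 40 cells; a gene is tested only when
   strictly more than 50% of the group's cells express it and its
   |log2 fold change| exceeds a configurable threshold (default 0.25, the
   conventional toolchain default — the 40-cell and 50% gates are the
   study-specified constants). BH adjustment is applied per comparison.
5. **Organ-specific signatures.** A gene enters the signature of
   (organ, cell type) iff it is significantly up-regulated in exactly one
   organ's comparison within that cell type *and* its pseudobulk value in
   that organ is at least `margin` (default 2.0) times the maximum across
   all other organs. Sharing across cell types is then summarized per
   (gene, organ): a gene is a pan-cell-type organ gene when it appears in
   the signatures of strictly more than 50% of the analyzed cell types.
6. **Module scoring and enrichment.** Per-cell activity of a gene module
   (e.g. NF-kB target genes, supplied as GMT) is scored with the rank-based
   UCell statistic; bulk validation profiles are scored with ssGSEA; ranked
   DE lists feed a preranked GSEA with a gene-label permutation null, and a
   cross-organ summary flags pathways unique to one organ or shared by more
   than three.

## Key parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `min_umi` | 1000 | minimum UMI per cell (exclusion is `< 1000`) |
| `min_genes` | 200 | minimum detected genes per cell |
| `max_mito_pct` | 15 | maximum mitochondrial percentage (exclusion `> 15`) |
| `max_cells_per_excluded_gene` | 4 | gene dropped when detected in `<= 4` cells |
| `cd45_min_count` | 1 | PTPRC reads defining an immune cell |
| `min_cells` | 40 | cells required in group *and* rest for DE |
| `min_pct` | 0.5 | fraction of group cells expressing (strict `>`) |
| `min_abs_log2fc` | 0.25 | fold-change gate before testing (configurable) |
| `margin` | 2.0 | pseudobulk uniqueness ratio for signatures |
| `max_rank` | 1500 | UCell rank cap (the statistic's conventional default) |
| `alpha` | 0.25 | ssGSEA rank-weight exponent |
| `weight`, `n_perm` | 1, 1000 | GSEA score exponent and permutations |

## Numerical and design choices

**Wilcoxon internals.** Average ranks on ties. For `n1 + n2 <= 12` the
two-sided p comes from exhaustive enumeration of all group labelings
(permutation-exact, valid under ties); beyond that, the tie-corrected
normal approximation with continuity correction — numerically identical to
the standard R implementation — is used. The approximation is accurate for
the pipeline's regime (>= 40 cells per side); on heavily tied tiny samples
the *approximation itself* can deviate visibly from enumeration, which is
why the exact path exists and is the default at small sizes.

**Fold-change scale.** log2FC is computed on the depth-normalized linear
scale, `log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`, the
behaviour of the cited single-cell toolchain.

**Pseudobulk scale for the uniqueness screen.** `pseudobulk_profiles()`
returns mean log-normalized values by default, but the signature screen
uses `expm1 = TRUE` (means on the linear depth-normalized scale, as the
cited toolchain's per-group averaging does). The margin rule is only
meaningful on a linear scale: a 4-fold expression difference moves
`ln(1 + x)` means by far less than a factor 2, so a log-scale margin of
2.0 would silently demand ~10-fold expression differences.

**Operationalizing the "hierarchical cluster analysis" screen.** The
original screening of uniquely overexpressed genes against the pseudobulk
table was a visual dendrogram inspection, which is not a reproducible
decision rule. We use the deterministic margin rule above and retain the
dendrogram (average linkage on 1 − Pearson distance across organ profiles)
as a Newick string in every signature report, so the clustering remains
inspectable.

**Uniqueness under size gating.** "Significant in exactly one organ" is
evaluated over the comparisons that passed the 40-cell gate; an organ too
small to be tested cannot veto a gene's uniqueness, and the analyzed
(organ, cell type) universe is recorded so sharing fractions use the right
denominator.

**Down-regulation.** The screen can be run with `direction = "down"`. On
data matching the study's structure the expected outcome is an empty or
near-empty set — organ effects are modeled (and were reported) as gains,
not organ-exclusive losses.

**Degenerate inputs.** Zero-UMI cells are excluded with mitochondrial
fraction defined as 0; zero-variance genes are dropped before correlations
(logged); constant profiles make ssGSEA and gene-score correlations return
a flagged `NA` rather than a number; empty bundles are rejected explicitly
by every computing stage.

## What the simulator emulates — and what it does not

`simulate_atlas()` draws negative-binomial counts (common dispersion 0.5,
variance `mu + phi mu^2`) with mean-`baseline_mean` log-normal per-gene
baselines, log-normal per-cell library-size factors (log-sd 0.3), a
per-cell mitochondrial fraction drawn from a stated range, and PTPRC
present in a stated fraction of cells (default 0.95). The defaults (150 to
250 cells per organ x cell-type stratum, 1,000 to 2,000 genes, total UMI of
a few thousand per cell) are chosen so that cells ordinarily pass the
study's QC gates while a configurable fraction of deliberately injected
violators (low depth, high mito, few genes) exercises each gate.

Planted truths are multiplicative effects on the NB mean: organ-specific
genes (fold applied only in the planted organ, optionally only in chosen
cell types), cell-type markers, and a gene module switched on in chosen
strata. Organ-specific and marker plants have their baseline means pinned
to `baseline_mean` so a planted fold is observable above the 50%-expressing
gate — an unobservable plant would make recovery tests meaningless. Module
genes deliberately keep their random baselines so an *inactive* module is
statistically exchangeable with random same-size gene sets.

The simulator does **not** model gene-gene correlation, batch effects
(batch correction is outside this package's scope), doublets (doublet
scores are consumed as optional metadata, and the simulated score is
independent of expression by construction), or realistic organ-specific
co-expression programs. A green recovery test therefore establishes that
the statistics and gates do what they claim on data matching their
assumptions — not that the biological conclusions of any particular atlas
are correct.

**Null-model testing.** With no planted effects the signature pipeline
should return nothing, and it does in >= 19/20 seeds at defaults. The DE
false-positive-rate check runs with the fold-change gate disabled
(`min_abs_log2fc = 0`): that gate is a *selection* applied before testing,
and conditioning the tested set on an observed fold change under the null
biases the selected p-values — FDR control is a property of the test, not
of a post-selection subset.

## A worked example

```{r demo, eval = FALSE}
design <- demo_design(seed = 1)       # 5 organs x 4 cell types, 2,000 genes
sim <- simulate_atlas(design)
b <- qc_pipeline(sim$bundle)          # CD45 gate + cell QC + gene filter
sigs <- detect_organ_signatures(b)
signature_sharing(sigs)
scores <- ucell_score(b, gene_set("module", design$module_genes))
```

The same chain, with artifact and provenance files, is available as
`run_pipeline(default_config(seed = 1, outdir = "out"))`, and
`scripts/acceptance.R` runs it from the command line.

## Known limitations

- Signatures depend on the annotation granularity of `cell_type`; the
  package takes annotations as given and does not cluster.
- The margin rule is a declared surrogate for the original visual screen;
  with `margin = 2.0` it is conservative for subtle (< 2-fold) organ
  effects, which is intended.
- GSEA uses a gene-label permutation null (the input is a preranked list);
  phenotype permutation is out of scope.
- BH adjustment is applied within each comparison, not globally across a
  whole atlas; the choice is logged in the outputs.
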