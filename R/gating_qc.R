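# CD45+ selection and quality control.
#
# Boundary convention: exclusion thresholds are strict (< 1000 UMI, < 200
# genes, > 15% mitochondrial), so a cell sitting exactly on a threshold is
# retained. All three cell rules and the CD45 gate are per-cell predicates on
# raw counts, hence idempotent and order-independent among themselves; the
# gene filter is applied after cell filtering (detection counted on
# QC-passing cells).

#' Quality-control thresholds
#'
#' Defaults reproduce the atlas study's gates: cells with fewer than 1,000
#' UMI, fewer than 200 detected genes or more than 15% mitochondrial UMI are
#' excluded; genes detected in at most 4 cells are excluded; an immune cell
#' must carry at least one PTPRC (CD45) read.
#'
#' @param min_umi minimum total UMI per cell.
#' @param min_genes minimum detected genes (count > 0) per cell.
#' @param max_mito_pct maximum mitochondrial percentage (0-100).
#' @param max_cells_per_excluded_gene genes detected in at most this many
#'   cells are dropped.
#' @param cd45_symbol gene symbol used for the immune gate.
#' @param cd45_min_count minimum raw count of `cd45_symbol`.
#' @export
qc_thresholds <- function(min_umi = 1000L, min_genes = 200L, max_mito_pct = 15,
                          max_cells_per_excluded_gene = 4L,
                          cd45_symbol = "PTPRC", cd45_min_count = 1L) {
  th <- list(min_umi = min_umi, min_genes = min_genes,
             max_mito_pct = max_mito_pct,
             max_cells_per_excluded_gene = max_cells_per_excluded_gene,
             cd45_symbol = cd45_symbol, cd45_min_count = cd45_min_count)
  num <- unlist(th[c("min_umi", "min_genes", "max_mito_pct",
                     "max_cells_per_excluded_gene", "cd45_min_count")])
  if (any(num < 0)) stop("all QC thresholds must be >= 0")
  structure(th, class = "qc_thresholds")
}

per_organ_log <- function(meta_before, keep) {
  org <- if (is.null(meta_before$organ)) rep("all", nrow(meta_before)) else meta_before$organ
  agg <- data.frame(organ = sort(unique(org)))
  agg$total <- as.integer(table(org)[agg$organ])
  kept <- table(factor(org[keep], levels = agg$organ))
  agg$retained <- as.integer(kept)
  agg$excluded <- agg$total - agg$retained
  agg
}

#' Gate on CD45 (PTPRC) expression
#'
#' Retains exactly the cells with at least `cd45_min_count` raw counts of the
#' configured CD45 symbol; this is the study's operational definition of an
#' immune cell.
#'
#' @param bundle an [atlas_bundle()].
#' @param thresholds a [qc_thresholds()].
#' @return Filtered bundle; a per-organ retained/excluded table is attached
#'   as attribute `"qc_log"`.
#' @export
cd45_gate <- function(bundle, thresholds = qc_thresholds()) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  gi <- match(thresholds$cd45_symbol, bundle$gene_table$symbol)
  if (is.na(gi))
    stop("CD45 gate gene '", thresholds$cd45_symbol, "' not found in the gene table")
  keep <- as.vector(bundle$counts[, gi] >= thresholds$cd45_min_count)
  log <- per_organ_log(bundle$cell_meta, keep)
  message(sprintf("cd45_gate: retained %d/%d cells", sum(keep), length(keep)))
  out <- subset_atlas(bundle, cell_mask = keep)
  attr(out, "qc_log") <- log
  out
}

#' Apply the per-cell quality-control rules
#'
#' A cell is retained iff total UMI >= `min_umi` AND detected genes >=
#' `min_genes` AND mitochondrial percentage <= `max_mito_pct` (conjunction;
#' order irrelevant). Zero-UMI cells are excluded (their mito fraction is
#' defined as 0) and logged.
#'
#' @inheritParams cd45_gate
#' @export
apply_cell_qc <- function(bundle, thresholds = qc_thresholds()) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  total <- Matrix::rowSums(bundle$counts)
  ngene <- Matrix::rowSums(bundle$counts > 0)
  mito <- bundle$gene_table$is_mito
  mito_umi <- if (any(mito)) Matrix::rowSums(bundle$counts[, mito, drop = FALSE]) else 0
  pct <- ifelse(total > 0, 100 * mito_umi / total, 0)
  keep <- total >= thresholds$min_umi & ngene >= thresholds$min_genes &
    pct <= thresholds$max_mito_pct & total > 0
  if (any(total == 0))
    message(sprintf("apply_cell_qc: %d zero-UMI cell(s) excluded", sum(total == 0)))
  log <- per_organ_log(bundle$cell_meta, keep)
  message(sprintf("apply_cell_qc: retained %d/%d cells", sum(keep), length(keep)))
  out <- subset_atlas(bundle, cell_mask = keep)
  attr(out, "qc_log") <- log
  out
}

#' Drop genes detected in too few cells
#'
#' A gene is retained iff its detection count (cells with count > 0) exceeds
#' `max_cells_per_excluded_gene` (default: genes detected in <= 4 cells are
#' excluded). Intended to run after the cell filters.
#'
#' @inheritParams cd45_gate
#' @export
apply_gene_filter <- function(bundle, thresholds = qc_thresholds()) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  det <- Matrix::colSums(bundle$counts > 0)
  keep <- det > thresholds$max_cells_per_excluded_gene
  message(sprintf("apply_gene_filter: retained %d/%d genes", sum(keep), length(keep)))
  subset_atlas(bundle, gene_mask = keep)
}

#' Run the full gating + QC chain
#'
#' CD45 gate, then per-cell QC, then the gene filter, accumulating a QC
#' report (per-organ retained/excluded counts per step).
#'
#' @inheritParams cd45_gate
#' @return Filtered bundle with attribute `"qc_report"`, a data.frame with
#'   columns step, organ, total, retained, excluded.
#' @export
qc_pipeline <- function(bundle, thresholds = qc_thresholds()) {
  steps <- list()
  b <- cd45_gate(bundle, thresholds)
  steps$cd45_gate <- attr(b, "qc_log")
  b <- apply_cell_qc(b, thresholds)
  steps$cell_qc <- attr(b, "qc_log")
  ng0 <- ncol(b$counts)
  b <- apply_gene_filter(b, thresholds)
  report <- do.call(rbind, lapply(names(steps), function(s)
    cbind(step = s, steps[[s]])))
  report <- rbind(report,
                  data.frame(step = "gene_filter", organ = "(genes)", total = ng0,
                             retained = ncol(b$counts), excluded = ng0 - ncol(b$counts)))
  attr(b, "qc_report") <- report
  b
}
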