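# Cell-composition enrichment, pseudobulk profiles and correlation maps.

#' Hypergeometric cluster-by-organ enrichment
#'
#' For each (row group r, column group c) cross-tabulated from the supplied
#' cell table: with N = total cells, K = cells in c, n = cells in r and
#' k = overlap, the upper-tail over-representation probability
#' P(X >= k), X ~ Hypergeometric(N, K, n), is reported together with
#' -log10(p) and a significance flag at `alpha` (raw p, as in the study;
#' a BH-adjusted matrix is additionally emitted for transparency).
#'
#' @param cell_meta data.frame of per-cell annotations (the population is
#'   exactly the table passed in).
#' @param row_var,col_var names of the two categorical columns (e.g. cell
#'   subpopulation and organ).
#' @param alpha significance level on the raw p (default 0.05).
#' @return Object of class `enrichment_map`: list of matrices `overlap`,
#'   `p`, `neglog10p`, `significant`, `p_bh`, plus the margins.
#' @export
hypergeometric_enrichment <- function(cell_meta, row_var, col_var, alpha = 0.05) {
  cell_meta <- as.data.frame(cell_meta)
  if (nrow(cell_meta) == 0L) stop("empty cell table")
  for (v in c(row_var, col_var))
    if (is.null(cell_meta[[v]])) stop("column '", v, "' not in the table")
  tab <- table(as.character(cell_meta[[row_var]]), as.character(cell_meta[[col_var]]))
  N <- sum(tab)
  K <- colSums(tab); n <- rowSums(tab)
  p <- tab
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    p[i, j] <- phyper(tab[i, j] - 1, K[j], N - K[j], n[i], lower.tail = FALSE)
  p <- pmin(unclass(as.matrix(p)), 1)
  if (any(p == 0)) {
    message("hypergeometric_enrichment: p numerically 0 reported as smallest positive normal")
    p[p == 0] <- .Machine$double.xmin
  }
  structure(list(overlap = unclass(as.matrix(tab)), p = p,
                 neglog10p = -log10(p), significant = p < alpha,
                 p_bh = matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p),
                               dimnames = dimnames(p)),
                 row_totals = n, col_totals = K, N = N, alpha = alpha),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("enrichment_map: %d x %d groups over %d cells (alpha = %g)\n",
              nrow(x$p), ncol(x$p), x$N, x$alpha))
  cat(sprintf("%d significant cell(s) at raw p < alpha\n", sum(x$significant)))
  invisible(x)
}

#' Flatten an enrichment map to a result table
#' @param x an `enrichment_map`.
#' @param ... unused.
#' @export
as.data.frame.enrichment_map <- function(x, ...) {
  g <- expand.grid(row_group = rownames(x$p), col_group = colnames(x$p),
                   stringsAsFactors = FALSE)
  g$overlap <- as.vector(x$overlap)
  g$p <- as.vector(x$p)
  g$neglog10p <- as.vector(x$neglog10p)
  g$p_bh <- as.vector(x$p_bh)
  g$significant <- as.vector(x$significant)
  g
}

#' Per-group pseudobulk expression profiles
#'
#' Entry (g, j) is the arithmetic mean over the cells of group g of gene j's
#' expression: log-normalized values by default (`normalized = TRUE`), their
#' expm1 (depth-normalized linear scale, the cited toolchain's
#' AverageExpression behaviour) with `expm1 = TRUE`, or raw counts with
#' `normalized = FALSE`. Groups with 0 cells are omitted.
#'
#' @param bundle an [atlas_bundle()].
#' @param group_by one or more metadata column names.
#' @param normalized use log-normalized expression (default) or raw counts.
#' @param expm1 average on the linear depth-normalized scale.
#' @param scale depth scale for [normalize_counts()].
#' @return groups x genes matrix with attribute `"group_key"` (data.frame of
#'   the grouping columns) and `"n_cells"`.
#' @export
pseudobulk_profiles <- function(bundle, group_by, normalized = TRUE,
                                expm1 = FALSE, scale = 1e4) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  if (nrow(bundle$counts) == 0L) stop("empty bundle: no cells to aggregate")
  for (v in group_by)
    if (is.null(bundle$cell_meta[[v]])) stop("grouping column '", v, "' not in cell metadata")
  mat <- if (normalized) normalize_counts(bundle, scale = scale) else bundle$counts
  if (expm1) { if (!normalized) stop("expm1 requires normalized = TRUE"); mat@x <- expm1(mat@x) }
  key <- interaction(bundle$cell_meta[group_by], sep = "|", drop = TRUE)
  ind <- Matrix::fac2sparse(key)                   # levels x cells
  sizes <- as.vector(ind %*% rep(1, ncol(ind)))
  pb <- as.matrix(ind %*% mat) / sizes
  rownames(pb) <- levels(key)
  colnames(pb) <- bundle$gene_table$symbol
  parts <- strsplit(levels(key), "|", fixed = TRUE)
  gk <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(gk) <- group_by
  attr(pb, "group_key") <- gk
  attr(pb, "n_cells") <- sizes
  pb
}

#' Pairwise Pearson correlation of pseudobulk rows
#'
#' Genes with zero variance across groups are dropped (logged) before
#' correlating; the result is a symmetric matrix with unit diagonal.
#'
#' @param pb a [pseudobulk_profiles()] matrix (>= 2 rows).
#' @export
correlation_matrix <- function(pb) {
  if (nrow(pb) < 2L) stop("need at least 2 groups to correlate")
  v <- apply(pb, 2L, stats::var)
  drop <- v == 0 | is.na(v)
  if (any(drop))
    message(sprintf("correlation_matrix: dropped %d zero-variance gene(s)", sum(drop)))
  if (sum(!drop) < 2L) stop("fewer than 2 variable genes; correlation undefined")
  cc <- cor(t(pb[, !drop, drop = FALSE]))
  diag(cc) <- 1
  cc
}

#' Correlate a gene's expression with a per-cell score
#'
#' Pearson correlation between the log-normalized expression of `gene` and a
#' numeric metadata column (e.g. a doublet score), within one organ. Used in
#' the study to show signature genes are not doublet artifacts.
#'
#' @param bundle an [atlas_bundle()].
#' @param gene gene symbol.
#' @param score_column numeric metadata column name.
#' @param within optional organ name restricting the cells.
#' @return The correlation, or `NA` with attribute `undefined = TRUE` (and a
#'   warning) when expression or score is constant.
#' @export
gene_score_correlation <- function(bundle, gene, score_column, within = NULL) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  if (!is.null(within))
    bundle <- subset_atlas(bundle, cell_mask = bundle$cell_meta$organ == within)
  if (nrow(bundle$counts) < 3L) stop("insufficient cells (need >= 3)")
  gi <- match(gene, bundle$gene_table$symbol)
  if (is.na(gi)) stop("gene '", gene, "' not found")
  sc <- bundle$cell_meta[[score_column]]
  if (is.null(sc) || !is.numeric(sc)) stop("score column '", score_column, "' missing or non-numeric")
  ex <- as.vector(normalize_counts(bundle)[, gi])
  if (stats::sd(ex) == 0 || stats::sd(sc) == 0) {
    warning("correlation undefined: constant expression or score")
    return(structure(NA_real_, undefined = TRUE))
  }
  cor(ex, sc)
}
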