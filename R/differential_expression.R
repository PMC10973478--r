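# Normalization and one-vs-rest Wilcoxon differential expression with the
# atlas study's gates: at least 40 cells in both the group and the rest, and
# strictly more than 50% of the group's cells expressing a gene for it to be
# tested. Benjamini-Hochberg adjustment is applied within each comparison.

#' Log-normalize raw counts
#'
#' The cited single-cell toolchain's default transform:
#' `ln(1 + scale * count / cell_total_UMI)`, zeros staying zero (and hence
#' sparsity preserved).
#'
#' @param bundle an [atlas_bundle()] (or a cells x genes sparse matrix).
#' @param scale depth scale factor, default 10,000.
#' @return Sparse cells x genes matrix of normalized expression.
#' @export
normalize_counts <- function(bundle, scale = 1e4) {
  counts <- if (inherits(bundle, "atlas_bundle")) bundle$counts else {
    if (is.matrix(bundle)) bundle <- Matrix::Matrix(bundle, sparse = TRUE,
                                                    doDiag = FALSE)
    as(as(bundle, "CsparseMatrix"), "generalMatrix")
  }
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0))
    stop("zero-total cell(s) present; remove them with apply_cell_qc() first")
  norm <- counts
  norm@x <- log1p(scale * counts@x / tot[counts@i + 1L])
  norm
}

# shared Wilcoxon core on pooled ranks; exact = permutation enumeration
wilcox_core <- function(x, y, exact) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (exact) {
    dev_obs <- abs(U - n1 * n2 / 2)
    combs <- combn(n, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - n1 * n2 / 2) >= dev_obs - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    ties <- rle(sort(r))$lengths
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p = max(p, .Machine$double.xmin))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Average ranks on ties. For small samples (`n1 + n2 <= 12` by default) the
#' two-sided p is computed by exhaustive enumeration of all group labelings
#' (permutation-exact, valid under ties); otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact force (`TRUE`) or suppress (`FALSE`) enumeration; default
#'   enumerates iff `length(x) + length(y) <= 12`.
#' @return list with `U` (Mann-Whitney U for `x`) and two-sided `p` in (0,1].
#' @export
wilcoxon_test <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  if (is.null(exact)) exact <- (length(x) + length(y)) <= 12L
  wilcox_core(as.numeric(x), as.numeric(y), exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control with monotonicity enforcement, order-preserving with
#' the input.
#'
#' @param p numeric vector of raw p-values, all in (0, 1].
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' One-vs-rest differential expression
#'
#' For each level of `group_var` (optionally within each level of a
#' stratifying variable), cells of the group are tested against all remaining
#' cells of the (stratum's) table with the Wilcoxon rank-sum test on
#' log-normalized expression. A comparison is skipped (and logged) unless
#' both group and rest hold at least `min_cells` cells; a gene is tested only
#' if strictly more than `min_pct` of the group's cells express it (raw
#' count > 0) and `|log2FC| >= min_abs_log2fc`. BH adjustment is applied per
#' comparison over its tested genes; up- and down-regulated genes are both
#' reported with a `direction` column.
#'
#' The fold change is computed Seurat-style on the depth-normalized linear
#' scale: `log2((mean(expm1(norm_in)) + 1) / (mean(expm1(norm_out)) + 1))`.
#'
#' @param bundle a QC'd [atlas_bundle()].
#' @param group_var metadata column defining the groups (e.g. `"organ"`).
#' @param within optional metadata column to stratify by (e.g. `"cell_type"`).
#' @param min_cells minimum cells in group and rest (default 40).
#' @param min_pct minimum fraction of group cells expressing (strict, 0.5).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 0.25).
#' @param norm optional precomputed [normalize_counts()] matrix.
#' @return data.frame of class `de_result` with columns gene, group, stratum,
#'   log2fc, pct_in, pct_out, U, p, p_adj, direction; skipped comparisons in
#'   attribute `"skipped"`.
#' @export
one_vs_rest_de <- function(bundle, group_var, within = NULL,
                           min_cells = 40L, min_pct = 0.5,
                           min_abs_log2fc = 0.25, norm = NULL) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  if (nrow(bundle$counts) == 0L) stop("empty bundle: no cells to test")
  meta <- bundle$cell_meta
  if (is.null(meta[[group_var]])) stop("group_var '", group_var, "' not in cell metadata")
  if (!is.null(within) && is.null(meta[[within]]))
    stop("stratifier '", within, "' not in cell metadata")
  if (is.null(norm)) norm <- normalize_counts(bundle)
  lin <- norm
  lin@x <- expm1(lin@x)                      # depth-normalized linear scale
  genes <- bundle$gene_table$symbol
  detected <- bundle$counts > 0

  strata <- if (is.null(within)) list(`(all)` = seq_len(nrow(meta))) else
    split(seq_len(nrow(meta)), meta[[within]])
  res <- list(); skipped <- list()
  for (sname in names(strata)) {
    sidx <- strata[[sname]]
    groups <- sort(unique(as.character(meta[[group_var]][sidx])))
    for (gname in groups) {
      in_idx <- sidx[meta[[group_var]][sidx] == gname]
      out_idx <- setdiff(sidx, in_idx)
      if (length(in_idx) < min_cells || length(out_idx) < min_cells) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          group = gname, stratum = sname,
          n_group = length(in_idx), n_rest = length(out_idx),
          reason = sprintf("fewer than %d cells", min_cells),
          stringsAsFactors = FALSE)
        next
      }
      pct_in <- Matrix::colSums(detected[in_idx, , drop = FALSE]) / length(in_idx)
      pct_out <- Matrix::colSums(detected[out_idx, , drop = FALSE]) / length(out_idx)
      m_in <- Matrix::colSums(lin[in_idx, , drop = FALSE]) / length(in_idx)
      m_out <- Matrix::colSums(lin[out_idx, , drop = FALSE]) / length(out_idx)
      log2fc <- log2((m_in + 1) / (m_out + 1))
      test <- which(pct_in > min_pct & abs(log2fc) >= min_abs_log2fc)
      if (length(test) == 0L) next
      sub_in <- as.matrix(norm[in_idx, test, drop = FALSE])
      sub_out <- as.matrix(norm[out_idx, test, drop = FALSE])
      stats <- vapply(seq_along(test), function(j) {
        w <- wilcoxon_test(sub_in[, j], sub_out[, j])
        c(w$U, w$p)
      }, numeric(2L))
      df <- data.frame(
        gene = genes[test], group = gname, stratum = sname,
        log2fc = log2fc[test], pct_in = pct_in[test], pct_out = pct_out[test],
        U = stats[1L, ], p = stats[2L, ], p_adj = bh_adjust(stats[2L, ]),
        direction = ifelse(log2fc[test] > 0, "up", "down"),
        stringsAsFactors = FALSE)
      res[[length(res) + 1L]] <- df
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(0), group = character(0), stratum = character(0),
               log2fc = numeric(0), pct_in = numeric(0), pct_out = numeric(0),
               U = numeric(0), p = numeric(0), p_adj = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(group = character(0), stratum = character(0),
               n_group = integer(0), n_rest = integer(0), reason = character(0))
  if (nrow(skipped))
    message(sprintf("one_vs_rest_de: skipped %d comparison(s) below the %d-cell gate",
                    nrow(skipped), min_cells))
  attr(out, "skipped") <- skipped
  class(out) <- c("de_result", class(out))
  out
}
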