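# Rank-based per-cell gene-signature scoring (the UCell statistic), ssGSEA
# for bulk profiles, and group comparisons of scores.

#' Per-cell UCell signature score
#'
#' Within each cell, genes are ranked by decreasing expression (average ranks
#' on ties; all-zero genes share the tied bottom ranks), ranks above
#' `max_rank` are capped at `max_rank + 1`, and with n = |set| and R the sum
#' of the set's ranks, `U' = R - n(n+1)/2` and
#' `score = 1 - U'/(n * max_rank)`, clamped to [0, 1]. The score depends on
#' expression only through ranks, so it is invariant to any strictly
#' monotone per-cell transform (and hence to sequencing depth scaling).
#'
#' @param bundle an [atlas_bundle()].
#' @param gene_set a [gene_set()]; only its intersection with the gene table
#'   is used (missing genes are logged).
#' @param max_rank rank cap (default 1500, the statistic's conventional
#'   default).
#' @return Named numeric vector of per-cell scores in [0, 1].
#' @export
ucell_score <- function(bundle, gene_set, max_rank = 1500L) {
  stopifnot(inherits(bundle, "atlas_bundle"), inherits(gene_set, "gene_set"))
  genes <- bundle$gene_table$symbol
  set_idx <- match(gene_set$genes, genes)
  missing <- gene_set$genes[is.na(set_idx)]
  if (length(missing))
    message(sprintf("ucell_score: %d gene(s) of set '%s' absent from the atlas: %s",
                    length(missing), gene_set$name,
                    paste(utils::head(missing, 5L), collapse = ", ")))
  set_idx <- set_idx[!is.na(set_idx)]
  if (length(set_idx) == 0L)
    stop("gene set '", gene_set$name, "' has empty intersection with the atlas")
  n <- length(set_idx)
  G <- length(genes)
  tg <- as(Matrix::t(bundle$counts), "CsparseMatrix")   # genes x cells
  pp <- tg@p; ii <- tg@i; xx <- tg@x
  ncells <- ncol(tg)
  scores <- numeric(ncells)
  for (j in seq_len(ncells)) {
    rng <- if (pp[j + 1L] > pp[j]) (pp[j] + 1L):pp[j + 1L] else integer(0)
    nz_genes <- ii[rng] + 1L
    v <- xx[rng]
    nnz <- length(v)
    zero_rank <- nnz + (G - nnz + 1) / 2            # tied bottom ranks
    pos <- match(set_idx, nz_genes)
    r_nz <- rank(-v, ties.method = "average")
    r_set <- ifelse(is.na(pos), zero_rank, r_nz[pos])
    r_set <- pmin(r_set, max_rank + 1)
    u <- sum(r_set) - n * (n + 1) / 2
    scores[j] <- min(1, max(0, 1 - u / (n * max_rank)))
  }
  names(scores) <- colnames(tg)
  scores
}

#' Single-sample GSEA score of one profile
#'
#' Genes are ranked by expression (largest value gets the largest rank).
#' Walking the genes from the top, the score is the sum over all positions of
#' the difference between the in-set ECDF, with in-set steps weighted by
#' rank^alpha, and the uniform out-of-set ECDF.
#'
#' @param profile named numeric vector of expression over genes.
#' @param gene_set a [gene_set()]; the intersection with `names(profile)` is
#'   used and must be non-empty.
#' @param alpha rank-weighting exponent (default 0.25; 0 gives the
#'   unweighted walk).
#' @return The score, or `NA` with attribute `undefined = TRUE` when the
#'   profile is constant.
#' @export
ssgsea_score <- function(profile, gene_set, alpha = 0.25) {
  stopifnot(inherits(gene_set, "gene_set"))
  if (is.null(names(profile))) stop("profile must be named by gene")
  if (length(unique(profile)) < 2L) {
    warning("ssGSEA undefined on a constant profile")
    return(structure(NA_real_, undefined = TRUE))
  }
  inset <- names(profile) %in% gene_set$genes
  if (!any(inset))
    stop("gene set '", gene_set$name, "' has empty intersection with the profile")
  if (all(inset)) stop("gene set covers the whole profile; out-of-set ECDF undefined")
  N <- length(profile)
  R <- rank(profile, ties.method = "average")       # top gene ~ rank N
  ord <- order(profile, decreasing = TRUE)
  inset <- inset[ord]; Rw <- abs(R[ord])^alpha
  step_in <- ifelse(inset, Rw, 0); step_in <- step_in / sum(step_in)
  step_out <- ifelse(inset, 0, 1 / (N - sum(inset)))
  sum(cumsum(step_in) - cumsum(step_out))
}

#' Compare signature scores across groups
#'
#' Per-group median and mean score, all pairwise two-sided Wilcoxon rank-sum
#' tests with BH adjustment, and a flag for the pair member with the higher
#' median. Groups with fewer than 3 scored cells are dropped with a warning.
#'
#' @param scores named numeric vector (e.g. from [ucell_score()]).
#' @param cell_meta per-cell metadata; rows matched to `names(scores)` by
#'   rownames or a `barcode` column.
#' @param group_var metadata column defining the groups.
#' @return list of class `score_comparison` with elements `summary` (group,
#'   n, median, mean) and `pairwise` (group1, group2, U, p, p_adj, higher).
#' @export
compare_group_scores <- function(scores, cell_meta, group_var) {
  cell_meta <- as.data.frame(cell_meta)
  key <- if (!is.null(cell_meta$barcode)) cell_meta$barcode else rownames(cell_meta)
  grp <- cell_meta[[group_var]][match(names(scores), key)]
  if (all(is.na(grp))) stop("no score barcodes found in the metadata")
  ok <- !is.na(grp)
  scores <- scores[ok]; grp <- as.character(grp[ok])
  sizes <- table(grp)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("dropping group(s) with < 3 cells: ", paste(small, collapse = ", "))
    keep <- !grp %in% small
    scores <- scores[keep]; grp <- grp[keep]
  }
  groups <- sort(unique(grp))
  if (length(groups) < 2L) stop("need >= 2 groups with at least 3 cells each")
  summary <- data.frame(
    group = groups,
    n = as.integer(table(grp)[groups]),
    median = vapply(groups, function(g) median(scores[grp == g]), numeric(1L)),
    mean = vapply(groups, function(g) mean(scores[grp == g]), numeric(1L)),
    stringsAsFactors = FALSE)
  prs <- combn(groups, 2L)
  pw <- data.frame(group1 = prs[1L, ], group2 = prs[2L, ],
                   U = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(prs))) {
    w <- wilcoxon_test(scores[grp == prs[1L, i]], scores[grp == prs[2L, i]])
    pw$U[i] <- w$U; pw$p[i] <- w$p
  }
  pw$p_adj <- bh_adjust(pw$p)
  med <- setNames(summary$median, summary$group)
  pw$higher <- ifelse(med[pw$group1] == med[pw$group2], "tie",
                      ifelse(med[pw$group1] > med[pw$group2], pw$group1, pw$group2))
  structure(list(summary = summary, pairwise = pw), class = "score_comparison")
}

#' @export
print.score_comparison <- function(x, ...) {
  cat("score_comparison across", nrow(x$summary), "groups\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("%d pairwise test(s); %d with BH-adjusted p < 0.05\n",
              nrow(x$pairwise), sum(x$pairwise$p_adj < 0.05)))
  invisible(x)
}
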