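# Fixtures and independent oracles, all built in code.

# small deterministic bundle: 3 organs x 2 cell types, hand-set counts scale
make_tiny_bundle <- function(n_cells = 30, n_genes = 20, seed = 11) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes)
  genes <- c(sprintf("g%02d", seq_len(n_genes - 3L)), "MT-A", "MT-B", "PTPRC")
  counts[, n_genes] <- 1L + rpois(n_cells, 1)      # PTPRC present everywhere
  meta <- data.frame(
    barcode = sprintf("bc%03d", seq_len(n_cells)),
    organ = rep(c("thymus", "kidney", "spleen"), length.out = n_cells),
    cell_type = rep(c("T", "B"), each = n_cells / 2),
    doublet_score = runif(n_cells),
    stringsAsFactors = FALSE)
  atlas_bundle(counts, meta, data.frame(symbol = genes, stringsAsFactors = FALSE))
}

# a bundle from an explicit counts matrix + organ labels
bundle_from_counts <- function(counts, organ = "organA", cell_type = NULL,
                               genes = NULL, ...) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(ncol(counts)))
  meta <- data.frame(barcode = sprintf("bc%03d", seq_len(nrow(counts))),
                     organ = rep_len(organ, nrow(counts)),
                     stringsAsFactors = FALSE)
  if (!is.null(cell_type)) meta$cell_type <- rep_len(cell_type, nrow(counts))
  extra <- list(...)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  atlas_bundle(counts, meta, data.frame(symbol = genes, stringsAsFactors = FALSE))
}

# hypergeometric upper tail by literal enumeration of all C(N, n) draws
enum_hypergeom <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)        # items 1..K form the column group
  mean(overlap >= k)
}

# two-sided permutation p for the rank-sum test by enumeration of labelings
enum_wilcox_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n - n1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  labelings <- utils::combn(n, n1)
  Us <- colSums(matrix(r[labelings], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(Us - mu) >= obs - 1e-9)
}

# UCell score by direct dense ranking of one cell's expression vector
oracle_ucell_cell <- function(expr, set_idx, max_rank) {
  r <- rank(-expr, ties.method = "average")
  r <- pmin(r[set_idx], max_rank + 1)
  n <- length(set_idx)
  u <- sum(r) - n * (n + 1) / 2
  min(1, max(0, 1 - u / (n * max_rank)))
}

# GSEA enrichment score by an explicit position-by-position running sum
oracle_gsea_es <- function(scores_sorted, hit_pos, weight) {
  N <- length(scores_sorted)
  hit <- seq_len(N) %in% hit_pos
  w <- abs(scores_sorted)^weight
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / (N - sum(hit)))
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

# ssGSEA score by an explicit walk (weighted in-set ECDF minus out-set ECDF)
oracle_ssgsea <- function(profile, set_genes, alpha) {
  N <- length(profile)
  R <- rank(profile, ties.method = "average")
  ord <- order(profile, decreasing = TRUE)
  inset <- names(profile)[ord] %in% set_genes
  num <- ifelse(inset, R[ord]^alpha, 0)
  ecdf_in <- cumsum(num) / sum(num)
  ecdf_out <- cumsum(!inset) / sum(!inset)
  sum(ecdf_in - ecdf_out)
}
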