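test_that("hypergeometric enrichment matches the closed example and edge cases", {
  # N = 10 cells, row group "r" has n = 5, column group "c" has K = 4, k = 4
  meta <- data.frame(
    cluster = c(rep("r", 5), rep("other", 5)),
    organ = c(rep("c", 4), "d", rep("d", 5)))
  em <- hypergeometric_enrichment(meta, "cluster", "organ")
  expect_equal(em$overlap["r", "c"], 4)
  expect_equal(em$p["r", "c"], 6 / 252, tolerance = 1e-12)   # C(4,4)C(6,1)/C(10,5)
  expect_true(em$significant["r", "c"])
  # k = 0: upper tail includes X = 0, so p = 1
  expect_equal(em$p["other", "c"], 1)
  # row group = entire population forces k = K and p = 1
  em2 <- hypergeometric_enrichment(data.frame(a = rep("all", 8),
                                              b = rep(c("x", "y"), 4)), "a", "b")
  expect_equal(unname(em2$p["all", ]), c(1, 1))
  expect_error(hypergeometric_enrichment(meta[0, ], "cluster", "organ"), "empty")
})

test_that("hypergeometric p equals draw enumeration on random small tables", {
  set.seed(21)
  for (rep in 1:12) {
    N <- sample(4:12, 1)
    meta <- data.frame(r = sample(c("a", "b"), N, replace = TRUE),
                       c = sample(c("x", "y", "z"), N, replace = TRUE))
    if (length(unique(meta$r)) < 2 || length(unique(meta$c)) < 2) next
    em <- hypergeometric_enrichment(meta, "r", "c")
    for (i in rownames(em$p)) for (j in colnames(em$p)) {
      expect_equal(em$p[i, j],
                   enum_hypergeom(em$N, em$col_totals[[j]], em$row_totals[[i]],
                                  em$overlap[i, j]),
                   tolerance = 1e-10)
    }
    # contingency conservation: overlaps in a column sum to the column total
    expect_equal(colSums(em$overlap), unclass(em$col_totals), ignore_attr = TRUE)
  }
})

test_that("pseudobulk rows are group means on the requested scale", {
  counts <- rbind(c(100L, 10L, 0L), c(100L, 30L, 0L), c(50L, 5L, 5L))
  b <- bundle_from_counts(counts, organ = c("A", "A", "B"))
  pb_raw <- pseudobulk_profiles(b, "organ", normalized = FALSE)
  expect_equal(unname(pb_raw["A", ]), c(100, 20, 0))   # arithmetic mean of counts
  pb_log <- pseudobulk_profiles(b, "organ")
  tot <- rowSums(counts)
  expect_equal(unname(pb_log["A", 2]),
               mean(log1p(1e4 * c(10, 30) / tot[1:2])), tolerance = 1e-12)
  # a group of identical cells reproduces any member's profile
  b2 <- bundle_from_counts(rbind(c(5L, 1L), c(5L, 1L)), organ = "A")
  pb2 <- pseudobulk_profiles(b2, "organ")
  expect_equal(unname(pb2["A", ]), unname(as.vector(normalize_counts(b2)[1, ])))
  expect_error(pseudobulk_profiles(b, "missing_col"), "missing_col")
})

test_that("pseudobulk covers exactly the non-empty simulated strata", {
  sim <- simulate_atlas(simulation_design(
    n_organs = 3, n_cell_types = 2,
    cells_per_stratum = matrix(c(30, 30, 30, 30, 30, 0), 3, 2),
    n_genes = 200, seed = 6))
  b <- sim$bundle
  pb <- pseudobulk_profiles(b, c("organ", "cell_type"))
  truth_strata <- unique(sim$truth$cell_labels[c("organ", "cell_type")])
  expect_equal(nrow(pb), nrow(truth_strata))    # empty stratum omitted
  expect_true(all(pb >= 0))
})

test_that("correlation matrix has the planted structure and invariances", {
  pb <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(4, 3, 2, 1))
  cc <- correlation_matrix(pb)
  expect_equal(cc["A", "B"], 1)
  expect_equal(cc["A", "C"], -1)       # x vs max - x pattern
  expect_equal(diag(cc), c(A = 1, B = 1, C = 1))
  # invariant to gene permutation and to adding a constant to all rows
  perm <- sample(ncol(pb))
  expect_equal(correlation_matrix(pb[, perm]), cc)
  expect_equal(correlation_matrix(pb + 7), cc)
  expect_error(correlation_matrix(pb[1, , drop = FALSE]), "at least 2")
  # zero-variance genes are dropped, with a message
  expect_message(correlation_matrix(cbind(pb, k = c(2, 2, 2))), "zero-variance")
})

test_that("a divergent organ has the lowest mean off-diagonal correlation", {
  d <- simulation_design(
    n_organs = 3, n_cell_types = 1, cells_per_stratum = 150, n_genes = 500,
    organ_specific_genes = data.frame(gene = sprintf("gene%04d", 51:70),
                                      organ = "spleen", fold = 8),
    seed = 13)
  b <- simulate_atlas(d)$bundle
  cc <- correlation_matrix(pseudobulk_profiles(b, "organ"))
  off_mean <- vapply(rownames(cc),
                     function(o) mean(cc[o, setdiff(rownames(cc), o)]),
                     numeric(1))
  expect_equal(names(which.min(off_mean)), "spleen")
})

test_that("gene-score correlation behaves at the identity, independence and edges", {
  b <- make_tiny_bundle(n_cells = 40)
  expr <- as.vector(normalize_counts(b)[, "g01"])
  b$cell_meta$score_same <- expr
  expect_equal(gene_score_correlation(b, "g01", "score_same"), 1)
  b$cell_meta$score_const <- 1
  expect_warning(r <- gene_score_correlation(b, "g01", "score_const"), "constant")
  expect_true(is.na(r))
  tiny <- subset_atlas(b, cell_mask = seq_len(nrow(b$counts)) <= 2)
  expect_error(gene_score_correlation(tiny, "g01", "score_same"),
               "insufficient cells")
  # doublet-score independence on a simulated organ (planted gene, n = 2000)
  d <- simulation_design(n_organs = 1, n_cell_types = 1, cells_per_stratum = 2000,
                         n_genes = 300, qc_violation_fraction = 0, seed = 17)
  sb <- simulate_atlas(d)$bundle
  r2 <- gene_score_correlation(sb, "gene0001", "doublet_score", within = sb$cell_meta$organ[1])
  expect_lt(abs(r2), 0.1)
})
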