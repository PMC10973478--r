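test_that("log-normalization follows ln(1 + scale*count/total) with zeros fixed", {
  counts <- rbind(c(100L, 9900L), c(0L, 500L))
  b <- bundle_from_counts(counts)
  norm <- normalize_counts(b)
  expect_equal(norm[1, 1], log(101), tolerance = 1e-12)  # 100 of 10,000 at scale 1e4
  expect_equal(norm[2, 1], 0)                            # zero stays zero
  # doubling a cell's counts leaves its normalized profile unchanged
  b2 <- bundle_from_counts(2L * counts)
  expect_equal(as.matrix(normalize_counts(b2)), as.matrix(norm),
               ignore_attr = TRUE)
  expect_error(normalize_counts(bundle_from_counts(rbind(c(0L, 0L), c(1L, 2L)))),
               "zero-total")
})

test_that("wilcoxon exact path matches enumeration and textbook cases", {
  # full ties: U = n1*n2/2, p = 1
  w <- wilcoxon_test(rep(2, 4), rep(2, 5))
  expect_equal(w$U, 10)
  expect_equal(w$p, 1)
  # separated samples: exact two-sided p = 2/20
  w <- wilcoxon_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$U, 0)
  expect_equal(w$p, 0.1, tolerance = 1e-12)
  # swap symmetry
  ws <- wilcoxon_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ws$U, 9)
  expect_equal(ws$p, w$p)
  expect_error(wilcoxon_test(numeric(0), 1:3), "non-empty")
  # agreement with stats::wilcox.test exact p when there are no ties
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(100, n1); y <- sample(100, n2)  # sampling without replacement
    while (any(y %in% x)) y <- sample(100, n2)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(wilcoxon_test(x, y)$p, unname(ref$p.value), tolerance = 1e-10)
  }
  # and with the permutation oracle when there are ties
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:3, n1, replace = TRUE); y <- sample(1:3, n2, replace = TRUE)
    expect_equal(wilcoxon_test(x, y)$p, enum_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation matches the reference and tracks enumeration", {
  set.seed(9)
  # dual route: identical to the canonical tie-corrected, continuity-corrected
  # normal path of stats::wilcox.test, including under heavy ties
  for (i in 1:25) {
    n1 <- sample(5:30, 1); n2 <- sample(8:30, 1)
    x <- sample(1:6, n1, replace = TRUE); y <- sample(1:6, n2, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(wilcoxon_test(x, y, exact = FALSE)$p,
                 unname(ref$p.value), tolerance = 1e-10)
  }
  # on continuous data (the DE regime: log-normalized expression, few ties)
  # the approximation stays within 0.02 of enumeration right past the cutoff
  for (i in 1:25) {
    n1 <- sample(6:8, 1); n2 <- sample(7:9, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_lt(abs(wilcoxon_test(x, y)$p - enum_wilcox_p(x, y)), 0.02)
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.002, 0.9, 0.04, 0.7)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))  # rank-order preserved
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

de_sim_bundle <- function(fold = 8, n = 100, seed = 31) {
  d <- simulation_design(
    n_organs = 2, n_cell_types = 1, cells_per_stratum = matrix(c(n, 3 * n), 2, 1),
    n_genes = 200, qc_violation_fraction = 0,
    organ_specific_genes = data.frame(gene = "gene0050", organ = "thymus",
                                      fold = fold),
    seed = seed)
  simulate_atlas(d)$bundle
}

test_that("one_vs_rest_de enforces the 40-cell and >50%-expressing gates", {
  b <- de_sim_bundle(n = 39)          # thymus stratum below the cell gate
  de <- suppressMessages(one_vs_rest_de(b, "organ"))
  expect_false("thymus" %in% de$group)
  expect_false("kidney" %in% de$group)  # rest (39) below the gate too
  sk <- attr(de, "skipped")
  expect_setequal(sk$group, c("thymus", "kidney"))
  expect_match(sk$reason[1], "40 cells")

  # a gene expressed in exactly 50.0% of the group must not be tested
  counts <- matrix(3L, 90, 4)
  counts[1:20, 2] <- 0L                # gene 2: exactly half of group A (20/40)
  b2 <- bundle_from_counts(counts, organ = rep(c("A", "B"), c(40, 50)))
  de2 <- one_vs_rest_de(b2, "organ", min_cells = 10, min_abs_log2fc = 0)
  expect_false("g002" %in% de2$gene[de2$group == "A"])
})

test_that("a planted fold-8 organ gene is recovered as up with tiny adjusted p", {
  b <- de_sim_bundle(fold = 8, n = 300)
  de <- one_vs_rest_de(b, "organ")
  hit <- de[de$gene == "gene0050" & de$group == "thymus", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$direction, "up")
  expect_lt(hit$p_adj, 1e-6)
  expect_gt(hit$log2fc, 1)
  # and it surfaces as "down" for the other organ's comparison or not at all
  other <- de[de$gene == "gene0050" & de$group == "kidney", ]
  expect_true(nrow(other) == 0L || other$direction == "down")
})

test_that("DE output is invariant to cell order", {
  b <- de_sim_bundle(n = 60, seed = 12)
  de1 <- one_vs_rest_de(b, "organ", min_cells = 40)
  set.seed(1)
  perm <- sample(nrow(b$counts))
  bp <- atlas_bundle(b$counts[perm, ], b$cell_meta[perm, ], b$gene_table)
  de2 <- one_vs_rest_de(bp, "organ", min_cells = 40)
  key <- function(d) d[order(d$group, d$gene), c("gene", "group", "log2fc", "p")]
  expect_equal(key(as.data.frame(de1)), key(as.data.frame(de2)),
               ignore_attr = TRUE)
})
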