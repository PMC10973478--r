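# helpers to fabricate candidate tables / signature sets
cand_row <- function(gene, organ, lfc = 2, pct = 0.9, padj = 1e-4) {
  data.frame(gene = gene, group = organ, stratum = "(all)", log2fc = lfc,
             pct_in = pct, pct_out = 0.2, U = 0, p = padj, p_adj = padj,
             direction = "up", pb_target = 4, pb_other_max = 1,
             uniqueness_ratio = 4, stringsAsFactors = FALSE)
}
fake_sig <- function(organ, cell_type, genes) {
  structure(list(organ = organ, cell_type = cell_type,
                 genes = do.call(rbind, lapply(genes, cand_row, organ = organ)),
                 newick = NA_character_, params = list()),
            class = "organ_signature")
}
fake_set <- function(sigs, analyzed) {
  structure(setNames(sigs, vapply(sigs, function(s)
    paste(s$organ, s$cell_type, sep = "|"), character(1))),
    analyzed = analyzed, class = "organ_signature_set")
}

test_that("uniqueness screen applies the margin rule and stays monotone", {
  pb <- rbind(thymus = c(a = 4.0, b = 4.0, c = 3.0),
              kidney = c(a = 1.9, b = 2.1, c = 0.1),
              spleen = c(a = 1.0, b = 1.0, c = 0.2))
  cand <- rbind(cand_row("a", "thymus"), cand_row("b", "thymus"),
                cand_row("c", "thymus"), cand_row("c", "kidney"))
  out <- uniqueness_screen(cand, pb, margin = 2)
  # a: 4.0 >= 2*1.9 retained; b: 4.0 < 2*2.1 dropped;
  # c: significant in two organs, dropped by rule (a)
  expect_equal(out$gene, "a")
  expect_equal(out$pb_target, 4.0)
  expect_equal(out$pb_other_max, 1.9)
  expect_error(uniqueness_screen(cand, pb, margin = 1), "margin")
  # margin just above 1 recovers all DE-unique candidates
  lo <- uniqueness_screen(cand, pb, margin = 1 + 1e-9)
  expect_setequal(lo$gene, c("a", "b"))
  # margin -> Inf empties the set; raising the margin never adds a gene
  expect_equal(nrow(uniqueness_screen(cand, pb, margin = 1e9)), 0L)
  for (m in c(1.5, 2, 3, 5)) {
    g_lo <- uniqueness_screen(cand, pb, margin = m)$gene
    g_hi <- uniqueness_screen(cand, pb, margin = m + 1)$gene
    expect_true(all(g_hi %in% g_lo))
  }
})

test_that("screen emits an average-linkage dendrogram readable as Newick", {
  pb <- rbind(thymus = c(a = 8, b = 7, d = 0.1),
              kidney = c(a = 0.5, b = 0.4, d = 6),
              spleen = c(a = 0.3, b = 0.5, d = 0.2))
  cand <- rbind(cand_row("a", "thymus"), cand_row("b", "thymus"),
                cand_row("d", "kidney"))
  out <- uniqueness_screen(cand, pb)
  nwk <- attr(out, "newick")
  tree <- ape::read.tree(text = nwk)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("a", "b", "d"))
})

test_that("null simulation yields no signatures; planted genes are recovered", {
  null_sim <- simulate_atlas(simulation_design(
    n_organs = 3, n_cell_types = 2, cells_per_stratum = 100, n_genes = 400,
    qc_violation_fraction = 0, seed = 23))
  sigs0 <- suppressMessages(detect_organ_signatures(null_sim$bundle))
  expect_length(sigs0, 0L)
  expect_equal(nrow(signature_table(sigs0)), 0L)
  expect_error(signature_sharing(sigs0), "at least one")

  plant <- simulate_atlas(simulation_design(
    n_organs = 3, n_cell_types = 2, cells_per_stratum = 150, n_genes = 400,
    qc_violation_fraction = 0,
    organ_specific_genes = data.frame(
      gene = c("gene0040", "gene0041", "gene0042", "gene0042"),
      organ = c("kidney", "kidney", "thymus", "spleen"),  # 0042 in TWO organs
      fold = 6),
    seed = 24))
  sigs <- suppressMessages(detect_organ_signatures(plant$bundle))
  tab <- signature_table(sigs)
  # pan-cell-type kidney plants appear in the kidney signature of every cell type
  for (ct in c("T-NK", "B")) {
    got <- tab$gene[tab$organ == "kidney" & tab$cell_type == ct]
    expect_true(all(c("gene0040", "gene0041") %in% got))
  }
  # the double-planted gene never appears anywhere
  expect_false("gene0042" %in% tab$gene)
  # signatures are disjoint across organs within a cell type
  for (ct in unique(tab$cell_type)) {
    sub <- tab[tab$cell_type == ct, ]
    expect_equal(anyDuplicated(sub$gene), 0L)
  }
  # sharing: pan-cell-type plants have fraction 1 and the shared flag
  sh <- signature_sharing(sigs)
  for (g in c("gene0040", "gene0041")) {
    row <- sh[sh$gene == g & sh$organ == "kidney", ]
    expect_equal(row$sharing_fraction, 1.0)
    expect_true(row$shared_flag)
  }
})

test_that("sharing fractions use the strict >50% rule", {
  analyzed <- expand.grid(cell_type = c("T", "B", "My", "Prog"),
                          organ = "thymus", stringsAsFactors = FALSE)
  sigs <- fake_set(list(fake_sig("thymus", "T", c("DNTT", "ACVR2B")),
                        fake_sig("thymus", "B", c("DNTT", "ACVR2B")),
                        fake_sig("thymus", "My", "DNTT")),
                   analyzed = analyzed)
  sh <- signature_sharing(sigs)
  dntt <- sh[sh$gene == "DNTT", ]
  expect_equal(dntt$sharing_fraction, 0.75)      # 3 of 4 -> shared
  expect_true(dntt$shared_flag)
  acvr <- sh[sh$gene == "ACVR2B", ]
  expect_equal(acvr$sharing_fraction, 0.5)       # 2 of 4 -> NOT shared (strict)
  expect_false(acvr$shared_flag)
})

test_that("cell types observed in a single organ are skipped with a warning", {
  counts <- matrix(5L, 120, 10)
  meta_organ <- rep(c("A", "B"), each = 60)
  ct <- c(rep("T", 60), rep("B", 60))            # each cell type: one organ only
  b <- bundle_from_counts(counts, organ = meta_organ, cell_type = ct)
  expect_warning(expect_warning(sigs <- detect_organ_signatures(b),
                                "single organ"), "single organ")
  expect_length(sigs, 0L)
})
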