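# Synthetic multi-organ immune atlas generator.
#
# Negative-binomial counts with log-normal per-gene baselines and per-cell
# library-size factors; planted organ-specific genes, cell-type markers and an
# active gene module are multiplicative effects on the NB mean, applied only
# in their planted strata. A configurable fraction of cells deliberately
# violates each QC rule so the gates are exercised, and PTPRC is simulated
# present in a configurable fraction of cells so the CD45 gate is non-trivial.

#' Describe a synthetic multi-organ atlas
#'
#' The design records everything the generator needs, including the planted
#' truths later recovered by the analysis stages. Counts for gene g in a cell
#' of stratum (organ o, cell type c) are NB with mean
#' `baseline_g * organ_fold * celltype_fold * module_fold * libsize_factor`
#' and common dispersion (variance `mu + dispersion * mu^2`).
#'
#' Planted genes (organ-specific, markers, module) have their baseline mean
#' pinned to `baseline_mean` instead of the log-normal draw, so a planted fold
#' is always observable above the detection gates.
#'
#' @param n_organs,n_cell_types numbers of organs and immune cell types.
#' @param cells_per_stratum scalar or organ x cell-type integer matrix.
#' @param n_genes total genes, including `n_mito_genes` MT- genes and PTPRC.
#' @param baseline_mean scale of the per-gene log-normal baseline NB mean
#'   (the draw is mean-`baseline_mean` log-normal with `baseline_sdlog`).
#' @param baseline_sdlog log-sd of the baseline draw.
#' @param nb_dispersion NB dispersion (1/size).
#' @param organ_specific_genes data.frame with columns `gene`, `organ`,
#'   `fold` (> 1) and optional `shared_cell_types` (comma-separated cell
#'   types, default all). A gene may appear on several rows to plant it in
#'   more than one organ.
#' @param cell_type_markers data.frame with columns `gene`, `cell_type`,
#'   `fold`.
#' @param module_genes character vector of module member genes.
#' @param module_active_strata data.frame with columns `organ`, `cell_type`,
#'   `fold`; strata where the module is switched on.
#' @param libsize_factor_sd log-sd of the per-cell library size factor.
#' @param mito_fraction_range per-cell target mitochondrial UMI fraction is
#'   drawn uniformly from this range.
#' @param n_mito_genes number of MT- genes carrying the mito fraction.
#' @param cd45_positive_fraction expected fraction of cells with PTPRC >= 1.
#' @param qc_violation_fraction fraction of cells per violation type
#'   (low UMI, high mito, few genes) injected to exercise the QC gates.
#' @param organs,cell_types label vectors (defaults are generic organ /
#'   immune compartment names).
#' @param seed RNG seed; the simulation is deterministic given the design.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_organs = 4, n_cell_types = 3,
                              cells_per_stratum = 150, n_genes = 1000,
                              baseline_mean = 2.5, baseline_sdlog = 1,
                              nb_dispersion = 0.5,
                              organ_specific_genes = NULL,
                              cell_type_markers = NULL,
                              module_genes = character(),
                              module_active_strata = NULL,
                              libsize_factor_sd = 0.3,
                              mito_fraction_range = c(0.02, 0.10),
                              n_mito_genes = 10,
                              cd45_positive_fraction = 0.95,
                              qc_violation_fraction = 0.02,
                              organs = NULL, cell_types = NULL,
                              seed = 1L) {
  default_organs <- c("thymus", "kidney", "spleen", "liver", "lung", "blood",
                      "heart", "colon", "brain", "bone_marrow")
  default_cts <- c("T-NK", "B", "myeloid", "progenitor", "plasma", "pDC")
  if (is.null(organs)) organs <- default_organs[seq_len(n_organs)]
  if (is.null(cell_types)) cell_types <- default_cts[seq_len(n_cell_types)]
  stopifnot(length(organs) == n_organs, length(cell_types) == n_cell_types)
  if (length(cells_per_stratum) == 1L)
    cells_per_stratum <- matrix(cells_per_stratum, n_organs, n_cell_types)
  dimnames(cells_per_stratum) <- list(organs, cell_types)
  if (any(cells_per_stratum < 0)) stop("cells_per_stratum entries must be >= 0")

  norm_plants <- function(df, cols) {
    if (is.null(df) || nrow(as.data.frame(df)) == 0L) return(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    stopifnot(all(cols %in% names(df)))
    if (any(df$fold <= 1)) stop("planted folds must be > 1")
    df
  }
  organ_specific_genes <- norm_plants(organ_specific_genes, c("gene", "organ", "fold"))
  cell_type_markers <- norm_plants(cell_type_markers, c("gene", "cell_type", "fold"))
  module_active_strata <- norm_plants(module_active_strata, c("organ", "cell_type", "fold"))

  planted <- list(organ = unique(organ_specific_genes$gene),
                  marker = unique(cell_type_markers$gene),
                  module = unique(module_genes))
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(planted[[i]], planted[[j]])))
      stop("planted gene lists must be disjoint (",
           names(planted)[i], " vs ", names(planted)[j], ")")

  # every planted effect must land in a populated stratum
  check_stratum <- function(o, ct) {
    if (!o %in% organs || !ct %in% cell_types || cells_per_stratum[o, ct] == 0L)
      stop(sprintf("planted effect unobservable: stratum (%s, %s) has no cells", o, ct))
  }
  if (!is.null(organ_specific_genes))
    for (r in seq_len(nrow(organ_specific_genes))) {
      o <- organ_specific_genes$organ[r]
      cts <- plant_cell_types(organ_specific_genes, r, cell_types)
      for (ct in cts) check_stratum(o, ct)
    }
  if (!is.null(module_active_strata))
    for (r in seq_len(nrow(module_active_strata)))
      check_stratum(module_active_strata$organ[r], module_active_strata$cell_type[r])

  structure(list(
    n_organs = n_organs, n_cell_types = n_cell_types,
    organs = organs, cell_types = cell_types,
    cells_per_stratum = cells_per_stratum, n_genes = n_genes,
    baseline_mean = baseline_mean, baseline_sdlog = baseline_sdlog,
    nb_dispersion = nb_dispersion,
    organ_specific_genes = organ_specific_genes,
    cell_type_markers = cell_type_markers,
    module_genes = unique(as.character(module_genes)),
    module_active_strata = module_active_strata,
    libsize_factor_sd = libsize_factor_sd,
    mito_fraction_range = mito_fraction_range,
    n_mito_genes = n_mito_genes,
    cd45_positive_fraction = cd45_positive_fraction,
    qc_violation_fraction = qc_violation_fraction,
    seed = as.integer(seed)), class = "simulation_design")
}

plant_cell_types <- function(df, row, all_cts) {
  s <- df$shared_cell_types
  if (is.null(s) || is.na(s[row]) || s[row] == "" || s[row] == "all") return(all_cts)
  trimws(strsplit(s[row], ",", fixed = TRUE)[[1L]])
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("simulation_design: %d organs x %d cell types, %d genes, %d cells\n",
              x$n_organs, x$n_cell_types, x$n_genes, sum(x$cells_per_stratum)))
  cat(sprintf("planted: %d organ-specific rows, %d markers, %d module genes (%d active strata)\n",
              NROW(x$organ_specific_genes), NROW(x$cell_type_markers),
              length(x$module_genes), NROW(x$module_active_strata)))
  invisible(x)
}

# gene naming: gene0001..; the last n_mito are MT-*, the very last is PTPRC
design_gene_names <- function(design) {
  g <- design$n_genes
  nm <- design$n_mito_genes
  names <- sprintf("gene%04d", seq_len(g))
  names[(g - nm):(g - 1L)] <- sprintf("MT-G%d", seq_len(nm))
  names[g] <- "PTPRC"
  names
}

# Deterministic draw of gene-level parameters. Consumes RNG state first so
# simulate_atlas() and simulate_sorted_bulk() agree on the generative means.
design_means <- function(design) {
  set.seed(design$seed)
  g <- design$n_genes
  genes <- design_gene_names(design)
  mito <- startsWith(genes, "MT-")
  ptprc <- genes == "PTPRC"
  # mean-baseline_mean log-normal baselines
  mu <- design$baseline_mean *
    rlnorm(g, meanlog = -design$baseline_sdlog^2 / 2, sdlog = design$baseline_sdlog)
  mito_w <- rlnorm(design$n_mito_genes, 0, 0.5)      # relative mito gene weights
  all_planted <- unique(c(design$organ_specific_genes$gene,
                          design$cell_type_markers$gene, design$module_genes))
  if (length(bad <- setdiff(all_planted, genes)))
    stop("planted genes not in the gene universe: ", paste(bad, collapse = ", "))
  # organ-specific and marker plants get a pinned, observable baseline; module
  # genes keep their drawn baselines so an *inactive* module stays
  # exchangeable with random same-size gene sets
  pinned <- unique(c(design$organ_specific_genes$gene,
                     design$cell_type_markers$gene))
  if (length(pinned)) mu[match(pinned, genes)] <- design$baseline_mean
  mu[ptprc] <- 0                                     # PTPRC drawn separately

  # stratum-level fold matrix: genes x strata
  strata <- expand.grid(organ = design$organs, cell_type = design$cell_types,
                        stringsAsFactors = FALSE)
  fold <- matrix(1, g, nrow(strata))
  osg <- design$organ_specific_genes
  if (!is.null(osg)) for (r in seq_len(nrow(osg))) {
    gi <- match(osg$gene[r], genes)
    cts <- plant_cell_types(osg, r, design$cell_types)
    j <- which(strata$organ == osg$organ[r] & strata$cell_type %in% cts)
    fold[gi, j] <- fold[gi, j] * osg$fold[r]
  }
  mk <- design$cell_type_markers
  if (!is.null(mk)) for (r in seq_len(nrow(mk))) {
    gi <- match(mk$gene[r], genes)
    j <- which(strata$cell_type == mk$cell_type[r])
    fold[gi, j] <- fold[gi, j] * mk$fold[r]
  }
  mas <- design$module_active_strata
  module_idx <- match(design$module_genes, genes)
  if (!is.null(mas) && length(module_idx)) for (r in seq_len(nrow(mas))) {
    j <- which(strata$organ == mas$organ[r] & strata$cell_type == mas$cell_type[r])
    fold[module_idx, j] <- fold[module_idx, j] * mas$fold[r]
  }
  list(genes = genes, mu = mu, fold = fold, strata = strata,
       mito = mito, ptprc = ptprc, mito_w = mito_w)
}

#' Simulate a multi-organ immune atlas with planted truths
#'
#' @param design a [simulation_design()].
#' @return list with elements `bundle` (an [atlas_bundle()]) and `truth`
#'   (the realized planted assignments, per-cell labels and QC violators).
#' @export
simulate_atlas <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  dm <- design_means(design)                 # sets the seed, draws gene params
  g <- design$n_genes
  genes <- dm$genes
  size <- 1 / design$nb_dispersion
  n_total <- sum(design$cells_per_stratum)

  counts <- matrix(0, nrow = n_total, ncol = g)
  organ_lab <- character(n_total); ct_lab <- character(n_total)
  module_active <- logical(n_total)
  off <- 0L
  lo <- design$mito_fraction_range[1L]; hi <- design$mito_fraction_range[2L]
  for (s in seq_len(nrow(dm$strata))) {
    o <- dm$strata$organ[s]; ct <- dm$strata$cell_type[s]
    nc <- design$cells_per_stratum[o, ct]
    if (nc == 0L) next
    mu_s <- dm$mu * dm$fold[, s]
    lf <- rlnorm(nc, 0, design$libsize_factor_sd)
    # per-cell mito means hit a drawn target fraction of the non-mito total
    f <- runif(nc, lo, hi)
    nonmito_total <- sum(mu_s[!dm$mito])
    mito_mu_unit <- dm$mito_w / sum(dm$mito_w)
    mu_mat <- outer(lf, mu_s)                        # nc x g
    mu_mat[, dm$mito] <- (lf * f / (1 - f) * nonmito_total) %o% mito_mu_unit
    cnt <- matrix(rnbinom(nc * g, mu = as.vector(mu_mat), size = size), nc, g)
    idx <- off + seq_len(nc)
    counts[idx, ] <- cnt
    organ_lab[idx] <- o; ct_lab[idx] <- ct
    active <- !is.null(design$module_active_strata) &&
      any(design$module_active_strata$organ == o &
          design$module_active_strata$cell_type == ct)
    module_active[idx] <- active
    off <- off + nc
  }

  # PTPRC: present (>= 1 count) with probability cd45_positive_fraction
  pos <- rbinom(n_total, 1L, design$cd45_positive_fraction)
  counts[, dm$ptprc] <- pos * (1L + rpois(n_total, 1.5))

  # deliberate QC violators (disjoint cell sets, recorded in the truth)
  nv <- min(floor(design$qc_violation_fraction * n_total), floor(n_total / 3))
  viol <- data.frame(barcode = character(0), type = character(0),
                     stringsAsFactors = FALSE)
  if (nv > 0L) {
    pick <- sample(n_total, min(3L * nv, n_total))
    low_umi <- pick[seq_len(nv)]
    high_mito <- pick[nv + seq_len(nv)]
    few_genes <- pick[2L * nv + seq_len(nv)]
    for (i in low_umi) {                     # thin to < 1000 total UMI
      tot <- sum(counts[i, ])
      target <- runif(1, 200, 900)
      if (tot > 0) counts[i, ] <- rbinom(g, counts[i, ], min(1, target / tot))
    }
    for (i in high_mito) {                   # push mito fraction above 15%
      tot_nm <- sum(counts[i, !dm$mito])
      f <- runif(1, 0.25, 0.45)
      counts[i, dm$mito] <- rpois(design$n_mito_genes,
                                  f / (1 - f) * tot_nm / design$n_mito_genes)
    }
    keep_g <- sample(which(!dm$mito & !dm$ptprc), 100L)
    for (i in few_genes) {                   # < 200 detected genes
      z <- rep(0, g); z[keep_g] <- counts[i, keep_g]
      z[dm$ptprc] <- counts[i, dm$ptprc]
      counts[i, ] <- z
    }
    barcodes_tmp <- sprintf("cell%05d", seq_len(n_total))
    viol <- data.frame(
      barcode = barcodes_tmp[c(low_umi, high_mito, few_genes)],
      type = rep(c("low_umi", "high_mito", "few_genes"), each = nv),
      stringsAsFactors = FALSE)
  }

  barcodes <- sprintf("cell%05d", seq_len(n_total))
  meta <- data.frame(
    barcode = barcodes, organ = organ_lab, cell_type = ct_lab,
    sample_id = paste0(organ_lab, "_s", 1L + (seq_len(n_total) %% 2L)),
    project_id = paste0("proj_", organ_lab),
    doublet_score = runif(n_total, 0, 0.25),
    stringsAsFactors = FALSE)

  bundle <- atlas_bundle(Matrix::Matrix(counts, sparse = TRUE), meta,
                         data.frame(symbol = genes, stringsAsFactors = FALSE))
  truth <- list(
    organ_specific = design$organ_specific_genes,
    cell_type_markers = design$cell_type_markers,
    module_genes = design$module_genes,
    module_active_strata = design$module_active_strata,
    cell_labels = data.frame(barcode = barcodes, organ = organ_lab,
                             cell_type = ct_lab, module_active = module_active,
                             stringsAsFactors = FALSE),
    qc_violators = viol,
    seed = design$seed)
  list(bundle = bundle, truth = truth)
}

#' Simulate sorted pseudo-bulk profiles from one stratum
#'
#' Emulates bulk RNA-seq of a FACS-sorted population (e.g. CD19+ thymic B
#' cells): each sample is an NB draw around the stratum's generative gene
#' means scaled to a bulk library size. Module genes are elevated iff the
#' stratum is module-active in the design.
#'
#' @param design a [simulation_design()].
#' @param stratum length-2 character vector `(organ, cell_type)`.
#' @param n_samples number of bulk samples (0 gives an empty table).
#' @param seed RNG seed for the bulk draws (independent of the atlas draws).
#' @param library_size expected bulk depth per sample.
#' @return data.frame with a `gene` column and one column per sample.
#' @export
simulate_sorted_bulk <- function(design, stratum, n_samples, seed = 1L,
                                 library_size = 5e5) {
  stopifnot(inherits(design, "simulation_design"), length(stratum) == 2L)
  dm <- design_means(design)
  s <- which(dm$strata$organ == stratum[1L] & dm$strata$cell_type == stratum[2L])
  if (length(s) != 1L)
    stop(sprintf("unknown stratum (%s, %s)", stratum[1L], stratum[2L]))
  out <- data.frame(gene = dm$genes, stringsAsFactors = FALSE)
  if (n_samples == 0L) return(out[, "gene", drop = FALSE][0, , drop = FALSE])
  set.seed(as.integer(seed))
  mu_s <- dm$mu * dm$fold[, s]
  mu_s[dm$ptprc] <- design$baseline_mean
  mu_s <- mu_s / sum(mu_s) * library_size
  size <- 1 / design$nb_dispersion
  for (j in seq_len(n_samples))
    out[[paste0("sample", j)]] <- rnbinom(length(mu_s), mu = mu_s, size = size)
  out
}

#' Write a simulation's ground truth as JSON
#' @param truth the `truth` element returned by [simulate_atlas()].
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
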