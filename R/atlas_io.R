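#' @importFrom methods as is
#' @importFrom stats cor median rlnorm rnbinom rpois rbinom runif setNames
#'   p.adjust pnorm phyper hclust dist as.dist
#' @importFrom utils read.delim write.table combn packageVersion modifyList head tail
NULL

# ---- AtlasBundle -----------------------------------------------------------

#' Construct an atlas bundle
#'
#' An `atlas_bundle` holds a sparse raw UMI count matrix (cells x genes), an
#' aligned per-cell metadata table and a gene table. It is the object every
#' pipeline stage consumes and produces subsets of.
#'
#' @param counts non-negative integer-valued matrix or sparse Matrix,
#'   cells x genes.
#' @param cell_meta data.frame with one row per cell; rownames (or a
#'   `barcode` column) are the cell barcodes. Expected columns: `organ`,
#'   optionally `sample_id`, `project_id`, `cell_type`, `doublet_score`.
#' @param gene_table data.frame with one row per gene; a `symbol` column (or
#'   the first column) holds gene symbols, optional logical `is_mito`.
#' @param mito_prefix symbol prefix used to derive `is_mito` when absent
#'   (default `"MT-"`, the human convention).
#' @return An object of class `atlas_bundle`.
#' @export
atlas_bundle <- function(counts, cell_meta, gene_table, mito_prefix = "MT-") {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    counts <- Matrix::Matrix(counts, sparse = TRUE, doDiag = FALSE)
  }
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (!is(counts, "dMatrix")) counts <- as(counts, "dMatrix")
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  gene_table <- as.data.frame(gene_table, stringsAsFactors = FALSE)

  if (!is.null(cell_meta$barcode)) {
    if (anyDuplicated(cell_meta$barcode)) stop("cell barcodes must be unique")
    rownames(cell_meta) <- cell_meta$barcode
  } else if (is.null(rownames(cell_meta)) ||
             identical(rownames(cell_meta), as.character(seq_len(nrow(cell_meta))))) {
    rownames(cell_meta) <- paste0("cell", seq_len(nrow(cell_meta)))
  }
  if (anyDuplicated(rownames(cell_meta)))
    stop("cell barcodes must be unique")
  if (nrow(cell_meta) != nrow(counts))
    stop(sprintf("cell count mismatch: counts matrix has %d rows but cell metadata has %d",
                 nrow(counts), nrow(cell_meta)))

  if (is.null(gene_table$symbol)) {
    gene_table$symbol <- as.character(gene_table[[1L]])
  }
  gene_table$symbol <- as.character(gene_table$symbol)
  if (nrow(gene_table) != ncol(counts))
    stop(sprintf("gene count mismatch: counts matrix has %d columns but gene table has %d rows",
                 ncol(counts), nrow(gene_table)))
  if (anyDuplicated(gene_table$symbol)) {
    dup <- unique(gene_table$symbol[duplicated(gene_table$symbol)])
    warning(sprintf("de-duplicated %d gene symbol(s) by suffixing: %s",
                    length(dup), paste(utils::head(dup, 5L), collapse = ", ")))
    gene_table$symbol <- dedup_symbols(gene_table$symbol)
  }
  if (is.null(gene_table$is_mito)) {
    gene_table$is_mito <- startsWith(gene_table$symbol, mito_prefix)
  }
  gene_table$is_mito <- as.logical(gene_table$is_mito)

  x <- counts@x
  if (any(x < 0) || any(x != floor(x)))
    stop("counts must be non-negative integers")

  dimnames(counts) <- list(rownames(cell_meta), gene_table$symbol)
  structure(list(counts = counts, cell_meta = cell_meta, gene_table = gene_table),
            class = "atlas_bundle")
}

dedup_symbols <- function(sym) {
  # suffix repeats with -1, -2, ... (first occurrence keeps the bare symbol)
  idx <- stats::ave(seq_along(sym), sym, FUN = seq_along)
  ifelse(idx > 1L, paste0(sym, "-", idx - 1L), sym)
}

#' @export
dim.atlas_bundle <- function(x) dim(x$counts)

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("atlas_bundle: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$cell_meta$organ)) {
    tab <- table(x$cell_meta$organ)
    cat("organs:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(x$cell_meta$cell_type))
    cat("cell types:", paste(unique(x$cell_meta$cell_type), collapse = ", "), "\n")
  cat(sprintf("mitochondrial genes flagged: %d\n", sum(x$gene_table$is_mito)))
  invisible(x)
}

# ---- readers ---------------------------------------------------------------

read_table_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Load an atlas from Matrix Market + metadata tables
#'
#' Reads a sparse coordinate count matrix together with a per-cell metadata
#' table and a gene table. Orientation (cells x genes vs genes x cells) is
#' auto-detected from the number of rows in the two tables and normalized to
#' cells x genes; the total UMI sum is conserved by construction.
#'
#' @param matrix_path path to a Matrix Market `.mtx` file of raw counts.
#' @param cells_path path to a TSV/CSV table with one row per cell barcode.
#' @param genes_path path to a TSV/CSV table with one row per gene.
#' @param mito_prefix see [atlas_bundle()].
#' @return An [atlas_bundle()].
#' @export
load_atlas <- function(matrix_path, cells_path, genes_path, mito_prefix = "MT-") {
  m <- Matrix::readMM(matrix_path)
  cells <- read_table_auto(cells_path)
  genes <- read_table_auto(genes_path)
  nc <- nrow(cells); ng <- nrow(genes)
  if (nrow(m) == nc && ncol(m) == ng) {
    # already cells x genes
  } else if (nrow(m) == ng && ncol(m) == nc) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "cell count mismatch: counts matrix is %d x %d but %d cells and %d genes were declared",
      nrow(m), ncol(m), nc, ng))
  }
  atlas_bundle(m, cells, genes, mito_prefix = mito_prefix)
}

#' Load a small dense atlas from a single delimited table
#'
#' Convenience reader for tiny fixtures: a TSV/CSV whose first column holds
#' cell barcodes and remaining columns are genes.
#'
#' @inheritParams load_atlas
#' @param counts_path dense counts table, cells in rows.
#' @param cells_path optional metadata table; when `NULL` a minimal metadata
#'   frame with only barcodes is built.
#' @export
load_atlas_dense <- function(counts_path, cells_path = NULL, mito_prefix = "MT-") {
  tab <- read_table_auto(counts_path)
  barcodes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- barcodes
  meta <- if (is.null(cells_path)) {
    data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  } else read_table_auto(cells_path)
  atlas_bundle(Matrix::Matrix(m, sparse = TRUE), meta,
               data.frame(symbol = colnames(m), stringsAsFactors = FALSE),
               mito_prefix = mito_prefix)
}

# ---- subsetting ------------------------------------------------------------

#' Subset an atlas bundle, keeping all components aligned
#'
#' @param bundle an [atlas_bundle()].
#' @param cell_mask logical vector over cells (or `NULL` to keep all).
#' @param gene_mask logical vector over genes (or `NULL` to keep all).
#' @return The subset `atlas_bundle`; an empty bundle (0 cells) is allowed and
#'   must be rejected explicitly by downstream stages.
#' @export
subset_atlas <- function(bundle, cell_mask = NULL, gene_mask = NULL) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  if (is.null(cell_mask)) cell_mask <- rep(TRUE, nrow(bundle$counts))
  if (is.null(gene_mask)) gene_mask <- rep(TRUE, ncol(bundle$counts))
  if (!is.logical(cell_mask) || length(cell_mask) != nrow(bundle$counts))
    stop("cell_mask length does not match the number of cells")
  if (!is.logical(gene_mask) || length(gene_mask) != ncol(bundle$counts))
    stop("gene_mask length does not match the number of genes")
  out <- bundle
  out$counts <- bundle$counts[cell_mask, gene_mask, drop = FALSE]
  out$cell_meta <- bundle$cell_meta[cell_mask, , drop = FALSE]
  out$gene_table <- bundle$gene_table[gene_mask, , drop = FALSE]
  out
}

# ---- result tables ---------------------------------------------------------

#' Write a result table as TSV
#'
#' Floats are written at full double precision so tables round-trip
#' losslessly through [read_results_table()].
#'
#' @param table a data.frame (rows may be 0, columns may not).
#' @param path output path.
#' @export
write_results_table <- function(table, path) {
  table <- as.data.frame(table)
  if (ncol(table) == 0L) stop("refusing to write a table with no columns")
  if (anyDuplicated(names(table))) stop("column names must be unique")
  num <- vapply(table, is.double, logical(1L))
  table[num] <- lapply(table[num], function(x) sprintf("%.17g", x))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_results_table()]
#' @param path path to the TSV.
#' @export
read_results_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write an atlas bundle in Matrix Market + TSV form
#'
#' Emits `matrix.mtx`, `cells.tsv` and `genes.tsv` under `dir`, the same
#' formats [load_atlas()] reads.
#'
#' @param bundle an [atlas_bundle()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_atlas <- function(bundle, dir) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             cells = file.path(dir, "cells.tsv"),
             genes = file.path(dir, "genes.tsv"))
  Matrix::writeMM(bundle$counts, paths[["matrix"]])
  meta <- bundle$cell_meta
  meta <- cbind(barcode = rownames(meta), meta[setdiff(names(meta), "barcode")])
  write_results_table(meta, paths[["cells"]])
  write_results_table(bundle$gene_table, paths[["genes"]])
  invisible(paths)
}

# ---- gene sets (GMT) -------------------------------------------------------

#' Construct a gene set
#' @param name set name.
#' @param genes character vector of gene symbols; must be non-empty, made
#'   unique.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT format: one set per line, tab-separated `name`, `description`,
#' then gene symbols.
#'
#' @param path path to the `.gmt` file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_set(f[1L], f[-(1:2)])
  })
  setNames(sets, vapply(sets, `[[`, character(1L), "name"))
}

#' Write gene sets to a GMT file
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
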