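# Config-driven orchestration of the full atlas analysis with provenance
# tracking. Stages: simulate, qc, composition, de, signatures, score, gsea,
# report. Every stage writes its tables (TSV) plus a JSON provenance block;
# deterministic stages are bit-identical across reruns of the same config.

#' The packaged demo simulation design
#'
#' A 5-organ x 4-cell-type atlas (250 cells per stratum, 2,000 genes) with
#' pan-cell-type organ-specific plants for kidney and thymus (fold 6), one
#' gene deliberately planted in two organs (must never survive the
#' uniqueness screen), cell-type markers, and a 30-gene module active in
#' thymic B cells (fold 4).
#'
#' @param seed RNG seed.
#' @export
demo_design <- function(seed = 1L) {
  plants <- data.frame(
    gene = c("gene0101", "gene0102", "gene0103",
             "gene0201", "gene0202", "gene0203",
             "gene0301", "gene0301"),
    organ = c("kidney", "kidney", "kidney",
              "thymus", "thymus", "thymus",
              "kidney", "thymus"),
    fold = 6, stringsAsFactors = FALSE)
  markers <- data.frame(
    gene = c("gene0401", "gene0402", "gene0403", "gene0404"),
    cell_type = c("T-NK", "B", "myeloid", "progenitor"),
    fold = 5, stringsAsFactors = FALSE)
  simulation_design(
    n_organs = 5, n_cell_types = 4, cells_per_stratum = 250, n_genes = 2000,
    organ_specific_genes = plants, cell_type_markers = markers,
    module_genes = sprintf("gene%04d", 501:530),
    module_active_strata = data.frame(organ = "thymus", cell_type = "B",
                                      fold = 4, stringsAsFactors = FALSE),
    seed = seed)
}

#' Default pipeline configuration
#'
#' Every default equals the study's stated threshold where one exists (QC
#' gates, 40-cell and 50%-expressing DE gates, alpha 0.05, GSEA FDR 0.01).
#'
#' @param seed RNG seed recorded in every output's provenance.
#' @param outdir output directory.
#' @export
default_config <- function(seed = 1L, outdir = "immunatlas_out") {
  list(seed = as.integer(seed), outdir = outdir,
       input = list(matrix = NULL, cells = NULL, genes = NULL),
       qc = list(min_umi = 1000, min_genes = 200, max_mito_pct = 15,
                 max_cells_per_excluded_gene = 4,
                 cd45_symbol = "PTPRC", cd45_min_count = 1),
       de = list(min_cells = 40, min_pct = 0.5, min_abs_log2fc = 0.25,
                 fdr = 0.05),
       screen = list(margin = 2, linkage = "average"),
       scoring = list(max_rank = 1500, alpha = 0.25),
       gsea = list(weight = 1, n_perm = 1000, q_threshold = 0.01,
                   min_size = 5),
       enrichment_alpha = 0.05,
       gmt = NULL)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the atlas analysis pipeline
#'
#' Executes the requested stages in canonical order, carrying intermediate
#' objects in memory and writing each stage's tables under
#' `config$outdir`. A stage whose dependency was neither run nor loadable is
#' a hard error naming the missing stage; a failing stage removes its
#' partial outputs before rethrowing. Rerunning with an identical config is
#' bit-identical for the deterministic stages.
#'
#' @param config a [default_config()]-shaped list, or the path of a JSON
#'   file holding one (missing entries are filled with the defaults).
#' @param stages subset of `c("simulate", "qc", "composition", "de",
#'   "signatures", "score", "gsea", "report")`.
#' @param design a [simulation_design()] for the simulate stage (default
#'   [demo_design()] under the config seed).
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "qc", "composition", "de",
                                    "signatures", "score", "gsea", "report"),
                         design = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- modifyList(default_config(), config)
  all_stages <- c("simulate", "qc", "composition", "de", "signatures",
                  "score", "gsea", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]

  # inputs are validated before any computation
  if (!"simulate" %in% stages && "qc" %in% stages) {
    paths <- unlist(config$input)
    if (length(paths) < 3L || any(!nzchar(paths)) || !all(file.exists(paths)))
      stop("stage 'qc' requires either stage 'simulate' or existing input paths ",
           "(config$input$matrix/cells/genes)")
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(config[setdiff(names(config), "outdir")])
  state <- new.env(parent = emptyenv())
  artifacts <- list()

  provenance <- function(stage, files) {
    pth <- file.path(outdir, paste0(stage, ".provenance.json"))
    jsonlite::write_json(
      list(package = "immunatlas",
           version = as.character(packageVersion("immunatlas")),
           stage = stage, seed = config$seed, config_hash = chash,
           files = basename(unlist(files))),
      pth, auto_unbox = TRUE, digits = NA)
    pth
  }
  run_stage <- function(stage, fn) {
    written <- character(0)
    note <- function(p) { written <<- c(written, p); p }
    tryCatch({
      files <- fn(note)
      files <- c(files, provenance(stage, files))
      artifacts[[stage]] <<- unlist(files)
    }, error = function(e) {
      unlink(written)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  need <- function(what, stage, dep) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' requires stage '", dep, "' (not run)")
    state[[what]]
  }
  th <- do.call(qc_thresholds, config$qc)

  for (stage in stages) switch(stage,
    simulate = run_stage("simulate", function(note) {
      if (is.null(design)) design <- demo_design(seed = config$seed)
      sim <- simulate_atlas(design)
      state$bundle <- sim$bundle; state$truth <- sim$truth
      paths <- write_atlas(sim$bundle, file.path(outdir, "atlas"))
      for (p in paths) note(p)
      note(write_ground_truth(sim$truth, file.path(outdir, "ground_truth.json")))
      paths
    }),
    qc = run_stage("qc", function(note) {
      if (is.null(state$bundle))
        state$bundle <- load_atlas(config$input$matrix, config$input$cells,
                                   config$input$genes)
      b <- qc_pipeline(state$bundle, th)
      state$qc_bundle <- b
      rep_path <- note(file.path(outdir, "qc_report.tsv"))
      write_results_table(attr(b, "qc_report"), rep_path)
      sum_path <- note(file.path(outdir, "qc_summary.json"))
      jsonlite::write_json(
        list(cells_in = nrow(state$bundle$counts), cells_out = nrow(b$counts),
             genes_in = ncol(state$bundle$counts), genes_out = ncol(b$counts),
             thresholds = unclass(th), seed = config$seed),
        sum_path, auto_unbox = TRUE, digits = NA)
      c(rep_path, sum_path)
    }),
    composition = run_stage("composition", function(note) {
      b <- need("qc_bundle", "composition", "qc")
      files <- character(0)
      if (!is.null(b$cell_meta$cell_type)) {
        em <- hypergeometric_enrichment(b$cell_meta, "cell_type", "organ",
                                        alpha = config$enrichment_alpha)
        files <- c(files, note(file.path(outdir, "enrichment.tsv")))
        write_results_table(as.data.frame(em), utils::tail(files, 1))
      }
      pb <- pseudobulk_profiles(b, "organ")
      state$pb_organ <- pb
      files <- c(files, note(file.path(outdir, "pseudobulk_organ.tsv")))
      write_results_table(cbind(group = rownames(pb), as.data.frame(pb)),
                          utils::tail(files, 1))
      cc <- correlation_matrix(pb)
      files <- c(files, note(file.path(outdir, "organ_correlation.tsv")))
      write_results_table(cbind(group = rownames(cc), as.data.frame(cc)),
                          utils::tail(files, 1))
      files
    }),
    de = run_stage("de", function(note) {
      b <- need("qc_bundle", "de", "qc")
      de <- one_vs_rest_de(b, "organ",
                           within = if (!is.null(b$cell_meta$cell_type)) "cell_type",
                           min_cells = config$de$min_cells,
                           min_pct = config$de$min_pct,
                           min_abs_log2fc = config$de$min_abs_log2fc)
      state$de <- de
      p1 <- note(file.path(outdir, "de_results.tsv"))
      write_results_table(as.data.frame(de), p1)
      p2 <- note(file.path(outdir, "de_skipped.tsv"))
      write_results_table(attr(de, "skipped"), p2)
      c(p1, p2)
    }),
    signatures = run_stage("signatures", function(note) {
      b <- need("qc_bundle", "signatures", "qc")
      sigs <- detect_organ_signatures(
        b, de_params = config$de, screen_params = config$screen)
      state$signatures <- sigs
      p1 <- note(file.path(outdir, "signatures.tsv"))
      write_results_table(signature_table(sigs), p1)
      p2 <- note(file.path(outdir, "signatures.json"))
      jsonlite::write_json(
        lapply(unname(sigs), function(s)
          list(organ = s$organ, cell_type = s$cell_type,
               genes = s$genes$gene, newick = s$newick)),
        p2, auto_unbox = TRUE, digits = NA)
      files <- c(p1, p2)
      if (length(sigs)) {
        p3 <- note(file.path(outdir, "signature_sharing.tsv"))
        write_results_table(signature_sharing(sigs), p3)
        files <- c(files, p3)
      }
      files
    }),
    score = run_stage("score", function(note) {
      b <- need("qc_bundle", "score", "qc")
      sets <- pipeline_gene_sets(config, state)
      scores <- ucell_score(b, sets[[1L]], max_rank = config$scoring$max_rank)
      state$scores <- scores
      p1 <- note(file.path(outdir, "ucell_scores.tsv"))
      write_results_table(data.frame(barcode = names(scores), score = scores), p1)
      grp_var <- if (!is.null(b$cell_meta$cell_type)) {
        b$cell_meta$stratum <- paste(b$cell_meta$organ, b$cell_meta$cell_type,
                                     sep = "|")
        "stratum"
      } else "organ"
      cmp <- compare_group_scores(scores, b$cell_meta, grp_var)
      p2 <- note(file.path(outdir, "score_groups.tsv"))
      write_results_table(cmp$summary, p2)
      p3 <- note(file.path(outdir, "score_pairwise.tsv"))
      write_results_table(cmp$pairwise, p3)
      c(p1, p2, p3)
    }),
    gsea = run_stage("gsea", function(note) {
      de <- need("de", "gsea", "de")
      sets <- pipeline_gene_sets(config, state, n_random = 3)
      combos <- unique(as.data.frame(de)[c("group", "stratum")])
      res <- list()
      for (i in seq_len(nrow(combos))) {
        rk <- rank_genes_de(de, combos$group[i], combos$stratum[i])
        if (length(rk) < config$gsea$min_size + 1L) next
        r <- preranked_gsea(rk, sets, weight = config$gsea$weight,
                            n_perm = config$gsea$n_perm, seed = config$seed,
                            min_size = config$gsea$min_size)
        if (nrow(r))
          res[[i]] <- cbind(organ = combos$group[i],
                            cell_type = combos$stratum[i], as.data.frame(r))
      }
      res <- if (length(res)) do.call(rbind, res) else
        data.frame(organ = character(0), cell_type = character(0),
                   set = character(0), q = numeric(0))
      p1 <- note(file.path(outdir, "gsea_results.tsv"))
      write_results_table(res, p1)
      files <- p1
      if (length(unique(res$organ)) >= 2L) {
        pu <- pathway_uniqueness(res, q_threshold = config$gsea$q_threshold)
        p2 <- note(file.path(outdir, "pathway_uniqueness.tsv"))
        write_results_table(pu, p2)
        files <- c(files, p2)
      }
      files
    }),
    report = run_stage("report", function(note) {
      p <- note(file.path(outdir, "run_report.json"))
      jsonlite::write_json(
        list(package = "immunatlas",
             version = as.character(packageVersion("immunatlas")),
             seed = config$seed, config_hash = chash,
             stages = names(artifacts),
             artifacts = lapply(artifacts, basename)),
        p, auto_unbox = TRUE, digits = NA)
      p
    })
  )
  invisible(artifacts)
}

# gene sets for the scoring / gsea stages: user GMT, else the simulation's
# planted module plus size-matched random sets (deterministic in the seed)
pipeline_gene_sets <- function(config, state, n_random = 0) {
  if (!is.null(config$gmt)) return(read_gmt(config$gmt))
  if (is.null(state$truth) || length(state$truth$module_genes) == 0L)
    stop("no gene sets: supply config$gmt or run the simulate stage")
  sets <- list(planted_module = gene_set("planted_module", state$truth$module_genes))
  if (n_random > 0) {
    genes <- setdiff(state$qc_bundle$gene_table$symbol, state$truth$module_genes)
    set.seed(config$seed + 1000L)
    for (i in seq_len(n_random)) {
      nm <- paste0("random_set_", i)
      sets[[nm]] <- gene_set(nm, sample(genes, length(state$truth$module_genes)))
    }
  }
  sets
}
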