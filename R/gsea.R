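# Preranked gene set enrichment with a gene-label permutation null, and the
# cross-organ pathway-uniqueness summary.

# Running-sum extremum from hit positions only (O(n_hits)); hits increment by
# |score|^weight normalized over the set, misses decrement by 1/(N - n_hit).
gsea_es <- function(scores_sorted, hit_pos, weight) {
  N <- length(scores_sorted)
  nh <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- abs(scores_sorted[hit_pos])^weight
  if (sum(w) == 0) w <- rep(1, nh)                 # degenerate all-zero scores
  inc <- cumsum(w / sum(w))
  dec <- 1 / (N - nh)
  peaks <- inc - (hit_pos - seq_len(nh)) * dec     # just after each hit
  troughs <- c(0, inc[-nh]) - (hit_pos - seq_len(nh)) * dec        # just before
  cand <- c(peaks, troughs)
  es <- cand[which.max(abs(cand))]
  j <- which.max(abs(cand))
  at_hit <- ((j - 1L) %% nh) + 1L
  leading <- if (es >= 0) hit_pos[seq_len(at_hit)] else hit_pos[at_hit:nh]
  list(es = es, leading = leading)
}

#' Preranked gene set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov-like enrichment score of each
#' gene set along a ranked gene list, with significance from gene-label
#' permutations: NES is the ES divided by the mean of the same-sign null ES
#' values, and the nominal p is the one-sided permutation fraction with +1
#' smoothing (so p is never 0). BH adjustment is applied across sets.
#'
#' @param ranked named numeric vector of ranking scores (e.g.
#'   `sign(log2FC) * -log10(p)`), or a data.frame with columns `gene` and
#'   `score`. Genes must be unique; sorted internally in decreasing order.
#' @param sets list of [gene_set()] objects.
#' @param weight score-weighting exponent (default 1; 0 gives the classical
#'   unweighted KS walk).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param min_size minimum set size after intersecting with the ranking
#'   (smaller sets are skipped with a message).
#' @return data.frame of class `gsea_result`: set, size, es, nes, p, q,
#'   leading_edge (comma-separated gene list).
#' @export
preranked_gsea <- function(ranked, sets, weight = 1, n_perm = 1000L,
                           seed = 1L, min_size = 5L) {
  if (is.data.frame(ranked)) ranked <- setNames(ranked$score, ranked$gene)
  if (is.null(names(ranked))) stop("ranking must be named by gene")
  if (anyDuplicated(names(ranked))) stop("ranked genes must be unique")
  if (inherits(sets, "gene_set")) sets <- list(sets)
  ord <- order(ranked, decreasing = TRUE)
  s <- as.numeric(ranked[ord]); genes <- names(ranked)[ord]
  N <- length(s)
  set.seed(as.integer(seed))
  rows <- list()
  for (gs in sets) {
    hit <- which(genes %in% gs$genes)
    nh <- length(hit)
    if (nh < min_size || nh >= N) {
      message(sprintf("preranked_gsea: set '%s' skipped (%d gene(s) in the ranking)",
                      gs$name, nh))
      next
    }
    obs <- gsea_es(s, hit, weight)
    null_es <- vapply(seq_len(n_perm), function(b)
      gsea_es(s, sample.int(N, nh), weight)$es, numeric(1L))
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same)) obs$es / abs(mean(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    rows[[gs$name]] <- data.frame(
      set = gs$name, size = nh, es = obs$es, nes = nes, p = p,
      leading_edge = paste(genes[obs$leading], collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), size = integer(0), es = numeric(0),
               nes = numeric(0), p = numeric(0), leading_edge = character(0))
  out$q <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  rownames(out) <- NULL
  class(out) <- c("gsea_result", class(out))
  out
}

#' Rank genes from a DE comparison for preranked GSEA
#'
#' Default ranking key: `sign(log2FC) * -log10(raw p)`; `"log2fc"` ranks by
#' fold change alone.
#'
#' @param de a [one_vs_rest_de()] result.
#' @param group,stratum the comparison to extract.
#' @param key ranking key.
#' @return named numeric vector of scores.
#' @export
rank_genes_de <- function(de, group, stratum = NULL,
                          key = c("signed_logp", "log2fc")) {
  key <- match.arg(key)
  rows <- de$group == group
  if (!is.null(stratum)) rows <- rows & de$stratum == stratum
  d <- de[rows, , drop = FALSE]
  if (nrow(d) == 0L) stop("no DE rows for the requested comparison")
  score <- if (key == "log2fc") d$log2fc else
    sign(d$log2fc) * -log10(pmax(d$p, .Machine$double.xmin))
  setNames(score, d$gene)
}

#' Cross-organ pathway uniqueness summary
#'
#' For every pathway enriched (BH-FDR q below `q_threshold`) in at least one
#' (organ, cell type), lists where it is enriched and flags pathways unique
#' to exactly one organ and pathways targeted in more than three organs.
#'
#' @param results data.frame combining [preranked_gsea()] outputs, with
#'   added columns `organ` and `cell_type` (at least two organs analyzed).
#' @param q_threshold FDR cutoff (default 0.01).
#' @return data.frame with columns set, organs, cell_types, n_organs,
#'   unique, shared_3plus.
#' @export
pathway_uniqueness <- function(results, q_threshold = 0.01) {
  results <- as.data.frame(results)
  empty <- data.frame(set = character(0), organs = character(0),
                      cell_types = character(0), n_organs = integer(0),
                      unique = logical(0), shared_3plus = logical(0))
  if (nrow(results) == 0L) return(empty)
  stopifnot(all(c("organ", "cell_type", "set", "q") %in% names(results)))
  if (length(unique(results$organ)) < 2L)
    stop("need results from at least 2 organs")
  hits <- results[results$q < q_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  do.call(rbind, lapply(split(hits, hits$set), function(h) {
    orgs <- sort(unique(h$organ))
    data.frame(set = h$set[1L],
               organs = paste(orgs, collapse = ","),
               cell_types = paste(sort(unique(h$cell_type)), collapse = ","),
               n_organs = length(orgs),
               unique = length(orgs) == 1L,
               shared_3plus = length(orgs) > 3L,
               stringsAsFactors = FALSE)
  }))
}
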