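#' Hypergeometric over-representation of a gene list in GMT gene sets
#'
#' For each set, computes the upper-tail hypergeometric probability of the
#' observed overlap between the list and the set, both restricted to the
#' gene universe: `p = P(X >= overlap)` for X hypergeometric with the
#' universe size, the in-universe set size and the list size. This is the
#' plain over-representation test (equivalent to a one-sided Fisher exact
#' test on the 2x2 overlap table); no service-specific score modification
#' is applied.
#'
#' @param gene_list character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param gene_sets named list of gene-id vectors (e.g. [read_gmt()]).
#' @param universe background gene ids; defaults in the pipeline to all
#'   detected genes of the count matrix.
#' @param bh also report Benjamini-Hochberg adjusted p-values.
#' @return data.frame sorted by p then overlap fraction: set, overlap,
#'   set_size (in universe), list_size, universe_size, p_value, (fdr),
#'   members (comma-joined overlapping genes).
#' @export
hypergeom_enrich <- function(gene_list, gene_sets, universe, bh = FALSE) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  extra <- setdiff(gene_list, universe)
  if (length(extra)) {
    stop("gene_list contains ", length(extra), " gene(s) outside the universe")
  }
  empty <- data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), list_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (!length(gene_list)) {
    warning("empty gene list; returning empty enrichment table")
    return(empty)
  }
  n_u <- length(universe)
  n_l <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- intersect(set, gene_list)
    k <- length(ov)
    p <- stats::phyper(k - 1, length(set), n_u - length(set), n_l,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               list_size = n_l, universe_size = n_u, p_value = p,
               members = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  frac <- ifelse(out$set_size > 0, out$overlap / out$set_size, 0)
  out <- out[order(out$p_value, -frac), , drop = FALSE]
  rownames(out) <- NULL
  if (bh) out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Report the top-k significant pathways
#'
#' Mirrors the "top three pathways" style of reporting: keeps sets with
#' `p < alpha`, ordered as returned by [hypergeom_enrich()], and truncates
#' to at most `k` rows (no padding when fewer are significant).
#'
#' @param results enrichment table from [hypergeom_enrich()].
#' @param k maximum number of sets to report (default 3).
#' @param alpha significance level (default 0.05).
#' @return data.frame subset of `results` with a `label` column
#'   `"set (overlap)"`.
#' @export
top_pathways <- function(results, k = 3, alpha = 0.05) {
  if (k < 1) stop("k must be >= 1")
  sig <- results[results$p_value < alpha, , drop = FALSE]
  sig <- utils::head(sig, k)
  sig$label <- sprintf("%s (%d)", sig$set, sig$overlap)
  rownames(sig) <- NULL
  sig
}
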