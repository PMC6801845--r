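#' Trimmed-mean scaling factors (TMM-style)
#'
#' Computes per-sample scaling factors by the trimmed weighted mean of
#' gene-wise log2 expression ratios (M values) against a reference sample,
#' the standard approach for relative-abundance count normalization. The
#' reference is the column whose upper-quartile of count proportions is
#' closest to the mean upper-quartile. For each sample, genes with zero
#' counts in either the sample or the reference are excluded; the most
#' extreme `trim_m` fraction of M values on each side and `trim_a` fraction
#' of A values (average log abundance) on each side are trimmed; remaining
#' M values are averaged with inverse asymptotic-variance weights and
#' exponentiated. Factors are rescaled so their geometric mean is exactly 1.
#'
#' @param counts nonnegative count matrix, genes x samples (>= 2 samples).
#' @param trim_m fraction trimmed from each tail of the M values (default 0.3).
#' @param trim_a fraction trimmed from each tail of the A values (default 0.05).
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  prop <- sweep(counts, 2, lib, "/")
  f75 <- apply(prop, 2, stats::quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(j) {
    if (j == ref) return(1)
    keep0 <- counts[, j] > 0 & counts[, ref] > 0
    x <- counts[keep0, j]
    r <- counts[keep0, ref]
    if (!length(x)) return(1)
    m <- log2((x / lib[j]) / (r / lib[ref]))
    a <- 0.5 * log2((x / lib[j]) * (r / lib[ref]))
    # inverse of the delta-method variance of M
    w <- 1 / ((lib[j] - x) / (lib[j] * x) + (lib[ref] - r) / (lib[ref] * r))
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m, ties.method = "first")
    ra_ <- rank(a, ties.method = "first")
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep) || sum(w[keep]) == 0) return(1)
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Normalized expression values (counts per million after factor adjustment)
#'
#' `value(g, s) = count(g, s) / (library_size(s) * factor(s)) * 1e6`,
#' the factor-adjusted counts-per-million scale on which the screening
#' thresholds of this pipeline are defined. Genes with zero counts
#' everywhere are retained with value 0 so gene universes stay aligned
#' across stages.
#'
#' @param counts count matrix, genes x samples.
#' @param factors per-sample scaling factors (e.g. from [tmm_factors()]);
#'   strictly positive, one per sample.
#' @return Numeric matrix of the same shape as `counts`.
#' @export
normalize_counts <- function(counts, factors = tmm_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) {
    stop("need one factor per sample (got ", length(factors), " for ",
         ncol(counts), " samples)")
  }
  if (any(factors <= 0)) stop("scaling factors must be strictly positive")
  lib <- colSums(counts)
  sweep(counts, 2, lib * factors, "/") * 1e6
}
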