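#' Exact negative-binomial two-group test and dispersion estimation
#'
#' The inferential engine of the pipeline: a re-implementation of the
#' conditioned exact test for negative-binomial counts ("Empirical Analysis
#' of DGE" family). Counts are first placed on a common effective library
#' size by a quantile-to-quantile adjustment; the test then conditions on
#' the total of the two group sums and enumerates the conditional
#' distribution of the observed split.
#'
#' @name detest
NULL

# Quantile-to-quantile NB adjustment: map a count observed under mean
# `mean_in` to the equivalent quantile under mean `mean_out`, holding the
# dispersion fixed. Average of a variance-stabilized normal mapping and a
# gamma quantile mapping (both mean/variance matched), the published
# approach for equalizing effective library sizes before conditioning.
q2q_nbinom <- function(x, mean_in, mean_out, phi) {
  mean_in <- pmax(mean_in, 1e-8)
  mean_out <- pmax(mean_out, 1e-8)
  v_in <- mean_in + phi * mean_in^2
  v_out <- mean_out + phi * mean_out^2
  xc <- x + 0.125  # continuity offset keeps zeros mappable
  out_n <- mean_out + sqrt(v_out / v_in) * (xc - mean_in)
  shape_in <- mean_in^2 / v_in
  shape_out <- mean_out^2 / v_out
  # map through the tail the observation sits in, so extreme counts keep
  # quantile precision instead of saturating at p = 1
  upper <- xc > mean_in
  p <- stats::pgamma(xc, shape = shape_in, scale = v_in / mean_in,
                     lower.tail = FALSE)
  p[!upper] <- stats::pgamma(xc[!upper], shape = shape_in[!upper],
                             scale = (v_in / mean_in)[!upper])
  out_g <- stats::qgamma(p, shape = shape_out, scale = v_out / mean_out,
                         lower.tail = FALSE)
  out_g[!upper] <- stats::qgamma(p[!upper], shape = shape_out[!upper],
                                 scale = (v_out / mean_out)[!upper])
  pmax(0.5 * (out_n + out_g) - 0.125, 0)
}

#' Equalize effective library sizes
#'
#' Produces pseudocounts adjusted so that every sample sits on the common
#' (geometric-mean) library size, given a working dispersion. Gene means
#' under the null of no group effect are used as the input means.
#'
#' @param counts count matrix (genes x samples).
#' @param phi working NB dispersion.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return List with `pseudo` (adjusted matrix) and `common_lib`.
#' @export
equalize_lib_sizes <- function(counts, phi, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  common <- exp(mean(log(lib_sizes)))
  rate <- rowSums(counts) / sum(lib_sizes)  # per-gene abundance under null
  pseudo <- counts
  for (j in seq_len(ncol(counts))) {
    pseudo[, j] <- q2q_nbinom(counts[, j], rate * lib_sizes[j],
                              rate * common, phi)
  }
  list(pseudo = pseudo, common_lib = common)
}

# Conditional log-likelihood of within-group counts given the group total,
# for one group of n replicates with common dispersion phi (r = 1/phi):
#   sum_i lgamma(y_i + r) + lgamma(n r) - lgamma(z + n r) - n lgamma(r)
# (terms free of phi dropped). Summed over genes.
cond_loglik_group <- function(y, phi) {
  r <- 1 / max(phi, 1e-8)
  n <- ncol(y)
  z <- rowSums(y)
  rowSums(lgamma(y + r)) + lgamma(n * r) - lgamma(z + n * r) - n * lgamma(r)
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the conditional log-likelihood of within-group counts given
#' group totals, summed over genes and groups, over phi in `[0, 10]`
#' (golden-section-based search, tolerance 1e-6), after equalizing
#' effective library sizes with [equalize_lib_sizes()]; the equalization
#' and maximization are iterated twice so the adjustment uses the estimated
#' dispersion. Falls back to a pooled method-of-moments estimate when the
#' conditional likelihood is degenerate.
#'
#' @param counts count matrix (genes x samples).
#' @param groups factor (or coercible) of group membership per sample; at
#'   least one group needs >= 2 replicates.
#' @param interval search interval for phi.
#' @param tol search tolerance.
#' @param lib_sizes per-sample (effective) library sizes; pass
#'   `colSums(counts) * factors` to estimate on the normalized scale.
#' @return List of class `dispersion_estimate`: `phi`, `method`
#'   (`"cml"` or `"moments"`).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       interval = c(0, 10), tol = 1e-6,
                                       lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("groups must have one entry per sample")
  }
  sizes <- table(groups)
  if (all(sizes < 2)) {
    stop("no group has replicates; supply a dispersion value explicitly")
  }
  multi <- names(sizes)[sizes >= 2]
  keep_genes <- rowSums(counts) > 0

  cll <- function(phi, pseudo) {
    tot <- 0
    for (g in multi) {
      y <- pseudo[keep_genes, groups == g, drop = FALSE]
      tot <- tot + sum(cond_loglik_group(y, phi))
    }
    tot
  }

  phi <- 0.01
  opt <- NULL
  for (iter in 1:2) {
    eq <- equalize_lib_sizes(counts, phi, lib_sizes = lib_sizes)
    opt <- try(stats::optimize(cll, interval = interval, pseudo = eq$pseudo,
                               maximum = TRUE, tol = tol), silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$objective)) {
      return(moments_dispersion(counts, groups, lib_sizes))
    }
    phi <- opt$maximum
  }
  if (phi >= interval[2] - 1e-3) {
    return(moments_dispersion(counts, groups, lib_sizes))
  }
  if (phi < 1e-5) phi <- 0  # boundary: no detectable excess variance
  structure(list(phi = phi, method = "cml"), class = "dispersion_estimate")
}

# Pooled method-of-moments dispersion on library-size-equalized counts.
moments_dispersion <- function(counts, groups, lib_sizes = colSums(counts)) {
  eq <- equalize_lib_sizes(counts, phi = 0, lib_sizes = lib_sizes)
  pseudo <- eq$pseudo
  groups <- as.factor(groups)
  sizes <- table(groups)
  multi <- names(sizes)[sizes >= 2]
  num <- 0
  den <- 0
  for (g in multi) {
    y <- pseudo[, groups == g, drop = FALSE]
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  phi <- if (den > 0) max(0, num / den) else 0
  structure(list(phi = phi, method = "moments"),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("Common NB dispersion: phi = %.6g (%s)\n", x$phi, x$method))
  invisible(x)
}

#' Exact conditional negative-binomial test for two group sums
#'
#' Conditions on `s = sum_a + sum_b`. Under a common mean and dispersion,
#' the group sums are NB with means `n_a * mu` and `n_b * mu` and sizes
#' `n_a / phi`, `n_b / phi`; the two-sided p-value is the total conditional
#' probability of all splits `k in [0, s]` whose probability does not
#' exceed that of the observed split, normalized by the total conditional
#' probability. With phi = 0 the conditional law is exactly binomial with
#' success probability `n_a / (n_a + n_b)`. For very large totals the
#' support is truncated where the excluded cumulative mass is below 1e-12.
#'
#' @param sum_a,sum_b group sums of library-size-equalized counts (rounded
#'   to integers internally).
#' @param n_a,n_b number of replicates per group.
#' @param phi NB dispersion.
#' @return Two-sided p-value in (0, 1]; `s = 0` returns 1 by convention
#'   (untestable gene).
#' @export
exact_nb_test <- function(sum_a, sum_b, n_a, n_b, phi) {
  ka <- round(sum_a)
  kb <- round(sum_b)
  s <- ka + kb
  if (s == 0) return(1)
  mu <- s / (n_a + n_b)

  if (s > 5e6) {
    # truncate support; excluded mass < 1e-12 of either marginal
    lo <- stats::qnbinom(1e-13, mu = n_a * mu,
                         size = if (phi > 0) n_a / phi else Inf)
    hi <- stats::qnbinom(1e-13, mu = n_b * mu,
                         size = if (phi > 0) n_b / phi else Inf,
                         lower.tail = FALSE)
    k <- seq.int(max(0, min(lo, ka)), min(s, max(s - hi, ka)))
  } else {
    k <- 0:s
  }

  if (phi <= 0) {
    lp <- stats::dbinom(k, s, n_a / (n_a + n_b), log = TRUE)
  } else {
    lp <- stats::dnbinom(k, mu = n_a * mu, size = n_a / phi, log = TRUE) +
      stats::dnbinom(s - k, mu = n_b * mu, size = n_b / phi, log = TRUE)
  }
  lp_obs <- lp[match(ka, k)]
  m <- max(lp)
  pr <- exp(lp - m)
  min(1, sum(pr[lp <= lp_obs + 1e-10]) / sum(pr))
}

#' Build a two-group contrast
#'
#' @param design design data.frame.
#' @param condition_a,condition_b condition labels whose samples form group
#'   A and group B.
#' @param name contrast label; default `"B_vs_A"` style.
#' @return List of class `contrast` with `name`, `group_a`, `group_b`.
#' @export
make_contrast <- function(design, condition_a, condition_b, name = NULL) {
  a <- samples_of(design, condition_a)
  b <- samples_of(design, condition_b)
  if (is.null(name)) {
    name <- paste0(paste(condition_b, collapse = "+"), "_vs_",
                   paste(condition_a, collapse = "+"))
  }
  contrast(name, a, b)
}

#' @rdname make_contrast
#' @param group_a,group_b sample-id vectors (disjoint, nonempty).
#' @export
contrast <- function(name, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("contrast '", name, "': both groups must be nonempty")
  }
  if (length(intersect(group_a, group_b))) {
    stop("contrast '", name, "': groups overlap")
  }
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "contrast")
}

#' Run the exact NB test for every gene of a contrast
#'
#' Tests group B against group A for each gene: counts are equalized to the
#' common library size of the contrast's samples (library sizes taken from
#' the full count matrix), group sums are compared with [exact_nb_test()],
#' and fold changes are computed on normalized group means with a 0.01
#' pseudocount on both means. A gene is flagged significant when `p <
#' alpha` and the fold change exceeds `fc_threshold` in either direction
#' (ratio > threshold or < 1/threshold). Optional Benjamini-Hochberg
#' adjustment replaces the raw p in the significance rule.
#'
#' @param counts raw count matrix (all genes; library sizes are computed
#'   from it).
#' @param normalized matching normalized matrix (see [normalize_counts()]).
#' @param contrast a [contrast()] object.
#' @param phi NB dispersion (e.g. [estimate_common_dispersion()]`$phi`).
#' @param alpha significance level (default 0.05).
#' @param fc_threshold fold-change threshold (default 2).
#' @param genes optional gene-id subset to test.
#' @param factors optional per-sample scaling factors (named, covering the
#'   contrast's samples); when given, the test equalizes to effective
#'   library sizes `colSums(counts) * factors`, so that compositional
#'   differences between groups do not masquerade as differential
#'   expression.
#' @param bh apply Benjamini-Hochberg adjustment (adds an `fdr` column and
#'   bases `significant` on it). Off by default: the screening procedure
#'   this package implements uses unadjusted p-values.
#' @return data.frame (class `de_result`): gene_id, mean_a, mean_b,
#'   fold_change, log2_fc, p_value, (fdr), significant.
#' @export
run_contrast <- function(counts, normalized, contrast, phi,
                         alpha = 0.05, fc_threshold = 2,
                         genes = NULL, factors = NULL, bh = FALSE) {
  stopifnot(inherits(contrast, "contrast"))
  samples <- c(contrast$group_a, contrast$group_b)
  miss <- setdiff(samples, colnames(counts))
  if (length(miss)) {
    stop("contrast '", contrast$name, "': sample(s) not in matrix: ",
         paste(miss, collapse = ", "))
  }
  if (is.null(genes)) genes <- rownames(counts)
  genes <- intersect(genes, rownames(counts))
  if (!length(genes)) stop("no genes to test")

  lib <- colSums(counts)[samples]
  if (!is.null(factors)) {
    miss_f <- setdiff(samples, names(factors))
    if (length(miss_f)) {
      stop("factors missing for sample(s): ", paste(miss_f, collapse = ", "))
    }
    lib <- lib * factors[samples]
  }
  eq <- equalize_lib_sizes(counts[, samples, drop = FALSE], phi,
                           lib_sizes = lib)
  pseudo <- eq$pseudo[genes, , drop = FALSE]
  ia <- match(contrast$group_a, samples)
  ib <- match(contrast$group_b, samples)
  sum_a <- rowSums(pseudo[, ia, drop = FALSE])
  sum_b <- rowSums(pseudo[, ib, drop = FALSE])
  n_a <- length(ia)
  n_b <- length(ib)

  p <- vapply(seq_along(genes), function(i) {
    exact_nb_test(sum_a[i], sum_b[i], n_a, n_b, phi)
  }, numeric(1))

  mean_a <- rowMeans(normalized[genes, contrast$group_a, drop = FALSE])
  mean_b <- rowMeans(normalized[genes, contrast$group_b, drop = FALSE])
  fc <- (mean_b + 0.01) / (mean_a + 0.01)
  out <- data.frame(gene_id = genes, mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc, log2_fc = log2(fc), p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  crit_p <- p
  if (bh) {
    out$fdr <- stats::p.adjust(p, method = "BH")
    crit_p <- out$fdr
  }
  out$significant <- crit_p < alpha &
    (fc > fc_threshold | fc < 1 / fc_threshold)
  attr(out, "contrast") <- contrast$name
  class(out) <- c("de_result", class(out))
  out
}
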