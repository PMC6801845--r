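#' Configuration of the five-step synergy screen
#'
#' @param panel character vector of panel gene ids (the designated
#'   cell-cycle gene list).
#' @param step2_threshold expression threshold on the normalized
#'   (counts-per-million) scale for Step 2 (default 1000). The original
#'   normalization scale is tool-defined, so this threshold is explicitly
#'   user-overridable.
#' @param alpha significance level for Steps 3 and 4 (default 0.05).
#' @param step2_scope which samples count as the "standing (1G)" set for
#'   Step 2: `"standing_all"` (all ST samples, irradiated included; the
#'   default reading) or `"standing_nonirradiated"` (ST cultures only).
#' @param step2_max take the Step-2 maximum over individual replicates
#'   (`"replicate"`, default) or over condition means (`"condition_mean"`).
#' @return List of class `screen_config`.
#' @export
screen_config <- function(panel,
                          step2_threshold = 1000,
                          alpha = 0.05,
                          step2_scope = c("standing_all",
                                          "standing_nonirradiated"),
                          step2_max = c("replicate", "condition_mean")) {
  if (!length(panel)) stop("panel must be nonempty")
  if (step2_threshold <= 0) stop("step2_threshold must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(panel = unique(panel),
                 step2_threshold = step2_threshold,
                 alpha = alpha,
                 step2_scope = match.arg(step2_scope),
                 step2_max = match.arg(step2_max),
                 conditions = irradiated_conditions()),
            class = "screen_config")
}

# the four standing-vs-rotating irradiated pairs, named by radiation-time
contrast_pairs <- function() {
  pairs <- c("X3", "X24", "C3", "C24")
  stats::setNames(lapply(pairs, function(p) {
    list(st = paste0("ST-", p), ro = paste0("RO-", p))
  }), pairs)
}

#' Step 1: restrict the gene universe to the detected panel
#'
#' @param counts raw count matrix (detection = at least one nonzero count).
#' @param panel panel gene ids.
#' @return Character vector: detected panel genes, in panel order.
#' @export
step1_panel_filter <- function(counts, panel) {
  detected <- rownames(counts)[rowSums(counts > 0) > 0]
  out <- intersect(panel, detected)
  if (!length(out)) {
    warning("no panel gene is detected in the count matrix")
  }
  out
}

#' Step 2: expression filter on standing (1G) samples
#'
#' Keeps genes whose maximum normalized value across the designated
#' standing samples reaches the threshold (`>=`).
#'
#' @param normalized normalized matrix.
#' @param genes genes entering the step (from [step1_panel_filter()]).
#' @param standing_samples sample ids forming the standing (1G) set.
#' @param threshold normalized-expression threshold (default 1000).
#' @param use `"replicate"`: maximum over individual samples (default);
#'   `"condition_mean"`: maximum over per-condition replicate means.
#' @param design design data.frame; required for `use = "condition_mean"`.
#' @return Character vector of retained gene ids.
#' @export
step2_expression_filter <- function(normalized, genes, standing_samples,
                                    threshold = 1000,
                                    use = c("replicate", "condition_mean"),
                                    design = NULL) {
  use <- match.arg(use)
  if (!length(standing_samples)) stop("standing_samples must be nonempty")
  m <- normalized[genes, standing_samples, drop = FALSE]
  if (use == "replicate") {
    mx <- apply(m, 1, max)
  } else {
    if (is.null(design)) stop("design needed for condition_mean maxima")
    cond <- design$condition[match(standing_samples, design$sample_id)]
    means <- sapply(unique(cond), function(cc) {
      rowMeans(m[, cond == cc, drop = FALSE])
    })
    mx <- apply(as.matrix(means), 1, max)
  }
  genes[mx >= threshold]
}

#' Step 3: gravity effect within each irradiated condition
#'
#' For each radiation-time pair (X3, X24, C3, C24), tests the standing
#' irradiated replicates against the rotating irradiated replicates with
#' the exact NB test. A gene passes when p < alpha in at least one pair;
#' every per-pair p-value is retained.
#'
#' @param counts,normalized full matrices.
#' @param design design data.frame.
#' @param genes genes entering the step.
#' @param phi NB dispersion.
#' @param alpha significance level.
#' @param factors per-sample scaling factors forwarded to [run_contrast()].
#' @return List: `p` (genes x pairs matrix), `pass` (named logical).
#' @export
step3_gravity_contrasts <- function(counts, normalized, design, genes,
                                    phi, alpha = 0.05, factors = NULL) {
  pairs <- contrast_pairs()
  need <- unlist(lapply(pairs, unlist))
  miss <- setdiff(need, design$condition)
  if (length(miss)) {
    stop("design is missing condition(s): ", paste(miss, collapse = ", "))
  }
  pmat <- sapply(names(pairs), function(nm) {
    ct <- make_contrast(design, pairs[[nm]]$st, pairs[[nm]]$ro,
                        name = paste0("RO-", nm, "_vs_ST-", nm))
    run_contrast(counts, normalized, ct, phi, alpha = alpha,
                 genes = genes, factors = factors)$p_value
  })
  pmat <- matrix(pmat, nrow = length(genes),
                 dimnames = list(genes, names(pairs)))
  pass <- apply(pmat < alpha, 1, any)
  list(p = pmat, pass = pass)
}

#' Step 4: microgravity effect alone for Step-3 failures
#'
#' Tests non-irradiated standing vs non-irradiated rotating cultures
#' (N = 6 vs 6 under the default design) with the exact NB test.
#'
#' @inheritParams step3_gravity_contrasts
#' @param genes genes that failed Step 3.
#' @return List: `p` (named numeric), `pass` (named logical).
#' @export
step4_microgravity_alone <- function(counts, normalized, design, genes,
                                     phi, alpha = 0.05, factors = NULL) {
  if (!length(genes)) {
    return(list(p = stats::setNames(numeric(0), character(0)),
                pass = stats::setNames(logical(0), character(0))))
  }
  ct <- make_contrast(design, "ST", "RO", name = "RO_vs_ST")
  res <- run_contrast(counts, normalized, ct, phi, alpha = alpha,
                      genes = genes, factors = factors)
  p <- stats::setNames(res$p_value, res$gene_id)
  list(p = p, pass = p < alpha)
}

#' Step 5: gravity-corrected fold change and synergy classification
#'
#' Corrects each irradiated rotating-condition mean for the baseline
#' gravity effect, then compares it with the matching standing irradiated
#' mean. Per gene: `r = mean(ST non-irradiated) / mean(RO non-irradiated)`;
#' `converted(c) = r * mean(RO-c)`; `adjusted_fc(c) = converted(c) /
#' mean(ST-c)` for each radiation-time pair c. A pair is classified
#' `enhanced_decrease` when the adjusted fold change is strictly below 1,
#' `enhanced_increase` when strictly above 1, `none` at exactly 1.
#'
#' @param normalized normalized matrix.
#' @param design design data.frame.
#' @param genes genes passing Step 3 or Step 4.
#' @return data.frame: gene_id, ratio_r, then per pair converted_*,
#'   adjusted_fc_*, class_*, plus `classifiable` (FALSE when the
#'   non-irradiated RO mean is zero).
#' @export
step5_convert_and_classify <- function(normalized, design, genes) {
  pairs <- contrast_pairs()
  st0 <- samples_of(design, "ST")
  ro0 <- samples_of(design, "RO")
  mean_st0 <- rowMeans(normalized[genes, st0, drop = FALSE])
  mean_ro0 <- rowMeans(normalized[genes, ro0, drop = FALSE])
  classifiable <- mean_ro0 > 0
  r <- ifelse(classifiable, mean_st0 / mean_ro0, NA_real_)

  out <- data.frame(gene_id = genes, ratio_r = r,
                    classifiable = classifiable,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (nm in names(pairs)) {
    m_ro <- rowMeans(normalized[genes, samples_of(design, pairs[[nm]]$ro),
                                drop = FALSE])
    m_st <- rowMeans(normalized[genes, samples_of(design, pairs[[nm]]$st),
                                drop = FALSE])
    conv <- r * m_ro
    afc <- ifelse(m_st > 0, conv / m_st, NA_real_)
    cls <- rep("none", length(genes))
    cls[!is.na(afc) & afc < 1] <- "enhanced_decrease"
    cls[!is.na(afc) & afc > 1] <- "enhanced_increase"
    cls[is.na(afc)] <- NA_character_
    out[[paste0("converted_", nm)]] <- conv
    out[[paste0("adjusted_fc_", nm)]] <- afc
    out[[paste0("class_", nm)]] <- cls
  }
  out
}

#' Run the full five-step synergy screen
#'
#' Applies Steps 1-5 in sequence: panel restriction, standing-expression
#' threshold, per-irradiated-condition gravity contrasts, the
#' microgravity-alone rescue test for Step-3 failures, and the
#' gravity-corrected fold-change classification. The returned record table
#' traces every panel gene through the funnel.
#'
#' @param counts raw count matrix.
#' @param normalized normalized matrix ([normalize_counts()]).
#' @param design design data.frame.
#' @param config a [screen_config()].
#' @param phi NB dispersion; estimated from the per-condition design with
#'   [estimate_common_dispersion()] when NULL.
#' @param factors per-sample scaling factors matching those used to build
#'   `normalized`; the exact tests equalize to the resulting effective
#'   library sizes. Recomputed with [tmm_factors()] by default.
#' @return List of class `screen_result`: `records` (one row per panel
#'   gene), `selected` (gene ids), `phi`, `config`. The gene-level
#'   `synergy_class` is the classification at the strongest-evidence pair
#'   (smallest Step-3 p for Step-3 entrants, largest |log2 adjusted fold
#'   change| for Step-4 entrants).
#' @export
run_screen <- function(counts, normalized, design, config, phi = NULL,
                       factors = tmm_factors(counts)) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(
      counts, design$condition[match(colnames(counts), design$sample_id)],
      lib_sizes = colSums(counts) * factors)$phi
  }
  alpha <- config$alpha
  pairs <- names(contrast_pairs())

  g1 <- step1_panel_filter(counts, config$panel)
  standing <- if (config$step2_scope == "standing_all") {
    design$sample_id[design$gravity == "ST"]
  } else {
    samples_of(design, "ST")
  }
  g2 <- step2_expression_filter(normalized, g1, standing,
                                threshold = config$step2_threshold,
                                use = config$step2_max, design = design)
  s3 <- if (length(g2)) {
    step3_gravity_contrasts(counts, normalized, design, g2, phi, alpha,
                            factors = factors)
  } else {
    list(p = matrix(numeric(0), 0, 4, dimnames = list(NULL, pairs)),
         pass = stats::setNames(logical(0), character(0)))
  }
  g3_fail <- g2[!s3$pass]
  s4 <- step4_microgravity_alone(counts, normalized, design, g3_fail,
                                 phi, alpha, factors = factors)
  g5 <- c(g2[s3$pass], g3_fail[s4$pass])
  s5 <- if (length(g5)) step5_convert_and_classify(normalized, design, g5)

  records <- data.frame(gene_id = config$panel, stringsAsFactors = FALSE)
  records$step1_pass <- records$gene_id %in% g1
  records$step2_pass <- records$gene_id %in% g2
  for (nm in pairs) {
    records[[paste0("step3_p_", nm)]] <-
      s3$p[match(records$gene_id, rownames(s3$p)), nm]
  }
  records$step3_pass <- records$gene_id %in% g2[s3$pass]
  records$step4_p <- s4$p[match(records$gene_id, names(s4$p))]
  records$step4_pass <- ifelse(records$gene_id %in% g3_fail,
                               records$gene_id %in% g3_fail[s4$pass], NA)
  records$ratio_r <- NA_real_
  records$classifiable <- NA
  for (nm in pairs) {
    records[[paste0("converted_", nm)]] <- NA_real_
    records[[paste0("adjusted_fc_", nm)]] <- NA_real_
    records[[paste0("class_", nm)]] <- NA_character_
  }
  records$synergy_class <- "none"
  if (length(g5)) {
    idx <- match(s5$gene_id, records$gene_id)
    for (col in setdiff(names(s5), "gene_id")) {
      records[[col]][idx] <- s5[[col]]
    }
    # gene-level class at the strongest-evidence pair
    for (i in seq_along(s5$gene_id)) {
      ri <- idx[i]
      if (!isTRUE(records$classifiable[ri])) next
      if (records$step3_pass[ri]) {
        best <- pairs[which.min(s3$p[s5$gene_id[i], ])]
      } else {
        afc <- unlist(s5[i, paste0("adjusted_fc_", pairs)])
        best <- pairs[which.max(abs(log2(afc)))]
      }
      records$synergy_class[ri] <- s5[[paste0("class_", best)]][i]
    }
  }
  records$selected <- records$step1_pass & records$step2_pass &
    (records$step3_pass | (!is.na(records$step4_pass) & records$step4_pass)) &
    !is.na(records$classifiable) & records$classifiable

  structure(list(records = records,
                 selected = records$gene_id[records$selected],
                 phi = phi, config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  r <- x$records
  cat("Five-step synergy screen\n")
  cat(sprintf("  panel %d | detected %d | above threshold %d | Step3 pass %d | Step4 pass %d\n",
              nrow(r), sum(r$step1_pass), sum(r$step2_pass),
              sum(r$step3_pass), sum(r$step4_pass, na.rm = TRUE)))
  cat(sprintf("  selected: %d gene(s)%s\n", length(x$selected),
              if (length(x$selected)) {
                paste0(" [", paste(x$selected, collapse = ", "), "]")
              } else ""))
  invisible(x)
}

#' Relative expression summaries (per-gene max-scaled condition profiles)
#'
#' For each gene, divides each condition's mean normalized value by the
#' gene's maximum condition mean, so the highest condition sits at exactly
#' 1. Standard errors are the standard deviation of the max-scaled
#' replicate values divided by sqrt(N). When raw counts and a dispersion
#' are supplied, the standing-vs-rotating pair within each irradiated
#' condition (and the non-irradiated pair) is tested with the exact NB
#' test, yielding a direction call per pair: `up` / `down` (significant
#' increase / decrease under rotation) or `ns`.
#'
#' @param normalized normalized matrix.
#' @param design design data.frame.
#' @param genes gene ids to summarize (nonempty).
#' @param counts optional raw counts for the direction tests.
#' @param phi NB dispersion (required with `counts`).
#' @param alpha significance level for the direction calls.
#' @param factors per-sample scaling factors for the direction tests.
#' @return data.frame with one row per gene x condition: gene_id,
#'   condition, relative, se; attribute `"directions"` holds the per-pair
#'   calls when tests were run.
#' @export
relative_expression <- function(normalized, design, genes,
                                counts = NULL, phi = NULL, alpha = 0.05,
                                factors = NULL) {
  if (!length(genes)) stop("genes must be nonempty")
  conds <- intersect(condition_labels(), unique(design$condition))
  m <- normalized[genes, , drop = FALSE]
  cond_means <- sapply(conds, function(cc) {
    rowMeans(m[, samples_of(design, cc), drop = FALSE])
  })
  cond_means <- matrix(cond_means, nrow = length(genes),
                       dimnames = list(genes, conds))
  mx <- apply(cond_means, 1, max)
  mx[mx == 0] <- 1  # all-zero gene: flat profile of zeros

  rel <- cond_means / mx
  se <- sapply(conds, function(cc) {
    cols <- samples_of(design, cc)
    reps <- m[, cols, drop = FALSE] / mx
    apply(reps, 1, stats::sd) / sqrt(length(cols))
  })
  se <- matrix(se, nrow = length(genes), dimnames = list(genes, conds))

  out <- data.frame(gene_id = rep(genes, times = length(conds)),
                    condition = rep(conds, each = length(genes)),
                    relative = as.vector(rel), se = as.vector(se),
                    stringsAsFactors = FALSE)

  if (!is.null(counts)) {
    if (is.null(phi)) stop("phi required for direction tests")
    pairs <- c(list(none = list(st = "ST", ro = "RO")), contrast_pairs())
    dirs <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    for (nm in names(pairs)) {
      st <- pairs[[nm]]$st
      ro <- pairs[[nm]]$ro
      if (!all(c(st, ro) %in% design$condition)) next
      ct <- make_contrast(design, st, ro)
      res <- run_contrast(counts, normalized, ct, phi, alpha = alpha,
                          genes = genes, factors = factors)
      call <- ifelse(res$p_value < alpha,
                     ifelse(res$log2_fc > 0, "up", "down"), "ns")
      dirs[[nm]] <- call
    }
    attr(out, "directions") <- dirs
  }
  out
}
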