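#' Configuration for the end-to-end pipeline
#'
#' @param counts,design,panel,gmt input file paths (counts TSV, design TSV,
#'   panel file, GMT collection).
#' @param out_dir output directory for all stage reports.
#' @param alpha significance level used throughout (default 0.05).
#' @param fc_threshold fold-change threshold for the per-contrast
#'   differential-expression lists (default 2).
#' @param step2_threshold Step-2 normalized-expression threshold
#'   (default 1000).
#' @param step2_scope see [screen_config()].
#' @param phi optional dispersion override; estimated when NULL.
#' @param bh apply Benjamini-Hochberg adjustment in the contrast tables.
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic given the inputs).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, panel, gmt, out_dir,
                            alpha = 0.05, fc_threshold = 2,
                            step2_threshold = 1000,
                            step2_scope = "standing_all",
                            phi = NULL, bh = FALSE, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (fc_threshold <= 0 || step2_threshold <= 0) {
    stop("thresholds must be positive")
  }
  structure(list(counts = counts, design = design, panel = panel,
                 gmt = gmt, out_dir = out_dir, alpha = alpha,
                 fc_threshold = fc_threshold,
                 step2_threshold = step2_threshold,
                 step2_scope = step2_scope, phi = phi, bh = bh,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  message(sprintf("[%s] started", name))
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done (%.1f s)", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full screening pipeline
#'
#' Executes normalization, the differential-expression contrasts (every
#' condition against the non-irradiated standing reference), the five-step
#' synergy screen, the heatmap export for the detected panel, relative
#' expression summaries for the selected genes, and over-representation of
#' each contrast's up/down lists — writing every stage output plus a
#' machine-readable JSON run manifest to `config$out_dir`. Identical
#' configuration and inputs give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`normalized`, `factors`, `phi`, `contrasts`, `screen`, `heatmap`,
#'   `relative`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("counts", "design", "panel", "gmt")) {
    if (!file.exists(config[[f]])) {
      stop("input file for '", f, "' not found: ", config[[f]])
    }
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  counts <- read_counts_tsv(config$counts)
  design <- read_design_tsv(config$design)
  panel <- read_panel(config$panel)
  sets <- read_gmt(config$gmt)

  norm <- stage("normalize", {
    factors <- tmm_factors(counts)
    normalized <- normalize_counts(counts, factors)
    utils::write.table(
      data.frame(sample_id = names(factors), factor = factors,
                 row.names = NULL),
      file.path(out_dir, "factors.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_counts_tsv(normalized, file.path(out_dir, "normalized.tsv"))
    list(factors = factors, normalized = normalized)
  })
  normalized <- norm$normalized

  phi <- stage("dispersion", {
    if (!is.null(config$phi)) config$phi else {
      estimate_common_dispersion(
        counts,
        design$condition[match(colnames(counts), design$sample_id)],
        lib_sizes = colSums(counts) * norm$factors)$phi
    }
  })

  contrasts <- stage("detest", {
    ref <- "ST"
    others <- intersect(condition_labels(), unique(design$condition))
    others <- setdiff(others, ref)
    res <- lapply(others, function(cc) {
      ct <- make_contrast(design, ref, cc)
      run_contrast(counts, normalized, ct, phi, alpha = config$alpha,
                   fc_threshold = config$fc_threshold,
                   factors = norm$factors, bh = config$bh)
    })
    names(res) <- paste0(others, "_vs_", ref)
    for (nm in names(res)) {
      utils::write.table(res[[nm]],
                         file.path(out_dir, paste0("de_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
  })

  scr <- stage("screen", {
    cfg <- screen_config(panel, step2_threshold = config$step2_threshold,
                         alpha = config$alpha,
                         step2_scope = config$step2_scope)
    res <- run_screen(counts, normalized, design, cfg, phi = phi,
                      factors = norm$factors)
    utils::write.table(res$records,
                       file.path(out_dir, "screen_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel <- res$records[res$records$selected, , drop = FALSE]
    jsonlite::write_json(
      lapply(seq_len(nrow(sel)), function(i) {
        list(gene_id = sel$gene_id[i], ratio_r = sel$ratio_r[i],
             synergy_class = sel$synergy_class[i],
             classes = as.list(sel[i, grep("^class_", names(sel))]))
      }),
      file.path(out_dir, "selected_genes.json"), auto_unbox = TRUE,
      digits = NA)
    res
  })

  hm <- stage("heatmap", {
    g1 <- step1_panel_filter(counts, panel)
    tv <- transform_values(normalized, design, genes = g1)
    grp <- allocate_groups(tv, reference = "ST")
    write_heatmap(tv, grp, out_dir)
    list(values = tv, groups = grp)
  })

  rel <- stage("relative_expression", {
    genes <- if (length(scr$selected)) scr$selected else character(0)
    if (length(genes)) {
      r <- relative_expression(normalized, design, genes, counts = counts,
                               phi = phi, alpha = config$alpha,
                               factors = norm$factors)
      utils::write.table(r, file.path(out_dir, "relative_expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dirs <- attr(r, "directions")
      utils::write.table(dirs,
                         file.path(out_dir, "relative_directions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      r
    } else NULL
  })

  enr <- stage("enrich", {
    universe <- rownames(counts)[rowSums(counts > 0) > 0]
    tabs <- list()
    for (nm in names(contrasts)) {
      de <- contrasts[[nm]]
      for (dirn in c("up", "down")) {
        lst <- de$gene_id[de$significant &
                            (if (dirn == "up") de$log2_fc > 0
                             else de$log2_fc < 0)]
        lst <- intersect(lst, universe)
        if (!length(lst)) next
        tab <- hypergeom_enrich(lst, sets, universe)
        tabs[[paste0(nm, "_", dirn)]] <- tab
        utils::write.table(tab,
                           file.path(out_dir,
                                     paste0("enrich_", nm, "_", dirn, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    tabs
  })

  manifest <- list(
    package = "clinoscreen",
    version = as.character(utils::packageVersion("clinoscreen")),
    inputs = list(counts = config$counts, design = config$design,
                  panel = config$panel, gmt = config$gmt),
    parameters = list(alpha = config$alpha,
                      fc_threshold = config$fc_threshold,
                      step2_threshold = config$step2_threshold,
                      step2_scope = config$step2_scope,
                      phi = phi, bh = config$bh, seed = config$seed),
    n_genes = nrow(counts), n_samples = ncol(counts),
    selected_genes = scr$selected,
    files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(normalized = normalized, factors = norm$factors,
                 phi = phi, contrasts = contrasts, screen = scr,
                 heatmap = hm, relative = rel, enrichment = enr,
                 manifest = manifest))
}

#' Generate the bundled default fixture
#'
#' Convenience wrapper: simulates the default 36-sample experiment with
#' the given seed and writes the fixture files to `dir`.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param ... overrides forwarded to [sim_config()].
#' @return Named vector of written file paths (invisibly the simulation
#'   object is attached as attribute `"sim"`).
#' @export
bootstrap_fixture <- function(seed, dir, ...) {
  sim <- simulate_counts(sim_config(seed = seed, ...))
  paths <- write_fixture(sim, dir)
  attr(paths, "sim") <- sim
  invisible(paths)
}
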