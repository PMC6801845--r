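#' Configuration for the synthetic two-stressor count simulator
#'
#' Builds and validates the configuration driving [simulate_counts()]. The
#' defaults emulate, at desk scale, a 36-sample factorial RNA-seq screen:
#' 10 conditions (gravity ST/RO x radiation none/X/C x time 3/24 h), 6
#' replicates for the two non-irradiated cultures and 3 for each of the 8
#' irradiated ones. A designated cell-cycle panel of `panel_size` genes is
#' planted, of which `panel_detected` are expressed; `n_step2_genes` of the
#' detected panel genes carry high baseline expression (above the screening
#' expression threshold on the counts-per-million scale), and
#' `n_synergy_genes` of those additionally carry a gravity x radiation
#' interaction — the "synergy" signal the five-step screen is built to
#' recover. A separate small non-panel gene set responds to microgravity
#' alone, and a larger non-panel program responds to radiation, so that
#' every branch of the screen and the over-representation stage sees
#' signal.
#'
#' @param n_genes total simulated genes (desk-scale stand-in for a
#'   whole-transcriptome quantification).
#' @param panel_size size of the designated cell-cycle panel.
#' @param panel_detected number of panel genes with nonzero expression;
#'   the remainder are simulated as undetected (all-zero).
#' @param baseline_mean median of the log-normal gene baseline means
#'   (expected counts at library factor 1).
#' @param baseline_sdlog sdlog of the log-normal baseline distribution.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param lib_size_range length-2 range of per-sample library-size
#'   multipliers, drawn uniformly.
#' @param effect_log2fc_radiation log2 fold change applied to
#'   radiation-program genes (and, with alternating sign, to detected panel
#'   genes) in every irradiated condition.
#' @param effect_log2fc_microgravity log2 fold change applied to the
#'   microgravity-alone program genes in every rotated (RO) condition.
#' @param effect_log2fc_synergy extra interaction log2 fold change applied
#'   only under gravity = RO and radiation != none.
#' @param n_synergy_genes number of planted interaction genes (subset of
#'   the high-expression panel genes).
#' @param n_synergy_down how many of the synergy genes are
#'   enhanced_decrease (the rest are enhanced_increase).
#' @param n_step2_genes number of panel genes planted above the screening
#'   expression threshold.
#' @param high_mean_range baseline-mean range (log-uniform) for the
#'   high-expression panel genes.
#' @param n_mug_genes size of the non-panel microgravity-alone program.
#' @param n_radiation_genes size of the non-panel radiation program (half
#'   up, half down).
#' @param replicates named integer map condition -> replicate count; see
#'   [default_replicates()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 7)
#' sim <- simulate_counts(cfg)
#' dim(sim$counts)
#' @export
sim_config <- function(n_genes = 2000L,
                       panel_size = 84L,
                       panel_detected = 82L,
                       baseline_mean = 60,
                       baseline_sdlog = 1.1,
                       dispersion = 0.1,
                       lib_size_range = c(0.7, 1.3),
                       effect_log2fc_radiation = 1.5,
                       effect_log2fc_microgravity = 1.5,
                       effect_log2fc_synergy = 2.0,
                       n_synergy_genes = 9L,
                       n_synergy_down = 3L,
                       n_step2_genes = 13L,
                       high_mean_range = c(1500, 6000),
                       n_mug_genes = 30L,
                       n_radiation_genes = 240L,
                       replicates = default_replicates(),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              panel_size = as.integer(panel_size),
              panel_detected = as.integer(panel_detected),
              baseline_mean = baseline_mean,
              baseline_sdlog = baseline_sdlog,
              dispersion = dispersion,
              lib_size_range = lib_size_range,
              effect_log2fc_radiation = effect_log2fc_radiation,
              effect_log2fc_microgravity = effect_log2fc_microgravity,
              effect_log2fc_synergy = effect_log2fc_synergy,
              n_synergy_genes = as.integer(n_synergy_genes),
              n_synergy_down = as.integer(n_synergy_down),
              n_step2_genes = as.integer(n_step2_genes),
              high_mean_range = high_mean_range,
              n_mug_genes = as.integer(n_mug_genes),
              n_radiation_genes = as.integer(n_radiation_genes),
              replicates = replicates,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$baseline_mean <= 0) stop("baseline_mean must be strictly positive")
  if (cfg$baseline_sdlog <= 0) stop("baseline_sdlog must be strictly positive")
  if (cfg$dispersion < 0) stop("dispersion must be non-negative")
  if (length(cfg$lib_size_range) != 2L || any(cfg$lib_size_range <= 0) ||
      diff(cfg$lib_size_range) < 0) {
    stop("lib_size_range must be an increasing pair of positive reals")
  }
  if (length(cfg$high_mean_range) != 2L || any(cfg$high_mean_range <= 0)) {
    stop("high_mean_range must be a pair of positive reals")
  }
  if (cfg$panel_detected > cfg$panel_size) {
    stop("panel_detected cannot exceed panel_size")
  }
  if (cfg$n_step2_genes > cfg$panel_detected) {
    stop("n_step2_genes cannot exceed panel_detected")
  }
  if (cfg$n_synergy_genes > cfg$n_step2_genes) {
    stop("n_synergy_genes cannot exceed n_step2_genes (synergy genes must ",
         "be screenable)")
  }
  if (cfg$n_synergy_down > cfg$n_synergy_genes) {
    stop("n_synergy_down cannot exceed n_synergy_genes")
  }
  if (!setequal(names(cfg$replicates), condition_labels())) {
    stop("replicates map must cover exactly the 10 design conditions")
  }
  # radiation-program size is capped to the available non-panel genes, so
  # only panel + microgravity blocks are hard requirements
  if (cfg$n_genes < cfg$panel_size + cfg$n_mug_genes) {
    stop("n_genes too small for the configured panel and program sizes")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-stressor count simulation config\n")
  cat(sprintf("  genes: %d (panel %d, detected %d; %d above threshold, %d synergy)\n",
              x$n_genes, x$panel_size, x$panel_detected,
              x$n_step2_genes, x$n_synergy_genes))
  cat(sprintf("  samples: %d over %d conditions; dispersion phi = %g; seed %d\n",
              sum(x$replicates), length(x$replicates), x$dispersion, x$seed))
  invisible(x)
}

# True per-condition mean matrix (genes x 10 conditions) plus gene annotation.
# Effects are multiplicative on the baseline:
#   mu(g, c) = base_g * 2^(rad_g [c irradiated]) * 2^(mug_g [c rotated])
#                     * 2^(syn_g [c rotated & irradiated])
build_truth <- function(cfg) {
  labs <- condition_labels()
  info <- parse_condition(labs)
  irr <- info$radiation != "none"
  rot <- info$gravity == "RO"

  n_panel <- cfg$panel_size
  ids <- c(sprintf("CC%03d", seq_len(n_panel)),
           if (cfg$n_mug_genes > 0) sprintf("MU%03d", seq_len(cfg$n_mug_genes)),
           sprintf("G%05d", seq_len(cfg$n_genes - n_panel - cfg$n_mug_genes)))

  in_panel <- startsWith(ids, "CC")
  mug_program <- startsWith(ids, "MU")
  detected <- rep(TRUE, cfg$n_genes)
  # undetected panel genes are the tail of the panel block
  if (cfg$panel_size > cfg$panel_detected) {
    undet <- seq.int(cfg$panel_detected + 1L, cfg$panel_size)
    detected[undet] <- FALSE
  }

  base <- stats::rlnorm(cfg$n_genes, meanlog = log(cfg$baseline_mean),
                        sdlog = cfg$baseline_sdlog)
  # detected low-expression panel genes are capped well below the screening
  # threshold so the Step-2 cut is decided by construction, not by noise
  low_panel <- in_panel & detected
  low_panel[seq_len(cfg$n_step2_genes)] <- FALSE
  base[low_panel] <- pmin(pmax(base[low_panel], 3), 30)
  # high-expression panel genes: log-uniform inside high_mean_range
  hi <- seq_len(cfg$n_step2_genes)
  base[hi] <- exp(stats::runif(cfg$n_step2_genes,
                               log(cfg$high_mean_range[1]),
                               log(cfg$high_mean_range[2])))
  base[!detected] <- 0

  # radiation program: all detected panel genes respond (alternating sign,
  # emulating the radiation-dominated heatmap pattern), plus a dedicated
  # non-panel block split half up / half down
  rad_lfc <- numeric(cfg$n_genes)
  panel_idx <- which(in_panel & detected)
  rad_lfc[panel_idx] <- cfg$effect_log2fc_radiation *
    ifelse(seq_along(panel_idx) %% 2L == 0L, -1, 1)
  non_panel <- which(!in_panel & !mug_program)
  n_rad <- min(cfg$n_radiation_genes, length(non_panel))
  rad_idx <- non_panel[seq_len(n_rad)]
  rad_lfc[rad_idx] <- cfg$effect_log2fc_radiation *
    ifelse(seq_len(n_rad) <= n_rad / 2, 1, -1)

  mug_lfc <- numeric(cfg$n_genes)
  mug_lfc[mug_program] <- cfg$effect_log2fc_microgravity

  syn_lfc <- numeric(cfg$n_genes)
  syn_class <- rep("none", cfg$n_genes)
  if (cfg$n_synergy_genes > 0) {
    syn_idx <- seq_len(cfg$n_synergy_genes)
    n_up <- cfg$n_synergy_genes - cfg$n_synergy_down
    sign_vec <- rep(c(1, -1), c(n_up, cfg$n_synergy_down))
    syn_lfc[syn_idx] <- sign_vec * cfg$effect_log2fc_synergy
    syn_class[syn_idx] <- ifelse(sign_vec > 0, "enhanced_increase",
                                 "enhanced_decrease")
  }

  mu <- outer(base, rep(1, length(labs)))
  for (j in seq_along(labs)) {
    lfc <- rad_lfc * irr[j] + mug_lfc * rot[j] + syn_lfc * (rot[j] && irr[j])
    mu[, j] <- base * 2^lfc
  }
  colnames(mu) <- labs
  rownames(mu) <- ids

  truth <- data.frame(gene_id = ids, in_panel = in_panel,
                      detected = detected, mug_program = mug_program,
                      radiation_program = rad_lfc != 0,
                      synergy_class_truth = syn_class,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(mu, check.names = FALSE))
  names(truth)[seq.int(7L, 6L + length(labs))] <- paste0("mean_", labs)
  list(truth = truth, mu = mu)
}

#' Simulate a two-stressor factorial count experiment
#'
#' Draws a gene-by-sample negative-binomial count matrix with the factorial
#' structure, planted effects and library-size variation described in
#' [sim_config()]. Counts for gene g in sample s are NB with mean
#' `lib_factor(s) * mu(g, condition(s))` and dispersion phi
#' (variance = mu + phi mu^2); phi = 0 draws Poisson counts.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `clino_sim` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples.}
#'     \item{design}{per-sample design data.frame (see [build_design()]).}
#'     \item{truth}{gene-level ground-truth table: panel membership,
#'       detection, program membership, synergy class, and the true mean of
#'       every condition (columns `mean_<condition>`).}
#'     \item{lib_factors}{named per-sample library-size multipliers.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_counts <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  design <- build_design(config$replicates)
  tr <- build_truth(config)
  n_s <- nrow(design)
  lib <- stats::runif(n_s, config$lib_size_range[1], config$lib_size_range[2])
  names(lib) <- design$sample_id

  mu_samp <- tr$mu[, design$condition, drop = FALSE] *
    rep(lib, each = config$n_genes)
  if (config$dispersion > 0) {
    counts <- stats::rnbinom(length(mu_samp), mu = mu_samp,
                             size = 1 / config$dispersion)
  } else {
    counts <- stats::rpois(length(mu_samp), lambda = mu_samp)
  }
  counts <- matrix(as.integer(counts), nrow = config$n_genes,
                   dimnames = list(rownames(tr$mu), design$sample_id))
  structure(list(counts = counts, design = design, truth = tr$truth,
                 lib_factors = lib, config = config),
            class = "clino_sim")
}

#' @export
print.clino_sim <- function(x, ...) {
  cat(sprintf("Simulated two-stressor experiment: %d genes x %d samples (%d conditions)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$design$condition))))
  cat(sprintf("  planted synergy genes: %d; seed %d\n",
              sum(x$truth$synergy_class_truth != "none"), x$config$seed))
  invisible(x)
}

#' Write a simulated experiment to plain-text fixture files
#'
#' Emits `counts.tsv` (first column gene_id, one column per sample),
#' `design.tsv`, `truth.tsv`, `panel.txt` (one panel gene id per line) and
#' `sets.gmt`. The GMT holds the cell-cycle panel, the microgravity-alone
#' program set and three deterministic decoy sets, so the
#' over-representation stage can run against the fixture out of the box.
#' Files round-trip losslessly through [read_counts_tsv()],
#' [read_design_tsv()] and [read_gmt()].
#'
#' @param sim a `clino_sim` object from [simulate_counts()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "clino_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"),
             panel = file.path(dir, "panel.txt"),
             gmt = file.path(dir, "sets.gmt"))
  write_counts_tsv(sim$counts, paths["counts"])
  utils::write.table(sim$design, paths["design"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  panel_ids <- sim$truth$gene_id[sim$truth$in_panel]
  writeLines(panel_ids, paths["panel"])

  mug_ids <- sim$truth$gene_id[sim$truth$mug_program]
  other <- sim$truth$gene_id[!sim$truth$in_panel & !sim$truth$mug_program]
  decoy <- list(DECOY_A = other[seq_len(min(50, length(other)))],
                DECOY_B = other[seq.int(51, min(100, length(other)))],
                DECOY_C = other[seq.int(101, min(150, length(other)))])
  sets <- c(list(CELL_CYCLE_PANEL = panel_ids),
            if (length(mug_ids)) list(MUG_RESPONSE = mug_ids),
            decoy)
  write_gmt(sets, paths["gmt"])
  invisible(paths)
}
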