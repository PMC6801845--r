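#' Log2 transformed per-condition expression values for heatmap export
#'
#' Averages normalized values over replicates within each condition, adds
#' the 0.01 pseudocount and takes log2:
#' `transformed(g, c) = log2(mean normalized(g, c) + 0.01)`. Conditions are
#' ordered ST, ST-X3, ..., RO-C24.
#'
#' @param normalized normalized matrix.
#' @param design design data.frame.
#' @param genes optional gene subset (default: all rows).
#' @return Numeric matrix genes x conditions with attribute
#'   `"color_scale"` = c(-7, 0, 13), the display bounds used for
#'   visualization.
#' @export
transform_values <- function(normalized, design, genes = rownames(normalized)) {
  conds <- intersect(condition_labels(), unique(design$condition))
  tv <- sapply(conds, function(cc) {
    log2(rowMeans(normalized[genes, samples_of(design, cc),
                             drop = FALSE]) + 0.01)
  })
  tv <- matrix(tv, nrow = length(genes), dimnames = list(genes, conds))
  attr(tv, "color_scale") <- c(-7, 0, 13)
  tv
}

#' Allocate genes to no-change / down / up groups per condition
#'
#' Compares each condition's transformed value with the reference
#' condition: with `delta = transformed(c) - transformed(reference)`,
#' `|delta| < 1` is `no_change`, `delta <= -1` is `down`, `delta >= 1` is
#' `up` (a difference of exactly 1 counts as changed). The reference column
#' carries no group.
#'
#' @param tv transformed-value matrix from [transform_values()].
#' @param reference reference condition label (default `"ST"`).
#' @return Character matrix genes x non-reference conditions.
#' @export
allocate_groups <- function(tv, reference = "ST") {
  if (!reference %in% colnames(tv)) {
    stop("reference condition '", reference, "' not in matrix")
  }
  others <- setdiff(colnames(tv), reference)
  delta <- tv[, others, drop = FALSE] - tv[, reference]
  grp <- matrix("no_change", nrow = nrow(tv), ncol = length(others),
                dimnames = list(rownames(tv), others))
  grp[delta <= -1] <- "down"
  grp[delta >= 1] <- "up"
  grp
}

#' Write the heatmap matrix and group allocations to TSV
#'
#' Emits a matrix-visualization-ready TSV (genes as rows, conditions as
#' columns, transformed values), a parallel groups TSV, and a small JSON
#' metadata file recording the reference condition and the color-scale
#' bounds (-7.00 / 0.00 / 13.00).
#'
#' @param tv transformed-value matrix.
#' @param groups group matrix from [allocate_groups()].
#' @param dir output directory.
#' @return Invisibly, named vector of written paths.
#' @export
write_heatmap <- function(tv, groups, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(values = file.path(dir, "heatmap.tsv"),
             groups = file.path(dir, "heatmap_groups.tsv"),
             meta = file.path(dir, "heatmap_meta.json"))
  write_counts_tsv(tv, paths["values"])
  write_counts_tsv(groups, paths["groups"])
  jsonlite::write_json(list(reference = "ST",
                            color_scale = attr(tv, "color_scale"),
                            conditions = colnames(tv)),
                       paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
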