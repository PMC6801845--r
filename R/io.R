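#' Read / write gene-by-sample matrices and design tables
#'
#' Tab-separated plain-text interchange: the counts (or normalized) TSV has
#' `gene_id` as first column and one column per sample; the design TSV has
#' columns sample_id, gravity, radiation, time, replicate, condition.
#'
#' @param path file path.
#' @return `read_counts_tsv()`: numeric matrix with gene rownames;
#'   `read_design_tsv()`: data.frame.
#' @name fixture_io
NULL

#' @rdname fixture_io
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id: ", path)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' @rdname fixture_io
#' @param m matrix with gene rownames and sample colnames.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname fixture_io
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gravity", "radiation", "time", "replicate",
            "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read a gene panel file (one gene id per line)
#' @param path file path; blank lines and `#` comments ignored.
#' @return character vector of gene ids.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read / write GMT gene-set collections
#'
#' Reading delegates to [fgsea::gmtPathways()] (set name, description,
#' tab-separated members). `write_gmt()` emits one line per set with a `na`
#' description field.
#'
#' @param path GMT file path.
#' @param sets named list of character vectors (for writing).
#' @return `read_gmt()`: named list of member gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
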