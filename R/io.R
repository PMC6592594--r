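# Plain-text readers and writers for the pipeline's interchange formats.
# Everything is TSV (or GMT / JSON) so stage outputs diff cleanly and each
# stage can be rerun from files alone.

#' Write / read a count matrix and gene lengths as TSV
#'
#' The counts file has the gene id in the first column and one column per
#' sample; the lengths file has columns `gene`, `length`.
#'
#' @param counts A [count_matrix()].
#' @param counts_path,lengths_path Output paths.
#' @return [read_counts()] returns a [count_matrix()].
#' @export
write_counts <- function(counts, counts_path, lengths_path) {
  stopifnot(inherits(counts, "count_matrix"))
  df <- data.frame(gene = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(data.frame(gene = names(counts$lengths),
                       length = unname(counts$lengths)), lengths_path)
  invisible(c(counts_path, lengths_path))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, lengths_path) {
  df <- read_tsv(counts_path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  len <- read_tsv(lengths_path)
  count_matrix(mat, stats::setNames(len$length, len$gene))
}

#' Write / read a sample sheet as TSV
#'
#' Columns `sample`, `day`, `condition`, `pair`.
#'
#' @param samples Sample sheet data frame.
#' @param path File path.
#' @export
write_sample_sheet <- function(samples, path) {
  stopifnot(all(c("sample", "day", "condition", "pair") %in% names(samples)))
  write_tsv(samples, path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sample", "day", "condition") %in% names(df))) {
    stop("sample sheet needs columns sample, day, condition", call. = FALSE)
  }
  df
}

#' Write an expression matrix as TSV
#'
#' @param x An `expression_matrix`.
#' @param path File path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression
#' @param unit Unit tag to attach on read (`"TPM"` or `"RPKM"`).
#' @export
read_expression <- function(path, unit) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  expression_matrix(mat, unit)
}

#' Write a network edge table as 3-column TSV
#'
#' @param net A [confidence_network()].
#' @param path File path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "confidence_network"))
  write_tsv(net$edges, path)
}

#' Write / read a plain gene list (one id per line)
#'
#' @param genes Character vector.
#' @param path File path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
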