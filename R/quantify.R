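#' Construct a gene-level count matrix with effective lengths
#'
#' The raw substrate of the pipeline: a genes-by-samples matrix of
#' non-negative integer transcript counts together with one effective length
#' (bp) per gene.  Effective length here is the annotated transcript length as
#' supplied; no fragment-length correction is applied.
#'
#' @param counts Numeric matrix of non-negative counts with gene ids as row
#'   names and sample ids as column names.
#' @param lengths Numeric vector of strictly positive transcript lengths in
#'   bp, either named by gene id or in row order of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix) and `lengths` (named numeric, bp).
#' @examples
#' cm <- count_matrix(matrix(c(10, 20, 30), 3, 1,
#'                           dimnames = list(c("g1", "g2", "g3"), "s1")),
#'                    lengths = c(g1 = 1000, g2 = 2000, g3 = 500))
#' compute_tpm(cm)
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("`counts` must have gene ids as row names", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids in `counts`", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in `counts`", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts)) {
      stop("`lengths` must match the number of genes", call. = FALSE)
    }
    names(lengths) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(lengths))) {
    stop("every gene in `counts` needs a length", call. = FALSE)
  }
  lengths <- lengths[rownames(counts)]
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be strictly positive", call. = FALSE)
  }
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Tag a numeric matrix as an expression matrix
#'
#' @param values Numeric genes-by-samples matrix with dimnames.
#' @param unit Unit tag, `"TPM"` or `"RPKM"`.
#' @return The matrix with class `expression_matrix` and a `unit` attribute.
#' @export
expression_matrix <- function(values, unit) {
  unit <- match.arg(unit, c("TPM", "RPKM"))
  values <- as.matrix(values)
  structure(values, unit = unit, class = c("expression_matrix", "matrix"))
}

#' Unit tag of an expression matrix
#'
#' @param x An `expression_matrix`.
#' @return `"TPM"` or `"RPKM"`.
#' @export
expression_unit <- function(x) attr(x, "unit")

#' Transcripts per kilobase million (TPM)
#'
#' Per sample, each count is converted to a length-normalised rate
#' `count / (length in kb)` and rates are rescaled so the sample sums to one
#' million.  TPM is the unit on which group differences are tested downstream.
#'
#' @param counts A [count_matrix()].
#' @return An `expression_matrix` (unit `"TPM"`).  Every column with at least
#'   one nonzero count sums to 1e6; an all-zero sample stays all-zero.
#' @export
compute_tpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  rate <- counts$counts / (counts$lengths / 1000)
  total <- colSums(rate)
  scale <- ifelse(total > 0, total, 1)
  tpm <- sweep(rate, 2, scale, "/") * 1e6
  expression_matrix(tpm, "TPM")
}

#' Reads per kilobase of transcript per million mapped reads (RPKM)
#'
#' `RPKM = 1e9 * count / (length_bp * library_size)` with library size the
#' sample's total count.  RPKM is the unit of the expression floor.
#'
#' @param counts A [count_matrix()].
#' @return An `expression_matrix` (unit `"RPKM"`).  A sample with zero total
#'   counts yields an all-zero column (with a warning).
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(counts$counts)
  if (any(lib == 0)) {
    warning("sample(s) with zero total counts produce all-zero RPKM columns: ",
            paste(colnames(counts$counts)[lib == 0], collapse = ", "),
            call. = FALSE)
  }
  scale <- ifelse(lib > 0, lib, 1)
  rpkm <- 1e9 * sweep(counts$counts / counts$lengths, 2, scale, "/")
  expression_matrix(rpkm, "RPKM")
}

#' Expression floor: which genes count as expressed
#'
#' A gene is considered expressed when its RPKM strictly exceeds `floor`
#' (default 0.4).  The scope controls how the rule is applied across the
#' samples of the contrast at hand:
#' \describe{
#'   \item{`"any"`}{(default) expressed in at least one sample -- retains any
#'     gene detectably expressed somewhere in the contrast, maximising power
#'     while dropping globally silent genes;}
#'   \item{`"all"`}{expressed in every sample;}
#'   \item{`"condition_mean"`}{the per-condition mean RPKM exceeds the floor
#'     in at least one condition (requires `sample_sheet`).}
#' }
#'
#' @param rpkm An `expression_matrix` with unit `"RPKM"`.
#' @param floor Strict lower bound on RPKM (default 0.4).
#' @param scope One of `"any"`, `"all"`, `"condition_mean"`.
#' @param samples Optional character vector of sample ids restricting the
#'   columns considered (e.g. the four samples of one embryo day).
#' @param sample_sheet Data frame with columns `sample` and `condition`;
#'   required for `scope = "condition_mean"`.
#' @return Character vector of retained gene ids (in matrix row order).
#' @export
filter_expressed <- function(rpkm, floor = 0.4,
                             scope = c("any", "all", "condition_mean"),
                             samples = NULL, sample_sheet = NULL) {
  scope <- match.arg(scope)
  if (!identical(expression_unit(rpkm), "RPKM")) {
    stop("the expression floor is defined on RPKM values; got unit ",
         expression_unit(rpkm) %||% "<none>", call. = FALSE)
  }
  m <- unclass(rpkm)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- m[, samples, drop = FALSE]
  }
  keep <- switch(scope,
    any = rowSums(m > floor) > 0,
    all = rowSums(m > floor) == ncol(m),
    condition_mean = {
      if (is.null(sample_sheet)) {
        stop('scope "condition_mean" requires `sample_sheet`', call. = FALSE)
      }
      cond <- sample_sheet$condition[match(colnames(m), sample_sheet$sample)]
      if (anyNA(cond)) {
        stop("sample sheet does not cover all samples", call. = FALSE)
      }
      means <- vapply(split(seq_len(ncol(m)), cond), function(j) {
        rowMeans(m[, j, drop = FALSE])
      }, numeric(nrow(m)))
      rowSums(as.matrix(means) > floor) > 0
    }
  )
  rownames(m)[keep]
}
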