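# Ortholog-phenotype intersection.
#
# Emulates querying a mouse-knockout phenotype database for the orthologs
# of candidate genes: given a packaged gene -> (ortholog, phenotype terms)
# table, report which candidates carry developmental annotations such as
# "embryonic lethality before implantation-complete penetrance".  A real
# MGI/HomoloGene export with the same schema can be dropped in.

#' Read an ortholog-phenotype mapping table
#'
#' Expects a TSV with columns `gene`, `ortholog`, `terms` (pipe-separated
#' phenotype term strings).  One-to-many orthology is expressed as one row
#' per ortholog.
#'
#' @param path File path.
#' @return A `phenotype_map` data frame.
#' @export
read_phenotype_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene", "ortholog", "terms") %in% names(df))) {
    stop("phenotype map needs columns gene, ortholog, terms", call. = FALSE)
  }
  for (col in c("gene", "ortholog", "terms")) df[[col]] <- as.character(df[[col]])
  if (any(!nzchar(df$terms))) {
    stop("phenotype terms must be non-empty", call. = FALSE)
  }
  structure(df[, c("gene", "ortholog", "terms")],
            class = c("phenotype_map", "data.frame"))
}

#' Intersect a gene list with ortholog-phenotype annotations
#'
#' Returns one row per (gene, ortholog) pair in which the ortholog carries
#' at least one phenotype term (restricted to `term_filter` when given),
#' plus a frequency table of the matched terms.
#'
#' @param genes Character vector of query gene ids.
#' @param map A `phenotype_map` from [read_phenotype_map()] or
#'   [simulate_phenotype_map()].
#' @param term_filter Optional character vector of phenotype terms to
#'   restrict to (e.g. lethality terms); `NULL` or empty means no filter.
#' @return A list of class `phenotype_hits`: `hits` (data frame `gene`,
#'   `ortholog`, `terms` pipe-separated) and `term_frequency` (data frame
#'   `term`, `count`, decreasing).
#' @export
phenotype_hits <- function(genes, map, term_filter = NULL) {
  stopifnot(inherits(map, "phenotype_map") ||
              all(c("gene", "ortholog", "terms") %in% names(map)))
  genes <- unique(as.character(genes))
  sub <- map[map$gene %in% genes, , drop = FALSE]
  term_list <- strsplit(as.character(sub$terms), "|", fixed = TRUE)
  if (!is.null(term_filter) && length(term_filter) > 0) {
    term_list <- lapply(term_list, intersect, y = term_filter)
  }
  keep <- lengths(term_list) > 0
  hits <- data.frame(gene = sub$gene[keep], ortholog = sub$ortholog[keep],
                     terms = vapply(term_list[keep], paste, "",
                                    collapse = "|"),
                     stringsAsFactors = FALSE, row.names = NULL)
  hits <- hits[order(hits$gene, hits$ortholog), , drop = FALSE]
  rownames(hits) <- NULL
  freq <- sort(table(unlist(term_list[keep])), decreasing = TRUE)
  term_frequency <- data.frame(term = names(freq),
                               count = as.integer(freq),
                               stringsAsFactors = FALSE, row.names = NULL)
  structure(list(hits = hits, term_frequency = term_frequency),
            class = "phenotype_hits")
}

#' @export
print.phenotype_hits <- function(x, ...) {
  cat(sprintf("phenotype_hits: %d annotated gene-ortholog pair(s), %d term(s)\n",
              nrow(x$hits), nrow(x$term_frequency)))
  invisible(x)
}
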