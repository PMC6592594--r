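# Gene-set over-representation with the EASE score.
#
# The EASE score is the conservative variant of Fisher's exact test used by
# DAVID-style annotation charts: the one-sided hypergeometric upper-tail
# probability of the 2x2 overlap table computed after removing one gene from
# the overlap.  Single-gene overlaps therefore can never be significant.

#' Gene-set collection over an explicit universe
#'
#' @param sets Named list of character vectors (member gene ids).
#' @param universe Character vector of all gene ids under consideration;
#'   members outside the universe are dropped, empty sets pruned.
#' @param category Optional named character vector assigning each set a
#'   category (e.g. GO BP / KEGG-like / phenotype); multiple-testing
#'   correction is applied within categories.
#' @return A list of class `gene_sets` with elements `sets`, `universe`,
#'   `category`.
#' @export
gene_sets <- function(sets, universe, category = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("`sets` must be uniquely named", call. = FALSE)
  }
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (is.null(category)) {
    category <- stats::setNames(rep("sets", length(sets)), names(sets))
  } else {
    category <- category[names(sets)]
    category[is.na(category)] <- "sets"
    names(category) <- names(sets)
  }
  structure(list(sets = sets, universe = universe, category = category),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets over %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT lines are `set name <tab> description <tab> member...`.  On read, the
#' universe defaults to the union of all members unless supplied.
#'
#' @param path File path.
#' @param universe Optional explicit universe for [read_gmt()].
#' @return [read_gmt()] returns a [gene_sets()] collection.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  category <- stats::setNames(vapply(parts, `[[`, "", 2), names(sets))
  category[!nzchar(category)] <- "sets"
  gene_sets(sets, universe = universe %||% unique(unlist(sets)),
            category = category)
}

#' @rdname read_gmt
#' @param collection A [gene_sets()] collection to write.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_sets"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$category[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

check_margins <- function(k, n, K, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & N >= 0 & k <= n & k <= K & n <= N & K <= N
  if (any(!ok)) {
    stop("inconsistent 2x2 margins: need 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
}

#' EASE score (modified Fisher's exact test)
#'
#' One-sided hypergeometric upper tail of the overlap table with the overlap
#' decremented by one (floored at zero): `P(X >= k - 1)` for X hypergeometric
#' with `n` draws, `K` successes in a universe of `N`.  Overlaps of 0 or 1
#' give P = 1 exactly.
#'
#' @param k Overlap between the query list and the set.
#' @param n Query list size.
#' @param K Set size.
#' @param N Universe size.
#' @return P values (vectorised over the arguments).
#' @examples
#' ease_score(4, 10, 10, 100)   # = P(X >= 3), the decremented tail
#' ease_score(1, 10, 10, 100)   # = 1: one-gene overlaps never score
#' @export
ease_score <- function(k, n, K, N) {
  check_margins(k, n, K, N)
  # P(X >= k-1) = 1 - P(X <= k-2) = phyper(k-2, ...) upper tail
  ifelse(k <= 1, 1,
         stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE))
}

#' Fold enrichment of an overlap
#'
#' `(k / n) / (K / N)`: observed overlap rate relative to the rate expected
#' if the query list were drawn uniformly from the universe.
#'
#' @inheritParams ease_score
#' @return Fold enrichment; `NA` when a margin is zero.
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_margins(k, n, K, N)
  ifelse(n == 0 | K == 0 | N == 0, NA_real_, (k / n) / (K / N))
}

#' Gene-set over-representation chart
#'
#' Scores every set of the collection against a query gene list with the
#' EASE score, computes fold enrichment, and controls the FDR by
#' Benjamini-Hochberg within each category.  Genes outside the universe are
#' dropped (with a message).  Sets with fewer than `min_set_size` members
#' are pruned (an EASE test on a one-gene set can never be significant).
#'
#' @param genes Character vector: the query list (e.g. down-regulated
#'   candidates).
#' @param collection A [gene_sets()] collection.
#' @param fdr_threshold Significance cutoff on BH FDR (default 0.05).
#' @param min_set_size Minimum set size tested (default 2).
#' @return A data frame of class `enrichment_result`, sorted by P, with
#'   columns `term`, `category`, `overlap` (k), `list_size` (n), `set_size`
#'   (K), `universe_size` (N), `fold_enrichment`, `p_value`, `fdr`,
#'   `significant`.
#' @export
enrich <- function(genes, collection, fdr_threshold = 0.05,
                   min_set_size = 2) {
  stopifnot(inherits(collection, "gene_sets"))
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, collection$universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
  }
  genes <- intersect(genes, collection$universe)
  sets <- collection$sets[lengths(collection$sets) >= min_set_size]
  n <- length(genes)
  big_n <- length(collection$universe)
  if (n == 0 || length(sets) == 0) {
    res <- data.frame(term = character(0), category = character(0),
                      overlap = integer(0), list_size = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0))
    return(structure(res, class = c("enrichment_result", "data.frame")))
  }
  k <- vapply(sets, function(s) length(intersect(s, genes)), integer(1))
  big_k <- lengths(sets)
  p <- ease_score(k, n, big_k, big_n)
  fe <- fold_enrichment(k, n, big_k, big_n)
  category <- unname(collection$category[names(sets)])
  fdr <- stats::ave(p, category,
                    FUN = function(x) stats::p.adjust(x, method = "BH"))
  res <- data.frame(term = names(sets), category = category, overlap = k,
                    list_size = n, set_size = big_k, universe_size = big_n,
                    fold_enrichment = fe, p_value = p, fdr = fdr,
                    significant = fdr < fdr_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_value, -res$overlap), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}
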