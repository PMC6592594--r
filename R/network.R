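# Confidence-thresholded interaction-network analysis.
#
# Mirrors the STRING-style workflow locally: keep edges at or above a
# combined-confidence cutoff (0.700 = the conventional "high confidence"
# level), count interactions among a query gene list, and score that count
# against a permutation null of equally sized random node sets.  The
# analytic enrichment model of the STRING service is proprietary in detail,
# so the P value here is an explicitly seeded permutation P, and is
# labelled as such in reports.

#' Construct a confidence-scored undirected network
#'
#' Canonicalises an edge table: endpoints ordered within each pair,
#' self-loops dropped, duplicate pairs collapsed to their maximum score.
#'
#' @param edges Data frame with columns `a`, `b`, `score` (combined
#'   confidence in [0, 1]).
#' @param nodes Optional character vector of node ids (a superset of the
#'   edge endpoints; allows isolated nodes).
#' @return A list of class `confidence_network` with elements `edges`
#'   (canonical data frame) and `nodes`.
#' @export
confidence_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "score") %in% names(edges)))
  edges$a <- as.character(edges$a); edges$b <- as.character(edges$b)
  if (any(!is.finite(edges$score)) || any(edges$score < 0) ||
      any(edges$score > 1)) {
    stop("edge scores must lie in [0, 1]", call. = FALSE)
  }
  loops <- edges$a == edges$b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  edges$a <- lo; edges$b <- hi
  key <- paste(edges$a, edges$b, sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate pair(s) collapsed (max score)")
    ord <- order(key, -edges$score)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  all_nodes <- unique(c(edges$a, edges$b))
  if (!is.null(nodes)) {
    nodes <- unique(as.character(nodes))
    if (!all(all_nodes %in% nodes)) {
      stop("`nodes` must contain every edge endpoint", call. = FALSE)
    }
  } else {
    nodes <- sort(all_nodes)
  }
  rownames(edges) <- NULL
  structure(list(edges = edges[, c("a", "b", "score")], nodes = nodes),
            class = "confidence_network")
}

#' @export
print.confidence_network <- function(x, ...) {
  cat(sprintf("confidence_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a STRING-like edge list
#'
#' Expects a 3-column TSV (node a, node b, combined score).  Scores on the
#' STRING 0--1000 integer scale are detected (any score above 1) and
#' rescaled to [0, 1] with a message.
#'
#' @param path File path.
#' @param nodes Optional node superset, as in [confidence_network()].
#' @return A [confidence_network()].
#' @export
read_network <- function(path, nodes = NULL) {
  df <- read_tsv(path)
  if (ncol(df) < 3) stop("edge table needs 3 columns", call. = FALSE)
  names(df)[1:3] <- c("a", "b", "score")
  df$score <- as.numeric(df$score)
  if (any(df$score > 1, na.rm = TRUE)) {
    message("scores look like the 0-1000 scale; rescaling by 1/1000")
    df$score <- df$score / 1000
  }
  confidence_network(df[, 1:3], nodes = nodes)
}

#' Keep edges at or above a confidence cutoff
#'
#' The cutoff is inclusive (an edge scored exactly 0.700 is a positive
#' interaction at the 0.700 threshold, matching the high-confidence
#' convention).  Nodes are preserved, so thresholding can only isolate
#' nodes, never remove them.
#'
#' @param net A [confidence_network()].
#' @param cutoff Combined-score threshold in [0, 1] (default 0.700).
#' @return A thresholded `confidence_network`.
#' @export
threshold_edges <- function(net, cutoff = 0.700) {
  stopifnot(inherits(net, "confidence_network"))
  stopifnot_scalar_prob(cutoff, "cutoff")
  out <- net
  out$edges <- net$edges[net$edges$score >= cutoff, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Permutation PPI-enrichment test
#'
#' Counts edges of the (already thresholded) network whose endpoints both
#' lie in the query list, then draws `n_draws` node sets of the same size
#' uniformly from the network's nodes and counts their internal edges.
#' `P = (1 + #\{null >= observed\}) / (n_draws + 1)`.
#'
#' @param net A [confidence_network()] (threshold first with
#'   [threshold_edges()]).
#' @param query Character vector of query gene ids; ids absent from the
#'   network are dropped with a message.
#' @param n_draws Number of null draws (default 10000).
#' @param seed Integer RNG seed.
#' @return A list of class `ppi_report`: `n_nodes`, `n_edges`,
#'   `query_size`, `observed`, `expected` (mean null count), `p_value`,
#'   `null` (the vector of null counts), `n_draws`, `seed`, `method`.
#' @export
ppi_enrichment <- function(net, query, n_draws = 10000, seed = 1) {
  stopifnot(inherits(net, "confidence_network"))
  if (!is_count(n_draws)) stop("`n_draws` must be a positive integer",
                               call. = FALSE)
  query <- unique(as.character(query))
  outside <- setdiff(query, net$nodes)
  if (length(outside)) {
    message(length(outside), " query gene(s) not in the network dropped")
    query <- setdiff(query, outside)
  }
  n <- length(net$nodes)
  q <- length(query)
  base <- list(n_nodes = n, n_edges = nrow(net$edges), query_size = q,
               n_draws = n_draws, seed = seed,
               method = "seeded permutation of uniformly drawn node sets")
  if (q < 2) {
    return(structure(c(base, list(observed = 0L, expected = 0,
                                  p_value = 1, null = integer(0))),
                     class = "ppi_report"))
  }
  idx <- stats::setNames(seq_len(n), net$nodes)
  ea <- idx[net$edges$a]; eb <- idx[net$edges$b]
  in_query <- logical(n); in_query[idx[query]] <- TRUE
  observed <- sum(in_query[ea] & in_query[eb])

  null <- with_seed(seed, {
    if (nrow(net$edges) == 0) {
      integer(n_draws)
    } else {
      draws <- replicate(n_draws, sample.int(n, q))
      x <- Matrix::sparseMatrix(i = as.vector(draws),
                                j = rep(seq_len(n_draws), each = q),
                                x = 1, dims = c(n, n_draws))
      adj <- Matrix::sparseMatrix(i = c(ea, eb), j = c(eb, ea), x = 1,
                                  dims = c(n, n))
      as.integer(round(Matrix::colSums(x * (adj %*% x)) / 2))
    }
  })
  p <- (1 + sum(null >= observed)) / (n_draws + 1)
  structure(c(base, list(observed = as.integer(observed),
                         expected = mean(null), p_value = p, null = null)),
            class = "ppi_report")
}

#' @export
print.ppi_report <- function(x, ...) {
  cat(sprintf(
    "ppi_report: %d/%d query genes, %d observed internal edges (expected %.2f)\nPPI enrichment P = %.3g (%s, %d draws)\n",
    x$query_size, x$n_nodes, x$observed, x$expected, x$p_value, x$method,
    x$n_draws))
  invisible(x)
}

#' Cluster the query-induced subgraph
#'
#' Induces the subgraph of the (thresholded) network on the query genes and
#' partitions its non-isolated nodes: by connected components (default) or
#' greedy modularity communities.  Clusters are ordered by decreasing size;
#' isolated query nodes are reported separately as singletons.
#'
#' @param net A [confidence_network()] (threshold first).
#' @param query Optional character vector of query gene ids (default: all
#'   network nodes).
#' @param method `"components"` (default) or `"greedy_modularity"`.
#' @return List with `clusters` (named list of gene-id vectors, size >= 2)
#'   and `singletons` (character vector).
#' @export
cluster_network <- function(net, query = NULL,
                            method = c("components", "greedy_modularity")) {
  stopifnot(inherits(net, "confidence_network"))
  method <- match.arg(method)
  query <- if (is.null(query)) net$nodes else
    intersect(unique(as.character(query)), net$nodes)
  edges <- net$edges[net$edges$a %in% query & net$edges$b %in% query, ,
                     drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = query))
  membership <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    igraph::membership(igraph::cluster_fast_greedy(g))
  }
  groups <- split(names(membership), membership)
  singles <- unlist(groups[lengths(groups) == 1], use.names = FALSE)
  multi <- groups[lengths(groups) >= 2]
  multi <- multi[order(-lengths(multi))]
  names(multi) <- if (length(multi)) {
    sprintf("cluster_%02d", seq_along(multi))
  } else {
    character(0)
  }
  list(clusters = multi, singletons = sort(singles %||% character(0)))
}
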