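# Permutation-null differential expression.
#
# The study design has only two embryos per condition per day, so no
# parametric per-gene test has usable power.  Instead, per-gene TPM
# differences between conditions are referred to an empirical null built by
# permutation, crossed with a fold-change filter.  The default null
# reassigns each gene's observed TPM values to pseudo-groups at random and
# pools the resulting pseudo-differences genome-wide: with 2-vs-2 samples a
# single gene admits only choose(4,2) = 6 label splits, so pooling across
# genes is the only way to obtain a fine-grained null.  The aggregate
# fraction of null genes declared significant at level alpha is then alpha
# by construction (each observed difference is itself a draw from the
# pooled mixture), even though individual genes with unusually large or
# small expression are not separately calibrated.

#' Specify a two-group contrast
#'
#' @param day Day selector (matched against the sample sheet `day` column).
#' @param group_a,group_b Condition labels; differences and fold changes are
#'   B relative to A (default CRYO relative to FRSH).
#' @param mode Permutation scheme: `"label_within_gene"` (default) reassigns
#'   each gene's values to pseudo-groups and pools pseudo-differences
#'   genome-wide; `"global_score_shuffle"` shuffles values across genes
#'   within each sample before differencing.
#' @param n_permutations Number of sampled permutations (default 10000).
#' @param p_threshold Candidate P cutoff (default 0.01; 0.05 and a stricter
#'   0.001 are the conventional alternatives).
#' @param fold_threshold Minimum fold change for candidates (default 2).
#' @param pseudocount TPM pseudocount added to both group means before the
#'   log2 ratio (default 0.5), so condition-absent genes have finite fold
#'   changes.
#' @param seed Integer RNG seed for the permutation stream.
#' @return A validated list of class `contrast_spec`.
#' @export
contrast_spec <- function(day, group_a = "FRSH", group_b = "CRYO",
                          mode = c("label_within_gene",
                                   "global_score_shuffle"),
                          n_permutations = 10000, p_threshold = 0.01,
                          fold_threshold = 2, pseudocount = 0.5, seed = 1) {
  mode <- match.arg(mode)
  if (identical(group_a, group_b)) {
    stop("`group_a` and `group_b` must differ", call. = FALSE)
  }
  if (!is_count(n_permutations)) {
    stop("`n_permutations` must be a positive integer", call. = FALSE)
  }
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("`p_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (fold_threshold < 1) stop("`fold_threshold` must be >= 1", call. = FALSE)
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  structure(list(day = day, group_a = group_a, group_b = group_b,
                 mode = mode, n_permutations = as.integer(n_permutations),
                 p_threshold = p_threshold, fold_threshold = fold_threshold,
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "contrast_spec")
}

# Resolve the sample columns of each group for a contrast.
contrast_columns <- function(tpm, samples, contrast) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "day", "condition") %in% names(samples)))
  sel <- samples[samples$day == contrast$day, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop(sprintf("no samples for day '%s' in the sample sheet", contrast$day),
         call. = FALSE)
  }
  a <- sel$sample[sel$condition == contrast$group_a]
  b <- sel$sample[sel$condition == contrast$group_b]
  if (length(a) == 0 || length(b) == 0) {
    stop(sprintf("contrast needs samples in both groups ('%s': %d, '%s': %d)",
                 contrast$group_a, length(a), contrast$group_b, length(b)),
         call. = FALSE)
  }
  missing <- setdiff(c(a, b), colnames(tpm))
  if (length(missing)) {
    stop("sample(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  list(a = a, b = b)
}

#' Observed per-gene group difference
#'
#' Mean TPM in group B minus mean TPM in group A, per gene.
#'
#' @param tpm An `expression_matrix` (TPM).
#' @param samples Sample sheet data frame (`sample`, `day`, `condition`).
#' @param contrast A [contrast_spec()].
#' @return Named numeric vector of differences (B - A).
#' @export
observed_difference <- function(tpm, samples, contrast) {
  cols <- contrast_columns(tpm, samples, contrast)
  m <- unclass(tpm)
  rowMeans(m[, cols$b, drop = FALSE]) - rowMeans(m[, cols$a, drop = FALSE])
}

# All distinct pseudo-group assignments for nA + nB values: a weight matrix
# W (n_tot x K) such that V %*% W gives every possible pseudo-difference
# (mean of pseudo-B minus mean of pseudo-A) for each row of V.
assignment_weights <- function(n_a, n_b) {
  n_tot <- n_a + n_b
  picks <- utils::combn(n_tot, n_b)
  w <- matrix(-1 / n_a, n_tot, ncol(picks))
  for (k in seq_len(ncol(picks))) w[picks[, k], k] <- 1 / n_b
  w
}

#' Permutation null distribution of group differences
#'
#' Builds the empirical null against which observed differences are scored.
#' In `label_within_gene` mode, each permutation reassigns every gene's
#' nA + nB TPM values to pseudo-groups uniformly at random and records each
#' gene's pseudo-difference; the null is the pooled genome-wide collection
#' (`n_genes * n_permutations` values).  With `exhaustive = TRUE` all
#' distinct assignments are enumerated once per gene instead, giving the
#' exact pooled null.  In `global_score_shuffle` mode, TPM values are
#' shuffled across genes within each sample before differencing.
#'
#' @inheritParams observed_difference
#' @param exhaustive Enumerate all assignments instead of sampling
#'   (`label_within_gene` mode only).
#' @return Numeric vector of null differences with attributes `mode`,
#'   `n_permutations`, and `seed`.
#' @export
permutation_null <- function(tpm, samples, contrast, exhaustive = FALSE) {
  cols <- contrast_columns(tpm, samples, contrast)
  m <- unclass(tpm)
  v <- m[, c(cols$a, cols$b), drop = FALSE]
  n_a <- length(cols$a); n_b <- length(cols$b)
  g <- nrow(v)
  b_perm <- contrast$n_permutations

  null <- with_seed(contrast$seed, {
    if (contrast$mode == "label_within_gene") {
      w <- assignment_weights(n_a, n_b)
      d <- v %*% w                       # g x K matrix of pseudo-differences
      k <- ncol(w)
      if (exhaustive) {
        as.numeric(d)
      } else {
        # canonicalise assignment order per gene by |difference| so the
        # sampled null is invariant under swapping the group labels
        # (assignments come in +/- complementary pairs, so only signs can
        # depend on the labeling, and P values use absolute values only)
        o <- apply(abs(d), 1, order)
        d <- matrix(d[cbind(rep(seq_len(g), each = k), as.vector(o))],
                    g, k, byrow = TRUE)
        idx <- sample.int(k, g * b_perm, replace = TRUE)
        d[(idx - 1) * g + rep(seq_len(g), times = b_perm)]
      }
    } else {
      if (exhaustive) {
        stop("exhaustive enumeration applies to label_within_gene mode only",
             call. = FALSE)
      }
      wa <- seq_len(n_a); wb <- n_a + seq_len(n_b)
      out <- vector("list", b_perm)
      for (p in seq_len(b_perm)) {
        shuf <- apply(v, 2, function(col) col[sample.int(g)])
        out[[p]] <- rowMeans(shuf[, wb, drop = FALSE]) -
          rowMeans(shuf[, wa, drop = FALSE])
      }
      unlist(out, use.names = FALSE)
    }
  })
  attributes(null) <- list(mode = contrast$mode,
                           n_permutations = b_perm,
                           exhaustive = exhaustive,
                           seed = contrast$seed)
  null
}

#' Permutation P values by two-sided exceedance
#'
#' `P = (1 + #\{|null| >= |observed|\}) / (N_null + 1)`: the add-one
#' correction keeps P away from zero and ties in the null count as
#' exceedances (conservative).  A gene "more extreme than 99 percent of the
#' random cases" is exactly a gene with P < 0.01.
#'
#' @param observed Named numeric vector of observed differences.
#' @param null Numeric vector from [permutation_null()] (any empirical null).
#' @return Named numeric vector of P values in `[1/(N+1), 1]`.
#' @export
permutation_pvalue <- function(observed, null) {
  if (length(null) == 0) stop("empty null distribution", call. = FALSE)
  sorted <- sort(abs(null))
  n <- length(sorted)
  # a gene's own label assignments put +/- its observed difference into the
  # null; a hair of floating-point jitter between the two computation paths
  # must not stop those algebraic ties from counting as exceedances, so the
  # comparison carries a small relative tolerance
  thr <- abs(observed) * (1 - 1e-9)
  n_ge <- n - findInterval(thr, sorted, left.open = TRUE)
  stats::setNames((1 + n_ge) / (n + 1), names(observed))
}

#' Run the permutation differential-expression test for one contrast
#'
#' Combines observed differences, the permutation null, P values, log2 fold
#' changes (with pseudocount) and candidate flags into one per-gene table.
#'
#' @inheritParams observed_difference
#' @param genes Optional character vector restricting the test to these
#'   genes (e.g. the output of [filter_expressed()]).
#' @return A data frame of class `de_result` with columns `gene`, `mean_a`,
#'   `mean_b`, `diff`, `log2fc`, `p_value`, `passed_p`, `passed_fc`,
#'   `candidate`, `direction` (up/down/none for candidates/others), carrying
#'   the contrast and null size as attributes.
#' @export
run_diffexp <- function(tpm, samples, contrast, genes = NULL) {
  m <- unclass(tpm)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      stop(length(missing), " gene(s) not in the expression matrix",
           call. = FALSE)
    }
    m <- m[genes, , drop = FALSE]
    tpm <- expression_matrix(m, expression_unit(tpm))
  }
  cols <- contrast_columns(tpm, samples, contrast)
  mean_a <- rowMeans(m[, cols$a, drop = FALSE])
  mean_b <- rowMeans(m[, cols$b, drop = FALSE])
  diff <- mean_b - mean_a
  null <- permutation_null(tpm, samples, contrast)
  p <- permutation_pvalue(diff, null)
  pc <- contrast$pseudocount
  log2fc <- log2((mean_b + pc) / (mean_a + pc))
  passed_p <- p < contrast$p_threshold
  passed_fc <- abs(log2fc) >= log2(contrast$fold_threshold)
  candidate <- passed_p & passed_fc
  direction <- ifelse(!candidate, "none",
                      ifelse(log2fc > 0, "up", "down"))
  res <- data.frame(gene = rownames(m), mean_a = mean_a, mean_b = mean_b,
                    diff = diff, log2fc = log2fc, p_value = p,
                    passed_p = passed_p, passed_fc = passed_fc,
                    candidate = candidate, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("de_result", "data.frame"),
            contrast = contrast, n_null = length(null))
}

#' Partition candidates into up- and down-regulated lists
#'
#' A gene is a candidate when `P < p_threshold` and
#' `|log2 FC| >= log2(fold_threshold)`.  Thresholds default to those stored
#' in the result's contrast but can be overridden (e.g. re-thresholding a
#' large day's list at P < 0.001), which only re-flags rows -- the test is
#' not rerun.
#'
#' @param results A `de_result` from [run_diffexp()].
#' @param p_threshold,fold_threshold Optional overrides.
#' @return List with elements `up` and `down`, each a data frame sorted by
#'   P then decreasing |log2 FC|.
#' @export
select_candidates <- function(results, p_threshold = NULL,
                              fold_threshold = NULL) {
  contrast <- attr(results, "contrast")
  p_thr <- p_threshold %||% contrast$p_threshold
  f_thr <- fold_threshold %||% contrast$fold_threshold
  if (f_thr < 1) stop("`fold_threshold` must be >= 1", call. = FALSE)
  cand <- results$p_value < p_thr & abs(results$log2fc) >= log2(f_thr)
  sel <- results[cand, , drop = FALSE]
  sel <- sel[order(sel$p_value, -abs(sel$log2fc)), , drop = FALSE]
  list(up = sel[sel$log2fc > 0, , drop = FALSE],
       down = sel[sel$log2fc < 0, , drop = FALSE])
}

#' Volcano table and figure
#'
#' Plot-ready coordinates following the usual conventions: x is the log2
#' ratio of mean expression in group B (CRYO) over group A (FRSH), y is
#' -log10 P capped at the attainable maximum `-log10(1/(N_null + 1))`.
#' Guide lines sit at x = -1 and +1 (twofold change) and y = 1.30
#' (P = 0.05); candidate genes are flagged for red rendering.
#'
#' @param results A `de_result` from [run_diffexp()].
#' @return Data frame (`gene`, `log2fc`, `neg_log10_p`, `candidate`,
#'   `direction`) with attribute `guides = list(x = c(-1, 1), y = 1.30)`.
#' @export
volcano_table <- function(results) {
  n_null <- attr(results, "n_null") %||% Inf
  cap <- -log10(1 / (n_null + 1))
  tab <- data.frame(gene = results$gene, log2fc = results$log2fc,
                    neg_log10_p = pmin(-log10(results$p_value), cap),
                    candidate = results$candidate,
                    direction = results$direction,
                    stringsAsFactors = FALSE)
  attr(tab, "guides") <- list(x = c(-1, 1), y = -log10(0.05))
  tab
}

#' @rdname volcano_table
#' @param title Plot title.
#' @return `volcano_plot()` returns a ggplot object.
#' @export
volcano_plot <- function(results, title = NULL) {
  tab <- volcano_table(results)
  guides <- attr(tab, "guides")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2fc,
                                    y = .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$candidate),
                        size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::geom_vline(xintercept = guides$x, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = guides$y, linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change (CRYO / FRSH)",
                  y = "-log10 P", title = title) +
    ggplot2::theme_bw()
}
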