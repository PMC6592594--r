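# Independent oracles and small fixture builders used across the suite.

# Hypergeometric upper tail P(X >= k) computed by direct summation of
# choose() products -- independent of stats::phyper.
hyper_tail_oracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  i <- seq(k, min(n, K))
  if (length(i) == 0) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# All pseudo-differences (mean pseudo-B minus mean pseudo-A) obtainable by
# reassigning one gene's nA + nB values, computed by direct enumeration of
# index subsets and plain means.
enum_pseudo_diffs <- function(v, n_a, n_b) {
  n <- n_a + n_b
  picks <- utils::combn(n, n_b)
  apply(picks, 2, function(bset) {
    mean(v[bset]) - mean(v[setdiff(seq_len(n), bset)])
  })
}

# Benjamini-Hochberg step-up computed from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Minimal TPM/RPKM matrix builder.
toy_expr <- function(values, unit = "TPM", genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  expression_matrix(m, unit)
}

# Sample sheet for a single day, two conditions, `reps` each.
toy_sheet <- function(day = 8, reps = 2) {
  data.frame(
    sample = c(sprintf("D%d_FRSH_%d", day, seq_len(reps)),
               sprintf("D%d_CRYO_%d", day, seq_len(reps))),
    day = day,
    condition = rep(c("FRSH", "CRYO"), each = reps),
    pair = rep(sprintf("D%d_pair%d", day, seq_len(reps)), 2),
    stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
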