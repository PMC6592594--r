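sheet22 <- toy_sheet(day = 8, reps = 2)

test_that("observed differences are plain group-mean differences", {
  tpm <- toy_expr(rbind(c(10, 10, 30, 50),
                        c(5, 5, 5, 5)),
                  samples = sheet22$sample)
  ct <- contrast_spec(day = 8, n_permutations = 10)
  d <- observed_difference(tpm, sheet22, ct)
  expect_equal(unname(d), c(30, 0))

  # swapping group labels negates every difference
  swapped <- contrast_spec(day = 8, group_a = "CRYO", group_b = "FRSH",
                           n_permutations = 10)
  expect_equal(observed_difference(tpm, sheet22, swapped), -d)
})

test_that("contrasts validate their groups", {
  tpm <- toy_expr(matrix(1, 2, 4), samples = sheet22$sample)
  expect_error(contrast_spec(day = 8, group_a = "X", group_b = "X"), "differ")
  ct9 <- contrast_spec(day = 9, n_permutations = 10)
  expect_error(observed_difference(tpm, sheet22, ct9), "no samples")
  odd <- sheet22; odd$condition <- "FRSH"
  ct <- contrast_spec(day = 8, n_permutations = 10)
  expect_error(observed_difference(tpm, odd, ct), "both groups")
  expect_error(contrast_spec(day = 8, n_permutations = 0), "positive integer")
})

test_that("the within-gene null has exactly choose(4,2) support points per gene", {
  set.seed(31)
  vals <- matrix(rlnorm(4 * 4, 4, 1), 4, 4)
  tpm <- toy_expr(vals, samples = sheet22$sample)
  ct <- contrast_spec(day = 8, n_permutations = 500, seed = 2)
  null_ex <- permutation_null(tpm, sheet22, ct, exhaustive = TRUE)
  expect_length(null_ex, 4 * choose(4, 2))

  # per gene, the exhaustive null equals direct enumeration of all splits
  for (g in 1:4) {
    oracle <- enum_pseudo_diffs(vals[g, ], 2, 2)
    mine <- null_ex[seq(g, length(null_ex), by = 4)]
    expect_equal(sort(mine), sort(oracle))
  }

  # sampled null values all lie on the exhaustive support
  null_s <- permutation_null(tpm, sheet22, ct)
  expect_length(null_s, 4 * 500)
  expect_true(all(round(null_s, 9) %in% round(null_ex, 9)))
})

test_that("a gene with four equal values contributes only zeros to the null", {
  tpm <- toy_expr(rbind(c(7, 7, 7, 7)), samples = sheet22$sample)
  ct <- contrast_spec(day = 8, n_permutations = 50, seed = 1)
  expect_true(all(permutation_null(tpm, sheet22, ct) == 0))
})

test_that("permutation P values follow the add-one two-sided exceedance rule", {
  null <- c(-3, -1, 0, 1, 3)
  expect_equal(unname(permutation_pvalue(2, null)), (1 + 2) / 6)
  expect_equal(unname(permutation_pvalue(0, null)), 1)
  expect_equal(unname(permutation_pvalue(10, null)), 1 / 6)
  # ties count as exceedances (conservative)
  expect_equal(unname(permutation_pvalue(3, null)), (1 + 2) / 6)
  expect_error(permutation_pvalue(1, numeric(0)), "empty")
})

test_that("the null and the full test are reproducible under a fixed seed", {
  set.seed(32)
  tpm <- toy_expr(matrix(rlnorm(40, 4, 1), 10, 4), samples = sheet22$sample)
  ct <- contrast_spec(day = 8, n_permutations = 200, seed = 7)
  expect_identical(permutation_null(tpm, sheet22, ct),
                   permutation_null(tpm, sheet22, ct))
  expect_identical(run_diffexp(tpm, sheet22, ct),
                   run_diffexp(tpm, sheet22, ct))
  ct2 <- contrast_spec(day = 8, n_permutations = 200, seed = 8)
  expect_false(identical(permutation_null(tpm, sheet22, ct),
                         permutation_null(tpm, sheet22, ct2)))
})

test_that("the global shuffle mode preserves sample values and is seeded", {
  set.seed(33)
  vals <- matrix(rlnorm(40, 4, 1), 10, 4)
  tpm <- toy_expr(vals, samples = sheet22$sample)
  ct <- contrast_spec(day = 8, mode = "global_score_shuffle",
                      n_permutations = 20, seed = 3)
  null <- permutation_null(tpm, sheet22, ct)
  expect_length(null, 10 * 20)
  expect_identical(null, permutation_null(tpm, sheet22, ct))
  expect_error(permutation_null(tpm, sheet22, ct, exhaustive = TRUE),
               "label_within_gene")
})

test_that("de_result flags respect both thresholds and direction semantics", {
  set.seed(34)
  tpm <- toy_expr(matrix(rlnorm(80, 4, 1), 20, 4), samples = sheet22$sample)
  ct <- contrast_spec(day = 8, n_permutations = 500, p_threshold = 0.05,
                      seed = 5)
  res <- run_diffexp(tpm, sheet22, ct)
  expect_true(all(res$p_value >= 1 / (attr(res, "n_null") + 1)))
  expect_true(all(res$p_value <= 1))
  expect_equal(res$candidate, res$passed_p & res$passed_fc)
  expect_true(all(res$direction[res$candidate & res$log2fc > 0] == "up"))
  expect_true(all(res$direction[res$candidate & res$log2fc < 0] == "down"))
  expect_true(all(res$direction[!res$candidate] == "none"))
})

test_that("candidate selection crosses the P and fold-change thresholds", {
  fake <- structure(
    data.frame(gene = c("a", "b", "c"),
               mean_a = c(10, 80, 10), mean_b = c(17, 10, 90),
               diff = c(7, -70, 80),
               log2fc = c(0.8, -3, 3.2),
               p_value = c(0.005, 0.02, 0.001),
               stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"),
    contrast = contrast_spec(day = 8, p_threshold = 0.01,
                             n_permutations = 1000),
    n_null = 1000)

  # P passes but fold 2^0.8 < 2: not a candidate
  strict <- select_candidates(fake)
  expect_false("a" %in% c(strict$up$gene, strict$down$gene))
  # P = 0.02 fails at 0.01 ...
  expect_false("b" %in% strict$down$gene)
  # ... but is a down candidate at the 0.05 threshold
  loose <- select_candidates(fake, p_threshold = 0.05)
  expect_true("b" %in% loose$down$gene)
  expect_true("c" %in% strict$up$gene)
})

test_that("tightening thresholds only ever shrinks candidate lists", {
  set.seed(36)
  tpm <- toy_expr(matrix(rlnorm(400, 4, 1.5), 100, 4),
                  samples = sheet22$sample)
  ct <- contrast_spec(day = 8, n_permutations = 1000, p_threshold = 0.05,
                      seed = 6)
  res <- run_diffexp(tpm, sheet22, ct)
  lists <- lapply(c(0.05, 0.01, 0.001), function(p) {
    sel <- select_candidates(res, p_threshold = p)
    c(sel$up$gene, sel$down$gene)
  })
  expect_true(all(lists[[2]] %in% lists[[1]]))
  expect_true(all(lists[[3]] %in% lists[[2]]))
  wide <- select_candidates(res, fold_threshold = 2)
  narrow <- select_candidates(res, fold_threshold = 4)
  expect_true(all(narrow$up$gene %in% wide$up$gene))
  expect_true(all(narrow$down$gene %in% wide$down$gene))
})

test_that("swapping condition labels exactly exchanges up and down lists", {
  set.seed(37)
  tpm <- toy_expr(matrix(rlnorm(200, 4, 1.5), 50, 4),
                  samples = sheet22$sample)
  fwd <- contrast_spec(day = 8, n_permutations = 800, p_threshold = 0.1,
                       pseudocount = 0, seed = 9)
  rev <- contrast_spec(day = 8, group_a = "CRYO", group_b = "FRSH",
                       n_permutations = 800, p_threshold = 0.1,
                       pseudocount = 0, seed = 9)
  a <- select_candidates(run_diffexp(tpm, sheet22, fwd))
  b <- select_candidates(run_diffexp(tpm, sheet22, rev))
  expect_setequal(a$up$gene, b$down$gene)
  expect_setequal(a$down$gene, b$up$gene)
})

test_that("volcano coordinates follow the plotting conventions", {
  fake <- structure(
    data.frame(gene = c("a", "b"),
               mean_a = c(1, 1), mean_b = c(1, 1), diff = c(0, 0),
               log2fc = c(0, 2.5), p_value = c(1, 0.05),
               passed_p = c(FALSE, FALSE), passed_fc = c(FALSE, TRUE),
               candidate = c(FALSE, FALSE),
               direction = c("none", "none"), stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"),
    contrast = contrast_spec(day = 8), n_null = 1e6)
  tab <- volcano_table(fake)
  expect_equal(round(tab$neg_log10_p[2], 2), 1.30)   # P = 0.05
  expect_equal(tab$log2fc[1], 0)                     # null point at origin
  expect_equal(tab$neg_log10_p[1], 0)
  expect_false(tab$candidate[1])
  guides <- attr(tab, "guides")
  expect_equal(guides$x, c(-1, 1))
  expect_equal(round(guides$y, 2), 1.30)
  p <- volcano_plot(fake)
  expect_s3_class(p, "ggplot")
})

test_that("the P cap equals the attainable permutation floor", {
  fake <- structure(
    data.frame(gene = "a", mean_a = 1, mean_b = 1, diff = 0, log2fc = 0,
               p_value = 1e-12, passed_p = TRUE, passed_fc = FALSE,
               candidate = FALSE, direction = "none",
               stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"),
    contrast = contrast_spec(day = 8), n_null = 999)
  expect_equal(volcano_table(fake)$neg_log10_p, -log10(1 / 1000))
})
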