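down30 <- list(list(name = "down_mod", size = 30, effect = -2))
up20 <- list(list(name = "up_mod", size = 20, effect = 2))

test_that("identical configurations give byte-identical studies", {
  cfg <- sim_config(n_genes = 300, seed = 7, planted_down_sets = down30,
                    planted_up_sets = up20)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$samples, b$samples)
  expect_identical(simulate_annotations(a$truth, 10, seed = 3),
                   simulate_annotations(b$truth, 10, seed = 3))
  na <- simulate_network(a$truth, seed = 5)
  nb <- simulate_network(b$truth, seed = 5)
  expect_identical(na$edges, nb$edges)
})

test_that("study dimensions follow the matched-pair design", {
  cfg <- sim_config(n_genes = 120, n_days = 3, replicates_per_condition = 2,
                    seed = 1)
  sim <- simulate_counts(cfg)
  expect_equal(dim(sim$counts$counts), c(120, 12))
  expect_equal(sort(unique(sim$samples$day)), c(8, 10, 12))
  strata <- table(sim$samples$day, sim$samples$condition)
  expect_true(all(strata == 2))
  expect_true(all(sim$counts$counts >= 0))
  expect_true(all(sim$counts$counts == round(sim$counts$counts)))
})

test_that("a configuration with no planted effects is null", {
  cfg <- sim_config(n_genes = 400, n_days = 1, seed = 21)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$status == "null"))
  expect_true(all(sim$truth$effect == 0))
  cryo <- sim$samples$sample[sim$samples$condition == "CRYO"]
  frsh <- sim$samples$sample[sim$samples$condition == "FRSH"]
  tpm <- compute_tpm(sim$counts)
  ratio <- rowMeans(tpm[, cryo]) / rowMeans(tpm[, frsh])
  expect_lt(abs(median(log2(ratio))), 0.15)
})

test_that("planted TPM ratios converge to 2^effect at low noise", {
  cfg <- sim_config(n_genes = 500, n_days = 1, mean_library_size = 1e7,
                    library_size_cv = 0, nb_dispersion = 1e-4, seed = 9,
                    planted_down_sets = down30)
  sim <- simulate_counts(cfg)
  tpm <- compute_tpm(sim$counts)
  cryo <- sim$samples$sample[sim$samples$condition == "CRYO"]
  frsh <- sim$samples$sample[sim$samples$condition == "FRSH"]
  planted <- sim$truth$gene[sim$truth$status == "down"]
  ratio <- rowMeans(tpm[planted, cryo]) / rowMeans(tpm[planted, frsh])
  expect_true(all(abs(ratio - 0.25) <= 0.1 * 0.25))
})

test_that("planted log2 effects are conserved exactly in the generating means", {
  cfg <- sim_config(n_genes = 200, n_days = 1, seed = 3,
                    planted_down_sets = down30, planted_up_sets = up20)
  sim <- simulate_counts(cfg)
  cryo <- sim$samples$sample[sim$samples$condition == "CRYO"]
  frsh <- sim$samples$sample[sim$samples$condition == "FRSH"]
  # library sizes differ between samples, so compare like with like: mean
  # generating proportion per condition
  prop <- sweep(sim$mu, 2, colSums(sim$mu), "/")
  obs_eff <- log2(rowMeans(prop[, cryo]) / rowMeans(prop[, frsh]))
  # proportions are renormalised within CRYO, shifting all genes by the same
  # small constant; recover it from the null genes
  shift <- median(obs_eff[sim$truth$status == "null"])
  expect_true(all(abs((obs_eff - shift) - sim$truth$effect) <= 0.1))
})

test_that("the count law has the negative-binomial mean-variance relation", {
  # one gene, fixed library, no effects: repeated draws of the same NB
  cfg <- sim_config(n_genes = 1, n_days = 1, replicates_per_condition = 6000,
                    mean_library_size = 50, library_size_cv = 0,
                    nb_dispersion = 0.2, seed = 13)
  sim <- simulate_counts(cfg)
  x <- as.numeric(sim$counts$counts)
  m <- mean(sim$mu)
  expect_gte(length(x), 1e4)
  expect_lt(abs(mean(x) - m) / m, 0.05)
  v_expected <- m + 0.2 * m^2
  expect_lt(abs(var(x) - v_expected) / v_expected, 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 10, planted_down_sets =
    list(list(name = "a", size = 8, effect = -1),
         list(name = "b", size = 5, effect = -1))), "exceed")
  expect_error(sim_config(planted_down_sets =
    list(list(name = "a", size = 5, effect = 1))), "wrong sign")
  expect_error(sim_config(planted_down_sets =
    list(list(name = "a", size = 5, effect = -1)),
    planted_up_sets = list(list(name = "a", size = 5, effect = 1))),
    "disjoint")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(mean_library_size = -1), "positive")
})

test_that("annotations return planted sets verbatim plus null-gene decoys", {
  cfg <- sim_config(n_genes = 300, n_days = 1, seed = 4,
                    planted_down_sets = down30, planted_up_sets = up20)
  truth <- simulate_counts(cfg)$truth

  none <- simulate_annotations(truth, n_decoy_sets = 0, seed = 1)
  expect_setequal(names(none$sets), c("down_mod", "up_mod"))
  expect_setequal(none$sets$down_mod, truth$gene[truth$status == "down"])
  expect_setequal(none$sets$up_mod, truth$gene[truth$status == "up"])

  ann <- simulate_annotations(truth, n_decoy_sets = 15, decoy_size = 20,
                              seed = 2)
  expect_length(ann$sets, 17)
  null_genes <- truth$gene[truth$status == "null"]
  decoys <- ann$sets[ann$category == "decoy"]
  expect_true(all(unlist(decoys) %in% null_genes))
  expect_setequal(ann$universe, truth$gene)
})

test_that("decoy overlap with a null query matches the hypergeometric mean", {
  cfg <- sim_config(n_genes = 400, n_days = 1, seed = 5,
                    planted_down_sets = down30)
  truth <- simulate_counts(cfg)$truth
  null_genes <- truth$gene[truth$status == "null"]
  set.seed(99)
  query <- sample(null_genes, 60)    # a fixed null-gene candidate list
  decoy_size <- 25
  overlaps <- vapply(1:40, function(s) {
    ann <- simulate_annotations(truth, n_decoy_sets = 5,
                                decoy_size = decoy_size, seed = s)
    mean(vapply(ann$sets[ann$category == "decoy"],
                function(d) length(intersect(d, query)), numeric(1)))
  }, numeric(1))
  expected <- decoy_size * length(query) / length(null_genes)
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - expected), 4 * se + 0.05)
})

test_that("network edge probabilities and scores behave as configured", {
  cfg <- sim_config(n_genes = 150, n_days = 1, seed = 6,
                    planted_down_sets = down30)
  truth <- simulate_counts(cfg)$truth

  empty <- simulate_network(truth, intra_set_edge_prob = 0,
                            background_edge_prob = 0, seed = 1)
  expect_equal(nrow(empty$edges), 0)

  sure <- simulate_network(truth, intra_set_edge_prob = 1,
                           background_edge_prob = 0,
                           score_means = c(0.95, 0.4), score_sd = 0.001,
                           seed = 2)
  kept <- threshold_edges(sure, 0.700)
  expect_equal(nrow(kept$edges), choose(30, 2))

  expect_error(simulate_network(truth, intra_set_edge_prob = 0.1,
                                background_edge_prob = 0.5), ">=")
})

test_that("expected edge counts match the closed-form expectation", {
  cfg <- sim_config(n_genes = 200, n_days = 1, seed = 8,
                    planted_down_sets = down30)
  truth <- simulate_counts(cfg)$truth
  p_in <- 0.6; p_bg <- 0.03
  m_intra <- choose(30, 2)
  m_bg <- choose(200, 2) - m_intra
  expected <- p_in * m_intra + p_bg * m_bg
  counts <- vapply(1:30, function(s) {
    nrow(simulate_network(truth, p_in, p_bg, seed = s)$edges)
  }, numeric(1))
  sd_one <- sqrt(p_in * (1 - p_in) * m_intra + p_bg * (1 - p_bg) * m_bg)
  expect_lt(abs(mean(counts) - expected), 3 * sd_one / sqrt(30))
  expect_true(all(counts >= 0))
})

test_that("scores are clipped to the unit interval", {
  cfg <- sim_config(n_genes = 100, n_days = 1, seed = 10,
                    planted_down_sets = down30)
  truth <- simulate_counts(cfg)$truth
  net <- simulate_network(truth, 0.9, 0.05, score_means = c(0.99, 0.01),
                          score_sd = 0.5, seed = 3)
  expect_true(all(net$edges$score >= 0 & net$edges$score <= 1))
})

test_that("the phenotype map annotates down genes with lethality terms", {
  cfg <- sim_config(n_genes = 200, n_days = 1, seed = 11,
                    planted_down_sets = down30)
  truth <- simulate_counts(cfg)$truth
  map <- simulate_phenotype_map(truth, seed = 12)
  expect_true(all(c("gene", "ortholog", "terms") %in% names(map)))
  down <- truth$gene[truth$status == "down"]
  annotated_down <- intersect(map$gene, down)
  expect_gt(length(annotated_down), 0)
  lethal <- grepl("lethal|embryo|zygotic", map$terms[map$gene %in% down])
  expect_true(all(lethal))
  expect_identical(simulate_phenotype_map(truth, seed = 12), map)
})
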