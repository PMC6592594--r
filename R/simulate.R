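# Synthetic-data generator.
#
# Emulates the study design the pipeline targets: a matched-pair,
# two-condition (FRSH vs CRYO) embryo RNA-seq experiment sampled on several
# days, two replicates per condition per day, with condition effects planted
# in designated annotation sets (mimicking coordinated down-regulation of
# e.g. oxidative-phosphorylation / histone / ribosome genes).

#' Simulation configuration
#'
#' Collects and validates the parameters of the negative-binomial count
#' simulator.  Counts for gene g in sample j are drawn
#' `NB(mean = mu_gj, var = mu_gj + nb_dispersion * mu_gj^2)` where `mu_gj`
#' scales a log-normal per-gene baseline by transcript length and the
#' sample's library size; CRYO-condition means of planted genes are
#' multiplied by `2^effect`.
#'
#' @param n_genes Number of genes (default 29196, the scale of an embryo
#'   transcriptome; tests and examples use far fewer).
#' @param n_days Number of sampling days (default 3, labelled 8, 10, 12...).
#' @param replicates_per_condition Embryos per condition per day (default 2).
#' @param mean_library_size Mean sequencing depth in reads (default 5e6).
#' @param library_size_cv Coefficient of variation of log-normal library
#'   sizes (default 0.2); set 0 for fixed depth.
#' @param nb_dispersion Negative-binomial dispersion (default 0.2).
#' @param planted_down_sets,planted_up_sets Lists of planted condition
#'   effects, each element `list(name=, size=, effect=)` with `effect` the
#'   signed log2 fold change applied to CRYO means (negative for down sets,
#'   positive for up sets).
#' @param baseline_log_mean_sd SD of per-gene baseline log2 abundance
#'   (default 0.25).
#' @param gene_length_range Range (bp) of log-uniform transcript lengths
#'   (default 300--15000).
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 1,
#'                   planted_down_sets = list(
#'                     list(name = "oxphos_like", size = 20, effect = -2)))
#' sim <- simulate_counts(cfg)
#' @export
sim_config <- function(n_genes = 29196,
                       n_days = 3,
                       replicates_per_condition = 2,
                       mean_library_size = 5e6,
                       library_size_cv = 0.2,
                       nb_dispersion = 0.2,
                       planted_down_sets = list(),
                       planted_up_sets = list(),
                       baseline_log_mean_sd = 0.25,
                       gene_length_range = c(300, 15000),
                       seed = 1) {
  if (!is_count(n_genes)) stop("`n_genes` must be a positive integer",
                               call. = FALSE)
  if (!is_count(n_days)) stop("`n_days` must be a positive integer",
                              call. = FALSE)
  if (!is_count(replicates_per_condition)) {
    stop("`replicates_per_condition` must be a positive integer",
         call. = FALSE)
  }
  if (mean_library_size <= 0) stop("`mean_library_size` must be positive",
                                   call. = FALSE)
  if (library_size_cv < 0) stop("`library_size_cv` must be >= 0",
                                call. = FALSE)
  if (nb_dispersion <= 0) stop("`nb_dispersion` must be positive",
                               call. = FALSE)
  if (baseline_log_mean_sd <= 0) {
    stop("`baseline_log_mean_sd` must be positive", call. = FALSE)
  }
  if (length(gene_length_range) != 2 || any(gene_length_range <= 0) ||
      gene_length_range[1] > gene_length_range[2]) {
    stop("`gene_length_range` must be (min bp, max bp) with 0 < min <= max",
         call. = FALSE)
  }
  check_sets <- function(sets, sign, what) {
    for (s in sets) {
      if (!all(c("name", "size", "effect") %in% names(s))) {
        stop(sprintf("each %s element needs fields name, size, effect", what),
             call. = FALSE)
      }
      if (!is_count(s$size)) {
        stop(sprintf("planted set '%s' has a non-positive size", s$name),
             call. = FALSE)
      }
      if (s$effect * sign < 0) {
        stop(sprintf(
          "planted set '%s': effect %g has the wrong sign for %s",
          s$name, s$effect, what), call. = FALSE)
      }
    }
  }
  check_sets(planted_down_sets, -1, "planted_down_sets")
  check_sets(planted_up_sets, +1, "planted_up_sets")
  all_names <- c(vapply(planted_down_sets, `[[`, "", "name"),
                 vapply(planted_up_sets, `[[`, "", "name"))
  if (anyDuplicated(all_names)) {
    stop("planted set names overlap: planted up and down sets must be ",
         "disjoint and uniquely named", call. = FALSE)
  }
  total_planted <- sum(vapply(c(planted_down_sets, planted_up_sets),
                              `[[`, numeric(1), "size"))
  if (total_planted > n_genes) {
    stop("planted set sizes exceed `n_genes`", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_days = as.integer(n_days),
                 replicates_per_condition = as.integer(replicates_per_condition),
                 mean_library_size = mean_library_size,
                 library_size_cv = library_size_cv,
                 nb_dispersion = nb_dispersion,
                 planted_down_sets = planted_down_sets,
                 planted_up_sets = planted_up_sets,
                 baseline_log_mean_sd = baseline_log_mean_sd,
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a matched-pair two-condition count study
#'
#' Draws gene lengths log-uniformly, per-gene baseline abundances
#' log-normally, library sizes log-normally around `mean_library_size`, and
#' counts negative-binomially.  Planted genes have their CRYO-condition
#' expected count multiplied exactly by `2^effect`; FRSH means are untouched,
#' matching the CRYO-relative-to-FRSH framing of the contrast.  Identical
#' configurations (including seed) give identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study` with elements
#'   \describe{
#'     \item{counts}{a [count_matrix()];}
#'     \item{samples}{sample sheet data frame (`sample`, `day`, `condition`,
#'       `pair`);}
#'     \item{truth}{ground-truth data frame (`gene`, `status` in
#'       down/up/null, `effect` log2, `set`);}
#'     \item{mu}{the generating expected-count matrix (before NB noise);}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    g <- config$n_genes
    genes <- sprintf("G%05d", seq_len(g))
    lengths <- round(exp(stats::runif(g,
                                      log(config$gene_length_range[1]),
                                      log(config$gene_length_range[2]))))
    baseline <- 2^stats::rnorm(g, 0, config$baseline_log_mean_sd)

    # ground truth: assign planted members from a single shuffle so sets are
    # disjoint by construction
    truth <- data.frame(gene = genes, status = "null", effect = 0,
                        set = NA_character_, stringsAsFactors = FALSE)
    shuffled <- sample.int(g)
    pos <- 1L
    for (dir in c("down", "up")) {
      sets <- if (dir == "down") config$planted_down_sets else
        config$planted_up_sets
      for (s in sets) {
        idx <- shuffled[pos:(pos + s$size - 1L)]
        pos <- pos + s$size
        truth$status[idx] <- dir
        truth$effect[idx] <- s$effect
        truth$set[idx] <- s$name
      }
    }

    days <- seq(8L, by = 2L, length.out = config$n_days)
    reps <- config$replicates_per_condition
    sheet <- expand.grid(pair = seq_len(reps),
                         condition = c("FRSH", "CRYO"),
                         day = days,
                         stringsAsFactors = FALSE)
    sheet <- sheet[, c("day", "condition", "pair")]
    sheet$sample <- sprintf("D%d_%s_%d", sheet$day, sheet$condition,
                            sheet$pair)
    sheet$pair <- sprintf("D%d_pair%d", sheet$day, sheet$pair)
    sheet <- sheet[, c("sample", "day", "condition", "pair")]

    n_samp <- nrow(sheet)
    sdlog <- sqrt(log(1 + config$library_size_cv^2))
    lib <- stats::rlnorm(n_samp,
                         meanlog = log(config$mean_library_size) - sdlog^2 / 2,
                         sdlog = sdlog)

    w <- baseline * lengths            # expected read weight per gene (FRSH)
    denom <- sum(w)                    # fixed so planted ratios are exact
    mult <- 2^truth$effect
    mu <- matrix(0, g, n_samp, dimnames = list(genes, sheet$sample))
    for (j in seq_len(n_samp)) {
      mj <- if (sheet$condition[j] == "CRYO") w * mult else w
      mu[, j] <- lib[j] * mj / denom
    }
    counts <- matrix(stats::rnbinom(g * n_samp, mu = mu,
                                    size = 1 / config$nb_dispersion),
                     g, n_samp, dimnames = dimnames(mu))

    structure(list(counts = count_matrix(counts,
                                         stats::setNames(lengths, genes)),
                   samples = sheet, truth = truth, mu = mu, config = config),
              class = "sim_study")
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "sim_study: %d genes x %d samples (%d days x 2 conditions x %d reps)\n",
    nrow(x$counts$counts), ncol(x$counts$counts), x$config$n_days,
    x$config$replicates_per_condition))
  tab <- table(x$truth$status)
  cat("planted:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate gene-set annotations around a ground truth
#'
#' Returns the planted sets verbatim plus decoy sets drawn uniformly from
#' null genes, over the universe of all simulated genes.  Decoys carry
#' category `"decoy"`, planted sets `"planted"`.
#'
#' @param truth Ground-truth data frame from [simulate_counts()].
#' @param n_decoy_sets Number of decoy sets (default 50).
#' @param decoy_size Genes per decoy set (default 30).
#' @param seed Integer RNG seed.
#' @return A [gene_sets()] collection.
#' @export
simulate_annotations <- function(truth, n_decoy_sets = 50, decoy_size = 30,
                                 seed = 1) {
  stopifnot(is.data.frame(truth), nrow(truth) > 0)
  with_seed(seed, {
    planted <- split(truth$gene[!is.na(truth$set)],
                     truth$set[!is.na(truth$set)])
    null_genes <- truth$gene[truth$status == "null"]
    if (n_decoy_sets > 0 && decoy_size > length(null_genes)) {
      stop("`decoy_size` exceeds the number of null genes", call. = FALSE)
    }
    decoys <- lapply(seq_len(n_decoy_sets), function(i) {
      sample(null_genes, decoy_size)
    })
    names(decoys) <- sprintf("decoy_%03d", seq_len(n_decoy_sets))
    sets <- c(planted, decoys)
    category <- stats::setNames(
      c(rep("planted", length(planted)), rep("decoy", length(decoys))),
      names(sets))
    gene_sets(sets, universe = truth$gene, category = category)
  })
}

#' Simulate a confidence-scored interaction network
#'
#' Edges within each planted set are drawn with probability
#' `intra_set_edge_prob` and confidence scores around `score_means[1]`;
#' all remaining gene pairs with probability `background_edge_prob` and
#' scores around `score_means[2]`.  Scores are Gaussian with SD `score_sd`,
#' clipped to [0, 1].  This gives the network module a testbed in which
#' planted modules survive a high confidence cutoff while background noise
#' largely does not.
#'
#' @param truth Ground-truth data frame from [simulate_counts()].
#' @param intra_set_edge_prob Edge probability within planted sets
#'   (default 0.8).
#' @param background_edge_prob Edge probability elsewhere (default 0.02).
#' @param score_means Mean confidence for (intra, background) edges
#'   (default `c(0.85, 0.45)`).
#' @param score_sd SD of confidence scores (default 0.15).
#' @param seed Integer RNG seed.
#' @return A [confidence_network()].
#' @export
simulate_network <- function(truth, intra_set_edge_prob = 0.8,
                             background_edge_prob = 0.02,
                             score_means = c(0.85, 0.45), score_sd = 0.15,
                             seed = 1) {
  stopifnot(is.data.frame(truth), nrow(truth) > 0)
  stopifnot_scalar_prob(intra_set_edge_prob, "intra_set_edge_prob")
  stopifnot_scalar_prob(background_edge_prob, "background_edge_prob")
  if (intra_set_edge_prob < background_edge_prob) {
    stop("`intra_set_edge_prob` must be >= `background_edge_prob`",
         call. = FALSE)
  }
  with_seed(seed, {
    genes <- truth$gene
    n <- length(genes)
    idx_of <- stats::setNames(seq_len(n), genes)

    # membership key: pairs within the same planted set
    set_of <- stats::setNames(truth$set, truth$gene)
    ea <- integer(0); eb <- integer(0); sc <- numeric(0)
    for (s in split(truth$gene[!is.na(truth$set)],
                    truth$set[!is.na(truth$set)])) {
      if (length(s) < 2) next
      pr <- utils::combn(idx_of[s], 2)
      keep <- stats::runif(ncol(pr)) < intra_set_edge_prob
      if (any(keep)) {
        ea <- c(ea, pr[1, keep]); eb <- c(eb, pr[2, keep])
        sc <- c(sc, stats::rnorm(sum(keep), score_means[1], score_sd))
      }
    }

    # background: Bernoulli over all pairs, then discard pairs that fall
    # inside a planted set, leaving Binomial(remaining pairs, p) exactly
    m_all <- n * (n - 1) / 2
    n_bg <- stats::rbinom(1, m_all, background_edge_prob)
    if (n_bg > 0) {
      pick <- sample(m_all, n_bg)
      # decode triangular index (1-based, column-major over i < j)
      j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
      i <- pick - (j - 1) * (j - 2) / 2
      same_set <- !is.na(set_of[genes[i]]) &
        set_of[genes[i]] == set_of[genes[j]]
      same_set[is.na(same_set)] <- FALSE
      i <- i[!same_set]; j <- j[!same_set]
      if (length(i)) {
        ea <- c(ea, i); eb <- c(eb, j)
        sc <- c(sc, stats::rnorm(length(i), score_means[2], score_sd))
      }
    }
    sc <- pmin(pmax(sc, 0), 1)
    edges <- data.frame(a = genes[ea], b = genes[eb], score = sc,
                        stringsAsFactors = FALSE)
    confidence_network(edges, nodes = genes)
  })
}

#' Simulate an ortholog-phenotype table
#'
#' Builds a synthetic stand-in for a mouse-knockout phenotype export: a
#' fraction of planted down-regulated genes (and a smaller fraction of null
#' genes) are given mouse ortholog ids and developmental-lethality phenotype
#' terms; other annotated genes receive unrelated terms.
#'
#' @param truth Ground-truth data frame from [simulate_counts()].
#' @param frac_down_lethal Fraction of planted down genes annotated with
#'   lethality terms (default 0.6).
#' @param frac_null_annotated Fraction of null genes annotated with any term
#'   (default 0.1).
#' @param seed Integer RNG seed.
#' @return A `phenotype_map` data frame (`gene`, `ortholog`, `terms`
#'   pipe-separated), as read by [read_phenotype_map()].
#' @export
simulate_phenotype_map <- function(truth, frac_down_lethal = 0.6,
                                   frac_null_annotated = 0.1, seed = 1) {
  lethal_terms <- c(
    "embryonic lethality before implantation-complete penetrance",
    "embryonic growth retardation",
    "embryonic growth arrest",
    "decreased embryo size",
    "failure of zygotic division",
    "prenatal lethality-complete penetrance")
  other_terms <- c("increased body weight", "abnormal coat colour",
                   "decreased bone density", "abnormal gait")
  with_seed(seed, {
    down <- truth$gene[truth$status == "down"]
    nulls <- truth$gene[truth$status == "null"]
    pick_down <- down[stats::runif(length(down)) < frac_down_lethal]
    pick_null <- nulls[stats::runif(length(nulls)) < frac_null_annotated]
    rows <- lapply(c(pick_down, pick_null), function(g) {
      lethal <- g %in% pick_down
      terms <- if (lethal) {
        sample(lethal_terms, sample(1:3, 1))
      } else {
        sample(other_terms, sample(1:2, 1))
      }
      data.frame(gene = g, ortholog = paste0(tolower(g), "_mus"),
                 terms = paste(terms, collapse = "|"),
                 stringsAsFactors = FALSE)
    })
    map <- do.call(rbind, c(rows, list(
      data.frame(gene = character(0), ortholog = character(0),
                 terms = character(0)))))
    map <- map[order(map$gene), , drop = FALSE]
    rownames(map) <- NULL
    class(map) <- c("phenotype_map", "data.frame")
    map
  })
}

#' Write a simulated study to disk as plain-text tables
#'
#' Emits counts, lengths, sample sheet and ground truth as TSV in `dir`.
#'
#' @param sim A `sim_study` from [simulate_counts()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             lengths = file.path(dir, "lengths.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(sim$counts, paths["counts"], paths["lengths"])
  write_tsv(sim$samples, paths["samples"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
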