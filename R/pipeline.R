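# End-to-end orchestration: simulate -> quantify -> differential expression
# -> enrichment -> network -> phenotype, as one configured, seeded, logged
# run.  Every stage consumes and produces plain-text files under the output
# directory, so any stage can be rerun in isolation, and a manifest records
# every threshold, seed and input hash that affects the result.

pipeline_defaults <- function() {
  list(
    seed = 1,
    floor = 0.4,
    floor_scope = "any",
    diffexp = list(mode = "label_within_gene", n_permutations = 10000,
                   p_threshold = 0.01, fold_threshold = 2, pseudocount = 0.5),
    enrichment = list(fdr_threshold = 0.05, n_decoy_sets = 50,
                      decoy_size = 30),
    network = list(cutoff = 0.700, n_draws = 10000,
                   intra_set_edge_prob = 0.8, background_edge_prob = 0.02),
    phenotype = list(term_filter = NULL),
    figures = FALSE
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages for a simulated or file-based study.  The
#' configuration is a named list (or the path of a YAML file holding one)
#' with entries:
#' \describe{
#'   \item{outdir}{output directory (required).}
#'   \item{seed}{global seed; per-stage seeds are derived from it and
#'     recorded in the manifest.}
#'   \item{simulate}{optional list of [sim_config()] arguments.  When
#'     present, counts, annotations, network and phenotype map are all
#'     generated; otherwise paths `counts`, `lengths`, `samples` (and
#'     `gmt`, `edges`, `phenotype_map`) must point to existing files.}
#'   \item{floor, floor_scope}{expression floor (RPKM, default 0.4) and its
#'     scope (see [filter_expressed()]).}
#'   \item{days}{days to contrast (default: all days in the sample sheet).}
#'   \item{diffexp}{`mode`, `n_permutations`, `p_threshold`,
#'     `fold_threshold`, `pseudocount`, plus optional `per_day`, a named
#'     list of per-day overrides (e.g. `per_day = list("8" =
#'     list(p_threshold = 0.001))` to re-threshold a crowded day).}
#'   \item{enrichment}{`fdr_threshold` plus simulation knobs.}
#'   \item{network}{`cutoff`, `n_draws` plus simulation knobs.}
#'   \item{phenotype}{`term_filter`: optional term vector or file.}
#'   \item{figures}{write volcano PNGs (default FALSE; the volcano table is
#'     always written).}
#' }
#' Up- and down-regulated candidate lists are enriched and network-tested
#' separately for every day; phenotype intersection is run on the
#' down-regulated lists.  Reruns with the same configuration produce
#' identical tables.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a report bundle: `outdir`, `files` (named paths),
#'   `summary` (per-day candidate counts, top enrichment terms, PPI P
#'   values, phenotype hit counts) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$outdir)) stop("config needs `outdir`", call. = FALSE)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- list()

  ## ---- validation & input stage -------------------------------------
  simulated <- !is.null(cfg$simulate)
  if (!simulated) {
    for (f in c("counts", "lengths", "samples")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        stop(sprintf("config `%s` must point to an existing file", f),
             call. = FALSE)
      }
    }
  }

  if (simulated) {
    run_stage("simulate", {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% cfg$seed
      sim_args$planted_down_sets <- sim_args$planted_down_sets %||% list()
      sim_args$planted_up_sets <- sim_args$planted_up_sets %||% list()
      sim <- simulate_counts(do.call(sim_config, sim_args))
      paths <- write_simulation(sim, file.path(outdir, "inputs"))
      files$counts <- unname(paths["counts"])
      files$lengths <- unname(paths["lengths"])
      files$samples <- unname(paths["samples"])
      files$truth <- unname(paths["truth"])
      ann <- simulate_annotations(sim$truth,
                                  n_decoy_sets = cfg$enrichment$n_decoy_sets,
                                  decoy_size = cfg$enrichment$decoy_size,
                                  seed = cfg$seed + 101)
      files$gmt <- file.path(outdir, "inputs", "annotations.gmt")
      write_gmt(ann, files$gmt)
      net <- simulate_network(
        sim$truth,
        intra_set_edge_prob = cfg$network$intra_set_edge_prob,
        background_edge_prob = cfg$network$background_edge_prob,
        seed = cfg$seed + 202)
      files$edges <- file.path(outdir, "inputs", "network.tsv")
      write_network(net, files$edges)
      pmap <- simulate_phenotype_map(sim$truth, seed = cfg$seed + 303)
      files$phenotype_map <- file.path(outdir, "inputs", "phenotype.tsv")
      write_tsv(pmap, files$phenotype_map)
    })
  } else {
    files$counts <- cfg$counts
    files$lengths <- cfg$lengths
    files$samples <- cfg$samples
    files$gmt <- cfg$gmt
    files$edges <- cfg$edges
    files$phenotype_map <- cfg$phenotype_map
  }

  sheet <- read_sample_sheet(files$samples)
  days <- cfg$days %||% sort(unique(sheet$day))
  unknown <- setdiff(days, sheet$day)
  if (length(unknown)) {
    stop("config `days` not present in the sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  ## ---- quantify ------------------------------------------------------
  run_stage("quantify", {
    cm <- read_counts(files$counts, files$lengths)
    files$tpm <- file.path(outdir, "tpm.tsv")
    files$rpkm <- file.path(outdir, "rpkm.tsv")
    write_expression(compute_tpm(cm), files$tpm)
    write_expression(compute_rpkm(cm), files$rpkm)
  })

  summary <- list()
  contrasts <- list()
  for (i in seq_along(days)) {
    day <- days[[i]]
    tag <- paste0("day", day)

    ## ---- differential expression ------------------------------------
    run_stage(paste0("diffexp_", tag), {
      tpm <- read_expression(files$tpm, "TPM")
      rpkm <- read_expression(files$rpkm, "RPKM")
      day_samples <- sheet$sample[sheet$day == day]
      expressed <- filter_expressed(rpkm, floor = cfg$floor,
                                    scope = cfg$floor_scope,
                                    samples = day_samples,
                                    sample_sheet = sheet)
      over <- cfg$diffexp$per_day[[as.character(day)]] %||% list()
      de_cfg <- merge_config(cfg$diffexp, over)
      contrast <- contrast_spec(
        day = day, mode = de_cfg$mode,
        n_permutations = de_cfg$n_permutations,
        p_threshold = de_cfg$p_threshold,
        fold_threshold = de_cfg$fold_threshold,
        pseudocount = de_cfg$pseudocount,
        seed = cfg$seed + i)
      contrasts[[tag]] <- contrast
      res <- run_diffexp(tpm, sheet, contrast, genes = expressed)
      files[[paste0("de_", tag)]] <- file.path(outdir,
                                                paste0("de_", tag, ".tsv"))
      write_tsv(res, files[[paste0("de_", tag)]])
      vt <- volcano_table(res)
      files[[paste0("volcano_", tag)]] <-
        file.path(outdir, paste0("volcano_", tag, ".tsv"))
      write_tsv(vt, files[[paste0("volcano_", tag)]])
      if (isTRUE(cfg$figures)) {
        fig <- file.path(outdir, paste0("volcano_", tag, ".png"))
        tryCatch({
          ggplot2::ggsave(fig, volcano_plot(res, title = tag),
                          width = 5, height = 4, dpi = 150)
          files[[paste0("volcano_fig_", tag)]] <- fig
        }, error = function(e) {
          warning("volcano figure for ", tag, " skipped: ",
                  conditionMessage(e), call. = FALSE)
        })
      }
      cand <- select_candidates(res)
      for (dir in c("up", "down")) {
        key <- paste0(dir, "_", tag)
        files[[key]] <- file.path(outdir, paste0(key, ".txt"))
        write_gene_list(cand[[dir]]$gene, files[[key]])
      }
      summary[[tag]] <- list(n_expressed = length(expressed),
                              n_up = nrow(cand$up), n_down = nrow(cand$down),
                              p_threshold = contrast$p_threshold)
    })

    ## ---- enrichment (up and down separately) ------------------------
    if (!is.null(files$gmt)) {
      run_stage(paste0("enrich_", tag), {
        rpkm <- read_expression(files$rpkm, "RPKM")
        day_samples <- sheet$sample[sheet$day == day]
        expressed <- filter_expressed(rpkm, floor = cfg$floor,
                                      scope = cfg$floor_scope,
                                      samples = day_samples,
                                      sample_sheet = sheet)
        collection <- read_gmt(files$gmt, universe = expressed)
        for (dir in c("up", "down")) {
          genes <- read_gene_list(files[[paste0(dir, "_", tag)]])
          chart <- enrich(genes, collection,
                          fdr_threshold = cfg$enrichment$fdr_threshold)
          key <- paste0("enrich_", dir, "_", tag)
          files[[key]] <- file.path(outdir, paste0(key, ".tsv"))
          write_tsv(chart, files[[key]])
          summary[[tag]][[paste0("top_term_", dir)]] <-
            if (nrow(chart)) chart$term[1] else NA_character_
          summary[[tag]][[paste0("n_significant_terms_", dir)]] <-
            sum(chart$significant)
        }
      })
    }

    ## ---- network ----------------------------------------------------
    if (!is.null(files$edges)) {
      run_stage(paste0("network_", tag), {
        net <- threshold_edges(read_network(files$edges),
                               cutoff = cfg$network$cutoff)
        for (dir in c("up", "down")) {
          genes <- read_gene_list(files[[paste0(dir, "_", tag)]])
          rep <- ppi_enrichment(net, genes,
                                n_draws = cfg$network$n_draws,
                                seed = cfg$seed + 500 + i)
          cl <- cluster_network(net, genes)
          key <- paste0("network_", dir, "_", tag)
          files[[key]] <- file.path(outdir, paste0(key, ".json"))
          jsonlite::write_json(
            list(n_nodes = rep$n_nodes, n_edges = rep$n_edges,
                 query_size = rep$query_size, observed = rep$observed,
                 expected = rep$expected, p_value = rep$p_value,
                 n_draws = rep$n_draws, method = rep$method,
                 clusters = cl$clusters, singletons = cl$singletons),
            files[[key]], auto_unbox = TRUE, digits = NA)
          summary[[tag]][[paste0("ppi_p_", dir)]] <- rep$p_value
        }
      })
    }

    ## ---- phenotype (down lists, matching the study's question) ------
    if (!is.null(files$phenotype_map)) {
      run_stage(paste0("phenotype_", tag), {
        map <- read_phenotype_map(files$phenotype_map)
        term_filter <- cfg$phenotype$term_filter
        if (is.character(term_filter) && length(term_filter) == 1 &&
            file.exists(term_filter)) {
          term_filter <- read_gene_list(term_filter)
        }
        genes <- read_gene_list(files[[paste0("down_", tag)]])
        hits <- phenotype_hits(genes, map, term_filter = term_filter)
        key <- paste0("phenotype_", tag)
        files[[key]] <- file.path(outdir, paste0(key, ".tsv"))
        write_tsv(hits$hits, files[[key]])
        fkey <- paste0("phenotype_terms_", tag)
        files[[fkey]] <- file.path(outdir, paste0(fkey, ".json"))
        jsonlite::write_json(hits$term_frequency, files[[fkey]],
                             auto_unbox = TRUE, digits = NA)
        summary[[tag]]$n_phenotype_hits <- nrow(hits$hits)
      })
    }
  }

  ## ---- manifest ------------------------------------------------------
  input_files <- unlist(files[c("counts", "lengths", "samples", "gmt",
                                "edges", "phenotype_map")])
  input_files <- input_files[!is.na(input_files) & file.exists(input_files)]
  manifest <- list(
    package = "permde",
    version = as.character(utils::packageVersion("permde")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    floor = cfg$floor, floor_scope = cfg$floor_scope,
    days = days,
    contrasts = lapply(contrasts, unclass),
    enrichment = cfg$enrichment[c("fdr_threshold")],
    network = cfg$network[c("cutoff", "n_draws")],
    input_md5 = as.list(tools::md5sum(input_files)),
    outputs = lapply(files, as.character)
  )
  files$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(outdir = outdir, files = files, summary = summary,
                 manifest = manifest))
}
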