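#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), checks it
#' against the known schema, fills documented defaults (`pseudocount` 1,
#' `n_bins` 10, `min_cell_fraction` 0.10, `seed` 1) and reports every
#' problem at once. Unknown keys are rejected with a nearest-key hint.
#'
#' Top-level keys: `outdir`, `seed`, `pseudocount`, `n_bins`,
#' `min_cell_fraction`, `simulate` (preset simulation: `n_genes`,
#' `n_cells`, plus [simulation_design()] overrides), `datasets` (list of
#' entries with `id`, `path`, `format`, `protocol`, `qc_preset` or
#' explicit `max_dropout` / `min_library_size` / `max_spikein_fraction`),
#' `gene_filter` ([gene_filter_policy()] fields), and `analysis` with
#' toggles `bias`, `combine`, `overlap` (with `group_a` / `group_b`
#' dataset ids), `enrich` (with `gmt`), `de` (with `dataset`,
#' `lfc_cutoff`, `alpha`).
#'
#' @param config path to a YAML file, or a list.
#' @return Normalized list of class `RunConfig`; stops listing all errors
#'   otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "RunConfig")) return(config)
  errors <- character(0)
  note <- function(...) errors <<- c(errors, paste0(...))
  known <- c("outdir", "seed", "pseudocount", "n_bins", "min_cell_fraction",
             "simulate", "datasets", "gene_filter", "analysis")
  for (key in setdiff(names(config), known)) {
    d <- utils::adist(key, known)
    hint <- if (min(d) <= 3) paste0(" (did you mean '", known[which.min(d)],
                                    "'?)") else ""
    note("unknown key '", key, "'", hint)
  }
  defaults <- list(outdir = "results", seed = 1L, pseudocount = 1,
                   n_bins = 10L, min_cell_fraction = 0.10)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!is.null(config$datasets)) {
    ids <- vapply(config$datasets, function(d)
      if (is.null(d$id)) NA_character_ else d$id, character(1))
    if (anyNA(ids)) note("every dataset entry needs an 'id'")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0)
      note("duplicate dataset ids: ", paste(dup, collapse = ", "))
    for (d in config$datasets) {
      if (is.null(d$path)) {
        note("dataset '", d$id, "' has no path")
      } else if (!file.exists(d$path)) {
        note("dataset '", d$id, "' path does not exist: ", d$path)
      }
      if (!is.null(d$qc_preset))
        tryCatch(qc_preset(d$qc_preset),
                 error = function(e) note(conditionMessage(e)))
    }
  }
  if (is.null(config$datasets) && is.null(config$simulate))
    note("config needs 'datasets' and/or 'simulate'")
  if (!is.null(config$analysis$overlap)) {
    ov <- config$analysis$overlap
    if (is.null(ov$group_a) || is.null(ov$group_b))
      note("analysis$overlap needs group_a and group_b dataset ids")
  }
  if (!is.null(config$analysis$enrich) &&
      is.null(config$analysis$enrich$gmt))
    note("analysis$enrich needs a 'gmt' path")
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  config$seed <- as.integer(config$seed)
  class(config) <- "RunConfig"
  config
}

# Self-describing TSV: comment header lines carrying column meanings and
# the package version, then the table.
write_stage_tsv <- function(df, path, what = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("sclenbias"))
  writeLines(c(sprintf("# sclenbias %s", ver),
               if (!is.null(what)) paste0("# ", what),
               paste0("# columns: ", paste(names(df), collapse = ", "))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline stage TSV
#'
#' Stage tables are written with `#` comment headers describing their
#' columns; this reads one back as a data frame.
#'
#' @param path a TSV written by [run_pipeline()].
#' @return data frame.
#' @export
read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

.stage <- function(name, expr, logfile = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulation (optional), ingest, cell and gene QC, the
#' length-bias summaries, multi-dataset combination with PCA, the
#' detection-overlap comparison with its rank-sum length test, gene-set
#' enrichment of the uniquely detected sets, and the two-group DE stage,
#' writing per-stage TSV/JSON artifacts plus a single-page `summary.json`
#' under the configured output directory. Deterministic given the config
#' and seed.
#'
#' @param config YAML path, list or `RunConfig` from [validate_config()].
#' @param outdir optional override of the configured output directory.
#' @param seed optional override of the configured seed.
#' @return Invisible list with the filtered datasets and the computed
#'   stage results.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  config <- validate_config(config)
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "pipeline.log")
  cat("", file = logfile)
  run_summary <- list(seed = config$seed)
  datasets <- list()

  if (!is.null(config$simulate)) {
    datasets <- .stage("simulate", {
      sim <- config$simulate
      args <- sim[setdiff(names(sim), c("n_genes", "n_cells"))]
      pair <- do.call(mesc_pair, c(list(
        n_genes = if (is.null(sim$n_genes)) 12000L else sim$n_genes,
        n_cells = if (is.null(sim$n_cells)) 200L else sim$n_cells,
        seed = config$seed), args))
      for (nm in c("full_length", "umi"))
        write_dataset(pair[[nm]], file.path(out, "simulate", nm))
      write_stage_tsv(pair$truth$genes, file.path(out, "simulate", "truth_genes.tsv"),
                      "per-gene simulation ground truth")
      list(sim_full_length = pair$full_length, sim_umi = pair$umi)
    }, logfile)
  }
  for (entry in config$datasets) {
    datasets[[entry$id]] <- .stage(paste0("load:", entry$id), {
      ds <- read_count_matrix(
        entry$path,
        format = if (is.null(entry$format)) "mtx_triplet" else entry$format,
        protocol = if (is.null(entry$protocol)) "full_length" else
          entry$protocol)
      ds$cells$dataset_id <- entry$id
      ds
    }, logfile)
  }

  qc_dir <- file.path(out, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  policy <- do.call(gene_filter_policy,
                    config$gene_filter %||% list())
  thresholds_for <- function(id) {
    entry <- NULL
    for (e in config$datasets) if (identical(e$id, id)) entry <- e
    if (is.null(entry)) return(qc_thresholds())
    if (!is.null(entry$qc_preset)) return(qc_preset(entry$qc_preset))
    qc_thresholds(
      max_dropout = entry$max_dropout %||% 1,
      min_library_size = entry$min_library_size %||% 0,
      max_spikein_fraction = entry$max_spikein_fraction %||% NA_real_)
  }
  filtered <- list()
  for (id in names(datasets)) {
    filtered[[id]] <- .stage(paste0("qc:", id), {
      before <- datasets[[id]]
      after <- filter_genes(filter_cells(before, thresholds_for(id)), policy)
      rep <- qc_report(before, after)
      write_qc_report(rep, file.path(qc_dir, id))
      run_summary$qc[[id]] <- list(cells = ncol(after$counts),
                                genes = nrow(after$counts))
      after
    }, logfile)
  }

  results <- list(datasets = filtered)
  if (isTRUE(config$analysis$bias) || is.null(config$analysis$bias)) {
    bias_dir <- file.path(out, "bias")
    dir.create(bias_dir, showWarnings = FALSE)
    for (id in names(filtered)) {
      results$bias[[id]] <- .stage(paste0("bias:", id), {
        gs <- gene_summaries(filtered[[id]], pseudocount = config$pseudocount,
                             n_bins = config$n_bins)
        write_stage_tsv(gs, file.path(bias_dir, paste0(id, "_gene_summaries.tsv")),
                        "per-gene mean log2 CPM, dropout rate, mean log2 RPKM, length bin")
        write_stage_tsv(bin_summaries(gs),
                        file.path(bias_dir, paste0(id, "_bin_summaries.tsv")),
                        "per-length-bin quartiles of the three statistics")
        stats <- length_bias_statistics(gs)
        jsonlite::write_json(as.list(stats),
                             file.path(bias_dir, paste0(id, "_bias_stats.json")),
                             auto_unbox = TRUE, digits = NA)
        run_summary$bias[[id]] <- as.list(stats)
        stats
      }, logfile)
    }
  }

  if (isTRUE(config$analysis$combine) && length(filtered) >= 2) {
    results$combined <- .stage("combine", {
      genes <- common_genes(filtered, config$min_cell_fraction)
      combined <- combine_datasets(filtered, genes)
      expr <- t(log_cpm(combined$counts, config$pseudocount))
      k <- min(3, nrow(expr) - 1, ncol(expr))
      emb <- pca_embedding(expr, k)
      coords <- data.frame(cell_id = combined$cells$cell_id,
                           dataset_id = combined$cells$dataset_id,
                           protocol = combined$cells$protocol,
                           emb$coordinates)
      dir.create(file.path(out, "combine"), showWarnings = FALSE)
      write_stage_tsv(coords, file.path(out, "combine", "pca_coordinates.tsv"),
                      "PCA embedding of cells on commonly detected genes")
      run_summary$combine <- list(n_common_genes = length(genes),
                               n_cells = ncol(combined$counts))
      list(genes = genes, combined = combined, pca = emb)
    }, logfile)
  }

  if (!is.null(config$analysis$overlap)) {
    results$overlap <- .stage("overlap", {
      ov_cfg <- config$analysis$overlap
      ga <- filtered[unlist(ov_cfg$group_a)]
      gb <- filtered[unlist(ov_cfg$group_b)]
      ov <- detection_overlap(ga, gb, config$min_cell_fraction)
      dir.create(file.path(out, "overlap"), showWarnings = FALSE)
      regions <- rbind(
        data.frame(gene_id = ov$genes_in_both, region = "in_both"),
        data.frame(gene_id = ov$genes_only_a, region = "only_a"),
        data.frame(gene_id = ov$genes_only_b, region = "only_b"))
      write_stage_tsv(regions, file.path(out, "overlap", "regions.tsv"),
                      "Venn region membership of detected genes")
      lengths <- stats::setNames(filtered[[1]]$genes$length_bp,
                                 filtered[[1]]$genes$gene_id)
      for (id in names(filtered))
        lengths[filtered[[id]]$genes$gene_id] <- filtered[[id]]$genes$length_bp
      wt <- if (ov$only_a >= 2 && ov$only_b >= 2)
        wilcoxon_rank_sum(lengths[ov$genes_only_a], lengths[ov$genes_only_b])
      else list(statistic = NA_real_, p_value = NA_real_, method = "skipped")
      res <- list(universe_size = ov$universe_size, in_both = ov$in_both,
                  only_a = ov$only_a, only_b = ov$only_b,
                  median_length_only_a =
                    stats::median(lengths[ov$genes_only_a]),
                  median_length_only_b =
                    stats::median(lengths[ov$genes_only_b]),
                  length_wilcoxon_p = wt$p_value)
      jsonlite::write_json(res, file.path(out, "overlap", "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      run_summary$overlap <- res
      c(list(overlap = ov), res)
    }, logfile)
  }

  if (!is.null(config$analysis$enrich) && !is.null(results$overlap)) {
    results$enrich <- .stage("enrich", {
      cats <- read_gmt(config$analysis$enrich$gmt)
      ov <- results$overlap$overlap
      lengths <- stats::setNames(filtered[[1]]$genes$length_bp,
                                 filtered[[1]]$genes$gene_id)
      dir.create(file.path(out, "enrich"), showWarnings = FALSE)
      res <- list()
      for (region in c("genes_only_a", "genes_only_b")) {
        if (length(ov[[region]]) == 0) next
        tab <- enrich(intersect(ov[[region]], ov$universe), cats,
                      ov$universe,
                      fdr_alpha = config$analysis$enrich$fdr_alpha %||% 0.05,
                      lengths = lengths)
        write_stage_tsv(tab, file.path(out, "enrich",
                                       paste0(region, "_enrichment.tsv")),
                        "hypergeometric enrichment with BH FDR")
        res[[region]] <- tab
      }
      run_summary$enrich <- lapply(res, function(t) sum(t$significant))
      res
    }, logfile)
  }

  if (!is.null(config$analysis$de)) {
    results$de <- .stage("de", {
      de_cfg <- config$analysis$de
      id <- de_cfg$dataset %||% names(filtered)[1]
      de <- de_two_group(filtered[[id]],
                         lfc_cutoff = de_cfg$lfc_cutoff %||% 0,
                         alpha = de_cfg$alpha %||% 0.05,
                         pseudocount = config$pseudocount)
      dir.create(file.path(out, "de"), showWarnings = FALSE)
      write_stage_tsv(de, file.path(out, "de", paste0(id, "_de.tsv")),
                      "two-group rank-sum DE with BH FDR and LFC cutoff")
      run_summary$de[[id]] <- list(n_significant = sum(de$significant),
                                n_tested = nrow(de))
      de
    }, logfile)
  }

  jsonlite::write_json(run_summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
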