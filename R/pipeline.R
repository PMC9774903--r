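#' Pipeline thresholds
#'
#' All stage thresholds in one place, at their conventional FPKM-scale
#' defaults: activity 1, constitutive-expression 1, top-rank fraction 0.25,
#' other-tissue sum ratio 0.5, fold change 3, particular-TSG silence
#' threshold 1, replicate filter 2 samples.
#'
#' @param activity_threshold FPKM activity cutoff.
#' @param min_samples Replicate-filter minimum.
#' @param hkg_threshold Constitutive-expression cutoff.
#' @param top_fraction,sum_ratio,fold TSG criteria.
#' @param silence_threshold Particular-TSG cutoff on tissue means.
#' @param top_particular_n Size of the reported particular-TSG shortlist.
#' @param network A [network_config()].
#' @return A list of class `pipeline_settings`.
#' @export
pipeline_settings <- function(activity_threshold = 1.0, min_samples = 2L,
                              hkg_threshold = 1.0, top_fraction = 0.25,
                              sum_ratio = 0.5, fold = 3.0,
                              silence_threshold = 1.0,
                              top_particular_n = 19L,
                              network = network_config()) {
  structure(list(activity_threshold = activity_threshold,
                 min_samples = as.integer(min_samples),
                 hkg_threshold = hkg_threshold,
                 top_fraction = top_fraction, sum_ratio = sum_ratio,
                 fold = fold, silence_threshold = silence_threshold,
                 top_particular_n = as.integer(top_particular_n),
                 network = network),
            class = "pipeline_settings")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full multi-tissue pipeline
#'
#' Executes every stage in order — replicate filter, per-tissue summaries
#' and activity report, tissue clustering, sample PCA, housekeeping-gene
#' detection and tiering, tissue-specific-gene detection with the
#' particular refinement, the weighted co-expression network, and (when
#' gene sets are supplied) over-representation tests of the per-tissue TSG
#' lists — writing one TSV per output plus a JSON run manifest with content
#' hashes.
#'
#' @param x An `ExpressionMatrix` with design, or a path to a matrix TSV
#'   (then `design` must be given).
#' @param out_dir Output directory (created if needed).
#' @param design Optional design path/table when `x` is a path or
#'   design-less.
#' @param gene_sets Optional named list of gene sets (e.g. [read_gmt()]);
#'   enables the enrichment stage.
#' @param settings A [pipeline_settings()].
#' @param run_network Set `FALSE` to skip the network stage.
#' @param network_genes Optional cap: when the network input would exceed
#'   this many genes, a deterministic subsample of this size (highest
#'   variance first) is used.
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_all <- function(x, out_dir, design = NULL, gene_sets = NULL,
                    settings = pipeline_settings(), run_network = TRUE,
                    network_genes = NULL) {
  if (is.character(x)) x <- read_expression_matrix(x)
  if (!is.null(design)) x <- attach_design(x, design)
  if (is.null(x$design)) stop("no design attached and none supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  res <- withCallingHandlers({
    run_all_stages(x, out_dir, gene_sets, settings, run_network,
                   network_genes)
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  res$manifest <- write_manifest(out_dir, settings, res, warnings_seen)
  invisible(res)
}

run_all_stages <- function(x, out_dir, gene_sets, settings, run_network,
                           network_genes) {
  files <- character(0)
  xf <- filter_min_expressed_samples(x, settings$min_samples)
  summary <- summarize_by_tissue(xf)
  files <- c(files, write_tsv(summary, file.path(out_dir, "tissue_summary.tsv")))
  act <- activity_report(x, settings$activity_threshold)
  files <- c(files, write_tsv(act, file.path(out_dir, "activity_report.tsv")))
  clus <- tissue_correlation_clustering(summary)
  writeLines(clus$newick, file.path(out_dir, "tissue_dendrogram.nwk"))
  files <- c(files, file.path(out_dir, "tissue_dendrogram.nwk"))
  cor_df <- data.frame(tissue = rownames(clus$correlation),
                       clus$correlation, check.names = FALSE,
                       stringsAsFactors = FALSE)
  files <- c(files, write_tsv(cor_df, file.path(out_dir, "tissue_correlations.tsv")))
  pca <- sample_pca(x, settings$activity_threshold)
  pca_df <- data.frame(sample_id = rownames(pca$scores),
                       tissue = unname(x$design[rownames(pca$scores)]),
                       pca$scores, check.names = FALSE,
                       stringsAsFactors = FALSE)
  files <- c(files, write_tsv(pca_df, file.path(out_dir, "pca_scores.tsv")))
  files <- c(files, write_tsv(
    data.frame(component = seq_along(pca$var_explained),
               var_explained = pca$var_explained),
    file.path(out_dir, "pca_variance.tsv")))

  hkg <- detect_hkg(summary, matrix = xf, threshold = settings$hkg_threshold)
  files <- c(files, write_tsv(hkg, file.path(out_dir, "hkg_table.tsv")))
  shortlist <- hkg_shortlist(hkg)
  files <- c(files, write_tsv(shortlist, file.path(out_dir, "hkg_shortlist.tsv")))

  tsg <- detect_tsg(summary, settings$top_fraction, settings$sum_ratio,
                    settings$fold)
  tsg <- detect_particular_tsg(tsg, summary, settings$silence_threshold)
  files <- c(files, write_tsv(tsg, file.path(out_dir, "tsg_table.tsv")))
  counts <- tsg_counts_by_tissue(tsg)
  files <- c(files, write_tsv(counts, file.path(out_dir, "tsg_counts.tsv")))
  files <- c(files, write_tsv(top_particular_tsg(tsg, settings$top_particular_n),
                              file.path(out_dir, "particular_tsg_top.tsv")))

  net <- NULL
  if (run_network) {
    xn <- xf
    if (!is.null(network_genes)) {
      cand <- filter_for_network(xf, min_genes = settings$network$min_module_size)
      if (nrow(cand$values) > network_genes) {
        vars <- apply(log_fpkm(cand), 1, stats::var)
        keep <- names(sort(vars, decreasing = TRUE))[seq_len(network_genes)]
        keep <- rownames(cand$values)[rownames(cand$values) %in% keep]
        xn$values <- cand$values[keep, , drop = FALSE]
      }
    }
    net <- build_coexpression_network(xn, settings$network)
    assign_df <- data.frame(gene_id = names(net$modules$assignment),
                            module_id = unname(net$modules$assignment),
                            stringsAsFactors = FALSE)
    files <- c(files, write_tsv(assign_df, file.path(out_dir, "module_assignments.tsv")))
    eg <- net$modules$eigengenes
    eg_df <- data.frame(sample_id = rownames(eg), eg, check.names = FALSE,
                        stringsAsFactors = FALSE)
    files <- c(files, write_tsv(eg_df, file.path(out_dir, "module_eigengenes.tsv")))
    files <- c(files, write_tsv(net$trait_table, file.path(out_dir, "module_trait.tsv")))
    files <- c(files, write_tsv(net$hub_table, file.path(out_dir, "hub_genes.tsv")))
    if (!is.null(net$fit_table))
      files <- c(files, write_tsv(net$fit_table,
                                  file.path(out_dir, "soft_threshold_fit.tsv")))
  }

  enrich <- NULL
  if (!is.null(gene_sets)) {
    groups <- split(tsg$gene_id[tsg$is_tsg], tsg$tissue[tsg$is_tsg])
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    if (length(groups)) {
      universe <- unique(summary$gene_id)
      enrich <- enrich_gene_groups(groups, gene_sets, universe)
      for (g in names(enrich)) {
        fn <- file.path(out_dir, paste0("enrichment_", g, ".tsv"))
        files <- c(files, write_tsv(enrich[[g]], fn))
      }
    }
  }

  list(filtered = xf, summary = summary, activity = act, clustering = clus,
       pca = pca, hkg = hkg, hkg_shortlist = shortlist, tsg = tsg,
       tsg_counts = counts, network = net, enrichment = enrich,
       files = files, out_dir = out_dir)
}

write_manifest <- function(out_dir, settings, res, warnings_seen,
                           extra = list()) {
  files <- sort(unique(res$files))
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(files)
  manifest <- c(list(
    package = "multitissue",
    version = as.character(utils::packageVersion("multitissue")),
    settings = settings_snapshot(settings),
    stages = list(
      profile = basename(files[grepl("tissue_|activity|pca", basename(files))]),
      hkg = basename(files[grepl("hkg", basename(files))]),
      tsg = basename(files[grepl("tsg|particular", basename(files))]),
      network = basename(files[grepl("module|hub|soft_threshold", basename(files))]),
      enrichment = basename(files[grepl("enrichment", basename(files))])),
    files = hashes,
    warnings = warnings_seen), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

settings_snapshot <- function(settings) {
  s <- unclass(settings)
  s$network <- unclass(s$network)
  s$network$beta_candidates <-
    paste(range(s$network$beta_candidates), collapse = ":")
  s
}

#' Generate synthetic data, run the pipeline, score recovery
#'
#' Writes the synthetic expression matrix, design and ground truth, runs
#' [run_all()] on them, evaluates precision/recall of the housekeeping,
#' tissue-specific and module calls against the planted truth, and records
#' everything (with file hashes) in the run manifest.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory.
#' @param settings A [pipeline_settings()].
#' @param gene_sets Optional gene sets for the enrichment stage.
#' @param run_network Set `FALSE` to skip the network stage.
#' @param network_genes Optional network-size cap (see [run_all()]).
#' @return Invisibly, the [run_all()] result list plus `synthetic` (the
#'   generated data) and `recovery` (per-role metrics).
#' @export
run_synthetic <- function(config = synth_config(), out_dir,
                          settings = pipeline_settings(), gene_sets = NULL,
                          run_network = TRUE, network_genes = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  synth <- generate_synthetic_expression(config)
  mat_path <- file.path(out_dir, "expression_matrix.tsv")
  write_expression_matrix(synth$matrix, mat_path)
  des_path <- file.path(out_dir, "design.tsv")
  write_design(synth$matrix$design, des_path)
  truth_path <- file.path(out_dir, "ground_truth.tsv")
  write_tsv(synth$truth, truth_path)

  warnings_seen <- character(0)
  res <- withCallingHandlers({
    run_all_stages(synth$matrix, out_dir, gene_sets, settings, run_network,
                   network_genes)
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  res$files <- c(res$files, mat_path, des_path, truth_path)
  res$synthetic <- synth
  res$recovery <- score_recovery(res, synth$truth)
  res$manifest <- write_manifest(
    out_dir, settings, res, warnings_seen,
    extra = list(seed = config$seed, synth_config = unclass(config),
                 recovery = res$recovery))
  invisible(res)
}

score_recovery <- function(res, truth) {
  out <- list()
  hkg_calls <- res$hkg$gene_id
  out$hkg <- truth_eval(hkg_calls, truth, "hkg")
  tsg_calls <- res$tsg$gene_id[res$tsg$is_tsg]
  out$tsg <- truth_eval(tsg_calls, truth, "tsg")
  # tissue assignment correctness among recovered planted TSGs
  tt <- truth[truth$role == "tsg", ]
  hit <- res$tsg[res$tsg$is_tsg & res$tsg$gene_id %in% tt$gene_id, ]
  out$tsg$correct_tissue_fraction <- if (nrow(hit))
    mean(hit$tissue == tt$target_tissue[match(hit$gene_id, tt$gene_id)])
  else NA_real_
  if (!is.null(res$network)) {
    mt <- truth[truth$role == "module", ]
    detected <- res$network$modules$assignment[mt$gene_id]
    detected[is.na(detected)] <- "unfiltered"
    out$module <- list(
      ari = mclust::adjustedRandIndex(detected, mt$module_id),
      n_modules = length(res$network$modules$modules),
      n_hubs = sum(res$network$hub_table$is_hub))
  }
  out
}
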