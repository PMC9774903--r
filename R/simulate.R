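PIG_TISSUES <- c("backfat", "gallbladder", "heart", "ileum", "jejunum",
                 "kidney", "liver", "longissimus_dorsi", "lung", "muscle",
                 "ovary", "endocrine_brain", "skeletal_muscle", "spleen")

# per-tissue sample counts of the motivating 609-sample pig panel
PIG_SAMPLE_COUNTS <- c(backfat = 31, gallbladder = 19, heart = 28,
                       ileum = 27, jejunum = 21, kidney = 16, liver = 63,
                       longissimus_dorsi = 96, lung = 77, muscle = 28,
                       ovary = 56, endocrine_brain = 27,
                       skeletal_muscle = 91, spleen = 46)

#' Synthetic-data configuration
#'
#' Defaults emulate a 14-tissue pig expression panel at desk scale:
#' 5 replicate samples per tissue and 3740 genes split into 500 planted
#' housekeeping genes, 500 planted single-tissue-specific genes, 4 planted
#' co-expression modules of 60 genes each (tied to distinct tissues),
#' 2000 background genes and 500 inactive genes (FPKM < 1 everywhere).
#' Replicate noise is multiplicative log2-normal with sd 0.25.
#'
#' @param n_tissues Number of tissues (default 14; up to 14 draws pig
#'   tissue names, beyond that generic labels).
#' @param samples_per_tissue Scalar or per-tissue integer vector of
#'   replicate counts (default 5).
#' @param n_hkg,n_tsg,n_background,n_inactive Gene counts per role.
#' @param n_modules,module_size Planted co-expression modules (default
#'   4 x 60).
#' @param noise_sd_log2 Replicate noise sd on the log2 scale (default 0.25).
#' @param seed Integer seed; fully determines the dataset.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_tissues = 14L, samples_per_tissue = 5L,
                         n_hkg = 500L, n_tsg = 500L, n_modules = 4L,
                         module_size = 60L, n_background = 2000L,
                         n_inactive = 500L, noise_sd_log2 = 0.25,
                         seed = 1L) {
  stopifnot(n_tissues >= 2, all(samples_per_tissue >= 1),
            n_hkg >= 0, n_tsg >= 0, n_modules >= 0, module_size >= 0,
            n_background >= 0, n_inactive >= 0, noise_sd_log2 > 0,
            n_modules <= n_tissues)
  if (length(samples_per_tissue) == 1L)
    samples_per_tissue <- rep(as.integer(samples_per_tissue), n_tissues)
  if (length(samples_per_tissue) != n_tissues)
    stop("samples_per_tissue must be scalar or one count per tissue")
  tissue_names <- if (n_tissues <= length(PIG_TISSUES))
    PIG_TISSUES[seq_len(n_tissues)]
  else paste0("tissue", sprintf("%02d", seq_len(n_tissues)))
  structure(list(n_tissues = as.integer(n_tissues),
                 samples_per_tissue = as.integer(samples_per_tissue),
                 tissue_names = tissue_names,
                 n_hkg = as.integer(n_hkg), n_tsg = as.integer(n_tsg),
                 n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 n_background = as.integer(n_background),
                 n_inactive = as.integer(n_inactive),
                 noise_sd_log2 = noise_sd_log2, seed = as.integer(seed)),
            class = "synth_config")
}

#' Paper-scale synthetic preset
#'
#' Structural stress-test preset: 28,000 genes over the pig panel's
#' per-tissue sample counts (626 samples in 14 tissues as printed in the
#' source panel's collection table). Role counts are scaled to keep the
#' share of constitutive and tissue-specific genes realistic.
#'
#' @param seed Integer seed.
#' @return A `synth_config`.
#' @export
paper_scale_config <- function(seed = 1L) {
  synth_config(n_tissues = 14L,
               samples_per_tissue = unname(PIG_SAMPLE_COUNTS),
               n_hkg = 2400L, n_tsg = 3000L,
               n_modules = 4L, module_size = 60L,
               n_background = 13360L, n_inactive = 9000L,
               seed = seed)
}

#' Generate a synthetic multi-tissue FPKM matrix with ground truth
#'
#' Planted structure, per role:
#' * **hkg** — a per-gene base level drawn log-uniform in \[5, 200\] FPKM,
#'   identical in every tissue, with multiplicative log2-normal replicate
#'   noise, so the across-tissue CV is small by construction;
#' * **tsg** — a target tissue (assigned round-robin) with mean drawn
#'   log-uniform in \[20, 500\]; every other sample drawn uniform in
#'   \[0, 0.5\], below the FPKM < 1 activity rule;
#' * **module** — each of the planted modules is tied to one tissue through
#'   a latent sample vector (tissue indicator plus 0.3 x standard-normal
#'   noise); a member gene is loading x latent + noise on the log2 scale
#'   (loading uniform in \[0.5, 1\]), mapped to FPKM via 2^x and scaled so
#'   the assigned tissue's samples all exceed 1;
#' * **background** — independent per-tissue means log-uniform in
#'   \[0.5, 50\] with replicate noise;
#' * **inactive** — every sample uniform in \[0, 0.9\].
#'
#' Values are rounded to 4 decimals; the RNG is fully determined by
#' `config$seed`, so the same configuration reproduces the matrix
#' bit-for-bit.
#'
#' @param config A [synth_config()].
#' @return List with `matrix` (an `ExpressionMatrix` with design), `truth`
#'   (data.frame: `gene_id`, `role`, `target_tissue`, `module_id`) and
#'   `config`.
#' @export
generate_synthetic_expression <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n_genes <- with(config, n_hkg + n_tsg + n_modules * module_size +
                            n_background + n_inactive)
  if (n_genes == 0) stop("configuration yields zero genes")
  set.seed(config$seed)
  tis <- config$tissue_names
  tissue_of_sample <- rep(tis, config$samples_per_tissue)
  s <- length(tissue_of_sample)
  sample_ids <- unlist(lapply(seq_along(tis), function(i)
    paste0(tis[i], "_s", seq_len(config$samples_per_tissue[i]))))
  design <- stats::setNames(tissue_of_sample, sample_ids)
  noise_sd <- config$noise_sd_log2
  luni <- function(n, lo, hi) 2^stats::runif(n, log2(lo), log2(hi))

  blocks <- list(); roles <- list()
  # constitutive genes
  if (config$n_hkg > 0) {
    base <- luni(config$n_hkg, 5, 200)
    eps <- matrix(stats::rnorm(config$n_hkg * s, 0, noise_sd), config$n_hkg)
    blocks$hkg <- base * 2^eps
    roles$hkg <- data.frame(role = "hkg", target_tissue = NA_character_,
                            module_id = NA_character_,
                            stringsAsFactors = FALSE)[rep(1, config$n_hkg), ]
  }
  # single-tissue-specific genes
  if (config$n_tsg > 0) {
    target <- tis[((seq_len(config$n_tsg) - 1) %% length(tis)) + 1]
    m <- luni(config$n_tsg, 20, 500)
    vals <- matrix(stats::runif(config$n_tsg * s, 0, 0.5), config$n_tsg)
    for (i in seq_len(config$n_tsg)) {
      in_t <- tissue_of_sample == target[i]
      vals[i, in_t] <- m[i] * 2^stats::rnorm(sum(in_t), 0, noise_sd)
    }
    blocks$tsg <- vals
    roles$tsg <- data.frame(role = "tsg", target_tissue = target,
                            module_id = NA_character_,
                            stringsAsFactors = FALSE)
  }
  # planted co-expression modules, one tissue each
  if (config$n_modules > 0 && config$module_size > 0) {
    mod_tissue <- tis[seq_len(config$n_modules)]
    vals <- matrix(NA_real_, config$n_modules * config$module_size, s)
    loadings <- numeric(nrow(vals))
    mod_id <- character(nrow(vals))
    row <- 0L
    for (mm in seq_len(config$n_modules)) {
      latent <- as.numeric(tissue_of_sample == mod_tissue[mm]) +
        0.3 * stats::rnorm(s)
      in_t <- tissue_of_sample == mod_tissue[mm]
      for (g in seq_len(config$module_size)) {
        row <- row + 1L
        u <- stats::runif(1, 0.5, 1)
        x <- u * latent + stats::rnorm(s, 0, noise_sd)
        floor_fpkm <- luni(1, 2, 20)
        vals[row, ] <- floor_fpkm / min(2^x[in_t]) * 2^x
        loadings[row] <- u
        mod_id[row] <- paste0("planted", mm)
      }
    }
    blocks$module <- vals
    roles$module <- data.frame(
      role = "module",
      target_tissue = rep(mod_tissue, each = config$module_size),
      module_id = mod_id, stringsAsFactors = FALSE)
    attr_loadings <- loadings
  } else attr_loadings <- numeric(0)
  # background genes: independent per-tissue means
  if (config$n_background > 0) {
    mt <- matrix(luni(config$n_background * length(tis), 0.5, 50),
                 config$n_background)
    eps <- matrix(stats::rnorm(config$n_background * s, 0, noise_sd),
                  config$n_background)
    blocks$background <- mt[, match(tissue_of_sample, tis)] * 2^eps
    roles$background <- data.frame(
      role = "background", target_tissue = NA_character_,
      module_id = NA_character_,
      stringsAsFactors = FALSE)[rep(1, config$n_background), ]
  }
  # inactive genes: below the FPKM < 1 rule everywhere
  if (config$n_inactive > 0) {
    blocks$inactive <- matrix(stats::runif(config$n_inactive * s, 0, 0.9),
                              config$n_inactive)
    roles$inactive <- data.frame(
      role = "inactive", target_tissue = NA_character_,
      module_id = NA_character_,
      stringsAsFactors = FALSE)[rep(1, config$n_inactive), ]
  }

  values <- do.call(rbind, blocks)
  values <- round(values, 4)
  gene_ids <- sprintf("gene%0*d", nchar(as.character(n_genes)),
                      seq_len(n_genes))
  dimnames(values) <- list(gene_ids, sample_ids)
  truth <- do.call(rbind, roles)
  truth <- data.frame(gene_id = gene_ids, truth,
                      row.names = NULL, stringsAsFactors = FALSE)
  if (length(attr_loadings))
    truth$loading <- c(rep(NA_real_, config$n_hkg + config$n_tsg),
                       attr_loadings,
                       rep(NA_real_, config$n_background + config$n_inactive))
  list(matrix = ExpressionMatrix(values, design = design),
       truth = truth, config = config)
}

#' Precision and recall of calls against planted truth
#'
#' @param calls Character vector of gene ids called positive.
#' @param truth Ground-truth table from [generate_synthetic_expression()].
#' @param role Role whose planted genes are the positive set.
#' @return List with `precision` (`NA` with a flag when no calls), `recall`
#'   (`NA` with a flag when the role has no planted genes), `tp`, `fp`,
#'   `fn`, and `flag` (character; `""` when both are defined).
#' @export
truth_eval <- function(calls, truth, role) {
  positives <- truth$gene_id[truth$role == role]
  calls <- unique(calls)
  tp <- length(intersect(calls, positives))
  fp <- length(setdiff(calls, positives))
  fn <- length(setdiff(positives, calls))
  flag <- character(0)
  precision <- if (length(calls)) tp / length(calls) else NA_real_
  if (!length(calls)) flag <- c(flag, "no calls: precision undefined")
  recall <- if (length(positives)) tp / length(positives) else NA_real_
  if (!length(positives))
    flag <- c(flag, paste0("no planted '", role, "' genes: recall undefined"))
  list(precision = precision, recall = recall, tp = tp, fp = fp, fn = fn,
       flag = paste(flag, collapse = "; "))
}
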