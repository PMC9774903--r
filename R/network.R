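#' Co-expression network configuration
#'
#' Bundles the tunable thresholds of the weighted co-expression network
#' stage. Defaults follow common practice for tissue-panel FPKM data:
#' soft-threshold candidates 1..20 with a scale-free fit target of 0.8,
#' minimum module size 30, eigengene merge cut height 0.25, module-tissue
#' correlation threshold 0.65, and hub-gene thresholds |GS| > 0.2,
#' |MM| > 0.8.
#'
#' @param beta_candidates Integer vector of soft-threshold powers to try.
#' @param rsq_target Scale-free topology fit target (signed R^2).
#' @param min_module_size Smallest gene count for a retained module.
#' @param merge_cut_height Eigengene dissimilarity (1 - r) below which
#'   modules are merged.
#' @param tissue_module_r Module-tissue Pearson correlation above which a
#'   module counts as tissue-specific (one-sided, positive).
#' @param gs_min,mm_min Hub-gene thresholds on |gene significance| and
#'   |module membership|.
#' @param cut_height Absolute dissimilarity (1 - TOM) height at which the
#'   gene dendrogram is cut into modules (default 0.98: merges driven by
#'   unrelated genes saturate within a few percent of the maximal
#'   dissimilarity 1, so structured subtrees complete below this height).
#' @param adjacency_type `"unsigned"` (|cor|^beta, default) or `"signed"`
#'   (((1 + cor)/2)^beta).
#' @param beta Optional fixed soft threshold; when `NULL` (default) it is
#'   chosen by [pick_soft_threshold()].
#' @param max_genes Hard cap on network size; larger inputs are an error.
#' @return A list of class `network_config`.
#' @export
network_config <- function(beta_candidates = 1:20, rsq_target = 0.8,
                           min_module_size = 30L, merge_cut_height = 0.25,
                           tissue_module_r = 0.65, gs_min = 0.2,
                           mm_min = 0.8, cut_height = 0.98,
                           adjacency_type = c("unsigned", "signed"),
                           beta = NULL, max_genes = 20000L) {
  adjacency_type <- match.arg(adjacency_type)
  stopifnot(length(beta_candidates) >= 1, all(beta_candidates >= 1),
            rsq_target > 0, rsq_target <= 1,
            min_module_size >= 2,
            merge_cut_height >= 0, merge_cut_height < 1,
            tissue_module_r > 0, tissue_module_r < 1,
            gs_min >= 0, gs_min < 1, mm_min >= 0, mm_min < 1,
            cut_height > 0, cut_height <= 1)
  structure(list(beta_candidates = as.integer(beta_candidates),
                 rsq_target = rsq_target,
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height,
                 tissue_module_r = tissue_module_r,
                 gs_min = gs_min, mm_min = mm_min,
                 cut_height = cut_height,
                 adjacency_type = adjacency_type,
                 beta = beta, max_genes = as.integer(max_genes)),
            class = "network_config")
}

#' Expression filter for network construction
#'
#' Default mode retains genes with FPKM > 1 in every sample of at least one
#' tissue; strict mode requires FPKM > 1 in every sample of every tissue.
#' The strict-mode result is always a subset of the default-mode result.
#'
#' @param x An `ExpressionMatrix` with design.
#' @param mode `"any_tissue"` (default) or `"all_tissues"` (strict).
#' @param threshold FPKM cutoff (default 1, strict inequality).
#' @param min_genes Error if fewer genes survive (defaults to the usual
#'   minimum module size, 30).
#' @return Filtered `ExpressionMatrix` with a `filter_mode` attribute.
#' @export
filter_for_network <- function(x, mode = c("any_tissue", "all_tissues"),
                               threshold = 1.0, min_genes = 30L) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(x$design)) stop("no design attached")
  v <- x$values
  per_tissue <- sapply(tissues(x), function(t) {
    sub <- v[, tissue_samples(x, t), drop = FALSE]
    rowSums(sub > threshold) == ncol(sub)
  })
  keep <- if (mode == "any_tissue") rowSums(per_tissue) >= 1
          else rowSums(per_tissue) == ncol(per_tissue)
  if (sum(keep) < min_genes)
    stop(sum(keep), " gene(s) pass the '", mode,
         "' network filter but >= ", min_genes, " are needed; ",
         "consider mode = 'any_tissue' or a lower threshold")
  x$values <- v[keep, , drop = FALSE]
  attr(x, "filter_mode") <- mode
  x
}

#' log2(FPKM + 1) transform
#' @param x An `ExpressionMatrix` or numeric matrix.
#' @return Numeric matrix of log2(value + 1).
#' @export
log_fpkm <- function(x) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else x
  log2(v + 1)
}

#' Soft-thresholded adjacency
#'
#' Pairwise gene adjacency from Pearson correlations over samples:
#' unsigned `|cor|^beta` or signed `((1 + cor)/2)^beta`. The diagonal is set
#' to zero so that row sums equal network connectivity.
#'
#' @param lexpr Genes x samples matrix (log scale).
#' @param beta Soft-threshold power.
#' @param type `"unsigned"` or `"signed"`.
#' @return Symmetric gene x gene matrix with zero diagonal.
#' @export
adjacency_matrix <- function(lexpr, beta, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  sds <- apply(lexpr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from the network: ",
            paste(utils::head(rownames(lexpr)[sds == 0], 5), collapse = ", "),
            if (sum(sds == 0) > 5) ", ..." else "")
    lexpr <- lexpr[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(lexpr), method = "pearson")
  a <- if (type == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit index
#'
#' Bins the connectivity distribution into `n_bins` equal-width bins,
#' regresses log10(bin frequency) on log10(mean connectivity per bin) and
#' returns -sign(slope) * R^2, so an index near 1 indicates a decreasing
#' power-law-like degree distribution. Empty bins enter at their midpoint
#' with a vanishing frequency floor (1e-9), following the field-standard
#' formulation of the index.
#'
#' @param k Numeric vector of connectivities.
#' @param n_bins Number of bins (default 10).
#' @return List with `fit` (signed R^2, `NA` when the distribution is
#'   degenerate), `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  if (brk[1] == brk[n_bins + 1] || length(unique(k)) < 3)
    return(list(fit = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- as.numeric(tapply(k, bin, mean))
  mids <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  kmean[is.na(kmean) | kmean == 0] <- mids[is.na(kmean) | kmean == 0]
  usable <- kmean > 0
  if (sum(usable) < 2) return(list(fit = NA_real_, slope = NA_real_))
  fitlm <- stats::lm(log10(freq[usable] + 1e-9) ~ log10(kmean[usable]))
  r2 <- summary(fitlm)$r.squared
  slope <- unname(stats::coef(fitlm)[2])
  if (is.na(slope)) return(list(fit = NA_real_, slope = NA_real_))
  list(fit = -sign(slope) * r2, slope = slope)
}

#' Choose the soft-threshold power
#'
#' Evaluates each candidate power: builds the adjacency, computes
#' connectivity `k_i = sum_j a_ij`, and measures the scale-free fit index of
#' the degree distribution. Returns the smallest power whose fit exceeds
#' `rsq_target`; if none does, the power with maximal fit, with a warning.
#'
#' @param lexpr Genes x samples matrix (log scale).
#' @param config A [network_config()].
#' @return List with `beta`, `rsq`, and `fit_table` (one row per candidate:
#'   `beta`, `fit`, `slope`, `mean_k`, `max_k`).
#' @export
pick_soft_threshold <- function(lexpr, config = network_config()) {
  if (nrow(lexpr) < 2) stop("need >= 2 genes")
  if (ncol(lexpr) < 3) stop("need >= 3 samples")
  sds <- apply(lexpr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from soft-threshold search")
    lexpr <- lexpr[sds > 0, , drop = FALSE]
  }
  cc <- abs(stats::cor(t(lexpr), method = "pearson"))
  diag(cc) <- 0
  if (config$adjacency_type == "signed") {
    cc_raw <- stats::cor(t(lexpr), method = "pearson")
    cc <- (1 + cc_raw) / 2
    diag(cc) <- 0
  }
  rows <- lapply(config$beta_candidates, function(b) {
    k <- rowSums(cc^b)
    sf <- scale_free_fit(k)
    data.frame(beta = b, fit = sf$fit, slope = sf$slope,
               mean_k = mean(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$fit)
  if (!any(ok))
    stop("scale-free fit undefined for every candidate power ",
         "(degree distribution collapses to < 2 bins)")
  hit <- ok & tab$fit > config$rsq_target
  if (any(hit)) {
    i <- which(hit)[1]
  } else {
    i <- which.max(ifelse(ok, tab$fit, -Inf))
    warning(sprintf(
      "no candidate power reaches fit > %.2f; using beta = %d (fit %.3f)",
      config$rsq_target, tab$beta[i], tab$fit[i]))
  }
  list(beta = tab$beta[i], rsq = tab$fit[i], fit_table = tab)
}

#' Topological overlap matrix
#'
#' Unsigned TOM: for i != j,
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is 1.
#' Entries lie in \[0, 1\] and measure shared network neighborhood on top of
#' direct adjacency.
#'
#' @param adj Symmetric adjacency matrix with entries in \[0, 1\]; a nonzero
#'   diagonal is zeroed before the computation.
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix")
  if (max(abs(adj - t(adj))) > 1e-8)
    stop("adjacency must be symmetric")
  diag(adj) <- 0
  if (any(adj < 0) || any(adj > 1))
    stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(adj)
  l <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  # exact symmetry despite floating-point matmul asymmetries
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' cut at the fixed height `config$cut_height`; clusters below
#' `min_module_size` stay unassigned ("grey").
#' Modules are labelled `M1`, `M2`, ... by decreasing size, ties broken by
#' first gene position.
#'
#' @param tom Topological overlap matrix.
#' @param config A [network_config()].
#' @return A `module_set` list: `modules` (named list of gene id vectors),
#'   `unassigned`, `assignment` (named vector gene -> module or "grey"),
#'   `cut_height`, `hclust`.
#' @export
detect_modules <- function(tom, config = network_config()) {
  if (is.null(rownames(tom))) stop("TOM must carry gene ids as dimnames")
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cut_h <- config$cut_height
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= config$min_module_size]
  if (!length(big))
    warning("no cluster reaches min_module_size = ", config$min_module_size,
            "; all genes left unassigned")
  # order retained clusters by decreasing size, then first occurrence
  first_pos <- vapply(big, function(b) min(which(cl == as.integer(b))),
                      integer(1))
  ord <- order(-as.integer(sizes[big]), first_pos)
  big <- big[ord]
  assignment <- stats::setNames(rep("grey", length(cl)), names(cl))
  modules <- list()
  for (i in seq_along(big)) {
    id <- paste0("M", i)
    genes <- names(cl)[cl == as.integer(big[i])]
    modules[[id]] <- genes
    assignment[genes] <- id
  }
  structure(list(modules = modules,
                 unassigned = names(cl)[assignment == "grey"],
                 assignment = assignment,
                 cut_height = cut_h,
                 hclust = hc),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules, %d assigned / %d genes\n",
              length(x$modules),
              sum(x$assignment != "grey"), length(x$assignment)))
  if (length(x$modules)) {
    sz <- vapply(x$modules, length, integer(1))
    cat(paste(sprintf("%s(%d)", names(sz), sz), collapse = " "), "\n")
  }
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix:
#' each gene is centered and scaled to unit variance across samples, and the
#' eigengene is the leading right singular vector (unit norm over samples),
#' signed so that the mean correlation with member genes is positive.
#'
#' @param expr Module genes x samples matrix (log scale).
#' @return List with `eigengene` (named numeric vector over samples),
#'   `var_explained`, `n_genes_used`.
#' @export
module_eigengene <- function(expr) {
  if (nrow(expr) < 2) stop("module eigengene needs >= 2 genes")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped from eigengene computation")
    expr <- expr[sds > 0, , drop = FALSE]
    if (nrow(expr) < 2) stop("fewer than 2 non-constant genes in module")
  }
  z <- t(scale(t(expr)))
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (mean(z %*% e) < 0) e <- -e
  names(e) <- colnames(expr)
  list(eigengene = e,
       var_explained = sv$d[1]^2 / sum(sv$d^2),
       n_genes_used = nrow(expr))
}

# eigengene matrix (samples x modules) for every module in a module_set
compute_module_eigengenes <- function(modules, lexpr) {
  if (!length(modules$modules)) {
    modules$eigengenes <- matrix(numeric(0), nrow = ncol(lexpr), ncol = 0,
                                 dimnames = list(colnames(lexpr), NULL))
    modules$var_explained <- numeric(0)
    return(modules)
  }
  egs <- lapply(modules$modules, function(g)
    module_eigengene(lexpr[g, , drop = FALSE]))
  modules$eigengenes <- do.call(cbind, lapply(egs, `[[`, "eigengene"))
  colnames(modules$eigengenes) <- names(modules$modules)
  modules$var_explained <- vapply(egs, `[[`, numeric(1), "var_explained")
  modules
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the most correlated eigengenes
#' while their dissimilarity 1 - cor falls below `merge_cut_height`,
#' recomputing the merged eigengene after every merge, until a fixpoint.
#' Modules are then relabelled `M1`, `M2`, ... by decreasing size.
#'
#' @param modules A `module_set` (eigengenes are computed if absent).
#' @param lexpr Genes x samples matrix used for eigengene recomputation.
#' @param config A [network_config()].
#' @return The merged `module_set` with updated eigengenes.
#' @export
merge_close_modules <- function(modules, lexpr, config = network_config()) {
  if (is.null(modules$eigengenes))
    modules <- compute_module_eigengenes(modules, lexpr)
  mods <- modules$modules
  while (length(mods) >= 2) {
    e <- do.call(cbind, lapply(mods, function(g)
      module_eigengene(lexpr[g, , drop = FALSE])$eigengene))
    cc <- stats::cor(e)
    diag(cc) <- -Inf
    i <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - cc[i[1], i[2]] >= config$merge_cut_height) break
    a <- min(i); b <- max(i)
    mods[[a]] <- c(mods[[a]], mods[[b]])
    mods[[b]] <- NULL
  }
  # relabel by decreasing size, stable on first gene position
  gene_pos <- stats::setNames(seq_along(modules$assignment),
                              names(modules$assignment))
  ord <- order(-vapply(mods, length, integer(1)),
               vapply(mods, function(g) min(gene_pos[g]), numeric(1)))
  mods <- mods[ord]
  names(mods) <- paste0("M", seq_along(mods))
  out <- modules
  out$modules <- mods
  out$assignment[] <- "grey"
  for (id in names(mods)) out$assignment[mods[[id]]] <- id
  out$unassigned <- names(out$assignment)[out$assignment == "grey"]
  compute_module_eigengenes(out, lexpr)
}

#' Module-tissue association
#'
#' Pearson correlation between each module eigengene and each tissue's
#' binary sample indicator, with a Student-t p-value on S - 2 degrees of
#' freedom. A module is called tissue-specific for a tissue when
#' r > `tissue_module_r` (one-sided, positive, as is conventional for
#' trait indicators). A Benjamini-Hochberg column over the whole table is
#' included for transparency; the threshold rule uses raw r only.
#'
#' @param modules A `module_set` with eigengenes.
#' @param design Named character vector sample -> tissue covering the
#'   eigengene samples.
#' @param config A [network_config()].
#' @return data.frame with columns `module_id`, `tissue`, `r`, `p`, `p_bh`,
#'   `is_tissue_specific`.
#' @export
module_trait_association <- function(modules, design,
                                     config = network_config()) {
  e <- modules$eigengenes
  if (is.null(e)) stop("modules carry no eigengenes; run compute first")
  smp <- rownames(e)
  tis <- unique(unname(design[smp]))
  s <- length(smp)
  rows <- list()
  for (mod in colnames(e)) {
    for (t in tis) {
      ind <- as.numeric(unname(design[smp]) == t)
      if (stats::sd(ind) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          module_id = mod, tissue = t, r = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      r <- stats::cor(e[, mod], ind)
      p <- cor_t_pvalue(r, s)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = mod, tissue = t, r = r, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module_id = character(), tissue = character(),
                      r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$is_tissue_specific <- !is.na(out$r) & out$r > config$tissue_module_r
  out
}

# two-sided p for a Pearson correlation via the t transform, n - 2 df
cor_t_pvalue <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(.Machine$double.xmin)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Hub genes of tissue-specific modules
#'
#' For every (module, tissue) pair flagged tissue-specific, computes for
#' each member gene its gene significance GS (correlation with the tissue
#' indicator) and module membership MM (correlation with the module
#' eigengene); a gene is a hub when |GS| > `gs_min` and |MM| > `mm_min`.
#'
#' @param modules A `module_set` with eigengenes.
#' @param lexpr Genes x samples matrix (log scale).
#' @param design Named character vector sample -> tissue.
#' @param trait_table Output of [module_trait_association()].
#' @param config A [network_config()].
#' @return data.frame with columns `gene_id`, `module_id`, `tissue`, `gs`,
#'   `mm`, `is_hub`; empty (with a warning) when no module is
#'   tissue-specific.
#' @export
call_hub_genes <- function(modules, lexpr, design, trait_table,
                           config = network_config()) {
  ts <- trait_table[trait_table$is_tissue_specific, , drop = FALSE]
  empty <- data.frame(gene_id = character(), module_id = character(),
                      tissue = character(), gs = numeric(), mm = numeric(),
                      is_hub = logical(), stringsAsFactors = FALSE)
  if (!nrow(ts)) {
    warning("no tissue-specific module at r > ", config$tissue_module_r,
            "; empty hub table")
    return(empty)
  }
  smp <- rownames(modules$eigengenes)
  rows <- lapply(seq_len(nrow(ts)), function(i) {
    mod <- ts$module_id[i]; t <- ts$tissue[i]
    genes <- modules$modules[[mod]]
    ind <- as.numeric(unname(design[smp]) == t)
    ex <- t(lexpr[genes, smp, drop = FALSE])
    gs <- as.numeric(stats::cor(ex, ind))
    mm <- as.numeric(stats::cor(ex, modules$eigengenes[, mod]))
    data.frame(gene_id = genes, module_id = mod, tissue = t,
               gs = gs, mm = mm,
               is_hub = abs(gs) > config$gs_min & abs(mm) > config$mm_min,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-call weighted co-expression network
#'
#' Composes the full network stage: expression filter, log2(FPKM + 1)
#' transform, soft-threshold selection (unless `config$beta` fixes it),
#' adjacency, topological overlap, module detection by average-linkage
#' clustering with a fixed-height cut, eigengenes, eigengene-based module
#' merging, module-tissue association, and hub-gene calling.
#'
#' @param x An `ExpressionMatrix` with design.
#' @param config A [network_config()].
#' @param filter_mode Passed to [filter_for_network()].
#' @return List with elements `modules` (a `module_set`), `trait_table`,
#'   `hub_table`, `beta_used`, `rsq_achieved`, `fit_table`, `filter_mode`,
#'   `n_genes`, `lexpr`.
#' @export
build_coexpression_network <- function(x, config = network_config(),
                                       filter_mode = c("any_tissue",
                                                       "all_tissues")) {
  filter_mode <- match.arg(filter_mode)
  xf <- filter_for_network(x, mode = filter_mode,
                           min_genes = config$min_module_size)
  if (nrow(xf$values) > config$max_genes)
    stop(nrow(xf$values), " genes exceed the network cap of ",
         config$max_genes, "; pre-filter or raise max_genes")
  lexpr <- log_fpkm(xf)
  sds <- apply(lexpr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) removed before correlation")
    lexpr <- lexpr[sds > 0, , drop = FALSE]
  }
  if (is.null(config$beta)) {
    pick <- pick_soft_threshold(lexpr, config)
    beta <- pick$beta; rsq <- pick$rsq; fit_table <- pick$fit_table
  } else {
    beta <- config$beta
    fit_table <- NULL
    k <- rowSums(adjacency_matrix(lexpr, beta, config$adjacency_type))
    rsq <- scale_free_fit(k)$fit
  }
  adj <- adjacency_matrix(lexpr, beta, config$adjacency_type)
  tom <- topological_overlap(adj)
  modules <- detect_modules(tom, config)
  modules <- compute_module_eigengenes(modules, lexpr)
  modules <- merge_close_modules(modules, lexpr, config)
  modules$beta_used <- beta
  modules$rsq_achieved <- rsq
  design <- xf$design[colnames(xf$values)]
  trait_table <- module_trait_association(modules, design, config)
  hub_table <- if (length(modules$modules))
    call_hub_genes(modules, lexpr, design, trait_table, config)
  else data.frame(gene_id = character(), module_id = character(),
                  tissue = character(), gs = numeric(), mm = numeric(),
                  is_hub = logical(), stringsAsFactors = FALSE)
  list(modules = modules, trait_table = trait_table, hub_table = hub_table,
       beta_used = beta, rsq_achieved = rsq, fit_table = fit_table,
       filter_mode = filter_mode, n_genes = nrow(lexpr), lexpr = lexpr)
}
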