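#' Per-tissue mean and median expression
#'
#' Summarizes each gene within each tissue over that tissue's replicate
#' samples. The mean feeds housekeeping- and tissue-specific-gene detection;
#' the median is the conventional statistic for tissue-level clustering.
#'
#' @param x An `ExpressionMatrix` with design attached.
#' @return data.frame with columns `gene_id`, `tissue`, `mean_fpkm`,
#'   `median_fpkm`, `n_samples`; one row per (gene, tissue), genes in matrix
#'   order within tissues in order of first appearance.
#' @export
summarize_by_tissue <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(x$design)) stop("no design attached; see attach_design()")
  v <- x$values
  tis <- tissues(x)
  out <- vector("list", length(tis))
  for (k in seq_along(tis)) {
    idx <- which(unname(x$design[colnames(v)]) == tis[[k]])
    sub <- v[, idx, drop = FALSE]
    out[[k]] <- data.frame(
      gene_id = rownames(v),
      tissue = tis[[k]],
      mean_fpkm = rowMeans(sub),
      median_fpkm = apply(sub, 1, stats::median),
      n_samples = length(idx),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  class(out) <- c("tissue_summary", "data.frame")
  out
}

#' Reshape a tissue summary into a gene x tissue matrix
#'
#' @param summary Output of [summarize_by_tissue()].
#' @param statistic `"mean"` or `"median"`.
#' @return Numeric matrix, genes x tissues, in the summary's own order.
#' @export
summary_matrix <- function(summary, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  col <- paste0(statistic, "_fpkm")
  genes <- unique(summary$gene_id)
  tis <- unique(summary$tissue)
  m <- matrix(NA_real_, length(genes), length(tis),
              dimnames = list(genes, tis))
  m[cbind(match(summary$gene_id, genes), match(summary$tissue, tis))] <-
    summary[[col]]
  if (anyNA(m)) stop("summary does not cover every (gene, tissue) pair")
  m
}

#' Per-tissue gene-activity report
#'
#' A gene is *detected* in a tissue when its FPKM is positive in at least one
#' of that tissue's samples, and *inactive* when it is detected but stays
#' strictly below `active_threshold` in every sample of the tissue
#' (FPKM < 1 by convention).
#'
#' @param x An `ExpressionMatrix` with design.
#' @param active_threshold Activity cutoff in FPKM units (default 1).
#' @return data.frame with columns `tissue`, `n_detected`, `n_inactive`,
#'   `fraction_inactive`.
#' @export
activity_report <- function(x, active_threshold = 1.0) {
  stopifnot(inherits(x, "ExpressionMatrix"), active_threshold > 0)
  if (is.null(x$design)) stop("no design attached")
  v <- x$values
  tis <- tissues(x)
  rows <- lapply(tis, function(t) {
    sub <- v[, tissue_samples(x, t), drop = FALSE]
    detected <- rowSums(sub > 0) > 0
    inactive <- detected & rowSums(sub >= active_threshold) == 0
    nd <- sum(detected); ni <- sum(inactive)
    data.frame(tissue = t, n_detected = nd, n_inactive = ni,
               fraction_inactive = if (nd > 0) ni / nd else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene, per-tissue inactivity calls
#'
#' @param x An `ExpressionMatrix` with design.
#' @param active_threshold Activity cutoff (default 1 FPKM).
#' @return Logical gene x tissue matrix: `TRUE` when the gene is below the
#'   threshold in every sample of the tissue.
#' @export
inactive_by_tissue <- function(x, active_threshold = 1.0) {
  stopifnot(inherits(x, "ExpressionMatrix"), active_threshold > 0)
  v <- x$values
  tis <- tissues(x)
  m <- sapply(tis, function(t) {
    sub <- v[, tissue_samples(x, t), drop = FALSE]
    rowSums(sub >= active_threshold) == 0
  })
  dimnames(m) <- list(rownames(v), tis)
  m
}

#' Keep genes expressed in enough replicate samples
#'
#' Retains genes with positive FPKM in at least `min_samples` samples of at
#' least one tissue (replicates = samples of the same tissue). With
#' `min_samples = 1` this reduces to dropping all-zero genes. Idempotent.
#'
#' @param x An `ExpressionMatrix` with design.
#' @param min_samples Minimum number of positive replicate samples
#'   (default 2).
#' @return Filtered `ExpressionMatrix`; row order preserved.
#' @export
filter_min_expressed_samples <- function(x, min_samples = 2L) {
  stopifnot(inherits(x, "ExpressionMatrix"), min_samples >= 1)
  if (is.null(x$design)) stop("no design attached")
  v <- x$values
  keep <- rep(FALSE, nrow(v))
  for (t in tissues(x)) {
    sub <- v[, tissue_samples(x, t), drop = FALSE]
    keep <- keep | rowSums(sub > 0) >= min_samples
  }
  if (!any(keep))
    warning("no gene is expressed in >= ", min_samples,
            " replicate samples of any tissue; returning an empty matrix")
  x$values <- v[keep, , drop = FALSE]
  x
}

#' Tissue-level correlation and hierarchical clustering
#'
#' Computes Pearson correlations between tissues over log2(x + 1)
#' transformed per-tissue statistics (median by default) and clusters
#' tissues by average linkage on the distance 1 - r. Tissues whose
#' transformed vector is constant have undefined correlations; they are
#' excluded from the dendrogram with a warning and reported as `NA` in the
#' correlation matrix.
#'
#' @param summary Output of [summarize_by_tissue()].
#' @param statistic `"median"` (default) or `"mean"`.
#' @return List with elements `correlation` (tissue x tissue matrix),
#'   `hclust` (average-linkage tree over 1 - r) and `newick` (the same tree
#'   as a Newick string).
#' @export
tissue_correlation_clustering <- function(summary,
                                          statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  m <- summary_matrix(summary, statistic)
  if (ncol(m) < 2) stop("need >= 2 tissues to cluster")
  lm2 <- log2(m + 1)
  sds <- apply(lm2, 2, stats::sd)
  ok <- sds > 0
  if (any(!ok))
    warning("tissue(s) with constant expression vector excluded from clustering: ",
            paste(colnames(m)[!ok], collapse = ", "))
  cormat <- matrix(NA_real_, ncol(m), ncol(m),
                   dimnames = list(colnames(m), colnames(m)))
  cormat[ok, ok] <- stats::cor(lm2[, ok, drop = FALSE], method = "pearson")
  if (sum(ok) < 2) stop("fewer than 2 tissues with non-constant vectors")
  hc <- stats::hclust(stats::as.dist(1 - cormat[ok, ok]), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(correlation = cormat, hclust = hc, newick = nwk)
}

#' Principal component analysis of samples
#'
#' Restricts to genes with FPKM above `active_threshold` in at least one
#' sample, transforms to log2(x + 1), centers each gene, and computes sample
#' scores by PCA.
#'
#' @param x An `ExpressionMatrix` (design optional).
#' @param active_threshold Gene filter: keep genes exceeding this FPKM in
#'   >= 1 sample (default 1).
#' @param n_components Number of components to return (default 10, capped at
#'   the matrix rank).
#' @return List with `scores` (samples x components), `var_explained`
#'   (fraction per component) and `n_genes_used`.
#' @export
sample_pca <- function(x, active_threshold = 1.0, n_components = 10L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  keep <- rowSums(v > active_threshold) >= 1
  if (sum(keep) < 2)
    stop("fewer than 2 genes pass the activity filter; cannot run PCA")
  if (ncol(v) < 2) stop("need >= 2 samples")
  lv <- log2(v[keep, , drop = FALSE] + 1)
  pc <- stats::prcomp(t(lv), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)],
       n_genes_used = sum(keep))
}

#' Biotype composition of a gene list
#'
#' Thin descriptive group-by against a gene annotation table.
#'
#' @param genes Character vector of gene ids.
#' @param annotation data.frame from [read_gene_annotation()].
#' @return data.frame with columns `biotype`, `n`, `fraction`.
#' @export
biotype_composition <- function(genes, annotation) {
  b <- annotation$biotype[match(genes, annotation$gene_id)]
  b[is.na(b)] <- "unannotated"
  tab <- sort(table(b), decreasing = TRUE)
  data.frame(biotype = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / length(genes),
             row.names = NULL, stringsAsFactors = FALSE)
}
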