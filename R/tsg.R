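#' Tissue-specific gene detection
#'
#' Scores every (gene, tissue) pair with positive tissue-level expression
#' against three criteria and calls a gene tissue-specific (TSG) in a tissue
#' when all three hold:
#'
#' 1. `crit_top`: the gene's expression in the tissue ranks within the top
#'    `top_fraction` (default 25%) of genes with positive expression there
#'    (ties at the rank boundary are all included);
#' 2. `crit_sum`: its expression exceeds `sum_ratio` (default 0.5) times the
#'    sum of its expression in all other tissues;
#' 3. `crit_fold`: its expression exceeds `fold` (default 3) times its
#'    expression in every other tissue.
#'
#' All inequalities are strict. Criteria 2 and 3 jointly imply at most one
#' specific tissue per gene. The tissue-level statistic is the mean by
#' default.
#'
#' @param summary Output of [summarize_by_tissue()].
#' @param top_fraction Rank criterion fraction (default 0.25).
#' @param sum_ratio Other-tissue sum multiplier (default 0.5).
#' @param fold Fold-change over the strongest other tissue (default 3).
#' @param statistic `"mean"` (default) or `"median"`.
#' @return data.frame with one row per (gene, tissue) pair with positive
#'   statistic, columns `gene_id`, `tissue`, `target_mean`,
#'   `max_other_mean`, `sum_other_means`, `crit_top`, `crit_sum`,
#'   `crit_fold`, `is_tsg`, `is_particular` (initialized `NA`; see
#'   [detect_particular_tsg()]).
#' @export
detect_tsg <- function(summary, top_fraction = 0.25, sum_ratio = 0.5,
                       fold = 3.0, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(top_fraction > 0, top_fraction <= 1, sum_ratio >= 0, fold > 0)
  m <- summary_matrix(summary, statistic)
  if (ncol(m) < 2) stop("need >= 2 tissues")
  tsg_from_stat_matrix(m, top_fraction, sum_ratio, fold)
}

# core on a gene x tissue statistic matrix; kept separate so tests can feed
# literal matrices
tsg_from_stat_matrix <- function(m, top_fraction, sum_ratio, fold) {
  rowtot <- rowSums(m)
  rows <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    pos <- v > 0
    if (!any(pos)) next
    g_t <- sum(pos)
    k <- ceiling(top_fraction * g_t)
    cutoff <- sort(v[pos], decreasing = TRUE)[k]
    max_other <- do.call(pmax, as.data.frame(m[, -j, drop = FALSE]))
    sum_other <- rowtot - v
    crit_top <- pos & v >= cutoff
    crit_sum <- v > sum_ratio * sum_other
    crit_fold <- v > fold * max_other
    sel <- which(pos)
    rows[[j]] <- data.frame(
      gene_id = rownames(m)[sel],
      tissue = colnames(m)[j],
      target_mean = unname(v[sel]),
      max_other_mean = unname(max_other[sel]),
      sum_other_means = unname(sum_other[sel]),
      crit_top = unname(crit_top[sel]),
      crit_sum = unname(crit_sum[sel]),
      crit_fold = unname(crit_fold[sel]),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    gene_id = character(), tissue = character(), target_mean = numeric(),
    max_other_mean = numeric(), sum_other_means = numeric(),
    crit_top = logical(), crit_sum = logical(), crit_fold = logical(),
    stringsAsFactors = FALSE)
  out$is_tsg <- out$crit_top & out$crit_sum & out$crit_fold
  out$is_particular <- rep(NA, nrow(out))
  # stable gene-major ordering
  out <- out[order(match(out$gene_id, rownames(m)),
                   match(out$tissue, colnames(m))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Particular (single-tissue) TSG refinement
#'
#' A TSG is *particular* when it is effectively expressed only in its target
#' tissue: every other tissue's mean falls below the activity threshold
#' (FPKM < 1 by convention) while the target tissue's mean reaches it.
#'
#' @param tsg Output of [detect_tsg()] on the same summary.
#' @param summary Output of [summarize_by_tissue()].
#' @param silence_threshold Activity cutoff applied to tissue means
#'   (default 1).
#' @param statistic Statistic used in `detect_tsg`.
#' @return `tsg` with `is_particular` filled in.
#' @export
detect_particular_tsg <- function(tsg, summary, silence_threshold = 1.0,
                                  statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  m <- summary_matrix(summary, statistic)
  gi <- match(tsg$gene_id, rownames(m))
  tj <- match(tsg$tissue, colnames(m))
  if (anyNA(gi) || anyNA(tj))
    stop("'tsg' refers to genes or tissues absent from 'summary'")
  n_above <- rowSums(m >= silence_threshold)
  target_above <- m[cbind(gi, tj)] >= silence_threshold
  tsg$is_particular <- tsg$is_tsg & target_above &
    (n_above[gi] - as.integer(target_above)) == 0
  tsg
}

#' Per-tissue TSG counts
#'
#' @param tsg Output of [detect_tsg()] (with or without the particular
#'   refinement).
#' @return data.frame with columns `tissue`, `n_tsg`, `n_particular`.
#' @export
tsg_counts_by_tissue <- function(tsg) {
  tis <- unique(tsg$tissue)
  part <- tsg$is_particular
  if (all(is.na(part))) part <- rep(FALSE, nrow(tsg))
  data.frame(
    tissue = tis,
    n_tsg = vapply(tis, function(t) sum(tsg$is_tsg[tsg$tissue == t]),
                   integer(1)),
    n_particular = vapply(tis, function(t)
      sum(part[tsg$tissue == t], na.rm = TRUE), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Top particular TSGs by target-tissue expression
#'
#' Reporting helper: the `n` particular TSGs with the highest target-tissue
#' means, across all tissues (heatmap-style shortlist).
#'
#' @param tsg Output of [detect_particular_tsg()].
#' @param n Number of genes to keep (default 19).
#' @return Subset of `tsg` rows ordered by decreasing `target_mean`.
#' @export
top_particular_tsg <- function(tsg, n = 19L) {
  sel <- tsg[tsg$is_particular %in% TRUE, , drop = FALSE]
  sel <- sel[order(-sel$target_mean, sel$gene_id), , drop = FALSE]
  utils::head(sel, n)
}
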