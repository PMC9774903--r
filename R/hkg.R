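#' Preliminary housekeeping genes
#'
#' A gene is a preliminary housekeeping gene (HKG) when its mean FPKM
#' exceeds `threshold` (strictly) in every tissue, i.e. it is
#' constitutively expressed.
#'
#' @param summary Output of [summarize_by_tissue()].
#' @param threshold Mean-FPKM cutoff, strict (default 1).
#' @return Character vector of gene ids, in input order.
#' @export
detect_preliminary_hkg <- function(summary, threshold = 1.0) {
  m <- summary_matrix(summary, "mean")
  rownames(m)[rowSums(m > threshold) == ncol(m)]
}

#' Coefficient of variation
#'
#' CV = sigma / mu: the standard deviation of the per-tissue means divided
#' by their mean. The sample (n - 1) standard deviation is the default;
#' the population (n) denominator is available for comparison.
#'
#' @param x Numeric vector of positive values (per-tissue means).
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return Non-negative scalar.
#' @export
compute_cv <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(x) < 2) stop("CV needs >= 2 values")
  if (any(x <= 0)) stop("CV is defined here for positive values only")
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  s / mean(x)
}

#' Tier genes by expression variability
#'
#' Splits a CV distribution at its first and third quartiles (linear
#' interpolation, the standard type-7 rule): low when CV <= Q1, high when
#' CV >= Q3, medium otherwise. In the degenerate case Q1 = Q3 (e.g. all CVs
#' identical) a gene satisfying both boundary rules is classed low.
#'
#' @param cv Named numeric vector of per-gene CVs (>= 4 genes).
#' @return data.frame with columns `gene_id`, `cv`, `variability_tier`, and
#'   attributes `q1`, `q3`.
#' @export
tier_by_variability <- function(cv) {
  if (length(cv) < 4) stop("need >= 4 genes to form quartile tiers")
  if (is.null(names(cv))) stop("'cv' must be named by gene id")
  q <- stats::quantile(cv, c(0.25, 0.75), names = FALSE, type = 7)
  tier <- ifelse(cv <= q[[1]], "low",
                 ifelse(cv >= q[[2]], "high", "medium"))
  out <- data.frame(gene_id = names(cv), cv = unname(cv),
                    variability_tier = unname(tier),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "q1") <- q[[1]]
  attr(out, "q3") <- q[[2]]
  out
}

#' Tier genes by expression level
#'
#' Classifies each gene's grand mean expression (the mean of its per-tissue
#' means) as low (FPKM <= 10), medium (10 < FPKM <= 50) or high (FPKM > 50).
#' Intended for the low-variability housekeeping tier, whose members already
#' exceed FPKM 1 everywhere.
#'
#' @param grand_mean Named numeric vector of grand mean FPKM per gene.
#' @return Character vector of tiers (`"low"`, `"medium"`, `"high"`), named
#'   by gene.
#' @export
tier_by_expression <- function(grand_mean) {
  tier <- ifelse(grand_mean <= 10, "low",
                 ifelse(grand_mean <= 50, "medium", "high"))
  stats::setNames(tier, names(grand_mean))
}

#' Full housekeeping-gene table
#'
#' Runs the housekeeping pipeline: constitutive-gene screen, coefficient of
#' variation across per-tissue means (or across all samples), quartile
#' variability tiers, and expression tiers for the low-variability group.
#'
#' @param summary Output of [summarize_by_tissue()].
#' @param matrix The `ExpressionMatrix`; only needed when
#'   `cv_scope = "samples"`.
#' @param threshold Constitutive-expression cutoff (default 1 FPKM, strict).
#' @param cv_scope `"tissue_means"` (default): CV over the per-tissue means;
#'   `"samples"`: CV over all individual samples.
#' @param sd_type Passed to [compute_cv()].
#' @return data.frame with columns `gene_id`, `cv`, `variability_tier`,
#'   `expression_tier` (`NA` outside the low-variability tier),
#'   `grand_mean`, then one `mean_<tissue>` column per tissue; attributes
#'   `q1`, `q3`, `cv_scope`.
#' @export
detect_hkg <- function(summary, matrix = NULL, threshold = 1.0,
                       cv_scope = c("tissue_means", "samples"),
                       sd_type = c("sample", "population")) {
  cv_scope <- match.arg(cv_scope)
  sd_type <- match.arg(sd_type)
  genes <- detect_preliminary_hkg(summary, threshold)
  if (!length(genes)) {
    warning("no constitutively expressed gene at threshold ", threshold)
    return(empty_hkg_table())
  }
  means <- summary_matrix(summary, "mean")[genes, , drop = FALSE]
  if (cv_scope == "tissue_means") {
    cv <- apply(means, 1, compute_cv, sd_type = sd_type)
  } else {
    if (is.null(matrix))
      stop("cv_scope = 'samples' needs the expression matrix")
    v <- matrix$values[genes, , drop = FALSE]
    cv <- apply(v, 1, function(row) {
      s <- stats::sd(row)
      if (sd_type == "population")
        s <- s * sqrt((length(row) - 1) / length(row))
      s / mean(row)
    })
  }
  tiers <- tier_by_variability(cv)
  grand <- rowMeans(means)
  expr_tier <- rep(NA_character_, length(genes))
  low <- tiers$variability_tier == "low"
  expr_tier[low] <- tier_by_expression(grand[low])
  out <- data.frame(gene_id = genes, cv = unname(cv),
                    variability_tier = tiers$variability_tier,
                    expression_tier = expr_tier,
                    grand_mean = unname(grand),
                    row.names = NULL, stringsAsFactors = FALSE)
  mcols <- as.data.frame(means)
  colnames(mcols) <- paste0("mean_", colnames(means))
  out <- cbind(out, mcols, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "q1") <- attr(tiers, "q1")
  attr(out, "q3") <- attr(tiers, "q3")
  attr(out, "cv_scope") <- cv_scope
  out
}

empty_hkg_table <- function() {
  data.frame(gene_id = character(), cv = numeric(),
             variability_tier = character(), expression_tier = character(),
             grand_mean = numeric(), stringsAsFactors = FALSE)
}

#' Low-variability, high-expression housekeeping shortlist
#'
#' The stable, abundant core of the housekeeping set: genes in the low
#' variability tier whose expression tier is high (grand mean FPKM > 50).
#'
#' @param hkg_table Output of [detect_hkg()].
#' @return Subset of `hkg_table` rows, ordered by increasing CV.
#' @export
hkg_shortlist <- function(hkg_table) {
  sel <- hkg_table$variability_tier == "low" &
    !is.na(hkg_table$expression_tier) & hkg_table$expression_tier == "high"
  out <- hkg_table[sel, , drop = FALSE]
  out[order(out$cv, out$gene_id), , drop = FALSE]
}
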