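# Builders and independent oracles shared across test files.

# ExpressionMatrix from a plain matrix and a tissue label per sample
make_em <- function(values, tissue, genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  ExpressionMatrix(values, design = stats::setNames(tissue, samples))
}

# summary table from a gene x tissue matrix of means (medians set equal)
summary_from_means <- function(m, n_samples = 3L) {
  do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    data.frame(gene_id = rownames(m), tissue = colnames(m)[j],
               mean_fpkm = m[, j], median_fpkm = m[, j],
               n_samples = n_samples, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

random_mean_matrix <- function(n_genes, n_tissues, zero_frac = 0.2) {
  m <- matrix(stats::runif(n_genes * n_tissues, 0, 20), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("t", seq_len(n_tissues))))
  m[stats::runif(length(m)) < zero_frac] <- 0
  m
}

# brute-force two-pass CV
oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1)) / m
}

# brute-force three-criterion evaluation on a mean matrix, one row per
# (gene, tissue) pair with positive mean; rank handled by direct counting
oracle_tsg <- function(m, top_fraction = 0.25, sum_ratio = 0.5, fold = 3) {
  rows <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      v <- m[i, j]
      if (v <= 0) next
      pos_vals <- m[m[, j] > 0, j]
      k <- ceiling(top_fraction * length(pos_vals))
      crit_top <- sum(pos_vals > v) < k
      others <- m[i, -j]
      crit_sum <- v > sum_ratio * sum(others)
      crit_fold <- v > fold * max(others)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = rownames(m)[i], tissue = colnames(m)[j],
        crit_top = crit_top, crit_sum = crit_sum, crit_fold = crit_fold,
        is_tsg = crit_top && crit_sum && crit_fold,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# triple-loop topological overlap
oracle_tom <- function(a) {
  g <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(g)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# exact hypergeometric upper tail by enumeration over overlap outcomes
oracle_hyper <- function(ov, k, n, big_n) {
  kk <- seq(ov, min(k, n))
  if (!length(kk) || ov <= max(0, n + k - big_n)) return(1)
  sum(choose(k, kk) * choose(big_n - k, n - kk)) / choose(big_n, n)
}

# two-sided p for a correlation via the incomplete-beta form of the t CDF
oracle_cor_p <- function(r, n) {
  stats::pbeta((n - 2) / ((n - 2) + r^2 * (n - 2) / (1 - r^2)),
               (n - 2) / 2, 1 / 2)
}

# memoized default synthetic run shared by the planted-recovery tests
.run_cache <- new.env(parent = emptyenv())
get_default_run <- function() {
  if (is.null(.run_cache$res)) {
    dir <- file.path(tempdir(), "mt-default-run")
    .run_cache$res <- suppressWarnings(
      run_synthetic(synth_config(seed = 1), out_dir = dir))
  }
  .run_cache$res
}
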