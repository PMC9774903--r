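#!/usr/bin/env Rscript
# Per-tissue activity profile of the panel: which genes are detected and
# inactive per tissue, how tissues cluster on median expression, and how
# samples spread in PCA space.

library(multitissue)

em <- attach_design(read_expression_matrix("results/data/expression_matrix.tsv"),
                    "results/data/design.tsv")
out <- "results/profile"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

emf <- filter_min_expressed_samples(em, min_samples = 2)
cat(sprintf("replicate filter: %d of %d genes expressed in >= 2 samples of a tissue\n",
            nrow(emf$values), nrow(em$values)))

summary <- summarize_by_tissue(emf)
utils::write.table(summary, file.path(out, "tissue_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

act <- activity_report(em)
utils::write.table(act, file.path(out, "activity_report.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("fraction of detected genes inactive per tissue:\n")
print(data.frame(tissue = act$tissue,
                 fraction = round(act$fraction_inactive, 3)))

clus <- tissue_correlation_clustering(summary)
writeLines(clus$newick, file.path(out, "tissue_dendrogram.nwk"))
cat("tissue dendrogram (median log2 expression, average linkage on 1 - r):\n")
cat(clus$newick, "\n")

pca <- sample_pca(em)
utils::write.table(
  data.frame(sample_id = rownames(pca$scores),
             tissue = unname(em$design[rownames(pca$scores)]), pca$scores),
  file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("PCA on %d active genes: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            pca$n_genes_used, 100 * pca$var_explained[1],
            100 * pca$var_explained[2]))
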