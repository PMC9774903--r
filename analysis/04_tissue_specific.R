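#!/usr/bin/env Rscript
# Tissue-specific genes by the three-criterion rule (top-25% rank, > 50% of
# the other-tissue sum, > 3x any other tissue), refined to single-tissue
# "particular" TSGs via the FPKM < 1 activity rule on tissue means.

library(multitissue)

em <- attach_design(read_expression_matrix("results/data/expression_matrix.tsv"),
                    "results/data/design.tsv")
truth <- utils::read.delim("results/data/ground_truth.tsv")
out <- "results/tsg"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

summary <- summarize_by_tissue(filter_min_expressed_samples(em))
tsg <- detect_particular_tsg(detect_tsg(summary), summary)
utils::write.table(tsg, file.path(out, "tsg_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

counts <- tsg_counts_by_tissue(tsg)
utils::write.table(counts, file.path(out, "tsg_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d TSGs, %d particular TSGs across %d tissues\n",
            sum(tsg$is_tsg), sum(tsg$is_particular), nrow(counts)))
print(counts)

top <- top_particular_tsg(tsg, n = 19)
utils::write.table(top, file.path(out, "particular_tsg_top19.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

ev <- truth_eval(tsg$gene_id[tsg$is_tsg], truth, "tsg")
planted <- truth[truth$role == "tsg", ]
hit <- tsg[tsg$is_tsg & tsg$gene_id %in% planted$gene_id, ]
cat(sprintf("planted single-tissue recovery: recall %.3f, correct tissue %.3f\n",
            ev$recall,
            mean(hit$tissue == planted$target_tissue[
              match(hit$gene_id, planted$gene_id)])))
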