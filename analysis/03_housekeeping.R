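#!/usr/bin/env Rscript
# Housekeeping-gene detection: constitutive screen (mean FPKM > 1 in all
# tissues), CV-based variability tiers, expression tiers for the stable
# group, and the low-variability/high-expression shortlist.

library(multitissue)

em <- attach_design(read_expression_matrix("results/data/expression_matrix.tsv"),
                    "results/data/design.tsv")
truth <- utils::read.delim("results/data/ground_truth.tsv")
out <- "results/hkg"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

summary <- summarize_by_tissue(filter_min_expressed_samples(em))
hkg <- detect_hkg(summary, matrix = em)
utils::write.table(hkg, file.path(out, "hkg_table.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d constitutively expressed genes (mean FPKM > 1 in all %d tissues)\n",
            nrow(hkg), length(tissues(em))))
cat(sprintf("CV quartiles over tissue means: Q1 = %.3f, Q3 = %.3f\n",
            attr(hkg, "q1"), attr(hkg, "q3")))
print(table(hkg$variability_tier))
print(table(hkg$expression_tier[hkg$variability_tier == "low"]))

sl <- hkg_shortlist(hkg)
utils::write.table(sl, file.path(out, "hkg_shortlist.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("shortlist (low variability, grand mean > 50 FPKM): %d genes\n",
            nrow(sl)))

ev <- truth_eval(hkg$gene_id, truth, "hkg")
cat(sprintf("planted-constitutive recovery: recall %.3f, precision %.3f (%d fp from background)\n",
            ev$recall, ev$precision, ev$fp))
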