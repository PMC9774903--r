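#!/usr/bin/env Rscript
# Generate the synthetic 14-tissue FPKM panel used by every later step:
# 3740 genes (500 constitutive, 500 single-tissue, 4 x 60 co-expression
# module genes, 2000 background, 500 inactive) over 70 samples, with the
# planted ground truth written alongside.

library(multitissue)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(seed = 1)
syn <- generate_synthetic_expression(cfg)

write_expression_matrix(syn$matrix, file.path(out, "expression_matrix.tsv"))
write_design(syn$matrix$design, file.path(out, "design.tsv"))
utils::write.table(syn$truth, file.path(out, "ground_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("wrote %d genes x %d samples across %d tissues to %s\n",
            nrow(syn$matrix$values), ncol(syn$matrix$values),
            length(tissues(syn$matrix)), out))
print(table(syn$truth$role))
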