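#!/usr/bin/env Rscript
# Tissue expression: FPKM from counts, the EL tissue-specificity statistic
# (per-tissue log2(FPKM+1) as a share of the gene's total), and
# leaf-dominance calls at the default thresholds (EL >= 40, FPKM >= 1).

library(c4ortho)

scen <- "results/scenario"
out <- "results/expression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts_df <- read.delim(file.path(scen, "counts.tsv"), check.names = FALSE)
counts <- as.matrix(counts_df[, -1]); rownames(counts) <- counts_df[[1]]
lens <- read.delim(file.path(scen, "gene_lengths.tsv"))
libs <- read.delim(file.path(scen, "lib_sizes.tsv"))

fp <- fpkm(counts, setNames(lens$length, lens$gene_id),
           setNames(libs$mapped_fragments, libs$tissue))
em <- el_matrix(fp)
calls <- leaf_calls(fp)

write.table(data.frame(gene_id = rownames(em$el), round(em$el, 2),
                       leaf_call = calls, check.names = FALSE),
            file.path(out, "el_matrix.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Leaf-dominance calls:\n")
print(table(calls))
cat(sprintf("EL rows sum to 100 within %.1e\n",
            max(abs(rowSums(em$el)[!em$unexpressed] - 100))))
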