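#!/usr/bin/env Rscript
# Genome context: tandem arrays from gene ranks (rank-gap rule, at most 5
# intervening non-family genes), 2000-bp promoter extraction, cis-element
# scanning, and the CAAT-box density comparison between C4 and
# C4-orthologous carbonic-anhydrase copies by upstream bin.

library(c4ortho)

scen <- "results/scenario"
out <- "results/genome_context"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- read.delim(file.path(scen, "ground_truth.tsv"))
models <- read_gene_models(file.path(scen, "genes.gff3"))
loci <- merge(models$genes,
              truth[, c("gene_id", "family", "orthogroup", "type")],
              by = "gene_id")
arrays <- detect_tandem(loci, max_intervening = 5)
cat(sprintf("%d tandem arrays (%d genes)\n", length(arrays),
            length(unlist(arrays))))
for (fam in unique(loci$family)) {
  ts <- tandem_summary(loci$gene_id[loci$family == fam], arrays)
  cat(sprintf("  %-8s %d/%d tandem (%.2f%%)\n", fam, ts$n_tandem,
              ts$n_total, ts$percent))
}

genome <- read_fasta_proteins(file.path(scen, "genome.fa"))
hits <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
  scan_elements(extract_promoter(genome, loci[i, ]),
                gene_id = loci$gene_id[i])
}))
write.table(hits, file.path(out, "element_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ca3 <- loci[loci$family == "beta-CA" & loci$orthogroup == "og3", ]
cmp <- compare_element_counts(hits[hits$gene_id %in% ca3$gene_id[ca3$type == "C3"], ],
                              hits[hits$gene_id %in% ca3$gene_id[ca3$type == "C4"], ],
                              ca3$gene_id[ca3$type == "C3"],
                              ca3$gene_id[ca3$type == "C4"])
names(cmp)[3:4] <- c("mean_C3_orthologs", "mean_C4_copies")
write.table(cmp, file.path(out, "ca3_caat_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
caat <- cmp[cmp$element == "CAAT-box", ]
cat("CAAT-box mean counts, C4-orthologous (C3 crops) vs C4 copies:\n")
print(caat, row.names = FALSE)
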