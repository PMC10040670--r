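#!/usr/bin/env Rscript
# Neighbour-joining trees from JTT maximum-likelihood distances (pairwise
# deletion), bootstrap support, and orthogroup delimitation. The orthogroup
# containing each family's known C4 anchor gene is its C4 orthogroup.

library(c4ortho)

scen <- "results/scenario"
out <- "results/phylogeny"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
anchors <- read.delim(file.path(scen, "anchors.tsv"), header = FALSE,
                      col.names = c("family", "anchor"))

short <- c("beta-CA" = "CA", "RbcS" = "RbcS", "PEPC" = "PEPC",
           "NADP-ME" = "ME", "MDH" = "MDH", "PPDK" = "PPDK")
rows <- list()
for (fam in names(short)) {
  members <- read.delim(file.path("results/screening",
                                  paste0("members_", short[fam], ".tsv")))
  aln <- read_fasta_proteins(file.path(scen, paste0("aln_", short[fam], ".faa")))
  aln <- aln[names(aln) %in% members$gene_id]
  tree <- bootstrap_support(aln, replicates = 100, seed = 1)
  ape::write.tree(tree, file.path(out, paste0("tree_", short[fam], ".nwk")))
  species_of <- setNames(sub("_.*$", "", names(aln)), names(aln))
  cut <- cut_orthogroups(tree, species_of, min_support = 50, max_copies = 1)
  anchor <- anchors$anchor[anchors$family == fam]
  for (og in names(cut$groups))
    rows[[paste(fam, og)]] <- data.frame(
      family = fam, orthogroup = og, gene_id = cut$groups[[og]],
      is_c4_orthogroup = anchor %in% cut$groups[[og]])
  cat(sprintf("%-8s %d orthogroups, %d leaves ungrouped\n", fam,
              length(cut$groups), length(cut$ungrouped)))
}
og <- do.call(rbind, rows)
write.table(og, file.path(out, "orthogroups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("C4 orthogroups:",
    paste(unique(paste(og$family, og$orthogroup)[og$is_c4_orthogroup]),
          collapse = ", "), "\n")
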