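#!/usr/bin/env Rscript
# Family-membership screening: BLAST best-hit thresholds (E < 1e-5,
# identity >= 60%) plus required conserved domains, per family.

library(c4ortho)

scen <- "results/scenario"
out <- "results/screening"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

short <- c("beta-CA" = "CA", "RbcS" = "RbcS", "PEPC" = "PEPC",
           "NADP-ME" = "ME", "MDH" = "MDH", "PPDK" = "PPDK")
for (fam in names(short)) {
  hits <- read_blast_tabular(file.path(scen, paste0("blast_", short[fam], ".tsv")))
  doms <- read_hmmer_domtbl(file.path(scen, paste0("domtbl_", short[fam], ".txt")))
  members <- write_family_members(hits, doms, family_spec(fam),
                                  file.path(out, paste0("members_", short[fam], ".tsv")))
  decoys <- setdiff(unique(hits$subject_id), members$gene_id)
  cat(sprintf("%-8s %2d members kept, %d candidates rejected\n",
              fam, nrow(members), length(decoys)))
}
cat("Membership tables written to", out, "\n")
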