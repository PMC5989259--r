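#!/usr/bin/env Rscript
# Stage 5: map outlier windows to genes (with a 5-kb flank on both sides of
# each window) and classify every differentiated SNP's genomic area as
# CDS, intron or intergenic.

library(pooldiff)

sim <- "results/study/sim"
models <- read_gene_models(file.path(sim, "genes.gff3"))

for (treatment in c("hypo", "hyper")) {
  wins <- read.table(sprintf("results/study/windows_%s_vs_control.tsv",
                             treatment), header = TRUE, sep = "\t")
  fst_genes <- genes_overlapping_windows(wins, models, flank_bp = 5000)
  writeLines(fst_genes, sprintf("results/study/fst_genes_%s_vs_control.txt",
                                treatment))

  afd <- read.table(sprintf("results/study/afd_%s_vs_control.tsv",
                            treatment), header = TRUE, sep = "\t")
  hits <- afd[afd$pass, ]
  hits$area <- classify_snp_area(hits$scaffold, hits$pos, models)
  write.table(hits, sprintf("results/study/differentiated_snps_%s_vs_control.tsv",
                            treatment),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s vs control: %d F_ST genes; SNP areas: %s\n",
              treatment, length(fst_genes),
              paste(names(table(hits$area)), table(hits$area),
                    collapse = ", ")))
}
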