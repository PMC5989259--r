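#!/usr/bin/env Rscript
# Stage 3: allele-frequency-difference scan. Each selected pool is compared
# with the control; SNPs with AFD strictly above 0.6 are the differentiated
# SNPs, and genes whose span contains one are the AFD-differentiated genes.

library(pooldiff)

sim <- "results/study/sim"
sites <- read_pool_sites(file.path(sim, "pools.sync"), format = "sync")
mask <- read_mask(file.path(sim, "ssr_mask.bed"))
sites <- apply_site_filters(sites, filter_params(), mask = mask)$sites
models <- read_gene_models(file.path(sim, "genes.gff3"))

for (treatment in c("hypo", "hyper")) {
  afd <- scan_afd(sites, treatment, "control", threshold = 0.6)
  genes <- afd_genes(afd, models, flank_bp = 0)
  write.table(afd, sprintf("results/study/afd_%s_vs_control.tsv", treatment),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(genes$gene_ids,
             sprintf("results/study/afd_genes_%s_vs_control.txt", treatment))
  cat(sprintf("%s vs control: %d differentiated SNPs on %d genes (%d SNPs intergenic)\n",
              treatment, sum(afd$pass), length(genes$gene_ids),
              genes$n_intergenic))
}
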