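#!/usr/bin/env Rscript
# Stage 6: integrate the evidence streams. The AFD and F_ST gene sets are
# merged (with provenance) into the DNA-level differentiated set; a
# three-way Venn with the DE list defines the candidate set as
# (AFD u FST) n DE; candidates are tested for term enrichment with the
# hypergeometric tail and BH correction.

library(pooldiff)

sim <- "results/study/sim"
models <- read_gene_models(file.path(sim, "genes.gff3"))
background <- sort(models$genes$gene_id)
de <- readLines(file.path(sim, "de_genes.txt"))
terms <- read.table(file.path(sim, "gene_terms.tsv"), header = TRUE,
                    sep = "\t")
truth <- read.table(file.path(sim, "truth_genes.tsv"), header = TRUE,
                    sep = "\t")

for (treatment in c("hypo", "hyper")) {
  afd_g <- readLines(sprintf("results/study/afd_genes_%s_vs_control.txt",
                             treatment))
  fst_g <- readLines(sprintf("results/study/fst_genes_%s_vs_control.txt",
                             treatment))
  merged <- merge_differentiated(afd_g, fst_g,
                                 label = paste0(treatment, "_vs_control"))
  write.table(merged,
              sprintf("results/study/differentiated_genes_%s_vs_control.tsv",
                      treatment),
              sep = "\t", quote = FALSE, row.names = FALSE)
  v <- venn3(afd_g, fst_g, de)
  writeLines(v$candidates,
             sprintf("results/study/candidates_%s_vs_control.txt", treatment))
  cat(sprintf("%s vs control: %d differentiated genes (AFD %d, FST %d), Venn regions [%s], %d candidates\n",
              treatment, nrow(merged), length(afd_g), length(fst_g),
              paste(v$counts, collapse = " "), length(v$candidates)))
  if (length(v$candidates) > 0) {
    enr <- enrich_terms(v$candidates, background, terms)
    write.table(enr, sprintf("results/study/enrichment_%s_vs_control.tsv",
                             treatment),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat("  top term:", enr$term[1], "adjusted p =",
        signif(enr$p_adj[1], 3), "\n")
  }
  if (treatment == "hypo") {
    planted <- truth$gene_id[truth$contains_outlier]
    cat(sprintf("  truth check: %d/%d outlier genes recovered in the candidate set\n",
                sum(planted %in% v$candidates), length(planted)))
  }
}
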